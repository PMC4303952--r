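---
title: "Classifying discordant expression between same-gene probeset pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying discordant expression between same-gene probeset pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probepair)
```

## The problem

Expression microarrays such as the Affymetrix HG-U133A measure many genes
with two or more probesets, each a set of 11–20 25-mer probes summarised
into one intensity per array. Two probesets annotated to the same gene
should report the same tissue profile; often they do not. probepair
quantifies that disagreement for every gene covered by exactly two
probesets and classifies it by a two-coefficient rule that separates
technical failure from biologically interpretable divergence.

## The classification model

For a pair of probesets $(a, b)$ with intensities across $T \ge 3$ tissues,
two coefficients are computed:

* Pearson's product-moment $r$, sensitive to agreement of absolute
  intensities (and to spikes);
* Spearman's $\rho$, the product-moment correlation of mid-ranks
  (average ranks for ties), sensitive only to rank order.

With cutoffs $h = 0.7$ and $l = 0.3$ (strict inequalities; a value exactly
at a cutoff falls in no quadrant), the pair's category is

| category | rule | reading |
|---|---|---|
| RELIABLE | $r > h$ and $\rho > h$ | both probesets report the same profile |
| TISSUE_SPECIFIC | $r > h$ and $\rho < l$ | shared spikes in a few tissues; background ranks are noise, so $\rho$ collapses while $r$ stays high |
| ISOFORM_SPECIFIC | $\rho > h$ and $r < l$ | rank order preserved but one probeset carries an absolute spike the other lacks, e.g. a tissue-restricted isoform or UTR variant |
| DISCORDANT | $r < l$ and $\rho < l$ | the two probesets disagree outright |
| INTERMEDIATE | otherwise | excluded from the extreme-category analysis |

The five rules are mutually exclusive and exhaustive on $[-1,1]^2$ (a
property test checks a $201 \times 201$ grid). Both coefficients are
always computed; the Shapiro–Wilk p-values stored per probeset are
reporting aids only, documenting that intensity profiles are typically
non-normal and that the rank-based coefficient is therefore the safer
default of the two.

## Reannotation into gene groups

Probesets with identical gene-symbol sets form primary groups; a group
whose gene set is contained in a multi-gene group's set is then absorbed
into it (the union of `C///D` with `C` is `C///D`), iterated to a fixed
point. Group labels are canonical (lexicographically sorted,
`" /// "`-joined), so the merge is order-independent, and the final groups
partition the annotated probesets. Differentiating-probeset counts (per
gene, probesets annotated to that gene alone) are recorded per group.

Two open corners were decided as follows:

* **Non-nested overlapping multi-gene labels** (`{C,D}` and `{D,E}`): merged
  transitively into `{C,D,E}` with a warning. Any non-transitive rule would
  put a probeset into two groups and break the partition invariant.
* **Symbol matching is case-sensitive**: chip annotations are
  case-consistent, and silent case-folding could fuse distinct symbols.

Only groups with exactly two probesets enter the concordance analysis; the
group-size census is reported alongside so chip composition remains
visible.

## Probe quality classes

Each probe's alignment evidence reduces to three flags: mismatches to the
target gene, a perfect-or-one-mismatch hit to another gene, a perfect hit
to a non-coding region. The colour classes are green (clean unique match),
yellow (non-coding side hit), red (cross-gene hit) and black (any target
mismatch), with precedence BLACK > RED > YELLOW > GREEN when flags
conflict — black is defined solely by the target mismatch, so it dominates.
A probeset's quality class is a pure colour only when its probes are
unanimous, otherwise MIXED. "Same-quality" pair selection is strict by
default (both probesets pure, same colour); a majority rule (modal colour)
is available but off, since the strict reading is the conservative one and
mixed-composition pairs are not obviously comparable.

## Group-level statistics

* **Colour-group comparison**: per coefficient, a Kruskal–Wallis test
  across the same-quality colour groups, then all pairwise Mann–Whitney
  tests with Bonferroni correction (each p multiplied by the number of
  pairwise tests, capped at 1) at family level 0.05.
* **Quality versus correlation strength**: pairs are binned by $\rho$
  (left-closed bins at 0.3, 0.5, 0.7, 0.9) and each bin's probe-colour
  composition is tabulated, each probeset contributing its colour
  fractions. Two summaries are computed. The Friedman test asks whether
  composition differs between strength bins, taking colours as blocks and
  bins as treatments. Kendall's W (tie-corrected) measures how consistently
  the bins rank the colours, taking bins as judges. The two layouts differ
  deliberately: with identical composition in every bin the Friedman test
  finds nothing (p = 1, reported as such even where the raw statistic
  degenerates to 0/0 on a fully tied table) while W = 1 — quality
  composition is stable and its internal ranking perfectly concordant
  across strength bins. The blocking is interpretive, since a contingency
  table of counts admits several; this one answers "does probe quality
  track correlation strength" in both directions.
* **Mean/CV concordance**: per strength bin, OLS of probeset B's mean on
  A's mean and of B's CV (sample sd over mean) on A's CV; the $R^2$ values
  score how far averaging the two probesets is defensible at that
  correlation strength. Bins with fewer than 3 pairs are flagged
  not-estimable rather than fitted.

Replicates are collapsed to tissues by the arithmetic mean before any
correlation (median and first-replicate are selectable; the choice is
recorded in the output provenance). Intensities are analysed on their
absolute scale by default — the Pearson arm of the classification is
*about* absolute values — with an optional log2(x+1) transform for
sensitivity analysis.

## The synthetic validation panel

`generate_dataset()` emulates a two-replicate multi-tissue atlas at the
probeset-summary level (79 tissues × 2 replicates by default, matching the
replicate structure of the public expression atlas this analysis is
designed for; tissue count is a parameter since published descriptions of
such panels vary). Each gene contributes two probesets under one archetype:

* **RELIABLE** — both probesets = one latent profile + independent noise.
* **TISSUE_SPECIFIC** — shared spikes (5000) in 3 tissues; elsewhere
  independent draws near background (50), so absolute values agree while
  background ranks are uncorrelated.
* **ISOFORM_SPECIFIC** — a shared compact baseline, log-uniform on
  [50, 500] (ubiquitous low-level expression), plus a spike in 3 tissues in
  one probeset only. The narrow baseline is deliberate: the spike must
  dominate probeset A's variance for $r$ to collapse, while shared
  baseline ranks keep $\rho$ high.
* **DISCORDANT** — two independent latent profiles.
* **PSEUDOGENE_RED** — reliable expression, but every probe flagged as
  cross-matching a second locus: concordant all-red pairs, the signature
  of an untranscribed pseudogene family.
* **MULTIGENE_GROUP** — two genes sharing one probeset plus one
  differentiating probeset each; exercises the merge step (three-probeset
  groups are correctly excluded from pair analysis).

Latent profiles are log-uniform on [background, spike] so marginals are
right-skewed (non-normal, as real intensity panels are); all noise is
Gaussian truncated at zero (intensity sd 15, replicate sd 10), the
simplest model preserving non-negativity. Defaults were chosen once so
that the four correlation signatures separate cleanly at the 0.3/0.7
cutoffs, and are not tuned per run; the seed is a mandatory argument and
there is no hidden RNG state.

What the panel does *not* emulate: probe-level intensities and mismatch
probes (simulation is at the summary level, where the analysis operates),
array normalisation artefacts, correlated noise between tissues, and the
long-tailed gene-family structure of a real chip. Passing the recovery
tests therefore shows the classifier does what it claims under its own
assumptions, not that any particular real chip meets them.

## Numerical and reporting choices

* Spearman is computed as the product-moment correlation of mid-ranks, not
  the $1 - 6\sum d^2/(n(n^2-1))$ shortcut, because intensity ties occur;
  on tie-free inputs the two agree to machine precision (tested over all
  permutations up to n = 6).
* Constant tissue vectors make both coefficients undefined; such pairs are
  flagged and excluded from classification, and the flagged count is
  reconciled in the run manifest.
* Percentages are rounded half-up to one decimal, matching conventional
  reporting.
* Category cutoffs sit at strict inequalities; boundary values are
  INTERMEDIATE.

## Problem sizes

The reference validation run uses 200 genes per archetype (1000 gene
groups, 2000 probesets, 79 tissues × 2 replicates) and completes in a few
seconds; unit tests use 5–15 genes per archetype over 20–30 tissues. At
these sizes every archetype's recovery rate is well above the 90%
acceptance bar (see `scripts/acceptance.R`).

## Worked example

```{r example}
ds <- generate_dataset(default_archetype_panel(25), n_tissues = 40,
                       n_replicates = 2, seed = 42)
fit <- probeset_concordance(ds$expression, ds$sample_map,
                            ds$annotation, ds$probe_table)
summary(fit)
```

```{r plot, fig.width = 6, fig.height = 5}
plot(fit, main = "Pearson vs Spearman, one dot per probeset pair")
```

## Known limitations

* The analysis consumes precomputed probe-alignment flags; it does not
  align probes to a genome, so quality classes are only as good as the
  supplied evidence.
* Two-probeset genes only: genes covered by three or more probesets are
  censused but not analysed (outlier-probeset detection among ≥3 probesets
  is a different design).
* The category semantics (tissue-specific, isoform-specific) are
  correlation signatures, not mechanistic claims; confirming an isoform
  explanation requires sequence-level evidence outside this package's
  scope.
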