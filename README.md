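# probepair

Concordance analysis of same-gene microarray probeset pairs.

Many genes on expression microarrays (e.g. Affymetrix HG-U133A) are
measured by two probesets, and those probesets do not always tell the same
story across tissues. probepair reannotates the chip's probeset-to-gene
mapping into *gene groups* (a multi-gene label `C///D` absorbs its member
genes), selects genes covered by exactly two probesets, and classifies each
pair by the joint behaviour of Pearson's *r* and Spearman's *ρ* across a
tissue panel, with cutoffs at 0.3 and 0.7:

| category | signature | typical cause |
|---|---|---|
| RELIABLE | r > 0.7, ρ > 0.7 | both probesets measure the gene |
| TISSUE_SPECIFIC | r > 0.7, ρ < 0.3 | shared spikes, random background ranks |
| ISOFORM_SPECIFIC | ρ > 0.7, r < 0.3 | a spike in one probeset only (isoform/UTR) |
| DISCORDANT | r < 0.3, ρ < 0.3 | outright disagreement |
| INTERMEDIATE | otherwise | excluded from the extreme sets |

Around this core: probe-level quality classes (green/yellow/red/black
cross-hybridisation evidence, aggregated to probeset profiles),
Kruskal–Wallis and Bonferroni-corrected Mann–Whitney comparisons of
correlation across same-quality colour groups, a Friedman/Kendall-W
analysis of quality versus correlation strength, per-bin mean/CV
concordance regressions, and a synthetic tissue-expression generator with
ground-truth archetypes that makes the whole pipeline testable end to end.

## Worked example

```r
library(probepair)

ds <- generate_dataset(default_archetype_panel(25), n_tissues = 40,
                       n_replicates = 2, seed = 42)
fit <- probeset_concordance(ds$expression, ds$sample_map,
                            ds$annotation, ds$probe_table)
summary(fit)
```

```
Probeset-pair concordance analysis

                 count percent
RELIABLE            50    40.0
TISSUE_SPECIFIC     19    15.2
ISOFORM_SPECIFIC    20    16.0
DISCORDANT          24    19.2
INTERMEDIATE        12     9.6

extreme categories: 113 of 125 pairs (90.4%)

rho ~ r: slope 0.371, intercept 0.363, R^2 = 0.1661 (n = 125)

Correlation coefficients across probe-colour groups
  groups: GREEN=100, RED=25 
  Kruskal-Wallis: Pearson p = 0.0002077, Spearman p = 1.569e-08
  Spearman pairwise (Bonferroni, p < 0.05): GREEN-RED 

Probe-colour composition by Spearman-strength bin
          GREEN YELLOW RED BLACK
[-1,0.3)     86      0   0     0
[0.3,0.5)    14      0   0     0
[0.5,0.7)     6      0   0     0
[0.7,0.9)    36      0   0     0
[0.9,1]      58      0  50     0
Friedman p = 0.2548, Kendall's W = 0.9273
```

The panel holds 25 genes of each archetype (125 pairs). The 50 RELIABLE
pairs are the reliable and pseudogene-red genes: the latter carry all-red
probes yet report concordant profiles, which is why they populate the
`[0.9,1]` bin's RED column and drive the significant green-vs-red contrast.
The tissue-specific and isoform-specific archetypes land in their designed
quadrants (19/25 and 20/25 here; recovery exceeds 90% at the reference
panel size of 200 genes per archetype). `plot(fit)` draws the r-vs-ρ
quadrant scatter; `coef(fit)`, `predict(fit)` and `residuals(fit)` expose
the fitted ρ-on-r line.

File-based runs go through `run_pipeline(pipeline_config(...))`, which
writes `gene_groups.tsv`, `pair_stats.tsv`, `category_summary.tsv`,
`probeset_quality.tsv`, `color_comparison.tsv`, `quality_strength.tsv`,
`bin_regressions.tsv` and a `manifest.json`, byte-identically for a fixed
seed. A thin CLI with `simulate`, `reannotate`, `analyze` and `all`
subcommands is installed at `inst/cli/probepair.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/probepair.R", package="probepair"))')" \
  all --outdir out --seed 7 --n-genes 50
```

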