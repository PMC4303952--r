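# Synthetic tissue-expression data with known ground truth.
#
# The generator emulates a two-replicate multi-tissue expression atlas
# (probeset-summary level, non-negative intensities in arbitrary units) for
# genes measured by two probesets each, under archetypes that reproduce the
# four correlation signatures plus two annotation/quality scenarios:
#
#   RELIABLE        both probesets track one latent tissue profile
#   TISSUE_SPECIFIC shared spikes in a few tissues, independent background
#                   elsewhere (high r, low rho)
#   ISOFORM_SPECIFIC shared low baseline, a spike in one probeset only
#                   (high rho, low r)
#   DISCORDANT      two independent latent profiles (both low)
#   PSEUDOGENE_RED  RELIABLE expression but every probe cross-matches a
#                   second locus (all-red probes)
#   MULTIGENE_GROUP two genes sharing one probeset plus per-gene
#                   differentiating probesets (exercises group merging)
#
# Latent profiles are log-uniform over [background_level, spike_level], so
# marginals are right-skewed (non-normal); all noise is Gaussian truncated
# at zero, the simplest model preserving non-negativity.

ARCHETYPES <- c("RELIABLE", "TISSUE_SPECIFIC", "ISOFORM_SPECIFIC",
                "DISCORDANT", "PSEUDOGENE_RED", "MULTIGENE_GROUP")

#' Specify one archetype block of the synthetic dataset
#'
#' Defaults are the generator's reference conditions: background 50,
#' spikes at 5000, intensity noise sd 15 and replicate noise sd 10
#' (arbitrary intensity units), 3 spiked tissues -- chosen so the four
#' correlation signatures separate cleanly at the 0.3/0.7 cutoffs.
#'
#' @param archetype one of `RELIABLE`, `TISSUE_SPECIFIC`,
#'   `ISOFORM_SPECIFIC`, `DISCORDANT`, `PSEUDOGENE_RED`,
#'   `MULTIGENE_GROUP`.
#' @param n_genes number of genes generated under this archetype.
#' @param n_spike_tissues tissues receiving a spike (restricted/isoform
#'   archetypes).
#' @param spike_level,background_level intensities; `spike_level` must
#'   exceed `background_level >= 0`.
#' @param noise_sd sd of the per-probeset intensity noise.
#' @param replicate_sd sd of the per-sample replicate noise.
#' @return an `archetype_spec` list.
#' @export
archetype_spec <- function(archetype, n_genes,
                           n_spike_tissues = 3L,
                           spike_level = 5000,
                           background_level = 50,
                           noise_sd = 15,
                           replicate_sd = 10) {
  archetype <- match.arg(archetype, ARCHETYPES)
  if (n_genes < 0) stop("n_genes must be >= 0")
  if (!(spike_level > background_level && background_level >= 0)) {
    stop("require spike_level > background_level >= 0")
  }
  if (noise_sd < 0 || replicate_sd < 0) {
    stop("noise_sd and replicate_sd must be >= 0")
  }
  structure(list(archetype = archetype, n_genes = as.integer(n_genes),
                 n_spike_tissues = as.integer(n_spike_tissues),
                 spike_level = spike_level,
                 background_level = background_level,
                 noise_sd = noise_sd, replicate_sd = replicate_sd),
            class = "archetype_spec")
}

#' Default archetype panel
#'
#' The reference validation panel: `n_per_archetype` genes of each of the
#' four correlation archetypes plus the pseudogene scenario.
#'
#' @param n_per_archetype genes per archetype (default 200).
#' @param include_pseudogene also generate a `PSEUDOGENE_RED` block.
#' @param ... passed to [archetype_spec()].
#' @return list of `archetype_spec`.
#' @export
default_archetype_panel <- function(n_per_archetype = 200L,
                                    include_pseudogene = TRUE, ...) {
  kinds <- c("RELIABLE", "TISSUE_SPECIFIC", "ISOFORM_SPECIFIC", "DISCORDANT")
  if (include_pseudogene) kinds <- c(kinds, "PSEUDOGENE_RED")
  lapply(kinds, archetype_spec, n_genes = n_per_archetype, ...)
}

rtrunc_norm <- function(n, mean, sd) pmax(0, stats::rnorm(n, mean, sd))

log_uniform <- function(n, lo, hi) {
  lo <- max(lo, 1e-6)  # guard log(0) when background_level = 0
  exp(stats::runif(n, log(lo), log(hi)))
}

# per-gene tissue-level profiles for the two probesets, a list(a, b)
archetype_profiles <- function(spec, n_tissues) {
  bg <- spec$background_level
  sp <- spec$spike_level
  ns <- spec$noise_sd
  noisy <- function(latent) rtrunc_norm(n_tissues, latent, ns)
  switch(spec$archetype,
    RELIABLE = ,
    PSEUDOGENE_RED = {
      latent <- log_uniform(n_tissues, bg, sp)
      list(a = noisy(latent), b = noisy(latent))
    },
    DISCORDANT = {
      list(a = noisy(log_uniform(n_tissues, bg, sp)),
           b = noisy(log_uniform(n_tissues, bg, sp)))
    },
    TISSUE_SPECIFIC = {
      spike_at <- sample.int(n_tissues, spec$n_spike_tissues)
      make <- function() {
        v <- rtrunc_norm(n_tissues, bg, ns)  # independent background draws
        v[spike_at] <- rtrunc_norm(length(spike_at), sp, ns)
        v
      }
      list(a = make(), b = make())
    },
    ISOFORM_SPECIFIC = {
      # shared compact baseline (ubiquitous low-level expression); the
      # spike in probeset A then dominates its variance while ranks of
      # non-spiked tissues stay shared
      baseline <- log_uniform(n_tissues, bg, 10 * bg)
      spike_at <- sample.int(n_tissues, spec$n_spike_tissues)
      a <- baseline
      a[spike_at] <- a[spike_at] + sp
      list(a = noisy(a), b = noisy(baseline))
    },
    stop("archetype_profiles: unsupported archetype ", spec$archetype)
  )
}

#' Generate a synthetic dataset with ground truth
#'
#' Produces the three analysis inputs -- sample-level expression matrix,
#' probeset annotation, probe-alignment table -- plus the sample-to-tissue
#' map and per-gene-group truth labels.  Each tissue gets `n_replicates`
#' samples; a sample value is the tissue value plus Gaussian noise
#' (`replicate_sd`) truncated at zero.  Probes are 11 per probeset, all
#' green except for `PSEUDOGENE_RED` genes, whose probes all carry a
#' cross-gene hit (red).  Fully deterministic for a fixed seed.
#'
#' @param specs list of [archetype_spec()] blocks.
#' @param n_tissues number of tissues (>= 3; default 79).
#' @param n_replicates samples per tissue (>= 1; default 2).
#' @param seed mandatory integer seed; there is no hidden RNG state.
#' @param n_probes probes per probeset (default 11).
#' @return a `synthetic_dataset` list: `expression` (probesets x samples),
#'   `sample_map`, `annotation` (data.frame in the chip-annotation dialect),
#'   `probe_table`, `truth` (data.frame `gene_group_id`, `archetype`) and
#'   `tissues`.
#' @examples
#' ds <- generate_dataset(list(archetype_spec("RELIABLE", 5)),
#'                        n_tissues = 10, n_replicates = 2, seed = 1)
#' dim(ds$expression)  # 10 probesets x 20 samples
#' @export
generate_dataset <- function(specs, n_tissues = 79L, n_replicates = 2L,
                             seed, n_probes = 11L) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_tissues < 3L) stop("n_tissues must be >= 3")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (n_probes < 1L) stop("n_probes must be >= 1")
  if (inherits(specs, "archetype_spec")) specs <- list(specs)
  for (s in specs) {
    if (!inherits(s, "archetype_spec")) stop("specs must be archetype_spec")
    if (s$n_spike_tissues >= n_tissues) {
      stop("n_spike_tissues must be smaller than n_tissues")
    }
  }
  set.seed(as.integer(seed))

  tissues <- sprintf("tissue_%03d", seq_len(n_tissues))
  sample_map <- data.frame(
    sample_id = as.vector(t(outer(tissues, seq_len(n_replicates),
                                  function(t, r) sprintf("%s_rep%d", t, r)))),
    tissue = rep(tissues, each = n_replicates),
    stringsAsFactors = FALSE
  )

  rows <- list()        # tissue-level probeset profiles
  ann_id <- character() # annotation rows
  ann_sym <- character()
  probe_rows <- list()
  truth_id <- character()
  truth_arch <- character()
  ps_counter <- 0L

  next_ps <- function() {
    ps_counter <<- ps_counter + 1L
    sprintf("%06d_at", 200000L + ps_counter)
  }
  add_probes <- function(ps, red) {
    probe_rows[[length(probe_rows) + 1L]] <<- data.frame(
      probe_id = sprintf("%s_%d", ps, seq_len(n_probes)),
      probeset_id = ps,
      target_mismatches = 0L,
      cross_gene_hit = as.integer(red),
      noncoding_perfect_hit = 0L,
      stringsAsFactors = FALSE
    )
  }

  for (spec in specs) {
    for (g in seq_len(spec$n_genes)) {
      if (spec$archetype == "MULTIGENE_GROUP") {
        # two genes, one shared probeset plus one differentiating each
        g1 <- sprintf("%s_%04d_A", spec$archetype, g)
        g2 <- sprintf("%s_%04d_B", spec$archetype, g)
        latent <- log_uniform(n_tissues, spec$background_level,
                              spec$spike_level)
        for (sym in c(paste(g1, "///", g2), g1, g2)) {
          ps <- next_ps()
          ann_id <- c(ann_id, ps)
          ann_sym <- c(ann_sym, sym)
          add_probes(ps, red = FALSE)
          rows[[ps]] <- rtrunc_norm(n_tissues, latent, spec$noise_sd)
        }
        truth_id <- c(truth_id, group_label(c(g1, g2)))
        truth_arch <- c(truth_arch, spec$archetype)
      } else {
        gene <- sprintf("%s_%04d", spec$archetype, g)
        prof <- archetype_profiles(spec, n_tissues)
        for (side in c("a", "b")) {
          ps <- next_ps()
          ann_id <- c(ann_id, ps)
          ann_sym <- c(ann_sym, gene)
          add_probes(ps, red = spec$archetype == "PSEUDOGENE_RED")
          rows[[ps]] <- prof[[side]]
        }
        truth_id <- c(truth_id, gene)
        truth_arch <- c(truth_arch, spec$archetype)
      }
    }
  }

  tissue_mat <- do.call(rbind, rows)
  n_samples <- nrow(sample_map)
  expression <- matrix(0, nrow = nrow(tissue_mat), ncol = n_samples,
                       dimnames = list(rownames(tissue_mat),
                                       sample_map$sample_id))
  rep_sd <- rep(NA_real_, nrow(tissue_mat))
  i <- 1L
  for (spec in specs) {
    n_ps <- spec$n_genes * if (spec$archetype == "MULTIGENE_GROUP") 3L else 2L
    if (n_ps > 0L) rep_sd[i:(i + n_ps - 1L)] <- spec$replicate_sd
    i <- i + n_ps
  }
  tissue_of <- match(sample_map$tissue, tissues)
  for (j in seq_len(n_samples)) {
    base <- tissue_mat[, tissue_of[j]]
    expression[, j] <- pmax(0, base + stats::rnorm(length(base), 0, rep_sd))
  }

  out <- list(
    expression = expression,
    sample_map = sample_map,
    annotation = data.frame(`Probe Set ID` = ann_id,
                            `Gene Symbol` = ann_sym,
                            check.names = FALSE, stringsAsFactors = FALSE),
    probe_table = do.call(rbind, probe_rows),
    truth = data.frame(gene_group_id = truth_id, archetype = truth_arch,
                       stringsAsFactors = FALSE),
    tissues = tissues
  )
  class(out) <- "synthetic_dataset"
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic tissue-expression dataset\n")
  cat("  ", nrow(x$expression), " probesets x ", ncol(x$expression),
      " samples (", length(x$tissues), " tissues)\n", sep = "")
  cat("  archetypes:", paste(names(table(x$truth$archetype)),
                             table(x$truth$archetype),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic dataset to analysis input files
#'
#' Writes `expression.tsv` (first column `probeset_id`), `sample_map.tsv`,
#' `annotation.csv`, `probes.tsv` and `truth.tsv` into `dir`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr <- data.frame(probeset_id = rownames(dataset$expression),
                     dataset$expression, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_tsv(expr, file.path(dir, "expression.tsv"))
  write_tsv(dataset$sample_map, file.path(dir, "sample_map.tsv"))
  utils::write.csv(dataset$annotation, file.path(dir, "annotation.csv"),
                   row.names = FALSE, quote = TRUE)
  write_tsv(dataset$probe_table, file.path(dir, "probes.tsv"))
  write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
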