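# End-to-end pipeline: generate-or-load inputs, fit, write the report
# bundle.  Designed so that two runs with the same configuration and seed
# produce byte-identical TSV outputs.

#' Build a pipeline configuration
#'
#' Either all four input paths are given, or a synthetic specification
#' (`synthetic` + `seed`); never neither.
#'
#' @param outdir output directory.
#' @param annotation,expression,sample_map,probes input file paths.
#' @param synthetic list of [archetype_spec()] (or the output of
#'   [default_archetype_panel()]) to generate inputs instead of reading
#'   them.
#' @param seed integer seed for synthetic generation.
#' @param n_tissues,n_replicates synthetic panel dimensions.
#' @param high_cutoff,low_cutoff,bin_edges,collapse,quality_rule,log2
#'   analysis parameters, see [probeset_concordance()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            annotation = NULL, expression = NULL,
                            sample_map = NULL, probes = NULL,
                            synthetic = NULL, seed = NULL,
                            n_tissues = 79L, n_replicates = 2L,
                            high_cutoff = 0.7, low_cutoff = 0.3,
                            bin_edges = c(0.3, 0.5, 0.7, 0.9),
                            collapse = "mean",
                            quality_rule = "strict",
                            log2 = FALSE) {
  paths <- list(annotation = annotation, expression = expression,
                sample_map = sample_map, probes = probes)
  have_paths <- !vapply(paths[c("annotation", "expression", "sample_map")],
                        is.null, logical(1))
  if (is.null(synthetic) && !all(have_paths)) {
    stop("config needs either input paths (annotation, expression, ",
         "sample_map) or a synthetic spec")
  }
  if (!is.null(synthetic) && is.null(seed)) {
    stop("synthetic runs require a seed")
  }
  if (high_cutoff <= low_cutoff) stop("high_cutoff must exceed low_cutoff")
  if (any(bin_edges <= 0) || any(bin_edges >= 1) ||
      is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing within (0, 1)")
  }
  structure(list(outdir = outdir, paths = paths, synthetic = synthetic,
                 seed = seed, n_tissues = n_tissues,
                 n_replicates = n_replicates,
                 high_cutoff = high_cutoff, low_cutoff = low_cutoff,
                 bin_edges = bin_edges, collapse = collapse,
                 quality_rule = quality_rule, log2 = log2),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Sequences generation-or-loading, reannotation, quality profiling and
#' concordance analysis, then writes the report bundle to
#' `config$outdir`: `gene_groups.tsv`, `pair_stats.tsv`,
#' `category_summary.tsv`, `bin_regressions.tsv`, and with probe input
#' `probeset_quality.tsv`, `color_comparison.tsv`, `quality_strength.tsv`,
#' plus `manifest.json` (configuration echo, seed, package version, row
#' counts per stage).  Synthetic inputs are also written under
#' `outdir/inputs/`.
#'
#' @param config a [pipeline_config()].
#' @return the `probeset_concordance` fit, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$synthetic)) {
    ds <- generate_dataset(config$synthetic, n_tissues = config$n_tissues,
                           n_replicates = config$n_replicates,
                           seed = config$seed)
    write_dataset(ds, file.path(config$outdir, "inputs"))
    inputs <- list(expression = ds$expression, sample_map = ds$sample_map,
                   annotation = ds$annotation, probes = ds$probe_table)
  } else {
    for (nm in c("annotation", "expression", "sample_map")) {
      p <- config$paths[[nm]]
      if (!file.exists(p)) stop("input file for '", nm, "' not found: ", p)
    }
    if (!is.null(config$paths$probes) &&
        !file.exists(config$paths$probes)) {
      stop("input file for 'probes' not found: ", config$paths$probes)
    }
    inputs <- list(expression = config$paths$expression,
                   sample_map = config$paths$sample_map,
                   annotation = config$paths$annotation,
                   probes = config$paths$probes)
  }

  fit <- probeset_concordance(
    inputs$expression, inputs$sample_map, inputs$annotation, inputs$probes,
    high_cutoff = config$high_cutoff, low_cutoff = config$low_cutoff,
    bin_edges = config$bin_edges, collapse = config$collapse,
    quality_rule = config$quality_rule, log2 = config$log2)

  write_report_bundle(fit, config)
  invisible(fit)
}

write_report_bundle <- function(fit, config) {
  out <- config$outdir
  write_tsv(gene_groups_table(fit$groups), file.path(out, "gene_groups.tsv"))

  rec <- fit$records
  rec$category <- as.character(rec$category)
  write_tsv(rec, file.path(out, "pair_stats.tsv"))

  s <- fit$summary
  write_tsv(data.frame(category = c(names(s$counts), "EXTREME_TOTAL"),
                       count = c(s$counts, s$extreme_total),
                       percent = c(s$percentages, s$extreme_percentage)),
            file.path(out, "category_summary.tsv"))

  br <- do.call(rbind, lapply(names(fit$bin_regressions), function(b) {
    f <- fit$bin_regressions[[b]]
    if (!f$estimable) {
      return(data.frame(bin = b, n = f$n, means_slope = NA, means_r2 = NA,
                        cv_slope = NA, cv_r2 = NA))
    }
    data.frame(bin = b, n = f$n,
               means_slope = f$means$slope, means_r2 = f$means$r_squared,
               cv_slope = f$cv$slope, cv_r2 = f$cv$r_squared)
  }))
  write_tsv(br, file.path(out, "bin_regressions.tsv"))

  if (!is.null(fit$profiles)) {
    write_tsv(fit$profiles, file.path(out, "probeset_quality.tsv"))
  }
  if (!is.null(fit$color_comparison)) {
    cc <- fit$color_comparison
    rows <- lapply(c("pearson", "spearman"), function(coefname) {
      pw <- cc[[coefname]]$pairwise
      data.frame(coefficient = coefname,
                 kruskal_p = cc[[coefname]]$kruskal_p, pw)
    })
    write_tsv(do.call(rbind, rows), file.path(out, "color_comparison.tsv"))
  }
  if (!is.null(fit$quality_strength)) {
    qs <- fit$quality_strength
    write_tsv(data.frame(bin = rownames(qs$composition), qs$composition,
                         friedman_p = qs$friedman_p,
                         kendall_w = qs$kendall_w, check.names = FALSE),
              file.path(out, "quality_strength.tsv"))
  }

  manifest <- list(
    config = list(
      seed = config$seed, n_tissues = config$n_tissues,
      n_replicates = config$n_replicates,
      high_cutoff = config$high_cutoff, low_cutoff = config$low_cutoff,
      bin_edges = config$bin_edges, collapse = config$collapse,
      quality_rule = config$quality_rule, log2 = config$log2,
      synthetic = !is.null(config$synthetic)
    ),
    package_version = as.character(utils::packageVersion("probepair")),
    counts = list(
      gene_groups = length(fit$groups),
      pairs = nrow(fit$records),
      pairs_classified = sum(!fit$records$flagged),
      pairs_flagged = sum(fit$records$flagged),
      tissues = ncol(fit$tissue_expression)
    )
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}
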