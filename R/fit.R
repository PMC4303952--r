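#' Fit the probeset-pair concordance analysis
#'
#' The package's central estimator.  Starting from a chip annotation, a
#' sample-level expression matrix with its tissue map, and (optionally) a
#' probe-alignment table, it
#' \enumerate{
#'   \item reannotates probesets into gene groups
#'     ([form_primary_groups()], [merge_gene_groups()]) and selects the
#'     groups covered by exactly two probesets;
#'   \item collapses replicate samples to per-tissue values;
#'   \item computes, per pair, Pearson r, Spearman rho, Shapiro-Wilk
#'     normality p-values, means and coefficients of variation, and the
#'     quadrant category ([classify_pair()]);
#'   \item summarises categories, fits the rho-on-r regression, bins pairs
#'     by Spearman strength and fits the within-bin mean/CV concordance
#'     regressions;
#'   \item when probe alignments are given, derives probeset quality
#'     profiles, compares correlation coefficients across same-quality
#'     colour groups and relates quality composition to correlation
#'     strength.
#' }
#'
#' @param expression numeric matrix (probesets x samples) or path to an
#'   `expression.tsv` (first column `probeset_id`).
#' @param sample_map data.frame (`sample_id`, `tissue`) or path to a TSV.
#' @param annotation annotation table, data.frame or file path; parsed with
#'   [parse_probeset_annotation()].
#' @param probe_table optional probe-alignment table (data.frame or
#'   `probes.tsv` path); `NULL` skips the quality analyses.
#' @param high_cutoff,low_cutoff classification cutoffs (defaults 0.7, 0.3).
#' @param bin_edges Spearman-strength bin edges.
#' @param collapse replicate-collapse method, see [collapse_replicates()].
#' @param quality_rule `"strict"` or `"majority"`, see
#'   [select_same_quality_pairs()].
#' @param log2 log2-transform intensities (with +1 offset) before analysis;
#'   off by default -- the classification operates on absolute intensities.
#' @param annotation_cols named list overriding the annotation column names
#'   (`id_col`, `symbol_col`).
#' @return an object of class `probeset_concordance`; see Details.
#' @details The returned object contains `records` (one row per pair with
#'   all statistics), `groups`, `size_counts`, `summary`
#'   ([summarize_categories()] output), `correlation_fit`, `bins`,
#'   `bin_regressions`, and -- with probe input -- `profiles`,
#'   `same_quality`, `color_comparison`, `quality_strength`.  Methods:
#'   [print()], [summary()], [coef()] (rho-on-r line), [predict()],
#'   [residuals()], [plot()].
#' @examples
#' ds <- generate_dataset(default_archetype_panel(10), n_tissues = 20,
#'                        n_replicates = 2, seed = 42)
#' fit <- probeset_concordance(ds$expression, ds$sample_map,
#'                             ds$annotation, ds$probe_table)
#' summary(fit)
#' @export
probeset_concordance <- function(expression, sample_map, annotation,
                                 probe_table = NULL,
                                 high_cutoff = 0.7, low_cutoff = 0.3,
                                 bin_edges = c(0.3, 0.5, 0.7, 0.9),
                                 collapse = c("mean", "median", "first"),
                                 quality_rule = c("strict", "majority"),
                                 log2 = FALSE,
                                 annotation_cols = list()) {
  cl <- match.call()
  collapse <- match.arg(collapse)
  quality_rule <- match.arg(quality_rule)

  if (is.character(expression)) expression <- read_expression(expression)
  if (is.character(sample_map)) {
    sample_map <- utils::read.delim(sample_map, stringsAsFactors = FALSE)
  }
  if (is.character(probe_table)) {
    probe_table <- utils::read.delim(probe_table, stringsAsFactors = FALSE)
  }
  ann <- do.call(parse_probeset_annotation,
                 c(list(annotation), annotation_cols))

  groups <- merge_gene_groups(form_primary_groups(ann))
  sel <- select_two_probeset_groups(groups)
  pairs <- sel$pairs

  tissue_expr <- collapse_replicates(expression, sample_map, collapse)
  if (log2) tissue_expr <- log2(tissue_expr + 1)

  present <- pairs$probeset_a %in% rownames(tissue_expr) &
    pairs$probeset_b %in% rownames(tissue_expr)
  if (any(!present)) {
    warning(sum(!present), " pair(s) dropped: probeset missing from the ",
            "expression matrix", call. = FALSE)
    pairs <- pairs[present, , drop = FALSE]
  }

  records <- pair_records(pairs, tissue_expr, high_cutoff, low_cutoff)

  cat_summary <- summarize_categories(records)
  corr_fit <- if (sum(is.finite(records$pearson_r)) >= 2L) {
    fit_correlation_relationship(records)
  } else NULL
  classified <- records[!is.na(records$category), , drop = FALSE]
  bins <- bin_pairs_by_spearman(classified, bin_edges)
  bin_regs <- lapply(bins, fit_concordance_regression)

  profiles <- same_quality <- color_comparison <- quality_strength <- NULL
  if (!is.null(probe_table)) {
    profiles <- probeset_quality_profile(
      probe_table, probesets = unique(c(pairs$probeset_a, pairs$probeset_b)))
    same_quality <- select_same_quality_pairs(pairs, profiles, quality_rule)
    color_records <- lapply(same_quality, function(p) {
      classified[classified$group_id %in% p$group_id, , drop = FALSE]
    })
    nonempty <- vapply(color_records, function(d)
      nrow(d) >= 2L, logical(1))
    if (sum(nonempty) >= 2L) {
      color_comparison <- compare_color_groups(color_records[nonempty])
    }
    quality_strength <- tryCatch(
      quality_vs_strength(classified, profiles, bin_edges),
      error = function(e) NULL)
  }

  structure(list(
    records = records,
    groups = groups,
    size_counts = sel$size_counts,
    summary = cat_summary,
    correlation_fit = corr_fit,
    bins = bins,
    bin_regressions = bin_regs,
    profiles = profiles,
    same_quality = same_quality,
    color_comparison = color_comparison,
    quality_strength = quality_strength,
    tissue_expression = tissue_expr,
    params = list(high_cutoff = high_cutoff, low_cutoff = low_cutoff,
                  bin_edges = bin_edges, collapse = collapse,
                  quality_rule = quality_rule, log2 = log2),
    call = cl
  ), class = "probeset_concordance")
}

read_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  m
}

# one row per pair with the full statistics block
pair_records <- function(pairs, tissue_expr, high_cutoff, low_cutoff) {
  n <- nrow(pairs)
  stats_mat <- matrix(NA_real_, n, 8L,
                      dimnames = list(NULL,
                        c("pearson_r", "spearman_rho", "shapiro_p_a",
                          "shapiro_p_b", "mean_a", "mean_b", "cv_a", "cv_b")))
  sw <- function(v) tryCatch(normality_pvalue(v), error = function(e)
    NA_real_)
  for (i in seq_len(n)) {
    x <- tissue_expr[pairs$probeset_a[i], ]
    y <- tissue_expr[pairs$probeset_b[i], ]
    rs <- pair_correlations(x, y)
    ma <- mean_and_cv(x)
    mb <- mean_and_cv(y)
    stats_mat[i, ] <- c(rs, sw(x), sw(y), ma["mean"], mb["mean"],
                        ma["cv"], mb["cv"])
  }
  out <- cbind(pairs, as.data.frame(stats_mat))
  out$category <- classify_pair(out$pearson_r, out$spearman_rho,
                                high_cutoff, low_cutoff)
  out$flagged <- is.na(out$category)
  rownames(out) <- NULL
  out
}

#' @export
print.probeset_concordance <- function(x, ...) {
  cat("Probeset-pair concordance analysis\n")
  cat("  ", x$summary$total, " pairs over ",
      ncol(x$tissue_expression), " tissues",
      if (x$summary$n_flagged)
        paste0(" (", x$summary$n_flagged, " flagged/unclassified)"),
      "\n", sep = "")
  cat("  categories:",
      paste(names(x$summary$counts), x$summary$counts, sep = "=",
            collapse = ", "), "\n")
  if (!is.null(x$correlation_fit) && x$correlation_fit$estimable) {
    cat(sprintf("  rho ~ r: R^2 = %.4f\n", x$correlation_fit$r_squared))
  }
  invisible(x)
}

#' Summarise a concordance fit
#'
#' @param object a `probeset_concordance` fit.
#' @param ... unused.
#' @return the object, invisibly, after printing the category table, the
#'   rho-on-r regression, and (if available) the colour-group comparison.
#' @export
summary.probeset_concordance <- function(object, ...) {
  s <- object$summary
  cat("Probeset-pair concordance analysis\n\n")
  tab <- data.frame(count = s$counts, percent = s$percentages)
  print(tab)
  cat(sprintf("\nextreme categories: %d of %d pairs (%.1f%%)\n",
              s$extreme_total, s$total, s$extreme_percentage))
  if (s$n_flagged) {
    cat(s$n_flagged, "pair(s) flagged (undefined correlation)\n")
  }
  if (!is.null(object$correlation_fit) && object$correlation_fit$estimable) {
    f <- object$correlation_fit
    cat(sprintf("\nrho ~ r: slope %.3f, intercept %.3f, R^2 = %.4f (n = %d)\n",
                f$slope, f$intercept, f$r_squared, f$n))
  }
  if (!is.null(object$color_comparison)) {
    cat("\n")
    print(object$color_comparison)
  }
  if (!is.null(object$quality_strength)) {
    cat("\n")
    print(object$quality_strength)
  }
  invisible(object)
}

#' @export
coef.probeset_concordance <- function(object, ...) {
  f <- object$correlation_fit
  if (is.null(f)) return(c(intercept = NA_real_, slope = NA_real_))
  c(intercept = f$intercept, slope = f$slope)
}

#' Predict Spearman rho from Pearson r
#'
#' Uses the fitted rho-on-r line; mainly a diagnostic of how far the two
#' coefficients are interchangeable for these data.
#'
#' @param object a `probeset_concordance` fit.
#' @param newdata optional data.frame with a `pearson_r` column (default:
#'   the fitted pairs).
#' @param ... unused.
#' @return numeric vector of predicted rho values.
#' @export
predict.probeset_concordance <- function(object, newdata = NULL, ...) {
  b <- coef(object)
  r <- if (is.null(newdata)) object$records$pearson_r else newdata$pearson_r
  unname(b["intercept"] + b["slope"] * r)
}

#' @export
residuals.probeset_concordance <- function(object, ...) {
  object$records$spearman_rho - predict(object)
}

#' Quadrant plot of Pearson versus Spearman coefficients
#'
#' One dot per pair, cutoff lines delimiting the four extreme quadrants,
#' and the fitted rho-on-r regression line.
#'
#' @param x a `probeset_concordance` fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.probeset_concordance <- function(x, ...) {
  rec <- x$records[!is.na(x$records$category), , drop = FALSE]
  cols <- c(RELIABLE = "forestgreen", TISSUE_SPECIFIC = "steelblue",
            ISOFORM_SPECIFIC = "darkorange", DISCORDANT = "firebrick",
            INTERMEDIATE = "grey60")
  graphics::plot(rec$pearson_r, rec$spearman_rho,
                 col = cols[as.character(rec$category)], pch = 16,
                 cex = 0.6, xlim = c(-1, 1), ylim = c(-1, 1),
                 xlab = "Pearson r", ylab = "Spearman rho", ...)
  graphics::abline(h = c(x$params$low_cutoff, x$params$high_cutoff),
                   v = c(x$params$low_cutoff, x$params$high_cutoff),
                   lty = 2, col = "grey40")
  if (!is.null(x$correlation_fit) && x$correlation_fit$estimable) {
    graphics::abline(x$correlation_fit$intercept, x$correlation_fit$slope,
                     col = "darkred", lty = 2, lwd = 2)
  }
  graphics::legend("bottomright", legend = names(cols), col = cols,
                   pch = 16, cex = 0.7, bty = "n")
  invisible(x)
}
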