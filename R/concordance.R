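# Per-pair concordance statistics and group-level comparisons.
#
# The unit of analysis is a gene (group) measured by exactly two probesets.
# Across a tissue panel, the pair's Pearson r captures agreement of absolute
# intensities and the Spearman rho agreement of rank order; the joint
# (r, rho) position classifies the pair into one of four extreme categories
# or an intermediate zone.

PAIR_CATEGORIES <- c("RELIABLE", "TISSUE_SPECIFIC", "ISOFORM_SPECIFIC",
                     "DISCORDANT", "INTERMEDIATE")

#' Collapse replicate samples to per-tissue values
#'
#' @param expression numeric matrix, probesets x samples, column names are
#'   sample ids.
#' @param sample_map data.frame with columns `sample_id` and `tissue`
#'   covering every expression column.
#' @param method collapse method per tissue: arithmetic `"mean"` (default),
#'   `"median"` or `"first"` replicate.
#' @return probesets x tissues matrix, tissue order as first appearance in
#'   `sample_map`; the collapse method is recorded in attribute
#'   `"collapse"`.
#' @export
collapse_replicates <- function(expression, sample_map,
                                method = c("mean", "median", "first")) {
  method <- match.arg(method)
  samples <- colnames(expression)
  unmapped <- setdiff(samples, sample_map$sample_id)
  if (length(unmapped)) {
    stop("sample(s) missing from sample_map: ",
         paste(utils::head(unmapped, 5L), collapse = ", "))
  }
  tissue <- sample_map$tissue[match(samples, sample_map$sample_id)]
  tissue_levels <- unique(sample_map$tissue)
  tissue <- factor(tissue, levels = tissue_levels[tissue_levels %in% tissue])
  collapse_fun <- switch(method,
    mean = rowMeans,
    median = function(m) apply(m, 1, stats::median),
    first = function(m) m[, 1L]
  )
  out <- matrix(
    vapply(levels(tissue), function(tt) {
      collapse_fun(expression[, tissue == tt, drop = FALSE])
    }, numeric(nrow(expression))),
    nrow = nrow(expression),
    dimnames = list(rownames(expression), levels(tissue)))
  attr(out, "collapse") <- method
  out
}

#' Shapiro-Wilk normality p-value
#'
#' Reporting aid only: both correlation coefficients are always computed
#' downstream regardless of normality.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return the p-value, or `NA` for a constant vector (undefined).
#' @export
normality_pvalue <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk test requires 3 <= n <= 5000, got n = ", n)
  }
  if (stats::sd(values) == 0) return(NA_real_)
  stats::shapiro.test(values)$p.value
}

#' Pearson and Spearman correlations of a probeset pair
#'
#' Spearman's rho is the product-moment correlation of mid-ranks (ties get
#' average ranks), not the Sum-d-squared shortcut, since intensity ties
#' occur in real tables.
#'
#' @param x,y numeric tissue vectors of equal length >= 3.
#' @return named numeric vector `c(pearson_r, spearman_rho)`; both `NA` for
#'   constant input (undefined correlation -- the pair is flagged upstream
#'   and excluded from classification).
#' @export
pair_correlations <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 tissues")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(pearson_r = NA_real_, spearman_rho = NA_real_))
  }
  c(pearson_r = stats::cor(x, y),
    spearman_rho = stats::cor(x, y, method = "spearman"))
}

#' Classify a probeset pair from its two correlation coefficients
#'
#' Quadrant rule with strict inequalities at both cutoffs (values exactly at
#' a cutoff are INTERMEDIATE): RELIABLE iff both coefficients exceed the
#' high cutoff; TISSUE_SPECIFIC iff r is high and rho low (absolute spikes
#' agree, background ranks are noise); ISOFORM_SPECIFIC iff rho is high and
#' r low (rank order preserved, a spike in only one probeset);
#' DISCORDANT iff both are low; INTERMEDIATE otherwise.
#'
#' @param r,rho numeric vectors of Pearson and Spearman coefficients in
#'   \eqn{[-1, 1]}; recycled to common length.
#' @param high_cutoff,low_cutoff the quadrant cutoffs (defaults 0.7, 0.3).
#' @return factor with levels `RELIABLE`, `TISSUE_SPECIFIC`,
#'   `ISOFORM_SPECIFIC`, `DISCORDANT`, `INTERMEDIATE`; `NA` where either
#'   coefficient is `NA`.
#' @examples
#' classify_pair(0.148, 0.144)  # DISCORDANT
#' classify_pair(0.998, 0.220)  # TISSUE_SPECIFIC
#' @export
classify_pair <- function(r, rho, high_cutoff = 0.7, low_cutoff = 0.3) {
  if (high_cutoff <= low_cutoff) stop("high_cutoff must exceed low_cutoff")
  n <- max(length(r), length(rho))
  r <- rep_len(r, n)
  rho <- rep_len(rho, n)
  ok <- !is.na(r) & !is.na(rho)
  if (any(abs(r[ok]) > 1) || any(abs(rho[ok]) > 1)) {
    stop("correlation coefficients must lie in [-1, 1]")
  }
  cat <- rep(NA_character_, n)
  cat[ok] <- "INTERMEDIATE"
  cat[ok & r > high_cutoff & rho > high_cutoff] <- "RELIABLE"
  cat[ok & r > high_cutoff & rho < low_cutoff] <- "TISSUE_SPECIFIC"
  cat[ok & rho > high_cutoff & r < low_cutoff] <- "ISOFORM_SPECIFIC"
  cat[ok & r < low_cutoff & rho < low_cutoff] <- "DISCORDANT"
  factor(cat, levels = PAIR_CATEGORIES)
}

#' Category counts and percentages
#'
#' @param records data.frame with a `category` column (factor as returned by
#'   [classify_pair()]); rows with `NA` category (undefined correlations)
#'   are counted separately as `n_flagged` and excluded from the total.
#' @return list with `counts` (named integer, five categories),
#'   `percentages` (of total pairs, rounded half-up to one decimal),
#'   `total`, `extreme_total` (sum of the four non-intermediate counts),
#'   `extreme_percentage` and `n_flagged`.
#' @examples
#' rec <- data.frame(category = classify_pair(
#'   c(0.9, 0.9, 0.1, 0.5), c(0.8, 0.1, 0.1, 0.5)))
#' summarize_categories(rec)$counts
#' @export
summarize_categories <- function(records) {
  cat <- factor(records$category, levels = PAIR_CATEGORIES)
  n_flagged <- sum(is.na(cat))
  counts <- table(cat)
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * as.numeric(counts) / total, 1L)
         else rep(0, length(counts))
  extreme <- sum(counts[setdiff(PAIR_CATEGORIES, "INTERMEDIATE")])
  list(
    counts = stats::setNames(as.integer(counts), names(counts)),
    percentages = stats::setNames(pct, names(counts)),
    total = as.integer(total),
    extreme_total = as.integer(extreme),
    extreme_percentage = if (total > 0)
      round_half_up(100 * extreme / total, 1L) else 0,
    n_flagged = as.integer(n_flagged)
  )
}

ols_fit <- function(y, x) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L || stats::sd(x) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, p_value = NA_real_,
                n = length(x), estimable = FALSE))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_value = if (nrow(sm$coefficients) > 1L)
         sm$coefficients[2L, 4L] else NA_real_,
       n = length(x),
       estimable = TRUE,
       lm = fit)
}

#' Linear relationship between the two correlation coefficients
#'
#' Ordinary least squares of Spearman's rho on Pearson's r across all pairs;
#' the R-squared measures how far the two coefficients are interchangeable
#' over the chip.
#'
#' @param records data.frame with columns `pearson_r`, `spearman_rho`
#'   (non-finite rows dropped).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`,
#'   `estimable` and the underlying `lm` fit.  Fewer than 3 usable rows, or
#'   constant r, give `estimable = FALSE` with `NA` statistics.
#' @export
fit_correlation_relationship <- function(records) {
  fit <- ols_fit(records$spearman_rho, records$pearson_r)
  if (fit$n < 3L) {
    fit$estimable <- FALSE
    if (fit$n == 2L) {
      warning("regression on 2 points is degenerate (R^2 = 1 by construction)",
              call. = FALSE)
      fit$estimable <- TRUE
    }
  }
  fit
}

#' Mean and coefficient of variation of a tissue profile
#'
#' CV = sample standard deviation (n-1 denominator) / mean: the scale-free
#' dispersion of a probeset's profile, an indicator of ubiquitous versus
#' restricted expression.
#'
#' @param values numeric vector, n >= 2.
#' @return named vector `c(mean, cv)`; `cv` is `NA` (with a warning) when
#'   the mean is zero.
#' @export
mean_and_cv <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) {
    warning("mean is zero; cv undefined", call. = FALSE)
    return(c(mean = m, cv = NA_real_))
  }
  c(mean = m, cv = stats::sd(values) / m)
}

#' Bin pairs by Spearman correlation strength
#'
#' Left-closed bins over rho: with the default edges,
#' `[-1, 0.3) [0.3, 0.5) [0.5, 0.7) [0.7, 0.9) [0.9, 1]`; every record
#' falls in exactly one bin (rho = 0.9 is in the top bin).
#'
#' @param records data.frame with a `spearman_rho` column.
#' @param bin_edges strictly increasing interior edges in (-1, 1).
#' @return `records` split into an ordered named list of bins.
#' @export
bin_pairs_by_spearman <- function(records, bin_edges = c(0.3, 0.5, 0.7, 0.9)) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing")
  }
  breaks <- c(-1, bin_edges, 1)
  labels <- sprintf("[%s,%s%s", breaks[-length(breaks)], breaks[-1L],
                    c(rep(")", length(breaks) - 2L), "]"))
  bin <- cut(records$spearman_rho, breaks = breaks, labels = labels,
             right = FALSE, include.lowest = TRUE)
  split(records, bin)
}

#' Within-bin concordance of means and CVs
#'
#' For all pairs in one correlation-strength bin, OLS of probeset B's mean
#' on probeset A's mean, and of B's CV on A's CV.  The R-squared values are
#' the bin's concordance scores: how far averaging the two probesets is
#' justified at that correlation strength.
#'
#' @param bin data.frame of records with `mean_a`, `mean_b`, `cv_a`, `cv_b`.
#' @return list with `means` and `cv` fit lists (see
#'   [fit_correlation_relationship()]) and `estimable`; bins with fewer than
#'   3 pairs are flagged not-estimable.
#' @export
fit_concordance_regression <- function(bin) {
  if (nrow(bin) < 3L) {
    return(list(means = NULL, cv = NULL, n = nrow(bin), estimable = FALSE))
  }
  list(means = ols_fit(bin$mean_b, bin$mean_a),
       cv = ols_fit(bin$cv_b, bin$cv_a),
       n = nrow(bin),
       estimable = TRUE)
}

#' Compare correlation coefficients across probe-colour groups
#'
#' For Pearson and Spearman coefficients separately: a Kruskal-Wallis test
#' across the colour groups, then all pairwise Mann-Whitney (Wilcoxon
#' rank-sum) tests with Bonferroni correction (each p multiplied by the
#' number of pairwise tests, capped at 1) at family level 0.05.
#'
#' @param same_quality_pairs named list (colour -> data.frame of records
#'   with `pearson_r` and `spearman_rho`), e.g. pair records subset by
#'   [select_same_quality_pairs()]; empty groups are dropped.
#' @return object of class `color_group_comparison`: per coefficient a list
#'   with `kruskal_p` and a `pairwise` data.frame (`group1`, `group2`, `p`,
#'   `p_bonferroni`, `significant`).
#' @export
compare_color_groups <- function(same_quality_pairs) {
  groups <- Filter(function(d) nrow(d) > 0L, same_quality_pairs)
  if (length(groups) < 2L) {
    stop("need at least 2 non-empty colour groups")
  }
  small <- names(groups)[vapply(groups, nrow, integer(1)) < 2L]
  if (length(small)) {
    stop("colour group(s) with fewer than 2 records: ",
         paste(small, collapse = ", "))
  }
  one_coef <- function(col) {
    vals <- lapply(groups, `[[`, col)
    # all observations identical: no between-group variation, p = 1 by
    # convention (the rank tests return NaN from a zero tie-correction)
    degenerate <- length(unique(unlist(vals))) == 1L
    kp <- if (degenerate) 1 else stats::kruskal.test(vals)$p.value
    combos <- utils::combn(names(groups), 2L)
    n_tests <- ncol(combos)
    pw <- apply(combos, 2L, function(gg) {
      a <- vals[[gg[1L]]]
      b <- vals[[gg[2L]]]
      if (length(unique(c(a, b))) == 1L) return(1)
      stats::wilcox.test(a, b, exact = FALSE)$p.value
    })
    p_bonf <- pmin(1, pw * n_tests)
    list(kruskal_p = kp,
         pairwise = data.frame(group1 = combos[1L, ], group2 = combos[2L, ],
                               p = pw, p_bonferroni = p_bonf,
                               significant = p_bonf < 0.05,
                               stringsAsFactors = FALSE))
  }
  out <- list(pearson = one_coef("pearson_r"),
              spearman = one_coef("spearman_rho"),
              group_sizes = vapply(groups, nrow, integer(1)))
  class(out) <- "color_group_comparison"
  out
}

#' @export
print.color_group_comparison <- function(x, ...) {
  cat("Correlation coefficients across probe-colour groups\n")
  cat("  groups:", paste(names(x$group_sizes), x$group_sizes, sep = "=",
                         collapse = ", "), "\n")
  cat(sprintf("  Kruskal-Wallis: Pearson p = %.4g, Spearman p = %.4g\n",
              x$pearson$kruskal_p, x$spearman$kruskal_p))
  sig <- x$spearman$pairwise[x$spearman$pairwise$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("  Spearman pairwise (Bonferroni, p < 0.05):",
        paste(sig$group1, sig$group2, sep = "-", collapse = ", "), "\n")
  }
  invisible(x)
}

# Friedman rank test over a blocks x treatments matrix; a fully tied table
# (every block constant) carries no evidence of treatment differences and
# returns p = 1 by convention (friedman.test yields NaN there, its tie
# correction degenerating to 0/0).
friedman_pvalue <- function(blocks_by_treatments) {
  if (all(apply(blocks_by_treatments, 1L,
                function(row) length(unique(row)) == 1L))) {
    return(1)
  }
  p <- stats::friedman.test(blocks_by_treatments)$p.value
  if (is.nan(p)) 1 else p
}

# Kendall's W of m judges (rows) ranking k objects (columns), with the
# standard tie correction; 1 = identical rankings. Returns 0 when every row
# is fully tied (no ranking information).
kendall_w <- function(m) {
  ranks <- t(apply(m, 1L, rank))
  nj <- nrow(m)
  k <- ncol(m)
  S <- sum((colSums(ranks) - nj * (k + 1) / 2)^2)
  ties <- sum(apply(m, 1L, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  }))
  denom <- nj^2 * (k^3 - k) - nj * ties
  if (denom <= 0) return(0)
  12 * S / denom
}

#' Probe quality versus correlation strength
#'
#' Builds the colour-composition table over Spearman-strength bins: for each
#' bin, the colour composition of all member probesets (each probeset
#' contributes its colour fractions, so a mixed probeset is spread across
#' colours).  Two statistics summarise the table:
#' \itemize{
#'   \item `friedman_p` -- Friedman rank test of whether composition differs
#'     between strength bins (bins as treatments, colour classes as blocks);
#'     a large p means probe quality does not track correlation strength.
#'   \item `kendall_w` -- Kendall's coefficient of concordance of the colour
#'     rankings across bins (bins as judges ranking the colours,
#'     tie-corrected); 1 means every bin ranks the colours identically.
#' }
#'
#' @param records data.frame of pair records with `spearman_rho`,
#'   `probeset_a`, `probeset_b`.
#' @param profiles output of [probeset_quality_profile()].
#' @param bin_edges passed to [bin_pairs_by_spearman()].
#' @return object of class `quality_strength` with `composition`
#'   (bins x colours matrix of fraction-weighted probeset counts),
#'   `friedman_p` and `kendall_w`.  Empty bins are dropped with a warning;
#'   fewer than 2 occupied bins is an error (the tests need blocks to
#'   compare).
#' @export
quality_vs_strength <- function(records, profiles,
                                bin_edges = c(0.3, 0.5, 0.7, 0.9)) {
  rownames(profiles) <- profiles$probeset_id
  bins <- bin_pairs_by_spearman(records, bin_edges)
  empty <- names(bins)[vapply(bins, nrow, integer(1)) == 0L]
  if (length(empty)) {
    warning("dropping empty Spearman bin(s): ",
            paste(empty, collapse = ", "), call. = FALSE)
    bins <- bins[vapply(bins, nrow, integer(1)) > 0L]
  }
  if (length(bins) < 2L) {
    stop("quality-vs-strength tests need at least 2 occupied bins")
  }
  frac_cols <- c("frac_green", "frac_yellow", "frac_red", "frac_black")
  composition <- t(vapply(bins, function(b) {
    ids <- c(b$probeset_a, b$probeset_b)
    colSums(profiles[ids, frac_cols, drop = FALSE])
  }, numeric(4L)))
  colnames(composition) <- PROBE_COLORS
  # blocks = colours, treatments = bins: does composition depend on bin?
  friedman_p <- friedman_pvalue(t(composition))
  out <- list(composition = composition,
              friedman_p = friedman_p,
              kendall_w = kendall_w(composition),
              bin_edges = bin_edges)
  class(out) <- "quality_strength"
  out
}

#' @export
print.quality_strength <- function(x, ...) {
  cat("Probe-colour composition by Spearman-strength bin\n")
  print(round(x$composition, 2))
  cat(sprintf("Friedman p = %.4g, Kendall's W = %.4f\n",
              x$friedman_p, x$kendall_w))
  invisible(x)
}
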