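test_that("replicate collapse averages within tissues preserving order", {
  expr <- matrix(c(100, 110, 20, 40, 7, 7), nrow = 1,
                 dimnames = list("ps1", sprintf("s%d", 1:6)))
  map <- data.frame(sample_id = sprintf("s%d", 1:6),
                    tissue = rep(c("liver", "brain", "lung"), each = 2))
  out <- collapse_replicates(expr, map)
  expect_equal(out["ps1", ], c(liver = 105, brain = 30, lung = 7))
  expect_equal(attr(out, "collapse"), "mean")
  # single replicate per tissue: identity
  expr1 <- expr[, c(1, 3, 5), drop = FALSE]
  map1 <- map[c(1, 3, 5), ]
  expect_equal(unname(collapse_replicates(expr1, map1)["ps1", ]),
               c(100, 20, 7))
  # median and first are selectable
  expect_equal(unname(collapse_replicates(expr, map, "first")["ps1", ]),
               c(100, 20, 7))
  expect_error(collapse_replicates(expr, map[-1, ]), "s1")
})

test_that("normality p-values behave as expected on Gaussian and spiked vectors", {
  set.seed(101)
  gauss <- rnorm(79, 500, 50)
  expect_gt(normality_pvalue(gauss), 0.05)
  spiked <- c(rnorm(78, 50, 5), 5000)
  expect_lt(normality_pvalue(spiked), 0.05)
  expect_true(is.na(normality_pvalue(rep(7, 10))))
  expect_error(normality_pvalue(c(1, 2)), "n = 2")
})

test_that("pair correlations are affine/monotone invariant and symmetric", {
  set.seed(5)
  x <- runif(20, 0, 10)
  rs <- pair_correlations(x, 2 * x + 3)
  expect_equal(unname(rs), c(1, 1))
  rs <- pair_correlations(x, exp(x))
  expect_equal(unname(rs["spearman_rho"]), 1)
  expect_lt(rs["pearson_r"], 1)
  y <- runif(20)
  expect_equal(pair_correlations(x, y), pair_correlations(y, x))
  # rho invariant under strictly monotone transforms, r under positive affine
  expect_equal(pair_correlations(x, y)["spearman_rho"],
               pair_correlations(log(x + 1), y^3)["spearman_rho"])
  expect_equal(pair_correlations(x, y)["pearson_r"],
               pair_correlations(10 * x + 2, y)["pearson_r"])
  # constant input: undefined, flagged as NA
  expect_true(all(is.na(pair_correlations(rep(1, 5), y[1:5]))))
  expect_error(pair_correlations(x, y[1:5]), "equal length")
})

test_that("Spearman via mid-ranks equals the d-squared closed form (no ties)", {
  # frozen worked example: ranks (1..5) vs (2,1,4,3,5), sum d^2 = 4
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  expect_equal(spearman_d2(x, y), 0.8)
  expect_equal(unname(pair_correlations(x, y)["spearman_rho"]), 0.8)

  # all permutations up to n = 6 with distinct values
  for (n in 3:6) {
    base <- seq_len(n)
    perms <- as.matrix(expand.grid(rep(list(base), n)))
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ,
                   drop = FALSE]
    for (i in seq_len(nrow(perms))) {
      p <- perms[i, ]
      expect_equal(unname(pair_correlations(base, p)["spearman_rho"]),
                   spearman_d2(base, p), tolerance = 1e-12)
    }
  }
})

test_that("pair classification reproduces the quadrant semantics", {
  expect_equal(as.character(classify_pair(0.148, 0.144)), "DISCORDANT")
  expect_equal(as.character(classify_pair(0.998, 0.220)), "TISSUE_SPECIFIC")
  expect_equal(as.character(classify_pair(0.057, 0.914)), "ISOFORM_SPECIFIC")
  expect_equal(as.character(classify_pair(0.899, 0.756)), "RELIABLE")
  expect_equal(as.character(classify_pair(0.5, 0.5)), "INTERMEDIATE")
  # strict boundaries: values exactly at a cutoff fall inside no quadrant
  expect_equal(as.character(classify_pair(c(0.7, 0.3, 0.8), c(0.8, 0.2, 0.3))),
               rep("INTERMEDIATE", 3))
  expect_true(is.na(classify_pair(NA, 0.5)))
  expect_error(classify_pair(1.2, 0), "\\[-1, 1\\]")
  expect_error(classify_pair(0.5, 0.5, high_cutoff = 0.2), "exceed")
})

test_that("classification partitions the (r, rho) square exhaustively", {
  g <- seq(-1, 1, length.out = 201)
  grid <- expand.grid(r = g, rho = g)
  cat <- classify_pair(grid$r, grid$rho)
  expect_false(anyNA(cat))
  expect_equal(sum(table(cat)), nrow(grid))
  # spot-check each quadrant is hit
  expect_true(all(c("RELIABLE", "TISSUE_SPECIFIC", "ISOFORM_SPECIFIC",
                    "DISCORDANT", "INTERMEDIATE") %in%
                  names(which(table(cat) > 0))))
})

test_that("category summaries recompose counts and percentages", {
  rec <- make_records(r = c(0.9, 0.9, 0.1, 0.5, 0.9),
                      rho = c(0.8, 0.1, 0.1, 0.5, 0.9))
  s <- summarize_categories(rec)
  expect_equal(sum(s$counts), s$total)
  expect_equal(s$extreme_total, s$total - s$counts[["INTERMEDIATE"]])
  all_rel <- summarize_categories(
    make_records(r = rep(0.9, 4), rho = rep(0.9, 4)))
  expect_equal(all_rel$percentages[["RELIABLE"]], 100)
  empty <- summarize_categories(make_records(numeric(0), numeric(0)))
  expect_equal(empty$total, 0L)
  expect_true(all(empty$counts == 0L))
  # NA categories are flagged, not counted
  rec$category[1] <- NA
  expect_equal(summarize_categories(rec)$n_flagged, 1L)
})

test_that("the rho-on-r regression recovers exact and degenerate cases", {
  r <- seq(0.1, 0.9, length.out = 20)
  # perfect fit triggers summary.lm's reliability warning; harmless here
  fit <- suppressWarnings(fit_correlation_relationship(make_records(r, r)))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 1)
  # rho independent of r: R^2 near zero
  set.seed(9)
  fit0 <- fit_correlation_relationship(
    make_records(runif(400, -1, 1), runif(400, -1, 1)))
  expect_lt(fit0$r_squared, 0.05)
  # two points are fit perfectly but flagged degenerate
  expect_warning(
    fit2 <- fit_correlation_relationship(
      make_records(c(0.1, 0.5), c(0.2, 0.4))), "degenerate")
  expect_equal(fit2$r_squared, 1)
  # constant r: not estimable
  fitc <- fit_correlation_relationship(
    make_records(rep(0.5, 5), runif(5)))
  expect_false(fitc$estimable)
})

test_that("mean and CV follow the direct arithmetic definitions", {
  v <- c(2, 4, 4, 4, 5, 5, 7, 9)
  out <- mean_and_cv(v)
  expect_equal(out[["mean"]], 5)
  expect_equal(out[["cv"]], sqrt(32 / 7) / 5)
  expect_equal(mean_and_cv(rep(3, 6)), c(mean = 3, cv = 0))
  # scale invariance of CV
  expect_equal(mean_and_cv(13 * v)[["cv"]], out[["cv"]])
  expect_warning(z <- mean_and_cv(c(0, 0)), "cv undefined")
  expect_true(is.na(z[["cv"]]))
  expect_error(mean_and_cv(5), "at least 2")
})

test_that("Spearman bins are left-closed with full coverage", {
  rho <- c(-0.5, 0.29, 0.3, 0.5, 0.69, 0.7, 0.89, 0.9, 1)
  bins <- bin_pairs_by_spearman(make_records(rep(0.5, 9), rho))
  expect_length(bins, 5L)
  expect_equal(vapply(bins, nrow, integer(1), USE.NAMES = FALSE),
               c(2L, 1L, 2L, 2L, 2L))
  # rho = 0.9 in the top bin, 0.7 in the fourth
  expect_true(0.9 %in% bins[["[0.9,1]"]]$spearman_rho)
  expect_true(0.7 %in% bins[["[0.7,0.9)"]]$spearman_rho)
  expect_equal(sum(vapply(bins, nrow, integer(1))), 9L)
  expect_error(bin_pairs_by_spearman(make_records(0.5, 0.5),
                                     bin_edges = c(0.5, 0.3)), "increasing")
})

test_that("within-bin mean/CV concordance regressions score agreement", {
  # identical reporting: both regressions perfect
  rec <- make_records(r = rep(0.9, 5), rho = rep(0.95, 5),
                      mean_a = c(10, 50, 200, 800, 3000),
                      mean_b = c(10, 50, 200, 800, 3000),
                      cv_a = c(0.1, 0.4, 0.7, 1, 1.5),
                      cv_b = c(0.1, 0.4, 0.7, 1, 1.5))
  f <- suppressWarnings(fit_concordance_regression(rec))
  expect_equal(f$means$r_squared, 1)
  expect_equal(f$means$slope, 1)
  expect_equal(f$cv$r_squared, 1)
  # undersized bin: not estimable
  expect_false(fit_concordance_regression(rec[1:2, ])$estimable)
})

test_that("colour-group comparisons detect shifts and respect Bonferroni", {
  set.seed(21)
  base <- function(n) data.frame(pearson_r = runif(n, 0.2, 0.9),
                                 spearman_rho = runif(n, 0.2, 0.9))
  same <- list(GREEN = base(40), RED = base(40), BLACK = base(40))
  cmp <- compare_color_groups(same)
  expect_gt(cmp$pearson$kruskal_p, 0.05)
  expect_gt(cmp$spearman$kruskal_p, 0.05)
  expect_equal(nrow(cmp$spearman$pairwise), choose(3, 2))
  expect_true(all(cmp$spearman$pairwise$p_bonferroni <= 1))

  shifted <- same
  shifted$RED$spearman_rho <- pmin(1, shifted$RED$spearman_rho + 0.5)
  cmp2 <- compare_color_groups(shifted)
  expect_lt(cmp2$spearman$kruskal_p, 0.005)
  flagged <- cmp2$spearman$pairwise[cmp2$spearman$pairwise$significant, ]
  expect_true(all(grepl("RED", paste(flagged$group1, flagged$group2))))

  # identical values across groups: no between-group variation, p = 1
  ident <- list(GREEN = data.frame(pearson_r = rep(0.5, 5),
                                   spearman_rho = rep(0.5, 5)),
                RED = data.frame(pearson_r = rep(0.5, 5),
                                 spearman_rho = rep(0.5, 5)))
  cmp3 <- suppressWarnings(compare_color_groups(ident))
  expect_equal(cmp3$spearman$kruskal_p, 1)
  expect_error(compare_color_groups(list(GREEN = base(5))), "at least 2")
})

test_that("quality-vs-strength contingency yields Friedman p and Kendall W", {
  prof <- probeset_quality_profile(rbind(
    do.call(rbind, lapply(sprintf("g%d", 1:10), make_probes)),
    do.call(rbind, lapply(sprintf("r%d", 1:10), make_probes, cross = TRUE))))
  # identical composition in every bin: one green pair + one red pair per bin
  rec <- make_records(
    r = rep(0.5, 10),
    rho = rep(c(0.1, 0.4, 0.6, 0.8, 0.95), each = 2),
    probeset_a = c("g1", "r1", "g2", "r2", "g3", "r3", "g4", "r4", "g5", "r5"),
    probeset_b = c("g6", "r6", "g7", "r7", "g8", "r8", "g9", "r9",
                   "g10", "r10"))
  qs <- quality_vs_strength(rec, prof)
  expect_equal(qs$kendall_w, 1)
  expect_gt(qs$friedman_p, 0.99)
  expect_equal(dim(qs$composition), c(5L, 4L))
  expect_equal(unname(rowSums(qs$composition)), rep(4, 5))

  # reversed colour ranking in half the bins destroys concordance
  rec_rev <- make_records(
    r = rep(0.5, 6),
    rho = c(0.1, 0.1, 0.1, 0.95, 0.95, 0.95),
    probeset_a = c("g1", "g2", "g3", "r1", "r2", "r3"),
    probeset_b = c("g4", "g5", "g6", "r4", "r5", "r6"))
  expect_warning(qs_rev <- quality_vs_strength(rec_rev, prof),
                 "empty")
  expect_lt(qs_rev$kendall_w, 1)

  expect_error(suppressWarnings(quality_vs_strength(
    make_records(0.5, 0.95, probeset_a = "g1", probeset_b = "g2"), prof)),
    "2 occupied bins")
})
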