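# Shared fixture builders; everything is constructed in code.

# annotation data.frame in the chip dialect
make_annotation <- function(ids, symbols) {
  data.frame(`Probe Set ID` = ids, `Gene Symbol` = symbols,
             check.names = FALSE, stringsAsFactors = FALSE)
}

# probe table with uniform flags for one probeset
make_probes <- function(probeset_id, n = 11L, mismatches = 0L,
                        cross = FALSE, noncoding = FALSE) {
  data.frame(probe_id = sprintf("%s_%d", probeset_id, seq_len(n)),
             probeset_id = probeset_id,
             target_mismatches = rep_len(mismatches, n),
             cross_gene_hit = as.integer(rep_len(cross, n)),
             noncoding_perfect_hit = as.integer(rep_len(noncoding, n)),
             stringsAsFactors = FALSE)
}

# minimal pair-record table for the summary/regression/bin operations
make_records <- function(r, rho, mean_a = NULL, mean_b = NULL,
                         cv_a = NULL, cv_b = NULL,
                         probeset_a = NULL, probeset_b = NULL) {
  n <- length(r)
  data.frame(
    group_id = sprintf("G%04d", seq_len(n)),
    probeset_a = probeset_a %||% sprintf("psA%04d", seq_len(n)),
    probeset_b = probeset_b %||% sprintf("psB%04d", seq_len(n)),
    pearson_r = r, spearman_rho = rho,
    mean_a = mean_a %||% rep(100, n), mean_b = mean_b %||% rep(100, n),
    cv_a = cv_a %||% rep(0.5, n), cv_b = cv_b %||% rep(0.5, n),
    category = classify_pair(r, rho),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Spearman rho by the classical sum-of-squared-rank-differences closed form;
# valid for distinct values (no ties) -- the independent oracle.
spearman_d2 <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# tiny reference dataset reused across fit/pipeline tests
small_panel <- function(n = 8L) {
  default_archetype_panel(n)
}
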