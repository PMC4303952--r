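# Probe cross-hybridisation quality classes.
#
# Each 25-mer probe is classified from precomputed alignment evidence into
# one of four classes: green (unique perfect match to its target), yellow
# (perfect target match plus a perfect hit in a non-coding region), red
# (perfect target match and a perfect-or-one-mismatch hit to another gene)
# and black (at least one mismatch to the target).  Probeset-level quality
# is the colour composition of the member probes.

PROBE_COLORS <- c("GREEN", "YELLOW", "RED", "BLACK")
QUALITY_CLASSES <- c(PROBE_COLORS, "MIXED")

#' Classify probes into colour quality classes
#'
#' Vectorised over probes.  Precedence when flags conflict is
#' BLACK > RED > YELLOW > GREEN: black is defined solely by a target
#' mismatch, so it dominates; a cross-gene hit dominates a non-coding hit.
#'
#' @param target_mismatches integer, mismatches in the best alignment to the
#'   target gene (0-25).
#' @param cross_gene_hit logical (or 0/1), perfect-or-one-mismatch alignment
#'   to at least one other gene.
#' @param noncoding_perfect_hit logical (or 0/1), perfect alignment to a
#'   non-coding region.
#' @return factor with levels `GREEN`, `YELLOW`, `RED`, `BLACK`.
#' @examples
#' classify_probe(0, FALSE, FALSE)  # GREEN
#' classify_probe(5, FALSE, FALSE)  # BLACK: 20/25 nt match
#' @export
classify_probe <- function(target_mismatches, cross_gene_hit,
                           noncoding_perfect_hit) {
  if (any(target_mismatches < 0 | target_mismatches > 25)) {
    stop("target_mismatches must lie in 0..25")
  }
  cross <- as.logical(cross_gene_hit)
  nc <- as.logical(noncoding_perfect_hit)
  color <- rep("GREEN", length(target_mismatches))
  color[nc] <- "YELLOW"
  color[cross] <- "RED"
  color[target_mismatches >= 1L] <- "BLACK"
  factor(color, levels = PROBE_COLORS)
}

#' Probeset quality profiles from a probe alignment table
#'
#' Aggregates per-probe colours to a per-probeset colour composition.  The
#' quality class is a pure colour iff the composition is unanimous,
#' otherwise `MIXED`.
#'
#' @param probe_table data.frame with columns `probe_id`, `probeset_id`,
#'   `target_mismatches`, `cross_gene_hit`, `noncoding_perfect_hit`
#'   (the `probes.tsv` dialect, flags as 0/1 or logical).
#' @param probesets optional character vector of probesets that must be
#'   present; a requested probeset with no probes is an error naming it.
#' @return data.frame with one row per probeset: `probeset_id`, fractions
#'   `frac_green`, `frac_yellow`, `frac_red`, `frac_black` (summing to 1),
#'   `n_probes` and `quality_class`.
#' @export
probeset_quality_profile <- function(probe_table, probesets = NULL) {
  required <- c("probeset_id", "target_mismatches", "cross_gene_hit",
                "noncoding_perfect_hit")
  missing_cols <- setdiff(required, names(probe_table))
  if (length(missing_cols)) {
    stop("probe table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.null(probesets)) {
    absent <- setdiff(probesets, probe_table$probeset_id)
    if (length(absent)) {
      stop("no probes found for probeset(s): ", paste(absent, collapse = ", "))
    }
  }
  color <- classify_probe(probe_table$target_mismatches,
                          probe_table$cross_gene_hit,
                          probe_table$noncoding_perfect_hit)
  counts <- table(probe_table$probeset_id, color)
  n <- rowSums(counts)
  frac <- counts / n
  pure <- PROBE_COLORS[apply(frac == 1, 1, function(z) {
    w <- which(z)
    if (length(w) == 1L) w else NA_integer_
  })]
  out <- data.frame(
    probeset_id = rownames(counts),
    frac_green = as.numeric(frac[, "GREEN"]),
    frac_yellow = as.numeric(frac[, "YELLOW"]),
    frac_red = as.numeric(frac[, "RED"]),
    frac_black = as.numeric(frac[, "BLACK"]),
    n_probes = as.integer(n),
    quality_class = factor(ifelse(is.na(pure), "MIXED", pure),
                           levels = QUALITY_CLASSES),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

modal_color <- function(profile_row) {
  fr <- as.numeric(profile_row[c("frac_green", "frac_yellow",
                                 "frac_red", "frac_black")])
  PROBE_COLORS[which.max(fr)]
}

#' Select probeset pairs of matching probe quality
#'
#' A pair enters a colour bucket iff both probesets carry the same quality.
#' Under the default strict rule the shared quality must be a *pure* colour
#' (every probe of both probesets that colour); `MIXED` probesets are
#' excluded even when their compositions coincide.  The `"majority"` rule
#' relaxes this to the modal colour of each probeset.
#'
#' @param pairs data.frame of probeset pairs (`probeset_a`, `probeset_b`),
#'   as produced by [select_two_probeset_groups()].
#' @param profiles output of [probeset_quality_profile()] covering every
#'   probeset in `pairs`.
#' @param rule `"strict"` (unanimous colour, default) or `"majority"`.
#' @return named list, one element per colour (`GREEN`, `YELLOW`, `RED`,
#'   `BLACK`) holding the selected subset of `pairs` (possibly zero rows).
#' @export
select_same_quality_pairs <- function(pairs, profiles,
                                      rule = c("strict", "majority")) {
  rule <- match.arg(rule)
  needed <- unique(c(pairs$probeset_a, pairs$probeset_b))
  absent <- setdiff(needed, profiles$probeset_id)
  if (length(absent)) {
    stop("quality profiles missing for probeset(s): ",
         paste(utils::head(absent, 5L), collapse = ", "))
  }
  rownames(profiles) <- profiles$probeset_id
  color_of <- function(ids) {
    if (rule == "strict") {
      as.character(profiles[ids, "quality_class"])
    } else {
      apply(profiles[ids, , drop = FALSE], 1, modal_color)
    }
  }
  ca <- color_of(pairs$probeset_a)
  cb <- color_of(pairs$probeset_b)
  same <- ca == cb & ca %in% PROBE_COLORS
  out <- lapply(PROBE_COLORS, function(col) {
    pairs[same & ca == col, , drop = FALSE]
  })
  names(out) <- PROBE_COLORS
  out
}
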