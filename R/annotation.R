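# Gene-group reannotation of chip probeset annotations.
#
# Affymetrix-style annotation tables map each probeset to one or more gene
# symbols, multi-gene cells using the " /// " separator.  Reannotation is a
# two-step procedure: probesets with identical symbol sets are grouped, then
# any group whose gene set is contained in a multi-gene group's set is merged
# into it (C///D "absorbs" C and D).  Genes finally covered by exactly two
# probesets form the analysis universe.

#' Parse a probeset annotation table
#'
#' Reads a chip annotation file (CSV or TSV) and returns one record per
#' probeset with its parsed gene-symbol set.  Multi-gene cells are split on
#' the `"///"` separator with surrounding whitespace stripped.  Empty cells
#' and the `"---"` placeholder mark a probeset as unannotated; unannotated
#' probesets (including `AFFX-` control probes, which carry no symbol) are
#' retained in the output but flagged, and are excluded from grouping.
#'
#' @param file path to a delimited text file with a header row, or a
#'   `data.frame` already holding the two required columns.
#' @param id_col,symbol_col names of the probeset-identifier and gene-symbol
#'   columns. Defaults follow the Affymetrix convention.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line of a file input.
#' @return a `data.frame` with columns `probeset_id` (character),
#'   `symbols` (list of character vectors, canonically sorted and unique)
#'   and `unannotated` (logical).
#' @examples
#' ann <- parse_probeset_annotation(data.frame(
#'   "Probe Set ID" = c("209544_at", "217225_x_at", "AFFX-1_at"),
#'   "Gene Symbol"  = c("RIPK2", "NOMO1 /// NOMO2 /// NOMO3", "---"),
#'   check.names = FALSE))
#' ann$symbols[[2]]
#' @export
parse_probeset_annotation <- function(file,
                                      id_col = "Probe Set ID",
                                      symbol_col = "Gene Symbol",
                                      sep = NULL) {
  if (is.data.frame(file)) {
    tab <- file
  } else {
    if (is.null(sep)) {
      header <- readLines(file, n = 1L)
      sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0)
        "\t" else ","
    }
    tab <- utils::read.table(file, header = TRUE, sep = sep, quote = "\"",
                             check.names = FALSE, stringsAsFactors = FALSE,
                             comment.char = "")
  }
  for (col in c(id_col, symbol_col)) {
    if (!col %in% names(tab)) {
      stop("annotation table is missing required column '", col, "'")
    }
  }
  ids <- as.character(tab[[id_col]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate probeset_id in annotation: ",
         paste(unique(dup), collapse = ", "))
  }
  raw <- as.character(tab[[symbol_col]])
  symbols <- lapply(raw, function(cell) {
    if (is.na(cell)) return(character(0))
    parts <- trimws(strsplit(cell, "///", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts) & parts != "---"]
    sort(unique(parts))
  })
  data.frame(
    probeset_id = ids,
    symbols = I(symbols),
    unannotated = lengths(symbols) == 0L,
    stringsAsFactors = FALSE
  )
}

group_label <- function(genes) paste(sort(genes), collapse = " /// ")

new_gene_group <- function(genes, probesets, differentiating = NULL) {
  genes <- sort(unique(genes))
  g <- list(group_id = group_label(genes),
            genes = genes,
            probesets = sort(unique(probesets)),
            differentiating_counts = differentiating)
  class(g) <- "gene_group"
  g
}

#' @export
print.gene_group <- function(x, ...) {
  cat("gene group '", x$group_id, "': ", length(x$probesets),
      " probeset(s)\n", sep = "")
  invisible(x)
}

#' Form primary gene groups
#'
#' First reannotation step: probesets with identical gene-symbol sets are
#' pooled into one group, labelled by the canonical `"///"`-join of the
#' sorted symbols (so `C///D` and `D///C` are the same group).  Unannotated
#' probesets are skipped.
#'
#' @param annotations output of [parse_probeset_annotation()].
#' @return list of gene-group objects (`group_id`, `genes`, `probesets`).
#' @export
form_primary_groups <- function(annotations) {
  keep <- !annotations$unannotated
  ids <- annotations$probeset_id[keep]
  keys <- vapply(annotations$symbols[keep], group_label, character(1))
  split_ids <- split(ids, keys)
  groups <- lapply(names(split_ids), function(k) {
    genes <- strsplit(k, " /// ", fixed = TRUE)[[1]]
    new_gene_group(genes, split_ids[[k]])
  })
  groups[order(vapply(groups, `[[`, character(1), "group_id"))]
}

#' Merge gene groups under the multi-gene absorption rule
#'
#' Second reannotation step: any group whose gene set is a subset of a
#' multi-gene group's set is merged into it, pooling probesets, until a
#' fixed point (C///D absorbs C and D).  Per-probeset annotations are never
#' rewritten; the group records, per member gene, how many probesets are
#' *differentiating* -- annotated to that gene alone.
#'
#' Multi-gene groups that overlap without being nested (such as `{C,D}` and
#' `{D,E}`) are merged transitively into one group (`{C,D,E}`) with a
#' warning: any non-transitive rule would place a probeset in two groups and
#' break the partition invariant.
#'
#' @param primary_groups list of groups from [form_primary_groups()].
#' @return list of merged gene-group objects with `differentiating_counts`.
#' @export
merge_gene_groups <- function(primary_groups) {
  n <- length(primary_groups)
  if (n == 0L) return(list())
  gene_sets <- lapply(primary_groups, `[[`, "genes")

  # union-find over groups linked by any shared gene symbol
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  gene_index <- split(rep(seq_len(n), lengths(gene_sets)), unlist(gene_sets))
  for (members in gene_index) {
    if (length(members) > 1L) {
      r <- find(members[1L])
      for (j in members[-1L]) parent[find(j)] <- r
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))

  merged <- lapply(split(seq_len(n), comp), function(members) {
    union_genes <- sort(unique(unlist(gene_sets[members])))
    if (length(members) > 1L) {
      covered <- any(vapply(gene_sets[members],
                            function(g) setequal(g, union_genes), logical(1)))
      if (!covered) {
        warning("overlapping multi-gene groups without a containing label ",
                "merged transitively into '", group_label(union_genes), "'",
                call. = FALSE)
      }
    }
    diff_counts <- vapply(union_genes, function(g) {
      sum(vapply(members, function(i) {
        identical(gene_sets[[i]], g) *
          length(primary_groups[[i]]$probesets)
      }, numeric(1)))
    }, numeric(1))
    new_gene_group(union_genes,
                   unlist(lapply(primary_groups[members], `[[`, "probesets")),
                   differentiating = diff_counts)
  })
  names(merged) <- NULL
  merged[order(vapply(merged, `[[`, character(1), "group_id"))]
}

#' Select gene groups covered by exactly two probesets
#'
#' Emits one ordered probeset pair per two-probeset group (member ids in
#' lexicographic order) together with a composition report of group sizes,
#' the basis of the chip-composition summary.
#'
#' @param groups list of merged gene groups.
#' @return list with `pairs` (data.frame: `group_id`, `n_genes`,
#'   `probeset_a`, `probeset_b`) and `size_counts` (named integer vector,
#'   groups per probeset count).
#' @export
select_two_probeset_groups <- function(groups) {
  sizes <- vapply(groups, function(g) length(g$probesets), integer(1))
  size_counts <- table(factor(sizes, levels = sort(unique(sizes))))
  two <- groups[sizes == 2L]
  pairs <- data.frame(
    group_id = vapply(two, `[[`, character(1), "group_id"),
    n_genes = vapply(two, function(g) length(g$genes), integer(1)),
    probeset_a = vapply(two, function(g) g$probesets[1L], character(1)),
    probeset_b = vapply(two, function(g) g$probesets[2L], character(1)),
    stringsAsFactors = FALSE
  )
  list(pairs = pairs,
       size_counts = stats::setNames(as.integer(size_counts),
                                     names(size_counts)))
}

# flatten groups to a TSV-ready table
gene_groups_table <- function(groups) {
  data.frame(
    group_id = vapply(groups, `[[`, character(1), "group_id"),
    genes = vapply(groups, function(g) paste(g$genes, collapse = ";"),
                   character(1)),
    probesets = vapply(groups, function(g) paste(g$probesets, collapse = ";"),
                       character(1)),
    n_probesets = vapply(groups, function(g) length(g$probesets), integer(1)),
    differentiating_counts = vapply(groups, function(g) {
      d <- g$differentiating_counts
      if (is.null(d)) "" else paste(names(d), d, sep = ":", collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}
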