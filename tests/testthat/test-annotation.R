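test_that("annotation parsing splits multi-gene cells and flags placeholders", {
  ann <- parse_probeset_annotation(make_annotation(
    c("209544_at", "217225_x_at", "AFFX-control_at", "1_at"),
    c("RIPK2", "NOMO1 /// NOMO2 /// NOMO3", "---", " XPO7 ")))
  expect_equal(ann$symbols[[1]], "RIPK2")
  expect_equal(ann$symbols[[2]], c("NOMO1", "NOMO2", "NOMO3"))
  expect_true(ann$unannotated[3])
  expect_equal(ann$symbols[[4]], "XPO7")  # whitespace stripped
  expect_equal(sum(ann$unannotated), 1L)
})

test_that("parsing reads CSV and TSV files and enforces the hard errors", {
  tab <- make_annotation(c("a_at", "b_at"), c("G1", "G1 /// G2"))
  csv <- tempfile(fileext = ".csv")
  write.csv(tab, csv, row.names = FALSE)
  tsv <- tempfile(fileext = ".tsv")
  write.table(tab, tsv, sep = "\t", row.names = FALSE)
  expect_equal(parse_probeset_annotation(csv)$symbols[[2]], c("G1", "G2"))
  expect_equal(parse_probeset_annotation(tsv)$probeset_id, c("a_at", "b_at"))

  expect_error(parse_probeset_annotation(
    make_annotation(c("a_at", "a_at"), c("G1", "G2"))), "duplicate")
  expect_error(parse_probeset_annotation(
    data.frame(x = 1)), "Probe Set ID")
})

test_that("primary grouping pools identical symbol sets under canonical labels", {
  ann <- parse_probeset_annotation(make_annotation(
    c("ps1", "ps2", "ps3", "ps4", "ps7"),
    c("A", "B", "B", "C /// D", "D /// C")))
  groups <- form_primary_groups(ann)
  ids <- vapply(groups, `[[`, character(1), "group_id")
  expect_setequal(ids, c("A", "B", "C /// D"))
  expect_equal(groups[[which(ids == "B")]]$probesets, c("ps2", "ps3"))
  # D///C and C///D are the same canonical group
  expect_equal(groups[[which(ids == "C /// D")]]$probesets, c("ps4", "ps7"))
  expect_length(form_primary_groups(ann[0, ]), 0L)
})

test_that("multi-gene groups absorb their member genes with differentiating counts", {
  ann <- parse_probeset_annotation(make_annotation(
    c("ps4", "ps5", "ps6"), c("C /// D", "C", "D")))
  merged <- merge_gene_groups(form_primary_groups(ann))
  expect_length(merged, 1L)
  expect_equal(merged[[1]]$group_id, "C /// D")
  expect_equal(merged[[1]]$probesets, c("ps4", "ps5", "ps6"))
  expect_equal(merged[[1]]$differentiating_counts, c(C = 1, D = 1))

  # no multi-gene label present: merging is a no-op
  ann2 <- parse_probeset_annotation(make_annotation(
    c("ps1", "ps2", "ps3"), c("A", "B", "B")))
  merged2 <- merge_gene_groups(form_primary_groups(ann2))
  expect_setequal(vapply(merged2, `[[`, character(1), "group_id"),
                  c("A", "B"))
})

test_that("merging is idempotent and order-independent", {
  ann <- parse_probeset_annotation(make_annotation(
    sprintf("ps%d", 1:7),
    c("A", "B", "B", "C /// D", "C", "D", "E /// F")))
  primary <- form_primary_groups(ann)
  once <- merge_gene_groups(primary)
  twice <- merge_gene_groups(once)
  expect_equal(vapply(once, `[[`, character(1), "group_id"),
               vapply(twice, `[[`, character(1), "group_id"))

  ids_of <- function(perm) {
    g <- merge_gene_groups(primary[perm])
    list(ids = vapply(g, `[[`, character(1), "group_id"),
         ps = lapply(g, `[[`, "probesets"))
  }
  ref <- ids_of(seq_along(primary))
  set.seed(11)
  for (i in 1:10) {
    perm <- sample(seq_along(primary))
    expect_equal(ids_of(perm), ref)
  }
})

test_that("non-nested overlapping multi-gene labels merge transitively with a warning", {
  ann <- parse_probeset_annotation(make_annotation(
    c("ps1", "ps2"), c("C /// D", "D /// E")))
  expect_warning(merged <- merge_gene_groups(form_primary_groups(ann)),
                 "transitively")
  expect_length(merged, 1L)
  expect_equal(merged[[1]]$group_id, "C /// D /// E")
  expect_equal(merged[[1]]$probesets, c("ps1", "ps2"))
})

test_that("gene groups partition the annotated probeset universe", {
  set.seed(3)
  n <- 150
  syms <- c(sprintf("G%02d", sample(40, n, replace = TRUE)))
  multi <- sample(n, 15)
  syms[multi] <- paste(syms[multi], "///",
                       sprintf("G%02d", sample(40, 15, replace = TRUE)))
  ann <- parse_probeset_annotation(
    make_annotation(sprintf("ps%03d", seq_len(n)), syms))
  merged <- suppressWarnings(merge_gene_groups(form_primary_groups(ann)))
  all_ps <- unlist(lapply(merged, `[[`, "probesets"))
  expect_equal(sort(all_ps), sort(ann$probeset_id[!ann$unannotated]))
  expect_false(any(duplicated(all_ps)))
  # every probeset's annotated symbols are contained in its group's genes
  sym_of <- setNames(ann$symbols, ann$probeset_id)
  for (g in merged) {
    for (ps in g$probesets) expect_true(all(sym_of[[ps]] %in% g$genes))
  }
})

test_that("two-probeset selection emits ordered pairs and a size census", {
  ann <- parse_probeset_annotation(make_annotation(
    sprintf("ps%d", 1:7),
    c("A", "A", "B", "B", "B", "C", "D /// E")))
  sel <- select_two_probeset_groups(
    merge_gene_groups(form_primary_groups(ann)))
  expect_equal(sel$pairs$group_id, "A")
  expect_true(all(sel$pairs$probeset_a < sel$pairs$probeset_b))
  expect_equal(sel$size_counts, c("1" = 2L, "2" = 1L, "3" = 1L))
  # a three-probeset group (B) is excluded
  expect_false("B" %in% sel$pairs$group_id)
  # selected pairs involve exactly 2 x n_pairs distinct probesets
  expect_equal(length(unique(c(sel$pairs$probeset_a, sel$pairs$probeset_b))),
               2L * nrow(sel$pairs))
})
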