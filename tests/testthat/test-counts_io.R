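test_that("count matrix TSV parsing preserves values and order", {
  path <- write_tsv_lines(c("gene_id\ts1\ts2", "gA\t2\t4", "gB\t4\t8"))
  cm <- read_count_matrix(path)
  expect_identical(cm$gene_ids, c("gA", "gB"))
  expect_identical(cm$sample_ids, c("s1", "s2"))
  expect_equal(unname(cm$values), matrix(c(2, 4, 4, 8), 2, byrow = TRUE))
  expect_false(cm$normalized)

  # unnamed first-column header is tolerated
  path2 <- write_tsv_lines(c("s1\ts2", "gA\t2\t4", "gB\t4\t8"))
  cm2 <- read_count_matrix(path2)
  expect_identical(cm2$sample_ids, c("s1", "s2"))
  expect_equal(cm2$values, cm$values, ignore_attr = TRUE)
})

test_that("malformed count matrices are rejected with the right error", {
  dup_sample <- write_tsv_lines(c("gene_id\ts1\ts1", "gA\t1\t2", "gB\t3\t4"))
  expect_error(read_count_matrix(dup_sample), "duplicate sample identifier")
  dup_gene <- write_tsv_lines(c("gene_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"))
  expect_error(read_count_matrix(dup_gene), "duplicate gene identifier")
  negative <- write_tsv_lines(c("gene_id\ts1\ts2", "gA\t1\t-3", "gB\t3\t4"))
  expect_error(read_count_matrix(negative), "negative")
  non_numeric <- write_tsv_lines(c("gene_id\ts1\ts2", "gA\t1\tx", "gB\t3\t4"))
  expect_error(read_count_matrix(non_numeric), "non-numeric")
  empty <- write_tsv_lines("gene_id\ts1\ts2")
  expect_error(read_count_matrix(empty), "empty")
})

test_that("count matrix write/read round-trips identifiers and values", {
  set.seed(7)
  vals <- matrix(round(rexp(60, 0.01), 3), 10, 6)
  cm <- count_matrix(vals, gene_ids = sprintf("FBgn%04d", 1:10),
                     sample_ids = sprintf("s%d", 1:6))
  path <- tempfile(fileext = ".tsv")
  write_count_matrix(cm, path)
  back <- read_count_matrix(path)
  expect_identical(back$gene_ids, cm$gene_ids)
  expect_identical(back$sample_ids, cm$sample_ids)
  expect_equal(back$values, cm$values)
})

test_that("sample table validation enforces the design contract", {
  # the study design at day 20: 2 control replicates + 15 irradiated samples
  df <- expand.grid(replicate = 1:3,
                    dose_roentgen = c(0, 10, 1000, 5000, 10000, 20000))
  df$timepoint_days <- 20
  df$sample_id <- sprintf("s%02d", seq_len(nrow(df)))
  df <- df[!(df$dose_roentgen == 0 & df$replicate == 3), ]
  st <- sample_table(df)
  expect_equal(nrow(st), 17)
  census <- condition_census(st)
  expect_equal(census$n_samples[census$dose_roentgen == 0], 2)
  expect_true(all(census$n_samples[census$dose_roentgen > 0] == 3))

  # a timepoint without its dose-0 control is a design error
  expect_error(sample_table(df[df$dose_roentgen > 0, ]), "dose-0")
  # non-numeric replicate index is a value error
  bad <- df
  bad$replicate[1] <- "a"
  expect_error(sample_table(bad), "non-numeric")
  # duplicated sample id
  dup <- df
  dup$sample_id[2] <- dup$sample_id[1]
  expect_error(sample_table(dup), "duplicate")
})

test_that("sample table TSV reader and design cross-check work together", {
  path <- write_tsv_lines(c(
    "sample_id\ttimepoint_days\tdose_roentgen\treplicate",
    "s1\t2\t0\t1", "s2\t2\t0\t2", "s3\t2\t1000\t1"))
  st <- read_sample_table(path)
  expect_equal(nrow(st), 3)
  cm <- count_matrix(matrix(1:6, 2, dimnames = list(c("gA", "gB"),
                                                    c("s1", "s2", "s3"))))
  expect_true(check_design(cm, st))
  cm2 <- count_matrix(matrix(1:4, 2, dimnames = list(c("gA", "gB"),
                                                     c("s1", "s2"))))
  expect_error(check_design(cm2, st), "consistency error")
})

test_that("result tables and overlap summary reproduce set arithmetic", {
  res <- bare_result(list("2" = c("A", "B"), "10" = c("B", "C"),
                          "20" = "B"))
  out <- tempfile()
  files <- write_result_tables(res, out)
  expect_true(all(file.exists(files)))
  ov <- read.delim(file.path(out, "linear_overlaps.tsv"))
  get <- function(lab) ov$n_intersection[ov$subset == lab]
  expect_equal(get("d2"), 2)
  expect_equal(get("d10"), 2)
  expect_equal(get("d20"), 1)
  expect_equal(get("d2&d10"), 1)
  expect_equal(get("d2&d20"), 1)
  expect_equal(get("d10&d20"), 1)
  expect_equal(get("d2&d10&d20"), 1)
  expect_equal(ov$genes[ov$subset == "d2&d10&d20"], "B")
  # exclusive regions: A only at d2, C only at d10, B in all three
  expect_equal(ov$n_exclusive[ov$subset == "d2"], 1)
  expect_equal(ov$n_exclusive[ov$subset == "d2&d10&d20"], 1)
  expect_equal(ov$n_exclusive[ov$subset == "d2&d10"], 0)
})

test_that("empty and single-timepoint results write valid degenerate tables", {
  res <- bare_result(list("2" = character(0), "10" = character(0),
                          "20" = character(0)))
  out <- tempfile()
  write_result_tables(res, out)
  sets <- read.delim(file.path(out, "linear_sets.tsv"))
  expect_equal(nrow(sets), 0)
  ov <- read.delim(file.path(out, "linear_overlaps.tsv"))
  expect_true(all(ov$n_intersection == 0))

  solo <- bare_result(list("2" = c("A", "B")))
  out2 <- tempfile()
  write_result_tables(solo, out2)
  ov2 <- read.delim(file.path(out2, "linear_overlaps.tsv"))
  expect_equal(ov2$subset, "d2")   # no pairwise rows for a single timepoint
})
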