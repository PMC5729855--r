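doses5 <- c(10, 1000, 5000, 10000, 20000)

test_that("condition means average the replicates that are present", {
  vals <- rbind(c(10, 20, 30, 5, 7), c(2, 4, 6, 1, 1))
  cm <- count_matrix(vals, gene_ids = c("gA", "gB"),
                     sample_ids = paste0("s", 1:5), normalized = TRUE)
  st <- sample_table(data.frame(
    sample_id = paste0("s", 1:5),
    timepoint_days = 2,
    dose_roentgen = c(0, 0, 0, 1000, 1000),
    replicate = c(1, 2, 3, 1, 2)))
  mt <- condition_means(cm, st)
  g <- function(gene, dose) mt$mean_expression[mt$gene_id == gene &
                                                 mt$dose_roentgen == dose]
  expect_equal(g("gA", 0), 20)      # (10, 20, 30)
  expect_equal(g("gA", 1000), 6)    # two replicates: (5, 7)
  expect_equal(g("gB", 0), 4)
  expect_equal(mt$n_replicates[mt$dose_roentgen == 1000][1], 2)
})

test_that("presence cutoff is the interpolated quantile of condition means", {
  mt <- make_mean_table(list(gA = c("0" = 10, "10" = 20),
                             gB = c("0" = 30, "10" = 40)))
  expect_equal(presence_cutoff(mt, 2, 0.25)$cutoff, 17.5)
  expect_equal(presence_cutoff(mt, 2, 0)$cutoff, 10)       # minimum
  const <- make_mean_table(list(gA = c("0" = 5, "10" = 5),
                                gB = c("0" = 5, "10" = 5)))
  expect_equal(presence_cutoff(const, 2, 0.25)$cutoff, 5)
  expect_error(presence_cutoff(mt, 99), "no mean-expression")
})

test_that("fold-change statuses implement the present/absent contract", {
  mt <- make_mean_table(list(
    pass = c("0" = 20, "1000" = 40),     # defined: 40 / 20 = 2
    low  = c("0" = 12, "1000" = 10),     # both below cutoff -> absent
    zctl = c("0" = 0,  "1000" = 30),     # zero control, exp over cutoff
    half = c("0" = 10, "1000" = 25)))    # control below, exp above: defined
  cutoff <- data.frame(timepoint_days = 2, cutoff = 18)
  fc <- fold_change_table(mt, cutoff)
  row <- function(g) fc[fc$gene_id == g, ]
  expect_equal(row("pass")$fold_change, 2)
  expect_equal(row("pass")$status, "defined")
  expect_equal(row("low")$status, "absent_below_cutoff")
  expect_true(is.na(row("low")$fold_change))
  expect_equal(row("zctl")$status, "undefined_zero_control")
  expect_equal(row("half")$fold_change, 2.5)
  expect_equal(row("half")$status, "defined")
})

test_that("linear_r2 matches hand-checked cases", {
  exact <- linear_r2(doses5, 1 + 1e-4 * doses5)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  expect_equal(exact$slope, 1e-4, tolerance = 1e-12)
  expect_equal(exact$intercept, 1, tolerance = 1e-9)

  wk <- linear_r2(c(1000, 5000, 10000, 20000), c(1.0, 1.1, 1.4, 2.2))
  # frozen from the lm()/normal-equations oracle
  expect_equal(wk$r_squared, 0.9719147, tolerance = 1e-7)
  expect_equal(wk$r_squared, oracle_r2(c(1000, 5000, 10000, 20000),
                                       c(1.0, 1.1, 1.4, 2.2))$r_squared,
               tolerance = 1e-12)

  expect_true(is.na(linear_r2(doses5[1:4], rep(2, 4))$r_squared))
  expect_equal(linear_r2(doses5[1], 1)$status, "insufficient_data")
})

test_that("R-squared is affine-invariant and bounded in [0, 1]", {
  set.seed(31)
  for (i in 1:50) {
    y <- rnorm(5, 1, 0.3)
    base <- linear_r2(doses5, y)$r_squared
    expect_gte(base, 0); expect_lte(base, 1)
    for (ab in list(c(3, 0), c(-2, 5), c(0.1, -1))) {
      expect_equal(linear_r2(doses5, ab[1] * y + ab[2])$r_squared, base,
                   tolerance = 1e-9)
    }
  }
})

test_that("linear screen applies the dose-count gate and strict threshold", {
  fc <- make_fc_table(list(
    perfect5 = setNames(1 + 1e-4 * doses5, doses5),
    perfect3 = setNames(c(1.001, 1.1, 1.5, NA, NA), doses5),
    noisy    = setNames(c(1.0, 0.8, 1.9, 1.7, 3.1), doses5),
    flat     = setNames(rep(2, 5), doses5)))
  res <- select_linear_genes(fc)
  expect_identical(res$sets[["2"]], "perfect5")   # only the full-dose line
  st <- res$stats
  expect_equal(st$n_doses_used[st$gene_id == "perfect3"], 3)
  expect_false(st$selected[st$gene_id == "perfect3"])  # perfect but 3 doses
  expect_true(is.na(st$r_squared[st$gene_id == "flat"]))

  # strict inequality at the boundary: r2_min equal to the gene's own R^2
  r2_noisy <- st$r_squared[st$gene_id == "noisy"]
  at <- select_linear_genes(fc, r2_min = r2_noisy, min_doses = 4)
  below <- select_linear_genes(fc, r2_min = r2_noisy - 1e-9, min_doses = 4)
  expect_false("noisy" %in% at$sets[["2"]])
  expect_true("noisy" %in% below$sets[["2"]])
})

test_that("screen agrees with per-gene linear_r2 on the same points", {
  set.seed(17)
  fcs <- lapply(1:30, function(i) setNames(rlnorm(5, 0, 0.5), doses5))
  names(fcs) <- paste0("g", 1:30)
  res <- select_linear_genes(make_fc_table(fcs), min_doses = 2)
  for (g in names(fcs)) {
    ref <- linear_r2(doses5, fcs[[g]])
    row <- res$stats[res$stats$gene_id == g, ]
    expect_equal(row$r_squared, ref$r_squared, tolerance = 1e-10)
    expect_equal(row$slope, ref$slope, tolerance = 1e-10)
    expect_equal(row$intercept, ref$intercept, tolerance = 1e-8)
  }
})

test_that("raising r2_min never adds a selected gene (monotonicity)", {
  set.seed(41)
  fcs <- lapply(1:60, function(i)
    setNames(1 + 5e-5 * doses5 + rnorm(5, 0, 0.25), doses5))
  names(fcs) <- paste0("g", 1:60)
  fc <- make_fc_table(fcs)
  prev <- NULL
  for (thr in c(0.5, 0.7, 0.9, 0.95, 0.99)) {
    cur <- select_linear_genes(fc, r2_min = thr)$sets[["2"]]
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("excluding the lowest dose leaves exactly the four high doses", {
  fcs <- list(gA = setNames(1 + 1e-4 * doses5, doses5),
              gB = setNames(c(5, 1.1, 1.4, 1.9, 2.9), doses5))
  res <- select_linear_genes(make_fc_table(fcs), exclude_doses = 10)
  expect_true(all(res$stats$n_doses_used == 4))
  expect_equal(res$label, "excluding-10R")
  # gB's outlier at 10 R no longer hurts: selected without it
  expect_true("gB" %in% res$sets[["2"]])
  expect_false("gB" %in% select_linear_genes(make_fc_table(fcs))$sets[["2"]])
  expect_error(select_linear_genes(make_fc_table(fcs),
                                   exclude_doses = doses5), "design error")
})

test_that("overlap sets compute intersections and exclusive regions", {
  sets <- list("2" = c("A", "B"), "10" = c("B", "C"), "20" = "B")
  ov <- overlap_sets(sets)
  expect_identical(ov[["d2&d10&d20"]]$intersection, "B")
  expect_identical(sort(ov[["d2"]]$intersection), c("A", "B"))
  expect_identical(ov[["d2"]]$exclusive, "A")
  # disjoint sets: every multi-way intersection empty
  dis <- overlap_sets(list("2" = "A", "10" = "B", "20" = "C"))
  expect_length(dis[["d2&d10"]]$intersection, 0)
  # identical sets: every intersection equals the set
  same <- overlap_sets(list("2" = c("X", "Y"), "10" = c("X", "Y")))
  expect_identical(sort(same[["d2&d10"]]$intersection), c("X", "Y"))
  # nesting invariant: triple within every pairwise within every single
  expect_true(all(ov[["d2&d10&d20"]]$intersection %in%
                    ov[["d2&d10"]]$intersection))
  expect_true(all(ov[["d2&d10"]]$intersection %in% ov[["d2"]]$intersection))
})
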