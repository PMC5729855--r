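# Shared fixture builders; everything is generated in code at test time.

tiny_counts <- function(values = matrix(c(2, 4, 4, 8), 2, byrow = TRUE),
                        normalized = FALSE) {
  count_matrix(values,
               gene_ids = paste0("g", seq_len(nrow(values))),
               sample_ids = paste0("s", seq_len(ncol(values))),
               normalized = normalized)
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# a mean_table built directly from per-gene condition means:
# `means` is a named list gene_id -> named numeric vector dose -> mean
make_mean_table <- function(means, timepoint = 2) {
  rows <- do.call(rbind, lapply(names(means), function(g) {
    data.frame(gene_id = g, timepoint_days = timepoint,
               dose_roentgen = as.numeric(names(means[[g]])),
               mean_expression = unname(means[[g]]), n_replicates = 3,
               stringsAsFactors = FALSE)
  }))
  class(rows) <- c("mean_table", "data.frame")
  rows
}

# fold-change table for one or more timepoints from gene -> dose -> fc,
# bypassing means (all statuses "defined" unless fc is NA)
make_fc_table <- function(fcs, timepoint = 2) {
  rows <- do.call(rbind, lapply(names(fcs), function(g) {
    v <- fcs[[g]]
    data.frame(gene_id = g, timepoint_days = timepoint,
               dose_roentgen = as.numeric(names(v)),
               fold_change = unname(v),
               status = ifelse(is.na(v), "absent_below_cutoff", "defined"),
               stringsAsFactors = FALSE)
  }))
  class(rows) <- c("fold_change_table", "data.frame")
  rows
}

# independent brute-force median-of-ratios oracle (plain loops)
oracle_size_factors <- function(mat) {
  ref <- numeric(nrow(mat))
  for (g in seq_len(nrow(mat))) {
    ref[g] <- if (all(mat[g, ] > 0)) exp(mean(log(mat[g, ]))) else NA
  }
  sf <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    r <- mat[, j] / ref
    sf[j] <- stats::median(r[!is.na(r)])
  }
  sf / exp(mean(log(sf)))   # unit-geometric-mean convention
}

# independent OLS oracle through lm()
oracle_r2 <- function(x, y) {
  f <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(f)[2]),
       intercept = unname(stats::coef(f)[1]),
       r_squared = summary(f)$r.squared)
}

# minimal screen_result from bare per-timepoint gene sets
bare_result <- function(sets, screen = "linear") {
  stats <- data.frame(gene_id = character(0), timepoint_days = numeric(0),
                      n_doses_used = integer(0), slope = numeric(0),
                      intercept = numeric(0), r_squared = numeric(0),
                      selected = logical(0))
  structure(list(screen = screen, label = "test", stats = stats,
                 sets = sets, overlaps = overlap_sets(sets)),
            class = "screen_result")
}
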