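#' Per-condition mean expression
#'
#' Arithmetic mean of normalized expression over the replicates present for
#' each (gene, timepoint, dose) condition. Conditions with unequal replicate
#' counts (e.g. a dropped control sample) are averaged over the replicates
#' they have.
#'
#' @param counts A normalized [count_matrix].
#' @param samples A [sample_table] covering the matrix columns to use.
#' @return A `mean_table` data frame: `gene_id`, `timepoint_days`,
#'   `dose_roentgen`, `mean_expression`, `n_replicates`.
#' @export
condition_means <- function(counts, samples) {
  check_design(counts, samples)
  if (!counts$normalized) {
    warning("condition_means on a matrix not flagged as normalized")
  }
  conds <- unique(samples[c("timepoint_days", "dose_roentgen")])
  conds <- conds[order(conds$timepoint_days, conds$dose_roentgen), ]
  out <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    sel <- samples$sample_id[
      samples$timepoint_days == conds$timepoint_days[i] &
      samples$dose_roentgen == conds$dose_roentgen[i]]
    if (!length(sel)) stop("design error: condition with zero samples",
                           call. = FALSE)
    sub <- counts$values[, sel, drop = FALSE]
    out[[i]] <- data.frame(
      gene_id = counts$gene_ids,
      timepoint_days = conds$timepoint_days[i],
      dose_roentgen = conds$dose_roentgen[i],
      mean_expression = rowMeans(sub),
      n_replicates = length(sel),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  mt <- do.call(rbind, out)
  class(mt) <- c("mean_table", "data.frame")
  mt
}

#' Present/absent cutoff from the mean-expression distribution
#'
#' The detection floor of the screen: the bottom-quartile (by default)
#' threshold of the per-(gene, condition) mean expression values at one
#' timepoint. A fold change is later ignored when both the irradiated and
#' the control mean fall below this cutoff. Quantiles use the
#' linear-interpolation convention (R type 7).
#'
#' @param means A `mean_table` from [condition_means()].
#' @param timepoint Timepoint (days) to compute the cutoff for.
#' @param quantile Quantile level, default 0.25.
#' @return A one-row data frame `timepoint_days`, `cutoff`.
#' @export
presence_cutoff <- function(means, timepoint, quantile = 0.25) {
  x <- means$mean_expression[means$timepoint_days == timepoint]
  if (!length(x)) stop("no mean-expression values at timepoint ", timepoint,
                       call. = FALSE)
  data.frame(timepoint_days = timepoint,
             cutoff = unname(stats::quantile(x, quantile, type = 7)))
}

#' @rdname presence_cutoff
#' @return `presence_cutoffs`: one row per timepoint present in `means`.
#' @export
presence_cutoffs <- function(means, quantile = 0.25) {
  do.call(rbind, lapply(sort(unique(means$timepoint_days)),
                        function(tp) presence_cutoff(means, tp, quantile)))
}

#' Fold changes against the unirradiated control
#'
#' For every gene, timepoint, and dose > 0, the ratio of the condition mean
#' to the dose-0 control mean at the same timepoint. Status is one of:
#' `defined` (ratio computed), `absent_below_cutoff` (both means under the
#' presence cutoff; the fold change is ignored), or `undefined_zero_control`
#' (control mean is zero while the experimental mean clears the cutoff; the
#' ratio is infinite and the dose is treated as non-passing).
#'
#' @param means A `mean_table` from [condition_means()].
#' @param cutoffs Data frame from [presence_cutoffs()] (or a single-timepoint
#'   row from [presence_cutoff()]).
#' @return A `fold_change_table` data frame: `gene_id`, `timepoint_days`,
#'   `dose_roentgen`, `fold_change` (`NA` unless defined), `status`.
#' @export
fold_change_table <- function(means, cutoffs = presence_cutoffs(means)) {
  out <- vector("list", nrow(cutoffs))
  for (i in seq_len(nrow(cutoffs))) {
    tp <- cutoffs$timepoint_days[i]
    cut <- cutoffs$cutoff[i]
    mt <- means[means$timepoint_days == tp, ]
    ctrl <- mt[mt$dose_roentgen == 0, ]
    if (!nrow(ctrl)) stop("no dose-0 control at timepoint ", tp, call. = FALSE)
    ctrl_mean <- stats::setNames(ctrl$mean_expression, ctrl$gene_id)
    exp_rows <- mt[mt$dose_roentgen > 0, ]
    cm <- ctrl_mean[exp_rows$gene_id]
    both_below <- exp_rows$mean_expression < cut & cm < cut
    zero_ctrl <- !both_below & cm == 0
    status <- ifelse(both_below, "absent_below_cutoff",
                     ifelse(zero_ctrl, "undefined_zero_control", "defined"))
    fc <- ifelse(status == "defined", exp_rows$mean_expression / cm, NA_real_)
    out[[i]] <- data.frame(
      gene_id = exp_rows$gene_id,
      timepoint_days = tp,
      dose_roentgen = exp_rows$dose_roentgen,
      fold_change = fc,
      status = status,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  fct <- do.call(rbind, out)
  class(fct) <- c("fold_change_table", "data.frame")
  fct
}

#' Ordinary least-squares fit of fold change on dose
#'
#' Simple linear regression (with intercept) of fold change on dose, on the
#' linear roentgen scale, via the closed-form normal equations. Returns the
#' coefficient of determination R^2 = 1 - SS_resid / SS_total; R^2 is
#' undefined (`NA`) when the fold changes have zero variance, and the fit is
#' marked insufficient with fewer than two points.
#'
#' @param doses Numeric vector of doses (roentgen).
#' @param fold_changes Numeric vector of fold changes, same length.
#' @return List: `n`, `slope`, `intercept`, `r_squared`, `status`
#'   (`"ok"` or `"insufficient_data"`).
#' @examples
#' linear_r2(c(10, 1000, 5000, 10000, 20000),
#'           1 + 1e-4 * c(10, 1000, 5000, 10000, 20000))  # exact line, R^2 = 1
#' @export
linear_r2 <- function(doses, fold_changes) {
  keep <- is.finite(doses) & is.finite(fold_changes)
  x <- doses[keep]; y <- fold_changes[keep]
  n <- length(x)
  if (n < 2L) {
    return(list(n = n, slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, status = "insufficient_data"))
  }
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  syy <- sum((y - yb)^2)
  sxy <- sum((x - xb) * (y - yb))
  slope <- sxy / sxx
  # constant fold changes (to relative rounding noise) have zero total
  # variance: R^2 undefined
  constant <- (max(y) - min(y)) <= 1e-9 * max(abs(y))
  r2 <- if (constant) NA_real_ else min(sxy^2 / (sxx * syy), 1)
  list(n = n, slope = slope, intercept = yb - slope * xb,
       r_squared = r2, status = "ok")
}

# Vectorized per-gene OLS over a gene x dose fold-change matrix with an
# NA mask; centered sums, same normal equations as linear_r2. Rows whose
# defined fold changes are exactly constant get an undefined R^2.
.rowwise_ols <- function(fc_mat, doses) {
  m <- is.finite(fc_mat)
  y <- fc_mat
  y[!m] <- 0
  x <- matrix(doses, nrow = nrow(fc_mat), ncol = length(doses), byrow = TRUE)
  x[!m] <- 0
  n <- rowSums(m)
  xb <- rowSums(x) / n
  yb <- rowSums(y) / n
  xc <- (x - xb) * m
  yc <- (y - yb) * m
  sxx <- rowSums(xc^2); syy <- rowSums(yc^2); sxy <- rowSums(xc * yc)
  ylo <- fc_mat; ylo[!m] <- Inf
  yhi <- fc_mat; yhi[!m] <- -Inf
  rlo <- apply(ylo, 1L, min)
  rhi <- apply(yhi, 1L, max)
  constant <- (rhi - rlo) <= 1e-9 * pmax(abs(rhi), abs(rlo))
  slope <- ifelse(n >= 2 & sxx > 0, sxy / sxx, NA_real_)
  intercept <- ifelse(is.na(slope), NA_real_, yb - slope * xb)
  r2 <- ifelse(n >= 2 & sxx > 0 & !constant & syy > 0,
               pmin(sxy^2 / (sxx * syy), 1), NA_real_)
  data.frame(n_doses_used = n, slope = slope, intercept = intercept,
             r_squared = r2, row.names = NULL)
}

#' Select genes with a linear dose response
#'
#' The linear screen: per timepoint, a gene is selected when (a) at least
#' `min_doses` of the analyzed doses have a defined fold change (passed the
#' present/absent cutoff and a non-zero control), and (b) the R^2 of the
#' least-squares line of fold change on dose over those defined points
#' exceeds `r2_min` strictly. The dose-0 control (fold change identically 1)
#' is not a regression point. Doses in `exclude_doses` are dropped before
#' both the count gate and the fit, which is how the
#' lowest-dose-excluded secondary analysis is run.
#'
#' @param fc A `fold_change_table` from [fold_change_table()].
#' @param r2_min Strict R^2 threshold, default 0.9.
#' @param min_doses Minimum number of defined fold changes, default 4.
#' @param exclude_doses Doses (roentgen) to drop from the analysis.
#' @param label Analysis label stored in the result (defaults to
#'   `"all-doses"` or `"excluding-<doses>"`).
#' @return A `screen_result`: list with `screen = "linear"`, `label`,
#'   `stats` (per gene x timepoint fit statistics and selection flag),
#'   `sets` (selected gene ids per timepoint), and `overlaps`
#'   (see [overlap_sets()]).
#' @export
select_linear_genes <- function(fc, r2_min = 0.9, min_doses = 4,
                                exclude_doses = numeric(0), label = NULL) {
  stopifnot(inherits(fc, "data.frame"))
  fc_use <- fc[!(fc$dose_roentgen %in% exclude_doses), ]
  if (!nrow(fc_use)) stop("design error: exclude_doses removes all doses",
                          call. = FALSE)
  if (is.null(label)) {
    label <- if (!length(exclude_doses)) "all-doses" else
      paste0("excluding-", paste(sort(exclude_doses), collapse = "-"), "R")
  }
  tps <- sort(unique(fc_use$timepoint_days))
  stats_list <- vector("list", length(tps))
  sets <- stats::setNames(vector("list", length(tps)), as.character(tps))
  for (k in seq_along(tps)) {
    tp <- tps[k]
    sub <- fc_use[fc_use$timepoint_days == tp, ]
    doses <- sort(unique(sub$dose_roentgen))
    genes <- unique(sub$gene_id)
    fc_mat <- matrix(NA_real_, length(genes), length(doses),
                     dimnames = list(genes, as.character(doses)))
    fc_mat[cbind(match(sub$gene_id, genes),
                 match(sub$dose_roentgen, doses))] <- sub$fold_change
    ols <- .rowwise_ols(fc_mat, doses)
    ols$gene_id <- genes
    ols$timepoint_days <- tp
    ols$selected <- !is.na(ols$r_squared) & ols$r_squared > r2_min &
      ols$n_doses_used >= min_doses
    stats_list[[k]] <- ols[c("gene_id", "timepoint_days", "n_doses_used",
                             "slope", "intercept", "r_squared", "selected")]
    sets[[k]] <- genes[ols$selected]
  }
  stats_df <- do.call(rbind, stats_list)
  structure(list(screen = "linear", label = label,
                 r2_min = r2_min, min_doses = min_doses,
                 exclude_doses = exclude_doses,
                 stats = stats_df, sets = sets,
                 overlaps = overlap_sets(sets)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("%s screen (%s): ", x$screen, x$label))
  cat(paste(sprintf("day %s: %d", names(x$sets),
                    vapply(x$sets, length, 1L)), collapse = ", "), "\n")
  if (length(x$sets) > 1L) {
    all_lab <- paste(paste0("d", names(x$sets)), collapse = "&")
    cat(sprintf("  overlap of all timepoints: %d\n",
                length(x$overlaps[[all_lab]]$intersection)))
  }
  invisible(x)
}

#' Intersections of per-timepoint gene sets
#'
#' For every non-empty subset of timepoints: the plain intersection of the
#' corresponding selected sets, and the exclusive region (genes selected at
#' exactly those timepoints) — the regions of a Venn diagram.
#'
#' @param sets Named list of character vectors, one per timepoint.
#' @return Named list keyed by subset label (`"d2"`, `"d2&d10"`, ...), each
#'   element a list with `timepoints`, `intersection`, `exclusive`.
#' @export
overlap_sets <- function(sets) {
  stopifnot(length(sets) >= 1L, !is.null(names(sets)))
  tps <- names(sets)
  n <- length(tps)
  out <- list()
  for (size in seq_len(n)) {
    for (idx in utils::combn(n, size, simplify = FALSE)) {
      inter <- Reduce(intersect, sets[idx])
      excl <- setdiff(inter, unlist(sets[setdiff(seq_len(n), idx)]))
      lab <- paste(paste0("d", tps[idx]), collapse = "&")
      out[[lab]] <- list(timepoints = as.numeric(tps[idx]),
                         intersection = inter, exclusive = excl)
    }
  }
  out
}

#' Tabular summary of an overlap structure
#' @param overlaps Result of [overlap_sets()].
#' @return Data frame: `subset`, `n_intersection`, `n_exclusive`, `genes`
#'   (semicolon-joined intersection members).
#' @export
overlap_summary <- function(overlaps) {
  data.frame(
    subset = names(overlaps),
    n_intersection = vapply(overlaps, function(o) length(o$intersection), 1L),
    n_exclusive = vapply(overlaps, function(o) length(o$exclusive), 1L),
    genes = vapply(overlaps, function(o)
      paste(o$intersection, collapse = ";"), ""),
    stringsAsFactors = FALSE, row.names = NULL)
}
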