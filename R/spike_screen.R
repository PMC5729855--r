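#' Spike statistic for one gene at one timepoint
#'
#' A gene "spikes" when its expression bursts at a single dose rather than
#' trending with dose: the largest defined fold change is at least
#' `ratio_min` (default 5) times the second largest, and the spiking fold
#' change itself exceeds 1 (expression above control). Ties for the maximum
#' give ratio 1 and can never spike. A spike whose arg-max dose is the
#' highest analyzed dose is flagged `at_top_dose`, since a maximum there is
#' as consistent with a monotone increase as with a burst.
#'
#' @param doses Numeric vector of doses (roentgen).
#' @param fold_changes Numeric vector of defined fold changes, same length;
#'   `NA` entries are dropped.
#' @param ratio_min Inclusive ratio threshold, default 5.
#' @param min_defined Minimum number of defined fold changes for the
#'   statistic to be meaningful, default 3.
#' @return List: `n`, `spike_dose`, `max_fold_change`, `second_fold_change`,
#'   `ratio`, `is_spike`, `at_top_dose`, `status`.
#' @examples
#' spike_statistic(c(10, 1000, 5000, 10000, 20000),
#'                 c(1.1, 0.9, 12, 1.3, 0.8))  # spike at 5000 R, ratio 9.23
#' @export
spike_statistic <- function(doses, fold_changes, ratio_min = 5,
                            min_defined = 3) {
  keep <- is.finite(fold_changes)
  x <- doses[keep]; y <- fold_changes[keep]
  n <- length(y)
  if (n < max(2L, min_defined)) {
    return(list(n = n, spike_dose = NA_real_, max_fold_change = NA_real_,
                second_fold_change = NA_real_, ratio = NA_real_,
                is_spike = FALSE, at_top_dose = FALSE,
                status = "insufficient_data"))
  }
  imax <- which.max(y)
  mx <- y[imax]
  second <- max(y[-imax])
  ratio <- if (second == 0) {
    if (mx == 0) 1 else Inf
  } else mx / second
  list(n = n, spike_dose = x[imax], max_fold_change = mx,
       second_fold_change = second, ratio = ratio,
       is_spike = ratio >= ratio_min && mx > 1,
       at_top_dose = x[imax] == max(x),
       status = "ok")
}

#' Select spike genes per timepoint
#'
#' Runs [spike_statistic()] for every gene at every timepoint of a
#' fold-change table (after dropping `exclude_doses`), collects per-timepoint
#' spike gene sets and their overlaps, and builds a spikes-grouped-by-dose
#' report. When `drop_top_dose_spikes_for_grouping` is `TRUE` (the default)
#' spikes at the highest analyzed dose are omitted from the dose-grouping
#' report only — such genes still count as spike genes in the sets and
#' overlaps, since the overlap analysis precedes the dose grouping.
#'
#' @param fc A `fold_change_table` from [fold_change_table()].
#' @param ratio_min Inclusive max/second ratio threshold, default 5.
#' @param min_defined Minimum defined fold changes per gene, default 3.
#' @param exclude_doses Doses (roentgen) to drop before the statistic.
#' @param drop_top_dose_spikes_for_grouping Logical, default `TRUE`.
#' @param label Analysis label (defaults as in [select_linear_genes()]).
#' @return A `screen_result` with `screen = "spike"`: `stats` (one row per
#'   gene x timepoint), `sets`, `overlaps`, and `dose_grouping` (data frame
#'   of spike genes by spike dose).
#' @export
select_spike_genes <- function(fc, ratio_min = 5, min_defined = 3,
                               exclude_doses = numeric(0),
                               drop_top_dose_spikes_for_grouping = TRUE,
                               label = NULL) {
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
    top_dose <- max(doses)
    genes <- unique(sub$gene_id)
    fc_mat <- matrix(NA_real_, length(genes), length(doses),
                     dimnames = list(genes, as.character(doses)))
    fc_mat[cbind(match(sub$gene_id, genes),
                 match(sub$dose_roentgen, doses))] <- sub$fold_change
    m <- is.finite(fc_mat)
    n_def <- rowSums(m)
    neg <- fc_mat
    neg[!m] <- -Inf
    imax <- max.col(neg, ties.method = "first")
    mx <- neg[cbind(seq_along(genes), imax)]
    neg[cbind(seq_along(genes), imax)] <- -Inf
    second <- apply(neg, 1L, max)
    ok <- n_def >= max(2L, min_defined)
    ratio <- ifelse(second > 0, mx / second,
                    ifelse(mx > 0, Inf, 1))
    spike_dose <- doses[imax]
    df <- data.frame(
      gene_id = genes, timepoint_days = tp,
      n_defined = n_def,
      spike_dose = ifelse(ok, spike_dose, NA_real_),
      max_fc = ifelse(ok, mx, NA_real_),
      second_fc = ifelse(ok, second, NA_real_),
      ratio = ifelse(ok, ratio, NA_real_),
      is_spike = ok & ratio >= ratio_min & mx > 1,
      at_top_dose = ok & spike_dose == top_dose,
      stringsAsFactors = FALSE, row.names = NULL)
    stats_list[[k]] <- df
    sets[[k]] <- genes[df$is_spike]
  }
  stats_df <- do.call(rbind, stats_list)
  grouped <- stats_df[stats_df$is_spike &
                        !(drop_top_dose_spikes_for_grouping &
                            stats_df$at_top_dose), , drop = FALSE]
  dose_grouping <- grouped[order(grouped$timepoint_days, grouped$spike_dose,
                                 grouped$gene_id),
                           c("timepoint_days", "spike_dose", "gene_id",
                             "max_fc", "ratio")]
  rownames(dose_grouping) <- NULL
  structure(list(screen = "spike", label = label,
                 ratio_min = ratio_min, min_defined = min_defined,
                 exclude_doses = exclude_doses,
                 stats = stats_df, sets = sets,
                 overlaps = overlap_sets(sets),
                 dose_grouping = dose_grouping),
            class = "screen_result")
}
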