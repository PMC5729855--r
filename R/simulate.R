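#' Simulation configuration
#'
#' Parameters of the synthetic count generator. The defaults reproduce the
#' study design the screen targets: 3 timepoints (2, 10, 20 days
#' post-irradiation) x 6 X-ray exposures (0, 10, 1000, 5000, 10,000, 20,000
#' roentgen) x 3 replicates, with one control replicate dropped at
#' (20 d, 0 R), and a baseline expression scale whose bottom quartile sits
#' near 18-20 counts.
#'
#' Gene classes: a `linear` gene has expected fold change 1 + slope * dose
#' (floored at 0.05 so means stay positive); a `spike` gene is amplified by
#' `spike_amplitude` at a single spike dose and flat elsewhere; a `null`
#' gene is flat. Counts are negative binomial with variance
#' mean + dispersion * mean^2 (dispersion 0 = Poisson); `zero_noise = TRUE`
#' emits the expected values exactly (real-valued), for exact-recovery
#' testing. Per-sample sequencing-depth multipliers are log-normal with
#' log-scale spread `size_factor_sd`.
#'
#' @param n_genes Number of genes.
#' @param timepoints Days post-irradiation.
#' @param doses Exposures in roentgen; must include 0 (the control).
#' @param replicates Replicates per condition.
#' @param dropped_samples Data frame (`timepoint_days`, `dose_roentgen`,
#'   `replicate`) of samples removed from the design.
#' @param baseline_log_mean,baseline_log_sd Log-normal baseline expression.
#' @param nb_dispersion Negative-binomial dispersion (0 = Poisson).
#' @param zero_noise If `TRUE`, counts are the exact expected values.
#' @param frac_linear,frac_spike Fractions of dose-linear and spike genes
#'   (the remainder is null); must sum to at most 1.
#' @param slope_range Range of planted slopes (fold-change units per
#'   roentgen).
#' @param spike_doses Doses eligible to carry a planted spike. Default: the
#'   interior positive doses (neither the lowest nor the highest), so a
#'   planted spike stays identifiable when the lowest dose is excluded from
#'   analysis and is never discarded by the top-dose grouping rule.
#' @param spike_amplitude_range Range of planted spike amplitudes (> 5).
#' @param size_factor_sd Log-scale SD of per-sample depth multipliers.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000,
                       timepoints = c(2, 10, 20),
                       doses = c(0, 10, 1000, 5000, 10000, 20000),
                       replicates = 3,
                       dropped_samples = data.frame(
                         timepoint_days = 20, dose_roentgen = 0,
                         replicate = 3),
                       baseline_log_mean = 4,
                       baseline_log_sd = 1.5,
                       nb_dispersion = 0.05,
                       zero_noise = FALSE,
                       frac_linear = 0.05,
                       frac_spike = 0.01,
                       slope_range = c(5e-05, 1.5e-04),
                       spike_doses = NULL,
                       spike_amplitude_range = c(8, 30),
                       size_factor_sd = 0.15,
                       seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), timepoints = timepoints,
              doses = doses, replicates = as.integer(replicates),
              dropped_samples = dropped_samples,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              nb_dispersion = nb_dispersion, zero_noise = isTRUE(zero_noise),
              frac_linear = frac_linear, frac_spike = frac_spike,
              slope_range = slope_range, spike_doses = spike_doses,
              spike_amplitude_range = spike_amplitude_range,
              size_factor_sd = size_factor_sd, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) stop("config error: n_genes must be positive",
                             call. = FALSE)
  if (!0 %in% cfg$doses) stop("config error: doses must include 0 (control)",
                              call. = FALSE)
  pos <- cfg$doses[cfg$doses > 0]
  if (anyDuplicated(cfg$doses) || any(pos <= 0) || length(pos) < 1L) {
    stop("config error: positive doses must be distinct and positive",
         call. = FALSE)
  }
  if (cfg$frac_linear < 0 || cfg$frac_spike < 0 ||
      cfg$frac_linear + cfg$frac_spike > 1) {
    stop("config error: frac_linear + frac_spike must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$nb_dispersion < 0) stop("config error: nb_dispersion must be >= 0",
                                  call. = FALSE)
  if (!is.null(cfg$spike_doses) && !all(cfg$spike_doses %in% pos)) {
    stop("config error: spike_doses must be positive doses of the design",
         call. = FALSE)
  }
  invisible(cfg)
}

# expected expression of one gene across conditions: gene x dose matrix
.expected_fc <- function(truth_row, doses) {
  fc <- rep(1, length(doses))
  if (truth_row$class == "linear") {
    fc <- pmax(1 + truth_row$slope * doses, 0.05)
  } else if (truth_row$class == "spike") {
    fc[doses == truth_row$spike_dose] <- truth_row$spike_amplitude
  }
  fc
}

#' Simulate a count dataset with planted ground truth
#'
#' Draws baselines, assigns gene classes, plants dose-linear and spike
#' signals, and emits counts under the configured noise model, together with
#' the sample design and a truth table for recovery scoring. Signal genes
#' are planted among genes whose baseline lies above the 30th percentile of
#' the baseline distribution: a signal planted below the screen's
#' bottom-quartile detection floor would be unrecoverable by construction.
#'
#' All randomness flows from a single seeded stream in a fixed draw order
#' (baselines, class assignment, signal parameters, depth multipliers, then
#' counts ordered by gene within sample), so the same config yields
#' bit-identical output on any platform.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (raw [count_matrix]), `samples`
#'   ([sample_table]), `truth` (data frame: `gene_id`, `class`, `slope`,
#'   `spike_dose`, `spike_amplitude`, `baseline`), and `depth` (named vector
#'   of planted per-sample depth multipliers).
#' @export
simulate_dataset <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  G <- cfg$n_genes
  gene_ids <- sprintf("gene_%04d", seq_len(G))

  # sample design
  design <- expand.grid(replicate = seq_len(cfg$replicates),
                        dose_roentgen = cfg$doses,
                        timepoint_days = cfg$timepoints)
  design <- design[order(design$timepoint_days, design$dose_roentgen,
                         design$replicate), ]
  if (!is.null(cfg$dropped_samples) && nrow(cfg$dropped_samples)) {
    key <- function(d) paste(d$timepoint_days, d$dose_roentgen, d$replicate)
    design <- design[!(key(design) %in% key(cfg$dropped_samples)), ]
  }
  design$sample_id <- sprintf("d%02d_r%05d_rep%d", design$timepoint_days,
                              design$dose_roentgen, design$replicate)
  samples <- sample_table(design[c("sample_id", "timepoint_days",
                                   "dose_roentgen", "replicate")])
  S <- nrow(design)

  set.seed(cfg$seed)
  baseline <- stats::rlnorm(G, cfg$baseline_log_mean, cfg$baseline_log_sd)

  n_lin <- round(cfg$frac_linear * G)
  n_spk <- round(cfg$frac_spike * G)
  eligible <- which(baseline > stats::quantile(baseline, 0.30, type = 7))
  if (length(eligible) < n_lin + n_spk) {
    stop("config error: too few well-expressed genes to plant signals",
         call. = FALSE)
  }
  planted <- sample(eligible, n_lin + n_spk)
  lin_idx <- planted[seq_len(n_lin)]
  spk_idx <- planted[n_lin + seq_len(n_spk)]
  class <- rep("null", G)
  class[lin_idx] <- "linear"
  class[spk_idx] <- "spike"

  slope <- rep(NA_real_, G)
  slope[lin_idx] <- stats::runif(n_lin, cfg$slope_range[1], cfg$slope_range[2])
  pos <- sort(cfg$doses[cfg$doses > 0])
  spike_pool <- cfg$spike_doses
  if (is.null(spike_pool)) {
    spike_pool <- if (length(pos) > 2L) pos[-c(1L, length(pos))] else pos
  }
  spike_dose <- rep(NA_real_, G)
  spike_amplitude <- rep(NA_real_, G)
  if (n_spk > 0) {
    spike_dose[spk_idx] <- spike_pool[
      sample.int(length(spike_pool), n_spk, replace = TRUE)]
    spike_amplitude[spk_idx] <- stats::runif(n_spk,
                                             cfg$spike_amplitude_range[1],
                                             cfg$spike_amplitude_range[2])
  }
  truth <- data.frame(gene_id = gene_ids, class = class, slope = slope,
                      spike_dose = spike_dose,
                      spike_amplitude = spike_amplitude,
                      baseline = baseline, stringsAsFactors = FALSE)

  depth <- stats::rlnorm(S, 0, cfg$size_factor_sd)
  names(depth) <- design$sample_id

  # expected expression per gene x condition (fold-change plan x baseline)
  fc_plan <- matrix(1, G, length(cfg$doses),
                    dimnames = list(gene_ids, as.character(cfg$doses)))
  for (i in c(lin_idx, spk_idx)) {
    fc_plan[i, ] <- .expected_fc(truth[i, ], cfg$doses)
  }
  mu <- matrix(0, G, S, dimnames = list(gene_ids, design$sample_id))
  for (j in seq_len(S)) {
    mu[, j] <- baseline * fc_plan[, as.character(design$dose_roentgen[j])] *
      depth[j]
  }
  # one draw per cell, gene outermost then (timepoint, dose, replicate),
  # so iteration order elsewhere cannot perturb reproducibility
  counts <- if (cfg$zero_noise) {
    mu
  } else if (cfg$nb_dispersion == 0) {
    t(matrix(stats::rpois(G * S, lambda = as.vector(t(mu))), S, G,
             dimnames = dimnames(t(mu))))
  } else {
    t(matrix(stats::rnbinom(G * S, mu = as.vector(t(mu)),
                            size = 1 / cfg$nb_dispersion), S, G,
             dimnames = dimnames(t(mu))))
  }
  list(counts = count_matrix(counts, normalized = cfg$zero_noise &&
                               cfg$size_factor_sd == 0),
       samples = samples, truth = truth, depth = depth, config = cfg)
}

#' Write a simulated dataset's TSV files
#' @param sim Result of [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_simulated_dataset <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p1 <- write_count_matrix(sim$counts, file.path(out_dir, "counts.tsv"))
  p2 <- write_sample_table(sim$samples, file.path(out_dir, "samples.tsv"))
  p3 <- file.path(out_dir, "truth.tsv")
  utils::write.table(sim$truth, p3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Score a screen against planted ground truth
#'
#' Per timepoint and for the intersection of all timepoints: sensitivity
#' (fraction of planted genes of the screen's target class that were
#' selected), false-positive rate among null genes, and — for a linear
#' screen — the rate at which planted spike genes leak into the linear sets.
#'
#' @param truth Truth table from [simulate_dataset()].
#' @param result A `screen_result`.
#' @param target_class Planted class the screen should recover; defaults to
#'   `"linear"` or `"spike"` to match `result$screen`.
#' @return List with `per_timepoint` (data frame: `timepoint_days`,
#'   `sensitivity`, `null_fpr`, `spike_in_linear`), and the same three
#'   measures for the all-timepoint overlap (`overlap_sensitivity`,
#'   `overlap_null_fpr`, `overlap_spike_in_linear`).
#' @export
recovery_metrics <- function(truth, result, target_class = result$screen) {
  stopifnot(inherits(result, "screen_result"))
  if (!all(unlist(result$sets) %in% truth$gene_id)) {
    stop("consistency error: screened gene ids absent from truth table",
         call. = FALSE)
  }
  pos_genes <- truth$gene_id[truth$class == target_class]
  null_genes <- truth$gene_id[truth$class == "null"]
  spk_genes <- truth$gene_id[truth$class == "spike"]
  rate <- function(selected, pool) {
    if (!length(pool)) return(NA_real_)
    length(intersect(selected, pool)) / length(pool)
  }
  per_tp <- data.frame(
    timepoint_days = as.numeric(names(result$sets)),
    sensitivity = vapply(result$sets, rate, 1, pool = pos_genes),
    null_fpr = vapply(result$sets, rate, 1, pool = null_genes),
    spike_in_linear = if (result$screen == "linear")
      vapply(result$sets, rate, 1, pool = spk_genes) else NA_real_,
    row.names = NULL)
  all_lab <- paste(paste0("d", names(result$sets)), collapse = "&")
  inter <- result$overlaps[[all_lab]]$intersection
  list(per_timepoint = per_tp,
       overlap_sensitivity = rate(inter, pos_genes),
       overlap_null_fpr = rate(inter, null_genes),
       overlap_spike_in_linear = if (result$screen == "linear")
         rate(inter, spk_genes) else NA_real_)
}
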