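#' Pipeline configuration
#'
#' Bundles every knob of the screen so a whole analysis is reproducible from
#' one object: either paths to a count matrix + sample table or a simulation
#' block (exactly one of the two), the normalization switch, and the screen
#' thresholds.
#'
#' @param counts_path,samples_path TSV inputs (see [read_count_matrix()] and
#'   [read_sample_table()]). Mutually exclusive with `simulate`.
#' @param simulate A [sim_config()] to generate the inputs instead.
#' @param normalized_input `TRUE` if the count file is already normalized,
#'   in which case median-of-ratios normalization is skipped.
#' @param r2_min,min_doses Linear-screen thresholds (defaults 0.9 and 4).
#' @param presence_quantile Present/absent cutoff quantile (default 0.25).
#' @param spike_ratio_min,spike_min_defined Spike-screen thresholds
#'   (defaults 5 and 3).
#' @param secondary_exclude_doses Doses dropped in the secondary analyses
#'   (default 10 R, the lowest exposure — negligible for flies).
#' @param include_control_in_fit If `TRUE`, the dose-0 point (fold change
#'   identically 1) is added as a regression point. Off by default: a
#'   point that is 1 by construction inflates R^2.
#' @param out_dir Output directory, or `NULL` for no files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts_path = NULL, samples_path = NULL,
                            simulate = NULL, normalized_input = FALSE,
                            r2_min = 0.9, min_doses = 4,
                            presence_quantile = 0.25,
                            spike_ratio_min = 5, spike_min_defined = 3,
                            secondary_exclude_doses = 10,
                            include_control_in_fit = FALSE,
                            out_dir = NULL) {
  have_paths <- !is.null(counts_path) || !is.null(samples_path)
  if (have_paths && !is.null(simulate)) {
    stop("config error: give either input paths or a simulate block, not both",
         call. = FALSE)
  }
  if (!have_paths && is.null(simulate)) {
    stop("config error: either input paths or a simulate block is required",
         call. = FALSE)
  }
  if (have_paths && (is.null(counts_path) || is.null(samples_path))) {
    stop("config error: both counts_path and samples_path are required",
         call. = FALSE)
  }
  structure(list(counts_path = counts_path, samples_path = samples_path,
                 simulate = simulate, normalized_input = normalized_input,
                 r2_min = r2_min, min_doses = min_doses,
                 presence_quantile = presence_quantile,
                 spike_ratio_min = spike_ratio_min,
                 spike_min_defined = spike_min_defined,
                 secondary_exclude_doses = secondary_exclude_doses,
                 include_control_in_fit = isTRUE(include_control_in_fit),
                 out_dir = out_dir),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full biodosimetry screen
#'
#' End-to-end cascade: read or simulate inputs, normalize (median of
#' ratios), per-condition means, per-timepoint presence cutoffs, fold
#' changes, then four named analyses mirroring the screen's result
#' structure — `linear` (all doses), `linear_no_low` (secondary doses
#' excluded), `spike`, `spike_no_low` — plus overlap summaries, result
#' TSVs, and a JSON run manifest of every threshold, seed, and input
#' checksum. Per-stage gene counts surviving each gate are logged via
#' `message()` (suppress with [suppressMessages()]).
#'
#' @param config A [pipeline_config()].
#' @return List: `fold_changes`, `cutoffs`, `size_factors`, the four
#'   `screen_result`s under `analyses`, `recovery` (when simulated truth is
#'   available), and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- .stage("simulate", simulate_dataset(config$simulate))
    counts <- sim$counts; samples <- sim$samples; truth <- sim$truth
    inputs <- list(simulate_seed = config$simulate$seed)
  } else {
    counts <- .stage("read_counts",
                     read_count_matrix(config$counts_path,
                                       normalized = config$normalized_input))
    samples <- .stage("read_samples", read_sample_table(config$samples_path))
    inputs <- list(counts_md5 = unname(tools::md5sum(config$counts_path)),
                   samples_md5 = unname(tools::md5sum(config$samples_path)))
  }
  .stage("check_design", check_design(counts, samples))
  message(sprintf("input: %d genes, %d samples", nrow(counts$values),
                  ncol(counts$values)))

  sf <- NULL
  if (!counts$normalized) {
    sf <- .stage("size_factors", size_factors(counts))
    counts <- .stage("normalize", normalize_counts(counts, sf))
  }
  means <- .stage("condition_means", condition_means(counts, samples))
  cutoffs <- .stage("presence_cutoffs",
                    presence_cutoffs(means, config$presence_quantile))
  message(paste(sprintf("cutoff day %d: %.2f", cutoffs$timepoint_days,
                        cutoffs$cutoff), collapse = "; "))
  fc <- .stage("fold_changes", fold_change_table(means, cutoffs))
  if (config$include_control_in_fit) {
    ctrl <- fc[!duplicated(fc[c("gene_id", "timepoint_days")]),
               c("gene_id", "timepoint_days")]
    ctrl$dose_roentgen <- 0
    ctrl$fold_change <- 1
    ctrl$status <- "defined"
    fc_fit <- rbind(fc, ctrl[names(fc)])
  } else {
    fc_fit <- fc
  }
  message(sprintf("fold changes: %d defined of %d",
                  sum(fc$status == "defined"), nrow(fc)))

  excl <- config$secondary_exclude_doses
  analyses <- list(
    linear = .stage("linear_screen",
      select_linear_genes(fc_fit, config$r2_min, config$min_doses)),
    linear_no_low = .stage("linear_screen_excluded",
      select_linear_genes(fc_fit, config$r2_min, config$min_doses,
                          exclude_doses = excl)),
    spike = .stage("spike_screen",
      select_spike_genes(fc, config$spike_ratio_min,
                         config$spike_min_defined)),
    spike_no_low = .stage("spike_screen_excluded",
      select_spike_genes(fc, config$spike_ratio_min,
                         config$spike_min_defined, exclude_doses = excl)))
  for (nm in names(analyses)) {
    message(sprintf("%s: %s selected", nm,
                    paste(vapply(analyses[[nm]]$sets, length, 1L),
                          collapse = "/")))
  }

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- list(
      linear = recovery_metrics(truth, analyses$linear),
      linear_no_low = recovery_metrics(truth, analyses$linear_no_low),
      spike = recovery_metrics(truth, analyses$spike),
      spike_no_low = recovery_metrics(truth, analyses$spike_no_low))
  }

  manifest <- list(
    inputs = inputs,
    thresholds = list(r2_min = config$r2_min, min_doses = config$min_doses,
                      presence_quantile = config$presence_quantile,
                      spike_ratio_min = config$spike_ratio_min,
                      spike_min_defined = config$spike_min_defined,
                      secondary_exclude_doses = config$secondary_exclude_doses,
                      include_control_in_fit = config$include_control_in_fit),
    cutoffs = cutoffs,
    n_genes = nrow(counts$values), n_samples = ncol(counts$values))

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    for (nm in names(analyses)) {
      write_result_tables(analyses[[nm]], file.path(out, nm))
    }
    if (!is.null(sf)) write_size_factors(sf, file.path(out, "size_factors.tsv"))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(size_factors = sf, means = means, cutoffs = cutoffs,
       fold_changes = fc, analyses = analyses, recovery = recovery,
       truth = truth, manifest = manifest)
}
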