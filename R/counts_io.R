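#' Construct a count matrix
#'
#' A `count_matrix` is the package's container for a gene x sample table of
#' non-negative expression values (raw or normalized counts), with unique
#' gene and sample identifiers and a flag recording whether the values have
#' already been depth-normalized.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are used as gene and sample identifiers if `gene_ids` /
#'   `sample_ids` are not given.
#' @param gene_ids Character vector of gene identifiers (one per row).
#' @param sample_ids Character vector of sample identifiers (one per column).
#' @param normalized Logical; `TRUE` if the values are already normalized.
#' @return An object of class `count_matrix`: a list with elements `values`
#'   (numeric matrix with dimnames), `gene_ids`, `sample_ids`, `normalized`.
#' @examples
#' m <- count_matrix(matrix(c(2, 4, 4, 8), 2, byrow = TRUE),
#'                   gene_ids = c("g1", "g2"), sample_ids = c("s1", "s2"))
#' m$values
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         sample_ids = colnames(values), normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("count matrix is empty", call. = FALSE)
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lists do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifier: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifier: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values) || !all(is.finite(values))) {
    stop("count matrix contains missing or non-finite values", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("count matrix contains negative values", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         normalized = isTRUE(normalized)),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              length(x$gene_ids), length(x$sample_ids),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Read a count matrix from tab-separated text
#'
#' Expects genes in rows and samples in columns: a header row of sample
#' identifiers (with or without a leading `gene_id` field) and a first column
#' of gene identifiers, the GEO supplementary-file convention. Row and column
#' order of the file is preserved.
#'
#' @param path Path to a TSV file.
#' @param normalized Logical; set `TRUE` if the file already holds
#'   depth-normalized values, so downstream steps skip re-normalization.
#' @return A [count_matrix].
#' @export
read_count_matrix <- function(path, normalized = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) stop("malformed count matrix: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, header = FALSE, skip = 1L, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop("empty count matrix: ", path, call. = FALSE))
  if (nrow(df) == 0L) stop("empty count matrix: ", path, call. = FALSE)
  # the header may or may not name the gene-id column
  sample_ids <- if (length(header) == ncol(df)) header[-1L]
                else if (length(header) == ncol(df) - 1L) header
                else stop("malformed count matrix header: ", path,
                          call. = FALSE)
  gene_ids <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(values <- matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(values)) {
    bad <- cells[is.na(values)]
    stop("non-numeric cell in count matrix: ",
         paste(utils::head(unique(bad), 3L), collapse = ", "), call. = FALSE)
  }
  count_matrix(values, gene_ids = gene_ids, sample_ids = sample_ids,
               normalized = normalized)
}

#' Write a count matrix as tab-separated text
#'
#' Inverse of [read_count_matrix()]: header row `gene_id` + sample ids,
#' one row per gene.
#'
#' @param x A [count_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = x$gene_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct / read a sample table
#'
#' The sample table maps each sequencing sample to its experimental
#' condition: timepoint in days post-irradiation, dose in roentgen, and a
#' replicate index. Every timepoint must include a dose-0 (unirradiated
#' control) condition, since fold changes are taken against it.
#'
#' @param df Data frame with columns `sample_id`, `timepoint_days`,
#'   `dose_roentgen`, `replicate`.
#' @return A `sample_table`: the validated data frame, with a
#'   `census` attribute counting samples per (timepoint, dose) condition.
#' @export
sample_table <- function(df) {
  req <- c("sample_id", "timepoint_days", "dose_roentgen", "replicate")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("sample table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[req]
  df$sample_id <- as.character(df$sample_id)
  for (col in req[-1L]) {
    v <- df[[col]]
    if (is.character(v) || is.factor(v)) {
      suppressWarnings(v <- as.numeric(as.character(v)))
    }
    if (anyNA(v)) stop("non-numeric value in column ", col, call. = FALSE)
    df[[col]] <- v
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample identifier in sample table", call. = FALSE)
  }
  if (any(df$timepoint_days <= 0) ||
      any(df$timepoint_days != round(df$timepoint_days))) {
    stop("timepoint_days must be positive integers", call. = FALSE)
  }
  if (any(df$dose_roentgen < 0)) {
    stop("dose_roentgen must be non-negative", call. = FALSE)
  }
  if (any(df$replicate <= 0) || any(df$replicate != round(df$replicate))) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  for (tp in unique(df$timepoint_days)) {
    if (!any(df$dose_roentgen[df$timepoint_days == tp] == 0)) {
      stop("design error: timepoint ", tp,
           " days has no dose-0 control condition", call. = FALSE)
    }
  }
  census <- stats::aggregate(
    list(n_samples = df$sample_id),
    by = list(timepoint_days = df$timepoint_days,
              dose_roentgen = df$dose_roentgen),
    FUN = length
  )
  census <- census[order(census$timepoint_days, census$dose_roentgen), ]
  rownames(census) <- NULL
  structure(df, census = census, class = c("sample_table", "data.frame"))
}

#' @rdname sample_table
#' @param path Path to a TSV file with the four columns above.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  sample_table(df)
}

#' Write a sample table as TSV
#' @param x A [sample_table].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Samples-per-condition census of a sample table
#' @param samples A [sample_table].
#' @return Data frame with `timepoint_days`, `dose_roentgen`, `n_samples`.
#' @export
condition_census <- function(samples) attr(samples, "census")

#' Cross-validate a count matrix against a sample table
#'
#' Every sample in the table must be a column of the matrix. Extra matrix
#' columns are tolerated (and ignored downstream); a table sample missing
#' from the matrix is a consistency error.
#'
#' @param counts A [count_matrix].
#' @param samples A [sample_table].
#' @return `TRUE`, invisibly; stops on inconsistency.
#' @export
check_design <- function(counts, samples) {
  stopifnot(inherits(counts, "count_matrix"), inherits(samples, "sample_table"))
  absent <- setdiff(samples$sample_id, counts$sample_ids)
  if (length(absent)) {
    stop("consistency error: sample(s) absent from count matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write all result tables for a screen
#'
#' Emits the per-gene statistics table, the selected-set memberships, and an
#' overlap-count summary (per-timepoint set sizes plus every pairwise and
#' higher-order intersection and exclusive region, the counts a Venn diagram
#' of the screen would display).
#'
#' @param result A `screen_result` from [select_linear_genes()] or
#'   [select_spike_genes()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_result_tables <- function(result, out_dir) {
  stopifnot(inherits(result, "screen_result"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  files <- character(0)
  stats_path <- file.path(out_dir, paste0(result$screen, "_stats.tsv"))
  df <- result$stats
  if (result$screen == "linear") {
    for (col in c("slope", "intercept", "r_squared")) {
      df[[col]] <- ifelse(is.na(df[[col]]), NA, sprintf("%.6f", df[[col]]))
    }
  } else {
    df$ratio <- ifelse(is.na(df$ratio), NA,
                       ifelse(is.infinite(df$ratio), "Inf",
                              sprintf("%.4f", df$ratio)))
  }
  for (col in intersect(c("selected", "is_spike", "at_top_dose"), names(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  utils::write.table(df, stats_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, stats_path)

  ov_path <- file.path(out_dir, paste0(result$screen, "_overlaps.tsv"))
  ov <- overlap_summary(result$overlaps)
  utils::write.table(ov, ov_path, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, ov_path)

  sets_path <- file.path(out_dir, paste0(result$screen, "_sets.tsv"))
  sets_df <- do.call(rbind, c(list(
    data.frame(timepoint_days = numeric(0), gene_id = character(0))),
    lapply(names(result$sets), function(tp) {
      genes <- result$sets[[tp]]
      if (!length(genes)) return(NULL)
      data.frame(timepoint_days = as.numeric(tp), gene_id = genes,
                 stringsAsFactors = FALSE)
    })))
  utils::write.table(sets_df, sets_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, sets_path)

  if (!is.null(result$dose_grouping)) {
    dg_path <- file.path(out_dir, paste0(result$screen, "_dose_grouping.tsv"))
    utils::write.table(result$dose_grouping, dg_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, dg_path)
  }
  invisible(files)
}
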