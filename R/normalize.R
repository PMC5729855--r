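#' Median-of-ratios normalization
#'
#' Per-sample size factors computed from the median-of-ratios estimator: each
#' sample's factor is the median, over reference genes, of that sample's
#' count divided by the gene's geometric mean across samples. Genes with any
#' zero count are excluded from the reference (their log-ratio is undefined)
#' but are still normalized. Factors are rescaled to unit geometric mean:
#' the common scale cancels in fold changes, and the convention makes
#' normalization idempotent — the factors of an already-normalized matrix
#' are exactly 1 (without it they equal the geometric mean of the original
#' factors, a constant).
#'
#' @param counts A [count_matrix] of raw counts.
#' @return `geometric_reference`: named numeric vector, one entry per gene;
#'   `NA` for genes excluded from the reference (any zero count).
#' @examples
#' m <- count_matrix(matrix(c(2, 4, 4, 8), 2, byrow = TRUE,
#'                          dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' geometric_reference(m)   # sqrt(8), sqrt(32)
#' size_factors(m)          # 1/sqrt(2), sqrt(2)
#' @name normalization
NULL

#' @rdname normalization
#' @export
geometric_reference <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  v <- counts$values
  ref <- exp(rowMeans(log(v)))
  ref[apply(v == 0, 1L, any)] <- NA_real_
  if (all(is.na(ref))) {
    stop("normalization infeasible: no gene has all-positive counts",
         call. = FALSE)
  }
  names(ref) <- counts$gene_ids
  ref
}

#' @rdname normalization
#' @return `size_factors`: named positive numeric vector, one per sample.
#'   Even-length medians use the midpoint of the two central values.
#' @export
size_factors <- function(counts) {
  ref <- geometric_reference(counts)
  use <- !is.na(ref)
  ratios <- counts$values[use, , drop = FALSE] / ref[use]
  sf <- apply(ratios, 2L, stats::median)
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("normalization infeasible: non-positive size factor", call. = FALSE)
  }
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- counts$sample_ids
  sf
}

#' @rdname normalization
#' @param factors Named numeric vector of size factors covering every sample
#'   of `counts` (as from `size_factors`).
#' @return `normalize_counts`: a [count_matrix] with each column divided by
#'   its size factor and `normalized = TRUE`.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(names(factors))) {
    if (length(factors) != length(counts$sample_ids)) {
      stop("consistency error: one size factor per sample required",
           call. = FALSE)
    }
    names(factors) <- counts$sample_ids
  }
  missing_sf <- setdiff(counts$sample_ids, names(factors))
  if (length(missing_sf)) {
    stop("consistency error: missing size factor for sample(s): ",
         paste(missing_sf, collapse = ", "), call. = FALSE)
  }
  f <- factors[counts$sample_ids]
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("size factors must be positive and finite", call. = FALSE)
  }
  count_matrix(sweep(counts$values, 2L, f, "/"),
               gene_ids = counts$gene_ids, sample_ids = counts$sample_ids,
               normalized = TRUE)
}

#' Write size factors as TSV
#' @param factors Named vector from [size_factors()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_size_factors <- function(factors, path) {
  utils::write.table(
    data.frame(sample_id = names(factors), factor = unname(factors)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
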