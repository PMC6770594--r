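#' Median-ratio normalization size factors
#'
#' The DESeq-style median-of-ratios estimator: the reference expression of a
#' gene is its geometric mean over samples, computed on the genes that are
#' strictly positive in every sample; a sample's size factor is the median,
#' over those reference genes, of the ratio of its counts to the reference.
#' Factors are rescaled so their geometric mean is exactly 1, so only their
#' ratios carry meaning.
#'
#' @param m Raw count matrix (genes x samples); at least one gene must be
#'   positive in all samples.
#' @return Named numeric vector of positive size factors, one per sample,
#'   geometric mean 1.
#' @seealso [normalize_counts()]
#' @export
mrn_size_factors <- function(m) {
  mm <- unclass(m)
  if (ncol(mm) < 1L) stop2("matrix has no samples")
  kind <- value_kind(m)
  if (!is.null(kind) && kind != "raw_count")
    warning("mrn_size_factors expects raw counts; got value_kind = ", kind)
  ref_rows <- rowSums(mm > 0) == ncol(mm)
  if (!any(ref_rows))
    stop2(paste0("median-ratio normalization needs at least one gene with ",
                 "positive counts in every sample; none found. Consider ",
                 "filter_genes() or providing deeper coverage."))
  sub <- mm[ref_rows, , drop = FALSE]
  log_ref <- rowMeans(log(sub))
  factors <- apply(exp(log(sub) - log_ref), 2L, median)
  factors <- factors / exp(mean(log(factors)))
  setNames(factors, colnames(mm))
}

#' Apply size factors to a raw count matrix
#'
#' Divides each sample (column) by its size factor; zeros remain zeros. The
#' result is marked `value_kind = "normalized"`.
#'
#' @param m Raw count matrix (genes x samples).
#' @param f Size factors named by sample id, e.g. from [mrn_size_factors()];
#'   must cover every sample of `m`.
#' @return Normalized [expression_matrix()].
#' @export
normalize_counts <- function(m, f = mrn_size_factors(m)) {
  mm <- unclass(m)
  missing_f <- setdiff(colnames(mm), names(f))
  if (length(missing_f))
    stop2("no size factor for sample(s): %s",
          paste(head(missing_f, 5L), collapse = ", "))
  f <- f[colnames(mm)]
  if (any(!is.finite(f) | f <= 0)) stop2("size factors must be positive and finite")
  expression_matrix(sweep(mm, 2L, f, "/"), value_kind = "normalized")
}
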