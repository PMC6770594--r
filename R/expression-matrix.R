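#' Construct a validated expression matrix
#'
#' A light wrapper around a plain numeric matrix: genes as rows, samples as
#' columns, unique ids on both margins, no negative or missing values, and a
#' `value_kind` attribute recording whether the values are raw counts,
#' normalized counts or TPMs. All scoring functions accept these objects (or
#' any plain matrix of the same shape).
#'
#' @param values Numeric matrix, genes x samples, with rownames and colnames.
#' @param value_kind One of `"raw_count"`, `"normalized"`, `"tpm"`.
#' @return The matrix with class `expression_matrix` and the `value_kind`
#'   attribute attached.
#' @export
expression_matrix <- function(values,
                              value_kind = c("raw_count", "normalized", "tpm")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop2("values must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop2("values must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop2("duplicate gene ids: %s",
          paste(head(unique(rownames(values)[duplicated(rownames(values))]), 5L),
                collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop2("duplicate sample ids: %s",
          paste(head(unique(colnames(values)[duplicated(colnames(values))]), 5L),
                collapse = ", "))
  if (any(!is.finite(values)))
    stop2("expression values must be finite (no NA/NaN/Inf)")
  if (any(values < 0))
    stop2("expression values must be non-negative")
  structure(values, value_kind = value_kind,
            class = c("expression_matrix", "matrix", "array"))
}

#' Value kind of an expression matrix
#'
#' @param m A matrix; returns `NULL` when no kind was recorded.
#' @return `"raw_count"`, `"normalized"`, `"tpm"` or `NULL`.
#' @export
value_kind <- function(m) attr(m, "value_kind", exact = TRUE)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s), %.1f%% zeros\n",
              nrow(x), ncol(x), value_kind(x) %||% "unknown kind",
              100 * mean(unclass(x) == 0)))
  invisible(x)
}

#' @export
`[.expression_matrix` <- function(x, i, j, ..., drop = FALSE) {
  kind <- value_kind(x)
  out <- NextMethod()
  if (is.matrix(out))
    out <- structure(out, value_kind = kind,
                     class = c("expression_matrix", "matrix", "array"))
  out
}

#' Filter genes by fraction of samples with nonzero expression
#'
#' Keeps genes expressed (value > 0) in at least `min_nonzero_fraction` of
#' samples, preserving gene order. The default 0 keeps everything; filtering
#' is opt-in.
#'
#' @param m Expression matrix (genes x samples).
#' @param min_nonzero_fraction Fraction in \[0, 1\].
#' @return The filtered matrix (possibly with zero rows).
#' @export
filter_genes <- function(m, min_nonzero_fraction = 0) {
  if (length(min_nonzero_fraction) != 1L || !is.finite(min_nonzero_fraction) ||
      min_nonzero_fraction < 0 || min_nonzero_fraction > 1)
    stop2("min_nonzero_fraction must be a single value in [0, 1]")
  keep <- rowMeans(unclass(m) > 0) >= min_nonzero_fraction
  m[keep, , drop = FALSE]
}
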