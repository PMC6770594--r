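#' Benford reference distribution
#'
#' Expected first-digit frequencies under the Benford (first-digit) law,
#' `E_d = log10(1 + 1/d)` for digits d = 1..9. The frequencies telescope to
#' exactly 1 and are strictly decreasing in d.
#'
#' @return Named numeric vector of length 9 (names `"1"`..`"9"`).
#' @examples
#' benford_expected()["1"] # log10(2)
#' @export
benford_expected <- function() {
  setNames(log10(1 + 1 / (1:9)), as.character(1:9))
}

#' Theoretical maximum of the Benford MAE
#'
#' The MAE between a digit distribution and the Benford reference is maximal
#' for a point mass on digit 9: `2 * (1 - log10(10/9)) / 9`, about 0.212054.
#' Used as the fallback score for a cell that expresses no panel gene.
#'
#' @return A single numeric value.
#' @export
benford_mae_max <- function() {
  2 * (1 - log10(10 / 9)) / 9
}

# vectorized digit extraction; zeros -> NA, negatives/NaN/Inf -> error.
# Extraction reads the first character of a 12-significant-digit scientific
# rendering, so binary-float artifacts (0.2999999999999998 meaning 0.3) round
# away instead of flipping the digit.
first_digits <- function(x, what = "values") {
  if (!is.numeric(x)) stop2("%s must be numeric", what)
  bad <- !is.finite(x) | x < 0
  if (any(bad))
    stop2("%s must be finite and non-negative (%d offending value(s))",
          what, sum(bad))
  d <- rep(NA_integer_, length(x))
  pos <- x > 0
  if (any(pos))
    d[pos] <- as.integer(substr(formatC(x[pos], format = "e", digits = 11L),
                                1L, 1L))
  d
}

#' First significant digit of positive numbers
#'
#' Returns the leading nonzero decimal digit, invariant to multiplication by
#' any power of ten. Values are rendered with 12 significant digits before the
#' digit is read off, so near-boundary floating-point representations (e.g. a
#' stored `0.2999999999999998` intended as 0.3) do not flip the digit.
#'
#' @param x Numeric vector of strictly positive, finite values.
#' @return Integer vector of digits in 1..9.
#' @examples
#' first_significant_digit(c(305.2, 0.0047, 6.02e23)) # 3 4 6
#' @export
first_significant_digit <- function(x) {
  if (!is.numeric(x)) stop2("x must be numeric")
  if (any(!is.finite(x) | x <= 0))
    stop2("x must be strictly positive and finite; zeros are a digit-histogram policy, not a digit")
  first_digits(x)
}

#' First-digit matrix of an expression matrix
#'
#' Computes the first significant digit of every entry once, with `NA` marking
#' zeros. Pass the result to the `digits` argument of the gene-/cell-centered
#' scoring functions to avoid recomputing digit renderings per group or panel.
#'
#' @param m Non-negative numeric matrix (genes x samples).
#' @return Integer matrix of the same shape and dimnames; `NA` where `m == 0`.
#' @export
first_digit_matrix <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  d <- first_digits(as.vector(unclass(m)), what = "matrix values")
  matrix(d, nrow = nrow(m), dimnames = dimnames(m))
}

#' Tabulate first digits of a set of values
#'
#' Zeros carry no leading digit: they are excluded from the histogram and
#' reported in `n_zero_excluded`. Negative, NA or infinite values are errors.
#'
#' @param values Numeric vector of finite, non-negative values.
#' @return A `digit_histogram`: list with `counts` (integer, per digit 1..9),
#'   `n_used` and `n_zero_excluded`.
#' @examples
#' digit_histogram(c(1.2, 0, 13, 0.9))
#' @export
digit_histogram <- function(values) {
  d <- first_digits(values)
  counts <- tabulate(d, nbins = 9L)
  structure(
    list(counts = setNames(as.integer(counts), as.character(1:9)),
         n_used = sum(counts),
         n_zero_excluded = sum(is.na(d))),
    class = "digit_histogram"
  )
}

#' @export
print.digit_histogram <- function(x, ...) {
  cat("First-digit histogram:", x$n_used, "digits,",
      x$n_zero_excluded, "zeros excluded\n")
  print(x$counts)
  invisible(x)
}

# accept either a digit_histogram or a raw count vector of length 9
as_digit_counts <- function(h) {
  if (inherits(h, "digit_histogram")) return(h$counts)
  if (is.numeric(h) && length(h) == 9L && all(h >= 0)) return(h)
  stop2("expected a digit_histogram or a length-9 count vector")
}

#' Observed digit distribution from a histogram
#'
#' @param h A [digit_histogram()] (or length-9 count vector) with at least one
#'   counted digit.
#' @return Named numeric vector of frequencies A_1..A_9 summing to 1.
#' @export
to_distribution <- function(h) {
  counts <- as_digit_counts(h)
  n <- sum(counts)
  if (n == 0)
    stop2("empty digit distribution: no nonzero values contributed a digit")
  setNames(as.numeric(counts) / n, as.character(1:9))
}

#' Benford adherence score (MAE over the nine digit frequencies)
#'
#' `MAE = (1/9) * sum_d |A_d - E_d|`, the mean absolute error between an
#' observed first-digit distribution and the Benford reference. The denominator
#' is always 9, even when some digits are unobserved. The score lies in
#' \[0, [benford_mae_max()]\]; 0 means exact adherence.
#'
#' @param a Observed digit distribution (length-9 frequencies summing to 1).
#' @param e Expected distribution; defaults to [benford_expected()].
#' @return A single numeric MAE.
#' @examples
#' benford_mae(to_distribution(digit_histogram(10^runif(1000, 0, 3))))
#' @export
benford_mae <- function(a, e = benford_expected()) {
  for (v in list(a, e)) {
    if (length(v) != 9L || any(!is.finite(v)) || any(v < 0) ||
        abs(sum(v) - 1) > 1e-8)
      stop2("digit distributions must be 9 non-negative frequencies summing to 1")
  }
  mean(abs(a - e))
}

#' Pearson chi-square goodness-of-fit against the Benford reference
#'
#' Tests the observed digit counts against expected counts `n_used * E_d`
#' (9 categories, 8 degrees of freedom, no continuity correction). Under the
#' convention that the null hypothesis is adherence, p > 0.05 is read as
#' "consistent with Benford".
#'
#' @param h A [digit_histogram()] (or length-9 count vector), `n_used > 0`.
#' @param e Expected distribution; defaults to [benford_expected()].
#' @return A `gof_result`: list with `statistic`, `p_value`, `df`.
#' @export
chisq_gof <- function(h, e = benford_expected()) {
  counts <- as_digit_counts(h)
  n <- sum(counts)
  if (n == 0)
    stop2("empty digit distribution: no nonzero values contributed a digit")
  expected <- n * e
  stat <- sum((counts - expected)^2 / expected)
  structure(
    list(statistic = stat, p_value = pchisq(stat, df = 8L, lower.tail = FALSE),
         df = 8L),
    class = "gof_result"
  )
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Pearson GOF vs Benford: X-squared = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
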