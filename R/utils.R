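# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded internals never
#' perturb the user's random stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# coerce a label vector (named character/factor keyed by sample id) to a
# named factor covering exactly the given sample ids
as_group_labels <- function(labels, sample_ids = NULL) {
  if (is.null(names(labels)))
    stop2("labels must be named by sample id")
  if (anyDuplicated(names(labels)))
    stop2("duplicate sample ids in labels: %s",
          paste(unique(names(labels)[duplicated(names(labels))]), collapse = ", "))
  lab <- factor(as.character(labels))
  names(lab) <- names(labels)
  if (!is.null(sample_ids)) {
    missing_lab <- setdiff(sample_ids, names(lab))
    if (length(missing_lab))
      stop2("samples missing from labels: %s",
            paste(head(missing_lab, 5L), collapse = ", "))
    lab <- droplevels(lab[sample_ids])
  }
  if (any(is.na(lab))) stop2("labels contain NA group assignments")
  lab
}
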