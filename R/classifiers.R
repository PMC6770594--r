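# Internal classifier backends behind a uniform fit/predict-probability
# surface. Backends: randomForest, e1071 (linear/radial SVM), MASS::lda, and
# an in-package nearest-shrunken-centroids (NSC) classifier. Features reaching
# SVM/LDA are standardized with train-set mean/sd by the harness; tree models
# and NSC (which standardizes internally by pooled within-class sd) see raw
# features.

algorithm_names <- function() {
  c("rf", "svm_linear", "svm_radial", "nsc", "lda")
}

needs_scaling <- function(algorithm) {
  algorithm %in% c("svm_linear", "svm_radial", "lda")
}

# small, standard hyperparameter grids; data enters only through the scale
# heuristic for the RBF width and the NSC shrinkage range
default_grid <- function(algorithm, x, y) {
  switch(algorithm,
    rf = data.frame(mtry = seq_len(min(ncol(x), nlevels(y)))),
    svm_linear = data.frame(cost = c(0.25, 1, 4)),
    svm_radial = {
      g0 <- 1 / (ncol(x) * max(var(as.vector(x)), .Machine$double.eps))
      expand.grid(cost = c(0.25, 1, 4, 16), gamma = g0 * c(0.5, 1, 2))
    },
    nsc = data.frame(delta = nsc_delta_grid(x, y)),
    lda = data.frame(dummy = 0),
    stop2("unknown algorithm: %s", algorithm)
  )
}

# probability = FALSE skips the SVMs' internal probability-model fit, which
# the CV grid search does not need (it selects on class accuracy)
fit_classifier <- function(algorithm, x, y, params, seed, probability = TRUE) {
  with_seed(seed, switch(algorithm,
    rf = randomForest::randomForest(x = x, y = y, ntree = 500L,
                                    mtry = params$mtry),
    svm_linear = e1071::svm(x = x, y = y, kernel = "linear",
                            cost = params$cost, scale = FALSE,
                            probability = probability),
    svm_radial = e1071::svm(x = x, y = y, kernel = "radial",
                            cost = params$cost, gamma = params$gamma,
                            scale = FALSE, probability = probability),
    nsc = nsc_fit(x, y, delta = params$delta),
    lda = MASS::lda(x = x, grouping = y),
    stop2("unknown algorithm: %s", algorithm)
  ))
}

# strip environment-carrying slots so that serialize() comparisons of two
# identically trained models are byte-identical
clean_model <- function(algorithm, fit) {
  fit$call <- NULL
  if (!is.null(fit$terms)) fit$terms <- NULL
  fit
}

predict_prob <- function(algorithm, fit, x, classes) {
  p <- switch(algorithm,
    rf = predict(fit, x, type = "prob"),
    svm_linear = ,
    svm_radial = {
      pr <- predict(fit, x, probability = TRUE)
      attr(pr, "probabilities")
    },
    nsc = nsc_predict_prob(fit, x),
    lda = predict(fit, x)$posterior,
    stop2("unknown algorithm: %s", algorithm)
  )
  missing_cls <- setdiff(classes, colnames(p))
  if (length(missing_cls))
    stop2("classifier returned no probability column for class(es): %s",
          paste(missing_cls, collapse = ", "))
  p[, classes, drop = FALSE]
}

# hard class predictions (no probability model required)
predict_class <- function(algorithm, fit, x, classes) {
  pred <- switch(algorithm,
    rf = predict(fit, x),
    svm_linear = ,
    svm_radial = predict(fit, x),
    nsc = {
      p <- nsc_predict_prob(fit, x)
      fit$classes[max.col(p, ties.method = "first")]
    },
    lda = predict(fit, x)$class,
    stop2("unknown algorithm: %s", algorithm)
  )
  factor(as.character(pred), levels = classes)
}

# --- nearest shrunken centroids (Tibshirani-style) -------------------------
# Class centroids are shrunk toward the overall centroid by soft-thresholding
# the standardized differences d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0)),
# with m_k = sqrt(1/n_k + 1/n) and s0 = median(s_i). Class posteriors follow
# from Gaussian discriminant scores on the shrunken centroids.

nsc_stats <- function(x, y) {
  n <- nrow(x)
  classes <- levels(y)
  nk <- as.numeric(table(y))
  centroids <- t(vapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                        numeric(ncol(x))))
  overall <- colMeans(x)
  # pooled within-class variance per feature
  ss <- Reduce(`+`, lapply(classes, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    colSums((xc - matrix(colMeans(xc), nrow(xc), ncol(xc), byrow = TRUE))^2)
  }))
  s <- sqrt(ss / (n - length(classes)))
  s0 <- median(s)
  mk <- sqrt(1 / nk + 1 / n)
  dik <- (centroids - matrix(overall, length(classes), ncol(x), byrow = TRUE)) /
    (outer(mk, s + s0))
  list(classes = classes, nk = nk, n = n, centroids = centroids,
       overall = overall, s = s, s0 = s0, mk = mk, dik = dik)
}

nsc_delta_grid <- function(x, y, length_out = 10L) {
  st <- nsc_stats(x, y)
  dmax <- max(abs(st$dik))
  if (!is.finite(dmax) || dmax <= 0) return(0)
  exp(seq(log(dmax * 1e-3), log(dmax), length.out = length_out))
}

nsc_fit <- function(x, y, delta) {
  st <- nsc_stats(x, y)
  shrunk <- sign(st$dik) * pmax(abs(st$dik) - delta, 0)
  st$shrunk_centroids <- matrix(st$overall, length(st$classes), ncol(x),
                                byrow = TRUE) +
    shrunk * outer(st$mk, st$s + st$s0)
  st$delta <- delta
  st$prior <- st$nk / st$n
  class(st) <- "nsc_fit"
  st
}

nsc_predict_prob <- function(fit, x) {
  denom <- (fit$s + fit$s0)^2
  disc <- vapply(seq_along(fit$classes), function(k) {
    dev <- sweep(x, 2L, fit$shrunk_centroids[k, ])
    rowSums(sweep(dev^2, 2L, denom, "/")) - 2 * log(fit$prior[k])
  }, numeric(nrow(x)))
  disc <- matrix(disc, nrow = nrow(x))
  w <- exp(-(disc - apply(disc, 1L, min)) / 2)
  p <- w / rowSums(w)
  dimnames(p) <- list(rownames(x), fit$classes)
  p
}
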