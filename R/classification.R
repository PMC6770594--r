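# Evaluation harness: stratified 80/20 split, panels derived from training
# data only, k-fold CV hyperparameter selection, multiclass AUC, repeats.

#' Stratified train/test split
#'
#' Splits samples into train and test sets, stratified by group so that each
#' group contributes `fraction` of its samples (within one sample) to the
#' training set; without stratification a small group could vanish from a
#' split entirely. Deterministic given the seed.
#'
#' @param labels Group labels named by sample id.
#' @param fraction Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return A `split_plan`: list with `train_ids`, `test_ids`, `fraction`,
#'   `seed`, `stratified`.
#' @export
split_train_test <- function(labels, fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop2("fraction must be in (0, 1)")
  lab <- as_group_labels(labels)
  sizes <- table(lab)
  if (any(sizes < 2L))
    stop2("every group needs >= 2 samples to split; too small: %s",
          paste(names(sizes)[sizes < 2L], collapse = ", "))
  train <- with_seed(seed, {
    unlist(lapply(levels(lab), function(g) {
      ids <- names(lab)[lab == g]
      n_train <- min(max(round(fraction * length(ids)), 1L), length(ids) - 1L)
      sample(ids, n_train)
    }), use.names = FALSE)
  })
  structure(list(train_ids = train,
                 test_ids = setdiff(names(lab), train),
                 fraction = fraction, seed = as.integer(seed),
                 stratified = TRUE),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %d train / %d test (fraction %.2f, seed %d, %s)\n",
              length(x$train_ids), length(x$test_ids), x$fraction, x$seed,
              if (isTRUE(x$stratified)) "stratified" else "unstratified"))
  invisible(x)
}

# stratified, seeded fold assignment for cross-validation
cv_fold_assignment <- function(y, cv_folds, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (g in levels(y)) {
      idx <- which(y == g)
      folds[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
  })
  folds
}

#' One-vs-one multiclass AUC (Hand-Till style)
#'
#' Averages, over all unordered class pairs (i, j) present in the truth, the
#' mean of the two directed pairwise AUCs: column i ranking class-i against
#' class-j samples, and column j ranking class-j against class-i samples.
#' Ties contribute 1/2. For two classes this is the ordinary AUC.
#'
#' @param prob Numeric matrix, samples x classes, rows summing to 1; column
#'   names are class names.
#' @param truth Class membership of each row (factor or character).
#' @return A single numeric AUC in \[0, 1\].
#' @export
multiclass_auc <- function(prob, truth) {
  if (!is.matrix(prob) || is.null(colnames(prob)))
    stop2("prob must be a matrix with class names as colnames")
  if (nrow(prob) != length(truth))
    stop2("prob has %d rows but truth has %d values", nrow(prob), length(truth))
  if (any(abs(rowSums(prob) - 1) > 1e-6))
    stop2("probability rows must sum to 1")
  truth <- factor(as.character(truth))
  present <- levels(truth)[tabulate(truth, nlevels(truth)) > 0L]
  if (length(present) < 2L) stop2("truth must contain at least 2 classes")
  absent <- setdiff(present, colnames(prob))
  if (length(absent))
    stop2("no probability column for class(es): %s", paste(absent, collapse = ", "))
  directed_auc <- function(score, pos) {
    np <- sum(pos); nn <- sum(!pos)
    r <- rank(score)  # midranks: ties count 1/2
    (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  }
  pair_aucs <- c()
  for (i in seq_len(length(present) - 1L)) {
    for (j in seq(i + 1L, length(present))) {
      ci <- present[i]; cj <- present[j]
      sub <- truth %in% c(ci, cj)
      a_ij <- directed_auc(prob[sub, ci], truth[sub] == ci)
      a_ji <- directed_auc(prob[sub, cj], truth[sub] == cj)
      pair_aucs <- c(pair_aucs, (a_ij + a_ji) / 2)
    }
  }
  mean(pair_aucs)
}

derive_panels <- function(m, labels, mode, k, alpha, min_nonzero,
                          digits = NULL) {
  lab <- as_group_labels(labels, colnames(m))
  groups <- sort(levels(lab))
  panels <- lapply(groups, function(g) {
    tryCatch(switch(mode,
      high_mae = select_top_k(
        gene_centered_mae(m, lab, g, min_nonzero = min_nonzero, digits = digits),
        k, "highest", group = g, mode = mode),
      low_mae = select_top_k(
        gene_centered_mae(m, lab, g, min_nonzero = min_nonzero, digits = digits),
        k, "lowest", group = g, mode = mode),
      high_exp = select_top_k(gene_centered_mean_exp(m, lab, g),
                              k, "highest", group = g, mode = mode),
      low_exp = select_top_k(gene_centered_mean_exp(m, lab, g),
                             k, "lowest", group = g, mode = mode),
      de = select_de(de_ttest(m, lab, g), k, alpha = alpha, group = g)
    ), error = function(e) {
      stop2("panel construction failed for group %s (mode %s): %s",
            g, mode, conditionMessage(e))
    })
  })
  setNames(panels, groups)
}

tune_classifier <- function(algorithm, x, y, cv_folds, seed) {
  grid <- default_grid(algorithm, x, y)
  if (nrow(grid) == 1L)
    return(list(best = grid[1L, , drop = FALSE], cv_accuracy = NA_real_,
                grid = grid))
  folds <- cv_fold_assignment(y, cv_folds, seed)
  acc <- vapply(seq_len(nrow(grid)), function(gi) {
    fold_acc <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      if (!any(!tr) || nlevels(droplevels(y[tr])) < nlevels(y)) return(NA_real_)
      fit <- fit_classifier(algorithm, x[tr, , drop = FALSE], y[tr],
                            grid[gi, , drop = FALSE],
                            seed = seed + 131L * gi + f, probability = FALSE)
      mean(predict_class(algorithm, fit, x[!tr, , drop = FALSE],
                         levels(y)) == y[!tr])
    }, numeric(1))
    mean(fold_acc, na.rm = TRUE)
  }, numeric(1))
  best_i <- which.max(acc)  # ties: first grid row
  list(best = grid[best_i, , drop = FALSE], cv_accuracy = acc[best_i],
       grid = cbind(grid, cv_accuracy = acc))
}

#' Run the full feature-selection + classification pipeline once
#'
#' Given a train/test split: (1) derives one gene panel per group from the
#' training samples only; (2) builds the train and test score matrices from
#' those panels; (3) per algorithm, selects hyperparameters by stratified
#' k-fold cross-validation on the training scores; (4) refits the best
#' configuration on the full training set; (5) scores the held-out test set by
#' one-vs-one multiclass AUC. Test labels and test expression values never
#' influence panel derivation or tuning.
#'
#' Features are standardized with train-set mean/sd before the SVMs and LDA;
#' the random forest and the nearest-shrunken-centroids classifier (which
#' standardizes internally by pooled within-class sd) see raw scores.
#'
#' @param m Expression matrix (genes x samples), normalized counts or TPM.
#' @param labels Group labels named by sample id.
#' @param plan A [split_train_test()] plan.
#' @param mode Panel mode: `"high_mae"`, `"low_mae"`, `"high_exp"`,
#'   `"low_exp"` or `"de"`.
#' @param k Panel size per group (default 200).
#' @param algorithms Subset of `c("rf", "svm_linear", "svm_radial", "nsc",
#'   "lda")`.
#' @param cv_folds Cross-validation folds for tuning (default 10).
#' @param alpha Raw p cutoff for the DE route (default 0.05).
#' @param min_nonzero Digit-eligibility minimum for gene-centered MAE.
#' @param seed Seed for folds and model fitting; defaults to the plan's seed.
#' @param keep_models Keep the fitted model objects in the report (needed for
#'   audits; drop to save memory).
#' @param digits Optional precomputed [first_digit_matrix()] of `m`.
#' @return A `classification_report`: list with `panels`, per-algorithm
#'   results (`auc`, `best_params`, `cv_accuracy`, `confusion`, `model`),
#'   `score_kind`, `mode`, `seed`.
#' @export
run_pipeline <- function(m, labels, plan, mode = "high_mae", k = 200L,
                         algorithms = algorithm_names(), cv_folds = 10L,
                         alpha = 0.05, min_nonzero = 10L, seed = plan$seed,
                         keep_models = TRUE, digits = NULL) {
  mode <- match.arg(mode, panel_modes())
  algorithms <- match.arg(algorithms, algorithm_names(), several.ok = TRUE)
  lab <- as_group_labels(labels, colnames(m))
  bad_ids <- setdiff(c(plan$train_ids, plan$test_ids), colnames(m))
  if (length(bad_ids))
    stop2("split plan names samples absent from the matrix: %s",
          paste(head(bad_ids, 5L), collapse = ", "))
  mae_mode <- mode %in% c("high_mae", "low_mae")
  if (mae_mode && is.null(digits)) digits <- first_digit_matrix(unclass(m))

  m_train <- m[, plan$train_ids, drop = FALSE]
  m_test <- m[, plan$test_ids, drop = FALSE]
  d_train <- if (mae_mode) digits[, plan$train_ids, drop = FALSE]
  d_test <- if (mae_mode) digits[, plan$test_ids, drop = FALSE]

  panels <- derive_panels(m_train, lab[plan$train_ids], mode, k, alpha,
                          min_nonzero, digits = d_train)
  s_train <- build_score_matrix(m_train, panels, digits = d_train)
  s_test <- build_score_matrix(m_test, panels, digits = d_test)
  score_kind <- attr(s_train, "score_kind")

  y_train <- factor(lab[plan$train_ids], levels = sort(levels(lab)))
  y_test <- factor(lab[plan$test_ids], levels = sort(levels(lab)))
  classes <- levels(y_train)

  results <- lapply(seq_along(algorithms), function(ai) {
    algorithm <- algorithms[ai]
    x_train <- unclass(s_train); x_test <- unclass(s_test)
    scaling <- NULL
    if (needs_scaling(algorithm)) {
      ctr <- colMeans(x_train)
      scl <- apply(x_train, 2L, sd)
      scl[scl == 0] <- 1
      x_train <- scale(x_train, ctr, scl)
      x_test <- scale(x_test, ctr, scl)
      scaling <- list(center = ctr, scale = scl)
    }
    tuned <- tune_classifier(algorithm, x_train, y_train, cv_folds, seed)
    fit <- fit_classifier(algorithm, x_train, y_train, tuned$best,
                          seed = seed + 7919L * ai, probability = TRUE)
    prob <- predict_prob(algorithm, fit, x_test, classes)
    pred <- factor(classes[max.col(prob, ties.method = "first")],
                   levels = classes)
    list(algorithm = algorithm,
         auc = multiclass_auc(prob, y_test),
         best_params = as.list(tuned$best),
         cv_accuracy = tuned$cv_accuracy,
         confusion = table(truth = y_test, predicted = pred),
         scaling = scaling,
         model = if (keep_models) clean_model(algorithm, fit))
  })
  structure(list(mode = mode, score_kind = score_kind, k = k,
                 panels = panels, algorithms = setNames(results, algorithms),
                 train_score_matrix = s_train, test_score_matrix = s_test,
                 seed = as.integer(seed), plan = plan),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification_report: mode %s (%s scores), %d panels, seed %d\n",
              x$mode, x$score_kind, length(x$panels), x$seed))
  for (res in x$algorithms)
    cat(sprintf("  %-10s AUC = %.4f\n", res$algorithm, res$auc))
  invisible(x)
}

#' Repeat the split/train/test pipeline and aggregate AUCs
#'
#' Runs [run_pipeline()] on `n_repeats` fresh stratified splits (seeds
#' `base_seed`, `base_seed + 1`, ...) and reports the per-algorithm median
#' AUC and interquartile range.
#'
#' @inheritParams run_pipeline
#' @param n_repeats Number of repeated splits (default 10).
#' @param base_seed Seed of the first repeat.
#' @param fraction Training fraction per split.
#' @return An `evaluation_summary`: list with `auc` (one row per algorithm
#'   and repeat) and `summary` (per-algorithm `median_auc` and `iqr`).
#' @export
repeat_evaluation <- function(m, labels, mode = "high_mae", n_repeats = 10L,
                              base_seed = 1L, fraction = 0.8, k = 200L,
                              algorithms = algorithm_names(), cv_folds = 10L,
                              alpha = 0.05, min_nonzero = 10L, digits = NULL) {
  if (n_repeats < 1L) stop2("n_repeats must be >= 1")
  if (mode %in% c("high_mae", "low_mae") && is.null(digits))
    digits <- first_digit_matrix(unclass(m))
  rows <- list()
  for (i in seq_len(n_repeats)) {
    seed_i <- as.integer(base_seed) + i - 1L
    plan <- split_train_test(labels, fraction = fraction, seed = seed_i)
    rep_i <- run_pipeline(m, labels, plan, mode = mode, k = k,
                          algorithms = algorithms, cv_folds = cv_folds,
                          alpha = alpha, min_nonzero = min_nonzero,
                          seed = seed_i, keep_models = FALSE, digits = digits)
    rows[[i]] <- data.frame(algorithm = algorithms, repeat_i = i,
                            seed = seed_i,
                            auc = vapply(rep_i$algorithms, `[[`, numeric(1),
                                         "auc"),
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  auc_table <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(auc_table, auc_table$algorithm),
    function(df) data.frame(algorithm = df$algorithm[1],
                            median_auc = median(df$auc),
                            iqr = stats::IQR(df$auc),
                            n_repeats = nrow(df), row.names = NULL)))
  summ <- summ[match(algorithms, summ$algorithm), , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(auc = auc_table, summary = summ, mode = mode, k = k,
                 fraction = fraction, base_seed = as.integer(base_seed)),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("evaluation_summary: mode %s, %d repeat(s), fraction %.2f\n",
              x$mode, max(x$auc$repeat_i), x$fraction))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Wilcoxon rank-sum test of focus-group scores vs the rest
#'
#' Two-sided rank-sum comparison of one group's per-sample scores against all
#' other groups combined. The p-value is computed by exact enumeration when
#' both sides have at most 25 samples and there are no ties, and by the
#' normal approximation with tie correction (and continuity correction)
#' otherwise.
#'
#' @param scores Per-sample scores named by sample id (e.g. one column of a
#'   [build_score_matrix()] result).
#' @param labels Group labels named by sample id.
#' @param group Focus group name.
#' @return The two-sided p-value.
#' @export
wilcoxon_focus_vs_rest <- function(scores, labels, group) {
  if (is.null(names(scores))) stop2("scores must be named by sample id")
  lab <- as_group_labels(labels, names(scores))
  if (!group %in% levels(lab)) stop2("unknown group: %s", group)
  focus <- scores[lab == group]
  rest <- scores[lab != group]
  if (!length(focus) || !length(rest))
    stop2("both the focus group and the rest must be non-empty")
  use_exact <- length(focus) <= 25L && length(rest) <= 25L &&
    !anyDuplicated(c(focus, rest))
  wilcox.test(focus, rest, alternative = "two.sided", exact = use_exact,
              correct = TRUE)$p.value
}
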