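# Per-group gene panels by three routes (Benford MAE, mean expression,
# Welch-t differential expression) and the per-cell panel scores.

#' Construct a gene panel
#'
#' An ordered gene list selected for one focus group, with selection metadata.
#' `signs` (+1 up-, -1 down-regulated in the focus group) are present exactly
#' for differential-expression panels and feed the polygenic score.
#'
#' @param genes Character vector of unique gene ids, in rank order.
#' @param group Focus group name.
#' @param mode One of `"high_mae"`, `"low_mae"`, `"high_exp"`, `"low_exp"`,
#'   `"de"`.
#' @param signs Integer vector in \{-1, +1\} aligned with `genes` (DE mode
#'   only).
#' @param k_requested The panel size that was asked for (the panel may be
#'   shorter when fewer genes are eligible).
#' @return A `gene_panel` object.
#' @export
gene_panel <- function(genes, group, mode, signs = NULL,
                       k_requested = length(genes)) {
  mode <- match.arg(mode, panel_modes())
  if (anyDuplicated(genes)) stop2("panel genes must be unique")
  if (length(genes) > k_requested)
    stop2("panel holds more genes (%d) than requested (%d)",
          length(genes), k_requested)
  if (mode == "de") {
    if (is.null(signs) || length(signs) != length(genes) ||
        !all(signs %in% c(-1L, 1L)))
      stop2("DE panels require one sign in {-1, +1} per gene")
    signs <- setNames(as.integer(signs), genes)
  } else if (!is.null(signs)) {
    stop2("signs are only meaningful for DE panels")
  }
  structure(list(group = as.character(group), genes = as.character(genes),
                 mode = mode, signs = signs,
                 k_requested = as.integer(k_requested)),
            class = "gene_panel")
}

panel_modes <- function() c("high_mae", "low_mae", "high_exp", "low_exp", "de")

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel: %d genes (requested %d), mode = %s, focus group = %s\n",
              length(x$genes), x$k_requested, x$mode, x$group))
  invisible(x)
}

group_columns <- function(m, labels, group) {
  lab <- as_group_labels(labels, colnames(m))
  if (!group %in% levels(lab)) stop2("unknown group: %s", group)
  ids <- names(lab)[lab == group]
  if (!length(ids)) stop2("group %s has no samples", group)
  ids
}

# digit counts per row (gene) of a digit matrix: genes x 9
row_digit_counts <- function(D) {
  counts <- matrix(0L, nrow(D), 9L, dimnames = list(rownames(D), 1:9))
  for (d in 1:9) counts[, d] <- rowSums(D == d, na.rm = TRUE)
  counts
}

col_digit_counts <- function(D) {
  counts <- matrix(0L, ncol(D), 9L, dimnames = list(colnames(D), 1:9))
  for (d in 1:9) counts[, d] <- colSums(D == d, na.rm = TRUE)
  counts
}

mae_from_counts <- function(counts, e = benford_expected()) {
  n_used <- rowSums(counts)
  A <- counts / n_used  # rows with n_used == 0 become NaN, handled by caller
  mae <- rowMeans(abs(A - matrix(e, nrow(counts), 9L, byrow = TRUE)))
  list(mae = mae, n_used = n_used)
}

#' Gene-centered Benford MAE within one group
#'
#' For each gene, the first digits of its expression values across the cells
#' of the focus group (zeros excluded) are tabulated and the Benford MAE of
#' the resulting distribution is returned. Genes contributing fewer than
#' `min_nonzero` digits are reported as `NA` (ineligible): an MAE estimated
#' from one or two digits is noise and would otherwise dominate the extremes.
#'
#' @param m Expression matrix (genes x samples).
#' @param labels Group labels named by sample id.
#' @param group Focus group name.
#' @param min_nonzero Minimum digits required per gene (default 10).
#' @param digits Optional precomputed [first_digit_matrix()] of `m`.
#' @return Named numeric vector of per-gene MAE, `NA` for ineligible genes,
#'   with the per-gene digit count in attribute `n_nonzero`.
#' @export
gene_centered_mae <- function(m, labels, group, min_nonzero = 10L,
                              digits = NULL) {
  if (min_nonzero < 1L) stop2("min_nonzero must be >= 1")
  ids <- group_columns(m, labels, group)
  D <- if (is.null(digits)) first_digit_matrix(unclass(m)[, ids, drop = FALSE])
       else digits[, ids, drop = FALSE]
  res <- mae_from_counts(row_digit_counts(D))
  mae <- res$mae
  mae[res$n_used < min_nonzero] <- NA_real_
  structure(setNames(mae, rownames(m)), n_nonzero = res$n_used)
}

#' Gene-centered mean expression within one group
#'
#' Arithmetic mean including zeros, per gene, over the focus group's cells.
#'
#' @inheritParams gene_centered_mae
#' @return Named numeric vector of per-gene means.
#' @export
gene_centered_mean_exp <- function(m, labels, group) {
  ids <- group_columns(m, labels, group)
  rowMeans(unclass(m)[, ids, drop = FALSE])
}

#' Welch t-test of each gene: focus group vs all other groups combined
#'
#' Two-sided Welch (unequal-variance) two-sample t-test per gene, vectorized
#' over genes. The sign is +1 when the focus-group mean is at least the rest
#' mean, -1 otherwise. Genes with zero variance on both sides and equal means
#' carry no evidence and are reported `NA`; zero variance with unequal means
#' yields p = 0.
#'
#' @inheritParams gene_centered_mae
#' @return Data frame with one row per gene: `gene_id`, `t_stat`, `df`,
#'   `p_value`, `sign`, `mean_focus`, `mean_rest`.
#' @export
de_ttest <- function(m, labels, group) {
  lab <- as_group_labels(labels, colnames(m))
  if (!group %in% levels(lab)) stop2("unknown group: %s", group)
  focus <- lab == group
  n1 <- sum(focus); n2 <- sum(!focus)
  if (n1 < 2L || n2 < 2L)
    stop2("group %s needs >= 2 samples on each side for a t-test (focus %d, rest %d)",
          group, n1, n2)
  mm <- unclass(m)
  x1 <- mm[, focus, drop = FALSE]
  x2 <- mm[, !focus, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)
  degenerate <- se2 == 0
  # equal means, no variance: no evidence either way
  t_stat[degenerate & m1 == m2] <- NA_real_
  p[degenerate & m1 == m2] <- NA_real_
  p[degenerate & m1 != m2] <- 0
  t_stat[degenerate & m1 != m2] <- sign(m1 - m2)[degenerate & m1 != m2] * Inf
  df[degenerate] <- NA_real_
  data.frame(gene_id = rownames(mm), t_stat = t_stat, df = df, p_value = p,
             sign = ifelse(m1 >= m2, 1L, -1L),
             mean_focus = m1, mean_rest = m2, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Select the top-k genes by a score
#'
#' Ineligible (`NA`) genes are dropped; the rest are sorted by score
#' (descending for `"highest"`, ascending for `"lowest"`) with ties broken by
#' gene id ascending, so panels are deterministic. Returns up to `k` genes.
#'
#' @param scores Named numeric vector (gene id -> score), `NA` = ineligible.
#' @param k Panel size requested (>= 1).
#' @param direction `"highest"` or `"lowest"`.
#' @param group Focus group name recorded in the panel.
#' @param mode Panel mode recorded in the panel (e.g. `"high_mae"`).
#' @return A [gene_panel()].
#' @export
select_top_k <- function(scores, k, direction = c("highest", "lowest"),
                         group = NA_character_, mode) {
  direction <- match.arg(direction)
  if (k < 1L) stop2("k must be >= 1")
  if (is.null(names(scores))) stop2("scores must be named by gene id")
  eligible <- scores[!is.na(scores)]
  if (!length(eligible))
    stop2("empty panel: no eligible genes for group %s", group)
  key <- if (direction == "highest") -eligible else eligible
  ord <- order(key, names(eligible))
  genes <- names(eligible)[ord][seq_len(min(k, length(eligible)))]
  gene_panel(genes, group = group, mode = mode, k_requested = k)
}

#' Select a differential-expression panel
#'
#' Keeps genes with `p <= alpha`, ranks by p ascending (ties by |t|
#' descending, then gene id), takes up to `k`, and attaches the regulation
#' signs for the polygenic score.
#'
#' @param de Result of [de_ttest()].
#' @param k Panel size requested.
#' @param alpha Raw p-value cutoff (default 0.05; no multiplicity correction,
#'   by design of the comparator route).
#' @param group Focus group name recorded in the panel.
#' @return A [gene_panel()] with `mode = "de"` and signs.
#' @export
select_de <- function(de, k, alpha = 0.05, group = NA_character_) {
  if (k < 1L) stop2("k must be >= 1")
  if (alpha <= 0 || alpha > 1) stop2("alpha must be in (0, 1]")
  pass <- de[!is.na(de$p_value) & de$p_value <= alpha, , drop = FALSE]
  if (!nrow(pass))
    stop2("empty panel: no gene reaches p <= %g for group %s", alpha, group)
  ord <- order(pass$p_value, -abs(pass$t_stat), pass$gene_id)
  pass <- pass[ord, , drop = FALSE][seq_len(min(k, nrow(pass))), , drop = FALSE]
  gene_panel(pass$gene_id, group = group, mode = "de", signs = pass$sign,
             k_requested = k)
}

check_panel_genes <- function(m, panel) {
  missing_genes <- setdiff(panel$genes, rownames(m))
  if (length(missing_genes))
    stop2("panel gene(s) absent from matrix: %s%s",
          paste(head(missing_genes, 5L), collapse = ", "),
          if (length(missing_genes) > 5L)
            sprintf(" (and %d more)", length(missing_genes) - 5L) else "")
}

#' Cell-centered Benford MAE over a gene panel
#'
#' For each cell, the first digits of its expression over the panel's genes
#' (zeros excluded) give a digit distribution whose Benford MAE is the cell's
#' score. A cell expressing none of the panel genes is assigned the
#' theoretical maximum [benford_mae_max()] with a warning: on that panel the
#' cell is maximally non-Benford, and dropping it would break the fixed-width
#' feature table the classifiers need.
#'
#' @param m Expression matrix (genes x samples).
#' @param panel A [gene_panel()]; genes must all be present in `m`.
#' @param digits Optional precomputed [first_digit_matrix()] of `m`.
#' @return Named numeric vector of per-cell MAE.
#' @export
cell_centered_mae <- function(m, panel, digits = NULL) {
  check_panel_genes(m, panel)
  D <- if (is.null(digits)) first_digit_matrix(unclass(m)[panel$genes, , drop = FALSE])
       else digits[panel$genes, , drop = FALSE]
  res <- mae_from_counts(col_digit_counts(D))
  empty <- res$n_used == 0
  if (any(empty)) {
    warning(sprintf("%d cell(s) express none of the %d panel genes (group %s); assigned the maximal MAE %.7f",
                    sum(empty), length(panel$genes), panel$group,
                    benford_mae_max()))
    res$mae[empty] <- benford_mae_max()
  }
  setNames(res$mae, colnames(m))
}

#' Cell-centered mean expression over a gene panel
#'
#' Arithmetic mean (zeros included) of the panel genes in each cell.
#'
#' @inheritParams cell_centered_mae
#' @return Named numeric vector of per-cell means.
#' @export
cell_centered_mean_exp <- function(m, panel) {
  check_panel_genes(m, panel)
  colMeans(unclass(m)[panel$genes, , drop = FALSE])
}

#' Polygenic score over a DE panel
#'
#' `PS = sum_i s_i * e_i`: the signed sum of normalized expression values over
#' the panel genes, with s_i = +1 for genes up-regulated in the focus group
#' and -1 for down-regulated ones. Expression is used as-is (normalized counts
#' or TPM), without log transformation.
#'
#' @inheritParams cell_centered_mae
#' @return Named numeric vector of per-cell polygenic scores.
#' @export
polygenic_score <- function(m, panel) {
  if (panel$mode != "de" || is.null(panel$signs))
    stop2("polygenic scores require a DE panel with signs")
  check_panel_genes(m, panel)
  colSums(unclass(m)[panel$genes, , drop = FALSE] * as.numeric(panel$signs))
}

#' Build the samples-by-groups score matrix
#'
#' Given one panel per group (all of the same mode), computes the
#' corresponding cell-centered score of every sample against every panel:
#' `"mae"` via [cell_centered_mae()], `"mean_exp"` via
#' [cell_centered_mean_exp()], `"ps"` via [polygenic_score()]. Columns are
#' ordered by group name, so the feature table is deterministic.
#'
#' @param m Expression matrix (genes x samples).
#' @param panels Named list of [gene_panel()]s, one per group.
#' @param score_kind `"mae"`, `"mean_exp"` or `"ps"`; defaults to the kind
#'   implied by the panels' mode.
#' @param digits Optional precomputed [first_digit_matrix()] of `m`.
#' @return Numeric matrix samples x groups with attribute `score_kind`.
#' @export
build_score_matrix <- function(m, panels, score_kind = NULL, digits = NULL) {
  if (!length(panels)) stop2("need at least one panel")
  modes <- vapply(panels, function(p) p$mode, character(1))
  if (length(unique(modes)) != 1L)
    stop2("mixed panel modes: %s", paste(unique(modes), collapse = ", "))
  groups <- vapply(panels, function(p) p$group, character(1))
  names(panels) <- groups
  if (anyDuplicated(groups)) stop2("multiple panels for the same group")
  score_kind <- score_kind %||% switch(modes[1],
    high_mae = "mae", low_mae = "mae",
    high_exp = "mean_exp", low_exp = "mean_exp",
    de = "ps")
  score_kind <- match.arg(score_kind, c("mae", "mean_exp", "ps"))
  if (score_kind == "ps" && modes[1] != "de")
    stop2("polygenic scores require DE panels")
  if (score_kind == "mae" && is.null(digits))
    digits <- first_digit_matrix(unclass(m))
  groups <- sort(groups)
  scores <- vapply(groups, function(g) {
    p <- panels[[g]]
    switch(score_kind,
           mae      = cell_centered_mae(m, p, digits = digits),
           mean_exp = cell_centered_mean_exp(m, p),
           ps       = polygenic_score(m, p))
  }, numeric(ncol(m)))
  structure(matrix(scores, ncol = length(groups),
                   dimnames = list(colnames(m), groups)),
            score_kind = score_kind)
}

#' Pairwise overlap between gene panels
#'
#' Counts shared genes between panels (e.g. the high-MAE, low-mean-expression
#' and DE panels of one focus group), reproducing the panel-overlap comparison
#' in which Benford-deviant genes coincide mostly with lowly expressed ones.
#'
#' @param panels Named list of [gene_panel()]s.
#' @return Symmetric integer matrix of intersection sizes (diagonal = panel
#'   sizes).
#' @export
panel_overlap <- function(panels) {
  if (is.null(names(panels)) || any(names(panels) == ""))
    stop2("panels must be a named list")
  n <- length(panels)
  out <- matrix(0L, n, n, dimnames = list(names(panels), names(panels)))
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- length(intersect(panels[[i]]$genes, panels[[j]]$genes))
  out
}

#' Per-gene score table for one focus group
#'
#' Convenience summary joining the three per-gene statistics the selection
#' routes use: gene-centered Benford MAE (with eligibility), mean expression,
#' and the Welch t-test vs the other groups.
#'
#' @inheritParams gene_centered_mae
#' @param de Logical; include the Welch t-test columns (needs >= 2 samples on
#'   both sides).
#' @return Data frame with one row per gene: `gene_id`, `group`, `mae`,
#'   `n_nonzero`, `mean_exp`, and (when `de`) `t_stat`, `p_value`, `sign`.
#' @export
gene_score_table <- function(m, labels, group, min_nonzero = 10L,
                             digits = NULL, de = TRUE) {
  mae <- gene_centered_mae(m, labels, group, min_nonzero = min_nonzero,
                           digits = digits)
  out <- data.frame(gene_id = rownames(m), group = group,
                    mae = as.numeric(mae),
                    n_nonzero = as.integer(attr(mae, "n_nonzero")),
                    mean_exp = gene_centered_mean_exp(m, labels, group),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (de) {
    tt <- de_ttest(m, labels, group)
    out$t_stat <- tt$t_stat
    out$p_value <- tt$p_value
    out$sign <- tt$sign
  }
  out
}
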