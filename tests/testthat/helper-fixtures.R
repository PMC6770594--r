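# shared fixtures and independent oracles, built in code at test time

# string-prefix oracle for the first significant digit: scan a positional
# (non-scientific) 12-significant-digit rendering for the first char in 1..9
oracle_first_digit <- function(x) {
  rendered <- format(x, scientific = FALSE, digits = 12, trim = TRUE)
  vapply(strsplit(rendered, ""), function(chars) {
    hit <- match(TRUE, chars %in% as.character(1:9))
    as.integer(chars[hit])
  }, integer(1))
}

# arithmetic route to the first digit (the rendering-free alternative)
arithmetic_first_digit <- function(x) {
  as.integer(floor(x / 10^floor(log10(x))))
}

# direct 9-term oracle for Eq.-style MAE arithmetic
oracle_mae <- function(a, e = log10(1 + 1 / (1:9))) {
  stopifnot(length(a) == 9, length(e) == 9)
  total <- 0
  for (d in 1:9) total <- total + abs(a[d] - e[d])
  total / 9
}

# tiny labeled matrix: 2 groups x 3 cells, 4 genes, hand-set values
tiny_dataset <- function() {
  values <- rbind(
    g_all   = c(12, 22, 31, 47, 55, 68),     # positive everywhere
    g_a     = c(900, 850, 920, 0, 0, 1),     # high in group A
    g_b     = c(0, 1, 0, 300, 310, 290),     # high in group B
    g_zero  = c(0, 0, 0, 0, 0, 0)
  )
  colnames(values) <- paste0("c", 1:6)
  list(matrix = expression_matrix(values, "raw_count"),
       labels = setNames(factor(rep(c("A", "B"), each = 3)),
                         colnames(values)))
}

# small synthetic scenario used across tests; 3 groups, narrow low markers
small_scenario <- function(seed = 11, ...) {
  args <- list(n_groups = 3L, cells_per_group = 60L,
               n_background_genes = 800L, n_markers_per_group = 40L,
               marker_location = c(6.7, 7.4, 8.1), marker_cv = 0.15,
               dropout_rate = 0.3, seed = seed)
  do.call(synthetic_spec, modifyList(args, list(...)))
}

# expression matrix whose high-exp panels separate groups perfectly:
# each group has exclusive genes expressed only in its own cells
separable_dataset <- function(n_per_group = 30, n_groups = 3, seed = 42) {
  with_seed_local <- function(code) { set.seed(seed); code }
  groups <- paste0("T", seq_len(n_groups))
  cells <- sprintf("s%03d", seq_len(n_per_group * n_groups))
  lab <- setNames(factor(rep(groups, each = n_per_group)), cells)
  with_seed_local({
    bg <- matrix(round(10^runif(50 * length(cells), 0, 3)), nrow = 50,
                 dimnames = list(sprintf("bg%02d", 1:50), cells))
    marker_rows <- do.call(rbind, lapply(groups, function(g) {
      block <- matrix(0, 5, length(cells),
                      dimnames = list(sprintf("ex_%s_%d", g, 1:5), cells))
      block[, lab == g] <- 5000 + matrix(rpois(5 * n_per_group, 50), 5)
      block
    }))
    m <- expression_matrix(rbind(bg, marker_rows), "normalized")
  })
  list(matrix = m, labels = lab)
}
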