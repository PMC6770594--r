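test_that("gene-centered MAE matches digit arithmetic on constructed genes", {
  n_cells <- 54
  cells <- sprintf("c%02d", 1:n_cells)
  v <- rbind(
    const7 = rep(7.0, n_cells),                      # point mass on digit 7
    unif   = rep(1:9, length.out = n_cells) * 1.0,   # uniform digits
    sparse = c(rep(0, n_cells - 3), 5, 5, 5)         # too few digits
  )
  colnames(v) <- cells
  lab <- setNames(factor(rep("A", n_cells)), cells)
  mae <- gene_centered_mae(expression_matrix(v, "normalized"), lab, "A",
                           min_nonzero = 10)
  # frozen from the 9-term oracle: point mass on d gives 2*(1 - E_d)/9
  expect_equal(unname(mae["const7"]), 2 * (1 - log10(8 / 7)) / 9,
               tolerance = 1e-12)
  expect_equal(unname(mae["const7"]), 0.2093351229, tolerance = 1e-9)
  expect_equal(unname(mae["unif"]), oracle_mae(rep(1 / 9, 9)),
               tolerance = 1e-12)
  expect_true(is.na(mae["sparse"]))
  expect_identical(unname(attr(mae, "n_nonzero")["sparse"]), 3)
  expect_error(gene_centered_mae(expression_matrix(v, "normalized"), lab, "B"),
               "unknown group")
})

test_that("a Benford-exact gene has near-zero gene-centered MAE", {
  set.seed(601)
  n <- 20000
  v <- matrix(10^runif(n, 0, 3), 1, dimnames = list("g", sprintf("c%05d", 1:n)))
  lab <- setNames(factor(rep("A", n)), colnames(v))
  expect_lt(gene_centered_mae(expression_matrix(v, "normalized"), lab, "A")["g"],
            0.01)
})

test_that("gene_centered_mean_exp averages over the group including zeros", {
  d <- tiny_dataset()
  me_a <- gene_centered_mean_exp(d$matrix, d$labels, "A")
  expect_equal(unname(me_a["g_b"]), mean(c(0, 1, 0)))
  expect_equal(unname(me_a["g_a"]), mean(c(900, 850, 920)))
  # brute-force oracle on a random matrix
  set.seed(602)
  v <- matrix(rpois(50 * 20, 7), 50,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
  lab <- setNames(factor(rep(c("X", "Y"), each = 10)), colnames(v))
  got <- gene_centered_mean_exp(expression_matrix(v, "raw_count"), lab, "Y")
  oracle <- apply(v[, 11:20], 1, mean)
  expect_equal(got, oracle)
})

test_that("select_top_k ranks with deterministic tie-breaks", {
  p <- select_top_k(c(g1 = 0.1, g2 = 0.3, g3 = 0.2), 2, "highest",
                    group = "A", mode = "high_mae")
  expect_identical(p$genes, c("g2", "g3"))
  expect_identical(p$k_requested, 2L)

  # k beyond the eligible count returns everything eligible
  p2 <- select_top_k(c(g1 = 0.1, g2 = NA, g3 = 0.2), 10, "lowest",
                     group = "A", mode = "low_mae")
  expect_identical(p2$genes, c("g1", "g3"))

  # sorted-pairs oracle on 10,000 scores with planted duplicates
  set.seed(603)
  scores <- round(runif(10000), 3)  # heavy ties
  names(scores) <- sprintf("g%05d", sample(1:10000))
  scores[sample(10000, 100)] <- NA
  got <- select_top_k(scores, 500, "highest", group = "A", mode = "high_mae")
  elig <- scores[!is.na(scores)]
  oracle <- names(elig)[order(-elig, names(elig))][1:500]
  expect_identical(got$genes, oracle)
  got_low <- select_top_k(scores, 500, "lowest", group = "A", mode = "low_mae")
  oracle_low <- names(elig)[order(elig, names(elig))][1:500]
  expect_identical(got_low$genes, oracle_low)

  expect_error(select_top_k(c(g1 = NA_real_), 5, "highest", group = "A",
                            mode = "high_mae"), "empty panel")
})

test_that("de_ttest is the Welch test, vectorized", {
  cells <- paste0("c", 1:6)
  lab <- setNames(factor(rep(c("F", "R"), each = 3)), cells)
  v <- rbind(spec_case = c(1, 2, 3, 4, 5, 6))
  set.seed(604)
  v <- rbind(v, matrix(rpois(40 * 6, 20) + runif(240), 40,
                       dimnames = list(paste0("g", 1:40), NULL)))
  colnames(v) <- cells
  de <- de_ttest(expression_matrix(v, "normalized"), lab, "F")

  expect_equal(de$t_stat[1], -3.674235, tolerance = 1e-6)
  expect_equal(de$df[1], 4, tolerance = 1e-9)
  expect_equal(de$p_value[1], 0.02131164, tolerance = 1e-6)
  expect_identical(de$sign[1], -1L)

  # stats::t.test as the oracle for every gene
  for (i in seq_len(nrow(v))) {
    ref <- stats::t.test(v[i, 1:3], v[i, 4:6])
    expect_equal(de$t_stat[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(de$p_value[i], ref$p.value, tolerance = 1e-10)
  }

  expect_error(de_ttest(expression_matrix(v[, 1:4], "normalized"),
                        lab[1:4][c(1, 2, 3, 4)], "R"),
               ">= 2 samples")
})

test_that("degenerate genes in de_ttest follow the documented policy", {
  cells <- paste0("c", 1:8)
  lab <- setNames(factor(rep(c("F", "R"), each = 4)), cells)
  v <- rbind(flat = rep(2, 8),                 # no variance, equal means -> NA
             step = rep(c(5, 1), each = 4))    # no variance, shifted -> p = 0
  colnames(v) <- cells
  de <- de_ttest(expression_matrix(v, "normalized"), lab, "F")
  expect_true(is.na(de$p_value[de$gene_id == "flat"]))
  expect_identical(de$p_value[de$gene_id == "step"], 0)
  expect_identical(de$sign[de$gene_id == "step"], 1L)
})

test_that("select_de filters by alpha and ranks by p with signs attached", {
  de <- data.frame(gene_id = c("gene1", "gene2", "gene3"),
                   t_stat = c(3, 1, -2.5), p_value = c(0.01, 0.2, 0.04),
                   sign = c(1L, 1L, -1L))
  p <- select_de(de, k = 2, alpha = 0.05, group = "A")
  expect_identical(p$genes, c("gene1", "gene3"))
  expect_identical(unname(p$signs), c(1L, -1L))
  expect_identical(p$mode, "de")

  all_null <- transform(de, p_value = c(0.2, 0.3, 0.9))
  expect_error(select_de(all_null, 2, 0.05, "A"), "empty panel")
})

test_that("null genes pass alpha at the nominal rate", {
  set.seed(605)
  n_genes <- 5000
  cells <- sprintf("c%03d", 1:60)
  lab <- setNames(factor(rep(c("F", "R"), each = 30)), cells)
  v <- matrix(rnorm(n_genes * 60, mean = 50, sd = 5), n_genes,
              dimnames = list(paste0("g", 1:n_genes), cells))
  de <- de_ttest(expression_matrix(v, "normalized"), lab, "F")
  n_pass <- sum(de$p_value <= 0.05)
  # binomial(5000, 0.05): mean 250, sd 15.4; allow +- 4 sd
  expect_gte(n_pass, 250 - 62)
  expect_lte(n_pass, 250 + 62)
})

test_that("cell-centered MAE scores panels per cell with max-MAE fallback", {
  cells <- c("full", "empty", "benford")
  set.seed(606)
  v <- matrix(0, 10, 3, dimnames = list(paste0("g", 1:10), cells))
  v[1:9, "full"] <- 1:9                 # uniform digits
  v[1:9, "benford"] <- 10^runif(9, 0, 3)
  panel <- gene_panel(paste0("g", 1:9), group = "A", mode = "high_mae")
  m <- expression_matrix(v, "normalized")
  expect_warning(sc <- cell_centered_mae(m, panel), "maximal MAE")
  expect_equal(unname(sc["full"]), oracle_mae(rep(1 / 9, 9)), tolerance = 1e-12)
  expect_equal(unname(sc["empty"]), benford_mae_max())

  bad <- gene_panel(c("g1", "nope"), group = "A", mode = "high_mae")
  expect_error(cell_centered_mae(m, bad), "nope")
})

test_that("cell-centered MAE over all genes equals the module-level MAE", {
  sim <- generate_expression(small_scenario(seed = 607))
  m <- sim$matrix
  panel <- gene_panel(rownames(m), group = "all", mode = "high_mae",
                      k_requested = nrow(m))
  sc <- cell_centered_mae(m, panel)
  for (cell in sample(colnames(m), 5)) {
    h <- digit_histogram(unclass(m)[, cell])
    expect_equal(unname(sc[cell]), benford_mae(to_distribution(h)),
                 tolerance = 1e-12)
  }
})

test_that("cell_centered_mean_exp and polygenic_score are exact sums", {
  v <- matrix(c(2, 4, 0,
                5, 2, 7), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  m <- expression_matrix(v, "normalized")
  pe <- gene_panel(c("a", "b"), group = "A", mode = "low_exp")
  expect_equal(unname(cell_centered_mean_exp(m, pe)), c(3.5, 3, 3.5))

  pd <- gene_panel(c("a", "b"), group = "A", mode = "de", signs = c(1L, -1L))
  expect_equal(unname(polygenic_score(m, pd)), c(2 - 5, 4 - 2, 0 - 7))
  expect_error(polygenic_score(m, pe), "DE panel")

  # elementwise-product-sum oracle on a 200-gene panel
  set.seed(608)
  v2 <- matrix(runif(250 * 8, 0, 100), 250,
               dimnames = list(paste0("g", 1:250), paste0("s", 1:8)))
  genes <- sample(rownames(v2), 200)
  signs <- sample(c(-1L, 1L), 200, TRUE)
  p200 <- gene_panel(genes, group = "A", mode = "de", signs = signs)
  got <- polygenic_score(expression_matrix(v2, "normalized"), p200)
  oracle <- apply(v2[genes, ], 2, function(col) sum(col * signs))
  expect_equal(got, oracle)
  # all-zero expression gives PS 0
  z <- expression_matrix(matrix(0, 250, 2,
                                dimnames = list(rownames(v2), c("z1", "z2"))),
                         "normalized")
  expect_equal(unname(polygenic_score(z, p200)), c(0, 0))
})

test_that("build_score_matrix is complete, ordered, and kind-checked", {
  sim <- generate_expression(small_scenario(seed = 609))
  m <- normalize_counts(sim$matrix)
  lab <- sim$truth$labels
  panels <- lapply(levels(lab), function(g)
    select_top_k(gene_centered_mae(m, lab, g), 40, "highest",
                 group = g, mode = "high_mae"))
  s <- build_score_matrix(m, panels)
  expect_identical(dim(s), c(ncol(m), 3L))
  expect_identical(colnames(s), sort(levels(lab)))
  expect_identical(rownames(s), colnames(m))
  expect_identical(attr(s, "score_kind"), "mae")
  expect_false(anyNA(s))

  # single panel column equals the per-cell operation directly
  s1 <- build_score_matrix(m, panels[1])
  expect_equal(s1[, 1], cell_centered_mae(m, panels[[1]]))

  mixed <- panels
  mixed[[2]] <- gene_panel(panels[[2]]$genes, group = panels[[2]]$group,
                           mode = "low_exp")
  expect_error(build_score_matrix(m, mixed), "mixed panel modes")
})

test_that("focus-group scores separate focus from rest (Wilcoxon)", {
  sim <- generate_expression(small_scenario(seed = 610, cells_per_group = 100L))
  m <- normalize_counts(sim$matrix)
  lab <- sim$truth$labels
  g <- levels(lab)[1]
  panel <- select_top_k(gene_centered_mae(m, lab, g), 40, "highest",
                        group = g, mode = "high_mae")
  sc <- cell_centered_mae(m, panel)
  expect_lt(wilcoxon_focus_vs_rest(sc, lab, g), 1e-6)
})

test_that("panels are byte-deterministic given identical inputs", {
  sim <- generate_expression(small_scenario(seed = 611))
  m <- normalize_counts(sim$matrix)
  lab <- sim$truth$labels
  p1 <- select_top_k(gene_centered_mae(m, lab, levels(lab)[2]), 40, "highest",
                     group = levels(lab)[2], mode = "high_mae")
  p2 <- select_top_k(gene_centered_mae(m, lab, levels(lab)[2]), 40, "highest",
                     group = levels(lab)[2], mode = "high_mae")
  expect_identical(serialize(p1, NULL), serialize(p2, NULL))
})

test_that("high-MAE and low-EXP panels overlap far more than high-EXP", {
  sim <- generate_expression(small_scenario(seed = 612))
  m <- normalize_counts(sim$matrix)
  lab <- sim$truth$labels
  g <- levels(lab)[1]
  tab <- gene_score_table(m, lab, g)
  # k sized to the full marker pool (all groups' markers are narrow and low
  # in every group), where the deviant and lowly expressed gene sets coincide
  k <- 100
  panels <- list(
    high_mae = select_top_k(setNames(tab$mae, tab$gene_id), k, "highest",
                            group = g, mode = "high_mae"),
    low_exp = select_top_k(setNames(tab$mean_exp, tab$gene_id), k, "lowest",
                           group = g, mode = "low_exp"),
    high_exp = select_top_k(setNames(tab$mean_exp, tab$gene_id), k, "highest",
                            group = g, mode = "high_exp"),
    de = select_de(tab[, c("gene_id", "t_stat", "p_value", "sign")], k,
                   group = g)
  )
  ov <- panel_overlap(panels)
  expect_identical(ov["high_mae", "high_mae"], 100L)
  # Benford-deviant genes are the lowly expressed ones, never the high ones
  expect_gt(ov["high_mae", "low_exp"], 0.7 * k)
  expect_lt(ov["high_mae", "high_exp"], 0.05 * k)
})

test_that("narrow low-expression genes out-score broad-range genes on MAE", {
  sim <- generate_expression(small_scenario(seed = 613))
  m <- normalize_counts(sim$matrix)
  lab <- sim$truth$labels
  g <- levels(lab)[1]
  mae <- gene_centered_mae(m, lab, g)
  mexp <- gene_centered_mean_exp(m, lab, g)
  markers <- sim$truth$marker_genes[[g]]
  background <- sim$truth$background_genes
  expect_gt(median(mae[markers], na.rm = TRUE),
            median(mae[background], na.rm = TRUE) + 0.05)
  expect_lt(median(mexp[markers]), median(mexp[background]))
})
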