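# Construct a tiny bundle directly with controlled properties.
toy_bundle <- function(counts, meta = NULL) {
  if (is.null(meta))
    meta <- data.frame(barcode = colnames(counts),
                       condition = "c")
  cell_bundle(counts, meta)
}

test_that("QC boundaries are strict in the stated direction", {
  set.seed(1)
  n_genes <- 600
  counts <- matrix(0L, n_genes, 4,
                   dimnames = list(paste0("g", 1:n_genes),
                                   paste0("c", 1:4)))
  counts[1:499, 1] <- 1L   # 499 expressed genes -> removed
  counts[1:500, 2] <- 1L   # 500 -> retained
  counts[1:550, 3] <- 1L
  counts[1:550, 4] <- 1L
  meta <- data.frame(barcode = paste0("c", 1:4), condition = "x",
                     mito_frac = c(0.05, 0.05, 0.16, 0.15),
                     doublet_score = c(0.1, 0.1, 0.1, 0.1))
  out <- qc_filter(toy_bundle(counts, meta))
  expect_identical(colnames(out$counts), c("c2", "c4"))
  rep <- attr(out, "qc_report")
  expect_equal(rep$fail_min_genes, 1L)
  expect_equal(rep$fail_max_mito, 1L)
  expect_equal(rep$n_removed, 2L)
  # doublet boundary and missing-column behaviour
  meta$doublet_score <- c(0.26, 0.25, 0.1, 0.1)
  out2 <- qc_filter(toy_bundle(counts, meta))
  expect_false("c1" %in% colnames(out2$counts))
  expect_warning(qc_filter(toy_bundle(counts, meta[, -4])), "doublet")
  expect_error(qc_filter(toy_bundle(counts, meta[, -4]), strict = TRUE),
               "doublet_score")
})

test_that("planted QC violations are exactly the removed set", {
  cfg <- tiny_cfg(seed = 21)
  sc <- gen_sc(cfg)
  b <- cell_bundle(sc$counts, sc$meta)
  min_genes <- 50
  bad <- Matrix::colSums(b$counts > 0) < min_genes |
    b$meta$mito_frac > 0.08 | b$meta$doublet_score > 0.25
  out <- qc_filter(b, min_genes = min_genes, max_mito = 0.08)
  expect_identical(colnames(out$counts), colnames(b$counts)[!bad])
})

test_that("normalisation matches the closed form and preserves totals", {
  counts <- matrix(0L, 3, 2, dimnames = list(c("g1", "g2", "g3"),
                                             c("c1", "c2")))
  counts[, 1] <- c(25L, 2475L, 0L)   # total 2500, g1 scales to 100
  counts[, 2] <- c(10L, 40L, 0L)
  b <- normalize_cells(toy_bundle(counts))
  expect_equal(b$norm["g1", "c1"], log(101), tolerance = 1e-12)
  expect_equal(unname(Matrix::colSums(expm1(as.matrix(b$norm)))),
               c(1e4, 1e4), tolerance = 1e-6)
  expect_true(all(b$norm["g3", ] == 0))  # all-zero gene stays zero
  counts[, 2] <- 0L
  expect_error(normalize_cells(toy_bundle(counts)), "zero-count")
})

test_that("rank-sum p matches the textbook example and degenerate cases", {
  expect_equal(mirshift:::rank_sum_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(mirshift:::rank_sum_p(c(5, 5, 5), c(5, 5, 5)), 1)
  # symmetry: swapping groups preserves p
  set.seed(2)
  for (i in 1:20) {
    a <- sample(0:4, 6, replace = TRUE); b <- sample(0:4, 7, replace = TRUE)
    expect_equal(mirshift:::rank_sum_p(a, b), mirshift:::rank_sum_p(b, a))
  }
})

test_that("exact rank-sum equals the exhaustive-enumeration oracle with ties", {
  set.seed(3)
  for (i in 1:40) {
    nA <- sample(2:7, 1); nB <- sample(2:7, 1)
    # ties likely: small discrete support
    a <- sample(0:3, nA, replace = TRUE)
    b <- sample(0:3, nB, replace = TRUE)
    expect_equal(mirshift:::rank_sum_p(a, b), oracle_rank_sum_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("wilcoxon DE returns calibrated, symmetric, corrected results", {
  cfg <- tiny_cfg(seed = 22, state_props = list(
    control = c(homeostatic = 0.6, DAM = 0.2, IRM = 0.2),
    perturbed = c(homeostatic = 0.5, DAM = 0.3, IRM = 0.2)))
  sc_c <- gen_sc(cfg, condition = "control", direction = "KD")
  sc_p <- gen_sc(cfg, condition = "perturbed", direction = "KD")
  b <- cell_bundle(cbind(sc_c$counts, sc_p$counts),
                   rbind(sc_c$meta, sc_p$meta))
  b <- normalize_cells(qc_filter(b, min_genes = 30))
  de <- wilcoxon_de(b, cell_type = "MG",
                    contrast = c("perturbed", "control"))
  de_rev <- wilcoxon_de(b, cell_type = "MG",
                        contrast = c("control", "perturbed"))
  expect_equal(de$logFC, -de_rev$logFC, tolerance = 1e-12)
  expect_equal(de$p, de_rev$p, tolerance = 1e-12)
  expect_true(all(de$p_adj >= de$p - 1e-15))
  expect_equal(de$p_adj, pmin(1, de$p * nrow(de)))
  # bonferroni by hand: p = 0.01, m = 5 -> 0.05
  expect_equal(pmin(1, 0.01 * 5), 0.05)
  # planted targets move in the DE (derepression under KD)
  up <- de$gene[de$p_adj < 0.05 & de$logFC > 0]
  expect_gte(length(intersect(up, sc_c$truth$true_target_ids)), 1L)
  # too few cells: empty table with warning
  expect_warning(empty <- wilcoxon_de(b, cell_type = "absent",
                                      contrast = c("perturbed", "control")),
                 "fewer than")
  expect_equal(nrow(empty), 0L)
})

test_that("label permutation within a cell type keeps raw p calibrated", {
  cfg <- sim_config(seed = 23, n_genes = 2000, n_true_targets = 10,
                    n_cells_per_condition = 80, genes_per_program = 20)
  sc <- gen_sc(cfg, condition = "control")
  b <- normalize_cells(qc_filter(cell_bundle(sc$counts, sc$meta),
                                 min_genes = 30))
  set.seed(24)
  fake <- sample(rep(c("A", "B"), length.out = ncol(b$counts)))
  b$meta$condition <- fake
  de <- wilcoxon_de(b, cell_type = "MG", contrast = c("A", "B"))
  expect_lt(abs(mean(de$p < 0.05) - 0.05), 0.015)
})

test_that("markers recover planted state programs and respect thresholds", {
  recalls <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = 500 + s, n_genes = 400, n_true_targets = 10,
                      n_cells_per_condition = 240, genes_per_program = 15,
                      program_strength = 2)
    sc <- gen_sc(cfg, condition = "control")
    b <- normalize_cells(qc_filter(cell_bundle(sc$counts, sc$meta),
                                   min_genes = 30))
    mk <- find_markers(b, b$meta$true_state)
    tr <- sc$truth
    rec <- vapply(tr$states, function(st) {
      found <- mk$gene[mk$cluster == st & mk$marker]
      mean(tr$state_programs[[st]] %in% found)
    }, numeric(1))
    mean(rec)
  }, numeric(1))
  expect_gte(mean(recalls), 0.9)
})

test_that("a gene can pass the screen without reaching marker thresholds", {
  # construct two clusters where one gene has logFC between 0.25 and 0.5
  set.seed(25)
  nc <- 40
  counts <- matrix(rpois(2 * 2 * nc, 50), 2, 2 * nc,
                   dimnames = list(c("gA", "gB"),
                                   paste0("c", seq_len(2 * nc))))
  b <- toy_bundle(counts)
  b <- normalize_cells(b)
  # engineer a modest shift on gA in cluster 1 on the normalised scale
  b$norm["gA", seq_len(nc)] <- b$norm["gA", seq_len(nc)] + 0.05
  cl <- rep(c("one", "two"), each = nc)
  lfc <- mirshift:::ln_fold_change(
    as.matrix(b$norm[, cl == "one", drop = FALSE]),
    as.matrix(b$norm[, cl == "two", drop = FALSE]))
  mk <- find_markers(b, cl, screen_logfc = 0.01, marker_logfc = 0.5)
  row <- mk[mk$cluster == "one" & mk$gene == "gA", ]
  expect_equal(nrow(row), 1L)        # screened in
  expect_false(row$marker)           # but logFC <= 0.5
  expect_lt(row$logFC, 0.5)
})

test_that("shuffled cluster labels yield no Bonferroni-level markers", {
  cfg <- sim_config(seed = 26, n_genes = 500, n_true_targets = 10,
                    n_cells_per_condition = 200, genes_per_program = 15,
                    program_strength = 2)
  sc <- gen_sc(cfg, condition = "control")
  b <- normalize_cells(qc_filter(cell_bundle(sc$counts, sc$meta),
                                 min_genes = 30))
  set.seed(27)
  shuffled <- sample(b$meta$true_state)
  mk <- find_markers(b, shuffled)
  m <- nrow(b$counts)
  expect_equal(sum(mk$p < 0.05 / m), 0L)
})

test_that("pseudobulk concordance follows the covariance formula", {
  sc <- data.frame(gene = paste0("g", 1:10), logFC = c(1:10) / 5)
  pr <- data.frame(protein = paste0("g", 1:10), log2FC = c(1:10) / 5)
  expect_equal(pseudobulk_corr(sc, pr)$r, 1)
  pr$log2FC <- -pr$log2FC
  expect_equal(pseudobulk_corr(sc, pr)$r, -1)
  set.seed(28)
  sc$logFC <- rnorm(10); pr$log2FC <- rnorm(10)
  got <- pseudobulk_corr(sc, pr)
  x <- sc$logFC; y <- pr$log2FC
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_oracle, tolerance = 1e-12)
  expect_equal(got$n_pairs, 10L)
  expect_warning(out <- pseudobulk_corr(sc[1:2, ], pr), "fewer than 3")
  expect_true(is.na(out$r))
})
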