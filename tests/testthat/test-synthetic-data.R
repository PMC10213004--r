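pats <- seed_patterns("UAACAGUCUACAGCCAUGGUCG")

test_that("config validation rejects malformed settings", {
  expect_error(sim_config(n_genes = 0), "count")
  expect_error(sim_config(gc = 1), "\\(0, 1\\)")
  expect_error(sim_config(state_props = list(a = c(x = 0.5, y = 0.4),
                                             b = c(x = 0.5, y = 0.5))),
               "sum to 1")
  expect_error(sim_config(planted_sites = c(foo = 1L)), "site types")
  expect_error(sim_config(n_true_targets = 10, n_genes = 5), "more true")
})

test_that("UTRs carry the planted sites and only true targets carry them", {
  cfg <- sim_config(seed = 5, n_utrs = 10, utr_len = 200, n_genes = 50,
                    n_true_targets = 5, genes_per_program = 5,
                    planted_sites = c("8mer" = 1L))
  u <- gen_utrs(cfg, pats)
  expect_length(u$utrs, 10L)
  has_site <- grepl(chartr("U", "T", pats[["8mer"]]), u$utrs, fixed = TRUE)
  is_target <- names(u$utrs) %in% u$truth$true_target_ids
  expect_true(all(has_site[is_target]))
  expect_equal(sum(is_target), 5L)
  # planted positions are recorded exactly
  for (i in seq_len(nrow(u$planted))) {
    s <- u$planted$start[i]
    pat <- chartr("U", "T", pats[[u$planted$site_type[i]]])
    expect_identical(substr(u$utrs[[u$planted$utr_id[i]]], s,
                            s + nchar(pat) - 1L), pat)
  }
})

test_that("substring search recovers at least the planted counts per type", {
  for (rep in 1:25) {
    cfg <- sim_config(seed = 100 + rep, n_utrs = 8, utr_len = 150,
                      n_genes = 40, n_true_targets = 4,
                      genes_per_program = 5,
                      planted_sites = c("8mer" = 1L, "6mer" = 2L))
    u <- gen_utrs(cfg, pats)
    for (ty in c("8mer", "6mer")) {
      pat <- chartr("U", "T", pats[[ty]])
      for (id in u$truth$true_target_ids) {
        n_found <- length(gregexpr(pat, u$utrs[[id]], fixed = TRUE)[[1]])
        expect_gte(n_found, cfg$planted_sites[[ty]])
      }
    }
  }
})

test_that("identical config yields byte-identical artifacts; alphabet is clean", {
  cfg <- tiny_cfg(seed = 9)
  expect_identical(gen_utrs(cfg, pats)$utrs, gen_utrs(cfg, pats)$utrs)
  expect_identical(gen_evidence(cfg), gen_evidence(cfg))
  expect_identical(gen_proteome(cfg)$intensity, gen_proteome(cfg)$intensity)
  s1 <- gen_sc(cfg); s2 <- gen_sc(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$meta, s2$meta)
  expect_false(grepl("[^ACGTUN]", paste(gen_utrs(cfg, pats)$utrs,
                                        collapse = "")))
  expect_true(all(s1$counts@x >= 0 & s1$counts@x == round(s1$counts@x)))
})

test_that("requested sites that cannot fit raise a sizing error", {
  cfg <- sim_config(seed = 1, n_utrs = 4, utr_len = 20, n_genes = 10,
                    n_true_targets = 2, genes_per_program = 2,
                    planted_sites = c("8mer" = 3L))
  expect_error(gen_utrs(cfg, pats), "fit|place")
})

test_that("noiseless evidence recovers exactly the true targets", {
  cfg <- tiny_cfg(seed = 2, predictor_sens = 1, predictor_spec = 1,
                  clip_lambda_true = 50, clip_lambda_false = 0)
  ev <- gen_evidence(cfg)
  tr <- sim_truth(cfg)
  sel <- select_predicted(ev, min_predictors = 2, min_clip = 1)
  expect_identical(sel, sort(tr$true_target_ids))
  # zero sensitivity: no predictor hits on true targets
  ev0 <- gen_evidence(tiny_cfg(seed = 2, predictor_sens = 0))
  flags <- as.matrix(ev0[grep("^pred", names(ev0))])
  expect_equal(sum(flags[ev0$gene %in% tr$true_target_ids, ]), 0)
})

test_that("per-predictor hit rates are within 3 binomial SDs of nominal", {
  cfg <- sim_config(seed = 31, n_genes = 2000, n_true_targets = 200,
                    predictor_sens = 0.9, predictor_spec = 0.95)
  ev <- gen_evidence(cfg)
  tr <- sim_truth(cfg)
  is_true <- ev$gene %in% tr$true_target_ids
  flags <- as.matrix(ev[grep("^pred", names(ev))])
  for (j in seq_len(ncol(flags))) {
    r_true <- mean(flags[is_true, j])
    sd_true <- sqrt(0.9 * 0.1 / sum(is_true))
    expect_lt(abs(r_true - 0.9), 3 * sd_true)
    r_false <- mean(flags[!is_true, j])
    sd_false <- sqrt(0.05 * 0.95 / sum(!is_true))
    expect_lt(abs(r_false - 0.05), 3 * sd_false)
  }
})

test_that("proteome plants the promised group difference", {
  # null: no planted effect
  cfg0 <- tiny_cfg(seed = 3, repression_log2 = 0)
  pr0 <- gen_proteome(cfg0)
  tr0 <- pr0$truth
  x <- log2(pr0$intensity)
  is_true <- rownames(x) %in% tr0$true_target_ids
  diff <- rowMeans(x[is_true, pr0$groups == "perturbed"], na.rm = TRUE) -
    rowMeans(x[is_true, pr0$groups == "control"], na.rm = TRUE)
  se <- stats::sd(diff) / sqrt(length(diff))
  expect_lt(abs(mean(diff)), 3 * se)
  # overexpression: targets shift down by repression_log2
  cfg1 <- tiny_cfg(seed = 4, repression_log2 = 1)
  pr1 <- gen_proteome(cfg1, direction = "OE")
  x1 <- log2(pr1$intensity)
  is_true1 <- rownames(x1) %in% pr1$truth$true_target_ids
  d1 <- rowMeans(x1[is_true1, pr1$groups == "perturbed"], na.rm = TRUE) -
    rowMeans(x1[is_true1, pr1$groups == "control"], na.rm = TRUE)
  se1 <- stats::sd(d1) / sqrt(length(d1))
  expect_lt(abs(mean(d1) + 1), 3 * se1)
})

test_that("degenerate state proportions put every cell in the first state", {
  cfg <- tiny_cfg(seed = 6, state_props = list(
    control = c(homeostatic = 1, DAM = 0, IRM = 0),
    perturbed = c(homeostatic = 1, DAM = 0, IRM = 0)))
  sc <- gen_sc(cfg, condition = "control")
  expect_true(all(sc$meta$true_state == "homeostatic"))
})

test_that("empirical state fractions track state_props within 3 multinomial SDs", {
  cfg <- sim_config(seed = 8, n_genes = 200, n_true_targets = 10,
                    n_cells_per_condition = 2000, genes_per_program = 15)
  sc <- gen_sc(cfg, condition = "control")
  props <- cfg$state_props$control
  for (s in names(props)) {
    obs <- mean(sc$meta$true_state == s)
    sd_s <- sqrt(props[[s]] * (1 - props[[s]]) / 2000)
    expect_lt(abs(obs - props[[s]]), 3 * sd_s + 1e-12)
  }
})

test_that("program_strength = 0 removes state-specific expression", {
  frac_flat <- vapply(1:20, function(r) {
    cfg <- sim_config(seed = 400 + r, n_genes = 150, n_true_targets = 6,
                      n_cells_per_condition = 150, genes_per_program = 10,
                      program_strength = 0)
    sc <- gen_sc(cfg, condition = "control")
    tr <- sc$truth
    x <- as.matrix(sc$counts)
    ps <- unlist(lapply(tr$states, function(s) {
      in_s <- sc$meta$true_state == s
      vapply(tr$state_programs[[s]], function(g)
        tryCatch(stats::t.test(x[g, in_s], x[g, !in_s])$p.value,
                 error = function(e) 1), numeric(1))
    }))
    mean(ps > 0.01)
  }, numeric(1))
  expect_gte(mean(frac_flat), 0.95)
})

test_that("fixture bundle writes a complete, deterministic, round-tripping set", {
  cfg <- sim_config(seed = 12, n_genes = 120, n_true_targets = 6,
                    n_utrs = 30, utr_len = 150,
                    n_cells_per_condition = 60, genes_per_program = 10)
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- write_fixture_bundle(cfg, d1)
  m2 <- write_fixture_bundle(cfg, d2)
  expect_gte(length(m1), 8L)
  expect_true(all(file.exists(file.path(d1, names(m1)))))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_identical(unlist(m1), unlist(m2))  # same seed, same hashes
  # truth JSON round-trips
  tr_disk <- read_truth(file.path(d1, "truth.json"))
  tr_mem <- sim_truth(cfg)
  expect_identical(sort(tr_disk$true_target_ids),
                   sort(tr_mem$true_target_ids))
  expect_identical(lapply(tr_disk$state_programs, sort),
                   lapply(tr_mem$state_programs, sort))
  # written artifacts reload consistently
  pr <- read_proteome(file.path(d1, "proteome.tsv"))
  expect_equal(dim(pr$intensity), c(120L, 2L * cfg$n_samples_per_group))
  counts <- Matrix::readMM(file.path(d1, "counts.mtx"))
  expect_equal(dim(counts), c(120L, 120L))
  sigs <- read_gmt(file.path(d1, "signatures.gmt"))
  expect_identical(lapply(sigs, sort), lapply(tr_mem$state_programs, sort))
  unlink(c(d1, d2), recursive = TRUE)
})
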