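test_that("simulation is deterministic and truth-consistent", {
  cfg <- sim_config(n_genes = 200, seed = 42)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)

  expect_equal(nrow(a$design), 16L)
  expect_setequal(a$truth$gene_id, rownames(a$counts$counts))
  expect_true(all(a$truth[a$truth$class == "null",
                          grep("^lfc_", names(a$truth))] == 0))
  expect_error(simulate_counts(sim_config(n_genes = 0)), "positive")
})

test_that("column sums track the expected library sizes", {
  cfg <- sim_config(n_genes = 3000, seed = 8)
  sim <- simulate_counts(cfg)
  expected <- attr(sim$counts, "expected_library_sizes")
  phi <- sim$truth$dispersion
  # sd of a column sum of independent NB draws
  for (k in seq_along(expected)) {
    mu <- expected[k] * sim$truth$baseline / sum(sim$truth$baseline)
    sd_k <- sqrt(sum(mu + phi * mu^2))
    expect_lt(abs(sim$counts$library_sizes[k] - expected[k]), 3 * sd_k)
  }
})

test_that("variance/mean approaches the Poisson limit as dispersion -> 0", {
  cfg <- sim_config(n_genes = 4000, dispersion_shape = 1e-4,
                    dispersion_scale = 1e-4, baseline_sdlog = 0.2,
                    lib_size_range = c(1, 1),
                    class_fractions = c(null = 1, shared_up = 0,
                                        shared_down = 0,
                                        resistant_specific_up = 0,
                                        sensitive_specific_up = 0,
                                        divergent_opposite = 0,
                                        inconsistent_within_group = 0),
                    seed = 4)
  sim <- simulate_counts(cfg)
  y <- sim$counts$counts
  # all 16 samples share one mean per gene: pooled variance/mean ratio ~ 1
  ratio <- mean(apply(y, 1, stats::var) / rowMeans(y))
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("planted fold changes are recovered at low dispersion", {
  cfg <- sim_config(n_genes = 3000,
                    dispersion_shape = 2, dispersion_scale = 0.01,
                    class_fractions = c(null = 0.95, shared_up = 0,
                                        shared_down = 0,
                                        resistant_specific_up = 0.05,
                                        sensitive_specific_up = 0,
                                        divergent_opposite = 0,
                                        inconsistent_within_group = 0),
                    effect_sizes = c(shared_up = 2, shared_down = 2,
                                     resistant_specific_up = 3,
                                     sensitive_specific_up = 2,
                                     divergent_opposite = 3,
                                     inconsistent_within_group = 2),
                    within_sd = 0, seed = 3)
  sim <- simulate_counts(cfg)
  norm <- tmm_factors(sim$counts)
  gr <- make_groupings(sim$design)
  tr <- sim$truth
  sel <- tr$class == "resistant_specific_up" & tr$baseline >= 50
  expect_gt(sum(sel), 30)
  for (gt in c("Hermes", "TMP1919")) {
    fc <- fold_changes(norm$cpm, gr[[gt]], pseudo = 0.5)
    err <- fc$log2FC[match(tr$gene_id[sel], fc$gene_id)] - 3
    expect_gte(mean(abs(err) <= 0.5), 0.9)
  }
  # sensitive genotypes are untouched by this class
  fc_sens <- fold_changes(norm$cpm, gr$Lira, pseudo = 0.5)
  err_sens <- fc_sens$log2FC[match(tr$gene_id[sel], fc_sens$gene_id)]
  expect_lt(abs(mean(err_sens)), 0.2)
})

test_that("Ct simulation inverts planted log2FC exactly when noise-free", {
  truth <- data.frame(gene_id = c("q1", "q2", "q3"), class = "x",
                      lfc_Hermes = c(2, 0, -1.5), stringsAsFactors = FALSE)
  design <- one_genotype_design("Hermes")
  ct <- simulate_ct_table(truth, truth$gene_id, noise_sd = 0, seed = 9)
  dd <- ddct_table(ct, design, genotypes = "Hermes")
  expect_equal(dd$ddCt[match(truth$gene_id, dd$target_gene)],
               -truth$lfc_Hermes, tolerance = 1e-12)
  expect_error(simulate_ct_table(truth, "absent_gene"), "absent_gene")
})

test_that("Ct values outside the 23-32 cycle range are clamped with warning", {
  truth <- data.frame(gene_id = "q1", class = "x", lfc_Hermes = 8,
                      stringsAsFactors = FALSE)
  expect_warning(ct <- simulate_ct_table(truth, "q1", noise_sd = 0, seed = 2),
                 "clamped")
  expect_true(all(ct$ct >= 23 & ct$ct <= 32))
})
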