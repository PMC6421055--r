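test_that("consistency score matches its defining cases", {
  expect_equal(consistency_score(c(1, 1)), 1)
  expect_equal(consistency_score(c(1, -1)), 0)
  # printed resistant-cultivar values for the top MADS-box transcript
  expect_equal(consistency_score(c(2.3, 3.0)), 5.3 / 6, tolerance = 1e-12)
  expect_equal(consistency_score(c(0, 0)), 1)  # identical zero changes
  expect_error(consistency_score(numeric(0)), "non-empty")
  expect_error(consistency_score(c(1, NA)), "finite")
  # scale-free
  x <- c(0.4, 1.7, -0.2)
  expect_equal(consistency_score(3.7 * x), consistency_score(x),
               tolerance = 1e-12)
})

delta_one <- function(res, sens) {
  lm <- matrix(c(res, sens), 1,
               dimnames = list("g", c("R1", "R2", "S1", "S2")))
  delta_scores(lm, list(resistant = c("R1", "R2"),
                        sensitive = c("S1", "S2")))
}

test_that("delta-score reproduces the hand-evaluated printed-input example", {
  d <- delta_one(c(2.3, 3.0), c(-0.3, -0.5))
  expect_equal(d$C_res, 5.3 / 6, tolerance = 1e-12)
  expect_equal(d$C_sens, 0.8, tolerance = 1e-12)
  expect_equal(d$mean_res, 2.65)
  expect_equal(d$mean_sens, -0.4)
  expect_equal(d$S_delta, (5.3 / 6) * 0.8 * 2.65 * 3.05^2, tolerance = 1e-12)
  expect_equal(d$S_delta, 17.42048, tolerance = 1e-5)
})

test_that("delta-score vanishes without divergence or without consistency", {
  expect_equal(delta_one(c(1.2, 1.2), c(1.2, 1.2))$S_delta, 0)
  for (x in c(0.5, 1, 3))  # within-group sign disagreement nullifies
    expect_equal(delta_one(c(x, -x), c(5, 4))$S_delta, 0)
})

test_that("delta-score obeys group-swap symmetry and the lambda^3 scaling law", {
  set.seed(33)
  for (i in 1:25) {
    res <- rnorm(2, 0, 2); sens <- rnorm(2, 0, 2)
    lam <- runif(1, 0.1, 5)
    s <- delta_one(res, sens)$S_delta
    expect_equal(delta_one(sens, res)$S_delta, s, tolerance = 1e-12)
    expect_equal(delta_one(lam * res, lam * sens)$S_delta, lam^3 * s,
                 tolerance = 1e-10)
    # permutation within a group changes nothing
    expect_equal(delta_one(rev(res), sens)$S_delta, s, tolerance = 1e-12)
  }
})

test_that("delta table validates inputs and orders deterministically", {
  lm <- matrix(c(2, 2, 0, 0,
                 1, 1, -1, -1,
                 0.1, -0.1, 0, 0), 3, byrow = TRUE,
               dimnames = list(c("gA", "gB", "gC"),
                               c("R1", "R2", "S1", "S2")))
  groups <- list(resistant = c("R1", "R2"), sensitive = c("S1", "S2"))
  d <- delta_scores(lm, groups)
  expect_identical(d$gene_id, c("gA", "gB", "gC"))  # S: 8 > 4 > 0
  expect_identical(d$rank, 1:3)

  lm_na <- lm; lm_na[2, 1] <- NA
  expect_error(delta_scores(lm_na, groups), "gB")

  d2 <- top_divergent(d, 2)
  expect_identical(d2$gene_id, c("gA", "gB"))
  expect_warning(all3 <- top_divergent(d, 10), "exceeds")
  expect_equal(nrow(all3), 3L)
  expect_error(top_divergent(d, 0), ">= 1")
})

test_that("delta_scores accepts per-genotype fold-change tables and a design", {
  sim <- simulate_counts(sim_config(n_genes = 100, seed = 2))
  cpm <- compute_cpm(sim$counts)
  gr <- make_groupings(sim$design)
  gts <- unique(sim$design$genotype)
  fc <- lapply(gr[gts], function(g) fold_changes(cpm, g))
  d <- delta_scores(fc, sim$design)
  expect_equal(nrow(d), 100L)
  expect_true(all(d$S_delta >= 0))
  expect_true(all(d$C_res >= 0 & d$C_res <= 1))
  expect_true(!is.unsorted(-d$S_delta))
})

test_that("within-group-inconsistent genes score below equally-sized divergent ones", {
  cfg <- sim_config(n_genes = 2000,
                    class_fractions = c(null = 0.9, shared_up = 0,
                                        shared_down = 0,
                                        resistant_specific_up = 0,
                                        sensitive_specific_up = 0,
                                        divergent_opposite = 0.05,
                                        inconsistent_within_group = 0.05),
                    effect_sizes = c(shared_up = 2, shared_down = 2,
                                     resistant_specific_up = 2,
                                     sensitive_specific_up = 2,
                                     divergent_opposite = 2,
                                     inconsistent_within_group = 2),
                    seed = 19)
  sim <- simulate_counts(cfg)
  filt <- filter_low_expression(sim$counts)
  norm <- tmm_factors(filt)
  gr <- make_groupings(sim$design)
  gts <- unique(sim$design$genotype)
  fc <- lapply(gr[gts], function(g) fold_changes(norm$cpm, g))
  d <- delta_scores(fc, sim$design)
  cls <- sim$truth$class[match(d$gene_id, sim$truth$gene_id)]
  expect_gt(mean(d$S_delta[cls == "divergent_opposite"]),
            mean(d$S_delta[cls == "inconsistent_within_group"]))
})
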