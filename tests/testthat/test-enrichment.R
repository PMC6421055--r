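test_that("top lists follow the significance, direction and capping rules", {
  set.seed(40)
  n <- 400
  # 220 significant, 130 of them up; the rest well above alpha
  tab <- data.frame(gene_id = sprintf("g%03d", 1:n),
                    log2FC = c(rep(1, 130), rep(-1, 90), rep(1, 180)),
                    p_value = c(seq(1e-6, 0.049, length.out = 220),
                                seq(0.06, 0.9, length.out = 180)))
  ranked <- rank_by_significance(tab)
  expect_warning(expect_warning(build_top_lists(ranked, sizes = 300),
                                "only 130"), "only 90")
  tops <- suppressWarnings(build_top_lists(ranked))
  expect_equal(lengths(tops$up), c(`50` = 50, `100` = 100, `300` = 130,
                                   all = 130))
  expect_equal(unname(lengths(tops$down)["all"]), 90)

  # zero log2FC genes belong to neither direction
  tab0 <- data.frame(gene_id = c("a", "b"), log2FC = c(0, 2),
                     p_value = c(0.001, 0.001))
  suppressWarnings(t0 <- build_top_lists(rank_by_significance(tab0),
                                         sizes = 1))
  expect_identical(t0$up[["all"]], "b")
  expect_length(t0$down[["all"]], 0)
})

test_that("hypergeometric enrichment matches brute-force enumeration", {
  uni <- sprintf("u%02d", 1:20)
  annot <- make_annot(c(
    stats::setNames(lapply(1:5, function(i) c("T1", "T2")), uni[1:5]),
    stats::setNames(lapply(6:20, function(i) "T2"), uni[6:20])))
  top <- uni[c(1:4, 20)]  # k = 4 of K = 5 for T1
  res <- hypergeom_enrich(top, uni, annot)
  # brute force: sum over overlap j >= 4 of C(5,j) C(15,5-j) / C(20,5)
  brute <- (choose(5, 4) * choose(15, 1) + choose(5, 5)) / choose(20, 5)
  expect_equal(res$p_value[res$term_id == "T1"], brute, tolerance = 1e-12)
  expect_equal(res$p_value[res$term_id == "T1"], 76 / 15504,
               tolerance = 1e-12)
  # term covering the whole universe is never enriched
  expect_equal(res$p_value[res$term_id == "T2"], 1)

  # zero overlap gives the whole mass
  res0 <- hypergeom_enrich(uni[6:10], uni, annot, min_term_size = 3)
  expect_equal(res0$p_value[res0$term_id == "T1"], 1)

  expect_error(hypergeom_enrich(c(top, "stranger"), uni, annot), "stranger")
})

test_that("hypergeometric p is monotone in the overlap and the pmf sums to 1", {
  N <- 30; K <- 8; n <- 10
  p <- stats::phyper(0:min(K, n) - 1, K, N - K, n, lower.tail = FALSE)
  expect_true(all(diff(p) <= 1e-12))
  expect_equal(sum(stats::dhyper(0:K, K, N - K, n)), 1, tolerance = 1e-12)
})

test_that("Wallenius with unit weights reduces to the hypergeometric test", {
  uni <- sprintf("u%02d", 1:20)
  annot <- make_annot(c(
    stats::setNames(lapply(1:5, function(i) c("T1", "T2")), uni[1:5]),
    stats::setNames(lapply(6:20, function(i) "T2"), uni[6:20])))
  top <- uni[c(1:4, 20)]
  h <- hypergeom_enrich(top, uni, annot)
  w1 <- wallenius_enrich(top, uni, annot,
                         weights = stats::setNames(rep(1, 20), uni))
  expect_lt(max(abs(w1$p_value[match(h$term_id, w1$term_id)] - h$p_value)),
            1e-9)
  # doubling all weights leaves the odds (and p) unchanged
  w2 <- wallenius_enrich(top, uni, annot,
                         weights = stats::setNames(rep(2, 20), uni))
  expect_equal(w2$p_value, w1$p_value, tolerance = 1e-12)
  expect_error(wallenius_enrich(top, uni, annot,
                                weights = stats::setNames(rep(-1, 20), uni)),
               "positive")
})

test_that("Wallenius pmf matches exact urn enumeration at odds 2 (N = 20)", {
  N <- 20; K <- 5; n <- 5; w <- 2
  # exact: propagate draw-by-draw probabilities through the biased urn
  probs <- matrix(0, n + 1, n + 1)
  probs[1, 1] <- 1
  for (d in 0:(n - 1)) for (k in 0:d) {
    pr <- probs[d + 1, k + 1]
    if (pr == 0) next
    remK <- K - k; remO <- (N - K) - (d - k)
    tot <- w * remK + remO
    if (remK > 0)
      probs[d + 2, k + 2] <- probs[d + 2, k + 2] + pr * w * remK / tot
    if (remO > 0)
      probs[d + 2, k + 1] <- probs[d + 2, k + 1] + pr * remO / tot
  }
  exact_pmf <- probs[n + 1, ]
  ours <- vapply(0:n, altox:::.dwallenius, numeric(1), N = N, K = K,
                 n = n, w = w)
  expect_lt(max(abs(ours - exact_pmf)), 1e-10)
  expect_equal(altox:::.pwallenius_upper(4, N, K, n, w), sum(exact_pmf[5:6]),
               tolerance = 1e-10)
})

test_that("a GO term planted on divergent genes tops the enrichment list", {
  set.seed(55)
  universe <- sprintf("g%04d", 1:800)
  divergent <- universe[1:50]
  top <- c(divergent[1:40], universe[701:710])  # 80% of divergent in the top
  map <- lapply(stats::setNames(universe, universe), function(g) character(0))
  map[divergent] <- list("GO:DIV")
  # 49 decoy terms of random size
  for (i in 1:49) {
    members <- sample(universe, 25)
    for (g in members) map[[g]] <- c(map[[g]], sprintf("GO:%04d", i))
  }
  map <- map[lengths(map) > 0]
  res <- hypergeom_enrich(top, universe, make_annot(map))
  expect_identical(res$term_id[1], "GO:DIV")
  expect_equal(min(res$bh_fdr), res$bh_fdr[res$term_id == "GO:DIV"])
})
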