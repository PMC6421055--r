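#' Build the four comparison groupings of the design
#'
#' The analysis contrasts aluminum stress vs control within: the pool of all
#' genotypes, the pool of resistant cultivars, the pool of sensitive
#' cultivars, and each individual genotype.
#'
#' @param design Validated sample design (see [validate_design]).
#' @return Named list of groupings; each is a list with `name`, `stress` and
#'   `control` sample-id vectors.
#' @export
make_groupings <- function(design) {
  pick <- function(rows, name) {
    g <- list(name = name,
              stress = design$sample_id[rows & design$condition == "stress"],
              control = design$sample_id[rows & design$condition == "control"])
    if (!length(g$stress) || !length(g$control))
      stop("grouping '", name, "' has an empty arm")
    g
  }
  out <- list(all = pick(rep(TRUE, nrow(design)), "all"),
              resistant = pick(design$tolerance == "resistant", "resistant"),
              sensitive = pick(design$tolerance == "sensitive", "sensitive"))
  for (gt in unique(design$genotype))
    out[[gt]] <- pick(design$genotype == gt, gt)
  out
}

#' Per-gene fold changes for one comparison grouping
#'
#' Fold change is the ratio of mean stress CPM to mean control CPM, with a
#' small pseudocount added to both arm means so the ratio is defined for
#' genes silent in one condition; `log2FC = log2(FC)`.
#'
#' @param cpm CPM matrix (genes x samples), typically the effective CPM from
#'   [tmm_factors].
#' @param grouping One element of [make_groupings].
#' @param pseudo Pseudocount in CPM units added to both arm means
#'   (default 0.5).
#' @return Data frame: `gene_id`, `unit` (grouping name), `mean_cpm_control`,
#'   `mean_cpm_stress`, `FC`, `log2FC`.
#' @export
fold_changes <- function(cpm, grouping, pseudo = 0.5) {
  miss <- setdiff(c(grouping$stress, grouping$control), colnames(cpm))
  if (length(miss))
    stop("samples absent from CPM matrix: ", paste(miss, collapse = ", "))
  if (!length(grouping$stress) || !length(grouping$control))
    stop("grouping '", grouping$name, "' has an empty arm")
  ms <- rowMeans(cpm[, grouping$stress, drop = FALSE])
  mc <- rowMeans(cpm[, grouping$control, drop = FALSE])
  fc <- (ms + pseudo) / (mc + pseudo)
  data.frame(gene_id = rownames(cpm), unit = grouping$name,
             mean_cpm_control = mc, mean_cpm_stress = ms,
             FC = fc, log2FC = log2(fc),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Pooled method-of-moments common dispersion across genes, from counts
# already scaled to a common library size. Arms given as column indices.
.mom_common_dispersion <- function(y, arms) {
  num <- 0; den <- 0
  for (idx in arms) {
    n_j <- length(idx)
    if (n_j < 2) next
    sub <- y[, idx, drop = FALSE]
    m <- rowMeans(sub)
    ss <- rowSums((sub - m)^2)
    num <- num + sum(ss - (n_j - 1) * m)
    den <- den + sum((n_j - 1) * m^2)
  }
  if (den == 0)
    stop("common dispersion not estimable (no replicated arms); ",
         "supply 'dispersion' explicitly")
  max(0, num / den)
}

# Two-sided conditional NB exact p for one gene: s1 successes in arm 1 out
# of total s, with the conditional law Beta-Binomial(s, n1/phi, n2/phi)
# (binomial(s, n1/(n1+n2)) in the phi -> 0 limit). Doubling the smaller
# tail, capped at 1.
.exact_p_one <- function(s1, s, n1, n2, phi) {
  if (s == 0) return(1)
  if (phi <= 1e-12) {
    pr <- n1 / (n1 + n2)
    lower <- stats::pbinom(s1, s, pr)
    upper <- stats::pbinom(s1 - 1, s, pr, lower.tail = FALSE)
  } else {
    r1 <- n1 / phi; r2 <- n2 / phi
    x <- 0:s
    logp <- lchoose(s, x) + lbeta(x + r1, s - x + r2) - lbeta(r1, r2)
    pmf <- exp(logp)
    lower <- sum(pmf[x <= s1])
    upper <- sum(pmf[x >= s1])
  }
  min(1, 2 * min(lower, upper))
}

#' Conditional negative-binomial exact test
#'
#' A documented analogue of the classic two-group NB exact test: counts are
#' scaled to a common effective library size (mean scaling) and rounded, a
#' common dispersion is estimated across genes by a pooled method-of-moments
#' ratio estimator (variance = mu + phi mu^2) unless supplied, and for each
#' gene the two-sided p-value is the doubled smaller tail of the
#' conditional distribution of the first arm's sum given the gene's total
#' -- a beta-binomial with shape parameters proportional to the arm sizes
#' over phi (binomial when phi = 0). Equivalence with edgeR's
#' quantile-adjusted conditional likelihood numbers is not claimed.
#'
#' @param counts A [count_matrix].
#' @param grouping One element of [make_groupings].
#' @param norm Optional [tmm_factors] result; its factors define the
#'   effective library sizes.
#' @param dispersion Optional fixed common dispersion phi; `NULL` (default)
#'   estimates it from the data. `0` gives the Poisson/binomial limit.
#' @return Named numeric vector of p-values in (0, 1], one per gene;
#'   attribute `dispersion` carries the value used.
#' @export
exact_test <- function(counts, grouping, norm = NULL, dispersion = NULL) {
  y <- counts$counts
  i1 <- match(grouping$control, colnames(y))
  i2 <- match(grouping$stress, colnames(y))
  if (anyNA(i1) || anyNA(i2))
    stop("grouping samples absent from counts")
  eff <- counts$library_sizes
  if (!is.null(norm)) eff <- eff * norm$factors[names(eff)]
  n_mean <- mean(eff[c(i1, i2)])
  ys <- round(sweep(y[, c(i1, i2), drop = FALSE], 2,
                    n_mean / eff[c(i1, i2)], "*"))
  k1 <- seq_along(i1); k2 <- length(i1) + seq_along(i2)
  if (all(colSums(ys) == 0))
    stop("all counts zero in the tested arms")
  if (is.null(dispersion))
    dispersion <- .mom_common_dispersion(ys, list(k1, k2))
  s1 <- rowSums(ys[, k1, drop = FALSE])
  s2 <- rowSums(ys[, k2, drop = FALSE])
  n1 <- length(k1); n2 <- length(k2)
  p <- vapply(seq_len(nrow(ys)), function(g) {
    .exact_p_one(s1[g], s1[g] + s2[g], n1, n2, dispersion)
  }, numeric(1))
  names(p) <- rownames(y)
  attr(p, "dispersion") <- dispersion
  p
}

#' Order a fold-change table by statistical significance
#'
#' Ascending p-value, ties broken by descending absolute log2FC and then by
#' gene id; a Benjamini-Hochberg FDR column and a rank column are appended.
#'
#' @param table Data frame with columns `gene_id`, `log2FC` and `p_value`.
#' @return The table re-ordered, with `fdr` and `rank` columns.
#' @export
rank_by_significance <- function(table) {
  if (!all(c("gene_id", "log2FC", "p_value") %in% names(table)))
    stop("table needs gene_id, log2FC and p_value columns")
  table$fdr <- stats::p.adjust(table$p_value, method = "BH")
  ord <- order(table$p_value, -abs(table$log2FC), table$gene_id)
  table <- table[ord, , drop = FALSE]
  table$rank <- seq_len(nrow(table))
  rownames(table) <- NULL
  table
}

#' Fold changes plus exact-test significance for one grouping
#'
#' Convenience wrapper combining [fold_changes], [exact_test] and
#' [rank_by_significance] into the ranked differential-expression table for
#' one comparison grouping.
#'
#' @inheritParams exact_test
#' @param pseudo Pseudocount for the fold-change ratio (default 0.5 CPM).
#' @return Ranked data frame with fold-change, `p_value`, `fdr` and `rank`
#'   columns.
#' @export
de_table <- function(counts, grouping, norm = NULL, pseudo = 0.5,
                     dispersion = NULL) {
  cpm <- if (is.null(norm)) compute_cpm(counts) else norm$cpm
  fc <- fold_changes(cpm, grouping, pseudo)
  p <- exact_test(counts, grouping, norm, dispersion)
  fc$p_value <- as.numeric(p[fc$gene_id])
  rank_by_significance(fc)
}
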