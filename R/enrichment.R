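#' Top lists of up- and downregulated genes
#'
#' From a significance-ranked differential-expression table, builds per
#' direction (up: `log2FC > 0`; down: `log2FC < 0`; zero log2FC belongs to
#' neither) the tops of the requested sizes among genes significant at
#' `alpha`, plus an `"all"` list of every significant gene in that
#' direction. Requested sizes larger than the number of significant genes
#' are capped (with a warning).
#'
#' @param ranked Table from [rank_by_significance] (columns `gene_id`,
#'   `log2FC`, `p_value`, ordered by rank).
#' @param sizes Top-list sizes (default `c(50, 100, 300)`).
#' @param alpha Significance cutoff on the raw p-value (default 0.05).
#' @return List with elements `up` and `down`; each a named list of gene-id
#'   vectors (`"50"`, `"100"`, `"300"`, `"all"` by default).
#' @export
build_top_lists <- function(ranked, sizes = c(50, 100, 300), alpha = 0.05) {
  if (!all(c("gene_id", "log2FC", "p_value") %in% names(ranked)))
    stop("ranked table needs gene_id, log2FC and p_value columns")
  sig <- ranked[ranked$p_value < alpha, , drop = FALSE]
  one_dir <- function(dir) {
    genes <- if (dir == "up") sig$gene_id[sig$log2FC > 0]
             else sig$gene_id[sig$log2FC < 0]
    out <- list()
    for (s in sizes) {
      if (s > length(genes))
        warning("only ", length(genes), " significant ", dir,
                " genes for requested top ", s)
      out[[as.character(s)]] <- utils::head(genes, s)
    }
    out[["all"]] <- genes
    out
  }
  list(up = one_dir("up"), down = one_dir("down"))
}

# term -> genes index restricted to the universe
.term_index <- function(annot, universe) {
  map <- if (is.list(annot) && !is.null(annot$map)) annot$map else annot
  map <- map[intersect(names(map), universe)]
  if (!length(map)) return(list())
  gene <- rep(names(map), lengths(map))
  split(gene, unlist(map, use.names = FALSE))
}

.annot_labels <- function(annot) {
  if (is.list(annot) && !is.null(annot$labels)) annot$labels else character(0)
}

.enrich_frame <- function(terms, labels, N, K, n, k, p) {
  lab <- unname(labels[terms]); lab[is.na(lab)] <- ""
  out <- data.frame(term_id = terms, term_label = lab,
                    n_universe = N, n_annotated = K, n_top = n,
                    n_overlap = k, p_value = p,
                    stringsAsFactors = FALSE)
  out$bh_fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric GO over-representation of a top list
#'
#' For every GO term annotating at least `min_term_size` universe genes,
#' tests over-representation in the top list with the upper-tail
#' hypergeometric probability `P(X >= k)`, `X ~ Hypergeom(N, K, n)`, where
#' `N` is the universe size (genes tested after filtering), `K` the term's
#' universe genes and `k` its overlap with the top list. BH correction is
#' applied across the tested terms.
#'
#' @param top Gene-id vector; must be a subset of `universe`.
#' @param universe Gene-id vector of all tested genes.
#' @param annot Annotation map: result of [read_go_map] or a named list
#'   `gene id -> character vector of term ids`. Genes absent from the map
#'   are simply unannotated.
#' @param min_term_size Minimum universe genes per tested term (default 3).
#' @return Data frame: `term_id`, `term_label`, `n_universe`, `n_annotated`,
#'   `n_top`, `n_overlap`, `p_value`, `bh_fdr`, ordered by p-value.
#' @export
hypergeom_enrich <- function(top, universe, annot, min_term_size = 3) {
  offenders <- setdiff(top, universe)
  if (length(offenders))
    stop("top genes outside the universe: ",
         paste(utils::head(offenders, 5), collapse = ", "))
  idx <- .term_index(annot, universe)
  K <- lengths(idx)
  idx <- idx[K >= min_term_size]
  if (!length(idx))
    return(.enrich_frame(character(0), character(0), integer(0), integer(0),
                         integer(0), integer(0), numeric(0)))
  N <- length(unique(universe))
  n <- length(unique(top))
  K <- lengths(idx)
  k <- vapply(idx, function(g) length(intersect(g, top)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  .enrich_frame(names(idx), .annot_labels(annot), N, K, n, k, p)
}

# Wallenius' noncentral hypergeometric pmf at x for (N, K, n) and odds w,
# by numerical integration of the standard integral representation.
.dwallenius <- function(x, N, K, n, w) {
  d <- w * (K - x) + (N - K - (n - x))
  if (d <= 0) return(if (x == K && n - x == N - K) 1 else 0)
  integrand <- function(t) (1 - t^(w / d))^x * (1 - t^(1 / d))^(n - x)
  int <- stats::integrate(integrand, 0, 1, rel.tol = 1e-12,
                          subdivisions = 500L)$value
  exp(lchoose(K, x) + lchoose(N - K, n - x)) * int
}

# Upper-tail P(X >= k), mass normalized over the support.
.pwallenius_upper <- function(k, N, K, n, w) {
  supp <- max(0, n - (N - K)):min(n, K)
  pmf <- vapply(supp, .dwallenius, numeric(1), N = N, K = K, n = n, w = w)
  pmf <- pmf / sum(pmf)
  sum(pmf[supp >= k])
}

#' Weighted (Wallenius) GO over-representation
#'
#' Variant of [hypergeom_enrich] for a biased sampling of the top list
#' (e.g. gene-length bias): the null is Wallenius' noncentral hypergeometric
#' distribution with odds equal to the mean user weight of the term's genes
#' over the mean weight of the remaining universe. With all weights equal it
#' reduces to the central hypergeometric test.
#'
#' @inheritParams hypergeom_enrich
#' @param weights Positive per-gene weights, named by gene id, covering the
#'   universe.
#' @return As [hypergeom_enrich], with an extra `odds` column.
#' @export
wallenius_enrich <- function(top, universe, annot, weights,
                             min_term_size = 3) {
  offenders <- setdiff(top, universe)
  if (length(offenders))
    stop("top genes outside the universe: ",
         paste(utils::head(offenders, 5), collapse = ", "))
  if (is.null(names(weights)) || length(setdiff(universe, names(weights))))
    stop("weights must be named and cover the universe")
  w <- weights[universe]
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  idx <- .term_index(annot, universe)
  K <- lengths(idx)
  idx <- idx[K >= min_term_size]
  if (!length(idx)) {
    out <- .enrich_frame(character(0), character(0), integer(0), integer(0),
                         integer(0), integer(0), numeric(0))
    out$odds <- numeric(0)
    return(out)
  }
  N <- length(unique(universe))
  n <- length(unique(top))
  K <- lengths(idx)
  k <- vapply(idx, function(g) length(intersect(g, top)), integer(1))
  odds <- vapply(idx, function(g) {
    rest <- setdiff(universe, g)
    if (!length(rest)) return(1)  # term covers the whole universe
    mean(w[g]) / mean(w[rest])
  }, numeric(1))
  p <- mapply(.pwallenius_upper, k = k, K = K, w = odds,
              MoreArgs = list(N = N, n = n))
  out <- .enrich_frame(names(idx), .annot_labels(annot), N, K, n, k, p)
  out$odds <- odds[match(out$term_id, names(idx))]
  out
}
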