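#' Within-group consistency score of expression changes
#'
#' For the per-genotype log2 fold changes of one tolerance group,
#' `C = |sum(logfc)| / (n * max(|logfc|))`. C is 1 when the changes are
#' unidirectional and equal, 0 when they cancel exactly, and scale-free
#' (`C(lambda x) = C(x)` for `lambda > 0`), so magnitude enters the
#' delta-score only through its second multiplier. A group whose changes are
#' all exactly zero is treated as maximally consistent (`C = 1`);
#' between-group divergence is handled by the delta-score's third component.
#'
#' @param logfc Numeric vector of per-genotype log2 fold changes within one
#'   group (length >= 1, finite).
#' @return Consistency score in `[0, 1]`.
#' @examples
#' consistency_score(c(1, 1))     # 1
#' consistency_score(c(1, -1))    # 0
#' consistency_score(c(2.3, 3.0)) # ~0.883
#' @export
consistency_score <- function(logfc) {
  if (!length(logfc)) stop("logfc must be non-empty")
  if (any(!is.finite(logfc))) stop("logfc must be finite")
  m <- max(abs(logfc))
  if (m == 0) return(1)
  abs(sum(logfc)) / (length(logfc) * m)
}

# Gene x genotype log2FC matrix from a named list of fold-change tables
# (one per genotype, as returned by fold_changes / de_table).
.logfc_matrix <- function(fc) {
  if (is.matrix(fc)) return(fc)
  if (is.data.frame(fc)) return(as.matrix(fc))
  if (!is.list(fc) || is.null(names(fc)))
    stop("fc must be a matrix or a named list of per-genotype tables")
  genes <- fc[[1]]$gene_id
  out <- matrix(NA_real_, length(genes), length(fc),
                dimnames = list(genes, names(fc)))
  for (gt in names(fc)) {
    tab <- fc[[gt]]
    out[, gt] <- tab$log2FC[match(genes, tab$gene_id)]
  }
  out
}

#' Delta-scores ranking genes by divergence between tolerance groups
#'
#' For each gene, with per-genotype log2 fold changes split into resistant
#' and sensitive groups:
#' \deqn{S_\Delta = C_{res} \times C_{sens} \times
#'   \max(|\bar{m}_{res}|, |\bar{m}_{sens}|) \times
#'   (\bar{m}_{res} - \bar{m}_{sens})^2}
#' where `C` is [consistency_score] and the means are the group means of the
#' log2FC. The first multiplier rewards consistent within-group changes, the
#' second their maximum magnitude, and the squared third term gives the
#' between-group difference two-fold greater weight. Genes are sorted by
#' decreasing score; ties broken by descending `|mean_res - mean_sens|`,
#' then by gene id.
#'
#' @param fc Gene-by-genotype log2FC matrix, or named list of per-genotype
#'   fold-change tables (names are genotypes; each table as from
#'   [fold_changes]).
#' @param design Validated sample design providing the genotype-to-tolerance
#'   mapping, or a list with `resistant`/`sensitive` genotype name vectors.
#' @return Data frame of class `delta_scores`: `gene_id`, one `lfc_<genotype>`
#'   column per genotype, `C_res`, `C_sens`, `mean_res`, `mean_sens`,
#'   `S_delta`, `rank`.
#' @export
delta_scores <- function(fc, design) {
  lm <- .logfc_matrix(fc)
  if (anyNA(lm)) {
    bad <- rownames(lm)[which(rowSums(is.na(lm)) > 0)]
    stop("gene(s) missing a genotype log2FC: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (is.data.frame(design) || inherits(design, "sample_design")) {
    map <- unique(data.frame(genotype = design$genotype,
                             tolerance = design$tolerance,
                             stringsAsFactors = FALSE))
    groups <- list(resistant = map$genotype[map$tolerance == "resistant"],
                   sensitive = map$genotype[map$tolerance == "sensitive"])
  } else {
    groups <- design
  }
  miss <- setdiff(unlist(groups), colnames(lm))
  if (length(miss))
    stop("genotype(s) without log2FC columns: ", paste(miss, collapse = ", "))
  res <- lm[, groups$resistant, drop = FALSE]
  sens <- lm[, groups$sensitive, drop = FALSE]
  c_res <- apply(res, 1, consistency_score)
  c_sens <- apply(sens, 1, consistency_score)
  m_res <- rowMeans(res)
  m_sens <- rowMeans(sens)
  s_delta <- c_res * c_sens * pmax(abs(m_res), abs(m_sens)) *
    (m_res - m_sens)^2
  out <- data.frame(gene_id = rownames(lm), as.data.frame(lm),
                    C_res = c_res, C_sens = c_sens,
                    mean_res = m_res, mean_sens = m_sens,
                    S_delta = s_delta, row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out)[2:(1 + ncol(lm))] <- paste0("lfc_", colnames(lm))
  ord <- order(-out$S_delta, -abs(out$mean_res - out$mean_sens), out$gene_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("delta_scores", "data.frame")
  out
}

#' @export
print.delta_scores <- function(x, n = 10, ...) {
  cat("delta_scores: ", nrow(x), " genes ranked by divergence ",
      "between tolerance groups\n", sep = "")
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more rows\n", sep = "")
  invisible(x)
}

#' Top divergent genes
#'
#' @param records A `delta_scores` table.
#' @param k Number of genes to keep (>= 1); if `k` exceeds the table size,
#'   all rows are returned with a warning.
#' @return The first `k` records in delta-score order.
#' @export
top_divergent <- function(records, k) {
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(records)) {
    warning("k = ", k, " exceeds table size ", nrow(records),
            "; returning all rows")
    k <- nrow(records)
  }
  records[seq_len(k), , drop = FALSE]
}
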