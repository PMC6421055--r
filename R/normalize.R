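#' Counts per million
#'
#' `CPM_gk = counts_gk / (N_k * f_k) * 1e6`, where `N_k` is the stored
#' library size and `f_k` an optional normalization factor.
#'
#' @param counts A [count_matrix].
#' @param factors Optional per-sample normalization factors: a numeric
#'   vector (named or in column order) or a [tmm_factors] result. `NULL`
#'   gives raw (library-size-only) CPM.
#' @return Numeric matrix of CPM values, same dimnames as the counts.
#' @export
compute_cpm <- function(counts, factors = NULL) {
  if (!inherits(counts, "count_matrix")) stop("counts must be a count_matrix")
  lib <- counts$library_sizes
  zero <- names(lib)[lib <= 0]
  if (length(zero))
    stop("zero library size for sample(s): ", paste(zero, collapse = ", "))
  if (!is.null(factors)) {
    if (inherits(factors, "tmm_norm")) factors <- factors$factors
    if (!is.null(names(factors))) factors <- factors[names(lib)]
    if (length(factors) != length(lib) || anyNA(factors))
      stop("factors must cover every sample")
    lib <- lib * factors
  }
  sweep(counts$counts, 2, lib, "/") * 1e6
}

#' Filter genes with low expression
#'
#' Keeps genes whose *raw* CPM reaches `cpm_threshold` in at least
#' `min_samples` samples (the 1.5 CPM cutoff with `min_samples` equal to the
#' smallest replicate-group size, 2 in the default design, is the intended
#' use). Library sizes are deliberately NOT recomputed after filtering:
#' removing genes is a selection step, not a resequencing of the library, so
#' downstream CPM stays on the original scale.
#'
#' @param counts A [count_matrix].
#' @param cpm_threshold Positive CPM cutoff (default 1.5).
#' @param min_samples In how many samples the cutoff must be reached
#'   (default 2).
#' @return A [count_matrix] restricted to the surviving genes, carrying the
#'   pre-filter library sizes.
#' @export
filter_low_expression <- function(counts, cpm_threshold = 1.5,
                                  min_samples = 2) {
  if (cpm_threshold <= 0) stop("cpm_threshold must be > 0")
  n_samp <- ncol(counts$counts)
  if (min_samples < 1 || min_samples > n_samp)
    stop("min_samples must be in [1, ", n_samp, "]")
  cpm <- compute_cpm(counts)
  keep <- rowSums(cpm >= cpm_threshold) >= min_samples
  if (!any(keep))
    stop("all genes removed at CPM >= ", cpm_threshold, " in >= ",
         min_samples, " samples; review the threshold")
  count_matrix(counts$counts[keep, , drop = FALSE],
               library_sizes = counts$library_sizes)
}

# Trimmed, precision-weighted mean of M-values for one sample against the
# reference; obs/ref are count columns, n_obs/n_ref their library sizes.
.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_M, trim_A, weighted) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) stop("no genes with positive counts in both sample and reference")
  obs <- obs[pos]; ref <- ref[pos]
  p_o <- obs / n_obs
  p_r <- ref / n_ref
  M <- log2(p_o / p_r)
  A <- (log2(p_o) + log2(p_r)) / 2
  # inverse asymptotic (delta-method) variance of M
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) return(1)
  f <- if (weighted) {
    sum(M[keep] / v[keep]) / sum(1 / v[keep])
  } else {
    mean(M[keep])
  }
  2^f
}

#' Trimmed mean of M-values normalization factors
#'
#' From-scratch implementation of TMM between-sample normalization. The
#' reference is the sample whose 75th-percentile count-to-library-size ratio
#' is closest to the mean of those percentiles. For every other sample the
#' per-gene log-ratios `M = log2((y_k/N_k)/(y_r/N_r))` and average
#' abundances `A = 0.5 log2((y_k/N_k)(y_r/N_r))`, over genes positive in
#' both, are doubly trimmed (`trim_M` on M, `trim_A` on A, both tails), and
#' the factor is `2^` of the precision-weighted mean of the surviving M
#' values (weights are inverse delta-method variances). Factors are
#' re-centered to geometric mean 1.
#'
#' @param counts A [count_matrix] (>= 2 samples).
#' @param trim_M Two-sided trim fraction on M (default 0.30).
#' @param trim_A Two-sided trim fraction on A (default 0.05).
#' @param weighted Use precision weights (default `TRUE`); with
#'   `trim_M = trim_A = 0` and `weighted = FALSE` the factor reduces to
#'   `2^mean(M)`.
#' @return An object of class `tmm_norm`: list with `factors` (named, geometric
#'   mean 1), `effective_lib_sizes` (`N_k * f_k`), `ref_sample`, and `cpm`
#'   (the effective CPM matrix).
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05,
                        weighted = TRUE) {
  if (!inherits(counts, "count_matrix")) stop("counts must be a count_matrix")
  y <- counts$counts
  if (ncol(y) < 2) stop("TMM needs >= 2 samples")
  lib <- counts$library_sizes
  f75 <- apply(y, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref_idx <- which.min(abs(f75 - mean(f75)))
  factors <- vapply(seq_len(ncol(y)), function(k) {
    if (k == ref_idx) return(1)
    .tmm_pair(y[, k], y[, ref_idx], lib[k], lib[ref_idx],
              trim_M, trim_A, weighted)
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))
  names(factors) <- colnames(y)
  res <- structure(list(factors = factors,
                        effective_lib_sizes = lib * factors,
                        ref_sample = colnames(y)[ref_idx],
                        cpm = NULL),
                   class = "tmm_norm")
  res$cpm <- compute_cpm(counts, res)
  res
}

#' @export
print.tmm_norm <- function(x, ...) {
  cat("TMM normalization (reference sample: ", x$ref_sample, ")\n", sep = "")
  print(round(x$factors, 4))
  invisible(x)
}
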