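#' Simulation configuration for the 4-genotype aluminum-stress design
#'
#' Defaults emulate the study layout the pipeline targets: four flax
#' genotypes split 2/2 into resistant (Hermes, TMP1919) and sensitive
#' (Lira, Orshanskiy) groups, control vs aluminum stress, two biological
#' replicates per cell (16 samples). Counts are negative binomial with
#' variance mu + phi * mu^2 (edgeR's dispersion convention), log-normal
#' baseline means, gamma-distributed per-gene dispersions around 0.1, and
#' uniform library-size variation.
#'
#' Planted gene-response classes operationalize the response patterns the
#' divergence scoring is built to detect: genes changed in all genotypes
#' (`shared_up`/`shared_down`), only in one tolerance group
#' (`resistant_specific_up`, `sensitive_specific_up`), in opposite
#' directions between groups (`divergent_opposite`, planted at +/- half the
#' class effect size so the between-group gap equals the effect size), or in
#' opposite directions within one group (`inconsistent_within_group`, which
#' the consistency score should null out). `null` genes have planted log2
#' fold change exactly 0.
#'
#' @param n_genes Number of genes (default 5000).
#' @param genotypes Named list with character vectors `resistant` and
#'   `sensitive` (two genotypes each by default).
#' @param replicates Biological replicates per (genotype, condition) cell.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   mean counts (defaults `log(100)` and 1.5).
#' @param dispersion_shape,dispersion_scale Gamma parameters of per-gene NB
#'   dispersion phi (defaults shape 2, scale 0.05: mean 0.1).
#' @param lib_size_range Range of library-size factors times `lib_size_base`
#'   (default uniform 0.8--1.2 x 2e6).
#' @param lib_size_base Nominal library size (default 2e6).
#' @param class_fractions Named fractions over the seven gene classes;
#'   must sum to 1.
#' @param effect_sizes Named log2-fold-change magnitudes per non-null class.
#'   For `divergent_opposite` the value is the *between-group* difference.
#' @param within_sd Standard deviation of per-genotype jitter added to the
#'   planted log2FC of non-null genes (default 0.25).
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       genotypes = list(resistant = c("Hermes", "TMP1919"),
                                        sensitive = c("Lira", "Orshanskiy")),
                       replicates = 2,
                       baseline_meanlog = log(100),
                       baseline_sdlog = 1.5,
                       dispersion_shape = 2,
                       dispersion_scale = 0.05,
                       lib_size_range = c(0.8, 1.2),
                       lib_size_base = 2e6,
                       class_fractions = c(null = 0.85,
                                           shared_up = 0.03,
                                           shared_down = 0.03,
                                           resistant_specific_up = 0.03,
                                           sensitive_specific_up = 0.02,
                                           divergent_opposite = 0.02,
                                           inconsistent_within_group = 0.02),
                       effect_sizes = c(shared_up = 2, shared_down = 2,
                                        resistant_specific_up = 2,
                                        sensitive_specific_up = 2,
                                        divergent_opposite = 3,
                                        inconsistent_within_group = 2),
                       within_sd = 0.25,
                       seed = 1L) {
  if (n_genes < 1) stop("n_genes must be positive")
  if (!all(c("resistant", "sensitive") %in% names(genotypes)) ||
      !length(genotypes$resistant) || !length(genotypes$sensitive))
    stop("genotypes must name >=1 resistant and >=1 sensitive cultivar")
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stop("class_fractions must sum to 1")
  if (any(class_fractions < 0)) stop("class_fractions must be non-negative")
  if (any(!is.finite(effect_sizes))) stop("effect sizes must be finite")
  structure(list(n_genes = as.integer(n_genes), genotypes = genotypes,
                 replicates = as.integer(replicates),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion_shape = dispersion_shape,
                 dispersion_scale = dispersion_scale,
                 lib_size_range = lib_size_range,
                 lib_size_base = lib_size_base,
                 class_fractions = class_fractions,
                 effect_sizes = effect_sizes,
                 within_sd = within_sd, seed = as.integer(seed)),
            class = "sim_config")
}

.SIM_CLASSES <- c("null", "shared_up", "shared_down", "resistant_specific_up",
                  "sensitive_specific_up", "divergent_opposite",
                  "inconsistent_within_group")

# Planted per-genotype log2FC pattern for one gene of a given class.
.class_pattern <- function(cls, effect, n_res, n_sens) {
  res <- numeric(n_res); sens <- numeric(n_sens)
  switch(cls,
    null = NULL,
    shared_up = { res[] <- effect; sens[] <- effect },
    shared_down = { res[] <- -effect; sens[] <- -effect },
    resistant_specific_up = { res[] <- effect },
    sensitive_specific_up = { sens[] <- effect },
    divergent_opposite = { res[] <- effect / 2; sens[] <- -effect / 2 },
    inconsistent_within_group = {
      # opposite signs inside the resistant group; sensitive flat
      res <- effect * rep_len(c(1, -1), n_res)
    },
    stop("unknown class: ", cls))
  c(res, sens)
}

#' Simulate a planted-truth count matrix for the full design
#'
#' Draws negative-binomial counts with mean
#' `baseline x 2^(planted log2FC if stress) x library-size factor` and
#' per-gene dispersion phi (variance mu + phi mu^2), for all genotype x
#' condition x replicate combinations, together with the sample sheet and a
#' truth table of planted classes and per-genotype log2 fold changes.
#'
#' @param config A [sim_config].
#' @return List with elements `counts` ([count_matrix]), `design` (validated
#'   sample sheet) and `truth` (data frame: `gene_id`, `class`, `baseline`
#'   mean, NB `dispersion`, and one `lfc_<genotype>` column per genotype).
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 50, seed = 7))
#' table(sim$truth$class)
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  set.seed(config$seed)
  n <- config$n_genes
  gts <- c(config$genotypes$resistant, config$genotypes$sensitive)
  n_res <- length(config$genotypes$resistant)
  n_gt <- length(gts)

  frac <- config$class_fractions[.SIM_CLASSES]
  frac[is.na(frac)] <- 0
  n_per <- floor(frac * n)
  rem <- n - sum(n_per)
  if (rem > 0) {  # give the remainder to the largest class (deterministic)
    n_per[which.max(frac)] <- n_per[which.max(frac)] + rem
  }
  if (all(n_per == 0)) stop("degenerate config: no genes in any class")
  classes <- sample(rep(.SIM_CLASSES, times = n_per))

  gene_ids <- sprintf("gene%05d", seq_len(n))
  baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  phi <- stats::rgamma(n, shape = config$dispersion_shape,
                       scale = config$dispersion_scale)

  lfc <- matrix(0, n, n_gt, dimnames = list(gene_ids, gts))
  for (g in seq_len(n)) {
    cls <- classes[g]
    if (cls == "null") next
    pat <- .class_pattern(cls, config$effect_sizes[[cls]], n_res,
                          n_gt - n_res)
    lfc[g, ] <- pat + stats::rnorm(n_gt, 0, config$within_sd)
  }

  reps <- config$replicates
  design <- expand.grid(replicate = seq_len(reps),
                        condition = .CONDITION_LEVELS,
                        genotype = gts,
                        stringsAsFactors = FALSE)[, 3:1]
  design$tolerance <- ifelse(design$genotype %in% config$genotypes$resistant,
                             "resistant", "sensitive")
  design$sample_id <- paste(design$genotype, design$condition,
                            design$replicate, sep = "_")
  design <- design[, c("sample_id", "genotype", "tolerance", "condition",
                       "replicate")]
  n_samp <- nrow(design)

  size_factor <- stats::runif(n_samp, config$lib_size_range[1],
                              config$lib_size_range[2])
  counts <- matrix(0, n, n_samp, dimnames = list(gene_ids, design$sample_id))
  expected_colsum <- numeric(n_samp)
  for (k in seq_len(n_samp)) {
    stress <- design$condition[k] == "stress"
    mu <- baseline * size_factor[k] *
      (if (stress) 2^lfc[, design$genotype[k]] else 1)
    expected_colsum[k] <- sum(mu)
    pois <- phi < 1e-12
    draws <- numeric(n)
    if (any(pois)) draws[pois] <- stats::rpois(sum(pois), mu[pois])
    if (any(!pois)) draws[!pois] <- stats::rnbinom(sum(!pois),
                                                   mu = mu[!pois],
                                                   size = 1 / phi[!pois])
    counts[, k] <- draws
  }

  truth <- data.frame(gene_id = gene_ids, class = classes,
                      baseline = baseline, dispersion = phi,
                      stringsAsFactors = FALSE)
  for (gt in gts) truth[[paste0("lfc_", gt)]] <- lfc[, gt]

  cm <- count_matrix(counts)
  attr(cm, "expected_library_sizes") <- stats::setNames(expected_colsum,
                                                        design$sample_id)
  attr(cm, "dispersion") <- stats::setNames(phi, gene_ids)
  list(counts = cm, design = validate_design(design, cm), truth = truth)
}

#' Simulate a qPCR Ct table consistent with planted fold changes
#'
#' Generates cycle-threshold values such that, per gene and genotype,
#' the negative delta-delta-Ct equals the planted log2 fold change plus
#' Gaussian measurement noise: the target's control-condition Ct is a random
#' baseline, its stress Ct is shifted by minus the planted log2FC, and the
#' reference gene's Ct is constant across conditions up to noise. Values are
#' clamped to the instrument's plausible 23--32 cycle range (with a warning
#' when clamping occurs).
#'
#' @param truth Truth table from [simulate_counts] (columns `gene_id` and
#'   `lfc_<genotype>`).
#' @param selected_genes Gene ids to assay (must exist in `truth`).
#' @param noise_sd Per-measurement Gaussian noise, in cycles.
#' @param seed Integer seed.
#' @param replicates Biological replicates per condition (default 2).
#' @param tech_reps Technical replicates per well (default 3).
#' @param reference_gene Reference transcript id (default `"ETIF3E"`).
#' @return Data frame with columns `target_gene`, `sample_id`,
#'   `technical_replicate`, `ct`; attribute `reference_gene`. Sample ids
#'   follow the `<genotype>_<condition>_<replicate>` convention of
#'   [simulate_counts].
#' @export
simulate_ct_table <- function(truth, selected_genes, noise_sd = 0.3,
                              seed = 1L, replicates = 2, tech_reps = 3,
                              reference_gene = "ETIF3E") {
  missing_g <- setdiff(selected_genes, truth$gene_id)
  if (length(missing_g))
    stop("genes not in truth table: ", paste(missing_g, collapse = ", "))
  gts <- sub("^lfc_", "", grep("^lfc_", names(truth), value = TRUE))
  if (!length(gts)) stop("truth table has no lfc_<genotype> columns")
  set.seed(seed)
  rows <- list()
  ref_ct <- 25  # reference sits mid-range, condition-independent
  for (gt in gts) {
    samples <- expand.grid(replicate = seq_len(replicates),
                           condition = .CONDITION_LEVELS,
                           stringsAsFactors = FALSE)
    samples$sample_id <- paste(gt, samples$condition, samples$replicate,
                               sep = "_")
    base_ct <- stats::runif(length(selected_genes), 26, 29)
    names(base_ct) <- selected_genes
    for (s in seq_len(nrow(samples))) {
      stress <- samples$condition[s] == "stress"
      for (gene in selected_genes) {
        lfc <- truth[truth$gene_id == gene, paste0("lfc_", gt)]
        true_ct <- base_ct[[gene]] - (if (stress) lfc else 0)
        rows[[length(rows) + 1L]] <- data.frame(
          target_gene = gene, sample_id = samples$sample_id[s],
          technical_replicate = seq_len(tech_reps),
          ct = true_ct + stats::rnorm(tech_reps, 0, noise_sd),
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        target_gene = reference_gene, sample_id = samples$sample_id[s],
        technical_replicate = seq_len(tech_reps),
        ct = ref_ct + stats::rnorm(tech_reps, 0, noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  ct <- do.call(rbind, rows)
  out_of_range <- ct$ct < 23 | ct$ct > 32
  if (any(out_of_range)) {
    warning(sum(out_of_range), " Ct value(s) clamped to [23, 32]")
    ct$ct <- pmin(pmax(ct$ct, 23), 32)
  }
  attr(ct, "reference_gene") <- reference_gene
  ct
}
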