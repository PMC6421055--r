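#' Delta-delta-Ct relative expression for one gene and genotype
#'
#' Technical replicates are averaged per (gene, sample); per-sample means
#' are averaged across biological replicates within each condition; then
#' `dCt = mean Ct_target - mean Ct_reference` per condition,
#' `ddCt = dCt_stress - dCt_control`, and the log2 relative expression is
#' `-ddCt` (assuming 100% amplification efficiency). Adding a constant to
#' every Ct of one condition cancels in the difference.
#'
#' @param ct Ct table (see [read_ct_table] / [simulate_ct_table]): columns
#'   `target_gene`, `sample_id`, `technical_replicate`, `ct`.
#' @param target Target gene id.
#' @param genotype Genotype whose samples to use.
#' @param design Validated sample design mapping sample ids to genotype and
#'   condition.
#' @param reference_gene Reference gene id; defaults to the table's
#'   `reference_gene` attribute, else `"ETIF3E"`.
#' @return One-row data frame: `target_gene`, `genotype`, `dCt_control`,
#'   `dCt_stress`, `ddCt`, `log2_rel_expr`.
#' @export
ddct <- function(ct, target, genotype, design,
                 reference_gene = NULL) {
  if (is.null(reference_gene))
    reference_gene <- attr(ct, "reference_gene")
  if (is.null(reference_gene)) reference_gene <- "ETIF3E"
  des <- design[design$genotype == genotype, , drop = FALSE]
  if (!nrow(des)) stop("no samples for genotype '", genotype, "'")
  cond_mean <- function(gene, condition) {
    ids <- des$sample_id[des$condition == condition]
    sub <- ct[ct$target_gene == gene & ct$sample_id %in% ids, , drop = FALSE]
    if (!nrow(sub))
      stop("gene '", gene, "' not measured under ", condition,
           " for genotype '", genotype, "'")
    # technical replicates first, then biological replicates
    per_sample <- tapply(sub$ct, sub$sample_id, mean)
    mean(per_sample)
  }
  d_ctrl <- cond_mean(target, "control") - cond_mean(reference_gene, "control")
  d_str <- cond_mean(target, "stress") - cond_mean(reference_gene, "stress")
  dd <- d_str - d_ctrl
  data.frame(target_gene = target, genotype = genotype,
             dCt_control = d_ctrl, dCt_stress = d_str,
             ddCt = dd, log2_rel_expr = -dd,
             stringsAsFactors = FALSE)
}

#' Delta-delta-Ct records for all (gene, genotype) pairs in a Ct table
#'
#' @inheritParams ddct
#' @param targets Target genes (default: every non-reference gene in `ct`).
#' @param genotypes Genotypes (default: every genotype in `design` with
#'   samples in `ct`).
#' @return Data frame of [ddct] rows.
#' @export
ddct_table <- function(ct, design, targets = NULL, genotypes = NULL,
                       reference_gene = NULL) {
  if (is.null(reference_gene))
    reference_gene <- attr(ct, "reference_gene")
  if (is.null(reference_gene)) reference_gene <- "ETIF3E"
  if (is.null(targets))
    targets <- setdiff(unique(ct$target_gene), reference_gene)
  if (is.null(genotypes)) {
    present <- unique(design$genotype[design$sample_id %in% ct$sample_id])
    genotypes <- present
  }
  rows <- list()
  for (gt in genotypes)
    for (g in targets)
      rows[[length(rows) + 1L]] <- ddct(ct, g, gt, design, reference_gene)
  do.call(rbind, rows)
}

#' Spearman correlation between qPCR and sequencing fold changes
#'
#' Matches delta-delta-Ct records to sequencing log2 fold changes on
#' (gene, genotype) and correlates `-ddCt` with `log2FC` by Spearman's
#' rank correlation (exact p-value for n <= 10 pairs, normal approximation
#' otherwise).
#'
#' @param ddct_records Data frame from [ddct_table] / [ddct].
#' @param seq_logfc Fold-change table with columns `gene_id`, `unit`
#'   (genotype) and `log2FC`, e.g. stacked per-genotype [fold_changes]
#'   tables.
#' @return List: `rho`, `p_value`, `n_pairs`.
#' @export
validate_correlation <- function(ddct_records, seq_logfc) {
  key_q <- paste(ddct_records$target_gene, ddct_records$genotype)
  key_s <- paste(seq_logfc$gene_id, seq_logfc$unit)
  hit <- match(key_q, key_s)
  ok <- !is.na(hit)
  n <- sum(ok)
  if (n < 3) stop("need >= 3 matched (gene, genotype) pairs, got ", n)
  x <- ddct_records$log2_rel_expr[ok]
  y <- seq_logfc$log2FC[hit[ok]]
  test <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = n <= 10))
  list(rho = unname(test$estimate), p_value = test$p.value, n_pairs = n)
}

# round half away from zero at `digits` decimals (base round() is half-even)
.round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Phenotype decline percentages under aluminum stress
#'
#' For each (cultivar, trait) pair, the decline is the stress mean as a
#' percentage of the control mean, rounded half-up to one decimal:
#' `decline_pct = round(100 * stress / control, 1)`. Equal means give 100.
#'
#' @param table Phenotype table (see [read_phenotype]): columns `cultivar`,
#'   `condition`, `trait`, `mean`.
#' @return Data frame: `cultivar`, `trait`, `stress_mean`, `control_mean`,
#'   `decline_pct`.
#' @export
phenotype_decline <- function(table) {
  pairs <- unique(table[, c("cultivar", "trait")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sub <- table[table$cultivar == pairs$cultivar[i] &
                 table$trait == pairs$trait[i], , drop = FALSE]
    ctrl <- sub$mean[sub$condition == "control"]
    str <- sub$mean[sub$condition == "stress"]
    if (length(ctrl) != 1 || length(str) != 1)
      stop("need exactly one control and one stress mean for ",
           pairs$cultivar[i], " / ", pairs$trait[i])
    if (ctrl == 0) stop("control mean is zero for ", pairs$cultivar[i],
                        " / ", pairs$trait[i])
    data.frame(cultivar = pairs$cultivar[i], trait = pairs$trait[i],
               stress_mean = str, control_mean = ctrl,
               decline_pct = .round_half_up(100 * str / ctrl, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
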