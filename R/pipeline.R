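#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: input/output paths,
#' the CPM filter, top-list sizes, significance cutoff, fold-change
#' pseudocount, and the global seed (fanned out to per-stage child seeds by
#' fixed offsets so each stage is independently reproducible).
#'
#' @param out_dir Output directory (created if missing).
#' @param counts,design,go_map,ct,phenotype Optional input TSV paths; when
#'   `counts`/`design` are `NULL` and `simulate` is `TRUE`, inputs are
#'   simulated.
#' @param simulate Simulate inputs instead of reading them.
#' @param sim Optional [sim_config] used when simulating (its seed is
#'   overridden by `seed + 1`).
#' @param cpm_threshold,min_samples CPM filter (defaults 1.5 in >= 2 samples).
#' @param top_sizes,alpha Top-list sizes and significance cutoff.
#' @param pseudo Fold-change pseudocount (CPM).
#' @param seed Global integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "altox_out", counts = NULL,
                            design = NULL, go_map = NULL, ct = NULL,
                            phenotype = NULL, simulate = is.null(counts),
                            sim = NULL, cpm_threshold = 1.5, min_samples = 2,
                            top_sizes = c(50, 100, 300), alpha = 0.05,
                            pseudo = 0.5, seed = 1L) {
  if (cpm_threshold <= 0 || min_samples < 1 || alpha <= 0 || pseudo < 0)
    stop("thresholds must be positive")
  structure(list(out_dir = out_dir, counts = counts, design = design,
                 go_map = go_map, ct = ct, phenotype = phenotype,
                 simulate = simulate, sim = sim,
                 cpm_threshold = cpm_threshold, min_samples = min_samples,
                 top_sizes = top_sizes, alpha = alpha, pseudo = pseudo,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates: input (or simulation) -> design validation -> CPM filter +
#' TMM normalization -> differential expression for the seven comparison
#' groupings (all / resistant / sensitive / each genotype) -> delta-score
#' ranking -> optional GO over-representation of the pooled-all top lists ->
#' optional qPCR delta-delta-Ct validation -> optional phenotype declines.
#' All outputs are TSV files in `config$out_dir`; a `manifest.tsv` records
#' per-stage row counts and the configuration. Identical config + seed gives
#' identical outputs.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest data frame.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, rows, file = "") {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, rows = rows, file = file, stringsAsFactors = FALSE)
  }
  outp <- function(f) file.path(config$out_dir, f)

  truth <- NULL
  if (config$simulate) {
    sim_cfg <- config$sim
    if (is.null(sim_cfg)) sim_cfg <- sim_config(seed = config$seed + 1L)
    else sim_cfg$seed <- config$seed + 1L
    sim <- .stage("simulate", simulate_counts(sim_cfg))
    counts <- sim$counts; design <- sim$design; truth <- sim$truth
    write_table(counts, outp("counts.tsv"))
    write_table(as.data.frame(design), outp("design.tsv"))
    write_table(truth, outp("truth.tsv"))
    note("simulate", nrow(counts$counts), "counts.tsv")
  } else {
    counts <- .stage("read_counts", read_counts(config$counts))
    design <- .stage("read_design", read_design(config$design, counts))
    note("ingest", nrow(counts$counts), basename(config$counts))
  }
  design <- .stage("validate", validate_design(design, counts))
  note("validate", nrow(design))

  filtered <- .stage("filter",
                     filter_low_expression(counts, config$cpm_threshold,
                                           config$min_samples))
  note("filter", nrow(filtered$counts))
  norm <- .stage("normalize", tmm_factors(filtered))
  write_table(data.frame(sample_id = names(norm$factors),
                         tmm_factor = norm$factors,
                         effective_lib_size = norm$effective_lib_sizes,
                         stringsAsFactors = FALSE),
              outp("factors.tsv"))
  cpm_df <- data.frame(gene_id = rownames(norm$cpm), norm$cpm,
                       check.names = FALSE, stringsAsFactors = FALSE)
  write_table(cpm_df, outp("cpm.tsv"))
  note("normalize", ncol(filtered$counts), "factors.tsv")

  groupings <- .stage("groupings", make_groupings(design))
  de <- list()
  for (gname in names(groupings)) {
    de[[gname]] <- .stage(paste0("de:", gname),
                          de_table(filtered, groupings[[gname]], norm,
                                   config$pseudo))
    write_table(de[[gname]], outp(paste0("de_", gname, ".tsv")))
    note(paste0("de:", gname), nrow(de[[gname]]),
         paste0("de_", gname, ".tsv"))
  }

  genotypes <- unique(design$genotype)
  delta <- .stage("delta", delta_scores(de[genotypes], design))
  write_table(as.data.frame(delta), outp("delta_scores.tsv"))
  note("delta", nrow(delta), "delta_scores.tsv")

  enrich <- NULL
  if (!is.null(config$go_map)) {
    annot <- .stage("enrich", read_go_map(config$go_map))
    tops <- .stage("enrich", build_top_lists(de[["all"]], config$top_sizes,
                                             config$alpha))
    universe <- de[["all"]]$gene_id
    enrich <- list()
    for (dir in c("up", "down")) {
      for (sz in names(tops[[dir]])) {
        res <- .stage("enrich",
                      hypergeom_enrich(tops[[dir]][[sz]], universe, annot))
        res$direction <- dir
        res$top_size <- sz
        enrich[[paste(dir, sz, sep = "_")]] <- res
        write_table(res, outp(paste0("enrich_", dir, "_", sz, ".tsv")))
        note(paste0("enrich:", dir, ":", sz), nrow(res),
             paste0("enrich_", dir, "_", sz, ".tsv"))
      }
    }
  }

  qpcr <- NULL
  if (!is.null(config$ct)) {
    ct_tab <- .stage("qpcr", read_ct_table(config$ct))
    dd <- .stage("qpcr", ddct_table(ct_tab, design))
    seq_fc <- do.call(rbind, de[genotypes])
    corr <- .stage("qpcr", validate_correlation(dd, seq_fc))
    write_table(dd, outp("ddct.tsv"))
    write_table(data.frame(spearman_rho = corr$rho, p_value = corr$p_value,
                           n_pairs = corr$n_pairs),
                outp("qpcr_correlation.tsv"))
    qpcr <- list(ddct = dd, correlation = corr)
    note("qpcr", nrow(dd), "ddct.tsv")
  }

  declines <- NULL
  if (!is.null(config$phenotype)) {
    ph <- .stage("phenotype", read_phenotype(config$phenotype))
    declines <- .stage("phenotype", phenotype_decline(ph))
    write_table(declines, outp("decline.tsv"))
    note("phenotype", nrow(declines), "decline.tsv")
  }

  manifest <- do.call(rbind, manifest)
  cfg_str <- paste(names(unclass(config)),
                   vapply(unclass(config), function(v)
                     paste(format(v), collapse = ","), character(1)),
                   sep = "=", collapse = "; ")
  manifest$config_hash <- substr(.config_hash(cfg_str), 1, 12)
  manifest$seed <- config$seed
  write_table(manifest, outp("manifest.tsv"))
  invisible(list(counts = counts, design = design, truth = truth,
                 filtered = filtered, norm = norm, de = de, delta = delta,
                 enrichment = enrich, qpcr = qpcr, declines = declines,
                 manifest = manifest))
}

.config_hash <- function(s) {
  tmp <- tempfile()
  writeLines(s, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}
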