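# Small in-code fixtures shared across test files.

tiny_counts <- function(values, genes = NULL, samples = NULL, lib = NULL) {
  m <- matrix(values, nrow = if (is.null(genes)) 3 else length(genes))
  rownames(m) <- if (is.null(genes)) paste0("g", seq_len(nrow(m))) else genes
  colnames(m) <- if (is.null(samples)) paste0("s", seq_len(ncol(m))) else samples
  count_matrix(m, library_sizes = lib)
}

# 16-sample sheet for the standard 4-genotype x 2-condition x 2-replicate design
full_design <- function() {
  gts <- c(Hermes = "resistant", TMP1919 = "resistant",
           Lira = "sensitive", Orshanskiy = "sensitive")
  d <- expand.grid(replicate = 1:2, condition = c("control", "stress"),
                   genotype = names(gts), stringsAsFactors = FALSE)[, 3:1]
  d$tolerance <- unname(gts[d$genotype])
  d$sample_id <- paste(d$genotype, d$condition, d$replicate, sep = "_")
  d[, c("sample_id", "genotype", "tolerance", "condition", "replicate")]
}

# annotation map in read_go_map() shape
make_annot <- function(gene_terms, labels = character(0)) {
  list(map = gene_terms, labels = labels)
}

# single-genotype design for qPCR tests
one_genotype_design <- function(genotype = "Hermes", tolerance = "resistant",
                                replicates = 2) {
  data.frame(
    sample_id = paste(genotype, rep(c("control", "stress"), each = replicates),
                      seq_len(replicates), sep = "_"),
    genotype = genotype, tolerance = tolerance,
    condition = rep(c("control", "stress"), each = replicates),
    replicate = seq_len(replicates), stringsAsFactors = FALSE)
}
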