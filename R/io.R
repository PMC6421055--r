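#' Construct a validated count matrix
#'
#' Bundles a gene-by-sample matrix of non-negative integer read counts with
#' its per-sample library sizes (column sums). This is the container every
#' downstream stage (filtering, normalization, testing) consumes.
#'
#' @param counts Numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names. Fractional values (e.g. RSEM expected
#'   counts) are rounded half-to-even with a warning.
#' @param library_sizes Optional named numeric vector of per-sample totals.
#'   If supplied it must equal the column sums exactly; normally left `NULL`
#'   and computed. Kept as an explicit field so that gene filtering can
#'   retain the pre-filter totals.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer-valued matrix) and `library_sizes` (named numeric).
#' @examples
#' m <- matrix(c(10, 5, 0, 0, 5, 20), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' cm <- count_matrix(m)
#' cm$library_sizes
#' @export
count_matrix <- function(counts, library_sizes = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have gene row names and sample column names")
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g))
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  if (anyNA(counts))
    stop("counts contain missing values")
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative count at gene '", rownames(counts)[neg[1, 1]],
         "', sample '", colnames(counts)[neg[1, 2]], "'")
  }
  rounded <- round(counts)  # round() is round-half-to-even in R
  if (any(rounded != counts)) {
    warning(sum(rounded != counts),
            " fractional count(s) rounded half-to-even at ingest")
    counts <- rounded
  }
  storage.mode(counts) <- "double"  # integer-valued, double storage avoids overflow
  cs <- colSums(counts)
  if (is.null(library_sizes)) {
    library_sizes <- cs
  } else {
    if (is.null(names(library_sizes)))
      names(library_sizes) <- colnames(counts)
    library_sizes <- library_sizes[colnames(counts)]
    if (anyNA(library_sizes))
      stop("library_sizes must be named by sample id and cover all samples")
  }
  structure(list(counts = counts, library_sizes = library_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("library sizes: ",
      paste0(names(x$library_sizes), "=", format(x$library_sizes),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a gene-by-sample count table
#'
#' Expects a TSV with a header row of sample ids and gene ids in the first
#' column. RSEM-style fractional expected counts are accepted and rounded
#' half-to-even (with a warning).
#'
#' @param path Path to the TSV file.
#' @return A [count_matrix].
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("count table needs a gene-id column plus >=1 sample")
  ids <- as.character(tab[[1]])
  body <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(body)) stop("non-numeric values in count table body")
  rownames(body) <- ids
  count_matrix(body)
}

.TOLERANCE_LEVELS <- c("resistant", "sensitive")
.CONDITION_LEVELS <- c("control", "stress")

#' Validate a sample design table
#'
#' Checks the per-sample metadata (genotype, tolerance group, condition,
#' replicate) underlying the 4-genotype x 2-condition design: unique sample
#' ids, recognized enum tokens (case-insensitive), at least one replicate per
#' (genotype, condition) cell and at least one genotype per tolerance group.
#' When `counts` is given, the sample-id sets must match exactly: silent
#' subsetting hides design errors.
#'
#' @param design Data frame with columns `sample_id`, `genotype`,
#'   `tolerance`, `condition`, `replicate`.
#' @param counts Optional [count_matrix] to cross-validate sample ids against.
#' @return The design, with `tolerance` and `condition` lower-cased, invisibly
#'   classed as `sample_design`.
#' @export
validate_design <- function(design, counts = NULL) {
  need <- c("sample_id", "genotype", "tolerance", "condition", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design lacks columns: ", paste(miss, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  design$genotype <- as.character(design$genotype)
  design$tolerance <- tolower(as.character(design$tolerance))
  design$condition <- tolower(as.character(design$condition))
  design$replicate <- as.integer(design$replicate)
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample ids in design")
  bad_tol <- which(!design$tolerance %in% .TOLERANCE_LEVELS)
  if (length(bad_tol))
    stop("unknown tolerance '", design$tolerance[bad_tol[1]],
         "' in design row ", bad_tol[1])
  bad_cond <- which(!design$condition %in% .CONDITION_LEVELS)
  if (length(bad_cond))
    stop("unknown condition '", design$condition[bad_cond[1]],
         "' in design row ", bad_cond[1])
  if (any(is.na(design$replicate)) || any(design$replicate < 1))
    stop("replicate indices must be positive integers")
  cells <- table(design$genotype, design$condition)
  if (any(cells == 0))
    stop("every (genotype, condition) cell needs >= 1 replicate")
  groups <- unique(design[, c("genotype", "tolerance")])
  for (tl in .TOLERANCE_LEVELS) {
    if (!any(groups$tolerance == tl))
      stop("tolerance group '", tl, "' has no genotypes")
  }
  if (!is.null(counts)) {
    extra <- setdiff(design$sample_id, colnames(counts$counts))
    absent <- setdiff(colnames(counts$counts), design$sample_id)
    if (length(extra) || length(absent))
      stop("sample ids in design and counts must match exactly; ",
           "design-only: {", paste(extra, collapse = ", "),
           "}, counts-only: {", paste(absent, collapse = ", "), "}")
  }
  class(design) <- c("sample_design", "data.frame")
  invisible(design)
}

#' Read and validate a sample sheet
#'
#' @param path TSV with columns `sample_id`, `genotype`, `tolerance`,
#'   `condition`, `replicate`.
#' @param counts Optional [count_matrix] for strict sample-id cross-checking.
#' @return A validated design data frame (see [validate_design]).
#' @export
read_design <- function(path, counts = NULL) {
  if (!file.exists(path)) stop("design file not found: ", path)
  design <- utils::read.delim(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  validate_design(design, counts)
}

#' Read a gene-to-GO annotation map
#'
#' Two-or-three-column TSV: gene id, GO term id, optional term label. Genes
#' absent from the map are treated downstream as unannotated, not as errors.
#'
#' @param path TSV path.
#' @return A list with `map` (named list: gene id -> character vector of term
#'   ids) and `labels` (named character: term id -> label, possibly empty).
#' @export
read_go_map <- function(path) {
  if (!file.exists(path)) stop("GO map file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("GO map needs columns gene_id, term_id[, label]")
  gene <- as.character(tab[[1]])
  term <- as.character(tab[[2]])
  if (any(!nzchar(term))) stop("empty GO term id in map")
  map <- split(term, gene)
  map <- lapply(map, unique)
  labels <- character(0)
  if (ncol(tab) >= 3) {
    lab <- as.character(tab[[3]])
    keep <- !duplicated(term)
    labels <- stats::setNames(lab[keep], term[keep])
  }
  list(map = map, labels = labels)
}

#' Read a qPCR Ct table
#'
#' @param path TSV with columns `target_gene`, `sample_id`,
#'   `technical_replicate`, `ct`.
#' @param reference_gene Id of the reference transcript (default `"ETIF3E"`,
#'   the translation-initiation-factor gene used as the flax qPCR reference).
#' @return Data frame of Ct rows with attribute `reference_gene`; Ct values
#'   must be finite and positive and the reference gene present in every
#'   sample.
#' @export
read_ct_table <- function(path, reference_gene = "ETIF3E") {
  if (!file.exists(path)) stop("Ct file not found: ", path)
  ct <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("target_gene", "sample_id", "technical_replicate", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stop("Ct table lacks columns: ", paste(miss, collapse = ", "))
  ct$ct <- as.numeric(ct$ct)
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be finite and > 0")
  samples <- unique(ct$sample_id)
  ref_samples <- unique(ct$sample_id[ct$target_gene == reference_gene])
  if (length(setdiff(samples, ref_samples)))
    stop("reference gene '", reference_gene, "' not measured in sample(s): ",
         paste(setdiff(samples, ref_samples), collapse = ", "))
  attr(ct, "reference_gene") <- reference_gene
  ct
}

#' Read a phenotype means table
#'
#' @param path TSV with columns `cultivar`, `condition`, `trait`, `mean`,
#'   `stderr`; one control and one stress row per (cultivar, trait).
#' @return Validated data frame.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  ph <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("cultivar", "condition", "trait", "mean", "stderr")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("phenotype table lacks columns: ",
                         paste(miss, collapse = ", "))
  ph$condition <- tolower(ph$condition)
  if (any(!ph$condition %in% .CONDITION_LEVELS))
    stop("phenotype condition must be control/stress")
  if (any(!is.finite(ph$mean)) || any(ph$mean <= 0))
    stop("phenotype means must be positive")
  tab <- table(ph$cultivar, ph$trait, ph$condition)
  if (any(tab != 1))
    stop("each (cultivar, trait) needs exactly one control and one stress row")
  ph
}

#' Write a result table as TSV
#'
#' Tab-separated, UTF-8, header row, '.' decimal separator, fixed (not
#' scientific) notation. A [count_matrix] is written with gene ids in a
#' leading `gene_id` column so that `read_counts(write_table(x))` round-trips
#' exactly.
#'
#' @param records Data frame or [count_matrix]. An empty data frame yields a
#'   header-only file.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_table <- function(records, path) {
  if (inherits(records, "count_matrix")) {
    df <- data.frame(gene_id = rownames(records$counts),
                     records$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(records)
  }
  old <- options(scipen = 15)  # keep plain notation well below 1e-4
  on.exit(options(old))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, dec = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a key=value configuration file
#'
#' Minimal `key = value` format (one pair per line, `#` comments); numeric
#' values are coerced. Used by the command-line front end for decimal
#' precision and logging level.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
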