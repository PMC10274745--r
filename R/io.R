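#' Read a gene x sample count matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Cells must be non-negative integers; the offending cell is named
#' otherwise. Duplicate gene or sample ids are rejected.
#'
#' @param path TSV path.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(df)[-1]))
    stop("duplicate sample ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count at gene ", gene_ids[bad[1, 1]],
         ", sample ", colnames(m)[bad[1, 2]])
  storage.mode(m) <- "integer"
  rownames(m) <- gene_ids
  m
}

#' Write a count matrix as TSV
#'
#' @param counts Matrix with gene rownames, sample colnames.
#' @param path Output path.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Requires columns `sample_id`, `x_copies`, `y_copies`; `cell_type`,
#' `chr21_copies`, `batch`, `condition` are optional and defaulted.
#' Validates x_copies >= 1 and y_copies >= 0 (fractional copies allowed
#' for mosaics).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "x_copies", "y_copies")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("sample sheet missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  if (any(df$x_copies < 1)) stop("x_copies must be >= 1")
  if (any(df$y_copies < 0)) stop("y_copies must be >= 0")
  if (is.null(df$cell_type)) df$cell_type <- "other"
  if (is.null(df$chr21_copies)) df$chr21_copies <- 2
  if (is.null(df$batch)) df$batch <- "1"
  if (is.null(df$condition)) df$condition <- "control"
  df$batch <- factor(df$batch)
  df
}

#' Read a gene annotation table from TSV
#'
#' Columns: `gene_id`, `chrom`, `start`, `end` (0-based half-open),
#' `strand` (+/-), `length` (effective length, bases), optional `biotype`.
#' Adds `tss` (start on +, end on -) and `effective_length`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand", "length")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("annotation missing columns: ", paste(missing, collapse = ", "))
  if (any(df$start >= df$end)) stop("annotation intervals need start < end")
  if (any(df$length <= 0)) stop("effective length must be > 0")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be + or -")
  df$effective_length <- df$length
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  if (is.null(df$biotype)) df$biotype <- "protein_coding"
  df
}

#' Read peak intervals from a BED3+ file
#'
#' @param path BED path (chrom, start, end, optional name/score; no
#'   header).
#' @return data.frame `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  df$name <- if (ncol(df) >= 4) as.character(df[[4]]) else
    paste0("peak_", seq_len(nrow(df)))
  if (any(df$start >= df$end)) stop("BED intervals need start < end")
  df[, c("chrom", "start", "end", "name")]
}

#' Write a generic results table as TSV
#'
#' @param df data.frame.
#' @param path Output path.
#' @export
write_results_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the simulated cohort to a directory
#'
#' Writes `counts.tsv` (gene x sample), `samples.tsv` and `truth.tsv`
#' (per-gene truth) in the formats the readers expect.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(sim$counts, file.path(dir, "counts.tsv"))
  write_results_tsv(sim$samples, file.path(dir, "samples.tsv"))
  write_results_tsv(sim$truth$genes, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Validate and normalize a pipeline configuration
#'
#' A configuration is a named list (or YAML file) with paths (`counts`,
#' `samples`, optionally `annotation`), a `design` character vector of
#' covariates, optional `cell_type`, `test_coefs`, thresholds
#' (`padj_threshold`, `tpm_threshold`), `seed` and `out_dir`. All
#' referenced paths must exist.
#'
#' @param config Named list or path to a YAML file.
#' @return Validated config list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(design = c("x_copies", "y_copies", "batch"),
                   test_coefs = c("x_copies", "y_copies"),
                   padj_threshold = 0.05, tpm_threshold = 1,
                   cell_type = NULL, annotation = NULL,
                   seed = 1L, out_dir = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (p in c("counts", "samples")) {
    if (is.null(config[[p]])) stop("config is missing required path: ", p)
    if (!file.exists(config[[p]]))
      stop("config path does not exist: ", p, " = ", config[[p]])
  }
  if (!is.null(config$annotation) && !file.exists(config$annotation))
    stop("config path does not exist: annotation = ", config$annotation)
  if (config$padj_threshold <= 0 || config$tpm_threshold <= 0)
    stop("thresholds must be positive")
  config
}

#' Run the dosage-response pipeline
#'
#' Orchestrates the main analysis: read counts and samples (and annotation
#' when provided), TPM-filter expressed genes on euploid medians, compute
#' size factors, fit the per-gene NB dosage model, and compare the X and Y
#' response vectors with a weighted Deming fit and a significant-set
#' overlap test. Results are written as TSVs plus a JSON manifest (package
#' version, seed, input checksums) when `out_dir` is set.
#'
#' @param config See [pipeline_config()].
#' @return List with `fit`, per-coefficient `results` tables, `deming`,
#'   `overlap`, `expressed_genes`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  set.seed(as.integer(config$seed))
  counts <- read_count_matrix(config$counts)
  samples <- read_sample_sheet(config$samples)
  if (!all(colnames(counts) %in% samples$sample_id))
    stop("stage 'input': count matrix has samples absent from sample sheet")
  samples <- samples[match(colnames(counts), samples$sample_id), ]

  expressed <- rownames(counts)
  if (!is.null(config$annotation)) {
    annotation <- read_gene_annotation(config$annotation)
    tpm <- compute_tpm(counts, annotation)
    expressed <- filter_expressed(tpm, samples, cell_type = config$cell_type,
                                  threshold = config$tpm_threshold)
    if (!length(expressed)) stop("stage 'filter': no expressed genes")
  }
  counts_f <- counts[expressed, , drop = FALSE]
  sf <- compute_size_factors(counts_f)
  fit <- fit_dosage_model(counts_f, samples, config$design,
                          size_factors = sf, test_coefs = config$test_coefs)

  results <- lapply(fit$test_coefs, function(co) dosage_results(fit, co))
  names(results) <- fit$test_coefs

  deming <- overlap <- NULL
  if (all(c("x_copies", "y_copies") %in% fit$test_coefs)) {
    rx <- results$x_copies; ry <- results$y_copies
    ok <- rx$converged & is.finite(rx$SE) & is.finite(ry$SE) &
      rx$SE > 0 & ry$SE > 0
    if (sum(ok) >= 3)
      deming <- deming_fit(rx$log2FC[ok], ry$log2FC[ok],
                           se_x = rx$SE[ok], se_y = ry$SE[ok])
    sigx <- rx$gene_id[!is.na(rx$padj) & rx$padj < config$padj_threshold]
    sigy <- ry$gene_id[!is.na(ry$padj) & ry$padj < config$padj_threshold]
    overlap <- hypergeom_overlap(length(expressed), length(sigx),
                                 length(sigy),
                                 length(intersect(sigx, sigy)))
  }

  manifest <- list(
    package = "xydosage",
    version = as.character(utils::packageVersion("xydosage")),
    seed = config$seed,
    n_genes = nrow(counts_f), n_samples = ncol(counts_f),
    design = config$design,
    inputs = list(counts = unname(tools::md5sum(config$counts)),
                  samples = unname(tools::md5sum(config$samples))))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (co in names(results))
      write_results_tsv(results[[co]],
                        file.path(config$out_dir,
                                  paste0("results_", co, ".tsv")))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(fit = fit, results = results, deming = deming, overlap = overlap,
       expressed_genes = expressed, manifest = manifest)
}
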