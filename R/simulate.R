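#' Default karyotype table for a simulated cohort
#'
#' Sample-size-weighted mixture of sex chromosome constitutions spanning one
#' to four X chromosomes and zero to four Y chromosomes, the kind of cohort
#' needed to fit a single linear dosage model rather than pairwise
#' karyotype contrasts. Copy numbers may be fractional to represent mosaic
#' individuals (expression averages across subclones).
#'
#' @return data.frame with columns `label`, `x_copies`, `y_copies`,
#'   `chr21_copies`, `n_samples`.
#' @export
default_karyotype_table <- function() {
  data.frame(
    label = c("45,X", "46,XX", "46,XY", "47,XXY", "47,XYY", "47,XXX",
              "48,XXYY", "49,XXXXY", "49,XYYYY"),
    x_copies = c(1, 2, 1, 2, 1, 3, 2, 4, 1),
    y_copies = c(0, 0, 1, 1, 2, 0, 2, 1, 4),
    chr21_copies = 2,
    n_samples = c(10L, 25L, 25L, 15L, 15L, 10L, 8L, 6L, 6L),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the cohort count simulator
#'
#' Defines the generative model for a gene x sample count matrix:
#' \deqn{count_{gs} \sim NB(\mu_{gs}, \alpha_g), \quad
#'   \mu_{gs} = L_s \, 2^{\beta_{0g} + \beta_{Xg} x_s + \beta_{Yg} y_s +
#'   \beta_{21g} c_s + b_{g,batch(s)}}}
#' with NB variance \eqn{\mu + \alpha\mu^2}. Genes are partitioned into
#' disjoint truth classes: X-responsive only, Y-responsive only, shared
#' (same-sign response to X and Y), chr21-responsive, and null.
#'
#' Default effect sizes are uniform on 0.1-0.5 log2 units per chromosome
#' copy with random sign, i.e. mostly under 1.5-fold per copy, matching the
#' modest per-gene magnitudes such dosage responses show in practice.
#'
#' @param n_genes Number of genes.
#' @param karyotype_table data.frame with columns `x_copies`, `y_copies`,
#'   `chr21_copies`, `n_samples` (and optionally `label`); fractional
#'   copies allowed for mosaics, `x_copies >= 1`.
#' @param frac_x_responsive,frac_y_responsive,frac_shared,frac_chr21_responsive
#'   Fractions of genes in each (disjoint) responsive class; must sum to
#'   <= 1.
#' @param effect_size_law Law for |log2FC| per chromosome copy; sign is
#'   drawn at random (shared genes get the same sign for X and Y).
#' @param baseline_law Law for per-gene mean baseline expression (counts at
#'   library size factor 1).
#' @param dispersion_law Law for the NB dispersion alpha.
#' @param n_batches Number of library-preparation batches.
#' @param batch_sd SD (log2 units) of per-gene batch offsets; batch 1 is
#'   the reference with offset 0.
#' @param library_size_law Law for per-sample library size factors.
#' @param cell_type Cell type label written to the sample sheet.
#' @param seed Integer seed; identical configs and seeds give identical
#'   output.
#' @return A `sim_cohort_config` list.
#' @export
sim_cohort_config <- function(n_genes = 1000,
                              karyotype_table = default_karyotype_table(),
                              frac_x_responsive = 0.05,
                              frac_y_responsive = 0.02,
                              frac_shared = 0.03,
                              frac_chr21_responsive = 0,
                              effect_size_law = law("uniform", min = 0.1, max = 0.5),
                              baseline_law = law("lognormal",
                                                 meanlog = log(150), sdlog = 1.2),
                              dispersion_law = law("lognormal",
                                                   meanlog = log(0.05), sdlog = 0.5),
                              n_batches = 3,
                              batch_sd = 0.1,
                              library_size_law = law("lognormal",
                                                     meanlog = 0, sdlog = 0.25),
                              cell_type = "LCL",
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), karyotype_table = karyotype_table,
              frac_x_responsive = frac_x_responsive,
              frac_y_responsive = frac_y_responsive,
              frac_shared = frac_shared,
              frac_chr21_responsive = frac_chr21_responsive,
              effect_size_law = effect_size_law, baseline_law = baseline_law,
              dispersion_law = dispersion_law, n_batches = as.integer(n_batches),
              batch_sd = batch_sd, library_size_law = library_size_law,
              cell_type = cell_type, seed = as.integer(seed))
  class(cfg) <- "sim_cohort_config"
  validate_sim_cohort_config(cfg)
  cfg
}

validate_sim_cohort_config <- function(cfg) {
  kt <- cfg$karyotype_table
  if (cfg$n_genes <= 0)
    stop("n_genes must be positive")
  if (is.null(kt) || nrow(kt) == 0)
    stop("karyotype_table must have at least one row")
  need <- c("x_copies", "y_copies", "chr21_copies", "n_samples")
  if (!all(need %in% names(kt)))
    stop("karyotype_table needs columns: ", paste(need, collapse = ", "))
  if (any(kt$x_copies < 1))
    stop("x_copies must be >= 1 (every cell carries one active X)")
  if (any(kt$y_copies < 0) || any(kt$chr21_copies < 0))
    stop("copy numbers must be non-negative")
  fr <- cfg$frac_x_responsive + cfg$frac_y_responsive + cfg$frac_shared +
    cfg$frac_chr21_responsive
  if (fr > 1 + 1e-12)
    stop("responsive-class fractions must sum to <= 1")
  invisible(cfg)
}

#' Simulate a gene expression cohort with known dosage-response truth
#'
#' Generates a count matrix, sample sheet and the underlying truth
#' (per-gene baselines, log2 fold changes per chromosome copy, dispersions,
#' batch offsets, per-sample library size factors) under the NB model
#' described in [sim_cohort_config()].
#'
#' @param config A [sim_cohort_config()].
#' @return List with elements `counts` (integer matrix, genes x samples),
#'   `samples` (sample sheet data.frame), `truth` (list with `genes`
#'   data.frame carrying `beta0`, `betaX`, `betaY`, `beta21`, `alpha`,
#'   `class`; `batch_offsets` matrix; `library_sizes` vector).
#' @examples
#' sim <- simulate_cohort(sim_cohort_config(n_genes = 50, seed = 7))
#' dim(sim$counts)
#' table(sim$truth$genes$class)
#' @export
simulate_cohort <- function(config) {
  validate_sim_cohort_config(config)
  set.seed(config$seed)
  ng <- config$n_genes
  kt <- config$karyotype_table
  ns <- sum(kt$n_samples)

  gene_ids <- sprintf("G%05d", seq_len(ng))
  sample_ids <- sprintf("S%04d", seq_len(ns))

  ki <- rep(seq_len(nrow(kt)), kt$n_samples)
  samples <- data.frame(
    sample_id = sample_ids,
    cell_type = config$cell_type,
    x_copies = kt$x_copies[ki],
    y_copies = kt$y_copies[ki],
    chr21_copies = kt$chr21_copies[ki],
    batch = factor(sample(seq_len(config$n_batches), ns, replace = TRUE),
                   levels = seq_len(config$n_batches)),
    condition = "control",
    group_label = if ("label" %in% names(kt)) kt$label[ki] else NA_character_,
    stringsAsFactors = FALSE
  )

  # disjoint truth classes
  cls <- rep("null", ng)
  n_x <- round(config$frac_x_responsive * ng)
  n_y <- round(config$frac_y_responsive * ng)
  n_sh <- round(config$frac_shared * ng)
  n_21 <- round(config$frac_chr21_responsive * ng)
  idx <- sample.int(ng, n_x + n_y + n_sh + n_21)
  cls[idx[seq_len(n_x)]] <- "x_responsive"
  cls[idx[n_x + seq_len(n_y)]] <- "y_responsive"
  cls[idx[n_x + n_y + seq_len(n_sh)]] <- "shared"
  cls[idx[n_x + n_y + n_sh + seq_len(n_21)]] <- "chr21_responsive"

  rsign <- function(n) sample(c(-1, 1), n, replace = TRUE)
  betaX <- betaY <- beta21 <- numeric(ng)
  ix <- cls == "x_responsive"
  betaX[ix] <- rsign(sum(ix)) * draw_law(config$effect_size_law, sum(ix))
  iy <- cls == "y_responsive"
  betaY[iy] <- rsign(sum(iy)) * draw_law(config$effect_size_law, sum(iy))
  ish <- cls == "shared"
  if (any(ish)) {
    bx <- rsign(sum(ish)) * draw_law(config$effect_size_law, sum(ish))
    betaX[ish] <- bx
    # same sign, magnitude jittered around the X response
    betaY[ish] <- bx * stats::runif(sum(ish), 0.6, 1.4)
  }
  i21 <- cls == "chr21_responsive"
  beta21[i21] <- rsign(sum(i21)) * draw_law(config$effect_size_law, sum(i21))

  beta0 <- log2(draw_law(config$baseline_law, ng))
  alpha <- draw_law(config$dispersion_law, ng)
  libsize <- draw_law(config$library_size_law, ns)

  batch_off <- matrix(0, ng, config$n_batches)
  if (config$n_batches > 1 && config$batch_sd > 0)
    batch_off[, -1] <- stats::rnorm(ng * (config$n_batches - 1),
                                    sd = config$batch_sd)

  bi <- as.integer(samples$batch)
  log2mu <- outer(beta0, rep(1, ns)) +
    outer(betaX, samples$x_copies) +
    outer(betaY, samples$y_copies) +
    outer(beta21, samples$chr21_copies - 2) +
    batch_off[, bi, drop = FALSE]
  mu <- sweep(2^log2mu, 2, libsize, `*`)

  counts <- matrix(0L, ng, ns, dimnames = list(gene_ids, sample_ids))
  size <- 1 / pmax(alpha, 1e-12)
  for (s in seq_len(ns)) {
    counts[, s] <- ifelse(alpha < 1e-10,
                          stats::rpois(ng, mu[, s]),
                          stats::rnbinom(ng, mu = mu[, s], size = size))
  }
  storage.mode(counts) <- "integer"

  truth_genes <- data.frame(gene_id = gene_ids, class = cls, beta0 = beta0,
                            betaX = betaX, betaY = betaY, beta21 = beta21,
                            alpha = alpha, stringsAsFactors = FALSE)
  list(counts = counts, samples = samples,
       truth = list(genes = truth_genes, batch_offsets = batch_off,
                    library_sizes = stats::setNames(libsize, sample_ids)))
}

#' Configuration for the allelic-ratio study simulator
#'
#' Describes five study "dialects" used in meta-analyses of expression from
#' the inactive X (Xi): per-gene summary allelic ratios (AR) with SD and n;
#' precomputed adjusted p values with bulk and single-cell arms; per-sample
#' active-X read fractions; per-sample allele counts with an XCI skewing
#' coefficient; and per-sample bulk ARs. AR is the ratio of reads from the
#' lower- to the higher-expressed allele, 0 = monoallelic, 1 = balanced.
#'
#' Subject (silenced-on-Xi) genes draw true ARs with mass concentrated near
#' zero; escape genes draw strictly positive ARs.
#'
#' @param n_genes Number of X-linked genes.
#' @param frac_escape Fraction of genes escaping X inactivation (ignored if
#'   `true_escape_set` given).
#' @param true_escape_set Character vector of escaping gene ids; may be
#'   empty (all-subject simulation).
#' @param study_designs List of five lists (`summaryAR`, `precomputed`,
#'   `singlecell_fraction`, `skew_adjusted`, `bulkAR`), each with
#'   `n_samples` and `missingness` (probability a gene x sample observation
#'   is absent).
#' @param skew_law Law for per-sample skewing coefficients, support (0.5, 1].
#' @param ar_escape_law,ar_subject_law Laws for true Xi/Xa expression ratios
#'   of escape and subject genes. Subject genes are silenced on Xi, so their
#'   default law concentrates essentially all mass below 0.02.
#' @param array_noise_sd SD of per-sample AR measurement noise in the
#'   array-intensity dialects (studies 1 and 2); intensity-ratio noise is
#'   symmetric around the true AR and may dip below zero.
#' @param cell_noise_sd SD of per-cell AR noise in the single-cell fraction
#'   dialect (study 3); clamped to [0, 1].
#' @param read_depth_law Law for total allele-informative read counts in
#'   the count-based dialects (studies 4 and 5); minor-allele reads are
#'   binomial in the true allele fraction, so silenced genes yield mostly
#'   exact-zero ARs.
#' @param background_rate Residual minor-allele read rate (mapping error /
#'   leaky silencing) added to the true AR in count-based dialects.
#' @param seed Integer seed.
#' @return A `sim_allelic_config` list.
#' @export
sim_allelic_config <- function(n_genes = 500,
                               frac_escape = 0.2,
                               true_escape_set = NULL,
                               study_designs = list(
                                 summaryAR = list(n_samples = 20, missingness = 0.3),
                                 precomputed = list(n_samples = 3, missingness = 0.3),
                                 singlecell_fraction = list(n_samples = 5, missingness = 0.4),
                                 skew_adjusted = list(n_samples = 30, missingness = 0.3),
                                 bulkAR = list(n_samples = 15, missingness = 0.3)),
                               skew_law = law("uniform", min = 0.8, max = 1),
                               ar_escape_law = law("uniform", min = 0.15, max = 0.6),
                               ar_subject_law = law("exponential", rate = 300, max = 0.02),
                               array_noise_sd = 0.05,
                               cell_noise_sd = 0.02,
                               read_depth_law = law("uniform", min = 100, max = 600),
                               background_rate = 0.001,
                               seed = 1L) {
  gene_ids <- sprintf("XG%04d", seq_len(n_genes))
  if (is.null(true_escape_set)) {
    n_esc <- round(frac_escape * n_genes)
    true_escape_set <- gene_ids[seq_len(n_esc)]
  } else {
    if (!all(true_escape_set %in% gene_ids))
      stop("true_escape_set must be a subset of the simulated gene ids ",
           "(XG0001..)")
  }
  need <- c("summaryAR", "precomputed", "singlecell_fraction",
            "skew_adjusted", "bulkAR")
  if (!all(need %in% names(study_designs)))
    stop("study_designs must name: ", paste(need, collapse = ", "))
  structure(list(n_genes = as.integer(n_genes), gene_ids = gene_ids,
                 true_escape_set = true_escape_set,
                 study_designs = study_designs, skew_law = skew_law,
                 ar_escape_law = ar_escape_law, ar_subject_law = ar_subject_law,
                 array_noise_sd = array_noise_sd, cell_noise_sd = cell_noise_sd,
                 read_depth_law = read_depth_law,
                 background_rate = background_rate, seed = as.integer(seed)),
            class = "sim_allelic_config")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Simulate five allelic-ratio study tables with known escape truth
#'
#' Generates one table per study dialect (see [sim_allelic_config()]):
#' \describe{
#'   \item{summaryAR}{per-gene `mean_ar`, `sd_ar`, `n_informative`.}
#'   \item{precomputed}{per-gene single-cell arm (`sc_n_individuals`,
#'     `sc_padj`) and bulk arm (`bulk_present`, `bulk_padj`) plus `mean_ar`.}
#'   \item{singlecell_fraction}{per-sample active-X read fraction
#'     `xa_fraction` = Xa reads / total reads.}
#'   \item{skew_adjusted}{per-sample allele counts (`a1_count` lower,
#'     `a2_count` higher) and the sample's `skew` coefficient. The observed
#'     minor-allele fraction follows from mixing cells inactivating either
#'     parental X: with skewing s and true Xi/Xa ratio r, allele expression
#'     is proportional to (1-s) + s r (minor) vs s + (1-s) r (major).}
#'   \item{bulkAR}{per-sample `ar`.}
#' }
#'
#' Measurement noise matches each dialect's technology: SNP-array intensity
#' ratios (studies 1, 2) carry symmetric Gaussian noise and may dip below
#' zero; single-cell fractions (study 3) carry clamped Gaussian noise; the
#' sequencing dialects (studies 4, 5) draw minor-allele read counts
#' binomially from the true allele fraction, so silenced genes produce
#' mostly exact-zero ARs.
#'
#' @param config A [sim_allelic_config()].
#' @return List with `studies` (named list of five data.frames) and `truth`
#'   (data.frame `gene_id`, `escape`, `true_ar`).
#' @export
simulate_allelic_studies <- function(config) {
  if (!inherits(config, "sim_allelic_config"))
    stop("config must come from sim_allelic_config()")
  set.seed(config$seed)
  ids <- config$gene_ids
  ng <- config$n_genes
  escape <- ids %in% config$true_escape_set
  true_ar <- numeric(ng)
  true_ar[escape] <- draw_law(config$ar_escape_law, sum(escape))
  true_ar[!escape] <- draw_law(config$ar_subject_law, sum(!escape))

  # array-intensity AR: symmetric noise, can be slightly negative
  array_ar <- function(gene_idx, n) {
    true_ar[gene_idx] + stats::rnorm(n, sd = config$array_noise_sd)
  }
  # single-cell AR: clamped to the physical range
  cell_ar <- function(gene_idx, n) {
    clamp01(true_ar[gene_idx] + stats::rnorm(n, sd = config$cell_noise_sd))
  }
  # sequencing AR: minor reads binomial in the true allele fraction
  count_ar <- function(gene_idx, n) {
    r <- true_ar[gene_idx] + config$background_rate
    total <- round(draw_law(config$read_depth_law, n))
    minor <- stats::rbinom(n, total, r / (1 + r))
    minor / pmax(total - minor, 1)
  }
  keep <- function(n, miss) stats::runif(n) >= miss
  sd_cfg <- config$study_designs

  ## study 1: per-gene summary AR
  d1 <- sd_cfg$summaryAR
  obs1 <- lapply(seq_len(ng), function(g) {
    k <- keep(d1$n_samples, d1$missingness)
    if (!any(k)) return(c(NA, NA, 0))
    a <- array_ar(g, sum(k))
    c(mean(a), stats::sd(a), sum(k))
  })
  obs1 <- do.call(rbind, obs1)
  summaryAR <- data.frame(gene_id = ids, mean_ar = obs1[, 1],
                          sd_ar = obs1[, 2], n_informative = obs1[, 3],
                          stringsAsFactors = FALSE)

  ## study 2: precomputed adjusted p values, single-cell + bulk arms
  d2 <- sd_cfg$precomputed
  sc_n <- stats::rbinom(ng, d2$n_samples, 1 - d2$missingness)
  bulk_present <- keep(ng, d2$missingness)
  arm_p <- function(n_obs) {
    # z-style one-sided evidence that the arm's mean AR exceeds zero
    vapply(seq_len(ng), function(g) {
      if (n_obs[g] == 0) return(NA_real_)
      m <- mean(array_ar(g, max(n_obs[g], 1)))
      stats::pnorm(m / (config$array_noise_sd / sqrt(n_obs[g])),
                   lower.tail = FALSE)
    }, numeric(1))
  }
  sc_p <- arm_p(sc_n)
  bulk_p <- arm_p(as.integer(bulk_present))
  precomputed <- data.frame(
    gene_id = ids,
    sc_n_individuals = sc_n,
    sc_padj = adjust_bh(sc_p),
    bulk_present = bulk_present,
    bulk_padj = adjust_bh(bulk_p),
    mean_ar = vapply(seq_len(ng), function(g)
      mean(clamp01(array_ar(g, 3))), numeric(1)),
    stringsAsFactors = FALSE)

  ## study 3: per-sample Xa fractions (single-cell)
  d3 <- sd_cfg$singlecell_fraction
  rows3 <- lapply(seq_len(ng), function(g) {
    k <- which(keep(d3$n_samples, d3$missingness))
    if (!length(k)) return(NULL)
    a <- cell_ar(g, length(k))
    data.frame(gene_id = ids[g], sample_id = sprintf("SC%02d", k),
               xa_fraction = 1 / (1 + a), stringsAsFactors = FALSE)
  })
  singlecell_fraction <- do.call(rbind, rows3)

  ## study 4: per-sample allele counts with skewing coefficients
  d4 <- sd_cfg$skew_adjusted
  skew <- pmin(draw_law(config$skew_law, d4$n_samples), 1)
  skew <- pmax(skew, 0.5 + 1e-6)
  rows4 <- lapply(seq_len(ng), function(g) {
    k <- which(keep(d4$n_samples, d4$missingness))
    if (!length(k)) return(NULL)
    r <- true_ar[g] + config$background_rate
    minor_frac <- ((1 - skew[k]) + skew[k] * r) / (1 + r)
    total <- round(draw_law(config$read_depth_law, length(k)))
    minor <- stats::rbinom(length(k), total, minor_frac)
    data.frame(gene_id = ids[g], sample_id = sprintf("SK%03d", k),
               a1_count = pmin(minor, total - minor),
               a2_count = pmax(minor, total - minor),
               skew = skew[k], stringsAsFactors = FALSE)
  })
  skew_adjusted <- do.call(rbind, rows4)

  ## study 5: per-sample bulk ARs
  d5 <- sd_cfg$bulkAR
  rows5 <- lapply(seq_len(ng), function(g) {
    k <- which(keep(d5$n_samples, d5$missingness))
    if (!length(k)) return(NULL)
    data.frame(gene_id = ids[g], sample_id = sprintf("BK%03d", k),
               ar = count_ar(g, length(k)), stringsAsFactors = FALSE)
  })
  bulkAR <- do.call(rbind, rows5)

  list(studies = list(summaryAR = summaryAR, precomputed = precomputed,
                      singlecell_fraction = singlecell_fraction,
                      skew_adjusted = skew_adjusted, bulkAR = bulkAR),
       truth = data.frame(gene_id = ids, escape = escape, true_ar = true_ar,
                          stringsAsFactors = FALSE))
}

#' Simulate binned depth-of-coverage profiles for tandem-repeat copy number
#'
#' Emulates whole-genome sequencing depth over a high-copy tandem repeat
#' (DYZ1, the Yq heterochromatin satellite) and a single-copy reference
#' region, with a smooth multiplicative GC bias shared by both regions and
#' per-bin lognormal noise:
#' \deqn{depth = base \times copy \times gcbias(GC) \times noise.}
#' Single-copy bins have copy number 1; the ratio of GC-corrected region
#' means estimates the repeat copy number.
#'
#' @param n_samples Number of samples.
#' @param copy_law Law for the true repeat copy number per sample.
#' @param gc_bias_amplitude Amplitude A of the sinusoidal GC bias curve
#'   `1 + A sin(2 pi (gc - 0.5))`; must be non-negative and < 1 so depth
#'   stays positive.
#' @param noise_sd SD (log scale) of per-bin depth noise.
#' @param base_depth_law Law for per-sample base (haploid) depth.
#' @param n_bins_dyz1,n_bins_single Number of bins per region; bin GC
#'   fractions are genome properties, drawn once and shared by all samples.
#' @param gc_range_dyz1,gc_range_single GC-fraction ranges of the two
#'   regions. The defaults make the repeat region AT-rich relative to the
#'   single-copy reference (satellite DNA is AT-biased), so GC bias does
#'   not cancel in the depth ratio and correction matters.
#' @param seed Integer seed.
#' @return List with `depths` (data.frame `sample_id`, `bin_id`, `region`,
#'   `gc_fraction`, `depth`) and `truth` (data.frame `sample_id`,
#'   `copy_number`, `base_depth`).
#' @export
simulate_depth_profiles <- function(n_samples,
                                    copy_law = law("uniform", min = 20, max = 900),
                                    gc_bias_amplitude = 0.5,
                                    noise_sd = 0.05,
                                    base_depth_law = law("uniform", min = 20, max = 40),
                                    n_bins_dyz1 = 40,
                                    n_bins_single = 100,
                                    gc_range_dyz1 = c(0.30, 0.45),
                                    gc_range_single = c(0.30, 0.65),
                                    seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (gc_bias_amplitude < 0) stop("gc_bias_amplitude must be non-negative")
  set.seed(as.integer(seed))
  gc_dyz1 <- stats::runif(n_bins_dyz1, gc_range_dyz1[1], gc_range_dyz1[2])
  gc_single <- stats::runif(n_bins_single, gc_range_single[1],
                            gc_range_single[2])
  gcbias <- function(gc) 1 + gc_bias_amplitude * sin(2 * pi * (gc - 0.5))

  copy <- draw_law(copy_law, n_samples)
  base <- draw_law(base_depth_law, n_samples)
  sample_ids <- sprintf("D%03d", seq_len(n_samples))

  one <- function(s) {
    noise <- function(n) if (noise_sd > 0)
      stats::rlnorm(n, -noise_sd^2 / 2, noise_sd) else rep(1, n)
    rbind(
      data.frame(sample_id = sample_ids[s],
                 bin_id = sprintf("dyz1_%03d", seq_len(n_bins_dyz1)),
                 region = "DYZ1", gc_fraction = gc_dyz1,
                 depth = base[s] * copy[s] * gcbias(gc_dyz1) * noise(n_bins_dyz1),
                 stringsAsFactors = FALSE),
      data.frame(sample_id = sample_ids[s],
                 bin_id = sprintf("sc_%03d", seq_len(n_bins_single)),
                 region = "single_copy", gc_fraction = gc_single,
                 depth = base[s] * 1 * gcbias(gc_single) * noise(n_bins_single),
                 stringsAsFactors = FALSE))
  }
  depths <- do.call(rbind, lapply(seq_len(n_samples), one))
  list(depths = depths,
       truth = data.frame(sample_id = sample_ids, copy_number = copy,
                          base_depth = base, stringsAsFactors = FALSE))
}
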