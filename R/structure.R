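#' GC-bias correction of binned read depths
#'
#' Estimates a smooth GC -> relative depth curve from the single-copy
#' reference bins of each sample (binned medians over GC, normalized so the
#' overall single-copy median maps to 1, linearly interpolated between bin
#' midpoints) and divides every bin's depth by the curve evaluated at its
#' GC fraction. Only single-copy bins inform the curve, so copy-number
#' signal in the repeat region cannot leak into its own correction. With
#' fewer than two distinct GC bins the transform is the identity.
#'
#' @param depths data.frame with `sample_id`, `bin_id`, `region` (values
#'   `DYZ1` / `single_copy`), `gc_fraction`, `depth`.
#' @param n_gc_bins Number of GC bins for the median curve (default 10).
#' @return `depths` with corrected `depth` (original kept as `raw_depth`).
#' @export
gc_correct_depth <- function(depths, n_gc_bins = 10) {
  need <- c("sample_id", "bin_id", "region", "gc_fraction", "depth")
  stopifnot(all(need %in% names(depths)))
  depths$raw_depth <- depths$depth
  for (s in unique(depths$sample_id)) {
    rows <- depths$sample_id == s
    sc <- rows & depths$region == "single_copy"
    gc_sc <- depths$gc_fraction[sc]
    if (length(unique(gc_sc)) < 2) next  # identical GC: identity transform
    brks <- unique(stats::quantile(gc_sc, probs = seq(0, 1,
                                                      length.out = n_gc_bins + 1)))
    if (length(brks) < 3) next
    bin <- cut(gc_sc, brks, include.lowest = TRUE)
    med <- tapply(depths$depth[sc], bin, stats::median)
    mids <- tapply(gc_sc, bin, stats::median)
    okb <- !is.na(med) & !is.na(mids)
    if (sum(okb) < 2) next
    curve <- med[okb] / stats::median(depths$depth[sc])
    rel <- stats::approx(mids[okb], curve, xout = depths$gc_fraction[rows],
                         rule = 2)$y
    depths$depth[rows] <- depths$depth[rows] / rel
  }
  depths
}

#' Repeat-region to single-copy depth ratio
#'
#' Per sample, the mean (corrected) depth over the tandem-repeat region
#' divided by the mean over the single-copy reference region. The ratio is
#' invariant to global depth rescaling of a sample and estimates the
#' repeat's copy number; for DYZ1 it indexes Yq heterochromatin length.
#'
#' @param depths Depth table, ideally after [gc_correct_depth()].
#' @return data.frame `sample_id`, `dyz1_mean`, `single_copy_mean`, `ratio`.
#' @export
dyz1_ratio <- function(depths) {
  sp <- split(depths, depths$sample_id)
  rows <- lapply(sp, function(d) {
    dm <- mean(d$depth[d$region == "DYZ1"])
    sm <- mean(d$depth[d$region == "single_copy"])
    if (!is.finite(sm) || sm <= 0)
      stop("zero single-copy coverage in sample ", d$sample_id[1])
    data.frame(sample_id = d$sample_id[1], dyz1_mean = dm,
               single_copy_mean = sm, ratio = dm / sm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Model expression as a function of repeat depth-of-coverage
#'
#' Delegates to [fit_dosage_model()] with covariate log2(depth ratio) plus
#' any categorical confounders (sequencing population, lab). The reported
#' coefficient is the log2 fold change in expression per doubling of
#' repeat content.
#'
#' @param counts Count matrix, genes x samples.
#' @param ratios data.frame `sample_id`, `ratio` (positive), matching the
#'   columns of `counts`.
#' @param covariates Optional data.frame of per-sample confounders
#'   (character/factor columns), with `sample_id`.
#' @param ... Passed to [fit_dosage_model()].
#' @return A `dosage_fit` with test coefficient `log2_depth`.
#' @export
fit_depth_expression_model <- function(counts, ratios, covariates = NULL,
                                       ...) {
  m <- match(colnames(counts), ratios$sample_id)
  if (anyNA(m)) stop("depth ratios missing for some samples")
  if (any(ratios$ratio[m] <= 0)) stop("depth ratios must be positive")
  samples <- data.frame(sample_id = colnames(counts),
                        log2_depth = log2(ratios$ratio[m]),
                        stringsAsFactors = FALSE)
  covs <- "log2_depth"
  if (!is.null(covariates)) {
    cm <- match(colnames(counts), covariates$sample_id)
    if (anyNA(cm)) stop("covariates missing for some samples")
    for (v in setdiff(names(covariates), "sample_id")) {
      vals <- covariates[[v]][cm]
      if (length(unique(vals)) > 1) {  # constant confounders are dropped
        samples[[v]] <- vals
        covs <- c(covs, v)
      }
    }
  }
  fit_dosage_model(counts, samples, covs, test_coefs = "log2_depth", ...)
}

#' Log-transform, batch-correct and project samples by PCA
#'
#' Normalized counts are transformed as log2(count/sizefactor + 1) (a
#' variance-stabilizing surrogate), optionally residualized per gene on
#' batch indicators (retaining the gene mean, so only batch deviations are
#' removed), restricted to a gene set of interest, gene-standardized
#' (centered, unit variance), and decomposed by SVD.
#'
#' @param counts Count matrix, genes x samples.
#' @param size_factors Per-sample size factors (computed when NULL).
#' @param gene_set Genes to project on (e.g. the shared dosage-responsive
#'   set); must intersect the count matrix.
#' @param batch Optional per-sample batch factor to residualize out.
#' @param n_components Number of components to retain.
#' @return List of class `pca_projection`: `scores` (samples x components),
#'   `var_fraction`, `rotation`, `gene_ids`.
#' @export
transform_and_pca <- function(counts, size_factors = NULL, gene_set = NULL,
                              batch = NULL, n_components = 10) {
  if (ncol(counts) < 3) stop("need at least 3 samples")
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  lt <- log2(sweep(counts, 2, size_factors, `/`) + 1)
  if (!is.null(gene_set)) {
    gene_set <- intersect(gene_set, rownames(lt))
    if (!length(gene_set)) stop("gene_set has no genes in the count matrix")
    lt <- lt[gene_set, , drop = FALSE]
  }
  if (!is.null(batch) && length(unique(batch)) > 1) {
    X <- stats::model.matrix(~ factor(batch))
    fitted <- t(X %*% solve(crossprod(X), crossprod(X, t(lt))))
    lt <- lt - fitted + rowMeans(lt)
  }
  sds <- apply(lt, 1, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all genes constant after transformation")
  Z <- (lt[keep, , drop = FALSE] - rowMeans(lt[keep, , drop = FALSE])) /
    sds[keep]
  sv <- svd(t(Z))
  k <- min(n_components, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  dimnames(scores) <- list(colnames(counts), paste0("PC", seq_len(k)))
  structure(list(scores = scores,
                 var_fraction = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
                 rotation = sv$v[, seq_len(k), drop = FALSE],
                 gene_ids = rownames(Z)),
            class = "pca_projection")
}

#' Per-group confidence ellipses in PC space
#'
#' For every group with at least three samples, the 95% (by default)
#' confidence region around the group centroid on (PC1, PC2): center =
#' group mean, shape = sample covariance scaled by the chi-square(2)
#' quantile (5.991 at level 0.95). Groups whose covariance is singular
#' (e.g. collinear points) are flagged degenerate.
#'
#' @param scores Sample x component score matrix (>= 2 columns).
#' @param groups Group label per sample.
#' @param level Confidence level (default 0.95).
#' @return data.frame per retained group: `group`, `n`, `center1`,
#'   `center2`, `cov11`, `cov12`, `cov22`, `chisq_scale`, `semi_major`,
#'   `semi_minor`, `angle` (radians), `degenerate`. Groups with n < 3 are
#'   skipped with a message.
#' @export
group_ellipse <- function(scores, groups, level = 0.95) {
  stopifnot(ncol(scores) >= 2, nrow(scores) == length(groups))
  q <- stats::qchisq(level, df = 2)
  out <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 3) {
      message("group_ellipse: skipping group '", g, "' (n = ",
              length(idx), " < 3)")
      next
    }
    pts <- scores[idx, 1:2, drop = FALSE]
    ctr <- colMeans(pts)
    S <- stats::cov(pts)
    ev <- eigen(S, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    out[[length(out) + 1L]] <- data.frame(
      group = g, n = length(idx), center1 = ctr[1], center2 = ctr[2],
      cov11 = S[1, 1], cov12 = S[1, 2], cov22 = S[2, 2], chisq_scale = q,
      semi_major = sqrt(lam[1] * q), semi_minor = sqrt(lam[2] * q),
      angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
      degenerate = lam[2] < 1e-12 * max(lam[1], 1),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign peaks to genes by TSS proximity
#'
#' A gene is "bound" if any peak overlaps the window
#' `[tss - window, tss + window)` on its chromosome (0-based half-open
#' coordinates, clipped at 0). The TSS is the interval start for + strand
#' genes and the interval end for - strand genes. Peaks on chromosomes
#' absent from the annotation are skipped with a warning.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param annotation data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param window Half-width of the TSS window in bases (default 1000).
#' @return Named logical vector (one element per annotation gene).
#' @export
assign_peaks_to_genes <- function(peaks, annotation, window = 1000) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)),
            all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(annotation)))
  if (any(peaks$start >= peaks$end)) stop("peaks must have start < end")
  bound <- stats::setNames(logical(nrow(annotation)), annotation$gene_id)
  unknown <- setdiff(unique(peaks$chrom), unique(annotation$chrom))
  if (length(unknown)) {
    warning("skipping peaks on chromosome(s) absent from annotation: ",
            paste(unknown, collapse = ", "))
    peaks <- peaks[!peaks$chrom %in% unknown, , drop = FALSE]
  }
  if (nrow(peaks) == 0) return(bound)
  tss <- ifelse(annotation$strand == "+", annotation$start, annotation$end)
  win_start <- pmax(tss - window, 0)
  win_end <- tss + window
  # 0-based half-open [s, e) maps to 1-based closed [s + 1, e]
  gene_gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(start = win_start + 1, end = win_end))
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
  hits <- GenomicRanges::findOverlaps(gene_gr, peak_gr)
  bound[unique(S4Vectors::queryHits(hits))] <- TRUE
  bound
}

#' Fraction of expressing cell lines with binding
#'
#' Per gene, the number of cell lines with a peak near the TSS divided by
#' the number of cell lines in which the gene is expressed; lines where the
#' gene is not expressed are excluded from numerator and denominator.
#' Undefined (NA) when the gene is expressed in no line.
#'
#' @param bound Logical matrix, genes x cell lines (peak near TSS).
#' @param expressed Logical matrix, same shape (e.g. median TPM >= 1).
#' @return Named numeric vector of fractions in [0, 1] (NA when
#'   undefined).
#' @export
binding_proportion <- function(bound, expressed) {
  stopifnot(identical(dim(bound), dim(expressed)))
  num <- rowSums(bound & expressed)
  den <- rowSums(expressed)
  out <- ifelse(den > 0, num / den, NA_real_)
  stats::setNames(out, rownames(bound))
}
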