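#' Transcripts per million
#'
#' Length-normalized within-sample expression: each count is divided by the
#' gene's effective length, and the resulting rates are rescaled so that
#' every column sums to one million.
#'
#' @param counts Non-negative matrix, genes x samples, rownames = gene ids.
#' @param annotation data.frame with columns `gene_id` and
#'   `effective_length` (bases, > 0); every gene in `counts` must appear.
#' @return TPM matrix with the dimensions and dimnames of `counts`.
#' @export
compute_tpm <- function(counts, annotation) {
  len <- annotation$effective_length[match(rownames(counts), annotation$gene_id)]
  if (anyNA(len))
    stop("missing effective_length for genes: ",
         paste(utils::head(rownames(counts)[is.na(len)], 5), collapse = ", "))
  if (any(len <= 0)) stop("effective_length must be > 0")
  rate <- counts / len
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("zero total rate in sample(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  sweep(rate, 2, tot, `/`) * 1e6
}

#' Expression filter on euploid medians
#'
#' A gene is retained, within a cell type, if its median TPM across 46,XX
#' samples or across 46,XY samples is at least `threshold` (inclusive).
#'
#' @param tpm TPM matrix (genes x samples).
#' @param samples Sample sheet with `sample_id`, `cell_type`, `x_copies`,
#'   `y_copies`.
#' @param cell_type Cell type to filter within; default uses all samples.
#' @param threshold Minimum median TPM (default 1).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(tpm, samples, cell_type = NULL, threshold = 1) {
  stopifnot(all(samples$sample_id %in% colnames(tpm)))
  if (!is.null(cell_type)) samples <- samples[samples$cell_type == cell_type, ]
  xx <- samples$sample_id[samples$x_copies == 2 & samples$y_copies == 0]
  xy <- samples$sample_id[samples$x_copies == 1 & samples$y_copies == 1]
  if (length(xx) == 0 && length(xy) == 0)
    stop("no euploid (46,XX or 46,XY) samples",
         if (!is.null(cell_type)) paste0(" in cell type ", cell_type))
  med <- function(ids) if (length(ids))
    apply(tpm[, ids, drop = FALSE], 1, stats::median) else
      rep(-Inf, nrow(tpm))
  keep <- med(xx) >= threshold | med(xy) >= threshold
  rownames(tpm)[keep]
}

#' Median-of-ratios size factors
#'
#' For each gene with no zero counts, a pseudo-reference is the geometric
#' mean of its counts across samples; a sample's size factor is the median
#' over genes of count/reference, rescaled so the size factors have
#' geometric mean 1. `gene_subset` restricts the reference genes (e.g. to
#' autosomes, so sex-linked dosage does not leak into normalization).
#'
#' @param counts Count matrix, genes x samples.
#' @param gene_subset Optional character vector of gene ids to compute the
#'   reference from.
#' @param pseudo_reference If TRUE, genes with zeros are kept and the
#'   per-gene median ignores zero counts (fallback for sparse data).
#' @return Named numeric vector of positive size factors, geometric mean 1.
#' @export
compute_size_factors <- function(counts, gene_subset = NULL,
                                 pseudo_reference = FALSE) {
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, rownames(counts))
    if (length(missing))
      stop("gene_subset genes absent from counts: ",
           paste(utils::head(missing, 5), collapse = ", "))
    counts <- counts[gene_subset, , drop = FALSE]
  }
  if (!pseudo_reference) {
    usable <- rowSums(counts == 0) == 0
    if (!any(usable))
      stop("no genes without zero counts; consider pseudo_reference = TRUE")
    counts <- counts[usable, , drop = FALSE]
    ref <- exp(rowMeans(log(counts)))
    sf <- apply(counts, 2, function(cnt) stats::median(cnt / ref))
  } else {
    lc <- log(counts)
    lc[!is.finite(lc)] <- NA
    ref <- exp(rowMeans(lc, na.rm = TRUE))
    ok <- is.finite(ref) & ref > 0
    if (!any(ok)) stop("no usable genes for pseudo-reference size factors")
    sf <- apply(counts[ok, , drop = FALSE], 2, function(cnt) {
      r <- cnt / ref[ok]
      stats::median(r[cnt > 0])
    })
  }
  sf / exp(mean(log(sf)))
}

#' Build a design matrix from a sample sheet
#'
#' Numeric covariates (`x_copies`, `y_copies`, `chr21_copies`, `log2_depth`,
#' ...) enter as given; character/factor covariates (`batch`, `condition`,
#' `population`, `lab`, ...) are expanded to treatment-coded dummies. An
#' intercept is always included. The design must be full rank; aliased
#' columns are reported.
#'
#' @param samples Sample sheet data.frame.
#' @param covariates Character vector of column names of `samples`.
#' @param reference_levels Named list: reference level per categorical
#'   covariate.
#' @return Numeric design matrix, one row per sample.
#' @export
build_design <- function(samples, covariates, reference_levels = list()) {
  missing <- setdiff(covariates, names(samples))
  if (length(missing))
    stop("covariates absent from sample sheet: ",
         paste(missing, collapse = ", "))
  for (v in covariates) {
    if (is.character(samples[[v]]) || is.factor(samples[[v]])) {
      samples[[v]] <- factor(samples[[v]])
      ref <- reference_levels[[v]]
      if (!is.null(ref)) samples[[v]] <- stats::relevel(samples[[v]], ref)
    }
  }
  fml <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  X <- stats::model.matrix(fml, data = samples)
  rownames(X) <- samples$sample_id
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  X
}

#' Method-of-moments NB dispersion estimates
#'
#' On size-factor-normalized counts q, the NB law implies
#' Var(q) ~ xi * mu + alpha * mu^2 with xi = mean(1/sf). The residual
#' variance after an OLS fit of q on the design replaces Var(q), so
#' covariate structure does not inflate the estimate. Estimates are floored
#' at `min_disp`; optional shrinkage pulls log-dispersions halfway toward a
#' fitted `a0 + a1/mu` trend.
#'
#' @param counts Count matrix, genes x samples.
#' @param size_factors Positive per-sample size factors.
#' @param design Design matrix (defaults to intercept-only).
#' @param min_disp Dispersion floor.
#' @param trend If TRUE, shrink toward the mean-dispersion trend.
#' @return Named per-gene dispersion vector.
#' @export
estimate_dispersion <- function(counts, size_factors,
                                design = NULL, min_disp = 1e-8,
                                trend = FALSE) {
  n <- ncol(counts)
  if (is.null(design)) design <- matrix(1, n, 1)
  p <- ncol(design)
  if (n <= p) stop("fewer samples than design columns; cannot estimate ",
                   "dispersion (need residual degrees of freedom)")
  q <- sweep(counts, 2, size_factors, `/`)
  H <- design %*% solve(crossprod(design), t(design))
  resid <- q - q %*% t(H)
  s2 <- rowSums(resid^2) / (n - p)
  mu <- rowMeans(q)
  xi <- mean(1 / size_factors)
  alpha <- (s2 - xi * mu) / mu^2
  alpha[!is.finite(alpha)] <- min_disp
  alpha <- pmax(alpha, min_disp)
  if (trend) {
    ok <- alpha > min_disp & mu > 0
    if (sum(ok) >= 10) {
      fit <- stats::lm(alpha[ok] ~ I(1 / mu[ok]))
      pred <- pmax(stats::coef(fit)[1] + stats::coef(fit)[2] / mu, min_disp)
      alpha <- exp((log(alpha) + log(pred)) / 2)
    }
  }
  stats::setNames(alpha, rownames(counts))
}

# Fisher-scoring IRLS for a single-gene NB GLM with log link, fixed
# dispersion alpha and offset (log size factors). Weights mu/(1+alpha*mu)
# are the inverse variance of the working response on the linear scale.
nb_irls <- function(y, X, offset, alpha, maxit = 100L, tol = 1e-8) {
  p <- ncol(X)
  if (all(y == 0))
    return(list(beta = rep(NA_real_, p), se = rep(NA_real_, p),
                converged = FALSE, deviance = NA_real_))
  beta <- qr.coef(qr(X), log(y + 0.5) - offset)
  beta[!is.finite(beta)] <- 0
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (anyNA(beta_new)) break
    beta <- beta_new
    dev <- nb_deviance(y, exp(pmin(pmax(drop(X %*% beta) + offset, -30), 30)),
                       alpha)
    if (is.finite(dev) && abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  xtwx <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(xtwx), error = function(e) matrix(NA_real_, p, p))
  list(beta = beta, se = sqrt(pmax(diag(cov), 0)), converged = converged,
       deviance = nb_deviance(y, mu, alpha))
}

# NB deviance with fixed alpha; alpha -> 0 recovers the Poisson deviance.
nb_deviance <- function(y, mu, alpha) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  if (alpha < 1e-12) return(2 * sum(t1 - (y - mu)))
  t2 <- (y + 1 / alpha) * log((1 + alpha * y) / (1 + alpha * mu))
  2 * sum(t1 - t2)
}

# NB log-likelihood (used by the profile-likelihood cross-check in tests)
nb_loglik <- function(y, mu, alpha) {
  if (alpha < 1e-12) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

#' Benjamini-Hochberg adjustment with NA propagation
#'
#' Step-up FDR adjustment over the non-missing p values; NA/NaN inputs stay
#' missing and do not count toward the number of tests.
#'
#' @param p Numeric vector of p values in [0, 1] (NA allowed).
#' @return Adjusted p values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must lie in [0, 1]")
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Fit per-gene negative-binomial dosage models
#'
#' For every gene, fits a NB GLM with log link and offset log(size factor)
#' by iteratively reweighted least squares at a fixed per-gene dispersion,
#' then reports natural-log coefficients converted to log2, Wald statistics
#' (beta/SE against the standard normal, two-sided) and BH-adjusted p
#' values per covariate of interest. Non-converged genes are flagged and
#' excluded from multiplicity correction.
#'
#' @param counts Count matrix, genes x samples.
#' @param samples Sample sheet aligned with `counts` columns.
#' @param design Either a design matrix (rows = samples) or a character
#'   vector of covariate names passed to [build_design()].
#' @param size_factors Optional size factors; computed by
#'   [compute_size_factors()] when NULL.
#' @param dispersions Optional per-gene dispersions; estimated by
#'   [estimate_dispersion()] when NULL.
#' @param test_coefs Design columns to test; default all non-intercept
#'   columns.
#' @param reference_levels Passed to [build_design()].
#' @return A `dosage_fit` object: list with matrices `log2fc`, `se`,
#'   `stat`, `pvalue` (genes x coefficients), `padj` (test coefficients
#'   only), vectors `base_mean`, `dispersion`, `converged`, plus
#'   `size_factors` and `design`.
#' @seealso [dosage_results()] to extract one coefficient as a table.
#' @export
fit_dosage_model <- function(counts, samples, design,
                             size_factors = NULL, dispersions = NULL,
                             test_coefs = NULL, reference_levels = list()) {
  if (is.character(design))
    design <- build_design(samples, design, reference_levels)
  stopifnot(nrow(design) == ncol(counts))
  if (qr(design)$rank < ncol(design)) {
    qrX <- qr(design)
    stop("design matrix is rank deficient; aliased columns: ",
         paste(colnames(design)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "))
  }
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(counts, size_factors, design)
  offset <- log(size_factors)
  ng <- nrow(counts)
  p <- ncol(design)
  cn <- colnames(design)
  log2fc <- se <- matrix(NA_real_, ng, p, dimnames = list(rownames(counts), cn))
  converged <- logical(ng)
  for (g in seq_len(ng)) {
    fit <- nb_irls(counts[g, ], design, offset, dispersions[g])
    log2fc[g, ] <- fit$beta / log(2)
    se[g, ] <- fit$se / log(2)
    converged[g] <- fit$converged
  }
  stat <- log2fc / se
  pvalue <- 2 * stats::pnorm(-abs(stat))
  if (is.null(test_coefs)) test_coefs <- setdiff(cn, "(Intercept)")
  test_coefs <- intersect(test_coefs, cn)
  padj <- matrix(NA_real_, ng, length(test_coefs),
                 dimnames = list(rownames(counts), test_coefs))
  for (co in test_coefs) {
    pv <- pvalue[, co]
    pv[!converged] <- NA
    padj[, co] <- adjust_bh(pv)
  }
  structure(list(
    log2fc = log2fc, se = se, stat = stat, pvalue = pvalue, padj = padj,
    base_mean = rowMeans(sweep(counts, 2, size_factors, `/`)),
    dispersion = dispersions,
    converged = stats::setNames(converged, rownames(counts)),
    size_factors = size_factors, design = design, test_coefs = test_coefs),
    class = "dosage_fit")
}

#' @export
print.dosage_fit <- function(x, ...) {
  cat("dosage_fit:", nrow(x$log2fc), "genes,", nrow(x$design), "samples\n")
  cat("coefficients:", paste(colnames(x$log2fc), collapse = ", "), "\n")
  cat("tested:", paste(x$test_coefs, collapse = ", "), ";",
      sum(!x$converged), "gene(s) not converged\n")
  invisible(x)
}

#' Extract one coefficient of a dosage fit as a results table
#'
#' @param fit A `dosage_fit`.
#' @param coef Design column name (e.g. `"x_copies"`).
#' @return data.frame with `gene_id`, `baseMean`, `log2FC`, `SE`, `stat`,
#'   `p`, `padj`, `converged`.
#' @export
dosage_results <- function(fit, coef) {
  stopifnot(inherits(fit, "dosage_fit"))
  if (!coef %in% colnames(fit$log2fc))
    stop("unknown coefficient: ", coef, "; available: ",
         paste(colnames(fit$log2fc), collapse = ", "))
  data.frame(
    gene_id = rownames(fit$log2fc),
    baseMean = fit$base_mean,
    log2FC = fit$log2fc[, coef],
    SE = fit$se[, coef],
    stat = fit$stat[, coef],
    p = fit$pvalue[, coef],
    padj = if (coef %in% colnames(fit$padj)) fit$padj[, coef] else NA_real_,
    converged = fit$converged,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Saturation (down-sampling) analysis of discovery counts
#'
#' Repeatedly subsamples the cohort without replacement at each requested
#' size, refits the full per-gene model (size factors and dispersions
#' re-estimated on the subsample), and records the number of genes with
#' padj below `sig_threshold` per tested covariate. Subsamples whose design
#' matrix loses full rank are redrawn (bounded retries).
#'
#' @param counts,samples,design,reference_levels As in [fit_dosage_model()].
#' @param sizes Integer vector of subsample sizes, each <= total samples.
#' @param reps Number of down-samplings per size (default 100).
#' @param seed Integer seed.
#' @param sig_threshold padj cutoff counted as a discovery.
#' @param test_coefs Covariates to count discoveries for.
#' @param max_retries Redraws allowed per (size, rep) to recover full rank.
#' @return data.frame with `n`, `rep`, `covariate`, `n_significant`.
#' @export
saturation_analysis <- function(counts, samples, design, sizes, reps = 100L,
                                seed = 1L, sig_threshold = 0.05,
                                test_coefs = NULL, reference_levels = list(),
                                max_retries = 20L) {
  ns <- ncol(counts)
  if (any(sizes > ns)) stop("subsample sizes exceed the cohort size")
  Xfull <- if (is.character(design))
    build_design(samples, design, reference_levels) else design
  if (any(sizes <= ncol(Xfull)))
    stop("subsample sizes must exceed the number of design columns (",
         ncol(Xfull), ") to leave residual degrees of freedom")
  set.seed(as.integer(seed))
  out <- list()
  for (n in sizes) {
    for (r in seq_len(reps)) {
      idx <- NULL
      for (try in seq_len(max_retries)) {
        cand <- sort(sample.int(ns, n))
        X <- Xfull[cand, , drop = FALSE]
        keepcol <- apply(X, 2, function(col) length(unique(col)) > 1)
        keepcol["(Intercept)"] <- TRUE
        X <- X[, keepcol, drop = FALSE]
        if (qr(X)$rank == ncol(X) && n > ncol(X)) { idx <- cand; break }
      }
      if (is.null(idx))
        stop("could not draw a full-rank subsample of size ", n)
      fit <- fit_dosage_model(counts[, idx, drop = FALSE], samples[idx, ],
                              X, test_coefs = test_coefs)
      for (co in fit$test_coefs) {
        out[[length(out) + 1L]] <- data.frame(
          n = n, rep = r, covariate = co,
          n_significant = sum(fit$padj[, co] < sig_threshold, na.rm = TRUE))
      }
    }
  }
  do.call(rbind, out)
}
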