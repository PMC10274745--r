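#' Hypergeometric overlap test
#'
#' Upper-tail probability of observing at least `k` genes in the overlap of
#' a size-`K` set and a size-`n` set drawn from a universe of `N` genes.
#'
#' @param N Universe size.
#' @param K First set size.
#' @param n Second set size.
#' @param k Observed overlap.
#' @return List of class `overlap_test` with `N`, `K`, `n`, `k`, `p`,
#'   `expected` (expected overlap under independence) and `fold`
#'   (observed/expected).
#' @export
hypergeom_overlap <- function(N, K, n, k) {
  if (K > N || n > N || k > min(K, n) || k < 0 || any(c(N, K, n) < 0))
    stop("inconsistent overlap counts: need 0 <= k <= min(K, n) <= N")
  expected <- K * n / N
  structure(list(N = N, K = K, n = n, k = k,
                 p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 expected = expected,
                 fold = if (expected > 0) k / expected else NA_real_),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("overlap %d of sets %d x %d in universe %d (expected %.2f)\n",
              x$k, x$K, x$n, x$N, x$expected))
  cat(sprintf("hypergeometric upper-tail p = %.3g\n", x$p))
  invisible(x)
}

#' Pearson or Spearman correlation with p value
#'
#' @param x,y Numeric vectors, length >= 3, finite.
#' @param method "pearson" or "spearman".
#' @return List with `r`, `p`, `n`, `method`. Zero-variance input yields
#'   `r = NA` with a warning.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(x), method = method))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}

#' Deming (errors-in-variables) regression, optionally weighted
#'
#' Fits y = intercept + slope * x when both axes are measured with error.
#' Unweighted: the closed-form Deming estimator with error-variance ratio
#' `delta` (default 1, orthogonal regression),
#' \deqn{slope = \frac{S_{yy} - \delta S_{xx} +
#'   \sqrt{(S_{yy} - \delta S_{xx})^2 + 4\delta S_{xy}^2}}{2 S_{xy}}.}
#' Weighted: per-point standard errors define weights 1/se^2 on each axis
#' and the slope is found by York-style iteration, reweighting each point
#' by \eqn{W_i = w_{xi} w_{yi} / (w_{xi} + b^2 w_{yi})} (the inverse
#' residual variance \eqn{\sigma_y^2 + b^2 \sigma_x^2}) until the slope
#' changes by less than `tol`. This minimizes the total weighted squared
#' distance from the points to the line along both axes.
#'
#' @param x,y Numeric vectors.
#' @param se_x,se_y Per-point standard errors (required for `weighted`).
#' @param weighted Use the per-point errors (default TRUE when both SEs are
#'   supplied).
#' @param delta Error-variance ratio var(err_y)/var(err_x) for the
#'   unweighted fit.
#' @param tol,max_iter Convergence control for the weighted iteration.
#' @return List of class `deming_fit`: `slope`, `intercept`, `r` (Pearson
#'   correlation of the pair), `r2`, `n`, `weighted`, `converged`,
#'   `degenerate` (TRUE when S_xy = 0 and the slope is undefined).
#' @export
deming_fit <- function(x, y, se_x = NULL, se_y = NULL,
                       weighted = !is.null(se_x) && !is.null(se_y),
                       delta = 1, tol = 1e-8, max_iter = 200L) {
  ok <- is.finite(x) & is.finite(y)
  if (weighted) {
    if (is.null(se_x) || is.null(se_y))
      stop("weighted fit requires se_x and se_y")
    if (any(se_x[ok] <= 0) || any(se_y[ok] <= 0))
      stop("standard errors must be positive")
    ok <- ok & is.finite(se_x) & is.finite(se_y)
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2); syy <- sum((y - yb)^2)
  sxy <- sum((x - xb) * (y - yb))
  if (abs(sxy) < 1e-300) {
    warning("S_xy = 0: Deming slope undefined (degenerate fit)")
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r = NA_real_, r2 = NA_real_, n = n,
                          weighted = weighted, converged = FALSE,
                          degenerate = TRUE), class = "deming_fit"))
  }
  slope <- (syy - delta * sxx +
              sqrt((syy - delta * sxx)^2 + 4 * delta * sxy^2)) / (2 * sxy)
  intercept <- yb - slope * xb
  converged <- TRUE
  if (weighted) {
    wx <- 1 / se_x[ok]^2
    wy <- 1 / se_y[ok]^2
    b <- slope
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      W <- wx * wy / (wx + b^2 * wy)
      xw <- sum(W * x) / sum(W)
      yw <- sum(W * y) / sum(W)
      U <- x - xw; V <- y - yw
      beta_i <- W * (U / wy + b * V / wx)
      b_new <- sum(W * beta_i * V) / sum(W * beta_i * U)
      if (!is.finite(b_new)) break
      done <- abs(b_new - b) < tol
      b <- b_new
      if (done) { converged <- TRUE; break }
    }
    W <- wx * wy / (wx + b^2 * wy)
    slope <- b
    intercept <- sum(W * y) / sum(W) - b * sum(W * x) / sum(W)
  }
  r <- stats::cor(x, y)
  structure(list(slope = unname(slope), intercept = unname(intercept),
                 r = r, r2 = r^2, n = n, weighted = weighted,
                 converged = converged, degenerate = FALSE),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("%s Deming fit (n = %d): slope %.4f, intercept %.4f, r2 %.3f\n",
              if (x$weighted) "weighted" else "unweighted", x$n,
              x$slope, x$intercept, x$r2))
  invisible(x)
}

#' Attribute copy-number responses to a knockdown
#'
#' Compares per-gene responses to chromosome copy number with responses to
#' knockdown of a candidate driver (a transcription factor whose loss
#' should mirror the loss of a chromosome copy). The sign-flipped knockdown
#' response (-log2FC) is regressed on the copy-number response with a
#' weighted Deming fit; the headline "fraction of effects explained" is the
#' fit's coefficient of determination r2. Alongside, each gene's effect
#' ratio -beta_kd/beta_chr (clamped to [0, 1]) is reported with its median
#' and interquartile range, since both summaries are in circulation.
#'
#' @param beta_chr,se_chr Copy-number log2FC per gene and its SE.
#' @param beta_kd,se_kd Knockdown log2FC per gene and its SE.
#' @return List with `r2`, `p` (correlation test p value), `fit` (the
#'   `deming_fit`), `percent_explained` (per-gene, percent), and `summary`
#'   (named vector: median, q25, q75 of the per-gene percent).
#' @export
attribute_effect <- function(beta_chr, se_chr, beta_kd, se_kd) {
  ok <- is.finite(beta_chr) & is.finite(beta_kd)
  if (!any(ok)) stop("no genes with finite responses to attribute")
  fit <- deming_fit(beta_chr[ok], -beta_kd[ok], se_x = se_chr[ok],
                    se_y = se_kd[ok])
  ct <- correlate(beta_chr[ok], -beta_kd[ok])
  pct <- rep(NA_real_, length(beta_chr))
  pct[ok] <- 100 * pmin(1, pmax(0, -beta_kd[ok] / beta_chr[ok]))
  qs <- stats::quantile(pct, c(0.5, 0.25, 0.75), na.rm = TRUE)
  list(r2 = fit$r2, p = ct$p, fit = fit, percent_explained = pct,
       summary = c(median = unname(qs[1]), q25 = unname(qs[2]),
                   q75 = unname(qs[3])))
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: tab-separated, one set per line, fields set name,
#'   description, then member genes.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 50))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Hypergeometric gene-set enrichment
#'
#' One upper-tail hypergeometric test per collection set, with memberships
#' restricted to the background (universe) — typically the expressed genes
#' of the relevant cell type, never the whole genome. P values are
#' BH-corrected across sets.
#'
#' @param target Character vector of genes of interest; must be a subset of
#'   `background`.
#' @param background Character vector: the universe.
#' @param collections Named list of gene sets (e.g. from [read_gmt()]).
#' @param min_set_size Sets with fewer background-restricted members are
#'   skipped (default 1).
#' @return data.frame `set`, `set_size`, `overlap`, `expected`, `p`, `fdr`,
#'   ordered by p.
#' @export
set_enrichment <- function(target, background, collections,
                           min_set_size = 1) {
  target <- unique(target); background <- unique(background)
  if (!all(target %in% background))
    stop("target genes missing from background: ",
         paste(utils::head(setdiff(target, background), 5), collapse = ", "))
  members <- lapply(collections, intersect, background)
  keep <- lengths(members) >= min_set_size
  if (!any(keep)) stop("no collection sets overlap the background")
  members <- members[keep]
  N <- length(background); n <- length(target)
  rows <- lapply(names(members), function(s) {
    K <- length(members[[s]])
    k <- length(intersect(target, members[[s]]))
    ht <- hypergeom_overlap(N, K, n, k)
    data.frame(set = s, set_size = K, overlap = k, expected = ht$expected,
               p = ht$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- adjust_bh(out$p)
  out[order(out$p), , drop = FALSE]
}
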