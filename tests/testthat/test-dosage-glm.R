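test_that("compute_tpm matches the per-column formula", {
  # equal length-normalized rates split a sample evenly
  counts <- matrix(c(100L, 200L), 2, 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  ann <- data.frame(gene_id = c("g1", "g2"), effective_length = c(1000, 2000))
  expect_equal(unname(compute_tpm(counts, ann)[, 1]), c(5e5, 5e5))

  # single gene takes the whole million
  expect_equal(unname(compute_tpm(counts[1, , drop = FALSE], ann)[1, 1]), 1e6)

  # random matrix against a brute-force per-column oracle
  set.seed(11)
  m <- matrix(rpois(15, 50), 5, 3,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  ann2 <- data.frame(gene_id = paste0("g", 1:5),
                     effective_length = sample(500:3000, 5))
  tpm <- compute_tpm(m, ann2)
  for (j in 1:3) {
    rate <- m[, j] / ann2$effective_length
    expect_equal(unname(tpm[, j]), unname(1e6 * rate / sum(rate)))
  }
  expect_equal(unname(colSums(tpm)), rep(1e6, 3))

  # a sample with zero total rate is named in the error
  m0 <- m; m0[, 2] <- 0L
  expect_error(compute_tpm(m0, ann2), "s2")
})

test_that("filter_expressed applies inclusive euploid-median rule", {
  set.seed(2)
  n <- 20
  samples <- data.frame(sample_id = paste0("s", 1:6), cell_type = "LCL",
                        x_copies = c(2, 2, 2, 1, 1, 1),
                        y_copies = c(0, 0, 0, 1, 1, 1))
  # planted medians straddling the threshold
  med_xx <- c(seq(0, 2.5, length.out = n))
  tpm <- matrix(0, n, 6, dimnames = list(paste0("g", 1:n), samples$sample_id))
  tpm[, 1:3] <- med_xx  # constant over XX samples -> median = value
  keep <- filter_expressed(tpm, samples)
  oracle <- paste0("g", which(med_xx >= 1))
  expect_identical(keep, oracle)

  # boundary: median exactly 1 retained (inclusive)
  expect_true(paste0("g", which.min(abs(med_xx - 1))) %in% keep ==
                (med_xx[which.min(abs(med_xx - 1))] >= 1))
  # all-zero gene excluded
  expect_false("g1" %in% keep)
  # no euploid samples -> error
  aneuploid <- samples; aneuploid$x_copies <- 3
  expect_error(filter_expressed(tpm, aneuploid), "euploid")
})

test_that("compute_size_factors is median-of-ratios with unit geometric mean", {
  # uniform 2x scaling splits symmetrically around 1
  m <- matrix(c(10L, 20L, 30L, 20L, 40L, 60L), 3, 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  sf <- compute_size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  # identical samples -> all ones
  m2 <- cbind(a = c(5L, 8L, 13L), b = c(5L, 8L, 13L))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(compute_size_factors(m2)), c(1, 1))

  # random matrix against the brute-force definition
  set.seed(5)
  m3 <- matrix(rpois(300, 100) + 1L, 50, 6,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  sf3 <- compute_size_factors(m3)
  ref <- exp(rowMeans(log(m3)))
  raw <- apply(m3, 2, function(cnt) median(cnt / ref))
  expect_equal(unname(sf3), unname(raw / exp(mean(log(raw)))))
  expect_equal(exp(mean(log(sf3))), 1)

  # all-zero-containing genes -> informative error
  m4 <- matrix(c(0L, 1L, 2L, 0L), 2, 2)
  rownames(m4) <- c("g1", "g2"); colnames(m4) <- c("a", "b")
  m4[, 1] <- 0L
  expect_error(compute_size_factors(m4), "pseudo_reference")
})

test_that("dispersion estimates recover the generating law", {
  set.seed(7)
  n <- 200
  sf <- rep(1, n)
  pois <- matrix(rpois(n, 100), 1, n)
  rownames(pois) <- "g"
  expect_lt(estimate_dispersion(pois[, 1:100, drop = FALSE], sf[1:100]), 1e-2)

  nb <- matrix(rnbinom(n, mu = 100, size = 2), 1, n)  # alpha = 0.5
  rownames(nb) <- "g"
  a <- estimate_dispersion(nb, sf)
  expect_gt(a, 0.3); expect_lt(a, 0.7)

  # zero excess variance floors the estimate
  const <- matrix(50L, 1, 10); rownames(const) <- "g"
  expect_equal(unname(estimate_dispersion(const, rep(1, 10))), 1e-8)

  # more design columns than residual df -> error
  expect_error(estimate_dispersion(const, rep(1, 10),
                                   design = diag(10)), "residual")
})

test_that("NB GLM recovers exact log-linear data and flags constants", {
  x <- rep(c(1, 2, 3), each = 4)
  samples <- data.frame(sample_id = paste0("s", seq_along(x)), x_copies = x)
  counts <- matrix(as.integer(200 * 2^x), 1, length(x))
  rownames(counts) <- "g"; colnames(counts) <- samples$sample_id
  fit <- fit_dosage_model(counts, samples, "x_copies",
                          size_factors = rep(1, length(x)),
                          dispersions = c(g = 1e-8))
  expect_equal(unname(fit$log2fc["g", "x_copies"]), 1, tolerance = 1e-6)
  expect_lt(fit$pvalue["g", "x_copies"], 1e-12)

  # constant gene across covariates -> zero slope
  counts2 <- matrix(100L, 1, length(x),
                    dimnames = list("g", samples$sample_id))
  fit2 <- fit_dosage_model(counts2, samples, "x_copies",
                           size_factors = rep(1, length(x)))
  expect_equal(unname(fit2$log2fc["g", "x_copies"]), 0, tolerance = 1e-8)
})

test_that("IRLS solution maximizes the NB log-likelihood (profile oracle)", {
  set.seed(9)
  x <- rep(c(1, 2, 3, 4), each = 5)
  X <- cbind(1, x)
  alpha <- 0.1
  mu_true <- exp(3 + 0.4 * x)
  y <- rnbinom(length(x), mu = mu_true, size = 1 / alpha)
  fit <- xydosage:::nb_irls(y, X, offset = rep(0, length(y)), alpha = alpha)
  expect_true(fit$converged)
  # independent numeric optimum of the same likelihood
  nll <- function(b) -xydosage:::nb_loglik(y, exp(drop(X %*% b)), alpha)
  opt <- optim(c(3, 0.4), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(fit$beta), opt$par, tolerance = 1e-4)
  expect_equal(-nll(fit$beta), -opt$value, tolerance = 1e-6)
})

test_that("coefficients agree with DESeq2 on a simulated cohort", {
  skip_if_not_installed("DESeq2")
  sim <- small_cohort(n_genes = 80, seed = 3)
  keep <- rowSums(sim$counts == 0) == 0
  counts <- sim$counts[keep, ]
  fit <- fit_dosage_model(counts, sim$samples,
                          c("x_copies", "y_copies", "batch"),
                          test_coefs = c("x_copies", "y_copies"))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      counts, S4Vectors::DataFrame(sim$samples),
      design = ~ x_copies + y_copies + batch)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds, name = "x_copies")
  })
  ours <- fit$log2fc[, "x_copies"]
  theirs <- res$log2FoldChange
  expect_gt(cor(ours, theirs), 0.98)
  expect_lt(median(abs(ours - theirs)), 0.05)
})

test_that("adjust_bh reproduces the hand-applied step-up", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(1)
  p <- runif(50)
  expect_true(all(adjust_bh(p) >= p))
  expect_true(all(adjust_bh(p) <= 1))
  # NA p values stay NA and do not count toward m
  p2 <- c(0.01, NA, 0.02)
  out <- adjust_bh(p2)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], p.adjust(c(0.01, 0.02), "BH"))
  expect_error(adjust_bh(c(0.5, 2)), "\\[0, 1\\]")
})

test_that("size-factor gene subset barely moves dosage coefficients", {
  # mirrors the robustness of renormalizing without sex-linked genes when
  # they are a small fraction of the library
  sim <- small_cohort(n_genes = 200, seed = 21)
  excl <- rownames(sim$counts)[1:6]  # < 5% of genes
  sf_all <- compute_size_factors(sim$counts)
  sf_sub <- compute_size_factors(sim$counts,
                                 setdiff(rownames(sim$counts), excl))
  f1 <- fit_dosage_model(sim$counts, sim$samples,
                         c("x_copies", "y_copies", "batch"),
                         size_factors = sf_all)
  f2 <- fit_dosage_model(sim$counts, sim$samples,
                         c("x_copies", "y_copies", "batch"),
                         size_factors = sf_sub)
  expect_lt(max(abs(f1$log2fc[, "x_copies"] - f2$log2fc[, "x_copies"]),
                na.rm = TRUE), 0.05)
  expect_lt(max(abs(f1$log2fc[, "y_copies"] - f2$log2fc[, "y_copies"]),
                na.rm = TRUE), 0.05)
})

test_that("rank-deficient designs report aliased columns", {
  samples <- data.frame(sample_id = paste0("s", 1:6),
                        x_copies = c(1, 1, 2, 2, 3, 3))
  samples$x2 <- samples$x_copies * 2
  expect_error(build_design(samples, c("x_copies", "x2")), "aliased")
})

test_that("saturation at full cohort size reproduces the full-data count", {
  sim <- small_cohort(n_genes = 120, seed = 33, frac_x_responsive = 0.15,
                      effect_size_law = law("uniform", min = 0.3, max = 0.6))
  full <- fit_dosage_model(sim$counts, sim$samples,
                           c("x_copies", "y_copies"),
                           test_coefs = "x_copies")
  n_full <- sum(full$padj[, "x_copies"] < 0.05, na.rm = TRUE)
  sat <- saturation_analysis(sim$counts, sim$samples,
                             c("x_copies", "y_copies"),
                             sizes = ncol(sim$counts), reps = 3, seed = 4,
                             test_coefs = "x_copies")
  expect_true(all(sat$n_significant == n_full))
  expect_error(
    saturation_analysis(sim$counts, sim$samples, c("x_copies", "y_copies"),
                        sizes = 2, reps = 1, seed = 1),
    "exceed")
})
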