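test_that("depth ratio is exact without bias and scale invariant", {
  dp <- simulate_depth_profiles(2, copy_law = law("point", value = 200),
                                gc_bias_amplitude = 0, noise_sd = 0,
                                seed = 1)
  r <- dyz1_ratio(dp$depths)
  expect_equal(r$ratio, c(200, 200))

  # doubling every bin depth doubles region means, not the ratio
  doubled <- dp$depths
  doubled$depth <- doubled$depth * 2
  r2 <- dyz1_ratio(doubled)
  expect_equal(r2$dyz1_mean, 2 * r$dyz1_mean)
  expect_equal(r2$ratio, r$ratio)

  # two samples differing only in copy number differ 2x in ratio
  dp2 <- simulate_depth_profiles(1, copy_law = law("point", value = 400),
                                 gc_bias_amplitude = 0, noise_sd = 0,
                                 seed = 1)
  expect_equal(dyz1_ratio(dp2$depths)$ratio / r$ratio[1], 2)

  zero <- dp$depths
  zero$depth[zero$region == "single_copy"] <- 0
  expect_error(dyz1_ratio(zero), "single-copy")
})

test_that("GC correction is identity without bias and recovers truth with it", {
  dp0 <- simulate_depth_profiles(3, gc_bias_amplitude = 0, noise_sd = 0.02,
                                 seed = 5)
  corr0 <- gc_correct_depth(dp0$depths)
  # flat curve: corrected depths stay within noise of the originals
  expect_equal(corr0$depth, corr0$raw_depth, tolerance = 0.1)

  dp <- simulate_depth_profiles(20, gc_bias_amplitude = 0.5, seed = 3)
  tru <- dp$truth$copy_number
  raw <- dyz1_ratio(dp$depths)$ratio
  corr <- dyz1_ratio(gc_correct_depth(dp$depths))$ratio
  expect_lt(max(abs(corr - tru) / tru), 0.05)
  expect_gt(median(abs(raw - tru) / tru), 0.05)  # bias without correction
})

test_that("depth-expression model finds planted genes and respects confounders", {
  set.seed(14)
  n <- 100
  ratio <- exp(runif(n, log(20), log(900)))
  ratios <- data.frame(sample_id = sprintf("s%03d", 1:n), ratio = ratio)
  ng <- 40
  base <- rpois(ng, 30) + 20
  counts <- sapply(1:n, function(s) rpois(ng, base))
  # plant one gene responding 0.5 log2 units per doubling of repeat content
  counts[1, ] <- rpois(n, 50 * 2^(0.5 * (log2(ratio) - mean(log2(ratio)))))
  dimnames(counts) <- list(sprintf("g%02d", 1:ng), ratios$sample_id)
  storage.mode(counts) <- "integer"
  fit <- fit_depth_expression_model(counts, ratios)
  res <- dosage_results(fit, "log2_depth")
  expect_lt(res$padj[1], 0.05)
  expect_equal(res$log2FC[1], 0.5, tolerance = 0.1)
  # null genes: at most a stray call
  expect_lte(sum(res$padj[-1] < 0.05, na.rm = TRUE), 1)

  # a lab effect aligned with depth inflates the coefficient until adjusted
  lab <- ifelse(ratio > median(ratio), "labA", "labB")
  counts2 <- counts
  counts2[2, lab == "labA"] <- counts2[2, lab == "labA"] + 60L
  covs <- data.frame(sample_id = ratios$sample_id, lab = lab)
  fit_unadj <- fit_depth_expression_model(counts2, ratios)
  fit_adj <- fit_depth_expression_model(counts2, ratios, covariates = covs)
  b_unadj <- fit_unadj$log2fc["g02", "log2_depth"]
  b_adj <- fit_adj$log2fc["g02", "log2_depth"]
  expect_lt(abs(b_adj), abs(b_unadj))
  expect_lt(abs(b_adj), 0.12)
})

test_that("PCA separates planted groups and is stable to ordering", {
  set.seed(22)
  ng <- 50; n <- 24
  counts <- matrix(rpois(ng * n, 100), ng, n,
                   dimnames = list(sprintf("g%02d", 1:ng),
                                   sprintf("s%02d", 1:n)))
  grp <- rep(c("A", "B"), each = n / 2)
  counts[1:30, grp == "B"] <- counts[1:30, grp == "B"] + 250L
  pp <- transform_and_pca(counts, size_factors = rep(1, n))
  expect_gt(pp$var_fraction[1], 0.5)
  expect_gt(abs(mean(pp$scores[grp == "A", 1]) -
                  mean(pp$scores[grp == "B", 1])), 2)
  expect_true(all(diff(pp$var_fraction) <= 1e-12))
  expect_lte(sum(pp$var_fraction), 1 + 1e-8)

  # gene order: identical scores; sample order: permuted scores (up to sign)
  perm_g <- sample(ng); perm_s <- sample(n)
  pp_g <- transform_and_pca(counts[perm_g, ], size_factors = rep(1, n))
  expect_lt(min(abs(cor(pp$scores[, 1], pp_g$scores[, 1])),
                abs(cor(pp$scores[, 2], pp_g$scores[, 2]))) < 1, TRUE)
  expect_equal(abs(cor(pp$scores[, 1], pp_g$scores[, 1])), 1,
               tolerance = 1e-8)
  pp_s <- transform_and_pca(counts[, perm_s], size_factors = rep(1, n))
  expect_equal(abs(cor(pp$scores[perm_s, 1], pp_s$scores[, 1])), 1,
               tolerance = 1e-8)

  # duplicated samples get identical scores
  counts_dup <- cbind(counts, dup = counts[, 1])
  pp_d <- transform_and_pca(counts_dup, size_factors = rep(1, n + 1))
  expect_equal(unname(pp_d$scores["dup", ]), unname(pp_d$scores[1, ]),
               tolerance = 1e-8)
})

test_that("batch residualization collapses orthogonal batch separation", {
  set.seed(30)
  ng <- 60; n <- 30
  counts <- matrix(rpois(ng * n, 120), ng, n,
                   dimnames = list(sprintf("g%02d", 1:ng),
                                   sprintf("s%02d", 1:n)))
  batch <- rep(c("b1", "b2"), length.out = n)
  counts[, batch == "b2"] <- counts[, batch == "b2"] + 90L
  sep <- function(scores) abs(mean(scores[batch == "b1", 1]) -
                                mean(scores[batch == "b2", 1]))
  before <- transform_and_pca(counts, size_factors = rep(1, n))
  after <- transform_and_pca(counts, size_factors = rep(1, n),
                             batch = batch)
  expect_gt(sep(before$scores), 5 * sep(after$scores))
})

test_that("group ellipses use the chi-square scaling", {
  set.seed(40)
  n <- 4000
  scores <- cbind(rnorm(n), rnorm(n))
  el <- group_ellipse(scores, rep("g", n))
  expect_equal(el$chisq_scale, qchisq(0.95, 2))
  expect_equal(el$semi_major, sqrt(qchisq(0.95, 2)), tolerance = 0.05)
  expect_equal(el$semi_minor, sqrt(qchisq(0.95, 2)), tolerance = 0.05)

  # collinear points are degenerate
  col3 <- cbind(1:3, 2 * (1:3))
  expect_true(group_ellipse(col3, rep("g", 3))$degenerate)

  # level 0 -> zero-area ellipse at the centroid
  el0 <- group_ellipse(scores, rep("g", n), level = 0)
  expect_equal(el0$semi_major, 0)
  expect_equal(el0$center1, mean(scores[, 1]))

  # undersized groups are skipped with a message
  expect_message(els <- group_ellipse(scores[1:5, ],
                                      c("a", "a", "a", "b", "b")), "b")
  expect_equal(els$group, "a")
})

test_that("peak assignment follows TSS windows on both strands", {
  ann <- data.frame(gene_id = c("plus", "minus"),
                    chrom = "chr1", start = c(1500, 5000),
                    end = c(3000, 8000), strand = c("+", "-"))
  # + strand TSS = 1500: peak [1000,1200) overlaps [500, 2500)
  peaks <- data.frame(chrom = "chr1", start = 1000, end = 1200)
  expect_equal(unname(assign_peaks_to_genes(peaks, ann, 1000)),
               c(TRUE, FALSE))
  # - strand TSS = 8000: peak at [8500, 8600) within 1 kb window
  peaks2 <- data.frame(chrom = "chr1", start = 8500, end = 8600)
  expect_equal(unname(assign_peaks_to_genes(peaks2, ann, 1000)),
               c(FALSE, TRUE))
  # strict window: peak 31 kb away misses a 30 kb window
  peaks3 <- data.frame(chrom = "chr1", start = 1500 + 31000,
                       end = 1500 + 31100)
  expect_false(unname(assign_peaks_to_genes(peaks3, ann[1, ], 30000)))
  expect_true(unname(assign_peaks_to_genes(peaks3, ann[1, ], 32000)))
  # a peak abutting the window end does not bind (closed-open window)
  peaks4 <- data.frame(chrom = "chr1", start = 2500, end = 2600)
  expect_equal(unname(assign_peaks_to_genes(peaks4, ann, 1000)),
               c(FALSE, FALSE))
  expect_warning(out <- assign_peaks_to_genes(
    data.frame(chrom = "chrUn", start = 1, end = 10), ann, 1000),
    "chrUn")
  expect_false(any(out))
})

test_that("binding proportion counts only expressing lines", {
  bound <- rbind(g1 = c(TRUE, TRUE, FALSE, FALSE),
                 g2 = c(TRUE, TRUE, TRUE, TRUE),
                 g3 = c(TRUE, FALSE, FALSE, FALSE))
  expressed <- rbind(g1 = c(TRUE, TRUE, TRUE, TRUE),
                     g2 = c(TRUE, TRUE, TRUE, TRUE),
                     g3 = c(FALSE, TRUE, TRUE, FALSE))
  bp <- binding_proportion(bound, expressed)
  expect_equal(unname(bp["g1"]), 0.5)
  expect_equal(unname(bp["g2"]), 1)
  # bound only in a non-expressing line -> excluded from both sides
  expect_equal(unname(bp["g3"]), 0)
  none <- binding_proportion(bound[1, , drop = FALSE],
                             matrix(FALSE, 1, 4, dimnames = list("g1", NULL)))
  expect_true(is.na(none))
})
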