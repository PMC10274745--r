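---
title: "Modeling autosomal responses to sex chromosome dosage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling autosomal responses to sex chromosome dosage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xydosage)
```

This vignette documents the statistical machinery of `xydosage`: the
count model and its assumptions, the allelic-ratio meta-analysis rules,
the errors-in-variables regression, the depth-based heterochromatin
quantification, and — because every one of these stages is exercised
against simulated data with known truth — what the synthetic-data
generator does and does not emulate.

## The dosage model

Cells carry one transcriptionally active X (Xa) regardless of karyotype;
additional X chromosomes are largely inactivated (Xi) and additional Y
chromosomes add dosage of Y-linked genes. Treating X and Y copy number
as *numeric* covariates in a single per-gene model, rather than
comparing karyotypes pairwise, pools information across the whole
constitution range (one to four X, zero to four Y) and yields one
interpretable coefficient per chromosome: the log2 fold change in
expression per additional copy.

For gene $g$ and sample $s$:

$$K_{gs} \sim \mathrm{NB}(\mu_{gs}, \alpha_g), \qquad
\log \mu_{gs} = \log L_s + x_s^\top \beta_g$$

with variance $\mu + \alpha\mu^2$, size factor $L_s$ as offset, and a
design containing an intercept, X copies, Y copies and
library-preparation batch (the same engine accepts chromosome 21
copies, knockdown condition, or log2 repeat depth — any full-rank
design built from the sample sheet). Assumptions worth stating:

- **Linearity in copy number.** Each extra copy multiplies expression
  by a constant factor. Fractional copies model mosaics: a sample that
  is half 46,X,i(Xq) and half 45,X is represented by its expected copy
  number, because bulk expression averages across subclones.
- **Gene-wise dispersion, no sharing.** Dispersions are estimated per
  gene by method of moments on normalized counts, using the residual
  variance after an OLS fit on the design so that real covariate
  structure does not masquerade as overdispersion; estimates are
  floored at $10^{-8}$. An optional shrinkage pulls log-dispersions
  halfway toward a fitted $a_0 + a_1/\mu$ trend, but the default is off:
  with cohorts of ~100+ samples the per-gene estimate is stable, and
  the inference target is the coefficient, not the dispersion.
- **Wald inference.** Coefficients are fitted by Fisher-scoring IRLS
  (max 100 iterations, relative deviance tolerance $10^{-8}$; linear
  predictors clamped to ±30 to prevent overflow) and tested two-sided
  against the standard normal. No fold-change shrinkage is applied —
  raw model coefficients are reported. Non-converged genes are flagged
  and excluded from multiplicity correction, which is
  Benjamini–Hochberg per covariate of interest.
- **Independent filtering is not performed.** Expression filtering is
  explicit and biological instead: a gene is "expressed" in a cell type
  if its median TPM across 46,XX or across 46,XY samples is ≥ 1, and
  testing is restricted to that set. No outlier-count handling (Cook's
  style) is applied either; both omissions are deliberate simplicity.

Size factors are median-of-ratios (per-sample median of count/reference
over genes with no zero counts, reference = per-gene geometric mean),
rescaled to geometric mean 1. They can be computed on a gene subset —
e.g. autosomes only, so that sex-linked dosage does not contaminate
normalization; on simulations where sex-linked genes are a few percent
of the library, refitting after that renormalization moves coefficients
by well under 0.05 log2 units (asserted in the test suite).

## Escape meta-analysis

Expression from Xi is measured as an allelic ratio, AR = reads from the
lower-expressed allele / reads from the higher-expressed allele, so
AR = 0 is monoallelic (silenced Xi) and AR = 1 balanced. Five published
dialects are harmonized:

1. **Summary AR** (array intensities): per-gene mean, SD, n; genes
   informative in ≥ 5 samples are tested for AR > 0 with a one-sided
   one-sample t-test, BH-corrected, escape at padj < 0.05.
2. **Precomputed two-arm**: single-cell and bulk arms with provided
   adjusted p values; inclusion requires ≥ 2 single-cell individuals or
   1 plus bulk; escape if either arm's padj < 0.05 (an OR rule).
3. **Single-cell fraction**: per-cell Xa read fractions converted via
   AR = 1/f − 1; genes with ≥ 2 informative samples are escape if any
   sample exceeds AR > 0.0526 (strictly — the AR at f = 0.95).
4. **Skew-adjusted bulk**: per-sample allele counts plus the XCI
   skewing coefficient $s$ (fraction of cells inactivating the same
   parental X). Complete silencing still yields a baseline
   AR = (1 − s)/s from the minority-cell population, so raw ARs are
   compared with the per-sample baseline by a paired one-sided t-test
   over ≥ 10 informative (s > 0.5) samples; escape at padj < 0.01.
5. **Bulk AR**: per-sample ARs; one-sided one-sample t-test vs 0, BH,
   escape at padj < 0.05.

Final classes combine the per-study verdicts, ignoring `no_data`
studies: **escape** if more than half call escape, or if at least one
does and either more than one does or the cross-study mean AR is
≥ 0.1; **subject** if none call escape, or if more than half call
subject and the mean AR is < 0.1. Two cells of this rule table deserve
comment, because the published wording leaves them open:

- The two rulesets can *both* fire (e.g. two escape, three subject,
  mean AR < 0.1). We give the escape ruleset precedence — its clause
  "more than one study with evidence of escape" is the more specific
  statement, and evidence of Xi expression in two independent datasets
  is hard to dismiss. The remaining truly undefined cell (exactly half
  escaping, one escaping study, low AR) returns `no_call`.
- Genes with no study data fall back to an Xi-hybrid-line panel:
  escape if expressed in ≥ 22% of hybrid lines. The below-threshold
  direction is unstated in the source rules; we default to `subject`
  (hybrid data present and unconvincing is evidence, not absence of
  evidence) and expose `hybrid_below = "no_call"` for the stricter
  reading.
- The cross-study mean AR is unweighted over studies reporting one.
  For the skew-adjusted dialect the reported study AR is the mean
  skew-corrected excess max(AR − baseline, 0), which is the quantity
  on the same Xi/Xa scale as the other dialects.

## Comparing response vectors

Both axes of a response–response comparison (X response vs Y response,
knockdown vs dosage) are *estimates* with known standard errors, so
ordinary least squares — which attributes all error to y — attenuates
slopes. `deming_fit()` implements the errors-in-variables fit: the
closed-form Deming estimator at error-variance ratio δ (default 1,
orthogonal regression), and a weighted mode that finds the slope by
York-style iteration with per-point weights
$W_i = w_{xi} w_{yi} / (w_{xi} + b^2 w_{yi})$ — the inverse residual
variance $\sigma_{yi}^2 + b^2 \sigma_{xi}^2$ — iterated to a slope
change below $10^{-8}$ (max 200 iterations). This minimizes the total
weighted squared distance to the line along both axes; the test suite
verifies the minimizer against a brute-force grid search and the
unweighted estimator's reciprocal symmetry under axis exchange.

"Fraction of dosage effects explained by the knockdown" has no single
published operationalization, so `attribute_effect()` computes both
candidates and reports the coefficient of determination $r^2$ of the
weighted Deming fit of (−knockdown log2FC) on (copy-number log2FC) as
primary — matching the convention of annotating scatterplots with
$r^2$ — alongside the per-gene effect ratio
$100 \cdot \mathrm{clamp}(-\beta_{kd}/\beta_{chr}, 0, 1)$ with its
median and interquartile range.

Set overlaps use the hypergeometric upper tail; gene-set enrichment
restricts every collection set to the *expressed* background of the
relevant cell type before testing — a whole-genome universe would
manufacture enrichment from expression alone.

## Heterochromatin from read depth

The Yq heterochromatic block is a tandem array of the DYZ1 satellite;
its length varies person to person and is invisible to expression data.
Sequencing depth over DYZ1, normalized by depth over a single-copy Y
reference region, indexes its copy number — provided GC bias is
removed, because the AT-rich satellite sits in a different part of the
GC–coverage curve than the reference. `gc_correct_depth()` estimates
the GC → relative-depth curve per sample from *single-copy bins only*
(binned medians over GC deciles, normalized to overall median 1,
interpolated between bin medians and extended flat beyond them),
then divides every bin by it; fitting on single-copy bins prevents the
repeat's own copy-number signal from leaking into its correction. The
binned-median curve is a deliberate, documented stand-in for the more
elaborate fragment-level corrections used with real WGS data. On
simulations with amplitude-0.5 sinusoidal bias the corrected ratio is
within 5% of truth while the uncorrected ratio is ~30% biased.

Sample structure among karyotypes is visualized by PCA of
log2(normalized count + 1) — a variance-stabilizing surrogate chosen
over a parametric VST because the conclusions rest on large
between-karyotype separations, not the fine shape of the transform —
after per-gene least-squares residualization on batch indicators
(retaining gene means) and gene standardization. Group ellipses are
95% confidence regions: centroid, sample covariance scaled by the
chi-square(2) quantile 5.991; groups need ≥ 3 samples, and singular
covariances are flagged degenerate.

Peak-to-gene assignment uses 0-based half-open coordinates throughout
(BED convention): TSS = interval start on +, interval end on −; the
window $[\mathrm{tss}-w, \mathrm{tss}+w)$ is closed-open, so a peak
abutting its end does not bind. Overlap is computed with
GenomicRanges; the tests compare it against a naive all-pairs oracle.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws counts from exactly the NB dosage model
above: disjoint truth classes (X-responsive, Y-responsive, shared with
concordant signs, chromosome-21, null), per-gene baselines log-normal
around 150 counts, |log2FC| per copy uniform on 0.1–0.5 with random
sign (mostly below 1.5-fold per copy, the magnitude regime these
responses occupy), dispersions log-normal around 0.05, three batches
with 0.1 log2-unit gene-level offsets, log-normal library sizes
(sdlog 0.25), and a nine-karyotype table totalling 120 samples from
45,X to 49,XYYYY. Everything is configurable; the defaults are the
package's reference study conditions.

`simulate_allelic_studies()` gives silenced genes true Xi/Xa ratios
essentially at zero (exponential, mean ~0.003, capped at 0.02) and
escape genes 0.15–0.6, then applies *dialect-appropriate* measurement
noise: symmetric Gaussian for array intensities (which may dip below
zero), clamped Gaussian per cell for single-cell fractions, and
binomial minor-allele read sampling (depth 100–600, background
mis-assignment rate 0.001) for the sequencing dialects — so silenced
genes yield mostly exact-zero ARs, as real allele counts do. The
skew-adjusted dialect mixes cell populations explicitly: with skewing
$s$ and true ratio $r$, minor-allele expression is proportional to
$(1-s) + sr$ and major to $s + (1-s)r$.

`simulate_depth_profiles()` multiplies base depth × copy number × a
sinusoidal GC-bias factor × log-normal noise over bins whose GC is
drawn once (a genome property), with the repeat region AT-shifted
(GC 0.30–0.45) relative to the single-copy region (0.30–0.65).

What passing these simulations does **not** show about real data:
counts here are honestly negative binomial with a correctly specified
linear mean — real RNA-seq carries GC and length biases, correlated
genes, outlier samples and misannotated karyotypes; allelic ratios here
have no reference-allele mapping bias or phasing errors; the depth
model has no mappability structure. Recovery results are therefore
statements about the implementation, not about robustness to
model misspecification.

## Numerical choices and degenerate inputs

- IRLS starts from the OLS fit of log(count + 0.5) − offset; all-zero
  genes are returned unconverged with NA coefficients.
- Zero-SD t-tests resolve by sign of the mean (p = 0, 1, or 0.5 at
  mean zero, with a $10^{-12}$ float tolerance); the degenerate
  "escape with p = 0" case is logged.
- BH adjustment propagates NA p values without counting them toward m.
- Deming fits with $S_{xy} = 0$ are flagged degenerate rather than
  returning an arbitrary vertical slope.
- Subsamples in the saturation analysis that lose design rank are
  redrawn (bounded retries), and constant design columns are dropped
  for that subsample.
- Genes containing any zero count are excluded from the size-factor
  reference; a pseudo-reference fallback (zeros ignored within gene)
  is available behind a flag.

## Problem sizes used by the tests

The suite's recovery experiments use 1,000 genes × 120 samples for
coefficient RMSE/FDR and the global null; 500 genes for the escape
classifier (20% escape, fixed seed); 400 genes with down-sampling sizes
20–120 × 25 replicates for the saturation sweep; 40 samples spanning
ratios 20–900 for depth recovery; and 1,000 random peaks × 50 genes for
the interval oracle. These sizes were chosen to make Monte-Carlo
tolerances comfortable at desk scale.

## Known limitations

- The per-gene dispersion has no empirical-Bayes sharing, so at small
  n (≲ 20 samples) coefficients are fine but padj is conservative
  relative to moderated methods.
- The escape combiner treats studies symmetrically; there is no
  quality weighting of, say, a 136-sample bulk study against a
  5-sample single-cell study beyond their own inclusion rules.
- `transform_and_pca()`'s log transform under-stabilizes very
  low-count genes compared with a parametric VST.
- The GC correction interpolates within the observed single-copy GC
  range and extrapolates flat outside it; repeat regions far outside
  that range would be under-corrected.
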