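#' Convert an active-X read fraction to an allelic ratio
#'
#' Allelic ratio (AR) is the ratio of reads from the lower-expressed (Xi)
#' allele to the higher-expressed (Xa) allele. Given the fraction f of
#' reads from the active X, AR = 1/f - 1: f = 0.5 gives balanced biallelic
#' expression (AR = 1), f = 1 monoallelic (AR = 0).
#'
#' @param f Xa reads / total reads, in (0, 1].
#' @return AR value(s) in [0, Inf).
#' @examples
#' ar_from_xa_fraction(0.95)  # 0.0526..., a common per-sample threshold
#' @export
ar_from_xa_fraction <- function(f) {
  if (any(f <= 0) || any(f > 1))
    stop("Xa fraction must lie in (0, 1]")
  1 / f - 1
}

#' Baseline allelic ratio implied by XCI skewing
#'
#' In a sample where a fraction `skew` of cells inactivate the same
#' parental X, complete silencing of Xi still yields a nonzero minor-allele
#' ratio of (1 - skew)/skew from the minority-cell population; observed ARs
#' must beat this baseline to indicate expression from Xi.
#'
#' @param skew Skewing coefficient(s) in (0.5, 1].
#' @return Baseline AR value(s).
#' @export
baseline_ar <- function(skew) {
  if (any(skew <= 0.5) || any(skew > 1))
    stop("skewing coefficient must lie in (0.5, 1]")
  (1 - skew) / skew
}

study_call_frame <- function(gene_id, call, mean_ar, p = NA_real_,
                             padj = NA_real_) {
  n <- length(gene_id)
  data.frame(gene_id = gene_id, call = rep_len(call, n),
             mean_ar = rep_len(mean_ar, n), p = rep_len(p, n),
             padj = rep_len(padj, n), row.names = NULL,
             stringsAsFactors = FALSE)
}

# one-sided upper-tail one-sample t p value with the degenerate cases the
# study rules require: all-zero differences -> 0.5, zero SD with positive
# mean -> 0 (logged by callers)
one_sided_t_p <- function(m, s, n) {
  if (n < 2 || is.na(s)) return(NA_real_)
  if (s <= 1e-12) {
    if (m > 1e-12) return(0)
    if (m < -1e-12) return(1)
    return(0.5)
  }
  stats::pt(m / (s / sqrt(n)), df = n - 1, lower.tail = FALSE)
}

#' Call escape from per-gene summary allelic ratios
#'
#' Study dialect: per-gene mean AR, SD and number of informative samples.
#' Genes informative in at least `min_n` samples are tested for AR > 0 with
#' a one-sample, one-sided t test; p values are BH-corrected across
#' included genes and padj < `padj_threshold` is called escape. Genes
#' failing inclusion are `no_data`.
#'
#' @param records data.frame with `gene_id`, `mean_ar`, `sd_ar`,
#'   `n_informative`.
#' @param min_n Minimum informative samples (default 5).
#' @param padj_threshold Escape cutoff on adjusted p (default 0.05).
#' @return data.frame `gene_id`, `call`, `mean_ar`, `p`, `padj`.
#' @export
call_summary_ar_study <- function(records, min_n = 5, padj_threshold = 0.05) {
  inc <- !is.na(records$mean_ar) & records$n_informative >= min_n
  p <- rep(NA_real_, nrow(records))
  p[inc] <- mapply(one_sided_t_p, records$mean_ar[inc], records$sd_ar[inc],
                   records$n_informative[inc])
  if (any(inc & !is.na(p) & p == 0 & records$mean_ar > 0, na.rm = TRUE))
    message("call_summary_ar_study: degenerate zero-SD gene(s) called ",
            "escape with p = 0")
  padj <- adjust_bh(p)
  call <- ifelse(!inc | is.na(padj), "no_data",
                 ifelse(padj < padj_threshold, "escape", "subject"))
  study_call_frame(records$gene_id, call,
                   ifelse(inc, records$mean_ar, NA_real_), p, padj)
}

#' Call escape from per-sample Xa fractions with a fixed AR threshold
#'
#' Study dialect: single-cell active-X read fractions per gene and sample.
#' Fractions are converted to ARs via [ar_from_xa_fraction()]; genes with
#' data in at least `min_samples` samples are included, and a gene is
#' escape if any sample's AR strictly exceeds `ar_threshold`.
#'
#' @param records data.frame with `gene_id`, `sample_id` and either
#'   `xa_fraction` or a precomputed `ar` column.
#' @param min_samples Minimum samples with data (default 2).
#' @param ar_threshold Per-sample AR threshold (default 0.0526, the AR at
#'   an Xa fraction of 0.95).
#' @return data.frame `gene_id`, `call`, `mean_ar`.
#' @export
call_per_sample_threshold_study <- function(records, min_samples = 2,
                                            ar_threshold = 0.0526) {
  ar <- if ("ar" %in% names(records)) records$ar else
    ar_from_xa_fraction(records$xa_fraction)
  sp <- split(ar, records$gene_id)
  ids <- names(sp)
  n <- lengths(sp)
  call <- ifelse(n < min_samples, "no_data",
                 ifelse(vapply(sp, function(a) any(a > ar_threshold),
                               logical(1)),
                        "escape", "subject"))
  study_call_frame(ids, unname(call),
                   ifelse(n >= min_samples,
                          vapply(sp, mean, numeric(1)), NA_real_))
}

#' Call escape from skew-adjusted per-sample allelic ratios
#'
#' Study dialect: per-sample allele counts plus the sample's XCI skewing
#' coefficient. Raw ARs (lower/higher allele counts) are compared with the
#' per-sample baseline AR implied by skewing ([baseline_ar()]) using a
#' paired, one-sided t test of mean(AR - baseline) > 0 over informative
#' samples (skew > 0.5). Genes with at least `min_samples` informative
#' samples are included; BH-corrected padj < `padj_threshold` is escape.
#'
#' The study-level mean AR reported for the cross-study average is the mean
#' skew-corrected excess, max(AR - baseline, 0): the quantity on the same
#' Xi/Xa scale as the other studies' ARs.
#'
#' @param records data.frame with `gene_id`, `sample_id`, `a1_count`,
#'   `a2_count`, `skew` (or precomputed `ar` instead of counts).
#' @param min_samples Minimum informative samples (default 10).
#' @param padj_threshold Escape cutoff on adjusted p (default 0.01).
#' @return data.frame `gene_id`, `call`, `mean_ar`, `p`, `padj`.
#' @export
call_skew_adjusted_study <- function(records, min_samples = 10,
                                     padj_threshold = 0.01) {
  if (!"ar" %in% names(records)) {
    lo <- pmin(records$a1_count, records$a2_count)
    hi <- pmax(records$a1_count, records$a2_count)
    records$ar <- ifelse(hi > 0, lo / hi, NA_real_)
  }
  records <- records[!is.na(records$ar) & records$skew > 0.5, , drop = FALSE]
  if (nrow(records) == 0)
    return(study_call_frame(character(0), character(0), numeric(0)))
  d <- records$ar - baseline_ar(records$skew)
  sp <- split(d, records$gene_id)
  ids <- names(sp)
  n <- lengths(sp)
  inc <- n >= min_samples
  p <- rep(NA_real_, length(ids))
  p[inc] <- vapply(sp[inc], function(di)
    one_sided_t_p(mean(di), stats::sd(di), length(di)), numeric(1))
  padj <- adjust_bh(p)
  call <- ifelse(!inc | is.na(padj), "no_data",
                 ifelse(padj < padj_threshold, "escape", "subject"))
  study_call_frame(ids, unname(call),
                   ifelse(inc, vapply(sp, function(di) mean(pmax(di, 0)),
                                      numeric(1)), NA_real_),
                   p, padj)
}

#' Call escape from precomputed arm-level adjusted p values
#'
#' Study dialect: a single-cell arm (number of individuals with data, arm
#' padj) and a bulk arm (present flag, arm padj). A gene is included if it
#' has data from at least two individuals in the single-cell arm, or one
#' single-cell individual plus bulk data. Included genes are escape if any
#' arm with data has padj < `padj_threshold` (OR rule; conflicting arms
#' resolve toward escape).
#'
#' @param records data.frame with `gene_id`, `sc_n_individuals`, `sc_padj`,
#'   `bulk_present`, `bulk_padj`, optional `mean_ar`.
#' @param padj_threshold Escape cutoff (default 0.05).
#' @return data.frame `gene_id`, `call`, `mean_ar`.
#' @export
call_precomputed_study <- function(records, padj_threshold = 0.05) {
  inc <- records$sc_n_individuals >= 2 |
    (records$sc_n_individuals >= 1 & records$bulk_present)
  sc_hit <- records$sc_n_individuals >= 1 & !is.na(records$sc_padj) &
    records$sc_padj < padj_threshold
  bulk_hit <- records$bulk_present & !is.na(records$bulk_padj) &
    records$bulk_padj < padj_threshold
  call <- ifelse(!inc, "no_data",
                 ifelse(sc_hit | bulk_hit, "escape", "subject"))
  mean_ar <- if ("mean_ar" %in% names(records)) records$mean_ar else NA_real_
  study_call_frame(records$gene_id, call, ifelse(inc, mean_ar, NA_real_))
}

#' Call escape from per-sample bulk allelic ratios
#'
#' Study dialect: per-sample ARs from bulk RNA-seq of skewed cell lines.
#' Genes with at least `min_samples` samples are tested for mean AR > 0
#' with a one-sided, one-sample t test, BH-corrected; padj <
#' `padj_threshold` is escape.
#'
#' @param records data.frame with `gene_id`, `sample_id`, `ar`.
#' @param min_samples Minimum samples with data (default 2; the t test
#'   needs at least two observations).
#' @param padj_threshold Escape cutoff (default 0.05).
#' @return data.frame `gene_id`, `call`, `mean_ar`, `p`, `padj`.
#' @export
call_bulk_ar_study <- function(records, min_samples = 2,
                               padj_threshold = 0.05) {
  sp <- split(records$ar, records$gene_id)
  ids <- names(sp)
  n <- lengths(sp)
  inc <- n >= max(min_samples, 2)
  p <- rep(NA_real_, length(ids))
  p[inc] <- vapply(sp[inc], function(a)
    one_sided_t_p(mean(a), stats::sd(a), length(a)), numeric(1))
  padj <- adjust_bh(p)
  call <- ifelse(!inc | is.na(padj), "no_data",
                 ifelse(padj < padj_threshold, "escape", "subject"))
  study_call_frame(ids, unname(call),
                   ifelse(inc, vapply(sp, mean, numeric(1)), NA_real_),
                   p, padj)
}

# the per-gene combining rule; exported via combine_calls
combine_one <- function(n_escape, n_subject, mean_ar, hybrid_fraction,
                        ar_threshold = 0.1, hybrid_threshold = 0.22,
                        hybrid_below = c("subject", "no_call")) {
  hybrid_below <- match.arg(hybrid_below)
  n <- n_escape + n_subject
  if (n == 0) {
    if (is.na(hybrid_fraction)) return("no_call")
    if (hybrid_fraction >= hybrid_threshold) return("escape")
    return(hybrid_below)
  }
  ar_high <- !is.na(mean_ar) && mean_ar >= ar_threshold
  # escape ruleset (takes precedence where the subject ruleset also fires)
  if (n_escape > n / 2) return("escape")
  if (n_escape > 0 && (n_escape > 1 || ar_high)) return("escape")
  # subject ruleset
  if (n_escape == 0) return("subject")
  if (n_subject > n / 2 && !ar_high) return("subject")
  "no_call"
}

#' Combine per-study escape calls into a final three-way classification
#'
#' Studies with `no_data` are dropped from both numerator and denominator.
#' A gene is escape if (1) more than half of the informative studies call
#' escape, or (2) half or fewer (but at least one) do, and either more than
#' one study calls escape or the cross-study mean AR is >= `ar_threshold`.
#' A gene is subject if all informative studies call subject, or more than
#' half do and the mean AR is < `ar_threshold`. Where both rulesets fire
#' (possible for e.g. 2 escape / 3 subject with low AR), escape takes
#' precedence. Genes with no study data fall back to the Xi-hybrid panel:
#' escape if expressed in at least `hybrid_threshold` of hybrid lines,
#' otherwise `hybrid_below` ("subject" by default); `no_call` when hybrid
#' data is also missing. The cross-study mean AR is the unweighted mean
#' over studies reporting one.
#'
#' @param study_calls Named list of per-study call tables as returned by
#'   the `call_*_study()` functions (columns `gene_id`, `call`, `mean_ar`).
#' @param hybrid Optional data.frame `gene_id`, `hybrid_fraction` (fraction
#'   of Xi hybrid lines expressing the gene).
#' @param ar_threshold Mean-AR cutoff in the combining rules (default 0.1).
#' @param hybrid_threshold Hybrid-panel escape cutoff (default 0.22).
#' @param hybrid_below Class assigned when hybrid data is present but below
#'   threshold and no study has data.
#' @return data.frame with one row per gene: per-study calls
#'   (`call_<study>`), `n_escape`, `n_subject`, `n_with_data`, `mean_ar`,
#'   `hybrid_fraction`, `final`.
#' @export
combine_calls <- function(study_calls, hybrid = NULL, ar_threshold = 0.1,
                          hybrid_threshold = 0.22,
                          hybrid_below = c("subject", "no_call")) {
  hybrid_below <- match.arg(hybrid_below)
  stopifnot(is.list(study_calls), length(study_calls) >= 1)
  if (is.null(names(study_calls)) || any(names(study_calls) == ""))
    names(study_calls) <- paste0("study", seq_along(study_calls))
  ids <- sort(unique(unlist(lapply(study_calls, `[[`, "gene_id"))))
  if (!is.null(hybrid)) ids <- sort(unique(c(ids, hybrid$gene_id)))
  calls <- matrix("no_data", length(ids), length(study_calls),
                  dimnames = list(NULL, names(study_calls)))
  ars <- matrix(NA_real_, length(ids), length(study_calls))
  for (j in seq_along(study_calls)) {
    sc <- study_calls[[j]]
    m <- match(ids, sc$gene_id)
    calls[!is.na(m), j] <- sc$call[m[!is.na(m)]]
    ars[, j] <- sc$mean_ar[m]
  }
  n_escape <- rowSums(calls == "escape")
  n_subject <- rowSums(calls == "subject")
  mean_ar <- rowMeans(ars, na.rm = TRUE)
  mean_ar[is.nan(mean_ar)] <- NA_real_
  hf <- rep(NA_real_, length(ids))
  if (!is.null(hybrid))
    hf <- hybrid$hybrid_fraction[match(ids, hybrid$gene_id)]
  final <- vapply(seq_along(ids), function(i)
    combine_one(n_escape[i], n_subject[i], mean_ar[i], hf[i],
                ar_threshold, hybrid_threshold, hybrid_below), character(1))
  out <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  for (s in names(study_calls)) out[[paste0("call_", s)]] <- calls[, s]
  out$n_escape <- n_escape
  out$n_subject <- n_subject
  out$n_with_data <- n_escape + n_subject
  out$mean_ar <- mean_ar
  out$hybrid_fraction <- hf
  out$final <- final
  out
}

#' Classify X-inactivation escape from five study tables
#'
#' Convenience orchestrator: applies the dialect-specific caller to each of
#' the five study tables (named as in [simulate_allelic_studies()]) and
#' combines the calls with [combine_calls()].
#'
#' @param studies Named list with elements `summaryAR`, `precomputed`,
#'   `singlecell_fraction`, `skew_adjusted`, `bulkAR`.
#' @param hybrid Optional hybrid-panel data.frame (see [combine_calls()]).
#' @param ... Passed to [combine_calls()].
#' @return The [combine_calls()] table.
#' @export
classify_escape <- function(studies, hybrid = NULL, ...) {
  need <- c("summaryAR", "precomputed", "singlecell_fraction",
            "skew_adjusted", "bulkAR")
  missing <- setdiff(need, names(studies))
  if (length(missing))
    stop("missing study tables: ", paste(missing, collapse = ", "))
  sc <- list(
    summaryAR = call_summary_ar_study(studies$summaryAR),
    precomputed = call_precomputed_study(studies$precomputed),
    singlecell_fraction = call_per_sample_threshold_study(
      studies$singlecell_fraction),
    skew_adjusted = call_skew_adjusted_study(studies$skew_adjusted),
    bulkAR = call_bulk_ar_study(studies$bulkAR))
  combine_calls(sc, hybrid = hybrid, ...)
}
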