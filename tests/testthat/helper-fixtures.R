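# Shared fixtures, built in code.

# tiny cohort with known structure for fast GLM tests
small_cohort <- function(n_genes = 60, seed = 42, ...) {
  simulate_cohort(sim_cohort_config(n_genes = n_genes, seed = seed, ...))
}

# annotation table covering a count matrix, equal-length genes by default
make_annotation <- function(gene_ids, lengths = 1000, chrom = "chr1",
                            strand = "+") {
  n <- length(gene_ids)
  start <- seq(0, by = 10000, length.out = n)
  data.frame(gene_id = gene_ids, chrom = chrom, start = start,
             end = start + 2000,
             strand = rep(strand, length.out = n),
             length = rep(lengths, length.out = n),
             effective_length = rep(lengths, length.out = n),
             tss = ifelse(rep(strand, length.out = n) == "+", start,
                          start + 2000),
             stringsAsFactors = FALSE)
}

# single-row study-call table for combiner tests
one_call <- function(gene_id, call, mean_ar = NA_real_) {
  n <- length(gene_id)
  data.frame(gene_id = gene_id, call = rep_len(call, n),
             mean_ar = rep_len(mean_ar, n), stringsAsFactors = FALSE)
}
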