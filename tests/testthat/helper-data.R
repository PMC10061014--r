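# Small fixture builders (all data generated in code).

make_annotations <- function(snp_ids, chrom = "1", gene_ids = "",
                             autosomal = TRUE) {
  n <- length(snp_ids)
  data.frame(snp_id = snp_ids, chrom = rep_len(chrom, n),
             pos = seq(100L, by = 1000L, length.out = n),
             ref = rep_len("A", n), alt = rep_len("G", n),
             gene_ids = rep_len(gene_ids, n),
             is_autosomal = rep_len(autosomal, n),
             stringsAsFactors = FALSE)
}

make_counts <- function(snp_id, sample_id, condition, ref_count, alt_count) {
  data.frame(snp_id = snp_id, sample_id = sample_id, condition = condition,
             ref_count = as.integer(ref_count),
             alt_count = as.integer(alt_count), stringsAsFactors = FALSE)
}

# counts for n_samples at one SNP in given conditions, fixed counts
balanced_counts <- function(snp_id, n_samples, conditions, ref, alt) {
  expand <- expand.grid(sample_id = sprintf("S%02d", seq_len(n_samples)),
                        condition = conditions, stringsAsFactors = FALSE)
  make_counts(snp_id, expand$sample_id, expand$condition, ref, alt)
}

# transform: swap every record's ref and alt counts
swap_alleles <- function(counts) {
  tmp <- counts$ref_count
  counts$ref_count <- counts$alt_count
  counts$alt_count <- tmp
  counts
}

# randomized (Stevens) p-values for discrete exact tests: given observed
# p-values and, per observation, the largest achievable p strictly below
# it, returns values exactly Uniform(0,1) under the null.
randomize_p <- function(p_obs, p_prev) {
  p_prev + stats::runif(length(p_obs)) * (p_obs - p_prev)
}

# largest achievable p strictly below p_obs in a support vector (0 if none)
prev_support <- function(p_obs, support) {
  support <- sort(unique(support))
  idx <- findInterval(p_obs * (1 - 1e-9), support)
  c(0, support)[idx + 1L]
}
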