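# Haplotype-level allelic ratios and their comparison across conditions.
#
# Given the phase of a locus's transcribed SNPs (which allele of each SNP
# lies on haplotype H1), reads are pooled across SNPs per haplotype and
# the haplotype ratio h1 / (h1 + h2) is computed per heterozygous sample
# and condition. Treatment-induced shifts are tested per contrast with
# paired t-tests on the per-sample ratios (the same individuals are
# measured in every condition), Bonferroni-corrected over the contrasts.

#' Haplotype-level allelic ratio for one sample and condition
#'
#' Pools reads across a locus's phased SNPs: each SNP's count of the allele
#' assigned to H1 accrues to `h1_reads`, the other to `h2_reads`. Reads
#' spanning two phased SNPs are counted at each (counts are per-SNP), as in
#' any per-SNP count representation.
#'
#' @param records count data.frame rows of one sample in one condition at
#'   the locus's SNPs.
#' @param phase phase data.frame (see [read_phase_table()]) for one locus.
#' @param diplotype optional diplotype of the sample at the locus; anything
#'   other than `"H1H2"` is an error ("not informative").
#' @return one-row data.frame: `h1_reads`, `h2_reads`, `ratio`.
#' @export
haplotype_ratio <- function(records, phase, diplotype = "H1H2") {
  if (!identical(diplotype, "H1H2"))
    stop("not informative: sample is not heterozygous (diplotype ",
         diplotype, ") at the locus")
  hit <- match(records$snp_id, phase$snp_id)
  if (anyNA(hit)) {
    warning("no phase for SNP(s) ",
            paste(records$snp_id[is.na(hit)], collapse = ", "),
            "; skipped")
    records <- records[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  if (nrow(records) == 0)
    stop("no phased SNP with counts at the locus")
  ref_on_h1 <- phase$h1_allele[hit] == "ref"
  h1 <- sum(ifelse(ref_on_h1, records$ref_count, records$alt_count))
  h2 <- sum(ifelse(ref_on_h1, records$alt_count, records$ref_count))
  data.frame(h1_reads = h1, h2_reads = h2,
             ratio = if (h1 + h2 > 0) h1 / (h1 + h2) else NA_real_)
}

#' Haplotype-level allelic ratios for a whole dataset
#'
#' Applies [haplotype_ratio()] to every sample x condition of every locus
#' in the phase table. When `diplotypes` is supplied, samples that are not
#' `H1H2` at a locus are dropped as uninformative.
#'
#' @param counts count data.frame (typically filtered).
#' @param phase phase data.frame (possibly several loci).
#' @param diplotypes optional diplotype data.frame (see
#'   [read_diplotypes()]).
#' @return data.frame with columns `locus_id`, `sample_id`, `condition`,
#'   `h1_reads`, `h2_reads`, `ratio`.
#' @export
haplotype_ratios <- function(counts, phase, diplotypes = NULL) {
  out <- list()
  for (locus in unique(phase$locus_id)) {
    ph <- phase[phase$locus_id == locus, , drop = FALSE]
    sub <- counts[counts$snp_id %in% ph$snp_id, , drop = FALSE]
    if (nrow(sub) == 0) next
    if (!is.null(diplotypes)) {
      dp <- diplotypes[diplotypes$locus_id == locus, , drop = FALSE]
      het <- dp$sample_id[dp$diplotype == "H1H2"]
      sub <- sub[sub$sample_id %in% het, , drop = FALSE]
    }
    if (nrow(sub) == 0) next
    grp <- split(seq_len(nrow(sub)), list(sub$sample_id, sub$condition),
                 drop = TRUE)
    for (idx in grp) {
      rec <- sub[idx, , drop = FALSE]
      hr <- suppressWarnings(haplotype_ratio(rec, ph))
      out[[length(out) + 1L]] <- data.frame(
        locus_id = locus, sample_id = rec$sample_id[1],
        condition = rec$condition[1], hr, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(locus_id = character(), sample_id = character(),
                      condition = character(), h1_reads = integer(),
                      h2_reads = integer(), ratio = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$locus_id, res$condition, res$sample_id), , drop = FALSE]
}

#' Compare haplotype ratios between control and each treatment
#'
#' Paired t-test per contrast on the per-sample haplotype ratios (each
#' individual measured in both conditions), with Bonferroni correction
#' over the number of contrasts reported alongside the raw p-value. A
#' zero-variance difference vector is a degenerate case: the p-value is
#' reported as 1 when every difference is zero, otherwise as the smallest
#' positive double with `degenerate = 1`.
#'
#' @param ratios output of [haplotype_ratios()].
#' @param design a [study_design()]; its contrasts define the comparisons.
#' @return data.frame with columns `locus_id`, `contrast`, `n_pairs`,
#'   `mean_control`, `mean_treatment`, `mean_diff`, `p_raw`,
#'   `p_bonferroni`, `degenerate` (0/1).
#' @export
compare_ratios_across_conditions <- function(ratios, design) {
  out <- list()
  n_contrasts <- length(design$contrasts)
  for (locus in unique(ratios$locus_id)) {
    sub <- ratios[ratios$locus_id == locus, , drop = FALSE]
    for (ct in design$contrasts) {
      lab <- .contrast_label(ct)
      ctl <- sub[sub$condition == ct[1], , drop = FALSE]
      trt <- sub[sub$condition == ct[2], , drop = FALSE]
      m <- merge(ctl[c("sample_id", "ratio")], trt[c("sample_id", "ratio")],
                 by = "sample_id", suffixes = c("_control", "_treatment"))
      m <- m[stats::complete.cases(m), , drop = FALSE]
      if (nrow(m) < 2) {
        warning("contrast ", lab, " at locus ", locus,
                " skipped: fewer than 2 paired samples")
        next
      }
      d <- m$ratio_treatment - m$ratio_control
      # constant differences (up to floating-point noise) would make the
      # t statistic meaningless; report the degenerate case explicitly
      degenerate <-
        stats::sd(d) < 100 * .Machine$double.eps * max(1, abs(mean(d)))
      p <- if (degenerate) {
        if (all(d == 0)) 1 else .Machine$double.xmin
      } else {
        stats::t.test(m$ratio_treatment, m$ratio_control,
                      paired = TRUE)$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        locus_id = locus, contrast = lab, n_pairs = nrow(m),
        mean_control = mean(m$ratio_control),
        mean_treatment = mean(m$ratio_treatment),
        mean_diff = mean(d), p_raw = p,
        p_bonferroni = min(1, p * n_contrasts),
        degenerate = as.integer(degenerate), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(locus_id = character(), contrast = character(),
                      n_pairs = integer(), mean_control = numeric(),
                      mean_treatment = numeric(), mean_diff = numeric(),
                      p_raw = numeric(), p_bonferroni = numeric(),
                      degenerate = integer(), stringsAsFactors = FALSE))
  .order_results(do.call(rbind, out))
}

#' Diplotype effect on per-sample expression fold changes
#'
#' Convenience comparison of treatment-induced log2 fold changes between
#' samples heterozygous (H1H2) and homozygous at a locus, by Welch's
#' t-test. The fold changes come from an external expression analysis.
#'
#' @param fold_changes data.frame with columns `sample_id`, `log2_fc`.
#' @param diplotypes diplotype data.frame (see [read_diplotypes()]) for one
#'   locus.
#' @return one-row data.frame: group sizes, group means, `p`.
#' @export
compare_diplotype_foldchange <- function(fold_changes, diplotypes) {
  hit <- match(fold_changes$sample_id, diplotypes$sample_id)
  if (anyNA(hit)) stop("missing diplotype for sample(s): ",
                       paste(fold_changes$sample_id[is.na(hit)],
                             collapse = ", "))
  het <- diplotypes$diplotype[hit] == "H1H2"
  if (sum(het) < 2 || sum(!het) < 2)
    stop("need at least 2 samples per diplotype group")
  tt <- stats::t.test(fold_changes$log2_fc[het],
                      fold_changes$log2_fc[!het])
  data.frame(n_het = sum(het), n_hom = sum(!het),
             mean_het = mean(fold_changes$log2_fc[het]),
             mean_hom = mean(fold_changes$log2_fc[!het]),
             p = tt$p.value)
}
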