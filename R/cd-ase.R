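# SNP-wise condition-dependent ASE (control vs each treatment).
#
# Candidate SNPs are those with significant static ASE in at least one
# condition (the preselection used before the condition comparison). For
# each contrast, every sample whose records pass the informative-site
# filter in BOTH conditions contributes one 2x2 table (rows = conditions,
# columns = ref/alt counts) tested by Fisher's exact test; the per-sample
# p-values are combined by Fisher's method and BH-adjusted across all
# tested SNPs of the contrast.

#' Build one sample's 2x2 contrast table
#'
#' Returns the 2x2 allelic count table (rows = control, treatment; columns
#' = ref, alt) for one SNP and sample, or `NULL` when the sample is not
#' informative — i.e. it lacks a filtered record in either condition of the
#' contrast. `counts` is expected to be already filtered, so presence of a
#' record asserts it passed the thresholds.
#'
#' @param counts filtered count data.frame.
#' @param snp_id,sample_id identifiers of the observation.
#' @param contrast `c(control, treatment)` condition pair.
#' @return 2x2 integer matrix or `NULL`.
#' @export
build_contrast_table <- function(counts, snp_id, sample_id, contrast) {
  sel <- counts$snp_id == snp_id & counts$sample_id == sample_id
  ctl <- counts[sel & counts$condition == contrast[1], , drop = FALSE]
  trt <- counts[sel & counts$condition == contrast[2], , drop = FALSE]
  if (nrow(ctl) != 1 || nrow(trt) != 1) return(NULL)
  matrix(c(ctl$ref_count, trt$ref_count, ctl$alt_count, trt$alt_count),
         nrow = 2, dimnames = list(contrast, c("ref", "alt")))
}

#' SNP-wise condition-dependent ASE scan
#'
#' @param counts filtered count data.frame.
#' @param static a [scan_static_ase()] result used for candidate
#'   preselection; ignored when `candidates` is given.
#' @param annotations annotation data.frame.
#' @param design a [study_design()]; its contrasts define the comparisons.
#' @param sig_fdr FDR threshold for the `significant` column.
#' @param per_sample_alpha unadjusted per-sample p-value threshold used to
#'   count samples with individually significant condition dependence
#'   (default 0.05).
#' @param candidates optional explicit SNP id vector overriding the static
#'   preselection (useful for calibration studies).
#' @param p_floor clamp for zero/tiny p-values before log combination.
#' @return data.frame of class `cd_ase_scan` with columns `snp_id`,
#'   `chrom`, `pos`, `contrast`, `n_samples`, `n_sig_samples`,
#'   `delta_ratio` (mean treatment minus mean control allelic ratio),
#'   `chi2`, `df`, `p`, `fdr`, `significant` (0/1), `ge3_samples_flag`
#'   (0/1: condition dependence individually significant in >= 3 samples).
#'   Per-sample p-values are attached as `attr(, "per_sample")`.
#' @export
scan_cd_ase <- function(counts, static = NULL, annotations, design,
                        sig_fdr = 0.05, per_sample_alpha = 0.05,
                        candidates = NULL, p_floor = 1e-300) {
  if (is.null(candidates)) {
    if (is.null(static))
      stop("provide either a static scan result or explicit candidates")
    candidates <- unique(static$snp_id[static$significant == 1L])
  }
  counts <- counts[counts$snp_id %in% candidates, , drop = FALSE]
  counts <- counts[order(counts$snp_id, counts$sample_id), , drop = FALSE]
  res_list <- list()
  ps_list <- list()
  for (ct in design$contrasts) {
    lab <- .contrast_label(ct)
    ctl <- counts[counts$condition == ct[1], , drop = FALSE]
    trt <- counts[counts$condition == ct[2], , drop = FALSE]
    m <- merge(ctl, trt, by = c("snp_id", "sample_id"),
               suffixes = c("_control", "_treatment"))
    if (nrow(m) == 0) {
      warning("no informative sample pairs for contrast ", lab)
      next
    }
    m <- m[order(m$snp_id, m$sample_id), , drop = FALSE]
    p_rec <- .fisher_p_vec(m$ref_count_control, m$alt_count_control,
                           m$ref_count_treatment, m$alt_count_treatment)
    r_ctl <- m$ref_count_control /
      (m$ref_count_control + m$alt_count_control)
    r_trt <- m$ref_count_treatment /
      (m$ref_count_treatment + m$alt_count_treatment)
    ps_list[[lab]] <- data.frame(contrast = lab, snp_id = m$snp_id,
                                 sample_id = m$sample_id, p = p_rec,
                                 ratio_control = r_ctl,
                                 ratio_treatment = r_trt,
                                 stringsAsFactors = FALSE)
    grp <- m$snp_id
    chi2 <- rowsum(-2 * log(pmax(p_rec, p_floor)), grp)[, 1]
    k <- rowsum(rep(1L, length(grp)), grp)[, 1]
    nsig <- rowsum(as.integer(p_rec <= per_sample_alpha), grp)[, 1]
    delta <- (rowsum(r_trt, grp)[, 1] - rowsum(r_ctl, grp)[, 1]) / k
    df <- 2L * k
    comb_p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
    fdr <- adjust_bh(comb_p)
    hit <- match(names(chi2), annotations$snp_id)
    res_list[[lab]] <- data.frame(
      snp_id = names(chi2), chrom = annotations$chrom[hit],
      pos = annotations$pos[hit], contrast = lab,
      n_samples = as.integer(k), n_sig_samples = as.integer(nsig),
      delta_ratio = delta, chi2 = chi2, df = as.integer(df), p = comb_p,
      fdr = fdr, significant = as.integer(fdr <= sig_fdr),
      ge3_samples_flag = as.integer(nsig >= 3L),
      stringsAsFactors = FALSE)
  }
  res <- if (length(res_list)) .order_results(do.call(rbind, res_list))
         else data.frame(snp_id = character(), chrom = character(),
                         pos = integer(), contrast = character(),
                         n_samples = integer(), n_sig_samples = integer(),
                         delta_ratio = numeric(), chi2 = numeric(),
                         df = integer(), p = numeric(), fdr = numeric(),
                         significant = integer(),
                         ge3_samples_flag = integer(),
                         stringsAsFactors = FALSE)
  structure(res, class = c("cd_ase_scan", "data.frame"),
            per_sample = if (length(ps_list)) do.call(rbind, ps_list)
                         else NULL,
            candidates = candidates, sig_fdr = sig_fdr,
            per_sample_alpha = per_sample_alpha)
}

#' @export
print.cd_ase_scan <- function(x, ...) {
  cat("SNP-wise condition-dependent ASE scan:", nrow(x),
      "SNP x contrast tests\n")
  if (nrow(x)) {
    for (lab in unique(x$contrast)) {
      sub <- x[x$contrast == lab, ]
      cat(sprintf("  %s: %d tested, %d significant (FDR <= %g), %d with >=3 significant samples\n",
                  lab, nrow(sub), sum(sub$significant),
                  attr(x, "sig_fdr"), sum(sub$ge3_samples_flag)))
    }
  }
  invisible(x)
}
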