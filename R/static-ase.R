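# SNP-wise static ASE within each condition.
#
# Per informative sample: exact two-sided binomial test of the allelic
# counts against a balanced null. Per SNP: the per-sample p-values are
# combined across heterozygous samples by Fisher's method (chi-square with
# 2k df), then adjusted across all tested SNPs of the condition by
# Benjamini-Hochberg. A SNP is "tested" in a condition as soon as one
# sample passes the informative-site filter there; samples failing the
# filter contribute nothing, not even degrees of freedom.

#' SNP-wise static allele-specific expression scan
#'
#' For each condition independently: per-sample exact binomial p-values at
#' every informative SNP, Fisher's-method combination across samples, and
#' BH FDR adjustment across all tested SNPs of that condition.
#'
#' @param counts filtered count data.frame (pass the `counts` element of a
#'   [filter_dataset()] result).
#' @param annotations annotation data.frame.
#' @param conditions conditions to scan; default: all present in `counts`.
#'   A requested condition with no informative records yields a warning and
#'   no rows.
#' @param null_ratio balanced-expression reference fraction (default 0.5).
#' @param sig_fdr FDR threshold for the `significant` column (default 0.05).
#' @param p_floor clamp for zero/tiny p-values before log combination.
#' @param method two-sided binomial convention, see [binomial_ase_p()].
#' @return data.frame of class `static_ase_scan` with columns `snp_id`,
#'   `chrom`, `pos`, `condition`, `n_samples`, `mean_ratio`, `chi2`, `df`,
#'   `p`, `fdr`, `significant` (0/1), ordered by chromosome and position.
#'   The per-sample p-values are attached as `attr(, "per_sample")`.
#' @export
scan_static_ase <- function(counts, annotations, conditions = NULL,
                            null_ratio = 0.5, sig_fdr = 0.05,
                            p_floor = 1e-300,
                            method = c("minlik", "double_tail")) {
  method <- match.arg(method)
  if (is.null(conditions)) conditions <- sort(unique(counts$condition))
  empty <- setdiff(conditions, unique(counts$condition))
  if (length(empty))
    warning("no informative records for condition(s): ",
            paste(empty, collapse = ", "))
  counts <- counts[counts$condition %in% conditions, , drop = FALSE]
  # canonical internal order: results independent of input row order
  counts <- counts[order(counts$condition, counts$snp_id,
                         counts$sample_id), , drop = FALSE]
  if (nrow(counts) == 0) {
    res <- data.frame(snp_id = character(), chrom = character(),
                      pos = integer(), condition = character(),
                      n_samples = integer(), mean_ratio = numeric(),
                      chi2 = numeric(), df = integer(), p = numeric(),
                      fdr = numeric(), significant = integer(),
                      stringsAsFactors = FALSE)
    return(structure(res, class = c("static_ase_scan", "data.frame"),
                     per_sample = res[0, 0], sig_fdr = sig_fdr))
  }
  total <- counts$ref_count + counts$alt_count
  p_rec <- binomial_ase_p(counts$ref_count, counts$alt_count,
                          null_ratio = null_ratio, method = method)
  ratio <- counts$ref_count / total
  per_sample <- data.frame(condition = counts$condition,
                           snp_id = counts$snp_id,
                           sample_id = counts$sample_id,
                           ref_count = counts$ref_count,
                           alt_count = counts$alt_count,
                           ratio = ratio, p = p_rec,
                           stringsAsFactors = FALSE)
  grp <- paste(counts$condition, counts$snp_id, sep = "\r")
  chi2 <- rowsum(-2 * log(pmax(p_rec, p_floor)), grp)[, 1]
  k <- rowsum(rep(1L, length(grp)), grp)[, 1]
  mean_ratio <- rowsum(ratio, grp)[, 1] / k
  key <- strsplit(names(chi2), "\r", fixed = TRUE)
  cond <- vapply(key, `[`, "", 1L)
  snp <- vapply(key, `[`, "", 2L)
  df <- 2L * k
  comb_p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  fdr <- stats::ave(comb_p, cond, FUN = adjust_bh)
  hit <- match(snp, annotations$snp_id)
  res <- data.frame(snp_id = snp, chrom = annotations$chrom[hit],
                    pos = annotations$pos[hit], condition = cond,
                    n_samples = as.integer(k), mean_ratio = mean_ratio,
                    chi2 = chi2, df = as.integer(df), p = comb_p,
                    fdr = fdr, significant = as.integer(fdr <= sig_fdr),
                    stringsAsFactors = FALSE)
  res <- .order_results(res)
  structure(res, class = c("static_ase_scan", "data.frame"),
            per_sample = per_sample, null_ratio = null_ratio,
            sig_fdr = sig_fdr)
}

#' @export
print.static_ase_scan <- function(x, ...) {
  cat("SNP-wise static ASE scan:", nrow(x), "SNP x condition tests\n")
  if (nrow(x)) {
    tab <- stats::aggregate(significant ~ condition, data = x,
                            FUN = function(s) c(tested = length(s),
                                                significant = sum(s)))
    out <- data.frame(condition = tab$condition,
                      tested = tab$significant[, "tested"],
                      significant = tab$significant[, "significant"])
    cat("At FDR <=", attr(x, "sig_fdr"), ":\n")
    print(out, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.static_ase_scan <- function(object, ...) {
  print(object)
  invisible(object)
}
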