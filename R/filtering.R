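# Informative-site filtering.
#
# A heterozygous site enters the analyses for a given sample and condition
# only if its read coverage is informative: at least 30 reads in total, at
# least 3 reads for each allele, and a minor-allele contribution of at
# least 1% of the total. The 1% rule is evaluated on the minor allele only
# (the major allele satisfies it whenever the minor one does); it binds
# only at depths above 300, where 3 reads fall below 1%. All thresholds are
# inclusive. Sites on non-autosomal or unplaced sequence are dropped by
# default.

#' Read-coverage thresholds for informative sites
#'
#' @param min_total_reads minimum total read depth (default 30).
#' @param min_reads_per_allele minimum reads supporting each allele
#'   (default 3).
#' @param min_allele_fraction minimum minor-allele fraction of the total
#'   depth (default 0.01).
#' @param autosomes_only drop non-autosomal sites (default TRUE).
#' @return object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_total_reads = 30L,
                              min_reads_per_allele = 3L,
                              min_allele_fraction = 0.01,
                              autosomes_only = TRUE) {
  if (min_total_reads < 0 || min_reads_per_allele < 0)
    stop("read thresholds must be non-negative")
  if (min_allele_fraction < 0 || min_allele_fraction > 0.5)
    stop("min_allele_fraction must lie in [0, 0.5]")
  structure(list(min_total_reads = as.integer(min_total_reads),
                 min_reads_per_allele = as.integer(min_reads_per_allele),
                 min_allele_fraction = min_allele_fraction,
                 autosomes_only = isTRUE(autosomes_only)),
            class = "filter_thresholds")
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("Informative-site thresholds: total >=", x$min_total_reads,
      "| per allele >=", x$min_reads_per_allele,
      "| minor fraction >=", x$min_allele_fraction,
      if (x$autosomes_only) "| autosomes only" else "", "\n")
  invisible(x)
}

#' Does a count record pass the informative-site filter?
#'
#' Pure vectorised predicate. The minor-allele fraction rule is evaluated
#' as `min(ref, alt) >= f * (ref + alt)` to stay exact at the boundary.
#'
#' @param ref_count,alt_count allelic read counts (vectors).
#' @param is_autosomal logical vector (recycled); the record's chromosome
#'   status from the annotation.
#' @param thresholds a [filter_thresholds()] object.
#' @return logical vector.
#' @examples
#' th <- filter_thresholds()
#' passes_filter(20, 15, TRUE, th)    # TRUE
#' passes_filter(28, 2, TRUE, th)     # FALSE: allele below 3 reads
#' passes_filter(400, 3, TRUE, th)    # FALSE: 3/403 < 1%
#' @export
passes_filter <- function(ref_count, alt_count, is_autosomal = TRUE,
                          thresholds = filter_thresholds()) {
  total <- ref_count + alt_count
  minor <- pmin(ref_count, alt_count)
  total >= thresholds$min_total_reads &
    minor >= thresholds$min_reads_per_allele &
    minor >= thresholds$min_allele_fraction * total &
    (is_autosomal | !thresholds$autosomes_only)
}

#' Filter a count dataset to informative records
#'
#' Applies [passes_filter()] to every record independently (per sample and
#' condition) and reports per-condition retention summaries plus overall
#' per-rule exclusion counts (a record failing several rules is counted
#' under each).
#'
#' @param counts count data.frame (see package overview).
#' @param annotations matching annotation data.frame.
#' @param thresholds a [filter_thresholds()] object.
#' @return object of class `ase_filter_result`: list with `counts` (the
#'   surviving records), `summary` (per-condition data.frame), and
#'   `excluded_by_rule` (named integer vector).
#' @export
filter_dataset <- function(counts, annotations,
                           thresholds = filter_thresholds()) {
  hit <- match(counts$snp_id, annotations$snp_id)
  if (anyNA(hit))
    stop("count records reference unknown SNPs: ",
         paste(utils::head(unique(counts$snp_id[is.na(hit)]), 5),
               collapse = ", "))
  auto <- annotations$is_autosomal[hit]
  total <- counts$ref_count + counts$alt_count
  minor <- pmin(counts$ref_count, counts$alt_count)
  fail <- c(
    total_reads = sum(total < thresholds$min_total_reads),
    reads_per_allele = sum(minor < thresholds$min_reads_per_allele),
    allele_fraction = sum(minor < thresholds$min_allele_fraction * total),
    non_autosomal = if (thresholds$autosomes_only) sum(!auto) else 0L)
  keep <- passes_filter(counts$ref_count, counts$alt_count, auto, thresholds)
  surv <- counts[keep, , drop = FALSE]
  rownames(surv) <- NULL
  genes <- .split_genes(annotations$gene_ids[hit])
  summary <- do.call(rbind, lapply(
    sort(unique(counts$condition)), function(cond) {
      inc <- counts$condition == cond
      sv <- inc & keep
      data.frame(condition = cond,
                 n_records = sum(inc),
                 n_retained = sum(sv),
                 n_excluded = sum(inc) - sum(sv),
                 n_snps = length(unique(counts$snp_id[sv])),
                 mean_samples_per_snp =
                   if (any(sv)) sum(sv) / length(unique(counts$snp_id[sv]))
                   else 0,
                 n_genes = length(unique(unlist(genes[sv]))),
                 stringsAsFactors = FALSE)
    }))
  rownames(summary) <- NULL
  if (nrow(surv) == 0)
    warning("no records pass the informative-site filter")
  structure(list(counts = surv, summary = summary,
                 excluded_by_rule = fail, thresholds = thresholds),
            class = "ase_filter_result")
}

#' @export
print.ase_filter_result <- function(x, ...) {
  cat("Informative-site filtering:", sum(x$summary$n_retained), "of",
      sum(x$summary$n_records), "records retained\n")
  cat("Exclusions by rule (non-exclusive):",
      paste(names(x$excluded_by_rule), x$excluded_by_rule,
            sep = "=", collapse = ", "), "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
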