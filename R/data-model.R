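# Data model and file I/O.
#
# The pipeline's tabular containers are plain data.frames:
#   counts:      snp_id, sample_id, condition, ref_count, alt_count
#                (one row = one heterozygous SNP x sample x condition)
#   annotations: snp_id, chrom, pos, ref, alt, gene_ids (comma-joined,
#                possibly ""), is_autosomal
# Coordinates are 1-based (VCF convention); chromosome names are kept
# verbatim. Autosome status is decided against an explicit name list
# (default "1".."18", the Sus scrofa 11.1 autosomes); everything else —
# sex chromosomes, unplaced scaffolds — is non-autosomal.

COUNT_COLUMNS <- c("snp_id", "chrom", "pos", "ref", "alt",
                   "sample_id", "condition", "ref_count", "alt_count")

#' Default autosome name list (Sus scrofa 11.1)
#' @return character vector "1".."18".
#' @export
default_autosomes <- function() as.character(1:18)

#' Study design: samples, conditions and control-vs-treatment contrasts
#'
#' @param samples character vector of unique sample identifiers.
#' @param conditions ordered character vector of condition labels.
#' @param control the control condition label; must be one of `conditions`.
#' @param contrasts optional list of `c(control, treatment)` pairs; by
#'   default every non-control condition is contrasted against the control.
#' @return object of class `study_design`.
#' @examples
#' study_design(paste0("S", 1:20), c("C", "D", "L", "LD"), control = "C")
#' @export
study_design <- function(samples, conditions, control = conditions[1],
                         contrasts = NULL) {
  samples <- as.character(samples)
  conditions <- as.character(conditions)
  if (anyDuplicated(samples)) stop("sample identifiers must be unique")
  if (anyDuplicated(conditions)) stop("condition labels must be unique")
  if (!control %in% conditions) stop("control condition not among conditions")
  if (is.null(contrasts))
    contrasts <- lapply(setdiff(conditions, control), function(t) c(control, t))
  for (ct in contrasts) {
    if (length(ct) != 2 || ct[1] != control || !ct[2] %in% conditions)
      stop("each contrast must be c(control, treatment) with known labels")
  }
  structure(list(samples = samples, conditions = conditions,
                 control = control, contrasts = contrasts),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", length(x$samples), "samples x",
      length(x$conditions), "conditions (",
      paste(x$conditions, collapse = ", "), ")\n")
  cat("Control:", x$control, "| contrasts:",
      paste(vapply(x$contrasts, function(ct) paste(ct, collapse = " vs "),
                   ""), collapse = "; "), "\n")
  invisible(x)
}

.contrast_label <- function(ct) paste0(ct[1], "_vs_", ct[2])

.validate_annotations <- function(ann) {
  bad <- !(ann$ref %in% c("A", "C", "G", "T")) |
         !(ann$alt %in% c("A", "C", "G", "T")) | ann$ref == ann$alt
  if (any(bad))
    stop("non-biallelic-SNV annotation for: ",
         paste(utils::head(ann$snp_id[bad], 5), collapse = ", "))
  if (any(ann$pos < 1)) stop("positions must be >= 1")
  key <- paste(ann$chrom, ann$pos)
  if (anyDuplicated(key))
    stop("duplicated (chrom, pos) in annotation: ",
         paste(utils::head(key[duplicated(key)], 5), collapse = ", "))
  if (anyDuplicated(ann$snp_id)) stop("duplicated snp_id in annotation")
  invisible(ann)
}

.check_count_duplicates <- function(counts) {
  key <- paste(counts$snp_id, counts$sample_id, counts$condition, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (snp_id, sample_id, condition) records, e.g. row ",
         dup[1], ": ", gsub("\r", " / ", key[dup[1]]))
  }
  invisible(counts)
}

#' Read per-SNP allelic read counts
#'
#' Reads a count table either from the package's 9-column TSV dialect
#' (header `snp_id chrom pos ref alt sample_id condition ref_count
#' alt_count`) or from a VCF with per-sample AD-style allelic depths, where
#' the experimental condition is encoded in the sample name as
#' `sampleID.condition`. Rows violating the data model (non-integer counts,
#' invalid alleles, duplicate records) are rejected with their line numbers.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param autosomes chromosome names treated as autosomal.
#' @return list with elements `counts` and `annotations` (see package
#'   overview for the column contracts).
#' @export
read_count_table <- function(path, format = c("tsv", "vcf"),
                             autosomes = default_autosomes()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") .read_counts_tsv(path, autosomes)
  else .read_counts_vcf(path, autosomes)
}

.read_counts_tsv <- function(path, autosomes) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  missing <- setdiff(COUNT_COLUMNS, names(raw))
  if (length(missing))
    stop("count table is missing required column(s): ",
         paste(missing, collapse = ", "))
  line <- seq_len(nrow(raw)) + 1L  # account for the header line
  .assert_integer_col <- function(col) {
    bad <- !grepl("^[0-9]+$", raw[[col]])
    if (any(bad))
      stop("non-integer ", col, " at line(s) ",
           paste(utils::head(line[bad], 10), collapse = ", "))
  }
  for (col in c("pos", "ref_count", "alt_count")) .assert_integer_col(col)
  counts <- data.frame(snp_id = raw$snp_id, sample_id = raw$sample_id,
                       condition = raw$condition,
                       ref_count = as.integer(raw$ref_count),
                       alt_count = as.integer(raw$alt_count),
                       stringsAsFactors = FALSE)
  .check_count_duplicates(counts)
  ann_all <- data.frame(snp_id = raw$snp_id, chrom = raw$chrom,
                        pos = as.integer(raw$pos), ref = raw$ref,
                        alt = raw$alt, stringsAsFactors = FALSE)
  ann <- unique(ann_all)
  if (anyDuplicated(ann$snp_id)) {
    bad <- ann$snp_id[duplicated(ann$snp_id)]
    stop("inconsistent annotation across rows for snp_id: ",
         paste(utils::head(unique(bad), 5), collapse = ", "))
  }
  ann$gene_ids <- ""
  ann$is_autosomal <- ann$chrom %in% autosomes
  .validate_annotations(ann)
  list(counts = counts, annotations = ann[order(ann$chrom, ann$pos), ,
                                          drop = FALSE])
}

.read_counts_vcf <- function(path, autosomes) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  keep <- fix$REF %in% c("A", "C", "G", "T") &
          fix$ALT %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("no biallelic SNVs in VCF")
  snp_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                   paste0(fix$CHROM, "_", fix$POS), fix$ID)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT"),
                 error = function(e) NULL)
  samples <- colnames(ad)
  parts <- regmatches(samples, regexpr("\\.[^.]*$", samples))
  if (any(lengths(regmatches(samples, gregexpr("\\.", samples))) == 0))
    stop("VCF sample names must follow the sampleID.condition convention")
  sample_id <- sub("\\.[^.]*$", "", samples)
  condition <- sub("^\\.", "", parts)
  recs <- list()
  for (j in seq_along(samples)) {
    adj <- ad[keep, j]
    het <- if (is.null(gt)) rep(TRUE, sum(keep)) else
      gt[keep, j] %in% c("0/1", "1/0", "0|1", "1|0")
    ok <- het & !is.na(adj) & grepl("^[0-9]+,[0-9]+$", adj)
    if (!any(ok)) next
    sp <- strsplit(adj[ok], ",", fixed = TRUE)
    recs[[j]] <- data.frame(
      snp_id = snp_id[keep][ok], sample_id = sample_id[j],
      condition = condition[j],
      ref_count = as.integer(vapply(sp, `[`, "", 1L)),
      alt_count = as.integer(vapply(sp, `[`, "", 2L)),
      stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, recs)
  if (is.null(counts)) stop("no usable heterozygous AD records in VCF")
  .check_count_duplicates(counts)
  ann <- data.frame(snp_id = snp_id[keep], chrom = fix$CHROM[keep],
                    pos = as.integer(fix$POS[keep]), ref = fix$REF[keep],
                    alt = fix$ALT[keep], gene_ids = "",
                    is_autosomal = fix$CHROM[keep] %in% autosomes,
                    stringsAsFactors = FALSE)
  .validate_annotations(ann)
  list(counts = counts, annotations = ann[order(ann$chrom, ann$pos), ,
                                          drop = FALSE])
}

#' Attach gene assignments to SNP annotations
#'
#' @param annotations annotation data.frame from [read_count_table()].
#' @param gene_map data.frame (or TSV path) with columns `snp_id`,
#'   `gene_id`; a SNP may map to several genes (one row each).
#' @return annotations with `gene_ids` filled in (comma-joined, sorted).
#' @export
annotate_genes <- function(annotations, gene_map) {
  if (is.character(gene_map) && length(gene_map) == 1L)
    gene_map <- utils::read.delim(gene_map, colClasses = "character")
  if (!all(c("snp_id", "gene_id") %in% names(gene_map)))
    stop("gene_map needs columns snp_id and gene_id")
  joined <- vapply(split(gene_map$gene_id, gene_map$snp_id),
                   function(g) paste(sort(unique(g)), collapse = ","), "")
  hit <- match(annotations$snp_id, names(joined))
  annotations$gene_ids <- ifelse(is.na(hit), "", unname(joined[hit]))
  annotations
}

# gene list per SNP; "" -> character(0)
.split_genes <- function(gene_ids) {
  out <- strsplit(gene_ids, ",", fixed = TRUE)
  lapply(out, function(g) g[nzchar(g)])
}

#' Read a haplotype phase table
#'
#' TSV with columns `locus_id`, `snp_id`, `h1_allele` (`ref` or `alt`):
#' which of each SNP's two alleles lies on haplotype H1 (the other is
#' implied on H2).
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_phase_table <- function(path) {
  ph <- utils::read.delim(path, colClasses = "character")
  need <- c("locus_id", "snp_id", "h1_allele")
  if (!all(need %in% names(ph)))
    stop("phase table needs columns: ", paste(need, collapse = ", "))
  if (!all(ph$h1_allele %in% c("ref", "alt")))
    stop("h1_allele must be 'ref' or 'alt'")
  if (anyDuplicated(paste(ph$locus_id, ph$snp_id)))
    stop("duplicate snp within locus in phase table")
  ph
}

#' Read per-sample diplotypes
#'
#' TSV with columns `locus_id`, `sample_id`, `diplotype`
#' (`H1H1`, `H1H2` or `H2H2`).
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_diplotypes <- function(path) {
  dp <- utils::read.delim(path, colClasses = "character")
  need <- c("locus_id", "sample_id", "diplotype")
  if (!all(need %in% names(dp)))
    stop("diplotype table needs columns: ", paste(need, collapse = ", "))
  if (!all(dp$diplotype %in% c("H1H1", "H1H2", "H2H2")))
    stop("diplotype must be H1H1, H1H2 or H2H2")
  dp
}

# canonical row order shared by the scans and write_results()
.order_results <- function(results) {
  ordcols <- intersect(c("chrom", "pos", "condition", "contrast", "locus_id",
                         "gene_id", "snp_id", "sample_id"), names(results))
  if (length(ordcols))
    results <- results[do.call(order, results[ordcols]), , drop = FALSE]
  rownames(results) <- NULL
  results
}

# column-type registry used when result TSVs are read back
.RESULT_INT_COLS <- c("pos", "n_samples", "n_sig_samples", "df", "n_snps",
                      "n_obs", "n_pairs", "significant", "ge3_samples_flag",
                      "degenerate", "ref_count", "alt_count", "h1_reads",
                      "h2_reads")
.RESULT_NUM_COLS <- c("mean_ratio", "delta_ratio", "chi2", "p", "fdr",
                      "statistic", "empirical_p", "mean_control",
                      "mean_treatment", "mean_diff", "p_raw", "p_bonferroni",
                      "ratio")

#' Write a result table deterministically
#'
#' Writes any of the pipeline's result data.frames as TSV with a stable row
#' order (by `chrom`/`pos` and contrast or condition when those columns
#' exist, otherwise by the leading identifier columns) and floating-point
#' values rendered with 17 significant digits, so repeated writes of the
#' same results are byte-identical and values survive a read/write round
#' trip exactly.
#'
#' @param results data.frame; if an `fdr` column exists it must be fully
#'   populated (results finalized).
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_results <- function(results, path) {
  results <- as.data.frame(results)
  if ("fdr" %in% names(results) && anyNA(results$fdr))
    stop("results are not finalized: fdr column contains NA")
  results <- .order_results(results)
  out <- results
  for (cn in names(out)) {
    if (is.double(out[[cn]]))
      out[[cn]] <- sprintf("%.17g", out[[cn]])
    if (is.logical(out[[cn]]))
      out[[cn]] <- as.integer(out[[cn]])
  }
  con <- file(path, open = "wb")  # binary mode: fixed "\n" on any platform
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read back a result table written by [write_results()]
#' @param path TSV path.
#' @return data.frame with numeric/integer columns restored by name.
#' @export
read_results <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  for (cn in names(raw)) {
    if (cn %in% .RESULT_INT_COLS) raw[[cn]] <- as.integer(raw[[cn]])
    else if (cn %in% .RESULT_NUM_COLS) raw[[cn]] <- as.numeric(raw[[cn]])
  }
  raw
}
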