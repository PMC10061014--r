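# Gene-wise ASE via meta-analytic combination with a resampling null.
#
# Observations are SNP x sample pairs within a gene. Each observation's
# exact two-sided p-value (binomial within a condition; Fisher exact
# between conditions) is converted to a non-negative z-score and the
# z-scores are pooled by a depth-weighted Stouffer sum
# S = sum(w z) / sqrt(sum(w^2)). Significance comes from an empirical null
# obtained by redrawing every observation under its null distribution with
# depths/margins held fixed (Binomial(depth, 0.5) within condition; the
# hypergeometric with the observed margins between conditions) and
# recomputing S; the empirical p-value uses the add-one rule so it can
# never be zero. Only genes covered by at least two informative SNPs that
# map to that single gene are tested.

#' Configuration of the gene-wise ASE scan
#'
#' @param min_snps_per_gene minimum distinct informative SNPs a gene needs
#'   to be tested (default 2).
#' @param n_resamples size of the resampling null (default 10000).
#' @param seed integer seed from which all of the scan's randomness derives.
#' @param weight_scheme `"sqrt_depth"` (weight each observation by the
#'   square root of its total read depth) or `"equal"`.
#' @return object of class `gene_ase_config`.
#' @export
gene_ase_config <- function(min_snps_per_gene = 2L, n_resamples = 10000L,
                            seed = 1L,
                            weight_scheme = c("sqrt_depth", "equal")) {
  weight_scheme <- match.arg(weight_scheme)
  if (min_snps_per_gene < 2) stop("min_snps_per_gene must be >= 2")
  if (n_resamples < 100) stop("n_resamples must be >= 100")
  structure(list(min_snps_per_gene = as.integer(min_snps_per_gene),
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed), weight_scheme = weight_scheme),
            class = "gene_ase_config")
}

.obs_weights <- function(total_depth, scheme) {
  if (scheme == "sqrt_depth") sqrt(total_depth) else rep(1, length(total_depth))
}

# Null S draws for static-mode observations (depths fixed, ref redrawn
# from Binomial(depth, null_ratio)).
.static_null_S <- function(depths, weights, n_resamples, null_ratio = 0.5,
                           p_floor = 1e-300) {
  zmat <- matrix(0, n_resamples, length(depths))
  for (j in seq_along(depths)) {
    zt <- .binom_z_table(depths[j], null_ratio, p_floor)
    zmat[, j] <- zt[stats::rbinom(n_resamples, depths[j], null_ratio) + 1L]
  }
  as.numeric(zmat %*% weights) / sqrt(sum(weights^2))
}

# Null S draws for conditional-mode observations (2x2 margins fixed, table
# redrawn from the hypergeometric).
.cond_null_S <- function(a, b, c, d, weights, n_resamples,
                         p_floor = 1e-300) {
  zmat <- matrix(0, n_resamples, length(a))
  for (j in seq_along(a)) {
    m <- a[j] + c[j]; nn <- b[j] + d[j]; k <- a[j] + b[j]
    tp <- .fisher_p_table(m, nn, k)
    zt <- stats::qnorm(pmax(tp$p, p_floor) / 2, lower.tail = FALSE)
    zmat[, j] <- zt[stats::rhyper(n_resamples, m, nn, k) - tp$lo + 1L]
  }
  as.numeric(zmat %*% weights) / sqrt(sum(weights^2))
}

#' Empirical null distribution of a gene's meta-analytic statistic
#'
#' Redraws every observation of one gene under its null distribution
#' (depths and margins held fixed) and recomputes the Stouffer statistic,
#' `config$n_resamples` times.
#'
#' @param obs data.frame of the gene's observations. Static mode: columns
#'   `ref_count`, `alt_count`. Conditional mode: columns
#'   `ref_count_control`, `alt_count_control`, `ref_count_treatment`,
#'   `alt_count_treatment`.
#' @param config a [gene_ase_config()]; its seed is applied before drawing,
#'   making the distribution reproducible.
#' @param mode `"static"` or `"conditional"`.
#' @param null_ratio balanced null reference fraction (static mode).
#' @param p_floor p-value floor before z conversion.
#' @return numeric vector of `n_resamples` null statistics.
#' @export
resample_null <- function(obs, config = gene_ase_config(),
                          mode = c("static", "conditional"),
                          null_ratio = 0.5, p_floor = 1e-300) {
  mode <- match.arg(mode)
  set.seed(config$seed)
  if (mode == "static") {
    depths <- obs$ref_count + obs$alt_count
    w <- .obs_weights(depths, config$weight_scheme)
    .static_null_S(depths, w, config$n_resamples, null_ratio, p_floor)
  } else {
    tot <- obs$ref_count_control + obs$alt_count_control +
      obs$ref_count_treatment + obs$alt_count_treatment
    w <- .obs_weights(tot, config$weight_scheme)
    .cond_null_S(obs$ref_count_control, obs$alt_count_control,
                 obs$ref_count_treatment, obs$alt_count_treatment,
                 w, config$n_resamples, p_floor)
  }
}

#' Gene-wise ASE scan (static or condition-dependent)
#'
#' Static mode tests, per condition, whether a gene's allelic counts
#' deviate from balanced expression; conditional mode tests, per contrast,
#' whether the allelic ratio changes between control and treatment.
#' Conditional mode is restricted to genes showing static ASE at >= 1 SNP
#' in >= 1 condition (pass the static scan, or override with
#' `candidate_genes`). SNPs that do not map to exactly one gene are
#' excluded up front. BH adjustment is across genes, per condition or
#' contrast.
#'
#' @param counts filtered count data.frame.
#' @param annotations annotation data.frame with `gene_ids` populated
#'   (see [annotate_genes()]).
#' @param design a [study_design()] (required for conditional mode).
#' @param config a [gene_ase_config()].
#' @param mode `"static"` or `"conditional"`.
#' @param static a [scan_static_ase()] result (conditional mode
#'   preselection).
#' @param candidate_genes explicit gene preselection overriding `static`.
#' @param conditions conditions to scan in static mode (default: all).
#' @param sig_fdr FDR threshold for the `significant` column.
#' @param null_ratio balanced null reference fraction.
#' @param p_floor p-value floor.
#' @return data.frame of class `gene_ase_scan` with columns `gene_id`,
#'   `mode`, `condition` (static) or `contrast` (conditional), `n_snps`,
#'   `n_obs`, `statistic`, `empirical_p`, `fdr`, `significant` (0/1).
#'   Per-sample gene statistics (diagnostics) are in
#'   `attr(, "per_sample")`; skipped-gene counts in `attr(, "n_skipped")`.
#' @export
scan_gene_ase <- function(counts, annotations, design = NULL,
                          config = gene_ase_config(),
                          mode = c("static", "conditional"),
                          static = NULL, candidate_genes = NULL,
                          conditions = NULL, sig_fdr = 0.05,
                          null_ratio = 0.5, p_floor = 1e-300) {
  mode <- match.arg(mode)
  genes_per_snp <- .split_genes(annotations$gene_ids)
  uniq <- lengths(genes_per_snp) == 1L
  gene_of <- rep(NA_character_, nrow(annotations))
  gene_of[uniq] <- unlist(genes_per_snp[uniq])
  counts$gene_id <- gene_of[match(counts$snp_id, annotations$snp_id)]
  n_multi <- sum(!is.na(match(unique(counts$snp_id),
                              annotations$snp_id[!uniq])))
  if (n_multi > 0)
    message(n_multi, " SNP(s) without a unique gene assignment excluded")
  counts <- counts[!is.na(counts$gene_id), , drop = FALSE]
  counts <- counts[order(counts$gene_id, counts$snp_id,
                         counts$sample_id), , drop = FALSE]
  if (mode == "conditional") {
    if (is.null(design)) stop("conditional mode requires a study design")
    if (is.null(candidate_genes)) {
      if (is.null(static))
        stop("conditional mode requires a static scan result or candidate_genes")
      sig_snps <- unique(static$snp_id[static$significant == 1L])
      candidate_genes <- unique(
        counts$gene_id[counts$snp_id %in% sig_snps])
    }
    counts <- counts[counts$gene_id %in% candidate_genes, , drop = FALSE]
  }
  units <- if (mode == "static") {
    if (is.null(conditions)) conditions <- sort(unique(counts$condition))
    conditions
  } else vapply(design$contrasts, .contrast_label, "")
  res_list <- list()
  ps_list <- list()
  n_skipped <- 0L
  for (ui in seq_along(units)) {
    unit <- units[ui]
    obs <- if (mode == "static") {
      counts[counts$condition == unit, , drop = FALSE]
    } else {
      ct <- design$contrasts[[ui]]
      ctl <- counts[counts$condition == ct[1], , drop = FALSE]
      trt <- counts[counts$condition == ct[2], , drop = FALSE]
      m <- merge(ctl[c("gene_id", "snp_id", "sample_id", "ref_count",
                       "alt_count")],
                 trt[c("snp_id", "sample_id", "ref_count", "alt_count")],
                 by = c("snp_id", "sample_id"),
                 suffixes = c("_control", "_treatment"))
      m[order(m$gene_id, m$snp_id, m$sample_id), , drop = FALSE]
    }
    if (nrow(obs) == 0) next
    set.seed((config$seed + 7919L * ui) %% .Machine$integer.max)
    by_gene <- split(seq_len(nrow(obs)), obs$gene_id)
    for (g in names(by_gene)) {
      idx <- by_gene[[g]]
      gobs <- obs[idx, , drop = FALSE]
      n_snps <- length(unique(gobs$snp_id))
      if (n_snps < config$min_snps_per_gene) {
        n_skipped <- n_skipped + 1L
        next
      }
      if (mode == "static") {
        depths <- gobs$ref_count + gobs$alt_count
        p_obs <- binomial_ase_p(gobs$ref_count, gobs$alt_count, null_ratio)
        w <- .obs_weights(depths, config$weight_scheme)
        z <- stats::qnorm(pmax(p_obs, p_floor) / 2, lower.tail = FALSE)
        s_obs <- gene_statistic(z, w)
        s_null <- .static_null_S(depths, w, config$n_resamples,
                                 null_ratio, p_floor)
      } else {
        tot <- gobs$ref_count_control + gobs$alt_count_control +
          gobs$ref_count_treatment + gobs$alt_count_treatment
        p_obs <- .fisher_p_vec(gobs$ref_count_control,
                               gobs$alt_count_control,
                               gobs$ref_count_treatment,
                               gobs$alt_count_treatment)
        w <- .obs_weights(tot, config$weight_scheme)
        z <- stats::qnorm(pmax(p_obs, p_floor) / 2, lower.tail = FALSE)
        s_obs <- gene_statistic(z, w)
        s_null <- .cond_null_S(gobs$ref_count_control,
                               gobs$alt_count_control,
                               gobs$ref_count_treatment,
                               gobs$alt_count_treatment,
                               w, config$n_resamples, p_floor)
      }
      emp_p <- (1 + sum(s_null >= s_obs)) / (config$n_resamples + 1)
      res_list[[paste(unit, g, sep = "\r")]] <- data.frame(
        gene_id = g, mode = mode, unit = unit, n_snps = n_snps,
        n_obs = nrow(gobs), statistic = s_obs, empirical_p = emp_p,
        stringsAsFactors = FALSE)
      samp_S <- vapply(split(seq_along(z), gobs$sample_id),
                       function(i) gene_statistic(z[i], w[i]), 0)
      ps_list[[paste(unit, g, sep = "\r")]] <- data.frame(
        gene_id = g, unit = unit, sample_id = names(samp_S),
        statistic = unname(samp_S), stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0)
    message(n_skipped, " gene x ", if (mode == "static") "condition"
            else "contrast", " unit(s) below min_snps_per_gene skipped")
  unit_col <- if (mode == "static") "condition" else "contrast"
  if (length(res_list) == 0) {
    warning("no genes eligible for the gene-wise ", mode, " scan")
    res <- data.frame(gene_id = character(), mode = character(),
                      unit = character(), n_snps = integer(),
                      n_obs = integer(), statistic = numeric(),
                      empirical_p = numeric(), fdr = numeric(),
                      significant = integer(), stringsAsFactors = FALSE)
    names(res)[names(res) == "unit"] <- unit_col
    return(structure(res, class = c("gene_ase_scan", "data.frame"),
                     per_sample = NULL, n_skipped = n_skipped,
                     config = config, sig_fdr = sig_fdr))
  }
  res <- do.call(rbind, res_list)
  res$fdr <- stats::ave(res$empirical_p, res$unit, FUN = adjust_bh)
  res$significant <- as.integer(res$fdr <= sig_fdr)
  names(res)[names(res) == "unit"] <- unit_col
  res <- .order_results(res)
  structure(res, class = c("gene_ase_scan", "data.frame"),
            per_sample = if (length(ps_list)) do.call(rbind, ps_list)
                         else NULL,
            n_skipped = n_skipped, config = config, sig_fdr = sig_fdr)
}

#' @export
print.gene_ase_scan <- function(x, ...) {
  unit_col <- if ("condition" %in% names(x)) "condition" else "contrast"
  cat("Gene-wise ASE scan (", if (nrow(x)) x$mode[1] else "empty",
      " mode): ", nrow(x), " gene x ", unit_col, " tests\n", sep = "")
  if (nrow(x)) {
    for (u in unique(x[[unit_col]])) {
      sub <- x[x[[unit_col]] == u, ]
      cat(sprintf("  %s: %d tested, %d significant (FDR <= %g)\n",
                  u, nrow(sub), sum(sub$significant), attr(x, "sig_fdr")))
    }
  }
  invisible(x)
}
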