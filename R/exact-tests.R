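# Exact per-sample tests and p-value combination.
#
# Both exact tests use the minimum-likelihood definition of two-sidedness:
# the p-value is the total null probability of all outcomes whose point
# probability does not exceed that of the observed outcome (relative tie
# tolerance 1e-7). Probability tables are computed once per depth / margin
# set and cached, because the gene-level resampling null evaluates these
# tests millions of times per scan.

.TIE_REL_TOL <- 1e-7

.cdase_cache <- new.env(parent = emptyenv())

# Two-sided minimum-likelihood p-value for every k = 0..n under
# Binomial(n, p0). Returns a numeric vector of length n + 1.
.binom_p_table <- function(n, null_ratio = 0.5) {
  key <- paste0("b", n, "_", format(null_ratio, digits = 17))
  tab <- .cdase_cache[[key]]
  if (!is.null(tab)) return(tab)
  d <- stats::dbinom(0:n, n, null_ratio)
  ord <- order(d)
  ds <- d[ord]
  cs <- cumsum(ds)
  p <- pmin(cs[findInterval(d * (1 + .TIE_REL_TOL), ds)], 1)
  .cdase_cache[[key]] <- p
  p
}

# z-score table matching .binom_p_table (z = upper-tail normal quantile of p/2).
.binom_z_table <- function(n, null_ratio = 0.5, p_floor = 1e-300) {
  key <- paste0("z", n, "_", format(null_ratio, digits = 17), "_", p_floor)
  tab <- .cdase_cache[[key]]
  if (!is.null(tab)) return(tab)
  tab <- stats::qnorm(pmax(.binom_p_table(n, null_ratio), p_floor) / 2,
                      lower.tail = FALSE)
  .cdase_cache[[key]] <- tab
  tab
}

# Fisher exact p-values over the full support of a 2x2 table with fixed
# margins. m = total reference reads (column 1 sum), nn = total alternative
# reads (column 2 sum), k = row 1 total (first condition's depth). Returns
# list(lo, x, p, prob): support, p-value and point probability per value of
# the top-left cell.
.fisher_p_table <- function(m, nn, k) {
  lo <- max(0L, k - nn)
  hi <- min(k, m)
  x <- lo:hi
  d <- stats::dhyper(x, m, nn, k)
  ord <- order(d)
  ds <- d[ord]
  cs <- cumsum(ds)
  p <- pmin(cs[findInterval(d * (1 + .TIE_REL_TOL), ds)], 1)
  list(lo = lo, x = x, p = p, prob = d)
}

#' Exact two-sided binomial test for allelic imbalance
#'
#' Computes, for each pair of allelic read counts, the exact two-sided
#' p-value under \eqn{X \sim \mathrm{Binomial}(n = ref + alt, p)} with
#' \eqn{p} = `null_ratio`. The default two-sided convention is the
#' minimum-likelihood rule (sum of the probabilities of all outcomes no more
#' probable than the observed one), the convention used by
#' [stats::binom.test()]; `method = "double_tail"` instead doubles the
#' smaller one-sided tail (capped at 1), for sensitivity analysis.
#'
#' @param ref_count,alt_count non-negative integer vectors of reference and
#'   alternative allele read counts (recycled to common length).
#' @param null_ratio expected reference-allele fraction under the null
#'   hypothesis of balanced expression; default 0.5.
#' @param method two-sided p-value convention; see Details.
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' binomial_ase_p(15, 15)        # balanced: p = 1
#' binomial_ase_p(0, 30)         # monoallelic at depth 30
#' binomial_ase_p(c(20, 28), c(15, 2))
#' @export
binomial_ase_p <- function(ref_count, alt_count, null_ratio = 0.5,
                           method = c("minlik", "double_tail")) {
  method <- match.arg(method)
  nmax <- max(length(ref_count), length(alt_count))
  ref_count <- rep_len(as.numeric(ref_count), nmax)
  alt_count <- rep_len(as.numeric(alt_count), nmax)
  if (any(is.na(ref_count)) || any(is.na(alt_count)) ||
      any(ref_count < 0) || any(alt_count < 0) ||
      any(ref_count != floor(ref_count)) || any(alt_count != floor(alt_count)))
    stop("ref_count and alt_count must be non-negative integers")
  n <- ref_count + alt_count
  if (any(n < 1)) stop("ref_count + alt_count must be >= 1")
  if (length(null_ratio) != 1L || null_ratio <= 0 || null_ratio >= 1)
    stop("null_ratio must be a single value in (0, 1)")
  if (method == "double_tail") {
    lo <- stats::pbinom(ref_count, n, null_ratio)
    hi <- stats::pbinom(ref_count - 1, n, null_ratio, lower.tail = FALSE)
    return(pmin(1, 2 * pmin(lo, hi)))
  }
  out <- numeric(nmax)
  for (un in unique(n)) {
    sel <- n == un
    out[sel] <- .binom_p_table(un, null_ratio)[ref_count[sel] + 1L]
  }
  out
}

#' Fisher exact test on a 2x2 allelic count table
#'
#' Exact two-sided p-value for a 2x2 contingency table of allelic read
#' counts (rows = conditions, columns = ref/alt alleles), by enumeration of
#' all tables with the observed margins and summation of hypergeometric
#' probabilities not exceeding that of the observed table (relative tie
#' tolerance 1e-7) — the convention of [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative integer counts; both row sums
#'   (per-condition depths) must be positive.
#' @return single two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
#' fisher_exact_2x2(rbind(c(40, 60), c(70, 30)))
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("table must be 2x2")
  if (any(is.na(table)) || any(table < 0) || any(table != floor(table)))
    stop("table must contain non-negative integer counts")
  if (any(rowSums(table) == 0))
    stop("both row sums must be positive (sample not informative in one condition)")
  .fisher_p_one(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
}

# scalar workhorse shared with the scans (no validation)
.fisher_p_one <- function(a, b, c, d) {
  tp <- .fisher_p_table(a + c, b + d, a + b)
  tp$p[a - tp$lo + 1L]
}

# vectorised over table rows
.fisher_p_vec <- function(a, b, c, d) {
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- .fisher_p_one(a[i], b[i], c[i], d[i])
  out
}

#' Combine independent p-values by Fisher's method
#'
#' Computes \eqn{\chi^2 = -2 \sum_i \log p_i}, which is chi-square
#' distributed with \eqn{2k} degrees of freedom when the \eqn{k} p-values
#' are independent and uniform under the null. P-values of exactly zero are
#' clamped to `p_floor` (with a warning) before taking logs.
#'
#' @param p_values non-empty numeric vector of p-values in \[0, 1\].
#' @param p_floor positive clamp applied to zero p-values; default 1e-300.
#' @return list with elements `chi2`, `df` (= 2k) and `p` (upper-tail
#'   chi-square probability).
#' @examples
#' fisher_combine(c(0.05, 0.05))
#' @export
fisher_combine <- function(p_values, p_floor = 1e-300) {
  if (length(p_values) == 0) stop("p_values must be non-empty")
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p_values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warning("p-values of exactly 0 clamped to ", p_floor)
    p_values <- pmax(p_values, p_floor)
  }
  chi2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjusted p-values, in input order. A thin
#' wrapper around [stats::p.adjust()] with `method = "BH"` so the adjustment
#' convention is fixed at one place in the pipeline.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
adjust_bh <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Per-observation effect z-score for gene-level meta-analysis
#'
#' Converts one SNP-sample observation into a non-negative z-score
#' \eqn{z = \Phi^{-1}(1 - p/2)} where \eqn{p} is the exact two-sided
#' p-value: binomial (static mode, from a ref/alt count pair) or Fisher
#' exact (conditional mode, from a 2x2 table). The p-value is floored at
#' `p_floor` before inversion.
#'
#' @param ref_count,alt_count allelic counts for the static (within
#'   condition) observation; ignored when `table` is given.
#' @param table 2x2 count table for the conditional (between conditions)
#'   observation.
#' @param null_ratio binomial null reference fraction (static mode).
#' @param p_floor p-value floor applied before quantile inversion.
#' @return non-negative z-score (0 when p = 1).
#' @examples
#' snp_effect_z(15, 15)                       # balanced: z = 0
#' snp_effect_z(0, 30)                        # strong imbalance
#' snp_effect_z(table = rbind(c(5, 5), c(5, 5)))
#' @export
snp_effect_z <- function(ref_count = NULL, alt_count = NULL, table = NULL,
                         null_ratio = 0.5, p_floor = 1e-300) {
  p <- if (!is.null(table)) fisher_exact_2x2(table)
       else binomial_ase_p(ref_count, alt_count, null_ratio)
  stats::qnorm(pmax(p, p_floor) / 2, lower.tail = FALSE)
}

#' Weighted Stouffer combination of SNP-wise effects within a gene
#'
#' Meta-analytic gene statistic \eqn{S = \sum_i w_i z_i / \sqrt{\sum_i
#' w_i^2}}. With `weights = NULL` all observations weigh equally; the gene
#' scan uses the square root of each observation's total read depth.
#'
#' @param z numeric vector of per-observation z-scores.
#' @param weights optional non-negative weights, same length as `z`.
#' @return the scalar statistic S.
#' @examples
#' gene_statistic(c(2, 2))   # = 4 / sqrt(2)
#' @export
gene_statistic <- function(z, weights = NULL) {
  if (length(z) == 0) stop("z must be non-empty")
  if (is.null(weights)) weights <- rep(1, length(z))
  if (length(weights) != length(z)) stop("weights must match z in length")
  if (any(weights < 0)) stop("weights must be non-negative")
  denom <- sqrt(sum(weights^2))
  if (denom == 0) stop("all weights are zero")
  sum(weights * z) / denom
}
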