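# Independent oracles used across the suite. These deliberately take
# different routes than the package internals: stats::binom.test /
# stats::fisher.test for exact p-values, choose()-based direct enumeration
# for tail sums, and the textbook step-up rule for BH rejection sets.

oracle_binom_p <- function(ref, alt, p0 = 0.5) {
  stats::binom.test(ref, ref + alt, p = p0)$p.value
}

oracle_fisher_p <- function(tab) stats::fisher.test(tab)$p.value

# Two-sided minimum-likelihood p for every table with margins
# (row1 = r1, row2 = r2, column1 = c1), by direct enumeration with
# binomial-coefficient probabilities. Returns p indexed by the top-left
# cell over its support.
oracle_fisher_table <- function(r1, r2, c1) {
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  a <- lo:hi
  prob <- choose(r1, a) * choose(r2, c1 - a) / choose(r1 + r2, c1)
  le <- outer(prob, prob * (1 + 1e-7), "<=")
  pmin(colSums(prob * le), 1)
}

# Same enumeration route for the binomial: p over k = 0..n.
oracle_binom_table <- function(n, p0 = 0.5) {
  k <- 0:n
  prob <- choose(n, k) * p0^k * (1 - p0)^(n - k)
  le <- outer(prob, prob * (1 + 1e-7), "<=")
  pmin(colSums(prob * le), 1)
}

# Textbook BH step-up: indices rejected at level alpha.
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= alpha * seq_len(m) / m)
  if (length(below) == 0) return(integer(0))
  sort(ord[seq_len(max(below))])
}

# Chi-square upper tail at even df = 2k in closed form:
# exp(-x/2) * sum_{j<k} (x/2)^j / j!
oracle_chisq_surv_even <- function(x, k) {
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}
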