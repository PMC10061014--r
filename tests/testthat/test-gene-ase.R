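# two-SNP gene fixture: counts for `n_samples` at given true ratios
two_snp_gene_counts <- function(n_samples, depth, ratio, seed) {
  set.seed(seed)
  expand <- expand.grid(snp_id = c("rs1", "rs2"),
                        sample_id = sprintf("S%02d", seq_len(n_samples)),
                        stringsAsFactors = FALSE)
  ref <- rbinom(nrow(expand), depth, ratio)
  make_counts(expand$snp_id, expand$sample_id, "C", ref, depth - ref)
}

test_that("the resampling null is reproducible and matches a bigger independent run", {
  obs <- make_counts(c("rs1", "rs2"), "S01", "C", c(60, 45), c(40, 55))
  cfg <- gene_ase_config(n_resamples = 10000, seed = 123)
  s1 <- resample_null(obs, cfg, mode = "static")
  s2 <- resample_null(obs, cfg, mode = "static")
  expect_identical(s1, s2)
  expect_length(s1, 10000L)
  # independent oracle: z-table from stats::binom.test, own draws
  set.seed(321)
  zt <- vapply(0:100, function(k) {
    p <- stats::binom.test(k, 100, 0.5)$p.value
    qnorm(p / 2, lower.tail = FALSE)
  }, 0)
  w <- sqrt(c(100, 100))
  draws <- matrix(zt[rbinom(2 * 100000, 100, 0.5) + 1L], ncol = 2)
  s_oracle <- as.numeric(draws %*% w) / sqrt(sum(w^2))
  expect_lt(abs(quantile(s1, 0.95) - quantile(s_oracle, 0.95)), 0.1)
  expect_lt(abs(mean(s1) - mean(s_oracle)), 0.03)
})

test_that("the conditional resampling null preserves the table margins", {
  obs <- data.frame(ref_count_control = c(40, 10),
                    alt_count_control = c(60, 90),
                    ref_count_treatment = c(70, 30),
                    alt_count_treatment = c(30, 70))
  cfg <- gene_ase_config(n_resamples = 2000, seed = 9)
  s <- resample_null(obs, cfg, mode = "conditional")
  expect_length(s, 2000L)
  expect_identical(s, resample_null(obs, cfg, mode = "conditional"))
  expect_true(all(is.finite(s)))
})

test_that("degenerate depth-1 observations do not crash the resampler", {
  obs <- make_counts(c("rs1", "rs2"), "S01", "C", c(1, 0), c(0, 1))
  s <- resample_null(obs, gene_ase_config(n_resamples = 500, seed = 2),
                     mode = "static")
  # at depth 1 every outcome has p = 1, z = 0: one support point, no crash
  expect_lte(length(unique(s)), 2L)
  expect_true(all(is.finite(s)))
})

test_that("a perfectly balanced gene gets empirical p near 1 and is never zero", {
  ann <- make_annotations(c("rs1", "rs2"), gene_ids = "G1")
  counts <- rbind(
    make_counts("rs1", c("S01", "S02"), "C", 50, 50),
    make_counts("rs2", c("S01", "S02"), "C", 50, 50))
  res <- scan_gene_ase(counts, ann,
                       config = gene_ase_config(n_resamples = 500,
                                                seed = 3))
  expect_equal(res$empirical_p, 1)  # S_obs = 0, every null draw >= 0
  expect_equal(res$n_snps, 2L)
  expect_equal(res$n_obs, 4L)
})

test_that("a coherent 3-SNP imbalanced gene is strongly significant", {
  set.seed(33)
  ann <- make_annotations(c("rs1", "rs2", "rs3"), gene_ids = "G1")
  expand <- expand.grid(snp_id = c("rs1", "rs2", "rs3"),
                        sample_id = sprintf("S%02d", 1:5),
                        stringsAsFactors = FALSE)
  ref <- rbinom(nrow(expand), 100, 0.7)
  counts <- make_counts(expand$snp_id, expand$sample_id, "C", ref,
                        100 - ref)
  res <- scan_gene_ase(counts, ann,
                       config = gene_ase_config(n_resamples = 1000,
                                                seed = 4))
  expect_lte(res$empirical_p, 0.01)
  expect_gte(res$empirical_p, 1 / 1001)
})

test_that("genes below the SNP minimum and non-unique-gene SNPs are excluded", {
  ann <- make_annotations(c("rs1", "rs2", "rs3", "rs4"),
                          gene_ids = c("G1", "G1,G2", "G3", ""))
  counts <- rbind(
    make_counts(c("rs1", "rs2", "rs3", "rs4"), "S01", "C", 80, 20),
    make_counts(c("rs1", "rs2", "rs3", "rs4"), "S02", "C", 80, 20))
  # rs2 maps to two genes, rs4 to none -> G1 and G3 each have 1 usable SNP
  expect_message(
    expect_warning(
      res <- scan_gene_ase(counts, ann,
                           config = gene_ase_config(n_resamples = 200,
                                                    seed = 5)),
      "no genes eligible"),
    "without a unique gene")
  expect_equal(nrow(res), 0L)
})

test_that("conditional mode only tests genes preselected by static ASE", {
  sim <- simulate_counts(simulation_config(
    n_snps = 200, n_genes = 40, n_samples = 6, conditions = c("C", "L"),
    class_proportions = c(null = 0.6, static_ase = 0.2, cd_ase = 0.2),
    seed = 44))
  filt <- filter_dataset(sim$counts, sim$annotations)$counts
  st <- scan_static_ase(filt, sim$annotations)
  res <- scan_gene_ase(filt, sim$annotations, design = sim$design,
                       config = gene_ase_config(n_resamples = 300,
                                                seed = 6),
                       mode = "conditional", static = st)
  sig_snps <- st$snp_id[st$significant == 1L]
  genes_per_snp <- strsplit(sim$annotations$gene_ids, ",")
  uniq <- lengths(genes_per_snp) == 1
  sig_genes <- unique(unlist(
    genes_per_snp[uniq & sim$annotations$snp_id %in% sig_snps]))
  expect_true(all(res$gene_id %in% sig_genes))
  expect_true("contrast" %in% names(res))
  expect_true(all(res$empirical_p >= 1 / 301))
})

test_that("a fixed seed makes the whole gene scan bit-reproducible", {
  counts <- two_snp_gene_counts(4, 80, 0.6, seed = 55)
  ann <- make_annotations(c("rs1", "rs2"), gene_ids = "G1")
  cfg <- gene_ase_config(n_resamples = 400, seed = 77)
  a <- scan_gene_ase(counts, ann, config = cfg)
  b <- scan_gene_ase(counts, ann, config = cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # and is invariant to input row order
  c_ <- scan_gene_ase(counts[rev(seq_len(nrow(counts))), ], ann,
                      config = cfg)
  expect_identical(as.data.frame(a), as.data.frame(c_))
})

test_that("configuration bounds are enforced", {
  expect_error(gene_ase_config(min_snps_per_gene = 1), ">= 2")
  expect_error(gene_ase_config(n_resamples = 50), ">= 100")
})
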