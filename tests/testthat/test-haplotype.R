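phase_two_snps <- data.frame(locus_id = "LOC1", snp_id = c("rs1", "rs2"),
                             h1_allele = c("ref", "ref"),
                             stringsAsFactors = FALSE)

test_that("haplotype ratios pool phased allele counts correctly", {
  rec <- make_counts(c("rs1", "rs2"), "S01", "C", c(30, 50), c(10, 30))
  hr <- haplotype_ratio(rec, phase_two_snps)
  expect_equal(hr$h1_reads, 80)
  expect_equal(hr$h2_reads, 40)
  expect_equal(hr$ratio, 2 / 3, tolerance = 1e-12)
  # alt on H1 flips the mapping
  ph <- data.frame(locus_id = "LOC1", snp_id = "rs1", h1_allele = "alt")
  hr2 <- haplotype_ratio(make_counts("rs1", "S01", "C", 10, 30), ph)
  expect_equal(hr2$ratio, 0.75)
  # balanced counts at every SNP give 0.5
  bal <- make_counts(c("rs1", "rs2"), "S01", "C", c(20, 40), c(20, 40))
  expect_equal(haplotype_ratio(bal, phase_two_snps)$ratio, 0.5)
})

test_that("a single phased SNP reduces to its allelic ratio and sums are order-invariant", {
  rec <- make_counts("rs1", "S01", "C", 30, 10)
  expect_equal(haplotype_ratio(rec, phase_two_snps)$ratio, 0.75)
  rec2 <- make_counts(c("rs1", "rs2"), "S01", "C", c(30, 50), c(10, 30))
  expect_equal(haplotype_ratio(rec2[2:1, ], phase_two_snps),
               haplotype_ratio(rec2, phase_two_snps))
})

test_that("homozygous samples and unphased SNPs are handled per contract", {
  rec <- make_counts("rs1", "S01", "C", 30, 10)
  expect_error(haplotype_ratio(rec, phase_two_snps, diplotype = "H1H1"),
               "not informative")
  rec3 <- make_counts(c("rs1", "rs9"), "S01", "C", c(30, 99), c(10, 1))
  expect_warning(hr <- haplotype_ratio(rec3, phase_two_snps), "rs9")
  expect_equal(hr$ratio, 0.75)  # rs9 skipped
  expect_error(suppressWarnings(
    haplotype_ratio(make_counts("rs9", "S01", "C", 5, 5),
                    phase_two_snps)), "no phased SNP")
})

test_that("dataset-level ratios respect diplotypes and swap symmetry", {
  counts <- rbind(
    make_counts(c("rs1", "rs2"), "S01", "C", c(30, 50), c(10, 30)),
    make_counts(c("rs1", "rs2"), "S01", "L", c(20, 20), c(20, 20)),
    make_counts(c("rs1", "rs2"), "S02", "C", c(40, 40), c(40, 40)))
  dipl <- data.frame(locus_id = "LOC1", sample_id = c("S01", "S02"),
                     diplotype = c("H1H2", "H1H1"))
  hr <- haplotype_ratios(counts, phase_two_snps, dipl)
  expect_equal(sort(unique(hr$sample_id)), "S01")  # S02 not heterozygous
  expect_equal(hr$ratio[hr$condition == "C"], 2 / 3, tolerance = 1e-12)
  # swapping the H1/H2 labels maps every ratio r -> 1 - r
  flipped <- phase_two_snps
  flipped$h1_allele <- c("alt", "alt")
  hr2 <- haplotype_ratios(counts, flipped, dipl)
  expect_equal(hr2$ratio, 1 - hr$ratio, tolerance = 1e-12)
})

test_that("identical ratios across conditions give p = 1; label swap leaves p unchanged", {
  design <- study_design(sprintf("S%02d", 1:5), c("C", "L"))
  ratios <- data.frame(locus_id = "LOC1",
                       sample_id = rep(sprintf("S%02d", 1:5), 2),
                       condition = rep(c("C", "L"), each = 5),
                       h1_reads = 50L, h2_reads = 50L,
                       ratio = rep(c(0.41, 0.52, 0.47, 0.55, 0.49), 2))
  cmp <- compare_ratios_across_conditions(ratios, design)
  expect_equal(cmp$p_raw, 1)
  expect_equal(cmp$mean_diff, 0)
  expect_equal(cmp$degenerate, 1L)  # zero-variance differences, all zero
  # H1/H2 label swap: r -> 1 - r, comparison p unchanged
  shifted <- ratios
  shifted$ratio[shifted$condition == "L"] <-
    shifted$ratio[shifted$condition == "L"] - rnorm(5, 0.06, 0.01)
  a <- compare_ratios_across_conditions(shifted, design)
  flipped <- shifted
  flipped$ratio <- 1 - flipped$ratio
  b <- compare_ratios_across_conditions(flipped, design)
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-9)
  expect_equal(a$mean_diff, -b$mean_diff, tolerance = 1e-12)
})

test_that("a constant nonzero shift is flagged as a degenerate near-zero p", {
  design <- study_design(sprintf("S%02d", 1:5), c("C", "L"))
  ratios <- data.frame(locus_id = "LOC1",
                       sample_id = rep(sprintf("S%02d", 1:5), 2),
                       condition = rep(c("C", "L"), each = 5),
                       h1_reads = 50L, h2_reads = 50L,
                       ratio = c(0.41, 0.52, 0.47, 0.55, 0.49,
                                 0.51, 0.62, 0.57, 0.65, 0.59))
  cmp <- compare_ratios_across_conditions(ratios, design)
  expect_equal(cmp$degenerate, 1L)
  expect_lt(cmp$p_raw, 1e-300)
  expect_equal(cmp$mean_diff, 0.1, tolerance = 1e-12)
})

test_that("contrasts with fewer than two pairs are skipped with a warning", {
  design <- study_design(c("S01", "S02"), c("C", "L"))
  ratios <- data.frame(locus_id = "LOC1", sample_id = c("S01", "S02"),
                       condition = c("C", "L"), h1_reads = 10L,
                       h2_reads = 10L, ratio = 0.5)
  expect_warning(cmp <- compare_ratios_across_conditions(ratios, design),
                 "fewer than 2")
  expect_equal(nrow(cmp), 0L)
})

test_that("Bonferroni correction spans the contrast count", {
  design <- study_design(sprintf("S%02d", 1:6), c("C", "D", "L"))
  set.seed(61)
  base <- rnorm(6, 0.49, 0.02)
  ratios <- data.frame(
    locus_id = "LOC1", sample_id = rep(sprintf("S%02d", 1:6), 3),
    condition = rep(c("C", "D", "L"), each = 6), h1_reads = 10L,
    h2_reads = 10L,
    ratio = c(base, base + rnorm(6, 0, 0.02), base - 0.06 + rnorm(6, 0, 0.02)))
  cmp <- compare_ratios_across_conditions(ratios, design)
  expect_equal(nrow(cmp), 2L)
  expect_equal(cmp$p_bonferroni, pmin(1, cmp$p_raw * 2), tolerance = 1e-12)
})

test_that("diplotype fold-change comparison contrasts het against hom samples", {
  dipl <- data.frame(locus_id = "LOC1", sample_id = sprintf("S%02d", 1:8),
                     diplotype = rep(c("H1H2", "H1H1"), each = 4))
  set.seed(62)
  fc <- data.frame(sample_id = sprintf("S%02d", 1:8),
                   log2_fc = c(rnorm(4, 3, 0.1), rnorm(4, 1, 0.1)))
  res <- compare_diplotype_foldchange(fc, dipl)
  expect_equal(res$n_het, 4L)
  expect_lt(res$p, 0.01)
  expect_gt(res$mean_het, res$mean_hom)
  expect_error(compare_diplotype_foldchange(
    data.frame(sample_id = "S99", log2_fc = 1), dipl), "missing diplotype")
})
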