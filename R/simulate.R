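# Synthetic allelic count data with known truth.
#
# The generator emulates the post-alignment count structure of a
# stimulated-PBMC cohort: a fixed panel of individuals measured in every
# condition, tens to thousands of autosomal biallelic heterozygous sites,
# overdispersed read depths, balanced allelic fractions under the null and
# shifted / condition-dependent fractions at effect sites. Effect classes
# are assigned per gene by default (cis-regulatory effects are shared by
# the SNPs of a gene), optionally per SNP. Allelic counts are drawn from a
# beta-binomial parameterized by mean mu and intra-class correlation rho
# (alpha = mu(1-rho)/rho, beta = (1-mu)(1-rho)/rho; pure binomial at
# rho = 0), with an optional additive reference bias shifting every mean
# toward the reference allele.

#' Configuration of the synthetic allele-count generator
#'
#' Defaults mirror the study design the pipeline targets: 20 individuals
#' measured in four conditions (vehicle control C, dexamethasone D, LPS L,
#' and the combination LD), negative-binomial read depths around 100x, and
#' a small fraction of static-ASE and condition-dependent-ASE genes.
#'
#' @param n_snps number of SNPs (default 2000).
#' @param n_genes number of genes; each SNP is assigned to one gene
#'   uniformly at random (default 500).
#' @param n_samples number of individuals (default 20).
#' @param conditions condition labels (default C, D, L, LD).
#' @param control control condition label.
#' @param het_prob probability that an individual is heterozygous (and
#'   hence measurable) at a SNP (default 0.5).
#' @param depth_model `list(type = "fixed", depth = n)` or
#'   `list(type = "negative_binomial", mean = m, dispersion = size)`;
#'   default NB(mean 100, size 5). Zero depths produce no record.
#' @param class_proportions named proportions over effect classes `null`,
#'   `static_ase`, `cd_ase`; must sum to 1.
#' @param static_ratio true reference fraction of static-ASE sites in all
#'   conditions (default 0.7).
#' @param cd_ratio_control,cd_ratio_treatment true reference fraction of
#'   cd-ASE sites in the control / in affected treatments (defaults 0.5 and
#'   0.65).
#' @param cd_affected treatment conditions whose ratio shifts at cd-ASE
#'   sites; default: all non-control conditions.
#' @param class_by `"gene"` (default; all SNPs of a gene share the class)
#'   or `"snp"`.
#' @param rho beta-binomial intra-class correlation (0 = binomial).
#' @param ref_bias additive shift of every mean toward the reference
#'   allele (default 0).
#' @param multi_gene_frac fraction of SNPs annotated to two overlapping
#'   genes (default 0.02); exercises the unique-gene exclusion.
#' @param sex_frac fraction of SNPs placed on chromosome X (default 0.02);
#'   exercises the autosome filter.
#' @param seed integer seed; the generator is fully reproducible.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_snps = 2000L, n_genes = 500L,
                              n_samples = 20L,
                              conditions = c("C", "D", "L", "LD"),
                              control = conditions[1], het_prob = 0.5,
                              depth_model = list(type = "negative_binomial",
                                                 mean = 100, dispersion = 5),
                              class_proportions = c(null = 0.9,
                                                    static_ase = 0.05,
                                                    cd_ase = 0.05),
                              static_ratio = 0.7, cd_ratio_control = 0.5,
                              cd_ratio_treatment = 0.65,
                              cd_affected = NULL, class_by = c("gene", "snp"),
                              rho = 0, ref_bias = 0,
                              multi_gene_frac = 0.02, sex_frac = 0.02,
                              seed = 1L) {
  class_by <- match.arg(class_by)
  if (is.null(cd_affected)) cd_affected <- setdiff(conditions, control)
  if (!control %in% conditions) stop("control must be one of conditions")
  if (!all(cd_affected %in% setdiff(conditions, control)))
    stop("cd_affected must be non-control conditions")
  if (het_prob <= 0 || het_prob > 1) stop("het_prob must lie in (0, 1]")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (abs(sum(class_proportions) - 1) > 1e-8 || any(class_proportions < 0))
    stop("class_proportions must be non-negative and sum to 1")
  if (!all(names(class_proportions) %in% c("null", "static_ase", "cd_ase")))
    stop("unknown effect class in class_proportions")
  ratios <- c(0.5, static_ratio, cd_ratio_control, cd_ratio_treatment)
  if (any(ratios + ref_bias <= 0) || any(ratios + ref_bias >= 1))
    stop("ratio + ref_bias must stay inside (0, 1)")
  if (!depth_model$type %in% c("fixed", "negative_binomial"))
    stop("depth_model$type must be 'fixed' or 'negative_binomial'")
  structure(list(n_snps = as.integer(n_snps), n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples), conditions = conditions,
                 control = control, het_prob = het_prob,
                 depth_model = depth_model,
                 class_proportions = class_proportions,
                 static_ratio = static_ratio,
                 cd_ratio_control = cd_ratio_control,
                 cd_ratio_treatment = cd_ratio_treatment,
                 cd_affected = cd_affected, class_by = class_by,
                 rho = rho, ref_bias = ref_bias,
                 multi_gene_frac = multi_gene_frac, sex_frac = sex_frac,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.draw_depth <- function(n, model) {
  switch(model$type,
         fixed = rep(as.integer(model$depth), n),
         negative_binomial = stats::rnbinom(n, mu = model$mean,
                                            size = model$dispersion))
}

.draw_betabinom <- function(depth, mu, rho) {
  if (rho == 0) return(stats::rbinom(length(depth), depth, mu))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  stats::rbinom(length(depth), depth, stats::rbeta(length(depth), a, b))
}

#' Simulate an allele-specific count dataset with known truth
#'
#' @param config a [simulation_config()].
#' @return object of class `ase_simulation`: list with `counts`,
#'   `annotations`, `design` (a [study_design()]), `truth` (per SNP: the
#'   effect class and the true reference fraction in every condition) and
#'   the `config`.
#' @export
simulate_counts <- function(config = simulation_config()) {
  set.seed(config$seed)
  ns <- config$n_snps
  snp_id <- sprintf("snp%05d", seq_len(ns))
  gene_pool <- sprintf("G%04d", seq_len(config$n_genes))
  gene1 <- sample(gene_pool, ns, replace = TRUE)
  multi <- stats::runif(ns) < config$multi_gene_frac
  gene2 <- sample(gene_pool, ns, replace = TRUE)
  gene_ids <- ifelse(multi & gene2 != gene1,
                     paste(pmin(gene1, gene2), pmax(gene1, gene2), sep = ","),
                     gene1)
  chrom <- as.character(sample(1:18, ns, replace = TRUE))
  chrom[stats::runif(ns) < config$sex_frac] <- "X"
  pos <- integer(ns)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    pos[sel] <- sort(sample.int(2e8, sum(sel)))
  }
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, ns, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")
  classes <- names(config$class_proportions)
  cls_unit <- if (config$class_by == "gene") {
    gcls <- sample(classes, config$n_genes, replace = TRUE,
                   prob = config$class_proportions)
    names(gcls) <- gene_pool
    unname(gcls[gene1])
  } else {
    sample(classes, ns, replace = TRUE, prob = config$class_proportions)
  }
  truth <- data.frame(snp_id = snp_id, class = cls_unit,
                      stringsAsFactors = FALSE)
  ratio_mat <- matrix(0.5, ns, length(config$conditions),
                      dimnames = list(snp_id, config$conditions))
  ratio_mat[cls_unit == "static_ase", ] <- config$static_ratio
  is_cd <- cls_unit == "cd_ase"
  ratio_mat[is_cd, ] <- config$cd_ratio_control
  ratio_mat[is_cd, config$cd_affected] <- config$cd_ratio_treatment
  for (cond in config$conditions)
    truth[[paste0("ratio_", cond)]] <- ratio_mat[, cond]
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  het <- matrix(stats::runif(ns * config$n_samples) < config$het_prob,
                ns, config$n_samples)
  pair_snp <- rep(seq_len(ns), times = config$n_samples)
  pair_smp <- rep(seq_len(config$n_samples), each = ns)
  keep <- het[cbind(pair_snp, pair_smp)]
  pair_snp <- pair_snp[keep]
  pair_smp <- pair_smp[keep]
  recs <- list()
  for (cond in config$conditions) {
    depth <- .draw_depth(length(pair_snp), config$depth_model)
    mu <- ratio_mat[pair_snp, cond] + config$ref_bias
    refc <- .draw_betabinom(depth, mu, config$rho)
    ok <- depth > 0
    recs[[cond]] <- data.frame(snp_id = snp_id[pair_snp[ok]],
                               sample_id = samples[pair_smp[ok]],
                               condition = cond,
                               ref_count = as.integer(refc[ok]),
                               alt_count = as.integer(depth[ok] - refc[ok]),
                               stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, recs)
  rownames(counts) <- NULL
  ann <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos, ref = ref,
                    alt = unname(alt), gene_ids = gene_ids,
                    is_autosomal = chrom %in% default_autosomes(),
                    stringsAsFactors = FALSE)
  structure(list(counts = counts, annotations = ann,
                 design = study_design(samples, config$conditions,
                                       config$control),
                 truth = truth, config = config),
            class = "ase_simulation")
}

#' @export
print.ase_simulation <- function(x, ...) {
  cat("Synthetic ASE dataset:", nrow(x$counts), "records |",
      x$config$n_snps, "SNPs |", x$config$n_samples, "samples |",
      length(x$config$conditions), "conditions\n")
  print(table(x$truth$class))
  invisible(x)
}

#' Confusion summary of scan calls against the simulated truth
#'
#' Joins a SNP-wise scan result with the generator's truth table and
#' reports, per condition (static scans) or contrast (cd scans) among the
#' tested SNPs: true/false positive/negative counts at the scan's
#' significance calls, sensitivity and the realized false discovery
#' proportion (NA when nothing was called).
#'
#' A SNP counts as truly positive in a condition when its true reference
#' fraction there differs from 0.5; in a contrast, when its true fractions
#' differ between the two conditions.
#'
#' @param truth truth data.frame from [simulate_counts()].
#' @param scan a [scan_static_ase()] or [scan_cd_ase()] result.
#' @return data.frame with one row per condition/contrast.
#' @export
summarize_truth_vs_calls <- function(truth, scan) {
  if (!all(scan$snp_id %in% truth$snp_id))
    stop("scan contains SNPs absent from the truth table")
  is_static <- "condition" %in% names(scan)
  unit_col <- if (is_static) "condition" else "contrast"
  out <- list()
  for (u in unique(scan[[unit_col]])) {
    sub <- scan[scan[[unit_col]] == u, , drop = FALSE]
    hit <- match(sub$snp_id, truth$snp_id)
    pos <- if (is_static) {
      abs(truth[[paste0("ratio_", u)]][hit] - 0.5) > 1e-12
    } else {
      parts <- strsplit(u, "_vs_", fixed = TRUE)[[1]]
      abs(truth[[paste0("ratio_", parts[1])]][hit] -
            truth[[paste0("ratio_", parts[2])]][hit]) > 1e-12
    }
    called <- sub$significant == 1L
    tp <- sum(called & pos); fp <- sum(called & !pos)
    fn <- sum(!called & pos); tn <- sum(!called & !pos)
    out[[u]] <- data.frame(
      unit = u, n_tested = nrow(sub), tp = tp, fp = fp, fn = fn, tn = tn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      realized_fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  names(res)[1] <- unit_col
  rownames(res) <- NULL
  res
}
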