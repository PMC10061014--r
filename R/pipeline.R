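# Pipeline orchestration: filter -> static scan -> cd scan -> gene scans
# -> optional haplotype verification, with deterministic outputs and a
# JSON run manifest.

#' Assemble and validate a pipeline configuration
#'
#' All referenced paths are checked at construction time, before any stage
#' runs. Counts may be given as a file path (TSV or VCF dialect of
#' [read_count_table()]) or as an in-memory data.frame together with
#' `annotations`.
#'
#' @param counts count-table path or data.frame.
#' @param out_dir output directory (created if missing).
#' @param conditions,control,contrasts study design; conditions default to
#'   those present in the counts, control to the first.
#' @param annotations annotation data.frame (required when `counts` is a
#'   data.frame).
#' @param format `"tsv"` or `"vcf"` (when `counts` is a path).
#' @param gene_map optional SNP-to-gene TSV path or data.frame; required
#'   for the gene-wise stages.
#' @param phase,diplotypes optional phase / diplotype TSV paths or
#'   data.frames enabling the haplotype stage.
#' @param thresholds a [filter_thresholds()].
#' @param gene_config a [gene_ase_config()]; its seed is overridden by
#'   `seed` so one top-level seed drives the whole run.
#' @param sig_fdr significance threshold applied by every stage.
#' @param per_sample_alpha per-sample p threshold of the cd scan.
#' @param autosomes autosome name list for path inputs.
#' @param seed top-level seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, out_dir, conditions = NULL,
                            control = NULL, contrasts = NULL,
                            annotations = NULL, format = "tsv",
                            gene_map = NULL, phase = NULL,
                            diplotypes = NULL,
                            thresholds = filter_thresholds(),
                            gene_config = gene_ase_config(),
                            sig_fdr = 0.05, per_sample_alpha = 0.05,
                            autosomes = default_autosomes(), seed = 1L) {
  for (p in list(counts, gene_map, phase, diplotypes)) {
    if (is.character(p) && length(p) == 1L && !file.exists(p))
      stop("configured input path does not exist: ", p)
  }
  if (is.data.frame(counts) && is.null(annotations))
    stop("in-memory counts require annotations")
  structure(list(counts = counts, annotations = annotations,
                 format = format, gene_map = gene_map, phase = phase,
                 diplotypes = diplotypes, out_dir = out_dir,
                 conditions = conditions, control = control,
                 contrasts = contrasts, thresholds = thresholds,
                 gene_config = gene_config, sig_fdr = sig_fdr,
                 per_sample_alpha = per_sample_alpha,
                 autosomes = autosomes, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full condition-dependent ASE pipeline
#'
#' Executes informative-site filtering, the SNP-wise static ASE scan, the
#' SNP-wise cd-ASE scan, the gene-wise static and conditional scans (when
#' a gene map is configured), and the haplotype verification (when phase
#' information is configured). All stage results are written as
#' deterministic TSVs under `out_dir` together with `manifest.json`
#' recording the configuration, seed, package version and per-stage row
#' counts; rerunning with the same configuration and seed reproduces every
#' output byte for byte. A stage failure aborts the run, names the stage,
#' and removes any partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list (with an extra `results` element
#'   holding the in-memory stage results).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  stage <- "input"
  emit <- function(res, file) {
    path <- file.path(config$out_dir, file)
    write_results(as.data.frame(res), path)
    written <<- c(written, path)
    path
  }
  result <- tryCatch({
    dat <- if (is.character(config$counts))
      read_count_table(config$counts, config$format, config$autosomes)
    else list(counts = config$counts, annotations = config$annotations)
    if (!is.null(config$gene_map))
      dat$annotations <- annotate_genes(dat$annotations, config$gene_map)
    conditions <- if (is.null(config$conditions))
      sort(unique(dat$counts$condition)) else config$conditions
    control <- if (is.null(config$control)) conditions[1] else config$control
    design <- study_design(sort(unique(dat$counts$sample_id)), conditions,
                           control, config$contrasts)

    stage <- "filter"
    filt <- filter_dataset(dat$counts, dat$annotations, config$thresholds)
    emit(filt$summary, "filter_summary.tsv")

    stage <- "static_ase"
    static <- scan_static_ase(filt$counts, dat$annotations,
                              conditions = conditions,
                              sig_fdr = config$sig_fdr)
    emit(static, "static_ase.tsv")

    stage <- "cd_ase"
    cdres <- scan_cd_ase(filt$counts, static, dat$annotations, design,
                         sig_fdr = config$sig_fdr,
                         per_sample_alpha = config$per_sample_alpha)
    emit(cdres, "cd_ase.tsv")

    gene_static <- gene_cond <- NULL
    if (!is.null(config$gene_map) ||
        any(nzchar(dat$annotations$gene_ids))) {
      stage <- "gene_ase_static"
      gcfg <- config$gene_config
      gcfg$seed <- (config$seed + 101L) %% .Machine$integer.max
      gene_static <- scan_gene_ase(filt$counts, dat$annotations,
                                   design = design, config = gcfg,
                                   mode = "static",
                                   sig_fdr = config$sig_fdr)
      emit(gene_static, "gene_ase_static.tsv")
      stage <- "gene_ase_conditional"
      gcfg$seed <- (config$seed + 202L) %% .Machine$integer.max
      gene_cond <- scan_gene_ase(filt$counts, dat$annotations,
                                 design = design, config = gcfg,
                                 mode = "conditional", static = static,
                                 sig_fdr = config$sig_fdr)
      emit(gene_cond, "gene_ase_conditional.tsv")
    }

    hap <- hap_cmp <- NULL
    if (!is.null(config$phase)) {
      stage <- "haplotype"
      phase <- if (is.character(config$phase))
        read_phase_table(config$phase) else config$phase
      dipl <- if (is.null(config$diplotypes)) NULL
      else if (is.character(config$diplotypes))
        read_diplotypes(config$diplotypes) else config$diplotypes
      hap <- haplotype_ratios(filt$counts, phase, dipl)
      emit(hap, "haplotype_ratios.tsv")
      hap_cmp <- compare_ratios_across_conditions(hap, design)
      emit(hap_cmp, "haplotype_contrasts.tsv")
    }

    stage <- "manifest"
    manifest <- list(
      pipeline = "cdase",
      version = as.character(utils::packageVersion("cdase")),
      seed = config$seed,
      design = list(samples = design$samples, conditions = conditions,
                    control = control,
                    contrasts = vapply(design$contrasts, .contrast_label,
                                       "")),
      thresholds = unclass(config$thresholds),
      gene_config = unclass(config$gene_config),
      sig_fdr = config$sig_fdr,
      per_sample_alpha = config$per_sample_alpha,
      inputs = list(
        counts = if (is.character(config$counts)) config$counts
                 else "<in-memory>",
        gene_map = if (is.character(config$gene_map)) config$gene_map
                   else if (is.null(config$gene_map)) NULL
                   else "<in-memory>",
        phase = if (is.character(config$phase)) config$phase
                else if (is.null(config$phase)) NULL else "<in-memory>"),
      rows = list(
        records_in = nrow(dat$counts),
        records_filtered = nrow(filt$counts),
        static_ase = nrow(static), cd_ase = nrow(cdres),
        gene_ase_static = if (is.null(gene_static)) NULL
                          else nrow(gene_static),
        gene_ase_conditional = if (is.null(gene_cond)) NULL
                               else nrow(gene_cond),
        haplotype_ratios = if (is.null(hap)) NULL else nrow(hap)),
      files = basename(written))
    mpath <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, mpath)
    manifest$results <- list(filter = filt, static = static, cd = cdres,
                             gene_static = gene_static,
                             gene_conditional = gene_cond,
                             haplotype = hap, haplotype_contrasts = hap_cmp)
    manifest
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
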