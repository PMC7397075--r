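# End-to-end orchestration: one configuration object holding every threshold,
# validation up front, and a run that simulates (or accepts) data, executes
# all analysis stages and writes the report bundle with a hashed manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one list with the package
#' defaults; override any field by name. See \code{\link{validate_config}}
#' for the invariants.
#'
#' @param ... Named overrides of default fields.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # design / generator
    n_diploid = 3, n_tetraploid = 1, n_hexaploid = 3, stages = 4,
    n_genes = 2000,
    class_proportions = c(null = 0.7, ploidy = 0.1, po_4x = 0.1,
                          po_2x = 0.05, transgressive = 0.05),
    effect_size = 3, noise_sd = 0.3, probes_per_gene = 3, affinity_sd = 0.5,
    baseline_mean = 8, baseline_sd = 2,
    # thresholds
    variance_threshold = 0.7, alpha = 0.01, lfc_min = 2, q_max = 0.05,
    k = 2, sd_floor = 1e-6, n_perm = 1000, min_depth = 10,
    n_snps_per_gene = 16,
    # modes
    paired = FALSE, pooled_fdr = FALSE, include_tetraploid_in_filter = FALSE,
    apply_variance_filter = TRUE, quantile_normalize = TRUE,
    seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("config error: unknown field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Character vector of violations, empty when the configuration is
#'   valid (each message names the offending field).
#' @export
validate_config <- function(config) {
  v <- character()
  prob01 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
    x > 0 && x < 1
  if (!prob01(config$alpha)) v <- c(v, "alpha must lie in (0, 1)")
  if (!prob01(config$q_max)) v <- c(v, "q_max must lie in (0, 1)")
  if (!is.numeric(config$variance_threshold) ||
      config$variance_threshold < 0 || config$variance_threshold > 1)
    v <- c(v, "variance_threshold must lie in [0, 1]")
  if (!is.numeric(config$lfc_min) || config$lfc_min < 0)
    v <- c(v, "lfc_min must be >= 0")
  if (!is.numeric(config$k) || config$k <= 0)
    v <- c(v, "k (SD band half-width) must be > 0")
  if (!is.numeric(config$n_perm) || config$n_perm < 100)
    v <- c(v, "n_perm must be >= 100")
  if (!is.numeric(config$min_depth) || config$min_depth < 1)
    v <- c(v, "min_depth must be >= 1")
  if (!is.numeric(config$noise_sd) || config$noise_sd < 0)
    v <- c(v, "noise_sd must be >= 0")
  if (!is.numeric(config$effect_size) || config$effect_size <= 0)
    v <- c(v, "effect_size must be > 0")
  counts <- c(config$n_diploid, config$n_tetraploid, config$n_hexaploid)
  if (any(counts < 1) || any(counts != round(counts)))
    v <- c(v, "genotype counts must be positive integers")
  if (config$stages < 2) v <- c(v, "stages must be >= 2")
  if (abs(sum(config$class_proportions) - 1) > 1e-9)
    v <- c(v, "class_proportions must sum to 1")
  if (!is.numeric(config$seed) || config$seed != round(config$seed))
    v <- c(v, "seed must be an integer")
  v
}

#' Run the full analysis pipeline on simulated data
#'
#' Simulates a probe-level dataset under the configured design, then runs
#' summarization, quantile normalization, the variance filter, PCA QC,
#' stage-wise differential expression with Venn summaries, expression-state
#' classification with the stage-by-class summary, profile-based heterochrony
#' analysis on the DE gene set, the SNP parental-origin screen on
#' parent-of-origin genes, and a qPCR validation round on the strongest up-
#' and downregulated genes. Deterministic for a fixed \code{config$seed}.
#'
#' @param config A valid \code{\link{pipeline_config}}.
#' @param out_dir Optional output directory; when given, every table is
#'   written (TSV/CSV) together with \code{manifest.tsv} (file, md5) and
#'   \code{pipeline.log}.
#' @return Invisibly, a list with all intermediate and final objects:
#'   \code{design}, \code{truth}, \code{expression} (normalized matrix),
#'   \code{filter_report}, \code{pca}, \code{de}, \code{venn},
#'   \code{class_table}, \code{class_summary}, \code{recovery},
#'   \code{heterochrony}, \code{origin}, \code{qpcr}, \code{config}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  viol <- validate_config(config)
  if (length(viol))
    stop("invalid config:\n  - ", paste(viol, collapse = "\n  - "))
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  design <- generate_design(config$n_diploid, config$n_tetraploid,
                            config$n_hexaploid, config$stages)
  truth <- plant_truth(config$n_genes, config$class_proportions,
                       config$effect_size,
                       stages = stage_labels(config$stages),
                       seed = config$seed)
  probes <- simulate_expression(truth, design, config$baseline_mean,
                                config$baseline_sd, config$noise_sd,
                                config$probes_per_gene, config$affinity_sd,
                                seed = config$seed + 1)
  note("simulated %d genes x %d arrays (%d probes/gene)", config$n_genes,
       nrow(design), config$probes_per_gene)
  expr <- summarize_probes(probes)
  norm <- if (config$quantile_normalize) quantile_normalize(expr) else expr
  vf <- variance_filter(norm, config$variance_threshold, design,
                        config$include_tetraploid_in_filter)
  de_matrix <- if (config$apply_variance_filter) vf$matrix else norm
  note("variance filter kept %d / %d genes", nrow(vf$matrix), nrow(norm))
  pca <- pca_scores(norm)

  de <- de_all_stages(de_matrix, design, alpha = config$alpha,
                      lfc_min = config$lfc_min, q_max = config$q_max,
                      paired = config$paired, pooled_fdr = config$pooled_fdr)
  venn <- venn_summary(de)
  sel <- select_de_any_stage(de)
  note("%d genes DE in >= 1 stage; %d non-DE", length(sel$de_genes),
       length(sel$non_de_genes))

  class_table <- suppressWarnings(
    classify_expression(norm, design, de, config$k, config$sd_floor))
  class_summary <- summarize_classes(class_table,
                                     stages = stage_labels(config$stages))
  recovery <- planted_class_recovery(truth, class_table)

  heterochrony <- NULL
  hgenes <- intersect(rownames(norm), sel$de_genes)
  if (length(hgenes) >= 2) {
    hmat <- norm[hgenes, , drop = FALSE]
    profiles <- enumerate_profiles(config$stages, 1)
    as_sex <- assign_profiles(hmat, design, "sexual", profiles)
    as_apo <- assign_profiles(hmat, design, "apomictic", profiles)
    heterochrony <- list(
      sexual = as_sex$assignments, apomictic = as_apo$assignments,
      significance_sexual = profile_significance(as_sex, config$n_perm,
                                                 seed = config$seed + 2),
      significance_apomictic = profile_significance(as_apo, config$n_perm,
                                                    seed = config$seed + 3),
      comparison = compare_modes(as_sex, as_apo))
    note("heterochrony analysis over %d DE genes, %d candidate profiles",
         length(hgenes), length(profiles$profile_id))
  }

  origin <- NULL
  po_genes <- sort(unique(class_table$gene_id[
    class_table$class %in% c("po_4x", "po_2x")]))
  if (length(po_genes)) {
    snp <- simulate_snp_table(length(po_genes), config$n_snps_per_gene,
                              gene_ids = po_genes, seed = config$seed + 4)
    covered <- suppressMessages(coverage_filter(snp, config$min_depth))
    origin <- parental_similarity(covered)
    note("SNP screen on %d parent-of-origin genes", length(po_genes))
  }

  qpcr <- NULL
  all_de <- do.call(rbind, de)
  sig <- all_de[all_de$significant, ]
  if (nrow(sig)) {
    sig <- sig[order(-abs(sig$log2fc)), ]
    sig <- sig[!duplicated(sig$gene_id), ]
    top <- rbind(utils::head(sig[sig$log2fc > 0, ], 5),
                 utils::head(sig[sig$log2fc < 0, ], 5))
    if (nrow(top) >= 2) {
      lfc <- stats::setNames(top$log2fc, top$gene_id)
      ct <- simulate_ct_table(lfc, seed = config$seed + 5)
      rq <- delta_delta_ct(ct, calibrator = "sexual")
      conc <- qpcr_concordance(top, rq, group = "apomictic")
      qpcr <- list(ct_table = ct, quant = rq, concordance = conc)
      note("qPCR validation on %d genes: concordance %.2f", nrow(top),
           conc$fraction)
    }
  }

  result <- list(design = design, truth = truth, expression = norm,
                 filter_report = vf$report, pca = pca, de = de, venn = venn,
                 class_table = class_table, class_summary = class_summary,
                 recovery = recovery, heterochrony = heterochrony,
                 origin = origin, qpcr = qpcr, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(obj, name, writer) {
      path <- file.path(out_dir, name)
      writer(obj, path)
      path
    }
    files <- c(
      wr(design, "sample_sheet.csv", write_sample_sheet),
      wr(truth, "truth_table.tsv", write_table_tsv),
      wr(norm, "expression_matrix.tsv", write_matrix_tsv),
      wr(vf$report, "variance_filter_report.tsv", write_table_tsv),
      wr(pca$scores, "pca_scores.csv",
         function(o, p) utils::write.csv(o, p, row.names = FALSE)),
      wr(do.call(rbind, de), "de_results.tsv", write_table_tsv),
      wr(venn$regions, "venn_regions.csv",
         function(o, p) utils::write.csv(o, p, row.names = FALSE)),
      wr(venn$per_stage, "venn_per_stage.csv",
         function(o, p) utils::write.csv(o, p, row.names = FALSE)),
      wr(class_table, "class_table.tsv", write_table_tsv),
      wr(class_summary, "class_summary.csv",
         function(o, p) utils::write.csv(o, p, row.names = FALSE)),
      wr(recovery, "class_recovery.tsv", write_table_tsv))
    if (!is.null(heterochrony)) {
      files <- c(files,
        wr(heterochrony$sexual, "profiles_sexual.tsv", write_table_tsv),
        wr(heterochrony$apomictic, "profiles_apomictic.tsv", write_table_tsv),
        wr(heterochrony$comparison$pairs, "profile_pairs.csv",
           function(o, p) utils::write.csv(o, p, row.names = FALSE)))
    }
    if (!is.null(origin))
      files <- c(files, wr(origin, "origin_report.tsv", write_table_tsv))
    if (!is.null(qpcr)) {
      files <- c(files,
        wr(qpcr$quant, "qpcr_quant.tsv", write_table_tsv),
        wr(qpcr$concordance$per_gene, "qpcr_concordance.tsv",
           write_table_tsv))
    }
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    write_table_tsv(manifest, file.path(out_dir, "manifest.tsv"))
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  invisible(result)
}
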