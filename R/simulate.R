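# Synthetic-data generator: planted expression classes, probe-level
# intensities, SNP tables and qPCR Ct tables with known ground truth.

#' Expression-state classes used throughout the package
#'
#' \code{"null"}: no group differences. \code{"ploidy"}: additive expression
#' scaling monotonically with genome dosage (2x -> 4x -> 6x). \code{"po_4x"}:
#' parent-of-origin / expression-level dominance toward the tetraploid parent
#' (4x and 6x share a level differing from 2x). \code{"po_2x"}: dominance
#' toward the diploid parent (2x and 6x share a level, the tetraploid
#' deviates; these genes are not differentially expressed between 6x and 2x).
#' \code{"transgressive"}: hybrid expression outside the parental range (2x
#' and 4x share a level, 6x deviates from both).
#'
#' @export
expression_classes <- c("null", "ploidy", "po_4x", "po_2x", "transgressive")

#' Plant ground-truth expression classes
#'
#' Draws a class label per gene from a multinomial mixture and assigns each
#' non-null gene a direction (up/down in the hexaploid, or in the tetraploid
#' for \code{po_2x}) and the set of developmental stages in which its effect
#' is active.
#'
#' @param n_genes Number of genes.
#' @param class_proportions Named probabilities over
#'   \code{\link{expression_classes}}; must sum to 1 (tolerance 1e-9).
#' @param effect_size Planted effect in log2 units (> 0 when any non-null
#'   class has positive mass). Default 3: comfortably beyond the pipeline's
#'   |log2 FC| > 2 gate so that class recovery is a sharp test.
#' @param stages Stage labels of the design the truth is meant for.
#' @param affected_stages \code{"all"} (default: effects active at every
#'   stage) or a character vector of stage labels.
#' @param seed Integer seed; the same call with the same seed returns an
#'   identical table.
#' @return A \code{data.frame} with columns \code{gene_id},
#'   \code{planted_class}, \code{direction} (\code{up}/\code{down}/\code{none}),
#'   \code{affected_stages} (comma-separated labels, empty for null genes) and
#'   \code{effect_size} (0 for null genes).
#' @export
plant_truth <- function(n_genes,
                        class_proportions = c(null = 0.7, ploidy = 0.1,
                                              po_4x = 0.1, po_2x = 0.05,
                                              transgressive = 0.05),
                        effect_size = 3,
                        stages = stage_labels(4),
                        affected_stages = "all",
                        seed = 1) {
  p <- class_proportions
  if (is.null(names(p)) || !all(names(p) %in% expression_classes))
    stop("config error: class_proportions must be named with classes among: ",
         paste(expression_classes, collapse = ", "))
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("config error: class_proportions must be non-negative and sum to 1")
  if (effect_size <= 0 && sum(p[setdiff(names(p), "null")]) > 0)
    stop("config error: effect_size must be > 0 when non-null classes are planted")
  set.seed(seed)
  cls <- sample(names(p), n_genes, replace = TRUE, prob = p)
  dir <- sample(c("up", "down"), n_genes, replace = TRUE)
  dir[cls == "null"] <- "none"
  aff <- if (identical(affected_stages, "all")) stages else {
    if (!all(affected_stages %in% stages))
      stop("config error: affected_stages must be a subset of stages")
    affected_stages
  }
  data.frame(
    gene_id = sprintf("g%05d", seq_len(n_genes)),
    planted_class = cls,
    direction = dir,
    affected_stages = ifelse(cls == "null", "", paste(aff, collapse = ",")),
    effect_size = ifelse(cls == "null", 0, effect_size),
    stringsAsFactors = FALSE)
}

#' Stage-offset preset for heterochronic expression in apomicts
#'
#' Returns the per-stage expression offsets (log2 units) applied to apomictic
#' samples of a heterochrony gene in a four-stage design: flat at stage I, a
#' rise at stage II followed by a sharp drop at stage III that persists into
#' stage IV. This is the mode-specific trajectory the profile module is built
#' to detect.
#'
#' @param effect_size Magnitude of the rise/drop in log2 units.
#' @return Named numeric vector over stages I-IV.
#' @export
heterochrony_profile <- function(effect_size = 3) {
  stats::setNames(c(0, effect_size, -effect_size, -effect_size),
                  stage_labels(4))
}

# log2 group offset of a gene in a ploidy group, given its class/direction.
.group_offsets <- function(cls, effect) {
  # returns list of numeric vectors off_2x, off_4x, off_6x
  off2 <- numeric(length(cls))
  off4 <- ifelse(cls == "ploidy", effect / 2,
          ifelse(cls %in% c("po_4x", "po_2x"), effect, 0))
  off6 <- ifelse(cls %in% c("ploidy", "po_4x", "transgressive"), effect, 0)
  list(`2` = off2, `4` = off4, `6` = off6)
}

#' Simulate probe-level array intensities with planted structure
#'
#' Builds gene-level log2 expression from the planted truth (see Details),
#' adds a fixed per-probe affinity and Gaussian noise, and exponentiates to
#' raw intensity scale. Probe affinities are drawn once per probe from a
#' zero-mean Gaussian so that median-polish summarization has real structure
#' to remove.
#'
#' Group means by class (offsets applied only in the gene's affected stages;
#' \code{s} is +1/-1 for direction up/down, \code{e} the effect size):
#' null: all groups at the gene baseline. ploidy: 2x baseline, 4x +s*e/2,
#' 6x +s*e (monotone in dosage, 6x - 2x = e). po_4x: 4x and 6x both +s*e.
#' po_2x: 4x +s*e only (2x and 6x equal, hence not DE). transgressive:
#' 6x +s*e only.
#'
#' @param truth Output of \code{\link{plant_truth}}.
#' @param design Sample sheet from \code{\link{generate_design}}; must contain
#'   all three ploidy groups.
#' @param baseline_mean,baseline_sd Per-gene baselines are drawn from
#'   N(baseline_mean, baseline_sd) in log2 units; the spread emulates the wide
#'   abundance range of real transcripts and avoids ties in rank-based steps.
#' @param noise_sd Gaussian noise SD per probe measurement, log2 units.
#'   \code{0} gives the exact noise-free limit.
#' @param probes_per_gene Probes per contig, 1 to 3.
#' @param affinity_sd SD of the fixed per-probe affinity (log2 units).
#' @param heterochrony_genes Optional gene ids given the apomict-specific
#'   stage trajectory of \code{\link{heterochrony_profile}} (4-stage designs).
#' @param heterochrony_effect Effect size for that trajectory.
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @return An object of class \code{probe_matrix}: a list with
#'   \code{intensities} (probe x sample matrix, raw positive scale),
#'   \code{probe_map} (probe_id -> gene_id), \code{gene_values} (true gene x
#'   sample log2 matrix, before probe effects/noise) and \code{design}.
#' @export
simulate_expression <- function(truth, design,
                                baseline_mean = 8, baseline_sd = 2,
                                noise_sd = 0.3, probes_per_gene = 3,
                                affinity_sd = 0.5,
                                heterochrony_genes = character(),
                                heterochrony_effect = 3,
                                seed = 1) {
  if (noise_sd < 0) stop("config error: noise_sd must be >= 0")
  if (!probes_per_gene %in% 1:3)
    stop("config error: probes_per_gene must be 1, 2 or 3")
  if (!all(c(2, 4, 6) %in% design$ploidy))
    stop("invalid design: all three ploidy groups (2x, 4x, 6x) are required")
  set.seed(seed)
  n <- nrow(truth)
  ns <- nrow(design)
  baseline <- stats::rnorm(n, baseline_mean, baseline_sd)
  sgn <- ifelse(truth$direction == "down", -1, 1)
  off <- .group_offsets(truth$planted_class, sgn * truth$effect_size)

  stages <- unique(design$stage)
  aff_list <- strsplit(truth$affected_stages, ",", fixed = TRUE)
  memb <- vapply(stages, function(st)
    vapply(aff_list, function(a) st %in% a, logical(1)), logical(n))
  if (n == 1) memb <- matrix(memb, nrow = 1, dimnames = list(NULL, stages))
  colnames(memb) <- stages

  gv <- matrix(baseline, n, ns)
  het <- truth$gene_id %in% heterochrony_genes
  if (any(het)) {
    if (!all(stage_labels(4) %in% stages))
      stop("heterochrony preset requires a four-stage (I-IV) design")
    hprof <- heterochrony_profile(heterochrony_effect)
  }
  for (j in seq_len(ns)) {
    pl <- as.character(design$ploidy[j])
    st <- design$stage[j]
    gv[, j] <- baseline + memb[, st] * off[[pl]]
    if (any(het) && design$mode[j] == "apomictic")
      gv[het, j] <- gv[het, j] + hprof[[st]]
  }
  dimnames(gv) <- list(truth$gene_id, design$sample_id)

  ppg <- probes_per_gene
  probe_gene <- rep(seq_len(n), each = ppg)
  probe_id <- sprintf("%s_p%d", truth$gene_id[probe_gene],
                      rep(seq_len(ppg), times = n))
  affinity <- stats::rnorm(n * ppg, 0, affinity_sd)
  noise <- matrix(stats::rnorm(n * ppg * ns, 0, noise_sd), n * ppg, ns)
  li <- gv[probe_gene, , drop = FALSE] + affinity + noise
  intensities <- 2^li
  dimnames(intensities) <- list(probe_id, design$sample_id)

  structure(list(intensities = intensities,
                 probe_map = data.frame(probe_id = probe_id,
                                        gene_id = truth$gene_id[probe_gene],
                                        stringsAsFactors = FALSE),
                 gene_values = gv,
                 design = design),
            class = "probe_matrix")
}

#' Simulate a SNP genotype table with planted parental origins
#'
#' Generates consensus allele calls for three individuals (a hexaploid hybrid
#' and its putative diploid and tetraploid parents) at a fixed number of SNP
#' positions per gene. Genes of origin \code{"tetraploid_parent"} match the
#' tetraploid at every SNP and differ from the diploid at >= 1 SNP (and
#' symmetrically for \code{"diploid_parent"}); \code{"shared"} genes match
#' both parents everywhere.
#'
#' @param n_genes Number of genes.
#' @param n_snps_per_gene SNPs per gene (>= 1).
#' @param origin Character vector of length \code{n_genes} with values in
#'   \code{c("tetraploid_parent", "diploid_parent", "shared")}, or NULL to
#'   sample origins uniformly.
#' @param gene_ids Optional gene identifiers (default \code{snp_gene_...}).
#' @param depth_mean Mean Poisson read depth per call.
#' @param seed Integer seed.
#' @return A \code{data.frame} with columns \code{gene_id}, \code{pos},
#'   \code{allele_hexaploid}, \code{allele_diploid}, \code{allele_tetraploid}
#'   and matching \code{depth_*} columns.
#' @export
simulate_snp_table <- function(n_genes, n_snps_per_gene = 16, origin = NULL,
                               gene_ids = NULL, depth_mean = 30, seed = 1) {
  if (n_snps_per_gene < 1) stop("config error: n_snps_per_gene must be >= 1")
  origins <- c("tetraploid_parent", "diploid_parent", "shared")
  set.seed(seed)
  if (is.null(origin))
    origin <- sample(origins, n_genes, replace = TRUE)
  if (length(origin) != n_genes || !all(origin %in% origins))
    stop("config error: origin must be length n_genes with known origin labels")
  if (is.null(gene_ids)) gene_ids <- sprintf("snp_gene_%04d", seq_len(n_genes))
  bases <- c("A", "C", "G", "T")
  other_base <- function(b) vapply(b, function(x)
    sample(setdiff(bases, x), 1), character(1), USE.NAMES = FALSE)
  out <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    m <- n_snps_per_gene
    pos <- cumsum(sample(10:100, m, replace = TRUE))
    ref <- sample(bases, m, replace = TRUE)
    alt <- other_base(ref)
    mm <- stats::runif(m) < 0.5
    if (!any(mm)) mm[sample.int(m, 1)] <- TRUE  # force >= 1 parental mismatch
    if (origin[g] == "tetraploid_parent") {
      tet <- ref; hex <- ref; dip <- ifelse(mm, alt, ref)
    } else if (origin[g] == "diploid_parent") {
      dip <- ref; hex <- ref; tet <- ifelse(mm, alt, ref)
    } else {
      dip <- ref; tet <- ref; hex <- ref
    }
    out[[g]] <- data.frame(
      gene_id = gene_ids[g], pos = pos,
      allele_hexaploid = hex, allele_diploid = dip, allele_tetraploid = tet,
      depth_hexaploid = stats::rpois(m, depth_mean),
      depth_diploid = stats::rpois(m, depth_mean),
      depth_tetraploid = stats::rpois(m, depth_mean),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "origin") <- stats::setNames(origin, gene_ids)
  res
}

#' Simulate a qPCR Ct table from known fold changes
#'
#' Builds a Ct table for target genes with given log2 fold changes (test group
#' relative to calibrator) plus housekeeping genes, with biological and
#' technical replicates and Gaussian cycle noise. A doubling of template
#' lowers Ct by one cycle, so a target with log2 FC \code{f} has mean Ct
#' \code{target_ct - f} in the test group.
#'
#' @param log2fc Named numeric vector: per-target-gene log2 fold change of the
#'   test group relative to the calibrator.
#' @param hk_genes Housekeeping gene names (equal Ct in both groups).
#' @param n_bio,n_tech Biological samples per group and technical replicates
#'   per sample.
#' @param target_ct,hk_ct Mean Ct of targets (in the calibrator group) and of
#'   housekeeping genes.
#' @param ct_sd Gaussian noise SD in cycles.
#' @param groups Named character vector with elements \code{test} and
#'   \code{calibrator} giving the group labels.
#' @param seed Integer seed.
#' @return A \code{data.frame} with columns \code{gene_id}, \code{sample_id},
#'   \code{replicate}, \code{ct}, \code{role} (\code{target} /
#'   \code{housekeeping}) and \code{group}.
#' @export
simulate_ct_table <- function(log2fc, hk_genes = c("UBQ", "ACT11"),
                              n_bio = 3, n_tech = 2,
                              target_ct = 26, hk_ct = 20, ct_sd = 0.2,
                              groups = c(test = "apomictic",
                                         calibrator = "sexual"),
                              seed = 1) {
  if (is.null(names(log2fc))) stop("log2fc must be a named vector")
  set.seed(seed)
  rows <- list()
  for (grp_role in names(groups)) {
    grp <- groups[[grp_role]]
    for (b in seq_len(n_bio)) {
      sid <- sprintf("%s_b%d", grp, b)
      for (r in seq_len(n_tech)) {
        tmean <- target_ct - if (grp_role == "test") log2fc else 0 * log2fc
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = c(names(log2fc), hk_genes),
          sample_id = sid, replicate = r,
          ct = c(tmean + stats::rnorm(length(log2fc), 0, ct_sd),
                 hk_ct + stats::rnorm(length(hk_genes), 0, ct_sd)),
          role = c(rep("target", length(log2fc)),
                   rep("housekeeping", length(hk_genes))),
          group = grp, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
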