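# Stage-wise differential expression between hexaploid apomicts and diploid
# sexuals, with the three-gate call (p < alpha, |log2 FC| > lfc_min,
# BH q < q_max) and Venn-style stage summaries.

#' Differential expression at one developmental stage
#'
#' Tests every gene for a difference between the hexaploid apomictic and
#' diploid sexual groups at one stage. The default is a Welch two-sample t
#' test on log2 values; \code{paired = TRUE} pairs genotypes by sorted
#' genotype id (requires equal group sizes). A gene is called significant
#' when all three gates hold: p < \code{alpha}, |log2 FC| > \code{lfc_min}
#' and Benjamini-Hochberg q < \code{q_max} (q-values computed over all genes
#' tested at this stage). The log2 fold change is the difference of group
#' means of log2 values (apomict minus sexual). Zero within-group variance is
#' handled by a variance floor so that clearly separated groups with
#' degenerate spread are still called.
#'
#' @param mat Gene x sample log2 expression matrix.
#' @param design Sample sheet (see \code{\link{generate_design}}).
#' @param stage Stage label present in the design.
#' @param alpha,lfc_min,q_max The three gate thresholds (defaults 0.01, 2,
#'   0.05).
#' @param paired Use a paired t test over genotype-matched samples.
#' @param var_floor Lower bound on within-group variances.
#' @return A \code{data.frame} with one row per gene: \code{gene_id},
#'   \code{stage}, \code{log2fc}, \code{p_value}, \code{q_value},
#'   \code{direction} (\code{up}/\code{down}/\code{none}) and
#'   \code{significant}.
#' @export
stage_de <- function(mat, design, stage, alpha = 0.01, lfc_min = 2,
                     q_max = 0.05, paired = FALSE, var_floor = 1e-12) {
  if (!stage %in% design$stage)
    stop(sprintf("stage '%s' absent from the design", stage))
  d <- design[design$stage == stage, ]
  apo <- d[d$ploidy == 6, ]
  sex <- d[d$ploidy == 2, ]
  if (!all(c(apo$sample_id, sex$sample_id) %in% colnames(mat)))
    stop("data error: design samples missing from the expression matrix")
  a <- mat[, apo$sample_id, drop = FALSE]
  s <- mat[, sex$sample_id, drop = FALSE]
  na <- ncol(a); ns <- ncol(s)
  if (paired) {
    if (na != ns) stop("paired test requires equal group sizes")
    if (na < 2) stop("need at least 2 genotype pairs for the paired test")
    dm <- a[, order(apo$genotype), drop = FALSE] -
      s[, order(sex$genotype), drop = FALSE]
    lfc <- rowMeans(dm)
    vd <- pmax(row_vars(dm), var_floor)
    tstat <- lfc / sqrt(vd / na)
    dfree <- na - 1
  } else {
    if (na < 2 || ns < 2) stop("need at least 2 samples per group")
    va <- pmax(row_vars(a), var_floor)
    vs <- pmax(row_vars(s), var_floor)
    se2 <- va / na + vs / ns
    lfc <- rowMeans(a) - rowMeans(s)
    tstat <- lfc / sqrt(se2)
    dfree <- se2^2 / ((va / na)^2 / (na - 1) + (vs / ns)^2 / (ns - 1))
  }
  p <- 2 * stats::pt(-abs(tstat), dfree)
  q <- stats::p.adjust(p, method = "BH")
  sig <- p < alpha & abs(lfc) > lfc_min & q < q_max
  data.frame(gene_id = rownames(mat), stage = stage, log2fc = lfc,
             p_value = p, q_value = q,
             direction = ifelse(!sig, "none", ifelse(lfc > 0, "up", "down")),
             significant = sig, row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential expression across all stages
#'
#' Runs \code{\link{stage_de}} per stage. FDR is controlled within each stage
#' by default (stages are screened separately); \code{pooled_fdr = TRUE}
#' recomputes q-values over all stage x gene tests jointly and re-applies the
#' gates.
#'
#' @inheritParams stage_de
#' @param stages Stage labels to test (default: all stages in the design).
#' @param pooled_fdr Pool BH adjustment across stages.
#' @return Named list of per-stage result data.frames.
#' @export
de_all_stages <- function(mat, design, stages = unique(design$stage),
                          alpha = 0.01, lfc_min = 2, q_max = 0.05,
                          paired = FALSE, pooled_fdr = FALSE) {
  res <- lapply(stages, function(st)
    stage_de(mat, design, st, alpha, lfc_min, q_max, paired))
  names(res) <- stages
  if (pooled_fdr) {
    all_p <- unlist(lapply(res, `[[`, "p_value"), use.names = FALSE)
    all_q <- stats::p.adjust(all_p, method = "BH")
    at <- 0
    for (st in stages) {
      n <- nrow(res[[st]])
      res[[st]]$q_value <- all_q[at + seq_len(n)]
      at <- at + n
      sig <- with(res[[st]], p_value < alpha & abs(log2fc) > lfc_min &
                    q_value < q_max)
      res[[st]]$significant <- sig
      res[[st]]$direction <- ifelse(!sig, "none",
                                    ifelse(res[[st]]$log2fc > 0, "up", "down"))
    }
  }
  res
}

#' Venn-style summary of stage-wise DE calls
#'
#' For up- and downregulated calls separately, counts every exclusive Venn
#' region over the stages (all 2^k - 1 regions) and reports per-stage totals
#' and stage-specific counts (genes significant at exactly that one stage).
#'
#' @param results Named list of per-stage DE tables (or one combined
#'   data.frame with a \code{stage} column).
#' @return A list with \code{regions} (\code{direction}, \code{region} label
#'   such as \code{"I&III"}, \code{count}) and \code{per_stage}
#'   (\code{direction}, \code{stage}, \code{total}, \code{stage_specific}).
#' @export
venn_summary <- function(results) {
  if (is.data.frame(results)) results <- split(results, results$stage)
  stages <- names(results)
  if (length(stages) < 1) stop("need at least one stage")
  k <- length(stages)
  regions <- list(); per_stage <- list()
  for (dir in c("up", "down")) {
    sets <- lapply(results, function(r) r$gene_id[r$significant & r$direction == dir])
    genes <- unique(unlist(sets))
    memb <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
    memb <- matrix(memb, nrow = length(genes), ncol = k,
                   dimnames = list(NULL, stages))
    for (mask in seq_len(2^k - 1)) {
      in_set <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
      cnt <- if (length(genes)) {
        sum(apply(memb, 1, function(m) all(m == in_set)))
      } else 0L
      regions[[length(regions) + 1]] <- data.frame(
        direction = dir, region = paste(stages[in_set], collapse = "&"),
        count = cnt, stringsAsFactors = FALSE)
    }
    for (i in seq_len(k)) {
      specific <- if (length(genes)) {
        sum(apply(memb, 1, function(m) m[i] && sum(m) == 1))
      } else 0L
      per_stage[[length(per_stage) + 1]] <- data.frame(
        direction = dir, stage = stages[i], total = length(sets[[i]]),
        stage_specific = specific, stringsAsFactors = FALSE)
    }
  }
  list(regions = do.call(rbind, regions),
       per_stage = do.call(rbind, per_stage))
}

#' Genes differentially expressed in at least one stage
#'
#' Union of significant genes over stages, plus its complement within the
#' tested universe (the non-DE set that feeds the secondary, tetraploid-vs-
#' hexaploid classification).
#'
#' @param results Named list of per-stage DE tables.
#' @return A list with \code{de_genes} and \code{non_de_genes}.
#' @export
select_de_any_stage <- function(results) {
  if (is.data.frame(results)) results <- split(results, results$stage)
  de <- unique(unlist(lapply(results, function(r) r$gene_id[r$significant])))
  universe <- unique(unlist(lapply(results, `[[`, "gene_id")))
  list(de_genes = de, non_de_genes = setdiff(universe, de))
}
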