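# Delta-delta-Ct relative quantification against housekeeping genes, a
# fixed-reallocation randomization test, and sign concordance with array
# fold changes. The method assumes amplification efficiency 2 (no Pfaffl
# correction).

# Replicate-level delta-Ct: target Ct minus the mean housekeeping Ct of the
# same sample x technical replicate. Multiple housekeeping genes enter via
# the arithmetic mean of their Cts (geometric mean on the expression scale).
.replicate_dct <- function(ct_table) {
  req <- c("gene_id", "sample_id", "replicate", "ct", "role", "group")
  miss <- setdiff(req, names(ct_table))
  if (length(miss))
    stop("data error: Ct table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(ct_table$ct)) || any(ct_table$ct <= 0))
    stop("data error: Ct values must be positive")
  hk <- ct_table[ct_table$role == "housekeeping", ]
  tg <- ct_table[ct_table$role == "target", ]
  key <- function(d) paste(d$sample_id, d$replicate, sep = "\r")
  href <- tapply(hk$ct, key(hk), mean)
  tkey <- key(tg)
  missing_hk <- unique(tg$sample_id[!tkey %in% names(href)])
  if (length(missing_hk))
    stop("data error: no housekeeping Ct for sample(s): ",
         paste(missing_hk, collapse = ", "))
  tg$dct <- tg$ct - unname(href[tkey])
  tg
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Per gene and sample group: delta-Ct is the mean target Ct minus the mean
#' housekeeping Ct; delta-delta-Ct subtracts the calibrator group's delta-Ct;
#' the expression ratio is 2^(-ddCt). Replicate scatter is propagated as
#' \code{sqrt(sd_group^2 + sd_calibrator^2)} over replicate-level delta-Ct
#' values.
#'
#' @param ct_table Ct table with columns \code{gene_id}, \code{sample_id},
#'   \code{replicate}, \code{ct}, \code{role} (\code{target} /
#'   \code{housekeeping}) and \code{group}.
#' @param calibrator Group label used as the calibrator.
#' @return A \code{data.frame} per gene x group: \code{gene_id},
#'   \code{group}, \code{delta_ct}, \code{delta_delta_ct}, \code{ratio},
#'   \code{dispersion}. The calibrator group appears with ddCt 0 and ratio 1.
#' @export
delta_delta_ct <- function(ct_table, calibrator) {
  tg <- .replicate_dct(ct_table)
  if (!calibrator %in% tg$group)
    stop(sprintf("calibrator group '%s' absent from the Ct table", calibrator))
  agg <- stats::aggregate(dct ~ gene_id + group, data = tg,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  res <- data.frame(gene_id = agg$gene_id, group = agg$group,
                    delta_ct = agg$dct[, "mean"], sd_rep = agg$dct[, "sd"],
                    stringsAsFactors = FALSE)
  cal <- res[res$group == calibrator, ]
  missing_cal <- setdiff(unique(res$gene_id), cal$gene_id)
  if (length(missing_cal))
    stop("data error: no calibrator measurements for gene(s): ",
         paste(missing_cal, collapse = ", "))
  i <- match(res$gene_id, cal$gene_id)
  res$delta_delta_ct <- res$delta_ct - cal$delta_ct[i]
  res$ratio <- 2^(-res$delta_delta_ct)
  res$dispersion <- sqrt(res$sd_rep^2 + cal$sd_rep[i]^2)
  res$sd_rep <- NULL
  res
}

#' Randomization test for qPCR group differences
#'
#' Fixed-reallocation test on replicate-level delta-Ct values: group labels
#' of the test and calibrator replicates are permuted and the difference of
#' group mean delta-Ct recomputed; the two-sided p-value carries the standard
#' pseudocount (so p is in (0, 1]). Adding a constant to all Cts leaves the
#' p-value unchanged.
#'
#' @param ct_table Ct table (see \code{\link{delta_delta_ct}}).
#' @param test,calibrator Group labels to compare.
#' @param n_perm Number of random reallocations (default 2000).
#' @param seed Integer seed.
#' @return A \code{data.frame}: \code{gene_id}, \code{observed_ddct},
#'   \code{p_value}.
#' @export
qpcr_significance <- function(ct_table, test, calibrator, n_perm = 2000,
                              seed = 1) {
  tg <- .replicate_dct(ct_table)
  genes <- unique(tg$gene_id)
  set.seed(seed)
  rows <- lapply(genes, function(g) {
    x <- tg$dct[tg$gene_id == g & tg$group == test]
    y <- tg$dct[tg$gene_id == g & tg$group == calibrator]
    if (length(x) < 2 || length(y) < 2)
      stop(sprintf("gene '%s': need >= 2 replicates per group", g))
    obs <- mean(x) - mean(y)
    pool <- c(x, y)
    nx <- length(x)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(pool), nx)
      if (abs(mean(pool[idx]) - mean(pool[-idx])) >= abs(obs))
        hits <- hits + 1L
    }
    data.frame(gene_id = g, observed_ddct = obs,
               p_value = (1 + hits) / (n_perm + 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sign concordance between array fold changes and qPCR ratios
#'
#' A gene is concordant when the sign of its qPCR log2 ratio matches the sign
#' of its array log2 fold change. Genes with ratio exactly 1 (log2 ratio 0)
#' are excluded from the denominator.
#'
#' @param array_results Data.frame with \code{gene_id} and \code{log2fc}
#'   (one row per gene; pick the stage of interest upstream).
#' @param quant Output of \code{\link{delta_delta_ct}}; if it contains more
#'   than one non-calibrator group, pass \code{group} to select one.
#' @param group Optional group label to filter \code{quant}.
#' @return A list with \code{per_gene} (\code{gene_id}, \code{log2fc_array},
#'   \code{log2_ratio_qpcr}, \code{concordant}) and \code{fraction}.
#' @export
qpcr_concordance <- function(array_results, quant, group = NULL) {
  if (!is.null(group)) quant <- quant[quant$group == group, ]
  shared <- intersect(array_results$gene_id, quant$gene_id)
  if (length(shared) == 0) stop("data error: no shared genes")
  ar <- array_results[match(shared, array_results$gene_id), ]
  qu <- quant[match(shared, quant$gene_id), ]
  l2r <- log2(qu$ratio)
  concordant <- sign(l2r) == sign(ar$log2fc)
  informative <- l2r != 0
  list(per_gene = data.frame(gene_id = shared, log2fc_array = ar$log2fc,
                             log2_ratio_qpcr = l2r, concordant = concordant,
                             stringsAsFactors = FALSE),
       fraction = mean(concordant[informative]))
}
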