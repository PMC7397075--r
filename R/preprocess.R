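# Probe summarization, cross-array normalization, variance filtering and
# PCA sample QC. The preprocessing chain (log2 -> quantile normalization ->
# median polish) carries the algorithmic substance of RMA; optical background
# correction is deliberately omitted because simulated arrays have none.

#' Summarize probe-level intensities to gene level by median polish
#'
#' Log2-transforms raw intensities and fits, per gene, the additive
#' probe-effect + sample-effect decomposition by Tukey's median polish
#' (\code{stats::medpolish}). The gene-level value of a sample is the overall
#' effect plus its column effect. Single-probe genes are passed through as
#' log2 intensities. Row (probe) order within a gene does not affect the
#' result.
#'
#' @param probes A \code{probe_matrix} (see \code{\link{simulate_expression}})
#'   or any list with \code{intensities} (probe x sample, positive) and
#'   \code{probe_map} (\code{probe_id}, \code{gene_id}).
#' @param eps,maxiter Median-polish convergence tolerance and iteration cap.
#'   Non-convergence at \code{maxiter} is accepted silently: after a handful
#'   of sweeps remaining changes are far below biological effect sizes.
#' @return Gene x sample matrix of log2 expression values.
#' @export
summarize_probes <- function(probes, eps = 1e-6, maxiter = 10L) {
  x <- probes$intensities
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(x))[1]
    stop(sprintf("data error: non-positive or missing intensity for probe '%s'",
                 rownames(x)[i]))
  }
  lx <- log2(x)
  map <- probes$probe_map
  genes <- unique(map$gene_id)
  idx <- split(seq_len(nrow(map)), factor(map$gene_id, levels = genes))
  out <- matrix(NA_real_, length(genes), ncol(x),
                dimnames = list(genes, colnames(x)))
  for (g in seq_along(idx)) {
    rows <- idx[[g]]
    if (length(rows) == 1L) {
      out[g, ] <- lx[rows, ]
    } else {
      mp <- suppressWarnings(
        stats::medpolish(lx[rows, , drop = FALSE], eps = eps,
                         maxiter = maxiter, trace.iter = FALSE))
      out[g, ] <- mp$overall + mp$col
    }
  }
  out
}

#' Quantile-normalize expression columns
#'
#' Forces every sample column onto the common reference distribution given by
#' the row-wise mean of the sorted columns, preserving within-sample ranks.
#' After normalization all columns hold the identical sorted multiset of
#' values (ties are broken by order of occurrence). Idempotent.
#'
#' @param mat Gene x sample matrix (>= 2 samples; a single sample is returned
#'   unchanged with a warning).
#' @return Normalized matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  if (ncol(mat) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input unchanged")
    return(mat)
  }
  if (any(!is.finite(mat))) stop("data error: matrix contains non-finite values")
  ref <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) out[order(mat[, j]), j] <- ref
  out
}

#' Filter genes by relative standard deviation (sigma / sigma-max)
#'
#' Computes each gene's sample SD across the sexual and apomictic arrays,
#' scales by the maximum SD over genes, and removes genes whose ratio falls
#' below \code{threshold}. The gene attaining the maximum SD (ratio 1) is
#' always kept. By default the SD is pooled over diploid + hexaploid samples;
#' the single-genotype tetraploid only contributes if
#' \code{include_tetraploid = TRUE}. Without a design, all columns are used.
#'
#' @param mat Gene x sample log2 expression matrix.
#' @param threshold Minimum sigma/sigma-max ratio in [0, 1]; default 0.7.
#' @param design Optional sample sheet used to select the columns entering
#'   the SD.
#' @param include_tetraploid Include tetraploid samples in the SD.
#' @return A list with \code{matrix} (kept genes) and \code{report}
#'   (\code{gene_id}, \code{sigma}, \code{sigma_ratio}, \code{kept}).
#' @export
variance_filter <- function(mat, threshold = 0.7, design = NULL,
                            include_tetraploid = FALSE) {
  if (threshold < 0 || threshold > 1)
    stop("config error: variance threshold must lie in [0, 1]")
  if (nrow(mat) == 0) {
    return(list(matrix = mat,
                report = data.frame(gene_id = character(), sigma = numeric(),
                                    sigma_ratio = numeric(), kept = logical(),
                                    stringsAsFactors = FALSE)))
  }
  cols <- seq_len(ncol(mat))
  if (!is.null(design)) {
    keep_pl <- c(2, 6, if (include_tetraploid) 4)
    cols <- which(colnames(mat) %in%
                    design$sample_id[design$ploidy %in% keep_pl])
  }
  sigma <- row_sds(mat[, cols, drop = FALSE])
  smax <- max(sigma)
  ratio <- if (smax > 0) sigma / smax else rep(0, length(sigma))
  kept <- ratio >= threshold
  list(matrix = mat[kept, , drop = FALSE],
       report = data.frame(gene_id = rownames(mat), sigma = sigma,
                           sigma_ratio = ratio, kept = kept,
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' PCA sample scores for expression QC
#'
#' Principal components of the samples (genes as variables, centered, not
#' scaled). In this design the leading components separate samples by ploidy
#' and reproductive mode; the scores are the standard visual QC for the
#' normalized matrix.
#'
#' @param mat Gene x sample matrix (>= 2 samples).
#' @param n_components Number of components to return (< number of samples).
#' @return A list with \code{scores} (data.frame: \code{sample_id} + one
#'   column per component, each centered at 0) and \code{var_explained}
#'   (non-increasing fractions of total variance, summing to <= 1).
#' @export
pca_scores <- function(mat, n_components = 2) {
  if (ncol(mat) < 2) stop("PCA requires at least 2 samples")
  if (n_components >= ncol(mat))
    stop("n_components must be smaller than the number of samples")
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- seq_len(n_components)
  scores <- data.frame(sample_id = colnames(mat), pc$x[, k, drop = FALSE],
                       row.names = NULL, stringsAsFactors = FALSE)
  list(scores = scores, var_explained = ve[k])
}
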