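# SNP-based parental-origin screen: coverage gating followed by allele
# identity between the hexaploid hybrid and each putative parent.

.AMBIGUOUS_CALLS <- c("ambiguous", "missing", "N", "-", "")

#' Filter SNPs by read depth in every individual
#'
#' Keeps SNPs whose depth is >= \code{min_depth} in all individuals (every
#' \code{depth_*} column). Genes losing all their SNPs are dropped and
#' reported via a message.
#'
#' @param snp_table SNP table with \code{gene_id}, \code{pos}, and paired
#'   \code{allele_*} / \code{depth_*} columns per individual.
#' @param min_depth Minimum read depth (>= 1; default 10 — the screen only
#'   requires "sufficient" coverage, so the threshold is exposed).
#' @return The filtered SNP table.
#' @export
coverage_filter <- function(snp_table, min_depth = 10) {
  if (min_depth < 1) stop("config error: min_depth must be >= 1")
  depth_cols <- grep("^depth_", names(snp_table), value = TRUE)
  if (length(depth_cols) == 0) stop("data error: no depth_* columns found")
  keep <- Reduce(`&`, lapply(depth_cols,
                             function(cn) snp_table[[cn]] >= min_depth))
  dropped <- setdiff(unique(snp_table$gene_id),
                     unique(snp_table$gene_id[keep]))
  if (length(dropped))
    message("genes dropped for insufficient coverage: ",
            paste(dropped, collapse = ", "))
  snp_table[keep, , drop = FALSE]
}

#' Parental-origin verdict per gene from SNP identity
#'
#' Computes, per gene, the percentage of SNPs at which the hybrid's allele
#' matches each parent, over the SNPs where all three calls are unambiguous.
#' Verdicts: 100% match to the tetraploid but not the diploid implies
#' \code{tetraploid_origin} (and symmetrically \code{diploid_origin}); 100%
#' to both is \code{shared}; neither is \code{ambiguous}; genes without any
#' evaluable SNP are \code{insufficient_coverage}.
#'
#' @param snp_table SNP table (typically after \code{\link{coverage_filter}}).
#' @param hybrid,parent_2x,parent_4x Individual names matching the
#'   \code{allele_<individual>} columns.
#' @return A \code{data.frame}: \code{gene_id}, \code{n_snps_evaluated},
#'   \code{pct_match_4x}, \code{pct_match_2x}, \code{verdict}.
#' @export
parental_similarity <- function(snp_table, hybrid = "hexaploid",
                                parent_2x = "diploid",
                                parent_4x = "tetraploid") {
  cols <- paste0("allele_", c(hybrid, parent_2x, parent_4x))
  missing_cols <- setdiff(cols, names(snp_table))
  if (length(missing_cols))
    stop("data error: missing columns: ", paste(missing_cols, collapse = ", "))
  genes <- unique(snp_table$gene_id)
  amb <- function(x) is.na(x) | x %in% .AMBIGUOUS_CALLS
  rows <- lapply(genes, function(g) {
    sub <- snp_table[snp_table$gene_id == g, ]
    h <- sub[[cols[1]]]; p2 <- sub[[cols[2]]]; p4 <- sub[[cols[3]]]
    ok <- !amb(h) & !amb(p2) & !amb(p4)
    n_eval <- sum(ok)
    if (n_eval == 0)
      return(data.frame(gene_id = g, n_snps_evaluated = 0L,
                        pct_match_4x = NA_real_, pct_match_2x = NA_real_,
                        verdict = "insufficient_coverage",
                        stringsAsFactors = FALSE))
    m4 <- 100 * mean(h[ok] == p4[ok])
    m2 <- 100 * mean(h[ok] == p2[ok])
    verdict <- if (m4 == 100 && m2 == 100) "shared"
      else if (m4 == 100) "tetraploid_origin"
      else if (m2 == 100) "diploid_origin"
      else "ambiguous"
    data.frame(gene_id = g, n_snps_evaluated = n_eval, pct_match_4x = m4,
               pct_match_2x = m2, verdict = verdict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
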