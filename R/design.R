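#' Build a genotype-by-stage microarray design
#'
#' Lays out the sample sheet for an ovule developmental series in a mixed
#' ploidy system: every genotype is hybridized to one array per developmental
#' stage. Diploid and tetraploid genotypes are sexual; hexaploid genotypes are
#' apomictic hybrids. The default design (3 diploid + 1 tetraploid + 3
#' hexaploid genotypes, four stages) yields 28 arrays from 7 genotypes.
#'
#' @param n_diploid,n_tetraploid,n_hexaploid Number of genotypes per cytotype
#'   (positive integers).
#' @param stages Number of developmental stages (>= 2), labelled with Roman
#'   numerals.
#' @return A sample sheet: a \code{data.frame} with columns \code{sample_id},
#'   \code{genotype}, \code{ploidy} (2, 4 or 6), \code{mode} (\code{"sexual"}
#'   or \code{"apomictic"}) and \code{stage}; one row per array.
#' @examples
#' design <- generate_design()
#' nrow(design)                      # 28
#' table(design$ploidy) / 4          # 3 diploid, 1 tetraploid, 3 hexaploid
#' @export
generate_design <- function(n_diploid = 3, n_tetraploid = 1,
                            n_hexaploid = 3, stages = 4) {
  counts <- c(n_diploid, n_tetraploid, n_hexaploid)
  if (length(stages) != 1 || is.na(stages) || stages < 2)
    stop("invalid design: need at least 2 developmental stages")
  if (any(is.na(counts)) || any(counts < 1) || any(counts != round(counts)))
    stop("invalid design: genotype counts must be positive integers")
  labels <- stage_labels(stages)
  genotype <- c(sprintf("dip_sex_%d", seq_len(n_diploid)),
                sprintf("tet_sex_%d", seq_len(n_tetraploid)),
                sprintf("hex_apo_%d", seq_len(n_hexaploid)))
  ploidy <- rep(c(2L, 4L, 6L), counts)
  mode <- rep(c("sexual", "sexual", "apomictic"), counts)
  out <- data.frame(
    genotype = rep(genotype, each = stages),
    ploidy   = rep(ploidy, each = stages),
    mode     = rep(mode, each = stages),
    stage    = rep(labels, times = length(genotype)),
    stringsAsFactors = FALSE)
  out$sample_id <- sprintf("%s_st%s", out$genotype, out$stage)
  out[, c("sample_id", "genotype", "ploidy", "mode", "stage")]
}
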