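# Small numeric helpers shared across modules.

# Row variances with the n-1 (sample) denominator; the pipeline uses sample
# SDs throughout.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

row_sds <- function(x) sqrt(row_vars(x))

#' Developmental stage labels
#'
#' Roman-numeral labels for a developmental series (I, II, III, IV, ...).
#'
#' @param stages Number of stages.
#' @return Character vector of stage labels.
#' @export
stage_labels <- function(stages) {
  as.character(utils::as.roman(seq_len(stages)))
}
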