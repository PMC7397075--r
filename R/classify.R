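# Expression-state classification: partitions genes, per stage, into
# transgressive, parent-of-origin and ploidy (additive) patterns using
# two-standard-deviation bands around the diploid and hexaploid groups, with
# the single-replicate tetraploid entering as a point value. Genes that are
# not differentially expressed get the secondary tetraploid-vs-hexaploid
# (diploid parent-of-origin) screen.

#' Per-stage group statistics for classification
#'
#' Mean and sample SD (n-1 denominator) of the diploid and hexaploid groups,
#' and the tetraploid value (the mean when more than one tetraploid sample is
#' available; the single-genotype default design has no tetraploid SD).
#'
#' @param mat Gene x sample log2 expression matrix.
#' @param design Sample sheet.
#' @param stage Stage label; needs >= 2 diploid, >= 2 hexaploid and >= 1
#'   tetraploid samples.
#' @return A \code{data.frame}: \code{gene_id}, \code{stage}, \code{mean_2x},
#'   \code{sd_2x}, \code{mean_6x}, \code{sd_6x}, \code{value_4x}.
#' @export
group_stats <- function(mat, design, stage) {
  d <- design[design$stage == stage, ]
  c2 <- d$sample_id[d$ploidy == 2]
  c4 <- d$sample_id[d$ploidy == 4]
  c6 <- d$sample_id[d$ploidy == 6]
  if (length(c2) < 2 || length(c6) < 2)
    stop("need at least 2 diploid and 2 hexaploid samples at the stage")
  if (length(c4) < 1) stop("missing tetraploid sample at the stage")
  data.frame(
    gene_id = rownames(mat), stage = stage,
    mean_2x = rowMeans(mat[, c2, drop = FALSE]),
    sd_2x = row_sds(mat[, c2, drop = FALSE]),
    mean_6x = rowMeans(mat[, c6, drop = FALSE]),
    sd_6x = row_sds(mat[, c6, drop = FALSE]),
    value_4x = rowMeans(mat[, c4, drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Floor degenerate group SDs, warning once per call.
.floor_sds <- function(stats_df, sd_floor) {
  if (nrow(stats_df) && any(stats_df$sd_2x < sd_floor | stats_df$sd_6x < sd_floor))
    warning(sprintf("group SD below %g for some genes; floored", sd_floor))
  stats_df$sd_2x <- pmax(stats_df$sd_2x, sd_floor)
  stats_df$sd_6x <- pmax(stats_df$sd_6x, sd_floor)
  stats_df
}

#' Classify differentially expressed genes into expression states
#'
#' Applies the two-standard-deviation band rules to genes already called
#' differentially expressed between hexaploid apomicts and diploid sexuals
#' (the caller enforces that precondition). Rules are evaluated in order,
#' first match wins; similarity clauses are inclusive (<=), difference
#' clauses exclusive (>), so boundary values count as "similar". Each band
#' uses the SD of the reference group being compared against:
#'
#' (a) transgressive: the tetraploid sits inside the diploid band
#' (|value_4x - mean_2x| <= k * sd_2x) while the hexaploid lies outside both
#' the diploid band and the hexaploid-SD band around the tetraploid
#' (|mean_6x - mean_2x| > k * sd_2x and |mean_6x - value_4x| > k * sd_6x) -
#' both parents agree, the hybrid is outside their range.
#'
#' (b) po_4x (tetraploid parent-of-origin / expression-level dominance): the
#' tetraploid matches the hexaploid (|value_4x - mean_6x| <= k * sd_6x) but
#' not the diploid (|value_4x - mean_2x| > k * sd_2x).
#'
#' (c) ploidy (additivity): group means ordered strictly monotonically with
#' dosage (mean_2x < value_4x < mean_6x or reversed) and both polyploids
#' outside the diploid band.
#'
#' (d) otherwise unclassified. Direction is the sign of mean_6x - mean_2x.
#'
#' @param stats A \code{\link{group_stats}} data.frame (rows restricted to DE
#'   genes).
#' @param k Band half-width in group SDs (default 2).
#' @param sd_floor Replacement for zero/near-zero reference SDs (with a
#'   warning).
#' @return The input rows with \code{class} (\code{transgressive},
#'   \code{po_4x}, \code{ploidy}, \code{unclassified}) and \code{direction}
#'   (\code{up}/\code{down}, NA when unclassified) appended.
#' @export
classify_de_gene <- function(stats, k = 2, sd_floor = 1e-6) {
  stats <- .floor_sds(stats, sd_floor)
  d42 <- stats$value_4x - stats$mean_2x
  d62 <- stats$mean_6x - stats$mean_2x
  d64 <- stats$mean_6x - stats$value_4x
  b2 <- k * stats$sd_2x
  b6 <- k * stats$sd_6x
  a <- abs(d42) <= b2 & abs(d62) > b2 & abs(d64) > b6
  b <- !a & abs(d64) <= b6 & abs(d42) > b2
  mono <- (stats$mean_2x < stats$value_4x & stats$value_4x < stats$mean_6x) |
          (stats$mean_2x > stats$value_4x & stats$value_4x > stats$mean_6x)
  cc <- !a & !b & mono & abs(d42) > b2 & abs(d62) > b2
  cls <- ifelse(a, "transgressive",
         ifelse(b, "po_4x",
         ifelse(cc, "ploidy", "unclassified")))
  out <- stats
  out$class <- cls
  out$direction <- ifelse(cls == "unclassified", NA_character_,
                          ifelse(d62 >= 0, "up", "down"))
  out
}

#' Secondary classification of non-DE genes (diploid parent-of-origin)
#'
#' For genes without a hexaploid-diploid expression difference, compares the
#' tetraploid value against the hexaploid mean: genes where the tetraploid
#' deviates by more than \code{k} hexaploid SDs are classified \code{po_2x}
#' (the hexaploid tracks the diploid parent; the tetraploid is the outlier).
#' Direction reports whether the tetraploid is higher (\code{up}) or lower
#' (\code{down}) than the hexaploid.
#'
#' @inheritParams classify_de_gene
#' @return The input rows with \code{class} (\code{po_2x} or
#'   \code{unclassified}) and \code{direction} appended.
#' @export
classify_non_de_gene <- function(stats, k = 2, sd_floor = 1e-6) {
  stats <- .floor_sds(stats, sd_floor)
  d46 <- stats$value_4x - stats$mean_6x
  hit <- abs(d46) > k * stats$sd_6x
  out <- stats
  out$class <- ifelse(hit, "po_2x", "unclassified")
  out$direction <- ifelse(hit, ifelse(d46 > 0, "up", "down"), NA_character_)
  out
}

#' Build the full per-stage expression-class table
#'
#' Splits the gene universe into the DE set (significant in at least one
#' stage) and its complement, and applies \code{\link{classify_de_gene}} or
#' \code{\link{classify_non_de_gene}} respectively at every stage.
#'
#' @param mat Gene x sample log2 expression matrix (the classification
#'   universe; genes absent from the DE tables are treated as non-DE).
#' @param design Sample sheet.
#' @param de_results Named list of per-stage DE tables from
#'   \code{\link{de_all_stages}}.
#' @param k,sd_floor Passed to the rule functions.
#' @return A \code{data.frame} with \code{gene_id}, \code{stage},
#'   \code{class}, \code{direction}, \code{de_flag}.
#' @export
classify_expression <- function(mat, design, de_results, k = 2,
                                sd_floor = 1e-6) {
  sel <- select_de_any_stage(de_results)
  stages <- names(de_results)
  out <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    gs <- group_stats(mat, design, stages[i])
    is_de <- gs$gene_id %in% sel$de_genes
    r1 <- classify_de_gene(gs[is_de, , drop = FALSE], k, sd_floor)
    r1$de_flag <- rep(TRUE, nrow(r1))
    r2 <- classify_non_de_gene(gs[!is_de, , drop = FALSE], k, sd_floor)
    r2$de_flag <- rep(FALSE, nrow(r2))
    cols <- c("gene_id", "stage", "class", "direction", "de_flag")
    out[[i]] <- rbind(r1[, cols], r2[, cols])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stage-by-class summary table with row fractions
#'
#' Counts classified DE genes per direction x stage x class (transgressive,
#' parent-of-origin, ploidy), with row totals and within-row fractions
#' rounded to 2 decimals, plus grand-total rows per direction.
#'
#' @param class_table An expression-class table (see
#'   \code{\link{classify_expression}}); only rows with class
#'   \code{transgressive}, \code{po_4x} or \code{ploidy} are counted.
#' @param stages Stage order for the summary rows (default: sorted unique
#'   stages of the table).
#' @return A \code{data.frame} with columns \code{direction}, \code{stage},
#'   \code{transgressive}, \code{transgressive_frac},
#'   \code{parent_of_origin}, \code{parent_of_origin_frac}, \code{ploidy},
#'   \code{ploidy_frac}, \code{total}; grand totals appear as stage
#'   \code{"Total"}.
#' @export
summarize_classes <- function(class_table, stages = NULL) {
  keep <- class_table$class %in% c("transgressive", "po_4x", "ploidy") &
    !is.na(class_table$direction)
  tab <- class_table[keep, , drop = FALSE]
  if (is.null(stages)) stages <- sort(unique(class_table$stage))
  frac <- function(n, tot) if (tot > 0) round(n / tot, 2) else 0
  rows <- list()
  for (dir in c("up", "down")) {
    tot_t <- tot_p <- tot_pl <- 0L
    for (st in stages) {
      sub <- tab[tab$direction == dir & tab$stage == st, ]
      n_t <- sum(sub$class == "transgressive")
      n_p <- sum(sub$class == "po_4x")
      n_pl <- sum(sub$class == "ploidy")
      tot <- n_t + n_p + n_pl
      rows[[length(rows) + 1]] <- data.frame(
        direction = dir, stage = st,
        transgressive = n_t, transgressive_frac = frac(n_t, tot),
        parent_of_origin = n_p, parent_of_origin_frac = frac(n_p, tot),
        ploidy = n_pl, ploidy_frac = frac(n_pl, tot),
        total = tot, stringsAsFactors = FALSE)
      tot_t <- tot_t + n_t; tot_p <- tot_p + n_p; tot_pl <- tot_pl + n_pl
    }
    grand <- tot_t + tot_p + tot_pl
    rows[[length(rows) + 1]] <- data.frame(
      direction = dir, stage = "Total",
      transgressive = tot_t, transgressive_frac = frac(tot_t, grand),
      parent_of_origin = tot_p, parent_of_origin_frac = frac(tot_p, grand),
      ploidy = tot_pl, ploidy_frac = frac(tot_pl, grand),
      total = grand, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Recovery of planted classes from a classification table
#'
#' Compares an expression-class table against the generator's truth: a gene
#' counts as recovered when its planted class was assigned at one or more of
#' its affected stages (mirroring the gene-level "differentially expressed in
#' at least one stage" selection the classification feeds on).
#'
#' @param truth Truth table from \code{\link{plant_truth}}.
#' @param class_table Output of \code{\link{classify_expression}}.
#' @return A \code{data.frame} per non-null planted class: \code{class},
#'   \code{n_planted}, \code{n_recovered}, \code{recovery_pct}.
#' @export
planted_class_recovery <- function(truth, class_table) {
  classes <- setdiff(expression_classes, "null")
  hits <- class_table[!is.na(class_table$class) &
                        class_table$class %in% classes, ]
  key <- paste(hits$gene_id, hits$stage, hits$class)
  rows <- lapply(classes, function(cl) {
    tg <- truth[truth$planted_class == cl, ]
    if (nrow(tg) == 0)
      return(data.frame(class = cl, n_planted = 0L, n_recovered = 0L,
                        recovery_pct = NA_real_, stringsAsFactors = FALSE))
    rec <- vapply(seq_len(nrow(tg)), function(i) {
      aff <- strsplit(tg$affected_stages[i], ",", fixed = TRUE)[[1]]
      any(paste(tg$gene_id[i], aff, cl) %in% key)
    }, logical(1))
    data.frame(class = cl, n_planted = nrow(tg), n_recovered = sum(rec),
               recovery_pct = 100 * mean(rec), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
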