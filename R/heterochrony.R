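# Short time-series profile analysis for heterochrony detection: enumerate
# candidate trajectories over the developmental stages, assign genes by
# correlation, assess profile occupancy against a within-gene permutation
# null, and compare sexual vs apomictic assignments by hypergeometric
# intersection tests. At four stages and one unit of change per transition
# the full candidate set (27 profiles) is tractable, so no greedy profile
# subselection is needed.

#' Enumerate candidate model profiles
#'
#' All trajectories over \code{stages} time points whose per-transition change
#' is an integer in [-c_units, c_units]; each profile carries its cumulative
#' vector anchored at 0 (stage I). Profile ids are assigned in lexicographic
#' order of the delta vectors, so ordering is deterministic.
#'
#' @param stages Number of stages (>= 2).
#' @param c_units Maximum unit change per transition (>= 1).
#' @return An object of class \code{model_profiles}: list with
#'   \code{profile_id}, \code{deltas} ((2c+1)^(stages-1) x (stages-1)
#'   matrix) and \code{cumulative} (profiles x stages, first column 0).
#' @export
enumerate_profiles <- function(stages = 4, c_units = 1) {
  if (stages < 2) stop("need at least 2 stages")
  if (c_units < 1) stop("c_units must be >= 1")
  vals <- seq.int(-c_units, c_units)
  g <- as.data.frame(expand.grid(rep(list(vals), stages - 1),
                                 KEEP.OUT.ATTRS = FALSE))
  g <- g[do.call(order, g), , drop = FALSE]
  deltas <- unname(as.matrix(g))
  cumulative <- cbind(0, t(apply(deltas, 1, cumsum)))
  if (stages == 2) cumulative <- cbind(0, deltas)
  structure(list(profile_id = sprintf("p%03d", seq_len(nrow(deltas))),
                 deltas = deltas, cumulative = unname(cumulative),
                 stages = stages, c_units = c_units),
            class = "model_profiles")
}

# Correlation-based argmax assignment of centered stage vectors to profiles.
# Flat genes (zero variance over stages) go to the all-zero profile; the
# all-zero profile is otherwise excluded (undefined correlation). Ties break
# toward the lowest profile id.
.assign_to_profiles <- function(stage_values, profiles) {
  x <- stage_values - rowMeans(stage_values)
  sdx <- sqrt(rowSums(x^2))
  p <- profiles$cumulative - rowMeans(profiles$cumulative)
  sdp <- sqrt(rowSums(p^2))
  r <- (x %*% t(p)) / outer(sdx, sdp)
  flat_profile <- sdp == 0
  r[, flat_profile] <- -Inf
  r[!is.finite(r)] <- -Inf
  idx <- max.col(r, ties.method = "first")
  corr <- r[cbind(seq_len(nrow(r)), idx)]
  flat_gene <- sdx == 0
  zero_idx <- which(flat_profile)[1]
  if (any(flat_gene)) {
    if (is.na(zero_idx))
      stop("flat genes present but no all-zero profile in the candidate set")
    idx[flat_gene] <- zero_idx
    corr[flat_gene] <- NA_real_
  }
  list(idx = idx, correlation = corr)
}

#' Assign genes of one reproductive mode to model profiles
#'
#' Computes per-gene stage means over the genotypes of one mode, centers them
#' at stage I, and assigns each gene to the profile with the highest Pearson
#' correlation between its stage trajectory and the profile's cumulative
#' vector. Constant genes go to the all-zero (flat) profile.
#'
#' @param mat Gene x sample log2 expression matrix.
#' @param design Sample sheet.
#' @param mode \code{"sexual"} or \code{"apomictic"}.
#' @param profiles Candidate set from \code{\link{enumerate_profiles}}.
#' @return An object of class \code{profile_assignment}: list with
#'   \code{assignments} (\code{gene_id}, \code{mode}, \code{profile_id},
#'   \code{correlation}), \code{stage_means}, \code{profiles}, \code{mode}.
#' @export
assign_profiles <- function(mat, design, mode, profiles) {
  d <- design[design$mode == mode, ]
  if (nrow(d) == 0) stop(sprintf("no samples with mode '%s'", mode))
  stages <- unique(design$stage)
  if (length(stages) != profiles$stages)
    stop("profile set and design disagree on the number of stages")
  sm <- vapply(stages, function(st)
    rowMeans(mat[, d$sample_id[d$stage == st], drop = FALSE]),
    numeric(nrow(mat)))
  if (nrow(mat) == 1) sm <- matrix(sm, nrow = 1)
  dimnames(sm) <- list(rownames(mat), stages)
  centered <- sm - sm[, 1]
  asg <- .assign_to_profiles(centered, profiles)
  structure(list(
    assignments = data.frame(gene_id = rownames(mat), mode = mode,
                             profile_id = profiles$profile_id[asg$idx],
                             correlation = asg$correlation,
                             row.names = NULL, stringsAsFactors = FALSE),
    stage_means = sm, profiles = profiles, mode = mode),
    class = "profile_assignment")
}

#' Permutation significance of profile occupancy
#'
#' The null is built by permuting each gene's stage values independently and
#' re-running the assignment. Two p-values are reported per profile. The
#' primary \code{p_value} is the binomial upper tail of the observed count
#' given the per-gene assignment probability estimated from all permutations
#' (more permutations sharpen that estimate); this is what the Bonferroni
#' flag uses, at familywise level \code{bonferroni_alpha} over the number of
#' profiles. \code{p_permutation} is the direct empirical tail with the
#' standard pseudocount, p = (1 + #{null count >= observed}) / (n_perm + 1),
#' always in (0, 1]; its resolution is bounded below by 1/(n_perm + 1), so
#' it cannot by itself resolve Bonferroni-corrected calls at small alpha.
#'
#' @param assignment A \code{profile_assignment}.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed.
#' @param bonferroni_alpha Familywise level for the significance flag.
#' @return A \code{data.frame}: \code{profile_id}, \code{observed},
#'   \code{expected}, \code{p_value}, \code{p_permutation},
#'   \code{bonferroni_significant}.
#' @export
profile_significance <- function(assignment, n_perm = 1000, seed = 1,
                                 bonferroni_alpha = 0.01) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  profiles <- assignment$profiles
  nprof <- length(profiles$profile_id)
  sm <- assignment$stage_means
  n_genes <- nrow(sm)
  obs <- tabulate(match(assignment$assignments$profile_id,
                        profiles$profile_id), nbins = nprof)
  set.seed(seed)
  ge <- integer(nprof)
  total <- numeric(nprof)
  for (b in seq_len(n_perm)) {
    perm <- t(apply(sm, 1, sample))
    idx <- .assign_to_profiles(perm - rowMeans(perm), profiles)$idx
    cnt <- tabulate(idx, nbins = nprof)
    ge <- ge + (cnt >= obs)
    total <- total + cnt
  }
  p_perm <- (1 + ge) / (n_perm + 1)
  prob <- pmax(total / (n_perm * n_genes), 1 / (n_perm * n_genes + 1))
  p_binom <- stats::pbinom(obs - 1, n_genes, prob, lower.tail = FALSE)
  data.frame(profile_id = profiles$profile_id, observed = obs,
             expected = prob * n_genes, p_value = p_binom,
             p_permutation = p_perm,
             bonferroni_significant = p_binom * nprof < bonferroni_alpha,
             stringsAsFactors = FALSE)
}

#' Compare profile assignments between reproductive modes
#'
#' For every (sexual profile, apomictic profile) pair, reports the size of
#' the gene intersection and its hypergeometric enrichment p-value over the
#' shared gene universe. Pairs with intersection >= \code{min_intersection}
#' and p < \code{p_max} are selected; genes in selected pairs whose two
#' profiles differ are returned as the mode-divergent (heterochrony
#' candidate) set.
#'
#' @param sexual,apomictic \code{profile_assignment} objects (or plain
#'   data.frames with \code{gene_id} and \code{profile_id}) over a shared
#'   gene universe.
#' @param min_intersection Minimum intersection size (default 1).
#' @param p_max Maximum uncorrected intersection p-value (default 0.05).
#' @return A list with \code{pairs} (\code{profile_sexual},
#'   \code{profile_apomictic}, \code{n_sexual}, \code{n_apomictic},
#'   \code{n_intersection}, \code{p_value}, \code{selected}) and
#'   \code{divergent_genes}.
#' @export
compare_modes <- function(sexual, apomictic, min_intersection = 1,
                          p_max = 0.05) {
  sx <- if (inherits(sexual, "profile_assignment")) sexual$assignments else sexual
  ap <- if (inherits(apomictic, "profile_assignment")) apomictic$assignments else apomictic
  universe <- intersect(sx$gene_id, ap$gene_id)
  if (length(universe) == 0) stop("assignments share no genes")
  sx <- sx[sx$gene_id %in% universe, ]
  ap <- ap[ap$gene_id %in% universe, ]
  n_univ <- length(universe)
  profs_s <- sort(unique(sx$profile_id))
  profs_a <- sort(unique(ap$profile_id))
  rows <- list(); divergent <- character()
  for (ps in profs_s) {
    set_s <- sx$gene_id[sx$profile_id == ps]
    for (pa in profs_a) {
      set_a <- ap$gene_id[ap$profile_id == pa]
      inter <- intersect(set_s, set_a)
      kk <- length(inter)
      p <- stats::phyper(kk - 1, length(set_s), n_univ - length(set_s),
                         length(set_a), lower.tail = FALSE)
      sel <- kk >= min_intersection && p < p_max
      rows[[length(rows) + 1]] <- data.frame(
        profile_sexual = ps, profile_apomictic = pa,
        n_sexual = length(set_s), n_apomictic = length(set_a),
        n_intersection = kk, p_value = p, selected = sel,
        stringsAsFactors = FALSE)
      if (sel && ps != pa) divergent <- c(divergent, inter)
    }
  }
  list(pairs = do.call(rbind, rows),
       divergent_genes = sort(unique(divergent)))
}
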