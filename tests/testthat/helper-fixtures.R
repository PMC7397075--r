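# Shared fixtures and independent oracles used across test files.

# Small simulated dataset: design, truth, probes, summarized matrix.
make_small_dataset <- function(n_genes = 200, noise_sd = 0.3, seed = 42,
                               probes_per_gene = 3, effect_size = 3) {
  design <- generate_design()
  truth <- plant_truth(n_genes, effect_size = effect_size, seed = seed)
  probes <- simulate_expression(truth, design, noise_sd = noise_sd,
                                probes_per_gene = probes_per_gene,
                                seed = seed + 1)
  list(design = design, truth = truth, probes = probes,
       expr = summarize_probes(probes))
}

# Expression-class table built from published stage-by-class counts
# (one row per counted gene), for marginal-arithmetic checks.
class_table_from_counts <- function(counts) {
  rows <- counts[rep(seq_len(nrow(counts)), counts$count), ]
  data.frame(gene_id = sprintf("ref_%05d", seq_len(nrow(rows))),
             stage = rows$stage, class = rows$class,
             direction = rows$direction, de_flag = TRUE,
             stringsAsFactors = FALSE)
}

reference_counts <- function() {
  path <- system.file("extdata", "ovule_class_counts.tsv",
                      package = "ploidyExpress")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Brute-force Venn region counts: for each non-empty stage subset, count the
# genes belonging to exactly that subset. Independent of venn_summary.
brute_force_regions <- function(sets) {
  stages <- names(sets)
  k <- length(stages)
  genes <- unique(unlist(sets))
  out <- list()
  for (mask in seq_len(2^k - 1)) {
    in_set <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    cnt <- sum(vapply(genes, function(g) {
      all(vapply(seq_len(k), function(i)
        (g %in% sets[[i]]) == in_set[i], logical(1)))
    }, logical(1)))
    out[[paste(stages[in_set], collapse = "&")]] <- cnt
  }
  out
}

# Exhaustive hypergeometric upper tail: probability that a uniform draw of
# size n_draw from a universe of size n_univ overlaps a fixed set of size
# n_fixed in >= k elements, by enumerating all draws.
exhaustive_overlap_p <- function(n_univ, n_fixed, n_draw, k) {
  draws <- utils::combn(n_univ, n_draw)
  hits <- apply(draws, 2, function(d) sum(d <= n_fixed) >= k)
  mean(hits)
}
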