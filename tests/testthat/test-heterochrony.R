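# Profile enumeration, correlation assignment, permutation significance and
# between-mode intersection tests.

test_that("profile enumeration covers the delta lattice exactly once", {
  p <- enumerate_profiles(4, 1)
  expect_equal(length(p$profile_id), 27)  # 3^3
  expect_equal(nrow(unique(as.data.frame(p$deltas))), 27)
  expect_true(all(p$deltas %in% -1:1))
  expect_equal(p$cumulative[, 1], rep(0, 27))
  expect_equal(t(apply(p$cumulative, 1, diff)), p$deltas,
               ignore_attr = TRUE)
  zero <- apply(p$deltas, 1, function(d) all(d == 0))
  expect_equal(sum(zero), 1)
  p2 <- enumerate_profiles(2, 1)
  expect_equal(length(p2$profile_id), 3)  # down, flat, up
  # deterministic ids
  expect_identical(enumerate_profiles(4, 1), p)
})

mk_mode_matrix <- function(stage_means, design, mode) {
  # expand per-gene stage means into a sample matrix for one mode (exact)
  d <- design
  m <- matrix(NA_real_, nrow(stage_means), nrow(d),
              dimnames = list(rownames(stage_means), d$sample_id))
  for (j in seq_len(nrow(d))) m[, j] <- stage_means[, d$stage[j]]
  m
}

test_that("assignment matches exact ramps and brute-force argmax", {
  design <- generate_design()
  profs <- enumerate_profiles(4, 1)
  sm <- rbind(ramp = c(0, 1, 2, 3),
              spike = c(0, 2, -1, -1),
              flat = c(5, 5, 5, 5))
  colnames(sm) <- stage_labels(4)
  m <- mk_mode_matrix(sm, design, "sexual")
  asg <- assign_profiles(m, design, "sexual", profs)
  a <- asg$assignments
  ramp_idx <- which(apply(profs$deltas, 1, function(d) all(d == 1)))
  expect_equal(a$profile_id[a$gene_id == "ramp"],
               profs$profile_id[ramp_idx])
  expect_equal(a$correlation[a$gene_id == "ramp"], 1)
  # brute force: highest Pearson correlation over all 27 cumulative vectors
  brute <- which.max(vapply(seq_len(27), function(i) {
    if (all(profs$deltas[i, ] == 0)) return(-Inf)
    cor(sm["spike", ] - sm["spike", 1], profs$cumulative[i, ])
  }, numeric(1)))
  expect_equal(a$profile_id[a$gene_id == "spike"], profs$profile_id[brute])
  zero_idx <- which(apply(profs$deltas, 1, function(d) all(d == 0)))
  expect_equal(a$profile_id[a$gene_id == "flat"], profs$profile_id[zero_idx])
  expect_true(is.na(a$correlation[a$gene_id == "flat"]))
})

test_that("assignment argmax equals brute force on random trajectories", {
  design <- generate_design()
  profs <- enumerate_profiles(4, 1)
  set.seed(51)
  sm <- matrix(rnorm(80), 20, 4,
               dimnames = list(sprintf("g%02d", 1:20), stage_labels(4)))
  m <- mk_mode_matrix(sm, design, "apomictic")
  a <- assign_profiles(m, design, "apomictic", profs)$assignments
  for (g in rownames(sm)) {
    brute <- which.max(vapply(seq_len(27), function(i) {
      if (all(profs$deltas[i, ] == 0)) return(-Inf)
      cor(sm[g, ], profs$cumulative[i, ])
    }, numeric(1)))
    expect_equal(a$profile_id[a$gene_id == g], profs$profile_id[brute],
                 info = g)
  }
  # adding a constant to a gene's trajectory changes nothing
  m2 <- m + 100
  a2 <- assign_profiles(m2, design, "apomictic", profs)$assignments
  expect_equal(a2$profile_id, a$profile_id)
})

test_that("permutation significance flags a planted ramp profile", {
  design <- generate_design()
  profs <- enumerate_profiles(4, 1)
  set.seed(52)
  n_sig <- 60; n_null <- 240
  sm <- rbind(
    matrix(rep(c(0, 1, 2, 3), each = n_sig), n_sig, 4) +
      matrix(rnorm(n_sig * 4, 0, 0.2), n_sig, 4),
    matrix(rnorm(n_null * 4), n_null, 4))
  dimnames(sm) <- list(sprintf("g%03d", seq_len(n_sig + n_null)),
                       stage_labels(4))
  m <- mk_mode_matrix(sm, design, "apomictic")
  asg <- assign_profiles(m, design, "apomictic", profs)
  sig <- profile_significance(asg, n_perm = 200, seed = 1)
  ramp_id <- profs$profile_id[apply(profs$deltas, 1,
                                    function(d) all(d == 1))]
  expect_true(sig$bonferroni_significant[sig$profile_id == ramp_id])
  # empirical permutation p carries the pseudocount: always in (0, 1]
  expect_true(all(sig$p_permutation > 0 & sig$p_permutation <= 1))
  expect_true(all(sig$p_value >= 0 & sig$p_value <= 1))
  expect_gt(sig$observed[sig$profile_id == ramp_id],
            sig$expected[sig$profile_id == ramp_id])
  expect_equal(sum(sig$observed), n_sig + n_null)
  expect_error(profile_significance(asg, n_perm = 50), ">= 100")
})

test_that("all-flat input yields no significant non-flat profile", {
  design <- generate_design()
  profs <- enumerate_profiles(4, 1)
  sm <- matrix(3, 30, 4, dimnames = list(sprintf("g%02d", 1:30),
                                         stage_labels(4)))
  m <- mk_mode_matrix(sm, design, "sexual")
  asg <- assign_profiles(m, design, "sexual", profs)
  sig <- profile_significance(asg, n_perm = 100, seed = 2)
  zero_id <- profs$profile_id[apply(profs$deltas, 1, function(d) all(d == 0))]
  nonflat <- sig[sig$profile_id != zero_id, ]
  expect_true(all(!nonflat$bonferroni_significant))
})

test_that("intersection p-values match exhaustive enumeration", {
  genes <- paste0("g", 1:10)
  set_a <- genes[1:4]    # sexual profile pA
  set_b <- genes[2:6]    # apomictic profile pB, overlap {g2, g3, g4} = 3
  sx <- data.frame(gene_id = genes,
                   profile_id = ifelse(genes %in% set_a, "pA", "pX"),
                   stringsAsFactors = FALSE)
  ap <- data.frame(gene_id = genes,
                   profile_id = ifelse(genes %in% set_b, "pB", "pY"),
                   stringsAsFactors = FALSE)
  cmp <- compare_modes(sx, ap, min_intersection = 1, p_max = 0.05)
  pr <- cmp$pairs
  row <- pr[pr$profile_sexual == "pA" & pr$profile_apomictic == "pB", ]
  expect_equal(row$n_intersection, 3)
  oracle <- exhaustive_overlap_p(10, 4, 5, 3)  # all C(10,5) draws
  expect_equal(row$p_value, oracle, tolerance = 1e-12)
})

test_that("mode comparison selection rules and symmetry", {
  genes <- paste0("g", 1:12)
  prof <- rep(c("p01", "p14", "p27"), each = 4)
  sx <- data.frame(gene_id = genes, profile_id = prof,
                   stringsAsFactors = FALSE)
  # identical assignments: every selected pair sits on the diagonal
  cmp <- compare_modes(sx, sx)
  sel <- cmp$pairs[cmp$pairs$selected, ]
  expect_true(all(sel$profile_sexual == sel$profile_apomictic))
  expect_length(cmp$divergent_genes, 0)
  # empty intersections are never selected
  ap <- data.frame(gene_id = genes, profile_id = rev(prof),
                   stringsAsFactors = FALSE)
  cmp2 <- compare_modes(sx, ap)
  expect_true(all(cmp2$pairs$n_intersection[cmp2$pairs$selected] >= 1))
  # symmetry up to transposition of the pair matrix
  cmp3 <- compare_modes(ap, sx)
  key2 <- with(cmp2$pairs, paste(profile_sexual, profile_apomictic))
  key3 <- with(cmp3$pairs, paste(profile_apomictic, profile_sexual))
  expect_equal(cmp2$pairs$n_intersection[order(key2)],
               cmp3$pairs$n_intersection[order(key3)])
  expect_equal(cmp2$pairs$p_value[order(key2)],
               cmp3$pairs$p_value[order(key3)])
  # disjoint universes are an error
  ap2 <- data.frame(gene_id = paste0("h", 1:3), profile_id = "p01")
  expect_error(compare_modes(sx, ap2), "share no genes")
})
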