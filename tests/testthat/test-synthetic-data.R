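test_that("generators are deterministic functions of the recipe seed", {
  rec <- small_recipe(seed = 41)
  s1 <- simulate_tree(rec)
  s2 <- simulate_tree(rec)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  m1 <- simulate_mk_matrix(s1$tree, rec)
  m2 <- simulate_mk_matrix(s2$tree, rec)
  expect_identical(m1$matrix, m2$matrix)
  expect_identical(m1$truth$ancestral, m2$truth$ancestral)
  a1 <- simulate_dna(s1$tree, rec)
  a2 <- simulate_dna(s2$tree, rec)
  expect_identical(a1$sequences, a2$sequences)
  p1 <- simulate_posterior_sample(s1$tree, rec)
  p2 <- simulate_posterior_sample(s2$tree, rec)
  expect_identical(lapply(p1$sample$runs[[1]], ape::write.tree),
                   lapply(p2$sample$runs[[1]], ape::write.tree))
  # a different seed changes the draw
  s3 <- simulate_tree(small_recipe(seed = 42))
  expect_false(identical(ape::write.tree(s1$tree), ape::write.tree(s3$tree)))
})

test_that("the clade plan is enforced: every named group is monophyletic", {
  rec <- simulation_recipe(seed = 5, clades = c(A = 3L, B = 5L, C = 4L),
                           n_outgroup = 3L)
  sim <- simulate_tree(rec)
  for (nm in names(sim$clades))
    expect_true(is_monophyletic(sim$tree, sim$clades[[nm]]))
  expect_true(is_monophyletic(sim$tree, sim$outgroup))
  expect_true(is_monophyletic(sim$tree, unlist(sim$clades)))  # ingroup
  expect_equal(length(sim$tree$tip.label), 15L)
})

test_that("tree depth is rescaled to the requested value", {
  depths <- vapply(1:20, function(i) {
    rec <- simulation_recipe(seed = i, clades = c(A = 5L, B = 5L),
                             n_outgroup = 3L, tree_depth = 0.4)
    tr <- simulate_tree(rec)$tree
    mean(ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)])
  }, 1)
  expect_equal(mean(depths), 0.4, tolerance = 1e-9)
})

test_that("a zero-length tree transmits the root state everywhere", {
  rec <- small_recipe(seed = 43)
  sim <- simulate_tree(rec)
  tr0 <- sim$tree
  tr0$edge.length[] <- 0
  mk <- simulate_mk_matrix(tr0, rec)
  for (j in seq_len(n_characters(mk$matrix))) {
    states <- unique(unlist(mk$truth$tip_states[, j]))
    expect_length(states, 1L)
  }
})

test_that("long branches drive tip states to the uniform stationary mix", {
  rec <- simulation_recipe(
    seed = 47, clades = c(A = 10L, B = 10L), n_outgroup = 4L,
    tree_depth = 60,
    characters = list(counts = c(`2` = 2000L), alpha = Inf,
                      missing_rate = 0, polymorphic_rate = 0))
  sim <- simulate_tree(rec)
  mk <- simulate_mk_matrix(sim$tree, rec)
  # a deep tip is near-independent of the root: frequency of state 1 ~ 0.5
  f1 <- mean(mk$truth$tip_states[1, ])
  expect_lt(abs(f1 - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("masking respects rates and polymorphism adds one extra state", {
  rec <- simulation_recipe(
    seed = 53, clades = c(A = 10L, B = 10L), n_outgroup = 5L,
    characters = list(counts = c(`3` = 400L), ordered_fraction = 1,
                      missing_rate = 0.2, polymorphic_rate = 0.1))
  sim <- simulate_tree(rec)
  mk <- simulate_mk_matrix(sim$tree, rec)
  cm <- mk$matrix
  sizes <- unlist(lapply(seq_along(cm$columns), function(j)
    vapply(cm$columns[[j]], length, 1L)))
  n <- length(sizes)
  expect_lt(abs(mean(sizes == 3) - 0.2), 0.02)      # missing = full set
  expect_lt(abs(mean(sizes == 2) - 0.08), 0.02)     # 0.1 of non-missing
  # ordered polymorphism: the two states are adjacent
  for (j in 1:50) {
    two <- cm$columns[[j]][vapply(cm$columns[[j]], length, 1L) == 2L]
    for (s in two) expect_equal(diff(s), 1L)
  }
  # polymorphic sets always contain the true tip state
  for (j in 1:50) {
    for (i in seq_along(cm$taxa)) {
      s <- cm$columns[[j]][[i]]
      if (length(s) == 2L)
        expect_true(mk$truth$tip_states[cm$taxa[i], j] %in% s)
    }
  }
})

test_that("planted diagnostic characters are clade-fixed with recorded truth", {
  rec <- small_recipe(seed = 59)
  rec$characters$planted <- 3L
  sim <- simulate_tree(rec)
  mk <- simulate_mk_matrix(sim$tree, rec, sim$clades)
  pl <- mk$truth$planted
  expect_equal(nrow(pl), 3L)
  for (r in seq_len(nrow(pl))) {
    j <- pl$character[r] + 1L
    memb <- sim$clades[[pl$clade[r]]]
    states <- vapply(mk$matrix$columns[[j]], `[`, 0L, 1)
    expect_true(all(states[mk$matrix$taxa %in% memb] == 1L))
    expect_true(all(states[!mk$matrix$taxa %in% memb] == 0L))
    nd <- node_for_clade(sim$tree, memb)
    expect_equal(unname(mk$truth$ancestral[as.character(nd), j]), 1L)
    root <- length(sim$tree$tip.label) + 1L
    expect_equal(unname(mk$truth$ancestral[as.character(root), j]), 0L)
  }
})

test_that("pseudo-posterior samples hit their intended split frequencies", {
  rec <- simulation_recipe(seed = 61, clades = c(A = 6L, B = 5L, C = 5L),
                           n_outgroup = 4L,
                           posterior = list(runs = 4L, n_per_run = 250L,
                                            perturb_p = 0.2))
  sim <- simulate_tree(rec)
  post <- simulate_posterior_sample(sim$tree, rec)
  expect_equal(unique(post$truth$intended_freq),
               1 - 0.2 / (20 - 3))
  cs <- clade_support(post$sample)
  m <- merge(post$truth, cs[, c("split", "mean_pp")], by = "split")
  se <- sqrt(m$intended_freq * (1 - m$intended_freq) / 1000)
  expect_true(all(abs(m$mean_pp - m$intended_freq) < 3 * se + 1e-9))
})

test_that("p = 0 reproduces the true topology in every sample", {
  rec <- simulation_recipe(seed = 67, clades = c(A = 4L, B = 4L),
                           n_outgroup = 3L,
                           posterior = list(runs = 2L, n_per_run = 20L,
                                            perturb_p = 0))
  sim <- simulate_tree(rec)
  post <- simulate_posterior_sample(sim$tree, rec, outgroup = sim$outgroup)
  truth <- bipartitions(sim$tree)
  for (run in post$sample$runs)
    for (tr in run)
      expect_setequal(bipartitions(tr), truth)
  cs <- clade_support(post$sample)
  expect_true(all(cs$mean_pp == 1))
})
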