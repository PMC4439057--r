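test_that("Mk generators have the right structure and unit mean rate", {
  Q2 <- rate_matrix(2)
  expect_equal(Q2, matrix(c(-1, 1, 1, -1), 2))
  expect_equal(rate_matrix(2, ordered = TRUE), Q2)  # k=2: same model

  Q3 <- rate_matrix(3, ordered = TRUE)
  expect_equal(Q3[1, 3], 0)  # no direct 0 -> 2 jump
  expect_equal(Q3[3, 1], 0)
  expect_true(all(Q3[cbind(c(1, 2, 2, 3), c(2, 1, 3, 2))] > 0))
  for (k in 2:6) for (ord in c(FALSE, TRUE)) {
    Q <- rate_matrix(k, ord)
    expect_equal(rowSums(Q), rep(0, k))
    expect_equal(-sum(diag(Q)) / k, 1)  # mean rate 1 at uniform freqs
  }
  expect_error(rate_matrix(1), ">= 2")
})

test_that("transition probabilities equal the matrix exponential", {
  m <- mk_model(4)
  expect_equal(transition_probs(m, 0), diag(4))
  # stationarity: long branches reach the uniform distribution
  expect_equal(transition_probs(m, 100), matrix(0.25, 4, 4), tolerance = 1e-10)
  # k=2 closed form: P(same) = 1/2 + 1/2 exp(-2t)
  m2 <- mk_model(2)
  for (t in c(0.01, 0.3, 2)) {
    P <- transition_probs(m2, t)
    expect_equal(P[1, 1], 0.5 + 0.5 * exp(-2 * t), tolerance = 1e-12)
  }
  # ordered k=5 vs independent exponential
  m5 <- mk_model(5, ordered = TRUE)
  expect_equal(transition_probs(m5, 0.3), ape::matexpo(m5$Q * 0.3),
               tolerance = 1e-10)
  expect_equal(transition_probs(m5, 0.3, r = 2),
               ape::matexpo(m5$Q * 0.6), tolerance = 1e-10)
  expect_error(transition_probs(m2, -1), "negative")
})

test_that("discrete gamma categories average to 1 and match quadrature", {
  expect_equal(discrete_gamma_rates(0.5, 1), 1)
  for (a in c(0.2, 0.5, 1, 5)) {
    r <- discrete_gamma_rates(a, 4)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    expect_true(all(diff(r) > 0))
  }
  # numeric-integration oracle: mean of each equal-probability class
  a <- 0.5; n <- 4
  bounds <- qgamma((0:n) / n, shape = a, rate = a)
  oracle <- vapply(seq_len(n), function(i) {
    n * integrate(function(x) x * dgamma(x, a, a),
                  bounds[i], bounds[i + 1])$value
  }, 1)
  expect_equal(discrete_gamma_rates(a, n), oracle, tolerance = 1e-6)
  expect_error(discrete_gamma_rates(-1, 4), "positive")
})

test_that("pruning likelihood matches enumeration on random small trees", {
  set.seed(701)
  for (rep in 1:30) {
    nt <- sample(4:6, 1)
    tr <- ape::rtree(nt)
    k <- sample(2:4, 1)
    m <- mk_model(k, ordered = sample(c(TRUE, FALSE), 1),
                  alpha = if (runif(1) < 0.5) Inf else runif(1, 0.3, 2),
                  ncat = 4)
    col <- random_column(tr, k)
    expect_equal(character_likelihood(tr, col, m),
                 enum_likelihood(tr, col, m), tolerance = 1e-10)
  }
})

test_that("likelihood limit cases behave as marginalization dictates", {
  tr <- ape::read.tree(text = "(a:0,b:0);")
  m <- mk_model(2)
  expect_equal(character_likelihood(tr, list(a = 0L, b = 0L), m), 0.5)
  # fully missing column marginalizes to 1
  tr2 <- ape::rtree(6)
  m3 <- mk_model(3, alpha = 0.8)
  col <- setNames(rep(list(0:2), 6), tr2$tip.label)
  expect_equal(character_likelihood(tr2, col, m3), 1, tolerance = 1e-9)
  # a taxon absent from the column is treated as missing
  col2 <- setNames(rep(list(0L), 5), tr2$tip.label[1:5])
  col3 <- c(col2, setNames(list(0:2), tr2$tip.label[6]))
  expect_equal(character_likelihood(tr2, col2, m3),
               character_likelihood(tr2, col3, m3))
})

test_that("gamma machinery with one category reproduces the homogeneous likelihood", {
  set.seed(702)
  tr <- ape::rtree(8)
  col <- random_column(tr, 3)
  l_hom <- character_likelihood(tr, col, mk_model(3))
  expect_equal(character_likelihood(tr, col, mk_model(3, ncat = 1L)), l_hom)
  expect_equal(character_likelihood(tr, col, mk_model(3, alpha = 1e6, ncat = 4)),
               l_hom, tolerance = 1e-4)
})

test_that("likelihood is invariant under state relabeling symmetry", {
  set.seed(703)
  tr <- ape::rtree(6)
  col <- random_column(tr, 3)
  relabel <- function(col, perm)
    lapply(col, function(s) sort(perm[s + 1L]))
  # unordered: any permutation
  m <- mk_model(3)
  for (i in 1:4) {
    perm <- sample(0:2)
    expect_equal(character_likelihood(tr, relabel(col, perm), m),
                 character_likelihood(tr, col, m), tolerance = 1e-12)
  }
  # ordered: reversal only
  mo <- mk_model(3, ordered = TRUE)
  expect_equal(character_likelihood(tr, relabel(col, 2:0), mo),
               character_likelihood(tr, col, mo), tolerance = 1e-12)
})

test_that("variable-only conditioning divides by the variable-pattern probability", {
  set.seed(704)
  tr <- ape::rtree(5)
  col <- random_column(tr, 2)
  m <- mk_model(2)
  mv <- mk_model(2, conditioning = "variable")
  # oracle: P(constant) by enumeration of the two constant columns
  pc <- sum(vapply(0:1, function(s) {
    cc <- setNames(rep(list(s), 5), tr$tip.label)
    enum_likelihood(tr, cc, m)
  }, 1))
  expect_equal(character_likelihood(tr, col, mv),
               character_likelihood(tr, col, m) / (1 - pc),
               tolerance = 1e-10)
})

test_that("marginal ancestral distributions match enumeration and sum to 1", {
  set.seed(705)
  for (rep in 1:15) {
    nt <- sample(4:6, 1)
    tr <- ape::rtree(nt)
    k <- sample(2:3, 1)
    m <- mk_model(k, alpha = if (runif(1) < 0.5) Inf else 1, ncat = 4)
    col <- random_column(tr, k)
    for (nd in (nt + 1):(nt + tr$Nnode)) {
      pp <- marginal_ancestral_pp(tr, col, m, nd)
      expect_equal(sum(pp), 1, tolerance = 1e-9)
      expect_equal(pp, enum_marginal(tr, col, m, nd), tolerance = 1e-10)
    }
  }
})

test_that("marginal reconstruction limits: certainty and stationarity", {
  tr <- ape::read.tree(text = "((a:0.01,b:0.01):0.01,(c:0.01,d:0.01):0.01);")
  m <- mk_model(2)
  col <- list(a = 0L, b = 0L, c = 0L, d = 0L)
  for (nd in 5:7)
    expect_gt(marginal_ancestral_pp(tr, col, m, nd)[1], 0.99)
  # very long branches: uniform 1/k
  trl <- ape::read.tree(text = "((a:50,b:50):50,(c:50,d:50):50);")
  col2 <- list(a = 0L, b = 1L, c = 0L, d = 1L)
  expect_equal(marginal_ancestral_pp(trl, col2, m, 5),
               c(0.5, 0.5), tolerance = 1e-6)
  expect_error(marginal_ancestral_pp(tr, col, m, 2), "internal")
})

test_that("marginal reconstruction is invariant to child order", {
  set.seed(706)
  tr <- ape::rtree(7)
  col <- random_column(tr, 3)
  m <- mk_model(3, alpha = 1)
  rot <- ape::rotateConstr(tr, rev(sort(tr$tip.label)))
  for (taxa in list(tr$tip.label[1:3], tr$tip.label[2:5])) {
    nd1 <- node_for_clade(tr, taxa)
    nd2 <- node_for_clade(rot, taxa)
    if (is.na(nd1) || is.na(nd2)) next
    expect_equal(marginal_ancestral_pp(tr, col, m, nd1),
                 marginal_ancestral_pp(rot, col, m, nd2),
                 tolerance = 1e-10)
  }
})

test_that("likelihoods of 100-leaf trees stay finite under scaling", {
  set.seed(707)
  tr <- ape::rtree(100)
  tr$edge.length <- tr$edge.length * 0.02
  col <- random_column(tr, 2)
  ll <- character_likelihood(tr, col, mk_model(2, alpha = 1), log = TRUE)
  expect_true(is.finite(ll))
  nd <- length(tr$tip.label) + 1L
  pp <- marginal_ancestral_pp(tr, col, mk_model(2, alpha = 1), nd)
  expect_equal(sum(pp), 1, tolerance = 1e-9)
})

test_that("sample-averaged ancestral PPs reduce to the single-tree case", {
  set.seed(708)
  rec <- small_recipe(seed = 31)
  sim <- simulate_tree(rec)
  mk <- simulate_mk_matrix(sim$tree, rec)
  clades <- c(sim$clades["TriA"],
              list(ancestor = unlist(sim$clades)))
  one <- tree_sample(list(c(sim$tree)))
  pp1 <- ancestral_pp_over_sample(one, mk$matrix, clades, alpha = 1,
                                  characters = 1:4)
  # identical trees give the same answer as one tree
  five <- tree_sample(list(rep(c(sim$tree), 5)))
  pp5 <- ancestral_pp_over_sample(five, mk$matrix, clades, alpha = 1,
                                  characters = 1:4)
  expect_equal(pp1$pp, pp5$pp, tolerance = 1e-12)
  # and match marginal_ancestral_pp directly
  nd <- node_for_clade(sim$tree, clades$TriA)
  m <- mk_model(mk$matrix$state_counts[1], mk$matrix$ordered[1], alpha = 1)
  direct <- marginal_ancestral_pp(
    sim$tree, setNames(mk$matrix$columns[[1]], mk$matrix$taxa), m, nd)
  got <- pp1$pp[pp1$clade == "TriA" & pp1$character == 0]
  expect_equal(got, unname(direct), tolerance = 1e-12)
})

test_that("trees lacking a clade are skipped and counted", {
  tr_yes <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,O:1);")
  tr_no <- ape::read.tree(text = "(((A:1,C:1):1,B:1):1,O:1);")
  cm <- character_matrix(c("A", "B", "C", "O"),
                         list(list(1L, 1L, 0L, 0L)), 2L)
  ts <- tree_sample(list(c(tr_yes, tr_no, tr_yes)))
  pp <- ancestral_pp_over_sample(ts, cm, list(AB = c("A", "B")))
  expect_equal(unname(attr(pp, "sample_size")["AB"]), 2L)
  expect_equal(unname(attr(pp, "skipped")["AB"]), 1L)
  expect_warning(
    ancestral_pp_over_sample(ts, cm, list(AB = c("A", "B"),
                                          AO = c("A", "O"))),
    "absent")
})
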