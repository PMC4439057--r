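# Independent oracles and small fixture builders shared across tests.
# The likelihood/marginal oracles sum over every internal-node state
# assignment using ape::matexpo for the transition kernels, so they
# share no code path with the pruning implementation they check.

enum_likelihood <- function(tree, column, model) {
  nt <- length(tree$tip.label)
  k <- model$k
  tot <- 0
  for (r in model$rates) {
    Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
      ape::matexpo(model$Q * tree$edge.length[e] * r))
    grid <- do.call(expand.grid, rep(list(1:k), tree$Nnode))
    s <- 0
    for (g in seq_len(nrow(grid))) {
      asg <- as.integer(grid[g, ])
      pr <- 1 / k
      for (e in seq_len(nrow(tree$edge))) {
        par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        pr <- pr * if (ch <= nt)
          sum(Ps[[e]][asg[par - nt], column[[tree$tip.label[ch]]] + 1L])
        else Ps[[e]][asg[par - nt], asg[ch - nt]]
      }
      s <- s + pr
    }
    tot <- tot + s / length(model$rates)
  }
  tot
}

enum_marginal <- function(tree, column, model, node) {
  nt <- length(tree$tip.label)
  k <- model$k
  out <- numeric(k)
  for (r in model$rates) {
    Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
      ape::matexpo(model$Q * tree$edge.length[e] * r))
    grid <- do.call(expand.grid, rep(list(1:k), tree$Nnode))
    for (g in seq_len(nrow(grid))) {
      asg <- as.integer(grid[g, ])
      pr <- 1 / k
      for (e in seq_len(nrow(tree$edge))) {
        par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        pr <- pr * if (ch <= nt)
          sum(Ps[[e]][asg[par - nt], column[[tree$tip.label[ch]]] + 1L])
        else Ps[[e]][asg[par - nt], asg[ch - nt]]
      }
      out[asg[node - nt]] <- out[asg[node - nt]] + pr
    }
  }
  out / sum(out)
}

# random tip data: mostly fixed states, some polymorphic sets
random_column <- function(tree, k) {
  setNames(lapply(seq_along(tree$tip.label), function(i) {
    n <- sample(1:k, 1, prob = c(0.8, rep(0.2 / (k - 1), k - 1)))
    sort(sample(0:(k - 1), n))
  }), tree$tip.label)
}

# random character matrix for round-trip tests
random_character_matrix <- function(ntax = 10, nchar = 20, kmax = 4,
                                    poly_rate = 0.15) {
  taxa <- sprintf("tax%02d", seq_len(ntax))
  ks <- sample(2:kmax, nchar, replace = TRUE)
  columns <- lapply(seq_len(nchar), function(j) {
    lapply(seq_len(ntax), function(i) {
      u <- runif(1)
      if (u < poly_rate) {
        n <- sample(2:ks[j], 1)
        sort(sample(0:(ks[j] - 1), n))
      } else if (u < poly_rate + 0.05) {
        0:(ks[j] - 1)  # missing
      } else sample(0:(ks[j] - 1), 1)
    })
  })
  character_matrix(taxa, columns, ks,
                   ordered = ks > 2 & runif(nchar) < 0.5)
}

# brute-force constraint oracle: enumerate floating subsets
constraint_oracle <- function(tree, required, floating) {
  subsets <- list(character(0))
  for (f in floating)
    subsets <- c(subsets, lapply(subsets, c, f))
  any(vapply(subsets, function(fs) {
    set <- c(required, fs)
    node <- tryCatch(node_for_clade(tree, set), error = function(e) NA)
    !is.na(node)
  }, TRUE))
}

# small recipe used by several end-to-end style tests
small_recipe <- function(seed = 11, ...) {
  simulation_recipe(
    seed = seed,
    clades = c(TriA = 4L, TriB = 4L, TriC = 3L, TriD = 3L),
    n_outgroup = 3L, tree_depth = 0.3,
    characters = list(counts = c(`2` = 12L, `3` = 6L), alpha = 1,
                      missing_rate = 0.05, polymorphic_rate = 0.02),
    posterior = list(runs = 2L, n_per_run = 30L, perturb_p = 0.1),
    ...)
}
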