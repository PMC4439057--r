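# Seeded generators for every input the pipeline consumes: clade-
# structured Yule trees, Mk character matrices with recorded ancestral
# states, compositionally biased DNA alignments, and multi-run pseudo-
# posterior tree samples with analytically known split-frequency
# targets. All generators are deterministic functions of the recipe
# seed.
#
# The default recipe mirrors the shape of a total-evidence gall-wasp
# dataset: 103 taxa (12 ingroup "tribes" plus outgroups), 239 discrete
# characters, and five molecular markers with the usual lengths; every
# size is configurable downward for quick tests.

#' Simulation recipe
#'
#' @param seed Integer seed; all generators derive their randomness from
#'   it, so identical recipes give identical output bytes.
#' @param clades Named integer vector of ingroup clade sizes. Default:
#'   12 tribes of sizes 20, 12, 10, 9, 8, 8, 7, 6, 5, 4, 3, 3.
#' @param n_outgroup Number of outgroup taxa (default 8, for 103 total).
#' @param tree_depth Mean root-to-tip depth of the true tree, in
#'   expected changes per character (default 0.5).
#' @param crown_fraction Share of the root-to-tip depth occupied by the
#'   within-clade (crown) radiations (default 0.3).
#' @param stem_fraction Share of the root-to-tip depth added to every
#'   clade's stem branch, guaranteeing each named group an appreciable
#'   stem regardless of where the backbone places it (default 0.2); the
#'   remaining depth is shared backbone.
#' @param characters List: `counts` (named vector, states -> number of
#'   characters; default 160 binary, 50 three-state, 20 four-state, 9
#'   five-state = 239), `ordered_fraction` (share of multistate
#'   characters evolved ordered, default 0.3), `alpha` (gamma shape of
#'   across-character rates, default 1), `ncat` (4),
#'   `missing_rate` (0.10), `polymorphic_rate` (0.02), and `planted`
#'   (number of clade-diagnostic binary characters appended, default 0).
#' @param dna List: `partitions` (data frame with `name`, `length`,
#'   `coding`), `gc_background` (0.5), `gc_by_clade` (named numeric,
#'   clade -> equilibrium GC reached from the clade's stem branch
#'   onwards), `kappa` (transition/transversion rate ratio, 4), `pinv`
#'   (proportion of invariable sites, 0.2), `pos3_rate` (rate multiplier
#'   of third codon positions, 3).
#' @param posterior List: `runs` (4), `n_per_run` (1000), `perturb_p`
#'   (probability a sampled tree is a random NNI neighbour of the true
#'   topology instead of the true topology, 0.1), `jitter_sd` (log-normal
#'   branch-length jitter sigma, 0.1).
#' @return An object of class `simulation_recipe`.
#' @export
simulation_recipe <- function(seed = 1L, clades = NULL, n_outgroup = 8L,
                              tree_depth = 0.5, crown_fraction = 0.3,
                              stem_fraction = 0.2, characters = list(),
                              dna = list(), posterior = list()) {
  if (is.null(clades)) {
    clades <- c(20L, 12L, 10L, 9L, 8L, 8L, 7L, 6L, 5L, 4L, 3L, 3L)
    names(clades) <- sprintf("Tribe%02d", seq_along(clades))
  }
  if (is.null(names(clades)) || anyDuplicated(names(clades)))
    stop("clades must be uniquely named")
  if (any(clades < 1L) || n_outgroup < 1L) stop("counts must be positive")
  chr <- modifyList(list(counts = c(`2` = 160L, `3` = 50L, `4` = 20L,
                                    `5` = 9L),
                         ordered_fraction = 0.3, alpha = 1, ncat = 4L,
                         missing_rate = 0.10, polymorphic_rate = 0.02,
                         planted = 0L), characters)
  dna_def <- list(partitions = data.frame(
                    name = c("COI", "EF1aF1", "28S", "EF1aF2", "LWRh"),
                    length = c(1078L, 367L, 1246L, 1101L, 481L),
                    coding = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                    stringsAsFactors = FALSE),
                  gc_background = 0.5, gc_by_clade = NULL,
                  kappa = 4, pinv = 0.2, pos3_rate = 3)
  dna <- modifyList(dna_def, dna)
  post <- modifyList(list(runs = 4L, n_per_run = 1000L, perturb_p = 0.1,
                          jitter_sd = 0.1), posterior)
  probs <- c(chr$missing_rate, chr$polymorphic_rate, dna$pinv,
             post$perturb_p)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (crown_fraction <= 0 || stem_fraction < 0 ||
      crown_fraction + stem_fraction >= 1)
    stop("crown_fraction + stem_fraction must lie in (0, 1)")
  structure(list(seed = as.integer(seed), clades = clades,
                 n_outgroup = as.integer(n_outgroup),
                 tree_depth = tree_depth, crown_fraction = crown_fraction,
                 stem_fraction = stem_fraction,
                 characters = chr, dna = dna, posterior = post),
            class = "simulation_recipe")
}

yule_newick <- function(labels, depth = NULL) {
  n <- length(labels)
  if (n == 1L) return(labels)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$tip.label <- labels
  if (!is.null(depth)) {
    d <- mean(ape::node.depth.edgelength(tr)[seq_len(n)])
    tr$edge.length <- tr$edge.length * depth / d
  }
  sub(";$", "", ape::write.tree(tr))
}

#' Simulate a clade-structured Yule tree
#'
#' Generates a rooted tree in which every named ingroup clade and the
#' outgroup are monophyletic by construction: a Yule backbone over the
#' clade stubs, each stub expanded into its own Yule subtree, branch
#' lengths rescaled so the mean root-to-tip depth equals the recipe's
#' `tree_depth`, and the tree rooted on the outgroup.
#'
#' @param recipe A [simulation_recipe()].
#' @return List with `tree` (rooted `phylo`), `clades` (named list of
#'   taxon labels per ingroup clade) and `outgroup` (labels).
#' @export
simulate_tree <- function(recipe) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  set.seed(recipe$seed)
  cl <- recipe$clades
  members <- lapply(names(cl), function(nm)
    sprintf("%s_t%02d", nm, seq_len(cl[[nm]])))
  names(members) <- names(cl)
  outgroup <- sprintf("Outgroup_t%02d", seq_len(recipe$n_outgroup))
  groups <- c(members, list(OUTGRP = outgroup))
  backbone <- ape::rphylo(length(groups), birth = 1, death = 0)
  backbone$tip.label <- names(groups)
  # depth structure: crown radiations occupy crown_fraction of the
  # root-to-tip depth, every clade stem gets an extra stem_fraction, and
  # the rest is shared backbone -- the shape under which clades carry
  # reconstructible ancestral states (a synapomorphy arising on a stem
  # pins the crown ancestor)
  f <- recipe$crown_fraction
  st <- recipe$stem_fraction
  bd <- mean(ape::node.depth.edgelength(backbone)[seq_along(groups)])
  backbone$edge.length <- backbone$edge.length * (1 - f - st) / bd
  bb <- ape::write.tree(backbone)
  # expand each stub into its subtree (labels occur exactly once, each
  # followed by ":"; longest-first avoids suffix collisions)
  for (nm in names(groups)[order(-nchar(names(groups)))]) {
    bb <- sub(paste0(nm, ":"),
              paste0(yule_newick(groups[[nm]], depth = f), ":"),
              bb, fixed = TRUE)
  }
  tree <- ape::read.tree(text = bb)
  for (nm in names(groups)) {
    node <- if (length(groups[[nm]]) == 1L)
      match(groups[[nm]], tree$tip.label)
    else ape::getMRCA(tree, match(groups[[nm]], tree$tip.label))
    tree$edge.length[tree$edge[, 2L] == node] <-
      tree$edge.length[tree$edge[, 2L] == node] + st
  }
  tree <- root_on_outgroup(tree, outgroup, quiet = TRUE)
  depth <- mean(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
  tree$edge.length <- tree$edge.length * recipe$tree_depth / depth
  list(tree = tree, clades = members, outgroup = outgroup)
}

# preorder edge matrix (parents before children)
preorder_edges <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  idx <- rev(seq_len(nrow(po$edge)))
  list(edge = po$edge[idx, , drop = FALSE],
       len = po$edge.length[idx])
}

#' Simulate an Mk character matrix with recorded ancestral states
#'
#' Each character evolves by the Mk continuous-time Markov chain from a
#' uniform root draw down the tree, with its rate drawn from the
#' discrete-gamma categories. States at every internal node are
#' recorded. A requested fraction of cells is then masked to missing and
#' another made polymorphic (true state plus an adjacent state for
#' ordered characters, a random other state for unordered). Planted
#' clade-diagnostic characters (binary, state 1 fixed in one clade and 0
#' elsewhere, unmasked) are appended last and cycled over the clades.
#'
#' @param tree A rooted `phylo` with branch lengths (from
#'   [simulate_tree()]).
#' @param recipe A [simulation_recipe()].
#' @param clades Named list of clade taxon sets (required when
#'   `recipe$characters$planted > 0`).
#' @return List: `matrix` (a [character_matrix()]) and `truth` (list
#'   with `ancestral` — internal-node-by-character state matrix, rows
#'   named by ape node id — `tip_states` before masking, `rates`,
#'   `planted` data frame of planted characters and their clades).
#' @export
simulate_mk_matrix <- function(tree, recipe, clades = NULL) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  set.seed(recipe$seed + 1L)
  chr <- recipe$characters
  ks <- rep(as.integer(names(chr$counts)), chr$counts)
  nchar_ <- length(ks)
  ordered <- ks > 2L & runif(nchar_) < chr$ordered_fraction
  rates_cat <- discrete_gamma_rates(chr$alpha, chr$ncat)
  cat_of <- sample.int(chr$ncat, nchar_, replace = TRUE)
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  pe <- preorder_edges(tree)
  states <- matrix(NA_integer_, nn, nchar_)  # 0-based
  root <- nt + 1L
  # group characters sharing (k, ordered, category): one transition
  # matrix per edge serves the whole group
  grp <- interaction(ks, ordered, cat_of, drop = TRUE)
  for (g in levels(grp)) {
    jj <- which(grp == g)
    k <- ks[jj[1]]
    model <- mk_model(k, ordered[jj[1]])
    r <- rates_cat[cat_of[jj[1]]]
    states[root, jj] <- sample.int(k, length(jj), replace = TRUE) - 1L
    for (e in seq_len(nrow(pe$edge))) {
      P <- transition_probs(model, pe$len[e], r)
      par <- states[pe$edge[e, 1L], jj]
      child <- integer(length(jj))
      for (s in unique(par)) {
        sel <- par == s
        child[sel] <- sample.int(k, sum(sel), replace = TRUE,
                                 prob = P[s + 1L, ]) - 1L
      }
      states[pe$edge[e, 2L], jj] <- child
    }
  }
  tip_states <- states[seq_len(nt), , drop = FALSE]
  rownames(tip_states) <- tree$tip.label
  columns <- vector("list", nchar_)
  for (j in seq_len(nchar_)) {
    k <- ks[j]
    cells <- as.list(tip_states[, j])
    mask <- runif(nt) < chr$missing_rate
    poly <- !mask & runif(nt) < chr$polymorphic_rate
    for (i in which(mask)) cells[[i]] <- 0:(k - 1L)
    for (i in which(poly)) {
      s <- tip_states[i, j]
      other <- if (ordered[j]) {
        adj <- c(s - 1L, s + 1L)
        adj <- adj[adj >= 0L & adj < k]
        sample(adj, 1L)
      } else sample(setdiff(0:(k - 1L), s), 1L)
      cells[[i]] <- sort(c(s, other))
    }
    columns[[j]] <- cells
  }
  planted_df <- NULL
  if (chr$planted > 0L) {
    if (is.null(clades)) stop("planted characters require a clade map")
    cl_names <- rep(names(clades), length.out = chr$planted)
    for (p in seq_len(chr$planted)) {
      memb <- tree$tip.label %in% clades[[cl_names[p]]]
      columns[[nchar_ + p]] <- as.list(as.integer(memb))
      ks <- c(ks, 2L)
      ordered <- c(ordered, FALSE)
      cat_of <- c(cat_of, NA_integer_)
      anc_col <- integer(tree$Nnode)
      sets <- node_tip_sets(tree)
      for (ni in seq_len(tree$Nnode))
        anc_col[ni] <- as.integer(all(tree$tip.label[sets[[nt + ni]]]
                                      %in% clades[[cl_names[p]]]))
      states <- cbind(states, c(rep(NA_integer_, nt), anc_col))
    }
    planted_df <- data.frame(character = nchar_ + seq_len(chr$planted) - 1L,
                             clade = cl_names, stringsAsFactors = FALSE)
  }
  cm <- character_matrix(tree$tip.label, columns, ks, ordered)
  ancestral <- states[(nt + 1L):nn, , drop = FALSE]
  rownames(ancestral) <- as.character((nt + 1L):nn)
  list(matrix = cm,
       truth = list(ancestral = ancestral, tip_states = tip_states,
                    rates = rates_cat[cat_of], planted = planted_df))
}

# HKY transition probabilities via the reversible symmetrization
hky_pmat <- function(pi, kappa, t) {
  R <- matrix(1, 4, 4)
  R[1, 3] <- R[3, 1] <- kappa  # A <-> G
  R[2, 4] <- R[4, 2] <- kappa  # C <-> T
  Q <- R * rep(pi, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  sq <- sqrt(pi)
  B <- Q * (sq / rep(sq, each = 4))  # diag(sq) Q diag(1/sq), symmetric
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- (eg$vectors %*% (exp(eg$values * t) * t(eg$vectors))) *
    (rep(sq, each = 4) / sq)
  P[P < 0] <- 0
  P / rowSums(P)
}

gc_to_pi <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

#' Simulate a compositionally biased DNA alignment
#'
#' HKY-style simulation in which designated clades switch to a different
#' equilibrium GC content on their stem branch (and keep it throughout
#' the clade), with a proportion of invariable sites and a faster rate
#' for third codon positions of coding partitions.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param recipe A [simulation_recipe()].
#' @param clades Named list of clade taxon sets (needed when
#'   `recipe$dna$gc_by_clade` names clades).
#' @return A [dna_alignment()] with per-marker partitions and codon
#'   offsets for the coding markers.
#' @export
simulate_dna <- function(tree, recipe, clades = NULL) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  set.seed(recipe$seed + 2L)
  d <- recipe$dna
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  pe <- preorder_edges(tree)
  # per-node composition regime: 0 = background, i = i-th switched clade
  regime <- integer(nn)
  gcs <- d$gc_background
  if (!is.null(d$gc_by_clade)) {
    if (is.null(clades)) stop("gc_by_clade requires a clade map")
    sets <- node_tip_sets(tree)
    for (i in seq_along(d$gc_by_clade)) {
      nm <- names(d$gc_by_clade)[i]
      memb <- clades[[nm]]
      if (is.null(memb)) stop("unknown clade in gc_by_clade: ", nm)
      inside <- vapply(sets, function(s)
        all(tree$tip.label[s[s <= nt]] %in% memb) &&
          length(s) > 0, TRUE)
      regime[inside] <- i
      gcs <- c(gcs, d$gc_by_clade[[i]])
    }
  }
  pis <- lapply(gcs, gc_to_pi)
  bases <- c("A", "C", "G", "T")
  seqs <- matrix("", nt, 0)
  partitions <- list()
  codon_offsets <- integer(0)
  col_at <- 0L
  for (pi_row in seq_len(nrow(d$partitions))) {
    L <- d$partitions$length[pi_row]
    coding <- d$partitions$coding[pi_row]
    nm <- d$partitions$name[pi_row]
    site_rate <- rep(1, L)
    if (coding) site_rate[seq_len(L) %% 3L == 0L] <- d$pos3_rate
    site_rate[runif(L) < d$pinv] <- 0
    states <- matrix(NA_integer_, nn, L)
    root <- nt + 1L
    states[root, ] <- sample.int(4L, L, replace = TRUE,
                                 prob = pis[[regime[root] + 1L]])
    rate_grp <- match(site_rate, sort(unique(site_rate)))
    for (e in seq_len(nrow(pe$edge))) {
      ch <- pe$edge[e, 2L]
      pi_vec <- pis[[regime[ch] + 1L]]
      par <- states[pe$edge[e, 1L], ]
      child <- integer(L)
      for (rg in unique(rate_grp)) {
        r <- sort(unique(site_rate))[rg]
        sel <- rate_grp == rg
        if (r == 0) { child[sel] <- par[sel]; next }
        P <- hky_pmat(pi_vec, d$kappa, pe$len[e] * r)
        for (s in unique(par[sel])) {
          ss <- sel & par == s
          child[ss] <- sample.int(4L, sum(ss), replace = TRUE,
                                  prob = P[s, ])
        }
      }
      states[ch, ] <- child
    }
    seqs <- cbind(seqs, matrix(bases[states[seq_len(nt), ]], nt, L))
    partitions[[nm]] <- col_at + seq_len(L)
    if (coding) codon_offsets[nm] <- 1L
    col_at <- col_at + L
  }
  dna_alignment(tree$tip.label,
                apply(seqs, 1L, paste, collapse = ""),
                partitions = partitions,
                codon_offsets = if (length(codon_offsets)) codon_offsets)
}

#' Simulate a multi-run pseudo-posterior tree sample
#'
#' Each run contains `n_per_run` trees: with probability `1 - perturb_p`
#' the true topology (branch lengths jittered log-normally with median
#' 1), otherwise a random NNI neighbour of the true topology. Because an
#' NNI move disrupts exactly one internal split, every true internal
#' split has intended sampling frequency
#' `1 - perturb_p / (n_tips - 3)`, recorded in the returned truth table
#' so summarizer estimates have known targets.
#'
#' @param true_tree A `phylo` (the target topology).
#' @param recipe A [simulation_recipe()].
#' @param outgroup Optional taxon labels; when given, every sampled tree
#'   is rooted on the outgroup (MRCA rooting if an NNI made it
#'   non-monophyletic), as needed for ancestral reconstruction.
#' @return List: `sample` (a [tree_sample()]) and `truth` (data frame
#'   `split`, `intended_freq` for the true tree's internal splits).
#' @export
simulate_posterior_sample <- function(true_tree, recipe, outgroup = NULL) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  set.seed(recipe$seed + 3L)
  p <- recipe$posterior$perturb_p
  sdlog <- recipe$posterior$jitter_sd
  base <- ape::unroot(true_tree)
  runs <- list(); gens <- list()
  for (r in seq_len(recipe$posterior$runs)) {
    trees <- vector("list", recipe$posterior$n_per_run)
    for (i in seq_along(trees)) {
      tr <- if (runif(1) < p) phangorn::rNNI(base, moves = 1L) else base
      tr$edge.length <- tr$edge.length *
        rlnorm(length(tr$edge.length), meanlog = 0, sdlog = sdlog)
      if (!is.null(outgroup))
        tr <- root_on_outgroup(tr, outgroup, quiet = TRUE)
      trees[[i]] <- tr
    }
    class(trees) <- "multiPhylo"
    runs[[r]] <- trees
    gens[[r]] <- seq_along(trees) * 1000
  }
  splits <- bipartitions(true_tree)
  truth <- data.frame(split = splits,
                      intended_freq = 1 - p / (length(true_tree$tip.label) - 3),
                      stringsAsFactors = FALSE)
  list(sample = tree_sample(runs, gens), truth = truth)
}
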