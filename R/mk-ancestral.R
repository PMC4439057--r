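# Felsenstein pruning under the Mk(+gamma) model and marginal ancestral
# state reconstruction, per tree and averaged over a posterior tree
# sample. Partial likelihoods are rescaled node by node so 100-leaf
# trees stay in range; rescaling factors are carried on the log scale.

# tip partial vectors: 1 for each allowed state (polymorphic and missing
# cells marginalize over their state set). `column` is a named list of
# integer state sets.
tip_partial <- function(states, k) {
  v <- numeric(k)
  v[states + 1L] <- 1
  v
}

# one pruning pass for one rate category. Returns per-node down partials
# (likelihood of data below the node given its state), per-node log
# rescaling, child transition matrices, and the category root
# log-likelihood.
prune_category <- function(tree, column, model, rate) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  k <- model$k
  po <- ape::reorder.phylo(tree, "postorder")
  down <- matrix(0, nn, k)
  logsc <- numeric(nn)
  Ps <- vector("list", nn)  # transition matrix on the edge above a node
  for (i in seq_len(nt)) {
    st <- column[[tree$tip.label[i]]]
    if (is.null(st)) st <- 0:(k - 1L)  # no data: fully missing
    down[i, ] <- tip_partial(st, k)
  }
  edge <- po$edge
  elen <- po$edge.length
  if (is.null(elen)) {
    warning("tree has no branch lengths; assuming 1.0")
    elen <- rep(1, nrow(edge))
  }
  visited <- logical(nn)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    P <- transition_probs(model, elen[e], rate)
    Ps[[ch]] <- P
    contrib <- as.vector(P %*% down[ch, ])
    if (!visited[p]) {
      down[p, ] <- contrib
      visited[p] <- TRUE
    } else {
      down[p, ] <- down[p, ] * contrib
    }
    logsc[p] <- logsc[p] + logsc[ch]
    mx <- max(down[p, ])
    if (mx <= 0) {
      # data impossible under this category (e.g. ordered jump)
      logsc[p] <- -Inf
    } else if (mx < 1e-12 || mx > 1e12) {
      down[p, ] <- down[p, ] / mx
      logsc[p] <- logsc[p] + log(mx)
    }
  }
  root <- nt + 1L
  rl <- sum(model$pi * down[root, ])
  list(down = down, logsc = logsc, P = Ps, root = root,
       loglik = if (rl > 0 && is.finite(logsc[root]))
         log(rl) + logsc[root] else -Inf)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log-probability of a constant pattern (all tips identical), summed over
# states and averaged over categories -- for variable-only conditioning
log_prob_constant <- function(tree, model) {
  taxa <- tree$tip.label
  per_state <- vapply(0:(model$k - 1L), function(s) {
    col <- setNames(rep(list(s), length(taxa)), taxa)
    lls <- vapply(model$rates, function(r)
      prune_category(tree, col, model, r)$loglik, 1)
    logsumexp(lls) - log(model$ncat)
  }, 1)
  logsumexp(per_state)
}

#' Mk likelihood of one character on a tree
#'
#' Felsenstein-pruning likelihood of a single character column under an
#' Mk model, averaged over the model's discrete-gamma rate categories.
#' Polymorphic and missing cells enter as tip partials with 1 for every
#' allowed state; the root is weighted by the uniform stationary
#' frequencies. With `conditioning = "variable"` the likelihood is
#' divided by the probability of a variable pattern.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param column Named list (by taxon label) of integer state sets
#'   (0-based). Taxa of the tree absent from `column` are treated as
#'   missing.
#' @param model An [mk_model()].
#' @param log Return the log-likelihood?
#' @return Likelihood (or log-likelihood) of the column.
#' @export
character_likelihood <- function(tree, column, model, log = FALSE) {
  stopifnot(inherits(model, "mk_model"))
  extra <- setdiff(names(column), tree$tip.label)
  if (length(extra))
    stop("column refers to taxa not in tree: ", paste(extra, collapse = ", "))
  lls <- vapply(model$rates, function(r)
    prune_category(tree, column, model, r)$loglik, 1)
  ll <- logsumexp(lls) - log(model$ncat)
  if (model$conditioning == "variable") {
    lc <- log_prob_constant(tree, model)
    ll <- ll - log1p(-exp(lc))
  }
  if (log) ll else exp(ll)
}

# marginal ancestral distributions at every internal node, one tree /
# one character. Returns Nnode x k matrix (rows named by ape node id);
# rows sum to 1. Categories are combined weighted by their likelihood
# contribution.
marginal_ancestral_all <- function(tree, column, model) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  k <- model$k
  pre_joint <- vector("list", model$ncat)
  logw <- numeric(model$ncat)
  for (ci in seq_len(model$ncat)) {
    pc <- prune_category(tree, column, model, model$rates[ci])
    if (!is.finite(pc$loglik)) {
      pre_joint[[ci]] <- NULL
      logw[ci] <- -Inf
      next
    }
    # upward (outside) pass: up[v] = P(data outside v | state at v),
    # carried with its own log rescaling
    up <- matrix(0, nn, k)
    uplog <- rep(-Inf, nn)
    root <- pc$root
    up[root, ] <- model$pi
    uplog[root] <- 0
    pre <- ape::reorder.phylo(tree, "postorder")
    edge <- pre$edge[rev(seq_len(nrow(pre$edge))), , drop = FALSE]  # preorder
    children_of <- split(tree$edge[, 2L], tree$edge[, 1L])
    for (e in seq_len(nrow(edge))) {
      p <- edge[e, 1L]; ch <- edge[e, 2L]
      sibs <- setdiff(children_of[[as.character(p)]], ch)
      acc <- up[p, ]
      acclog <- uplog[p]
      for (sb in sibs) {
        acc <- acc * as.vector(pc$P[[sb]] %*% pc$down[sb, ])
        acclog <- acclog + pc$logsc[sb]
      }
      v <- as.vector(t(pc$P[[ch]]) %*% acc)
      mx <- max(v)
      if (mx > 0) {
        up[ch, ] <- v / mx
        uplog[ch] <- acclog + log(mx)
      }
    }
    jm <- up * pc$down  # unnormalized joint, per node
    attr(jm, "logf") <- uplog + pc$logsc
    pre_joint[[ci]] <- jm
    logw[ci] <- 0  # category prior weights equal; scale kept per node
  }
  if (all(!is.finite(vapply(seq_len(model$ncat), function(ci)
    if (is.null(pre_joint[[ci]])) -Inf else 0, 1))))
    stop("character has zero likelihood on this tree")
  out <- matrix(0, tree$Nnode, k)
  rownames(out) <- as.character((nt + 1L):nn)
  for (ni in seq_len(tree$Nnode)) {
    nd <- nt + ni
    lf <- vapply(seq_len(model$ncat), function(ci)
      if (is.null(pre_joint[[ci]])) -Inf
      else attr(pre_joint[[ci]], "logf")[nd], 1)
    m <- max(lf)
    if (!is.finite(m)) next
    acc <- numeric(k)
    for (ci in seq_len(model$ncat)) {
      if (!is.finite(lf[ci])) next
      acc <- acc + exp(lf[ci] - m) * pre_joint[[ci]][nd, ]
    }
    out[ni, ] <- acc / sum(acc)
  }
  out
}

#' Marginal ancestral-state distribution at a node
#'
#' Posterior distribution of the state at an internal node given the
#' observed column, the tree, and the Mk model — the product of the
#' downward (subtree) and upward (rest-of-tree) partial likelihoods,
#' summed over rate categories weighted by their likelihood
#' contributions, normalized over states.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param column Named list of integer state sets (0-based) per taxon.
#' @param model An [mk_model()].
#' @param node Internal node id (ape numbering).
#' @return Numeric vector of length k summing to 1.
#' @export
marginal_ancestral_pp <- function(tree, column, model, node) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  if (node <= nt || node > nn) stop("node must be an internal node id")
  all_pp <- marginal_ancestral_all(tree, column, model)
  all_pp[as.character(node), ]
}

#' Posterior-probability table constructor
#'
#' @param df Data frame with columns `clade`, `character` (0-based
#'   index), `state` and `pp`.
#' @param sample_size Optional named integer vector of contributing tree
#'   counts per clade.
#' @return A `pp_table` data frame.
#' @export
pp_table <- function(df, sample_size = NULL) {
  need <- c("clade", "character", "state", "pp")
  if (!all(need %in% names(df))) stop("missing pp_table columns")
  df <- as.data.frame(df)[, need]
  if (any(df$pp < -1e-9) || any(df$pp > 1 + 1e-9))
    stop("posterior probabilities outside [0, 1]")
  df$pp <- pmin(pmax(df$pp, 0), 1)
  sums <- tapply(df$pp, interaction(df$clade, df$character, drop = TRUE), sum)
  if (any(abs(sums - 1) > 1e-6))
    warning("some (clade, character) distributions do not sum to 1")
  attr(df, "sample_size") <- sample_size
  class(df) <- c("pp_table", "data.frame")
  df
}

#' Ancestral-state posterior probabilities over a tree sample
#'
#' For each named clade and each character, the marginal ancestral-state
#' distribution at the clade's subtending node is computed on every
#' post-burn-in tree that contains the clade, and averaged arithmetically
#' over those trees (the mean of the sampled per-tree PP values). Trees
#' in which a clade is not monophyletic are skipped for that clade and
#' counted.
#'
#' @param ts A [tree_sample()] with burn-in applied; trees must be
#'   rooted with branch lengths.
#' @param cm A [character_matrix()].
#' @param clades Named list of taxon-label vectors (e.g. the tribes plus
#'   the family ancestor clade).
#' @param alpha,ncat,conditioning Shared Mk model settings applied to
#'   every character with its own state count and ordered flag (see
#'   [mk_model()]).
#' @param characters Optional integer vector of character indices
#'   (1-based) to reconstruct; default all.
#' @return A [pp_table()] with attributes `sample_size` (contributing
#'   trees per clade) and `skipped` (trees lacking each clade).
#' @export
ancestral_pp_over_sample <- function(ts, cm, clades, alpha = Inf,
                                     ncat = 4L,
                                     conditioning = c("none", "variable"),
                                     characters = NULL) {
  stopifnot(inherits(ts, "tree_sample"), inherits(cm, "character_matrix"))
  conditioning <- match.arg(conditioning)
  if (is.null(names(clades)) || any(!nzchar(names(clades))))
    stop("clades must be a named list")
  if (is.null(characters)) characters <- seq_along(cm$columns)
  models <- lapply(characters, function(j)
    mk_model(cm$state_counts[j], cm$ordered[j], alpha = alpha,
             ncat = ncat, conditioning = conditioning))
  columns <- lapply(characters, function(j)
    setNames(cm$columns[[j]], cm$taxa))
  pooled <- do.call(c, lapply(ts$runs, as.list))
  acc <- list()    # clade -> char -> running sum of pp vectors
  contrib <- setNames(integer(length(clades)), names(clades))
  skipped <- setNames(integer(length(clades)), names(clades))
  for (tr in pooled) {
    sets <- node_tip_sets(tr)
    nodes <- vapply(names(clades), function(cl) {
      idx <- match(clades[[cl]], tr$tip.label)
      if (anyNA(idx)) stop("clade '", cl, "' refers to unknown taxa")
      hit <- which(vapply(sets, function(s) setequal(s, idx), TRUE))
      if (length(hit)) hit[1] else NA_integer_
    }, 1L)
    present <- !is.na(nodes)
    skipped[!present] <- skipped[!present] + 1L
    contrib[present] <- contrib[present] + 1L
    if (!any(present)) next
    for (ji in seq_along(characters)) {
      allpp <- marginal_ancestral_all(tr, columns[[ji]], models[[ji]])
      for (cl in names(clades)[present]) {
        key <- paste0(cl, "\r", ji)
        v <- allpp[as.character(nodes[[cl]]), ]
        acc[[key]] <- if (is.null(acc[[key]])) v else acc[[key]] + v
      }
    }
  }
  if (all(contrib == 0L)) stop("no clade present in any sampled tree")
  if (any(contrib == 0L))
    warning("clades absent from every tree: ",
            paste(names(clades)[contrib == 0L], collapse = ", "))
  rows <- list()
  for (cl in names(clades)[contrib > 0L]) {
    for (ji in seq_along(characters)) {
      v <- acc[[paste0(cl, "\r", ji)]] / contrib[[cl]]
      v <- v / sum(v)
      rows[[length(rows) + 1L]] <- data.frame(
        clade = cl, character = characters[ji] - 1L,
        state = seq_along(v) - 1L, pp = v, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- pp_table(out, sample_size = contrib)
  attr(out, "skipped") <- skipped
  out
}
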