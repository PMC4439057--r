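# Bipartition algebra, monophyly and floating-taxon constraints, and
# majority-rule consensus with exact split frequencies. Trees are ape
# "phylo" objects; splits are represented by canonical string keys so
# they can be counted across trees and across differently-rooted copies
# of the same topology.

# tip label sets for every node, postorder (list indexed by node id)
node_tip_sets <- function(tree) {
  nt <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- i
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, sort)
}

# canonical key of a split: the side NOT containing the alphabetically
# first taxon, as a comma-joined sorted label string
split_key <- function(side_labels, all_labels) {
  ref <- min(all_labels)
  if (ref %in% side_labels)
    side_labels <- setdiff(all_labels, side_labels)
  paste(sort(side_labels), collapse = ",")
}

#' Non-trivial bipartitions of a tree
#'
#' Returns the set of splits (both sides with at least two taxa) of the
#' unrooted version of a tree, as canonical keys: each split is
#' represented by the comma-joined sorted labels of the side that does
#' not contain the alphabetically first taxon, so keys are comparable
#' across trees and invariant under rerooting.
#'
#' @param tree A `phylo` object.
#' @return Character vector of unique split keys (empty for trees with
#'   fewer than 4 leaves).
#' @export
bipartitions <- function(tree) {
  labels <- tree$tip.label
  nt <- length(labels)
  if (nt < 4L) return(character(0))
  utree <- ape::unroot(tree)
  sets <- node_tip_sets(utree)
  nt2 <- length(utree$tip.label)
  keys <- character(0)
  internal_children <- utree$edge[, 2][utree$edge[, 2] > nt2]
  for (nd in unique(internal_children)) {
    side <- sets[[nd]]
    if (length(side) >= 2L && nt2 - length(side) >= 2L)
      keys <- c(keys, split_key(utree$tip.label[side], utree$tip.label))
  }
  unique(keys)
}

#' Test monophyly of a taxon set on a rooted tree
#'
#' True iff some node's descendant leaf set equals `taxa` exactly.
#'
#' @param tree A rooted `phylo` object.
#' @param taxa Character vector of taxon labels (subset of the leaves).
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, taxa) {
  !is.na(node_for_clade(tree, taxa))
}

#' Find the node subtending an exact clade
#'
#' Returns the most recent common ancestor of `taxa` if its descendant
#' set equals `taxa` exactly, and `NA` otherwise.
#'
#' @param tree A rooted `phylo` object.
#' @param taxa Character vector of taxon labels.
#' @return Integer node id (ape numbering) or `NA`.
#' @export
node_for_clade <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  idx <- match(taxa, tree$tip.label)
  if (anyNA(idx))
    stop("unknown taxa: ", paste(taxa[is.na(idx)], collapse = ", "))
  if (length(idx) < 1L) stop("empty taxon set")
  if (length(idx) == 1L) return(idx)
  mrca <- ape::getMRCA(tree, idx)
  desc <- descendant_tips(tree, mrca)
  if (setequal(desc, idx)) mrca else NA_integer_
}

descendant_tips <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(node)
  sets <- node_tip_sets(tree)
  sets[[node]]
}

#' Monophyly constraint with floating taxa
#'
#' A hypothesis that `required` forms a clade, while each member of
#' `floating` may fall inside or outside that clade (the "allowed to
#' float" device used when testing tribal monophyly hypotheses).
#'
#' @param required Character vector (>= 2 taxa) that must be
#'   monophyletic.
#' @param floating Character vector of taxa free to join the clade;
#'   disjoint from `required`.
#' @return An object of class `monophyly_constraint`.
#' @export
monophyly_constraint <- function(required, floating = character(0)) {
  required <- unique(as.character(required))
  floating <- unique(as.character(floating))
  if (length(required) < 2L) stop("required set needs >= 2 taxa")
  if (length(intersect(required, floating)))
    stop("required and floating sets overlap")
  structure(list(required = required, floating = floating),
            class = "monophyly_constraint")
}

#' Does a tree satisfy a monophyly constraint?
#'
#' True iff some subset F of the floating taxa makes
#' `required` + F monophyletic — equivalently, iff the smallest clade
#' containing all required taxa contains no taxon outside
#' `required` + `floating`.
#'
#' @param tree A rooted `phylo` object.
#' @param constraint A [monophyly_constraint()].
#' @return Logical scalar.
#' @export
satisfies_constraint <- function(tree, constraint) {
  stopifnot(inherits(constraint, "monophyly_constraint"))
  req <- constraint$required
  idx <- match(c(req, constraint$floating), tree$tip.label)
  if (anyNA(idx))
    stop("unknown taxa: ",
         paste(c(req, constraint$floating)[is.na(idx)], collapse = ", "))
  mrca <- ape::getMRCA(tree, match(req, tree$tip.label))
  desc <- tree$tip.label[descendant_tips(tree, mrca)]
  length(setdiff(desc, c(req, constraint$floating))) == 0L
}

#' Root a tree on a declared outgroup
#'
#' Places the root on the edge to the outgroup clade. When the outgroup
#' is not monophyletic in the tree, the tree is rooted at the MRCA node
#' of the outgroup set and a message is logged.
#'
#' @param tree A `phylo` object.
#' @param outgroup Character vector of outgroup taxon labels.
#' @param quiet Suppress the non-monophyletic-outgroup message.
#' @return A rooted `phylo` object.
#' @export
root_on_outgroup <- function(tree, outgroup, quiet = FALSE) {
  outgroup <- intersect(outgroup, tree$tip.label)
  if (!length(outgroup)) stop("no outgroup taxa present in tree")
  ok <- ape::is.monophyletic(tree, outgroup)
  if (ok) {
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else {
    if (!quiet)
      message("outgroup not monophyletic; rooting at outgroup MRCA node")
    mrca <- ape::getMRCA(tree, match(outgroup, tree$tip.label))
    ape::root(tree, node = mrca)
  }
}

#' Majority-rule consensus with exact split frequencies
#'
#' Builds the consensus containing exactly the splits whose relative
#' frequency across the sample is strictly greater than `threshold`
#' (default 0.70, the usual display rule for figures showing only clades
#' with posterior probability above 70%). Frequencies are raw counts
#' over trees — no smoothing — and annotate the consensus nodes.
#'
#' @param trees A list or `multiPhylo` of trees on a common taxon set.
#' @param threshold Frequency in (0.5, 1]; strictly-greater comparison,
#'   so splits at exactly the threshold are excluded.
#' @return A `phylo` object whose `node.label` carries the split
#'   frequency (empty at the root), with the full frequency table in
#'   attribute `split_freq`.
#' @export
majority_rule_consensus <- function(trees, threshold = 0.70) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (!length(trees)) stop("no trees supplied")
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must be in (0.5, 1]")
  labels <- sort(trees[[1]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), labels))
      stop("trees do not share a taxon set")
  n <- length(trees)
  counts <- table(unlist(lapply(trees, bipartitions)))
  freq <- as.numeric(counts) / n
  keys <- names(counts)
  keep <- freq > threshold
  freq_tab <- data.frame(split = keys, freq = freq,
                         stringsAsFactors = FALSE)
  freq_tab <- freq_tab[order(-freq_tab$freq, freq_tab$split), ]
  rownames(freq_tab) <- NULL

  ref <- min(labels)
  clades <- lapply(keys[keep], function(k) strsplit(k, ",", fixed = TRUE)[[1]])
  supports <- freq[keep]
  ord <- order(-vapply(clades, length, 1L))
  clades <- clades[ord]; supports <- supports[ord]

  # clades above a majority threshold are pairwise compatible, hence
  # laminar: nest them greedily from largest to smallest
  build <- function(set, idx) {
    idx <- idx[vapply(idx, function(i) all(clades[[i]] %in% set), TRUE)]
    used <- character(0)
    parts <- character(0)
    for (i in idx) {
      if (any(clades[[i]] %in% used)) next  # nested inside a sibling
      sub <- idx[vapply(idx, function(j)
        j != i && all(clades[[j]] %in% clades[[i]]), TRUE)]
      parts <- c(parts, paste0(build(clades[[i]], sub),
                               sprintf("[&support=%.10g]", supports[i])))
      used <- c(used, clades[[i]])
    }
    singles <- setdiff(set, used)
    paste0("(", paste(c(parts, singles), collapse = ","), ")")
  }
  top <- seq_along(clades)
  nwk <- paste0("(", ref, ",",
                sub("^\\(", "", sub("\\)$", "",
                    build(setdiff(labels, ref), top))), ");")
  # reparse with support comments as node labels
  nwk <- gsub("\\[&support=([0-9.eE+-]+)\\]", "\\1", nwk)
  cons <- ape::read.tree(text = nwk)
  attr(cons, "split_freq") <- freq_tab
  cons
}
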