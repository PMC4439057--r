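# Distinctness and uniqueness indices for reconstructed ancestral
# traits. For a focal clade and a trait (a particular state of a
# character), distinctness subtracts from the clade's ancestral PP the
# *mean* PP of the same trait over a comparison node set (the other
# clades plus the family ancestor); uniqueness subtracts the *maximum*.
# Both indices have a maximum value of 1.0: distinctness is high for
# unusual traits, uniqueness only for traits found nowhere else.

#' Distinctness of a trait (vectorized kernel)
#'
#' `pp - rowMeans(comparison)`: the ancestral posterior probability of
#' the trait in the focal clade minus the mean PP of the same trait
#' across the comparison nodes.
#'
#' @param pp Numeric vector of focal-clade PPs.
#' @param comparison Numeric matrix, one row per element of `pp`, one
#'   column per comparison node (or a vector when `pp` is scalar).
#' @return Numeric vector of distinctness values in `[-1, 1]`.
#' @export
distinctness_index <- function(pp, comparison) {
  if (is.vector(comparison)) comparison <- matrix(comparison, nrow = 1L)
  pp - rowMeans(comparison)
}

#' Uniqueness of a trait (vectorized kernel)
#'
#' `pp - max(comparison)` per row: the focal-clade PP minus the maximum
#' PP of the trait among the comparison nodes. Never exceeds the
#' distinctness of the same trait.
#'
#' @inheritParams distinctness_index
#' @return Numeric vector of uniqueness values in `[-1, 1]`.
#' @export
uniqueness_index <- function(pp, comparison) {
  if (is.vector(comparison)) comparison <- matrix(comparison, nrow = 1L)
  pp - apply(comparison, 1L, max)
}

pp_lookup <- function(pp, clade, char, state) {
  hit <- pp$clade == clade & pp$character == char & pp$state == state
  if (!any(hit))
    stop(sprintf("no PP entry for node '%s', character %d state %d",
                 clade, char, state))
  pp$pp[which(hit)[1]]
}

#' Distinctness of one trait of one clade
#'
#' @param pp A `pp_table`.
#' @param clade Focal clade name.
#' @param char Character index (0-based, as reported).
#' @param state State index (0-based).
#' @param comparison Character vector of comparison node names; every
#'   one must have a PP entry for the trait (missing entries are an
#'   error, never silently zero).
#' @return Scalar distinctness value.
#' @export
distinctness <- function(pp, clade, char, state, comparison) {
  focal <- pp_lookup(pp, clade, char, state)
  comp <- vapply(comparison, function(cl)
    pp_lookup(pp, cl, char, state), 1)
  distinctness_index(focal, comp)
}

#' Uniqueness of one trait of one clade
#'
#' @inheritParams distinctness
#' @return Scalar uniqueness value.
#' @export
uniqueness <- function(pp, clade, char, state, comparison) {
  focal <- pp_lookup(pp, clade, char, state)
  comp <- vapply(comparison, function(cl)
    pp_lookup(pp, cl, char, state), 1)
  uniqueness_index(focal, comp)
}

#' Compute both indices for every clade and trait
#'
#' For each focal clade, the comparison set defaults to all other clades
#' in the table plus the node named as `ancestor` (so with 12 focal
#' clades and a family ancestor the mean divisor is 12). Traits whose PP
#' is zero everywhere are retained with index 0, keeping trait
#' inventories complete.
#'
#' @param pp A `pp_table` containing the focal clades and the ancestor.
#' @param clades Character vector of focal clade names; defaults to all
#'   clades in the table except `ancestor`.
#' @param ancestor Name of the ancestor node included in every
#'   comparison set (default `"ancestor"`; `NULL` to omit).
#' @return An `index_table` data frame with columns `clade`,
#'   `character`, `state`, `distinctness`, `uniqueness`.
#' @export
trait_indices <- function(pp, clades = NULL, ancestor = "ancestor") {
  stopifnot(inherits(pp, "data.frame"))
  all_nodes <- unique(pp$clade)
  if (!is.null(ancestor) && !ancestor %in% all_nodes)
    stop("ancestor node '", ancestor, "' not in PP table")
  if (is.null(clades)) clades <- setdiff(all_nodes, ancestor)
  key <- paste(pp$character, pp$state, sep = ":")
  traits <- unique(data.frame(character = pp$character, state = pp$state,
                              key = key, stringsAsFactors = FALSE))
  traits <- traits[order(traits$character, traits$state), ]
  # PP matrix: traits x nodes, error on gaps
  mat <- matrix(NA_real_, nrow(traits), length(all_nodes),
                dimnames = list(traits$key, all_nodes))
  ij <- cbind(match(key, traits$key), match(pp$clade, all_nodes))
  mat[ij] <- pp$pp
  rows <- list()
  for (cl in clades) {
    comp_nodes <- c(setdiff(clades, cl), ancestor)
    sub <- mat[, comp_nodes, drop = FALSE]
    if (anyNA(sub) || anyNA(mat[, cl])) {
      bad <- comp_nodes[colSums(is.na(sub)) > 0]
      if (anyNA(mat[, cl])) bad <- c(cl, bad)
      stop("missing PP entries for node(s): ", paste(bad, collapse = ", "))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      clade = cl, character = traits$character, state = traits$state,
      distinctness = distinctness_index(mat[, cl], sub),
      uniqueness = uniqueness_index(mat[, cl], sub),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("index_table", "data.frame")
  out
}

#' Rank the traits of a clade by an index
#'
#' @param index An `index_table` from [trait_indices()].
#' @param clade Clade name.
#' @param by `"distinctness"` or `"uniqueness"`.
#' @param top_n How many traits to return (all available if fewer).
#' @return Data frame of the top traits in descending index order; ties
#'   broken by ascending character then state and flagged in the `tie`
#'   column.
#' @export
rank_traits <- function(index, clade, by = c("distinctness", "uniqueness"),
                        top_n = 6L) {
  by <- match.arg(by)
  sub <- index[index$clade == clade, ]
  if (!nrow(sub)) stop("no entries for clade '", clade, "'")
  ord <- order(-sub[[by]], sub$character, sub$state)
  sub <- sub[ord, ]
  n <- min(top_n, nrow(sub))
  out <- sub[seq_len(n), c("clade", "character", "state", by)]
  names(out)[4] <- "value"
  out$tie <- duplicated(out$value) | duplicated(out$value, fromLast = TRUE)
  rownames(out) <- NULL
  out
}

#' Tabular diagnostic report of ranked traits
#'
#' One row per clade, columns `trait1..trait<top_n>` formatted
#' `character:state (value)` with the index at two decimals — the layout
#' used for printed trait-diagnosis tables.
#'
#' @inheritParams rank_traits
#' @param clades Clades to report (default: all in the table, in order
#'   of appearance).
#' @return Data frame of formatted trait strings.
#' @export
format_index_report <- function(index, by = c("distinctness", "uniqueness"),
                                top_n = 6L, clades = NULL) {
  by <- match.arg(by)
  if (is.null(clades)) clades <- unique(index$clade)
  rows <- lapply(clades, function(cl) {
    rk <- rank_traits(index, cl, by, top_n)
    cells <- sprintf("%d:%d (%.2f)", rk$character, rk$state, rk$value)
    length(cells) <- top_n
    as.data.frame(c(list(clade = cl), setNames(as.list(cells),
                    paste0("trait", seq_len(top_n)))),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
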