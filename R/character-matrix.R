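#' Discrete character matrix with polymorphism and missing data
#'
#' Container for a taxa-by-characters matrix of discrete (morphological or
#' life-history) states. Each cell holds the *set* of states observed for
#' that taxon: a singleton for a fixed state, a multi-element set for a
#' polymorphic coding, and the full set `0:(k-1)` for missing data. States
#' are 0-based integers, matching the usual "character 1, state 0" reporting
#' convention for morphological matrices.
#'
#' @param taxa Character vector of taxon labels (unique, order-preserving).
#' @param columns List with one element per character; each element is a
#'   list with one integer vector per taxon giving the observed state set.
#' @param state_counts Integer vector, number of states `k` per character.
#' @param ordered Logical vector, per character: are state changes restricted
#'   to adjacent states (ordered) or free (unordered)?
#' @param partitions Optional named list of integer column indices grouping
#'   characters into partitions (e.g. morphology vs. life history).
#' @return An object of class `character_matrix`.
#' @export
character_matrix <- function(taxa, columns, state_counts,
                             ordered = rep(FALSE, length(columns)),
                             partitions = NULL) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  nchar_ <- length(columns)
  state_counts <- as.integer(state_counts)
  if (length(state_counts) != nchar_ || length(ordered) != nchar_)
    stop("state_counts and ordered must have one entry per character")
  if (any(state_counts < 1)) stop("state_counts must be >= 1")
  for (j in seq_len(nchar_)) {
    col <- columns[[j]] <- unname(columns[[j]])
    if (length(col) != length(taxa))
      stop(sprintf("character %d: expected %d cells, got %d",
                   j, length(taxa), length(col)))
    for (i in seq_along(col)) {
      s <- col[[i]]
      if (length(s) == 0L)
        stop(sprintf("character %d, taxon '%s': empty state set", j, taxa[i]))
      if (any(s < 0L) || any(s >= state_counts[j]))
        stop(sprintf("character %d, taxon '%s': state outside 0..%d",
                     j, taxa[i], state_counts[j] - 1L))
      columns[[j]][[i]] <- sort(unique(as.integer(s)))
    }
  }
  if (!is.null(partitions)) {
    idx <- unlist(partitions)
    if (any(idx < 1L) || any(idx > nchar_))
      stop("partition indices out of range")
  }
  structure(list(taxa = taxa, columns = columns,
                 state_counts = state_counts,
                 ordered = as.logical(ordered),
                 partitions = partitions),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("Character matrix: %d taxa x %d characters\n",
              length(x$taxa), length(x$columns)))
  npoly <- sum(vapply(x$columns, function(col)
    sum(vapply(col, length, 1L) > 1L), 1L))
  cat(sprintf("  state counts: %s; ordered: %d; cells with >1 state: %d\n",
              paste(range(x$state_counts), collapse = "-"),
              sum(x$ordered), npoly))
  invisible(x)
}

#' Number of characters in a matrix
#' @param x A `character_matrix`.
#' @return Integer count of characters (columns).
#' @export
n_characters <- function(x) length(x$columns)

is_missing_cell <- function(cell, k) length(cell) == k
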