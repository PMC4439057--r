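# GC-composition summaries per taxon, partition, codon position and
# taxon group -- the bookkeeping behind compositional-bias diagnostics
# (e.g. whether designated clades differ in GC content of a marker or of
# its third codon positions). Only unambiguous A/C/G/T count; gaps and
# IUPAC ambiguity codes (including S = G-or-C) are excluded from both
# numerator and denominator, a conservative counting rule recorded in
# the output.

#' GC fraction of a nucleotide string
#'
#' `(G + C) / (A + C + G + T)`, case-insensitive; gaps and ambiguity
#' codes are excluded from numerator and denominator.
#'
#' @param seq A nucleotide string (IUPAC alphabet, gaps allowed).
#' @return List with `gc` (fraction, `NA` when no unambiguous bases —
#'   flagged via `defined = FALSE`) and `bases` (count of unambiguous
#'   bases).
#' @export
gc_fraction <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n_gc <- sum(chars %in% c("G", "C"))
  n_at <- sum(chars %in% c("A", "T"))
  n <- n_gc + n_at
  list(gc = if (n > 0) n_gc / n else NA_real_,
       bases = n, defined = n > 0)
}

partition_columns <- function(aln, partition) {
  if (is.null(partition)) return(seq_len(nchar(aln$sequences[1])))
  if (is.null(aln$partitions) || !partition %in% names(aln$partitions))
    stop("unknown partition: ", partition)
  aln$partitions[[partition]]
}

#' Extract codon-position columns of a partition
#'
#' Returns the alignment restricted to the requested codon position(s)
#' of a coding partition. Position `"12"` returns first and second
#' positions interleaved in their original order. Trailing incomplete
#' codons contribute their columns to whichever positions they reach.
#'
#' @param aln A [dna_alignment()].
#' @param partition Partition name (must be declared).
#' @param position `1`, `2`, `3` or `"12"`.
#' @return A [dna_alignment()] containing only the selected columns.
#' @export
codon_position_slice <- function(aln, partition, position) {
  cols <- partition_columns(aln, partition)
  off <- 1L
  if (!is.null(aln$codon_offsets) && partition %in% names(aln$codon_offsets))
    off <- as.integer(aln$codon_offsets[[partition]])
  pos_of <- ((seq_along(cols) + off - 2L) %% 3L) + 1L
  want <- if (identical(as.character(position), "12")) c(1L, 2L)
          else as.integer(position)
  if (!all(want %in% 1:3)) stop("position must be 1, 2, 3 or \"12\"")
  sel <- cols[pos_of %in% want]
  seqs <- vapply(aln$sequences, function(s)
    paste(strsplit(s, "", fixed = TRUE)[[1]][sel], collapse = ""), "")
  dna_alignment(aln$taxa, seqs)
}

#' Per-taxon and per-group GC summaries
#'
#' Computes the GC fraction of every taxon over a partition (optionally
#' restricted to a codon-position class) and summarizes each named
#' taxon group by mean, min, quartiles and max — the quantities a
#' compositional-bias box plot displays.
#'
#' @param aln A [dna_alignment()].
#' @param groups Named list of taxon-label vectors (e.g. outgroups,
#'   focal clades, subsets of interest).
#' @param partition Optional partition name (default: all columns).
#' @param position Optional codon position class (`1`, `2`, `3`,
#'   `"12"`); requires `partition`.
#' @return List of class `composition_table`: `taxa` (per-taxon data
#'   frame with `gc` and `bases`) and `groups` (per-group summary data
#'   frame).
#' @export
group_gc_summary <- function(aln, groups, partition = NULL,
                             position = NULL) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list")
  for (nm in names(groups)) {
    if (!length(groups[[nm]])) stop("empty group: ", nm)
    bad <- setdiff(groups[[nm]], aln$taxa)
    if (length(bad))
      stop("group '", nm, "' has unknown taxa: ", paste(bad, collapse = ", "))
  }
  sub <- aln
  if (!is.null(position)) {
    if (is.null(partition)) stop("position slicing requires a partition")
    sub <- codon_position_slice(aln, partition, position)
  } else if (!is.null(partition)) {
    cols <- partition_columns(aln, partition)
    seqs <- vapply(aln$sequences, function(s)
      paste(strsplit(s, "", fixed = TRUE)[[1]][cols], collapse = ""), "")
    sub <- dna_alignment(aln$taxa, seqs)
  }
  per <- lapply(sub$sequences, gc_fraction)
  taxa_df <- data.frame(taxon = sub$taxa,
                        gc = vapply(per, `[[`, 1, "gc"),
                        bases = vapply(per, `[[`, 1L, "bases"),
                        stringsAsFactors = FALSE)
  rownames(taxa_df) <- NULL
  grp <- lapply(names(groups), function(nm) {
    g <- taxa_df$gc[match(groups[[nm]], taxa_df$taxon)]
    g <- g[!is.na(g)]
    if (!length(g)) stop("group '", nm, "' has no defined GC values")
    q <- stats::quantile(g, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = nm, n = length(g), mean = mean(g), min = min(g),
               q25 = q[1], median = q[2], q75 = q[3], max = max(g),
               stringsAsFactors = FALSE)
  })
  out <- list(taxa = taxa_df, groups = do.call(rbind, grp),
              ambiguity_policy = "excluded")
  class(out) <- "composition_table"
  out
}

#' @export
print.composition_table <- function(x, ...) {
  cat("GC composition summary\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}
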