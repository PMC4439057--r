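# NEXUS / FASTA / Newick / TSV input-output.
#
# Character matrices are parsed by hand because the polymorphism syntax
# ({..} state sets) and ASSUMPTIONS ctype statements of morphological
# NEXUS files are not covered by the usual sequence readers. Tree files
# (Newick lists or NEXUS TREES blocks with translate tables) go through
# ape.

# ---- low-level NEXUS helpers ------------------------------------------

# remove [..] comments (possibly spanning lines); returns single string
strip_nexus_comments <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  depth <- 0L
  out <- character(0)
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  keep <- logical(length(chars))
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "[") depth <- depth + 1L
    keep[i] <- depth == 0L
    if (ch == "]" && depth > 0L) depth <- depth - 1L
  }
  paste(chars[keep], collapse = "")
}

# split NEXUS text into named blocks of commands (each command a string)
nexus_blocks <- function(txt) {
  txt <- sub("^\\s*#NEXUS\\s*", "", txt, ignore.case = TRUE)
  cmds <- strsplit(txt, ";", fixed = TRUE)[[1]]
  cmds <- trimws(cmds)
  cmds <- cmds[nzchar(cmds)]
  blocks <- list()
  cur <- NULL
  curname <- NULL
  for (cmd in cmds) {
    lc <- tolower(cmd)
    if (grepl("^begin\\s+", lc)) {
      curname <- sub("^begin\\s+", "", lc)
      cur <- character(0)
    } else if (grepl("^end(block)?$", lc)) {
      if (!is.null(curname))
        blocks[[length(blocks) + 1L]] <- list(name = curname, cmds = cur)
      cur <- NULL; curname <- NULL
    } else if (!is.null(curname)) {
      cur <- c(cur, cmd)
    }
  }
  blocks
}

# parse "3 5-8 10" style 1-based index lists
parse_index_ranges <- function(txt, n_max) {
  toks <- strsplit(trimws(txt), "\\s+")[[1]]
  out <- integer(0)
  for (tk in toks) {
    if (grepl("^\\d+$", tk)) {
      out <- c(out, as.integer(tk))
    } else if (grepl("^\\d+-\\d+$", tk)) {
      ab <- as.integer(strsplit(tk, "-", fixed = TRUE)[[1]])
      out <- c(out, seq.int(ab[1], ab[2]))
    } else if (grepl("^\\d+-\\.$", tk)) {
      a <- as.integer(sub("-\\.$", "", tk))
      out <- c(out, seq.int(a, n_max))
    } else if (grepl("^\\d+-\\d+\\\\3$", tk)) {
      ab <- as.integer(strsplit(sub("\\\\3$", "", tk), "-")[[1]])
      out <- c(out, seq.int(ab[1], ab[2], by = 3L))
    } else {
      stop(sprintf("cannot parse index range token '%s'", tk))
    }
  }
  out
}

# key=value pairs from a FORMAT-style command (values possibly "quoted")
parse_format_command <- function(cmd) {
  body <- sub("^\\s*\\S+\\s*", "", cmd)  # drop command word
  out <- list()
  pat <- "([A-Za-z]+)\\s*=\\s*(\"[^\"]*\"|\\S+)"
  m <- gregexpr(pat, body, perl = TRUE)[[1]]
  if (m[1] != -1) {
    starts <- m
    lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      piece <- substr(body, starts[i], starts[i] + lens[i] - 1L)
      key <- tolower(sub("\\s*=.*$", "", piece))
      val <- sub("^[^=]*=\\s*", "", piece)
      val <- gsub('"', "", val)
      out[[key]] <- val
    }
  }
  # bare flags such as INTERLEAVE
  flags <- strsplit(gsub(pat, "", body, perl = TRUE), "\\s+")[[1]]
  for (fl in flags[nzchar(flags)]) out[[tolower(fl)]] <- TRUE
  out
}

# split a MATRIX command into rows of (label, data-string)
matrix_rows <- function(cmd) {
  body <- sub("^\\s*matrix", "", cmd, ignore.case = TRUE)
  lines <- strsplit(body, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  rows <- list()
  for (ln in lines) {
    if (grepl("^'", ln)) {
      close <- regexpr("'", substring(ln, 2), fixed = TRUE)
      if (close == -1) stop("unterminated quoted taxon label: ", ln)
      label <- substr(ln, 2L, close)
      rest <- trimws(substring(ln, close + 2L))
    } else {
      label <- sub("\\s.*$", "", ln)
      rest <- trimws(sub("^\\S+\\s*", "", ln))
    }
    rows[[length(rows) + 1L]] <- list(label = label, data = rest)
  }
  rows
}

# ---- character matrices -----------------------------------------------

#' Read a NEXUS discrete character matrix
#'
#' Parses a DATA or CHARACTERS block of a NEXUS file with standard
#' (morphological) data. Polymorphic cells coded `{ab}` or `(ab)` become
#' multi-element state sets, `?` becomes the full ambiguity set, and the
#' gap symbol is handled per `gap_policy`. Ordering statements
#' (`ctype ordered: ...` in an ASSUMPTIONS or MRBAYES block) populate the
#' per-character ordered flags, and `charset` statements populate
#' partitions.
#'
#' @param path Path to a NEXUS file.
#' @param gap_policy Either `"missing"` (gap cells treated as full
#'   ambiguity, the default — appropriate when inapplicable codings carry
#'   no state information) or `"error"` (refuse files containing gaps).
#' @return A [character_matrix()].
#' @export
read_character_matrix <- function(path, gap_policy = c("missing", "error")) {
  gap_policy <- match.arg(gap_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- strip_nexus_comments(readLines(path, warn = FALSE))
  blocks <- nexus_blocks(txt)
  bnames <- vapply(blocks, `[[`, "", "name")
  di <- which(bnames %in% c("data", "characters"))
  if (!length(di)) stop("no DATA or CHARACTERS block in ", path)
  blk <- blocks[[di[1]]]

  ntax <- nchar_ <- NA_integer_
  symbols <- strsplit("0123456789", "")[[1]]
  missing_sym <- "?"; gap_sym <- "-"
  rows_raw <- list()
  for (cmd in blk$cmds) {
    word <- tolower(sub("\\s.*$", "", cmd))
    if (word == "dimensions") {
      kv <- parse_format_command(cmd)
      if (!is.null(kv$ntax)) ntax <- as.integer(kv$ntax)
      if (!is.null(kv$nchar)) nchar_ <- as.integer(kv$nchar)
    } else if (word == "format") {
      kv <- parse_format_command(cmd)
      if (!is.null(kv$symbols)) symbols <- strsplit(gsub("\\s", "", kv$symbols), "")[[1]]
      if (!is.null(kv$missing)) missing_sym <- kv$missing
      if (!is.null(kv$gap)) gap_sym <- kv$gap
    } else if (word == "matrix") {
      rows_raw <- matrix_rows(cmd)
    }
  }
  if (!length(rows_raw)) stop("no MATRIX command in ", path)
  if (is.na(nchar_)) stop("DIMENSIONS nchar missing in ", path)

  # accumulate per-taxon cell lists (handles interleaved blocks)
  taxa <- character(0)
  cells <- list()
  for (row in rows_raw) {
    parsed <- parse_state_row(row$data, symbols, missing_sym, gap_sym,
                              gap_policy, row$label)
    if (row$label %in% taxa) {
      cells[[row$label]] <- c(cells[[row$label]], parsed)
    } else {
      taxa <- c(taxa, row$label)
      cells[[row$label]] <- parsed
    }
  }
  if (!is.na(ntax) && length(taxa) != ntax)
    stop(sprintf("expected %d taxa, found %d", ntax, length(taxa)))
  nc <- vapply(cells, length, 1L)
  if (any(nc != nchar_))
    stop(sprintf("taxon '%s' has %d characters, expected %d",
                 taxa[which(nc != nchar_)[1]], nc[nc != nchar_][1], nchar_))

  # per-character state count: an explicit statecounts statement in a
  # private block wins; otherwise the declared symbol space truncated to
  # max observed state + 1 (so a binary character among 0-9 symbols gets
  # k = 2), with a floor of 2
  state_counts <- NULL
  for (blk2 in blocks[bnames == "cladistinct"]) {
    for (cmd in blk2$cmds) {
      if (tolower(sub("\\s.*$", "", cmd)) == "statecounts") {
        state_counts <- as.integer(strsplit(trimws(
          sub("^\\s*\\S+", "", cmd)), "\\s+")[[1]])
        if (length(state_counts) != nchar_)
          stop("statecounts length does not match nchar")
      }
    }
  }
  if (is.null(state_counts)) {
    state_counts <- integer(nchar_)
    for (j in seq_len(nchar_)) {
      obs <- unlist(lapply(cells, function(cl) {
        s <- cl[[j]]
        if (identical(s, NA_integer_)) integer(0) else s
      }))
      state_counts[j] <- max(2L, if (length(obs)) max(obs) + 1L else 2L)
    }
  }
  columns <- vector("list", nchar_)
  for (j in seq_len(nchar_)) {
    columns[[j]] <- lapply(taxa, function(tx) {
      s <- cells[[tx]][[j]]
      if (length(s) == 1L && is.na(s)) 0:(state_counts[j] - 1L) else s
    })
  }

  ordered <- rep(FALSE, nchar_)
  partitions <- NULL
  for (blk2 in blocks[bnames %in% c("assumptions", "sets", "mrbayes")]) {
    for (cmd in blk2$cmds) {
      word <- tolower(sub("\\s.*$", "", cmd))
      if (word == "ctype") {
        body <- sub("^\\s*ctype\\s+", "", cmd, ignore.case = TRUE)
        typ <- tolower(trimws(sub(":.*$", "", body)))
        idx <- parse_index_ranges(sub("^[^:]*:", "", body), nchar_)
        if (typ %in% c("ordered", "ord"))
          ordered[idx] <- TRUE
      } else if (word == "charset") {
        body <- sub("^\\s*charset\\s+", "", cmd, ignore.case = TRUE)
        nm <- trimws(sub("=.*$", "", body))
        idx <- parse_index_ranges(sub("^[^=]*=", "", body), nchar_)
        if (is.null(partitions)) partitions <- list()
        partitions[[nm]] <- idx
      }
    }
  }
  character_matrix(taxa, columns, state_counts, ordered, partitions)
}

# one data row -> list of integer state sets (NA marker = missing)
parse_state_row <- function(dat, symbols, missing_sym, gap_sym,
                            gap_policy, label) {
  chars <- strsplit(gsub("\\s", "", dat), "")[[1]]
  out <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- i + 1L
      set <- integer(0)
      while (j <= n && chars[j] != close) {
        idx <- match(chars[j], symbols)
        if (is.na(idx))
          stop(sprintf("taxon '%s': symbol '%s' not in declared symbols",
                       label, chars[j]))
        set <- c(set, idx - 1L)
        j <- j + 1L
      }
      if (j > n) stop(sprintf("taxon '%s': unterminated state set", label))
      if (!length(set)) stop(sprintf("taxon '%s': empty state set", label))
      out[[length(out) + 1L]] <- sort(unique(set))
      i <- j + 1L
    } else if (ch == missing_sym) {
      out[[length(out) + 1L]] <- NA_integer_
      i <- i + 1L
    } else if (ch == gap_sym) {
      if (gap_policy == "error")
        stop(sprintf("taxon '%s': gap symbol present (gap_policy = 'error')",
                     label))
      out[[length(out) + 1L]] <- NA_integer_
      i <- i + 1L
    } else {
      idx <- match(ch, symbols)
      if (is.na(idx))
        stop(sprintf("taxon '%s': symbol '%s' not in declared symbols",
                     label, ch))
      out[[length(out) + 1L]] <- idx - 1L
      i <- i + 1L
    }
  }
  out
}

#' Write a character matrix as NEXUS
#'
#' Inverse of [read_character_matrix()]: emits a DATA block with standard
#' datatype, `{..}` polymorphism, `?` for missing cells, and an
#' ASSUMPTIONS block carrying ordering (`ctype ordered`) and partition
#' (`charset`) statements.
#'
#' @param x A [character_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(x, path) {
  stopifnot(inherits(x, "character_matrix"))
  kmax <- max(x$state_counts)
  symbols <- strsplit("0123456789", "")[[1]][seq_len(kmax)]
  lines <- c("#NEXUS", "", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                     length(x$taxa), length(x$columns)),
             sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
                     paste(symbols, collapse = "")),
             "  MATRIX")
  wid <- max(nchar(x$taxa))
  for (i in seq_along(x$taxa)) {
    cells <- vapply(seq_along(x$columns), function(j) {
      s <- x$columns[[j]][[i]]
      k <- x$state_counts[j]
      if (length(s) == k) "?"
      else if (length(s) == 1L) symbols[s + 1L]
      else paste0("{", paste(symbols[s + 1L], collapse = ""), "}")
    }, "")
    lines <- c(lines, sprintf("  %-*s %s", wid, x$taxa[i],
                              paste(cells, collapse = "")))
  }
  lines <- c(lines, "  ;", "END;")
  extras <- character(0)
  if (any(x$ordered))
    extras <- c(extras, sprintf("  ctype ordered: %s;",
                                paste(which(x$ordered), collapse = " ")))
  if (!is.null(x$partitions))
    for (nm in names(x$partitions))
      extras <- c(extras, sprintf("  charset %s = %s;", nm,
                                  collapse_ranges(x$partitions[[nm]])))
  if (length(extras))
    lines <- c(lines, "", "BEGIN ASSUMPTIONS;", extras, "END;")
  # private block preserving per-character state-space sizes (states
  # above the highest observed one are not recoverable from the data)
  lines <- c(lines, "", "BEGIN CLADISTINCT;",
             sprintf("  statecounts %s;",
                     paste(x$state_counts, collapse = " ")),
             "END;")
  writeLines(lines, path)
  invisible(path)
}

collapse_ranges <- function(idx) {
  idx <- sort(unique(as.integer(idx)))
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  paste(vapply(runs, function(r)
    if (length(r) == 1L) as.character(r) else sprintf("%d-%d", r[1], r[length(r)]),
    ""), collapse = " ")
}

# ---- alignments --------------------------------------------------------

#' Nucleotide alignment container
#'
#' @param taxa Character vector of taxon labels.
#' @param sequences Character vector of equal-length IUPAC nucleotide
#'   strings (one per taxon, gaps allowed).
#' @param partitions Optional named list of integer column index vectors.
#' @param codon_offsets Optional named integer vector giving, per coding
#'   partition, the codon position (1, 2 or 3) of its first column.
#' @return An object of class `dna_alignment`.
#' @export
dna_alignment <- function(taxa, sequences, partitions = NULL,
                          codon_offsets = NULL) {
  taxa <- as.character(taxa)
  sequences <- toupper(as.character(sequences))
  if (length(taxa) != length(sequences))
    stop("taxa and sequences differ in length")
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  if (!is.null(partitions)) {
    idx <- unlist(partitions)
    if (any(idx < 1L) || any(idx > lens[1]))
      stop("partition indices out of alignment bounds")
  }
  structure(list(taxa = taxa, sequences = setNames(sequences, taxa),
                 partitions = partitions, codon_offsets = codon_offsets),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("DNA alignment: %d taxa x %d columns", length(x$taxa),
              nchar(x$sequences[1])))
  if (!is.null(x$partitions))
    cat(sprintf("; partitions: %s", paste(names(x$partitions), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Read a FASTA or NEXUS alignment
#'
#' @param path Path to the alignment file; format auto-detected (`#NEXUS`
#'   header vs. `>` FASTA header) unless given.
#' @param format `"auto"`, `"fasta"` or `"nexus"`.
#' @return A [dna_alignment()]; NEXUS `charset` statements become
#'   partitions.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    first <- trimws(lines[nzchar(trimws(lines))][1])
    format <- if (grepl("^#NEXUS", first, ignore.case = TRUE)) "nexus" else "fasta"
  }
  if (format == "fasta") {
    hdr <- grepl("^>", lines)
    if (!any(hdr)) stop("no FASTA headers in ", path)
    grp <- cumsum(hdr)
    taxa <- sub("^>\\s*", "", lines[hdr])
    taxa <- sub("\\s.*$", "", taxa)
    seqs <- vapply(seq_along(taxa), function(i)
      paste(lines[grp == i & !hdr], collapse = ""), "")
    return(dna_alignment(taxa, gsub("\\s", "", seqs)))
  }
  txt <- strip_nexus_comments(lines)
  blocks <- nexus_blocks(txt)
  bnames <- vapply(blocks, `[[`, "", "name")
  di <- which(bnames %in% c("data", "characters"))
  if (!length(di)) stop("no DATA or CHARACTERS block in ", path)
  taxa <- character(0); seqs <- list()
  for (cmd in blocks[[di[1]]]$cmds) {
    if (tolower(sub("\\s.*$", "", cmd)) == "matrix") {
      for (row in matrix_rows(cmd)) {
        dat <- gsub("\\s", "", row$data)
        if (row$label %in% taxa) {
          seqs[[row$label]] <- paste0(seqs[[row$label]], dat)
        } else {
          taxa <- c(taxa, row$label)
          seqs[[row$label]] <- dat
        }
      }
    }
  }
  partitions <- NULL
  ncol_ <- nchar(seqs[[1]])
  for (blk in blocks[bnames %in% c("assumptions", "sets")]) {
    for (cmd in blk$cmds) {
      if (tolower(sub("\\s.*$", "", cmd)) == "charset") {
        body <- sub("^\\s*charset\\s+", "", cmd, ignore.case = TRUE)
        nm <- trimws(sub("=.*$", "", body))
        if (is.null(partitions)) partitions <- list()
        partitions[[nm]] <- parse_index_ranges(sub("^[^=]*=", "", body), ncol_)
      }
    }
  }
  dna_alignment(taxa, unlist(seqs[taxa]), partitions)
}

#' Write an alignment as FASTA or NEXUS
#'
#' @param x A [dna_alignment()].
#' @param path Output file path.
#' @param format `"fasta"` or `"nexus"` (the latter writes `charset`
#'   statements for any partitions).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path, format = c("fasta", "nexus")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "dna_alignment"))
  if (format == "fasta") {
    lines <- as.vector(rbind(paste0(">", x$taxa), unname(x$sequences)))
    writeLines(lines, path)
    return(invisible(path))
  }
  wid <- max(nchar(x$taxa))
  lines <- c("#NEXUS", "", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(x$taxa),
                     nchar(x$sequences[1])),
             "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
             "  MATRIX",
             sprintf("  %-*s %s", wid, x$taxa, unname(x$sequences)),
             "  ;", "END;")
  if (!is.null(x$partitions)) {
    lines <- c(lines, "", "BEGIN SETS;",
               vapply(names(x$partitions), function(nm)
                 sprintf("  charset %s = %s;", nm,
                         collapse_ranges(x$partitions[[nm]])), ""),
               "END;")
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- tree samples ------------------------------------------------------

#' Posterior tree sample (one or more independent runs)
#'
#' @param runs List of `multiPhylo` objects, one per independent run.
#' @param generations Optional list of numeric vectors (sampling
#'   generation of each tree); defaults to `1..n` per run. Must be
#'   strictly increasing within a run.
#' @return An object of class `tree_sample`.
#' @export
tree_sample <- function(runs, generations = NULL) {
  if (!length(runs)) stop("at least one run required")
  runs <- lapply(runs, function(r) {
    if (inherits(r, "phylo")) r <- c(r)  # promote to multiPhylo
    if (!inherits(r, "multiPhylo")) class(r) <- "multiPhylo"
    if (!is.null(attr(r, "TipLabel"))) r <- ape::.uncompressTipLabel(r)
    r
  })
  ref <- sort(runs[[1]][[1]]$tip.label)
  for (i in seq_along(runs)) {
    for (tr in runs[[i]]) {
      if (!identical(sort(tr$tip.label), ref))
        stop(sprintf("run %d: taxon set differs from run 1", i))
    }
  }
  if (is.null(generations))
    generations <- lapply(runs, function(r) seq_along(r))
  for (i in seq_along(runs)) {
    g <- generations[[i]]
    if (length(g) != length(runs[[i]]) || any(diff(g) <= 0))
      stop(sprintf("run %d: generations not strictly increasing", i))
  }
  structure(list(runs = runs, generations = generations),
            class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("Tree sample: %d run(s) of %s trees, %d taxa\n",
              length(x$runs),
              paste(vapply(x$runs, length, 1L), collapse = "/"),
              length(x$runs[[1]][[1]]$tip.label)))
  invisible(x)
}

#' Read posterior tree samples
#'
#' Each input file becomes one run. Files may be NEXUS TREES blocks
#' (MrBayes `.t` style, translate tables resolved) or plain Newick lists.
#' Sampling generations are recovered from tree names of the form
#' `STATE_<g>`, `gen.<g>` or any name with a trailing integer; otherwise
#' trees are numbered `1..n`.
#'
#' @param paths Character vector of file paths, one per run.
#' @return A [tree_sample()].
#' @export
read_tree_sample <- function(paths) {
  runs <- list(); gens <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p)
    lines <- readLines(p, warn = FALSE)
    first <- trimws(lines[nzchar(trimws(lines))][1])
    is_nexus <- grepl("^#NEXUS", first, ignore.case = TRUE)
    trees <- if (is_nexus) ape::read.nexus(p) else ape::read.tree(p)
    if (inherits(trees, "phylo")) trees <- c(trees)
    if (!length(trees)) stop("no trees in ", p)
    nm <- if (is_nexus) {
      # tree names straight from the TREES block (read.nexus drops the
      # name when a file holds a single tree)
      tl <- lines[grepl("^\\s*tree\\s+\\S+\\s*=", lines, ignore.case = TRUE)]
      sub("^\\s*tree\\s+(\\S+?)\\s*=.*$", "\\1", tl, ignore.case = TRUE)
    } else names(trees) %||% character(0)
    if (length(nm) != length(trees)) nm <- names(trees) %||% character(0)
    nm[!grepl("[0-9]$", nm)] <- ""
    g <- suppressWarnings(as.numeric(sub("^.*[^0-9]", "", nm)))
    if (length(g) != length(trees) || anyNA(g) || any(diff(g) <= 0))
      g <- seq_along(trees)
    runs[[length(runs) + 1L]] <- trees
    gens[[length(gens) + 1L]] <- g
  }
  tree_sample(runs, gens)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a tree sample to per-run NEXUS files
#'
#' @param ts A [tree_sample()].
#' @param paths Output paths, one per run; trees are named
#'   `STATE_<generation>` and a translate table is emitted.
#' @return `paths`, invisibly.
#' @export
write_tree_sample <- function(ts, paths) {
  stopifnot(inherits(ts, "tree_sample"), length(paths) == length(ts$runs))
  for (i in seq_along(ts$runs)) {
    trees <- ts$runs[[i]]
    names(trees) <- sprintf("STATE_%d", as.integer(ts$generations[[i]]))
    ape::write.nexus(trees, file = paths[i], translate = TRUE)
    # drop the writer's timestamp comment so identical samples produce
    # byte-identical files
    lines <- readLines(paths[i], warn = FALSE)
    writeLines(lines[!grepl("^\\[R-package APE", lines)], paths[i])
  }
  invisible(paths)
}

# ---- parameter traces --------------------------------------------------

#' Read MrBayes-style .p parameter traces
#'
#' Each file is a tab-separated table with an optional bracketed ID line
#' first, then a header naming the sampled scalar parameters.
#'
#' @param paths Character vector of trace file paths, one per run.
#' @return A named list of data frames (class `trace_set`).
#' @export
read_trace <- function(paths) {
  out <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    lines <- readLines(p, warn = FALSE)
    lines <- lines[!grepl("^\\s*\\[", lines)]
    read.table(text = lines, header = TRUE, sep = "\t",
               check.names = FALSE)
  })
  names(out) <- paste0("run", seq_along(out))
  class(out) <- "trace_set"
  out
}

# ---- reports -----------------------------------------------------------

#' Write a tabular report as TSV
#'
#' Numeric columns can be fixed to a decimal precision (2 for index
#' tables, matching the usual printed reporting of the indices); row
#' order is taken as given, so callers sort before writing.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @param digits Optional decimal places applied to all numeric columns;
#'   `NULL` writes full precision.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, digits = NULL) {
  x <- as.data.frame(x)
  if (!nrow(x)) stop("refusing to write an empty report")
  if (!is.null(digits)) {
    for (j in seq_along(x))
      if (is.numeric(x[[j]]))
        x[[j]] <- formatC(x[[j]], format = "f", digits = digits)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ancestral-state posterior-probability table
#'
#' Accepts the TSV layout written by [write_pp_table()]: columns
#' `clade`, `trait` (as `character:state`, 0-based) and `pp`, or the
#' explicit four-column `clade`, `character`, `state`, `pp` form.
#'
#' @param path Path to a TSV file.
#' @return A `pp_table` data frame.
#' @export
read_pp_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if ("trait" %in% names(df) && !"character" %in% names(df)) {
    cs <- strsplit(df$trait, ":", fixed = TRUE)
    df$character <- as.integer(vapply(cs, `[`, "", 1L))
    df$state <- as.integer(vapply(cs, `[`, "", 2L))
    df$trait <- NULL
  }
  need <- c("clade", "character", "state", "pp")
  if (!all(need %in% names(df)))
    stop("pp table must have columns clade, character(:state), pp")
  pp_table(df[, need])
}

#' Write a posterior-probability table as TSV
#'
#' @param pp A `pp_table` (see [ancestral_pp_over_sample()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pp_table <- function(pp, path) {
  df <- data.frame(clade = pp$clade,
                   trait = sprintf("%d:%d", pp$character, pp$state),
                   pp = pp$pp, stringsAsFactors = FALSE)
  write_report(df, path)
}
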