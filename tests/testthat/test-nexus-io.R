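test_that("minimal matrices parse with polymorphism, missing and gaps", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    "  DIMENSIONS NTAX=3 NCHAR=4;",
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"012\" MISSING=? GAP=-;",
    "  MATRIX",
    "  alpha 0{01}?2",
    "  beta  11-0",
    "  'gamma sp' 2010",
    "  ;",
    "END;"), f)
  cm <- read_character_matrix(f)
  expect_identical(cm$taxa, c("alpha", "beta", "gamma sp"))
  expect_identical(cm$columns[[1]], list(0L, 1L, 2L))
  expect_identical(cm$columns[[2]], list(0:1, 1L, 0L))
  # '?' and gap-as-missing both expand to the full state set
  expect_identical(cm$columns[[3]][[1]], 0:1)
  expect_identical(cm$columns[[3]][[2]], 0:1)
  expect_identical(cm$state_counts, c(3L, 2L, 2L, 3L))
  expect_error(read_character_matrix(f, gap_policy = "error"), "gap")
})

test_that("two-taxon one-character matrix gives singleton state sets", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "DIMENSIONS NTAX=2 NCHAR=1;",
               "FORMAT DATATYPE=STANDARD;",
               "MATRIX", "a 0", "b 1", ";", "END;"), f)
  cm <- read_character_matrix(f)
  expect_identical(cm$columns, list(list(0L, 1L)))
})

test_that("interleaved matrices and ctype/charset statements are honored", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    "  DIMENSIONS NTAX=2 NCHAR=6;",
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"0123\" INTERLEAVE;",
    "  MATRIX",
    "  a 012",
    "  b 210",
    "  a 333",
    "  b 030",
    "  ;",
    "END;",
    "BEGIN ASSUMPTIONS;",
    "  ctype ordered: 2 4-5;",
    "  charset morph = 1-4;",
    "  charset bio = 5-6;",
    "END;"), f)
  cm <- read_character_matrix(f)
  expect_identical(vapply(cm$columns, function(cl) cl[[1]], 1L),
                   c(0L, 1L, 2L, 3L, 3L, 3L))
  expect_identical(cm$ordered, c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_identical(cm$partitions, list(morph = 1:4, bio = 5:6))
})

test_that("malformed matrices fail with informative errors", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=2;",
               "FORMAT SYMBOLS=\"01\";", "MATRIX",
               "a 07", "b 00", ";", "END;"), f)
  expect_error(read_character_matrix(f), "symbol '7'")
  writeLines(c("#NEXUS", "BEGIN TAXA;", "END;"), f)
  expect_error(read_character_matrix(f), "no DATA")
})

test_that("character matrices survive a write/read round-trip", {
  set.seed(401)
  for (rep in 1:3) {
    cm <- random_character_matrix(10, 20)
    cm$partitions <- list(morph = 1:15, bio = 16:20)
    f <- withr::local_tempfile(fileext = ".nex")
    write_character_matrix(cm, f)
    cm2 <- read_character_matrix(f)
    expect_identical(cm2$taxa, cm$taxa)
    expect_identical(cm2$columns, cm$columns)
    expect_identical(cm2$state_counts, cm$state_counts)
    expect_identical(cm2$ordered, cm$ordered)
    expect_identical(cm2$partitions, lapply(cm$partitions, as.integer))
  }
})

test_that("tree samples read Newick lists and translate tables alike", {
  f1 <- withr::local_tempfile(fileext = ".nwk")
  writeLines(rep("(A:1,(B:1,C:1):1);", 3), f1)
  ts <- read_tree_sample(f1)
  expect_length(ts$runs, 1L)
  expect_length(ts$runs[[1]], 3L)
  expect_setequal(ts$runs[[1]][[1]]$tip.label, c("A", "B", "C"))

  f2 <- withr::local_tempfile(fileext = ".t")
  writeLines(c("#NEXUS", "begin trees;", "   translate",
               "      1 A,", "      2 B,", "      3 C;",
               "   tree STATE_1000 = (1:1,(2:1,3:1):1);",
               "end;"), f2)
  ts2 <- read_tree_sample(f2)
  expect_setequal(ts2$runs[[1]][[1]]$tip.label, c("A", "B", "C"))
  expect_equal(ts2$generations[[1]], 1000)
  expect_true(is_monophyletic(
    ape::root(ts2$runs[[1]][[1]], outgroup = "A", resolve.root = TRUE),
    c("B", "C")))
})

test_that("tree samples preserve bipartition sets through write/read", {
  set.seed(402)
  trees <- lapply(1:20, function(i) ape::rtree(20))
  class(trees) <- "multiPhylo"
  ts <- tree_sample(list(trees))
  p <- withr::local_tempfile(fileext = ".t")
  write_tree_sample(ts, p)
  ts2 <- read_tree_sample(p)
  for (j in seq_along(trees))
    expect_setequal(bipartitions(ts2$runs[[1]][[j]]),
                    bipartitions(trees[[j]]))
})

test_that("mixed taxon sets across runs are rejected", {
  t1 <- ape::rtree(5)
  t2 <- ape::rtree(5)
  t2$tip.label[1] <- "other"
  expect_error(tree_sample(list(c(t1), c(t2))), "taxon set")
})

test_that("alignments round-trip through FASTA and NEXUS", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s2", "AC-T"), f)
  aln <- read_alignment(f)
  expect_identical(unname(aln$sequences), c("ACGT", "AC-T"))

  set.seed(403)
  seqs <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T", "-"), 40, TRUE), collapse = ""), "")
  a <- dna_alignment(sprintf("t%d", 1:6), seqs,
                     partitions = list(g1 = 1:25, g2 = 26:40))
  for (fmt in c("fasta", "nexus")) {
    p <- withr::local_tempfile()
    write_alignment(a, p, fmt)
    b <- read_alignment(p)
    expect_identical(unname(b$sequences), unname(a$sequences))
    expect_identical(b$taxa, a$taxa)
    if (fmt == "nexus")
      expect_identical(b$partitions, lapply(a$partitions, as.integer))
  }
  expect_error(dna_alignment(c("a", "b"), c("ACGT", "ACG")), "ragged")
})

test_that("parameter traces parse with bracketed ID lines", {
  f <- withr::local_tempfile(fileext = ".p")
  writeLines(c("[ID: 123]", "Gen\tLnL\talpha",
               paste(seq(0, 4000, 1000), rnorm(5, -100), rgamma(5, 2),
                     sep = "\t")), f)
  tr <- read_trace(f)
  expect_length(tr, 1L)
  expect_named(tr[[1]], c("Gen", "LnL", "alpha"))
  expect_equal(nrow(tr[[1]]), 5L)
})

test_that("reports write at fixed precision and pp tables round-trip", {
  df <- data.frame(clade = "TriA", trait = "63:1", value = 0.8571)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_report(df, p, digits = 2)
  lines <- readLines(p)
  expect_length(lines, 2L)
  expect_match(lines[2], "0\\.86$")
  expect_error(write_report(df[0, ], p), "empty")

  pp <- pp_table(data.frame(
    clade = rep(c("A", "B"), each = 2),
    character = 0L, state = c(0L, 1L, 0L, 1L),
    pp = c(0.25, 0.75, 1, 0)))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_pp_table(pp, p2)
  pp2 <- read_pp_table(p2)
  expect_equal(pp2$pp, pp$pp)
  expect_identical(pp2$clade, pp$clade)
})
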