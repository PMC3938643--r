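# Build a labelled alignment from per-family column lists (each element a
# character vector over the family's sequences).
aln_from_columns <- function(colsA, colsB) {
  A <- do.call(cbind, colsA)
  B <- do.call(cbind, colsB)
  mat <- rbind(A, B)
  rownames(mat) <- c(sprintf("a%02d", seq_len(nrow(A))),
                     sprintf("b%02d", seq_len(nrow(B))))
  fam <- setNames(rep(c("A", "B"), c(nrow(A), nrow(B))), rownames(mat))
  labelled_alignment(mat, fam)
}

test_that("alignment validation catches ragged rows and bad characters", {
  expect_error(labelled_alignment(
    c(a1 = "ACDEFGHIKL", a2 = "ACDEFGHIKLM", b1 = "ACDEFGHIKL",
      b2 = "ACDEFGHIKL"),
    c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")), "ragged")
  expect_error(labelled_alignment(
    c(a1 = "ACJD", a2 = "ACDD", b1 = "ACDD", b2 = "ACDD"),
    c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")), "illegal character.*J")
  expect_error(labelled_alignment(
    c(a1 = "ACDD", a2 = "ACDD", b1 = "ACDD", b2 = "ACDD"),
    c(a1 = "A", a2 = "A", b1 = "B")), "no family.*b2")
  expect_error(labelled_alignment(
    c(a1 = "AC-D", a2 = "AC-D", b1 = "AC-D", b2 = "AC-D"),
    c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")), "all-gap")
})

test_that("read_alignment loads equal-length FASTA with a family map", {
  fasta <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a1 desc", "ACDE", ">a2", "ACDE",
               ">b1", "ACDF", ">b2", "ACDF"), fasta)
  fmap <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a1\tA", "a2\tA", "b1\tB", "b2\tB"), fmap)
  aln <- read_alignment(fasta, fmap)
  expect_equal(ncol(aln$mat), 4L)
  expect_equal(as.character(aln$family), c("A", "A", "B", "B"))
})

test_that("unanimous columns give an uppercase consensus", {
  aln <- labelled_alignment(
    c(a1 = "ACDE", a2 = "ACDE", a3 = "ACDE", a4 = "ACDE",
      b1 = "WWWW", b2 = "WWWW"),
    setNames(c("A", "A", "A", "A", "B", "B"),
             c("a1", "a2", "a3", "a4", "b1", "b2")))
  expect_equal(as.character(consensus(aln, "A")), "ACDE")
})

test_that("tier boundaries at 0.70/0.50 follow the column tallies", {
  colsA <- list(c(rep("K", 7), rep("R", 3)),   # 0.70  -> 'K'
                c(rep("K", 6), rep("R", 4)),   # 0.60  -> 'k'
                c(rep("K", 4), rep("R", 3), rep("E", 3)), # 0.40 -> '.'
                c(rep("-", 8), rep("K", 2)),   # gap 0.80 -> '-'
                c(rep("X", 8), rep("K", 2)))   # X never a consensus -> '.'
  colsB <- replicate(5, rep("G", 10), simplify = FALSE)
  aln <- aln_from_columns(colsA, colsB)
  expect_equal(as.character(consensus(aln, "A")), "Kk.-.")
  expect_equal(as.character(consensus(aln, "B")), "GGGGG")
})

test_that("consensus is invariant to sequence order and monotone in threshold", {
  syn <- make_alignment(alignment_recipe(n_a = 8, n_b = 8, length = 60,
                                         noise = 0.1, tail_length_a = 0,
                                         seed = 31))
  aln <- syn$alignment
  perm <- sample(nrow(aln$mat))
  aln_p <- labelled_alignment(aln$mat[perm, , drop = FALSE],
                              aln$family[perm])
  f <- levels(aln$family)[1]
  expect_identical(consensus(aln, f)$symbols, consensus(aln_p, f)$symbols)

  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lo <- consensus(aln, f, threshold_high = 0.70)$symbols
  hi <- consensus(aln, f, threshold_high = 0.90)$symbols
  expect_false(any(hi[!(lo %in% aa)] %in% aa))
})

test_that("site classification covers the example column patterns", {
  n <- 10
  colsA <- list(rep("D", n), rep("A", n), rep("K", n),
                c(rep("K", 6), rep("R", 4)), rep("-", n),
                c(rep("K", 4), rep("R", 3), rep("E", 3)))
  colsB <- list(rep("P", n), rep("A", n),
                c(rep("S", 4), rep("T", 3), rep("N", 3)),
                rep("W", n), rep("F", n),
                c(rep("S", 4), rep("T", 3), rep("N", 3)))
  aln <- aln_from_columns(colsA, colsB)
  cls <- classify_sites(consensus(aln, "A"), consensus(aln, "B"))
  expect_equal(as.character(cls$category),
               c("STRONG_DIFFERENTIAL",    # D vs P (alignment position 35)
                 "IDENTICALLY_CONSERVED",  # A vs A
                 "CONSERVED_A_ONLY",       # K vs unconserved
                 "CONSERVED_B_ONLY",       # lowercase k vs W
                 "INDEL",                  # gap vs F
                 "UNCONSERVED"))
  expect_true(cls$chemical_flag[1]) # D and P are chemically different
  expect_false(any(cls$chemical_flag[-1]))
  # exactly one category per column, counts conserved
  expect_equal(sum(table(cls$category)), ncol(aln$mat))
})

test_that("classify_sites rejects mismatched column spaces", {
  syn <- make_alignment(alignment_recipe(n_a = 4, n_b = 4, length = 20,
                                         tail_length_a = 0, seed = 3,
                                         insertions = data.frame(
                                           after = integer(0),
                                           width = integer(0),
                                           family = character(0))))
  a <- consensus(syn$alignment, "eEF1A")
  b <- consensus(syn$alignment, "EFL")
  b$symbols <- b$symbols[-1]
  expect_error(classify_sites(a, b), "length")
})

test_that("chemical classes split as documented", {
  expect_true(chemical_difference("D", "P"))
  expect_false(chemical_difference("K", "R"))
  expect_true(chemical_difference("G", "A"))
  expect_false(chemical_difference("Q", "S")) # both polar
  expect_true(chemical_difference("Q", "D"))  # polar vs acidic
  expect_false(chemical_difference("X", "D")) # indeterminate
  expect_error(chemical_difference("Z", "D"), "amino")
  # vectorized
  expect_equal(chemical_difference(c("D", "K"), c("P", "R")), c(TRUE, FALSE))
})

test_that("planted insertions and the single deletion are recovered", {
  syn <- make_alignment(alignment_recipe(seed = 17))
  aln <- syn$alignment
  cA <- consensus(aln, "eEF1A"); cB <- consensus(aln, "EFL")
  ind <- detect_indels(cA, cB)
  truth <- syn$truth$indels
  planted <- truth[!truth$is_tail, ]
  found <- ind[ind$end < min(truth$start[truth$is_tail]), ]
  expect_equal(found$start, planted$start)
  expect_equal(found$end, planted$end)
  expect_equal(found$direction, planted$direction)
  expect_true(all(found$conserved))
  expect_equal(sum(found$direction == "insertion_in_B"), 5L)
  expect_equal(sum(found$direction == "deletion_in_B"), 1L)
})

test_that("identical gap patterns yield an empty indel report", {
  aln <- aln_from_columns(
    list(rep("K", 6), c(rep("-", 5), "K"), rep("D", 6)),
    list(rep("R", 6), c(rep("-", 5), "R"), rep("E", 6)))
  # both consensuses gapped at column 2: not an indel between families
  ind <- detect_indels(consensus(aln, "A"), consensus(aln, "B"))
  expect_equal(nrow(ind), 0L)
})

test_that("column-to-residue mapping matches a prefix-scan oracle", {
  aln <- labelled_alignment(
    c(a1 = "A-CD", a2 = "AACD", b1 = "AAC-", b2 = "AACD"),
    c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_equal(map_column(aln, "a2", 4), 4L) # ungapped row
  expect_equal(map_column(aln, "a1", 3), 2L) # hand count over "A-CD"
  expect_true(is.na(map_column(aln, "a1", 2)))
  expect_error(map_column(aln, "zz", 1), "unknown sequence")
  expect_error(map_column(aln, "a1", 9), "out of range")

  set.seed(13)
  syn <- make_alignment(alignment_recipe(n_a = 5, n_b = 5, length = 40,
                                         noise = 0.2, seed = 19))
  aln2 <- syn$alignment
  for (rep in 1:30) {
    id <- sample(aln2$ids, 1)
    col <- sample(ncol(aln2$mat), 1)
    expect_identical(map_column(aln2, id, col),
                     map_column_oracle(aln2$mat[id, ], col))
  }
})

test_that("C-terminal extension averages planted tail lengths", {
  # no tails: A ends where the B consensus ends
  syn0 <- make_alignment(alignment_recipe(tail_length_a = 0, seed = 23))
  expect_equal(cterm_extension(syn0$alignment, "eEF1A", "EFL"), 0)
  # uniform 17-residue tails
  syn17 <- make_alignment(alignment_recipe(seed = 23))
  expect_equal(cterm_extension(syn17$alignment, "eEF1A", "EFL"), 17)
  # mixed tails {10, 20} on two A sequences -> mean 15
  A <- rbind(c(rep("K", 5), rep("W", 10), rep("-", 10)),
             c(rep("K", 5), rep("W", 20)))
  B <- rbind(rep(c("R", "-"), c(5, 20)), rep(c("R", "-"), c(5, 20)))
  mat <- rbind(A, B)
  rownames(mat) <- c("a1", "a2", "b1", "b2")
  aln <- labelled_alignment(mat, setNames(c("A", "A", "B", "B"),
                                          rownames(mat)))
  expect_equal(cterm_extension(aln, "A", "B"), 15)
})
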