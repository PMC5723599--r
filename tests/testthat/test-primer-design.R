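aln_from_strings <- function(rows) {
  alignment(lapply(seq_along(rows), function(i) {
    seq_record(paste0("r", i), rows[[i]], aligned = TRUE)
  }))
}

test_that("column identity counts the modal non-gap base", {
  aln <- aln_from_strings(c("GAT", "GCT", "GAT", "GAT"))
  expect_equal(column_identity(aln, 1), 1.0)
  expect_equal(column_identity(aln, 2), 0.75)
})

test_that("an all-gap column has identity zero and a lone base identity one", {
  aln <- aln_from_strings(c("-A", "-A", "-T", "-A"))
  expect_equal(column_identity(aln, 1), 0)
  expect_equal(column_identity(aln, 2), 0.75)
})

test_that("conserved windows are maximal runs above the identity threshold", {
  rows <- rep(strrep("ACGTG", 12), 4)
  aln <- aln_from_strings(rows)
  w <- find_conserved_windows(aln)
  expect_identical(nrow(w), 1L)
  expect_identical(c(w$start, w$end), c(1L, 60L))
  expect_identical(w$consensus, rows[[1]])

  # one divergent column at position 30 splits the run into 29 + 30
  m <- strsplit(rows, "")
  m[[1]][30] <- "T"; m[[2]][30] <- "T"
  aln2 <- aln_from_strings(vapply(m, paste, character(1), collapse = ""))
  w2 <- find_conserved_windows(aln2, min_len = 15L)
  expect_identical(nrow(w2), 2L)
  expect_setequal(w2$length, c(29L, 30L))

  # random columns never reach the threshold
  set.seed(9)
  rnd <- vapply(1:8, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  }, character(1))
  expect_identical(nrow(find_conserved_windows(aln_from_strings(rnd))), 0L)

  # windows shorter than min_len are dropped
  expect_identical(nrow(find_conserved_windows(aln2, min_len = 31L)), 0L)
})

test_that("windows are non-extendable and candidates stay inside them", {
  ap <- make_aligned_panel(n = 8, seed = 31)
  aln <- ap$alignment
  w <- find_conserved_windows(aln)
  expect_true(nrow(w) >= 2L)
  expect_true(all(w$start[-1] > head(w$end, -1) + 1L))  # disjoint, gap >= 1
  for (i in seq_len(nrow(w))) {  # maximality at both flanks
    if (w$start[i] > 1) {
      expect_lt(column_identity(aln, w$start[i] - 1L), 0.90)
    }
    if (w$end[i] < aln$length) {
      expect_lt(column_identity(aln, w$end[i] + 1L), 0.90)
    }
  }
  cands <- candidate_primers(aln, w, "forward")
  expect_true(all(cands$aln_start >= w$start[cands$window] &
                    cands$aln_end <= w$end[cands$window]))
})

test_that("consensus follows the majority and iupac rules", {
  aln <- aln_from_strings(rep("ACGT", 3))
  expect_identical(consensus(aln, "majority"), "ACGT")

  # column half C / half T in iupac mode
  aln2 <- aln_from_strings(c("AC", "AC", "AT", "AT"))
  expect_identical(consensus(aln2, "iupac"), "AY")

  # {A:0.9, G:0.1}: only bases at frequency >= 1 - threshold are covered
  rows <- c(rep("A", 9), "G")
  aln3 <- aln_from_strings(as.list(rows))
  expect_identical(consensus(aln3, "iupac", threshold = 0.2), "A")
  expect_identical(consensus(aln3, "iupac", threshold = 0.95), "R")

  # gap-majority columns are dropped
  aln4 <- aln_from_strings(c("-A", "-A", "GA"))
  expect_identical(consensus(aln4, "majority"), "A")
})

test_that("Wallace and nearest-neighbor melting temperatures behave", {
  expect_equal(tm("AAAATTTT"), 16)
  expect_equal(tm(P606F), 64)
  expect_error(tm("ACGT"), "shorter")

  # degenerate primer reports its lowest-Tm expansion
  expected <- min(vapply(expand_degenerate(P1084R), function(v) {
    ch <- strsplit(v, "")[[1]]
    2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
  }, numeric(1)))
  expect_equal(tm(P1084R), expected)

  # nn stays within 8 C of Wallace for typical design-range primers
  for (p in list(P29F, P606F, P1082R, P1084R)) {
    expect_lt(abs(tm(p, "nn") - tm(p, "wallace")), 8)
  }
  set.seed(13)
  for (i in 1:40) {
    repeat {
      n <- sample(19:24, 1)
      s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
      g <- gc_fraction(s)
      if (g >= 0.4 && g <= 0.6) break
    }
    expect_lt(abs(tm(s, "nn") - tm(s, "wallace")), 8)
  }
})

test_that("primer scoring flags 3'-A, extreme GC and self-complementarity", {
  s606 <- score_primer(P606F)
  expect_true(s606$three_prime_A)
  expect_identical(s606$degeneracy, 1L)

  expect_equal(score_primer("GGGGGGGGGGGG")$gc, 1.0)
  expect_false(score_primer(P1082R)$three_prime_A)

  # an EcoRI-site core is self-complementary over >= 6 bases
  expect_gte(score_primer("TGCAGAATTCAGGC")$max_self_dimer_run, 6L)

  # penalties lower the composite relative to a clean primer
  clean <- score_primer(P1084R)
  flagged <- score_primer(P606F)
  expect_true(is.finite(clean$composite) && is.finite(flagged$composite))
})

test_that("pairing respects product-length bounds and Tm difference", {
  # two conserved 20-mers flanking a variable 300-bp spacer
  set.seed(17)
  left <- "GTCGATGAAGAGCGCAGCCA"
  right <- "AAGCGGAGGAAAAGAAACTA"
  rows <- vapply(1:6, function(i) {
    paste0(left, paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""),
           right)
  }, character(1))
  aln <- aln_from_strings(rows)

  hit <- design_primers(aln, min_len = 200, max_len = 1250)
  expect_gt(nrow(hit), 0L)
  expect_true(all(hit$product_len >= 200 & hit$product_len <= 1250))
  expect_true(all(abs(hit$fwd_tm - hit$rev_tm) <= 8))

  # a ~340 bp product is excluded under whole-ITS bounds [400, 2500]
  expect_message(none <- design_primers(aln, min_len = 400, max_len = 2500),
                 "no pair")
  expect_identical(nrow(none), 0L)

  # a single window cannot be paired
  w <- find_conserved_windows(aln)
  fwd <- candidate_primers(aln, w[1, , drop = FALSE], "forward")
  expect_message(
    empty <- pair_primers(fwd, fwd[0, , drop = FALSE], 200, 1250),
    "no candidates")
  expect_identical(nrow(empty), 0L)
})

test_that("ranking is deterministic: score, then product length, then name", {
  ap <- make_aligned_panel(n = 6, seed = 41)
  d1 <- design_primers(ap$alignment, 200, 1250)
  d2 <- design_primers(ap$alignment, 200, 1250)
  expect_identical(d1, d2)
  key <- order(-d1$score, d1$product_len, d1$pair_name)
  expect_identical(key, seq_len(nrow(d1)))
})
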