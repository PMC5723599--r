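test_that("FASTA reading preserves order, upper-cases and converts U to T", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">seq_b extra header words", "acgu", "ACGT",
               ">seq_a", "TTTT"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2L)
  expect_identical(vapply(recs, `[[`, character(1), "id"),
                   c("seq_b", "seq_a"))
  expect_identical(recs[[1]]$sequence, "ACGTACGT")
})

test_that("FASTA round-trip is identity on content and order", {
  set.seed(3)
  recs <- lapply(1:5, function(i) {
    seq_record(sprintf("r%02d", i),
               paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""))
  })
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_identical(lapply(back, `[[`, "sequence"),
                   lapply(recs, `[[`, "sequence"))
  expect_identical(lapply(back, `[[`, "id"), lapply(recs, `[[`, "id"))
})

test_that("empty and malformed FASTA inputs are handled per contract", {
  f <- withr::local_tempfile()
  file.create(f)
  expect_identical(read_fasta(f), list())

  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">ok", "ACGT", ">bad", "ACGT", "AXGT"), f2)
  expect_error(read_fasta(f2), "line 5.*'X'")

  # gaps only legal in aligned mode
  f3 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g", "AC-T"), f3)
  expect_error(read_fasta(f3), "illegal")
  expect_identical(read_fasta(f3, aligned = TRUE)[[1]]$sequence, "AC-T")
})

test_that("primer table reading validates orientation and degeneracy", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tseq\torientation",
               "606F\tGTCGATGAAGAGCGCAGCCA\tforward",
               "1084R\tYGTTAGTTTCTTTTCCTCCGCTT\treverse"), f)
  ps <- read_primer_table(f)
  expect_length(ps, 2L)
  expect_identical(nchar(ps[[1]]$seq), 20L)
  expect_identical(degeneracy(ps[[2]]), 2L)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("name\tseq\torientation", f2)
  expect_identical(read_primer_table(f2), list())

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tseq\torientation",
               "p\tACGTACGTACGT\tupside-down"), f3)
  expect_error(read_primer_table(f3), "orientation")
})

test_that("primer and pair constructors enforce their invariants", {
  expect_error(primer("short", "ACGTACGT", "forward"), "12")
  expect_error(primer("gap", "ACGTACGT-ACGT", "forward"), "illegal")
  p <- primer("f", "ACGTACGTACGT", "forward")
  r <- primer("r", "ACGTACGTACGT", "reverse")
  expect_error(primer_pair(p, p, 100, 200), "forward and a reverse")
  expect_error(primer_pair(p, r, 300, 200), "min_len")
  expect_identical(primer_pair(p, r, 100, 200)$name, "f/r")
})

test_that("specimen table reading rejects duplicates and preserves order", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "specimen_id\tfamily\tspecies\tamplified_its2\tamplified_its\tits1_bp\tr58s_bp\tits2_bp\taccession"
  writeLines(c(hdr, "S1\tFam\tGen sp\t+\t+\t300\t153\t250\tXX1"), f)
  tab <- read_specimen_table(f)
  expect_identical(nrow(tab), 1L)

  writeLines(c(hdr,
               "S2\tFamB\tGenb sp\t+\t-\t-\t>70\t240\tXX2",
               "S1\tFam\tGen sp\t+\t+\t300\t153\t250\tXX1",
               "S1\tFam\tGen sp2\t+\t+\t300\t153\t250\tXX3"), f)
  expect_error(read_specimen_table(f), "duplicate specimen_id: S1")

  writeLines(c(hdr, "S1\tFam\tGen sp\tmaybe\t+\t300\t153\t250\tXX1"), f)
  expect_error(read_specimen_table(f), "outcome token")
})

test_that("amplicon export uses coordinate-suffixed ids and is byte-stable", {
  cs <- make_cassette(cassette_spec(seed = 91))
  hits <- amplify(its2_pair(), cs$record)
  expect_identical(nrow(hits), 1L)

  f <- withr::local_tempfile(fileext = ".fa")
  write_amplicons(hits, f)
  lines <- readLines(f)
  expect_identical(lines[1], sprintf(">%s:%d-%d:606F/1082R",
                                     cs$record$id, hits$start, hits$end))
  expect_identical(nchar(lines[2]), hits$length)
  side <- read.delim(paste0(f, ".tsv"))
  expect_identical(nrow(side), 1L)

  f2 <- withr::local_tempfile(fileext = ".fa")
  write_amplicons(hits, f2)
  expect_identical(readLines(f), readLines(f2))
  expect_identical(readLines(paste0(f, ".tsv")), readLines(paste0(f2, ".tsv")))

  # two hits on one template get distinct ids
  two <- rbind(hits, hits)
  two$start[2] <- two$start[2] + 5L; two$end[2] <- two$end[2] + 5L
  f3 <- withr::local_tempfile(fileext = ".fa")
  write_amplicons(two, f3)
  ids <- grep("^>", readLines(f3), value = TRUE)
  expect_length(unique(ids), 2L)

  # empty hit list: empty FASTA, header-only sidecar
  f4 <- withr::local_tempfile(fileext = ".fa")
  write_amplicons(NULL, f4)
  expect_identical(readLines(f4), character(0))
  expect_identical(nrow(read.delim(paste0(f4, ".tsv"))), 0L)
})

test_that("packaged specimen fixture tallies are stable", {
  sp <- read_specimen_table(spacerprime_extdata("clitellate_specimens.tsv"))
  t1 <- specimen_tallies(sp)
  t2 <- specimen_tallies(sp[sample(nrow(sp)), ])  # order-invariant
  expect_identical(t1$n_specimens, t2$n_specimens)
  expect_identical(t1$n_families, t2$n_families)
  expect_identical(t1$n_genera, t2$n_genera)
})
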