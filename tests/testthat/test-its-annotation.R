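test_that("landmarks are recovered at planted coordinates", {
  cs <- make_cassette(cassette_spec(seed = 101))
  lm <- find_landmarks(cs$record)
  expect_identical(lm$landmark, c("motif_18s_end", "anchor_58s", "anchor_28s"))
  expect_identical(lm$mismatches, c(0L, 0L, 0L))
  expect_identical(lm$start[lm$landmark == "motif_18s_end"], cs$truth$catta[1])
  expect_identical(lm$start[lm$landmark == "anchor_58s"], cs$truth$fwd_site[1])
  expect_identical(lm$start[lm$landmark == "anchor_28s"], cs$truth$rev_site[1])
})

test_that("a sequence without motifs or anchors yields no landmarks", {
  rec <- seq_record("none", strrep("ACG", 200))
  expect_identical(nrow(find_landmarks(rec)), 0L)
})

test_that("anchor mismatches within budget are found and reported", {
  cs <- make_cassette(cassette_spec(seed = 102, fwd_site_mm = 1L))
  lm <- find_landmarks(cs$record)
  expect_identical(lm$mismatches[lm$landmark == "anchor_58s"], 1L)
  expect_identical(lm$start[lm$landmark == "anchor_58s"], cs$truth$fwd_site[1])

  # beyond budget the anchor is absent
  cs3 <- make_cassette(cassette_spec(seed = 103, fwd_site_mm = 3L))
  lm3 <- find_landmarks(cs3$record)
  expect_false("anchor_58s" %in% lm3$landmark)
})

test_that("with several 18S-end motifs the one closest upstream of 5.8S wins", {
  cs <- make_cassette(cassette_spec(seed = 104))
  s <- cs$record$sequence
  # inject a decoy copy early in the 18S tail: planted one still wins
  substr(s, 3, 7) <- "CATTA"
  lm <- find_landmarks(seq_record(cs$record$id, s))
  expect_identical(lm$start[lm$landmark == "motif_18s_end"], cs$truth$catta[1])
  # inject a copy inside ITS1 (downstream of the planted one): it wins
  its1_mid <- cs$annotation$partitions$ITS1[1] + 50L
  s2 <- cs$record$sequence
  substr(s2, its1_mid, its1_mid + 4L) <- "CATTA"
  lm2 <- find_landmarks(seq_record(cs$record$id, s2))
  expect_identical(lm2$start[lm2$landmark == "motif_18s_end"], its1_mid)
})

test_that("annotation recovers generator boundaries exactly", {
  for (seed in c(11, 12, 13)) {
    cs <- make_cassette(cassette_spec(
      seed = seed, ITS1_len = sample(314:1117, 1), ITS2_len = sample(174:503, 1)))
    ann <- annotate_its(cs$record)
    expect_identical(ann$partitions, cs$annotation$partitions)
    expect_true(ann$complete[["ITS1"]] && ann$complete[["r58S"]] &&
                  ann$complete[["ITS2"]])
  }
})

test_that("truncation before the 18S motif leaves ITS1 incomplete with '>' length", {
  cs <- make_cassette(cassette_spec(seed = 105))
  cut <- cs$annotation$partitions$ITS1[1] + 100L  # starts inside ITS1
  rec <- seq_record(cs$record$id, substr(cs$record$sequence, cut, 1e7))
  ann <- annotate_its(rec)
  expect_false(ann$complete[["ITS1"]])
  obs_len <- cs$annotation$partitions$ITS1[2] - cut + 1L
  expect_identical(partition_lengths(ann)$its1_bp, paste0(">", obs_len))
})

test_that("no landmark at all gives an all-absent annotation with a warning", {
  rec <- seq_record("blank", strrep("GCA", 150))
  expect_warning(ann <- annotate_its(rec), "no landmark")
  expect_true(all(vapply(ann$partitions, is.null, logical(1))))
  expect_identical(unlist(partition_lengths(ann)[1, -1], use.names = FALSE),
                   c("-", "-", "-"))
})

test_that("partition length table prints complete lengths as bare integers", {
  cs <- make_cassette(cassette_spec(seed = 106, ITS1_len = 351L,
                                    ITS2_len = 251L))
  tab <- partition_lengths(annotate_its(cs$record))
  expect_identical(tab$its1_bp, "351")
  expect_identical(tab$r58s_bp, "153")
  expect_identical(tab$its2_bp, "251")
})

test_that("5.8S validation separates ok, atypical length and missing motifs", {
  ok <- make_cassette(cassette_spec(seed = 107))
  expect_identical(validate_58s(annotate_its(ok$record), ok$record), "ok")

  # 154 and 152 bp copies are still within the 153 +/- 1 convention
  for (len in c(152L, 154L)) {
    cs <- make_cassette(cassette_spec(seed = 108, r58S_len = len))
    ann <- annotate_its(cs$record)
    expect_identical(partition_length(ann, "r58S"), len)
    expect_identical(validate_58s(ann, cs$record), "ok")
  }

  cs155 <- make_cassette(cassette_spec(seed = 109, r58S_len = 157L))
  ann155 <- annotate_its(cs155$record)
  expect_identical(validate_58s(ann155, cs155$record), "length_atypical")

  # destroy CM2 inside an otherwise intact 5.8S
  cs2 <- make_cassette(cassette_spec(seed = 110))
  iv <- cs2$annotation$partitions$r58S
  mut <- mutate_window(cs2$record$sequence, c(iv[1] + 72L, iv[1] + 80L),
                       k = 6L, seed = 5)
  rec2 <- seq_record("cm2_broken", mut)
  ann2 <- annotate_its(rec2)
  expect_identical(validate_58s(ann2, rec2), "motif_missing")

  # incomplete 5.8S is a precondition error
  frag <- seq_record("frag", substr(ok$record$sequence, 1,
                                    ok$annotation$partitions$r58S[1] + 60L))
  annf <- annotate_its(frag)
  expect_false(isTRUE(annf$complete[["r58S"]]))
  expect_error(validate_58s(annf, frag), "complete")
})

test_that("partition ordering and coordinate conservation hold on random cassettes", {
  set.seed(21)
  for (i in 1:25) {
    cs <- make_cassette(cassette_spec(
      seed = 2000 + i,
      ITS1_len = sample(314:1117, 1), ITS2_len = sample(174:503, 1),
      fwd_site_mm = sample(0:2, 1), rev_site_mm = sample(0:2, 1)))
    ann <- annotate_its(cs$record)
    ivs <- Filter(Negate(is.null), ann$partitions[c("tail18S", "ITS1", "r58S",
                                                    "ITS2", "head28S")])
    flat <- unlist(ivs, use.names = FALSE)
    expect_true(all(diff(flat) >= 0))          # ordered, non-overlapping
    expect_true(all(vapply(ivs, function(iv) iv[2] >= iv[1], logical(1))))
    # conservation: partitions tile the sequence exactly
    total <- sum(vapply(ivs, function(iv) iv[2] - iv[1] + 1L, integer(1)))
    expect_identical(total, nchar(cs$record$sequence))
  }
})
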