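# Run expr under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. One stream per cassette keeps fixtures
# reproducible across platforms and call orders.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Random DNA at a given GC content.
.rand_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Specification for one synthetic rDNA cassette
#'
#' Defaults emulate the cassette architecture of clitellate rDNA: ITS1 and
#' ITS2 spacer lengths inside the published clitellate ranges (314-1117 and
#' 174-503 bp), a 153-bp 5.8S (the packaged synthetic reference), 60-bp
#' flanking 18S/28S stubs, and GC 0.59 in the random regions (the average
#' GC of successfully amplified clitellate amplicons).
#'
#' @param tail18S_len,ITS1_len,r58S_len,ITS2_len,head28S_len Partition
#'   lengths in bp. `r58S_len` may deviate from 153 by a few bases
#'   (atypical copies are built by indels in a neutral region of the
#'   reference).
#' @param gc GC fraction of the randomly generated regions.
#' @param fwd_site_mm Mismatches planted in the forward-primer site inside
#'   5.8S.
#' @param rev_site_mm Mismatches planted in the reverse-primer site inside
#'   the 28S head.
#' @param seed Integer seed; the cassette is fully reproducible from it.
#' @return List of class `cassette_spec`.
#' @export
cassette_spec <- function(tail18S_len = 60L, ITS1_len = 450L, r58S_len = 153L,
                          ITS2_len = 300L, head28S_len = 60L, gc = 0.59,
                          fwd_site_mm = 0L, rev_site_mm = 0L, seed = 1L) {
  spec <- list(tail18S_len = as.integer(tail18S_len),
               ITS1_len = as.integer(ITS1_len),
               r58S_len = as.integer(r58S_len),
               ITS2_len = as.integer(ITS2_len),
               head28S_len = as.integer(head28S_len),
               gc = gc, fwd_site_mm = as.integer(fwd_site_mm),
               rev_site_mm = as.integer(rev_site_mm), seed = as.integer(seed))
  stopifnot(all(unlist(spec[1:5]) > 0L), gc >= 0, gc <= 1,
            spec$fwd_site_mm >= 0L, spec$rev_site_mm >= 0L)
  structure(spec, class = "cassette_spec")
}

#' Mutate exactly k positions inside an interval
#'
#' Each chosen position is changed to a different base; positions listed in
#' `forbidden` are never touched. Deterministic for a given seed.
#'
#' @param seq DNA string.
#' @param interval `c(start, end)`, 1-based inclusive.
#' @param k Number of positions to change.
#' @param seed Integer seed.
#' @param forbidden Absolute positions excluded from mutation.
#' @return The mutated sequence (Hamming distance exactly `k` from the
#'   input over the interval).
#' @export
mutate_window <- function(seq, interval, k, seed = 1L, forbidden = integer(0)) {
  stopifnot(length(interval) == 2L, interval[1] >= 1L,
            interval[2] <= nchar(seq), interval[1] <= interval[2])
  pool <- setdiff(seq(interval[1], interval[2]), forbidden)
  if (k > length(pool)) {
    stop(sprintf("cannot plant %d mutations in %d available positions",
                 k, length(pool)), call. = FALSE)
  }
  if (k == 0L) return(seq)
  .with_seed(seed, {
    ch <- .chars(seq)
    at <- sample(pool, k)
    for (i in at) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    }
    paste(ch, collapse = "")
  })
}

# Plant exactly k primer mismatches in a site: each mutated position gets a
# base outside the primer's IUPAC set at that position (so the planted
# count equals the mismatch count reported by count_mismatches).
.plant_site_mm <- function(site, primer_seq, k) {
  if (k == 0L) return(site)
  n <- nchar(site)
  stopifnot(n == nchar(primer_seq), k <= n)
  ch <- .chars(site)
  pch <- .chars(primer_seq)
  at <- sample(n, k)
  for (i in at) {
    non_matching <- setdiff(c("A", "C", "G", "T"), .IUPAC_SETS[[pch[i]]])
    ch[i] <- sample(non_matching, 1L)
  }
  paste(ch, collapse = "")
}

# Build an r58S_len variant of the reference by indels in the neutral
# filler between the forward-primer site and CM2 (never touching the
# head/tail probes, the anchor site, or the conserved motifs).
.ref_58s_variant <- function(ref, len) {
  refL <- nchar(ref)
  if (len == refL) return(ref)
  delta <- len - refL
  at <- 45L  # inside the filler region downstream of the anchor site
  if (delta > 0L) {
    paste0(substr(ref, 1L, at), strrep("T", delta), substr(ref, at + 1L, refL))
  } else {
    if (refL + delta < 100L) stop("r58S_len too far from reference length")
    paste0(substr(ref, 1L, at), substr(ref, at - delta + 1L, refL))
  }
}

# Remove accidental copies of the 18S-end motif upstream of the 5.8S
# anchor: every occurrence before `before` other than the planted one is
# destroyed by flipping its middle base (always a spacer/tail position, so
# planted primer sites are never touched). Keeps the planted landmark the
# unique ground truth for annotation.
.scrub_motif <- function(seq, motif, keep_start, before) {
  repeat {
    occ <- gregexpr(motif, seq, fixed = TRUE)[[1L]]
    occ <- occ[occ > 0L & occ != keep_start & occ < before]
    if (length(occ) == 0L) return(seq)
    i <- occ[1L] + nchar(motif) %/% 2L
    old <- substr(seq, i, i)
    substr(seq, i, i) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
}

#' Generate one synthetic rDNA cassette with known ground truth
#'
#' Sequence layout: random 18S tail carrying the 29F annealing site and
#' ending in the CATTA motif; random ITS1; 5.8S copied from the reference
#' with `fwd_site_mm` mismatches planted in the forward-primer site; random
#' ITS2; 28S head *starting with* the reverse-primer annealing site (the
#' sense-strand reverse complement of 1082R, extended by two bases so the
#' longer whole-ITS reverse primer 1084R anneals at the same locus) with
#' `rev_site_mm` planted mismatches. Placing the reverse site at the very
#' start of 28S makes the generator's ITS2/28S boundary coincide with the
#' annotator's 28S-anchor convention. Regions upstream of the 5.8S anchor
#' are scrubbed of accidental CATTA copies so the planted landmark is the
#' unique ground truth. Fully reproducible from `spec$seed`.
#'
#' @param spec A [cassette_spec()].
#' @param id Record id.
#' @param is_target Target-clade flag stamped on the record.
#' @param fwd_primer,rev_primer Primers whose annealing sites are planted
#'   inside 5.8S and at the start of the 28S head (defaults: 606F and
#'   1082R).
#' @param ref_58s 5.8S template; default [ref_58s_synthetic()].
#' @param landmarks [landmark_set()] providing the 18S-end motif.
#' @return List with `record` ([seq_record()]), `annotation` (the true
#'   `its_annotation`), and `truth` (planted site coordinates and mismatch
#'   counts).
#' @export
make_cassette <- function(spec, id = sprintf("synth_%d", spec$seed),
                          is_target = TRUE,
                          fwd_primer = "GTCGATGAAGAGCGCAGCCA",
                          rev_primer = "TTAGTTTCTTTTCCTCCGCTT",
                          ref_58s = ref_58s_synthetic(),
                          landmarks = landmark_set()) {
  stopifnot(inherits(spec, "cassette_spec"))
  motif <- landmarks$motif_18s_end
  site29F <- "AAAGTCGTAACAAGGTTTCCGTA"  # forward site in the 18S tail
  # reverse site on the sense strand: the primer anneals as its reverse
  # complement; degenerate positions are fixed to a matching base
  rev_rc <- reverse_complement(rev_primer)
  rev_site <- paste(vapply(.chars(rev_rc), function(c) {
    .IUPAC_SETS[[c]][1L]
  }, character(1)), collapse = "")
  rev_ext <- "CA"  # continuation matching the two extra 5' bases of 1084R

  ref <- .ref_58s_variant(ref_58s, spec$r58S_len)
  fwd_at <- .best_site(fwd_primer, ref, max_mm = nchar(fwd_primer))
  if (spec$fwd_site_mm > nchar(fwd_primer) ||
      spec$rev_site_mm > nchar(rev_primer)) {
    stop("planted mismatch count exceeds primer length", call. = FALSE)
  }
  gap18 <- 4L
  min_tail <- nchar(site29F) + gap18 + nchar(motif)
  if (spec$tail18S_len < min_tail + 1L) {
    stop(sprintf("tail18S_len must exceed %d to hold the 29F site and the %s motif",
                 min_tail, motif), call. = FALSE)
  }
  min_head <- nchar(rev_site) + nchar(rev_ext)
  if (spec$head28S_len < min_head + 1L) {
    stop("head28S_len too short to hold the reverse-primer site", call. = FALSE)
  }

  .with_seed(spec$seed, {
    tail18S <- paste0(
      .rand_dna(spec$tail18S_len - min_tail, spec$gc),
      site29F, .rand_dna(gap18, spec$gc), motif)
    its1 <- .rand_dna(spec$ITS1_len, spec$gc)
    r58 <- ref
    substr(r58, fwd_at$start, fwd_at$end) <- .plant_site_mm(
      substr(r58, fwd_at$start, fwd_at$end), fwd_primer, spec$fwd_site_mm)
    its2 <- .rand_dna(spec$ITS2_len, spec$gc)
    planted_rev <- .plant_site_mm(rev_site, rev_rc, spec$rev_site_mm)
    head28S <- paste0(
      planted_rev, rev_ext,
      .rand_dna(spec$head28S_len - min_head, spec$gc))

    seqs <- c(tail18S, its1, r58, its2, head28S)
    offsets <- cumsum(c(0L, nchar(seqs)[-5L]))
    full <- paste(seqs, collapse = "")
    catta_start <- offsets[1L] + spec$tail18S_len - nchar(motif) + 1L
    full <- .scrub_motif(full, motif, catta_start,
                         before = offsets[3L] + fwd_at$start)

    bounds <- function(i) c(offsets[i] + 1L, offsets[i] + nchar(seqs[i]))
    parts <- list(tail18S = bounds(1L), ITS1 = bounds(2L), r58S = bounds(3L),
                  ITS2 = bounds(4L), head28S = bounds(5L))
    complete <- c(tail18S = FALSE, ITS1 = TRUE, r58S = TRUE, ITS2 = TRUE,
                  head28S = FALSE)
    record <- seq_record(id, full, is_target = is_target)
    truth <- list(
      fwd_site = offsets[3L] + c(fwd_at$start, fwd_at$end),
      fwd_mm = spec$fwd_site_mm,
      rev_site = offsets[5L] + c(1L, nchar(rev_site)),
      rev_mm = spec$rev_site_mm,
      site29F = offsets[1L] + spec$tail18S_len - min_tail + c(1L, nchar(site29F)),
      catta = c(catta_start, catta_start + nchar(motif) - 1L),
      spec = spec
    )
    list(record = record,
         annotation = .its_annotation(id, parts, as.list(complete)),
         truth = truth)
  })
}

#' Generate a panel of target and off-target cassettes
#'
#' Emulates a mixed reference database: target cassettes carry the primer
#' annealing sites with a configurable number of planted mismatches
#' (default 0-1 per primer); off-target cassettes carry at least 4
#' mismatches in the forward-primer site (so they drop out at any budget
#' up to 3) and randomized spacers. Spacer lengths are drawn uniformly
#' within the configured ranges. Fully reproducible from `seed`.
#'
#' @param n_target,n_offtarget Panel sizes (>= 0).
#' @param seed Integer master seed; per-cassette seeds are derived from it.
#' @param target_fwd_mm,target_rev_mm Integer vectors sampled from for each
#'   target cassette's planted per-primer mismatch counts.
#' @param offtarget_fwd_mm Vector (all >= 4) sampled from for off-target
#'   forward-site mismatches.
#' @param its1_range,its2_range Spacer length ranges in bp (defaults: the
#'   published clitellate ranges 314-1117 and 174-503).
#' @param gc GC fraction for random regions.
#' @param ... Further arguments passed to [make_cassette()].
#' @return List of `make_cassette()` results; record ids are
#'   `target_<i>` / `offtarget_<i>`.
#' @export
make_panel <- function(n_target, n_offtarget, seed = 1L,
                       target_fwd_mm = 0:1, target_rev_mm = 0:1,
                       offtarget_fwd_mm = 4:6,
                       its1_range = c(314L, 1117L), its2_range = c(174L, 503L),
                       gc = 0.59, ...) {
  stopifnot(n_target >= 0L, n_offtarget >= 0L, all(offtarget_fwd_mm >= 4L))
  n <- n_target + n_offtarget
  if (n == 0L) return(list())
  .with_seed(seed, {
    draws <- data.frame(
      seed = sample.int(.Machine$integer.max - 1L, n),
      its1 = sample(seq(its1_range[1], its1_range[2]), n, replace = TRUE),
      its2 = sample(seq(its2_range[1], its2_range[2]), n, replace = TRUE),
      fwd_mm = c(sample(rep(target_fwd_mm, 2L), max(n_target, 1L),
                        replace = TRUE)[seq_len(n_target)],
                 sample(rep(offtarget_fwd_mm, 2L), max(n_offtarget, 1L),
                        replace = TRUE)[seq_len(n_offtarget)]),
      rev_mm = sample(rep(target_rev_mm, 2L), n, replace = TRUE)
    )
    lapply(seq_len(n), function(i) {
      target <- i <= n_target
      make_cassette(
        cassette_spec(ITS1_len = draws$its1[i], ITS2_len = draws$its2[i],
                      gc = gc, fwd_site_mm = draws$fwd_mm[i],
                      rev_site_mm = draws$rev_mm[i], seed = draws$seed[i]),
        id = if (target) sprintf("target_%d", i)
             else sprintf("offtarget_%d", i - n_target),
        is_target = target, ...)
    })
  })
}

#' Generate a gap-free synthetic alignment panel
#'
#' For window-discovery and primer-design checks: `n` cassettes sharing
#' identical conserved blocks (18S tail, 5.8S, 28S head) and independently
#' randomized spacers of a common fixed length per panel, so the rows are
#' an alignment without an external aligner. Conserved blocks have column
#' identity 1; spacer columns scatter at random-base identity. Returns the
#' alignment plus the alignment-column coordinates of the planted primer
#' sites.
#'
#' @param n Number of rows (>= 2).
#' @param its1_len,its2_len Common spacer lengths for the panel.
#' @param seed Integer master seed.
#' @param gc GC fraction.
#' @return List with `alignment` (an [alignment()]) and `truth`
#'   (column ranges `fwd_site_cols`, `rev_site_cols`, `site29F_cols`).
#' @export
make_aligned_panel <- function(n = 12L, its1_len = 350L, its2_len = 300L,
                               seed = 1L, gc = 0.59) {
  stopifnot(n >= 2L)
  .with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    first <- make_cassette(cassette_spec(ITS1_len = its1_len,
                                         ITS2_len = its2_len, gc = gc,
                                         seed = seeds[1L]),
                           id = "row_1")
    p <- first$annotation$partitions
    sub <- function(iv) substr(first$record$sequence, iv[1], iv[2])
    rows <- vector("list", n)
    rows[[1L]] <- first$record
    for (i in seq(2L, n)) {
      rows[[i]] <- seq_record(
        sprintf("row_%d", i),
        paste0(sub(p$tail18S),
               .rand_dna(its1_len, gc),
               sub(p$r58S),
               .rand_dna(its2_len, gc),
               sub(p$head28S)),
        is_target = TRUE)
    }
    list(alignment = alignment(rows),
         truth = list(fwd_site_cols = first$truth$fwd_site,
                      rev_site_cols = first$truth$rev_site,
                      site29F_cols = first$truth$site29F,
                      partitions = p))
  })
}
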