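#' Synthetic 153-bp clitellate-style 5.8S reference
#'
#' A synthetic consensus used as the default 5.8S reference for annotation
#' and as the 5.8S template in the cassette generator. It is *not* a real
#' biological consensus (the deposited clitellate accessions are not shipped
#' with the package); it is constructed to have the hallmark features the
#' annotator relies on: 153 bp overall, GC close to 59%, the full 606F
#' annealing site at positions 16-35, and the three conserved 5.8S motifs
#' (see [cm_motifs()]) in cassette order.
#'
#' @return A 153-character DNA string.
#' @export
ref_58s_synthetic <- function() {
  paste0(
    "CGACTCAGTCCGTCA", "GTCGATGAAGAGCGCAGCCA",
    "ACGAGTGGGTGTCTTCACTCTGTGTCTCGCCTGGA", "GAATTGCAGAATTC",
    "TGAGCGTCCGGCCGTCTTCTGGGTGGACGCATGGGG", "TTTGAACGCA",
    "GCCACTGCACTGCCCCCTCTCGA"
  )
}

#' Conserved 5.8S motifs used for pseudogene screening
#'
#' Operational stand-ins for the three eukaryote 5.8S conservative motifs
#' (CM1-CM3): CM1 is the core of the clitellate-specific forward primer
#' 606F (which was designed to sit fully inside that motif), CM2 the
#' vertebrate-shared motif, CM3 a generic eukaryote 5.8S motif. A 5.8S copy
#' missing any of them under the mismatch budget is flagged as suspect
#' (pseudogene-like).
#'
#' @return Named character vector `c(CM1=, CM2=, CM3=)`.
#' @export
cm_motifs <- function() {
  c(CM1 = "TCGATGAAGAGCGCAGC",
    CM2 = "GAATTGCAGAATTC",
    CM3 = "TTTGAACGCA")
}

#' Landmark set for cassette annotation
#'
#' The annotator is anchored on three conserved elements of the rDNA
#' cassette: the pentamer marking the 3' end of 18S (ITS1 starts right
#' after it), an anchor inside 5.8S (by default the 606F annealing site),
#' and an anchor at the 5' end of 28S (by default the reverse complement
#' of the 1082R primer, i.e. its annealing site read on the sense strand).
#'
#' @param motif_18s_end 18S-terminal motif (default `"CATTA"`). Matched
#'   exactly: a pentamer is too short for mismatch-tolerant search.
#' @param anchor_58s IUPAC anchor inside 5.8S.
#' @param anchor_28s IUPAC anchor at the start of 28S (sense strand).
#' @param max_anchor_mismatches Mismatch budget for the two long anchors.
#' @return Object of class `landmark_set`.
#' @export
landmark_set <- function(motif_18s_end = "CATTA",
                         anchor_58s = "GTCGATGAAGAGCGCAGCCA",
                         anchor_28s = reverse_complement("TTAGTTTCTTTTCCTCCGCTT"),
                         max_anchor_mismatches = 2L) {
  stopifnot(nzchar(motif_18s_end), nzchar(anchor_58s), nzchar(anchor_28s),
            max_anchor_mismatches >= 0L)
  structure(list(motif_18s_end = toupper(motif_18s_end),
                 anchor_58s = toupper(anchor_58s),
                 anchor_28s = toupper(anchor_28s),
                 max_anchor_mismatches = as.integer(max_anchor_mismatches)),
            class = "landmark_set")
}

# Best placement of `probe` in `seq` restricted to [from, to] (template
# start positions): fewest mismatches, then leftmost. Returns
# list(start, end, mismatches) or NULL if nothing within budget.
.best_site <- function(probe, seq, max_mm, from = 1L, to = NA_integer_) {
  mm <- .mismatch_profile(probe, seq)
  if (length(mm) == 0L) return(NULL)
  if (is.na(to)) to <- length(mm)
  from <- max(1L, from); to <- min(length(mm), to)
  if (from > to) return(NULL)
  window <- mm[from:to]
  best <- min(window)
  if (best > max_mm) return(NULL)
  start <- from + which.max(window == best) - 1L
  list(start = start, end = start + nchar(probe) - 1L, mismatches = best)
}

#' Locate cassette landmarks in an unaligned sequence
#'
#' For each landmark the best occurrence (fewest mismatches, then leftmost)
#' within its budget is reported; absence is a valid result. Occurrences
#' must appear in cassette order (18S motif < 5.8S anchor < 28S anchor);
#' when several copies of the 18S-end motif exist, the one closest upstream
#' of the 5.8S anchor is chosen, and a landmark that conflicts with the
#' cassette order is dropped.
#'
#' @param record A [seq_record()] (unaligned).
#' @param landmarks A [landmark_set()].
#' @return `data.frame` with columns `landmark`, `start`, `end`,
#'   `mismatches` (1-based inclusive coordinates); zero rows when nothing
#'   is found.
#' @export
find_landmarks <- function(record, landmarks = landmark_set()) {
  stopifnot(inherits(record, "seq_record"), inherits(landmarks, "landmark_set"))
  seq <- record$sequence
  budget <- landmarks$max_anchor_mismatches
  out <- list()

  s58 <- .best_site(landmarks$anchor_58s, seq, budget)
  if (!is.null(s58)) out$anchor_58s <- s58

  # 18S-end motif: exact occurrences; pick the one closest upstream of the
  # 5.8S anchor (the motif is only meaningful as the 18S terminus).
  occ <- gregexpr(landmarks$motif_18s_end, seq, fixed = TRUE)[[1L]]
  occ <- occ[occ > 0L]
  if (length(occ) > 0L) {
    if (!is.null(s58)) occ <- occ[occ + nchar(landmarks$motif_18s_end) - 1L < s58$start]
    if (length(occ) > 0L) {
      start <- if (is.null(s58)) occ[1L] else max(occ)
      out$motif_18s_end <- list(start = start,
                                end = start + nchar(landmarks$motif_18s_end) - 1L,
                                mismatches = 0L)
    }
  }

  # 28S anchor: restricted downstream of the 5.8S anchor when present.
  from <- if (is.null(s58)) 1L else s58$end + 1L
  s28 <- .best_site(landmarks$anchor_28s, seq, budget, from = from)
  if (!is.null(s28)) out$anchor_28s <- s28

  if (length(out) == 0L) {
    return(data.frame(landmark = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  ord <- c("motif_18s_end", "anchor_58s", "anchor_28s")
  keep <- ord[ord %in% names(out)]
  data.frame(landmark = keep,
             start = unname(vapply(out[keep], `[[`, integer(1), "start")),
             end = unname(vapply(out[keep], `[[`, integer(1), "end")),
             mismatches = unname(vapply(out[keep], `[[`, integer(1), "mismatches")),
             row.names = NULL, stringsAsFactors = FALSE)
}

.PARTITIONS <- c("tail18S", "ITS1", "r58S", "ITS2", "head28S")

# Internal constructor for the annotation object.
.its_annotation <- function(seq_id, partitions, complete, warnings = character(0)) {
  structure(list(seq_id = seq_id, partitions = partitions,
                 complete = complete, warnings = warnings),
            class = "its_annotation")
}

#' Partition an rDNA cassette into its five regions
#'
#' Uses [find_landmarks()] to anchor the conserved elements, then places
#' the 5.8S gene by matching the head and tail of a 5.8S reference around
#' the seeded anchor (so 5.8S length may deviate by small indels from the
#' reference length). ITS1 spans from the end of the 18S-terminal motif to
#' the base before 5.8S; ITS2 from the base after 5.8S to the base before
#' the 28S anchor. Partitions whose outer boundary landmark is missing are
#' marked incomplete and reported with the `">"` length convention by
#' [partition_lengths()]; if no landmark at all is found, all partitions
#' are absent and a warning is recorded.
#'
#' @param record A [seq_record()].
#' @param landmarks A [landmark_set()].
#' @param ref_58s 5.8S reference sequence; default [ref_58s_synthetic()].
#' @param slack Half-width (bp) of the search window for the reference head
#'   and tail probes around their seeded positions; tolerates small indels.
#' @return Object of class `its_annotation`: per-partition intervals
#'   (1-based inclusive, `NULL` when absent) and completeness flags.
#' @export
annotate_its <- function(record, landmarks = landmark_set(),
                         ref_58s = ref_58s_synthetic(), slack = 8L) {
  stopifnot(inherits(record, "seq_record"))
  n <- nchar(record$sequence)
  lm <- find_landmarks(record, landmarks)
  parts <- stats::setNames(vector("list", length(.PARTITIONS)), .PARTITIONS)
  complete <- stats::setNames(rep(FALSE, length(.PARTITIONS)), .PARTITIONS)
  warns <- character(0)

  if (nrow(lm) == 0L) {
    warns <- sprintf("%s: no landmark found; all partitions absent", record$id)
    warning(warns, call. = FALSE)
    return(.its_annotation(record$id, parts, complete, warns))
  }
  site <- function(name) {
    i <- match(name, lm$landmark)
    if (is.na(i)) NULL else list(start = lm$start[i], end = lm$end[i])
  }
  catta <- site("motif_18s_end")
  s58 <- site("anchor_58s")
  s28 <- site("anchor_28s")

  r58 <- NULL
  if (!is.null(s58)) {
    r58 <- .place_58s(record$sequence, s58, landmarks, ref_58s, slack)
  }

  if (!is.null(catta)) {
    parts$tail18S <- c(1L, catta$end)  # 5' boundary unknown: partial by nature
  }
  if (!is.null(r58)) {
    its1_start <- if (!is.null(catta)) catta$end + 1L else 1L
    if (r58$start > its1_start) {
      parts$ITS1 <- c(its1_start, r58$start - 1L)
      complete["ITS1"] <- !is.null(catta)
    }
    parts$r58S <- c(r58$start, r58$end)
    complete["r58S"] <- r58$complete
    its2_end <- if (!is.null(s28)) s28$start - 1L else n
    if (its2_end >= r58$end + 1L) {
      parts$ITS2 <- c(r58$end + 1L, its2_end)
      complete["ITS2"] <- !is.null(s28)
    }
  }
  if (!is.null(s28)) {
    parts$head28S <- c(s28$start, n)  # 3' boundary unknown: partial by nature
  }
  .its_annotation(record$id, parts, complete, warns)
}

# Place the 5.8S gene: the anchor's offset inside the reference seeds the
# expected start/end; the reference head and tail (20-mers) are then
# re-matched within +/- slack to absorb small indels. Ties leftmost.
.place_58s <- function(seq, anchor, landmarks, ref_58s, slack) {
  n <- nchar(seq)
  refL <- nchar(ref_58s)
  probe_len <- min(20L, refL)
  off <- .best_site(landmarks$anchor_58s, ref_58s,
                    max_mm = nchar(landmarks$anchor_58s))  # always places
  exp_start <- anchor$start - (off$start - 1L)
  exp_end <- exp_start + refL - 1L

  head_probe <- substr(ref_58s, 1L, probe_len)
  tail_probe <- substr(ref_58s, refL - probe_len + 1L, refL)
  budget <- max(2L, landmarks$max_anchor_mismatches)

  h <- .best_site(head_probe, seq, budget,
                  from = exp_start - slack, to = exp_start + slack)
  t <- .best_site(tail_probe, seq, budget,
                  from = exp_end - probe_len + 1L - slack,
                  to = exp_end - probe_len + 1L + slack)
  start <- if (!is.null(h)) h$start else max(1L, exp_start)
  end <- if (!is.null(t)) t$end else min(n, exp_end)
  if (end <= start) return(NULL)
  list(start = start, end = end,
       complete = !is.null(h) && !is.null(t) &&
         exp_start >= 1L && exp_end <= n)
}

#' @export
print.its_annotation <- function(x, ...) {
  cat(sprintf("<its_annotation> %s\n", x$seq_id))
  for (p in .PARTITIONS) {
    iv <- x$partitions[[p]]
    if (is.null(iv)) {
      cat(sprintf("  %-8s -\n", p))
    } else {
      cat(sprintf("  %-8s %d-%d (%d bp%s)\n", p, iv[1], iv[2],
                  iv[2] - iv[1] + 1L,
                  if (x$complete[[p]]) "" else ", incomplete"))
    }
  }
  invisible(x)
}

#' Length of an annotated partition
#'
#' @param ann An `its_annotation`.
#' @param part One of `"tail18S"`, `"ITS1"`, `"r58S"`, `"ITS2"`, `"head28S"`.
#' @return Integer length in bp, or `NA` when the partition is absent.
#' @export
partition_length <- function(ann, part) {
  stopifnot(inherits(ann, "its_annotation"), part %in% .PARTITIONS)
  iv <- ann$partitions[[part]]
  if (is.null(iv)) NA_integer_ else iv[2] - iv[1] + 1L
}

#' Spacer/5.8S length table with the reporting conventions
#'
#' One row per annotation with the ITS1, 5.8S and ITS2 lengths as text:
#' complete partitions print bare integers, incomplete ones print
#' `">"` followed by the observed length, absent ones print `"-"` --
#' mirroring the conventions of published specimen tables.
#'
#' @param anns An `its_annotation` or a list of them.
#' @return `data.frame` with columns `seq_id`, `its1_bp`, `r58s_bp`,
#'   `its2_bp` (all character).
#' @export
partition_lengths <- function(anns) {
  if (inherits(anns, "its_annotation")) anns <- list(anns)
  fmt <- function(ann, part) {
    len <- partition_length(ann, part)
    if (is.na(len)) return("-")
    if (ann$complete[[part]]) as.character(len) else paste0(">", len)
  }
  data.frame(
    seq_id = vapply(anns, function(a) a$seq_id, character(1)),
    its1_bp = vapply(anns, fmt, character(1), "ITS1"),
    r58s_bp = vapply(anns, fmt, character(1), "r58S"),
    its2_bp = vapply(anns, fmt, character(1), "ITS2"),
    stringsAsFactors = FALSE
  )
}

#' Screen an annotated 5.8S for pseudogene-like irregularities
#'
#' A complete 5.8S is `"ok"` when its length is within 153 +/- 1 nt (the
#' typical clitellate 5.8S length) *and* all configured conserved motifs
#' occur inside it under the mismatch budget. Otherwise the specific
#' failure code is returned. Requires a complete 5.8S annotation.
#'
#' @param ann An `its_annotation` with a complete 5.8S.
#' @param record The corresponding [seq_record()].
#' @param motifs Named vector of conserved motifs; default [cm_motifs()].
#' @param expected_len Typical 5.8S length (153).
#' @param len_tol Tolerated deviation (1).
#' @param max_mm Mismatch budget for motif occurrence (1).
#' @return One of `"ok"`, `"length_atypical"`, `"motif_missing"`.
#' @export
validate_58s <- function(ann, record, motifs = cm_motifs(),
                         expected_len = 153L, len_tol = 1L, max_mm = 1L) {
  stopifnot(inherits(ann, "its_annotation"), inherits(record, "seq_record"))
  iv <- ann$partitions$r58S
  if (is.null(iv) || !isTRUE(ann$complete[["r58S"]])) {
    stop("validate_58s requires a complete 5.8S annotation", call. = FALSE)
  }
  len <- iv[2] - iv[1] + 1L
  if (abs(len - expected_len) > len_tol) return("length_atypical")
  sub <- substr(record$sequence, iv[1], iv[2])
  for (m in motifs) {
    if (is.null(.best_site(m, sub, max_mm))) return("motif_missing")
  }
  "ok"
}
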