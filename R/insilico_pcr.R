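#' Count primer/template mismatches over an annealing window
#'
#' Position-wise IUPAC set-intersection matching between a primer and a
#' template window of the same length. A mismatch is a mismatch regardless
#' of its position (no 3'-terminal weighting at matching time; the 3'
#' effect belongs to design-time scoring).
#'
#' @param primer A [primer()] or IUPAC string.
#' @param window Template window, same length as the primer.
#' @return List with `count` and `positions` (primer-relative 1-based
#'   indices of the mismatching positions).
#' @export
count_mismatches <- function(primer, window) {
  pseq <- if (inherits(primer, "primer")) primer$seq else toupper(primer)
  window <- toupper(window)
  if (nchar(window) != nchar(pseq)) {
    stop("window length must equal primer length", call. = FALSE)
  }
  pch <- .chars(pseq)
  wch <- .chars(window)
  ok <- vapply(seq_along(pch), function(i) {
    a <- match(pch[i], rownames(.IUPAC_MATCH))
    b <- match(wch[i], rownames(.IUPAC_MATCH))
    if (is.na(a) || is.na(b)) FALSE else .IUPAC_MATCH[a, b]
  }, logical(1))
  list(count = sum(!ok), positions = which(!ok))
}

#' Scan a template for primer annealing sites
#'
#' Reports every window on both strands with at most `max_mm` mismatches
#' under IUPAC set-intersection matching; overlapping hits are all
#' reported. A `+` strand hit is the primer matched left-to-right on the
#' given sequence; a `-` strand hit is the primer matched on the reverse
#' complement, reported in coordinates of the given strand.
#'
#' @param primer A [primer()] object.
#' @param template A [seq_record()].
#' @param max_mm Mismatch budget (>= 0).
#' @return `data.frame` with columns `template_id`, `strand`, `start`,
#'   `end`, `mismatches` (1-based inclusive template coordinates;
#'   `end - start + 1` equals the primer length).
#' @export
scan_primer <- function(primer, template, max_mm = 3L) {
  stopifnot(inherits(primer, "primer"), inherits(template, "seq_record"),
            max_mm >= 0L)
  seq <- template$sequence
  k <- nchar(primer$seq)
  plus <- .mismatch_profile(primer$seq, seq)
  minus <- .mismatch_profile(reverse_complement(primer$seq), seq)
  ip <- which(plus <= max_mm)
  im <- which(minus <= max_mm)
  data.frame(
    template_id = rep(template$id, length(ip) + length(im)),
    strand = c(rep("+", length(ip)), rep("-", length(im))),
    start = c(ip, im),
    end = c(ip, im) + k - 1L,
    mismatches = c(plus[ip], minus[im]),
    stringsAsFactors = FALSE
  )
}

# e-class of an amplicon: indexed by the maximum per-primer mismatch count.
.e_class <- function(fwd_mm, rev_mm) paste0("e", pmax(fwd_mm, rev_mm))

#' In silico PCR of one primer pair against one template
#'
#' ecoPCR-style simulation: every forward-primer site is combined with
#' every downstream reverse-primer site (the reverse primer matched as its
#' reverse complement on the same strand), and an amplicon is emitted iff
#' the primer-inclusive product length falls within the pair's
#' `[min_len, max_len]` window. Both template orientations are scanned, so
#' amplifying the reverse complement of a template yields the mirror-image
#' amplicon set. All qualifying combinations are emitted, including nested
#' and overlapping products; see [run_database()] for the collapsed
#' best-per-template view used in per-sequence counts.
#'
#' The e-class of an amplicon is `e<k>` with
#' `k = max(fwd_mm, rev_mm)`.
#'
#' @param pair A [primer_pair()] (carries the length window).
#' @param template A [seq_record()].
#' @param max_mm Per-primer mismatch budget (default 3, realistic PCR
#'   tolerance).
#' @return Amplicon hit `data.frame`: `template_id`, `pair_name`, `strand`,
#'   `start`, `end` (primer-inclusive, coordinates on the given sequence),
#'   `insert_start`, `insert_end` (between the primers), `length`,
#'   `fwd_mm`, `rev_mm`, `e_class`, `seq`.
#' @export
amplify <- function(pair, template, max_mm = 3L) {
  stopifnot(inherits(pair, "primer_pair"), inherits(template, "seq_record"))
  n <- nchar(template$sequence)
  fwd_len <- nchar(pair$fwd$seq)
  rev_len <- nchar(pair$rev$seq)

  one_strand <- function(seq, strand) {
    f_mm <- .mismatch_profile(pair$fwd$seq, seq)
    r_mm <- .mismatch_profile(reverse_complement(pair$rev$seq), seq)
    fi <- which(f_mm <= max_mm)
    ri <- which(r_mm <= max_mm)
    if (length(fi) == 0L || length(ri) == 0L) return(.empty_hits())
    grid <- expand.grid(f = fi, r = ri, KEEP.OUT.ATTRS = FALSE)
    prod_start <- grid$f
    prod_end <- grid$r + rev_len - 1L
    len <- prod_end - prod_start + 1L
    keep <- grid$r >= grid$f + fwd_len &   # reverse site fully downstream
      len >= pair$min_len & len <= pair$max_len
    if (!any(keep)) return(.empty_hits())
    grid <- grid[keep, , drop = FALSE]
    prod_start <- prod_start[keep]; prod_end <- prod_end[keep]; len <- len[keep]
    if (strand == "+") {
      start <- prod_start; end <- prod_end
    } else {
      start <- n - prod_end + 1L; end <- n - prod_start + 1L
    }
    data.frame(
      template_id = template$id, pair_name = pair$name, strand = strand,
      start = start, end = end,
      insert_start = if (strand == "+") prod_start + fwd_len else
        n - (prod_end - rev_len) + 1L,
      insert_end = if (strand == "+") prod_end - rev_len else
        n - (prod_start + fwd_len) + 1L,
      length = len,
      fwd_mm = f_mm[grid$f], rev_mm = r_mm[grid$r],
      e_class = .e_class(f_mm[grid$f], r_mm[grid$r]),
      seq = substr(rep(seq, nrow(grid)), prod_start, prod_end),
      stringsAsFactors = FALSE
    )
  }

  hits <- rbind(one_strand(template$sequence, "+"),
                one_strand(reverse_complement(template$sequence), "-"))
  hits <- hits[order(hits$start, hits$end, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Run primer pairs against a sequence database
#'
#' Concatenated [amplify()] results over all pairs and records, in
#' deterministic order (pair, then template input order, then
#' coordinates). Duplicate records yield duplicate hits: no
#' deduplication is performed.
#'
#' @param pairs A [primer_pair()] or list of them.
#' @param db List of [seq_record()] objects (carrying `is_target` labels).
#' @param max_mm Per-primer mismatch budget.
#' @param best_per_template Collapse to each template's single best hit per
#'   pair (lowest e-class, then longest product, then leftmost) -- the
#'   per-sequence counting view used by specificity tables.
#' @return Amplicon hit `data.frame` (see [amplify()]).
#' @export
run_database <- function(pairs, db, max_mm = 3L, best_per_template = FALSE) {
  if (inherits(pairs, "primer_pair")) pairs <- list(pairs)
  out <- list()
  for (pair in pairs) {
    for (i in seq_along(db)) {
      h <- amplify(pair, db[[i]], max_mm = max_mm)
      if (nrow(h) > 0L) {
        h$.tpl_order <- i
        out[[length(out) + 1L]] <- h
      }
    }
  }
  if (length(out) == 0L) return(.empty_hits())
  hits <- do.call(rbind, out)
  if (best_per_template) {
    hits <- do.call(rbind, lapply(
      split(hits, list(hits$pair_name, hits$template_id, hits$.tpl_order),
            drop = TRUE),
      .best_hit))
  }
  hits <- hits[order(match(hits$pair_name,
                           vapply(pairs, function(p) p$name, character(1))),
                     hits$.tpl_order, hits$start, hits$end), , drop = FALSE]
  hits$.tpl_order <- NULL
  rownames(hits) <- NULL
  hits
}

# Best single hit among one template's amplicons: lowest max-mismatch
# class, then longest product, then leftmost, then + strand.
.best_hit <- function(hits) {
  e <- pmax(hits$fwd_mm, hits$rev_mm)
  ord <- order(e, -hits$length, hits$start, hits$strand)
  hits[ord[1L], , drop = FALSE]
}
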