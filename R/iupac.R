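#' @importFrom Biostrings IUPAC_CODE_MAP
NULL

# Full working alphabet: 15 IUPAC nucleotide codes plus the alignment gap.
.IUPAC_CHARS <- c(names(Biostrings::IUPAC_CODE_MAP), "-")

# Named list mapping each IUPAC code to its set of unambiguous bases.
.IUPAC_SETS <- strsplit(Biostrings::IUPAC_CODE_MAP, "", fixed = TRUE)

# 15 x 15 logical matrix: do the base sets of two IUPAC codes intersect?
.IUPAC_MATCH <- local({
  codes <- names(.IUPAC_SETS)
  m <- matrix(FALSE, length(codes), length(codes), dimnames = list(codes, codes))
  for (a in codes) for (b in codes) {
    m[a, b] <- length(intersect(.IUPAC_SETS[[a]], .IUPAC_SETS[[b]])) > 0L
  }
  m
})

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N", `-` = "-"
)

# Split an upper-case DNA string into a character vector of single symbols.
.chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

.validate_alphabet <- function(seq, allow_gap = FALSE, what = "sequence") {
  legal <- if (allow_gap) .IUPAC_CHARS else setdiff(.IUPAC_CHARS, "-")
  bad <- setdiff(unique(.chars(seq)), legal)
  if (length(bad) > 0L) {
    stop(sprintf("illegal character(s) in %s: %s", what,
                 paste(shQuote(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(seq)
}

#' Reverse complement of an IUPAC DNA sequence
#'
#' IUPAC-aware: ambiguity codes map to the complement of their base set
#' (Y to R, K to M, B to V, ...); `N` and the gap character are fixed points.
#'
#' @param seq Upper-case IUPAC DNA string (gaps allowed).
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("ACGT")  # "ACGT"
#' reverse_complement("YGT")   # "ACR"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(seq)
  ch <- .chars(toupper(seq))
  comp <- .IUPAC_COMPLEMENT[ch]
  if (anyNA(comp)) {
    stop("illegal character(s) in sequence: ",
         paste(shQuote(unique(ch[is.na(comp)])), collapse = ", "), call. = FALSE)
  }
  paste(rev(comp), collapse = "")
}

#' Do two IUPAC codes match?
#'
#' Two symbols match when their unambiguous base sets intersect: `Y` matches
#' `C`, `N` matches anything, `A` does not match `G`. Symmetric in its
#' arguments; template ambiguity codes therefore participate in matching on
#' the same footing as primer codes.
#'
#' @param a,b Single upper-case IUPAC codes (no gaps).
#' @return Logical.
#' @export
base_match <- function(a, b) {
  if (!a %in% rownames(.IUPAC_MATCH) || !b %in% rownames(.IUPAC_MATCH)) {
    stop("illegal IUPAC code", call. = FALSE)
  }
  .IUPAC_MATCH[a, b]
}

#' Degeneracy of an IUPAC oligo
#'
#' Product over positions of the IUPAC base-set sizes; 1 for a fully
#' unambiguous oligo. Multiplicative under concatenation.
#'
#' @param seq IUPAC DNA string, or a [primer()] object.
#' @return Integer count of unambiguous sequence variants.
#' @examples
#' degeneracy("ACGT")  # 1
#' degeneracy("NY")    # 8
#' @export
degeneracy <- function(seq) {
  if (inherits(seq, "primer")) seq <- seq$seq
  .validate_alphabet(seq, allow_gap = FALSE)
  if (nchar(seq) == 0L) return(1L)
  d <- prod(lengths(.IUPAC_SETS[.chars(seq)]))
  if (d <= .Machine$integer.max) as.integer(d) else d
}

#' Expand a degenerate oligo into all unambiguous variants
#'
#' @param seq IUPAC DNA string.
#' @param max_variants Guard against combinatorial blow-up.
#' @return Character vector of plain ACGT sequences.
#' @export
expand_degenerate <- function(seq, max_variants = 1024L) {
  .validate_alphabet(seq, allow_gap = FALSE)
  d <- degeneracy(seq)
  if (d > max_variants) {
    stop(sprintf("degeneracy %d exceeds max_variants = %d", d, max_variants),
         call. = FALSE)
  }
  sets <- .IUPAC_SETS[.chars(seq)]
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}

#' GC fraction of a sequence
#'
#' Computed over unambiguous bases only: IUPAC ambiguity codes and gaps are
#' excluded from both numerator and denominator, so the value is
#' deterministic on degenerate input.
#'
#' @param seq IUPAC DNA string.
#' @return Fraction in `[0, 1]`; `NaN` for a sequence with no unambiguous base.
#' @export
gc_fraction <- function(seq) {
  ch <- .chars(toupper(seq))
  plain <- ch[ch %in% c("A", "C", "G", "T")]
  if (length(plain) == 0L) return(NaN)
  sum(plain %in% c("G", "C")) / length(plain)
}

# Vectorized sliding mismatch profile.
# Returns an integer vector m of length n - k + 1 where m[i] is the number
# of primer positions whose IUPAC set does not intersect the template's at
# window starting position i (1-based). Gap characters in the template never
# match. O(k * n) vector operations.
.mismatch_profile <- function(primer_seq, template_seq) {
  k <- nchar(primer_seq)
  n <- nchar(template_seq)
  if (n < k) return(integer(0))
  pch <- .chars(primer_seq)
  tch <- .chars(template_seq)
  tidx <- match(tch, rownames(.IUPAC_MATCH))  # NA for gaps / illegal
  nwin <- n - k + 1L
  mm <- integer(nwin)
  offs <- seq_len(nwin)
  for (j in seq_len(k)) {
    row <- unname(.IUPAC_MATCH[pch[j], ])
    ok <- row[tidx[offs + j - 1L]]
    ok[is.na(ok)] <- FALSE
    mm <- mm + !ok
  }
  mm
}
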