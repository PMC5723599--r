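#' Construct an alignment object
#'
#' A multiple sequence alignment as a list of equal-length gapped
#' [seq_record()]s plus a character matrix view used by the column
#' operations.
#'
#' @param records List of aligned [seq_record()]s (>= 2 rows, equal
#'   lengths, `-` allowed).
#' @return Object of class `alignment` with fields `records`, `matrix`
#'   (rows x columns), `length` (columns).
#' @export
alignment <- function(records) {
  stopifnot(is.list(records), length(records) >= 2L)
  lens <- vapply(records, function(r) nchar(r$sequence), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("alignment rows must all have the same length", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(records, function(r) .chars(r$sequence)))
  rownames(mat) <- vapply(records, function(r) r$id, character(1))
  structure(list(records = records, matrix = mat, length = lens[1L]),
            class = "alignment")
}

#' Read an aligned FASTA file into an [alignment()]
#'
#' @param path Aligned-FASTA file.
#' @inheritParams read_fasta
#' @return An `alignment`.
#' @export
read_alignment <- function(path, is_target = NA) {
  alignment(read_fasta(path, aligned = TRUE, is_target = is_target))
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d rows x %d columns\n", nrow(x$matrix), x$length))
  invisible(x)
}

#' Identity of one alignment column
#'
#' Frequency of the modal non-gap base among non-gap rows; a column of
#' gaps only has identity 0.
#'
#' @param aln An [alignment()].
#' @param col Column index (1-based).
#' @return Fraction in `[0, 1]`.
#' @export
column_identity <- function(aln, col) {
  stopifnot(inherits(aln, "alignment"), col >= 1L, col <= aln$length)
  bases <- aln$matrix[, col]
  bases <- bases[bases != "-"]
  if (length(bases) == 0L) return(0)
  max(table(bases)) / length(bases)
}

# Vectorized identity and gap-fraction over all columns.
.column_stats <- function(aln) {
  mat <- aln$matrix
  nr <- nrow(mat)
  gapfrac <- colMeans(mat == "-")
  ident <- vapply(seq_len(ncol(mat)), function(j) {
    b <- mat[, j]; b <- b[b != "-"]
    if (length(b) == 0L) 0 else max(tabulate(factor(b, levels = .IUPAC_CHARS))) / length(b)
  }, numeric(1))
  list(identity = ident, gap_fraction = gapfrac)
}

#' Find maximal conserved windows in an alignment
#'
#' Maximal runs of at least `min_len` consecutive columns whose identity is
#' at least `min_identity` and whose gap fraction does not exceed
#' `max_gap_fraction`; windows are disjoint, non-extendable, and sorted by
#' start. Each window carries the IUPAC consensus of its columns and its
#' minimum column identity.
#'
#' @param aln An [alignment()].
#' @param min_len Minimum window length in columns (default 15, i.e. the
#'   smallest integer run longer than 14 nt).
#' @param min_identity Minimum per-column identity (default 0.90).
#' @param max_gap_fraction Per-column gap cap (default 0.10).
#' @return `data.frame` with columns `start`, `end`, `length`,
#'   `consensus`, `min_column_identity`.
#' @export
find_conserved_windows <- function(aln, min_len = 15L, min_identity = 0.90,
                                   max_gap_fraction = 0.10) {
  stopifnot(inherits(aln, "alignment"))
  st <- .column_stats(aln)
  ok <- st$identity >= min_identity & st$gap_fraction <= max_gap_fraction
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) {
    return(data.frame(start = integer(0), end = integer(0), length = integer(0),
                      consensus = character(0), min_column_identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(
    start = starts, end = ends, length = ends - starts + 1L,
    consensus = vapply(seq_along(starts), function(i) {
      .consensus_cols(aln, starts[i]:ends[i], mode = "iupac", threshold = 0)
    }, character(1)),
    min_column_identity = vapply(seq_along(starts), function(i) {
      min(st$identity[starts[i]:ends[i]])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}

# Consensus over a set of columns. majority: modal non-gap base.
# iupac: smallest IUPAC code covering all bases with frequency >= (1 - threshold)
# relative to non-gap rows. Gap-majority columns are dropped.
.consensus_cols <- function(aln, cols, mode, threshold) {
  mat <- aln$matrix
  out <- character(0)
  for (j in cols) {
    b <- mat[, j]
    if (mean(b == "-") > 0.5) next
    b <- b[b != "-"]
    tab <- table(b) / length(b)
    if (mode == "majority") {
      out <- c(out, names(tab)[which.max(tab)])
    } else {
      keep <- names(tab)[tab >= (1 - threshold)]
      if (length(keep) == 0L) keep <- names(tab)[which.max(tab)]
      # union of base sets of the retained (possibly ambiguous) codes
      bases <- sort(unique(unlist(.IUPAC_SETS[keep])))
      code <- names(.IUPAC_SETS)[vapply(.IUPAC_SETS, function(s) {
        setequal(s, bases)
      }, logical(1))]
      out <- c(out, code)
    }
  }
  paste(out, collapse = "")
}

#' Consensus sequence of an alignment
#'
#' @param aln An [alignment()].
#' @param mode `"majority"` (modal base per column) or `"iupac"` (smallest
#'   ambiguity code covering every base whose column frequency is at least
#'   `1 - threshold`).
#' @param threshold Frequency tolerance for the `"iupac"` mode: bases rarer
#'   than `1 - threshold`... i.e. with frequency `< (1 - threshold)` are
#'   ignored. `threshold = 0.5` keeps bases at frequency >= 0.5;
#'   `threshold = 1` keeps all observed bases.
#' @return IUPAC consensus string (gap-majority columns dropped).
#' @export
consensus <- function(aln, mode = c("majority", "iupac"), threshold = 0.5) {
  mode <- match.arg(mode)
  .consensus_cols(aln, seq_len(aln$length), mode, threshold)
}

# --- melting temperature ------------------------------------------------

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K), 5'->3' stacks on the top strand.
.NN_DH <- c(AA = -7.9, AT = -7.2, AC = -8.4, AG = -7.8,
            TA = -7.2, TT = -7.9, TC = -8.2, TG = -8.5,
            CA = -8.5, CT = -7.8, CC = -8.0, CG = -10.6,
            GA = -8.2, GT = -8.4, GC = -9.8, GG = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, AC = -22.4, AG = -21.0,
            TA = -21.3, TT = -22.2, TC = -22.2, TG = -22.7,
            CA = -22.7, CT = -21.0, CC = -19.9, CG = -27.2,
            GA = -22.2, GT = -22.4, GC = -24.4, GG = -19.9)

.tm_wallace_one <- function(seq) {
  ch <- .chars(seq)
  2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
}

.tm_nn_one <- function(seq, na_molar, oligo_molar) {
  ch <- .chars(seq)
  n <- length(ch)
  stacks <- paste0(ch[-n], ch[-1L])
  dH <- sum(.NN_DH[stacks])
  dS <- sum(.NN_DS[stacks])
  for (term in ch[c(1L, n)]) {  # terminal initiation corrections
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else                       { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (n - 1L) * log(na_molar)  # salt correction
  dH * 1000 / (dS + 1.987 * log(oligo_molar / 4)) - 273.15
}

#' Primer melting temperature
#'
#' Two estimators: the Wallace rule `2(A+T) + 4(G+C)` and a
#' nearest-neighbor model (SantaLucia 1998 unified parameters with the
#' entropic salt correction; documented defaults 0.5 mol/L monovalent
#' cation and 50 nmol/L oligo). For a degenerate primer the worst-case
#' (lowest-Tm) unambiguous expansion is reported, since the weakest variant
#' limits annealing.
#'
#' @param p A [primer()] or IUPAC string, length >= 8.
#' @param method `"wallace"` or `"nn"`.
#' @param na_molar Monovalent cation concentration (mol/L), `"nn"` only.
#' @param oligo_molar Oligo concentration (mol/L), `"nn"` only.
#' @return Temperature in degrees Celsius.
#' @examples
#' tm("AAAATTTT")                        # 16
#' tm("GTCGATGAAGAGCGCAGCCA")            # 64
#' @export
tm <- function(p, method = c("wallace", "nn"), na_molar = 0.5,
               oligo_molar = 5e-8) {
  method <- match.arg(method)
  seq <- if (inherits(p, "primer")) p$seq else toupper(p)
  .validate_alphabet(seq, allow_gap = FALSE, what = "primer")
  if (nchar(seq) < 8L) stop("primer shorter than 8 nt", call. = FALSE)
  variants <- expand_degenerate(seq)
  f <- if (method == "wallace") .tm_wallace_one else {
    function(s) .tm_nn_one(s, na_molar, oligo_molar)
  }
  min(vapply(variants, f, numeric(1)))
}

# --- secondary-structure heuristics ------------------------------------

# Longest run k such that two non-overlapping k-mers of `seq` are reverse
# complements separated by a loop of >= min_loop bases (hairpin stem).
.max_hairpin_run <- function(seq, min_loop = 3L) {
  n <- nchar(seq)
  best <- 0L
  ch <- .chars(seq)
  for (k in seq_len(n %/% 2L)) {
    found <- FALSE
    for (i in seq_len(n - k + 1L)) {
      sub <- substr(seq, i, i + k - 1L)
      rc <- reverse_complement(sub)
      j0 <- i + k + min_loop
      if (j0 + k - 1L > n) next
      if (grepl(rc, substr(seq, j0, n), fixed = TRUE)) { found <- TRUE; break }
    }
    if (found) best <- k else break
  }
  best
}

# Longest complementary run between the primer and a second copy of itself
# (any offset): longest substring whose reverse complement is also a
# substring of the primer.
.max_self_dimer_run <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  for (k in seq_len(n)) {
    found <- FALSE
    for (i in seq_len(n - k + 1L)) {
      sub <- substr(seq, i, i + k - 1L)
      if (grepl(reverse_complement(sub), seq, fixed = TRUE)) { found <- TRUE; break }
    }
    if (found) best <- k else break
  }
  best
}

#' Default scoring parameters for [score_primer()]
#'
#' The composite score starts at 100 and subtracts documented penalties;
#' the weights are exposed so projects can tune them. Defaults: optimum Tm
#' 60 degrees C with weight 1 per degree of deviation, GC optimum 0.5 with
#' weight 50 per unit deviation, degeneracy cap 8 (5 points per doubling
#' beyond the cap), hairpin stem cap 4 bp and self-dimer run cap 8 bp
#' (2 points per excess base), and a flat 3 points for a 3'-terminal A
#' (less efficient extension with Taq polymerase).
#'
#' @param tm_opt,w_tm Tm optimum (C) and per-degree weight.
#' @param gc_opt,w_gc GC optimum (fraction) and weight.
#' @param max_degeneracy,w_degeneracy Degeneracy cap and per-doubling weight.
#' @param max_hairpin,w_hairpin Hairpin stem cap (bp) and per-base weight.
#' @param max_dimer,w_dimer Self-dimer run cap (bp) and per-base weight.
#' @param w_three_prime_A Flat penalty for a 3'-terminal A.
#' @param tm_method Tm estimator used in scoring.
#' @return Named list of parameters.
#' @export
score_params <- function(tm_opt = 60, w_tm = 1, gc_opt = 0.5, w_gc = 50,
                         max_degeneracy = 8L, w_degeneracy = 5,
                         max_hairpin = 4L, w_hairpin = 2,
                         max_dimer = 8L, w_dimer = 2,
                         w_three_prime_A = 3, tm_method = "wallace") {
  as.list(environment())
}

#' Score a primer candidate
#'
#' Populates Tm, GC fraction, degeneracy, longest hairpin stem, longest
#' self-dimer complementary run and the 3'-terminal-A flag, and combines
#' them into a composite score (100 minus documented penalties; see
#' [score_params()]). The 3'-terminal-A flag reflects reduced extension
#' efficiency of Taq polymerase on primers ending in A.
#'
#' @param p A [primer()] or IUPAC string.
#' @param params Parameter list from [score_params()].
#' @return List of class `primer_score` with fields `tm`, `gc`,
#'   `degeneracy`, `max_hairpin_run`, `max_self_dimer_run`,
#'   `three_prime_A`, `composite`.
#' @export
score_primer <- function(p, params = score_params()) {
  seq <- if (inherits(p, "primer")) p$seq else toupper(p)
  .validate_alphabet(seq, allow_gap = FALSE, what = "primer")
  deg <- degeneracy(seq)
  s <- list(
    tm = tm(seq, method = params$tm_method),
    gc = gc_fraction(seq),
    degeneracy = deg,
    max_hairpin_run = .max_hairpin_run(seq),
    max_self_dimer_run = .max_self_dimer_run(seq),
    three_prime_A = substr(seq, nchar(seq), nchar(seq)) == "A"
  )
  penalty <- params$w_tm * abs(s$tm - params$tm_opt) +
    params$w_gc * abs(s$gc - params$gc_opt) +
    params$w_degeneracy * max(0, log2(deg) - log2(params$max_degeneracy)) +
    params$w_hairpin * max(0L, s$max_hairpin_run - params$max_hairpin) +
    params$w_dimer * max(0L, s$max_self_dimer_run - params$max_dimer) +
    params$w_three_prime_A * s$three_prime_A
  s$composite <- 100 - penalty
  class(s) <- "primer_score"
  s
}

#' @export
print.primer_score <- function(x, ...) {
  cat(sprintf(paste0("<primer_score> Tm %.1fC  GC %.2f  degeneracy %d  ",
                     "hairpin %d  dimer %d  3'A %s  composite %.1f\n"),
              x$tm, x$gc, x$degeneracy, x$max_hairpin_run,
              x$max_self_dimer_run, x$three_prime_A, x$composite))
  invisible(x)
}

# Map alignment columns to ungapped template coordinates: per row the
# cumulative count of non-gap characters; the per-column coordinate is the
# median across rows (robust to private indels).
.column_template_coords <- function(aln) {
  mat <- aln$matrix
  pos <- apply(mat != "-", 1L, cumsum)  # columns x rows
  round(apply(pos, 1L, stats::median))
}

#' Enumerate scored primer candidates from conserved windows
#'
#' Slides a fixed-length frame over each conserved window, takes the IUPAC
#' consensus of the frame columns as the candidate oligo, and scores it.
#' Forward candidates read the consensus as-is; reverse candidates are its
#' reverse complement. Candidates exceeding the degeneracy cap are
#' dropped. Every candidate lies wholly inside one conserved window.
#'
#' @param aln An [alignment()].
#' @param windows Output of [find_conserved_windows()].
#' @param orientation `"forward"` or `"reverse"`.
#' @param primer_len Candidate oligo length (default 20).
#' @param params [score_params()].
#' @param consensus_threshold Threshold for the window IUPAC consensus.
#' @return `data.frame`: `name`, `seq`, `orientation`, `window`,
#'   `aln_start`, `aln_end`, `tpl_start`, `tpl_end` (median ungapped
#'   template coordinates), `tm`, `gc`, `degeneracy`, `three_prime_A`,
#'   `composite`.
#' @export
candidate_primers <- function(aln, windows, orientation = c("forward", "reverse"),
                              primer_len = 20L, params = score_params(),
                              consensus_threshold = 0) {
  orientation <- match.arg(orientation)
  tpl <- .column_template_coords(aln)
  rows <- list()
  for (w in seq_len(nrow(windows))) {
    if (windows$length[w] < primer_len) next
    for (a in seq(windows$start[w], windows$end[w] - primer_len + 1L)) {
      b <- a + primer_len - 1L
      cons <- .consensus_cols(aln, a:b, mode = "iupac",
                              threshold = consensus_threshold)
      if (nchar(cons) < primer_len) next  # gap-majority column inside frame
      if (degeneracy(cons) > params$max_degeneracy) next
      oligo <- if (orientation == "forward") cons else reverse_complement(cons)
      sc <- score_primer(oligo, params)
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("W%d%s%d", w, if (orientation == "forward") "F" else "R", a),
        seq = oligo, orientation = orientation, window = w,
        aln_start = a, aln_end = b,
        tpl_start = tpl[a], tpl_end = tpl[b],
        tm = sc$tm, gc = sc$gc, degeneracy = sc$degeneracy,
        three_prime_A = sc$three_prime_A, composite = sc$composite,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(name = character(0), seq = character(0),
                      orientation = character(0), window = integer(0),
                      aln_start = integer(0), aln_end = integer(0),
                      tpl_start = integer(0), tpl_end = integer(0),
                      tm = numeric(0), gc = numeric(0), degeneracy = integer(0),
                      three_prime_A = logical(0), composite = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Pair forward and reverse candidates under product constraints
#'
#' All forward x reverse combinations whose median primer-inclusive
#' product length lies within `[min_len, max_len]` and whose Tm difference
#' does not exceed `max_dTm`, ranked by combined composite score
#' (descending), then shorter product, then lexicographic pair name. With
#' no feasible pair an empty table is returned with a diagnostic message.
#'
#' @param fwd_cands,rev_cands Candidate tables from [candidate_primers()].
#' @param min_len,max_len Product length window (bp, primer-inclusive).
#' @param max_dTm Maximum |Tm_fwd - Tm_rev| (degrees C).
#' @return `data.frame`: `pair_name`, `fwd_seq`, `rev_seq`, `fwd_name`,
#'   `rev_name`, `product_len`, `fwd_tm`, `rev_tm`, `score`.
#' @export
pair_primers <- function(fwd_cands, rev_cands, min_len, max_len, max_dTm = 8) {
  empty <- data.frame(pair_name = character(0), fwd_seq = character(0),
                      rev_seq = character(0), fwd_name = character(0),
                      rev_name = character(0), product_len = integer(0),
                      fwd_tm = numeric(0), rev_tm = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (nrow(fwd_cands) == 0L || nrow(rev_cands) == 0L) {
    message("pair_primers: no candidates on one side; no feasible pair")
    return(empty)
  }
  grid <- expand.grid(f = seq_len(nrow(fwd_cands)), r = seq_len(nrow(rev_cands)),
                      KEEP.OUT.ATTRS = FALSE)
  prod_len <- rev_cands$tpl_end[grid$r] - fwd_cands$tpl_start[grid$f] + 1L
  dTm <- abs(fwd_cands$tm[grid$f] - rev_cands$tm[grid$r])
  keep <- prod_len >= min_len & prod_len <= max_len & dTm <= max_dTm &
    rev_cands$aln_start[grid$r] > fwd_cands$aln_end[grid$f]
  if (!any(keep)) {
    message(sprintf(
      "pair_primers: no pair satisfies length [%d, %d] and dTm <= %.1f",
      min_len, max_len, max_dTm))
    return(empty)
  }
  grid <- grid[keep, , drop = FALSE]
  out <- data.frame(
    pair_name = paste0(fwd_cands$name[grid$f], "/", rev_cands$name[grid$r]),
    fwd_seq = fwd_cands$seq[grid$f], rev_seq = rev_cands$seq[grid$r],
    fwd_name = fwd_cands$name[grid$f], rev_name = rev_cands$name[grid$r],
    product_len = prod_len[keep],
    fwd_tm = fwd_cands$tm[grid$f], rev_tm = rev_cands$tm[grid$r],
    score = fwd_cands$composite[grid$f] + rev_cands$composite[grid$r],
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$score, out$product_len, out$pair_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Design primer pairs from an alignment in one call
#'
#' Convenience wrapper: conserved windows, candidate enumeration on both
#' orientations, and pairing under the product-length window.
#'
#' @inheritParams find_conserved_windows
#' @inheritParams candidate_primers
#' @inheritParams pair_primers
#' @return As [pair_primers()].
#' @export
design_primers <- function(aln, min_len, max_len, primer_len = 20L,
                           min_identity = 0.90, max_gap_fraction = 0.10,
                           min_window = 15L, max_dTm = 8,
                           params = score_params()) {
  windows <- find_conserved_windows(aln, min_len = min_window,
                                    min_identity = min_identity,
                                    max_gap_fraction = max_gap_fraction)
  fwd <- candidate_primers(aln, windows, "forward", primer_len, params)
  rev <- candidate_primers(aln, windows, "reverse", primer_len, params)
  pair_primers(fwd, rev, min_len, max_len, max_dTm)
}
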