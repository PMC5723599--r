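.E_LEVELS <- c("e0", "e1", "e2", "e3")

#' Keep only successful amplicons
#'
#' An in silico amplicon counts as successful when its primer-inclusive
#' length is at least `min_len` (200 bp by default, the same success rule
#' applied to wet-lab products). Idempotent.
#'
#' @param hits Amplicon hit table.
#' @param min_len Success threshold in bp.
#' @return Filtered hit table.
#' @export
success_filter <- function(hits, min_len = 200L) {
  hits <- .as_hit_table(hits)
  hits[hits$length >= min_len, , drop = FALSE]
}

#' Per-e-class specificity table for one primer pair
#'
#' Counts *sequences*, not amplicons: each template that amplifies is
#' counted once, in the e-class of its best (lowest-mismatch) hit, split
#' into target vs off-target groups by the database's `is_target` labels.
#' Totals are invariant under template reordering.
#'
#' @param hits Amplicon hit table (any mix of pairs; filtered to `pair`).
#' @param db List of [seq_record()]s carrying `is_target`.
#' @param pair A [primer_pair()] or pair name string.
#' @return Object of class `specificity_table`: a 2 x 4 integer matrix
#'   (`target`, `off_target` rows; `e0`..`e3` columns) with attribute
#'   `pair_name`.
#' @export
build_specificity_table <- function(hits, db, pair) {
  pair_name <- if (inherits(pair, "primer_pair")) pair$name else pair
  hits <- .as_hit_table(hits)
  hits <- hits[hits$pair_name == pair_name, , drop = FALSE]
  counts <- matrix(0L, nrow = 2L, ncol = length(.E_LEVELS),
                   dimnames = list(c("target", "off_target"), .E_LEVELS))
  if (nrow(hits) > 0L) {
    target_of <- stats::setNames(
      vapply(db, function(r) isTRUE(r$is_target), logical(1)),
      vapply(db, function(r) r$id, character(1)))
    best <- do.call(rbind, lapply(split(hits, hits$template_id), .best_hit))
    e <- factor(.e_class(best$fwd_mm, best$rev_mm), levels = .E_LEVELS)
    grp <- ifelse(target_of[best$template_id], "target", "off_target")
    tab <- table(factor(grp, levels = c("target", "off_target")), e)
    counts[] <- as.integer(tab)
  }
  structure(counts, pair_name = pair_name, class = c("specificity_table", "matrix"))
}

#' @export
print.specificity_table <- function(x, ...) {
  cat(sprintf("<specificity_table> %s (sequences per e-class)\n",
              attr(x, "pair_name")))
  print(unclass(x))
  invisible(x)
}

#' Serialize specificity tables to TSV
#'
#' Fixed column order (pair, group, e0..e3) plus cumulative columns
#' (`e_le_0`..`e_le_3`, sequences amplified at *up to* k mismatches), so
#' both per-class and cumulative-up-to-class readings of stacked-bar
#' figures are available.
#'
#' @param tables A `specificity_table` or list of them.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_specificity <- function(tables, path) {
  if (inherits(tables, "specificity_table")) tables <- list(tables)
  rows <- lapply(tables, function(tb) {
    cum <- t(apply(tb, 1L, cumsum))
    data.frame(pair = attr(tb, "pair_name"),
               group = rownames(tb),
               e0 = tb[, "e0"], e1 = tb[, "e1"], e2 = tb[, "e2"], e3 = tb[, "e3"],
               e_le_0 = cum[, 1L], e_le_1 = cum[, 2L],
               e_le_2 = cum[, 3L], e_le_3 = cum[, 4L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-position mismatch profile of a primer across annotated haplotypes
#'
#' For each record the primer's annealing window is located inside the
#' given annotated partition (best match, leftmost tie-break); identical
#' windows are collapsed to unique haplotypes; each haplotype contributes
#' one row of per-position mismatch indicators versus the primer, and rows
#' are ranked by total mismatches (ascending), ties broken
#' lexicographically by haplotype sequence. Records lacking the partition
#' are skipped with a warning.
#'
#' @param primer A [primer()].
#' @param annotated List of `list(record =, annotation =)` pairs (or a
#'   list of records plus `annotations` as a parallel list).
#' @param partition Partition containing the annealing site
#'   (default `"r58S"`).
#' @return Object of class `mismatch_profile`: list with `primer_name`,
#'   `haplotypes` (character), `matrix` (0/1 indicators, haplotypes x
#'   primer positions), `totals`, `n_records` (records per haplotype).
#' @export
mismatch_profile <- function(primer, annotated, partition = "r58S") {
  stopifnot(inherits(primer, "primer"))
  k <- nchar(primer$seq)
  windows <- character(0)
  for (item in annotated) {
    rec <- item$record; ann <- item$annotation
    iv <- ann$partitions[[partition]]
    if (is.null(iv)) {
      warning(sprintf("%s: partition %s absent; skipped", rec$id, partition),
              call. = FALSE)
      next
    }
    sub <- substr(rec$sequence, iv[1L], iv[2L])
    if (nchar(sub) < k) {
      warning(sprintf("%s: partition %s shorter than primer; skipped",
                      rec$id, partition), call. = FALSE)
      next
    }
    mm <- .mismatch_profile(primer$seq, sub)
    best <- which.min(mm)  # leftmost minimum
    windows <- c(windows, substr(sub, best, best + k - 1L))
  }
  tab <- table(windows)
  haps <- names(tab)
  if (length(haps) == 0L) {
    m <- matrix(0L, 0L, k)
    return(structure(list(primer_name = primer$name, haplotypes = character(0),
                          matrix = m, totals = integer(0),
                          n_records = integer(0)),
                     class = "mismatch_profile"))
  }
  m <- t(vapply(haps, function(h) {
    ind <- integer(k)
    ind[count_mismatches(primer, h)$positions] <- 1L
    ind
  }, integer(k)))
  totals <- as.integer(rowSums(m))
  ord <- order(totals, haps)  # deterministic: total, then lexicographic
  structure(list(primer_name = primer$name, haplotypes = haps[ord],
                 matrix = m[ord, , drop = FALSE], totals = totals[ord],
                 n_records = as.integer(tab)[ord]),
            class = "mismatch_profile")
}

#' @export
print.mismatch_profile <- function(x, ...) {
  cat(sprintf("<mismatch_profile> %s: %d unique haplotype(s)\n",
              x$primer_name, length(x$haplotypes)))
  for (i in seq_along(x$haplotypes)) {
    cat(sprintf("  %s  mm=%d  (n=%d)\n", x$haplotypes[i], x$totals[i],
                x$n_records[i]))
  }
  invisible(x)
}

#' Serialize a mismatch profile to TSV
#'
#' @param profile A `mismatch_profile`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_mismatch_profile <- function(profile, path) {
  m <- profile$matrix
  colnames(m) <- paste0("p", seq_len(ncol(m)))
  out <- data.frame(primer = profile$primer_name,
                    haplotype = profile$haplotypes,
                    total_mm = profile$totals,
                    n_records = profile$n_records,
                    m, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summary statistics over amplicon inserts
#'
#' Length minimum / maximum / mean and mean GC fraction over the insert
#' sequences (between the primers). GC is computed on unambiguous bases
#' only.
#'
#' @param hits Amplicon hit table carrying `seq` (primer-inclusive) --
#'   inserts are extracted using the primer lengths encoded in
#'   `insert_start`/`insert_end`.
#' @return Named list `n`, `min_len`, `max_len`, `mean_len`, `mean_gc`
#'   (insert-based); empty input gives `n = 0` and `NA` statistics.
#' @export
amplicon_stats <- function(hits) {
  hits <- .as_hit_table(hits)
  if (nrow(hits) == 0L) {
    return(list(n = 0L, min_len = NA_integer_, max_len = NA_integer_,
                mean_len = NA_real_, mean_gc = NA_real_))
  }
  # hits$seq always reads fwd-primer-first; on "-" strand hits the
  # given-strand coordinates put the reverse primer on the left, so the
  # front trim is strand-dependent.
  fwd_trim <- ifelse(hits$strand == "+",
                     hits$insert_start - hits$start,
                     hits$end - hits$insert_end)
  insert_len <- hits$insert_end - hits$insert_start + 1L
  inserts <- substr(hits$seq, fwd_trim + 1L, fwd_trim + insert_len)
  lens <- nchar(inserts)
  list(n = nrow(hits), min_len = min(lens), max_len = max(lens),
       mean_len = mean(lens),
       mean_gc = mean(vapply(inserts, gc_fraction, numeric(1)), na.rm = TRUE))
}
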