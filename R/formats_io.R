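#' @importFrom Biostrings readBStringSet writeXStringSet BStringSet
#' @importFrom utils read.delim write.table
NULL

#' Construct a sequence record
#'
#' The basic unit passed around the toolkit: one rDNA cassette (or any DNA
#' sequence) plus taxonomy labels and a target-clade flag.
#'
#' @param id Sequence identifier.
#' @param sequence Upper-case IUPAC DNA string; `-` only in aligned contexts.
#' @param family,species Taxon labels (may be empty).
#' @param is_target Is the carrier a member of the focal clade
#'   (e.g. Clitellata)?
#' @param aligned Allow gap characters.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, sequence, family = "", species = "",
                       is_target = NA, aligned = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- gsub("U", "T", toupper(sequence), fixed = TRUE)
  if (nchar(sequence) == 0L) stop("empty sequence for record ", id, call. = FALSE)
  .validate_alphabet(sequence, allow_gap = aligned,
                     what = sprintf("record '%s'", id))
  structure(list(id = id, sequence = sequence, family = family,
                 species = species, is_target = is_target),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s  (%d bp%s%s)\n", x$id, nchar(x$sequence),
              if (nzchar(x$family)) paste0("; ", x$family) else "",
              if (isTRUE(x$is_target)) "; target" else ""))
  invisible(x)
}

#' Construct a PCR primer
#'
#' @param name Primer name (e.g. `"606F"`).
#' @param seq 5'-to-3' IUPAC DNA sequence, at least 12 nt, no gaps.
#' @param orientation `"forward"` or `"reverse"`.
#' @return An object of class `primer`.
#' @examples
#' primer("606F", "GTCGATGAAGAGCGCAGCCA", "forward")
#' @export
primer <- function(name, seq, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  seq <- toupper(seq)
  .validate_alphabet(seq, allow_gap = FALSE, what = sprintf("primer '%s'", name))
  if (nchar(seq) < 12L) {
    stop(sprintf("primer '%s' is shorter than 12 nt", name), call. = FALSE)
  }
  structure(list(name = name, seq = seq, orientation = orientation),
            class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> %s  %s  (%s, %d nt, degeneracy %d)\n",
              x$name, x$seq, x$orientation, nchar(x$seq), degeneracy(x$seq)))
  invisible(x)
}

#' Construct a primer pair with a product-length window
#'
#' @param fwd,rev [primer()] objects with forward and reverse orientation.
#' @param min_len,max_len Allowed primer-inclusive product length in bp.
#' @param name Pair label; defaults to `"<fwd>/<rev>"`.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(fwd, rev, min_len, max_len,
                        name = paste0(fwd$name, "/", rev$name)) {
  stopifnot(inherits(fwd, "primer"), inherits(rev, "primer"))
  if (fwd$orientation != "forward" || rev$orientation != "reverse") {
    stop("pair must combine a forward and a reverse primer", call. = FALSE)
  }
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (!(min_len > 0L && min_len <= max_len)) {
    stop("need 0 < min_len <= max_len", call. = FALSE)
  }
  structure(list(fwd = fwd, rev = rev, min_len = min_len, max_len = max_len,
                 name = name),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s  product %d-%d bp\n", x$name, x$min_len, x$max_len))
  print(x$fwd); print(x$rev)
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Parsing is delegated to Biostrings; on top of that the full IUPAC
#' alphabet is enforced and, on failure, the offending file line is named.
#' `U` is silently converted to `T` (rDNA records are sometimes deposited
#' as RNA); sequences are upper-cased; input order is preserved.
#'
#' @param path FASTA file.
#' @param aligned Allow `-` gap characters (aligned FASTA).
#' @param is_target Default target flag to stamp on all records.
#' @return List of [seq_record()] objects.
#' @export
read_fasta <- function(path, aligned = FALSE, is_target = NA) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(list())
  seqs <- gsub("U", "T", toupper(as.character(set)), fixed = TRUE)
  ids <- sub("\\s.*$", "", names(set))
  legal <- if (aligned) .IUPAC_CHARS else setdiff(.IUPAC_CHARS, "-")
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(.chars(seqs[[i]])), legal)
    if (length(bad) > 0L) {
      stop(sprintf("FASTA parse error near line %d (record '%s'): illegal character(s) %s",
                   .fasta_line_of(path, i, bad[1L]), ids[i],
                   paste(shQuote(bad), collapse = ", ")), call. = FALSE)
    }
  }
  mapply(function(id, s) seq_record(id, s, is_target = is_target, aligned = aligned),
         ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# Locate the first sequence line of record `rec` containing `char`,
# for error reporting only.
.fasta_line_of <- function(path, rec, char) {
  lines <- readLines(path, warn = FALSE)
  headers <- grep("^>", lines)
  from <- headers[rec] + 1L
  to <- if (rec < length(headers)) headers[rec + 1L] - 1L else length(lines)
  for (i in seq(from, to)) {
    if (grepl(char, toupper(lines[i]), fixed = TRUE)) return(i)
  }
  from
}

#' Write sequence records to a FASTA file
#'
#' @param records List of [seq_record()] objects.
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  seqs <- vapply(records, function(r) r$sequence, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- vapply(records, function(r) r$id, character(1))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a primer table
#'
#' Tab-separated file with columns `name`, `seq`, `orientation`
#' (`forward`/`reverse`).
#'
#' @param path TSV file.
#' @return List of [primer()] objects (empty list for a header-only table).
#' @export
read_primer_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "seq", "orientation")
  if (!all(need %in% names(tab))) {
    stop("primer table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) return(list())
  bad <- setdiff(unique(tab$orientation), c("forward", "reverse"))
  if (length(bad) > 0L) {
    stop("unknown orientation token(s): ", paste(shQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(tab)), function(i) {
    primer(tab$name[i], tab$seq[i], tab$orientation[i])
  })
}

#' Read a specimen/taxonomy table
#'
#' Tab-separated metadata table with at least the columns `specimen_id`,
#' `family`, `species`, `accession`, `amplified_its`, `amplified_its2`.
#' Amplification outcome columns use `+` (success), `-` (failure) and
#' `+/-` (weak/partial). Row order is preserved; duplicate specimen ids
#' are an error.
#'
#' @param path TSV file.
#' @return A `data.frame` with class `specimen_table`.
#' @seealso [specimen_tallies()] for family/genus summaries.
#' @export
read_specimen_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("specimen_id", "family", "species", "accession",
            "amplified_its", "amplified_its2")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("specimen table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- tab$specimen_id[duplicated(tab$specimen_id)]
  if (length(dup) > 0L) {
    stop("duplicate specimen_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  ok <- c("+", "-", "+/-")
  for (col in c("amplified_its", "amplified_its2")) {
    bad <- setdiff(unique(tab[[col]]), ok)
    if (length(bad) > 0L) {
      stop(sprintf("column %s: unknown outcome token(s) %s", col,
                   paste(shQuote(bad), collapse = ", ")), call. = FALSE)
    }
  }
  class(tab) <- c("specimen_table", "data.frame")
  tab
}

#' Summarise a specimen table
#'
#' Counts specimens, distinct families and distinct genera (first word of
#' the species label), and tallies the `+`/`-`/`+/-` amplification outcomes
#' for each primer pair column.
#'
#' @param specimens A `specimen_table` from [read_specimen_table()].
#' @return Named list: `n_specimens`, `n_families`, `n_genera`,
#'   `its` and `its2` outcome tables.
#' @export
specimen_tallies <- function(specimens) {
  stopifnot(inherits(specimens, "data.frame"))
  genus <- sub("\\s.*$", "", specimens$species)
  list(
    n_specimens = nrow(specimens),
    n_families  = length(unique(specimens$family)),
    n_genera    = length(unique(genus)),
    its  = table(factor(specimens$amplified_its, levels = c("+", "-", "+/-"))),
    its2 = table(factor(specimens$amplified_its2, levels = c("+", "-", "+/-")))
  )
}

#' Path to a packaged example/fixture file
#'
#' @param file File name under `extdata/`; with no argument, lists them.
#' @return Full path.
#' @export
spacerprime_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "spacerprime")))
  }
  path <- system.file("extdata", file, package = "spacerprime")
  if (!nzchar(path)) stop("no packaged file ", file, call. = FALSE)
  path
}

#' The four clitellate ITS primers shipped with the package
#'
#' Reads the packaged primer table: 29F and 1084R (whole-ITS pair) and
#' 606F and 1082R (ITS2 pair).
#'
#' @return Named list of [primer()] objects.
#' @export
clitellate_primers <- function() {
  ps <- read_primer_table(spacerprime_extdata("clitellate_primers.tsv"))
  names(ps) <- vapply(ps, function(p) p$name, character(1))
  ps
}

#' The two clitellate primer pairs with their simulation length windows
#'
#' 29F/1084R for the whole ITS region (400-2500 bp allowed) and 606F/1082R
#' for ITS2 (200-1250 bp allowed).
#'
#' @return Named list of two [primer_pair()] objects.
#' @export
clitellate_pairs <- function() {
  p <- clitellate_primers()
  list(
    "29F/1084R" = primer_pair(p[["29F"]], p[["1084R"]], 400L, 2500L),
    "606F/1082R" = primer_pair(p[["606F"]], p[["1082R"]], 200L, 1250L)
  )
}

#' Write amplicon hits as FASTA plus a TSV sidecar
#'
#' FASTA ids follow `"<templateID>:<start>-<end>:<pairName>"` (1-based,
#' inclusive coordinates), which keeps ids unique for multi-hit templates.
#' The sidecar (`<path>.tsv`) carries coordinates and mismatch counts.
#' Rerunning on the same input is byte-identical.
#'
#' @param hits Amplicon hit table from [amplify()] / [run_database()].
#' @param path Output FASTA path; the sidecar is written to `<path>.tsv`.
#' @return `path`, invisibly.
#' @export
write_amplicons <- function(hits, path) {
  hits <- .as_hit_table(hits)
  ids <- sprintf("%s:%d-%d:%s", hits$template_id, hits$start, hits$end,
                 hits$pair_name)
  lines <- character(0)
  if (nrow(hits) > 0L) {
    lines <- as.vector(rbind(paste0(">", ids), hits$seq))
  }
  writeLines(lines, path)
  side <- hits[, c("template_id", "pair_name", "strand", "start", "end",
                   "insert_start", "insert_end", "length",
                   "fwd_mm", "rev_mm", "e_class")]
  utils::write.table(side, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Canonical empty amplicon-hit table; every hit-producing function returns
# this column layout.
.empty_hits <- function() {
  data.frame(template_id = character(0), pair_name = character(0),
             strand = character(0), start = integer(0), end = integer(0),
             insert_start = integer(0), insert_end = integer(0),
             length = integer(0), fwd_mm = integer(0), rev_mm = integer(0),
             e_class = character(0), seq = character(0),
             stringsAsFactors = FALSE)
}

.as_hit_table <- function(hits) {
  if (is.null(hits) || (is.data.frame(hits) && nrow(hits) == 0L)) {
    return(.empty_hits())
  }
  stopifnot(is.data.frame(hits))
  hits
}
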