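# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. The oracles deliberately avoid the package's
# scanning code paths: degenerate primers are expanded to all plain
# variants and located with fixed-string matching.

P606F <- "GTCGATGAAGAGCGCAGCCA"
P1082R <- "TTAGTTTCTTTTCCTCCGCTT"
P29F <- "AAAGTCGTAACAAGGTTTCCGTA"
P1084R <- "YGTTAGTTTCTTTTCCTCCGCTT"

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# All fixed-string match start positions of any degenerate expansion.
oracle_exact_sites <- function(iupac, seq) {
  hits <- integer(0)
  for (v in expand_degenerate(iupac)) {
    m <- gregexpr(v, seq, fixed = TRUE)[[1]]
    hits <- c(hits, m[m > 0])
  }
  sort(unique(hits))
}

# Brute-force zero-mismatch amplification on both strands; returns a
# data.frame(strand, start, end) sorted, in coordinates of the input
# sequence.
oracle_amplify0 <- function(pair, record) {
  out <- list()
  n <- nchar(record$sequence)
  fwd_len <- nchar(pair$fwd$seq)
  rev_len <- nchar(pair$rev$seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") record$sequence else oracle_revcomp(record$sequence)
    fs <- oracle_exact_sites(pair$fwd$seq, s)
    rs <- oracle_exact_sites(oracle_revcomp(pair$rev$seq), s)
    for (f in fs) for (r in rs) {
      if (r < f + fwd_len) next
      len <- r + rev_len - f
      if (len < pair$min_len || len > pair$max_len) next
      if (strand == "+") {
        out[[length(out) + 1]] <- data.frame(strand = strand, start = f,
                                             end = f + len - 1L)
      } else {
        out[[length(out) + 1]] <- data.frame(strand = strand,
                                             start = n - (f + len - 1L) + 1L,
                                             end = n - f + 1L)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Random plain-ACGT template with optionally planted primer sites; used by
# the oracle-equivalence checks. Returns the seq_record.
random_template <- function(id, len, pair = NULL, plant = c("none", "fwd", "both"),
                            gc = 0.5) {
  plant <- match.arg(plant)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
             collapse = "")
  if (plant != "none") {
    fwd_site <- expand_degenerate(pair$fwd$seq)[1]
    at <- sample(seq_len(max(1, len %/% 3)), 1)
    substr(s, at, at + nchar(fwd_site) - 1) <- fwd_site
    if (plant == "both") {
      rev_site <- oracle_revcomp(expand_degenerate(pair$rev$seq)[1])
      at2 <- min(len - nchar(rev_site) + 1,
                 at + nchar(fwd_site) + sample(50:300, 1))
      if (at2 >= at + nchar(fwd_site)) {
        substr(s, at2, at2 + nchar(rev_site) - 1) <- rev_site
      }
    }
  }
  seq_record(id, s)
}

hit_coords <- function(hits) {
  h <- hits[order(hits$start, hits$end, hits$strand),
            c("strand", "start", "end"), drop = FALSE]
  rownames(h) <- NULL
  h
}

its2_pair <- function(min_len = 200L, max_len = 1250L) {
  primer_pair(primer("606F", P606F, "forward"),
              primer("1082R", P1082R, "reverse"), min_len, max_len)
}

its_pair <- function(min_len = 400L, max_len = 2500L) {
  primer_pair(primer("29F", P29F, "forward"),
              primer("1084R", P1084R, "reverse"), min_len, max_len)
}
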