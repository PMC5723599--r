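---
title: "spacerprime: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spacerprime: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacerprime)
```

## The problem

The nuclear ribosomal Internal Transcribed Spacer region —
(18S)–ITS1–5.8S–ITS2–(28S) — is a workhorse nuclear marker for species
delimitation in groups with poor morphological resolution, including the
clitellate annelids (earthworms, sludge worms, leeches). Amplifying it is
often frustrated by the poor specificity of "universal" ITS primers:
mismatches against the target clade depress PCR success, and good matches
to fungi, plants and other co-extracted organisms amplify contaminants
instead. The clitellate-specific primer system that this package ships as
its reference case — 29F/1084R for the whole ITS region and 606F/1082R
for ITS2 — was designed against conserved rDNA elements flanking the
spacers, with the forward ITS2 primer sitting entirely inside a conserved
5.8S motif.

`spacerprime` re-implements the computational side of that workflow as a
desk-scale toolkit:

1. **annotation** of rDNA cassettes into their five partitions,
2. **conserved-window primer design** on a multiple sequence alignment,
3. **mismatch-tolerant in silico PCR** of degenerate primer pairs, and
4. **taxon-partitioned specificity reporting**,

plus a **synthetic cassette generator** that provides planted ground
truth, so every stage is testable without downloading sequence databases.

## Cassette annotation

Profile-HMM annotators (ITSx-style) are the field standard for rDNA
partitioning but are heavyweight for a desk tool. `annotate_its()`
instead anchors on three conserved elements that the clitellate ITS
system itself exploits:

* the pentamer **CATTA** marking the 3' end of 18S — ITS1 starts
  immediately after it;
* the **606F annealing site** inside 5.8S (the primer was designed to sit
  fully inside the conserved 5.8S motif CM1);
* the **1082R annealing site** at the 5' start of 28S, matched on the
  sense strand as the primer's reverse complement.

The two 20+-mer anchors are located by best mismatch-tolerant match
(default budget 2 mismatches; fewest mismatches, then leftmost — a
deterministic tie-break). The pentamer is matched exactly: five bases
carry too little information for mismatch-tolerant search. When several
CATTA copies exist, the one closest upstream of the 5.8S anchor is taken,
because the motif is only meaningful as the 18S terminus; this is a
documented convention, and real spacers can contain spurious copies (see
*Limitations*).

The 5.8S gene is then placed by seeding a 153-bp reference at the anchor
and re-matching the reference's first and last 20-mers within ±8 bp of
their expected positions, which absorbs small indels and lets annotated
5.8S lengths deviate from the reference (152–155 bp annotate correctly).
Partitions whose outer landmark is missing are flagged incomplete;
`partition_lengths()` renders them with the `">"` prefix convention used
in published specimen tables, and absent partitions as `"-"`.

`validate_58s()` screens for pseudogene-like copies: a complete 5.8S is
`"ok"` iff its length is within 153 ± 1 nt (the typical clitellate 5.8S
length) *and* all configured conserved motifs occur in it within a
1-mismatch budget; otherwise `length_atypical` or `motif_missing` is
reported.

### The packaged 5.8S reference and CM motifs are synthetic

The deposited clitellate accessions cannot be redistributed with the
package, so `ref_58s_synthetic()` is a *constructed* 153-bp stand-in: it
carries the full 606F site at positions 16–35, the three conserved-motif
stand-ins in cassette order, and GC ≈ 0.59, with deterministic filler
elsewhere. Likewise `cm_motifs()` operationalizes the three conserved
eukaryote 5.8S motifs: CM1 is the 606F core (the primer was designed to
match that motif exactly), CM2 the vertebrate-shared motif
`GAATTGCAGAATTC`, CM3 a generic eukaryote motif stand-in. Users working
with real data should swap in a clade-specific reference and motif set;
every function takes them as arguments.

## Conserved-window primer design

A *conserved window* is a maximal run of ≥ 15 consecutive alignment
columns (the smallest integer satisfying "longer than 14 nt") whose
per-column identity — the frequency of the modal non-gap base among
non-gap rows — is at least 0.90 and whose gap fraction is at most 0.10.
The identity and gap thresholds are this package's defaults, chosen so
that a conserved 5.8S block qualifies in a clitellate-style alignment
while randomized spacer columns (expected modal frequency well below
0.5) do not; both are exposed as arguments.

`candidate_primers()` slides a fixed-length frame (default 20 nt) over
each window, takes the frame's IUPAC consensus as the candidate oligo
(degeneracy capped at 8 by default; the reference primers have degeneracy
≤ 2), and scores it. `pair_primers()` then emits every forward × reverse
combination whose median primer-inclusive product length lies in the
requested window and whose Tm difference is at most `max_dTm`, ranked by
combined composite score, then shorter product, then lexicographic name —
all ties broken deterministically.

`max_dTm` defaults to 8 °C. This is deliberately looser than the 5 °C
folklore figure: the published reference pair itself differs by 6 °C
under the Wallace rule (64 vs 58 °C), so a tool whose default excluded
its own reference design would be miscalibrated.

### Melting temperature

Two estimators are provided. The Wallace rule `2(A+T) + 4(G+C)` is exact
integer bookkeeping. The nearest-neighbor model uses the SantaLucia
(1998) unified ΔH/ΔS table with terminal initiation corrections, the
entropic salt correction `ΔS + 0.368 (N−1) ln[Na+]`, and
`Tm = 1000 ΔH / (ΔS + R ln(C/4)) − 273.15`; documented default
conditions are 0.5 mol/L monovalent cation and 50 nmol/L oligo,
hybridization-scale conditions under which the two estimators agree
within a few degrees for typical design-range primers (19–24 nt, GC
40–60 %). The two formulas scale differently with length — Wallace is
linear at 2–4 °C per base, the nearest-neighbor model sub-linear — so
they diverge at the length extremes; this is a property of the Wallace
rule, which was calibrated on short oligos. For degenerate primers the
lowest-Tm expansion is reported, since the weakest variant limits
annealing.

### Composite score

`score_primer()` starts at 100 and subtracts documented penalties: 1
point per °C of deviation from a 60 °C optimum, 50 × |GC − 0.5|, 5
points per doubling of degeneracy beyond the cap, 2 points per base of
hairpin stem beyond 4 bp or of self-dimer run beyond 8 bp, and a flat 3
points for a 3'-terminal A (reduced extension efficiency with Taq
polymerase — notably, all three of 29F, 606F and the reverse-complement
view of 1082R end in A, so the flag marks a known trade-off rather than
disqualifying a primer). Hairpin and dimer runs are complementary-run
heuristics (longest self-complementary substring with a ≥ 3-base loop;
longest substring whose reverse complement is also a substring), not
thermodynamic folding. The weights are exposed in `score_params()`; the
composite is a documented stand-in for proprietary commercial scoring
schemes, not a reproduction of any of them.

## In silico PCR

`amplify()` follows ecoPCR semantics. A primer matches a template window
by position-wise IUPAC set intersection: `Y` matches `C`, `N` matches
anything, and template ambiguity codes participate symmetrically (an `N`
in the template matches any primer base — a documented rule, since
databases contain Ns). A mismatch is a mismatch regardless of position:
no 3'-terminal weighting at matching time (the 3' effect is handled at
design-scoring time instead). The per-primer budget defaults to 3
mismatches, the tolerance used for realistic PCR simulation.

Every forward-primer site is combined with every downstream
reverse-primer site (the reverse primer matched as its reverse
complement on the same strand); an amplicon is emitted iff its
primer-inclusive length falls within the pair's `[min_len, max_len]`
window — 400–2500 bp for the whole-ITS pair and 200–1250 bp for the ITS2
pair, the simulation windows appropriate for clitellate ITS length
variation. Both template orientations are scanned, so amplifying a
reverse-complemented template yields the mirror-image amplicon set. All
qualifying combinations are reported, nested and overlapping ones
included: counting semantics should not silently collapse hits. The
collapsed per-sequence view (each template's best hit: lowest e-class,
then longest product, then leftmost) is available via
`run_database(best_per_template = TRUE)` and is what specificity tables
count, since published coverage figures count sequences, not amplicons.

Each amplicon carries an **e-class** `e0`–`e3`, indexed by the *maximum*
of the two per-primer mismatch counts; the classes partition the hits.
The per-primer (rather than per-pair) reading of the mismatch budget
follows the phrasing "between a primer and its annealing sequence" and
is applied consistently.

`success_filter()` applies the ≥ 200 bp success rule used for wet-lab
products to in silico hits. `amplicon_stats()` summarises insert lengths
and GC; GC is computed over unambiguous bases only, so it is
deterministic on IUPAC input.

## The synthetic cassette generator

`make_cassette()` emulates the architecture the annotator and the PCR
simulator are built for, with defaults fixed at the study conditions:

| parameter | default | rationale |
|---|---|---|
| ITS1 length | 450 bp (panels: uniform 314–1117) | published clitellate ITS1 range |
| ITS2 length | 300 bp (panels: uniform 174–503) | published clitellate ITS2 range |
| 5.8S | 153-bp packaged reference | typical clitellate 5.8S length |
| GC of random regions | 0.59 | mean GC of successfully amplified clitellate amplicons |
| 18S tail / 28S head | 60 bp | enough to hold the terminal landmarks |
| anchor mismatch budget | 2 | at most 2 mismatches observed in the 606F region across clitellate haplotypes |

The 18S tail carries the 29F site and ends in CATTA; the 5.8S is the
reference with `fwd_site_mm` mismatches planted inside the 606F site
(each planted base drawn outside the primer's IUPAC set, so planted
counts are exact); the 28S head *begins* with the reverse-primer site
(extended two bases so 1084R anneals at the same locus), making the
generator's ITS2/28S boundary coincide with the annotator's 28S-anchor
convention. Off-target panel members carry ≥ 4 forward-site mismatches,
so they drop out at any budget up to 3 by construction. Each cassette
consumes a single private RNG stream seeded from its spec and restores
the caller's RNG state.

Two deliberate departures from realism, both load-bearing for exact
ground truth: spacers are generated **CATTA-free** (an accidental copy
between the true motif and the 5.8S anchor would legitimately fool the
closest-upstream rule — as it would on real data), and
`make_aligned_panel()` holds spacer lengths constant within a panel so
the rows form an alignment without an external aligner, with conserved
blocks mutation-free so window boundaries are deterministic. Passing
tests therefore demonstrate correctness of the machinery under the
stated conditions, not robustness to real-data pathologies such as
spurious landmarks, heterozygous sites, chimeras, or indel-rich spacer
alignments. There is no substitution-model sequence evolution.

## Numerical and convention choices

* **Coordinates are 1-based inclusive** everywhere (the R/Bioconductor
  convention; length = end − start + 1), including amplicon FASTA ids
  `"<template>:<start>-<end>:<pair>"`.
* All best-match searches break ties **leftmost**; rankings break ties
  by score, then product length, then name; profile rows by total
  mismatches, then lexicographic haplotype — every output is
  deterministic given inputs and seeds.
* `U` is silently converted to `T` on input (rDNA is sometimes deposited
  as RNA); alphabet violations are reported with the offending FASTA
  line.
* The IUPAC consensus rule covers all bases with column frequency
  ≥ (1 − threshold); the default threshold 0.5 makes a 50/50 C/T column
  emit `Y`.
* Degenerate Tm/score evaluation enumerates expansions; degeneracy is
  capped (default 8) before enumeration, so the combinatorics stay
  trivial.

## Validation problem sizes

The test suite validates the pipeline at these sizes, chosen to make
sampling error negligible while keeping a laptop-scale run: exact
e-class distribution recovery on a 1,000-cassette mixed panel (900
target / 100 off-target, planted per-primer mismatches 0–3);
zero-mismatch equivalence against a brute-force degenerate-expansion
substring oracle on 1,000 random templates; exact boundary recovery on
500 unmutated cassettes; budget- and window-monotonicity on planted
cassettes across budgets 0–3. The packaged 71-specimen panel reproduces
its tallies (71 specimens, 11 families, 47 genera; 65/71 ITS2 and 52/71
whole-ITS successes) exactly, and the designer rediscovers the
606F/1082R pair from a 12-row synthetic conserved-region alignment.

## Known limitations

* The annotator is landmark-anchored, not a profile HMM: it requires the
  anchors to be present within the mismatch budget and will return
  absent partitions otherwise. It has no chimera detection and does not
  delimit ITS2 by secondary structure.
* Real 5.8S/28S variation beyond ±8 bp of indel drift from the reference
  placement window will misplace the 5.8S boundaries.
* The in silico PCR is a string-matching model: no thermodynamic
  extension efficiency, polymerase bias, or 3'-mismatch weighting.
* A linear scan is used (no index); adequate at desk scale (thousands of
  templates), not for EMBL-scale databases.
* The packaged 5.8S reference, CM motifs and specimen alignment panels
  are synthetic stand-ins as described above.
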