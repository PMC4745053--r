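---
title: "Batch primer design: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch primer design: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primerworks)
```

`primerworks` designs PCR primers in bulk: every input sequence is scanned
inside user-defined windows, every candidate substring is scored and
filtered, and the survivors are reported as tables, positional files and
SVG maps. This vignette explains the models behind each step, the
parameters that matter, and the choices made where the design was
genuinely open.

## The design procedure

For each template, forward candidates are all substrings of length
`len_min`..`len_max` lying fully inside the first `window5` bases, and
reverse candidates are the reverse complements of all substrings inside
the last `window3` bases (windows larger than the sequence are clipped to
it). Coordinates are 1-based and inclusive throughout, and a primer is
*named* by the plus-strand coordinate of its 5′ terminus — for a reverse
primer that is the right end of its template interval, so on a map the
name of a reverse primer is always to the right of its partner forward
primer's name.

A candidate is accepted when all enabled constraints pass:

| constraint | default | unit / rule |
|---|---|---|
| length | 18–27 | nt |
| GC content | 35–65 | % of bases |
| melting temperature | 52–62 | °C, default engine |
| repeats | excluded | run of >5 identical bases, or >4 tandem copies of a two-base motif |
| 3′ GC clamp | off | terminal base ∈ {G, C}; one base, as "clamp" names a single terminal interaction |
| self-complementarity | < 10 | maximal antiparallel pairing count |
| hairpin ΔG | ≥ −6.0 | kcal/mol under the additive model below |
| specificity | off | exactly one both-strand match in the whole input, ≤ `max_mismatches` |

Accepted primers are deduplicated by (sequence, orientation), keeping the
smallest start coordinate, and sorted by start. Filters are evaluated
cheapest first (composition → Tm → structure → specificity); the order
affects only which rejection reason a candidate gets, never the accepted
set. All passing candidates are returned rather than a ranked shortlist:
the goal is a dense map from which a user picks primers by position, and a
per-record cap would hide exactly the coverage information the maps exist
to show.

## Melting-temperature engines

Three engines are available through `thermo_conditions(engine = ...)`.

**`breslauer` (default).** Nearest-neighbor sum over the Breslauer 1986
stack table with helix-initiation entropy −10.8 cal mol⁻¹ K⁻¹:
Tm(K) = ΔH/(ΔS + R ln(C_T/4)), then the Schildkraut correction
+16.6 log₁₀[Na⁺] relative to the 1 M reference. This engine was chosen as
the default because Breslauer-based calculators are what the toolkit's Tm
values track most closely in the cross-engine study below, and because the
widely used Phusion-style and Primer3 defaults are Breslauer-based.

**`santalucia`.** The SantaLucia 1998 unified table with per-terminal
initiation terms (+0.1 kcal/−2.8 cal for a G·C end, +2.3/+4.1 for an A·T
end) and the Owczarzy 2004 salt correction in reciprocal-temperature form,
1/Tm([Na⁺]) = 1/Tm(1 M) + (4.29 f_GC − 3.95)·10⁻⁵ ln[Na⁺]
+ 9.40·10⁻⁶ ln²[Na⁺], which depends on the GC fraction f_GC and is
therefore not a constant offset across primers.

**`basic`.** The length/GC rule: 2(A+T)+4(G+C) below 14 nt, otherwise
64.9 + 41(G+C − 16.4)/L. Retained for compatibility with quick manual
calculations.

Default buffer conditions are 50 mM monovalent salt and 50 nM total primer
— the common defaults of public Tm calculators. Divalent cations and dNTP
corrections are out of scope; for Mg²⁺-dominated buffers the absolute Tm
values shift but the ranking of primers is essentially unchanged, which is
what the design filters consume.

`compare_tm_engines()` runs the paired study: `random_primers()` draws a
seeded panel (default used in the package's checks: 100 primers, 18–30 nt),
and the squared Pearson correlation of the two engines' Tm vectors is
returned. Because the Schildkraut correction is an additive shift, two
Breslauer configurations differing only in salt correlate with r² = 1
exactly; Breslauer vs SantaLucia/Owczarzy panels land near r² ≈ 0.96 under
the default panel settings. The generator draws each primer's GC target
uniformly on [0.2, 0.8] and then places exactly the rounded number of G/C
bases: i.i.d. uniform bases would concentrate GC near 50% and shrink the
Tm spread the correlation study needs.

## Structural scores

The primer-dimer score between primers *a* and *b* is the maximum, over
all relative offsets of *a* against the reverse complement of *b*, of the
number of aligned Watson–Crick pairings; self-complementarity is the same
score of a primer against itself. The score counts *total* pairings at the
best offset rather than the longest contiguous run — the two definitions
agree on the pathological cases (palindromes, perfect duplexes) and the
total is the more conservative screen; the contiguous-run variant is the
plausible alternative and would be a one-line change in the kernel.

The hairpin score enumerates every ungapped stem–loop with a stem of at
least 3 contiguous pairs and a loop of 3–12 nt, scoring
ΔG = +3.5 (loop) + Σ pairs (A·T −1.0, G·C −1.5 kcal/mol) and reporting the
minimum, or 0 when no net-stabilising fold exists. This is a deliberately
transparent stand-in for a full partition-function fold: it is exact for
the geometry it models, testable by brute-force enumeration, and
calibrated so that the default −6 kcal/mol floor rejects stems of about
five or more G·C pairs while tolerating the short weak folds ubiquitous in
random sequence. Internal loops, bulges and dangling ends are not modelled.

Both kernels are implemented in C++ (exhaustive enumeration over offsets
and foldings) and verified in the test suite against independent pure-R
brute-force implementations on hundreds of random sequences.

## Specificity

`specificity_count()` counts ungapped alignment positions on both strands
of every input record with Hamming distance ≤ `max_mismatches`, via
`Biostrings` pattern matching. The count includes the primer's own origin
site, so "specific" means a count of exactly 1. Gapped off-target
hybridisation is out of scope — at primer lengths the ungapped count is
the standard screen.

## SNP primers

`read_rs_fasta()` ingests dbSNP-style flanking files whose headers carry
`pos = <int>|len<int>` (spaced or unspaced — user-supplied files vary) and
whose sequence carries an IUPAC ambiguity code at the SNP site; the
declared length must match the actual sequence and the site must actually
be ambiguous, both hard errors otherwise. Record ids are the first
whitespace-delimited header token, with the full header preserved as the
description.

`design_snp_flanking()` restricts forward candidates to end strictly
before the SNP and reverse candidates to start strictly after it, so every
forward/reverse pair brackets the site and no candidate covers the
ambiguity code. `design_allele_specific()` anchors each primer's 3′
terminus exactly at the SNP with terminal base equal to the allele
(forward) or its complement (reverse); among admissible lengths the one
with in-range Tm closest to the Tm midpoint wins, ties going to the
shorter primer (less synthesis, equal discrimination). The GC-clamp
requirement is never applied to these primers, since their 3′ base is
dictated by the allele. The alphabetically first allele is labelled
"wildtype" and the rest "polymorphic" — a labelling convention only, as
flanking files do not mark which allele is ancestral.

## Maps and positional files

Positional records translate primers to plus-strand intervals (forward:
start..start+len−1 on "+"; reverse named *n*: n−len+1..n on "−") and
round-trip through TSV byte-identically. Maps are written as hand-generated
SVG: a scaled base-pair ruler, one arrowed glyph per primer pointing in
the direction of synthesis (blue by default), a green SNP marker where
applicable, and — in the concatenated view — all records laid end-to-end
in input order at zero-gap cumulative offsets with ticked, labelled
boundaries. Zero gap keeps global coordinates a bijection with (record,
local coordinate) pairs; boundaries are visual ticks, not coordinates.
Overlapping glyphs are stacked greedily into the first free lane, a
presentation choice with no semantic content. SVG was chosen as the
canonical graphic because it scales losslessly and is text-assertable in
tests; rendering is a pure function, so identical inputs give
byte-identical documents. A JSON-lines export (one object per primer)
serves external viewers; `primer_from_coordinates()` implements the
map-drawing rule that a left-to-right span returns a forward primer and a
right-to-left span its reverse complement, with GC% and Tm.

## Synthetic inputs and what the tests show

`simulate_dna()` draws records with per-record GC targets uniform on
[0.35, 0.65]; `simulate_snp()` builds the canonical flanking shape — odd
length, a biallelic ambiguity code at the centre, a conformant header
(1001 nt gives `pos = 501|len1001`). Both are seeded and byte-reproducible,
and stand in for remote GenBank/dbSNP retrieval so that every check runs
offline. The simulator emulates composition, not biology: real templates
have repeats, low-complexity tracts, GC isochores and paralogy that i.i.d.
sequence lacks, so passing tests demonstrate correctness of the scanning,
scoring and filtering machinery, not wet-lab primer performance. The
package's own checks run at deliberately modest sizes — 10 records × 1 kb
for design and specificity, 100-primer panels for the Tm study, pools up
to n = 100 for the dimer report — sizes at which every brute-force oracle
remains exhaustive.

## Numerical and degenerate-input choices

Tm functions require ≥ 8 unambiguous bases and refuse ambiguity codes
rather than averaging over expansions. Sequences containing ambiguity
codes are excluded from candidacy (only the SNP site itself is ambiguous
in flanking design, and it is excluded by construction). Characters
outside the 15 IUPAC letters are hard errors everywhere — malformed input
fails loudly rather than being silently stripped. An empty accepted-primer
set is legal output, not an error; a record shorter than `len_min` is a
per-record error that does not abort the batch. The dimer report requires
n ≥ 2. `compare_tm_engines()` treats zero Tm variance as a defined error
rather than returning NaN. All tabular numeric output is fixed to two
decimals so repeated runs are byte-identical.

## Limitations

No Mg²⁺/dNTP thermodynamics, mismatch or dangling-end corrections; no
partition-function secondary structure; no amplicon-level pair ranking
(the tool designs pools and maps, not ranked pairs with product-size
constraints); no remote database retrieval or remote BLAST submission
(the `blast` subcommand prints what it would submit and stops). The 3′
search window is counted from the 3′ end of the sequence, symmetric with
the 5′ description; absolute-coordinate windows can be emulated by
adjusting `window3` per record length.
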