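# primerworks

Batch PCR primer design for any number of DNA or SNP templates, with
thermodynamic screening, multiplex dimer vetting and scalable primer maps.

PCR-heavy workflows — primer walking across contigs, nested and multiplex
PCR, SNP genotyping panels — need dozens to hundreds of coordinated primers
rather than one optimised pair. `primerworks` is built for that regime: it
scans user-defined 5′ and 3′ search windows of every input sequence,
applies melting-temperature, composition and structural filters to every
candidate, designs allele-specific genotyping primers at SNP sites, scores
every pairwise primer combination for cross-dimer potential, and renders
per-sequence and concatenated SVG primer maps so coverage can be checked at
a glance.

## The models at the core

**Melting temperature.** The default engine is the Breslauer
nearest-neighbor model with the Schildkraut salt correction. For a primer
of sequence $s$ with dinucleotide steps $i$,

$$T_m = \frac{\Delta H}{\Delta S + R\,\ln(C_T/4)} - 273.15 + 16.6\,\log_{10}[\mathrm{Na}^+]$$

where $\Delta H = \sum_i \Delta H_i$ and
$\Delta S = \Delta S_{init} + \sum_i \Delta S_i$ sum the published
enthalpy/entropy contributions of each adjacent base stack
(kcal/mol and cal mol⁻¹ K⁻¹), $R$ is the gas constant and $C_T$ the total
primer concentration (defaults: 50 mM Na⁺, 50 nM primer). Two comparator
engines are built in: the SantaLucia unified nearest-neighbor set with the
Owczarzy GC-dependent reciprocal-temperature salt correction, and the
classic length/GC rule ($2(A{+}T)+4(G{+}C)$ below 14 nt,
$64.9 + 41\,(G{+}C-16.4)/L$ otherwise). `compare_tm_engines()` reproduces
the cross-calculator correlation study ($r^2$ of paired Tm values over a
random primer panel).

**Structure and composition.** Self- and cross-dimer potential are scored
as the maximum number of Watson–Crick pairings over all antiparallel
offsets of one primer against (a copy of) another; scores below 10 are
accepted. Hairpins are scored by exhaustive enumeration of ungapped
stem–loops (stem ≥ 3 pairs, loop 3–12 nt) under an additive energy model
(A·T −1.0, G·C −1.5, loop +3.5 kcal/mol), with a default floor of
−6 kcal/mol. Repetitive candidates (mononucleotide runs > 5, dinucleotide
tandems > 4) are excluded by default, a 3′ GC clamp can be required, and a
mismatch-tolerant both-strand scan can require each primer to be unique
across the whole input file.

**Multiplex compatibility.** For $n$ accepted primers, all
$\binom{n}{2} = n(n-1)/2$ unordered pairings are scored and flagged.

## Worked example

```r
library(primerworks)

recs <- simulate_dna(2, 600, seed = 20)               # two 600-nt templates
res  <- design_batch(recs, design_params(window5 = 100, window3 = 100))
nrow(res$primers)
#> [1] 280
head(res$primers, 3)
#>  source_id name orientation start length           sequence       tm gc_percent selfcomp hairpin_dg
#>     seq001   35     forward    35     18 CTAGCGCCACAACAGCGT 61.19231   61.11111        6         -1
#>     seq001   76     forward    76     18 CAGGTGTACCCGGCGTTT 61.91669   61.11111        8          0
#>     seq001   77     forward    77     18 AGGTGTACCCGGCGTTTT 60.37509   55.55556        6          0
```

Each row is one accepted primer: `name` is the 1-based plus-strand
coordinate of its 5′ terminus (reverse primers therefore carry the
rightmost coordinate of their template interval), `tm` its default-engine
melting temperature in °C, `selfcomp` the self-annealing pairing count
(accepted below 10) and `hairpin_dg` the stem–loop ΔG in kcal/mol (0 means
no stable fold; closer to zero is better).

Allele-specific genotyping primers anchor the SNP allele at the 3′ end:

```r
snp <- simulate_snp(1, 1001, seed = 20)   # 'W' at position 501 -> alleles A/T
design_allele_specific(snp, design_params())
#>    snp_id allele       label orientation name length                    sequence       tm
#>  rs378047      A    wildtype     forward  482     20        TGTGATGTATGTTGGGCAAA 58.38935
#>  rs378047      A    wildtype     reverse  527     27 CAGACTAGAAATTACAAGGTACTTGAT 55.87650
#>  rs378047      T polymorphic     forward  482     20        TGTGATGTATGTTGGGCAAT 57.24553
#>  rs378047      T polymorphic     reverse  527     27 CAGACTAGAAATTACAAGGTACTTGAA 56.73029
```

The forward pair ends exactly at position 501 with terminal base A or T;
the reverse pair's 3′ base is the allele's complement. Extension by a
polymerase succeeds only when the terminal base matches the template
allele, which is what makes the primers genotype-discriminating.

The same pipeline is available from a shell via the bundled driver
(`inst/cli/primerworks`, installed under the package's `cli/` directory):

```sh
primerworks design --in templates.fasta --out out/
primerworks snp --in snps.fasta --out out/
primerworks dimers --in out/primers.tsv --out out/
primerworks draw --in templates.fasta --id seq001 --a 30 --b 11
```

`design` writes `primers.tsv`, `positions.tsv`, `primers.json`, one
`map_<id>.svg` per record, a concatenated `map_all.svg` and a
`params_echo.txt` sufficient to re-run the identical job; `snp` adds
`allele_specific.tsv` and SNP-marked maps. All outputs are byte-identical
across repeated runs with the same inputs, flags and seed.

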