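# ragfrag

Chromosomal translocations in lymphoid cancers often arise where the RAG
recombinase acts outside the antigen-receptor loci: RAG binding is anchored
by the recombination signal sequence **nonamer** (`ACAAAAACC`), and cleavage
is directed to mismatches created when methylated cytosines at **CpG**
dinucleotides deaminate. Genomic regions where a cryptic (degenerate)
nonamer sits close to a CpG are therefore candidate fragile sites, and
patient breakpoints should cluster there.

ragfrag is an R package for testing that model on any genome + breakpoint
set. It is aimed at computational biologists who have breakpoint
coordinates (BED/TSV) and a reference FASTA and want reproducible,
statistically controlled co-occurrence analysis — plus a fully
ground-truthed synthetic-genome generator so every stage can be validated
offline.

## What it computes

* **Cryptic nonamer scan** — every 9-mer window on both strands within
  Hamming distance `m ≤ 4` of `ACAAAAACC` (equivalently, ≥ 5 of 9
  positions conserved). The accepted motif space is
  `Σ_{k≤4} C(9,k)·3^k = 12,826` of `4^9 = 262,144` 9-mers.
* **CpG scan** and per-breakpoint proximity: fractions of breaks with a
  nonamer, a CpG, or both within ±100 bp.
* **Break-cluster windows** — non-overlapping 100 bp / 1 kb tilings;
  windows with ≥ 3 unique breaks are "broken", contrasted against
  GC-matched unbroken windows using the Pearson chi-square

  `X² = N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))`

  on the pair-presence table, Mann–Whitney U (midranks) and Welch t on
  per-window counts.
* **CpG–nonamer distance distributions** — minimal edge gaps per break,
  stratified by mismatch class (2/3/4).
* **Iterated GC-matched null** — 1000 re-draws of control windows matched
  per-window to ±0.02 GC, with add-one empirical p-values
  `(1 + #extreme) / (1 + B)`.
* **Stratifications** — promoters, Giemsa chromatin classes
  (`gneg` → euchromatin, `gpos*/gvar` → heterochromatin), and
  lymphoid vs nonlymphoid cohorts.
* **PWM** of detected nonamers with per-position conservation.

All coordinates are 0-based half-open (BED convention). Every random
stage derives from one master seed, so runs are bit-reproducible.

## Worked example

The built-in `paper_like` scenario plants 39 fragile footprint windows
(CpG + tandem nonamer array, pair gaps 10–80 bp) in a 500 kb two-chromosome
genome and simulates breaks at 0.08/base inside footprints vs 2e-5 outside:

```r
library(ragfrag)

sc <- make_scenario("paper_like", seed = 1)
report <- run_full_analysis(sc$genome, sc$breaks, sc$config,
                            promoters = sc$annotations$promoters,
                            cytobands = sc$annotations$cytobands)
print(report)
#> <run_report> ragfrag 0.1.0, seed 1
#>   genome: 2 chromosome(s), 5e+05 bases
#>   breaks: 342 unique (342 raw); 684.00 per Mb
#>   features: 66785 nonamer hits, 4206 CpGs
#> <window_contrast> 39 broken vs 39 control windows
#>   nonamers/window: 37.77 vs 13.95 (MW p = 4.99e-13)
#>   %windows with pair: 100.0 vs 71.8 (chi-square 12.81, p = 0.000346)
#> <proximity_summary> 342 breakpoints, radius 100 bp
#>   with nonamer: 342 (100.0%)
#>   with CpG:     341 (99.7%)
#>   with both:    341 (99.7%)

round(report$null_p, 4)
#>  pct_with_cpg pct_with_pair mean_nonamers
#>         0.001         0.001         0.001
```

Reading the output: the 39 break-cluster windows carry 37.8 nonamers per
100 bp against 13.9 in GC-matched unbroken controls (2.7-fold,
Mann–Whitney p ≈ 5e-13); all broken windows contain a CpG–nonamer pair
with gap ≤ 80 bp versus 72% of matched controls; and each broken-window
summary exceeds all 1000 GC-matched null draws (empirical p = 1/1001).
The planted enrichment is recovered. `write_run_report(report, "out/")`
emits `report.json` plus BED/TSV tables of hits, CpGs, windows, distances
and the null distribution.

A thin command-line wrapper with `simulate`, `scan` and `run` subcommands
is installed at `inst/cli/ragfrag`.

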