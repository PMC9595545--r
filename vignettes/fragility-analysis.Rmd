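---
title: "Cryptic nonamer / CpG fragility analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cryptic nonamer / CpG fragility analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ragfrag)
```

## The model

Chromosomal translocations in lymphoid cancers are frequently initiated by
the RAG recombinase acting outside its physiological substrates. The RAG
complex is anchored by the nonamer element of the recombination signal
sequence, canonically `ACAAAAACC`; degenerate ("cryptic") copies of this
9-mer occur throughout the genome, and cleavage is thought to be directed
to mismatches arising at nearby CpG dinucleotides when methylated cytosine
deaminates to thymine. Under that model, regions where a CpG sits within a
short distance of a cryptic nonamer are fragile, and patient breakpoints
should cluster there.

ragfrag operationalises the model as a pipeline over three primitives:

1. **Cryptic nonamer scan.** A 9-mer window at position $i$ is a hit when
   its Hamming distance to the reference nonamer is at most
   `max_mismatch`, equivalently when at least $9 - \texttt{max\_mismatch}$
   positions are conserved. Both strands are scanned at every position;
   overlapping hits are all counted, because per-kilobase nonamer
   densities under a 4-mismatch tolerance are only consistent with dense,
   overlapping counting (the Hamming ball of radius 4 around a 9-mer
   contains $\sum_{k\le4}\binom{9}{k}3^k = 12{,}826$ of the $262{,}144$
   possible 9-mers, i.e. about 4.9% of random windows per strand).
2. **CpG scan.** Every occurrence of the dinucleotide `CG`; it is its own
   reverse complement, so a single strand suffices.
3. **Windowing.** The genome is tiled into non-overlapping windows
   (100 bp and 1 kb by default). Windows with at least
   `min_breaks_per_window` (3) deduplicated breakpoints are
   *break-cluster* ("broken") windows; windows with no breaks are
   *unbroken*; windows with 1–2 breaks are excluded from contrasts rather
   than pooled, since neither class describes them.

Enrichment is then quantified three ways: per-breakpoint proximity
fractions (features within ±`breakpoint_radius` of the break), per-window
contrasts of broken versus GC-matched unbroken windows (chi-square on the
pair-presence table, Mann–Whitney and Welch t on per-window counts), and
an iterated GC-matched null distribution with add-one empirical p-values.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `motif` | `ACAAAAACC` | — | canonical RSS nonamer |
| `max_mismatch` | 4 | nt | "cryptic" = at least 5 of 9 conserved |
| `breakpoint_radius` | 100 | bp | proximity window around a point break |
| `pair_gap_max` | 80 | bp | maximal CpG-to-nonamer edge gap of a fragility pair |
| `window_sizes` | 100, 1000 | bp | fine scale for clusters, coarse for densities |
| `min_breaks_per_window` | 3 | breaks | break-cluster threshold per 100 bp |
| `null_iterations` | 1000 | — | iterated GC-matched control draws |
| `gc_tolerance` | 0.02 | GC fraction | "comparable GC" is not quantified anywhere authoritative; ±2 points is strict enough to matter and loose enough to keep the pool non-empty |
| `require_positions` | empty | — | optional exact-match positions; off by default because even bound regions conserve the central adenines only partially (60–70%) |
| `window_context` | 0 | bp | see below |

All coordinates are 0-based half-open (the BED convention); a breakpoint
is a single base position, and BED intervals wider than one base
contribute their start. Every random stage draws from a child stream of
one master seed (`child_seed()`), so whole runs are bit-reproducible.

## Numerical and procedural choices

* **N handling.** `N` matches nothing: it contributes a mismatch in the
  scanner and is excluded from GC denominators. Windows consisting
  entirely of `N` carry undefined GC and are barred from GC matching.
  This is conservative — assembly gaps can never inflate hit counts.
* **Edge gap.** The CpG-to-nonamer distance is the edge-to-edge gap with
  overlap mapping to 0. It is the only definition under which an
  "within 10–80 bp" pair regime and 9 bp motifs coexist without negative
  distances, and it is symmetric in feature order.
* **Window assignment.** Features belong to the window containing their
  start. Any containment rule would drop or double-count
  boundary-straddling hits; the start rule conserves totals exactly, and
  the test suite asserts that conservation at every window size.
* **`has_pair` context.** A window's pair flag asks for a CpG–nonamer
  pair (gap ≤ `pair_gap_max`) fully inside the window itself
  (`window_context = 0`). Extending the context by the breakpoint radius
  is available via the config, but at realistic CpG densities a ±100 bp
  context saturates the flag to 1 for essentially every 100 bp window,
  which degenerates every contingency contrast; per-window co-occurrence
  percentages are meaningful only when evaluated within the window.
* **Chi-square.** Closed-form Pearson statistic on the 2×2 table, no
  Yates correction by default (the correction is available by flag). The
  p-value is the upper tail of $\chi^2_1$.
* **Mann–Whitney.** U from midranks; exact p (null Wilcoxon
  distribution) for tie-free samples of at most 8, otherwise the normal
  approximation with tie correction and no continuity correction. A
  tie-degenerate variance returns p = 1.
* **t test.** Welch by default; both-samples-constant input is an error
  rather than an infinite statistic.
* **Multiplicity.** The window contrast emits three p-values; raw values
  are primary and Benjamini–Hochberg adjusted values are attached.
* **Empirical p.** Add-one convention $(1 + \#\{\text{as extreme}\}) /
  (1 + B)$: never zero, and honest at small $B$.
* **GC matching.** One control per reference window (not a match on the
  sample mean), drawn without replacement within an iteration and
  independently across iterations. Failure to find an eligible control
  names the offending window and its GC.
* **Ties in PWM consensus.** Resolved to the first base in A,C,G,T
  order; conservation is flagged at a frequency threshold in (0, 1].

## What the synthetic generator emulates — and what it does not

`generate_genome()` draws i.i.d. bases at a target GC (default 0.41,
human-like) and then optionally thins CpGs: each `CG` survives with
probability `cpg_retention` (default 0.2), otherwise its cytosine is
replaced by `T`, mimicking the deamination process that depleted the real
genome about five-fold. The default is chosen so that roughly 57% of
100 bp windows contain a CpG — the regime in which per-window CpG
statistics are informative rather than saturated.

`plant_motif()` writes a variant at an exact Hamming distance on a random
strand; `plant_pair()` writes a CpG and a plus-strand nonamer at an exact
edge gap, optionally inside a poly-C *inert filler* that carries no CpG
and no cryptic nonamer on either strand. One subtlety is baked in: the
canonical nonamer overlaps itself at shift 1 with Hamming distance 3, so
an exact plant always drags in extra hits 1–2 bp to each side, which
would perturb exact gap recovery. Pair fixtures therefore default to the
shift-resistant distance-2 variant `ACAAGTACC`, verified to produce
exactly one hit when embedded in the filler with a CpG at any gap and
order.

`simulate_breakpoints()` is a per-base Bernoulli model: rate
`lambda_frag` inside fragile footprints, `lambda_bg` outside, with
per-break provenance recorded. `make_scenario()` assembles four
ready-made studies:

* `paper_like` — 500 kb, 39 footprint windows of 100 bp each carrying a
  planted CpG followed (gap uniform on 10–80 bp) by a tandem array of
  canonical nonamers filling the window. Seven of nine tandem phases lie
  within 4 mismatches of the motif, so footprint windows carry several
  times the background nonamer density. `lambda_frag = 0.08`/base gives
  about eight breaks per footprint window against a 2e-5 background.
* `null` — 100 kb, footprints laid out but unplanted,
  `lambda_frag = lambda_bg = 0.01` (about one break per 100 bp window,
  so break-cluster windows arise by Poisson chance); used for type-I
  calibration of the pair-presence contrast.
* `promoter_fixture` — 1000 breaks placed in 2.5 kb promoters
  (TSS −2000..+500 layout) with probability 0.02.
* `cohort_fixture` — CpG-free background with 2 planted CpGs per
  lymphoid footprint window versus 1 per nonlymphoid window, so the
  designed cohort CpG ratio is exactly 2.

The generator deliberately does **not** emulate: repeat structure,
centromeres/telomeres, CpG islands (thinning is homogeneous), methylation
state, chromatin, sequence-dependent break mechanisms beyond the footprint
rate model, or the composition of any real breakpoint database. Passing
recovery tests therefore demonstrates that the pipeline measures what it
claims on data with known structure — not that any particular real genome
shows the effect, and not that real breakpoint compilations would
reproduce specific published percentages, which depend on the exact
content of those databases.

## Problem sizes used by the test suite

The suite exercises the scanner against an independently written
brute-force oracle on one hundred 5 kb sequences at GC 0.3/0.5/0.7;
recovers 200 planted motifs and 200 planted pair gaps on a 1 Mb genome;
repeats the paper-like enrichment recovery over 100 seeds (500 kb each);
calibrates the null rejection rate over 1000 simulated 100 kb datasets;
and runs the GC-matched null for 1000 iterations over a pool of 1000
windows curated to exactly 57% CpG prevalence, with a reference chosen at
39 evenly spaced GC quantiles so its GC profile represents the pool (an
arbitrary random reference would tilt the conditional CpG prevalence
wherever its GC profile happened to land). These sizes keep the entire
suite in a few minutes on one core while leaving each check enough
resolution to fail loudly if a rule regresses.

## Known limitations and open choices

* Breakpoint records are points. Where a source reports junction *pairs*,
  the table accepts one coordinate per record; whether a pair contributes
  one or two points is a per-dataset decision the caller makes when
  preparing the input.
* The scanner is exhaustive rather than index-based; at ~0.8 s per
  megabase in pure R this is adequate for the intended scale (single
  genomes, synthetic studies), not for scanning many mammalian genomes in
  a loop.
* GC matching matches GC only. Repeat content, gene density and
  replication timing are all confounders a stricter null would control;
  with synthetic i.i.d. genomes they do not exist, but on real data the
  null should be read accordingly.
* `breaks_per_mb()` reports a Pearson correlation across chromosomes; it
  is undefined (and flagged) for single-chromosome genomes or empty break
  tables.
* A heptamer (`CACAGTG`) finder is intentionally absent from the
  statistics: mutagenesis evidence shows nicking does not depend on the
  CAC, so heptamer detection contributes to no report.
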