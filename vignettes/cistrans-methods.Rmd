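---
title: "Methods: classifying cis- and trans-regulatory divergence from hybrid ASE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying cis- and trans-regulatory divergence from hybrid ASE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistrans)
```

## The model

Consider a gene in two closely related subspecies (here labelled *pse* and
*bog*, after the *Drosophila pseudoobscura* subspecies pair this workflow
was designed around). Let `mu` be its baseline expression, `c` the
cis-regulatory fold effect carried by the *pse* allele relative to the
*bog* allele, and `t` the trans-regulatory fold effect of the *pse*
cellular environment relative to the *bog* environment.

* In the **parents**, allele and environment are confounded: the expected
  expression ratio is `P_pse / P_bog = c * t`.
* In an **F1/backcross hybrid**, both parental alleles sit in one common
  trans environment, so the trans effect cancels between them and the
  expected allelic ratio is `H_pse / H_bog = c`.

Reads are assigned to a parent of origin at *fixed diagnostic SNPs* —
sites where each subspecies is monomorphic for a different allele. Three
exact tests per gene then separate the two regulatory layers:

1. **parent test** — binomial exact test of `P_pse` vs `P_bog` against
   0.5: is there any expression divergence between the subspecies?
2. **hybrid test** — binomial exact test of `H_pse` vs `H_bog` against
   0.5: is there allelic imbalance inside the hybrid (a pure cis signal)?
3. **ratio test** — Fisher exact test of `(P_pse, P_bog)` vs
   `(H_pse, H_bog)`: does the parental ratio differ from the hybrid
   allelic ratio (a trans signal)?

Each test family is corrected across genes with Benjamini–Hochberg, and
the significance flags (q below `alpha`) map to six categories:

| parent | hybrid | ratio | category      |
|--------|--------|-------|---------------|
| —      | —      | —     | conserved     |
| sig    | sig    | —     | cis_only      |
| sig    | —      | sig   | trans_only    |
| sig    | sig    | sig   | cis_and_trans |
| —      | sig    | sig   | compensatory  |
| other  |        |       | ambiguous     |

Three of the eight flag combinations have no mechanistic interpretation
under the model and fall into `ambiguous`. The broad **cis effects**
group pools `cis_only`, `cis_and_trans` and `compensatory` — every
category in which the hybrid exposes allelic imbalance.

## Filters and depth adjustment

* A SNP is *fixed* only if each subspecies shows exactly one allele
  (tri-allelic or within-subspecies polymorphic sites are rejected) and
  each allele has at least `min_support = 3` reads summed over that
  subspecies' samples.
* Replicates are summed per allele class before testing; the exact tests
  operate on single count pairs, and summing is the conservative
  aggregation when no per-replicate model is fitted.
* Genes need at least `min_reads = 20` summed parental reads
  (`P_pse + P_bog`); the boundary is inclusive.
* `adjust_depth()` rescales each of the four classes by
  `min(class_totals) / class_totals[class]`, rounds half-up to integers,
  then replaces zeros with 1 so every test is defined. The binomial null
  of 0.5 is only meaningful *after* this step. Rounding half-up (not
  banker's rounding) is used everywhere a report needs integers or fixed
  decimals, so results do not depend on parity.

## Exact-test conventions

Two-sided exact p-values are computed by the minimum-likelihood rule: the
sum of the probabilities of all outcomes (binomial) or margin-preserving
tables (Fisher 2x2, Freeman–Halton up to 2x3) that are no more likely
than the observed one. Ties are accepted up to a relative guard of
`1 + 1e-7`, the standard floating-point convention, so mathematically
equal probabilities that differ only in rounding are treated as ties.
The Freeman–Halton enumeration is capped at 2x3 tables with total at most
200; larger problems are rejected rather than approximated. `bh_fdr()`
delegates to `stats::p.adjust(method = "BH")`.

`alpha` defaults to 0.005 (q below 0.5%), taken literally from the
workflow this package operationalizes; it is exposed as an argument
because many ASE studies use 5%.

## The simulator

`simulate_regulatory_counts()` draws, per gene and replicate, a
negative-binomial class total (`size = 1/dispersion`) and splits it
binomially: the parental total has mean `mu * (1 + c*t)` and *pse*
probability `c*t / (1 + c*t)`; the hybrid total has mean `mu * (1 + c)`
and *pse* probability `c / (1 + c)`. This matches the binomial tests
applied downstream while letting totals be overdispersed. Effect
magnitudes are drawn log-uniformly from the configured fold ranges, with
direction (above vs below 1) chosen with probability 1/2;
`compensatory` forces `t = 1/c`, and `cis_and_trans` resamples away from
that manifold. The `ambiguous` category has no generative definition —
no `(c, t)` pair produces its flag patterns in expectation — so planted
"ambiguous" genes reuse the `cis_and_trans` effect structure and exist to
exercise the classifier's error paths.

Defaults are chosen as typical for a three-replicate bulk RNA-seq
experiment on a closely related subspecies pair: `mu = 500` reads per
allele class, `dispersion = 0.05`, three replicates at equal depth, and
fold effects of 4 (`|log2| = 2`). The packaged benchmark is 600 genes,
100 per category, at these settings with seed 42; on it the classifier
recovers over 80% of planted categories overall and over 90% of
conserved genes, with the shortfall dominated by the unplantable
`ambiguous` class.

Randomness is hierarchical: the single user seed derives one substream
per gene (kept below 2^31), so per-gene draws are identical regardless of
how many genes are simulated or in what order — reruns are bit-identical.

What the simulator does **not** emulate: mapping and reference bias at
SNPs, variable SNP density and the resulting loss of testable genes,
correlated replicates, library-composition effects, or linked selection
across the introgressed segment. Passing tests on synthetic data
therefore demonstrate the statistical machinery, not robustness to
alignment artefacts.

## Inheritance modes

Hybrid expression is compared with each parent; with both differential
calls in hand, a gene is `transgressive_up`/`transgressive_down` if
significantly above/below *both* parents, `non_differential` if
significant versus neither, and `additive` otherwise (significant versus
at least one parent without being transgressive — the exhaustive residual
class, i.e. intermediate expression). Production use should supply
external calls (e.g. a DESeq2 + edgeR consensus at FDR 5% and |lfc| > 1,
via `read_de_calls()`); `simple_pairwise_test()` — Welch's t-test on
`log2(count + 1)` with the same lfc rule — is a deliberate stand-in so
synthetic end-to-end runs need no external caller. Spectra of modes
between two hybrid groups are compared with the Freeman–Halton test,
either 2x2 (transgressive vs rest) or 2x3.

## Genomic distribution

Gene spans listed high-to-low are canonicalized to `start <= end`; the
inter-gene distance is the closest-edge difference
`later.start - earlier.end` (0 for overlaps), with no off-by-one
correction — the convention that reproduces all four published pair
distances from their printed coordinates. Clusters chain adjacent genes
with gaps at most `max_gap`; the default is 5500 bp because the cluster
set this tool is validated against is described as "approximately 5 kb"
and includes a 5202 bp gap that a strict 5000 bp cutoff would drop.
Densities are targets per Mb rounded half-up to two decimals with an
`autosomes` pool of all non-X chromosomes; the chi-square goodness-of-fit
supports length-proportional and uniform expectations, per chromosome or
X-vs-autosomes. Unmapped genes should be excluded from the locus table
before these operations.

## Sequence screens

A column of a two-subspecies panel is a *fixed difference* iff each
subspecies carries exactly one residue among non-missing data and the two
differ; columns containing an alignment gap in any strain are skipped
for all counts, the conservative choice when indel placement is
uncertain. Ambiguity codes are alphabet-aware missing data: `N`/`X`/`?`
for nucleotides, `X`/`?`/`*` for proteins (`N` is asparagine). A column
cannot be both fixed and polymorphic-within-a-subspecies.

Upstream windows use a TSS-anchored axis with no position 0 (`-1` abuts
`+1`, the TSS column); window coordinates count alignment columns, with
gap columns skipped only at the counting stage. Fixed counts are
monotone over nested windows by construction. Within motif-site
intervals, the screen reports fixed columns and whether the joint residue
pattern over the interval's variable columns leaves no haplotype shared
between subspecies — which can hold with no single fixed site.

Protein substitutions are numbered on the ungapped first *pse* strain
(single-protein coordinates, as in `R24K`-style nomenclature).
`diagnostic_haplotypes()` reports a small distinguishing column set found
greedily (leftmost-first growth, one right-to-left pruning pass); the set
always separates when separation is possible, but exact minimality is
not guaranteed — finding the minimum set is a set-cover-type problem and
the biological claim only needs existence.

## Problem sizes and determinism

The test suite and the reproduction script use 600-gene benchmarks,
1000-gene null simulations, 31 + 5-strain panels of up to 3200 columns,
and exhaustive exact-test verification for binomial n up to 30, all 2x2
tables to total 24 and all 2x3 tables to total 9 (with seeded samples to
total 60) — sizes chosen so a full run completes in well under a minute
per stage while leaving the statistical conclusions unchanged at larger
n. Every stochastic stage takes an explicit integer seed and is
bit-reproducible; `run_pipeline()` writes a manifest of parameters and
per-file MD5 digests so identical configs can be verified identical.

## Known limitations

* The six-category map inherits the power asymmetries of its tests:
  compensatory calls require two rejections and are harder to reach than
  cis_only at equal effect size, and `ambiguous` is a power boundary, not
  a mechanism.
* Depth adjustment assumes class totals reflect sequencing depth only;
  if one library is biologically globally shifted, rescaling absorbs the
  shift into every gene.
* The Freeman–Halton cap (2x3, total 200) suits mode-spectrum tables of
  tens of genes; larger tables need an asymptotic test outside this
  package's scope.
* Window counts use alignment columns, not ungapped reference positions;
  heavily gapped promoter alignments will report slightly different
  window extents than a reference-coordinate convention.
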