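# cistrans

Classifying cis- and trans-regulatory divergence from allele-specific
expression (ASE) in subspecies hybrids.

## The problem

When two closely related (sub)species are crossed, both parental alleles
of every gene share a single cellular environment in the hybrid.
Cis-regulatory changes (promoter/enhancer sequence differences) act on
their own allele and survive as allelic imbalance inside the hybrid;
trans-regulatory changes (divergent transcription factors and other
diffusible regulators) act on both alleles equally and cancel between
them. Counting reads by parent of origin at fixed diagnostic SNPs
therefore splits expression divergence into its cis and trans components
— a workhorse design in speciation genomics, used for example to dissect
the misexpression of gene targets of X-linked sterility factors in
*Drosophila pseudoobscura* x *D. p. bogotana* hybrid males.

With parental counts `P_pse, P_bog` and hybrid allelic counts
`H_pse, H_bog` (depth-adjusted), each gene is scored by three exact
tests:

1. binomial exact test of `P_pse` vs `P_bog` (parental divergence;
   expected ratio `c * t`),
2. binomial exact test of `H_pse` vs `H_bog` (hybrid allelic imbalance;
   expected ratio `c`),
3. Fisher exact test of `(P_pse, P_bog)` vs `(H_pse, H_bog)` (parental
   vs hybrid ratio; the trans signal),

each FDR-corrected across genes (Benjamini–Hochberg, default q < 0.5%),
and the significance pattern maps to **conserved / cis-only / trans-only
/ cis-and-trans / compensatory / ambiguous**, with a broad "cis effects"
group pooling the three cis-bearing categories.

Around this core the package provides:

* fixed-SNP calling from parental allele observations, parent-of-origin
  aggregation, read filters and depth adjustment (`call_fixed_snps`,
  `aggregate_gene_counts`, `adjust_depth`);
* inheritance-mode classification of hybrid expression (transgressive /
  additive / non-differential) and exact 2x2 / 2x3 (Freeman–Halton)
  comparison of mode spectra between hybrid groups;
* chromosomal distribution statistics: targets per Mb, chi-square
  goodness-of-fit, and detection of gene clusters chained at ~5 kb gaps;
* fixed-difference, polymorphism, and diagnostic-haplotype screens on
  two-subspecies nucleotide and protein alignment panels, including
  TSS-anchored upstream windows and motif-site intervals;
* a ground-truth simulator (negative-binomial totals, binomial allele
  split, planted loci/panels/modes) and a deterministic end-to-end
  pipeline driver (`run_pipeline`).

## Worked example

```r
library(cistrans)

# simulate the packaged benchmark: 600 genes, 100 per category,
# fold effects of 4, mu = 500, three replicates
cfg <- simulation_config(600, seed = 42)
sim <- simulate_regulatory_counts(cfg)

res <- classify_regulatory_divergence(sim$counts, alpha = 0.005)
table(truth = sim$truth$true_category,
      called = as.character(res$calls$category))
#>                called
#> truth           ambiguous cis_and_trans cis_only compensatory conserved trans_only
#>   ambiguous             0           100        0            0         0          0
#>   cis_and_trans         0           100        0            0         0          0
#>   cis_only              0             0      100            0         0          0
#>   compensatory          0             0        0          100         0          0
#>   conserved             1             0        0            0        99          0
#>   trans_only            0             1        0            0         0         99

summarize_cis_effects(res$calls)$cis_effect_fraction
#> [1] 0.6683333
```

The confusion matrix shows near-perfect recovery of the five mechanistic
categories (planted "ambiguous" genes carry cis-and-trans effects and are
called as such — that flag pattern has no generative parameters of its
own). The cis-effect fraction 0.67 matches the planted share of
cis-bearing genes (4 of 6 categories).

A distribution example on published target counts:

```r
chromosome_density(c(X = 19, `2` = 10, `3` = 11, `4` = 11),
                   c(X = 49.5, `2` = 30.8, `3` = 19.8, `4` = 27.2))
#>   chromosome n_targets length_mb density_raw density
#> 1          X        19      49.5   0.3838384    0.38
#> 2          2        10      30.8   0.3246753    0.32
#> 3          3        11      19.8   0.5555556    0.56
#> 4          4        11      27.2   0.4044118    0.40
#> 5  autosomes        32      77.8   0.4113111    0.41
```

`run_pipeline(pipeline_config(out_dir = "out", seed = 42))` executes
simulate -> ase -> classify -> inherit -> distribution -> noncoding ->
protein end-to-end, writing one TSV per result plus a manifest of MD5
digests; identical configs reproduce identical digests. A thin CLI
wrapper lives at `inst/scripts/cistrans.R`.

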