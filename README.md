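# kdrhap

Fine-scale spatial and temporal analysis of knockdown-resistance (*kdr*)
haplotypes in *Aedes aegypti*.

Pyrethroid resistance in *Ae. aegypti* is driven largely by point mutations
in the voltage-gated sodium channel gene, notably F1534C and V1016I. Because
the two codons sit close together on the chromosome, routine surveys
genotype each mosquito at both loci but cannot observe phase: a double
heterozygote (FC at 1534, VI at 1016) is compatible with the haplotype pairs
{F/V, C/I} and {F/I, C/V}. `kdrhap` is a statistical pipeline for
surveillance programmes that sample adult mosquitoes per city block across
survey rounds and need block- and sector-level haplotype frequencies, their
spatial structure, and their change through time.

## What it computes

- **Haplotype frequencies by EM.** For each sampling unit and round, the
  maximum-likelihood frequencies of the four haplotypes (F/V wild type,
  F/I, C/V, C/I double mutant) from the 3×3 table of unphased joint
  genotypes, under random mating. Only the double-heterozygote class is
  phase-ambiguous; its count is split in the E-step with weight
  2p₍FV₎p₍CI₎ / (2p₍FV₎p₍CI₎ + 2p₍FI₎p₍CV₎) and haplotype counts are
  re-tallied in the M-step. Multi-start initialisation guards against the
  stationary saddle of symmetric tables.
- **Linkage disequilibrium.** D = p₍CI₎ − p_C·p_I, r² = D²/(p_C q_C p_I q_I),
  and χ² = 2N·r² with 1 df, on the 2N sampled alleles.
- **Heterogeneity tests.** Pearson χ² on k×2 tables of haplotype copies
  across blocks or sectors (df = k − 1), pairwise Yates-corrected
  two-proportion tests with Bonferroni/Holm adjustment.
- **Spatial autocorrelation.** Global Moran's I with inverse-distance
  weights (optional row standardisation), expectation −1/(n−1), closed-form
  normality or randomisation variance, and an optional permutation test.
- **Temporal mixed models.** REML linear mixed models (via `nlme`) of
  block-level frequencies: timepoint as categorical fixed effect with the
  first survey round as reference and block nested within sector as random
  intercepts; sector-level, season, and adult-abundance variants.
- **Survey design.** Normal-approximation sample size for the two-sided
  two-proportion test, reported both as alleles and as mosquitoes per group.
- **Synthetic studies.** A generator reproducing the full sampling design
  (4 sectors split by two main roads, 24 blocks, four wet/dry rounds,
  negative-binomial per-block catches, dry-season ovitrap supplementation,
  block-level frequency heterogeneity, strong positive LD, and a dry-season
  rise in the C1534/I1016 haplotype), so every stage is testable with no
  external data.

## Worked example

```r
library(kdrhap)

study <- simulate_study(simulation_config(seed = 42))
counts <- aggregate_counts(study$records, "block")

hap <- em_haplotype_frequencies(counts[[1]])
hap
#> Haplotype frequencies (n = 52, converged after 9 EM iterations)
#>       FV       FI       CV       CI
#> 0.777462 0.011000 0.126384 0.085154

ld_statistics(hap)
#> LD: D = 0.0648, r2 = 0.2898, chi2 = 30.14 (df = 1, 2N = 104), P = 4.02e-08

tab <- haplotype_frequency_table(counts)
haplotype_heterogeneity_test(tab[tab$timepoint == "wet2014", ], "CI")
#> k-sample test of equal proportions: chi2 = 192.4, df = 23, P = 1.029e-28

panel <- build_frequency_panel(tab, "CI", sector_lookup = study$geometry)
fit_timepoint_model(panel)
#> Linear mixed model (REML, containment (inner-outer) df), 95 obs
#> Reference level: wet2014
#>               term estimate std_error df t_value   p_value
#> 1      (Intercept)  0.34070   0.04427 68   7.696 7.812e-11
#> 2 timepointdry2015  0.12989   0.02028 68   6.404 1.649e-08
#> 3 timepointwet2015 -0.03192   0.02057 68  -1.552 1.254e-01
#> 4 timepointdry2016  0.12222   0.02028 68   6.026 7.645e-08
#> Random intercept sd: sector_id = 0.06056, unit_id = 0.139 ; residual = 0.07026
```

Reading the output: in this simulated town the double-mutant haplotype
starts at a block-mean frequency of 0.34 in the first wet season; it rises
by 0.13 into the following dry season (t = 6.4 on 68 containment df), falls
back in the next wet season, and rises again in the second dry season —
the seasonal signature the pipeline is built to detect. The LD line shows
the strong positive association between C1534 and I1016 (D > 0, χ² on one
df), and the heterogeneity test shows block-to-block differences far beyond
binomial sampling noise (χ² = 192.4 on 23 df). The block-level χ²
heterogeneity at every round, the near-zero Moran's I (frequencies random
in space), and the dry-season rise around 0.11 reproduce the behaviour of
published *kdr* surveillance data at this design and scale.

`run_all()` (or the CLI in `inst/cli/kdrhap.R`) chains every stage and
writes `haplotypes.csv`, `ld.csv`, `heterogeneity.csv`, `moran.csv`,
`temporal.csv` plus a deterministic `results.json` bundle.

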