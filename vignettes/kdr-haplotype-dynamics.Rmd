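---
title: "Methods: kdr haplotype dynamics at city-block scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kdr haplotype dynamics at city-block scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdrhap)
```

## The problem

Target-site pyrethroid resistance in *Aedes aegypti* rests on two sodium
channel substitutions, F1534C and V1016I. Control programmes genotype
field-caught adults at both codons, per city block and survey round, and
ask three questions: how the four haplotypes (F/V, F/I, C/V, C/I) are
distributed across blocks and sectors, whether that distribution is
spatially structured, and how it moves between wet and dry seasons. The
genotypes are unphased, the per-block samples are small and unbalanced, and
the design is hierarchical (blocks within sectors, repeated rounds). This
vignette documents the statistical machinery the package uses at each step,
the defaults and the reasoning behind them, and what the test suite does
and does not establish.

## Haplotype frequencies from unphased genotypes

With two biallelic loci, eight of the nine joint genotype classes determine
their two haplotypes uniquely; only the double heterozygote (FC, VI) is a
mixture of the coupling pair {F/V, C/I} and the repulsion pair {F/I, C/V}.
Under random mating the complete-data model is multinomial with class
probabilities given by products of haplotype frequencies, and the EM
iteration is:

* **E-step.** Split the double-heterozygote count with weight
  $w = 2 p_{FV} p_{CI} \,/\, (2 p_{FV} p_{CI} + 2 p_{FI} p_{CV})$ on the
  coupling configuration.
* **M-step.** Re-tally haplotype counts from the eight unambiguous classes
  plus the expected split and divide by $2N$.

Because the allele margins are fully observed, the M-step preserves the
sample allele frequencies, so the whole iteration moves along a
one-parameter family indexed by the coupling-haplotype frequency $p_{CI}$,
constrained by the margins to
$[\max(0, p_C + p_I - 1),\ \min(p_C, p_I)]$.

Numerical choices:

* convergence when the largest absolute frequency change falls below
  `tol = 1e-8`, capped at `max_iter = 1000`, with a `converged` flag rather
  than an error on cap-out;
* tables without double heterozygotes are completed in a single pass
  (gamete counting is already the MLE);
* initialisation is at linkage equilibrium *plus two extra starts near the
  ends of the feasible $p_{CI}$ interval*. The extra starts matter: a table
  dominated by double heterozygotes has a likelihood symmetric in the two
  phase configurations, and the equilibrium point is then an exact
  stationary saddle from which EM cannot move. The run with the highest
  final log-likelihood is returned; for symmetric tables the two boundary
  modes tie and either is a legitimate MLE. The likelihood is logged every
  iteration and is non-decreasing within each run, which the tests assert.

The test suite compares the EM fixed point against an exhaustive
grid-search maximiser of the multinomial likelihood (step $10^{-4}$ along
the feasible interval; the margin-fixing reduction is itself validated
against a coarse full-simplex grid) on hundreds of random tables with
$n \le 20$.

## Linkage disequilibrium

With the mutant alleles C1534 and I1016 focal,
$D = p_{CI} - p_C\,p_I$, $r^2 = D^2 / (p_C(1-p_C)\,p_I(1-p_I))$, and
$\chi^2 = 2N\,r^2$ on one degree of freedom, $2N$ being the number of
sampled alleles. The $2N$ convention reproduces the printed arithmetic of
the surveillance literature this package serves (e.g. $r^2 = 0.31$ over
874 dual-genotyped mosquitoes gives $\chi^2 = 541.9$). When a locus is
monomorphic in a unit, $D$ is still defined (and reported) but $r^2$ and
$\chi^2$ are returned as `NA` with an `undefined` flag instead of a silent
0/0.

## Heterogeneity across blocks, sectors and methods

The block/sector question — does at least one unit differ? — is a Pearson
$\chi^2$ on the $k \times 2$ table of haplotype copies versus other copies,
$df = k-1$, with no continuity correction for $k > 2$. Haplotype copies per
unit are the EM-expected counts rounded to integers
($\mathrm{round}(2n\hat p)$ out of $2n$), keeping the statistic on genuine
counts; each haplotype is tested one-versus-rest. Units with no
dual-genotyped mosquitoes at a round simply drop out, which is why the df
varies between rounds (23 when all 24 blocks yielded data, 22 when one did
not).

Two-sample comparisons (e.g. indoor-caught versus ovitrap-reared adults
from the same block) use the Yates-corrected 2×2 test, correction term
$\min(0.5, |O-E|)$ so the statistic is never negative. Pairwise
unit-by-unit comparisons apply this test to every pair with Bonferroni
adjustment by default (Holm by flag): the multiplicity method is a genuine
design freedom here, and Bonferroni was chosen as the conservative,
order-independent option.

Survey design uses the closed-form normal-approximation sample size for the
two-sided two-proportion test (pooled variance under the null, unpooled
under the alternative). Whether the denominator of a published "mosquitoes
per block" figure is alleles or individuals is often ambiguous, so the
report returns both `n_alleles_per_group` and
`n_mosquitoes_per_group = ceiling(n/2)`.

## Spatial autocorrelation

Moran's I over block centroids with inverse-distance weights
$w_{ij} = 1/d_{ij}$, zero diagonal, planar coordinates (at town scale
geodesic effects are irrelevant). Row standardisation is the default, as in
the standard ecology/phylogenetics routines; raw weights are a flag. The
expectation is exactly $-1/(n-1)$. Two null variances are available:

* `"normality"` (default): the $S_1, S_2$ closed form assuming normal
  values;
* `"randomization"`: the kurtosis-corrected form, which is what
  `ape::Moran.I` uses (the package's results are cross-checked against
  `ape` under this setting in the tests).

A permutation test (`nperm` random relabellings, two-sided around the
expectation) is available as a distribution-free alternative; on small null
instances it agrees with the normal approximation in accept/reject terms in
at least 95% of cases in the test suite. Units missing a value at a round
are dropped with their weight rows/columns, and row standardisation is
re-applied to the retained units.

## Temporal mixed models

All temporal models are REML linear mixed models fitted with `nlme::lme`,
whose fixed-effect t-tests use containment (inner–outer) degrees of
freedom; the df rule is recorded in every result object so that
discrepancies with other approximations (Satterthwaite, Kenward–Roger) are
auditable rather than mysterious.

* **Timepoint model:** frequency ~ timepoint (categorical, first round as
  reference), random intercepts for sector and block within sector.
* **Sector model:** the same on a sector-aggregated panel (count-weighted
  pooling of block haplotype counts), random intercept sector only.
* **Season model:** wet/dry fixed effect (wet reference), random intercept
  block.
* **Abundance model:** frequency ~ mean adults per house, random intercept
  block, wet-season rows only (dry-season indoor catches are too sparse to
  estimate abundance).

Responses are untransformed frequencies, so effects read directly on the
frequency scale (a coefficient of 0.11 is an 11-percentage-point rise); a
logit flag exists for users who prefer a bounded link, clamping block
frequencies away from 0 and 1 by half a chromosome count. Frequencies enter
unweighted by the per-block sample size — matching the convention of the
surveillance analyses this pipeline mirrors — with `weight_by_n = TRUE`
available (residual variance proportional to $1/n$). Degenerate, noise-free
panels make the default `lme` estimation exactly singular; the fitter falls
back through alternative controls (`niterEM = 0`, then `opt = "optim"`) so
that exact-recovery cases return the exact coefficient with a residual
variance at machine zero, and a `singular` flag is set whenever the
optimiser warned.

Because the residual pools EM sampling noise across rounds with different
per-block sample sizes, the confidence intervals of the timepoint effects
tend to be mildly conservative in simulation (coverage a little above
nominal); the unweighted default trades this for comparability with the
published convention.

## The synthetic-data generator

The generator produces complete studies with the structure the analysis
assumes, and is itself first-class, tested code:

* **Design:** 4 sectors (quadrants cut by two axis roads), 5+5+5+9 = 24
  blocks on a jittered grid (centroid units are metres), four rounds
  alternating wet/dry seasons.
* **Sampling:** per-block indoor catches are negative-binomial with
  mean/sd (39.5, 22.1), (9.1, 10.9), (17.1, 15.6), (2.2, 3.1) across the
  four rounds — the over-dispersion is real (sd exceeds the mean), hence
  negative-binomial rather than Poisson, with the size parameter matched by
  moments. Dry-season blocks under 30 indoor adults are supplemented with
  35–50 ovitrap-reared adults, so dry rounds mix both methods while wet
  rounds are indoor-only. Blocks with zero catch at a wet round drop out of
  that round, which exercises the df-varying paths downstream.
* **Genetics:** block baseline haplotype simplexes are logistic-normal
  perturbations (sd 0.5 on the log scale) of sector means chosen to give
  town-wide $p_C \approx 0.55$, $p_I \approx 0.35$, positive
  $D \approx 0.14$, and a rare F/I haplotype (capped at 0.05) — the regime
  of a population where the double mutant segregates on one background.
  Individuals receive two haplotypes iid from their block's simplex
  (random mating), phase is erased, and genotype calls fail independently
  per locus at rate 0.02.
* **Dynamics:** at each dry round the logit of the block's C/I frequency
  rises by $\delta = 0.505$ and the simplex is renormalised; wet rounds
  revert to baseline. $\delta$ was calibrated once so that the
  population-mean rise is 0.11 on the frequency scale under the default
  baselines and block noise (the raw logit shift at the mean baseline
  understates the frequency-scale mean because of the curvature of the
  logistic over the block distribution). Selection is a deterministic
  shift, not a viability model — sufficient to create the temporal signal
  the mixed models estimate, and no more.

What the generator does *not* emulate: mosquito dispersal and migration
between blocks, sibling clustering among ovitrap-reared adults (method is
a label only), inbreeding within blocks (the EM assumes random mating, and
the generator honours that assumption; a departure would bias both
equally), and any response to insecticide application history. Passing
tests therefore demonstrate that the pipeline is correct *under its own
model*, not that the model captures every feature of field data.

## Problem sizes in the test and acceptance runs

The suite checks the EM against the grid oracle on 500 random tables of up
to 20 individuals; calibrates the heterogeneity test's type-I error on
10,000 null replicates and Moran's I on 1,000; and assesses recovery of the
dry-season rise on 200 replicate studies of the full 24-block, four-round
design (mean fitted dry-season coefficient within ±0.01 of the realized
mean true shift; 95% CI coverage within 95% ± 4%). These sizes give
Monte-Carlo standard errors comfortably below the asserted tolerances while
keeping a full run in the low minutes on one core.

## Known limitations

* The EM's random-mating assumption is untested against the data it is
  applied to (no Hardy–Weinberg diagnostics are computed); strongly inbred
  samples would bias haplotype estimates.
* Heterogeneity tests on EM-expected rounded counts treat estimated
  haplotype copies as observed; for very small units the rounding
  granularity is visible.
* The mixed models assume homoscedastic residuals across rounds unless
  `weight_by_n` is set; with very unbalanced designs the unweighted default
  is conservative.
* Moran's I is a single global statistic; local structure (LISA,
  variograms) is out of scope.
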