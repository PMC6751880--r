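---
title: "Single-step genomic evaluation with major-gene information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation with major-gene information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ovistep` implements the genetic-evaluation toolchain of a dairy-sheep
breeding programme in which a known causal point mutation (a major gene
affecting somatic cell score, a mastitis-resistance proxy) is exploited in
three different ways: by weighting the SNPs of a medium-density chip inside
single-step genomic BLUP, by adding the causal genotype to the chip, and by
carrying the causal allele count as a correlated trait of a bivariate
pedigree model (the Gene Content method). A gene-dropping population
simulator provides data with the statistical structure these methods
assume, so every stage is testable without animal data.

```{r setup}
library(ovistep)
```

## The models

All evaluations solve Henderson's mixed-model equations for the
repeatability animal model

$$y = X\beta + Zg + Wp + \varepsilon,$$

where $y$ holds female lactation records, $\beta$ herd-year fixed effects
(corner-point coded), $g \sim N(0, K\sigma^2_g)$ additive breeding values,
$p \sim N(0, I\sigma^2_p)$ permanent-environment effects shared by an
animal's repeated records, and $\varepsilon \sim N(0, I\sigma^2_\varepsilon)$.
For single-record traits the $Wp$ term is dropped. The relationship matrix
$K$ is either the pedigree numerator matrix $A$ (pedigree BLUP) or the
single-step matrix $H$ whose inverse is

$$H^{-1} = A^{-1} +
\begin{bmatrix} 0 & 0 \\ 0 & G^{*-1} - A_{22}^{-1} \end{bmatrix},$$

with $G$ the VanRaden method-1 genomic relationship of the genotyped
animals (observed allele frequencies, missing calls mean-imputed),
$A_{22}$ their pedigree submatrix, and $G^* = 0.95\,G + 0.05\,A_{22}$ a
blend that guarantees invertibility. No scaling parameters are applied
($\tau = \omega = 1$), and G is not tuned to $A_{22}$'s means by default;
on the simulated populations the genotyped cohort drifts little from the
founder base, so tuning changes results negligibly (a fact we verified
directly before settling the default).

### Weighted ssGBLUP

SNP effects are back-solved from the genomic EBVs of the genotyped animals,

$$\hat a = D M' (M D M')^{-1} \hat g_{gen},$$

with $M$ the centered genotype matrix and $D$ the diagonal weight matrix
(all ones in plain ssGBLUP). Each SNP's explained variance
$\hat\sigma^2_{a,i} = \hat a_i^2\, 2 p_i (1-p_i)$ becomes its raw weight.
The windowed variants assign every SNP in a non-overlapping window of $n$
adjacent markers the window's mean, maximum or sum of raw weights; weights
are then renormalised to sum to the SNP count, floored at $10^{-8}$, and a
new $G$, $H^{-1}$ and fit follow. Two iterations are the default: the
first is ssGBLUP, the second applies the variance-derived weights, and
accuracy is known to degrade beyond that as a few large windows absorb all
weight. Windows restart at chromosome boundaries and trailing short
windows keep their own statistic.

When frequencies are computed from the genotyped animals themselves the
columns of $M$ sum to zero, so $MDM'$ is singular with null vector
$\mathbf 1$; the back-solve then switches to a least-norm (SVD) solution,
which reproduces $\hat g$ up to its mean. On fixtures with externally
supplied frequencies the system is full-rank and the projection identity
$M\hat a = \hat g_{gen}$ holds to solver precision.

### The Gene Content model

For populations without chip data but with (partial) genotypes at the
causal locus, the allele count $y_T \in \{0, 1, 2\}$ is treated as a second
trait with a single mean $\mu_T$ as fixed effect:

$$\begin{cases} y = X\beta + Zg + Wp + \varepsilon \\
y_T = \mu_T + Z_T g_T + \varepsilon_T \end{cases}$$

with genetic covariance $\mathrm{cov}(g, g_T) = G_0 \otimes A$. Only the
pedigree relationship is used — combining the gene-content trait with a
marker-based $H$ would duplicate the locus information. The gene-content
genetic variance is fixed at $2\hat f_T(1-\hat f_T)$ with $\hat f_T$ the
observed allele frequency, and its residual variance at
$0.01 \cdot \sigma^2_{g_T}$: gene content is observed essentially without
error, and freeing that residual lets it collapse toward zero and
destabilises the variance-component chain (a flag frees it for users who
want to try). The fitted solutions decompose exactly:

$$\mathrm{EBV}_{polygen} = \hat g - \hat g_T \hat\alpha, \qquad
\hat\alpha = \frac{\widehat{\mathrm{cov}}(g, g_T)}{\hat\sigma^2_{g_T}},$$

with $\hat\alpha$ the allele substitution effect. The fraction of genetic
variance explained by the locus, $\hat\alpha^2 \sigma^2_{g_T} /
\sigma^2_g$, equals the squared genetic correlation algebraically; the
package asserts that identity to $10^{-10}$.

## Variance components

`gibbs_single_trait()` and `gibbs_bivariate()` estimate the (co)variance
components by Gibbs sampling. Location effects are drawn **jointly** from
their multivariate-normal full conditional using a sparse Cholesky
factorisation whose symbolic analysis is computed once and refactorised
numerically each iteration — a block implementation. We chose the joint
block draw over a single-site sweep deliberately: it removes the
autocorrelation a scalar sweep induces between thousands of location
effects, and in R it is dramatically faster because the work is done
inside CHOLMOD rather than an interpreted loop. Variances are drawn from
scaled inverse chi-square full conditionals with weakly informative priors
(4 degrees of freedom, scale at the starting values — an equal split of
the phenotypic variance); the bivariate genetic block uses an inverse
Wishart, or, when $\sigma^2_{g_T}$ is held fixed, the conditional
regression/residual factorisation of the remaining row. The slowest-mixing
direction is the $\sigma^2_g$/$\sigma^2_p$ trade-off of the repeatability
model with two records per female; chains of a few thousand iterations
with a quarter burn-in mix adequately at the problem sizes below, and all
chains are seed-reproducible.

## What the simulator emulates — and what it does not

`simulate_population()` builds:

* a hierarchical AI pedigree (few sires, many dams, discrete generations;
  default 600 founders plus four generations of 600, about 3000 animals);
* founder haplotypes with first-order-Markov LD: a latent Gaussian AR(1)
  process thresholded at each SNP's frequency. The default correlation
  0.895 was calibrated once so that mean adjacent-marker $r^2 \approx
  0.25$, the value chip studies report for their shortest-distance bin;
  `calibrate_ld_rho()` reruns that calibration. SNPs are evenly spaced at
  0.064 Mb (the chip's mean interval), so the shortest realised pair
  distance is 0.064 Mb and `ld_decay_profile()` reports only non-empty
  bins — its first bin is the adjacent-pair bin;
* gene dropping with Poisson recombination at 1 cM/Mb;
* one causal locus pinned at founder frequency 0.2 whose substitution
  effect is scaled so it explains exactly 12% of the genetic variance at
  the realised frequency — the configuration reported for the mastitis
  mutation this methodology was built around;
* genome-borne polygenic values: normal effects at every background
  marker, rescaled to $(1-0.12)\,\sigma^2_g$ on the founder base. This is
  essential, not cosmetic: if polygenic values were drawn from the
  pedigree independently of the markers, $G$'s deviations from $A_{22}$
  would be noise and genomic prediction could only lose accuracy;
* repeatability phenotypes for females (mean 3.12, phenotypic SD 1.56 — a
  lactation somatic-cell-score scale; default $h^2 = 0.3$, mid-range of
  the nine traits such programmes evaluate, and permanent-environment
  fraction 0.15; three lactations by default), herd-year effects with SD
  half a phenotypic SD (the real magnitudes are never published; this is
  a deliberately conservative choice);
* genotyped males, phenotyped females, and a validation cohort: the sires
  of the last generation, whose daughters' records
  `training_phenotypes()` withholds.

It does **not** simulate selection (the real population is under
selection, which shifts allele frequencies and biases pedigree
relationships), unknown-parent groups, a coalescent-realistic LD spectrum,
or trait networks across nine traits. Passing tests therefore demonstrate
the estimators' internal correctness and their behaviour under the stated
generative model, not performance on selected field data.

## Numerical choices

* PCG with a Jacobi preconditioner, relative-residual tolerance $10^{-10}$
  (accuracy studies use $10^{-8}$), iteration cap 10000 with an explicit
  non-convergence flag.
* Corner-point fixed effects (intercept + treatment contrasts): PCG on a
  translation-invariant singular system would otherwise return an
  arbitrary translate. EBVs are unaffected.
* Blending $\beta = 0.05$; weight floor $10^{-8}$; A-inverse by
  Henderson's rules with Meuwissen–Luo inbreeding; $A_{22}$ by the tabular
  method on the ancestor closure (never the full matrix).
* The QTL scan slides a 20-SNP window (per chromosome, never across
  boundaries), calls windows at $\ge 1\%$ of genetic variance, and merges
  overlapping supra-threshold windows into one region that reports the
  maximal window value. The scan is deterministic.

## Problem sizes used by the test and acceptance suites

Simulation studies in the shipped suites run at reduced scale, chosen so a
single CPU completes them comfortably: populations of roughly 1500–2000
animals with 400–800 SNPs on 2–4 chromosomes, Gibbs chains of 2000–4000
iterations with a quarter burn-in, 10 replicates for method-ordering
comparisons and 20 for heritability-recovery coverage. The method-ordering
study mirrors the grid-search protocol of weighted single-step studies:
windowed variants (mean/maximum/sum at two window sizes) are all fitted
and the best is selected per replicate, exactly as evaluation tables
select the best method per trait. At these sizes the expected qualitative
results — ssGBLUP above pedigree BLUP, the best windowed variant at or
above ssGBLUP, 12% explained variance recovered to within a few points —
are stable across seeds; the quantitative accuracies of the real nine-trait
programme are not reproducible from simulation and are not targeted.

## Known limitations

* No selection in the simulator (see above); allele-frequency trends under
  selection are exercised only through constructed scenarios.
* Unknown parents are treated as founders; unknown-parent groups are not
  implemented. On real selected data this choice affects bias.
* The LD profile decays by marker lag, so its shape in physical distance
  is flatter than a coalescent simulation would produce; only the
  shortest-bin level (0.25) is calibrated.
* Dosage (composite) $r^2$ is used for LD, not haplotype $r^2$; with
  phased data the two differ slightly.
* DYDs use the simplified mate-adjusted form
  $2(\mathrm{YD}_d - 0.5\,\hat g_{dam})$ averaged over daughters; real
  programmes weight daughters by record counts.
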