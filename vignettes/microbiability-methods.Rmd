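---
title: "Partitioning milk-trait variance between host genome and rumen microbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning milk-trait variance between host genome and rumen microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microbiability)
```

## The problem

Milk fat and protein percentages and the milk fatty-acid (FA) profile of
dairy cows are shaped both by the cow's own genome and by the fermentation
activity of her rumen microbial community.  Odd-chain FA are largely
synthesized by rumen bacteria; polyunsaturated C18 FA are modified by
ruminal biohydrogenation; short- and medium-chain FA are synthesized de
novo in the mammary gland under strong genetic control.  This package
quantifies the two sources of variation on the same footing by placing a
*relationship kernel* on each: the genomic relationship matrix **G** for
the host additive-genetic effect and a microbial relationship matrix **M**
for the rumen bacterial community, with an optional Hadamard-product
kernel **M∘G** for genome-by-microbiome interaction.

## Models

For animal $l$ in herd $i$ and parity $j$ with $DIM_k$ days in milk, the
variance-partitioning models are

$$y_{ijkl} = \mu + herd_i + parity_j + b_1 DIM_k + b_2 e^{-0.05\,DIM_k}
           + u_l + e_{ijkl},$$

with a single random effect $u$ per model: $\mathbf{g} \sim
N(\mathbf{0}, \mathbf{G}\sigma^2_g)$ for the genomic model or
$\mathbf{m} \sim N(\mathbf{0}, \mathbf{M}\sigma^2_m)$ for the microbial
model, plus $\mathbf{e} \sim N(\mathbf{0}, \mathbf{I}\sigma^2_e)$.  The
exponential DIM term is the standard Wilmink lactation-curve adjustment;
its decay constant is fixed at $-0.05$ per day.  The reported ratios are

$$h^2_g = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_e}, \qquad
  h^2_B = \frac{\sigma^2_m}{\sigma^2_m + \sigma^2_e}\ \text{(microbiability)}.$$

Each ratio comes from its own single-kernel model, so the denominator
deliberately excludes the other random component.  At a few hundred
animals a joint **G** + **M** fit is weakly identified (the two variances
trade off along a likelihood ridge), which is why the single-kernel
definitions are the headline quantities; `reml_fit()` accepts any number
of kernels, so the joint fit remains available.

**Kernels.** `grm_vanraden()` builds
$\mathbf{G} = \mathbf{Z}\mathbf{Z}'/(2\sum_j p_j(1-p_j))$ from additive
genotype codes centered at twice the observed allele frequency, with
missing codes mean-imputed (their centered value is 0).
`microbial_relationship()` builds $\mathbf{M} = \mathbf{B}\mathbf{B}'/c$
from the OTU count matrix after each of the $c$ OTU columns is centered
and divided by its sample SD ($n-1$ divisor).  A consequence of that
divisor is $\mathrm{trace}(\mathbf{M}) = n-1$ exactly, which the tests
assert.  The interaction kernel is the elementwise product of **M** and
**G** with no rescaling, so its diagonal is the product of the parent
diagonals rather than ~1.

## REML estimation

`reml_fit()` maximizes the restricted likelihood over the per-kernel
variances and $\sigma^2_e$ by average-information (AI) updates.  Numerical
choices:

* every variance is bounded below by $10^{-9}$ (keeps $\mathbf{V}$
  invertible while allowing effectively-zero estimates; estimates pinned
  there carry a `boundary` flag);
* an AI step that would leave the feasible region or decrease the
  restricted log-likelihood is halved up to 10 times, then replaced by an
  EM step, which always ascends, so accepted iterations are monotone in
  the log-likelihood;
* components sitting at the bound with a negative gradient are held out
  of the AI system (an active set) and re-enter when their gradient turns
  positive — without this, boundary components make the joint AI step
  oscillate and fits stall;
* convergence is declared when the maximum relative parameter change
  drops below $10^{-8}$ (at most 200 iterations);
* when the AI matrix is numerically singular (reciprocal condition below
  $10^{-10}$) the fit is flagged non-identifiable with a warning — this is
  what happens, by design, if a kernel is confounded with the residual
  (e.g. $\mathbf{K} = \mathbf{I}$).

Standard errors of $h^2_g$ and $h^2_B$ use the delta method on the
inverse AI matrix.  `profile_reml_oracle()` provides an independent check
for single-kernel models: it profiles the restricted likelihood
analytically over the scale and the fixed effects on a grid of the ratio
$\lambda = \sigma^2_k/\sigma^2_e$ (one eigendecomposition, $O(np^2)$ per
grid point), refined by golden-section search.  The test suite requires
the AI-REML ratio to match this oracle to within $10^{-3}$ relative on
random instances.

## Cross-validated prediction

Prediction is two-step.  `adjust_phenotypes()` first removes the fixed
effects by OLS; the residuals $\tilde{y}$ are then modelled with an
intercept plus kernels: M4 uses **G**, M5 uses **M**, M6 uses both, M7
adds **M∘G**.  For each of 10 replicates, 50 of the 292 animals are held
out, variance components are re-estimated on the 242 training animals,
and validation animals are predicted by the conditional expectation

$$\hat{y}_v = \hat\mu + \textstyle\sum_k \hat\sigma^2_k
  \mathbf{K}^{(k)}_{v,t} \mathbf{V}_t^{-1} (\tilde{y}_t - \hat\mu).$$

Predictive ability (PA) is the Pearson correlation between predicted and
observed $\tilde{y}$ in the validation set; RMSE is reported alongside,
both averaged over replicates.  Splits are drawn once per run and shared
across models and traits, so model contrasts are paired.  Negative PAs
are reported as-is; a replicate with constant predictions gets PA 0 with
a warning.  Models are compared per trait with one-sided Welch's t tests
on the replicate PAs — the richer model on the "greater" arm (M6 > M4:
does the microbiome add information? M6 > M5: does the genome? M7 > M6:
does the interaction?) — under Bonferroni correction with the *total*
comparison count across traits (57 for a 19-trait panel), strict
inequality at the threshold.

Two scope choices: the fixed-effect adjustment is fitted once on all
animals before splitting (the conventional two-step shortcut; it leaks a
small amount of information from validation fixed-effect levels, which is
acceptable because all models share it), and kernels are computed once on
the full animal set and subset per fold.

## The synthetic cohort

`simulate_study()` generates the study conditions the estimators assume:
292 cows in 3 herds and 2 parities, days in milk 3–398, genotypes at 5000
loci in Hardy–Weinberg equilibrium with allele frequencies uniform on
(0.05, 0.5) and 1% missingness, and 3055 rumen OTUs.  OTU counts are
Dirichlet-multinomial: OTU $j$ receives concentration
$s\, j^{-1/s}$ with dominance shape $s = 1$ by default, giving a
top-heavy rank-abundance curve (the top 5% of OTUs carry more than half
of all reads, as checked in the tests) and strong between-animal
overdispersion from the small total concentration.  Library sizes are
uniform on 50,000–100,000 reads, above the read-depth filter.  Trait
phenotypes add herd, parity and Wilmink fixed effects to random effects
drawn from the *realized* kernels, with variances set from the target
ratios by $\sigma^2_c = \sigma^2_e\, h^2/(1-h^2)$ — the same per-model
ratio definition the estimators use.  The default trait panel spans
$(h^2_g, h^2_B)$ from $(0,0)$ to $(0.7, 0.4)$.  One master seed drives
deterministic sub-streams for genotypes, OTUs, cohort structure and
effects, so adding a stage never perturbs another stage's draws and a
given configuration is bit-reproducible.

**What the generator does not emulate.**  Animals are unrelated (no
pedigree or family structure) and OTU compositions are drawn
independently per animal around one shared concentration vector.  Real
cohorts have both relatedness and community covariance between animals,
which is precisely what gives **G** and **M** their off-diagonal
structure.  A consequence worth knowing: as the number of simulated OTUs
grows, **M** converges to $\mathbf{I} + O(1/\sqrt{c})$ noise and the
microbial variance becomes weakly identified — the profile likelihood
goes flat and single-dataset estimates can land anywhere including the
boundary, with large standard errors (the same qualitative behaviour the
boundary-scale estimates and large SEs of small real cohorts show).
Recovery and CV calibration checks therefore run at 800 OTUs and
1200–1500 SNPs, where both kernels retain usable structure at
$n \approx 300$; passing them demonstrates correctness of the machinery
under identifiable conditions, not that any 292-cow dataset pins these
ratios tightly.

## Problem sizes used by the checks

Kernel algebra is verified against brute-force double loops on 10×20
inputs; REML against the profile oracle on 20 instances at $n = 30$ with
a rank-15 kernel (rank $< n$ keeps the optimum interior, so the ratio is
well defined); ratio recovery over 50 replicates at $n = 300$ (mean
$\hat{h}^2_g$ within ±0.05 of 0.5, mean $\hat{h}^2_B$ within ±0.05 of
0.3, median null estimate below 0.02 with boundary flags); CV machinery
at $n = 292$, 50 validation animals, 10 replicates; and the full pipeline
twice at 292 × 5000 SNPs × 3055 OTUs to confirm byte-identical outputs
under a fixed seed.

## Known limitations

* Single records per animal; no repeated measures or permanent
  environment effect.
* Single-trait REML only; no multi-trait or dominance/epistatic kernels.
* The Bonferroni correction treats all contrasts as one family; no FDR
  alternative is offered.
* The 50,000-read sample filter is applied to OTU-table row totals,
  a stand-in for the original read-level filter applied before OTU
  clustering, since this package starts from the OTU table.
* The delta-method SEs inherit the quality of the AI approximation near
  boundaries; SEs of near-zero ratios should be read qualitatively.
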