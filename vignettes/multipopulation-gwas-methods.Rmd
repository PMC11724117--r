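---
title: "Methods: multi-population GWAS for inbred breeding populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-population GWAS for inbred breeding populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Commercial plant-breeding programmes run several closed populations in
parallel — in barley, typically the four combinations of growth habit
(winter/spring) and row type (two-/six-rowed). Each population on its own
is often too small for well-powered genome-wide association analysis, and
strong family structure (hundreds of full-sib families from biparental
crosses, inbred as doubled haploids or by single-seed descent) makes
naive association tests anticonservative. `mpgwas` implements a
plot-level mixed-model GWAS that can combine such populations, either by
forcing a common SNP effect (MP1) or by treating the trait in each
population as a distinct, genetically correlated response and merging the
per-population SNP regressions through a scaled Wald statistic (MP2).

## The plot model

Phenotypes are modelled at the plot level:

$$
\mathbf{y} = \mathbf{X}_1\mu + \mathbf{X}_2\mathbf{l}
+ \mathbf{Z}_1\mathbf{g}_a + \mathbf{Z}_2\mathbf{g}_l
+ \mathbf{Z}_3\mathbf{w} + \sum_{j=1}^{15}\mathbf{Z}_j\mathbf{s}
+ \mathbf{e}
$$

with $\mathbf{l}$ fixed year-by-location (environment) effects,
$\mathbf{g}_a \sim N(\mathbf{0}, \mathbf{G}\sigma^2_{g\alpha})$ the
genomic breeding values under a VanRaden method-1 relationship matrix
$\mathbf{G}$, $\mathbf{g}_l \sim N(\mathbf{0}, \mathbf{I}\sigma^2_{gl})$
residual line effects, $\mathbf{w} \sim N(\mathbf{0},
\mathbf{I}\sigma^2_w)$ line-by-environment interaction, spatial effects
$\mathbf{s} \sim N(\mathbf{0}, \mathbf{I}\sigma^2_s)$ summed over a
moving window, and i.i.d. errors. The window covers the occupied cells of
a 5-column by 3-row stencil centred on the plot, truncated at trial
boundaries, so an interior plot sums 15 spatial effects and a corner plot
6. For trials without y-coordinates the spatial term is replaced by fixed
x-coordinate effects (`spatial_mode = "fixed_x"`).

Reported components follow the field convention for inbred material: the
additive component is multiplied by the mean diagonal of $\mathbf{G}$
(about 2 for fully inbred lines), and the per-plot spatial component by
15 for the window sum. Heritabilities divide the (broad: additive + line;
narrow: additive) genetic variance by the phenotypic variance, at plot
level (all five reported components summed) and at entry level (GxE
divided by the number of environments $n_e$; spatial and error by the
average number of replicate plots per line $n_r$). We define $n_r$ as
total plots over (lines x environments); whether the convention should
instead count replicates within single environments is ambiguous in the
field, so the choice is stated here rather than inferred.

```{r}
library(mpgwas)
vc <- dplyr::filter(barley_varcomp(), population == "6RW",
                    trait == "heading_date")
heritability(vc, n_e = 9, n_r = 2)
```

## REML engine

All models are linear in their covariance parameters,
$\mathbf{V}(\theta) = \sum_k \theta_k \mathbf{V}_k$, which uniformly
covers the univariate plot model, bivariate trait models (additive and
residual covariance between traits on shared plots) and cross-population
models (additive covariance through the cross-population blocks of the
joint $\mathbf{G}$; no residual or GxE covariance across populations,
which share no plots). `reml_fit()` maximises the restricted likelihood
with average-information updates,
$\mathrm{AI}_{jk} = \tfrac12 (\mathbf{V}_j\mathbf{Py})' \mathbf{P}
(\mathbf{V}_k\mathbf{Py})$, taking the AI step on a log scale for
variances (which keeps them positive and conditions the information
matrix) and linearly for covariances, with step halving and an
expectation-maximisation fallback whenever a step would leave the
parameter space or decrease the likelihood. Covariance parameters are
kept inside $0.999\sqrt{\theta_i\theta_j}$ of their paired variances so
the corresponding block structure stays positive semi-definite —
without this guard the optimiser can stall crawling along the
positive-definiteness boundary. Convergence is declared when the
relative change in restricted log-likelihood falls below `tol`
(default $10^{-8}$); components are floored at $10^{-10}$; standard
errors come from the inverse AI matrix at convergence. Non-convergence
raises an error carrying the likelihood trajectory.

Exactness is checked against closed-form ANOVA estimators on balanced
one-way designs, against brute-force GLS and Henderson mixed-model
equations on instances small enough to invert explicitly, and against
lme4 on a model both can fit.

## Association testing

GWAS adds each SNP's alt-allele dosage as a fixed regression to the plot
model. Variance components are estimated once under the no-SNP null and
reused for all SNPs (the P3D convention); each SNP's coefficient and
standard error then come from generalised least squares through the
null-model projection. An exact per-SNP refit is available behind
`refit = TRUE` for validation. The alt allele of the unified VCF is the
effect allele in every population, so signs are comparable across
populations.

Three modes are provided:

* **single**: within one population, SNPs with minor allele count (MAC)
  at least 30;
* **MP1**: combined populations, one shared coefficient, environments
  nested within populations as fixed effects, joint $\mathbf{G}$; SNPs
  need total MAC $\ge$ 30 and MAC $\ge$ 10 in every population;
* **MP2**: one response per population with additive covariance across
  populations; per-population coefficients
  $\hat b_{i,j}$ and their estimation-error covariances come from the
  inverse coefficient matrix of the joint GLS system and are merged as
  $$b_{scaled,i} = \sum_j \hat b_{i,j}/SE(\hat b_{i,j}), \qquad
  SE = \sqrt{\mathbf{a}'\mathbf{V}_i\mathbf{a}},$$
  where $\mathbf{V}_i$ has unit diagonal and scaled covariances
  $\mathrm{cov}(\hat b_{i,j}, \hat b_{i,k}) / (SE_j SE_k)$ off the
  diagonal; $z_i = b_{scaled,i}/SE$ is referred to the standard normal.

Significance uses Bonferroni control at $\alpha = 0.05$ over the number
of SNPs tested in the run (the published barley panel of 12,644 SNPs
gives $3.95\times10^{-6}$, $-\log_{10} = 5.4$). Significant SNPs merge
into candidate QTLs while successive gaps are at most 5 Mbp (the
published intervals are delimited by visual peaks, which is not an
operational rule; the gap threshold is ours). The proportion of additive
genetic variance explained by a marker is
$2p(1-p)\hat b^2 / \sigma^2_{g\alpha}$ with the *raw* (pre-adjustment)
additive variance in the denominator.

## LD, LPS and power

Pairwise LD is the Pearson correlation of dosages; the kinship-corrected
$r_v$ is the generalised-least-squares correlation under
$\mathbf{K} = \mathbf{G} + 10^{-6}\,\overline{\mathrm{diag}}\,\mathbf{I}$
(the ridge guards against rank-deficient $\mathbf{G}$ from few markers);
with $\mathbf{K} = \mathbf{I}$ the two coincide exactly. Decay curves
bin intra-chromosomal pairs into left-closed 10-kbp intervals and report
the mean squared correlation per bin; the decay distance is the first
linear interpolated crossing of 0.2 between consecutive bin means,
anchored at (0 bp, 1). Linkage phase similarity between two populations
is the cosine similarity of signed $r_v$ values over shared pairs per
bin, and a windowed scan (1 Mbp, step 0.5 Mbp) flags windows with
negative LPS as candidate reverse-phase regions.

Theoretical power evaluates, for each SNP and each hypothetical effect
$b$ from 0 to $\sqrt 2$ in steps of 0.01 (values stored at 2 decimals,
so the grid ends at 1.41, the last step below $\sqrt 2$), the
non-central $\chi^2_1$ tail beyond the central $1-\alpha$ quantile with
NCP $(b/SE)^2$ — for MP2, the scaled coefficient's NCP — and averages
power over SNPs with MAC $\ge$ 30 in all populations. Standard errors
always come from an actual GWAS run, never from an analytic
approximation.

## The simulator

`simulate_breeding_data()` generates the validation data: ancestral
allele frequencies $\sim U(0.05, 0.5)$, Balding–Nichols divergence per
population (parameter `fst`), founder haplotypes sampled site-wise,
biparental crosses with Poisson crossover counts on a uniform 1 cM/Mbp
map (no interference), and either doubled-haploid or single-seed-descent
(F1 selfed to F4, genotyped at F5-equivalent, leaving $(1/2)^4$
residual heterozygosity) inbreeding. Chromosomes default to 150 Mbp —
the genetically active portion of a barley chromosome at this map
density rather than its full physical length. Polygenic values are built
from per-SNP marker effects drawn with a configurable correlation
matrix across populations (and traits), scaled so the additive values
satisfy $\mathbf{g} \sim N(\mathbf{0}, \mathbf{G}\sigma^2_{g\alpha})$
exactly under the population's own $\mathbf{G}$; QTLs add
population-specific dosage effects on top, and the generator records
every component of the truth. Phenotypes are composed per plot as
population mean + environment effect (drawn once per year-location from
$N(0, 2^2)$ and held fixed) + breeding value + line effect + GxE +
spatial window sum + error; all randomness flows from one generator
seeded once, in documented order (frequencies, haplotypes, meioses
population-by-population, marker effects, then plot-level draws).

What the generator does *not* emulate: alpha-lattice randomisation,
selection across cycles, genotyping error or missingness patterns, and
LD shaped by decades of recombination in a closed programme (family
structure dominates the simulated LD, as it does in the real data, but
ancient recombination does not). Passing tests therefore validate the
estimators under the stated model, not the full complexity of field
data.

## Validation studies and their sizes

The `experiment_*()` functions fix the study conditions used by the test
suite and the acceptance script:

* *Null calibration*: 2 populations x 144 lines, ~2400 SNPs, no QTLs
  but a real polygenic background that the models must correct through
  the genomic relationship matrix (the per-SNP null of a heritable
  trait); type-1 error at 0.05 and KS uniformity for all three modes.
  Under the *complete* null (polygenic variance also zero) P3D testing
  is conditionally conservative at these sizes: the null REML sometimes
  absorbs structure-aligned noise into the additive component and
  overcorrects exactly the SNPs being tested, so per-data-set type-1
  error scatters on the conservative side of nominal far beyond
  binomial noise. This is a known cost of fixing null-model components
  and is why the calibration study keeps a polygenic background.
* *Recovery*: 500 DH lines, 6 environments, 2 replicates, 10 x 25-plot
  trials, components 3.80/0.21/1.20/0.77/0.49 — the published heading
  date analysis of the six-row winter population; three replicate
  simulations (warm-started to reuse the previous optimum), summarised
  by the median relative error over components and seeds. The small
  line component (0.21) carries an REML standard error near 0.12 at
  this size, so its individual relative error is dominated by sampling
  noise; per-component medians are reported alongside.
* *Cross-population correlation*: 2 x 400 lines in 40 full-sib families
  each, marker-effect correlation 0.76; the estimate is the median of 5
  replicate fits because a single fit's Monte Carlo standard deviation
  (~0.16, limited by the number of families rather than lines) is of
  the same order as the target tolerance.
* *Method contrast*: 2 x 150 lines, one shared QTL placed on the most
  frequency-balanced SNP with MAC >= 30 in both populations, effect
  0.55 trait units — about 3.3 null-model standard errors, the
  operating point that maximises the probability of the
  "MP2-significant but single-population-insignificant" outcome. Note
  that with per-population scores $z_j \sim N(\mu, 1)$ and threshold
  $t \approx 3.9$ this probability is bounded near 0.5 for every
  $\mu$: the combined score gains only $\sqrt 2$, so a deterministic
  per-replicate contrast would require thresholds far beyond any
  realistic panel. The per-replicate outcome is therefore intrinsically
  stochastic, and the experiment reports rates.
* *MP1 attenuation*: 100 vs 400 lines, QTL only in the small
  population; the MP1 estimate is compared with the small population's
  own estimate.
* *Power agreement*: 10 independent blocks of 200 lines; each block
  fits its own null model (components then held fixed within the block,
  the same P3D convention as the scans) and contributes 40 phenotype
  replicates redrawn from the generator's stochastic model on the
  block's design. The probe effect is placed where the first block's
  theoretical curve predicts 60% power; blocking averages out per-fit
  error in the null components, which a single-fit design inherits as a
  systematic offset between theoretical and empirical power.

These sizes were chosen as the smallest faithful versions of the study
conditions; all are exercised by `tests/testthat/test-acceptance.R` and
recomputed by `scripts/acceptance.R`.

## Numerical choices and limitations

Missing dosages are mean-imputed per SNP within the analysis subset
before GRM construction and scanning; GRM allele frequencies always come
from the analysis subset (the merged set for multi-population runs).
PCA for outlier removal runs on centred, unstandardised dosages, and a
line is removed when its PC1–PC3 position is closer to another
population's median than to its own. Ordinal scores (like 1–9 lodging)
are treated as Gaussian. The engine holds every $\mathbf{V}_k$ densely,
which is comfortable to a few thousand plots per fit but is not designed
for hundred-thousand-plot data sets; autoregressive spatial models and
non-Gaussian traits are out of scope.
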