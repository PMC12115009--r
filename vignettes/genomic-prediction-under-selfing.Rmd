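---
title: "Genomic prediction in partially selfed populations: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction in partially selfed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`selfpred` implements the analysis stack used in genomic selection studies
of partially self-fertilized tree breeding populations — the setting of
*Eucalyptus* inbred-line programs, where commercial clones are selfed, the
resulting seedlings are a mixture of selfed and pollen-contaminated
outcrossed individuals, and the goal is to rank unphenotyped orchard
candidates by genomic estimated breeding value (GEBV). This vignette is the
package's own account of the models it fits, the synthetic populations it
generates, and the numerical and design decisions behind both.

## The mixed models

All four frequentist models share the linear mixed model

$$y = X\beta + Zu + \varepsilon,\qquad
  u \sim N(0, K\sigma_a^2),\quad \varepsilon \sim N(0, I\sigma_e^2),$$

where $y$ holds the phenotypes (DBH in cm), $\beta$ the fixed effects
(general mean and field blocks — the trial layout is a randomized complete
block design with one plant per plot, so there is no plot term), and $u$
the genetic values whose covariance is proportional to a relationship
matrix $K$:

* **ABLUP** — $K = A$, the pedigree numerator relationship matrix from the
  tabular method with inbreeding ($a_{ii} = 1 + \tfrac12 a_{sd}$). One
  selfing generation from a non-inbred parent gives $F = 0.5$; $t$
  generations give $F = 1 - (1/2)^t$.
* **GBLUP** — $K = G$, VanRaden method 1:
  $G = ZZ'/(2\sum_j p_j(1-p_j))$ with $Z$ the dosage matrix centred at
  $2p_j$. Allele frequencies are computed from the analysed sample (the
  study population is the only available reference; see *Open choices*).
* **GBLUP-AD** — adds a second random term $v \sim N(0, D\sigma_d^2)$ with
  the classical (Vitezica-style) dominance matrix: design entries
  $(-2p^2,\; 2pq,\; -2q^2)$ for dosages $(0,1,2)$ and
  $D = WW'/\sum_j (2p_jq_j)^2$.
* **HBLUP** — $K = H$, the single-step matrix blending $G$ with the
  pedigree: $G^* = (1-w)G + wA_{22}$ (default blend $w = 0.05$), the
  genomic correction propagated to non-genotyped relatives through the
  Legarra/Christensen projection. `tau`/`omega` scalings of
  $G^{*-1}$/$A_{22}^{-1}$ are exposed for the inverse-based form.

### REML

Variance components are estimated by EM-REML. For a single random term the
model is rotated into the eigenbasis of the observed kinship block, where
every EM iteration costs $O(np^2)$; the two-term additive + dominance model
uses the dense $V^{-1}$ form. EM updates are accepted under a guarded
Aitken extrapolation: the accelerated step is taken only when it does not
decrease the restricted likelihood, so the EM monotonicity guarantee (which
the test suite asserts iteration by iteration) is preserved. Components are
clamped at $10^{-8}$; iteration stops when the maximum relative parameter
change falls below $10^{-6}$ or the REML log-likelihood is stationary to
$10^{-9}$ relative — the latter matters because a component heading to the
boundary decays multiplicatively and would otherwise creep for thousands of
iterations after the fit has effectively converged. Near-singular kinships
(selfed populations contain near-duplicate genotypes) are handled by
flooring the kinship spectrum at $10^{-8}$ and, in the dense path, a
$10^{-6}$ diagonal ridge at inversion time; the ridge is *not* stored in
the built $G$/$D$ matrices, so their definitional values are exact.

GEBVs are reported for **every** individual in the kinship matrix:
unphenotyped candidates (the orchard set) enter with empty rows in $Z$, and
their BLUPs are $\hat u = \hat\sigma_a^2 K_{\cdot,\mathrm{obs}} P y$ — the
standard extension that propagates information through relationships.

## The Bayesian alphabet

The five whole-genome regressions model the phenotype, pre-adjusted for
intercept and blocks by OLS, as $y = X\beta + \varepsilon$ with $X$ the
centred dosage matrix and model-specific priors on marker effects
$\beta_j$:

| model | prior on $\beta_j$ |
|---|---|
| BRR | $N(0,\sigma_\beta^2)$, one common variance |
| BayesA | $N(0,\sigma_{\beta j}^2)$, per-marker scaled-inv-$\chi^2$ variances |
| BayesB | point mass at 0 w.p. $\pi$, else per-marker variance |
| BayesC | point mass at 0 w.p. $\pi$, else common variance |
| BL | Laplace via the normal–exponential scale mixture |

Variances follow scaled-inverse-$\chi^2(\nu, S)$ priors; the BL penalty
$\lambda^2$ follows a Gamma prior with per-marker latent scales updated by
inverse-Gaussian draws (Park–Casella parameterization). Fixed effects are
pre-adjusted rather than jointly sampled so the marker design is exactly
the genotype matrix; a `sample_mu` flag adds an intercept to the chain for
users who prefer joint sampling.

Defaults (all configurable): `n_iter = 20000`, `burn_in = 2000`,
`thin = 5`; $\nu_\beta = \nu_e = 5$ with scales solved from the heuristic
that markers explain $R^2 = 0.5$ of the phenotypic variance a priori;
$\pi = 0.99$ fixed for BayesB; $\pi$ estimated for BayesC under a
Beta(1, 9) prior; BL shape $a = 1.1$ with rate matched to the prior mode of
$\lambda^2$. The samplers are single-site Gibbs in compiled code drawing
from R's RNG, so chains are bit-reproducible under `set.seed()`. The test
suite validates the BRR chain against the closed-form ridge posterior with
fixed variances, the BayesC$\to$BRR degeneracy at $\pi = 0$, and the exact
all-zero chain at $\pi = 1$.

## Cross-validation and metrics

`kfold_cv()` winsorizes the phenotype once at the lower 5th percentile
(one-sided, matching the practice of clamping only low-DBH outliers),
shuffles the phenotyped ids under the given seed, and deals them
round-robin into $k = 10$ folds. Relationship matrices are built once on
all individuals; inside a fold only the held-out *phenotypes* are masked,
mirroring the orchard use case where candidates are genotyped but
unmeasured. Held-out predictions are fixed-effect estimates plus genetic
values; three metrics are computed per fold and aggregated as mean ± SD:
predictive capacity (Pearson correlation of predicted and observed), mean
squared error, and $R^2 = 1 - SS_{res}/SS_{tot}$ about the validation-set
mean (negative values allowed). All models are evaluated on one common
phenotype scale. Published tables in this literature sometimes report
Bayesian MSEs on a visibly different scale from frequentist ones
(pre-adjusted versus raw responses); the package deliberately does not
reproduce such a mixture.

The winsorization quantile uses linear interpolation between order
statistics (R type 7, recorded in the CV report metadata). One caveat:
with an interpolated quantile, winsorization is exactly idempotent only
when $(n-1)p$ is integral — otherwise a second pass can nudge
already-clamped boundary values upward by the interpolation gap.

## The synthetic-data generator

Because breeding data of this kind are proprietary, every analysis stage
is exercised on simulated populations with the structure the models
assume. Defaults emulate the study system: 28 parent clones, 1–33
offspring per parent, a 62% selfing rate, ~10,000 SNPs on 11 chromosomes,
a DBH-like trait with mean 12.25 cm and phenotypic SD 4.18 cm, $h^2 = 0.4$
(the middle of the 0.3–0.7 range reported for DBH), a dominance proportion
of 0.1, 30 field blocks, a 2% lower-tail outlier rate, 1% genotyping
error, 2% missingness, and 62 unphenotyped orchard candidates.

* **Founder LD** — haplotypes come from a latent Gaussian AR(1) process
  thresholded at per-locus target frequencies: a first-order Markov chain
  on alleles whose single knob (`adjacent_ld_rho`) controls adjacent-locus
  correlation while allowing arbitrary marginal frequencies above
  `maf_floor`. Loci monomorphic in the finite founder sample are redrawn
  independently (breaking LD only at those columns).
* **Meiosis** — Haldane model without interference: 100 cM per chromosome
  mapped linearly onto `chrom_length_bp`, Poisson(1) crossovers per
  gamete.
* **Trait** — marker effects are Gaussian on all markers (or on `n_qtl`
  markers for sparse architectures); additive and dominance components
  are scaled so their realized variances match $h^2\sigma_P^2$ and
  $d^2\sigma_P^2$, and the residual variance is set to
  $(1 - h^2 - d^2)\sigma_P^2$, so realized narrow-sense heritability
  matches the configuration.
* **Imperfections** — genotyping errors redraw the call from the marker's
  Hardy–Weinberg distribution (the same error concept the paternity LOD
  assumes); outliers are injected only in the lower tail, which is what
  one-sided winsorization is designed to absorb; truth is stored before
  errors, so parameter-recovery tests are exact.

What the simulator does **not** emulate: selection over generations,
epistasis, genotype-by-environment interaction, population structure
beyond one generation of mixed selfing/outcrossing, and real genome
coordinates. Passing tests therefore demonstrate correctness of the
machinery and qualitative behaviour (e.g. selfing raises LD; genomic
kinship beats pedigree kinship when markers are informative), not
quantitative transfer to any particular field trial.

## LD and paternity

Pairwise LD is the squared Pearson correlation of dosage vectors
(composite, unphased $r^2$ — appropriate because genotypes are unphased);
the gametic $D$ from two-locus EM haplotype frequencies is available on
request. Decay curves are distance-binned means. When comparing LD between
groups of different size (founders vs selfed progeny), the package's own
validation subsamples to matched $n$, because the $\approx 1/n$
small-sample inflation of $r^2$ otherwise dominates the contrast.

Paternity assignment uses the known-mother LOD with genotyping error
$e$: per locus,
$\log\frac{(1-e)\,T(g_o \mid g_m, g_c) + e\,\mathrm{HWE}(g_o)}
          {(1-e)\,T(g_o \mid g_m, \text{random father}) + e\,\mathrm{HWE}(g_o)}$,
summed over the marker subset (the 723 most polymorphic markers by
expected heterozygosity $2pq$, ties broken by MAF then id). The Δ statistic
is the difference between the two best candidates' LODs; its significance
threshold is simulated (default 10,000 replicates): offspring of known
parents are generated from the candidate pool with the same error rate,
and `delta_critical` is the smallest Δ at which the assignments exceeding
it reach the requested 80% success rate. A stricter 95% level is available
but off by default; all candidates are assumed genotyped at all subset
loci, which matches a breeding-orchard design and simplifies the full
Cervus-style simulation.

## Problem sizes used in validation

The packaged validation runs at sizes chosen to make the statistical
properties identifiable while keeping a laptop-scale footprint: solver
oracles on $n \le 30$ with 20 random fixtures; the fixed-variance BRR
check on $n=50, m=20$ with 50,000 iterations; heritability recovery and
the GBLUP≥ABLUP cross-validation ordering on 20 replicates of ~600
individuals × 2,000 markers; the selfing-LD contrast on 10 replicates of
24 founders × 600 markers; paternity accuracy on 1,000 offspring × 20
candidates × 500 markers at a 5% error rate.

## Known limitations

* EM-REML, while unconditionally stable, is slower than AI-REML on large
  dense problems; the eigenbasis path mitigates this for single-kinship
  models only.
* Mean imputation is adequate for relationship matrices but not a
  substitute for proper genotype imputation at high missingness.
* The Bayesian samplers are single-chain; diagnostics are effective sample
  sizes, not cross-chain $\hat R$.
* `build_H` with `tau`/`omega` ≠ 1 forms dense inverses and is intended
  for populations of at most a few thousand individuals.
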