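---
title: "Methods: latent-factor SEM multi-trait GWAS and colocalization"
author: "semscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent-factor SEM multi-trait GWAS and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

semscan analyses symptom-complex phenotypes — collections of correlated
questionnaire items thought to reflect one underlying condition, the motivating
case being computer vision syndrome (digital eye strain) — with a multi-trait
genome-wide association scan built on a one-common-factor structural equation
model.  This vignette is the package's account of the statistical machinery:
the models, the tunable parameters, the numerical choices, and what the test
suite does and does not establish.

## The measurement model

Each subject answers 14 items on a 1–7 scale under two conditions ("after
sustained eye use" and "after little eye use"); the per-item difference
(delta score, range −6…+6) is the analysed response.  Items map to four
symptom categories — asthenopic (q1–q3), ocular-surface-related (q4–q7),
visual (q8–q9), extra-ocular (q10–q14) — and each category score is the mean
of its member items' deltas.

The four category scores $y_k$ are modelled as indicators of a single latent
severity factor $F$:

$$y_k = \nu_k + \gamma_k F + \varepsilon_k,\qquad
\varepsilon_k \sim N(0, \delta_k),\qquad k = 1,\dots,4 .$$

Identification fixes the latent variance to 1 (the factor sign is resolved by
$\gamma_1 \ge 0$).  Estimation is maximum likelihood on the multivariate
normal likelihood; with four indicators and no covariates the model has 8 free
covariance parameters against 10 moments, so the fit statistic
$(N-1)\,F_{ML}$ is referred to $\chi^2_2$.  RMSEA is
$\sqrt{\max(\chi^2 - df, 0)/(df\,(N-1))}$ with a confidence interval obtained
by inverting the noncentral chi-square distribution (default coverage 0.90 —
the printed interval of the motivating study cannot be reproduced from its
printed numbers under any standard coverage, so the level is an explicit
parameter and no claim is made to match that interval).

Two deliberate conventions, made where the underlying convention was not
stated: fit statistics use the post-QC sample size (recorded as `n_obs` in
every fit object so the 1998-respondents vs 1966-post-QC ambiguity is
auditable), and estimation is complete-case (the count of used cases is also
recorded).  A model with a mean/covariate structure reports
$df = 2 + 3q$ for $q$ covariates; the package derives df from its own model
specification rather than forcing any published value.

## The per-variant model

For each variant the dosage $g$ and the covariates $w$ (age, sex, and
stratification PCs) enter as exogenous predictors of the latent factor:

$$F = \beta g + c^\top w + \zeta,\qquad \zeta \sim N(0, 1),$$

leaving the measurement part unchanged.  Covariates act on the latent factor
only, not on individual indicators.  The reported effect is $\beta$ with a
Wald test $p = 2\Phi(-|\beta/\widehat{se}|)$, standard errors from the inverse
observed information.  All likelihood evaluations are reduced to cross-product
moments of $(y, w, g)$, so the optimizer's cost per variant does not grow with
sample size.

Numerics: L-BFGS-B with analytic gradients; residual variances are
box-constrained at $10^{-6}$ (a fit ending on that bound is flagged as a
Heywood case); convergence uses `factr = 1e5` with a projected-gradient
tolerance of $10^{-10}$, and up to five deterministically jittered restarts on
failure.  Every genome-wide fit warm-starts from the no-SNP measurement fit.
The `factr` value matters: a much looser setting allows the optimizer to stop
with $\hat\beta$ still shrunk toward its zero start, which deflates the scan's
test statistics by several percent; the chosen setting reproduces a
reference fit at `factr = 100` to $|\Delta z| < 0.02$ at a quarter of the
cost, and the suite's null-calibration test guards this.

## Model specification diagnostics

Before any confirmatory fit, the item-level structure is examined:

* **Partial correlations** between items,
  $\rho_{ij\cdot\text{rest}} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$
  with $\Omega$ the inverse correlation matrix.  A ridge of $10^{-6}$ may be
  added to a singular correlation matrix (always logged).  A one-factor
  structure with positive loadings implies all-positive partials.
* **Covariance selection**: a Gaussian graphical model search that prunes
  weak conditional dependencies.  Candidate edges are examined in increasing
  order of |fitted partial correlation|; each tentative removal is refit by
  iterative proportional fitting over the edges (convergence $10^{-8}$, cap
  10,000 sweeps; rank-one/rank-two Woodbury updates of the implied covariance
  inside each sweep) and accepted only if it lowers
  $AIC = -2\ell + 2(\text{free parameters})$; the search stops when no single
  removal lowers the AIC, and the accepted AIC trace is strictly decreasing
  by construction.  A caution documented here because it is a property of the
  criterion, not of the code: removing a truly-absent edge changes the
  deviance by roughly a $\chi^2_1$ draw, so an AIC search retains each absent
  edge with probability $P(\chi^2_1 > 2) \approx 0.157$ *regardless of sample
  size*.  Exact recovery of a sparse graph is therefore capped (for a 5-node
  chain, at about $0.84^6 \approx 0.36$); AIC deliberately trades parsimony
  for predictive fit.  The `penalty` argument accepts $\log n$ for BIC-type
  selection, which is model-selection consistent, but the package default
  remains the AIC that defines the method.
* **Item PCA** on the partial correlation matrix, with coordinates scaled by
  the square roots of eigenvalues, and a **clique diagnostic**
  (Bron–Kerbosch on edges above a threshold, default 0.2): a dense clique of
  strong partials would suggest a second latent factor and argue against the
  one-factor model.

## Genome-wide scan, genomic control, loci

`run_scan()` fits the per-variant model for every polymorphic variant
(monomorphic and non-converged variants are excluded and counted).  Genomic
control computes $\lambda_{GC} = \mathrm{median}(z^2)/0.4549364$; when
$\lambda_{GC} > 1$ statistics are deflated to $z^2/\lambda_{GC}$, otherwise
p-values are left untouched (the standard one-sided convention, recorded in
the output either way).  Lead variants are those below the suggestive
threshold $10^{-5}$ (genome-wide $5\times10^{-8}$ is annotated in all
exports); loci are built greedily best-p-first, absorbing panel variants
within ±500 kb having $r^2 > 0.6$ with the lead (composite LD: squared
Pearson correlation of dosages), so every variant belongs to at most one
locus and an isolated lead yields a single-position locus.  Both raw and
adjusted p-value columns are emitted because published locus counts can be
defined on either.

## Colocalization

For a locus region (default ±100 kb flank), per-variant Wakefield log
approximate Bayes factors are

$$\mathrm{lABF} = \tfrac12\left[\log(1-r) + r z^2\right],\qquad
r = \frac{W}{V + W},$$

with $V = se^2$ and prior effect variance $W = 0.15^2$ for quantitative
traits; summary data lacking $(\beta, se)$ use $z$ from the p-value and
$V \approx 1/(2 n\,\mathrm{maf}(1-\mathrm{maf}))$.  The five-hypothesis sums
(no signal / GWAS only / eQTL only / distinct causal variants / one shared
causal variant) are accumulated in log space (log-sum-exp), so regions with
lABF up to several hundred remain finite; posteriors sum to one within
$10^{-12}$.  Priors default to $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ —
the reference defaults for this method family, configurable and echoed in
every result.  Variants are matched by id; batch mode flags PPH4 > 0.5 as
reported and > 0.75 as strong, the conventional interpretation thresholds.

## The synthetic cohort generator

No individual-level data of the motivating study are public, so the generator
is a first-class module reproducing its statistical structure:

* **Genotypes**: per-variant MAF uniform on a configurable range, two
  haplotypes per subject from a block-wise Gaussian AR(1) copula
  (`ld_block_size = 20`, `ld_rho = 0.8` by default) thresholded at
  $\Phi^{-1}(\mathrm{maf})$ — every variant is in HWE and within-block $r^2$
  decays with distance.  This is a controllable caricature of LD, not a human
  LD map.
* **Phenotypes**: the SEM run forward.  Latent
  $F = \sum \beta_j (g_j - \bar g_j) + 0.1\,\mathrm{age}_z + 0.1\,\mathrm{sex}_z + \zeta$,
  standardized; category scores $y_k = \gamma_k F + \sqrt{1-\gamma_k^2}\,e_k$
  with default loadings (0.842, 0.657, 0.787, 0.823) — the study's reported
  estimates treated as generator truth.  Each item adds idiosyncratic noise
  (sd 0.25); the "before" response thresholds a baseline propensity through
  six cut points (default an even grid chosen so the before-condition mean
  sits near 2 on the 1–7 scale, matching the study's marginal), and the
  "after" response thresholds the same propensity shifted by
  `likert_shift + likert_scale * item score` (defaults 2.0 and 1.3, placing
  the mean delta near 2.65 and its spread near the study's).  Sharing the
  baseline propensity makes the delta a dithered quantization of the item
  score, so category deltas track the continuous truth with correlation
  above 0.9.
* **eQTL panels**: an independent cohort on the same variant panel, with the
  expression causal variant equal to the GWAS causal variant ("shared"), a
  different variant in the same LD block ("distinct"), or absent ("null").
* Age (normal around 49, truncated to 20–79) and sex (~50% male) follow the
  study's marginals loosely; their exact distributions are free parameters.
  Ground truth (latent scores, causal map, continuous category scores) is
  exported as a sidecar table so recovery tests never reach into generator
  internals.

What passing tests show — and do not.  Ordinal thresholding attenuates
the observed category-score loadings by a few percent relative to the
continuous truth; this is a property of any Likert instrument, and the
study's own published loadings already live on the observed-ordinal scale.
Loading-recovery checks therefore validate the estimator on data drawn from
the model's own multivariate-normal law, while the SNP path coefficient
$\beta$ — which measurement noise dilutes into the residuals without bias —
is validated through the full questionnaire pipeline.  Null-scan calibration
is checked on LD-free panels because both the KS uniformity test and the
sampling band for a median-based $\lambda_{GC}$ presuppose independent
statistics; LD-structured panels are exercised by the locus-definition and
power tests.  None of this establishes behaviour under real human LD,
genuinely ordinal analysis misspecification, population substructure beyond
two-population toy models, or missing-not-at-random questionnaires.

## Genotype and sample QC

Variant filters run in a fixed, recorded order — call rate ≥ 0.95, MAF ≥
0.01, then the Hardy–Weinberg exact test at $p > 10^{-6}$ (two-sided by
probability ordering over heterozygote counts, no mid-p) — so per-filter
removal counts are conditional on the preceding filters; the order itself is
a package decision, since sequential-versus-joint application changes only
the attribution of removals, not the surviving set.  Relatedness uses the
method-of-moments IBD estimator whose 0.1875 cutoff convention it follows
(PI_HAT, clamped to [0,1], requiring ≥ 100 informative variants).
Stratification PCA standardizes by reference-panel allele frequencies,
takes eigenvectors from the reference only, and projects study samples;
the number of components is an explicit argument (all eigenvalues are
returned for scree inspection, mirroring how such judgments are actually
made), and outlier exclusion generalizes "outside the cluster" to a radius
rule of 6 reference SDs, as no numeric rule was published.

## Problem sizes and runtime choices

The test suite and the acceptance script use desk-scale problem sizes chosen
to give each statistical check adequate resolution: null-calibration scans
of 2,000 variants on 1,000 subjects, parameter-recovery studies of 100
replicates at n ≈ 2,000, covariance-selection studies at n = 5,000, and an
end-to-end pipeline of 120 variants on 400 subjects.  These are the package's
own choices of study condition; the generator accepts arbitrary sizes.

## Known limitations

* Estimation assumes multivariate-normal indicators; ordinal-threshold
  (polychoric/WLSMV) estimation and multi-factor models are out of scope.
* One causal variant per trait per region is assumed by the colocalization
  model; allelic heterogeneity (SuSiE-style multi-signal colocalization) is
  not handled.
* Genotype phasing/imputation, variant-effect annotation and external eQTL
  retrieval are outside the package; eQTL inputs are plain summary tables.
* The AIC covariance-selection search is deliberately not model-selection
  consistent (see above).
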