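---
title: "Methods: single-step genomic reaction norms for heat tolerance in sows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-step genomic reaction norms for heat tolerance in sows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Sow reproductive performance (total number born, number born alive,
average piglet birth weight) deteriorates under heat and humidity load,
and sows differ genetically in how strongly they respond. `heatnorm`
models each farrowing record as a *linear reaction norm* on an
environmental gradient:

$$ y = \alpha + \beta\,\phi_1(x) + CG + Par + a_0\,\phi_0 +
a_1\,\phi_1(x) + p + e $$

with $(a_0, a_1) \sim N(0, \mathbf H \otimes \mathbf G)$,
$p \sim N(0, \sigma^2_{pe})$, and a residual variance
$\sigma^2_{e,t}$ depending on which quintile class $t$ of the covariate
the record falls in. The covariate $x$ is one of 95 litter-specific
weekly climate summaries (five weather variables by 19 week intervals
spanning three weeks before conception to farrowing), standardized to
$[-1, 1]$.

Assumptions worth keeping in mind:

* the norm is linear in the standardized covariate (first-order
  polynomial only; curvature is out of scope);
* the genetic covariance across animals factorizes as
  $\mathbf H \otimes \mathbf G$ — the same relationship structure for
  intercept and slope;
* residual heteroscedasticity is a step function over covariate
  quintiles, not a smooth variance function;
* records are conditionally independent given the sow's effects (no
  service-sire, litter or farm-nested random effects).

## The Legendre basis

The basis is the *orthonormal* Legendre pair $\phi_0 = \sqrt{1/2}$,
$\phi_1(x) = \sqrt{3/2}\,x$, used identically for the fixed regression,
the random regression and every derived quantity. The choice is not
cosmetic: the across-environment correlation surface
$\Gamma = \Phi'\mathbf G\Phi$ depends on the basis through the relative
weighting of intercept and slope variance, and only the normalized basis
reproduces the published minimum correlations from the published
$(\sigma^2_0, \sigma_{01}, \sigma^2_1)$ posterior means (the package's
acceptance suite pins three of these anchors). The "intercept" of the
norm is therefore $\alpha$ evaluated at the covariate midpoint, and the
genetic intercept contribution enters the phenotype as
$a_0\sqrt{1/2}$.

## The temperature-humidity index

The weather sources cited in this literature compare several THI
definitions without printing one; `compute_thi()` implements the
NRC-1971 dry-bulb/relative-humidity form

$$ THI = T_F - (0.55 - 0.0055\,RH)\,(1.8\,T_C - 26), \qquad
T_F = 1.8\,T_C + 32 $$

the most common choice in that comparison (25 °C at 50 % RH gives
71.775; at 100 % RH the index equals $T_F$). A different index can be
substituted upstream by adding a column to the covariate table.

## Interval anchoring and classes

Intervals are half-open seven-day windows indexed from the conception
date: interval 1 is days $[-21, -14)$, interval 19 is days
$[105, 112)$; gestation is treated as fixed at 114 days. Residual
classes use the first four quintiles of the *covariate* (linear
interpolation percentile rule, type 7; ties go to the lower class) as
discriminants, giving balanced classes up to ties. Quintiles of the
covariate — rather than of the phenotype — are what make the class-wise
residual narrative (heritability changing across the gradient because
residual variance does) coherent, and the generator uses the same rule.
Records whose weather window is not fully covered raise an error listing
the missing days; nothing is imputed.

Phenotype editing is a single-pass 3.5-SD rule per trait with a strict
inequality at the boundary; the offending trait value is masked to `NA`
(fits are univariate, so this equals dropping the record from that
trait's dataset).

# Estimation

## Gibbs sampler

`gibbs_sample()` alternates two blocks: (1) *all* location effects
(fixed, $a_0$, $a_1$, permanent environment) drawn jointly from their
conditional multivariate normal via a sparse supernodal Cholesky
factorization whose symbolic analysis is reused across iterations; and
(2) the variance components from their conjugate conditionals —
inverse-Wishart for $\mathbf G$ (sufficient statistic
$\mathbf T'\mathbf H^{-1}\mathbf T$ over all animals), scaled
inverse-chi-square for $\sigma^2_{pe}$ and for each residual class using
only its own records. Joint location sampling is distributionally
equivalent to single-site Gibbs with far better mixing, and when the
variances are fixed the draws are i.i.d. from the exact location
posterior — which is what makes the mixed-model-equation oracle test
sharp. Chains are bit-reproducible given a seed.

The per-iteration coefficient matrix is assembled by scattering
precomputed numeric blocks (class-wise cross-products, the
$\mathbf G^{-1} \otimes \mathbf H^{-1}$ pattern, the permanent
environment diagonal) into a fixed sparsity template with a single
matrix-vector product, so the per-iteration cost is dominated by one
sparse Cholesky refactorization and stays modest even with a few
hundred genotyped animals in the dense block.

## Priors

Default priors are *flat* (improper) on all variance components, with
proper conditionals at any realistic data size. This is a deliberate
departure from the obvious "weakly informative" choice of IW($\nu = 4$,
$\mathbf I$): the genetic intercept variance and the permanent
environment variance are both constant within sow and are separated only
by relationship information, so their likelihood is nearly flat along
$0.5\,\sigma^2_0 + \sigma^2_{pe} = \text{const}$. Along such a ridge an
IW(4, $\mathbf I$) prior contributes several log-units of density
against variances of magnitude 5–40 and visibly drags $\sigma^2_0$
toward zero — we verified on simulated data that the exact restricted
likelihood peaks near the true value while the IW(4, $\mathbf I$)
posterior concentrated far below it. Flat priors restore agreement with
the likelihood. Proper priors remain available through `rn_priors()`
for small or ill-posed datasets.

## Two-step covariate screening

`screen_env()` mirrors the two-step strategy used in practice: a reduced
chain per candidate covariate with only sires' genotypes in the
single-step matrix, ranking candidates by the posterior mean of
$\sigma^2_1$; the winner is refit with the full chain and all genotypes.
The default reduced scheme is 30,000 iterations with 10,000 burn-in and
thinning 10 (burn-in/thinning proportional to the full second-step
scheme of 120,000/20,000/20). Note that weekly climate covariates are
strongly autocorrelated (adjacent weeks, and temperature vs THI in the
same week, are near-copies), so "the" driving week is only identifiable
up to that correlation structure; the package's ranking tests use decoy
covariates with pairwise correlation to the truth below ~0.7 for this
reason.

## Convergence

`geweke_diagnostic()` exposes the standard Geweke z-scores (first 10%
vs last 50% with spectral variance estimates, via `coda`); trace plots
can be drawn from the tidy chain tibble directly.

# Derived genetic parameters

$\Gamma = \Phi'\mathbf G\Phi$ is evaluated on a default grid of 201
equally spaced points on $[-1, 1]$. For a first-order norm the minimum
off-diagonal correlation is attained at the grid extremes and is
grid-insensitive (a property the test suite checks numerically); the
*median* off-diagonal correlation depends on the grid density and is
therefore always reported together with the grid size.
Environment-specific heritability
$h^2_k = \Gamma_{kk}/(\Gamma_{kk} + \sigma^2_{pe} + \sigma^2_{e,t(k)})$
is computed per posterior draw when a fit is supplied, yielding
equal-tail 95% bands; the class membership of each grid point uses the
fit's quintile boundaries, which produces the characteristic broken-line
profile across class borders.

Sire selection for reaction-norm reporting requires at least 50
daughters with records (configurable) *and* a gradient-spread rule:
daughters' covariate values must cover at least 60% of the observed
standardized range and touch at least 4 of the 5 residual classes. The
spread rule prevents a sire evaluated only in comfortable conditions
from being labelled tolerant; both thresholds are tunable arguments.

# Window-based ssGWAS

Marker effects are back-solved from the genotyped animals' breeding
values as $\hat u = \mathbf D\mathbf Z'\mathbf G^{-1}\hat a$ per term.
With frequencies computed from the data, $\mathbf Z$ is column-centered
and $\mathbf G = \mathbf Z\mathbf D\mathbf Z'$ is singular (the ones
vector is a null vector), so the inverse is the Moore–Penrose
pseudoinverse: any $\hat a$ in the column space — in particular any
$\mathbf Z u$ — is reconstructed exactly, which the tests assert at
relative error $10^{-8}$. Sliding 10-SNP windows (step 1, never
spanning chromosomes; a short chromosome forms one window) are scored by
$100\cdot\mathrm{Var}(DGV_w)/\mathrm{Var}(DGV)$ with population-divisor
variances across genotyped animals. The top 1% per term (ceiling rule,
ties broken by chromosome and position) are selected; selections are
per-term with the union also reported.

Selected windows are tested against a max-statistic null built from
random rearrangements of the effect vector. The default rearrangement
is a full permutation: under an i.i.d.-effects null any exchangeable
rearrangement gives an exactly calibrated test for the maximal window,
but a circular shift (offered as `method = "circular"`) keeps clustered
QTL effects adjacent and therefore cannot reject precisely when a
window is large because of a localized signal — full permutation
disperses the cluster and has power. Calibration is verified in the
acceptance suite against the binomial band around $\alpha$.

Window-gene overlap uses half-open intervals ($[start, end)$; a gene
ending exactly at a window start does not overlap) on IRanges interval
trees, with GFF3/BED input converted to that convention on read.

# The synthetic-data generator

`simulate_herd()` emulates the structure of a maternal-line nucleus
population: a sire-structured pedigree (defaults: 50 sires with 10
recorded daughters each, 500 founder dams), Hardy–Weinberg founder
genotypes gene-dropped through the pedigree, sinusoidal weather with
daily noise (defaults: 15 ± 10 °C season, 65 ± 15 % RH in
counter-phase, SD 3), conception dates uniform over the calendar so all
covariate classes are populated, fixed 114-day gestation, and phenotype
assembly *identical* to the fitted model, using the same covariate,
standardization, class and basis code paths. Breeding values are drawn
by the pedigree recursion (parent average plus Mendelian-sampling
deviation scaled by parental inbreeding), which realizes
$N(0, \mathbf A \otimes \mathbf G)$ exactly at linear cost. Default
variance magnitudes ($\mathbf G = [[9, 0.6], [0.6, 6.5]]$,
$\sigma^2_{pe} = 15$, $\sigma^2_e = 30 \ldots 38$) match the scale
reported for sow litter traits.

What the generator does *not* emulate — and what passing tests
therefore do not establish about real data: linkage disequilibrium
(loci segregate independently), selection across generations,
farm-by-farm climate heterogeneity (one weather series per dataset,
configurably more), litter-level piglet traits, and real missingness
patterns. The companion traits (NBA as TNB minus a loss, ABW as
independent noise) only preserve table invariants; the reaction-norm
signal is written on a single trait.

# Numerical choices and degenerate inputs

* Standardization is affine with observed (or user-supplied) min/max;
  constant covariate columns raise a classed error and are skipped with
  a warning during screening.
* Blending default $\omega = 0.95$ guarantees an invertible genomic
  block with negligible distortion; $\mathbf H^{-1}$ construction with
  no genotyped animals returns the sparse pedigree inverse bit-for-bit.
* The pedigree inverse uses Henderson's rules with inbreeding and
  agrees with the dense inverse to $10^{-10}$ (tested); pedigrees are
  topologically sorted and cycles are reported by animal id.
* The Cholesky factorization falls back to a fresh symbolic analysis if
  a variance draw changes the sparsity pattern (e.g. an exactly diagonal
  $\mathbf G$); a non-positive-definite conditional aborts with the
  iteration index.
* Problem sizes in the test suite were chosen to make each property
  measurable at desk scale: the study-scale recovery check runs ~500
  sows / 5,000 records / 2,000 SNPs with a 20,000-iteration chain;
  screening checks use 10 candidate covariates over 10 seeds with
  300-iteration reduced chains; bootstrap calibration uses 150
  replicates of a 150-SNP toy genome. Full-scale datasets of the kind
  this analysis targets (tens of thousands of litters, ~45–50k SNPs)
  are proprietary and far heavier; nothing in the implementation caps
  problem size.

# Known limitations

* First-order norms cannot express intermediate-optimum responses; the
  correlation minimum is then always at the gradient extremes.
* The intercept-variance / permanent-environment split is weakly
  identified in small designs (few, large half-sib families); expect
  wide, strongly negatively correlated posteriors there. Flat priors
  keep the posterior honest about this rather than hiding it.
* The Geweke diagnostic and credible intervals assume the chain has
  left its transient; for final inference run the full 120k-length
  scheme rather than the screening chains.
* `edit_phenotypes` is single-pass; iterating it would remove further
  records and is deliberately not done.
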