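---
title: "Models and methods for multi-environment diallel analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for multi-environment diallel analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diallelkit)
```

# The design

A full diallel crosses `p` inbred parents in all `p²` ordered combinations:
parental selfs, F1 hybrids, and reciprocal F1s (Griffing's Method I entry
set; Method III drops the selfs, leaving `p(p−1)` entries).  `diallelkit`
assumes the entries are evaluated in a randomized complete block design with
`r` blocks in each of `e` environments, giving `p²·e·r` plots.  The female
parent indexes the rows of every p × p grid and is listed first in cross
labels, matching the convention of reciprocal-effect tables.

All degrees of freedom are closed-form functions of `(p, e, r)`
(`anova_dof()`), and the package treats them as the design's skeleton:
Genotype `p²−1` partitions into GCA `p−1`, SCA `p(p−1)/2`, and Reciprocal
`p(p−1)/2`; with `e ≥ 2` the G×E interaction `(p²−1)(e−1)` partitions the
same way; replication is nested in environment; Error is
`e(r−1)(p²−1)`.  Under Method III the SCA df is `p(p−3)/2`, which is zero
at `p = 3` — the fit is then saturated without SCA and the SCA mean square
is undefined — and negative below, so Method III requires `p ≥ 3` (and
`p ≥ 4` for a nontrivial SCA test).

# Griffing's fixed-effects analysis

For cell means `Ȳ_jk` (averaged over environments and blocks) the Method I,
Model I decomposition is

y_jk = μ + g_j + g_k + s_jk + r_jk + ε,

with the standard identifiability constraints Σ g_j = 0, `s` symmetric with
zero row sums (including the diagonal under Method I), and `r`
antisymmetric.  The estimators are the classical closed forms, e.g.
ĝ_j = (Y_j· + Y_·j)/2p − Y··/p², and the package verifies them against a
generic equality-constrained least-squares solve in its test suite.  The
Genotype sum of squares decomposes *exactly* into the GCA, SCA, and
Reciprocal quadratic forms of the fitted effects (2pn·Σĝ², n·Σŝ², n·Σr̂²
with `n = e·r` observations per cell), and the G×E sum of squares
decomposes identically using per-environment fits — both identities are
asserted to 10⁻⁶ relative error on random data.

Standard errors for individual effects are obtained from the estimators'
squared coefficient norms as linear functions of the cell means (computed
once per `(p, method)` by applying the estimator to elementary cell-mean
matrices, and cached), times the Error mean square over `n`.  Because
Model I treats genotypes as fixed, every F and t test uses the Error mean
square as denominator.  Significance stars use 0.05/0.01/0.001 with no
multiplicity correction, as is conventional in combining-ability tables.
With noiseless data (zero Error MS) effects are flagged as exact fits
rather than given p-values.

Baker's ratio `2·MS_GCA/(2·MS_GCA + MS_SCA)` is reported under Method I and
under Method III; values near one indicate hybrid performance predictable
from GCA alone.  Method I includes the selfs, which biases combining-ability
variance upward, hence the Method III companion estimate.

# Multiple imputation

Model I needs complete balanced data, so missing plots are multiply imputed
by chained-equations predictive mean matching (PMM).  Per sweep and per
incomplete trait, the observed values are regressed on the predictors; the
coefficient vector for scoring *missing* rows is a Bayesian draw
(`β* ~ N(β̂, σ*²(XᵀX)⁻¹)`, `σ*² = RSS/χ²_ν`), while observed rows are scored
with `β̂` (type-1 matching); each missing cell then copies the observed
value of one donor sampled uniformly from the `donors` nearest predicted
means.  Imputed values are therefore always values actually observed for
that trait — PMM cannot extrapolate.

Choices the method description leaves open, fixed here:

* **Donor pool = 5**, the conventional PMM default.
* **70 sweeps per imputation**, recording the final sweep — well past the
  ~40 sweeps at which the chain typically stabilises; a per-sweep
  convergence trace (mean and SD of the imputed values) is returned so the
  user can check.
* **Predictors**: female, male, environment, and block as indicator
  contrasts, the 0–3 planting-density score, optionally the cross factor,
  and the *other traits at their current observed-or-imputed values* (this
  is what makes the equations "chained"; with a single incomplete trait the
  sweeps converge immediately).  Rank-deficient columns — the cross factor
  frequently, the rest occasionally — are dropped via pivoted QR.

Scalar estimates are pooled by Rubin's rules (`Q̄`, `Ū`, `B`,
`T = Ū + (1+1/m)B`, df `(m−1)(1 + Ū/((1+1/m)B))²`).  The ANOVA pooling
procedure cited for this style of analysis is unpublished; `pool_anova()`
therefore averages the per-imputation mean squares and re-forms F statistics
against the pooled Error mean square, and flags all pooled p-values as
approximate.  This is transparent, reduces to the complete-data ANOVA when
the imputations are identical, and is validated in the tests by the
coverage of Rubin-pooled GCA estimates against complete-data fits.

# The Bayesian hierarchical diallel model

The raw (unimputed) data are decomposed observation-wise as

y_i = μ + x_iᵀβ + Σ_r u_i^(r) + a_j + a_k + I{j=k}(β_inbred + b_j)
      + (m_j − m_k) + I{j≠k} v_(jk) ± w_(jk) + ε_i,

where the asymmetric effect enters with `+` when the female index is below
the male index and `−` otherwise.  Every random-effect class (`a`, `b`,
`m`, `v`, `w`, the environment levels, and the density-level deviations)
has its own variance τ² with a scaled inverse-χ² prior.  The prior stated
for these variances — inverse-χ² with "d.f. = 0.5, mean = 1" — is read
here as a *scaled* inverse-χ² with ν = 0.5 and scale s² = 1, since the
distribution's mean is undefined at ν = 0.5; both ν and s² are arguments
(`prior_df`, `prior_scale`) so other readings are available.  Fixed effects
(μ, β_inbred, the density slope) have N(0, 10³) priors.  The residual
variance prior is a scaled inverse-χ² with ν = 0.5 and scale equal to the
trait's sample variance — weakly informative and scale-adapted; the source
description does not state a residual prior.

Identifiability is by shrinkage, exactly as the model is written: no hard
sum-to-zero constraints are imposed, so only contrasts of `a` (and the
split between μ and the additive mean) are data-identified, with the
zero-mean priors resolving the remainder.  Posterior summaries of
individual effects consequently include that ridge uncertainty.

**Sampling.**  The sampler is blocked Gibbs, but with one deliberate
departure from a class-by-class sweep: *all* fixed and random coefficients
are drawn jointly from their exact multivariate-normal full conditional
each iteration (the coefficient dimension is ~60 for p = 6, so one Cholesky
per sweep is cheap), followed by the conjugate scaled inverse-χ² draws for
each τ² and σ².  The stationary distribution is identical to the
class-by-class sweep's, but the joint draw eliminates the severe
autocorrelation between μ and the additive effects that the per-class sweep
exhibits (split-chain R̂ near 1.9 at two thousand iterations versus ~1.00
for the joint draw on the same data).  A near-singular conditional is
jittered with a warning.  Defaults follow the 5-chain, 10 000-iteration,
1000 burn-in convention; chains use consecutive seeds.  Model nesting
`mu ⊂ a ⊂ Bab ⊂ Babm ⊂ fullu` is exposed via the `model` argument, and a
known residual variance can be supplied (`sigma2_fixed`) — used by the
conjugate-exactness test.

**Predicted grids** evaluate each draw's p × p ordered-cross means at a
population-level reference profile: density at its sample mean, random
environment and density-level deviations at zero.  **Hybrid rankings** rank
the `p(p−1)` ordered hybrids within each draw (rank 1 = largest predicted
value, ties averaged) and summarise each hybrid's rank by its mean and 95%
HPD interval; stratified-by-location fits (single-environment tables,
`use_location = FALSE`) give per-environment rankings for G×E inspection.
**HPD intervals** use the sorted-sample sliding-window method (shortest
contiguous interval of the requested mass); at least 100 draws are
required.  The Gelman–Rubin diagnostic is the standard between/within
variance ratio, truncated below at 1 so that identical chains report
exactly 1.

# Degree of dominance

For parents A and B the Comstock–Robinson degree of dominance is computed
per draw from the predicted grid as
`a_CR = 1 − 2(y_BB − y_Bb)/(y_BB − y_bb)`, with `y_BB` and `y_bb` the
predicted selfs and `y_Bb` the *average of the two reciprocal hybrid
cells* — averaging removes maternal and asymmetric contributions from what
is defined as a symmetric allele-dosage contrast.  Draws whose denominator
is within ε = 10⁻⁶ × (posterior SD of the predicted selfs) of zero are
excluded and the excluded fraction reported.  A pair is classified
(pseudo-under-recessive / recessive / additive / dominant /
pseudo-overdominant, with bin edges ±0.5 and ±1.5) only when the posterior
mean, the median, *and* more than half the draws fall in the same bin;
otherwise it is unclassified.  Pseudo-overdominance cannot be distinguished
from repulsion-phase linkage of partially dominant loci; the package makes
no attempt to.

# Diallel variance projection

VarP asks: in a future, complete, perfectly balanced diallel of these same
parents, what share of the phenotypic sum of squares would each inheritance
class contribute?  Per retained draw the package reconstructs the `p²` cell
contributions of each class from that draw's effects, adds one fresh
N(0, σ²) residual per cell (one observation per ordered cell; covariates at
the reference profile), and computes the *covariance projection*

VarP_c = Σ c̃·ỹ / Σ ỹ² × 100,

centering over cells.  Because the centered class contributions sum to the
centered phenotype, the class shares plus the residual (unexplained) share
add to exactly 100 in every draw — and an individual share can be
*negative* when a weak class contribution is negatively correlated with the
total.  A plain sum-of-squares ratio could do neither; the negative
credibility bounds routinely seen in published VarP tables are only
consistent with the projection form, which is why it is the definition used
here.  Summaries are posterior means with 95% HPD intervals.

# GGE tester selection

The entry × tester matrix of ordered-cross means is column-centered
(tester centering) and decomposed by SVD, splitting each singular value
evenly between entry and tester scores (symmetric scaling).  Axes whose
singular value is below 10⁻¹² of the largest are treated as numerically
null; two axes are retained by default.  Each left singular vector's
largest-magnitude coordinate is made positive, for deterministic output.
A tester's *discriminativeness* is the length of its score vector; its
*representativeness* is its angle to the average-tester axis (the direction
of the mean tester score; when the tester vectors cancel exactly the axis
is undefined and all projections are zero).  Because the original selection
is made visually from the biplot, the package adds a reproducible
scalarization: testers are ranked by length × cos(angle), i.e. the signed
projection onto the average-tester axis, with both components reported so
the visual judgment remains available.  Exact ties are flagged and all tied
testers returned.

# The synthetic-data generator

`simulate_diallel()` draws every effect class zero-mean normal with its
class SD, then assembles plot values by the same equation the Bayesian
model fits, so model-based recovery is meaningful by construction.  The
defaults emulate the motivating use case: a 6-parent diallel of a
height-like trait (cm) in 3 environments × 2 blocks (216 plots), grand
mean 45, inbred penalty −8 (selfs visibly shorter than hybrids), additive
and inbred-deviation SDs 4, maternal SD 2, cross-specific SDs 2 and 1,
environment SD 3, residual SD 4; density scores 0–3 drawn with
probabilities (0.05, 0.15, 0.40, 0.40), entering as a 1.5 cm/unit slope
plus small per-level deviations.  Missingness is plot- and trait-wise
independent within environment, with environment-specific rates defaulting
to 30% in the first environment and 4% in the last — the
disease-pressure pattern in which one location loses a third of its plots
while the others stay nearly complete (missing completely at random within
environment, missing at random across).

What the generator does *not* emulate: spatial field trends, genotype-
dependent (informative) missingness, measurement-error structure beyond a
single residual SD, multi-trait genetic correlation, or marker-level
genetics (effects are whole-genome aggregates).  Passing tests therefore
demonstrate correctness of the estimators and calibration under the
model's own assumptions, not robustness to violations of them.

When plots are measured as several subsamples, `average_subsamples()` takes
the available-case mean — a plot is missing only when every subsample is —
since averaging-before-analysis conventions rarely state a partial-missing
rule.  Log-transformed biomass-like traits are handled by `trait_spec()` /
`apply_transform()`, which refuse non-positive values and are exactly
inverted by `invert_transform()`.

# Numerical choices and test scales

* Constraint residuals of the Griffing fits are required below 10⁻¹⁰; fits
  match the constrained least-squares oracle to 10⁻⁸ across 50 random
  designs (p 3–7, e 1–3, r 1–2).
* Sampler calibration is checked three ways: conjugate exactness of the
  normal-mean submodel with known variance; 95%-interval coverage of the
  additive, inbred-penalty, and maternal effects at the full design scale
  (216 plots, 20 replicates, 2 chains × 2000 iterations) at ≥ 90%; and
  type-I error of the GCA t-tests under the global null (1000 replicates)
  inside 5% ± 2%.  These replicate counts keep the full suite under about
  a minute while leaving the binomial uncertainty of each check well inside
  its acceptance band.
* Imputation calibration: Rubin-pooled GCA intervals cover the
  complete-data estimates at ≥ 90% across 100 replicates of 20% MCAR
  missingness with m = 10.
* The HPD sliding window is exact for the sorted sample; its endpoints on
  10⁶ standard-normal draws land within 0.02 of ±1.96.

# Limitations

Griffing Methods II/IV and random-effects (Model II) variance components
are out of scope, as are the sexed variants of the Bayesian model family,
model selection among its nested submodels, and heteroscedastic residuals.
The ANOVA pooling across imputations is a documented approximation (exact
reference procedure unpublished).  Individual additive effects in the
Bayesian model are identified only through shrinkage; report contrasts when
absolute location matters.
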