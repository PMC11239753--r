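---
title: "Methods: GEE power for multilevel-intervention stepped wedge designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GEE power for multilevel-intervention stepped wedge designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mliswd)
```

## The design problem

A multilevel intervention acts at two levels at once: an individual-level
(IL) component delivered to people and a cluster-level (CL) component
delivered to the organizational units that contain them. Randomizing the CL
component as a stepped wedge — every cluster starts in control and crosses
over to the intervention at a randomized time — can make recruitment
feasible when withholding the CL component indefinitely would not be
acceptable, while independently randomizing individuals to the IL component
retains the efficiency of individual randomization for the IL, interaction
and combined effects. The cost is the stepped wedge's inherent confounding
of treatment with calendar time, which the analysis model must address and
the power calculation must reflect.

`mliswd` computes power analytically from the design: no outcome data are
involved. It targets *marginal, participant-average* effects as estimated
by generalized estimating equations (GEE) with a working correlation, using
the model-based (not sandwich) covariance, so the attained power describes
an analysis in which the working correlation is taken at its planning
values.

## Mean model

For individual $k$ in cluster $i$ at calendar period $j$ (period index
$T_{ijk}$), with $A^{IL}_{ijk}$ and $A^{CL}_{ijk}$ the numbers of periods
(including the current one) on the IL and CL interventions,

$$g(\mu_{ijk}) = f_T(T_{ijk})\beta + f_{IL}(A^{IL}_{ijk})\,\delta^{IL} +
f_{CL}(A^{CL}_{ijk})\,\delta^{CL} +
f_{Int}(A^{IL}_{ijk}, A^{CL}_{ijk})\,\delta^{Int}.$$

Two effect parameterizations are implemented.

* **Average effects**: $f(A) = 1\{A \ge 1\}$ for all three terms. Each
  coefficient is a time-constant effect of being exposed at all.
* **Incremental effects**: $f_{IL} = A^{IL}/c^{IL}$,
  $f_{CL} = A^{CL}/c^{CL}$, and
  $f_{Int} = \tfrac{1}{c^{Int}}\sum_{j' \le j} 1\{A^{IL}_{ij'k} \ge 1\}
  1\{A^{CL}_{ij'k} \ge 1\}$, the cumulative count of jointly exposed
  periods. The constants $c$ (units: periods) place the coefficients at a
  scientifically meaningful exposure duration — with $c = 3$ and two-month
  periods, $\delta^{CL}$ is the CL effect after six months. The joint-count
  interaction is deliberate: the product $A^{IL} A^{CL}$ grows
  quadratically in calendar time, which distorts a model whose other terms
  are linear, so it is not used.

Time trends may be linear, categorical (reference period 1 absorbed in the
intercept), or raw polynomials of the 1-based period index — raw rather
than orthogonal so the coefficients stay interpretable. Links: identity,
log, logit. Under the identity link the intercept and time-trend
coefficients do not affect power at all (the information matrix does not
involve $\mu$), which the test suite verifies; under log or logit they do,
through the variance function, and must be supplied as realistic values.

Exposure clocks: IL-treated individuals are on the IL intervention from
period 1 (concurrent randomization at study start); this is configurable
via `il_start_period` because designs that deliver the IL component later
are conceivable and nothing in the mechanics forces baseline delivery. The
CL clock starts at the cluster's crossover period. For open cohorts an
optional extra covariate counts the individual's own time in a treated
cluster, off by default because it is exactly collinear with the CL
covariate in complete designs.

## Working correlation and variance

The variance is $\phi\, v(\mu)$ with the gaussian ($v \equiv 1$), binomial
($v = \mu(1-\mu)$, $\phi = 1$ by convention) or poisson ($v = \mu$)
variance function. Dependence within a cluster uses one of:

* **block exchangeable** — three parameters: within-period $\alpha_0$
  (different people, same period), inter-period $\alpha_1$ (different
  people, different periods), within-individual $\alpha_2$ (same person,
  different periods);
* **block autoregressive** — $\alpha_2^{|lag|}$ within individuals; the
  between-individual pattern stays block exchangeable unless
  `inter_decay = TRUE`, in which case the inter-period correlation decays
  as $\alpha_1 \alpha_2^{|lag|-1}$ (the lag-1 value then matches the block
  value, which is the least surprising convention; the choice is exposed
  because either behavior is defensible);
* **independence**, for robustness experiments.

Rows are ordered individual-major — individual 1's periods
$1,\dots,J$, then individual 2's, and so on — everywhere (design matrices,
correlation matrices, incidence selection), which makes the closed-cohort
Kronecker constructions direct. Cross-sectional sampling reuses the same
machinery with the same-slot, different-period cells treated as different
people, so no within-individual correlations appear. Positive definiteness
is checked by Cholesky factorization with a $10^{-5}$ floor on the smallest
pivot, failing early with the offending $\alpha$ and dimensions rather than
in a downstream solve; for the all-equal case
$\alpha_0 = \alpha_1 = \alpha_2 = \rho$ this boundary is the exchangeable
$\rho > -1/(NJ-1)$, which the tests confirm is sharp.

## Power

With $X_i$ the cluster design matrix, $\Delta_i = \mathrm{diag}(\partial
\mu/\partial\eta)$ and $V_i = \phi A_i^{1/2} R_i A_i^{1/2}$, the
model-based covariance of the coefficient estimator is

$$\Omega = \Big(\sum_{i=1}^I D_i^\top V_i^{-1} D_i\Big)^{-1},
\qquad D_i = \Delta_i X_i,$$

computed once per distinct (sequence, arm-split) group of clusters and
multiplied by the group size. For a hypothesis $H_0: L\theta = \ell$ the
Wald noncentrality is
$\lambda = (L\theta - \ell)^\top (L \Omega L^\top)^{-1} (L\theta - \ell)$
and power is $P(\chi^2_{q,\lambda} > \chi^2_{q,1-\alpha})$, or by default
$P(F_{q, I-d, \lambda} > F_{q, I-d, 1-\alpha})$ with denominator degrees of
freedom $I - d$ — clusters minus mean-model coefficients — since stepped
wedges typically run with few clusters and the asymptotic reference is
anti-conservative there. Both references are reported by the `power`
command; they differ by under about one point at 60 degrees of freedom. The
same $I - d$ is used for incomplete designs with unequal cluster
observation counts; no refinement of the degrees of freedom for unequal
information content is attempted. Noncentral tail probabilities come from
R's `pchisq`/`pf`; results are clamped to $[0,1]$ and an extreme
noncentrality that exhausts their accuracy is reported as power 1, a regime
far from any decision boundary.

A multiplicity plan maps named families to per-test levels: Bonferroni
divides a family level equally over its members, `adjust: "none"` applies
the family level to each member verbatim. A contrast may carry its own
level *or* a family name, never both. For the packaged example this matters:
a secondary family at level 0.1 with two members runs each secondary test
at 0.05 under Bonferroni and at 0.1 unsplit; the configuration requires the
choice to be explicit, and the shipped file uses the Bonferroni split.

## Incomplete designs

An incomplete design is the complete design plus a planned observation
pattern. The incidence matrix $K_i$ (one row per observation, one column
per calendar period, a single 1 per row) records when each observation is
taken; for a closed cohort the representative individual's block $K_s$ is
replicated over the cohort ($\mathbf{1}_{N_i} \otimes K_s$ in
individual-major order), for open cohorts per-individual blocks are
concatenated. Operationally the pattern acts as a row-selection operator
$S$ on the complete layout: the restricted design matrix is $S X_i$ and the
restricted correlation $S R_i S^\top$ — the standard GEE treatment of
planned missingness. Power on a complete design equals power on the same
design expressed as all-observed incomplete, a property test in the suite.
The machinery describes *planned* missingness only; it is not an analysis
method for unplanned dropout.

## Sample-size search

`solve_cohort_size()` finds the smallest per-cluster cohort meeting the
power goal for every searched contrast: exponential bracketing, bisection,
then a certificate that $N-1$ fails; if the certificate detects
non-monotonicity it falls back to a linear scan, favoring robustness over
speed. Power is monotone in $N$ for the standard designs, so the fallback
is a safeguard rather than the normal path. Two boundary behaviors are
deliberate: cohorts too small to identify all coefficients (for example a
single individual per cluster, whose arm-specific covariates are collinear
with the time trend) are treated as failing rather than erroring, so the
search returns the smallest *identifiable* sufficient size; and an
unreachable goal raises an explicit infeasibility error reporting the power
attained at `n_max`. IL allocation uses the deterministic ceiling rule
$N_{i1} = \lceil N_i \cdot \text{split} \rceil$, reproducible and within
one individual of the target split. `power_frontier()` repeats the search
over a range of total cluster counts, distributing clusters as evenly as
possible with remainders to the earliest sequences.

## Simulation validation

The simulator exists to validate the analytic engine, and its defaults are
the packaged example's conditions. The Gaussian generator is exact: cluster
outcomes are drawn with mean $X_i\theta$ and covariance $V_i$ via Cholesky
factors, so the target moments hold by construction and any disagreement
with the analytic power indicts the engine, not the generator. The
estimator is generalized least squares with the true $\alpha$ plugged in —
deliberately not re-estimating the correlation, because the power formula
assumes it known; with known covariance the Wald statistic is exactly
(non)central chi-square, so empirical and analytic chi-square power agree
up to Monte Carlo error. Random streams are replicate-indexed
(`seed + replicate`), making replicates independently reproducible.
Estimator failures in a replicate are excluded and counted, never silently
dropped.

The binary generator thresholds a latent Gaussian vector whose pairwise
correlations are calibrated (via a one-dimensional integral for the
bivariate normal probability and root finding) so the binary outcomes'
Pearson correlations approximate the working correlation. This is an
approximation — exact multivariate binary generation with arbitrary block
exchangeable correlation is infeasible in general — and a requested
correlation outside the feasible range for the given margins raises an
error rather than being silently truncated.

What passing simulation tests establish: the analytic covariance and the
noncentral reference distribution are internally consistent for Gaussian
outcomes under the assumed correlation. What they do not establish:
robustness to misspecified correlation structure, to informative cluster
sizes, to unplanned missingness, or to binary/count small-sample behavior —
all analysis-stage questions outside a planning tool's scope.

Problem sizes used by the shipped tests: the example design (65 clusters,
90 observations each) with 2000 replicates for the calibration and
agreement checks, 20 random small trials (at most 4 clusters, 3
individuals, 4 periods, all three links) for the dense-oracle comparison at
relative tolerance $10^{-8}$, and 6000–20000 replicates of tiny clusters
for moment checks.

## Known limitations

* Effects are linear transformations of time-on-treatment (including the
  average model as the capped special case); functional summaries such as
  area-under-curve estimands are not expressible.
* Model-based covariance only: no sandwich variance, and no
  Kauermann–Carroll or Fay–Graubard small-sample corrections —
  `wald_power()` takes the covariance as an argument, so an externally
  corrected matrix can be supplied, but none is computed here.
* No estimation from data: the package plans studies; it does not analyze
  them.
* The open-cohort machinery covers observation patterns (who is seen when);
  it does not model how individuals come to join clusters, which can carry
  additional causal assumptions when joining is related to the CL
  assignment.
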