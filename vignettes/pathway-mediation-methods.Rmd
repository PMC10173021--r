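---
title: "Pathway mediation of socioeconomic disparities in cardiac-arrest survival: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway mediation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohcapath)
```

## The scientific problem

Low socioeconomic position (SEP) is associated with lower survival after
out-of-hospital cardiac arrest (OHCA). The association is not a single
mechanism: SEP shapes whether an arrest is witnessed, whether bystanders
give CPR, the initial cardiac rhythm found by EMS, which emergency
department receives the patient and, after admission, whether invasive
post-resuscitation care (coronary angiography, CAG; targeted temperature
management, TTM) is given. `ohcapath` quantifies how much of the SEP -
survival association travels through each of these channels.

The exposure is insurance-derived SEP in five ordered groups (National
Health Insurance premium quartiles Q1-Q4 and Medical Aid, MA, the lowest
stratum), binarized at one of four cutoffs; the main contrast is MA vs all
NHI. Outcomes are survival to discharge and good neurological recovery
(cerebral performance category 1-2). Age, sex, diabetes, hypertension and
metropolitan residence are confounders.

## The path model and its conventions

All modelled variables are observed; mediators and outcome are 0/1. The
model is a recursive system, **linear on the probability scale**. This is
the central modelling convention: published effect estimates of this
analysis type (a total effect near -0.03 for survival to discharge) are
risk differences, which only a linear path model composes multiplicatively
along pathways. A logistic system has no product-of-coefficients
decomposition on the outcome scale; the linear-probability convention is
what makes "effect of a pathway = product of its edge coefficients" exact.
The cost is that predicted probabilities are not automatically confined to
[0, 1]; the generator therefore counts and reports clipping events, and the
default calibration was chosen so that no clipping occurs (see below).

Estimation minimizes the normal-theory covariance discrepancy
$F_{ML} = \ln|\Sigma(\theta)| + tr(S\Sigma(\theta)^{-1}) - \ln|S| - p$ with
$S$ the usual $N-1$ sample covariance and $T = (N-1)F_{ML}$ at the optimum.
For a recursive model with diagonal residual covariance the Gaussian
likelihood factorizes along the DAG, so the per-equation least-squares
solution *is* the global optimum; the quasi-Newton pass from that start is
a verification (gradient norm below 1e-6) rather than a search. This
factorization is also used as an independent oracle in the test suite: the
covariance-structure optimizer must reproduce per-equation OLS to 1e-6,
saturated or not.

"Robust maximum likelihood" is implemented as ML point estimates plus (i) a
stacked heteroskedasticity-consistent sandwich covariance for all
regression coefficients, including cross-equation blocks (needed by the
delta method for path products that span equations), and (ii) a
Satorra-Bentler-type mean scaling factor $c = tr(U\Gamma_4)/df$ estimated
from fourth moments, giving the scaled statistic $T/c$. Exact robust
estimators differ across software; the variant here is selectable
(`se`, `scaling` arguments) and both plain and scaled fit indices are
reported, coinciding when $c = 1$.

Fit indices follow the stated closed forms:
RMSEA $= \sqrt{\max(T-df,0)/(df\,(N-1))}$ (0 when $df=0$); SRMR is the root
mean squared correlation-metric standardized residual over the lower
triangle *including* the diagonal; GFI $= 1 -
tr((\Sigma^{-1}S-I)^2)/tr((\Sigma^{-1}S)^2)$; CFI $= 1 -
\max(T-df,0)/\max(T_b-df_b, T-df, 0)$ against the independence baseline
(all covariances zero), whose discrepancy has the closed form $-\ln|R|$.
$N$ vs $N-1$ conventions are fixed as written here; software packages
differ and this choice is deliberate and documented.

## Pathways, exclusions, intervals

A pathway effect is the sum over selected simple exposure-to-outcome paths
of the product of edge coefficients; the mediation proportion is
$100\,\theta/\tau$ with $\tau$ the reduced-form total effect
$[(I-B)^{-1}]_{YX}$. The decomposition identity (direct + all path products
= total) holds to machine precision and is asserted at 1e-10 in the tests.
Through-mediator quantities overlap across mediators by construction and
need not sum to 100%.

"Through M but not through its intermediate confounders" excludes paths
containing any exposure-affected *direct parent* of M that also affects the
outcome. The direct-parent reading reproduces exactly the published
exclusion sets (bystander CPR excludes witnessed status; initial rhythm
excludes witnessed status and bystander CPR; CAG excludes rhythm and ED
level; TTM excludes ED level); a descendant-based reading would wrongly add
witnessed status to CAG's exclusion set.

Interval construction for products of coefficients is not uniquely standard,
so both are provided: the multivariate delta method (gradient of the
multilinear path sum times the joint sandwich covariance; ratio delta for
proportions) and a nonparametric bootstrap that refits the model on
resampled rows (percentile intervals; one model fit per resample serves all
requested pathways). Proportions for effect estimates whose interval covers
zero are suppressed in the decomposition table, mirroring the convention of
the published tables.

## The default DAG

The full-population model runs SEP -> {witnessed, bystander CPR, shockable
rhythm, ED level, survival}; witnessed -> {CPR, rhythm, survival}; CPR ->
{rhythm, survival}; rhythm -> survival; ED level -> survival, with the five
confounders exogenous to every equation and freely covarying. The published
diagram is not fully enumerated in text, so this is the minimal edge set
consistent with every published decomposition row: ED level has no
mediator parents (it has no published exclusion variant), and the
admitted-only model adds rhythm -> CAG, ED -> CAG, ED -> TTM (implied by
the published exclusion rows) plus SEP edges into both treatments. The DAG
is user-overridable (`dag_spec()`).

With this edge set the full-population model has 3 degrees of freedom (the
three omitted mediator-to-ED edges), so the test statistic is a real
overall-fit test, not vacuous.

## What the synthetic registry emulates

The generator draws subjects per SEP group with group-specific confounder
distributions (age truncated normal on [19, 105] with published medians and
IQR-derived scales; binary confounders at published group proportions),
then generates the registry variables in temporal order from the
structural equations. Defaults were calibrated analytically, before any
test was run, in two layers:

* **Margins.** Intercepts solve, node by node in temporal order, the exact
  linear relation `E[node] = intercept + sum(coef * E[parent])` so that the
  pooled non-MA margins equal the published cohort prevalences (witnessed
  48.9%, bystander CPR 61.1%, shockable rhythm 16.0%, ED level 1-2 64.3%,
  survival to discharge 8.0%, ...). The MA group is then shifted by the
  exposure coefficients.
* **Effects.** Exposure-to-mediator slopes reproduce published MA-vs-NHI
  prevalence gaps; mediator-to-outcome slopes were solved in closed form so
  that the generating total effect is about -0.031 with through-mediator
  proportions near 15% / 5% / 41% / 10% (witnessed / CPR / rhythm / ED) and
  a direct share near 38% — the headline structure of the published
  decomposition. All slopes live inside ranges where no linear predictor
  leaves [0, 1], so the linear path model is *exactly* correctly specified
  and generator coefficients are the estimands (sharp parameter recovery;
  this is why `linear_probability` is the default link, with `logistic`
  available for realism).

Three structural choices deserve comment. First, survival to discharge is
generated directly from the full-population equation and survival to
admission is drawn as a superset event (discharge forces admission; extra
admissions are drawn so the admission margin matches its own equation).
This keeps the full-population model exactly linear — the alternative,
generating discharge conditionally on admission, makes the marginal
discharge probability a product of linear terms and would bias parameter
recovery. The consequence is that CAG and TTM, generated only among
admitted subjects, have structural coefficient zero on discharge: the
admitted-only analysis exercises the workflow, the screening behaviour and
the algebraic identities, not parameter recovery. Second, TTM receives a
shockable-rhythm edge (+0.15, with the conditional intercept recalibrated
to keep the published admitted-only TTM prevalence): targeted temperature
management follows shockable arrests in practice, and without any
outcome-linked association the admitted-only mediator screen could never
flag TTM. Third, arrest location, bystander AED use and response time are
satellite nodes (no edges into the modelled mediators or outcome): the
published analysis found AED use and response time not to be significant
mediators, and keeping them out of the outcome equations keeps the default
analysis model exactly specified.

Missingness defaults are the published proportions (location 2.9%,
witnessed 9.0%, bystander CPR 2.5%, AED 1.4%, response time 0.2%, rhythm
0.6%), injected MAR with logistic dependence on fully observed covariates
(mild age and metropolitan effects by default) and the intercept calibrated
numerically so the expected rate is hit exactly; MCAR is the zero-slope
special case. Exposure and outcomes are never masked.

What the generator does **not** emulate: exposure-mediator or
mediator-mediator interactions (also absent from the published analysis),
continuous response times, calendar time, EMS system structure, and any
non-random selection into the registry. Passing tests on this generator
therefore demonstrate correctness of the estimators under the model's own
assumptions — not robustness to the ways real registry data violate them.

## Imputation design

Missing Utstein cells are completed by stochastic regression imputation:
logistic models fitted on complete cases, missing cells replaced by
Bernoulli draws at the predicted probability — never by thresholded point
predictions, which would shrink variances. Predictor sets are the full
conditionals: confounders, the 5-level SEP factor, the other Utstein
variables, ED level and the survival outcomes. Conditioning only on
temporally upstream variables looks natural but is wrong here: an imputed
cell would be conditionally independent of its downstream correlates, and
the corresponding path coefficients (e.g. witnessed -> bystander CPR)
attenuate by roughly the masked fraction — an effect that dwarfs sampling
noise at registry scale. Because full conditionals reference columns that
may themselves be missing, imputation runs as a short chained-equations
scheme: marginal-prevalence initialization, then two full-conditional
redraw sweeps in temporal order. At missingness rates of a few percent the
draws stabilize after the first sweep; the second is margin. A single
completed dataset is the default (matching the published analysis);
repeated single imputations under different seeds are available for
sensitivity.

The imputation models are logistic while the generator is
linear-probability; this mild misspecification leaves marginal prevalences
and path coefficients within Monte-Carlo range of complete-data fits at the
stated rates, which the test suite checks directly.

## Numerical choices and degenerate inputs

* Logistic fitting is iteratively reweighted least squares with a
  score-norm convergence check scaled by the information magnitude (an
  absolute 1e-8 norm is unattainable in double precision at N > 1e5 with
  age-scale covariates); separation and boundary fits are flagged, never
  returned silently. Rank-deficient designs error.
* The covariance-structure optimizer rejects non-positive-definite sample
  covariances and N not exceeding the free-parameter count; non-convergence
  is flagged on the fit object and downstream mediation functions refuse
  flagged fits.
* Mediation proportions are undefined at zero total effect and error
  explicitly; decomposition tables suppress proportions for nonsignificant
  effects instead.
* Bootstrap resampling errors if more than 5% of resamples fail to fit;
  resample fits reuse the closed-form solution (`optimize = FALSE`).
* Master seed, deterministic per-stage child seeds; every stage is
  byte-reproducible under a fixed seed, which the pipeline manifest records
  together with a config hash.

## Problem sizes used by the checks

The test suite runs parameter recovery at the published cohort's group
proportions scaled to N = 200 000 across 100 seeds (each structural
coefficient and each mediation proportion within 3 robust/delta SEs of its
generating value in at least 95% of seeds), interval calibration at
N = 20 000 across 100 replications (delta and bootstrap coverage pooled
over the six pathway quantities, B = 500 resamples), and the imputation
prevalence-recovery check at about N = 49 000. These sizes were chosen so
the Monte-Carlo noise floor sits well below the effect sizes being
verified while the whole suite stays comfortably fast on a single CPU.

## Known limitations

* The linear-probability convention can clip in configurations other than
  the calibrated default; clipping is counted and warned about, and the
  path-tracing ground-truth oracle refuses configurations where it occurs.
* "Robust ML" here is one member of a family; exact equivalence with any
  particular commercial implementation is not claimed.
* Single imputation understates imputation uncertainty relative to multiple
  imputation with pooling; at the registry's small missingness rates the
  effect is negligible for point estimates, and pooling is deliberately out
  of scope.
* The admitted-only decomposition conditions on a post-exposure event
  (admission); as in the published analysis it is a descriptive sensitivity
  analysis, not a causally identified quantity.
* Well-fitting indices on the synthetic registry confirm internal
  consistency of the machinery, not the causal truth of any hypothesized
  structure on real data.
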