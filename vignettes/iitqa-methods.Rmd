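---
title: "Quality assessment of investigator-initiated trials: scoring, validation, simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality assessment of investigator-initiated trials: scoring, validation, simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iitqa)
```

## The instrument

Quality of an ongoing investigator-initiated trial (IIT) is treated as a
latent construct measured through four attributes — progress, quality,
regulation, scientificity — each observed through three or four indexes
(thirteen in all), every index scored on a 0–10 scale:

```{r}
iit_instrument()
```

Three measurement kinds exist.

* **Checklist** (10 of 13 indexes): subindex items answered
  Yes / No / Can't answer / Not applicable. The score starts at 10 and
  each No or Can't-answer deducts one point, floored at 0. *Can't
  answer* deducts because an assessor who cannot verify a quality
  component from the submitted documents has found a documentation
  failure, which is itself a quality signal. *Not applicable* never
  deducts — an item that cannot apply (say, blinding in an open-label
  design) is evidence of nothing — and an index whose items are all
  inapplicable is **missing**, not 10: scoring it perfect would reward
  inapplicability.
* **Ratio** (enrollment progress, budget implementation):
  `10 · min(1, achieved/planned)`. The cap reflects that the score range
  is fixed; over-enrollment and overspend are neither rewarded nor
  penalized.
* **Staged** (overall progress): the four recruitment stages are ordered
  and must map monotonically onto 0–10. The mapping is not dictated by
  the construct beyond monotonicity, so the package uses the
  minimal-assumption equally spaced grid {0, 10/3, 20/3, 10}; it is a
  configurable argument of `score_stage()`.

Attribute scores are unweighted means of the present (non-missing) member
index scores, and the overall score the unweighted mean of the present
attribute scores. No aggregation weighting is inherent to the instrument;
as an alternative, `weights = "loading"` weights by the standardized
loadings of the shipped validation model (`reference_loadings()`), which
treats an index's factor loading as its reliability for the construct.
A second alternative reading of checklist scoring — the proportion of
satisfied applicable components, `10 · #Yes / #applicable` — is available
as `mode = "proportional"`; the deduction rule is the default because it
is the operationally stated rule.

Every checklist index carries ten subindex slots in the shipped
instrument. A deduction budget of one point per item with a floor of 0
spans the full scale exactly when ten deductible items exist, and it
makes the simulator's record synthesis exact for integer targets. Custom
instruments with other slot counts are supported (`iit_instrument()` with
a modified index table).

Two modelling choices about ambiguous index definitions: research type
(RCT versus cohort etc.) feeds project metadata and, conceptually, the
level-of-evidence checklist — it does not enter the overall-progress
score, which is purely the recruitment stage; and the subject-management
dropout threshold (dropout below 20% or below the protocol's own bound)
is an ordinary checklist item answered by the assessor, not a quantity
the package recomputes.

## The validation model

The instrument's construct validity is assessed with a second-order
confirmatory factor analysis: the 13 index scores $y$ load on the four
attribute factors $\eta$ (loading matrix $\Lambda$, one marker loading
per factor fixed to 1), which load on a single overall-quality factor
$\xi$ with variance fixed to 1:

$$y = \Lambda\eta + \varepsilon,\qquad \eta = \Gamma\xi + \zeta,$$
$$\Sigma(\theta) = \Lambda(\Gamma\Gamma' + \Psi)\Lambda' + \Theta,$$

with $\Theta = \mathrm{cov}(\varepsilon)$ and $\Psi = \mathrm{cov}(\zeta)$
diagonal. This identification (markers + unit second-order variance,
all four second-order loadings free) keeps every second-order loading
estimable and reproduces the conventional pattern of unit first-order
marker rows in the estimates table. The model has
$9 + 4 + 4 + 13 = 30$ free parameters, so $df = 91 - 30 = 61$.

Estimation minimizes the maximum-likelihood discrepancy
$F_{ML} = \ln|\Sigma| - \ln|S| + \mathrm{tr}(S\Sigma^{-1}) - p$ over the
sample covariance $S$ (denominator $N-1$; incomplete rows are dropped
listwise with a message, since the fitting input is a covariance).
Numerical choices:

* Variances are optimized on the log scale (and the unstructured factor
  covariance of first-order models through a log-diagonal Cholesky
  factor), so $\Sigma$ is positive definite on the whole search space and
  no inadmissibility penalty is needed during iteration.
* Gradients are analytic: with $A = \Sigma^{-1} - \Sigma^{-1}S\Sigma^{-1}$,
  $\partial F/\partial\Lambda = 2A\Lambda\Phi$,
  $\partial F/\partial\Phi = \Lambda'A\Lambda$,
  $\partial F/\partial\Theta = \mathrm{diag}(A)$, chained through the
  transforms.
* The optimizer is a quasi-Newton pass (`nlminb`, relative tolerance
  1e-12, at most 500 iterations) followed by a BFGS polish; the fit is
  declared converged when the transformed gradient's maximum absolute
  entry is below 1e-6. Start values: free loadings 1, residual variances
  half the sample variances, second-order loadings 0.7, disturbances 0.5.
* A Heywood case — a residual or disturbance variance collapsing to the
  boundary — cannot produce a negative estimate under this
  parameterization; it surfaces as a near-zero variance and is flagged
  (`fit$heywood`), typically together with a non-converged gradient,
  since the optimum then lies on the boundary. Small cohorts (tens of
  projects against 30 parameters) do hit this, which is why the pipeline
  refuses to fit when $N$ does not exceed the free-parameter count.
* The chi-square convention is $\chi^2 = (N-1)\,F_{ML}$ (Wishart
  likelihood), matching the $N-1$ in the RMSEA denominator below.
* Standard errors are observed-information: the numerical Hessian of
  $F_{ML}$ on the natural parameter scale at the optimum,
  $\widehat{\mathrm{cov}} = \frac{2}{N-1}H^{-1}$; Wald $z$ and two-sided
  $p$ values follow, with no multiplicity adjustment.

Fit is reported through six indices, computed from the model and
independence-baseline chi-squares ($\chi^2_B = -(N-1)\ln|R|$,
$df_B = p(p-1)/2$): CMIN/DF; the ML-based Jöreskog–Sörbom GFI
$1 - \mathrm{tr}[(\Sigma^{-1}S - I)^2]/\mathrm{tr}[(\Sigma^{-1}S)^2]$;
CFI; TLI; $\mathrm{RMSEA} = \sqrt{\max(\chi^2 - df, 0)/(df\,(N-1))}$;
and SRMR over correlation-metric residuals including the diagonal with
denominator $p(p+1)/2$. GFI and SRMR are named this precisely because
software differs on both (GFI has an unweighted variant; SRMR is
sometimes computed without diagonal terms or with a different
denominator). With $df = 0$ (a saturated model) CMIN/DF, TLI and RMSEA
are undefined and reported as `NA`.

The engine handles the general case — any number of first-order factors
with an unstructured factor covariance, or the single-second-order-factor
form — which is what the test fixtures use (one-factor/3-indicator,
two-factor/6-indicator, second-order/9-indicator, shipped as plain CSV
under `extdata/`). The one-factor fixture is just-identified, so its ML
solution has a closed algebraic form that the tests compare against; the
other fixtures are checked against reference solutions computed once by
an independently coded optimizer and frozen into the suite.

## The cohort simulator

`simulate_scores()` draws index scores from exactly the generating
process the validation model assumes: $\xi \sim N(0,1)$,
$\eta_k = \gamma_k\xi + \zeta_k$ scaled to unit variance,
$y_j = \lambda_j\eta_{f(j)} + \varepsilon_j$ scaled to unit variance,
using the shipped standardized loadings as defaults. The standardized
scores are then mapped to the 0–10 scale by an affine map and truncated.

* **Score scale, mean 8, SD 1.5 per index.** Real cohorts of funded,
  ethics-approved trials score high (observed index means run roughly
  from 6 to 9.5); mean 8 with SD 1.5 puts about ninety percent of scores
  in 5.5–10.5 before truncation. The choice is cosmetic for every
  statistical property tested — parameter recovery operates on the
  standardized scale — and is configurable in `sim_config()`.
* **Truncation attenuates correlations.** Clamping to [0, 10] piles
  probability at 10 and shrinks every correlation toward 0, so
  recovery experiments must run with `truncate = FALSE` and
  `standardized = TRUE`; the tests do.
* **Metadata** (research type, field, centers, funding band, status,
  sample-size band) is drawn independently per item from the reference
  cohort's category proportions. Items are independent across columns —
  the simulator does not model, say, RCTs being more often multicenter.
  Optional `group_shifts` add a mean offset on chosen indexes for chosen
  research types (e.g. an RCT enrollment deficit) before truncation,
  the simplest mechanism that produces group differences on a radar
  chart.
* **Normality is an assumption of this module, not a property of real
  score data**, which are discrete (checklist scores are integers) and
  bounded. Passing recovery tests therefore shows the engine estimates
  the model it was given; it does not show that real IIT scores follow
  a second-order normal factor model.

`synthesize_records()` inverts the scoring engine so that simulated
scores become full project records: a checklist index with target $s$
gets `round(10 - s)` No responses among its ten slots, ratio indexes get
`round(s/10 · planned)` as the achieved quantity, and the staged index
snaps to the nearest stage level. Scoring the synthesized records
reproduces integer checklist targets exactly (the round trip the tests
assert on a 1,000-project cohort); ratio targets come back within the
rounding granularity of the drawn denominator, and stage targets within
half a grid step.

`reference_cohort()` is the deterministic companion: it replicates the
published per-item category counts of the 272-project development cohort
(each item independently, so every marginal is exact) for reproducing the
cohort-summary percentages. Percentages are rounded half-up to 2
decimals, the convention of the printed tables, which differs from base
R's `round()` at exact midpoints.

## Problem sizes and runtime

The suite fits the 13-indicator model at $n$ = 20,000 (parameter
recovery, tolerance ±0.02 on extreme standardized loadings — a size
where a single fit takes well under a second with analytic gradients),
5,000 (self-consistency: CFI ≥ 0.99, RMSEA ≤ 0.03, SRMR ≤ 0.02),
and checks simulator convergence at $n = 10^5$ (empirical versus
model-implied correlations within 0.02; metadata shares within 0.5
percentage points). The fixture fits use $n$ = 200–300.

## Known limitations

* The published fit statistics of the instrument's original validation
  (CMIN/DF 1.868, GFI 0.916, CFI 0.936, TLI 0.919, RMSEA 0.063,
  SRMR 0.076 at $N = 257$) reflect a proprietary cohort that is not
  deposited; nothing in this package can or does reproduce them. The
  engine is validated by oracle equivalence, closed forms, and recovery
  instead. The simulator deliberately generates data that *fit* the
  model; it makes no attempt to replicate the original cohort's misfit.
* Only normal-theory ML is implemented: no robust or categorical
  estimators (WLSMV), modification indices, multi-group CFA, or
  exploratory factor analysis. For 0–10 bounded discrete scores treated
  as continuous indicators this is the conventional, not the optimal,
  choice.
* Expert-consensus machinery (Delphi rounds, authority coefficients)
  that produced the instrument's content is a human process with no
  recomputable inputs and is out of scope; the instrument ships as
  given.
* The flat CSV/JSON record dialect replaces a data-capture service; it
  validates tokens and structure but does not manage users, audit
  trails, or amendments.
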