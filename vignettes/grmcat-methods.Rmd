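---
title: "Methods: graded response modelling and adaptive-test simulation in grmcat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graded response modelling and adaptive-test simulation in grmcat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grmcat)
```

`grmcat` analyses short ordinal clinical questionnaires with a five-step
psychometric pipeline and simulates how the instrument would behave as a
computer adaptive test (CAT). This vignette is the package's own account
of the models it fits, the numerical choices it makes, what its synthetic
data generator does and does not emulate, and the limits of what a green
test establishes.

## The measurement model

Each of the $K$ items is scored in $m + 1$ ordered categories
$0, 1, \dots, m$ (the default bank has $m = 2$). Under the graded
response model, item $i$ is characterised by a discrimination
$\alpha_i > 0$ and strictly increasing thresholds
$\beta_{i1} < \dots < \beta_{im}$. The *boundary curves* give the
probability of responding in category $k$ or higher:

$$P^*_{ik}(\theta) = \frac{1}{1 + e^{-\alpha_i(\theta - \beta_{ik})}},
  \qquad P^*_{i0} \equiv 1,\; P^*_{i,m+1} \equiv 0,$$

and category probabilities are differences of adjacent boundaries,
$P_{ik} = P^*_{ik} - P^*_{i,k+1}$, which sum to 1 by construction. We use
the **pure logistic metric, without the historical 1.7 scaling
constant**. This is stated prominently because it changes every numeric
value downstream: discriminations reported on the normal-ogive metric
would differ by that factor. The default 19-item bank's published
parameters are consistent with the logistic convention of the R IRT
lineage that produced them.

Fisher information for an item is
$I_i(\theta) = \sum_k (w_{ik} - w_{i,k+1})^2 / P_{ik}$ with
$w_{ik} = \alpha_i P^*_{ik}(1 - P^*_{ik})$ and $w_{i0} = w_{i,m+1} = 0$;
test information is the sum over items. Category probabilities inside
information and likelihood ratios are floored at $10^{-10}$ to avoid
division underflow at extreme $\theta$; unit tests verify that the
information still agrees with the finite-difference curvature of the
log-likelihood to $10^{-4}$ at interior $\theta$.

## Calibration

The estimation algorithm is marginal maximum likelihood by EM, with a
standard-normal latent density and 41-node Gauss–Hermite quadrature
(`statmod::gauss.quad.prob`). The E-step computes each person's posterior
weight at each node; the M-step maximises each item's expected
complete-data log-likelihood by BFGS with analytic gradients in an
unconstrained parameterisation $(\log\alpha,\ \beta_1,\
\log(\beta_2-\beta_1), \dots)$ that enforces ordered thresholds. EM exits
when the marginal log-likelihood improves by less than $10^{-6}$, capped
at 500 iterations (returning `converged = FALSE` rather than erroring).
Standard errors use the per-item empirical cross-product of marginal
score vectors — a block-diagonal approximation to the observed
information that ignores cross-item covariance; it is accurate enough for
the screening purposes it serves here and cheap at any bank size.

Parameter recovery is checked by simulation: cohorts of $n = 2000$ drawn
from the default bank with $\theta \sim N(0,1)$ are refit, and the mean
absolute error over 20 replicates must stay below 0.35 for $\alpha$ and
0.15 for $\beta$. Note the **recovery cohorts use a standard-normal
trait**, not the clinical mixture: the latent scale is identified only up
to the calibration prior, so fitting mixture-generated data with an
$N(0,1)$ prior measures prior misspecification (a roughly 1.4-fold scale
inflation from the mixture's larger variance), not the estimator's
recovery error.

## Trait estimation

The default estimator is EAP: the posterior mean under an $N(0,1)$ prior,
evaluated on a fixed 61-node equispaced grid over $[-4.5, 4.5]$, with the
posterior standard deviation as its `se`. The grid covers the plotted and
clinically relevant range; tests require agreement with a $10^5$-point
dense-grid posterior mean to $10^{-3}$ on random partial patterns. MLE is
available but flagged at the boundary for all-minimum / all-maximum
patterns (its likelihood has no interior maximum there), which is exactly
the situation early in an adaptive administration — hence EAP is the CAT
default, and the choice is surfaced in `cat_config()` because branching
behaviour of the decision tree depends on it.

## Step 1–2 conventions

* Cronbach $\alpha$ uses the population-variance convention (divide by
  $n$), stated so that hand-computed toy examples match exactly. Item
  descriptives print sample SDs.
* PCA and CFA operate on **Pearson correlations of the raw 0/1/2
  scores**. Polychoric correlations and weighted least squares are
  deliberate non-goals: the source analyses do not name their correlation
  type, and Pearson + maximum likelihood is the simplest defensible
  choice. With three categories and a skewed trait, Pearson correlations
  attenuate loadings somewhat; the screens are pass/fail against
  conventional cut-offs (first component ≥ 20% of variance,
  first/second eigenvalue ratio ≥ 4), which the attenuation does not
  endanger on unidimensional data.
* The one-factor CFA is the ML factor solution (via `factanal`'s
  uniqueness optimisation); the model $\chi^2$ is $(n-1) F_{ML}$ with no
  Bartlett correction, applied identically to the independence baseline,
  so CFI/TLI are internally consistent. RMSEA confidence limits invert
  the noncentral $\chi^2$ distribution. SRMR averages squared residual
  correlations over the lower triangle *including* the diagonal (a stated
  convention; the diagonal residuals are zero under the unit-variance
  parameterisation, so this only rescales).
* Local independence is operationalised purely as the $|r| > .2$ flag on
  residual correlations, and monotonicity purely as the Mokken
  scalability flag $H_j < .3$ — the two flagging rules the pipeline's
  design prescribes. Full manifest-monotonicity restscore checks are not
  implemented. The maximal covariance in Loevinger's $H$ is computed
  from the comonotonic coupling of the observed marginals (sorting both
  items), which an exhaustive cross-table enumeration oracle confirms on
  small examples.

## DIF screening

The matching variable is the pooled EAP $\hat\theta$, computed once — no
iterative purification (the method family is named in the source
analyses, purification is not; this is the simplest faithful reading, and
it biases the screen slightly toward conservatism when large DIF
contaminates the matching score). For each item × binary covariate, three
nested proportional-odds models are fitted by Newton–Raphson (analytic
gradient and Hessian, step-halving, gradient norm $< 10^{-8}$; ridge
fallback under separation): M1 $y \sim \hat\theta$, M2 adding the group
main effect, M3 adding the interaction. The **2-df likelihood ratio of M3
against M1** carries the $\alpha = .01$ flag; uniform and nonuniform
components are reported informationally. Effect sizes are McFadden
pseudo-$R^2$ differences (M3 − M1 against the intercept-only null),
banded as negligible $< .13$, moderate $.13$–$.26$, large otherwise.
Age enters dichotomised exactly as the two printed bands (18–49 / 50–69);
persons outside them are excluded from that covariate's test.

Calibration is verified by simulation: under a no-DIF generative world
the per-test flag rate over 500 replicate cohorts ($n = 1000$) must fall
in $[0.002, 0.03]$, and uniform DIF injected as a 0.8 threshold shift at
$n = 2000$ must be flagged in more than 80% of 200 replicates.

## The CAT simulation

The post-hoc CAT replays each person's recorded full-instrument
responses: starting from the entry level $\theta = 0$, it administers the
unadministered item with maximum Fisher information at the current
estimate (ties broken to the lowest item id, making replay
deterministic), re-estimates $\theta$, and stops when the normal
$\hat\theta \pm z\,\mathrm{se}$ interval ($z = 2.5758$ at the default
99%) lies entirely on one side of the classification cut-off
$\theta = -1$ — the trait value mapped to the instrument's raw elevated
risk bound — provided at least `min_items` (default 3, matching the
standard comparison rows) have been administered; a cap of `max_items`
(default 6) bounds the burden for low-severity respondents, whose
information-poor region of the scale would otherwise exhaust the bank.
The full-test reference classification is the EAP over all items against
the same cut-off. `export_decision_tree()` enumerates every response
path of this algorithm into a clinical flow-chart (JSON or DOT).

Two documented reproducibility caveats: the original analyses' exact
branch structure below the root (which item follows a middling first
response) depends on the unstated trait estimator and scaling of the
software that produced them, so tests assert the root item and structural
properties of the tree, not specific deeper branches. Likewise, whether
the historical full-test classification used $\hat\theta$ or the raw sum
score is unstated; the package uses $\hat\theta$ and reports raw-score
counts alongside where relevant.

## The synthetic cohort: what it is and is not

With no deposited respondent data, every cohort-level behaviour is
demonstrated on synthetic data. The generator draws:

* $\theta$ from the mixture $0.2\,N(-2.2, 0.4^2) + 0.8\,N(0.6, 1^2)$ —
  a right-heavy clinical severity distribution whose floor group
  produces roughly a fifth of total scores equal to 0 under the default
  bank (about 21%; the motivating cohort showed 18.4%). This is a
  *stated world*, chosen once and documented, not a calibration target:
  no generator parameter is tuned against test outcomes.
* covariates (gender, age band, education, administration mode) as
  independent 50/50 Bernoulli draws, independent of $\theta$, so DIF
  type-I behaviour is clean by construction;
* responses from the GRM itself, with optional uniform DIF injected by
  shifting all of a target item's thresholds by a constant for the focal
  group.

Because responses are generated *from* the GRM, a green pipeline run on
synthetic data establishes internal consistency — the estimators recover
what generated the data, the screens pass where they should — but cannot
establish how the real instrument misbehaves. Concretely: the two items
whose published category curves warranted inspection (near-coincident
thresholds) do *not* reproduce their real-data category-mean overlap in
GRM-consistent synthetic data, because the model the data are drawn from
is exactly the model being diagnosed. The diagnostic
(`mean_theta_by_response()`, adjacent-category 95% CI overlap flags) is
therefore tested against a constructed trait-independent item, the misfit
pattern it exists to catch. Response styles, missingness, and
multidimensionality are likewise outside the generator's world.

## Numerical and degenerate-input policy

* Thresholds must be strictly increasing at construction; transiently
  disordered M-step iterates are re-sorted at exit.
* Items with all responses in one category abort calibration with an
  instruction to collapse; empty categories are flagged by
  `validate_dataset()` before fitting.
* Missing responses are rejected at load time (complete-case contract):
  the motivating analyses used only complete responders, and imputation
  is a non-goal.
* Zero-variance items error in PCA (named), are excluded with a warning
  from scalability, and make Cronbach $\alpha$ an explicit error when
  the total score is constant.
* Heywood cases in the CFA (uniqueness at its lower bound) are flagged
  in the report but the fit is still returned.
* All stochastic operations take an explicit seed; a cohort is a pure
  function of its `cohort_spec`.

## Known limitations

* Pearson-ML factor analysis on 3-category items is an approximation;
  polychoric/WLSMV alternatives are out of scope by design.
* MML standard errors are block-diagonal (per item) and ignore
  cross-item information.
* The DIF screen handles binary groups only, with no anchor
  purification and no IRT-likelihood-ratio variant.
* The CAT simulation is post-hoc: it replays recorded responses and
  cannot capture order or context effects of a live adaptive
  administration, nor exposure control or content balancing.
* The headline empirical quantities of the motivating study (its exact
  reliability, fit indices, and classification counts) depend on its
  undeposited patient data and are reproduced here only structurally —
  same tables, computable on any conforming cohort — never numerically.
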