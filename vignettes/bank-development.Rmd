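---
title: "Developing an adaptive depression measure with catgrm"
author: "catgrm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing an adaptive depression measure with catgrm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catgrm)
```

## The measurement problem

Self-report depression scales built on classical test theory require every
respondent to answer every item, and their scores are tied to the sample the
scale was normed on.  Item response theory (IRT) addresses both problems: it
models the probability of each response category as a function of a latent
severity $\theta$, so items can be added, dropped, or administered
adaptively while scores stay on a common scale.  `catgrm` implements the
full development workflow for such a measure from ordinal questionnaire
data: item screening, graded response model (GRM) calibration, item-level
diagnostics, computerized adaptive testing (CAT) simulation, and the
calibration of a legacy short form onto the new scale for a precision
comparison.

The package was designed around a study setting of roughly 400 oncology
patients answering about 60 five-category symptom items
(1 = none ... 5 = always) with low average severity, together with a
co-administered nine-item legacy form coded 0–3.  Since such datasets are
rarely shareable, a synthetic-cohort generator with known ground truth is a
first-class part of the package: every stage can be validated against
simulated data whose true parameters, severities, and planted assumption
violations are recorded.

## The graded response model

For an item with $K$ ordered categories, discrimination $a > 0$ and
thresholds $b_1 < \dots < b_{K-1}$, the cumulative ("operating") curves are
logistic in the latent severity,
$$P^*_k(\theta) = \frac{1}{1 + e^{-a(\theta - b_{k-1})}},\qquad k = 2,\dots,K,$$
with $P^*_1 = 1$ and $P^*_{K+1} = 0$; category $k$ has probability
$P^*_k(\theta) - P^*_{k+1}(\theta)$.  The logistic metric with scaling
constant $D = 1$ is used throughout, so parameters are directly comparable
to those printed by the common IRT packages.  $b_k$ is the severity at
which a respondent is equally likely to answer in category $k{+}1$ or above
as below; $a$ controls how sharply the item separates nearby severities.

Calibration maximizes the marginal likelihood with the latent density fixed
at $N(0,1)$ (the standard identification for a single group), by an EM
algorithm: the E-step forms each person's posterior over a quadrature grid,
the M-step maximizes each item's expected complete-data log-likelihood by
quasi-Newton ascent with analytic gradients, in an unconstrained
parameterization ($\log a$, $b_1$, log threshold gaps) that enforces the
parameter constraints by construction.  The default grid is 61 equally
spaced nodes on $[-6, 6]$ with renormalized normal weights; convergence is
declared when no parameter moves by more than $10^{-4}$ between cycles
(cap: 500 cycles, flagged rather than raised).  The marginal log-likelihood
is non-decreasing over cycles — a property the tests assert — and missing
responses are marginalized out of the likelihood.

Scoring offers the three classical estimators.  MLE maximizes the response
likelihood on the support $[-6,6]$; all-extreme response patterns have a
monotone likelihood, so the estimate is clamped to the support edge and
flagged rather than diverging.  BME (MAP) maximizes the posterior under the
$N(0,1)$ prior, and EAP is the posterior mean by quadrature.  The standard
error of measurement (SEM) follows the estimator: $1/\sqrt{I(\hat\theta)}$
for MLE, $1/\sqrt{I(\hat\theta)+1}$ for BME (the prior contributes one unit
of precision), and the posterior standard deviation for EAP.  With zero
answered items the Bayesian estimators return the prior ($\theta = 0$,
SEM $= 1$).  The Bayesian SEM conventions matter downstream: they are why
Bayesian CAT sessions terminate earlier than MLE sessions on the same data.

## The item-screening funnel

Items pass through a fixed sequence of checks, each mirroring a standard
step of bank development, and every exclusion is recorded in an audit whose
counts chain (entering − excluded = surviving at each stage):

1. **Unanswered categories.**  An item with a category no respondent chose
   cannot have all its thresholds estimated and is excluded.  In
   low-severity cohorts these are overwhelmingly the top categories.
2. **Item-remainder correlation.**  Items correlating below 0.3 with the
   sum of the remaining items violate internal consistency.  The rule is
   strict (`< 0.3`); the boundary value is retained.
3. **Unidimensionality (PCA).**  The first principal component of the
   Pearson correlation matrix must explain at least 20% of the variance and
   at least 4 times the second component.  While the criteria fail, the
   item with the smallest absolute first-component loading is dropped
   (floor: 3 items).
4. **Local independence.**  A one-factor maximum-likelihood factor model
   (via `stats::factanal`, with a principal-axis fallback and loadings
   clamped below 1 in Heywood cases) yields residual correlations
   $R - \Lambda\Lambda'$; of any pair above 0.2, the member with the lower
   first-factor PCA loading is excluded, in a single pass over flagged
   pairs ordered by residual size.
5. **Monotonicity (scalability).**  Loevinger coefficients in the
   polytomous covariance-ratio form,
   $H_{ij} = \mathrm{cov}(X_i, X_j)/\mathrm{cov}_{\max}(X_i, X_j)$ with the
   denominator from the comonotone coupling of the two margins, pooled into
   item coefficients $H_i$; items with $H_i < 0.3$ are excluded.

Correlation-based stages treat category codes as numeric — the classical
convention for this screening stage; polychoric correlations are out of
scope.  Cronbach's alpha uses complete-case rows; correlation matrices use
pairwise deletion with a complete-case fallback if the pairwise matrix is
indefinite.

After calibration two model-based checks continue the funnel: items with a
category that is never the modal response at any $\theta$ (scanned at 0.01
resolution on $[-6,6]$, ties to the lower category) are excluded, and items
failing the S-X² fit statistic at $\alpha = 0.01$ are excluded.  Finally,
likelihood-ratio DIF tests at $\alpha = 0.01$ check measurement equivalence
across person covariates (e.g. age group and sex).

### S-X² and DIF conventions

S-X² compares observed and expected category frequencies within
summed-score groups, with the score distribution of the remaining items
obtained by recursive convolution over the quadrature grid.  The exact
polytomous collapsing rule differs between software versions; here,
category cells with expected count below 1 merge into their neighbor within
each score group, degenerate extreme score groups collapse inward, and the
degrees of freedom are the independent cells after collapsing minus the
number of item parameters.  Under correctly specified simulations this
calibration holds the nominal $\alpha = 0.01$ (the acceptance suite checks
the rejection rate lands in [0.003, 0.03]).

DIF uses one-at-a-time likelihood-ratio tests: the baseline two-group model
shares all item parameters and frees the focal group's latent mean and
variance; the augmented model additionally frees the studied item's
parameters in the focal group (all other items anchor; no purification).
LR $= 2\Delta\log L$ with df equal to the number of freed parameters.
Because the statistic needs likelihood precision rather than parameter
precision, the internal EM accepts an additional per-cycle log-likelihood
stopping rule; LR values are stable to well under 0.1 across the exposed
tolerance range.

## The CAT engine

A session starts at $\theta_{est} = 0$, administers at least 3 items, and
repeats: select the most informative remaining item, obtain a response,
re-estimate $\theta$ and its SEM, and stop once the SEM falls to the
threshold (0.32 and 0.50 are the conventional choices, corresponding to
reliabilities of about 0.90 and 0.75) or the item budget — by default the
bank size — is exhausted.  Two selectors are provided: unweighted Fisher
information at $\theta_{est}$ (UW-FI), and the symmetrized pointwise
Kullback–Leibler divergence between the item's category distributions at
$\theta_{est} \pm \delta$ (FP-KL, default $\delta = 0.1$).  For small
$\delta$ the KL criterion is approximately $4\delta^2 I(\theta)$, so the
two selectors coincide in the limit — a property the tests exploit.  Ties
break to the lowest item id.

Responses are drawn from the graded model at the simulee's generating
severity, or replayed from a recorded response vector.  Cohort simulations
assign each simulee an independent substream of the master seed, so results
are reproducible and independent of processing order.  Accuracy is
summarized by the Pearson correlation between final estimates and
generating severities, with the 95% Fisher-z interval
$\tanh(\mathrm{atanh}(r) \pm 1.96/\sqrt{n-3})$.

A caveat worth knowing: on low-severity cohorts many simulees answer the
lowest category on every administered item, and their MLE sits clamped at
the support edge.  MLE rows of a simulation grid therefore show markedly
lower correlations than BME/EAP rows — an artifact of boundary handling on
sparse patterns, not of item selection.

## Legacy-form comparison

`fixedCalibrate` places a legacy short form on the bank's scale by EM with
the anchor items frozen: the E-step posterior uses all items, the M-step
updates only the legacy items, and the latent density stays $N(0,1)$.
Anchors are returned bit-identical, and fixing the anchors at a joint
maximum-likelihood solution reproduces that solution's legacy parameters
(idempotence, asserted to $10^{-3}$).  Scoring the cohort with the
calibrated legacy form only, and with fixed-length 4- and 8-item CATs,
yields (estimate, SEM) clouds that are smoothed by local-linear tricube
regression (`stats::lowess`, span 2/3, no robustness iterations, evaluated
on a common 50-node grid spanning the central 96% of the observed
estimates).  `precisionDominance` then reports whether one curve lies below
the other at every node — the formal version of "a 4-item adaptive test
beats the full legacy form".

## The synthetic cohort generator

Defaults emulate the design setting: 393 respondents, 62 five-category
items, discriminations uniform on [1.5, 3.4], first thresholds on
[0.0, 1.6], last thresholds on [2.5, 4.4], and a severity distribution
given by the two-component mixture $0.75\,N(-0.6, 0.8^2) +
0.25\,N(0.8, 1^2)$.  The mixture was chosen once so that the resulting
mean item score falls near 1.4 of 5 with rarely endorsed top categories —
the regime the workflow is built for; no single summary pins the
distribution down, so a right-skewed mixture is the natural choice for a
non-clinical oncology cohort.  Interior thresholds are sorted uniform
draws between the outer two, re-drawn a few times to keep neighboring
thresholds at least about 0.35 apart (equally spaced fallback): without a
gap floor, roughly half of a generated bank acquires never-modal
categories once fitted, and the funnel no longer resembles a realistic
bank.  Even with the floor, a study-like run excludes a substantial share
of items for unanswered top categories and degenerate category curves —
deliberately so, as that is the regime's signature.

A nine-item legacy form (four categories, raw 0–3 coding) is generated
from the same severities with moderate discriminations, and age/sex-like
group labels are drawn independently of severity, so DIF analyses on the
synthetic cohort are true nulls.  Violations are opt-in and recorded:
a shared binary nuisance factor of strength $\gamma = 2$ for one item pair
(local dependence), a +0.5 threshold shift in a random focal half (DIF),
a unimodal response profile $\theta \mapsto 0.5 - |\theta|$ (monotonicity
violation), and a regenerated item with $a = 0.2$ (low discrimination).

What passing tests on this generator do **not** show: real symptom data
have polytomous ordinal structure only approximately captured by Pearson
correlations, local dependence arising from item wording rather than a
binary nuisance factor, and respondent behaviors (careless responding,
acquiescence) that no GRM simulee exhibits.  Results on synthetic cohorts
validate the machinery, not the clinical instrument.

## Numerical choices and limitations

* Quadrature: 61 equally spaced nodes on $[-6,6]$; EAP agrees with a
  2001-node grid to $10^{-3}$ on random patterns, and probabilities are
  floored at $10^{-300}$ before logs.
* EM convergence: max parameter change $10^{-4}$ (500-cycle cap); an
  optional log-likelihood rule serves likelihood-ratio testing.
* Category codes are 1-based internally; 0-based legacy scales declare an
  offset and are shifted on import/export.
* Validation problem sizes: parameter recovery uses 28 items at
  $n = 1000$ over 20 seeds; type-I error checks use 200 replicates; CAT
  contract checks use $n = 393$ simulees; screening power checks use
  $n = 400$ — sizes chosen to estimate each property with useful precision
  while keeping a full validation run practical on one core.
* Not implemented (out of scope): polychoric correlations, bifactor and
  multidimensional models, Mokken automated item selection and manifest
  monotonicity tests, DIF purification, exposure control and content
  balancing, raw-score crosswalk tables.

## A minimal worked example

```{r example, eval = FALSE}
cohort <- makeStudyCohort(cohortSpec(seed = 20220517))
scr <- runScreening(cohort$responses)
fit <- fitGRM(cohort$responses[, scr$surviving])
theta <- scoreTheta(cohort$responses[, scr$surviving],
                    calibratedBank(fit), method = "BME")$theta
sim <- simulateCat(calibratedBank(fit), theta,
                   catConfig(estimator = "BME", selector = "UW-FI",
                             semThreshold = 0.50, seed = 1))
sim
```

For the full study flow — screening, calibration, maximality/S-X²/DIF
exclusions, the estimator × selector × threshold simulation grid, and the
legacy-form precision comparison — use `runPipeline()` and serialize the
result with `buildReport()`.
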