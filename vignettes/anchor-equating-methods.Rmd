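---
title: "Anchor-item equating and parameter recovery: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-item equating and parameter recovery: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorlink)
```

## The model

Responses are dichotomous and follow the logistic IRT family. For person
ability $\theta$ and item parameters $(a_i, b_i, c_i)$,

$$p_i(\theta) = c_i + (1 - c_i)\,
  \frac{\exp[a_i(\theta - b_i)]}{1 + \exp[a_i(\theta - b_i)]},$$

with $a_i$ forced to 1 under the 1PL and $c_i$ forced to 0 under the
1PL/2PL. The key identification fact driving everything else: a calibration
with a standard-normal latent prior expresses its estimates on the scale of
*its own sample*. Two forms calibrated on different samples therefore
disagree by (approximately) a linear map, and the anchor items — shared
between forms — are the data from which that map is estimated.

All five implemented linking methods estimate the same map
$b_{\mathrm{target}} = A\,b_{\mathrm{source}} + B$,
$a_{\mathrm{target}} = a_{\mathrm{source}}/A$, $c$ unchanged:

* **MS** (mean-sigma): $A = \sigma(b_t)/\sigma(b_s)$,
  $B = \bar b_t - A \bar b_s$.
* **MM** (mean-mean): $A = \sum a_s / \sum a_t$, same $B$.
* **MGM**: $A$ is the geometric mean of the per-anchor ratios $a_s/a_t$.
* **IRF** (Haebara): minimizes
  $\tfrac12 \int \sum_i [p_{t,i}(\theta) - p_{s,i}(\theta; a_s/A, A b_s + B, c_s)]^2 h(\theta)\,d\theta$.
* **TRF** (Stocking-Lord): the same criterion with the square outside the
  sum over anchors (test-level difference). With one anchor the two
  coincide.

A deliberate design choice: the mean-sigma slope is implemented as
$\sigma(b_t)/\sigma(b_s)$ — the orientation implied by
$b_t = A b_s + B$ (under which $\sigma(b_t) = A\,\sigma(b_s)$) and by the
MM/MGM formulas. The inverted ratio sometimes seen in print is
algebraically inconsistent with that transformation and would make MS
estimate the inverse map; all five methods here are consistent estimators
of the *same* map, which the test suite asserts by planting a known
$(A, B)$ on noiseless anchors.

Indirect (chained) equating composes links as linear maps: for
$1 \to 2 \to 3$, $A_c = A_{12} A_{23}$ and $B_c = A_{23} B_{12} + B_{23}$.
Composition is exact and associative; any printed closed form for the chain
constant must reduce to it, so the implementation *is* the composition.

## Calibration

`fit_irt()` maximizes the marginal likelihood by EM over a fixed quadrature
grid.

* **Grid**: 61 equally spaced nodes on $[-6, 6]$, standard-normal weights
  renormalized to sum to one. Dense enough for 3PL tails; deterministic, so
  identical inputs give identical outputs.
* **M-step**: per-item Fisher scoring on $(\log a, b, \mathrm{logit}(c/c_{\max}))$
  with step halving against the expected complete-data log-likelihood. A
  step is accepted only if it does not decrease that objective, which makes
  every cycle a generalized-EM ascent step; the marginal log-likelihood
  trace is returned and tested to be nondecreasing. (One subtlety worth
  recording: the entry reparameterization of $c$ must clamp consistently
  with the bound on its logit, otherwise a pinned-at-zero $c$ drifts by a
  few times $10^{-7}$ per cycle and the ascent property fails at the
  $10^{-8}$ tolerance.)
* **Convergence**: maximum absolute change in any item parameter
  $< 10^{-4}$ between cycles, budget 500 cycles. Exceeding the budget
  returns `converged = FALSE` with usable estimates; the study layer counts
  it as a non-convergence rather than an error.
* **3PL identification**: $c$ estimated under a box constraint $[0, 0.5]$
  via logit reparameterization, no prior — the likelihood stays pure and
  $c_{\max}$ is configurable.
* **Initialization**: $a = 1$, $b = \Phi^{-1}(1 - \bar p)$ clipped to
  $[-3, 3]$, $c = 0.1$.
* **Inestimable items**: all-correct or all-incorrect columns are excluded
  and listed in the result instead of crashing or producing infinities.
* **Abilities**: EAP (posterior mean on the grid). The scoring rule behind
  equated-ability comparisons is genuinely open in parts of the literature;
  EAP was chosen because shrinkage keeps every response pattern finite.
  Sensitivity of downstream conclusions to ML vs EAP scoring is untested.

## The synthetic world

The generator's defaults state one fixed world, and the tests interrogate
that world rather than tuning it:

* Three test forms of `tss` items each; forms 1–2 and 2–3 share
  `max(1, round(aip × tss))` anchors (round half up — a 5% proportion of a
  20-item form must still yield one anchor or equating cannot exist). No
  item is shared between forms 1 and 3.
* Discriminations are log-normal with mean 1.00 and SD 0.20 *of the
  discriminations themselves* (the underlying normal's parameters are
  solved from the moment equations — the printed moments then hold exactly
  in expectation). Difficulties are N(0, 1). All items of a scenario share
  its guessing probability $c \in \{0, .125, .167, .25\}$, i.e. $1/d$ for
  $d$ response options.
* The three samples are drawn from N(−0.5, 0.8²), N(0, 1), N(+0.5, 1.2²);
  sample $j$ takes form $j$. We read the design's "latent means drawn from
  normal distributions" as fixed population parameters per sample — the
  alternative (sample-level random means with SD up to 1.2) would destroy
  the factor manipulation the design depends on.
* Responses always honor $c$: the 2PL-vs-3PL distinction applies at
  calibration only, so a 2PL fit of guessing data is a (deliberate)
  misspecification scenario, not a bug.
* Randomness: each iteration owns a master seed; items, abilities and
  responses draw from deterministically derived child streams (a Lehmer
  step modulo $2^{31}-1$), so any stage is independently reproducible and
  both IRT models consume bit-identical responses.
* Anchor discriminations receive no special manipulation; the realized mean
  true anchor discrimination is recorded per iteration as a covariate
  (`M_aa`). Whether the original full-scale design manipulated anchor
  discrimination as a factor is not stated with levels anywhere we could
  verify; we expose the covariate rather than guessing a design.

What a green simulation test therefore establishes: the pipeline's
estimates converge on the generating values in the directions and orders of
magnitude expected. What it does not establish: behavior under real-data
features the generator omits — multidimensionality, item drift, missing
responses within a form, speededness, or dependence between items.

## The study pipeline

Per iteration: generate bank → draw samples → simulate responses → calibrate
each form under each model → for each method, link 1→2 and 3→2 directly,
compose 1→3 for chain checks → transform forms 1/3 item estimates and EAP
abilities onto form 2's scale → compute indices against the generating
values, pooling items of all forms (anchors contribute one estimate per
form hosting them) and all persons.

Form 2 is the reference scale because its sample is N(0, 1): its
standardized calibration coincides in expectation with the generating
metric, so true-vs-estimated comparisons need no re-standardization. True
values are used exactly as generated.

Recovery indices: Pearson $r$ (association-based; invariant to linear maps
of the estimates) and bias, MAE, RMSE, SEE (error-based; not invariant —
that contrast is the point of reporting both). SEE is defined as the
population SD of the errors, which buys the exact identity
$\mathrm{RMSE}^2 = \mathrm{bias}^2 + \mathrm{SEE}^2$, asserted to
$10^{-10}$ on random inputs. A regression-based SEE variant was rejected
for testability. Correlations on zero-variance input are recorded as
missing and excluded from cell means, with the exclusion counted.

Trimming: within each scenario × model × method × parameter × index cell,
values outside the central block delimited by the nearest-rank 2.5% tail
ranks are removed (for 1000 distinct values, exactly the central 950
remain; for $n = 3$ the tail rank does not exist and nothing is removed —
pinned by a unit test). Trimming granularity follows the "inner 95% of the
1,000 values" reading; a literal per-iteration reading is self-contradictory
since an iteration contributes one value per cell.

## Desk-scale testing strategy

The full design (400 scenarios × 1000 iterations × 2 models × 5 methods)
is a cluster job, not a test. The suite instead asserts:

1. exact/analytic targets (design arithmetic, closed-form sampling errors,
   $c = 1/d$, planted-link recovery, index algebra);
2. property tests (EM ascent, monotone ICCs, transform inverses, chain
   associativity, trimming idempotence, determinism);
3. a pilot profile (`pilot_config()`): {20, 40} items × {5%, 25%} anchors ×
   {100, 500} persons × {0, 0.25} guessing, 30 iterations, 2PL, MM + IRF —
   about two minutes of CPU — asserting the *directions* of the main
   effects: correlations fall as guessing rises (all three parameters),
   rise with sample size ($a$, $b$), and error indices shrink with sample
   size. Magnitudes at this scale are not comparable to full-scale grand
   means (the pilot omits the catastrophic n = 25/50 cells, so its means
   are much friendlier), and the acceptance report labels them as pilot
   values accordingly.

## Known limitations

* No standard errors for item estimates, no MCMC/JML estimators, no
  polytomous or multidimensional models, no equipercentile or concurrent
  linking — all out of scope by design.
* The linear mixed models and false-discovery-rate machinery used for
  full-scale inference are intentionally absent; `run_study()` exports the
  long-format records those tools consume (`write_results()`), and that is
  the supported hand-off.
* Config files are JSON (not YAML): no YAML parser is part of this
  package's dependency footprint.
* The characteristic-curve optimizers use Nelder-Mead with a warm start at
  the MM solution and one restart; pathological anchor sets (e.g. slopes
  near the $A > 10^{-3}$ bound) fall back to the warm start rather than
  failing.
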