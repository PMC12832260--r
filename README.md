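# anchorlink

Anchor-item test equating under item response theory (IRT), and a
Monte-Carlo engine for asking how well it works.

## The problem

When two groups take different forms of a test, their item and ability
estimates live on different scales: each form's calibration standardizes the
latent trait to its own sample. Anchor items — items shared between forms —
let us estimate the linear map between those scales,

    b₂ = A·b₁ + B,   a₂ = a₁ / A,   θ₂ = A·θ₁ + B,   c unchanged,

so that everything can be expressed on one common metric (and distant forms
can be linked *indirectly* by composing maps along a chain of anchors).
`anchorlink` is for psychometricians and test developers who want to (a)
compute such links from calibrated item parameters and (b) quantify, by
simulation, how design choices — test length, anchor proportion, sample
size, guessing probability, IRT model, linking method — affect how
faithfully the equated estimates recover the generating parameters.

## What is inside

* **IRT core** — 1PL/2PL/3PL item characteristic curves
  `p(θ) = c + (1−c)·logistic(a(θ−b))`, three-form item-bank generation with
  two disjoint anchor blocks, ability sampling, Bernoulli response
  simulation.
* **Calibration** — 2PL/3PL marginal maximum likelihood via EM on a fixed
  61-node quadrature grid (standard-normal prior), guarded M-steps so the
  marginal log-likelihood is provably nondecreasing, EAP ability scoring.
  The EM inner loops are compiled (Rcpp/RcppArmadillo).
* **Equating** — five linking methods: mean-sigma (MS), mean-mean (MM),
  mean-geometric-mean (MGM), Haebara / item response function (IRF),
  Stocking-Lord / test response function (TRF); plus parameter/ability
  transforms, inverses and chain composition for indirect equating.
* **Recovery** — association-based (Pearson r) and error-based (bias, RMSE,
  MAE, SEE) indices with the exact decomposition `RMSE² = bias² + SEE²`,
  and central-95% quantile trimming across iterations.
* **Study engine** — the factorial design (test set size {20, 40, 60, 80} ×
  anchor proportion {5–25%} × sample size {25–1000} × guessing
  {0, .125, .167, .25} = 400 scenarios), per-iteration pipelines with
  deterministic child seeds, convergence tracking, long-format records
  ready for mixed-model analysis.
* **CLI / IO** — `run-study`, `summarize`, `equate`, `make-fixtures`
  subcommands (`inst/cli/anchorlink`), CSV/JSON item tables, JSON configs
  and run manifests.

## Worked example

One Monte-Carlo iteration of a friendly scenario — 40 items per form, 25%
anchors per link, n = 500 per sample, no guessing, 2PL calibration, MM and
Haebara linking:

```r
library(anchorlink)
scen <- scenario_grid(tss = 40, aip = 0.25, n = 500, c = 0)[1, ]
rec <- run_iteration(scen, seed = 11, models = "2PL", methods = c("MM", "IRF"))
rec$indices[, c("method", "parameter", "r", "bias", "rmse", "mae", "see")]
#>   method parameter     r     bias  rmse   mae   see
#> 1     MM         a 0.804  0.01826 0.162 0.128 0.161
#> 2     MM         b 0.976 -0.00935 0.227 0.155 0.227
#> 3     MM     theta 0.937 -0.03770 0.371 0.292 0.369
#> 4    IRF         a 0.798  0.00578 0.161 0.127 0.161
#> 5    IRF         b 0.978  0.04524 0.223 0.146 0.219
#> 6    IRF     theta 0.938  0.03330 0.365 0.289 0.364
```

Read: after calibrating each of the three forms on its own sample and
mapping forms 1 and 3 onto form 2's scale through their anchor blocks, the
equated difficulties correlate r ≈ 0.98 with the generating ones and the
abilities r ≈ 0.94, with near-zero bias; discriminations are noisier
(r ≈ 0.80) — exactly the parameter that large samples help most.

Equating two item tables directly from files:

```r
src <- read_item_params(system.file("extdata", "anchors_source.csv", package = "anchorlink"))
tgt <- read_item_params(system.file("extdata", "anchors_target.csv", package = "anchorlink"))
mm_coefficients(anchor_pairs(src, tgt))
#> <equating_coef> MM: A = 2.000000, B = 1.000000 (3 anchors, form NA -> NA)
```

or from the shell:

```sh
Rscript inst/cli/anchorlink equate --method mm \
  --source inst/extdata/anchors_source.csv \
  --target inst/extdata/anchors_target.csv --out /tmp/eq
```

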