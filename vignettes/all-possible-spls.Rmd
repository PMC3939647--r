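---
title: "All-possible sparse partial least squares: model, tuning and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{All-possible sparse partial least squares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apspls)
```

## The problem

In neuroimaging, chemometrics and genetics one often regresses a single
continuous outcome (here, typically a cognitive test score) on many
strongly collinear predictors (regional brain volumes) with a modest sample
size. Ordinary least squares is unstable in that regime, and standard
partial least squares (PLS) — regression on latent components built to
covary with the outcome — handles the collinearity but assigns every
predictor a non-zero weight, so it does not select variables.

Sparse PLS (SPLS) adds a thresholding step that zeroes small predictor
weights. Its two tuning parameters are `K`, the number of latent
components (an integer between 1 and `min(p, (v-1)n/v)` when `v`-fold
cross-validation is used), and `eta` in `[0, 1)`, the fraction of the
largest weight magnitude below which weights are zeroed. Small `K` and
large `eta` both increase sparsity. The usual ("traditional") practice is
to pick the single `(K, eta)` pair minimizing cross-validated prediction
error and report the predictors selected at that pair — a dichotomy that
discards effect sizes for everything not selected, and that turns out to
be fragile: with k-fold cross-validation the winning pair depends on the
fold-assignment seed, and a one-unit change in `K` or `eta` can add or
drop several predictors.

## The all-possible procedure

Instead of one model, fit one SPLS model per cell of the whole tuning grid
(by default `K` in `1..p` and `eta` in `{0.1, ..., 0.9}`) and summarize,
per predictor,

* **percent chosen** — the percentage of grid cells in which the
  predictor's standardized coefficient is non-zero, and
* **mean non-zero coefficient** — the average of its standardized
  coefficient over exactly those cells.

Percent chosen orders predictors on a continuum from "selected under any
amount of sparsity" to "dropped as soon as sparsity bites", which serves
as a relative, assumption-light form of inference; the mean non-zero
estimate adds direction and magnitude even for predictors a traditional
fit would have zeroed. Because the grid includes barely-sparse cells
(large `K`, small `eta`) that select everything, all percentages are
pulled up — with the default grid most predictors exceed 70% — so the
*ranking*, not the absolute percentage, is the interpretable quantity; no
distributional cutoff is claimed.

```{r example, eval = FALSE}
d <- generate_dataset(simulation_spec(), seed = 1)
s <- selection_summary(run_grid(d))
head(s)
```

## The fitting algorithm

`fit_spls()` implements the univariate-response SPLS iteration. With
standardized predictors `X` and outcome `y` (sample SD, denominator
`n - 1`), and residual `r` initialized to `y`, for `k = 1..K`:

1. `z = t(X) %*% r`, the covariance of each predictor with the residual;
2. soft-threshold: `w_i = sign(z_i) max(0, |z_i| - eta * max|z|)`;
3. grow the active set by `{i : w_i != 0}`, plus any force-in predictors;
4. refit a PLS regression (NIPALS) of `y` on the active columns with
   `min(k, |active|)` components, capped at the rank of the active
   submatrix;
5. set `r = y -` fitted values and continue.

The final coefficient vector is embedded in length `p` with exact zeros
off the active set. Useful consequences: at `eta = 0` the procedure is
ordinary `K`-component PLS (it selects everything); at `K = 1` the active
set shrinks monotonically as `eta` grows; and the state after step `k`
does not depend on the total `K`, so `run_grid()` computes a whole column
of the grid in one pass per `eta` — a fit recorded after step `k` is
bit-identical to a separate run with `K = k` (asserted in the tests).

Confounders (age, sex, race, obesity, total gray matter in the motivating
application) are handled by the dataset's `force_in` set: those indices
are united into the active set at every step, so they are always refit and
always carry a coefficient, mirroring how confounders are retained in an
OLS analysis regardless of significance. The thresholding step itself is
left untouched; forcing happens at the active-set union, which is this
package's mechanism of choice (forcing inside the threshold would distort
the selection of the remaining predictors).

## Tuning by cross-validation, and why leave-one-out

`cv_mspe()` computes the mean squared prediction error of every grid cell
under `v`-fold cross-validation: rows are randomly permuted (under a
stated seed) and cut into contiguous near-equal folds; each fold is
predicted from a model fit on the others; `select_optimal()` returns the
minimizing pair, breaking ties toward smaller `K` and then larger `eta`
(the most parsimonious model — both choices reduce over-fitting risk; the
tie-break is a documented convention, not a claim of optimality). After
selection the final model is refit on all rows.

k-fold tuning inherits randomness from the fold assignment.
`seed_sensitivity()` makes that visible: it reruns the tuner under many
seeds and tallies how often each pair wins. A diffuse tally means the
"optimal" pair is an artifact of the seed; leave-one-out (`folds =
"loo"`), which has no randomness, is the recommended tuner when a single
model is wanted — and the all-possible summary sidesteps the instability
altogether. The diagnostic re-randomizes the fold assignment only; the
fitting algorithm itself is deterministic.

## The simulation design

`simulation_spec()` encodes a block-collinear design: for blocks `j` with
boundaries `(0, 7, 17, 27)`, a latent mean vector `m_j ~ N(0, 20 I_n)` is
shared by all predictors of the block, each predictor adding independent
`N(0, I_n)` noise, so the within-block population correlation is
`20/21 ≈ 0.95` while cross-block correlations are zero. The outcome is
`y = 2 m_1 - 0.2 m_2 + tau`, `tau ~ N(0, I_n)`, `n = 100`: block `S1`
(predictors 1–7) is strongly associated with `y`, `S2` (8–17) weakly and
negatively, `S3` (18–27) not at all. `N(0, 20 I)` is read as covariance
`20 I` (variance 20); all columns and the outcome are standardized per
replicate before fitting. Each replicate draws its own sub-seed from the
base seed up front, so results do not depend on processing order.

Two experiments build on the generator. `selection_surface()` averages,
over replicates, the percentage of each block selected at every grid
cell: `S1` sits at 100% everywhere, while `S2` and especially `S3` are
pruned as `K` falls and `eta` rises, reaching 100% for all cells with
`K >= 16`. `long_run_experiment()` averages the per-replicate
all-possible summaries; in the long run `S1` predictors are chosen in
100% of cells with standardized estimates near `0.145`, `S2` near `96.5%`
with estimates near `-0.011`, and `S3` near `90%` with estimates of mixed
sign hovering around zero.

Desk runs use `D = 100` replicates for the long-run summary and `D = 50`
for the surfaces (the package's default problem sizes; the block averages
are stable to well within the reported tolerances at these sizes, as the
acceptance checks compute). `D` is a parameter, so larger experiments
remain available. What the generator does *not* emulate about real
cohort data: non-Gaussian and heteroscedastic volumes, measurement
error correlated across regions, confounder structure, or missingness —
passing tests on this design demonstrate the selection mechanics under
known ground truth, not performance on any particular cohort.

## Data preparation

The pre-modelling utilities mirror a typical volumetric-MRI workflow:

* `transform_left_skew()` maps a ceiling-clustered 0–100 test score
  through `-ln(101 - score)`, strictly increasing, defined for scores
  below 101.
* `read_dataset()` can replace right-skewed volume columns (e.g., the
  pallidum) by their natural log, drops incomplete rows with a message,
  and resolves force-in columns by name.
* `influential_filter()` screens each predictor singly: regress the
  outcome on that predictor, compute externally studentized residuals
  (the residual scaled by an error SD estimated with the row deleted),
  and remove — once, jointly — every row exceeding the threshold
  (default 2.5, slightly less conservative than the common cutoff of 2)
  in any single-predictor fit. Numerically exact fits are treated as
  having zero residuals; constant predictors are skipped with a warning.
* `condition_number()` computes the Belsley collinearity diagnostic:
  columns of the intercept-augmented design are scaled to unit Euclidean
  norm and the ratio of extreme singular values is reported, with values
  above 100 flagged. The unit-norm/intercept convention is stated so
  users compare like with like; computing it on raw versus standardized
  predictors gives different values, and this package applies it to the
  predictors as supplied.

## Numerical choices and edge cases

* Standardization uses the `n - 1` sample SD; constant columns are an
  error naming the column.
* If cancellation zeroes the entire thresholded direction (possible only
  as `eta` approaches 1), the component with the largest `|z|` is
  retained (lowest index on ties) so the algorithm always progresses.
* Components are capped at `min(k, |active|, rank)`; NIPALS stops early
  when the residual covariance or score norm underflows a relative
  tolerance, with a warning from `fit_spls()` when the cap binds.
* A predictor never selected anywhere on the grid reports `NA` — not 0 —
  for its mean non-zero estimate; zero would be a misleading effect size.
* Ranking ties in the summary are broken by `|mean non-zero estimate|`
  descending, then predictor name, so output order is total and stable.
* `K` values violating the fold-dependent bound are dropped from the CV
  grid with a warning; an empty grid is an error.

## Limitations

The percent-chosen statistic has no null distribution, so no significance
threshold is provided; rankings are relative. Only a scalar outcome is
supported (no multivariate-response or classification variants). The grid
default `K <= p` is a convention — published analyses do not always state
their `K` range — and results should be reported together with the grid
used.
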