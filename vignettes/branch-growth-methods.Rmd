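---
title: "Modelling annual branch growth under competition and climate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling annual branch growth under competition and climate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(branchgrowth)
```

## The measurement model

Korean pine grows monopodially: each year the leader adds one internode and
leaves a whorl of lateral branches at the old apex. Three consequences make a
felled tree a complete annual archive:

* counting whorls from the tip ages every branch;
* branch basal rings and length marks date every year's increment
  (ΔBL in cm, ΔBD over bark in mm);
* the mean depth-into-crown (DINC) of the age-`k` whorl is the distance the
  leader has grown since year `felling − k`, so
  `HT(felling − k) = felling height − mean DINC(k)`
  (`reconstruct_height_series()`).

Stem chronologies come from increment cores: under-bark DBH at age `t` is
twice the cumulative mean ring width (orientations averaged — the dendro
convention; the source protocol cores east–west and north–south but does not
state the combiner), and over-bark DBH applies a bark coefficient
`KB = a·age^b` (`fit_bark_coefficient()`, `backcast_dbh()`). A ring or whorl
of age `k` at felling in year `Y` is assigned to calendar year `Y − k`.
Height series corrupted by DINC measurement noise are repaired by
pool-adjacent-violators (isotonic) regression and flagged; missing whorl
years are linearly interpolated and flagged.

## The growth model

Both responses share one log-linear annual model,

$$\log(\Delta) = a_0 + a_1 AGE + a_2 SIZE + a_3 BH + a_4 Dheight
  + a_5 BAS + a_6 CLIM + a_7\, BAS\!\cdot\!CLIM \;(+\,u_i),$$

where the natural logarithm is used throughout (the choice only rescales
coefficients and is recorded in the model metadata). `SIZE` is the branch's
cumulative size entering the year. **Units matter**: the published length
coefficients are only dimensionally consistent when cumulative branch length
enters in metres (at the observed mean, `a2` per cm would contribute ≈80 to a
log increment of ≈3), while the diameter model takes BD in millimetres. The
package stores lengths in cm in its file schemas and converts to metres in
`build_design()`.

The mixed form adds a tree-level random intercept `u_i ~ N(0, σu²)` — the
grouping level is the tree (54 groups), with plot grouping available via
`grouping = "plot_id"` — and optionally AR(1) within-branch errors with
correlation `ρ^{|Δyear|}`; branches of one tree are conditionally independent
given `u_i`, and within-group heteroscedasticity is fixed at identity.

### Estimation

`fit_mixed()` profiles the fixed effects and residual variance out of the
Gaussian likelihood and maximizes over `(log λ, atanh ρ)`, `λ = σu²/σ²`,
by multi-start BFGS (three λ starts; Brent/Nelder–Mead fallback;
relative-likelihood tolerance 1e-10, max 500 iterations). Per-tree
covariances are inverted by the Woodbury identity around the block-diagonal
AR(1) structure, so one likelihood evaluation is linear in the number of
branch-years; AR(1) Cholesky factors are cached per year-spacing pattern.
REML is the default for reported variance components; model comparison
should use ML AICs (REML AICs are not comparable across fixed-effect
structures). A REML random-intercept fit reproduces `lme4::lmer` to the
printed precision of both (a unit test asserts agreement to 1e-6 in the
log-likelihood), and the ML likelihood is checked against a dense
multivariate-normal evaluation on small stands (1e-8).

Prediction for a new tree without data is `Xβ`; with `m` calibration
residuals `r̄` the intercept is predicted by BLUP,
`û = m σu²/(m σu² + σ²)·r̄`, generalized through the AR(1) covariance when
present. Back-transformation defaults to plain `exp` — matching the
magnitude of the reported natural-scale errors — with the lognormal
`exp(σ²/2)` correction behind a flag.

## Competition indices

`hegyi_ci()` is the distance-dependent ratio sum `Σ (d_j/d_i)/L_ij` over
stems within the 8 m competition radius. `basal_area_indices()` scales the
competitors' basal area to m²/ha against a reference area `S_compete`:

* `"diameter"` (default, the formula as conventionally printed):
  `S = (π/4)R²` — the area of a circle whose *diameter* is R;
* `"radius"`: `S = πR²`, the geometric circle.

The printed formula is ambiguous, and the two readings differ by a factor 4.
The observed stand summaries are in fact mutually inconsistent under the
literal reading: 1666 stems/ha at quadratic mean diameter 27 cm imply
≈96 m²/ha of basal area, four times the top of the observed BAS range
(3.7–48.7 m²/ha) that the published coefficients require. The low-level
default therefore stays `"diameter"` (so the printed arithmetic reproduces
exactly), but `run_pipeline()`'s synthetic stands use `"radius"` together
with a default density of 480 stems/ha, which lands simulated BAS and Hegyi
CI inside the observed ranges. BAL restricts the same sum to competitors
larger than the subject; RD is the subject's DBH over the plot's quadratic
mean diameter (no formula is printed for it; this is the standard
definition). The subject is excluded from BAS by default (flag available).
No edge correction is applied: competitors are simulated in a buffer one
radius wide.

## The synthetic world

The generator states one fixed world and is not tuned to outcomes:

* 18 plots of 0.06 ha, 3 felled trees per plot (one per social status),
  annual window 1999–2022, felling 2023, 14 sampled whorls per tree
  (54 × 14 = 756 ≈ 745 series);
* felling DBH ~ Beta(3.5, 2.9) scaled to the observed 4.3–46.3 cm (matches
  the observed mean 27.4 and SD 7.7); height and age follow smooth
  allometries with noise;
* heights follow a Richards-type curve anchored at the felling height; the
  diameter curve shares the height curve's shape, so stand basal area
  co-moves with insertion height as it does in the observed joint
  distribution (tall whorls never face empty stands);
* climate is unprinted in the source tables, so it is declared: CMD_MAM ~
  N(60, 20) mm, Eref_MAM ~ N(250, 30) mm, AR(1) 0.2, truncated at 0 —
  plausible spring magnitudes for a temperate monsoon climate; all
  configurable, and no acceptance target depends on them;
* branch insertion height is fixed at formation (trees do not lift
  branches); increments are floored at 0.01 natural units (observed minima
  are sample artefacts, not structural zeros).

Two generators serve different purposes. `simulate_replicate_frame()` draws
covariates *exogenously*, uniform within the observed ranges with the
study's tree/branch/year hierarchy, and adds the linear predictor, a tree
intercept and (optionally AR(1)) noise. This is the parameter-recovery
protocol: estimates are unbiased for the generating values by construction,
and the log-scale variance decomposes exactly into σu² + σ².

`simulate_branch_growth()` instead runs the model *forward*, accumulating
increments so that `SIZE` feeds back. That recursion is structurally
unstable whenever a sustained increment exceeds `−a1/a2` (the positive size
feedback then outruns the age decline): ≈15 cm/yr for the published mixed
length slopes — *below* the observed mean increment of 20.8 cm — but
≈27 cm/yr for the single-level slopes. A fitted regression is not a stable
dynamical system, and no parameter choice of ours can make the mixed slopes
one. The pipeline's stand generator therefore defaults to the single-level
coefficient sets with a declared moderate tree variance (σu² = 0.10 length,
0.03 diameter), and caps single-year increments at the observed maxima
(66 cm, 13 mm), counting capped rows in an attribute. A green pipeline test
therefore establishes that the stages compose and reproduce chronologies —
not that the forward world is distributionally identical to the study.

## Validation design

* **Recovery protocol** (`parameter_recovery()`): 200 replicate datasets per
  study; OLS refits of the single-level sets recover every coefficient
  within 5% on the replicate mean; REML refits recover a1, σu², σ² within
  10% (15% for the diameter σu², whose true value is small relative to σ²).
  Replicate seeds derive from one base seed and stay below 2³¹.
* **Oracles**: dense multivariate-normal likelihood (1e-8); balanced one-way
  ANOVA closed form for σu²; direct-summation competition indices (1e-12);
  all-orders enumeration for hierarchical partitioning (1e-8); hand
  arithmetic for the metric suite, bark law, and basal-area conversion.
* **Properties**: BAL ≤ BAS; CI scale-invariance and BAS quadratic scaling;
  cumulative-sum conservation; seeded byte-identical reruns; LOOCV fold
  accounting; BLUP shrinkage closed form; the interaction-grid maximum at
  the low-competition/low-stress corner for any admissible sign pattern
  (a5 < 0, a6 < 0, a7 > 0).

Numerical edge policies: rank-deficient designs are errors naming the
collinear terms (hence an exactly constant climate column is an error, not a
tie); λ at the zero boundary is flagged, not fatal; forward selection uses
exact α = 0.05 marginal t-tests plus minimum AIC, so with `g` pure-noise
candidates the no-false-entry probability is 0.95^g by design — the suite's
thresholds are set from that arithmetic, not from aspiration. AIC counts all
free parameters (coefficients plus variance components). Climate-lag ties
break toward the smaller lag.

## Hierarchical partitioning and social status

`hierarchical_partition()` decomposes the full OLS R² over predictor groups
(branch age, branch size, branch height, tree height growth, competition,
climate, interaction) by Shapley-weighted averaging of R² increments over
the subset lattice (2^g fits, g ≤ 12); independent contributions sum to the
full R² to 1e-8. Goodness of fit is OLS R² — mixed-model partitioning
post-dates the classical method — and status-stratified partitions refit
within each stratum rather than decomposing one joint model (the source is
silent; this is the declared default). `classify_social_status()` ranks a
plot's trees by descending DBH, cuts cumulative basal area into five equal
intervals, and labels intervals 1/3/5 dominant/intermediate/suppressed,
assigning boundary-straddling trees by the midpoint of their basal-area
span.

## Known limitations

* The forward stand generator cannot use the published mixed-model slopes
  without caps (see above); its covariate joint distribution is smoother
  than real crowns.
* LOOCV predicts held-out trees with fixed effects only (no calibration data
  can exist for an unseen tree), so its errors bound the population-level
  model, not the calibrated one.
* Real-data quantities that depend on the undeposited dataset (observed R²,
  MAE, HP percentages) are not reproducible and are not claimed; the
  acceptance targets are parameter-recovery means against the printed
  estimates.
* Which climate lag (0–2) entered the final published models is unstated;
  `climate_lag` is a configuration knob and `lag_select()` reproduces the
  selection procedure, not the source's choice.
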