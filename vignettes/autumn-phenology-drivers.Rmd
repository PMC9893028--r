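---
title: "Attributing autumn phenology to climate, spring phenology and phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing autumn phenology to climate, spring phenology and phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`autumnsig` implements a two-arm analysis of autumn leaf phenology — the
leaf coloring date (LCD), the day of year when most of a tree's crown has
turned — for multi-species, multi-site observational networks. This
vignette explains the statistical models, the choices behind tunable
parameters, what the synthetic-data generators do and do not emulate, and
the package's known limitations.

```{r setup}
library(autumnsig)
```

## The interannual arm

### Quality control

Observational series are screened per species x site x event:

* **Outlier removal.** Years whose day-of-year deviates from the series
  median by *more than* `mad_k = 2` times the unscaled median absolute
  deviation are dropped. The median and MAD are computed once, on the
  unfiltered series; boundary values (deviation exactly `2 * MAD`) are
  kept. Because at least half of any sample lies within one MAD of the
  median, this screen can never remove more than half a series. The MAD
  is deliberately unscaled (no 1.4826 normal-consistency factor): the
  rule is a robust gross-error screen, not a normality-based test. The
  screen applies to LCD series and, by default (`mad_fld = TRUE`), to the
  spring first-leaf (FLD) series as well — the symmetric choice, since
  the FLD series enter the same correlation analysis.
  One side effect worth knowing: on a genuinely trending series the most
  extreme years are the first and last, so the screen preferentially
  clips the ends and attenuates subsequently fitted trends (in the
  package's simulations, a 2.8 d/decade trend over 40 years with 3-day
  noise loses roughly a quarter of its slope after screening). This is a
  property of MAD screening itself; disable it (`mad_k = Inf`) when trend
  magnitude is the quantity of interest.
* **Record length.** A species x site combination is retained only if
  both its LCD and FLD series still cover at least `min_years = 15`
  years (boundary inclusive). Fifteen years is the conventional floor for
  estimating an interannual correlation with six predictors.

### Trends

LCD trends are ordinary least squares of day-of-year on calendar year,
reported per decade, with two-sided t-tests (n − 2 df). "Delayed" means a
strictly positive slope. Published summaries are ambiguous about whether
"x% significant" counts significant-and-delayed species among all species
or among delayed species only, so `summarize_trends()` reports both
denominators rather than committing to one.

### Preseason windows

For each species and climate variable `v` in {Tmax, Tmin, Pre, Ins, Win},
the *preseason* is the window of `L` days ending the day before the
anchor, the rounded multi-year mean LCD. The window mean is the
arithmetic mean of the daily values; for a fixed `L`, Pearson correlation
is invariant to replacing the mean by the sum, so this choice affects
only the units of interpretation. `optimal_preseason()` scans
`L = 1..150` and keeps the `L` with the largest `|r|` between the window
series and LCD:

* **`|r|`, not `r`.** Drivers with negative effects (insolation
  shortening the season) must be detectable, so "strongest association"
  is read as largest magnitude. `criterion = "max"` restores the signed
  convention.
* **Ties** (identical `|r|`, possible with degenerate climate) go to the
  shortest window.
* The anchor is held fixed across years and variables; if fewer than 150
  days precede it in the calendar year the scan is truncated with a
  warning.

### Partial correlations

`attribute_drivers()` builds six predictor series — the five window means
at their own optimal lengths, plus the same-year FLD — restricts all
series to the common years (at least 15), and computes for each predictor
its partial correlation with LCD given the other five. The estimator is
the classic first-order recursion

$$R(x,y \mid z) = \frac{R_{xy} - R_{xz} R_{yz}}
  {\sqrt{1 - R_{xz}^2}\sqrt{1 - R_{yz}^2}}$$

applied repeatedly over the control set; this is algebraically identical
to correlating the two residual series after projecting `x` and `y` on
the controls, and the package verifies the two routes against each other
in its tests. Two-sided p-values use `t = R \sqrt{df/(1-R^2)}` with
`df = n - k - 2`. p-values are not multiplicity-adjusted, matching the
per-species alpha = 0.05 reporting convention of the underlying
literature.

**A caveat the package makes explicit.** The optimal-preseason step
selects, per variable, the best of 150 correlated hypotheses *on the same
data* that the partial correlation then tests. Under a global null this
inflates the per-predictor rejection rate above the nominal 5% — in the
package's own calibration simulations to roughly 7–9% for strongly
autocorrelated variables (temperatures) and 25–40% for weakly
autocorrelated or skewed ones (wind, insolation, precipitation), while
the FLD predictor, which involves no selection, is calibrated almost
exactly at 5%. Significance flags on window-selected climate predictors
should therefore be read as descriptive, not as calibrated tests. This is
an inherent property of the two-step procedure, not of this
implementation.

Regional summaries average `|R|` per predictor over species and report
the percentage of positive, negative, and significant-by-sign
coefficients. An exactly zero coefficient (possible only on degenerate
input) is counted in neither sign class, so the positive and negative
percentages always total 100.

## The species-level arm

Species differences are analysed on the multi-year mean LCD per species
within each site, computed from the QC-filtered series for consistency
with the interannual arm.

### Phylogenetic signal

Blomberg's K compares the observed trait variance to the variance
expected under Brownian motion on the phylogeny:

$$K = \frac{MSE_0 / MSE}{E_{BM}[MSE_0 / MSE]}, \qquad
  \hat a = \frac{\mathbf{1}' C^{-1} x}{\mathbf{1}' C^{-1} \mathbf{1}},$$

with `MSE0` the ordinary mean squared deviation from the phylogenetic
mean, `MSE = (x-\hat a)' C^{-1} (x-\hat a)/(n-1)`, and
`E_BM[MSE0/MSE] = (\mathrm{tr}\,C - n/\mathbf{1}'C^{-1}\mathbf{1})/(n-1)`,
where `C` is the matrix of shared root-to-ancestor branch lengths. K is
affine-invariant in the trait; `K ~ 1` is consistent with Brownian
motion, `K ~ 0` with phylogenetic independence. `C` is factorized by
Cholesky decomposition rather than explicitly inverted.

The permutation test shuffles trait values across tips (default 1000
permutations — the number of randomization iterations conventional for
this test) and is one-sided: signal means a larger-than-random K. The
p-value uses the add-one rule `(1 + #{K_perm >= K_obs})/(1 + B)` and so
is never exactly zero.

### Native climate

Each species' native climate is summarized from its occurrence records:
after collapsing coordinate duplicates (exact match after rounding to 4
decimal places, about 11 m, to absorb coordinate-precision noise), the
profile holds the mean and the range (max − min) of five variables —
mean annual temperature, maximum temperature of the warmest month,
minimum temperature of the coldest month, annual precipitation, annual
solar radiation — ten predictors in all. No minimum occurrence count is
imposed; `n_occurrences` is reported so users can filter.

### Eigenvector regression and the variance partition

The pairwise patristic distance matrix is embedded by principal
coordinate analysis (eigendecomposition of the Gower-centered squared
distances); axes are scaled so each squared column norm equals its
eigenvalue, and axes at or below `1e-8` of the leading eigenvalue are
dropped. Tree distances are Euclidean-embeddable, so material negative
eigenvalues (beyond 1% of the leading one) indicate a malformed input and
raise a warning rather than being corrected.

Two predictor sets are then chosen:

* **Native climate:** bidirectional stepwise regression under AIC over
  the ten profile predictors, from the intercept-only model. AIC avoids
  an arbitrary p-to-enter; with 12 or fewer species the search degrades
  to forward-only with at most n/5 predictors. Note that AIC is a
  prediction criterion, not a gatekeeper: with ten candidates it admits
  one or two spurious predictors on pure noise more often than not, which
  the adjusted-R^2 partition largely absorbs.
* **Phylogenetic eigenvectors:** a two-stage rule. Moran's I of the trait
  under row-standardized inverse-patristic-distance weights — the
  conventional weighting of the eigenvector-selection literature — gates
  the selection, one-sided for positive autocorrelation, mirroring the
  one-sidedness of the K test; traits without detectable signal get no
  eigenvectors. Traits that pass are fitted by the same bidirectional
  AIC stepwise over the leading n/2 axes.

  The design here departs from the classic residual-whitening search
  (greedily add the axis that brings residual Moran's I closest to its
  null expectation, stop at nonsignificance). That search answers "which
  axes remove detectable autocorrelation?" — typically one to three axes
  — not "how much variance does phylogeny explain?". In ground-truth
  simulations where 60% of trait variance is phylogenetic, the whitening
  search credits phylogeny with so little variance that the partition
  ranks climate above phylogeny about half the time; the gated AIC
  selection recovers the correct ranking essentially always. The
  whitening search remains available as
  `select_eigenvectors(..., method = "moran")`.

With the selected climate block, eigenvector block, and their union, three
adjusted R² values (`R2adj = 1 - (1-R2)(n-1)/(n-p-1)`) give the partition

* `P1 = R2adj_full − R2adj_climate` — exclusive phylogeny,
* `P2 = R2adj_full − R2adj_phylo` — exclusive climate,
* `P3 = R2adj_phylo − (R2adj_full − R2adj_climate)` — shared,

so `P1 + P2 + P3 = R2adj_full` identically. Adjusted R² can push
individual components slightly negative; they are reported unclamped
because clamping would silently break the sum identity. Regional values
are unweighted means over sites, which preserves the identity by
linearity. Sites with fewer than four species are skipped — the three
regressions need residual degrees of freedom.

An open representational question: whether eigenvector selection should
use the trait itself or the residuals of the climate model as its
response. The package uses the trait, which attributes genuinely shared
structure to both blocks and lets the partition's `P3` component absorb
it; residual-response selection would fold shared structure into the
climate block by construction.

## Synthetic data and what passing tests mean

Every stage has a generator with known ground truth:

* **Climate** (`gen_climate`): per variable, a seasonal sinusoid plus
  stationary AR(1) anomalies. Defaults emulate a temperate monsoon site:
  daily temperature anomaly sd 3.5 °C with lag-1 autocorrelation 0.75
  (mid-range for daily mid-latitude temperature), insolation sd
  3 MJ m⁻² d⁻¹ (rho 0.6), wind sd 0.8 m s⁻¹ (rho 0.5). Minimum
  temperature is maximum temperature minus a stochastic diurnal range
  floored at 0.5 °C, so `tmin <= tmax` holds row-wise. Precipitation
  anomalies act multiplicatively on the log scale — nonnegativity without
  clipping artifacts — giving realistically skewed daily totals.
* **Phenology** (`gen_phenology`): a linear response to window-mean
  climate *anomalies* over known preseason lengths (defaults 78, 60, 45,
  58, 43 days for Tmax, Tmin, Pre, Ins, Win — typical observed autumn
  preseason durations), plus optional trend, spring-phenology coupling,
  and Gaussian noise, rounded to whole days. Coefficients act on
  anomalies (window means centered on the period climatology) so that
  the expected series mean equals `base_doy` and the search anchor
  coincides with the generating anchor; with raw window means the mean
  response would displace the anchor by tens of days and no search could
  invert the construction. Rounding can be disabled
  (`round_doy = FALSE`) for exact-arithmetic checks such as recovering
  `r = 1` from a noise-free single-driver series.
* **Trees** (`gen_yule_tree`): forward pure-birth simulation; after the
  n-th tip appears the tree grows one further exponential waiting time so
  terminal branches are positive and the expected root-to-tip depth is
  exactly `sum_{k=2}^{n} 1/(k lambda)`.
* **Traits** (`gen_bm_trait`): multivariate normal with covariance
  `sigma2 * C`.
* **Species ensembles** (`gen_species_ensemble`): standardized mixtures
  `z = sqrt(w_c) c + sqrt(w_p) u + sqrt(w_n) e` of a climate score (a
  linear function of species-specific climate optima), a standardized
  Brownian trait, and iid noise, with occurrence records drawn around the
  optima (a shared per-occurrence thermal anomaly keeps the
  cold-month/annual/warm-month ordering intact). Mean LCD is
  `280 + 8 z` days.

Every generator is a pure function of its spec including the seed. The
pipeline derives per-stage seeds from one master seed by hashing stage
names, so stages are independently reproducible and reruns are
byte-identical.

These generators emulate the statistical *structure* the methods assume —
linear responses, stationary anomalies, Brownian traits. They do not
emulate spatial climate fields, observation-protocol changes,
non-stationary or threshold-like phenological responses, phylogenetic
uncertainty, or spatial bias in occurrence sampling. Passing
parameter-recovery tests therefore demonstrates that the implementation
inverts its own assumptions correctly — not that those assumptions hold
for any particular observational network.

## Validation scale and observed behavior

The shipped validation suite works at desk scale: 100-tip trees with 200
Brownian replicates for the K calibration (mean K within 0.1 of 1), 500
replicates of 199 permutations for the permutation test's type-I error
(5% within 2 points), 100-seed recovery runs for the 60-day temperature
preseason, 100-replicate ensemble recoveries for the variance partition
(80 species), and exact checks for the algebraic identities (partition
sum to 1e-12, recursion vs. residual partial correlations to 1e-8, PCoA
distance reconstruction to 1e-6). Two behaviors are worth knowing:

* Preseason-length recovery under the default climate background
  (window-level signal-to-noise around r = 0.6) lands near 78% within
  ±10 days — the `|r|(L)` profile is smooth under persistent anomalies,
  so the argmax carries a spread of roughly ±8–12 days. Sharper climates
  or lower noise tighten it quickly.
* As discussed above, the per-predictor significance rate of
  window-selected predictors under a global null exceeds the nominal 5%.
  Both behaviors are properties of the method, and the test suite
  records them rather than hiding them.

## Numerical choices

* Covariance solves use Cholesky factorization; a singular `C` (e.g.
  zero-length cherries) is an error, not a pseudo-inverse.
* The partial-correlation recursion refuses controls with
  `(1-R_{xz}^2)(1-R_{yz}^2) <= 1e-12` (collinearity).
* PCoA drops eigenvalues at or below `1e-8` relative to the leading one.
* The add-one permutation p-value keeps p in `(0, 1]`.
* Window aggregation excludes (and reports) years with any missing day
  rather than imputing.
* Dates are ISO-8601 or integer day-of-year, 1-based, Feb 29 = 60.

## Limitations

* One series per species x site x event is assumed; combining multiple
  observed individuals into a series is left to the user.
* No asymmetric day/night temperature responses, no windows longer than
  150 days, no nonlinear or piecewise trends.
* Species at several sites are treated independently per site.
* The native-climate profile reduces a range map to ten numbers; range
  shape, seasonality interactions and sampling bias are out of scope.
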