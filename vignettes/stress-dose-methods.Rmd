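---
title: "Stress-dose methods: model, generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-dose methods: model, generator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the measurement model the package implements, the
synthetic experiment generator and its limits, and the reasoning behind the
numerical and statistical choices. Code chunks are illustrative and not
evaluated when the package is built.

## 1. Measurement model

### Chamber gas exchange

A flow-through chamber supplies air at mass flow $\dot m$ (mol s$^{-1}$)
with water vapor content $W_{supply}$ (mmol mol$^{-1}$) and measures the
enriched outlet content $W_{sample}$. The derived quantities are:

1. Saturation vapor pressure (Tetens):
   $e_s = 0.6108\,\exp\!\big(17.27\,T/(T+237.3)\big)$ kPa.
2. Actual vapor pressure from a mixing ratio $ah$:
   $e_a = ah\,P/(0.62198 + ah)$.
3. $\mathrm{VPD} = e_s - e_a$.
4. Canopy transpiration (mass balance, mole fractions $w = W/1000$):
   $E_c = \dot m\,(w_{sample} - w_{supply})/(1 - w_{sample})$
   in mol tree$^{-1}$ s$^{-1}$.
5. Leaf-level transpiration: $E_{la} = E_c/\mathrm{area}_{needle}$.
6. Saturated needle vapor content (needle temperature assumed equal to air
   temperature): $W_{needle} = 1000\,e_s(T)/P$.
7. Canopy (or stomatal) conductance:
   $g_c = 1000\,E\,\big(1000 - (W_{needle}+W_{sample})/2\big) /
   (W_{needle}-W_{sample})$.

Records with $W_{needle} \le W_{sample}$ have no defined gradient
(condensation); `compute_fluxes()` flags them `"condensation"` and returns
`NA` conductance instead of clipping. A constant or per-timestamp
empty-chamber differential is subtracted from every concentration
difference before the mass balance. `qc_filter()` keeps daytime records
and applies a per-chamber Tukey fence (1.5 IQR) on $E_c$ repeatedly until
a fixed point is reached, which makes the filter idempotent.

### Zero-growth partition of dendrometer traces

Under the zero-growth concept, irreversible growth occurs only while the
stem diameter exceeds its historical maximum; any excursion below the
running maximum is reversible shrinkage — tree water deficit:

$$d_{max}(t) = \max_{s\le t} d(s), \qquad
  \mathrm{TWD}(t) = d_{max}(t) - d(t).$$

`zero_growth_partition()` implements this with a running maximum
(`cummax`), so the identity
$d(t) = d(0) + \mathrm{growth}(t) - \mathrm{TWD}(t)$ holds row by row.
`clean_dendro()` removes step artifacts (sensor reseats) by offsetting the
post-break segment back onto the pre-break level; this preserves TWD
continuity but absorbs whatever physiological change coincided with the
break, so recovery is exact only up to the concurrent step.

### Vulnerability curve

Percent loss of conductivity follows a two-parameter Weibull curve,
$\mathrm{PLC}(P) = 100\,(1 - \exp(-(|P|/b)^c))$, fitted by nonlinear least
squares with a linearised start
($\log(-\log(1-\mathrm{PLC}/100))$ is linear in $\log|P|$) and a
Levenberg–Marquardt fallback. The damage thresholds are the inverse curve:
$P_x = -b\,(-\log(1-x/100))^{1/c}$, with $P_{12}$ the embolism-onset
pressure and $P_{50}$ the half-loss pressure.

Confidence intervals resample *sample replicates* (cases), not residuals,
because PLC errors are strongly correlated within a sample. With only
$K = 6$ samples, raw percentile intervals of a cluster bootstrap
undercover badly (about 82 % instead of 95 % in our replicate studies),
which is the known small-$K$ failure of the bootstrap. The default
`ci_type = "t"` interval applies the standard correction:
$\hat\theta \pm t_{1-\alpha,\,K-1}\; \widehat{sd}_{boot}\,\sqrt{K/(K-1)}$.
In 200-replicate studies of the bundled generator this attains 96 %
coverage for $P_{50}$. Percentile intervals remain available and are
documented as anti-conservative at small $K$.

### Stress-dose metrics

Midday water potential is observed every 2–3 days; day-counting metrics
need a daily grid, so `daily_interpolate()` linearly interpolates each
tree's series onto every day (no extrapolation). On that grid:

- $\Psi_{min}$: minimum of *observed* values in the drought window
  (interpolated values never set the minimum);
- $dP_{12}$: number of grid days with $\Psi$ strictly below $P_{12}$;
- $\mathrm{TWD}_{P12}$: sum of daily-mean TWD over exactly those days —
  duration and dose share one mask, so the two metrics are consistent by
  construction;
- $\Psi_{cum}$: sum over window days of $\min(\Psi - \bar\Psi_{control},
  0)$, i.e. only days on which the tree is more stressed than the
  concurrent control mean contribute.

$\Psi_{cum}$ is accumulated over *all* days of the daily grid. An
alternative convention sums only measurement days; it produces numbers
roughly proportional to the measurement cadence and is therefore not
cadence-invariant. The daily-grid rule used here gives values that do not
change when the sampling interval changes, at the price of being roughly
(cadence)-fold larger than measurement-day sums.

### Recovery statistics

The recovery index of a drought tree is its window-mean flux as a percent
of the concurrent control mean, computed from daily tree means over the
last 8 days of the monitoring period (configurable). Each index is
regressed on each stress metric by OLS; models are compared with the
Gaussian-likelihood information criterion
$\mathrm{AIC} = n\,\ln(SS_{res}/n) + 2k$ with $k = 3$ (slope, intercept,
error variance). Since all candidate models have the same $k$, ranking by
this AIC is equivalent to ranking by $R^2$, but the AIC scale makes
differences interpretable across responses. `rank_metrics()` refuses to
rank fits whose response vectors differ, and flags exact AIC ties instead
of resolving them arbitrarily. Treatment contrasts use one-way ANOVA with
Tukey HSD contrasts and a compact letter display on per-tree means
(`group_compare()`); its type-I error is 4.8–5.4 % at $n = 4/5/9$ in
1000-cohort null studies.

## 2. The synthetic generator

`simulate_experiment()` produces the five streams the pipeline consumes —
chamber records, dendrometer traces, water-potential observations,
PLC measurements, damage records — plus a `truth` table holding every
planted quantity. The design mirrors a greenhouse drought experiment on
young conifers: 4 control, 5 short-drought (18 days) and 9 long-drought
(51 days) trees, the long treatment declining moderately at first (with a
managed mid-drought watering bump) before a final intense episode, both
treatments reaching similar minimum water potentials (−3.2 vs −4.1 MPa)
but very different doses (about 4 vs 7 days below $P_{12}$; cumulative
TWD$_{P12}$ about 3.8 vs 9.1 mm).

Causal structure: daily water-potential trajectories are the single root
cause. Stem shrinkage is $0.44\ \mathrm{mm\,MPa^{-1}}$ times the
water-potential deficit, with growth paused while any deficit exists (so
the zero-growth partition of a noiseless trace recovers the planted TWD
exactly). Stomatal closure is a logistic function of $\Psi$ centred near
$P_{12}$ (isohydric behaviour); the chamber stream is generated by
*inverting* the conductance and mass-balance equations for $w_{sample}$,
which makes `compute_fluxes()` an exact inverse of the generator on
noiseless data. The planted recovery fraction is linear in the true
TWD$_{P12}$ (clipped to $[0,1]$), with PLA and needle shedding monotone in
the same dose.

Tree-level variation: water-potential floor (truncated at ±2 SD — the
watering protocol intervenes on extreme trees), decline-shape exponent,
drought-onset shift, maximum conductance, needle area, initial diameter
and needle biomass. Onset shifts are discretised to whole steps of the
2-day water-potential sampling cadence: watering interventions happen on
measurement days, and this keeps every kink of the piecewise-linear
trajectories on the sampling grid so that daily interpolation of
noiseless observations reproduces the truth exactly. The onset spread is
the main mechanism decorrelating dose from peak intensity, which is what
lets the dose metric dominate the intensity metric in the ranking.

Realism and limits:

- Noise defaults mirror the between-tree spreads such an experiment
  reports (e.g. 0.10 MPa psychrometer noise, 5 % PLC noise, 0.005 mm
  dendrometer sensor noise).
- With default noise the dose–response fit of conductance recovery on
  TWD$_{P12}$ attains $R^2 \approx 0.87$ on average, and the planted slope
  lies within 2 SE of the estimate in about 93 % of replicates.
- The generator plants *linear* damage maps; saturation of damage at
  extreme doses is represented only by clipping. Diurnal water-potential
  dynamics are not modelled (one value per day), needle temperature equals
  air temperature, and CO$_2$ exchange is not simulated.

## 3. Numerical and computational choices

- **Strict threshold** (`psi < p12`, not `<=`): a tree exactly at the
  onset pressure has not yet crossed it; ties are resolved toward "no
  damage".
- **Interpolation, not smoothing**, for the Ψ series: with 2-day sampling
  a linear bridge is unbiased for piecewise-linear trajectories and keeps
  the day-count metrics integer-valued and auditable.
- **AIC from $SS_{res}$** rather than `stats::AIC()` keeps the criterion
  independent of R's likelihood constants and exactly reproducible from
  the normal equations.
- **Cluster bootstrap with a $t$ interval** for the vulnerability
  thresholds (see above).
- **Replicate studies** (coverage, ranking frequency, type-I error) run
  the generator at a 120-minute chamber/dendrometer cadence instead of the
  default 30 minutes. The derived daily means are cadence-invariant by
  construction, so this is purely a problem-size choice that makes
  200-replicate studies run in about two minutes.
- All generator randomness flows from a single integer seed; identical
  `(config, seed)` pairs give byte-identical streams.

## 4. Validation strategy

The test suite pins every elementary equation to hand-derived constants
(e.g. $e_s(25\,^\circ\mathrm{C}) = 3.167778$ kPa; a worked conductance of
0.943933 mmol s$^{-1}$), checks the zero-growth partition against a
brute-force prefix-maximum oracle and OLS against the normal equations,
and verifies the full pipeline on a noiseless experiment where every
number is frozen (dose table, recovery indices, fitted slope equal to the
planted slope to $10^{-13}$ relative). Statistical behaviour — coverage of
the planted slope, ranking frequency of the dose metric, bootstrap CI
coverage, ANOVA type-I error — is verified on fixed seed blocks committed
before measurement.
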