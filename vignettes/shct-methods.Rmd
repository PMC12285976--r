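---
title: "Methods: aerobic profiling, SHCT cycle programming and longitudinal evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aerobic profiling, SHCT cycle programming and longitudinal evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shct)
```

## The problem this package addresses

Elite team-sport squads often need to program aerobic training without
laboratory gas-exchange testing, heart-rate telemetry or GPS. The pipeline
implemented here supports that workflow end to end with a single field
measurement — the Cooper 12-minute run test, the distance $K$ (m) covered in
12 minutes of running:

1. **Profile** each athlete's aerobic parameters from $K$ and body weight.
2. **Program** a four-week cycle of Super High-Intensity Continuous
   Training (SHCT): 20-minute continuous runs at 75–100% of maximal
   aerobic speed, five mornings per week, with per-session oxygen and
   kilocalorie accounting.
3. **Re-measure and re-program** after each cycle.
4. **Evaluate** the longitudinal effect across the repeated measurements.

## The aerobic profile estimators

Four quantities are derived from $K$ (m) and body weight $BW$ (kg):

$$\mathrm{VO_{2rel}} = 3.134304\cdot 10^{-7}K^2 + 0.02077344\,K - 9.03125
  \quad [\mathrm{mL\,kg^{-1}\,min^{-1}}]$$
$$\mathrm{VO_{2max}} = \mathrm{VO_{2rel}} \cdot BW / 1000 \quad [\mathrm{L\,min^{-1}}]$$
$$\mathrm{vVO_{2max}} = 0.0014\,K + 0.1786 \quad [\mathrm{m\,s^{-1}}]$$
$$\eta = 100\cdot\frac{\mathrm{vVO_{2max}}}{5\cdot \mathrm{VO_{2max}}} \quad [\%]$$

The quadratic has its positive root at $K \approx 431.93$ m; `vo2rel_from_distance()`
rejects $K \le 432$ m (non-positive estimates) and $K \ge 6000$ m
(physiologically implausible). `velocity_at_vo2max()` is affine, so it
commutes with averaging — cohort-mean speeds can be computed either way —
while the quadratic does not: the VO2rel at a mean distance is *not* the
mean of per-athlete VO2rel values, which matters when comparing cohort
summaries.

**Efficiency parenthesization.** The efficiency ratio is implemented as
$100\,\mathrm{vVO_{2max}}/(5\,\mathrm{VO_{2max}})$, with 5 read as the
caloric equivalent of one liter of oxygen (kcal·L⁻¹): speed over metabolic
power. The alternative reading ($\mathrm{vVO_{2max}}/\mathrm{VO_{2max}}
\times 5$) produces values near 5.8% for typical profiles, which is
inconsistent with the reference squad whose mean efficiency is 23.4%; the
adopted form reproduces it.

**Performance zones.** VO2rel is banded into below-elite / elite
(≥ 51.3) / top-elite (≥ 55.8) / world-class (≥ 57.9 mL·kg⁻¹·min⁻¹). The
cutoffs are reference-group means minus one standard deviation
(54.2 − 2.9, 60.6 − 4.8, 64.3 − 6.4) and are treated as inclusive lower
bounds: a zone label asserts the athlete has *reached* that band.

## SHCT cycle programming

The default template (`default_template()`) is a 4×7 grid of session
intensities in percent of vVO2max — five sessions per week
(Thursday/Sunday rest), intensities 75–100%, with a wave structure of
peak (≥ 95%) sessions: 1, 2, 3, 1 across the four weeks. Each session is a
20-minute (1200 s) continuous run at $p \cdot \mathrm{vVO_{2max}}$;
warm-up and cool-down are excluded from load accounting because no oxygen
accounting is defined for them.

The oxygen cost of a submaximal session is derived by composing the three
estimators: map the session speed back to its Cooper-distance equivalent
(inverse of the affine speed map), read the VO2rel curve there, and divide
by the athlete's VO2rel:

$$f(p) = \frac{\mathrm{VO_{2rel}}\!\big(D^{-1}(p\,\mathrm{vVO_{2max}})\big)}
              {\mathrm{VO_{2rel}}(K)}, \qquad
  D^{-1}(v) = \frac{v - 0.1786}{0.0014}.$$

Because the VO2rel curve is convex while the speed map is affine,
$f(p) < p$ below maximal speed — running at 85% of maximal aerobic speed
elicits about 80% of VO2max for a mid-range profile. Session oxygen volume
is $\mathrm{VO_{2max}} \times 20\,\mathrm{min} \times f(p)$ liters, and
energy is fixed at 5 kcal per liter, so cycle kilocalories are exactly five
times cycle oxygen by construction.

**Two distance totals.** Session records and cycle summaries carry two
distances:

* `distance_m` — the distance actually run, prescribed speed × 1200 s;
* `load_distance_m` — distance credited at the *oxygen-equivalent* speed,
  $f(p)\cdot \mathrm{vVO_{2max}} \times 1200$ s.

The distinction is a deliberate design choice. The run distance is the
quantity a coach puts on the whiteboard, and it scales exactly linearly
with the template intensities. The load-accounted distance is the
convention under which published cycle totals of this training model are
tabulated alongside the oxygen totals — empirically, the reported
distance-to-oxygen ratio (≈ 69 m·L⁻¹) equals
$60\,\mathrm{vVO_{2max}}/\mathrm{VO_{2max}}$, which is only consistent with
distance credited at the oxygen-equivalent speed. For the mid-range profile
($K = 2324$ m, 72 kg) the two totals differ by about 5%:

```{r cycle}
prof <- aerobic_profile(2324, 72)
cyc <- build_cycle(prof, K = 2324)
cyc
```

`reprogram()` closes the loop: given the previous and the new Cooper
result it rebuilds the cycle from the new profile only (all 20 speeds
rescale by the ratio of maximal aerobic speeds, since the speed map is
affine) and reports the parameter deltas; a declining distance is legal
but flagged with a warning.

## Longitudinal effect evaluation

`rm_anova()` implements the one-way within-subjects ANOVA by explicit
decomposition of the $n \times T$ matrix into time, subject and error sums
of squares: $F = MS_{time}/MS_{error}$ on $(T-1,\,(n-1)(T-1))$ degrees of
freedom, with

$$\eta^2_p = \frac{SS_{time}}{SS_{time} + SS_{error}}, \qquad
  \eta^2_G = \frac{SS_{time}}{SS_{total}}.$$

For $n = 14$ athletes over $T = 5$ occasions the degrees of freedom are
(4, 52); `partial_eta_sq(F, 4, 52)` is the algebraic inverse and is how the
package reconstructs effect sizes from published $F$ statistics.
Diagnostics are Shapiro–Wilk normality per timepoint and the Mauchly
sphericity test (via `stats::mauchly.test` on the multivariate fit). No
sphericity correction is applied by default;
`correction = "greenhouse-geisser"` rescales both degrees of freedom by the
Greenhouse–Geisser $\hat\varepsilon$ computed from the double-centered
covariance matrix. The correction never decreases the p-value.

`bonferroni_pairwise()` runs a paired t-test for each of the
$\binom{T}{2}$ timepoint pairs and multiplies raw p-values by the number of
pairs, capped at 1 (all pairs count, not only adjacent ones). Degenerate
pairs (identical columns) are reported with $t = 0$, $p = 1$ rather than an
error, so census-style screens never abort.

Reliability uses two routes that are algebraically identical for the
consistency definition: `cronbach_alpha()` from the item-covariance
formula, and `icc_average()` as the Shrout–Fleiss ICC(C, k) —
$(MS_{subjects} - MS_{error})/MS_{subjects}$ — with an F-based confidence
interval on $(n-1,\,(n-1)(T-1))$ degrees of freedom. Under an
exchangeable correlation $\rho$ between occasions, the Spearman–Brown
relation predicts average-measures reliability $k\rho/(1+(k-1)\rho)$;
$\rho = 0.8$ over five occasions gives 0.952, which the synthetic cohorts
reproduce.

### Design-stage power

`power_at_n()` follows the G*Power convention for "ANOVA: repeated
measures, within factors": noncentral-F with

$$\lambda = \frac{f^2\, n\, m\, \varepsilon}{1-\rho}, \qquad
  df_1 = (m-1)\varepsilon, \qquad df_2 = (n-1)(m-1)\varepsilon,$$

where $f$ is Cohen's effect size, $m$ the number of measurements, $\rho$
the expected correlation among measures and $\varepsilon$ the
nonsphericity correction. With the planning values $f = 0.25$,
$\alpha = 0.05$, $m = 5$, $\rho = 0.8$, $\varepsilon = 1$:

```{r power}
power_at_n(11:13)
required_sample_size(target_power = 0.90)
```

Minimal-n answers are convention-sensitive (other software reports 11 or
12 depending on how $\varepsilon$ enters); the package therefore exposes
both the power curve and the search. The noncentral-F computation is exact
under compound symmetry, which the test suite confirms against a
Monte-Carlo rejection-rate oracle run through `rm_anova()` itself.

## The synthetic cohort generator

`generate_cohort()` exists so that every pipeline stage is testable
without athlete data. It emulates the *design conditions* of a
16-week SHCT intervention in an elite women's handball squad:

* athlete-level true baselines $b_i \sim N(2324, \sigma_b)$ m, truncated to
  [1200, 4000] m;
* five occasions with cumulative multiplicative gains
  $G = (1, 1.126, 1.190, 1.248, 1.247)$ — ratios of the occasion medians
  2360 → 2657 → 2808 → 2946 → 2943 m, i.e. diminishing improvements with a
  flat final interval;
* occasion noise scaled by the gain:
  $K_{it} = G_t\,(b_i + e_{it})$, $e_{it} \sim N(0, \sigma_e)$.

Scaling the noise multiplicatively (rather than adding it after the gain)
makes every between-occasion correlation exactly
$\rho = \sigma_b^2/(\sigma_b^2+\sigma_e^2)$; an additive form would drift
upward at later occasions. Defaults fix the occasion-1 total SD at 295 m
and $\rho = 0.8$, hence $\sigma_e = 295\sqrt{1-\rho} \approx 131.9$ m and
$\sigma_b = 295\sqrt{\rho}$. Body weight is $N(72, 6.4)$ kg truncated at
45 kg; age and height are drawn from the squad's descriptive distribution.
A single integer seed governs all draws in documented order (baselines,
occasion noise, weights, ages, heights), so a fixed seed reproduces the
dataset bit for bit.

**What the generator does and does not emulate.** It reproduces the
baseline distribution, the median gain trajectory, and the planning-stage
correlation $\rho = 0.8$. It does *not* reproduce two features visible in
real squad data: the shrinking cross-sectional SD over time (real cohorts
converge — weaker athletes improve proportionally more), and the very high
effective measurement correlation implied by observed effect sizes. Under
the stated conditions the expected within-subjects $\eta^2_p$ for the
Cooper distance is about 0.73 ("huge" by the conventional benchmark, where
0.5 already qualifies); published interventions of this kind report
$\eta^2_p \approx 0.92$, which would require occasion noise near 75 m,
i.e. a between-occasion correlation well above the 0.8 planning value.
We kept the stated conditions rather than tuning the generator to the
observed effect: passing tests therefore demonstrate calibration and
structure recovery under the declared model, not that real training data
look exactly like this.

## Numerical and testing choices

* All computation is double precision; rounding (speeds 2 dp, VO2rel 1–2
  dp, distances to integer meters) happens only at CSV output and in
  comparisons against printed reference values.
* Cycle totals are plain sums of the 20 session values — conservation is
  bit-exact, and `total_kcal` is exactly `5 * total_vo2_l`.
* Problem sizes in the test suite were chosen to make Monte-Carlo bounds
  decisive at desk scale: type-I calibration of `rm_anova()` uses 10,000
  null cohorts (binomial SE ≈ 0.002 against a ±0.01 band), the power
  oracle uses 20,000 replicates (MC SE ≈ 0.002), correlation recovery uses
  1,000 cohorts, and closed-form routes are checked against brute-force
  cell-level recomputations on small matrices at 10⁻⁹.
* Degenerate inputs are first-class: zero error variance yields a flagged
  result rather than a crash; identical timepoint pairs give $p = 1$;
  template grids with the wrong number of sessions, intensities outside
  (0, 100], incomplete designs, or out-of-domain Cooper distances all fail
  fast with descriptive errors.

## Known limitations

* The estimators are a single published field calibration for adult
  athletes; no alternative Cooper prediction equations, laboratory
  gas-exchange estimation, or heart-rate/GPS-driven intensity control are
  provided.
* The efficiency ratio is a proxy (speed over caloric power), not
  mechanical running economy.
* `rm_anova()` requires complete matrices — no mixed-effects fallback or
  imputation for dropouts.
* The zone cutoffs are specific to elite women's team handball; apply
  `classify_zone()` to other populations only with re-derived thresholds.
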