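---
title: "Methods: pediatric population PK of ceftobiprole and model-based dose simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pediatric population PK of ceftobiprole and model-based dose simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cebopedpk)
```

This vignette is the package's own account of its science: the disposition
and covariate model, the physiology behind the virtual pediatric
population, the dosing rules and exposure metrics, the qualification
diagnostics, and the numerical and design choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The disposition model

Ceftobiprole plasma kinetics are described by a mammillary three-compartment
model with first-order elimination from the central compartment. With
amounts $A = (A_1, A_{p1}, A_{p2})$ and zero-order infusion input $r(t)$
into the central compartment,

$$
\frac{dA}{dt} = M A + \begin{pmatrix} r(t) \\ 0 \\ 0 \end{pmatrix},
\qquad
M = \begin{pmatrix}
-(k_{10}+k_{12}+k_{13}) & k_{21} & k_{31} \\
k_{12} & -k_{21} & 0 \\
k_{13} & 0 & -k_{31}
\end{pmatrix},
$$

with the usual macro-to-micro mapping $k_{10} = CL/V_1$, $k_{12} = Q_1/V_1$,
$k_{21} = Q_1/V_{p1}$, $k_{13} = Q_2/V_1$, $k_{31} = Q_2/V_{p2}$. Units are
fixed by contract to mg, liters and hours, so concentration $A_1/V_1$ is
µg/ml with no conversion factors.

**Exact solution, not a generic ODE call.** Because a Monte Carlo run
evaluates tens of thousands of profiles, the simulator uses the closed-form
solution: the disposition matrix is eigendecomposed once per subject,
$M = V \Lambda V^{-1}$, and within each segment of constant infusion rate
the modal coordinates propagate as
$c(t) = e^{\lambda \tau} c_0 + \varphi(\lambda, \tau)\, V^{-1} b$ with
$\varphi(\lambda, \tau) = (e^{\lambda\tau} - 1)/\lambda$ (and
$\varphi \to \tau$ as $\lambda \to 0$, handled via `expm1` so degenerate
reduced models with $Q_i = 0$ are exact). Segments are the intervals
between infusion on/off switches; the state is propagated across segment
boundaries so the solution is continuous there. AUC is available in closed
form by one further analytic integration ($\psi(\lambda,\tau) =
(\varphi - \tau)/\lambda$), including to $t = \infty$, where
$\mathrm{AUC}_\infty = D/CL$ serves as an internal identity.

An adaptive ODE integrator (deSolve, integrated piecewise between infusion
switches so its right-hand side is smooth) serves as the independent oracle
in the test suite; the analytic path agrees with it to better than $10^{-6}$
relative error over 100 random parameter/dose configurations, and mass
balance (dose in = amounts remaining + $CL \times$ cumulative AUC) holds to
$10^{-8}$.

**Repeated eigenvalues.** Mammillary models with positive parameters have
three distinct negative eigenvalues; equality occurs only on a measure-zero
set. If two nonzero eigenvalues coincide to within $10^{-9}$ relative, the
parameters are perturbed by $10^{-9}$ relative with a warning rather than
evaluating the singular closed form. Exactly zero eigenvalues (reduced
models with $Q_1$ and/or $Q_2 = 0$) are not degenerate for the
$\varphi/\psi$ forms and are left alone.

**Cmax** is the maximum over the evaluation grid refined by a golden-section
search of the closed form within the bracketing grid interval, so the
reported value does not depend on grid resolution.

## 2. The covariate model

The final model's fixed effects and variance components (shipped in
`inst/extdata/ceftobiprole_ped_model.yaml`, mirrored by
`population_model()`):

| parameter | value | units / note |
|---|---|---|
| CL–GFR slope | 0.0548 | L/h per ml/min; CL = slope × GFR, CL_NR fixed to 0 |
| V1, Vp1, Vp2 at 70 kg | 16.1, 49.5, 6.13 | L; × (WT/70)^0.911 (fitted power) |
| Q1, Q2 at 70 kg | 0.545, 3.46 | L/h; × (WT/70)^0.75 (fixed allometric power) |
| ω²_CL, ω²_V1 | 0.0547, 0.0711 | log-normal IIV; %CV reported as 100·√ω² |
| σ²_prop, σ²_add | 0.0701, 0.000156 | combined residual; additive SD 0.0125 µg/ml |

The %CV convention `100*sqrt(omega2)` (not the exact log-normal
`100*sqrt(exp(omega2)-1)`) is used because it is the convention under which
the published variance/CV pairs are mutually consistent; both conversions
are numerically close at these magnitudes.

**Renal maturation.** GFR uses the Rhodin maturation model on fat-free
mass: a Hill function of postmenstrual age (PMA, weeks) with
TM50 = 47.7 weeks and Hill coefficient 3.40, times an allometric fat-free
mass term with exponent 0.75 against the 56.1 kg standard adult FFM, and a
mature value of 121.2 ml/min. At TM50 and reference size this is exactly
60.6 ml/min, half the mature value.

**Fat-free mass** is the Al-Sallami maturation equation for ages ≥ 3
months (sex-specific maturation multiplying the Janmahasatian adult form).
Below 3 months the equation's age term is not validated, and a fixed
fraction 0.86 × body weight is used instead; this choice makes the
week-old term neonate at median covariates land within 2% of the
neonatal-study median GFR. The reference FFM of 56.1 kg is the equation's
value for a 70 kg, 176 cm adult male, which makes the size term exactly 1
at the standard adult. The junction at 3 months is mildly discontinuous
(~8%); none of the shipped dosing rules or designs straddle it within a
subject.

**Body surface area** uses the Mosteller square-root formula
`sqrt(ht_cm × wt_kg / 3600)`. BSA only enters the normalization
`GFR_norm = GFR × 1.73/BSA` (and its inverse for renal-impairment
categories), so the few-percent differences among BSA formulas have no
effect on absolute clearance.

**Reference weight 70 kg** is implied rather than arbitrary: it is the
value under which the volume intercepts reproduce the weight-normalized
steady-state volume of the neonatal study (1.33 L/kg at 3.98 kg) through
the fitted 0.911 power.

The ω covariance is diagonal (no CL–V1 correlation is estimated in the
model), and the additive residual term applies on the µg/ml scale.

## 3. The virtual pediatric population

`sample_population()` generates the hypothetical population used for the
Monte Carlo simulations: five age groups (birth–<3 mo, 3 mo–<2 y, 2–<6 y,
6–<12 y, 12–<18 y) with equal counts (±1), ages uniform within group, sex
Bernoulli(0.5), and PMA = postnatal age + 40 weeks (term gestation).

**Body size** comes from an embedded, smoothed approximation of US
growth-chart medians (17 age knots per sex, log-linear interpolation) with
age-dependent coefficients of variation; a single standard-normal z-score
per subject drives both weight and height through log-normal
within-age distributions (weight–height rank correlation 1). This
reproduces the central tendency and a realistic spread of size-for-age; it
does not emulate secular trends, obesity/undernutrition subpopulations, or
the exact percentile tails of a reference population — conclusions about
extreme-size dosing should not lean on it.

**Renal function** for the normal-function population is the Rhodin-FFM
curve at the subject's PMA and FFM with a mean-preserving log-normal spread
of CV 15%. The spread magnitude is a documented knob
(`population_spec(gfr_cv = )`): some population spread is physiologic and
needed to produce realistic exposure distributions, and 15% is a
conventional between-subject CV for renal function in the absence of a
stated value. Renal-impairment populations resample the *normalized* GFR
uniformly within the category band (moderate 30–<50, severe
10–<30 ml/min/1.73 m²; the hard floor of 10 limits extrapolation toward
the model's zero clearance at zero GFR) and back-transform to absolute
ml/min through each subject's BSA.

What passing tests on this generator do show: the dosing rules, exposure
metrics and attainment machinery behave correctly on populations whose
size-age and GFR-age structure is realistic. What they do not show:
agreement with any particular real cohort's joint covariate distribution —
notably, real study enrollment can skew heavily toward very young neonates
within the 0–3 month band, where a uniform age draw sits higher in GFR.

## 4. Dosing rules and exposure metrics

The optimized regimen matrix (all 2-h infusions, 500 mg cap per dose):
15 mg/kg q12h below 3 months (10 mg/kg if under 4 kg; q24h if severe
impairment), 15 mg/kg q8h from 3 months up (10 mg/kg q12h/q24h for
moderate/severe impairment in 3 mo–<12 y, 7.5 mg/kg for adolescents). Age
intervals are half-open toward the older group, matching the `<` notation
of the rule; the under-4-kg reduction applies to the whole birth–<3 mo
column, including the severe-impairment cell. "Mild impairment"
(GFR_norm ≥ 50) is folded into normal. Doses are continuous mg (no
rounding rule is defined).

Exposure metrics are day-1 (0–24 h) quantities on a 15-minute grid: Cmax
(analytically refined), AUC by trapezoid, and %fT>MIC with *linear
interpolation of threshold crossings* rather than the fraction of grid
points above threshold — the interpolated version changes by under half a
percentage point when the grid is refined fivefold, making the metric
effectively grid-free. Free concentration is total × 0.84 (adult protein
binding of 16% carried over, the standard assumption absent pediatric
binding data), and the default MIC is 4 µg/ml. Day-1 rather than
steady-state metrics are used throughout because accumulation under q8h
dosing is minimal (trough accumulation ratio < 1.2 for typical subjects —
asserted in the test suite); PTA simulations include the interindividual
variability draws, since population attainment without IIV would
understate the spread of exposures.

The adult reference exposure band (mean ± 2 SD of steady-state AUC and
Cmax under 500 mg q8h) is deliberately *not* shipped: those values must be
supplied by the user (`compare_to_adult()` errors without them) rather than
silently defaulted.

## 5. Synthetic trials and diagnostics

`simulate_study()` reproduces the three pediatric study designs: single
2-h infusions with seven nominal samples over 24 h (ages 3 mo–<18 y,
age-banded 7–15 mg/kg), single 7.5 mg/kg 4-h infusions with six nominal
samples in term neonates, and q8h multi-dose (10–20 mg/kg by age) with
sparse day-3 sampling after the morning dose at 48 h. Observations carry
combined residual error; values below the LLOQ are flagged, not imputed.
The LLOQ defaults to 0.05 µg/ml — only the exclusion mechanics matter for
the artifact, so the threshold is configurable. Predose samples of
single-dose designs are true zeros flagged BLQ. Nominal times are used by
default with an optional uniform jitter. Datasets are NONMEM-style long
format (ID/TIME/AMT/RATE/EVID/MDV/DV/BLQ + covariates), round-trip through
CSV with `.` for missing, and are validated on read (a dose record with a
DV, or an observation with an AMT, is an error naming the row).

**MAP empirical-Bayes estimates** minimize the penalized deviance
$-2\sum_j \log N(y_j \mid f_j(\eta), \sigma^2_{prop} f_j^2 + \sigma^2_{add})
+ \eta^\top \Omega^{-1} \eta$ over the two η's, by quasi-Newton search from
η = 0 with objective tolerance $10^{-8}$. With noise-free typical data the
mode is η = 0; with a single sparse sample the estimates shrink toward
zero, as they must.

**PC-VPC** bins observations at the nominal sampling times (bins under 5
observations merge into their nearest neighbor with a warning),
prediction-corrects by the bin-median population prediction, and compares
observed 5th/50th/95th percentiles with 90% confidence bands from
re-simulated replicates. The calibration test asserts coverage of the
observed median at the nominal 90% rate *minus two binomial standard
errors* of the pooled bin count — a sharp ≥90% bound on a ~20-bin sample
would fail about half the time under a perfectly calibrated model.

**NPDE** is the rank-based simulation residual
$\Phi^{-1}\!\big((r + 0.5)/(n_{sim}+1)\big)$; the decorrelation step of the
full method is omitted because observations per subject are few and the
diagnostic is used for calibration testing, not publication claims. Under
self-simulation the mean is within ±0.1 and the variance within
[0.85, 1.15] at 1,000 observations; a twofold clearance misfit at 100
subjects moves the mean beyond ±0.5 in every tested replicate.

**Covariate-model recovery** fits each subject's CL and V1 by iteratively
reweighted least squares (weights frozen at the previous iterate's
predicted variances — extended least squares with a free log-variance term
rewards small predictions and biased recovered clearances upward by ~2%),
with the remaining parameters constrained to the population weight
scaling. The CL–GFR slope is then the *log-scale* zero-intercept
regression (geometric-mean ratio), which is median-consistent under
log-normal IIV — an arithmetic regression would recover
slope × exp(ω²/2). The volume exponent comes from log-log regression of
V1 on weight, and ω²_CL from the variance of the log ratios. The recovery
design uses 14 samples per subject with dense infusion-phase sampling (V1
is identified by the rising phase) across the full 0–18 y range. At n =
200 subjects the per-seed volume-exponent estimate carries irreducible
sampling noise of ≈ 0.03 from ω²_V1 alone, so recovery is assessed as the
median over 10 seeded replicates.

Full population estimation (FOCE-style linearized likelihood) is out of
scope: per-subject fits plus regression are sufficient to validate the
simulator and the covariate model, which is what the recovery surface is
for.

## 6. Problem sizes and tolerances

The default test and acceptance runs use 1,000 virtual subjects per age
group for attainment tables (binomial SE ≈ 0.5 points at 97%), 100 random
configurations for the oracle sweep, 500 simulation replicates for NPDE,
and 10 × 200-subject replicates for recovery — sizes chosen so the whole
suite completes comfortably on a single CPU while keeping Monte Carlo noise
well inside the stated tolerances. Deterministic identities are asserted at
$10^{-8}$–$10^{-12}$; stochastic checks at 2–3 standard errors.

## 7. Known limitations

- The model is linear: no saturable elimination, no prodrug conversion
  step, no drug–drug interactions, and protein binding fixed at the adult
  16%.
- Typical-subject predictions at a study's *median covariates* are not the
  same thing as the *median of per-subject estimates* in a small real
  cohort; for right-skewed quantities such as partial AUCs the two can
  differ by 10–20%, and the package makes no attempt to force agreement.
- The normal-function GFR assignment (Rhodin-FFM curve + 15% CV) is a
  reconstruction; other "standard equations adjusted for age and BSA" give
  GFR-age trajectories that differ most in the 1 month–2 year range, where
  maturation is steepest. Attainment numbers for the youngest groups at
  high fT>MIC targets (50–60%) are the most sensitive to this choice.
- The growth reference is a smoothed approximation; extreme size
  percentiles and non-term gestation (preterm strata) are not modeled.
- NPDE omits decorrelation; PC-VPC uses nominal-time binning only.
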