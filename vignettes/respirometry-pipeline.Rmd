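---
title: "From PO2 traces to metabolic phenotypes: methods and design"
author: "thermoresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From PO2 traces to metabolic phenotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoresp)
```

## The measurement model

Automated intermittent-flow respirometry alternates three phases: a **flush**
(the chamber is re-oxygenated to saturation), a short **wait**, and a sealed
**measure** phase during which the fish's oxygen consumption draws PO2 down.
For one sealed phase the oxygen consumption rate is

$$\dot M\mathrm{O}_2 = V_\mathrm{eff}\,\left|\frac{\Delta P\mathrm{O}_2}{\Delta t}\right|\,\beta(T,S),$$

where $V_\mathrm{eff}$ is the chamber volume minus the fish volume (1 kg of
fish displaces 1 L), $\Delta PO_2/\Delta t$ is the ordinary-least-squares
slope of PO2 on time (mm Hg h⁻¹), and $\beta(T,S)$ is the oxygen solubility
coefficient (mg O2 mmHg⁻¹ L⁻¹). Whole-animal rates divide by body mass to the
conventional mg O2 kg⁻¹ h⁻¹ — the defining formula yields mg O2 h⁻¹, and the
package makes that division explicit.

Assumptions: the chamber is well mixed (no PO2 gradients), the fish's MO2 is
constant within one sealed phase, and the PO2 decline is therefore linear. The
linearity assumption is also the quality filter: slopes whose regression
r² falls below 0.95 are excluded from all downstream estimation, as are
cycles whose measurement window overlaps a thermal ramp (their temperature is
undefined for binned analyses) and cycles with non-declining PO2.

**Solubility.** $\beta$ is computed from the Weiss (1970) seawater oxygen
solubility fit (mL L⁻¹, converted to mg L⁻¹ with 1 mL O2 = 1.42905 mg)
divided by the saturating oxygen partial pressure, 0.20946 × (760 − water
vapour pressure), with vapour pressure from Weiss & Price (1980). One
parameterization is used consistently by both the simulator and the
processor; an independently re-keyed transcription serves as the test oracle,
and the freshwater saturation values (14.62 mg L⁻¹ at 0 °C, 9.08 at 20 °C)
anchor it to published tables.

## Mass standardization

Metabolic rate scales allometrically with body mass, so rates are
standardized to a common mass before fish are compared:

$$\dot M\mathrm{O}_{2,\mathrm{std}} = \dot M\mathrm{O}_{2,\mathrm{obs}}\left(\frac{BW}{0.34\ \mathrm{kg}}\right)^{1-b}.$$

The cohorts the package emulates span too small a mass range to estimate $b$
internally, so the teleost-average exponents are used: $b = 0.948$ for
SMR-bound records and $b = 0.937$ for MMR-bound records; 0.34 kg is the
cohort mean mass. At $BW = 0.34$ kg, or with $b = 1$, the correction is the
identity; with $b < 1$ larger-than-standard fish are adjusted upward.

## SMR as the lowest normal-mixture component

During a trial the observed cycle MO2 values are a mixture: quiescent
readings at the standard metabolic rate, readings elevated by the
exponentially decaying handling-stress response, and spontaneous-activity
excursions. `estimate_smr()` fits univariate normal mixtures with 1–4
components by EM — both equal- and unequal-variance families — selects the
component count by BIC, and returns the mean of the lowest-mean component.

Numerical choices, all configurable:

- **Initialization** splits the sample at quantiles; five additional restarts
  jitter the split points from an internal seeded RNG stream, so fits are
  deterministic and the caller's RNG state is untouched.
- **Convergence**: relative log-likelihood change below 1e-8, capped at 500
  iterations.
- **Singular fits are disqualified, not compared.** The unequal-variance
  likelihood is unbounded as a component's variance collapses onto a single
  observation; a candidate whose component sd reaches the variance floor
  (1e-6 × sample sd) or whose component carries fewer than two effective
  observations is excluded from BIC selection rather than allowed to win it.
- **Ties favour fewer components** (strictly larger BIC is required to move
  to a bigger model).
- **Mixing-weight floor** (default 0.05): a component below the floor cannot
  be the SMR component, which protects the estimate from a spurious cluster
  formed by one or two low outliers.
- Constant input degenerates gracefully: a single component at the common
  value; a perfectly constant regression window is assigned r² = 0 (it
  carries no evidence of a decline and fails QC).

When BIC selects one component the estimator reduces to the sample mean. A
low-quantile estimator (`smr_quantile()`, default q = 0.2) is kept alongside
as an independent sanity check — the two agree within 10% of SMR on
simulated trials — and `mclust`, the standard mixture toolbox, is used as a
cross-check oracle in the test suite only.

MMR is the single highest QC-passed value at the acclimation temperature;
AAS = MMR − SMR and FAS = MMR/SMR follow by definition, and thermal
sensitivity is $Q_{10} = (R_2/R_1)^{10/(t_2-t_1)}$ from SMR at the extreme
holds of an arm (5→15 °C for the cold challenge, 20→30 °C for the heat
challenge).

## The trace simulator

`simulate_trial()` emits a full multi-hour PO2 trace with embedded ground
truth, emulating a two-arm acute thermal challenge: holds of 20, 5 and 18 h
at 15→10→5 °C (cold arm) or 20→25→30 °C (heat arm), connected by 2.5 °C h⁻¹
ramps (each 5 °C step completed within 2 h); cycles of 180 s flush + 60 s
wait + a temperature-dependent measure phase (1200 s at 5 °C shortening to
180 s at 30 °C, so a similar amount of oxygen is consumed per cycle at every
temperature).

The generative model for a fish:

- true SMR follows the Q10 law, $SMR(T) = SMR_\mathrm{ref}\,
  Q_{10}^{(T-T_\mathrm{ref})/10}$;
- handling stress multiplies SMR by $1 + A\,e^{-t/\tau}$ (defaults drawn per
  fish: amplitude 0.5–1.5, $\tau$ 2–4 h) — the long first hold exists so this
  decays before most quiescent cycles are recorded;
- spontaneous activity is a per-cycle Bernoulli event (rate 1–2 h⁻¹) adding a
  lognormally jittered excursion (mean ~1× SMR, sdlog 0.5) — any
  heavy-right-tail mechanism that leaves the MO2 mode at SMR would do;
- instantaneous MO2 is capped at `mmr_multiplier` × SMR (2.5–3.5), which
  makes "true MMR" well defined for recovery tests;
- within a sealed phase PO2 declines linearly at
  $-(\dot M\mathrm{O}_2 BW + \text{background})/(V_\mathrm{eff}\beta)$, with
  additive Gaussian sensor noise (default sd 0.25 mm Hg, the precision class
  of fibre-optic oxygen optodes) on every sample; each flush restores PO2 to
  155 mm Hg (air saturation — the real flush efficacy is not modelled).

Chambers are sized to the fish (4 L below 0.3 kg, 7 L above), which keeps the
per-cycle PO2 decline a few mm Hg deep — comfortably above the sensor noise,
so the r² ≥ 0.95 filter passes most genuine cycles. Background (microbial)
respiration defaults to zero — blank-run checks in this kind of experiment
typically find it below 1% of the fish's rate, and `check_background()`
implements exactly that negligibility report — but a nonzero rate is
supported and subtracted when configured. Sampling interval defaults to 1 s
(sensor frequency is rarely reported; it is configurable, and the examples
here use 5–10 s to keep run time down with no loss of slope information).

Cohort defaults (`make_cohort()`) mirror a two-population study: 10 northern
+ 11 southern fish in the cold arm (10 + 5 in the heat arm), body masses
spanning each population's observed range (e.g. 0.140–0.252 kg northern,
0.235–0.838 kg southern in the cold arm), population mean SMR at the
acclimation temperature (72.5 vs 53.8 mg O2 kg⁻¹ h⁻¹ cold; 100.2 vs 86.6
heat) with 14% between-fish CV, and Q10 drawn uniformly from each
population's span (northern 1.9–2.4, southern 1.4–3.4).

**What the simulator does not emulate** — and hence what passing tests do not
show about real data: chamber mixing transients at the start of a sealed
phase (real analysts sometimes trim the first seconds; the default here uses
the full window), PO2-dependent physiology (no hypoxia effects as the chamber
depletes), behavioural structure beyond stress decay plus memoryless spikes,
sensor drift or calibration error (noise is white), and incomplete flushes.
Parameter recovery on these traces validates the estimators' logic, not their
robustness to every field artefact.

## Population comparison

Per-temperature contrasts use the two-tailed **pooled-variance** Student's
t-test (df = n1 + n2 − 2) — the variant whose degrees of freedom match the
convention in this literature — with degenerate inputs (zero pooled variance)
handled explicitly. No multiplicity correction is applied by default, keeping
the per-test α = 0.05 convention; `adjust = "holm"` is available.

The design-wide model is the random-intercept linear mixed model

```
smr ~ origin * temperature + (1 | fish_id)
```

with temperature categorical, fitted by **maximum likelihood** (not REML,
because likelihood-ratio tests across fixed-effect structures require ML).
Each fixed effect is tested by refitting without it: origin and temperature
drop out of the additive model (df 1 and 2 for two origins and three
temperatures), the interaction out of the full model (df 2). χ² = 2Δℓ with
p from the χ² distribution. Cold and heat arms are fitted separately.
Singular designs (an empty origin × temperature cell) are reported as errors
rather than silently extrapolated.

**Predicted-SMR table.** Per cell: fit = $x^\top\hat\beta$ and
se = $\sqrt{x^\top \widehat{\mathrm{Var}}(\hat\beta)\,x}$ from the
fixed-effect covariance; sd = se·√n and ci = $t_{0.975,\,n-1}$·se with n the
number of fish of that origin. This sd/se/ci convention was chosen because it
reproduces the dispersion structure of the packaged worked-example table
(e.g. se 1.7 × √11 = 5.64 ≈ sd 5.7, and ci/se ≈ $t_{0.975,10}$) — the
alternative normal-theory half width (1.96·se) differs by a few percent at
these group sizes.

**Calibration of the origin LRT.** The χ² reference for a likelihood-ratio
test is asymptotic. For a between-fish effect the effective sample size is
the number of fish, so at 10 + 11 fish with a strong fish-level intercept the
χ²(1) test is mildly anticonservative — essentially
$P(F_{1,19} > 3.84) \approx 0.066$ rather than 0.05; the acceptance script
measures this directly (≈ 0.07 over 500 null replicates at the study size).
The package's calibration check therefore runs at 30 fish per origin, where
the asymptotic reference applies (measured size ≈ 0.05), and the small-sample
inflation is reported alongside rather than hidden. Users comparing small
cohorts should read origin p-values near 0.05 with that inflation in mind
(a Kenward–Roger or parametric-bootstrap test would be the stricter
alternative; it is out of scope here because the LRT is the method under
study).

## Reproducibility and problem sizes

Every stochastic component is seeded: `simulate_trial()` and
`fit_normal_mixture()` consume explicit seeds and restore the caller's RNG
state; `run_pipeline()` derives per-trial seeds from one master seed and
writes a manifest (config + seed + package version) with its CSVs, so a
bundle is reproducible byte-for-byte.

The test suite exercises full-protocol (47 h simulated) trials at 5 s
sampling for parameter-recovery checks (20 fish spanning Q10 1.4–3.4;
recovery within 15% for ≥ 90% of fish), shortened-protocol trials for
structural checks, 50 × 200-draw bimodal samples for mixture recovery (within
2% of the true low-component mean), and 500 null replicates for LRT size —
sizes chosen to keep the whole suite within a few minutes on one CPU while
leaving each check statistically meaningful.

## Known limitations

- SMR at briefly held temperatures (5 h holds yield ~20 cycles) rests on few
  observations; below `min_obs` (default 10) the package refuses an estimate
  (`skipped` in the phenotype set) instead of guessing.
- MMR from spontaneous activity is an observed maximum, not a chase-protocol
  maximum; with few cycles it underestimates the ceiling, and with noisy
  slopes the single-highest-value definition can overshoot it by a few
  percent.
- The QC filter preferentially removes shallow (low-MO2) slopes when noise is
  high relative to the per-cycle PO2 decline, which would bias SMR upward;
  chamber sizing keeps this marginal in the emulated designs, but users
  processing their own traces should check the excluded-cycle count the
  pipeline logs.
- The mixed model treats temperature as categorical and fish as exchangeable
  intercepts; metabolic scaling is multiplicative, so residual variance grows
  with temperature and the homoscedasticity assumption is only approximate —
  visible in the widening dispersion columns at warm temperatures.
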