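# thermoresp

Intermittent-flow respirometry simulation and metabolic phenotyping in R.

Comparative ecophysiologists measure a fish's aerobic metabolism by sealing it
in a respirometer and regressing the decline of oxygen partial pressure (PO2)
over repeated flush/wait/measure cycles while water temperature is stepped
through an ecologically relevant range. `thermoresp` implements that whole
workflow — from raw PO2 trace to population-level statistics — together with a
trace simulator with known ground truth, so every stage of the analysis can be
validated without any animal data.

## What it computes

For each measurement cycle, oxygen consumption is

&nbsp;&nbsp;&nbsp;&nbsp;MO2 = V · |ΔPO2/Δt| · β,

with V the chamber volume corrected for fish volume (1 kg ≡ 1 L), ΔPO2/Δt the
OLS slope of PO2 on time (cycles with r² < 0.95 are excluded), and β(T, S) the
seawater oxygen solubility (Weiss 1970 parameterization). Rates are
standardized to a 0.34 kg fish by MO2,std = MO2,obs · (BW/0.34)^(1−b), with
teleost-average exponents b = 0.948 (SMR) and b = 0.937 (MMR). Per fish and
temperature:

- **SMR** (standard metabolic rate): the mean of the lowest-mean component of
  a univariate normal mixture fitted by EM to the cycle MO2 values, with the
  number of components (1–4, equal or unequal variance) chosen by BIC —
  quiescent readings form the lowest mode, handling stress and spontaneous
  activity the upper ones.
- **MMR** (maximum metabolic rate): the single highest MO2 value.
- **AAS** = MMR − SMR, **FAS** = MMR/SMR (absolute/factorial aerobic scope).
- **Q10** = (R2/R1)^(10/(t2−t1)): thermal sensitivity of SMR.

Populations are compared per temperature with two-tailed pooled-variance
t-tests, and across the design with the random-intercept mixed model
`smr ~ origin * temperature + (1 | fish_id)` fitted by maximum likelihood,
with likelihood-ratio tests per fixed effect and a predicted-SMR table
(fit, sd, se, 95% ci per origin × temperature).

## Worked example

```r
library(thermoresp)

f  <- fish_profile("fish1", origin = "northern", body_weight = 0.25,
                   smr_ref = 72, t_ref = 15, q10_true = 2.1)
tr <- simulate_trial(f, cold_arm_protocol(), assign_chamber(f),
                     seed = 42, sample_interval = 5)
ph <- estimate_phenotypes(process_trace(tr), origin = "northern")
ph
#> <phenotype_set> fish1 (northern)
#>   SMR: 5 C: 33.7, 10 C: 48.7, 15 C: 71.8
#>   MMR @ 15 C: 213.3 | AAS 141.5 | FAS 2.97 | Q10(5-15 C) 2.13
```

The fish was simulated with a true SMR of 72 mg O2 kg⁻¹ h⁻¹ at 15 °C (hence
34.3 at 5 °C under its true Q10 of 2.1) and an aerobic ceiling at 3 × SMR;
after handling-stress decay, activity spikes, sensor noise and the r² filter,
the pipeline recovers SMR at every hold within ~2% and the Q10 within ~1.5%.

A full two-population experiment, with per-temperature contrasts and the mixed
model, is one call:

```r
pl <- run_pipeline(run_config(seed = 1, arm = "cold", sample_interval = 5))
pl$predicted_smr      # origin x temperature: n, fit, sd, se, ci
pl$lmm$lrt            # LRT chi-squared, df, p per fixed effect
```

The packaged worked-example tables (`seatrout_tables()`) hold mixed-model
predicted SMR for two wild spotted-seatrout populations; e.g. the northern
population's predicted SMR at 25 °C exceeds the southern one's by
`percent_difference(185.6, 135.1)` ≈ 37%.

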