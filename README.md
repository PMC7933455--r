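# pafc — sinus-rhythm ECG complexity scoring for PAF screening

`pafc` implements a screening pipeline for **paroxysmal atrial
fibrillation (PAF)** risk that needs nothing more than repeated short
sinus-rhythm ECG strips from a handheld single-lead recorder (28 s at
125 Hz, twice daily over a few weeks). PAF is intermittent and mostly
asymptomatic, so single recordings usually miss it; the idea here is
that atria prone to fibrillation leave a trace in the *day-to-day
variability* of the ECG's information content even while the rhythm is
normal.

## The method

Each strip is symbolized into two binary strings:

* **TC** (threshold crossing): `s(i) = 1` iff the voltage is at or
  above the strip's median, else `0` — the whole-waveform channel;
* **BD** (beat detection): `1` only at detected R-wave peaks, found by
  a smoothed-derivative QRS detector (Savitzky–Golay window 5, 6-s
  sliding search window, relative derivative threshold 0.7) — the
  beat-interval channel.

Each string gets a Lempel–Ziv 1976 complexity count `c(n)` (components
of the exhaustive production history), normalized to

    CS(n) = c(n) / b(n),    b(n) = n / log2(n),

so an i.i.d. fair-coin string scores ≈ 1. Per patient, the day-to-day
variability of each channel is the sum of squared deviations of the
per-strip scores about their mean, `varCS = Σ(CSᵢ − mean CS)²`, and
the two channels — empirically independent within patients — combine
into the composite discriminant

    h = sqrt(varCS_TC² + (k · varCS_BD)²),

where `k` (calibrated default 120.6) is the axis-intercept ratio of a
quarter-ellipse separating controls from cases in the
(varCS_TC, varCS_BD) plane; in the rescaled plane the ellipse is a
circle and the decision rule is `h > h*` (calibrated default
4.5·10⁻³). The package includes the full evaluation suite
(Mann–Whitney tests, empirical ROC with Hanley–McNeil CIs and paired
DeLong AUC comparison, Youden operating point, strips-needed curve,
threshold perturbation, additive-noise robustness) and a seeded
synthetic ECG cohort generator so the entire pipeline is testable
without clinical data.

## A worked example

```r
library(pafc)

cohort <- generate_cohort(n_controls = 24, n_cases = 28,
                          strips_per_patient = 35, seed = 1)
scores <- score_cohort(cohort)

model <- fit_ellipse(scores$var_cs_tc, scores$var_cs_bd, scores$label)
model
#> Separating-ellipse calibration
#>   intercepts: a = 5.1835e-02 (varCS_TC), b = 1.9545e-03 (varCS_BD)
#>   k = a/b = 26.5, circle radius = 5.1835e-02, h* = 5.1835e-02
#>   training balanced accuracy = 0.908 (sens 0.86, spec 0.96)

h <- h_score(scores$var_cs_tc, scores$var_cs_bd, k = model$k)
roc(h, scores$label)
#> Empirical ROC: 28 cases vs 24 controls
#>   AUC = 0.957 (95% CI 0.901-1.000)
#>   operating point: threshold 0.05181, sensitivity 0.86, specificity 0.96
```

Reading this: on a simulated 52-patient cohort whose cases differ from
controls only in *day-to-day* spread of beat morphology and heart
rate, the ellipse calibration finds the scale constant `k = 26.5` for
this cohort's score scale, and the composite h-score separates the
cohorts with AUC 0.957 — while the per-patient *mean* complexity score
alone is nearly uninformative (AUC ≈ 0.62 on the same data). That
ordering — variability scores beat mean scores, the composite beats
either axis — is the method's central claim.

The command-line front end wraps the same functions:

```sh
Rscript inst/cli/pafc.R simulate --controls 24 --cases 28 --strips 35 --seed 1 --out data/
Rscript inst/cli/pafc.R score --manifest data/manifest.csv --out scores.csv
Rscript inst/cli/pafc.R calibrate --scores scores.csv --out model.yaml
Rscript inst/cli/pafc.R evaluate --scores scores.csv
```

## Scope notes

The beat detector assumes sinus rhythm below 100 beats/min; decoding
any proprietary device format, arrhythmia/artifact screening, and
clinical validation are out of scope. The synthetic generator
emulates the structure of the study data (cohort sizes, strip counts,
heart-rate range, 15–20 dB SNR), not PAF electrophysiology — see the
methods vignette (`vignettes/paf-complexity-screening.Rmd`) for what
passing tests do and do not demonstrate.
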