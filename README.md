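# pltrecon

Semi-mechanistic modelling and MAP forecasting of platelet reconstitution
after allogeneic hematopoietic cell transplantation (allo-HCT).

Thrombocytopenia after allo-HCT — a mean of the last 12 platelet counts in
day +29..+180 below 75×10⁹/L — affects roughly a third of transplant
patients and carries a markedly worse prognosis. Identifying at-risk
patients from data available in the first weeks would leave time for
interventions such as thrombopoietin-receptor agonists or donor stem-cell
boosts. `pltrecon` implements, as a tested R library with a command-line
interface, a population model of 180-day platelet kinetics for exactly that
purpose, together with the machinery to forecast individual patients and to
quantify how well those forecasts predict thrombocytopenia.

## The model

Platelet counts are the sum of patient- and graft-derived cells,
`PLT(t) = PLT_PAT(t) + PLT_GT(t)`, each produced by a Friberg-type transit
chain (proliferating HSC → TR1..TR3 → circulating platelets, transit rate
`K = (n+1)/MMT`, `n = 3`). The 14-state system couples:

- conditioning, inhibiting patient HSC proliferation by ρ = 0.945 on the
  conditioning window (day −6..−2);
- a kinetic-pharmacodynamic ATG effect: a virtual amount with first-order
  decline multiplying platelet elimination by `1 + α·ATG(t)`;
- the graft dose (72.4×10⁹/L-equivalents) homing to the marrow through two
  transit compartments (`K_GR = 2/TTBM`, TTBM = 1.5 d);
- graft HSC proliferation under platelet feedback
  `(Graft1₀/PLT_GT)^γ` (γ = 0.19), a transplant-associated suppression
  `(1 − HCT(t))` with `HCT(0) = 4.22` declining at `K_EL = 0.353`/d
  (half-life 2.0 d), and a total-protein covariate effect
  `(TP/5.43)^0.197`;
- day-0 boluses (graft cells, HCT effect, a 20.1×10⁹/L platelet boost,
  ×2.75 for related donors) and 10.6×10⁹/L transfusion boluses.

Individual forecasting is MAP ("Bayesian forecasting"): log-normal random
effects on the eight parameters with published inter-individual
variability, estimated from pre-transplant data plus weekly counts up to a
cutoff (day +7/+14/+21/+28), then simulated forward to day +180. Because
the clinical data are protected, the package ships a synthetic-cohort
generator reproducing the study conditions (treatment mix, sampling
density, transfusion imputation at 12×10⁹/L, drifting total protein).

## Worked example

```r
library(pltrecon)

pop <- population_parameters()      # published typical values + IIV as prior

## typical patient, conditioning day -6..-2, unrelated donor, no ATG
traj <- simulate_individual(pop, treatment_regimen())
nadir_day(traj)
#> [1] 11
min(trajectory_at(traj, -6:180))
#> [1] 12.84215
trajectory_engraftment(traj)        # first sustained recovery >= 20e9/L
#> [1] 17

## a synthetic subject and its day-28 forecast
subj <- generate_subject(seed = 11)
subj
#> Synthetic subject 1: 59 observations, unrelated donor, ATG, 9 transfusion(s)
fc <- forecast(subj, pop, cutoff_day = 28, interval = FALSE)
fc
#> Forecast from day +28: predicted trailing mean 77.6 x10^9/L -> no thrombocytopenia
subj$true_label
#> [1] FALSE
```

The typical trajectory holds its 90.5×10⁹/L baseline until conditioning
takes effect, dips to ≈12.8×10⁹/L around day 10–11, and recovers with the
feedback-driven overshoot; sustained recovery above the 20×10⁹/L
engraftment threshold starts on day 17. The forecast conditions the prior
on the subject's first four weekly counts (plus pre-transplant data) and
classifies the subject by the predicted trailing mean against 75×10⁹/L —
here correctly calling the stored ground truth.

A thin CLI wraps the same functions
(`inst/cli/pltrecon <simulate|generate|forecast|evaluate> ...`); see
`?cli_main`.

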