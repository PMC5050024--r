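# pmfield

Quantitative tools for thylakoid bioenergetics: partitioning of the
proton motive force (pmf) and the consequences of its electric-field
component (Δψ) for photosystem II (PSII) photodamage.

## Who this is for

Plant photosynthesis researchers working with electrochromic shift
(ECS) spectroscopy and pulse-amplitude-modulated (PAM) chlorophyll
fluorescence. The package covers the full analysis chain of a
pmf-phenotyping study: dark-interval relaxation kinetics (DIRK) of the
ECS, pmf partitioning into Δψ and ΔpH, the standard quenching
parameters, an ECS → millivolt calibration, a field-dependent
charge-recombination model, a kinetic simulator of the PSII
back-reaction scheme, and a seeded synthetic-data generator so every
estimator is testable by round-trip recovery without instrument data.

## The model at the core

The rate of charge recombination from the S₂Q_A⁻ state of PSII is

    v_r = k_r · (1 − q_L) · 10^(Δψ_light−dark / 60 mV)

where `k_r = 0.3 s⁻¹` is the intrinsic zero-field rate with Q_A fully
reduced, `1 − q_L` estimates the reduced-Q_A fraction from
fluorescence, and every 60 mV of trans-thylakoid field accelerates
recombination tenfold by destabilising the charge-separated state
(0.06 eV per decade). Because the recombination route through the
P⁺Pheo⁻ radical pair generates chlorophyll triplets and hence singlet
oxygen, a high Δψ — from low ATP-synthase conductivity (g_H⁺) or from
Δψ "spikes" under fluctuating light — translates directly into PSII
photodamage. A three-state kinetic simulator of the back-reaction
scheme (S₂Q_A⁻ ⇌ S₂[P⁺Pheo⁻] → recombined, with a triplet branch)
reproduces this Boltzmann behaviour from explicit rate constants.

## Worked example

Synthesize a steady-state ECS measurement with a dark interval, fit
the DIRK decay, and feed the calibrated Δψ into the recombination
model:

```r
library(pmfield)
p <- plant_params()                      # gH+ = 10 s^-1, dark pmf 112 mV

tt <- seq(0, 12, by = 0.002)             # 8 s light, 4 s dark interval
state <- data.frame(time_s = tt, dpsi_mV = 56 + 80, dph_mV = 56 + 60,
                    irradiance_umol = 300)
trace <- synthesize_ecs_trace(state, p, data.frame(start_s = 8, end_s = 12))

fit <- fit_dirk(trace, dark_window = c(8, 12))
fit
#> DIRK first-order decay fit
#>   ECS_t  = 3.5 (normalised dA ug chl^-1 cm^2)
#>   tau    = 0.1 s   gH+ = 10 s^-1
#>   offset = -30, rmse = 9.04e-16, n = 2000

recombination_rate(q_L = 0.4, dpsi_mV = calibrate_ecs_to_mv(2.0))
#> v_r = 3.878 s^-1 (qL = 0.4, dpsi = 80 mV, physical sign)

predicted_fold_change(40)                # ~5-fold at a 40 mV flash
#> [1] 4.641589
```

The fitted amplitude (3.5 normalised ECS units) is the total
light-induced pmf; the inverse time constant recovers the generator's
proton conductivity exactly. An 80 mV light−dark Δψ (2.0 ECS units at
40 mV per flash-unit) with 60% of Q_A reduced accelerates
recombination to ≈3.9 s⁻¹, thirteen-fold over the field-free rate.

Higher-level drivers: `run_screen()` simulates and analyses a
multi-genotype, multi-day phenotyping screen (fold changes, daily
qE/qI integrals, Welch tests, qI-vs-pmf ANOVA);
`simulate_s2qa_decay()` and `gramicidin_comparison()` run the
back-reaction simulator. A thin command-line wrapper with
`simulate | dirk | pam | recombination | simulate-psii | screen`
subcommands lives at `inst/cli/pmfield.R`.

## Package layout

- `R/` — light schedules and pmf dynamics, trace generators, ECS/DIRK
  analysis, fluorescence parameters, calibration + recombination
  model, PSII kinetic simulator, screen driver, CSV/TSV/YAML I/O.
- `tests/testthat/` — unit, property and acceptance tests (round-trip
  recovery, conservation laws, closed-form oracles, statistical
  calibration).
- `vignettes/pmf-partitioning-and-psii-photodamage.Rmd` — the methods
  vignette: model assumptions, parameter defaults and their rationale,
  numerical choices, limitations.
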