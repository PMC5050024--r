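---
title: "Quantifying the thylakoid proton motive force and field-dependent PSII photodamage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the thylakoid proton motive force and field-dependent PSII photodamage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfield)
```

## The scientific problem

The light reactions of photosynthesis store energy in a transmembrane
proton motive force (pmf), the sum of an electric-field component
(Δψ) and a pH gradient (ΔpH) across the thylakoid membrane. Both
components drive ATP synthesis equally, but they regulate
photosynthesis differently: lumen acidification (ΔpH) switches on
energy-dependent exciton quenching (q~E~) and slows cytochrome b~6~f
turnover, whereas Δψ acts directly on every charge-separation
equilibrium inside the photosystems. When proton efflux through the ATP
synthase is slow (low proton conductivity, g~H~^+^), or when the light
fluctuates faster than counter-ion movements can convert Δψ into ΔpH,
the field across photosystem II (PSII) rises. A higher field
destabilises the charge-separated S~2~Q~A~^−^ state, accelerates
back-reactions through the P^+^Pheo^−^ radical pair, and thereby raises
the yield of the chlorophyll triplet ^3^P and of singlet oxygen — the
species that photodamages PSII.

`pmfield` implements the full measurement-and-model chain used to
study this mechanism: ECS/DIRK spectroscopy quantification, pmf
partitioning, PAM fluorescence quenching parameters, an ECS → mV
calibration, the field-dependent recombination-rate model, a kinetic
simulator of the PSII back-reaction scheme, and a synthetic-data
generator that stands in for the (undeposited) raw spectroscopy so the
whole pipeline is testable end to end.

## The recombination model

The central quantitative object is the rate of charge recombination
from S~2~Q~A~^−^,

$$v_r = k_r \,(1 - q_L)\, 10^{\,\Delta\psi_{light-dark}/60\ \mathrm{mV}},$$

with `k_r = 0.3` s^−1^ the intrinsic rate measured at zero field with
Q~A~ fully reduced, `1 − q_L` the reduced-Q~A~ fraction estimated from
fluorescence, and one decade of acceleration per 60 mV of field
(equivalently 0.06 eV of lost stabilisation free energy per decade).
`recombination_rate()` evaluates this; `predicted_fold_change()` gives
the pure Boltzmann factor, e.g. `10^(40/60) = 4.64 ≈ 5`-fold at the
~40 mV deposited by a saturating single-turnover flash.

**Sign convention.** The typeset form of the operational equation
carries a negative exponent, which contradicts the accompanying
free-energy argument (the field *lowers* the stabilisation energy, so
the rate must *rise* with Δψ) and the observed field-accelerated decay
and positive q~I~–Δψ correlation. The package therefore defaults to the
physical positive exponent and offers `sign_convention = "as_printed"`
for the literal form; every result object echoes the convention used.
An optional `dielectric_weight` scales the fraction of the field
applied to the Pheo→Q~A~ axis (default 1, the full field, matching the
operational equation).

## ECS/DIRK analysis

The electrochromic shift (ECS) at 520 nm reports Δψ linearly.
`deconvolute_ecs()` combines the 505/520/535 nm channels with weights
(−½, 1, −½); any background linear in wavelength cancels exactly. The
exact instrument coefficients vary between spectrometers, so the
weights are config-exposed and recorded in output metadata.

During a dark interval the ECS decays first order with rate g~H~^+^
(the ATP synthase proton conductivity) and inverts below the dark
baseline by an amount proportional to ΔpH, because the total pmf
re-equilibrates while the pH gradient collapses only slowly.
`fit_dirk()` fits `A·exp(−t/τ) + C` (log-linear initialisation, then
Levenberg–Marquardt; the lowest-RMSE start wins) and reports
`ecs_t = A` (total light-induced pmf, normalised to chlorophyll),
`τ`, and `g_H_plus = 1/τ`. `partition_pmf()` works from three levels —
the illuminated steady state `S`, the dark baseline `D`, and the
dark-interval extremum `M` — giving `ecs_t = S − M`,
`ecs_ss = S − D` (∝ Δψ) and `ecs_inv = D − M` (∝ ΔpH), which satisfy
`ecs_t = ecs_ss + ecs_inv` identically. On noisy traces the
definitional minimum for `M` is order-statistics biased;
`dark_stat = "tail_mean"` instead averages the final tenth of a dark
window long enough to reach the inverted asymptote. Negative
inversions are clamped to zero and flagged, never silently dropped.
Windows are half-open `[start, end)` in seconds.

`calibrate_ecs_to_mv()` converts normalised ECS amplitudes to
millivolts through the single-turnover-flash calibration (≈40 mV per
flash). The dark pmf is ≈112 mV; with dark partitioning of 0.5 the
conventional dark Δψ constant is the printed 60 mV
(`dark_dpsi_mV()`, with the exact 56 mV product retrievable). The same
arithmetic gives the steady-state light-driven Δψ range
(150–200 mV × 0.20–0.60 → 30–120 mV) and the transient bounds during
fluctuations (60 + 30–120 + 60–80 → 150–260 mV).

## PAM fluorescence parameters

The standard saturation-pulse set: `fvfm()`, `phi2()`,
`lef()` (with community-default leaf absorptance 0.84 and PSII
fraction 0.5 — both exposed, neither printed in primary sources),
Stern–Volmer `qe_qi_sv()` with
`qE(SV) = F_M/F_M′ − F_M/F_M^{rec}` and `qI = F_M/F_M^{rec} − 1`
(their sum is total Stern–Volmer NPQ exactly; the ≥10 min dark
relaxation behind `F_M^rec` is a protocol requirement, not part of the
formula), the lake-model `ql()`, and `estimate_f0prime()` for when
F₀′ is not measured — both the measured and estimated F₀′ paths are
supported because protocols differ. Negative quenching values are
flagged rather than clipped so instrument drift stays visible.
`integrate_daily()` and `log2_fold_change()` build the screen-level
summaries, and `qi_association()` runs the two-way Type II ANOVA of
q~I~ against the Δψ- and ΔpH-proportional ECS components (the additive
model makes drop-one F tests Type II; the ANOVA type is a package
choice).

## The synthetic-data generator

No raw traces are deposited with the source study, so the generator
produces the study's conditions from mechanism:

* **Light schedules** (`make_light_schedule()`): a constant
  100 µmol m^−2^ s^−1^ day; a "sinusoidal" day stepping from
  39 µmol m^−2^ s^−1^ by an exact multiplicative ratio every 30 min to
  peak at 500 at midday (14 ascending steps for the 16-h default, so
  the ratio is ≈1.2), mirror-symmetric descent; and a fluctuating day
  in which each baseline slot carries a 2× spike for 15 min, then
  1.5× of baseline for 12 min, then baseline for the remaining 3 min
  (the published timetable is not printed, so the slot layout is a
  declared convention), peaking at 1000.
* **pmf dynamics** (`simulate_pmf_dynamics()`): a capacitor model.
  Influx is a saturating function of irradiance scaled so the
  light-driven pmf spans ≈150–200 mV between 100 and
  500 µmol m^−2^ s^−1^ at the reference conductivity (half-saturation
  45 µmol m^−2^ s^−1^; this lumps photosynthetic control into the
  influx term). Efflux is `g_H_plus` times the light-driven pmf, so
  darkness relaxes to the 112 mV dark pmf and halving g~H~^+^ doubles
  the light-driven pmf. New pmf appears first as Δψ and relaxes toward
  the steady partition fraction with a single counter-ion time
  constant (default 20 s) — this produces the Δψ "spikes" at every
  upward light step. The system is linear with piecewise-constant
  input, so segments are propagated with the exact closed form
  (eigenvalues −g~H~^+^ and −1/τ~ion~); `dt` is only the output grid.
  `pmf = Δψ + ΔpH` holds identically at every sample.
* **ECS traces** (`synthesize_ecs_trace()`): 520 nm carries the
  Δψ-proportional signal over a shared background plus a
  wavelength-linear term (cancelled by deconvolution); dark intervals
  get the first-order decay with ΔpH-proportional inversion. Raw
  amplitudes scale with chlorophyll so normalisation round-trips.
* **Fluorescence traces** (`synthesize_fluorescence_trace()`): a lake
  model with photochemistry set by the dark-adapted F~V~/F~M~
  (default 0.75, the initial wild-type value of the photoinhibition
  experiments), q~E~ a Hill function of lumen pH (pK 5.5, Hill 3,
  saturating at 3.5 Stern–Volmer units), and damage expressed as loss
  of variable fluorescence at fixed F₀ (the damage-to-F₀ link is not
  constrained by data; this is the declared convention). In this model
  the Oxborough–Baker F₀′ expression is exact, which the F₀′
  round-trip tests exploit.
* **Photoinhibition** (`simulate_photoinhibition()`): damage rate =
  `damage_coeff × v_r(q_L, Δψ)`, repair first order (blocked by
  lincomycin). The damage probability per recombination event
  (7.5 × 10^−6^) is set so a wild-type leaf at
  1000 µmol m^−2^ s^−1^ with repair blocked loses F~V~/F~M~ with
  k ≈ 0.3 h^−1^, the scale of the leaf-infiltration experiments.
  Normalized F~V~/F~M~ is identified with the active-PSII fraction, so
  the lincomycin course is a single exponential by construction.
* **Flash pairs** (`simulate_flash_ecs()`): flash 1 ∝ PSI + active
  PSII, flash 2 ∝ PSI; the difference assays PSII activity.

What the generator does **not** emulate: optical artefacts
(chloroplast movement, leaf absorptance gradients), state transitions,
PSI photoinhibition, multi-exponential ECS decays from heterogeneous
lamellae, or instrument drift other than additive Gaussian noise.
Passing round-trip tests therefore demonstrates estimator correctness
under the stated model, not robustness to every failure mode of real
spectroscopy.

## The PSII back-reaction simulator

`recombination_scheme()`/`simulate_s2qa_decay()` integrate a
three-state scheme: A = S~2~Q~A~^−^ (the high-fluorescence state),
B = S~2~[P^+^Pheo^−^] re-formed by the back-reaction, and the
recombined ground state. A and B exchange rapidly with a zero-field
equilibrium constant K₀ ≪ 1 shifted by one decade per 60 mV of the
field fraction `f` spanning the Pheo→Q~A~ axis (default 1). Decay
proceeds directly from A (route R1) and from B (the radical-pair
routes); a triplet branch (default 0.7, reflecting the
triplet-generating route's dominance in functional PSII) yields ^3^P
and then ^1^O~2~. The direct and excitation-repopulating radical-pair
routes carry no published rates and are lumped into the non-triplet
remainder of the B route. R1 is field-independent by default (it is
likely in the Marcus inverted region, where extra driving force slows
rather than speeds transfer).

No individual rate of the scheme is published; the defaults
(K₀ = 10^−4^, k~B→A~ = 10^6^ s^−1^, k~R3~ = 3000 s^−1^, k~R1~ = 0) are
conventions pinned only to the observable zero-field decay
k~R1~ + K₀·k~R3~ = 0.3 s^−1^ and chosen deep enough in the
rapid-equilibrium regime that the simulated initial rate matches
`k_R1 + k_R3·K₀·10^{fΔψ/60}` within 1% up to 120 mV. Integration uses
the stiff solver `deSolve::lsoda` at rtol 10^−10^/atol 10^−12^ (mass
conservation holds to 10^−9^); the horizon is trimmed once the
surviving population falls below ~10^−13^ to avoid solver underflow.
The initial rate is measured from the log-slope of the surviving
population over the first output step, and the half-life by linear
interpolation of the first crossing of half the initial occupancy.
`gramicidin_comparison()` contrasts a decaying field
(Δψ₀·e^{−t/τ}, default τ = 20 s) with the uncoupled case and returns
the initial-rate and half-time ratios; the half-time ratio is monotone
in the field persistence τ, which is not independently constrained.

## The screen driver

`run_screen()` chains everything: per genotype and day it simulates
the pmf and damage dynamics, then *measures* the plant at the end of
every light step exactly as the instruments would — a densely sampled
DIRK episode analysed by `fit_dirk()`/`partition_pmf()`, and
saturation-pulse fluorescence levels analysed by `pam_quantify()` —
and assembles daily q~E~/q~I~ integrals, log₂ fold changes against the
single wild type, Welch t-tests (per-line, with an additional labelled
Benjamini–Hochberg column), a lincomycin photoinhibition assay fitted
with `fit_photoinhibition_course()`, and the q~I~ association ANOVA.
Genotype tables are sorted by ascending g~H~^+^ with lexicographic
tie-breaks, and all outputs carry the seed and a config fingerprint.
Constant days are measured hourly; ramped days at the end of each
light condition.

## Numerical choices and limitations

* Exponential fits: log-linear initialisation, `minpack.lm::nlsLM`,
  lowest-RMSE start wins; windows that do not decay raise an explicit
  fit failure rather than returning a degenerate fit.
* The pmf propagator handles the degenerate case
  g~H~^+^ = 1/τ~ion~ with the resonant closed form.
* The damage ODE uses a per-interval exact update with
  trapezoid-averaged rates, stable for arbitrarily large damage rates.
* Problem sizes in the shipped tests and examples are compact by
  design: two-hour screen days, 2–12 s kinetic traces at 2–5 ms
  sampling, 100-seed noise studies and 1000-seed null calibrations.
  These sizes were chosen to characterise the estimators, not to
  emulate full 16-h instrument sessions, which the same code runs by
  changing the schedule arguments.
* The generator's linear influx–conductivity relation means very low
  g~H~^+^ values extrapolate to unrealistically large pmf; screens
  should stay within ≈30–140% of the reference conductivity, the
  range the mutant library actually spans.
* Quantities that depend on real leaves (absolute ANOVA F values,
  measured F~V~/F~M~ trajectories, dye-based ^1^O~2~ kinetics) are
  outside what synthetic data can reproduce; the package instead
  verifies the property layer — round-trip recovery, conservation
  laws, closed-form agreement, rank ordering and statistical
  calibration.

## A compact worked chain

```{r chain}
p <- plant_params()
sched <- make_light_schedule("fluctuating", 2, 39, 500, step_minutes = 10)
dyn <- simulate_pmf_dynamics(p, sched, dt = 1)
range(dyn$dpsi_mV)

est <- recombination_rate(q_L = 0.4, dpsi_mV = 90)
est$v_r

sim <- gramicidin_comparison(recombination_scheme(), dpsi0_mV = 40)
c(rate_ratio = sim$rate_ratio, analytic = predicted_fold_change(40))
```
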