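#' Synthesize a three-wavelength ECS absorbance trace
#'
#' Emits the raw measurement channels of a dark-interval relaxation
#' kinetics (DIRK) experiment. The 520 nm channel carries the
#' delta-psi-proportional electrochromic signal on top of a shared
#' background; 505 and 535 nm carry the background plus a component
#' linear in wavelength, so the default three-wavelength deconvolution
#' (weights -1/2, 1, -1/2) cancels it exactly. Within each requested dark
#' interval the ECS decays first order at `g_H_plus` and inverts below
#' the dark baseline by an amount proportional to the light-driven
#' delta-pH, as observed in vivo.
#'
#' @param pmf_series Either a `pmf_dynamics` object or a data frame with
#'   columns `time_s`, `dpsi_mV`, `dph_mV` (and optionally
#'   `irradiance_umol`). Values are interpreted as absolute potentials;
#'   the ECS signal reports the difference from the dark levels implied
#'   by `params`.
#' @param params A [plant_params()] object. `ecs_per_mv` sets the
#'   normalised ECS units per mV; the raw trace amplitude additionally
#'   scales with `chl_per_area`, so that [normalize_to_chl()] recovers
#'   chlorophyll-independent units.
#' @param dark_intervals Data frame with columns `start_s`, `end_s`
#'   giving non-overlapping dark windows inside the series.
#' @param noise A [noise_model()] or `NULL` for a noiseless trace.
#' @param background Baseline absorbance common to all channels.
#' @param wl_slope Background slope per nm of wavelength (cancelled by
#'   the deconvolution).
#' @return An `ecs_trace`: data frame with columns `time_s`, `a505`,
#'   `a520`, `a535`, `irradiance_umol`, `phase` (`"light"`/`"dark"`),
#'   with attributes `chl_per_area` and `truth` (per-interval ground
#'   truth `ecs_ss`, `ecs_inv`, `ecs_t` in normalised units and
#'   `g_H_plus`).
#' @export
synthesize_ecs_trace <- function(pmf_series, params, dark_intervals = NULL,
                                 noise = NULL, background = 0.01,
                                 wl_slope = 1e-4) {
  stopifnot(inherits(params, "plant_params"))
  t <- pmf_series$time_s
  n <- length(t)
  dpsi_dark <- params$partition_fraction_dpsi * params$pmf_dark_mV
  dph_dark <- params$pmf_dark_mV - dpsi_dark
  scale <- params$ecs_per_mv * params$chl_per_area  # raw dA per mV

  sig <- (pmf_series$dpsi_mV - dpsi_dark) * scale
  dph_rel <- (pmf_series$dph_mV - dph_dark) * scale
  phase <- rep("light", n)

  truth <- NULL
  if (!is.null(dark_intervals) && nrow(dark_intervals) > 0) {
    di <- dark_intervals[order(dark_intervals$start_s), , drop = FALSE]
    if (any(di$end_s <= di$start_s)) stop("dark interval with end <= start")
    if (nrow(di) > 1 && any(di$start_s[-1] < di$end_s[-nrow(di)])) {
      stop("overlapping dark intervals")
    }
    if (min(di$start_s) < min(t) || max(di$end_s) > max(t)) {
      stop("dark intervals must lie within the time series")
    }
    truth <- data.frame(start_s = di$start_s, end_s = di$end_s,
                        ecs_ss = NA_real_, ecs_inv = NA_real_,
                        ecs_t = NA_real_, g_H_plus = params$g_H_plus)
    for (k in seq_len(nrow(di))) {
      idx <- which(t >= di$start_s[k] & t < di$end_s[k])
      if (!length(idx)) next
      i0 <- idx[1]
      S <- if (i0 > 1) sig[i0 - 1] else sig[i0]
      inv <- if (i0 > 1) dph_rel[i0 - 1] else dph_rel[i0]
      inv <- max(inv, 0)
      tt <- t[idx] - di$start_s[k]
      sig[idx] <- -inv + (S + inv) * exp(-params$g_H_plus * tt)
      phase[idx] <- "dark"
      truth$ecs_ss[k] <- S / params$chl_per_area
      truth$ecs_inv[k] <- inv / params$chl_per_area
      truth$ecs_t[k] <- (S + inv) / params$chl_per_area
    }
  }

  a505 <- background + wl_slope * (505 - 520)
  a535 <- background + wl_slope * (535 - 520)
  out <- data.frame(
    time_s = t,
    a505 = add_noise(rep(a505, n), noise, 0L),
    a520 = add_noise(background + sig, noise, 1L),
    a535 = add_noise(rep(a535, n), noise, 2L),
    irradiance_umol = if ("irradiance_umol" %in% names(pmf_series)) {
      ifelse(phase == "dark", 0, pmf_series$irradiance_umol)
    } else 0,
    phase = phase,
    stringsAsFactors = FALSE
  )
  structure(out, chl_per_area = params$chl_per_area, truth = truth,
            class = c("ecs_trace", "data.frame"))
}

# Lake-model fluorescence levels. Rate constants are expressed relative
# to kf + kd = 1; photochemistry kp is set by the dark-adapted Fv/Fm, and
# NPQ enters as an additional quencher kn (Stern-Volmer by construction).
# Damaged centers keep F0 but lose variable fluorescence (FM loss at
# fixed F0 convention).
fluor_levels <- function(params, dph_mV, damaged_frac, open_frac,
                         fm_scale = 4000) {
  fvfm <- params$fvfm_dark
  qe <- generator_qe(params, dph_mV)
  nn <- length(qe)
  fm <- rep(fm_scale, nn)
  f0 <- fm * (1 - fvfm)
  fv <- fm - f0
  fm_rec <- f0 + fv * (1 - damaged_frac)   # after full qE relaxation
  qi <- fm / fm_rec - 1
  fmp <- fm / (1 + qe + qi)                # SV-additive total NPQ
  # exact lake-model F0' (Oxborough-Baker form is exact here)
  f0p <- f0 / (fvfm + f0 / fmp)
  fs <- f0p + (1 - open_frac) * (fmp - f0p)
  list(F0 = f0, FM = fm, FS = fs, FMp = fmp, F0p = f0p, FM_rec = fm_rec,
       qe = qe, qi = qi,
       ql = open_frac * f0p / fs,
       phi2 = (fmp - fs) / fmp)
}

# Hill response of qE to the delta-pH component, through lumen pH.
generator_qe <- function(params, dph_mV, stroma_pH = 7.8, mv_per_pH = 59.16) {
  lumen_pH <- stroma_pH - dph_mV / mv_per_pH
  params$qe_max / (1 + 10^(params$qe_hill * (lumen_pH - params$qe_pK)))
}

#' Synthesize a saturation-pulse chlorophyll fluorescence trace
#'
#' Builds a pulse-annotated fluorescence time series from a pmf series:
#' qE follows a Hill function of the current delta-pH, photoinhibitory
#' quenching (qI) follows the supplied damaged-PSII fraction (variable
#' fluorescence lost at fixed F0), and the steady-state level reflects
#' the open-center fraction. A dark-adapted pulse reproduces the
#' configured Fv/Fm.
#'
#' @param pmf_series As in [synthesize_ecs_trace()]; additionally the
#'   column `q_L` (open-center fraction) is used when present.
#' @param params A [plant_params()] object.
#' @param pulse_times Sorted vector of saturation-pulse times (s). Pulses
#'   at times where the irradiance is zero are dark pulses (F0/FM or
#'   FM_rec if damage is present).
#' @param noise A [noise_model()] or `NULL`.
#' @param damaged_frac Damaged-PSII fraction, a single value or a vector
#'   along the series (default 0).
#' @param pulse_duration_s Width of each saturation pulse (s).
#' @param sample_dt Sampling interval of the emitted trace (s).
#' @return A `fluor_trace`: data frame with columns `time_s`, `fluor`,
#'   `event` (`none`, `pulse_start`, `pulse_end`, `dark_start`), with a
#'   `truth` attribute holding the per-pulse generator ground truth
#'   (F levels, qe, qi, ql, phi2).
#' @export
synthesize_fluorescence_trace <- function(pmf_series, params, pulse_times,
                                          noise = NULL, damaged_frac = 0,
                                          pulse_duration_s = 0.8,
                                          sample_dt = 0.2) {
  stopifnot(inherits(params, "plant_params"))
  if (is.unsorted(pulse_times, strictly = TRUE)) {
    stop("pulse_times must be sorted, strictly increasing")
  }
  if (min(pulse_times) < min(pmf_series$time_s)) {
    stop("pulses before trace start")
  }
  if (sample_dt >= pulse_duration_s) {
    stop("sample_dt must resolve the saturation pulse (< pulse_duration_s)")
  }
  t <- seq(min(pmf_series$time_s), max(pmf_series$time_s), by = sample_dt)
  lookup <- function(col, tq) {
    stats::approx(pmf_series$time_s, pmf_series[[col]], xout = tq,
                  method = "constant", rule = 2)$y
  }
  dph_dark <- (1 - params$partition_fraction_dpsi) * params$pmf_dark_mV
  dph_abs <- lookup("dph_mV", t)
  dph_rel <- pmax(dph_abs - dph_dark, 0)
  irr <- if ("irradiance_umol" %in% names(pmf_series)) {
    lookup("irradiance_umol", t)
  } else rep(0, length(t))
  open_frac <- if ("q_L" %in% names(pmf_series)) {
    lookup("q_L", t)
  } else generator_ql(params, irr)
  dmg <- if (length(damaged_frac) == 1L) rep(damaged_frac, length(t)) else {
    stats::approx(pmf_series$time_s, damaged_frac, xout = t,
                  method = "constant", rule = 2)$y
  }

  lv <- fluor_levels(params, dph_abs, dmg, open_frac)
  # dark baseline sits at F0 (damage leaves F0 by convention); light
  # baseline is the steady-state level FS
  fluor <- ifelse(irr > 0, lv$FS, lv$F0)

  event <- rep("none", length(t))
  truth <- NULL
  for (pt in pulse_times) {
    idx <- which(t >= pt & t < pt + pulse_duration_s)
    if (!length(idx)) next
    i0 <- idx[1]
    fmp_here <- lv$FMp[i0]
    dark_here <- irr[i0] == 0 && dph_rel[i0] <= 1e-9
    if (dark_here) fmp_here <- lv$FM_rec[i0]
    fluor[idx] <- fmp_here
    event[i0] <- "pulse_start"
    event[idx[length(idx)]] <- "pulse_end"
    truth <- rbind(truth, data.frame(
      time_s = pt, dark = dark_here,
      F0 = lv$F0[i0], FM = lv$FM[i0], FS = lv$FS[i0],
      FMp = fmp_here, F0p = lv$F0p[i0], FM_rec = lv$FM_rec[i0],
      qe = lv$qe[i0], qi = lv$qi[i0], ql = lv$ql[i0], phi2 = lv$phi2[i0],
      irradiance_umol = irr[i0]))
  }
  dark_on <- which(diff(c(1, sign(irr))) < 0)
  event[dark_on[event[dark_on] == "none"]] <- "dark_start"

  out <- data.frame(time_s = t,
                    fluor = add_noise(fluor, noise, 3L),
                    event = event, stringsAsFactors = FALSE)
  structure(out, truth = truth,
            class = c("fluor_trace", "data.frame"))
}

#' Simulate the flash-pair ECS assay of PSII activity
#'
#' Two saturating single-turnover flashes in the presence of DCMU: the
#' first flash drives charge separation in PSI plus all still-active
#' PSII centers; the second (QA already reduced, DCMU blocking reopening)
#' drives PSI only. The amplitude difference reports active PSII.
#'
#' @param psii_fraction_active Fraction of PSII capable of charge
#'   separation, in \[0, 1\].
#' @param psi_amplitude ECS amplitude contributed by PSI (dA units).
#' @param psii_amplitude ECS amplitude of a fully active PSII complement.
#' @param noise A [noise_model()] or `NULL`.
#' @return A `flash_pair` list with elements `amp1` and `amp2`.
#' @export
simulate_flash_ecs <- function(psii_fraction_active, psi_amplitude = 1,
                               psii_amplitude = 1, noise = NULL) {
  if (psii_fraction_active < 0 || psii_fraction_active > 1) {
    stop("psii_fraction_active must lie in [0, 1]")
  }
  amps <- c(psi_amplitude + psii_fraction_active * psii_amplitude,
            psi_amplitude)
  amps <- add_noise(amps, noise, 4L)
  structure(list(amp1 = amps[1], amp2 = amps[2]), class = "flash_pair")
}

# Stable stepwise solution of dA/dt = -kd(t) A + kr (1 - A) on a grid:
# per-interval exact update with the trapezoid-averaged rate.
integrate_damage <- function(time_s, kd, kr, active0) {
  n <- length(kd)
  lam <- kd + kr
  A <- numeric(n)
  A[1] <- active0
  for (i in seq_len(n - 1L)) {
    dt_i <- time_s[i + 1L] - time_s[i]
    lm_i <- (lam[i] + lam[i + 1L]) / 2
    if (lm_i <= 0) {
      A[i + 1L] <- A[i]
    } else {
      a_inf <- kr / lm_i
      A[i + 1L] <- a_inf + (A[i] - a_inf) * exp(-lm_i * dt_i)
    }
  }
  pmin(pmax(A, 0), 1)
}

#' Simulate a PSII photoinhibition time course
#'
#' The damage rate per unit time is `damage_coeff` times the modelled
#' S2QA- recombination rate evaluated at the current open-center fraction
#' (qL) and light-dark delta-psi; repair is first order at `repair_rate`
#' unless blocked by lincomycin. The normalized Fv/Fm trajectory is taken
#' as the active-PSII fraction, so with lincomycin and constant light it
#' is a single exponential.
#'
#' @param params A [plant_params()] object.
#' @param schedule A light schedule (or data frame of steps).
#' @param lincomycin If `TRUE`, repair is blocked.
#' @param t_end Simulation end (s); defaults as in
#'   [simulate_pmf_dynamics()].
#' @param dt Integration/sampling step for the (slow) damage dynamics, s.
#' @param seed Unused (deterministic); kept for interface symmetry.
#' @param start_at_steady_state If `TRUE`, the pmf starts at the
#'   steady state of the first light step instead of the dark state,
#'   removing the initial delta-psi spike from the damage integral.
#' @param model A [recombination_model()] used for the instantaneous
#'   recombination rate.
#' @return A `photoinhibition_course` data frame with columns `time_s`,
#'   `irradiance_umol`, `dpsi_rel_mV`, `q_L`, `v_r`, `active_frac` and
#'   `fvfm_norm`.
#' @export
simulate_photoinhibition <- function(params, schedule, lincomycin = FALSE,
                                     t_end = NULL, dt = 1, seed = NULL,
                                     start_at_steady_state = FALSE,
                                     model = recombination_model(k_r = params$k_r)) {
  dyn <- simulate_pmf_dynamics(params, schedule, dt = dt, t_end = t_end)
  dpsi_dark <- params$partition_fraction_dpsi * params$pmf_dark_mV
  dpsi_rel <- pmax(dyn$dpsi_mV - dpsi_dark, 0)
  if (start_at_steady_state) {
    # overwrite the equilibration transient with the first-segment
    # steady state (dpsi settles within a few tau_ion)
    first_seg <- dyn$irradiance_umol == dyn$irradiance_umol[1]
    seg_end <- which(!first_seg)[1]
    if (is.na(seg_end)) seg_end <- length(dpsi_rel) + 1L
    if (seg_end > 2) dpsi_rel[seq_len(seg_end - 1L)] <-
        dpsi_rel[seg_end - 1L]
  }
  vr <- vapply(seq_len(nrow(dyn)), function(i) {
    recombination_rate(dyn$q_L[i], dpsi_rel[i], model)$v_r
  }, numeric(1))

  kd <- params$damage_coeff * vr
  kr <- if (lincomycin) 0 else params$repair_rate
  A <- integrate_damage(dyn$time_s, kd, kr,
                        params$psii_fraction_active)

  out <- data.frame(time_s = dyn$time_s,
                    irradiance_umol = dyn$irradiance_umol,
                    dpsi_rel_mV = dpsi_rel,
                    q_L = dyn$q_L,
                    v_r = vr,
                    active_frac = A,
                    fvfm_norm = A / params$psii_fraction_active)
  structure(out, params = params, lincomycin = lincomycin,
            class = c("photoinhibition_course", "data.frame"))
}
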