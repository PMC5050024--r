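#' Simulate thylakoid pmf, delta-psi and delta-pH dynamics under a light
#' schedule
#'
#' Capacitor model of the thylakoid membrane. Proton influx is
#' proportional to the instantaneous (saturating) linear electron flow;
#' efflux through the ATP synthase is first order in the light-driven pmf
#' with rate `g_H_plus`. Because the membrane capacitance is low, newly
#' stored pmf appears first as the electric field (delta-psi) and then
#' relaxes toward the steady-state partition fraction by a first-order
#' counter-ion flux with time constant `tau_ion`. Every upward light step
#' therefore produces a transient delta-psi "spike" above its subsequent
#' steady-state level, and in prolonged darkness the total pmf returns to
#' the dark (ATP-equilibrated) level.
#'
#' The state equations are linear with piecewise-constant input, so each
#' schedule segment is propagated exactly (eigenvalues `-g_H_plus` and
#' `-1/tau_ion`); `dt` only sets the output sampling grid.
#'
#' @param params A [plant_params()] object.
#' @param schedule A [make_light_schedule()] schedule, or a data frame
#'   with columns `start_s` and `irradiance_umol`.
#' @param dt Output sampling interval in seconds (> 0).
#' @param t_end End of the simulation in seconds (default: the end of the
#'   photoperiod for `light_schedule` input, else the last step + 600 s).
#' @param seed Optional integer; kept for interface symmetry with the
#'   noisy generators (the pmf model itself is deterministic).
#' @return A `pmf_dynamics` data frame with columns `time_s`,
#'   `irradiance_umol`, `dpsi_mV`, `dph_mV`, `pmf_mV` and `q_L`, with the
#'   parameter set attached as attribute `params`. `pmf_mV` equals
#'   `dpsi_mV + dph_mV` at every time point.
#' @examples
#' p <- plant_params()
#' s <- make_light_schedule("constant", 1, 300)
#' dyn <- simulate_pmf_dynamics(p, s, dt = 0.5)
#' tail(dyn$pmf_mV, 1)
#' @export
simulate_pmf_dynamics <- function(params, schedule, dt = 0.1,
                                  t_end = NULL, seed = NULL) {
  stopifnot(inherits(params, "plant_params"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (is.null(t_end)) {
    t_end <- if (inherits(schedule, "light_schedule")) {
      attr(schedule, "photoperiod_h") * 3600
    } else {
      max(schedule$start_s) + 600
    }
  }

  g <- params$g_H_plus
  tau <- params$tau_ion
  f <- params$partition_fraction_dpsi
  pd <- params$pmf_dark_mV

  # segment boundaries: schedule steps clipped to [0, t_end]
  bounds <- sort(unique(c(0, schedule$start_s, t_end)))
  bounds <- bounds[bounds >= 0 & bounds <= t_end]
  if (bounds[length(bounds)] < t_end) bounds <- c(bounds, t_end)

  times <- seq(0, t_end, by = dt)
  n <- length(times)
  p_out <- numeric(n)      # light-driven pmf above the dark level
  dpsi_out <- numeric(n)

  # initial state: dark-equilibrated
  p0 <- 0
  dpsi0 <- f * pd
  irr_of <- function(t) {
    if (inherits(schedule, "light_schedule")) {
      schedule_irradiance(schedule, t)
    } else {
      idx <- findInterval(t, schedule$start_s)
      ifelse(idx >= 1, schedule$irradiance_umol[pmax(idx, 1)], 0)
    }
  }

  irr_out <- numeric(n)
  for (k in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1L]
    irr <- irr_of(t0)
    v <- pmf_influx(params, irr)       # mV/s into the light-driven pmf
    sel <- which(times >= t0 - dt * 1e-9 & times < t1 - dt * 1e-9)
    tt <- times[sel] - t0
    st <- propagate_pmf_segment(p0, dpsi0, v, g, tau, f, pd, tt)
    p_out[sel] <- st$p
    dpsi_out[sel] <- st$dpsi
    irr_out[sel] <- irr
    # advance state to the segment end
    endst <- propagate_pmf_segment(p0, dpsi0, v, g, tau, f, pd, t1 - t0)
    p0 <- endst$p
    dpsi0 <- endst$dpsi
  }
  # final sample (t == t_end) carries the end state of the last segment
  if (times[n] >= bounds[length(bounds)] - dt * 1e-9) {
    p_out[n] <- p0
    dpsi_out[n] <- dpsi0
    irr_out[n] <- irr_of(times[n])
  }

  pmf <- pd + p_out
  dpsi <- pmax(dpsi_out, 0)
  dph <- pmax(pmf - dpsi, 0)
  out <- data.frame(
    time_s = times,
    irradiance_umol = irr_out,
    dpsi_mV = dpsi,
    dph_mV = dph,
    pmf_mV = dpsi + dph,
    q_L = generator_ql(params, irr_out)
  )
  structure(out, params = params,
            class = c("pmf_dynamics", "data.frame"))
}

# Proton influx in mV of pmf per second: proportional to saturating LEF,
# scaled so the reference genotype reaches `pmf_per_lef` mV of
# light-driven pmf at saturating light.
pmf_influx <- function(params, irradiance) {
  sat <- irradiance / (irradiance + params$lef_i_half)
  params$g_ref * params$pmf_per_lef * sat
}

# Open-PSII fraction used by the generator as the qL ground truth:
# saturating function of irradiance (1 in darkness).
generator_ql <- function(params, irradiance) {
  1 / (1 + irradiance / params$ql_i_half)
}

# Exact propagation of the linear system over one constant-input segment:
#   p'    = v - g p
#   dpsi' = p' - (1/tau) (dpsi - f (pd + p))
# Lower-triangular structure gives eigenvalues -g and -1/tau.
propagate_pmf_segment <- function(p0, dpsi0, v, g, tau, f, pd, t) {
  a <- 1 / tau
  p_inf <- v / g
  e_g <- exp(-g * t)
  p <- p_inf + (p0 - p_inf) * e_g

  # dpsi' + a dpsi = v - g p(t) + a f (pd + p(t))
  # steady state: dpsi_inf = f (pd + p_inf)
  dpsi_inf <- f * (pd + p_inf)
  c1 <- (p0 - p_inf) * (a * f - g)      # coefficient of e^{-g t} forcing
  if (abs(g - a) > 1e-12 * max(g, a)) {
    part <- c1 / (a - g) * e_g
    e_a <- exp(-a * t)
    const <- dpsi0 - dpsi_inf - c1 / (a - g)
    dpsi <- dpsi_inf + part + const * e_a
  } else {
    # degenerate equal-eigenvalue limit: resonant t e^{-a t} term
    e_a <- exp(-a * t)
    dpsi <- dpsi_inf + (dpsi0 - dpsi_inf) * e_a + c1 * t * e_a
  }
  list(p = p, dpsi = dpsi)
}

#' @export
print.pmf_dynamics <- function(x, ...) {
  cat(sprintf("pmf dynamics: %d samples over %.1f s\n", nrow(x),
              max(x$time_s)))
  cat(sprintf("  final pmf %.1f mV (dpsi %.1f, dpH %.1f)\n",
              x$pmf_mV[nrow(x)], x$dpsi_mV[nrow(x)], x$dph_mV[nrow(x)]))
  invisible(x)
}

#' @export
plot.pmf_dynamics <- function(x, ...) {
  graphics::matplot(x$time_s, cbind(x$pmf_mV, x$dpsi_mV, x$dph_mV),
                    type = "l", lty = 1,
                    col = c("black", "darkorange", "steelblue"),
                    xlab = "time (s)", ylab = "potential (mV)", ...)
  graphics::legend("topright", c("pmf", "dpsi", "dpH"), lty = 1,
                   col = c("black", "darkorange", "steelblue"), bty = "n")
  invisible(x)
}
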