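#' PSII back-reaction scheme
#'
#' Three-state kinetic scheme for recombination from S2QA-:
#' state A (S2QA-, the high-fluorescence state), state B (the
#' back-populated radical pair S2\[P+Pheo-\]) and G (ground/recombined).
#' A and B exchange rapidly with zero-field equilibrium constant
#' `K0_AB` (<< 1); the trans-thylakoid field shifts the equilibrium by
#' one decade per 60 mV of the field fraction `dielectric_fraction`
#' spanning the Pheo -> QA axis. Decay to G proceeds directly from A
#' (route R1, field-independent by default) at `k_R1`, and from B at
#' `k_R3`; a fraction `triplet_branch` of the B-route events passes
#' through the chlorophyll triplet 3P (the direct and
#' excited-state-repopulating radical-pair routes are lumped into the
#' non-triplet remainder), of which `o2_quench_yield` yields singlet
#' oxygen.
#'
#' @param K0_AB Zero-field equilibrium constant \[B\]/\[A\] (<< 1).
#' @param k_R1 Direct QA- -> P+ recombination rate (s^-1).
#' @param k_R3 Recombination rate from B (s^-1).
#' @param k_relax B -> A relaxation rate setting the equilibration speed
#'   (s^-1); must greatly exceed `k_R3` for the rapid-equilibrium limit.
#' @param triplet_branch Fraction of B-route decays through 3P.
#' @param o2_quench_yield Fraction of 3P yielding singlet oxygen.
#' @param dielectric_fraction Portion of delta-psi acting on the A <-> B
#'   equilibrium (1 = full field).
#' @param decade_mV mV per 10-fold equilibrium shift.
#' @return A `recombination_scheme` object. The defaults put the entire
#'   zero-field decay through the triplet-forming route with
#'   `k_R3 * K0_AB = 0.3 s^-1`, the observed zero-field S2QA- decay
#'   rate.
#' @export
recombination_scheme <- function(K0_AB = 1e-4, k_R1 = 0, k_R3 = 3000,
                                 k_relax = 1e6, triplet_branch = 0.7,
                                 o2_quench_yield = 1,
                                 dielectric_fraction = 1,
                                 decade_mV = 60) {
  if (any(c(K0_AB, k_R1, k_R3, k_relax) < 0)) stop("rates must be >= 0")
  for (f in c(triplet_branch, o2_quench_yield, dielectric_fraction)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  if (K0_AB >= 1) stop("K0_AB must be << 1")
  structure(list(K0_AB = K0_AB, k_R1 = k_R1, k_R3 = k_R3,
                 k_relax = k_relax, triplet_branch = triplet_branch,
                 o2_quench_yield = o2_quench_yield,
                 dielectric_fraction = dielectric_fraction,
                 decade_mV = decade_mV),
            class = "recombination_scheme")
}

#' @export
print.recombination_scheme <- function(x, ...) {
  cat("PSII back-reaction scheme (A = S2QA-, B = S2[P+Pheo-])\n")
  cat(sprintf("  K0(A<->B) = %.3g, k_R1 = %.3g s^-1, k_R3 = %.3g s^-1\n",
              x$K0_AB, x$k_R1, x$k_R3))
  cat(sprintf("  zero-field rate k_R1 + K0*k_R3 = %.4g s^-1\n",
              x$k_R1 + x$K0_AB * x$k_R3))
  cat(sprintf("  triplet branch %.2f, 1O2 yield per 3P %.2f, field fraction %.2f\n",
              x$triplet_branch, x$o2_quench_yield, x$dielectric_fraction))
  invisible(x)
}

# field-shifted equilibrium constant
scheme_K <- function(scheme, dpsi_mV) {
  scheme$K0_AB * 10^(scheme$dielectric_fraction * dpsi_mV /
                       scheme$decade_mV)
}

#' Simulate the decay of the S2QA- state under a delta-psi profile
#'
#' Deterministic integration (stiff-safe `deSolve::lsoda`) of the
#' three-state scheme starting from the pre-equilibrated A/B mixture.
#' The initial rate is measured from the log-slope of the surviving
#' (A + B) population over the first output step; the half-life is the
#' interpolated time at which A falls to half its initial occupancy.
#'
#' @param scheme A [recombination_scheme()].
#' @param dpsi_profile Either a single delta-psi in mV, or a function of
#'   time (s) returning mV.
#' @param t_span Simulation length (s).
#' @param dt Output sampling step (s). For the explicit fixed-step
#'   methods (`method != "lsoda"`) the step must resolve the fastest
#'   rate (`dt * k_max < 0.1`), otherwise an error is raised.
#' @param method Integration method passed to [deSolve::ode()].
#' @return A `psii_decay` object: list with `trace` (data frame
#'   `time_s`, `occ_A`, `occ_B`, `occ_G`, `cum_R3`, `cum_1O2`),
#'   `initial_rate` (s^-1), `half_life` (s), `singlet_o2_yield` (per
#'   initial center) and the scheme.
#' @export
simulate_s2qa_decay <- function(scheme, dpsi_profile = 0, t_span = 10,
                                dt = 0.005, method = "lsoda") {
  stopifnot(inherits(scheme, "recombination_scheme"))
  if (dt <= 0 || t_span <= dt) stop("need 0 < dt < t_span")
  dpsi_fun <- if (is.function(dpsi_profile)) dpsi_profile else {
    force(dpsi_profile); function(t) dpsi_profile
  }
  k_max <- max(scheme$k_relax,
               scheme_K(scheme, dpsi_fun(0)) * scheme$k_relax,
               scheme$k_R3, scheme$k_R1)
  if (method != "lsoda" && dt * k_max >= 0.1) {
    stop("unstable step size: dt * k_max >= 0.1 for explicit method")
  }

  K0 <- scheme_K(scheme, dpsi_fun(0))
  # trim the horizon once the population has decayed to ~1e-13 of the
  # initial pool; integrating further only underflows the solver
  k_slow <- scheme$k_R1 + K0 * scheme$k_R3
  if (k_slow > 0) t_span <- min(t_span, max(30 / k_slow, 20 * dt))
  y0 <- c(A = 1 / (1 + K0), B = K0 / (1 + K0), G = 0, cumR3 = 0)
  rhs <- function(t, y, parms) {
    K <- scheme_K(scheme, dpsi_fun(t))
    kab <- K * scheme$k_relax      # A -> B
    kba <- scheme$k_relax          # B -> A
    dA <- -(kab + scheme$k_R1) * y[1] + kba * y[2]
    dB <- kab * y[1] - (kba + scheme$k_R3) * y[2]
    dG <- scheme$k_R1 * y[1] + scheme$k_R3 * y[2]
    list(c(dA, dB, dG, scheme$k_R3 * y[2]))
  }
  times <- seq(0, t_span, by = dt)
  sol <- deSolve::ode(y0, times, rhs, parms = NULL, method = method,
                      rtol = 1e-10, atol = 1e-12)
  tr <- as.data.frame(sol)
  names(tr)[1] <- "time_s"
  tr$cum_1O2 <- tr$cumR3 * scheme$triplet_branch * scheme$o2_quench_yield
  tr <- tr[, c("time_s", "A", "B", "G", "cumR3", "cum_1O2")]
  names(tr)[2:5] <- c("occ_A", "occ_B", "occ_G", "cum_R3")

  surv <- tr$occ_A + tr$occ_B
  initial_rate <- (log(surv[1]) - log(surv[2])) / dt
  half_life <- time_to_fraction(tr$time_s, tr$occ_A, 0.5)

  decayed <- tr$occ_G[nrow(tr)]
  yield <- if (decayed > 0) {
    (tr$cum_R3[nrow(tr)] / decayed) * scheme$triplet_branch *
      scheme$o2_quench_yield
  } else 0

  structure(list(trace = tr, initial_rate = initial_rate,
                 half_life = half_life, singlet_o2_yield = yield,
                 scheme = scheme),
            class = "psii_decay")
}

# linear interpolation of the first crossing of occ = frac * occ[1]
time_to_fraction <- function(time_s, occ, frac) {
  target <- occ[1] * frac
  below <- which(occ <= target)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(time_s[1])
  stats::approx(occ[(i - 1):i], time_s[(i - 1):i], xout = target)$y
}

#' @export
print.psii_decay <- function(x, ...) {
  cat("S2QA- decay simulation\n")
  cat(sprintf("  initial rate %.4g s^-1, half-life %.4g s\n",
              x$initial_rate, x$half_life))
  cat(sprintf("  1O2 yield per initial center: %.4g\n",
              x$singlet_o2_yield))
  invisible(x)
}

#' @export
plot.psii_decay <- function(x, ...) {
  tr <- x$trace
  graphics::matplot(tr$time_s, cbind(tr$occ_A, tr$occ_G, tr$cum_1O2),
                    type = "l", lty = 1,
                    col = c("black", "grey60", "red"),
                    xlab = "time (s)", ylab = "occupancy / yield", ...)
  graphics::legend("right", c("S2QA-", "recombined", "cum. 1O2"),
                   lty = 1, col = c("black", "grey60", "red"), bty = "n")
  invisible(x)
}

#' In-silico gramicidin comparison of S2QA- decay
#'
#' Simulates the decay with a decaying field
#' `dpsi(t) = dpsi0 * exp(-t / field_decay_tau)` (coupled thylakoids)
#' against the uncoupled, field-free case (gramicidin), returning the
#' initial-rate ratio and the ratio of times to lose half of the
#' initial S2QA- population (uncoupled / coupled, so both ratios are
#' >= 1 when the field accelerates decay).
#'
#' @param scheme A [recombination_scheme()].
#' @param dpsi0_mV Initial delta-psi of the coupled sample (mV).
#' @param field_decay_tau Field relaxation time constant (s).
#' @param t_span,dt Passed to [simulate_s2qa_decay()].
#' @return List with `rate_ratio`, `lifetime_ratio` and the two
#'   `psii_decay` results (`coupled`, `uncoupled`).
#' @export
gramicidin_comparison <- function(scheme, dpsi0_mV = 40,
                                  field_decay_tau = 20,
                                  t_span = NULL, dt = 0.005) {
  if (dpsi0_mV < 0) stop("dpsi0_mV must be >= 0")
  k0 <- scheme$k_R1 + scheme$K0_AB * scheme$k_R3
  if (is.null(t_span)) t_span <- max(10, 5 / max(k0, 1e-6))
  coupled <- simulate_s2qa_decay(
    scheme, function(t) dpsi0_mV * exp(-t / field_decay_tau),
    t_span = t_span, dt = dt)
  uncoupled <- simulate_s2qa_decay(scheme, 0, t_span = t_span, dt = dt)
  list(rate_ratio = coupled$initial_rate / uncoupled$initial_rate,
       lifetime_ratio = uncoupled$half_life / coupled$half_life,
       coupled = coupled, uncoupled = uncoupled)
}

#' Relative singlet-oxygen yield of a completed decay
#'
#' `(fraction of decays routed through B) * triplet_branch *
#' o2_quench_yield`.
#'
#' @param result A `psii_decay`.
#' @param scheme The scheme used (defaults to the one in `result`).
#' @return Yield per initial center, in \[0, 1\].
#' @export
singlet_oxygen_yield <- function(result, scheme = result$scheme) {
  tr <- result$trace
  decayed <- tr$occ_G[nrow(tr)]
  if (decayed <= 0) return(0)
  (tr$cum_R3[nrow(tr)] / decayed) * scheme$triplet_branch *
    scheme$o2_quench_yield
}
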