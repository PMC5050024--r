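# Shared fixtures: small synthetic traces with known ground truth.

# Constant-light pmf state with a single dark interval, in mV.
make_dirk_trace <- function(params = plant_params(),
                            dpsi_rel = 80, dph_rel = 60,
                            t_light = 4, t_dark = 4, dt = 0.002,
                            noise = NULL) {
  dpsi_dark <- params$partition_fraction_dpsi * params$pmf_dark_mV
  dph_dark <- params$pmf_dark_mV - dpsi_dark
  tt <- seq(0, t_light + t_dark, by = dt)
  mini <- data.frame(time_s = tt,
                     dpsi_mV = dpsi_dark + dpsi_rel,
                     dph_mV = dph_dark + dph_rel,
                     irradiance_umol = 300)
  synthesize_ecs_trace(mini, params,
                       data.frame(start_s = t_light,
                                  end_s = t_light + t_dark),
                       noise = noise)
}

# Prepend a relaxed pre-illumination dark baseline to an ecs trace.
with_dark_baseline <- function(trace, t_base = 2, dt = 0.002,
                               background = 0.01) {
  base <- data.frame(time_s = seq(-t_base, -dt, by = dt),
                     a505 = trace$a505[1], a520 = background,
                     a535 = trace$a535[1],
                     irradiance_umol = 0, phase = "dark")
  rbind(base, as.data.frame(trace))
}

# Plain exponential decay series for the generic decay fitters.
make_exp_series <- function(A = 1, tau = 0.05, C = 0.2, t_end = 0.5,
                            n = 500) {
  t <- seq(0, t_end, length.out = n)
  list(time_s = t, ecs = A * exp(-t / tau) + C)
}

# Brute-force (A, tau, C) grid search minimising SSE; independent oracle
# for the nonlinear decay fit.
grid_search_decay <- function(time_s, y, refine = 3) {
  t0 <- time_s - time_s[1]
  A_rng <- c(0.2, 3) * (max(y) - min(y))
  tau_rng <- c(0.05, 5) * (max(t0) / 3)
  C_rng <- range(y) + c(-1, 1) * 0.5 * diff(range(y))
  best <- NULL
  for (lvl in seq_len(refine)) {
    As <- seq(A_rng[1], A_rng[2], length.out = 21)
    taus <- exp(seq(log(tau_rng[1]), log(tau_rng[2]), length.out = 21))
    Cs <- seq(C_rng[1], C_rng[2], length.out = 21)
    sse_best <- Inf
    for (A in As) for (tau in taus) for (C in Cs) {
      sse <- sum((y - (A * exp(-t0 / tau) + C))^2)
      if (sse < sse_best) {
        sse_best <- sse
        best <- c(A = A, tau = tau, C = C, sse = sse)
      }
    }
    dA <- diff(A_rng) / 20; dtau <- best[["tau"]]
    A_rng <- best[["A"]] + c(-1, 1) * dA
    tau_rng <- best[["tau"]] * c(0.8, 1.25)
    C_rng <- best[["C"]] + c(-1, 1) * diff(C_rng) / 20
  }
  best
}
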