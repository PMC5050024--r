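#' Three-wavelength deconvolution of the electrochromic shift
#'
#' Combines the 505/520/535 nm absorbance channels with weights that
#' cancel any background varying linearly with wavelength; the default
#' `(-1/2, 1, -1/2)` leaves the 520 nm electrochromic component in
#' delta-A units.
#'
#' @param a505,a520,a535 Equal-length numeric absorbance vectors, or an
#'   `ecs_trace` passed as the first argument.
#' @param weights Length-3 deconvolution weights for (505, 520, 535).
#' @return Numeric vector of the deconvoluted ECS signal.
#' @examples
#' deconvolute_ecs(1:3, (1:3) + 0.5, 1:3)  # 0.5 0.5 0.5
#' @export
deconvolute_ecs <- function(a505, a520 = NULL, a535 = NULL,
                            weights = c(-0.5, 1, -0.5)) {
  if (inherits(a505, "ecs_trace") || (is.data.frame(a505) &&
                                      all(c("a505", "a520", "a535") %in% names(a505)))) {
    tr <- a505
    a520 <- tr$a520; a535 <- tr$a535; a505 <- tr$a505
  }
  if (length(a505) != length(a520) || length(a520) != length(a535)) {
    stop("channel length mismatch")
  }
  if (length(weights) != 3) stop("weights must have length 3")
  weights[1] * a505 + weights[2] * a520 + weights[3] * a535
}

# Core first-order exponential decay fit: y = A exp(-(t - t0)/tau) + C.
# Log-linear initialisation followed by nonlinear least squares
# (minpack.lm); lowest-RMSE solution wins.
fit_exp_decay <- function(time_s, y, min_points = 10) {
  if (length(y) < min_points) {
    stop("fit window too short (< ", min_points, " samples)")
  }
  t0 <- time_s[1]
  tt <- time_s - t0
  C0 <- min(y) - 0.05 * abs(diff(range(y)))
  amp0 <- y[1] - C0
  span <- diff(range(y))
  if (!is.finite(span) || span <= 0 || amp0 <= 0) {
    stop("fit failure: window does not decay")
  }
  # decay sanity: later half must sit below the earlier half
  n <- length(y)
  if (mean(y[seq_len(n %/% 2)]) <= mean(y[(n %/% 2 + 1):n]) + 1e-15) {
    stop("fit failure: window does not decay")
  }
  z <- pmax(y - C0, span * 1e-6)
  lf <- stats::lm(log(z) ~ tt)
  tau0 <- -1 / min(stats::coef(lf)[2], -1e-12)
  fits <- list()
  for (start in list(c(A = amp0, tau = tau0, C = C0),
                     c(A = amp0, tau = max(tt) / 3, C = min(y)))) {
    f <- try(minpack.lm::nlsLM(
      y ~ A * exp(-tt / tau) + C,
      start = as.list(start),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      silent = TRUE)
    if (!inherits(f, "try-error")) fits[[length(fits) + 1]] <- f
  }
  if (!length(fits)) stop("fit failure: exponential fit did not converge")
  rmses <- vapply(fits, function(f) sqrt(mean(stats::resid(f)^2)),
                  numeric(1))
  best <- fits[[which.min(rmses)]]
  cf <- stats::coef(best)
  if (cf[["A"]] <= 0 || !is.finite(cf[["tau"]]) || cf[["tau"]] <= 0) {
    stop("fit failure: zero-amplitude or non-decaying window")
  }
  list(A = cf[["A"]], tau = cf[["tau"]], C = cf[["C"]],
       rmse = sqrt(mean(stats::resid(best)^2)),
       fitted = stats::fitted(best), residuals = stats::resid(best),
       time_s = time_s)
}

#' Fit dark-interval relaxation kinetics (DIRK) of the ECS
#'
#' Fits a first-order exponential decay `A * exp(-t/tau) + C` to the
#' deconvoluted ECS signal inside a dark window. The decay amplitude
#' `A`, normalised to chlorophyll, estimates the total light-induced pmf
#' (ECS_t); the inverse time constant is the proton conductivity gH+.
#'
#' @param trace Either an `ecs_trace` (deconvoluted internally) or a
#'   data frame / list with `time_s` and a numeric `ecs` column, or a
#'   numeric vector of the deconvoluted signal with `time_s` supplied.
#' @param dark_window Numeric `c(start_s, end_s)` half-open window
#'   `[start, end)` selecting the decay; must contain >= 10 samples.
#' @param time_s Sample times when `trace` is a bare numeric vector.
#' @param chl_per_area Chlorophyll per area (ug cm^-2) used to normalise
#'   `ecs_t`; taken from the trace attribute when present.
#' @param weights Deconvolution weights (see [deconvolute_ecs()]).
#' @return A `dirk_fit` object with fields `ecs_t` (normalised), `tau`,
#'   `g_H_plus = 1/tau`, `baseline`, `fit_rmse`, plus methods `print`,
#'   `summary`, `coef`, `predict`, `residuals` and `plot`.
#' @export
fit_dirk <- function(trace, dark_window = NULL, time_s = NULL,
                     chl_per_area = NULL, weights = c(-0.5, 1, -0.5)) {
  prep <- prepare_decay_input(trace, dark_window, time_s, chl_per_area,
                              weights)
  fit <- fit_exp_decay(prep$time_s, prep$y)
  chl <- if (is.null(prep$chl)) 1 else prep$chl
  out <- list(ecs_t = normalize_to_chl(fit$A, chl),
              tau = fit$tau,
              g_H_plus = 1 / fit$tau,
              baseline = fit$C,
              fit_rmse = fit$rmse,
              chl_per_area = chl,
              weights = weights,
              window = prep$window,
              data = data.frame(time_s = fit$time_s, ecs = prep$y,
                                fitted = fit$fitted,
                                residuals = fit$residuals))
  class(out) <- "dirk_fit"
  out
}

prepare_decay_input <- function(trace, window, time_s, chl, weights) {
  if (inherits(trace, "ecs_trace") ||
      (is.data.frame(trace) && all(c("a505", "a520", "a535") %in% names(trace)))) {
    y <- deconvolute_ecs(trace, weights = weights)
    t <- trace$time_s
    if (is.null(chl)) chl <- attr(trace, "chl_per_area")
  } else if (is.data.frame(trace) || is.list(trace)) {
    y <- trace$ecs
    t <- trace$time_s
  } else {
    y <- trace
    t <- time_s
    if (is.null(t)) stop("time_s must be supplied with a bare signal vector")
  }
  if (!is.null(window)) {
    keep <- t >= window[1] & t < window[2]  # half-open [start, end)
    y <- y[keep]; t <- t[keep]
  }
  if (length(y) < 10) stop("dark window must contain at least 10 samples")
  list(time_s = t, y = y, chl = chl, window = window)
}

#' @export
print.dirk_fit <- function(x, ...) {
  cat("DIRK first-order decay fit\n")
  cat(sprintf("  ECS_t  = %.6g (normalised dA ug chl^-1 cm^2)\n", x$ecs_t))
  cat(sprintf("  tau    = %.4g s   gH+ = %.4g s^-1\n", x$tau, x$g_H_plus))
  cat(sprintf("  offset = %.4g, rmse = %.3g, n = %d\n", x$baseline,
              x$fit_rmse, nrow(x$data)))
  invisible(x)
}

#' @export
summary.dirk_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  residual range: [%.3g, %.3g]\n",
              min(object$data$residuals), max(object$data$residuals)))
  invisible(object)
}

#' @export
coef.dirk_fit <- function(object, ...) {
  c(ecs_t = object$ecs_t, tau = object$tau, g_H_plus = object$g_H_plus,
    baseline = object$baseline)
}

#' @export
predict.dirk_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_s else newdata$time_s
  A_raw <- object$ecs_t * object$chl_per_area
  A_raw * exp(-(t - object$data$time_s[1]) / object$tau) + object$baseline
}

#' @export
residuals.dirk_fit <- function(object, ...) object$data$residuals

#' @export
plot.dirk_fit <- function(x, ...) {
  graphics::plot(x$data$time_s, x$data$ecs, pch = 16, cex = 0.5,
                 xlab = "time (s)", ylab = "deconvoluted ECS (dA)", ...)
  graphics::lines(x$data$time_s, x$data$fitted, col = "red", lwd = 2)
  invisible(x)
}

#' Partition the light-induced pmf into delta-psi and delta-pH components
#'
#' Uses the three characteristic levels of a DIRK experiment: `S`, the
#' mean steady-state (light) signal; `D`, the dark baseline; `M`, the
#' dark-interval minimum (the inverted ECS level). Then
#' `ecs_t = S - M` (total light-induced pmf), `ecs_ss = S - D`
#' (delta-psi-proportional) and `ecs_inv = D - M`
#' (delta-pH-proportional), each normalised to chlorophyll.
#'
#' @param trace An `ecs_trace` or data frame with `time_s` plus either
#'   raw channels or an `ecs` column.
#' @param light_window `c(start, end)` seconds over which the signal is
#'   at its illuminated steady state (mean taken).
#' @param dark_window Window containing the dark-interval decay
#'   (minimum taken).
#' @param dark_baseline_window Window defining the relaxed dark baseline
#'   (mean taken), typically pre-illumination darkness.
#' @param chl_per_area,weights See [fit_dirk()].
#' @param dark_stat Estimator of the dark-interval extremum `M`:
#'   `"min"` (the definitional minimum; exact on noiseless decays) or
#'   `"tail_mean"` (mean of the final 10 percent of the window, an
#'   unbiased choice for noisy traces whose dark interval is long
#'   enough to reach the inverted asymptote).
#' @return A `pmf_partition` object: list with `ecs_t`, `ecs_ss`,
#'   `ecs_inv`, `fraction_dpsi = ecs_ss / ecs_t` and a `flags` character
#'   vector (e.g. `"no_inversion"` when the dark minimum never drops
#'   below the baseline, in which case `ecs_inv` is clamped to 0 with a
#'   warning).
#' @export
partition_pmf <- function(trace, light_window, dark_window,
                          dark_baseline_window, chl_per_area = NULL,
                          weights = c(-0.5, 1, -0.5),
                          dark_stat = c("min", "tail_mean")) {
  dark_stat <- match.arg(dark_stat)
  prep <- prepare_decay_input(trace, NULL, NULL, chl_per_area, weights)
  t <- prep$time_s; y <- prep$y
  chl <- if (is.null(prep$chl)) 1 else prep$chl
  win <- function(w) {
    sel <- t >= w[1] & t < w[2]
    if (!any(sel)) stop("empty window [", w[1], ", ", w[2], ")")
    y[sel]
  }
  if (!(light_window[1] <= dark_window[1])) {
    stop("windows must be ordered light -> dark")
  }
  S <- mean(win(light_window))
  dk <- win(dark_window)
  M <- if (dark_stat == "min") min(dk) else {
    mean(dk[seq.int(ceiling(0.9 * length(dk)), length(dk))])
  }
  D <- mean(win(dark_baseline_window))

  flags <- character(0)
  ecs_inv <- D - M
  if (ecs_inv < 0) {
    warning("no ECS inversion in dark window; ecs_inv clamped to 0")
    flags <- c(flags, "no_inversion")
    ecs_inv <- 0
    M <- D
  }
  out <- list(ecs_t = normalize_to_chl(S - M, chl),
              ecs_ss = normalize_to_chl(S - D, chl),
              ecs_inv = normalize_to_chl(ecs_inv, chl),
              fraction_dpsi = if (S - M > 0) (S - D) / (S - M) else NA_real_,
              levels = c(S = S, D = D, M = M),
              chl_per_area = chl,
              flags = flags)
  class(out) <- "pmf_partition"
  out
}

#' @export
print.pmf_partition <- function(x, ...) {
  cat("pmf partition (normalised ECS units)\n")
  cat(sprintf("  ECS_t = %.6g, ECS_ss = %.6g (dpsi), ECS_inv = %.6g (dpH)\n",
              x$ecs_t, x$ecs_ss, x$ecs_inv))
  cat(sprintf("  fraction as dpsi: %.3f%s\n", x$fraction_dpsi,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Normalise an ECS amplitude to chlorophyll content
#'
#' @param value Deconvoluted delta-A amplitude.
#' @param chl_per_area Chlorophyll per leaf area (ug cm^-2, > 0).
#' @return `value / chl_per_area`, in deconvoluted dA ug chl^-1 cm^2.
#' @export
normalize_to_chl <- function(value, chl_per_area) {
  if (!is.numeric(chl_per_area) || any(chl_per_area <= 0)) {
    stop("chl_per_area must be > 0")
  }
  value / chl_per_area
}

#' PSII activity from a saturating flash pair
#'
#' The ECS amplitude of the second of two closely spaced single-turnover
#' flashes (PSI only, DCMU present) is subtracted from the first
#' (PSI + active PSII).
#'
#' @param pair A `flash_pair` (see [simulate_flash_ecs()]) or a list
#'   with `amp1`, `amp2`.
#' @return List with `psii_activity = amp1 - amp2` and `flags`
#'   (`"negative_activity"` when amp2 > amp1; the value is reported, not
#'   clipped).
#' @export
psii_activity_from_flash_pair <- function(pair) {
  if (is.null(pair$amp1) || is.null(pair$amp2) ||
      !is.finite(pair$amp1) || !is.finite(pair$amp2)) {
    stop("flash pair must contain finite amp1 and amp2")
  }
  act <- pair$amp1 - pair$amp2
  flags <- if (act < 0) "negative_activity" else character(0)
  list(psii_activity = act, flags = flags)
}

#' Fit the P700+ dark-interval reduction kinetics
#'
#' First-order fit of the 810 nm absorbance relaxation; reports the
#' half-time `ln(2) * tau` of P700+ re-reduction, a proxy for
#' lumen-pH-sensitive cytochrome b6f turnover.
#'
#' @param series_810nm Data frame with `time_s` and `a810` (or `ecs`)
#'   columns, or numeric vector with `time_s` given.
#' @param dark_window Optional `c(start, end)` window (half-open).
#' @param time_s Times when `series_810nm` is a bare vector.
#' @return A `p700_fit` list: `half_time` (s), `rate` (s^-1,
#'   `= log(2) / half_time`), `tau`, `fit_rmse`.
#' @export
fit_p700_halftime <- function(series_810nm, dark_window = NULL,
                              time_s = NULL) {
  if (is.data.frame(series_810nm) && "a810" %in% names(series_810nm)) {
    series_810nm <- list(time_s = series_810nm$time_s,
                         ecs = series_810nm$a810)
  }
  prep <- prepare_decay_input(series_810nm, dark_window, time_s, NULL,
                              c(-0.5, 1, -0.5))
  fit <- fit_exp_decay(prep$time_s, prep$y)
  out <- list(half_time = log(2) * fit$tau,
              rate = 1 / fit$tau,
              tau = fit$tau,
              fit_rmse = fit$rmse)
  class(out) <- "p700_fit"
  out
}

#' @export
print.p700_fit <- function(x, ...) {
  cat(sprintf("P700+ reduction: half-time %.4g s (rate %.4g s^-1, rmse %.3g)\n",
              x$half_time, x$rate, x$fit_rmse))
  invisible(x)
}
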