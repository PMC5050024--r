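#' Configuration of an in-silico genotype screen
#'
#' @param genotypes Named list of [plant_params()] objects, one per
#'   genotype.
#' @param wild_type Name of the wild-type entry (exactly one).
#' @param schedules List of [make_light_schedule()] schedules, one per
#'   day (default: the three-day design — constant 100, sinusoidal
#'   39 -> 500, fluctuating with 1000 peak).
#' @param seed Integer seed driving measurement noise.
#' @param noise_sd Additive measurement noise on replicate-level summary
#'   values (relative sd).
#' @param n_reps Replicate plants per genotype for the reporting
#'   statistics.
#' @param model A [recombination_model()].
#' @param calibration A [pmf_calibration()].
#' @param dt Sampling step (s) of the underlying pmf dynamics.
#' @return A `screen_config` list.
#' @export
screen_config <- function(genotypes, wild_type,
                          schedules = list(
                            day1 = make_light_schedule("constant", 16, 100),
                            day2 = make_light_schedule("sinusoidal", 16, 39, 500),
                            day3 = make_light_schedule("fluctuating", 16, 39, 500)),
                          seed = 1L, noise_sd = 0, n_reps = 3L,
                          model = recombination_model(),
                          calibration = pmf_calibration(),
                          dt = 1) {
  if (is.null(names(genotypes)) || any(names(genotypes) == "")) {
    stop("genotypes must be a named list")
  }
  if (!wild_type %in% names(genotypes)) {
    stop("missing wild type: '", wild_type, "' not among genotypes")
  }
  if (sum(names(genotypes) == wild_type) != 1L) {
    stop("exactly one wild type required")
  }
  stopifnot(all(vapply(genotypes, inherits, logical(1), "plant_params")))
  structure(list(genotypes = genotypes, wild_type = wild_type,
                 schedules = schedules, seed = as.integer(seed),
                 noise_sd = noise_sd, n_reps = as.integer(n_reps),
                 model = model, calibration = calibration, dt = dt),
            class = "screen_config")
}

#' Run the end-to-end in-silico phenotyping screen
#'
#' For every genotype and day, simulates the pmf/damage dynamics under
#' the day's schedule, then measures the plant at the end of every light
#' step the way the instruments would: a synthesized DIRK episode is
#' analysed with [fit_dirk()] and [partition_pmf()] for gH+, ECS_t,
#' ECS_ss and ECS_inv, and the synthetic fluorescence levels are
#' analysed with [pam_quantify()] for Fv/Fm, Phi(II), LEF, qE(SV), qI
#' and qL. Daily qE/qI integrals, log2 fold changes versus the wild
#' type, Welch t-test and Benjamini-Hochberg columns, per-genotype
#' parameter recovery and the qI-vs-pmf-component ANOVA are assembled
#' from these per-timepoint measurements. Deterministic given the seed.
#'
#' @param config A [screen_config()].
#' @return A `screen_result` list with elements `timepoints`
#'   (per-genotype, per-timepoint table), `genotypes` (summary with
#'   recovered gH+ and partition fraction, fitted photoinhibition rate
#'   constant, daily integrals), `fold_changes`, `tests` (Welch +
#'   BH-adjusted p-values vs wild type), `association`
#'   (a [qi_association()] report) and `provenance`.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  gt_names <- names(config$genotypes)
  tp_list <- list()
  geno_rows <- list()

  for (g in gt_names) {
    pars <- config$genotypes[[g]]
    damage0 <- 0
    day_tp <- list()
    for (d in seq_along(config$schedules)) {
      sched <- config$schedules[[d]]
      res <- measure_day(pars, sched, config, damage0, genotype = g,
                         day = d)
      damage0 <- res$damage_end
      day_tp[[d]] <- res$timepoints
    }
    tp <- do.call(rbind, day_tp)
    tp_list[[g]] <- tp

    # lincomycin photoinhibition assay at constant high light gives the
    # genotype's damage rate constant
    pi_sched <- make_light_schedule("constant", 4, 1000)
    pi_course <- simulate_photoinhibition(pars, pi_sched, lincomycin = TRUE,
                                          dt = 5,
                                          start_at_steady_state = TRUE,
                                          model = config$model)
    sub <- pi_course[seq(1, nrow(pi_course), by = 120), ]
    pifit <- fit_photoinhibition_course(sub$time_s / 3600, sub$fvfm_norm)

    daily <- do.call(rbind, lapply(split(tp, tp$day), function(dd) {
      data.frame(day = dd$day[1],
                 qe_integral = integrate_daily(dd$time_s / 3600, dd$qe_sv),
                 qi_integral = integrate_daily(dd$time_s / 3600, dd$qi))
    }))
    geno_rows[[g]] <- data.frame(
      genotype = g,
      g_H_plus_true = pars$g_H_plus,
      g_H_plus_est = mean(tp$g_H_plus, na.rm = TRUE),
      fraction_dpsi_true = pars$partition_fraction_dpsi,
      fraction_dpsi_est = stats::median(tp$fraction_dpsi, na.rm = TRUE),
      photoinhibition_k_h = pifit$rate_constant,
      qe_day_integrals = I(list(daily)),
      stringsAsFactors = FALSE)
  }

  timepoints <- do.call(rbind, tp_list)
  rownames(timepoints) <- NULL
  genotypes <- do.call(rbind, lapply(geno_rows, function(r) {
    d <- r$qe_day_integrals[[1]]
    wide <- stats::setNames(
      as.list(c(d$qe_integral, d$qi_integral)),
      c(paste0("qe_int_day", d$day), paste0("qi_int_day", d$day)))
    cbind(r[, setdiff(names(r), "qe_day_integrals")],
          as.data.frame(wide))
  }))
  rownames(genotypes) <- NULL
  genotypes <- sort_by_ghplus(genotypes)

  # replicate-level noisy observations for reporting statistics
  reps <- make_replicates(genotypes, config)
  fold_changes <- fold_change_table(genotypes, config$wild_type)
  tests <- welch_tests(reps, config$wild_type)

  assoc_tab <- association_table(timepoints, reps, config)
  association <- qi_association(assoc_tab)

  structure(list(timepoints = timepoints, genotypes = genotypes,
                 replicates = reps,
                 fold_changes = fold_changes, tests = tests,
                 association = association,
                 provenance = list(seed = config$seed,
                                   config_hash = config_fingerprint(config),
                                   n_genotypes = length(gt_names))),
            class = "screen_result")
}

# Simulate one day for one genotype and measure at the end of each step.
measure_day <- function(pars, sched, config, damage0, genotype, day) {
  dyn <- simulate_pmf_dynamics(pars, sched, dt = config$dt)
  dpsi_dark <- pars$partition_fraction_dpsi * pars$pmf_dark_mV
  dpsi_rel <- pmax(dyn$dpsi_mV - dpsi_dark, 0)
  vr <- predict(config$model,
                data.frame(q_L = dyn$q_L, dpsi_mV = dpsi_rel))
  active <- integrate_damage(dyn$time_s, pars$damage_coeff * vr,
                             pars$repair_rate, 1 - damage0)
  damaged <- 1 - active

  span <- attr(sched, "photoperiod_h") * 3600
  t_meas <- unique(c(sched$start_s[-1], span)) - config$dt
  if (length(t_meas) < 4) {
    # constant days are measured hourly
    t_meas <- sort(unique(c(t_meas, seq(span / 16, span, by = span / 16) -
                              config$dt)))
  }
  t_meas <- t_meas[t_meas > 0]
  rows <- lapply(t_meas, function(tm) {
    i <- which.min(abs(dyn$time_s - tm))
    measure_timepoint(pars, dyn[i, ], dpsi_rel[i], damaged[i], config,
                      genotype, day, tm)
  })
  list(timepoints = do.call(rbind, rows),
       damage_end = overnight_repair(damaged[length(damaged)], pars))
}

# 8 h of dark repair between photoperiods
overnight_repair <- function(damaged, pars, hours = 8) {
  damaged * exp(-pars$repair_rate * hours * 3600)
}

# One instrument visit: DIRK episode + saturation-pulse fluorescence.
measure_timepoint <- function(pars, state, dpsi_rel, damaged, config,
                              genotype, day, tm) {
  # --- ECS/DIRK: 2 s light baseline, 2 s dark interval, analysed raw
  dtt <- 0.002
  n_l <- round(2 / dtt); n_d <- round(2 / dtt)
  tt <- seq(0, by = dtt, length.out = n_l + n_d)
  mini <- data.frame(time_s = tt,
                     dpsi_mV = rep(state$dpsi_mV, n_l + n_d),
                     dph_mV = rep(state$dph_mV, n_l + n_d),
                     irradiance_umol = rep(state$irradiance_umol, n_l + n_d))
  dark_iv <- data.frame(start_s = 2, end_s = max(tt))
  tr <- synthesize_ecs_trace(mini, pars, dark_iv)
  # a pre-illumination dark baseline is prepended at the relaxed level
  base <- data.frame(time_s = seq(-1, -dtt, by = dtt),
                     a505 = tr$a505[1], a520 = 0.01, a535 = tr$a535[1],
                     irradiance_umol = 0, phase = "dark")
  tr2 <- rbind(base, as.data.frame(tr))
  part <- partition_pmf(tr2, light_window = c(0, 2),
                        dark_window = c(2, max(tt)),
                        dark_baseline_window = c(-1, 0),
                        chl_per_area = pars$chl_per_area)
  dirk <- fit_dirk(as.data.frame(tr), dark_window = c(2, max(tt)),
                   chl_per_area = pars$chl_per_area)

  # --- PAM: generator fluorescence levels analysed by the PAM formulas
  lv <- fluor_levels(pars, state$dph_mV, damaged, state$q_L)
  pam <- pam_quantify(F0 = lv$F0, FM = lv$FM, FS = lv$FS, FMp = lv$FMp,
                      FM_rec = lv$FM_rec, par = state$irradiance_umol)

  vr <- recombination_rate(pam$ql, dpsi_rel, config$model)$v_r
  data.frame(genotype = genotype, day = day, time_s = tm,
             irradiance_umol = state$irradiance_umol,
             g_H_plus = dirk$g_H_plus,
             ecs_t = part$ecs_t, ecs_ss = part$ecs_ss,
             ecs_inv = part$ecs_inv,
             fraction_dpsi = part$fraction_dpsi,
             dpsi_rel_mV = calibrate_ecs_to_mv(part$ecs_ss,
                                               config$calibration),
             fvfm = pam$fvfm, phi2 = pam$phi2, lef = pam$lef,
             qe_sv = pam$qe_sv, qi = pam$qi, ql = pam$ql, npq = pam$npq,
             v_r = vr,
             stringsAsFactors = FALSE)
}

make_replicates <- function(genotypes, config) {
  metrics <- c("qe_int_day1", "qi_int_day1", "photoinhibition_k_h")
  metrics <- intersect(c(grep("^q[ei]_int_day", names(genotypes),
                              value = TRUE), "photoinhibition_k_h"),
                       names(genotypes))
  out <- list()
  for (i in seq_len(nrow(genotypes))) {
    g <- genotypes$genotype[i]
    for (r in seq_len(config$n_reps)) {
      vals <- as.list(genotypes[i, metrics, drop = FALSE])
      if (config$noise_sd > 0) {
        jit <- with_seed(config$seed + 1000L * i + r, function()
          stats::rnorm(length(metrics), 1, config$noise_sd))
        vals <- Map(`*`, vals, as.list(jit))
      }
      out[[length(out) + 1]] <- cbind(
        data.frame(genotype = g, rep = r, stringsAsFactors = FALSE),
        as.data.frame(vals))
    }
  }
  do.call(rbind, out)
}

fold_change_table <- function(genotypes, wild_type) {
  metrics <- grep("^(q[ei]_int_day|photoinhibition_k_h)",
                  names(genotypes), value = TRUE)
  wt <- genotypes[genotypes$genotype == wild_type, metrics, drop = FALSE]
  out <- genotypes[, c("genotype", metrics)]
  for (m in metrics) {
    out[[m]] <- log2_fold_change(pmax(genotypes[[m]], 1e-12),
                                 pmax(wt[[m]][1], 1e-12))
  }
  names(out)[-1] <- paste0("lfc_", metrics)
  out
}

welch_tests <- function(reps, wild_type) {
  metrics <- setdiff(names(reps), c("genotype", "rep"))
  rows <- list()
  for (g in setdiff(unique(reps$genotype), wild_type)) {
    for (m in metrics) {
      x <- reps[[m]][reps$genotype == g]
      y <- reps[[m]][reps$genotype == wild_type]
      p <- if (stats::sd(c(x, y)) == 0) 1 else {
        tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
      }
      rows[[length(rows) + 1]] <- data.frame(
        genotype = g, metric = m, p_welch = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_welch, method = "BH")
  out
}

association_table <- function(timepoints, reps, config) {
  # per-genotype measurements at the highest common irradiance
  hi <- max(timepoints$irradiance_umol)
  sel <- timepoints[timepoints$irradiance_umol >= 0.6 * hi, ]
  agg <- stats::aggregate(sel[, c("qi", "ecs_ss", "ecs_inv")],
                          by = list(genotype = sel$genotype), FUN = mean)
  # replicate jitter for degrees of freedom
  out <- do.call(rbind, lapply(seq_len(config$n_reps), function(r) {
    jit <- with_seed(config$seed + 77L * r, function()
      matrix(stats::rnorm(3 * nrow(agg), 1,
                          max(config$noise_sd, 0.02)), ncol = 3))
    data.frame(genotype = agg$genotype,
               q_I = agg$qi * jit[, 1],
               ecs_ss = agg$ecs_ss * jit[, 2],
               ecs_inv = agg$ecs_inv * jit[, 3])
  }))
  out
}

#' Sort a genotype table by ascending proton conductivity
#'
#' Stable ascending sort on the gH+ column with lexicographic
#' tie-breaking on the genotype name.
#'
#' @param results Data frame with columns `genotype` and one of
#'   `g_H_plus`, `g_H_plus_est` or `g_H_plus_true`.
#' @return The sorted data frame.
#' @export
sort_by_ghplus <- function(results) {
  col <- intersect(c("g_H_plus", "g_H_plus_est", "g_H_plus_true"),
                   names(results))[1]
  if (is.na(col)) stop("no gH+ column found")
  if (any(is.na(results[[col]]))) stop("missing gH+ values")
  results[order(results[[col]], results$genotype), , drop = FALSE]
}

#' Fit a single-exponential photoinhibition time course
#'
#' Fits `y(t) = y_inf + (1 - y_inf) * exp(-k t)` to a normalized Fv/Fm
#' series (normalisation to the initial value is applied when
#' `normalize = TRUE`).
#'
#' @param time Time points (same unit as the reported rate constant,
#'   e.g. hours); at least 4 required.
#' @param fvfm_series Fv/Fm values.
#' @param normalize Divide by the first value before fitting.
#' @return A `photoinhibition_fit`: list with `rate_constant` (per time
#'   unit), `plateau` (`y_inf`), `fit_rmse`, `fitted`, `residuals`,
#'   with `print`, `coef`, `predict` and `residuals` methods.
#' @export
fit_photoinhibition_course <- function(time, fvfm_series,
                                       normalize = TRUE) {
  if (length(time) < 4) stop("need at least 4 time points")
  y <- if (normalize) fvfm_series / fvfm_series[1] else fvfm_series
  if (y[length(y)] >= y[1] - 1e-12) {
    stop("fit failure: series does not decay")
  }
  t0 <- time - time[1]
  yinf0 <- max(min(y) * 0.9, 0)
  amp <- 1 - yinf0
  z <- pmax((y - yinf0) / amp, 1e-8)
  k0 <- max(-stats::coef(stats::lm(log(z) ~ t0))[[2]], 1e-6)
  fit <- minpack.lm::nlsLM(
    y ~ yinf + (1 - yinf) * exp(-k * t0),
    start = list(yinf = yinf0, k = k0),
    lower = c(yinf = 0, k = 0), upper = c(yinf = 1, k = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  out <- list(rate_constant = cf[["k"]], plateau = cf[["yinf"]],
              fit_rmse = sqrt(mean(stats::resid(fit)^2)),
              fitted = stats::fitted(fit),
              residuals = stats::resid(fit),
              time = time, y = y)
  class(out) <- "photoinhibition_fit"
  out
}

#' @export
print.photoinhibition_fit <- function(x, ...) {
  cat(sprintf("photoinhibition fit: k = %.4g per time unit, plateau %.3f, rmse %.3g\n",
              x$rate_constant, x$plateau, x$fit_rmse))
  invisible(x)
}

#' @export
coef.photoinhibition_fit <- function(object, ...) {
  c(k = object$rate_constant, plateau = object$plateau)
}

#' @export
predict.photoinhibition_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time else newdata$time
  object$plateau + (1 - object$plateau) *
    exp(-object$rate_constant * (t - object$time[1]))
}

#' @export
residuals.photoinhibition_fit <- function(object, ...) object$residuals

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Screen result: %d genotypes, %d timepoints (seed %d, config %s)\n",
              nrow(x$genotypes), nrow(x$timepoints),
              x$provenance$seed, x$provenance$config_hash))
  print(x$genotypes[, c("genotype", "g_H_plus_est",
                        "fraction_dpsi_est", "photoinhibition_k_h")])
  invisible(x)
}

#' @export
summary.screen_result <- function(object, ...) {
  print(object)
  cat("\nAssociation of q_I with pmf components:\n")
  print(object$association)
  invisible(object)
}
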