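#' ECS-to-millivolt calibration constants
#'
#' The single-turnover-flash calibration: one saturating flash deposits
#' about 40 mV of delta-psi across the thylakoid, the dark
#' (ATP-equilibrated) pmf is about 112 mV, and about half of it is
#' stored as delta-psi in darkness.
#'
#' @param mv_per_flash Delta-psi per saturating single-turnover flash
#'   (mV).
#' @param pmf_dark_mV Dark pmf (mV).
#' @param dark_fraction_dpsi Fraction of the dark pmf stored as
#'   delta-psi.
#' @param flash_ecs_amplitude Normalised ECS amplitude of one flash
#'   (same units as the signals to be calibrated).
#' @return A `pmf_calibration` list. `dark_dpsi_mV()` returns the
#'   conventional printed 60 mV constant; the exact product
#'   `pmf_dark_mV * dark_fraction_dpsi` (56 mV for the defaults) remains
#'   retrievable from the fields.
#' @export
pmf_calibration <- function(mv_per_flash = 40, pmf_dark_mV = 112,
                            dark_fraction_dpsi = 0.5,
                            flash_ecs_amplitude = 1) {
  vals <- c(mv_per_flash, pmf_dark_mV, dark_fraction_dpsi,
            flash_ecs_amplitude)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all calibration constants must be positive")
  }
  structure(list(mv_per_flash = mv_per_flash,
                 pmf_dark_mV = pmf_dark_mV,
                 dark_fraction_dpsi = dark_fraction_dpsi,
                 flash_ecs_amplitude = flash_ecs_amplitude),
            class = "pmf_calibration")
}

#' @rdname pmf_calibration
#' @param cal A `pmf_calibration`.
#' @param rounded If `TRUE` (default) return the conventional rounded
#'   60 mV dark delta-psi; otherwise the exact product.
#' @export
dark_dpsi_mV <- function(cal = pmf_calibration(), rounded = TRUE) {
  exact <- cal$pmf_dark_mV * cal$dark_fraction_dpsi
  if (rounded) round(exact, -1) else exact
}

#' Convert an ECS amplitude to millivolts of delta-psi
#'
#' Linear calibration through the single-turnover-flash amplitude:
#' `mV = ecs_value * mv_per_flash / flash_ecs_amplitude`.
#'
#' @param ecs_value Normalised ECS amplitude(s).
#' @param cal A [pmf_calibration()].
#' @return Delta-psi in mV.
#' @examples
#' calibrate_ecs_to_mv(1)    # 40
#' calibrate_ecs_to_mv(3)    # 120
#' @export
calibrate_ecs_to_mv <- function(ecs_value, cal = pmf_calibration()) {
  if (is.null(cal$flash_ecs_amplitude) || cal$flash_ecs_amplitude <= 0) {
    stop("calibration requires a positive flash ECS amplitude")
  }
  ecs_value * cal$mv_per_flash / cal$flash_ecs_amplitude
}

#' Delta-psi-dependent S2QA- recombination rate model
#'
#' The recombination rate from the S2QA- state is
#' `v_r = k_r * (1 - qL) * 10^(s * dpsi_mV / decade_mV)`, where `1 - qL`
#' estimates the reduced-QA fraction and the Boltzmann factor captures
#' the destabilisation of the charge-separated state by the
#' trans-thylakoid electric field: each `decade_mV` (default 60 mV,
#' equivalently `decade_eV = 0.06` eV) of field lowers the stabilisation
#' free energy by one decade of rate.
#'
#' The default sign convention is `"physical"` (`s = +1`): the rate
#' increases with delta-psi, as required by the destabilisation argument
#' and the observed field-accelerated decay. `"as_printed"` (`s = -1`)
#' reproduces the sign as it appears typeset in the source relation.
#' An optional dielectric weight scales the fraction of the field acting
#' on the Pheo/QA equilibrium (default 1, the full field).
#'
#' @param k_r Intrinsic zero-field rate with fully reduced QA (s^-1).
#' @param decade_mV mV of delta-psi per 10-fold rate change.
#' @param sign_convention `"physical"` or `"as_printed"`.
#' @param dielectric_weight Fraction of the field applied (0-1).
#' @return A `recombination_model` object with `print` and `predict`
#'   methods.
#' @export
recombination_model <- function(k_r = 0.3, decade_mV = 60,
                                sign_convention = c("physical",
                                                    "as_printed"),
                                dielectric_weight = 1) {
  sign_convention <- match.arg(sign_convention)
  if (k_r < 0 || decade_mV <= 0) stop("k_r >= 0 and decade_mV > 0 required")
  structure(list(k_r = k_r,
                 decade_mV = decade_mV,
                 decade_eV = decade_mV / 1000,
                 sign_convention = sign_convention,
                 dielectric_weight = dielectric_weight),
            class = "recombination_model")
}

#' @export
print.recombination_model <- function(x, ...) {
  cat(sprintf(
    "S2QA- recombination model: v_r = %.3g * (1 - qL) * 10^(%s dpsi / %g mV)\n",
    x$k_r, if (x$sign_convention == "physical") "+" else "-", x$decade_mV))
  if (x$dielectric_weight != 1) {
    cat(sprintf("  dielectric weight on the field: %.3g\n",
                x$dielectric_weight))
  }
  invisible(x)
}

#' Evaluate the recombination rate
#'
#' @param q_L Open-center fraction estimate, in \[0, 1\].
#' @param dpsi_mV Light-minus-dark delta-psi (mV).
#' @param model A [recombination_model()].
#' @return A `recombination_estimate` list: `v_r` (s^-1), the echoed
#'   inputs and the sign convention used.
#' @examples
#' recombination_rate(0, 0)$v_r        # 0.3
#' recombination_rate(0, 60)$v_r       # 3
#' @export
recombination_rate <- function(q_L, dpsi_mV, model = recombination_model()) {
  if (any(q_L < 0 | q_L > 1)) stop("q_L must lie in [0, 1]")
  s <- if (model$sign_convention == "physical") 1 else -1
  v <- model$k_r * (1 - q_L) *
    10^(s * model$dielectric_weight * dpsi_mV / model$decade_mV)
  structure(list(v_r = v, q_L = q_L, dpsi_mV = dpsi_mV,
                 sign_convention = model$sign_convention),
            class = "recombination_estimate")
}

#' @export
print.recombination_estimate <- function(x, ...) {
  cat(sprintf("v_r = %s s^-1 (qL = %s, dpsi = %s mV, %s sign)\n",
              paste(signif(x$v_r, 4), collapse = ", "),
              paste(x$q_L, collapse = ", "),
              paste(x$dpsi_mV, collapse = ", "), x$sign_convention))
  invisible(x)
}

#' @export
predict.recombination_model <- function(object, newdata, ...) {
  recombination_rate(newdata$q_L, newdata$dpsi_mV, object)$v_r
}

#' Predicted fold change of the recombination rate with delta-psi
#'
#' The pure Boltzmann factor `10^(dpsi / decade_mV)` under the physical
#' sign convention; at the ~40 mV imposed by a saturating
#' single-turnover flash this is 10^(2/3) = 4.64, i.e. an approximately
#' 5-fold acceleration.
#'
#' @param dpsi_mV Delta-psi (mV).
#' @param model A [recombination_model()].
#' @return Fold change (dimensionless).
#' @export
predicted_fold_change <- function(dpsi_mV, model = recombination_model()) {
  10^(model$dielectric_weight * dpsi_mV / model$decade_mV)
}

#' Steady-state light-driven delta-psi range from printed pmf bounds
#'
#' Combines the steady-state light-driven pmf range with the range of
#' pmf fractions stored as delta-psi: the defaults (150-200 mV, 0.20 to
#' 0.60) give 30-120 mV.
#'
#' @param pmf_low,pmf_high Light-driven pmf bounds (mV).
#' @param frac_low,frac_high Delta-psi fraction bounds in \[0, 1\].
#' @return `c(low_mV, high_mV)`.
#' @export
steady_state_dpsi_range <- function(pmf_low = 150, pmf_high = 200,
                                    frac_low = 0.20, frac_high = 0.60) {
  if (pmf_low > pmf_high || frac_low > frac_high) {
    stop("inverted bounds")
  }
  if (frac_low < 0 || frac_high > 1) stop("fractions must lie in [0, 1]")
  c(low_mV = pmf_low * frac_low, high_mV = pmf_high * frac_high)
}

#' Bounds on the transient delta-psi reached during light fluctuations
#'
#' Adds the dark delta-psi, the steady-state light-driven delta-psi
#' range and the fluctuation-induced spike amplitude range: the defaults
#' (60 mV dark; 30-120 mV steady; 60-80 mV spikes) give 150-260 mV.
#'
#' @param dark_dpsi Dark delta-psi (mV).
#' @param steady_range Length-2 steady-state delta-psi range (mV).
#' @param spike_range Length-2 spike amplitude range (mV).
#' @return `c(low_mV, high_mV)`.
#' @export
transient_dpsi_bounds <- function(dark_dpsi = 60,
                                  steady_range = c(30, 120),
                                  spike_range = c(60, 80)) {
  if (any(c(dark_dpsi, steady_range, spike_range) < 0)) {
    stop("inputs must be non-negative")
  }
  c(low_mV = dark_dpsi + steady_range[1] + spike_range[1],
    high_mV = dark_dpsi + steady_range[2] + spike_range[2])
}

#' Two-way ANOVA of qI against the pmf components
#'
#' Fits the additive linear model `q_I ~ ecs_ss + ecs_inv` over a
#' per-plant table and reports the Type II F statistic and p-value of
#' each pmf component (delta-psi-proportional `ecs_ss`,
#' delta-pH-proportional `ecs_inv`).
#'
#' @param table Data frame with columns `q_I` (or `qi`), `ecs_ss`,
#'   `ecs_inv`; at least 3 complete rows.
#' @return A `qi_association` object: data frame with one row per
#'   predictor (`term`, `F`, `p`, `df`), the fitted `lm` in attribute
#'   `fit`.
#' @export
qi_association <- function(table) {
  nm <- names(table)
  if ("qi" %in% nm && !"q_I" %in% nm) table$q_I <- table$qi
  need <- c("q_I", "ecs_ss", "ecs_inv")
  if (!all(need %in% names(table))) {
    stop("table must contain columns q_I (or qi), ecs_ss, ecs_inv")
  }
  tab <- stats::na.omit(table[, need])
  if (nrow(tab) < 4) stop("need at least 3 complete rows (and residual df)")
  for (p in c("ecs_ss", "ecs_inv")) {
    if (stats::sd(tab[[p]]) == 0) stop("constant predictor: ", p)
  }
  r <- abs(stats::cor(tab$ecs_ss, tab$ecs_inv))
  if (r > 1 - 1e-10) stop("collinear predictors: ecs_ss and ecs_inv")

  fit <- stats::lm(q_I ~ ecs_ss + ecs_inv, data = tab)
  # Type II sums of squares: each term after the other (drop-one F tests
  # are Type II for an additive model)
  dr <- stats::drop1(fit, test = "F")
  out <- data.frame(term = rownames(dr)[-1],
                    F = dr[["F value"]][-1],
                    p = dr[["Pr(>F)"]][-1],
                    df = dr[["Df"]][-1],
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  class(out) <- c("qi_association", "data.frame")
  out
}

#' @export
print.qi_association <- function(x, ...) {
  cat("Two-way (Type II) ANOVA of q_I against pmf components\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-8s F = %.3g, p = %.3g\n", x$term[i], x$F[i], x$p[i]))
  }
  invisible(x)
}
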