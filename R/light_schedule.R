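#' Generate a daily actinic light schedule
#'
#' Builds one of the three photoperiod designs used for fluorescence
#' phenotyping: a constant day, a "sinusoidal" day (a multiplicative ramp
#' stepping up every `step_minutes` from `start_irr` to exactly
#' `peak_irr` at midday, then descending mirror-symmetrically), and a
#' fluctuating day in which each sinusoidal-baseline slot is interrupted
#' by a 2x-of-baseline spike held 15 min followed by a 1.5x-of-baseline
#' segment of 12 min (remainder of the slot at baseline), so the peak
#' spike reaches twice the sinusoidal midday peak.
#'
#' The ramp ratio is `r = (peak_irr / start_irr)^(1 / n_up)` with
#' `n_up = photoperiod/(2 * step) - 2` ascending multiplications, which
#' reproduces the ~1.2x per 30 min ramp of a 39 -> 500 umol m^-2 s^-1
#' 16-h day and holds the peak for two slots around midday.
#'
#' @param day_type One of `"constant"`, `"sinusoidal"`, `"fluctuating"`.
#' @param photoperiod_h Photoperiod length in hours (> 0).
#' @param start_irr Irradiance at the start of the day
#'   (umol photons m^-2 s^-1); the constant level for a constant day.
#' @param peak_irr Midday peak of the sinusoidal baseline; ignored for a
#'   constant day.
#' @param step_minutes Ramp step length in minutes.
#' @return A `light_schedule`: a data frame with columns `start_s` and
#'   `irradiance_umol` (ordered, first step at 0) plus attributes
#'   `photoperiod_h` and `day_type`.
#' @examples
#' sched <- make_light_schedule("sinusoidal", 16, 39, 500)
#' max(sched$irradiance_umol)  # 500
#' @export
make_light_schedule <- function(day_type = c("constant", "sinusoidal",
                                             "fluctuating"),
                                photoperiod_h = 16,
                                start_irr = 100,
                                peak_irr = NULL,
                                step_minutes = 30) {
  day_type <- match.arg(day_type)
  if (!is.numeric(photoperiod_h) || photoperiod_h <= 0) {
    stop("photoperiod_h must be > 0")
  }
  if (!is.numeric(start_irr) || start_irr <= 0) {
    stop("start_irr must be > 0")
  }
  span <- photoperiod_h * 3600

  if (day_type == "constant") {
    steps <- data.frame(start_s = 0, irradiance_umol = start_irr)
    return(new_light_schedule(steps, photoperiod_h, day_type))
  }

  if (is.null(peak_irr) || !is.numeric(peak_irr) || peak_irr <= 0) {
    stop("peak_irr must be supplied (> 0) for ", day_type, " days")
  }
  if (peak_irr < start_irr) {
    stop("peak_irr must be >= start_irr for a sinusoidal ramp")
  }

  step_s <- step_minutes * 60
  n_half <- round(span / 2 / step_s)  # slots in each half-day
  if (n_half < 3) stop("photoperiod too short for the requested step length")
  n_up <- n_half - 2                  # multiplicative steps to the peak
  r <- (peak_irr / start_irr)^(1 / n_up)
  ascent <- start_irr * r^(seq_len(n_half) - 1)
  # snap float round-off at the top, then hold the peak in the last slots
  ascent[abs(ascent - peak_irr) < 1e-9 * peak_irr] <- peak_irr
  ascent[ascent > peak_irr] <- peak_irr
  ascent[n_half] <- peak_irr
  baseline <- c(ascent, rev(ascent))     # mirror-symmetric about midday
  starts <- (seq_along(baseline) - 1) * step_s

  if (day_type == "sinusoidal") {
    steps <- data.frame(start_s = starts, irradiance_umol = baseline)
  } else {
    # fluctuating: split every baseline slot into 2x (15'), 1.5x (12'),
    # baseline (remainder)
    sub_off <- c(0, 15 * 60, 27 * 60)
    sub_off <- sub_off[sub_off < step_s]
    mult <- c(2, 1.5, 1)[seq_along(sub_off)]
    starts_f <- rep(starts, each = length(sub_off)) + sub_off
    irr_f <- rep(baseline, each = length(sub_off)) * mult
    steps <- data.frame(start_s = starts_f, irradiance_umol = irr_f)
  }
  # collapse consecutive duplicate levels
  keep <- c(TRUE, diff(steps$irradiance_umol) != 0)
  steps <- steps[keep, , drop = FALSE]
  rownames(steps) <- NULL
  new_light_schedule(steps, photoperiod_h, day_type)
}

new_light_schedule <- function(steps, photoperiod_h, day_type) {
  stopifnot(all(diff(steps$start_s) > 0), steps$start_s[1] == 0,
            all(steps$irradiance_umol >= 0))
  structure(steps,
            photoperiod_h = photoperiod_h,
            day_type = day_type,
            class = c("light_schedule", "data.frame"))
}

#' Irradiance at arbitrary times under a schedule
#'
#' Piecewise-constant lookup; times outside the photoperiod return 0
#' (darkness).
#'
#' @param schedule A `light_schedule`.
#' @param time_s Numeric vector of times in seconds.
#' @return Irradiances in umol photons m^-2 s^-1.
#' @export
schedule_irradiance <- function(schedule, time_s) {
  span <- attr(schedule, "photoperiod_h") * 3600
  idx <- findInterval(time_s, schedule$start_s)
  irr <- ifelse(idx >= 1, schedule$irradiance_umol[pmax(idx, 1)], 0)
  irr[time_s < 0 | time_s >= span] <- 0
  irr
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("Light schedule (%s, %g h photoperiod): %d steps, %g-%g umol m^-2 s^-1\n",
              attr(x, "day_type"), attr(x, "photoperiod_h"), nrow(x),
              min(x$irradiance_umol), max(x$irradiance_umol)))
  invisible(x)
}

#' @export
plot.light_schedule <- function(x, ...) {
  span <- attr(x, "photoperiod_h") * 3600
  t <- c(x$start_s, span) / 3600
  i <- c(x$irradiance_umol, x$irradiance_umol[nrow(x)])
  graphics::plot(t, i, type = "s", xlab = "time (h)",
                 ylab = expression(paste("irradiance (", mu,
                                         "mol photons ", m^-2, s^-1, ")")),
                 main = paste0(attr(x, "day_type"), " day"), ...)
  invisible(x)
}
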