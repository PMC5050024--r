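#' Maximal PSII quantum efficiency Fv/Fm
#'
#' @param F0 Dark-adapted minimal fluorescence (> 0).
#' @param FM Dark-adapted maximal fluorescence (> F0).
#' @return `(FM - F0) / FM`.
#' @examples
#' fvfm(1, 4)  # 0.75
#' @export
fvfm <- function(F0, FM) {
  if (any(F0 <= 0)) stop("F0 must be > 0")
  if (any(FM < F0)) stop("FM must be >= F0")
  (FM - F0) / FM
}

#' PSII operating efficiency Phi(II)
#'
#' @param FS Steady-state fluorescence in the light (> 0).
#' @param FMp Maximal fluorescence during a saturating pulse in the
#'   light (>= FS).
#' @return `(FMp - FS) / FMp`.
#' @export
phi2 <- function(FS, FMp) {
  if (any(FS <= 0)) stop("FS must be > 0")
  if (any(FS > FMp)) stop("FS must not exceed FMp")
  (FMp - FS) / FMp
}

#' Linear electron flow from Phi(II) and irradiance
#'
#' `LEF = Phi(II) * PAR * absorptance * psii_fraction`. The default leaf
#' absorptance (0.84) and PSII excitation fraction (0.5) are the
#' community conventions for C3 leaves.
#'
#' @param phi2 PSII operating efficiency.
#' @param par Incident photosynthetically active radiation
#'   (umol photons m^-2 s^-1, >= 0).
#' @param absorptance Leaf absorptance.
#' @param psii_fraction Fraction of absorbed light reaching PSII.
#' @return LEF in umol electrons m^-2 s^-1.
#' @examples
#' lef(0.5, 100)  # 21
#' @export
lef <- function(phi2, par, absorptance = 0.84, psii_fraction = 0.5) {
  if (any(par < 0)) stop("par must be >= 0")
  phi2 * par * absorptance * psii_fraction
}

#' Stern-Volmer qE and qI from maximal fluorescence levels
#'
#' The Stern-Volmer derivation separates rapidly reversible,
#' energy-dependent quenching (qE) from the slowly reversible,
#' photoinhibitory component (qI) measured after at least 10 min of dark
#' relaxation: `qE(SV) = FM/FMp - FM/FM_rec` and `qI = FM/FM_rec - 1`.
#' Their sum is the total Stern-Volmer NPQ, `FM/FMp - 1`, exactly.
#'
#' @param FM Dark-adapted maximal fluorescence.
#' @param FMp Maximal fluorescence in the light.
#' @param FM_rec Maximal fluorescence after >= 10 min dark relaxation.
#' @return List with `qe_sv`, `qi` and `flags`
#'   (`"negative_quenching"` when the expected ordering
#'   `FM >= FM_rec >= FMp` is violated; values are reported, not
#'   clipped, to surface instrument drift).
#' @examples
#' qe_qi_sv(4000, 1000, 2000)  # qe_sv = 2, qi = 1
#' @export
qe_qi_sv <- function(FM, FMp, FM_rec) {
  if (any(c(FM, FMp, FM_rec) <= 0)) stop("fluorescence levels must be > 0")
  flags <- character(0)
  if (any(FMp > FM_rec + 1e-12) || any(FM_rec > FM + 1e-12)) {
    flags <- "negative_quenching"
  }
  list(qe_sv = FM / FMp - FM / FM_rec,
       qi = FM / FM_rec - 1,
       flags = flags)
}

#' Fraction of open PSII centers, qL
#'
#' The "lake model" estimate of the oxidised fraction of the primary
#' quinone acceptor QA:
#' `qL = ((FMp - FS) / (FMp - F0p)) * (F0p / FS)`.
#'
#' @param FS Steady-state fluorescence (> 0).
#' @param FMp Maximal fluorescence in the light.
#' @param F0p Minimal fluorescence in the light (measured, or estimated
#'   via [estimate_f0prime()]).
#' @return qL in \[0, 1\] for consistent inputs.
#' @examples
#' ql(800, 2000, 500)  # 0.5
#' @export
ql <- function(FS, FMp, F0p) {
  if (any(FMp <= F0p)) stop("degenerate levels: FMp must exceed F0p")
  if (any(F0p <= 0) || any(FS <= 0)) stop("fluorescence levels must be > 0")
  ((FMp - FS) / (FMp - F0p)) * (F0p / FS)
}

#' Estimate F0' when the minimal fluorescence in light is not measured
#'
#' The standard lake-model relation
#' `F0' = F0 / (Fv/Fm + F0/FMp)`; equals `F0` when no quenching is
#' present (`FMp = FM`), and is always smaller than `F0` under
#' quenching.
#'
#' @param F0 Dark-adapted minimal fluorescence.
#' @param fvfm Dark-adapted Fv/Fm.
#' @param FMp Maximal fluorescence in the light.
#' @return Estimated F0'.
#' @export
estimate_f0prime <- function(F0, fvfm, FMp) {
  if (any(F0 <= 0) || any(FMp <= 0)) stop("inputs must be > 0")
  den <- fvfm + F0 / FMp
  if (any(den <= 0)) stop("zero denominator in F0' estimate")
  F0 / den
}

#' Full PAM quantification from one saturation-pulse record
#'
#' Computes every quenching parameter from a pulse record; `F0p` is
#' estimated via [estimate_f0prime()] when not measured.
#'
#' @param F0,FM Dark-adapted fluorescence levels.
#' @param FS,FMp Light steady-state and pulse-maximal levels.
#' @param FM_rec Maximal fluorescence after >= 10 min dark relaxation
#'   (defaults to `FM`, i.e. no sustained quenching).
#' @param F0p Optional measured minimal fluorescence in light.
#' @param par Irradiance at the measurement (umol photons m^-2 s^-1).
#' @param absorptance,psii_fraction LEF conventions, see [lef()].
#' @return A one-row data frame of class `pam_quantification` with
#'   columns `fvfm`, `phi2`, `lef`, `qe_sv`, `qi`, `ql`, `npq` and
#'   `flags`.
#' @export
pam_quantify <- function(F0, FM, FS, FMp, FM_rec = FM, F0p = NULL,
                         par = 0, absorptance = 0.84,
                         psii_fraction = 0.5) {
  qq <- qe_qi_sv(FM, FMp, FM_rec)
  p2 <- phi2(FS, FMp)
  if (is.null(F0p)) F0p <- estimate_f0prime(F0, fvfm(F0, FM), FMp)
  out <- data.frame(
    fvfm = fvfm(F0, FM),
    phi2 = p2,
    lef = lef(p2, par, absorptance, psii_fraction),
    qe_sv = qq$qe_sv,
    qi = qq$qi,
    ql = ql(FS, FMp, F0p),
    npq = FM / FMp - 1,
    flags = if (length(qq$flags)) paste(qq$flags, collapse = ";") else "",
    stringsAsFactors = FALSE
  )
  class(out) <- c("pam_quantification", "data.frame")
  out
}

#' Extract per-pulse fluorescence levels from an annotated trace
#'
#' Walks the `event` markers of a fluorescence trace: for each
#' `pulse_start`/`pulse_end` pair, records the last pre-pulse sample as
#' the steady-state level and the in-pulse maximum as the pulse-maximal
#' level.
#'
#' @param trace A `fluor_trace` (or data frame with `time_s`, `fluor`,
#'   `event`).
#' @return Data frame with one row per pulse: `time_s`, `F_pre`,
#'   `F_pulse`.
#' @export
extract_pulses <- function(trace) {
  starts <- which(trace$event == "pulse_start")
  ends <- which(trace$event == "pulse_end")
  if (length(starts) != length(ends)) {
    stop("unbalanced pulse_start/pulse_end markers")
  }
  do.call(rbind, lapply(seq_along(starts), function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    data.frame(time_s = trace$time_s[i0],
               F_pre = if (i0 > 1) trace$fluor[i0 - 1] else NA_real_,
               F_pulse = max(trace$fluor[i0:i1]))
  }))
}

#' Trapezoidal integral of a daily parameter time course
#'
#' @param time_h Sorted measurement times (hours).
#' @param value Parameter values.
#' @return The trapezoidal integral, in hours x units.
#' @examples
#' integrate_daily(c(0, 1, 2), c(0, 1, 0))  # 1
#' @export
integrate_daily <- function(time_h, value) {
  if (is.data.frame(time_h)) {
    value <- time_h[[2]]
    time_h <- time_h[[1]]
  }
  if (length(time_h) < 2) stop("need at least 2 points to integrate")
  if (is.unsorted(time_h)) stop("times must be sorted")
  sum(diff(time_h) * (value[-1] + value[-length(value)]) / 2)
}

#' Log2 fold change relative to wild type
#'
#' @param mutant_value,wildtype_value Positive values.
#' @return `log2(mutant_value / wildtype_value)`.
#' @export
log2_fold_change <- function(mutant_value, wildtype_value) {
  if (any(mutant_value <= 0) || any(wildtype_value <= 0)) {
    stop("fold changes require positive values")
  }
  log2(mutant_value / wildtype_value)
}
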