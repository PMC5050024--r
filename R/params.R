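#' Physiological parameter set for a genotype
#'
#' Bundles the plant-level quantities that drive the synthetic trace
#' generators and the screen simulator: proton efflux capacity, dark pmf,
#' steady-state pmf partitioning, chlorophyll content, PSII recombination
#' and repair kinetics, and the lumen-pH response of energy-dependent
#' quenching (qE).
#'
#' @param g_H_plus Proton conductivity of the thylakoid (dominated by the
#'   ATP synthase), operationally the inverse time constant of the
#'   dark-interval ECS decay, in s^-1.
#' @param partition_fraction_dpsi Steady-state fraction of the pmf stored
#'   as the electric field (delta-psi); dimensionless in \[0, 1\].
#' @param pmf_dark_mV Dark ("basal") pmf maintained by equilibration with
#'   the ATP pool, in mV (default 112 mV).
#' @param chl_per_area Leaf chlorophyll content in ug chlorophyll cm^-2.
#' @param k_r Intrinsic S2QA- recombination rate at zero field with fully
#'   reduced QA, in s^-1 (default 0.3 s^-1).
#' @param repair_rate First-order PSII (D1) repair rate, s^-1; set to zero
#'   by lincomycin treatment.
#' @param qe_pK Apparent lumen pK of the qE response (pH units).
#' @param qe_hill Hill coefficient of the qE lumen-pH response.
#' @param qe_max Saturating qE extent (Stern-Volmer units); qE saturates
#'   near 3.5 units in vivo.
#' @param psii_fraction_active Initial fraction of photochemically active
#'   PSII centers, in \[0, 1\].
#' @param fvfm_dark Dark-adapted maximal PSII quantum efficiency Fv/Fm of
#'   the undamaged leaf.
#' @param tau_ion Counter-ion relaxation time constant (s) converting a
#'   freshly formed delta-psi into delta-pH after a light step.
#' @param damage_coeff Photodamage probability per S2QA- recombination
#'   event (dimensionless); multiplies the modelled recombination rate to
#'   give the first-order damage rate.
#' @param lef_i_half Irradiance (umol photons m^-2 s^-1) at which the
#'   pmf-generating proton influx is half-saturated in the generator.
#'   This is a lumped saturation including photosynthetic control, set
#'   so the steady-state light-driven pmf spans about 150-200 mV
#'   between 100 and 500 umol m^-2 s^-1 at the reference conductivity.
#' @param ql_i_half Irradiance at which the open-center fraction (and
#'   hence qL) falls to 0.5 in the generator.
#' @param pmf_per_lef Steady-state light-driven pmf (mV) produced per unit
#'   of relative saturated LEF at the reference conductivity
#'   `g_ref`; together with `lef_i_half` this sets the 150-200 mV
#'   steady-state light-driven pmf scale.
#' @param g_ref Reference conductivity (s^-1) at which `pmf_per_lef` is
#'   defined; lowering `g_H_plus` below `g_ref` raises the pmf
#'   proportionally.
#' @param ecs_per_mv Deconvoluted, chlorophyll-normalised ECS signal per
#'   mV of delta-psi (normalised ECS units mV^-1); 1/40 by the
#'   single-turnover-flash calibration (40 mV per flash).
#'
#' @return An object of class `plant_params` (a named list).
#' @examples
#' p <- plant_params()
#' p$g_H_plus
#' @export
plant_params <- function(g_H_plus = 10,
                         partition_fraction_dpsi = 0.5,
                         pmf_dark_mV = 112,
                         chl_per_area = 20,
                         k_r = 0.3,
                         repair_rate = 3e-4,
                         qe_pK = 5.5,
                         qe_hill = 3,
                         qe_max = 3.5,
                         psii_fraction_active = 1,
                         fvfm_dark = 0.75,
                         tau_ion = 20,
                         damage_coeff = 7.5e-6,
                         lef_i_half = 45,
                         ql_i_half = 500,
                         pmf_per_lef = 220,
                         g_ref = 10,
                         ecs_per_mv = 1 / 40) {
  p <- list(
    g_H_plus = g_H_plus,
    partition_fraction_dpsi = partition_fraction_dpsi,
    pmf_dark_mV = pmf_dark_mV,
    chl_per_area = chl_per_area,
    k_r = k_r,
    repair_rate = repair_rate,
    qe_pK = qe_pK,
    qe_hill = qe_hill,
    qe_max = qe_max,
    psii_fraction_active = psii_fraction_active,
    fvfm_dark = fvfm_dark,
    tau_ion = tau_ion,
    damage_coeff = damage_coeff,
    lef_i_half = lef_i_half,
    ql_i_half = ql_i_half,
    pmf_per_lef = pmf_per_lef,
    g_ref = g_ref,
    ecs_per_mv = ecs_per_mv
  )
  rates <- c("g_H_plus", "k_r", "repair_rate", "tau_ion", "damage_coeff",
             "pmf_dark_mV", "chl_per_area", "ecs_per_mv")
  for (nm in rates) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) ||
        p[[nm]] < 0) {
      stop("plant_params: '", nm, "' must be a single non-negative number")
    }
  }
  for (nm in c("partition_fraction_dpsi", "psii_fraction_active",
               "fvfm_dark")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop("plant_params: '", nm, "' must lie in [0, 1]")
    }
  }
  class(p) <- "plant_params"
  p
}

#' @export
print.plant_params <- function(x, ...) {
  cat("Plant parameter set:\n")
  cat(sprintf("  gH+ = %.3g s^-1, dark pmf = %.4g mV, dpsi fraction = %.2f\n",
              x$g_H_plus, x$pmf_dark_mV, x$partition_fraction_dpsi))
  cat(sprintf("  kr = %.3g s^-1, repair = %.3g s^-1, Fv/Fm = %.3f\n",
              x$k_r, x$repair_rate, x$fvfm_dark))
  cat(sprintf("  chl = %.3g ug cm^-2, qE: pK %.2f, hill %.1f, max %.2f\n",
              x$chl_per_area, x$qe_pK, x$qe_hill, x$qe_max))
  invisible(x)
}

#' Additive Gaussian measurement-noise model
#'
#' One integer seed drives a single generator per run; the same seed and
#' configuration yield bit-identical traces.
#'
#' @param additive_sd Standard deviation of the additive Gaussian noise,
#'   in trace units (>= 0).
#' @param seed Integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 0, seed = 1L) {
  if (!is.numeric(additive_sd) || additive_sd < 0) {
    stop("noise_model: additive_sd must be >= 0")
  }
  structure(list(additive_sd = additive_sd, seed = as.integer(seed)),
            class = "noise_model")
}

# Evaluate fn() with a local, restored RNG state seeded from `seed`,
# so generators are deterministic without clobbering the caller's stream.
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  fn()
}

# Additive Gaussian noise helper shared by the trace generators.
add_noise <- function(x, noise, stream_offset = 0L) {
  if (is.null(noise) || noise$additive_sd == 0) return(x)
  with_seed(noise$seed + stream_offset,
            function() x + stats::rnorm(length(x), 0, noise$additive_sd))
}

# Cheap stable fingerprint of a configuration object (provenance metadata).
config_fingerprint <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  raw <- utf8ToInt(txt)
  sprintf("%08x", sum(raw * (seq_along(raw) %% 97 + 1)) %% .Machine$integer.max)
}
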