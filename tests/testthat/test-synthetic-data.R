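test_that("a trace at the dark potentials deconvolutes to zero", {
  p <- plant_params()
  tt <- seq(0, 5, 0.01)
  mini <- data.frame(time_s = tt,
                     dpsi_mV = p$partition_fraction_dpsi * p$pmf_dark_mV,
                     dph_mV = (1 - p$partition_fraction_dpsi) * p$pmf_dark_mV)
  tr <- synthesize_ecs_trace(mini, p)
  expect_equal(max(abs(deconvolute_ecs(tr))), 0, tolerance = 1e-12)
})

test_that("known (dpsi, dpH) round-trips through partitioning", {
  # unit-scale generator: ecs_per_mv = 1, chl = 1, so trace units are mV
  p <- plant_params(ecs_per_mv = 1, chl_per_area = 1)
  tr <- make_dirk_trace(p, dpsi_rel = 1.0, dph_rel = 0.5)
  tr2 <- with_dark_baseline(tr)
  part <- partition_pmf(tr2, c(0, 4), c(4, 8), c(-2, 0),
                        chl_per_area = 1)
  expect_equal(part$ecs_ss, 1.0, tolerance = 1e-6)
  expect_equal(part$ecs_inv, 0.5, tolerance = 1e-6)
  expect_equal(part$ecs_t, 1.5, tolerance = 1e-6)
})

test_that("seeded generators are bit-identical across reruns", {
  p <- plant_params()
  n <- noise_model(1e-4, 99L)
  a <- make_dirk_trace(p, noise = n)
  b <- make_dirk_trace(p, noise = n)
  expect_identical(a, b)
  sch <- data.frame(start_s = c(0, 10), irradiance_umol = c(0, 300))
  dyn <- simulate_pmf_dynamics(p, sch, dt = 0.5, t_end = 60)
  fa <- synthesize_fluorescence_trace(dyn, p, c(5, 50), noise = n)
  fb <- synthesize_fluorescence_trace(dyn, p, c(5, 50), noise = n)
  expect_identical(fa, fb)
})

test_that("overlapping or out-of-range dark intervals are rejected", {
  p <- plant_params()
  tt <- seq(0, 10, 0.01)
  mini <- data.frame(time_s = tt, dpsi_mV = 100, dph_mV = 80)
  expect_error(synthesize_ecs_trace(
    mini, p, data.frame(start_s = c(2, 3), end_s = c(4, 5))),
    "overlap")
  expect_error(synthesize_ecs_trace(
    mini, p, data.frame(start_s = 8, end_s = 12)), "within")
})

test_that("fluorescence pulses respect level ordering and configured Fv/Fm", {
  p <- plant_params()
  sch <- data.frame(start_s = c(0, 120), irradiance_umol = c(0, 300))
  dyn <- simulate_pmf_dynamics(p, sch, dt = 0.5, t_end = 900)
  ft <- synthesize_fluorescence_trace(dyn, p, c(30, 800),
                                      damaged_frac = 0.1)
  tru <- attr(ft, "truth")
  expect_true(all(tru$FMp <= tru$FM + 1e-9))
  # FS sits between the quenched minimal and maximal levels
  expect_true(all(tru$F0p - 1e-9 <= tru$FS & tru$FS <= tru$FMp + 1e-9))
  expect_true(all(tru$F0p <= tru$F0 + 1e-9))
  # dark-adapted pulse on an undamaged leaf reproduces Fv/Fm = 0.75
  ft0 <- synthesize_fluorescence_trace(dyn, p, c(30), damaged_frac = 0)
  pl <- extract_pulses(ft0)
  expect_equal(fvfm(pl$F_pre[1], pl$F_pulse[1]), 0.75, tolerance = 1e-6)
})

test_that("zero quenching capacity and no damage give FMp equal to FM", {
  p <- plant_params(qe_max = 0)
  sch <- data.frame(start_s = 0, irradiance_umol = 300)
  dyn <- simulate_pmf_dynamics(p, sch, dt = 0.5, t_end = 600)
  ft <- synthesize_fluorescence_trace(dyn, p, c(100, 500))
  tru <- attr(ft, "truth")
  expect_equal(tru$FMp, tru$FM, tolerance = 1e-12)
})

test_that("qE rises monotonically with delta-pH through the Hill link", {
  p <- plant_params()
  dph <- seq(60, 220, by = 10)
  lv <- pmfield:::fluor_levels(p, dph, 0, 0.5)
  expect_true(all(diff(lv$qe) >= 0))
  qe_sv <- vapply(seq_along(dph), function(i) {
    qe_qi_sv(lv$FM[i], lv$FMp[i], lv$FM_rec[i])$qe_sv
  }, numeric(1))
  expect_true(all(diff(qe_sv) >= -1e-12))
})

test_that("pulses before the trace start are rejected", {
  p <- plant_params()
  sch <- data.frame(start_s = 0, irradiance_umol = 100)
  dyn <- simulate_pmf_dynamics(p, sch, dt = 0.5, t_end = 60)
  expect_error(synthesize_fluorescence_trace(dyn, p, c(-5, 30)),
               "before")
  expect_error(synthesize_fluorescence_trace(dyn, p, c(30, 20)),
               "sorted")
})

test_that("flash pair reflects the active PSII fraction", {
  fp0 <- simulate_flash_ecs(0)
  expect_equal(fp0$amp1, fp0$amp2)
  fp1 <- simulate_flash_ecs(1, psi_amplitude = 2, psii_amplitude = 1.5)
  expect_equal(fp1$amp1 - fp1$amp2, 1.5)
  fp <- simulate_flash_ecs(0.6)
  expect_equal(psii_activity_from_flash_pair(fp)$psii_activity, 0.6)
  expect_error(simulate_flash_ecs(1.2), "\\[0, 1\\]")
})

test_that("photoinhibition dynamics follow the field-damage model", {
  p0 <- plant_params(damage_coeff = 0)
  sch <- make_light_schedule("constant", 2, 1000)
  c0 <- simulate_photoinhibition(p0, sch, lincomycin = TRUE, dt = 5)
  expect_true(all(c0$fvfm_norm == 1))

  p <- plant_params()
  cl <- simulate_photoinhibition(p, sch, lincomycin = TRUE, dt = 5,
                                 start_at_steady_state = TRUE)
  ll <- stats::lm(log(cl$fvfm_norm) ~ cl$time_s)
  expect_gt(summary(ll)$r.squared, 0.999)

  cn <- simulate_photoinhibition(p, sch, lincomycin = FALSE, dt = 5,
                                 start_at_steady_state = TRUE)
  expect_gt(tail(cn$fvfm_norm, 1), tail(cl$fvfm_norm, 1))

  # a higher-field genotype photoinhibits faster
  hi <- simulate_photoinhibition(plant_params(partition_fraction_dpsi = 0.6),
                                 sch, lincomycin = TRUE, dt = 5,
                                 start_at_steady_state = TRUE)
  expect_lt(tail(hi$fvfm_norm, 1), tail(cl$fvfm_norm, 1))
})
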