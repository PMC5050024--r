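test_that("deconvolution cancels constant and wavelength-linear backgrounds", {
  n <- 50
  c0 <- rep(0.37, n)
  expect_equal(deconvolute_ecs(c0, c0, c0), rep(0, n))
  b <- runif(n); cc <- runif(n)
  expect_equal(deconvolute_ecs(b - cc, b, b + cc), rep(0, n),
               tolerance = 1e-12)
  s <- rnorm(n)
  expect_equal(deconvolute_ecs(b, b + s, b), s, tolerance = 1e-12)
  expect_error(deconvolute_ecs(1:3, 1:4, 1:3), "mismatch")
})

test_that("deconvolution is invariant to any wavelength-linear background", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 30
    sig <- rnorm(n)
    a <- rnorm(n); slope <- rnorm(n)
    bg <- function(wl) a + slope * (wl - 520)
    out <- deconvolute_ecs(bg(505), bg(520) + sig, bg(535))
    expect_equal(out, sig, tolerance = 1e-10)
  }
})

test_that("DIRK fit recovers a constructed first-order decay exactly", {
  s <- make_exp_series(A = 1, tau = 0.05, C = 0.2)
  fit <- fit_dirk(s)
  expect_equal(fit$g_H_plus, 20, tolerance = 1e-6)
  expect_equal(fit$tau, 0.05, tolerance = 1e-6)
  expect_equal(fit$g_H_plus, 1 / fit$tau)
  expect_lt(fit$fit_rmse, 1e-8)
})

test_that("flat or non-decaying windows raise a fit failure", {
  t <- seq(0, 1, length.out = 100)
  expect_error(fit_dirk(list(time_s = t, ecs = rep(0.3, 100))),
               "fit failure")
  expect_error(fit_dirk(list(time_s = t, ecs = 0.1 + 0.5 * t)),
               "fit failure")
  expect_error(fit_dirk(list(time_s = t[1:5], ecs = exp(-t[1:5]))),
               "at least 10|window")
})

test_that("DIRK fit matches a brute-force grid-search oracle", {
  s <- make_exp_series(A = 0.8, tau = 0.12, C = -0.1, t_end = 0.6,
                       n = 20)
  fit <- fit_dirk(s)
  grid <- grid_search_decay(s$time_s, s$ecs)
  sse_fit <- sum(residuals(fit)^2)
  expect_lte(sse_fit, grid[["sse"]] * 1.001)
  expect_equal(fit$tau, 0.12, tolerance = 1e-3)
  expect_equal(grid[["tau"]], 0.12, tolerance = 5e-2)
})

test_that("gH+ is recovered within 5% at 1% noise over 100 seeds", {
  s <- make_exp_series(A = 1, tau = 0.1, C = 0.05, t_end = 0.8, n = 500)
  errs <- vapply(1:100, function(seed) {
    set.seed(seed)
    y <- s$ecs + rnorm(500, 0, 0.01)
    fit <- fit_dirk(list(time_s = s$time_s, ecs = y))
    abs(fit$g_H_plus - 10) / 10
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
  expect_lt(stats::median(errs), 0.02)
})

test_that("partition arithmetic follows the S, D, M definitions", {
  t <- seq(0, 3, by = 0.01)
  lev <- function(S, D, M) {
    ecs <- ifelse(t < 1, S, ifelse(t < 2, M, D))
    list(time_s = t, ecs = ecs)
  }
  part <- partition_pmf(lev(1, 0, -0.5), c(0, 1), c(1, 2), c(2, 3))
  expect_equal(part$ecs_t, 1.5)
  expect_equal(part$ecs_ss, 1.0)
  expect_equal(part$ecs_inv, 0.5)
  expect_equal(part$ecs_t, part$ecs_ss + part$ecs_inv)

  z <- partition_pmf(lev(0.2, 0.2, 0.2), c(0, 1), c(1, 2), c(2, 3))
  expect_equal(c(z$ecs_t, z$ecs_ss, z$ecs_inv), c(0, 0, 0))

  expect_warning(
    nv <- partition_pmf(lev(1, 0, 0.4), c(0, 1), c(1, 2), c(2, 3)),
    "clamped")
  expect_equal(nv$ecs_inv, 0)
  expect_true("no_inversion" %in% nv$flags)
})

test_that("partition conserves ecs_t = ecs_ss + ecs_inv on synthetic traces", {
  p <- plant_params()
  tr <- with_dark_baseline(make_dirk_trace(p, dpsi_rel = 0.8 * 40,
                                           dph_rel = 0.4 * 40))
  part <- partition_pmf(tr, c(0, 4), c(4, 8), c(-2, 0), chl_per_area = 20)
  expect_equal(part$ecs_t, part$ecs_ss + part$ecs_inv, tolerance = 1e-9)
  expect_equal(part$ecs_ss, 0.8, tolerance = 0.01)
  expect_equal(part$ecs_inv, 0.4, tolerance = 0.01)
})

test_that("amplitudes are scale-equivariant and gH+ scale-invariant", {
  t <- seq(0, 3, by = 0.005)
  ecs <- 0.9 * exp(-pmax(t - 1, 0) * 8) - 0.3 * (t >= 1)
  ecs[t >= 2.5] <- 0  # relaxed baseline
  for (cc in c(2, 17.5)) {
    p1 <- partition_pmf(list(time_s = t, ecs = ecs),
                        c(0, 1), c(1, 2.4), c(2.5, 3))
    p2 <- partition_pmf(list(time_s = t, ecs = cc * ecs),
                        c(0, 1), c(1, 2.4), c(2.5, 3))
    expect_equal(p2$ecs_t, cc * p1$ecs_t, tolerance = 1e-9)
    expect_equal(p2$ecs_ss, cc * p1$ecs_ss, tolerance = 1e-9)
    expect_equal(p2$ecs_inv, cc * p1$ecs_inv, tolerance = 1e-9)
    s <- make_exp_series()
    f1 <- fit_dirk(s)
    f2 <- fit_dirk(list(time_s = s$time_s, ecs = cc * s$ecs))
    expect_equal(f2$g_H_plus, f1$g_H_plus, tolerance = 1e-6)
    expect_equal(f2$ecs_t, cc * f1$ecs_t, tolerance = 1e-6)
  }
})

test_that("chlorophyll normalisation is plain division with guards", {
  expect_equal(normalize_to_chl(1e-3, 20), 5e-5)
  expect_equal(normalize_to_chl(0, 7), 0)
  expect_equal(normalize_to_chl(normalize_to_chl(0.3, 20) * 20, 1), 0.3)
  expect_error(normalize_to_chl(1, 0), "chl")
  expect_error(normalize_to_chl(1, -2), "chl")
})

test_that("flash-pair PSII activity is the amplitude difference", {
  expect_equal(psii_activity_from_flash_pair(
    list(amp1 = 1.0e-3, amp2 = 4.0e-4))$psii_activity, 6.0e-4)
  eq <- psii_activity_from_flash_pair(list(amp1 = 0.5, amp2 = 0.5))
  expect_equal(eq$psii_activity, 0)
  neg <- psii_activity_from_flash_pair(list(amp1 = 0.3, amp2 = 0.5))
  expect_equal(neg$psii_activity, -0.2)
  expect_true("negative_activity" %in% neg$flags)
  expect_error(psii_activity_from_flash_pair(list(amp1 = 1)), "finite")
})

test_that("P700+ half-time fitting matches the constructed decay", {
  t <- seq(0, 0.03, length.out = 300)
  k <- log(2) / 0.005
  fit <- fit_p700_halftime(list(time_s = t, ecs = 0.4 * exp(-k * t) + 0.1))
  expect_equal(fit$half_time, 0.005, tolerance = 1e-6)
  expect_equal(fit$half_time, log(2) / fit$rate, tolerance = 1e-12)
  expect_error(fit_p700_halftime(list(time_s = t, ecs = rep(1, 300))),
               "fit failure")
  errs <- vapply(1:50, function(seed) {
    set.seed(seed)
    y <- 0.4 * exp(-k * t) + 0.1 + rnorm(300, 0, 0.004)
    abs(fit_p700_halftime(list(time_s = t, ecs = y))$half_time - 0.005) /
      0.005
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})
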