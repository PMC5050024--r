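test_that("ECS-to-mV calibration is linear through the flash amplitude", {
  cal <- pmf_calibration()
  expect_equal(calibrate_ecs_to_mv(1, cal), 40)
  expect_equal(calibrate_ecs_to_mv(0, cal), 0)
  expect_equal(calibrate_ecs_to_mv(3, cal), 120)
  set.seed(5)
  x <- runif(5); k <- runif(1, 0.1, 10)
  expect_equal(calibrate_ecs_to_mv(k * x, cal),
               k * calibrate_ecs_to_mv(x, cal), tolerance = 1e-12)
  cal2 <- pmf_calibration(flash_ecs_amplitude = 0.5)
  expect_equal(calibrate_ecs_to_mv(0.5, cal2), 40)
  expect_error(pmf_calibration(flash_ecs_amplitude = 0), "positive")
})

test_that("the printed dark delta-psi convention is 60 mV", {
  expect_equal(dark_dpsi_mV(), 60)
  expect_equal(dark_dpsi_mV(rounded = FALSE), 56)
})

test_that("the recombination rate follows the field-Boltzmann model", {
  expect_equal(recombination_rate(0, 0)$v_r, 0.3)
  expect_equal(recombination_rate(1, 90)$v_r, 0)
  expect_equal(recombination_rate(0, 60)$v_r, 3.0, tolerance = 1e-12)
  ap <- recombination_model(sign_convention = "as_printed")
  expect_equal(recombination_rate(0, 60, ap)$v_r, 0.03, tolerance = 1e-12)
  expect_error(recombination_rate(1.5, 0), "q_L")
})

test_that("the rate is monotone in qL and delta-psi with 10x per 60 mV", {
  dpsi <- seq(0, 120, by = 10)
  v <- vapply(dpsi, function(d) recombination_rate(0.3, d)$v_r,
              numeric(1))
  expect_true(all(diff(v) > 0))
  expect_equal(v[7] / v[1], 10, tolerance = 1e-12)   # +60 mV
  qls <- seq(0, 1, by = 0.1)
  vq <- vapply(qls, function(q) recombination_rate(q, 30)$v_r,
               numeric(1))
  expect_true(all(diff(vq) < 0))
})

test_that("the free-energy and operational forms of the rate law agree", {
  # energy form: v = [S2QA-] k0 10^(-dE_stab/0.06) with
  # dE_stab = dE0 - dpsi/1000 (eV) and k_r absorbing 10^(-dE0/0.06)
  set.seed(21)
  for (i in 1:20) {
    dE0 <- runif(1, 0.3, 0.8)
    dpsi <- runif(1, 0, 150)
    qL <- runif(1)
    k0 <- 0.3 * 10^(dE0 / 0.06)
    v_energy <- (1 - qL) * k0 * 10^(-(dE0 - dpsi / 1000) / 0.06)
    v_op <- recombination_rate(qL, dpsi)$v_r
    expect_equal(v_energy, v_op, tolerance = 1e-9)
  }
  m <- recombination_model()
  expect_equal(m$decade_eV * 1000, m$decade_mV)
})

test_that("fold-change prediction is a pure Boltzmann factor", {
  expect_equal(predicted_fold_change(0), 1)
  expect_equal(predicted_fold_change(60), 10)
  expect_equal(predicted_fold_change(40), 10^(2 / 3), tolerance = 1e-12)
  expect_equal(round(predicted_fold_change(40)), 5)
})

test_that("delta-psi ranges reproduce the calibration arithmetic", {
  expect_equal(unname(steady_state_dpsi_range()), c(30, 120))
  expect_equal(unname(steady_state_dpsi_range(150, 200, 1, 1)),
               c(150, 200))
  expect_equal(unname(steady_state_dpsi_range(200, 200, 0.2, 0.6)),
               c(40, 120))
  expect_error(steady_state_dpsi_range(200, 150), "inverted")

  expect_equal(unname(transient_dpsi_bounds()), c(150, 260))
  expect_equal(unname(transient_dpsi_bounds(0, c(0, 0), c(0, 0))),
               c(0, 0))
  expect_equal(unname(transient_dpsi_bounds(50)), c(140, 250))
  expect_error(transient_dpsi_bounds(-5), "non-negative")
})

test_that("qI association detects a constructed delta-psi effect", {
  F_ss <- F_inv <- numeric(100)
  for (seed in 1:100) {
    set.seed(seed)
    n <- 16
    ss <- runif(n, 0.5, 3); inv <- runif(n, 0.5, 3)
    qi <- 0.8 * ss + rnorm(n, 0, 0.2)
    a <- qi_association(data.frame(q_I = qi, ecs_ss = ss,
                                   ecs_inv = inv))
    F_ss[seed] <- a$F[a$term == "ecs_ss"]
    F_inv[seed] <- a$F[a$term == "ecs_inv"]
  }
  expect_gt(stats::median(F_ss), 10 * stats::median(F_inv))
  expect_gt(mean(F_ss > F_inv), 0.95)
})

test_that("the ANOVA matches brute-force normal equations and car::Anova", {
  set.seed(42)
  n <- 12
  tab <- data.frame(ecs_ss = runif(n), ecs_inv = runif(n))
  tab$q_I <- 1 + 2 * tab$ecs_ss - 0.5 * tab$ecs_inv + rnorm(n, 0, 0.3)
  a <- qi_association(tab)

  # normal-equations oracle: SSE of full vs reduced models by hand
  X_full <- cbind(1, tab$ecs_ss, tab$ecs_inv)
  sse <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% tab$q_I)
    sum((tab$q_I - X %*% beta)^2)
  }
  s_full <- sse(X_full)
  df_res <- n - 3
  for (term in c("ecs_ss", "ecs_inv")) {
    X_red <- if (term == "ecs_ss") cbind(1, tab$ecs_inv) else
      cbind(1, tab$ecs_ss)
    F_hand <- ((sse(X_red) - s_full) / 1) / (s_full / df_res)
    expect_equal(a$F[a$term == term], F_hand, tolerance = 1e-9)
    p_hand <- stats::pf(F_hand, 1, df_res, lower.tail = FALSE)
    expect_equal(a$p[a$term == term], p_hand, tolerance = 1e-9)
  }

  ca <- car::Anova(attr(a, "fit"), type = 2)
  expect_equal(a$F, ca[["F value"]][1:2], tolerance = 1e-9)
})

test_that("degenerate association tables are rejected", {
  base <- data.frame(q_I = c(1, 2, 3, 4, 5),
                     ecs_ss = c(1, 2, 3, 4, 5))
  dup <- base; dup$ecs_inv <- dup$ecs_ss
  expect_error(qi_association(dup), "collinear")
  con <- base; con$ecs_inv <- 1
  expect_error(qi_association(con), "constant")
  expect_error(qi_association(data.frame(q_I = 1:2, ecs_ss = 1:2,
                                         ecs_inv = 2:1)), "rows")
})
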