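test_that("the zero-field decay matches the closed-form two-state limit", {
  sc <- recombination_scheme()  # k_R1 = 0, K0 * k_R3 = 0.3 s^-1
  d <- simulate_s2qa_decay(sc, 0, t_span = 12, dt = 0.005)
  expect_equal(d$initial_rate, 0.3, tolerance = 0.01)
  expect_equal(d$half_life, log(2) / 0.3, tolerance = 0.01)
  # single-exponential occupancy after pre-equilibration
  tr <- d$trace
  k_fit <- -stats::coef(stats::lm(log(occ_A) ~ time_s,
                                  data = tr[tr$occ_A > 1e-6, ]))[[2]]
  pred <- tr$occ_A[1] * exp(-k_fit * tr$time_s)
  expect_lt(max(abs(pred - tr$occ_A)), 1e-6)
})

test_that("a 60 mV field accelerates the decay tenfold (Boltzmann oracle)", {
  sc <- recombination_scheme()
  d0 <- simulate_s2qa_decay(sc, 0, t_span = 2, dt = 5e-4)
  d60 <- simulate_s2qa_decay(sc, 60, t_span = 2, dt = 5e-4)
  expect_equal(d60$initial_rate / d0$initial_rate, 10, tolerance = 0.01)
})

test_that("occupancies are conserved to 1e-9 at every step", {
  sc <- recombination_scheme(k_R1 = 0.05)
  d <- simulate_s2qa_decay(sc, 45, t_span = 8, dt = 0.01)
  tots <- rowSums(d$trace[, c("occ_A", "occ_B", "occ_G")])
  expect_lt(max(abs(tots - 1)), 1e-9)
})

test_that("initial rate matches the rapid-equilibrium closed form", {
  sc <- recombination_scheme(k_R1 = 0.02)
  for (dpsi in c(0, 40, 80)) {
    d <- simulate_s2qa_decay(sc, dpsi, t_span = 1, dt = 2e-4)
    K <- sc$K0_AB * 10^(dpsi / 60)
    expect_equal(d$initial_rate, sc$k_R1 + sc$k_R3 * K,
                 tolerance = 0.01)
  }
})

test_that("simulated fold changes agree with the analytic prediction", {
  sc <- recombination_scheme()  # k_R1 = 0, f = 1
  d0 <- simulate_s2qa_decay(sc, 0, t_span = 1, dt = 2e-4)
  for (dpsi in c(40, 60)) {
    d <- simulate_s2qa_decay(sc, dpsi, t_span = 1, dt = 2e-4)
    expect_equal(d$initial_rate / d0$initial_rate,
                 predicted_fold_change(dpsi), tolerance = 0.01)
  }
})

test_that("halving the output step changes the initial rate by < 0.1%", {
  sc <- recombination_scheme()
  r1 <- simulate_s2qa_decay(sc, 40, t_span = 1, dt = 0.004)$initial_rate
  r2 <- simulate_s2qa_decay(sc, 40, t_span = 1, dt = 0.002)$initial_rate
  expect_lt(abs(r1 - r2) / r2, 0.001)
})

test_that("gramicidin comparison reproduces the field-induced acceleration", {
  sc <- recombination_scheme()
  null <- gramicidin_comparison(sc, 0, 20, t_span = 12)
  expect_equal(null$rate_ratio, 1, tolerance = 1e-6)
  expect_equal(null$lifetime_ratio, 1, tolerance = 1e-6)
  g40 <- gramicidin_comparison(sc, 40, 20, t_span = 12)
  expect_equal(g40$rate_ratio, 10^(40 / 60), tolerance = 0.01)
  expect_gt(g40$lifetime_ratio, 1)
  # lifetime ratio grows with the field persistence
  lr <- vapply(c(2, 8, 30), function(tau) {
    gramicidin_comparison(sc, 40, tau, t_span = 12)$lifetime_ratio
  }, numeric(1))
  expect_true(all(diff(lr) > 0))
})

test_that("singlet-oxygen yields follow the branching bookkeeping", {
  sc <- recombination_scheme(k_R1 = 0)  # all flux via the triplet route
  d <- simulate_s2qa_decay(sc, 0, t_span = 40, dt = 0.01)
  expect_equal(singlet_oxygen_yield(d),
               sc$triplet_branch * sc$o2_quench_yield, tolerance = 1e-6)
  sc0 <- recombination_scheme(triplet_branch = 0)
  d0 <- simulate_s2qa_decay(sc0, 0, t_span = 5, dt = 0.01)
  expect_equal(singlet_oxygen_yield(d0), 0)
  # with a field-independent direct route, yield rises with delta-psi
  sc1 <- recombination_scheme(k_R1 = 0.2)
  ys <- vapply(seq(0, 120, by = 30), function(d) {
    res <- simulate_s2qa_decay(sc1, d, t_span = 30, dt = 0.01)
    singlet_oxygen_yield(res)
  }, numeric(1))
  expect_true(all(diff(ys) > 0))
})

test_that("explicit integration refuses unstable step sizes", {
  sc <- recombination_scheme()
  expect_error(simulate_s2qa_decay(sc, 0, t_span = 1, dt = 0.01,
                                   method = "euler"), "unstable")
  expect_error(recombination_scheme(K0_AB = 2), "K0")
  expect_error(recombination_scheme(k_R3 = -1), "rates")
})
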