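test_that("macro-to-micro reparameterization matches hand arithmetic", {
  p <- macro_params(cl = 6.576, v1 = 16.1, q1 = 0.545, vp1 = 49.5,
                    q2 = 3.46, vp2 = 6.13)
  k <- to_micro(p)
  expect_equal(k$k10, 6.576 / 16.1, tolerance = 1e-12)
  expect_equal(k$k12, 0.545 / 16.1, tolerance = 1e-12)
  expect_equal(k$k21, 0.545 / 49.5, tolerance = 1e-12)
  expect_equal(k$k13, 3.46 / 16.1, tolerance = 1e-12)
  expect_equal(k$k31, 3.46 / 6.13, tolerance = 1e-12)
  # rounded spot values
  expect_equal(k$k10, 0.4084, tolerance = 2e-4)
  expect_equal(k$k31, 0.5644, tolerance = 2e-4)

  # degenerate one-compartment reduction
  k0 <- to_micro(macro_params(6.93, 10, 0, 1, 0, 1))
  expect_equal(c(k0$k12, k0$k21, k0$k13, k0$k31), rep(0, 4))

  # rate matrix built from micro rates has the expected structure
  M <- rate_matrix(p)
  expect_equal(M[1, 1], -(k$k10 + k$k12 + k$k13))
  expect_equal(M[2, 1], k$k12)
  expect_equal(M[1, 2], k$k21)
  expect_equal(M[3, 1], k$k13)
  expect_equal(M[1, 3], k$k31)
  expect_equal(M[2, 3], 0)
  expect_equal(colSums(M), c(-k$k10, 0, 0), tolerance = 1e-14)

  expect_error(macro_params(1, -1, 0.1, 1, 0.1, 1), "positive")
})

test_that("one-compartment bolus limit reproduces the exponential decay", {
  p <- macro_params(6.93, 10, 0, 1e-6, 0, 1e-6)
  d <- dose_event(0, 100, 1e-6)
  expect_equal(conc_at(p, d, 1), 10 * exp(-0.693), tolerance = 1e-3)
  expect_equal(phase_half_lives(p), log(2) / 0.693, tolerance = 1e-3)
})

test_that("analytic AUC to infinity equals dose/CL for any parameter set", {
  set.seed(42)
  for (i in 1:20) {
    cfg <- random_config()
    total_dose <- sum(cfg$doses$amount)
    expect_equal(auc(cfg$p, 0, Inf, "analytic", doses = cfg$doses),
                 total_dose / cfg$p$cl, tolerance = 1e-9)
  }
})

test_that("analytic profile matches the adaptive ODE oracle on the typical neonate", {
  # reduced-model parameter fixture spanning slow neonatal kinetics
  p <- macro_params(cl = 0.3233, v1 = 1.182, q1 = 0.0635, vp1 = 2.367,
                    q2 = 0.4027, vp2 = 0.450)
  d <- dose_event(0, 29.85, 4)
  tt <- seq(0, 24, 0.25)
  an <- simulate_profile(p, d, tt)$conc
  oc <- ode_oracle(p, d, tt)
  expect_lt(max(abs(an - oc) / pmax(oc, 1e-12)), 1e-6)
})

test_that("trapezoid and analytic AUC agree on a 15-min grid", {
  p <- typical_neonate()
  d <- dose_event(0, 29.85, 4)
  prof <- simulate_profile(p, d, seq(0, 24, 0.25))
  a_trap <- auc(prof, 0, 8, "trapezoid")
  a_exact <- auc(prof, 0, 8, "analytic")
  expect_lt(abs(a_trap - a_exact) / a_exact, 0.005)
  # constant-concentration sanity: flat 10 ug/ml over 24 h
  flat <- structure(
    list(times = seq(0, 24, 0.25), conc = rep(10, 97)),
    class = "concentration_profile"
  )
  expect_equal(auc(flat, 0, 24, "trapezoid"), 240)
  expect_error(auc(prof, 8, 8), "exceed")
})

test_that("steady-state volume sums the compartment volumes and scales linearly", {
  p <- macro_params(6.576, 16.1, 0.545, 49.5, 3.46, 6.13)
  expect_equal(vss(p), 71.73)
  s <- 0.0734
  p2 <- macro_params(6.576, 16.1 * s, 0.545, 49.5 * s, 3.46, 6.13 * s)
  expect_equal(vss(p2), s * vss(p), tolerance = 1e-12)
})

test_that("phase half-lives are positive and reproduce the terminal slope", {
  set.seed(7)
  for (i in 1:200) {
    cfg <- random_config()
    hl <- phase_half_lives(cfg$p)
    expect_length(hl, 3)
    expect_true(all(hl > 0))
    expect_true(all(diff(hl) > 0))
  }
  # terminal log-linear slope of the oracle profile equals the longest
  # half-life
  p <- macro_params(2, 10, 0.8, 20, 3, 6)
  d <- dose_event(0, 100, 0.5)
  hl <- phase_half_lives(p)
  tt <- seq(200, 260, 2) # deep terminal phase
  oc <- ode_oracle(p, d, tt, rtol = 1e-12, atol = 1e-14)
  slope <- coef(lm(log(oc) ~ tt))[2]
  expect_equal(unname(-log(2) / slope), max(hl), tolerance = 1e-3)
})

test_that("superposition holds: multi-dose profile is the sum of shifted single doses", {
  p <- typical_neonate()
  tt <- seq(0, 36, 0.25)
  d1 <- dose_event(0, 50, 2)
  d2 <- dose_event(12, 80, 2)
  both <- simulate_profile(p, rbind(d1, d2), tt)$conc
  sum_of <- simulate_profile(p, d1, tt)$conc + simulate_profile(p, d2, tt)$conc
  expect_lt(max(abs(both - sum_of)), 1e-10)
})

test_that("mass balance: dose in = remaining amounts + eliminated, at every grid point", {
  set.seed(99)
  for (i in 1:10) {
    cfg <- random_config()
    prep <- cebopedpk:::.pk_segments(cfg$p, cfg$doses)
    for (t in c(1, 5, 12, 24, 48)) {
      infused <- sum(pmin(pmax(t - cfg$doses$start_time, 0), cfg$doses$duration) /
                     cfg$doses$duration * cfg$doses$amount)
      amounts <- cebopedpk:::.amounts_at(prep, t)
      eliminated <- cfg$p$cl * auc(cfg$p, 0, t, "analytic", doses = cfg$doses)
      expect_equal(sum(amounts) + eliminated, infused,
                   tolerance = 1e-8)
    }
  }
})

test_that("concentration is continuous at infusion stop and Cmax is near end of infusion", {
  p <- typical_neonate()
  d <- dose_event(0, 29.85, 4)
  eps <- 1e-7
  expect_equal(conc_at(p, d, 4 - eps), conc_at(p, d, 4 + eps), tolerance = 1e-5)
  prof <- simulate_profile(p, d, seq(0, 24, 0.25))
  expect_gte(cmax(prof), conc_at(p, d, 4) - 1e-9)
})

test_that("simulation input validation and degenerate eigenvalue guard", {
  p <- typical_neonate()
  expect_error(simulate_profile(p, dose_event(0, 10, 2), c(0, 1, 1)),
               "strictly increasing")
  expect_error(dose_event(-1, 10, 2), "start_time")
  # near-degenerate kinetics (vanishing exchange with a huge peripheral
  # volume) stay finite and positive
  pdeg <- macro_params(cl = 5, v1 = 10, q1 = 1e-8, vp1 = 1e4, q2 = 3, vp2 = 6)
  cdeg <- conc_at(pdeg, dose_event(0, 100, 1), c(0.5, 1, 6, 24))
  expect_true(all(is.finite(cdeg)) && all(cdeg >= 0))
})
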