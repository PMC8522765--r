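test_that("fat-free mass anchors the standard adult and bounds above by weight", {
  expect_equal(fat_free_mass("male", 70, 176, 35), 56.1, tolerance = 0.001)
  # infant fixed fraction
  expect_equal(fat_free_mass("male", 3.98, 54, 0.02), 0.86 * 3.98, tolerance = 1e-9)
  # never exceeds weight, any plausible body
  set.seed(3)
  for (i in 1:100) {
    age <- runif(1, 0, 18)
    wt <- runif(1, 2.5, 100)
    ht <- runif(1, 48, 190)
    sx <- sample(c("male", "female"), 1)
    f <- fat_free_mass(sx, wt, ht, age)
    expect_true(f > 0 && f <= wt)
  }
  expect_error(fat_free_mass("male", -1, 100, 5), "positive")
})

test_that("Mosteller BSA matches the square-root form and its scaling", {
  expect_equal(body_surface_area(70, 170), sqrt(170 * 70 / 3600), tolerance = 1e-12)
  expect_equal(body_surface_area(70, 170), 1.818, tolerance = 1e-3)
  # neonatal check against the study's printed median (0.230 m^2, ~6% apart)
  expect_equal(body_surface_area(3.98, 54), 0.2443, tolerance = 1e-3)
  expect_lt(abs(body_surface_area(3.98, 54) - 0.230) / 0.230, 0.07)
  # quadrupling wt*ht doubles BSA
  expect_equal(body_surface_area(4 * 70, 170), 2 * body_surface_area(70, 170))
})

test_that("Rhodin FFM GFR: half-maturation, asymptote, neonatal value, monotonicity", {
  expect_equal(gfr_rhodin_ffm(47.7, 56.1), 121.2 / 2, tolerance = 1e-12)
  expect_equal(gfr_rhodin_ffm(1e7, 56.1), 121.2, tolerance = 1e-3)
  neo <- gfr_rhodin_ffm(42.0, 3.42)
  expect_equal(neo, 5.85, tolerance = 0.002)
  expect_lt(abs(neo - 5.90) / 5.90, 0.02) # printed neonatal median
  # strictly increasing in both arguments
  pma <- seq(30, 900, length.out = 50)
  expect_true(all(diff(gfr_rhodin_ffm(pma, 20)) > 0))
  ffm <- seq(2, 60, length.out = 50)
  expect_true(all(diff(gfr_rhodin_ffm(50, ffm)) > 0))
})

test_that("typical parameters reproduce the covariate model arithmetic", {
  pm <- population_model()
  p <- typical_params(pm, list(weight = 3.98, gfr = 5.90))
  expect_equal(p$cl, 0.0548 * 5.90, tolerance = 1e-12)
  expect_equal(p$cl / 3.98, 0.0810, tolerance = 0.005) # printed median CL/kg
  expect_equal(p$v1, 16.1 * (3.98 / 70)^0.911, tolerance = 1e-12)
  expect_equal(p$v1, 1.182, tolerance = 1e-3)
  expect_equal(vss(p) / 3.98, 1.33, tolerance = 0.006) # printed median Vss/kg
  expect_equal(p$q1, 0.545 * (3.98 / 70)^0.75, tolerance = 1e-12)
  # reference-size identity: volumes equal intercepts at 70 kg
  p70 <- typical_params(pm, list(weight = 70, gfr = 120))
  expect_equal(c(p70$v1, p70$vp1, p70$vp2), c(16.1, 49.5, 6.13))
  expect_equal(c(p70$q1, p70$q2), c(0.545, 3.46))
  # zero GFR gives zero clearance (nonrenal clearance fixed to zero)
  expect_equal(typical_params(pm, list(weight = 10, gfr = 0))$cl, 0)
  # monotonicity
  cls <- sapply(seq(5, 120, 5), function(g) typical_params(pm, list(weight = 20, gfr = g))$cl)
  expect_true(all(diff(cls) > 0))
  vols <- sapply(seq(3, 70, 5), function(w) typical_params(pm, list(weight = w, gfr = 50))$v1)
  expect_true(all(diff(vols) > 0))
})

test_that("individual parameters apply log-normal effects to CL and V1 only", {
  pm <- population_model()
  sc <- list(weight = 18, gfr = 80)
  p0 <- typical_params(pm, sc)
  expect_equal(unlist(individual_params(pm, sc, 0, 0)), unlist(p0))
  p2 <- individual_params(pm, sc, log(2), 0)
  expect_equal(p2$cl, 2 * p0$cl)
  expect_equal(p2$v1, p0$v1)
  expect_equal(c(p2$q1, p2$vp1, p2$q2, p2$vp2),
               c(p0$q1, p0$vp1, p0$q2, p0$vp2))
})

test_that("sampled random effects have the model variances and are seeded", {
  pm <- population_model()
  a <- sample_effects(pm, 50, seed = 123)
  b <- sample_effects(pm, 50, seed = 123)
  expect_identical(a, b)
  big <- sample_effects(pm, 1e5, seed = 5)
  expect_equal(var(big$eta_cl), 0.0547, tolerance = 0.03)
  expect_equal(var(big$eta_v1), 0.0711, tolerance = 0.03)
  expect_equal(mean(exp(big$eta_cl)), exp(0.0547 / 2), tolerance = 0.01)
  zero <- sample_effects(population_model(omega2_cl = 0, omega2_v1 = 0), 10, seed = 1)
  expect_true(all(zero == 0))
})

test_that("combined residual error has the additive-plus-proportional variance", {
  pm <- population_model()
  pm0 <- population_model(sigma2_prop = 0, sigma2_add = 0)
  expect_equal(apply_residual_error(pm0, c(0, 1, 10)), c(0, 1, 10))
  set.seed(11)
  y10 <- apply_residual_error(pm, rep(10, 1e5))
  expect_equal(sd(y10), sqrt(100 * 0.0701 + 0.000156), tolerance = 0.02)
  y0 <- apply_residual_error(pm, rep(0, 1e5))
  expect_equal(sd(y0), 0.0125, tolerance = 0.02)
  expect_error(apply_residual_error(pm, -1), "nonnegative")
})

test_that("percent CV convention matches the reported conversions", {
  expect_equal(cv_percent(0.0547), 23.4, tolerance = 0.002)
  expect_equal(cv_percent(0.0711), 26.7, tolerance = 0.002)
  expect_equal(cv_percent(0.0701), 26.5, tolerance = 0.002)
  expect_equal(cv_percent(0), 0)
  expect_equal(additive_sd(population_model()), 0.0125, tolerance = 1e-3)
  # round trip
  expect_equal(cv_percent(0.0547)^2 / 1e4, 0.0547, tolerance = 1e-12)
  expect_error(cv_percent(-1), "nonnegative")
})

test_that("subject covariate record is internally consistent", {
  sc <- subject_covariates("male", age_years = 0.022, weight = 3.98,
                           height = 54, gestational_age = 40.9)
  expect_equal(sc$pma, 40.9 + 0.022 * 365.25 / 7, tolerance = 1e-9)
  expect_equal(sc$gfr_norm, sc$gfr * 1.73 / sc$bsa, tolerance = 1e-9)
  expect_true(sc$ffm <= sc$weight)
})

test_that("model specification file round-trips and the shipped file is the final model", {
  spec <- default_model_spec()
  pm <- spec$population_model
  expect_equal(pm$cl_gfr_slope, 0.0548)
  expect_equal(pm$v1_ref, 16.1)
  expect_equal(pm$vol_exponent, 0.911)
  expect_equal(pm$omega2_cl, 0.0547)
  expect_equal(pm$sigma2_add, 0.000156)
  expect_equal(spec$rhodin_params$tm50, 47.7)
  tmp <- tempfile(fileext = ".yaml")
  write_model_spec(pm, spec$rhodin_params, tmp)
  back <- read_model_spec(tmp)
  expect_equal(unclass(back$population_model), unclass(pm), tolerance = 1e-12)
  expect_equal(unclass(back$rhodin_params), unclass(spec$rhodin_params),
               tolerance = 1e-12)
})
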