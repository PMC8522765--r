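# rich single-dose design over the full pediatric range, used by the MAP and
# recovery tests
rich_design <- function(age_range = c(0, 18)) {
  study_design(
    "RICH-SYNTH", age_range,
    schedule = list(list(age_max = Inf,
                         times = c(0.25, 0.5, 1, 1.5, 2, 2.5, 3, 4, 6, 8,
                                   12, 16, 20, 24))),
    lloq = 1e-6,
    regimen_rule = structure(regimen(15, 24, infusion_duration = 2),
                             single_dose = TRUE)
  )
}

test_that("MAP estimates sit at the prior mode when data equal typical predictions", {
  pm0 <- population_model(sigma2_prop = 0, sigma2_add = 0,
                          omega2_cl = 0, omega2_v1 = 0)
  ds <- simulate_study(rich_design(), pm0, n = 3, seed = 41)
  # estimate under the full model (nonzero omegas) against noise-free
  # typical data: posterior mode must be eta = 0
  ebe <- map_estimate(population_model(sigma2_prop = 1e-8, sigma2_add = 1e-10),
                      ds)
  expect_true(all(abs(ebe$eta_cl) < 1e-4))
  expect_true(all(abs(ebe$eta_v1) < 1e-4))
})

test_that("MAP recovers a known individual effect from rich low-noise data", {
  pm_gen <- population_model(omega2_cl = 0, omega2_v1 = 0,
                             sigma2_prop = 1e-8, sigma2_add = 1e-10)
  ds <- simulate_study(rich_design(c(2, 6)), pm_gen, n = 1, seed = 42)
  # scale the observations by exp(-eta_cl) effect: regenerate with a known
  # individual clearance by editing the subject's GFR-implied CL through DV
  rows <- ds
  obs <- rows$EVID == 0
  sc <- list(weight = rows$WT[1], gfr = rows$GFR[1])
  p_true <- individual_params(population_model(), sc, log(1.5), 0)
  drow <- rows[rows$EVID == 1, ]
  rows$DV[obs] <- conc_at(p_true, dose_event(drow$TIME, drow$AMT, drow$AMT / drow$RATE),
                          rows$TIME[obs])
  rows$BLQ[obs] <- 0
  ebe <- map_estimate(population_model(sigma2_prop = 1e-8, sigma2_add = 1e-10), rows)
  expect_equal(ebe$eta_cl, log(1.5), tolerance = 0.01)
  expect_lt(abs(ebe$eta_v1), 0.01)
  # deterministic given data
  ebe2 <- map_estimate(population_model(sigma2_prop = 1e-8, sigma2_add = 1e-10), rows)
  expect_identical(ebe, ebe2)
})

test_that("sparse sampling shrinks MAP effects toward zero", {
  pm <- population_model()
  sparse <- study_design(
    "SPARSE", c(2, 6),
    schedule = list(list(age_max = Inf, times = c(3))),
    lloq = 1e-6,
    regimen_rule = structure(regimen(15, 24, infusion_duration = 2),
                             single_dose = TRUE)
  )
  ds <- simulate_study(sparse, pm, n = 150, seed = 43)
  pop <- sample_population(
    population_spec(150, age_groups = list(c(2, 6)), seed = 43), pm = pm)
  ebe <- map_estimate(pm, ds)
  # estimated magnitudes are smaller than the generating magnitudes on
  # average (shrinkage), matched by the shared seed
  expect_lt(mean(abs(ebe$eta_cl)), mean(abs(pop$eta_cl)))
  expect_lt(mean(abs(ebe$eta_v1)), mean(abs(pop$eta_v1)))
  expect_error(map_estimate(pm, ds[ds$EVID == 1, ]), "quantifiable")
})

test_that("NPDE is calibrated under self-simulation and flags misfit", {
  pm <- population_model()
  ds <- simulate_study(builtin_design("CSI-1006"), pm, n = 180, seed = 44)
  res <- npde(ds, pm, n_sim = 500, seed = 45)
  n_obs <- nrow(res$table)
  expect_gte(n_obs, 900)
  expect_lt(abs(res$mean), 0.1)
  expect_gt(res$var, 0.85)
  expect_lt(res$var, 1.15)
  # halved clearance in the evaluation model: simulations overshoot the
  # data, pushing npde negative
  pm_bad <- population_model(cl_gfr_slope = pm$cl_gfr_slope / 2)
  bad <- npde(ds, pm_bad, n_sim = 500, seed = 45)
  expect_lt(bad$mean, -0.5)
  # an observation far above every replicate lands at the positive extreme
  ds1 <- simulate_study(rich_design(c(2, 6)), pm, n = 1, seed = 46)
  i <- which(ds1$EVID == 0)[5]
  ds1$DV[i] <- ds1$DV[i] * 50
  r1 <- npde(ds1, pm, n_sim = 500, seed = 47)
  expect_equal(max(r1$table$npde), qnorm((500 + 0.5) / 501), tolerance = 1e-9)
})

test_that("PC-VPC is calibrated under self-simulation and detects scale misfit", {
  pm <- population_model()
  ds <- simulate_study(builtin_design("CSI-1006"), pm, n = 120, seed = 48)
  v <- pc_vpc(ds, pm, n_sim = 150, seed = 49)
  # percentile ordering in every bin
  expect_true(all(v$obs_p5 <= v$obs_p50 & v$obs_p50 <= v$obs_p95))
  expect_true(all(v$sim_p50_lo <= v$sim_p50_hi))
  # observed medians fall inside the simulated 90% CI at about the nominal
  # rate: pooled over seeds, allow two binomial standard errors below 90%
  inside <- logical(0)
  for (s in 1:3) {
    dss <- simulate_study(builtin_design("CSI-1006"), pm, n = 120, seed = 60 + s)
    vs <- pc_vpc(dss, pm, n_sim = 120, seed = 70 + s)
    inside <- c(inside, vs$obs_p50 >= vs$sim_p50_lo & vs$obs_p50 <= vs$sim_p50_hi)
  }
  expect_gte(mean(inside), 0.9 - 2 * sqrt(0.9 * 0.1 / length(inside)))
  # doubling the observations shifts observed percentiles x2 but leaves the
  # simulated bands unchanged
  ds2 <- ds
  ds2$DV[ds2$EVID == 0] <- ds2$DV[ds2$EVID == 0] * 2
  v2 <- pc_vpc(ds2, pm, n_sim = 150, seed = 49)
  expect_equal(v2$obs_p50, 2 * v$obs_p50, tolerance = 1e-9)
  expect_equal(v2$sim_p50_lo, v$sim_p50_lo, tolerance = 1e-9)
  outside <- v2$obs_p50 < v2$sim_p50_lo | v2$obs_p50 > v2$sim_p50_hi
  expect_gt(mean(outside), 0.5)
  expect_error(pc_vpc(ds, pm, n_sim = 50), "at least 100")
})

test_that("covariate model is recovered from rich synthetic data", {
  pm <- population_model()
  # noise-free, no-IIV limit: slope and exponent recovered to < 1%
  pm0 <- population_model(omega2_cl = 0, omega2_v1 = 0,
                          sigma2_prop = 1e-10, sigma2_add = 1e-12)
  ds0 <- simulate_study(rich_design(), pm0, n = 60, seed = 50)
  rec0 <- recover_covariate_model(ds0, pm0)
  expect_lt(abs(rec0$rel_error["cl_gfr_slope"]), 0.01)
  expect_lt(abs(rec0$vol_exponent - 0.911), 0.01)
  expect_lt(rec0$omega2_cl, 0.005)
  # full noise: tolerances from the stochastic design
  ds <- simulate_study(rich_design(), pm, n = 200, seed = 51)
  rec <- recover_covariate_model(ds, pm)
  expect_lt(abs(rec$rel_error["cl_gfr_slope"]), 0.05)
  expect_lt(abs(rec$vol_exponent - 0.911), 0.05)
  expect_equal(rec$omega2_cl, 0.0547, tolerance = 0.35)
})
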