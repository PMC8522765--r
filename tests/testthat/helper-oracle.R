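# Independent numerical oracle: adaptive ODE integration of the
# three-compartment infusion system (deSolve), kept fully separate from the
# package's analytic solution path.
ode_oracle <- function(p, doses, times, rtol = 1e-10, atol = 1e-12) {
  k <- to_micro(p)
  rhs <- function(t, A, parms) {
    list(c(
      parms - (k$k10 + k$k12 + k$k13) * A[1] + k$k21 * A[2] + k$k31 * A[3],
      k$k12 * A[1] - k$k21 * A[2],
      k$k13 * A[1] - k$k31 * A[3]
    ))
  }
  # integrate piecewise, restarting at every infusion on/off switch so the
  # right-hand side is smooth within each call
  starts <- doses$start_time
  ends <- doses$start_time + doses$duration
  brk <- sort(unique(c(0, starts, ends, times)))
  state <- c(0, 0, 0)
  vals <- setNames(rep(NA_real_, length(brk)), format(brk, digits = 15))
  vals[1] <- state[1]
  for (i in seq_len(length(brk) - 1)) {
    t0 <- brk[i]; t1 <- brk[i + 1]
    rate <- sum(doses$amount[starts <= t0 + 1e-12 & ends > t0 + 1e-12] /
                doses$duration[starts <= t0 + 1e-12 & ends > t0 + 1e-12])
    out <- deSolve::ode(state, c(t0, t1), rhs, parms = rate,
                        rtol = rtol, atol = atol, method = "lsoda")
    state <- out[nrow(out), 2:4]
    vals[i + 1] <- state[1]
  }
  conc <- vals[match(times, brk)] / p$v1
  pmax(unname(conc), 0)
}

# random positive parameter/dose configuration spanning neonatal to adult
# magnitudes
random_config <- function() {
  p <- macro_params(
    cl = stats::runif(1, 0.05, 20),
    v1 = stats::runif(1, 0.5, 30),
    q1 = stats::runif(1, 0.01, 5),
    vp1 = stats::runif(1, 0.5, 80),
    q2 = stats::runif(1, 0.05, 10),
    vp2 = stats::runif(1, 0.2, 15)
  )
  n_dose <- sample(1:3, 1)
  doses <- dose_event(
    start_time = sort(stats::runif(n_dose, 0, 16)),
    amount = stats::runif(n_dose, 10, 500),
    duration = stats::runif(n_dose, 0.5, 4)
  )
  list(p = p, doses = doses)
}

# the typical neonate of the single-dose neonatal study: median covariates
# (GFR 5.90 ml/min, weight 3.98 kg) under the shipped model
typical_neonate <- function(pm = population_model()) {
  typical_params(pm, list(weight = 3.98, gfr = 5.90))
}
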