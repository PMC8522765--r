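#' Three-compartment macro-constant parameter set
#'
#' Constructs and validates the macro-constant parameterization of a
#' mammillary three-compartment disposition model with first-order
#' elimination from the central compartment. Units are fixed by contract to
#' mg / liters / hours, so that simulated concentrations come out in
#' micrograms per milliliter (equivalently mg/liter) without conversion.
#'
#' @param cl Clearance from the central compartment, liters/h.
#' @param v1 Central volume of distribution, liters.
#' @param q1 Distributional clearance central <-> peripheral 1, liters/h.
#'   May be zero to collapse peripheral compartment 1 (reduced model).
#' @param vp1 Peripheral-1 volume, liters. Ignored dynamically when `q1 = 0`.
#' @param q2 Distributional clearance central <-> peripheral 2, liters/h.
#' @param vp2 Peripheral-2 volume, liters.
#'
#' @return An object of class `macro_params` (named list of the six values).
#' @export
macro_params <- function(cl, v1, q1, vp1, q2, vp2) {
  vals <- c(cl = cl, v1 = v1, q1 = q1, vp1 = vp1, q2 = q2, vp2 = vp2)
  if (any(!is.finite(vals))) {
    stop("macro_params: all parameters must be finite numbers")
  }
  if (v1 <= 0 || vp1 <= 0 || vp2 <= 0) {
    stop("macro_params: v1, vp1 and vp2 must be strictly positive")
  }
  if (cl < 0) {
    stop("macro_params: cl must be nonnegative (zero only as a degenerate limit)")
  }
  if (q1 < 0 || q2 < 0) {
    stop("macro_params: q1 and q2 must be nonnegative")
  }
  structure(as.list(vals), class = "macro_params")
}

#' @export
print.macro_params <- function(x, ...) {
  cat("Three-compartment macro parameters (mg/L/h unit system):\n")
  cat(sprintf("  CL  = %.4g L/h    V1  = %.4g L\n", x$cl, x$v1))
  cat(sprintf("  Q1  = %.4g L/h    Vp1 = %.4g L\n", x$q1, x$vp1))
  cat(sprintf("  Q2  = %.4g L/h    Vp2 = %.4g L\n", x$q2, x$vp2))
  invisible(x)
}

#' Convert macro constants to first-order micro rate constants
#'
#' Standard reparameterization: `k10 = cl/v1`, `k12 = q1/v1`,
#' `k21 = q1/vp1`, `k13 = q2/v1`, `k31 = q2/vp2` (all 1/h).
#'
#' @param p A [macro_params()] object.
#' @return Named list of class `micro_rates` with elements
#'   `k10, k12, k21, k13, k31`.
#' @export
to_micro <- function(p) {
  stopifnot(inherits(p, "macro_params"))
  structure(
    list(
      k10 = p$cl / p$v1,
      k12 = p$q1 / p$v1,
      k21 = p$q1 / p$vp1,
      k13 = p$q2 / p$v1,
      k31 = p$q2 / p$vp2
    ),
    class = "micro_rates"
  )
}

#' Disposition rate matrix of the three-compartment model
#'
#' Returns the 3x3 matrix `M` such that `dA/dt = M A + input`, where `A` is
#' the vector of compartment amounts (central, peripheral 1, peripheral 2).
#'
#' @param p A [macro_params()] object.
#' @return 3x3 numeric matrix.
#' @export
rate_matrix <- function(p) {
  k <- to_micro(p)
  matrix(
    c(
      -(k$k10 + k$k12 + k$k13), k$k21, k$k31,
      k$k12, -k$k21, 0,
      k$k13, 0, -k$k31
    ),
    nrow = 3, byrow = TRUE
  )
}

#' Infusion dosing event
#'
#' A zero-order input of `amount` mg delivered over `duration` h starting at
#' `start_time` h. All regimens modeled here are infusions (2 h or 4 h);
#' a bolus can be approximated with a very short duration.
#'
#' @param start_time Start of the infusion, h since time origin (>= 0).
#' @param amount Dose amount, mg (> 0).
#' @param duration Infusion length, h (> 0).
#' @return A one-row data.frame of class `dose_event`.
#' @export
dose_event <- function(start_time, amount, duration) {
  if (any(start_time < 0) || any(amount <= 0) || any(duration <= 0)) {
    stop("dose_event: require start_time >= 0, amount > 0, duration > 0")
  }
  structure(
    data.frame(start_time = start_time, amount = amount, duration = duration),
    class = c("dose_event", "data.frame")
  )
}

# Internal: eigendecomposition of the disposition matrix with a guard for
# (measure-zero) repeated eigenvalues, where the closed form is singular.
# If two eigenvalues coincide to < 1e-9 relative, the micro rates are
# perturbed by 1e-9 relative and the decomposition redone, with a warning.
.pk_eigen <- function(p) {
  M <- rate_matrix(p)
  eg <- eigen(M)
  lam <- eg$values
  if (is.complex(lam)) {
    # mammillary models with nonnegative rates have real spectra; tiny
    # imaginary parts are numerical noise
    lam <- Re(lam)
    eg$vectors <- Re(eg$vectors)
  }
  scale <- max(abs(lam), 1e-12)
  gaps <- abs(diff(sort(lam)))
  # a repeated zero eigenvalue (both q's zero) is fine: those modes carry no
  # mass; only repeated *distinct-mode* eigenvalues are degenerate for the
  # closed form
  nz <- sort(lam[abs(lam) > 1e-14 * scale])
  if (length(nz) >= 2 && min(abs(diff(nz))) < 1e-9 * scale) {
    warning("near-repeated disposition eigenvalues; perturbing parameters by 1e-9 relative")
    p2 <- macro_params(
      cl = p$cl * (1 + 1e-9), v1 = p$v1,
      q1 = p$q1 * (1 - 1e-9), vp1 = p$vp1 * (1 + 2e-9),
      q2 = p$q2, vp2 = p$vp2 * (1 - 2e-9)
    )
    M <- rate_matrix(p2)
    eg <- eigen(M)
    lam <- Re(eg$values)
    eg$vectors <- Re(eg$vectors)
  }
  V <- eg$vectors
  Vi <- solve(V)
  list(lam = lam, V = V, Vi = Vi)
}

# phi(lambda, tau)   = integral_0^tau exp(lambda s) ds = expm1(lambda tau)/lambda
# psi(lambda, tau)   = integral_0^tau phi(lambda, s) ds
# both with removable singularities at lambda = 0
.phi <- function(lam, tau) {
  out <- outer(lam, tau, function(l, t) ifelse(abs(l) < 1e-300, t, expm1(l * t) / l))
  out
}
.psi <- function(lam, tau) {
  outer(lam, tau, function(l, t) {
    ifelse(abs(l) < 1e-300, t^2 / 2, (expm1(l * t) / l - t) / l)
  })
}

# Internal engine shared by simulation, pointwise evaluation and analytic
# integration. Splits time into segments at infusion on/off boundaries and
# propagates the modal coordinates exactly within each segment.
#
# Returns a list of segments, each with: t0 (start), t1 (end, possibly Inf),
# rate (mg/h into central), c0 (modal state at t0), plus the decomposition.
.pk_segments <- function(p, doses, t_max = Inf) {
  dec <- .pk_eigen(p)
  lam <- dec$lam
  Vi1 <- dec$Vi[, 1] # input enters the central compartment only
  starts <- doses$start_time
  ends <- doses$start_time + doses$duration
  brk <- sort(unique(c(0, starts, ends)))
  brk <- brk[brk < t_max]
  if (length(brk) == 0 || brk[1] > 0) brk <- c(0, brk)
  seg_t0 <- brk
  seg_t1 <- c(brk[-1], Inf)
  c0 <- numeric(3) # modal coordinates of the (zero) initial state
  segs <- vector("list", length(seg_t0))
  for (i in seq_along(seg_t0)) {
    active <- starts <= seg_t0[i] + 1e-12 & ends > seg_t0[i] + 1e-12
    rate <- sum(doses$amount[active] / doses$duration[active])
    segs[[i]] <- list(t0 = seg_t0[i], t1 = seg_t1[i], rate = rate, c0 = c0)
    if (is.finite(seg_t1[i])) {
      tau <- seg_t1[i] - seg_t0[i]
      cb <- Vi1 * rate
      c0 <- exp(lam * tau) * c0 + drop(.phi(lam, tau)) * cb
    }
  }
  list(segs = segs, dec = dec)
}

# central-compartment amount at arbitrary times, given prepared segments
.central_amount <- function(prep, times) {
  lam <- prep$dec$lam
  V1row <- prep$dec$V[1, ]
  Vi1 <- prep$dec$Vi[, 1]
  out <- numeric(length(times))
  seg_starts <- vapply(prep$segs, `[[`, numeric(1), "t0")
  idx <- findInterval(times, seg_starts)
  for (s in unique(idx)) {
    sel <- idx == s
    if (s == 0) {
      out[sel] <- 0
      next
    }
    seg <- prep$segs[[s]]
    tau <- times[sel] - seg$t0
    E <- exp(outer(lam, tau))
    P <- .phi(lam, tau)
    cb <- Vi1 * seg$rate
    out[sel] <- drop(V1row %*% (E * seg$c0 + P * cb))
  }
  pmax(out, 0)
}

# all three compartment amounts at one time (used in mass-balance tests)
.amounts_at <- function(prep, t) {
  lam <- prep$dec$lam
  seg_starts <- vapply(prep$segs, `[[`, numeric(1), "t0")
  s <- findInterval(t, seg_starts)
  if (s == 0) return(numeric(3))
  seg <- prep$segs[[s]]
  tau <- t - seg$t0
  cb <- prep$dec$Vi[, 1] * seg$rate
  drop(prep$dec$V %*% (exp(lam * tau) * seg$c0 + drop(.phi(lam, tau)) * cb))
}

#' Simulate a concentration-time profile
#'
#' Exact solution of the linear three-compartment system under a sequence of
#' zero-order infusions, by eigendecomposition of the disposition matrix and
#' piecewise propagation over infusion on/off segments (superposed over
#' doses). Concentration is the central amount divided by `v1`, in
#' micrograms/ml. The solution is continuous at segment boundaries.
#'
#' @param p A [macro_params()] object.
#' @param doses A [dose_event()] data.frame (one row per dose), sorted by
#'   `start_time`.
#' @param times Strictly increasing evaluation grid, h.
#' @return Object of class `concentration_profile`: list with `times`,
#'   `conc`, and the inputs.
#' @export
simulate_profile <- function(p, doses, times) {
  stopifnot(inherits(p, "macro_params"), is.numeric(times))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("simulate_profile: times must be strictly increasing")
  }
  doses <- doses[order(doses$start_time), , drop = FALSE]
  prep <- .pk_segments(p, doses)
  conc <- .central_amount(prep, times) / p$v1
  structure(
    list(times = times, conc = conc, params = p, doses = doses, prep = prep),
    class = "concentration_profile"
  )
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf(
    "Concentration profile: %d time points over [%g, %g] h, Cmax(grid) = %.3g ug/ml\n",
    length(x$times), min(x$times), max(x$times), max(x$conc)
  ))
  invisible(x)
}

#' Evaluate the analytic concentration at arbitrary times
#'
#' Pointwise exact evaluation (same closed form as [simulate_profile()]),
#' used for Cmax refinement between grid points.
#'
#' @inheritParams simulate_profile
#' @param t Numeric vector of times, h.
#' @return Numeric vector of concentrations, ug/ml.
#' @export
conc_at <- function(p, doses, t) {
  doses <- doses[order(doses$start_time), , drop = FALSE]
  prep <- .pk_segments(p, doses)
  .central_amount(prep, t) / p$v1
}

#' Area under the concentration-time curve
#'
#' `method = "analytic"` integrates the piecewise closed form exactly
#' (`t1` may be `Inf`); `method = "trapezoid"` integrates a simulated
#' profile's grid linearly.
#'
#' @param x Either a `concentration_profile` (for the trapezoid method, or
#'   analytic using its stored parameters/doses) or a [macro_params()] object
#'   (analytic method; supply `doses`).
#' @param t0,t1 Integration limits, h (`t0 < t1`).
#' @param method `"analytic"` or `"trapezoid"`.
#' @param doses Required when `x` is a `macro_params` object.
#' @return AUC in ug*h/ml.
#' @export
auc <- function(x, t0 = 0, t1 = Inf, method = c("analytic", "trapezoid"),
                doses = NULL) {
  method <- match.arg(method)
  if (t1 <= t0) stop("auc: t1 must exceed t0")
  if (method == "trapezoid") {
    if (!inherits(x, "concentration_profile")) {
      stop("auc: trapezoid method requires a concentration_profile")
    }
    if (!is.finite(t1)) stop("auc: trapezoid method requires finite t1")
    tt <- x$times
    if (t0 < min(tt) - 1e-9 || t1 > max(tt) + 1e-9) {
      stop("auc: [t0, t1] outside the simulated span")
    }
    # restrict to [t0, t1], interpolating the endpoints
    cc <- x$conc
    keep <- tt > t0 & tt < t1
    tgrid <- c(t0, tt[keep], t1)
    cgrid <- c(
      stats::approx(tt, cc, xout = t0, rule = 2)$y,
      cc[keep],
      stats::approx(tt, cc, xout = t1, rule = 2)$y
    )
    return(sum(diff(tgrid) * (utils::head(cgrid, -1) + utils::tail(cgrid, -1)) / 2))
  }
  if (inherits(x, "concentration_profile")) {
    p <- x$params
    doses <- x$doses
  } else {
    p <- x
    if (is.null(doses)) stop("auc: analytic method on macro_params requires doses")
  }
  doses <- doses[order(doses$start_time), , drop = FALSE]
  prep <- .pk_segments(p, doses)
  lam <- prep$dec$lam
  V1row <- prep$dec$V[1, ]
  Vi1 <- prep$dec$Vi[, 1]
  total <- 0
  for (seg in prep$segs) {
    a <- max(seg$t0, t0)
    b <- min(seg$t1, t1)
    if (b <= a) next
    cb <- Vi1 * seg$rate
    int_seg <- function(tau) {
      # integral of central amount over [seg$t0, seg$t0 + tau]
      drop(V1row %*% (drop(.phi(lam, tau)) * seg$c0 + drop(.psi(lam, tau)) * cb))
    }
    if (!is.finite(b)) {
      if (seg$rate != 0) stop("auc: infinite horizon during an active infusion")
      if (any(lam >= -1e-300 & abs(drop(seg$c0)) > 1e-12)) {
        stop("auc: non-decaying mode with mass; infinite AUC")
      }
      nzl <- lam < 0
      tail_int <- drop(V1row[nzl] %*% (-seg$c0[nzl] / lam[nzl]))
      total <- total + tail_int - if (a > seg$t0) int_seg(a - seg$t0) else 0
    } else {
      total <- total + int_seg(b - seg$t0) - if (a > seg$t0) int_seg(a - seg$t0) else 0
    }
  }
  total / p$v1
}

#' Steady-state volume of distribution
#'
#' Sum of the three compartment volumes, `v1 + vp1 + vp2` (liters).
#'
#' @param p A [macro_params()] object.
#' @return Vss in liters.
#' @export
vss <- function(p) {
  stopifnot(inherits(p, "macro_params"))
  p$v1 + p$vp1 + p$vp2
}

#' Disposition phase half-lives
#'
#' Half-lives `-ln(2)/lambda` for the eigenvalues of the disposition matrix,
#' sorted increasing (alpha, beta, gamma phases). For positive mammillary
#' parameters all three are positive and distinct. If `q1` and/or `q2` are
#' zero the corresponding phases are undefined (zero eigenvalues with no
#' mass) and only the defined ones are returned.
#'
#' @param p A [macro_params()] object.
#' @return Numeric vector of 1-3 half-lives, h, sorted increasing.
#' @export
phase_half_lives <- function(p) {
  dec <- .pk_eigen(p)
  lam <- dec$lam
  lam <- lam[lam < -1e-12 * max(abs(lam), 1e-12)]
  sort(-log(2) / lam)
}

#' Maximum concentration over a profile
#'
#' Grid maximum refined by a local analytic search within the bracketing
#' grid interval (the closed form is evaluated directly, so the refinement
#' does not depend on grid resolution).
#'
#' @param profile A `concentration_profile`.
#' @param refine Logical; if `TRUE` (default) run the local search.
#' @return Cmax in ug/ml.
#' @export
cmax <- function(profile, refine = TRUE) {
  stopifnot(inherits(profile, "concentration_profile"))
  i <- which.max(profile$conc)
  best <- profile$conc[i]
  if (!refine || length(profile$times) < 3 || is.null(profile$prep)) return(best)
  lo <- profile$times[max(1, i - 1)]
  hi <- profile$times[min(length(profile$times), i + 1)]
  if (hi <= lo) return(best)
  v1 <- profile$params$v1
  prep <- profile$prep
  opt <- stats::optimize(
    function(t) .central_amount(prep, t) / v1,
    lower = lo, upper = hi, maximum = TRUE, tol = 1e-8
  )
  max(best, opt$objective)
}
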