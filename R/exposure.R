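#' PK-PD target-attainment configuration
#'
#' @param mic MIC, ug/ml (default 4, the non-species-specific ceftobiprole
#'   PK-PD breakpoint).
#' @param free_fraction Unbound fraction (default 0.84, i.e. 16% protein
#'   binding carried over from adults).
#' @param grid_step Simulation grid step, h (default 0.25 = 15 min).
#' @param horizon Simulation horizon, h (default 24: day-1 metrics).
#' @param targets %fT>MIC thresholds evaluated, percent of the horizon.
#' @return Object of class `pta_config`.
#' @export
pta_config <- function(mic = 4, free_fraction = 0.84, grid_step = 0.25,
                       horizon = 24, targets = c(30, 40, 50, 60)) {
  if (free_fraction <= 0 || free_fraction > 1) {
    stop("pta_config: free_fraction must be in (0, 1]")
  }
  if (abs(horizon / grid_step - round(horizon / grid_step)) > 1e-9) {
    stop("pta_config: grid_step must divide horizon")
  }
  structure(
    list(mic = mic, free_fraction = free_fraction, grid_step = grid_step,
         horizon = horizon, targets = sort(targets)),
    class = "pta_config"
  )
}

#' Total-concentration threshold equivalent to the free-drug MIC
#'
#' The free-drug MIC expressed on the total-concentration scale,
#' `mic / free_fraction` (e.g. 4 / 0.84 = 4.76 ug/ml).
#'
#' @param cfg A [pta_config()].
#' @return Threshold in ug/ml of total drug.
#' @export
total_threshold <- function(cfg = pta_config()) cfg$mic / cfg$free_fraction

# time above threshold on [0, horizon] with linear interpolation of the
# crossing times between grid points
.time_above <- function(times, conc, threshold, horizon) {
  keep <- times <= horizon + 1e-9
  t <- times[keep]
  y <- conc[keep] - threshold
  above <- y > 0
  tt <- 0
  for (i in seq_len(length(t) - 1)) {
    dt <- t[i + 1] - t[i]
    if (above[i] && above[i + 1]) {
      tt <- tt + dt
    } else if (above[i] != above[i + 1]) {
      # linear crossing within the interval
      frac <- y[i] / (y[i] - y[i + 1])
      tt <- tt + if (above[i]) dt * frac else dt * (1 - frac)
    }
  }
  tt
}

#' Day-1 exposure metrics for one profile
#'
#' Cmax (grid maximum, analytically refined when the profile carries its
#' parameters), AUC over 0-24 h and 0-8 h by trapezoid on the grid, and
#' %fT>MIC: the percentage of the horizon during which free drug
#' (total x free_fraction) exceeds the MIC, with linear interpolation of
#' threshold crossings between grid points.
#'
#' @param profile A `concentration_profile` spanning `[0, horizon]`.
#' @param cfg A [pta_config()].
#' @return Object of class `exposure_metrics`: list with `cmax`,
#'   `auc_0_24`, `auc_0_8`, `ft_gt_mic`.
#' @export
exposure_metrics <- function(profile, cfg = pta_config()) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (max(profile$times) < cfg$horizon - 1e-9) {
    stop("exposure_metrics: profile does not span the configured horizon")
  }
  thr <- total_threshold(cfg)
  ft <- 100 * .time_above(profile$times, profile$conc, thr, cfg$horizon) /
    cfg$horizon
  structure(
    list(
      cmax = cmax(profile),
      auc_0_24 = auc(profile, 0, min(24, max(profile$times)), "trapezoid"),
      auc_0_8 = auc(profile, 0, 8, "trapezoid"),
      ft_gt_mic = ft
    ),
    class = "exposure_metrics"
  )
}

#' Simulate exposures for a dosed population
#'
#' For each virtual subject: pick the regimen (optimized policy column or a
#' fixed regimen), expand dose events with the 500 mg cap, build individual
#' macro parameters (typical covariate model x the subject's random
#' effects), simulate the day-1 profile on the configured grid, and compute
#' exposure metrics.
#'
#' @param pop A `virtual_population`.
#' @param pm A [population_model()].
#' @param cfg A [pta_config()].
#' @param policy `"optimized"` (the age/weight rule) or a single
#'   [regimen()] applied to everyone.
#' @param renal_column Column of the optimized matrix used for dosing
#'   (`"normal"` by default — the normal-function regimens; `NULL` to
#'   derive each subject's category from their `gfr_norm`).
#' @param use_iiv Include the population's interindividual variability
#'   (default TRUE; FALSE gives typical-subject profiles).
#' @return data.frame: one row per subject with id, group, regimen label,
#'   cmax, auc_0_24, auc_0_8, ft_gt_mic.
#' @export
cohort_exposures <- function(pop, pm = population_model(),
                             cfg = pta_config(), policy = "optimized",
                             renal_column = "normal", use_iiv = TRUE) {
  times <- seq(0, cfg$horizon, by = cfg$grid_step)
  n <- nrow(pop)
  out <- data.frame(
    id = pop$id, group = pop$group,
    regimen = character(n), cmax = numeric(n), auc_0_24 = numeric(n),
    auc_0_8 = numeric(n), ft_gt_mic = numeric(n)
  )
  age <- pop$age_years; wt <- pop$weight; gfrn <- pop$gfr_norm
  gfr <- pop$gfr; eta_cl <- pop$eta_cl; eta_v1 <- pop$eta_v1
  for (i in seq_len(n)) {
    s <- list(age_years = age[i], weight = wt[i], gfr = gfr[i])
    r <- if (inherits(policy, "regimen")) policy else {
      if (is.null(renal_column)) {
        optimized_regimen(age[i], wt[i], gfr_norm = gfrn[i])
      } else {
        optimized_regimen(age[i], wt[i], category = renal_column)
      }
    }
    doses <- expand_doses(r, wt[i], cfg$horizon)
    p <- if (use_iiv) {
      individual_params(pm, s, eta_cl[i], eta_v1[i])
    } else {
      typical_params(pm, s)
    }
    prof <- simulate_profile(p, doses, times)
    m <- exposure_metrics(prof, cfg)
    out$regimen[i] <- sprintf("%g mg/kg q%gh", r$dose_per_kg, r$interval)
    out$cmax[i] <- m$cmax
    out$auc_0_24[i] <- m$auc_0_24
    out$auc_0_8[i] <- m$auc_0_8
    out$ft_gt_mic[i] <- m$ft_gt_mic
  }
  out
}

#' Probability of PK-PD target attainment
#'
#' Per age group and %fT>MIC threshold, the percentage of subjects whose
#' %fT>MIC is at or above the threshold.
#'
#' @param metrics Per-subject exposure table (from [cohort_exposures()]):
#'   needs columns `group` and `ft_gt_mic`.
#' @param cfg A [pta_config()] (supplies the thresholds).
#' @return Object of class `pta_result`: data.frame with group, target,
#'   attainment (percent), n.
#' @export
pta <- function(metrics, cfg = pta_config()) {
  if (nrow(metrics) == 0) stop("pta: empty metric set")
  groups <- unique(metrics$group)
  rows <- list()
  for (g in groups) {
    ft <- metrics$ft_gt_mic[metrics$group == g]
    if (length(ft) == 0) stop("pta: empty group ", g)
    for (tg in cfg$targets) {
      rows[[length(rows) + 1]] <- data.frame(
        group = g, target = tg,
        attainment = 100 * mean(ft >= tg), n = length(ft)
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pta_result", "data.frame")
  out
}

#' @export
print.pta_result <- function(x, ...) {
  wide <- stats::reshape(
    as.data.frame(x)[, c("group", "target", "attainment")],
    idvar = "target", timevar = "group", direction = "wide"
  )
  names(wide) <- sub("^attainment\\.", "", names(wide))
  cat("PK-PD target attainment (% of subjects at or above each %fT>MIC target)\n")
  print(wide, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare pediatric exposures to an adult reference distribution
#'
#' Flags subjects whose metric falls outside the adult mean +- 2 SD band.
#' The adult steady-state reference values (500 mg q8h) are not shipped
#' with the model and must be supplied.
#'
#' @param metrics Per-subject exposure table.
#' @param adult_ref Named list with `mean` and `sd` of the adult reference
#'   for the chosen metric.
#' @param metric Which column to compare (`"auc_0_24"` or `"cmax"`).
#' @return List with the flagged per-subject table (`flag` in
#'   `"below"`/`"within"`/`"above"`) and a per-group summary of the
#'   fractions outside the band.
#' @export
compare_to_adult <- function(metrics, adult_ref, metric = c("auc_0_24", "cmax")) {
  metric <- match.arg(metric)
  if (missing(adult_ref) || is.null(adult_ref) ||
      is.null(adult_ref$mean) || is.null(adult_ref$sd)) {
    stop("compare_to_adult: adult reference (mean, sd) must be supplied; ",
         "no default is available")
  }
  lo <- adult_ref$mean - 2 * adult_ref$sd
  hi <- adult_ref$mean + 2 * adult_ref$sd
  x <- metrics[[metric]]
  flag <- ifelse(x > hi, "above", ifelse(x < lo, "below", "within"))
  per_subject <- cbind(metrics, flag = flag)
  summary <- stats::aggregate(
    list(frac_above = flag == "above", frac_below = flag == "below"),
    by = list(group = metrics$group), FUN = mean
  )
  list(per_subject = per_subject, summary = summary, band = c(lo, hi))
}
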