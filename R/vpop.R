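# Embedded smoothed growth reference (median weight/height by age and sex,
# with age-dependent coefficients of variation). Values are a compact
# approximation of US national growth-chart medians; within-age variation is
# log-normal, with a single size z-score shared between weight and height
# per subject (perfect weight-height rank correlation).
.growth_table <- data.frame(
  age = c(0, 0.125, 0.25, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 10, 12, 14, 16, 18),
  wt_m = c(3.5, 5.1, 6.4, 7.9, 10.3, 11.5, 12.7, 14.3, 16.3, 18.5, 20.8,
           25.6, 31.9, 40.5, 51.0, 60.9, 68.0),
  wt_f = c(3.4, 4.7, 5.8, 7.2, 9.5, 10.8, 12.1, 13.9, 15.9, 18.0, 20.2,
           25.8, 32.9, 41.5, 49.4, 53.9, 56.7),
  ht_m = c(50.0, 56.5, 61.0, 67.6, 75.7, 82.0, 87.0, 96.0, 103.0, 110.0,
           116.0, 128.0, 138.5, 149.0, 163.5, 173.5, 176.5),
  ht_f = c(49.3, 55.3, 59.5, 65.9, 74.0, 80.5, 86.0, 95.0, 102.0, 109.0,
           115.0, 127.5, 138.0, 151.5, 160.0, 162.5, 163.0),
  cv_wt = c(0.14, 0.13, 0.12, 0.11, 0.11, 0.11, 0.11, 0.12, 0.13, 0.14,
            0.15, 0.17, 0.19, 0.20, 0.20, 0.19, 0.19),
  cv_ht = c(0.035, 0.033, 0.032, 0.030, 0.030, 0.031, 0.032, 0.034, 0.036,
            0.037, 0.038, 0.040, 0.042, 0.044, 0.040, 0.035, 0.033)
)

#' Growth reference for the virtual pediatric population
#'
#' Smoothed median and coefficient-of-variation curves for weight-for-age
#' and height-for-age over 0-18 years, by sex. Medians are interpolated
#' log-linearly in age; within-age variation is log-normal.
#'
#' @return Object of class `growth_reference`.
#' @export
growth_reference <- function() {
  structure(list(table = .growth_table), class = "growth_reference")
}

#' @export
print.growth_reference <- function(x, ...) {
  cat("Growth reference: smoothed medians + CVs, 0-18 y, both sexes,",
      nrow(x$table), "age knots\n")
  invisible(x)
}

# median weight/height and CVs at given ages for one sex
.growth_at <- function(gr, age, sex) {
  tb <- gr$table
  wcol <- if (sex == "male") tb$wt_m else tb$wt_f
  hcol <- if (sex == "male") tb$ht_m else tb$ht_f
  interp_log <- function(y) exp(stats::approx(tb$age, log(y), xout = age, rule = 2)$y)
  list(
    wt = interp_log(wcol),
    ht = interp_log(hcol),
    cv_wt = stats::approx(tb$age, tb$cv_wt, xout = age, rule = 2)$y,
    cv_ht = stats::approx(tb$age, tb$cv_ht, xout = age, rule = 2)$y
  )
}

#' Virtual-population specification
#'
#' @param n_total Total number of virtual subjects (>= number of groups).
#' @param age_groups List of `c(min, max)` half-open age intervals in years;
#'   defaults to birth-<3 mo, 3 mo-<2 y, 2-<6 y, 6-<12 y, 12-<18 y. Must be
#'   non-overlapping and exhaustive over [0, 18).
#' @param male_fraction Probability a subject is male.
#' @param renal_category `"normal"`, `"moderate"` or `"severe"`.
#' @param gfr_cv Log-normal coefficient of variation of the spread of
#'   normal-function GFR around the maturation curve (default 0.15).
#' @param seed Optional integer seed.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n_total = 5000,
                            age_groups = list(
                              c(0, 0.25), c(0.25, 2), c(2, 6),
                              c(6, 12), c(12, 18)
                            ),
                            male_fraction = 0.5,
                            renal_category = c("normal", "moderate", "severe"),
                            gfr_cv = 0.15,
                            seed = NULL) {
  renal_category <- match.arg(renal_category)
  if (n_total < length(age_groups)) {
    stop("population_spec: n_total must be at least the number of age groups")
  }
  lo <- vapply(age_groups, `[`, numeric(1), 1)
  hi <- vapply(age_groups, `[`, numeric(1), 2)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]; age_groups <- age_groups[o]
  if (any(hi <= lo) || any(abs(utils::head(hi, -1) - utils::tail(lo, -1)) > 1e-12)) {
    stop("population_spec: age groups must be non-overlapping and exhaustive")
  }
  structure(
    list(n_total = n_total, age_groups = age_groups,
         male_fraction = male_fraction, renal_category = renal_category,
         gfr_cv = gfr_cv, seed = seed),
    class = "population_spec"
  )
}

.group_label <- function(grp) {
  vapply(grp, function(g) {
    fmt <- function(a) {
      if (a < 2) sprintf("%gmo", round(a * 12)) else sprintf("%gy", a)
    }
    paste0("[", fmt(g[1]), ",", fmt(g[2]), ")")
  }, character(1))
}

#' Assign normal-renal-function GFR
#'
#' Evaluates the maturation curve at the subject's PMA and FFM and applies a
#' log-normal population spread (`cv` fractional coefficient of variation;
#' `cv = 0` disables the spread and the assignment is deterministic).
#'
#' @param pma Postmenstrual age, weeks.
#' @param ffm Fat-free mass, kg.
#' @param cv Log-normal CV of the spread (default 0.15).
#' @param rp [rhodin_params()].
#' @param z Optional pre-drawn standard-normal deviates (recycled); if
#'   `NULL` they are drawn from the current RNG stream.
#' @return GFR in ml/min.
#' @export
assign_gfr_normal <- function(pma, ffm, cv = 0.15, rp = rhodin_params(),
                              z = NULL) {
  base <- gfr_rhodin_ffm(pma, ffm, rp)
  if (cv <= 0) return(base)
  if (is.null(z)) z <- stats::rnorm(length(base))
  sdlog <- sqrt(log(1 + cv^2))
  base * exp(z * sdlog - sdlog^2 / 2)
}

#' Generate the virtual pediatric population
#'
#' Samples `n_total` subjects with equal counts per age group (+-1), ages
#' uniform within group, sex Bernoulli(`male_fraction`), body size from the
#' growth reference (shared log-normal z-score between weight and height),
#' PMA = postnatal age + 40 weeks (term gestation), FFM/BSA derived, and
#' normal-function GFR from the maturation curve with log-normal spread.
#' For `renal_category` "moderate"/"severe" the normalized GFR is then
#' resampled within the impairment band (see [impose_renal_impairment()]).
#' Interindividual random effects on CL and V1 are drawn per subject.
#'
#' @param spec A [population_spec()].
#' @param gr A [growth_reference()].
#' @param pm A [population_model()] (for the random-effect variances).
#' @param rp A [rhodin_params()].
#' @return A data.frame of class `virtual_population`: one row per subject
#'   with id, group, sex, age_years, pma, weight, height, ffm, bsa, gfr,
#'   gfr_norm, eta_cl, eta_v1.
#' @export
sample_population <- function(spec = population_spec(),
                              gr = growth_reference(),
                              pm = population_model(),
                              rp = rhodin_params()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  ng <- length(spec$age_groups)
  base <- spec$n_total %/% ng
  extra <- spec$n_total %% ng
  n_per <- rep(base, ng) + c(rep(1, extra), rep(0, ng - extra))
  rows <- vector("list", ng)
  for (g in seq_len(ng)) {
    n <- n_per[g]
    lim <- spec$age_groups[[g]]
    age <- stats::runif(n, lim[1], lim[2])
    sex <- ifelse(stats::runif(n) < spec$male_fraction, "male", "female")
    z <- stats::rnorm(n)
    wt <- ht <- numeric(n)
    for (s in c("male", "female")) {
      idx <- sex == s
      if (!any(idx)) next
      ga <- .growth_at(gr, age[idx], s)
      wt[idx] <- ga$wt * exp(z[idx] * sqrt(log(1 + ga$cv_wt^2)))
      ht[idx] <- ga$ht * exp(z[idx] * sqrt(log(1 + ga$cv_ht^2)))
    }
    wt <- pmin(pmax(wt, 2), 120) # sanity bounds
    pma <- 40 + age * 365.25 / 7
    ffm <- fat_free_mass(sex, wt, ht, age)
    bsa <- body_surface_area(wt, ht)
    gfr <- assign_gfr_normal(pma, ffm, cv = spec$gfr_cv, rp = rp)
    rows[[g]] <- data.frame(
      group = .group_label(spec$age_groups)[g],
      sex = sex, age_years = age, pma = pma, weight = wt, height = ht,
      ffm = ffm, bsa = bsa, gfr = gfr, gfr_norm = gfr * 1.73 / bsa
    )
  }
  pop <- do.call(rbind, rows)
  pop <- cbind(id = seq_len(nrow(pop)), pop)
  eff <- sample_effects(pm, nrow(pop))
  pop$eta_cl <- eff$eta_cl
  pop$eta_v1 <- eff$eta_v1
  if (spec$renal_category != "normal") {
    pop <- impose_renal_impairment(pop, spec$renal_category)
  }
  class(pop) <- c("virtual_population", "data.frame")
  pop
}

#' Impose a renal-impairment category
#'
#' Resamples normalized GFR uniformly within the impairment band
#' (moderate: 30 to <50, severe: 10 to <30 ml/min/1.73 m^2; the 10 lower
#' bound limits extrapolation toward the model's zero clearance at zero
#' GFR) and back-transforms to absolute GFR via BSA:
#' `gfr = gfr_norm * bsa / 1.73`.
#'
#' @param subjects A `virtual_population` data.frame.
#' @param category `"moderate"` or `"severe"`.
#' @param seed Optional integer seed.
#' @return The modified population.
#' @export
impose_renal_impairment <- function(subjects, category, seed = NULL) {
  band <- switch(category,
    moderate = c(30, 50),
    severe = c(10, 30),
    stop("impose_renal_impairment: unknown category '", category, "'")
  )
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(subjects)
  subjects$gfr_norm <- stats::runif(n, band[1], band[2])
  subjects$gfr <- subjects$gfr_norm * subjects$bsa / 1.73
  subjects
}

#' @export
print.virtual_population <- function(x, ...) {
  cat(sprintf("Virtual pediatric population: %d subjects, %d age groups\n",
              nrow(x), length(unique(x$group))))
  print(stats::aggregate(
    cbind(age_years, weight, gfr, gfr_norm) ~ group, data = x, FUN = stats::median
  ))
  invisible(x)
}

#' Write a virtual population as a tidy CSV
#'
#' One row per subject with the columns id, group, sex, age_years,
#' pma_weeks, weight_kg, height_cm, ffm_kg, bsa_m2, gfr_ml_min, gfr_norm.
#'
#' @param pop A `virtual_population`.
#' @param path Output path.
#' @export
write_population <- function(pop, path) {
  out <- data.frame(
    id = pop$id, group = pop$group, sex = pop$sex,
    age_years = pop$age_years, pma_weeks = pop$pma,
    weight_kg = pop$weight, height_cm = pop$height, ffm_kg = pop$ffm,
    bsa_m2 = pop$bsa, gfr_ml_min = pop$gfr, gfr_norm = pop$gfr_norm
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
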