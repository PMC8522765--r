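#' Final pediatric population PK model specification
#'
#' Fixed effects, variance components and scaling rules of the final
#' population model. Clearance is a pure renal term, a slope on Rhodin
#' fat-free-mass GFR (nonrenal clearance fixed to zero); the three volumes
#' share a fitted body-weight power (0.911) and the two distributional
#' clearances a fixed allometric power (0.75), both against a 70 kg
#' reference. Interindividual variability is log-normal on CL and V1;
#' residual error is combined proportional + additive.
#'
#' Defaults are the final parameter estimates of the model.
#'
#' @param cl_gfr_slope Slope of CL on GFR, liters/h per ml/min.
#' @param v1_ref,vp1_ref,vp2_ref Volume intercepts at the reference weight,
#'   liters.
#' @param q1_ref,q2_ref Distributional clearances at the reference weight,
#'   liters/h.
#' @param vol_exponent Fitted body-weight power for the volume terms.
#' @param q_exponent Fixed allometric power for the distributional
#'   clearances.
#' @param cl_nr Nonrenal clearance, liters/h (fixed to zero).
#' @param ref_weight Reference body weight, kg.
#' @param omega2_cl,omega2_v1 Variances of the log-scale random effects on
#'   CL and V1.
#' @param sigma2_prop Variance of the proportional residual component.
#' @param sigma2_add Variance of the additive residual component, (ug/ml)^2.
#'
#' @return Object of class `population_model`.
#' @export
population_model <- function(cl_gfr_slope = 0.0548,
                             v1_ref = 16.1,
                             q1_ref = 0.545,
                             vp1_ref = 49.5,
                             q2_ref = 3.46,
                             vp2_ref = 6.13,
                             vol_exponent = 0.911,
                             q_exponent = 0.75,
                             cl_nr = 0,
                             ref_weight = 70,
                             omega2_cl = 0.0547,
                             omega2_v1 = 0.0711,
                             sigma2_prop = 0.0701,
                             sigma2_add = 0.000156) {
  if (cl_gfr_slope <= 0) stop("population_model: cl_gfr_slope must be positive")
  if (ref_weight <= 0) stop("population_model: ref_weight must be positive")
  if (any(c(v1_ref, vp1_ref, vp2_ref, q1_ref, q2_ref) <= 0)) {
    stop("population_model: reference volumes and clearances must be positive")
  }
  if (any(c(omega2_cl, omega2_v1, sigma2_prop, sigma2_add) < 0)) {
    stop("population_model: variance components must be nonnegative")
  }
  if (cl_nr < 0) stop("population_model: cl_nr must be nonnegative")
  structure(
    list(
      cl_gfr_slope = cl_gfr_slope, v1_ref = v1_ref, q1_ref = q1_ref,
      vp1_ref = vp1_ref, q2_ref = q2_ref, vp2_ref = vp2_ref,
      vol_exponent = vol_exponent, q_exponent = q_exponent,
      cl_nr = cl_nr, ref_weight = ref_weight,
      omega2_cl = omega2_cl, omega2_v1 = omega2_v1,
      sigma2_prop = sigma2_prop, sigma2_add = sigma2_add
    ),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat("Pediatric population PK model (ceftobiprole)\n")
  cat(sprintf("  CL = %.4g x GFR_Rhodin,FFM + %.4g  [L/h, GFR in ml/min]\n",
              x$cl_gfr_slope, x$cl_nr))
  cat(sprintf("  V1/Vp1/Vp2 = %.4g/%.4g/%.4g L x (WT/%g)^%.3g\n",
              x$v1_ref, x$vp1_ref, x$vp2_ref, x$ref_weight, x$vol_exponent))
  cat(sprintf("  Q1/Q2 = %.4g/%.4g L/h x (WT/%g)^%.3g\n",
              x$q1_ref, x$q2_ref, x$ref_weight, x$q_exponent))
  cat(sprintf("  IIV: omega2_CL = %.4g (%.1f%% CV), omega2_V1 = %.4g (%.1f%% CV)\n",
              x$omega2_cl, cv_percent(x$omega2_cl),
              x$omega2_v1, cv_percent(x$omega2_v1)))
  cat(sprintf("  Residual: prop var %.4g (%.1f%% CV) + add var %.3g (SD %.4g ug/ml)\n",
              x$sigma2_prop, cv_percent(x$sigma2_prop),
              x$sigma2_add, additive_sd(x)))
  invisible(x)
}

#' Rhodin GFR maturation parameters
#'
#' Sigmoid (Hill) maturation of glomerular filtration rate in postmenstrual
#' age, scaled allometrically by fat-free mass: half of the mature rate is
#' reached at `tm50` weeks PMA, and the mature value `gfr_std` applies at
#' the standard adult fat-free mass `ffm_ref`.
#'
#' @param gfr_std Mature GFR at standard size, ml/min.
#' @param tm50 PMA at half-maturation, weeks.
#' @param hill Hill coefficient.
#' @param ffm_ref Standard adult fat-free mass, kg.
#' @param size_exponent Allometric power on FFM.
#' @return Object of class `rhodin_params`.
#' @export
rhodin_params <- function(gfr_std = 121.2, tm50 = 47.7, hill = 3.40,
                          ffm_ref = 56.1, size_exponent = 0.75) {
  vals <- c(gfr_std, tm50, hill, ffm_ref, size_exponent)
  if (any(vals <= 0)) stop("rhodin_params: all parameters must be positive")
  structure(
    list(gfr_std = gfr_std, tm50 = tm50, hill = hill,
         ffm_ref = ffm_ref, size_exponent = size_exponent),
    class = "rhodin_params"
  )
}

#' Fat-free mass
#'
#' Pediatric/adult fat-free mass. For ages of 0.25 years and above the
#' Al-Sallami maturation-based equation is used (sex-specific maturation of
#' the Janmahasatian adult form); below 3 months FFM is taken as a fixed
#' fraction (0.86) of body weight, where the equation's age term is not
#' validated.
#'
#' @param sex `"male"` or `"female"` (vectorized).
#' @param weight Body weight, kg.
#' @param height Height/length, cm.
#' @param age_years Age in years.
#' @return FFM in kg (never exceeding `weight`).
#' @export
fat_free_mass <- function(sex, weight, height, age_years) {
  if (any(weight <= 0) || any(height <= 0) || any(age_years < 0)) {
    stop("fat_free_mass: weight and height must be positive, age nonnegative")
  }
  sex <- match.arg(sex, c("male", "female"), several.ok = TRUE)
  sex <- rep_len(sex, length(weight))
  bmi <- weight / (height / 100)^2
  male <- sex == "male"
  mat <- ifelse(
    male,
    0.88 + (1 - 0.88) / (1 + (age_years / 13.4)^(-12.7)),
    1.11 + (1 - 1.11) / (1 + (age_years / 7.1)^(-1.1))
  )
  denom <- ifelse(male, 6680 + 216 * bmi, 8780 + 244 * bmi)
  ffm <- mat * 9270 * weight / denom
  ffm <- ifelse(age_years < 0.25, 0.86 * weight, ffm)
  pmin(ffm, weight)
}

#' Body surface area (Mosteller)
#'
#' `sqrt(height_cm * weight_kg / 3600)`, m^2.
#'
#' @param weight Body weight, kg.
#' @param height Height, cm.
#' @return BSA in m^2.
#' @export
body_surface_area <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0)) {
    stop("body_surface_area: weight and height must be positive")
  }
  sqrt(height * weight / 3600)
}

#' Rhodin fat-free-mass GFR
#'
#' `gfr_std * pma^hill / (tm50^hill + pma^hill) * (ffm/ffm_ref)^size_exponent`
#' (ml/min); strictly increasing in both PMA and FFM.
#'
#' @param pma Postmenstrual age, weeks (> 0).
#' @param ffm Fat-free mass, kg (> 0).
#' @param rp A [rhodin_params()] object.
#' @return GFR in ml/min.
#' @export
gfr_rhodin_ffm <- function(pma, ffm, rp = rhodin_params()) {
  if (any(pma <= 0) || any(ffm <= 0)) {
    stop("gfr_rhodin_ffm: pma and ffm must be positive")
  }
  frac <- pma^rp$hill / (rp$tm50^rp$hill + pma^rp$hill)
  rp$gfr_std * frac * (ffm / rp$ffm_ref)^rp$size_exponent
}

#' Subject covariate record
#'
#' Validates and completes the covariate set used by the model: postmenstrual
#' age (weeks), body size, fat-free mass, BSA, and absolute/normalized GFR.
#' FFM, BSA and PMA are derived when not supplied; GFR must be supplied (see
#' [assign_gfr_normal()] for the normal-renal-function assignment) or is
#' derived from the maturation curve when `gfr = NULL`.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_years Postnatal age in years.
#' @param weight Body weight, kg.
#' @param height Height, cm.
#' @param gestational_age Gestational age at birth, weeks (default 40 when
#'   unrecorded).
#' @param gfr Absolute GFR, ml/min; `NULL` to evaluate the maturation curve.
#' @param ffm,bsa Optional overrides (derived otherwise).
#' @param rp Rhodin parameters used when deriving `gfr`.
#' @return A one-row data.frame of class `subject_covariates`.
#' @export
subject_covariates <- function(sex, age_years, weight, height,
                               gestational_age = 40, gfr = NULL,
                               ffm = NULL, bsa = NULL,
                               rp = rhodin_params()) {
  sex <- match.arg(sex, c("male", "female"))
  if (weight <= 0 || height <= 0 || age_years < 0) {
    stop("subject_covariates: invalid body size or age")
  }
  postnatal_weeks <- age_years * 365.25 / 7
  pma <- gestational_age + postnatal_weeks
  if (is.null(ffm)) ffm <- fat_free_mass(sex, weight, height, age_years)
  if (is.null(bsa)) bsa <- body_surface_area(weight, height)
  if (is.null(gfr)) gfr <- gfr_rhodin_ffm(pma, ffm, rp)
  structure(
    data.frame(
      sex = sex, postnatal_age = postnatal_weeks,
      gestational_age = gestational_age, pma = pma,
      age_years = age_years, weight = weight, height = height,
      ffm = ffm, bsa = bsa, gfr = gfr, gfr_norm = gfr * 1.73 / bsa
    ),
    class = c("subject_covariates", "data.frame")
  )
}

#' Population-typical individual parameters
#'
#' Maps subject covariates to the macro parameters of the disposition model:
#' `CL = slope * GFR + CL_NR`; volumes scale as `(WT/ref)^vol_exponent`;
#' distributional clearances as `(WT/ref)^q_exponent`.
#'
#' @param pm A [population_model()].
#' @param sc A subject record with columns/fields `gfr` and `weight` (e.g. a
#'   [subject_covariates()] row or a virtual-population row).
#' @return A [macro_params()] object.
#' @export
typical_params <- function(pm, sc) {
  wt_frac <- sc$weight / pm$ref_weight
  fv <- wt_frac^pm$vol_exponent
  fq <- wt_frac^pm$q_exponent
  cl <- pm$cl_gfr_slope * sc$gfr + pm$cl_nr
  macro_params(
    cl = cl,
    v1 = pm$v1_ref * fv,
    q1 = pm$q1_ref * fq,
    vp1 = pm$vp1_ref * fv,
    q2 = pm$q2_ref * fq,
    vp2 = pm$vp2_ref * fv
  )
}

#' Apply individual random effects
#'
#' Multiplies CL and V1 by `exp(eta)`; other parameters are unchanged
#' (interindividual variability was estimated for CL and V1 only).
#'
#' @param pm A [population_model()].
#' @param sc Subject covariates (as for [typical_params()]).
#' @param eta_cl,eta_v1 Log-scale random effects.
#' @return A [macro_params()] object.
#' @export
individual_params <- function(pm, sc, eta_cl = 0, eta_v1 = 0) {
  p <- typical_params(pm, sc)
  macro_params(
    cl = p$cl * exp(eta_cl), v1 = p$v1 * exp(eta_v1),
    q1 = p$q1, vp1 = p$vp1, q2 = p$q2, vp2 = p$vp2
  )
}

#' Sample interindividual random effects
#'
#' Independent normal draws `eta_cl ~ N(0, omega2_cl)`,
#' `eta_v1 ~ N(0, omega2_v1)` (diagonal covariance).
#'
#' @param pm A [population_model()].
#' @param n Number of subjects.
#' @param seed Optional integer seed for reproducibility.
#' @return data.frame with columns `eta_cl`, `eta_v1`.
#' @export
sample_effects <- function(pm, n, seed = NULL) {
  stopifnot(n >= 1)
  if (pm$omega2_cl < 0 || pm$omega2_v1 < 0) stop("negative variance")
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    eta_cl = stats::rnorm(n, 0, sqrt(pm$omega2_cl)),
    eta_v1 = stats::rnorm(n, 0, sqrt(pm$omega2_v1))
  )
}

#' Apply combined residual error
#'
#' `y = pred * (1 + eps_p) + eps_a` with `eps_p ~ N(0, sigma2_prop)` and
#' `eps_a ~ N(0, sigma2_add)`. Negative draws are retained; below-limit
#' handling is downstream (BLQ flagging).
#'
#' @param pm A [population_model()].
#' @param pred Vector of model predictions, ug/ml (>= 0).
#' @param seed Optional integer seed.
#' @return Vector of observed concentrations.
#' @export
apply_residual_error <- function(pm, pred, seed = NULL) {
  if (any(pred < 0)) stop("apply_residual_error: predictions must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  n <- length(pred)
  pred * (1 + stats::rnorm(n, 0, sqrt(pm$sigma2_prop))) +
    stats::rnorm(n, 0, sqrt(pm$sigma2_add))
}

#' Percent coefficient of variation of a log-normal variance component
#'
#' The reporting convention `100 * sqrt(variance)` (verified numerically
#' against the final parameter table), not the exact log-normal
#' `100 * sqrt(exp(variance) - 1)`.
#'
#' @param variance Variance (>= 0).
#' @return Percent CV.
#' @export
cv_percent <- function(variance) {
  if (any(variance < 0)) stop("cv_percent: variance must be nonnegative")
  100 * sqrt(variance)
}

#' Additive residual standard deviation
#'
#' @param pm A [population_model()].
#' @return SD of the additive residual component, ug/ml.
#' @export
additive_sd <- function(pm) sqrt(pm$sigma2_add)

#' Read / write a model specification file
#'
#' YAML serialization whose keys mirror the [population_model()] and
#' [rhodin_params()] fields. The file shipped with the package
#' (`system.file("extdata", "ceftobiprole_ped_model.yaml", package =
#' "cebopedpk")`) reproduces the final model estimates exactly.
#'
#' @param path File path.
#' @return `read_model_spec()` returns a list with elements
#'   `population_model` and `rhodin_params`.
#' @export
read_model_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  pm <- do.call(population_model, spec$population_model)
  rp <- do.call(rhodin_params, spec$rhodin_params)
  list(population_model = pm, rhodin_params = rp)
}

#' @rdname read_model_spec
#' @param pm A [population_model()].
#' @param rp A [rhodin_params()].
#' @export
write_model_spec <- function(pm, rp, path) {
  yaml::write_yaml(
    list(
      population_model = unclass(pm),
      rhodin_params = unclass(rp)
    ),
    path
  )
  invisible(path)
}

#' Default shipped model specification
#'
#' Loads the model file shipped under `inst/extdata`.
#'
#' @return As [read_model_spec()].
#' @export
default_model_spec <- function() {
  read_model_spec(
    system.file("extdata", "ceftobiprole_ped_model.yaml",
                package = "cebopedpk", mustWork = TRUE)
  )
}
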