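#' Dosing regimen
#'
#' Weight-based intermittent infusion regimen with a per-dose cap.
#'
#' @param dose_per_kg Dose, mg/kg.
#' @param interval Dosing interval, h (must divide 24: 8, 12 or 24).
#' @param infusion_duration Infusion length, h.
#' @param cap Maximum dose per administration, mg (default 500, applied
#'   regardless of body weight).
#' @return Object of class `regimen`.
#' @export
regimen <- function(dose_per_kg, interval, infusion_duration = 2, cap = 500) {
  if (dose_per_kg <= 0 || interval <= 0 || infusion_duration <= 0 || cap <= 0) {
    stop("regimen: all fields must be positive")
  }
  if (24 %% interval != 0) stop("regimen: interval must divide 24 h")
  structure(
    list(dose_per_kg = dose_per_kg, interval = interval,
         infusion_duration = infusion_duration, cap = cap),
    class = "regimen"
  )
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("%g mg/kg q%gh, %g-h infusion, cap %g mg\n",
              x$dose_per_kg, x$interval, x$infusion_duration, x$cap))
  invisible(x)
}

# renal category from normalized GFR (ml/min/1.73 m^2); "mild impairment"
# is folded into normal (>= 50)
.renal_category <- function(gfr_norm) {
  if (gfr_norm >= 50) "normal"
  else if (gfr_norm >= 30) "moderate"
  else if (gfr_norm >= 10) "severe"
  else stop("renal function below the supported range (GFR_norm < 10 ml/min/1.73 m^2)")
}

#' Optimized age/weight/renal dosing rule
#'
#' The model-derived optimal regimen matrix. All cells are 2-h infusions
#' with a 500 mg cap. Age intervals are half-open (a patient exactly 2
#' years old belongs to 2-<6 y). Renal categories by normalized GFR
#' (ml/min/1.73 m^2): normal or mild >= 50, moderate 30-<50, severe
#' 10-<30 (below 10 is outside the simulated range and errors).
#'
#' | Age            | Normal/mild | Moderate      | Severe        |
#' |----------------|-------------|---------------|---------------|
#' | birth-<3 mo    | 15 q12h *   | 15 q12h *     | 15 q24h *     |
#' | 3 mo-<12 y     | 15 q8h      | 10 q12h       | 10 q24h       |
#' | 12-<18 y       | 15 q8h      | 7.5 q12h      | 7.5 q24h      |
#'
#' (*) subjects under 4 kg receive 10 mg/kg instead of 15 mg/kg.
#'
#' @param age_years Age, years (0 <= age < 18).
#' @param weight_kg Body weight, kg.
#' @param gfr_norm Normalized GFR, ml/min/1.73 m^2. Ignored when
#'   `category` is given explicitly.
#' @param category Optional explicit renal category (`"normal"`,
#'   `"moderate"`, `"severe"`), e.g. to dose a whole simulated population
#'   by one column of the matrix.
#' @return A [regimen()].
#' @export
optimized_regimen <- function(age_years, weight_kg, gfr_norm = NULL,
                              category = NULL) {
  if (age_years < 0 || age_years >= 18) stop("age outside the supported 0-<18 y range")
  if (weight_kg <= 0) stop("weight must be positive")
  if (is.null(category)) {
    if (is.null(gfr_norm)) stop("supply gfr_norm or an explicit renal category")
    category <- .renal_category(gfr_norm)
  } else {
    category <- match.arg(category, c("normal", "moderate", "severe"))
  }
  if (age_years < 0.25) {
    dose <- if (weight_kg < 4) 10 else 15
    interval <- if (category == "severe") 24 else 12
    return(regimen(dose, interval))
  }
  if (age_years < 12) {
    return(switch(category,
      normal = regimen(15, 8),
      moderate = regimen(10, 12),
      severe = regimen(10, 24)
    ))
  }
  switch(category,
    normal = regimen(15, 8),
    moderate = regimen(7.5, 12),
    severe = regimen(7.5, 24)
  )
}

#' Regimens of the three clinical studies
#'
#' Age-banded doses as administered in the studies: CSI-1006 single 2-h
#' infusions (15 mg/kg at 3 mo-<6 y, 10 mg/kg at 6-<12 y, 7 mg/kg at
#' 12-<18 y); BPR-PIP-001 a single 7.5 mg/kg 4-h infusion in infants under
#' 3 months; BPR-PIP-002 q8h dosing (20 mg/kg over 4 h at 3 mo-<2 y,
#' 20 mg/kg over 2 h at 2-<6 y, 15 mg/kg at 6-<12 y, 10 mg/kg at
#' 12-<18 y), each dose capped at 500 mg.
#'
#' @param study One of `"CSI-1006"`, `"BPR-PIP-001"`, `"BPR-PIP-002"`.
#' @param age_years Age in years, within the study's enrollment range.
#' @return A [regimen()]; single-dose studies are encoded with a 24-h
#'   interval and attribute `single_dose = TRUE`.
#' @export
study_regimen <- function(study, age_years) {
  study <- match.arg(study, c("CSI-1006", "BPR-PIP-001", "BPR-PIP-002"))
  single <- function(r) {
    attr(r, "single_dose") <- TRUE
    r
  }
  if (study == "BPR-PIP-001") {
    if (age_years >= 0.25) stop("BPR-PIP-001 enrolled infants under 3 months")
    return(single(regimen(7.5, 24, infusion_duration = 4)))
  }
  if (age_years < 0.25 || age_years >= 18) {
    stop(study, " enrolled patients 3 months to <18 years")
  }
  if (study == "CSI-1006") {
    dose <- if (age_years < 6) 15 else if (age_years < 12) 10 else 7
    return(single(regimen(dose, 24, infusion_duration = 2)))
  }
  # BPR-PIP-002
  if (age_years < 2) regimen(20, 8, infusion_duration = 4)
  else if (age_years < 6) regimen(20, 8, infusion_duration = 2)
  else if (age_years < 12) regimen(15, 8, infusion_duration = 2)
  else regimen(10, 8, infusion_duration = 2)
}

#' Expand a regimen into dose events
#'
#' Dose amount is `min(dose_per_kg * weight, cap)`; events start at 0 and
#' repeat every `interval` hours while strictly before `horizon_h`.
#' Regimens flagged single-dose produce one event.
#'
#' @param r A [regimen()].
#' @param weight_kg Body weight, kg.
#' @param horizon_h Simulation horizon, h.
#' @return A [dose_event()] data.frame.
#' @export
expand_doses <- function(r, weight_kg, horizon_h = 24) {
  if (horizon_h <= 0) stop("expand_doses: horizon must be positive")
  amt <- min(r$dose_per_kg * weight_kg, r$cap)
  starts <- if (isTRUE(attr(r, "single_dose"))) 0 else {
    s <- seq(0, horizon_h, by = r$interval)
    s[s < horizon_h - 1e-9]
  }
  dose_event(starts, rep(amt, length(starts)), rep(r$infusion_duration, length(starts)))
}

#' The optimized dosing policy as a table
#'
#' Human-readable serialization of the full regimen matrix.
#'
#' @return data.frame with one row per age group x renal category.
#' @export
regimen_policy_table <- function() {
  grid <- expand.grid(
    age_group = c("birth-<3 mo", "3 mo-<2 yr", "2-<6 yr", "6-<12 yr", "12-<18 yr"),
    renal = c("normal", "moderate", "severe"),
    stringsAsFactors = FALSE
  )
  rep_age <- c(`birth-<3 mo` = 0.1, `3 mo-<2 yr` = 1, `2-<6 yr` = 4,
               `6-<12 yr` = 9, `12-<18 yr` = 15)
  rows <- mapply(function(ag, rc) {
    r <- optimized_regimen(rep_age[[ag]], weight_kg = 10, category = rc)
    data.frame(
      age_group = ag, renal = rc, dose_mg_kg = r$dose_per_kg,
      interval_h = r$interval, infusion_h = r$infusion_duration,
      cap_mg = r$cap,
      note = if (ag == "birth-<3 mo") "10 mg/kg if weight < 4 kg" else ""
    )
  }, grid$age_group, grid$renal, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
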