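#' Study sampling design
#'
#' Describes a PK sampling design: enrollment age range, the dosing rule,
#' nominal sampling times relative to the start of the (reference) infusion,
#' the sampling day offset, and the assay's lower limit of quantitation.
#'
#' @param study_id Character label.
#' @param age_range `c(min, max)` enrollment ages, years (half-open).
#' @param schedule List of `list(age_max =, times =)` entries; a subject
#'   uses the first entry whose `age_max` exceeds their age. Times are
#'   hours after the start of the sampling-day reference dose, sorted,
#'   nonnegative.
#' @param day_offset Hours from the first dose to the sampling-day
#'   reference dose (0 for day-1 single-dose studies, 48 for day-3
#'   sampling under q8h dosing).
#' @param lloq Lower limit of quantitation, ug/ml.
#' @param regimen_rule `NULL` to use [study_regimen()] for `study_id`, or
#'   a fixed [regimen()] applied to all subjects.
#' @return Object of class `study_design`.
#' @export
study_design <- function(study_id, age_range, schedule, day_offset = 0,
                         lloq = 0.05, regimen_rule = NULL) {
  for (sc in schedule) {
    if (any(sc$times < 0) || is.unsorted(sc$times)) {
      stop("study_design: sampling times must be nonnegative and sorted")
    }
  }
  structure(
    list(study_id = study_id, age_range = age_range, schedule = schedule,
         day_offset = day_offset, lloq = lloq, regimen_rule = regimen_rule),
    class = "study_design"
  )
}

#' Built-in designs of the three pediatric studies
#'
#' * `CSI-1006`: single 2-h infusion, 7 nominal samples (predose and 2, 3,
#'   5, 8, 12, 24 h after the start of infusion), ages 3 mo-<18 y.
#' * `BPR-PIP-001`: single 7.5 mg/kg 4-h infusion in term neonates/infants
#'   <3 mo, 6 nominal samples (predose and 2, 4, 6, 8, 12 h).
#' * `BPR-PIP-002`: q8h multi-dose, day-3 sparse sampling after the morning
#'   dose at 48 h — predose and 2, 4, 6, 8 h for ages >= 2 y; predose and
#'   4, 6, 8 h for ages < 2 y.
#'
#' @param study_id One of the three study labels.
#' @return A [study_design()].
#' @export
builtin_design <- function(study_id) {
  study_id <- match.arg(study_id, c("CSI-1006", "BPR-PIP-001", "BPR-PIP-002"))
  switch(study_id,
    "CSI-1006" = study_design(
      study_id, c(0.25, 18),
      schedule = list(list(age_max = Inf, times = c(0, 2, 3, 5, 8, 12, 24)))
    ),
    "BPR-PIP-001" = study_design(
      study_id, c(0, 0.25),
      schedule = list(list(age_max = Inf, times = c(0, 2, 4, 6, 8, 12)))
    ),
    "BPR-PIP-002" = study_design(
      study_id, c(0.25, 18),
      schedule = list(
        list(age_max = 2, times = c(0, 4, 6, 8)),
        list(age_max = Inf, times = c(0, 2, 4, 6, 8))
      ),
      day_offset = 48
    )
  )
}

.design_times <- function(design, age) {
  for (sc in design$schedule) {
    if (age < sc$age_max) return(sc$times)
  }
  stop("no sampling schedule for age ", age)
}

.design_regimen <- function(design, age) {
  if (!is.null(design$regimen_rule)) return(design$regimen_rule)
  study_regimen(design$study_id, age)
}

#' Simulate a synthetic PK study
#'
#' Draws `n` virtual subjects within the design's age range, doses them per
#' the design's regimen rule, evaluates the model's individual predictions
#' at the nominal sampling times, applies the combined residual error, and
#' flags observations below the LLOQ. The result is a NONMEM-style
#' long-format dataset: dose records (`EVID = 1, MDV = 1`, `DV` missing)
#' and observation records (`EVID = 0`, `AMT` missing), with covariate
#' columns.
#'
#' @param design A [study_design()].
#' @param pm A [population_model()]. With all variance components zero the
#'   simulated `DV` equals the typical-model prediction exactly.
#' @param n Number of subjects.
#' @param seed Optional integer seed (covers subjects, effects and noise).
#' @param jitter_sd If positive, sampling times (except predose) are
#'   jittered uniformly by +- `jitter_sd` fraction of the nominal time.
#' @param rp,gr Physiology inputs passed to the population sampler.
#' @return A data.frame of class `pk_dataset` with columns
#'   ID, TIME, AMT, RATE, EVID, MDV, DV, BLQ, AGE, WT, HT, SEX, PMA, GFR.
#' @export
simulate_study <- function(design, pm = population_model(), n, seed = NULL,
                           jitter_sd = 0, rp = rhodin_params(),
                           gr = growth_reference()) {
  stopifnot(n >= 1)
  pop <- sample_population(
    population_spec(n, age_groups = list(design$age_range), seed = seed),
    gr = gr, pm = pm, rp = rp
  )
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- pop[i, ]
    r <- .design_regimen(design, s$age_years)
    tnom <- .design_times(design, s$age_years)
    # dose through the sampling window; a dose starting exactly at the last
    # sample contributes nothing there and is omitted
    dose_horizon <- design$day_offset + max(max(tnom), 1e-6)
    doses <- expand_doses(r, s$weight, horizon_h = dose_horizon)
    obs_t <- design$day_offset + tnom
    if (jitter_sd > 0) {
      shift <- stats::runif(length(obs_t), -jitter_sd, jitter_sd)
      nonzero <- .design_times(design, s$age_years) > 0
      obs_t[nonzero] <- obs_t[nonzero] * (1 + shift[nonzero])
      obs_t <- sort(obs_t)
    }
    p <- individual_params(pm, s, s$eta_cl, s$eta_v1)
    pred <- conc_at(p, doses, obs_t)
    dv <- apply_residual_error(pm, pred)
    blq <- as.integer(dv < design$lloq)
    cov <- data.frame(
      AGE = s$age_years, WT = s$weight, HT = s$height,
      SEX = ifelse(s$sex == "male", 1L, 0L), PMA = s$pma, GFR = s$gfr
    )
    dose_rows <- data.frame(
      ID = s$id, TIME = doses$start_time, AMT = doses$amount,
      RATE = doses$amount / doses$duration, EVID = 1L, MDV = 1L,
      DV = NA_real_, BLQ = 0L, cov, row.names = NULL
    )
    obs_rows <- data.frame(
      ID = s$id, TIME = obs_t, AMT = NA_real_, RATE = NA_real_,
      EVID = 0L, MDV = 0L, DV = dv, BLQ = blq, cov, row.names = NULL
    )
    all <- rbind(dose_rows, obs_rows)
    rows[[i]] <- all[order(all$TIME, -all$EVID), ]
  }
  ds <- do.call(rbind, rows)
  rownames(ds) <- NULL
  class(ds) <- c("pk_dataset", "data.frame")
  ds
}

#' Validate a NONMEM-style dataset
#'
#' Checks the record conventions: dose records have `EVID = 1`, `MDV = 1`
#' and no `DV`; observation records have `EVID = 0` and no `AMT`; times are
#' nondecreasing within subject. Errors name the first offending row.
#'
#' @param ds A `pk_dataset` (or plain data.frame with the same columns).
#' @return The dataset, invisibly, with class `pk_dataset`.
#' @export
validate_pk_dataset <- function(ds) {
  req <- c("ID", "TIME", "AMT", "RATE", "EVID", "MDV", "DV", "BLQ")
  miss <- setdiff(req, names(ds))
  if (length(miss)) stop("pk_dataset: missing columns ", paste(miss, collapse = ", "))
  bad <- which(ds$EVID == 1 & !is.na(ds$DV))
  if (length(bad)) stop("pk_dataset: dose record with DV present at row ", bad[1])
  bad <- which(ds$EVID == 0 & !is.na(ds$AMT))
  if (length(bad)) stop("pk_dataset: observation record with AMT present at row ", bad[1])
  bad <- which(ds$EVID == 1 & (is.na(ds$AMT) | ds$AMT <= 0))
  if (length(bad)) stop("pk_dataset: dose record without a positive AMT at row ", bad[1])
  for (id in unique(ds$ID)) {
    tt <- ds$TIME[ds$ID == id]
    if (is.unsorted(tt)) {
      stop("pk_dataset: times not nondecreasing within ID ", id)
    }
  }
  class(ds) <- unique(c("pk_dataset", class(ds)))
  invisible(ds)
}

#' Read / write NONMEM-style datasets
#'
#' CSV with missing values written as `.` (dataset convention). Extra
#' covariate columns beyond the standard set are preserved. Reading
#' validates the record conventions.
#'
#' @param path File path.
#' @return `read_pk_dataset()` returns a validated `pk_dataset`.
#' @export
read_pk_dataset <- function(path) {
  ds <- utils::read.csv(path, na.strings = c(".", "NA", ""))
  validate_pk_dataset(ds)
  class(ds) <- c("pk_dataset", "data.frame")
  ds
}

#' @rdname read_pk_dataset
#' @param ds A `pk_dataset`.
#' @export
write_pk_dataset <- function(ds, path) {
  validate_pk_dataset(ds)
  utils::write.csv(ds, path, row.names = FALSE, na = ".")
  invisible(path)
}

#' Apply the analysis exclusion rules
#'
#' Removes below-LLOQ and missing-DV observation records (BLQ samples are
#' excluded, not imputed) and reports counts by reason. Optionally screens
#' the remaining observations against a supplied model, removing those with
#' an absolute standardized residual above `sr_cut` (a simplified stand-in
#' for a conditional-weighted-residual rule): the residual is
#' `(DV - pred) / sqrt(sigma2_prop * pred^2 + sigma2_add)` with `pred` the
#' typical-model prediction given the subject's doses and covariates.
#'
#' @param ds A `pk_dataset`.
#' @param pm Optional [population_model()] enabling the outlier screen.
#' @param sr_cut Standardized-residual cutoff (default 3).
#' @return List with `data` (the filtered dataset) and `counts` (named:
#'   blq, missing, outlier).
#' @export
apply_exclusions <- function(ds, pm = NULL, sr_cut = 3) {
  validate_pk_dataset(ds)
  is_obs <- ds$EVID == 0
  drop_blq <- is_obs & ds$BLQ == 1
  drop_na <- is_obs & !drop_blq & is.na(ds$DV)
  counts <- c(blq = sum(drop_blq), missing = sum(drop_na), outlier = 0L)
  keep <- !(drop_blq | drop_na)
  out <- ds[keep, , drop = FALSE]
  if (!is.null(pm)) {
    sr <- rep(NA_real_, nrow(out))
    for (id in unique(out$ID)) {
      sub <- out$ID == id
      rows <- out[sub, ]
      obs <- rows$EVID == 0
      if (!any(obs)) next
      dose_rows <- rows[rows$EVID == 1, ]
      doses <- dose_event(dose_rows$TIME, dose_rows$AMT,
                          dose_rows$AMT / dose_rows$RATE)
      sc <- list(weight = rows$WT[1], gfr = rows$GFR[1])
      p <- typical_params(pm, sc)
      pred <- conc_at(p, doses, rows$TIME[obs])
      v <- pm$sigma2_prop * pred^2 + pm$sigma2_add
      sr[sub][obs] <- (rows$DV[obs] - pred) / sqrt(v)
    }
    out_flag <- !is.na(sr) & abs(sr) > sr_cut
    counts["outlier"] <- sum(out_flag)
    out <- out[!out_flag, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("pk_dataset", "data.frame")
  list(data = out, counts = counts)
}
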