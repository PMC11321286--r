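#' Declarative clinical-trial eligibility criteria
#'
#' Encodes the imaging-based eligibility rules that differ between GA
#' trials: allowed age range, GA area bounds (inclusive at both ends),
#' whether CNV in the study or fellow eye is exclusionary, and lesion
#' location requirements relative to the fovea. GA itself is always
#' required. The HORIZON rule set from the main analysis is: age > 55,
#' no study-eye CNV, GA area between 1.25 and 17.5 mm^2 inclusive.
#'
#' @param trial_id Short identifier for the trial.
#' @param min_age_years,max_age_years Optional age bounds in years.
#' @param min_age_exclusive Whether the lower age bound is strict
#'   (HORIZON's "aged >55" is strict).
#' @param area_min_mm2,area_max_mm2 Inclusive GA area bounds, mm^2.
#' @param require_no_study_eye_cnv Exclude eyes with CNV.
#' @param require_no_fellow_eye_cnv Exclude when the fellow eye has CNV.
#' @param require_central_ga Require atrophy within 1500 um of the fovea.
#' @param require_non_fovea_involving Require the foveal center point
#'   itself to be spared.
#' @param fellow_missing_policy When fellow-eye data are missing and the
#'   fellow-eye CNV rule is enabled: `"strict"` marks the eye ineligible,
#'   `"lenient"` ignores the rule.
#' @return An object of class `trial_criteria`.
#' @export
trial_criteria <- function(trial_id,
                           min_age_years = NULL, max_age_years = NULL,
                           min_age_exclusive = TRUE,
                           area_min_mm2 = 0, area_max_mm2 = Inf,
                           require_no_study_eye_cnv = TRUE,
                           require_no_fellow_eye_cnv = FALSE,
                           require_central_ga = FALSE,
                           require_non_fovea_involving = FALSE,
                           fellow_missing_policy = c("strict", "lenient")) {
  fellow_missing_policy <- match.arg(fellow_missing_policy)
  if (area_min_mm2 < 0 || area_max_mm2 < 0)
    stop("criteria field area bounds must be >= 0 (area_min_mm2/area_max_mm2)",
         call. = FALSE)
  if (area_min_mm2 > area_max_mm2)
    stop("criteria field area_min_mm2 exceeds area_max_mm2", call. = FALSE)
  structure(
    list(trial_id = trial_id,
         min_age_years = min_age_years, max_age_years = max_age_years,
         min_age_exclusive = isTRUE(min_age_exclusive),
         area_min_mm2 = area_min_mm2, area_max_mm2 = area_max_mm2,
         require_no_study_eye_cnv = isTRUE(require_no_study_eye_cnv),
         require_no_fellow_eye_cnv = isTRUE(require_no_fellow_eye_cnv),
         require_central_ga = isTRUE(require_central_ga),
         require_non_fovea_involving = isTRUE(require_non_fovea_involving),
         fellow_missing_policy = fellow_missing_policy),
    class = "trial_criteria"
  )
}

# shared rule evaluation used by both the imaging pipeline and the
# ground-truth eligibility in the generator
check_criteria <- function(age, ga, cnv, fellow_cnv, area, central,
                           fovea_involving, criteria) {
  failed <- character(0)
  if (!is.null(criteria$min_age_years)) {
    ok <- if (criteria$min_age_exclusive) age > criteria$min_age_years
          else age >= criteria$min_age_years
    if (!ok) failed <- c(failed, "min_age")
  }
  if (!is.null(criteria$max_age_years) && age > criteria$max_age_years)
    failed <- c(failed, "max_age")
  if (!isTRUE(ga)) failed <- c(failed, "no_ga")
  if (criteria$require_no_study_eye_cnv && isTRUE(cnv))
    failed <- c(failed, "study_eye_cnv")
  if (criteria$require_no_fellow_eye_cnv) {
    if (is.na(fellow_cnv)) {
      if (criteria$fellow_missing_policy == "strict")
        failed <- c(failed, "fellow_eye_missing")
    } else if (isTRUE(fellow_cnv)) {
      failed <- c(failed, "fellow_eye_cnv")
    }
  }
  if (area < criteria$area_min_mm2) failed <- c(failed, "area_below_min")
  if (area > criteria$area_max_mm2) failed <- c(failed, "area_above_max")
  if (criteria$require_central_ga && !isTRUE(central))
    failed <- c(failed, "not_central")
  if (criteria$require_non_fovea_involving && isTRUE(fovea_involving))
    failed <- c(failed, "fovea_involving")
  list(eligible = length(failed) == 0, failed = failed)
}

#' Evaluate one eye against a trial's criteria
#'
#' The study eye is the eye under evaluation; the other eye acts as fellow.
#' Area bounds are inclusive at both ends. Returns the verdict together
#' with the list of failed criteria, so screening failures are auditable.
#'
#' @param profile An `imaging_profile` from [profile_eye()], or any list
#'   with `area_mm2`, `central_ga`, `fovea_involving`.
#' @param ga_flag,cnv_flag Study-eye diagnosis flags.
#' @param fellow_cnv_flag Fellow-eye CNV flag; `NA` when the fellow eye is
#'   missing.
#' @param age Patient age in years.
#' @param criteria A [trial_criteria()].
#' @return List with `eligible` (logical) and `failed` (character vector of
#'   failed criterion names, empty when eligible).
#' @examples
#' horizon <- trial_criteria("HORIZON", min_age_years = 55,
#'                           area_min_mm2 = 1.25, area_max_mm2 = 17.5)
#' prof <- list(area_mm2 = 1.25, central_ga = TRUE, fovea_involving = TRUE)
#' evaluate_eye(prof, TRUE, FALSE, FALSE, 70, horizon)$eligible  # TRUE
#' @export
evaluate_eye <- function(profile, ga_flag, cnv_flag, fellow_cnv_flag,
                         age, criteria) {
  stopifnot(inherits(criteria, "trial_criteria"))
  check_criteria(age = age, ga = ga_flag, cnv = cnv_flag,
                 fellow_cnv = fellow_cnv_flag, area = profile$area_mm2,
                 central = profile$central_ga,
                 fovea_involving = profile$fovea_involving,
                 criteria = criteria)
}

#' Evaluate every eye of a cohort and build per-patient verdicts
#'
#' @param cohort A `cohort`.
#' @param profiles Per-eye profiles from [profile_cohort()].
#' @param criteria A [trial_criteria()].
#' @return Data frame with one row per eye: `patient_id`, `laterality`,
#'   `eligible`, `failed` (semicolon-joined) and `patient_eligible`
#'   (TRUE when at least one of the patient's eyes is eligible).
#' @export
evaluate_cohort <- function(cohort, profiles, criteria) {
  stopifnot(inherits(cohort, "cohort"), inherits(criteria, "trial_criteria"))
  ages <- stats::setNames(
    vapply(cohort$patients, function(p) p$age_years, numeric(1)),
    vapply(cohort$patients, function(p) p$patient_id, character(1)))
  cnv_by_eye <- stats::setNames(profiles$cnv_flag,
                                paste(profiles$patient_id, profiles$laterality))
  out <- profiles[, c("patient_id", "laterality")]
  out$eligible <- FALSE
  out$failed <- ""
  for (i in seq_len(nrow(profiles))) {
    row <- profiles[i, ]
    fellow_lat <- if (row$laterality == "L") "R" else "L"
    fellow_cnv <- cnv_by_eye[paste(row$patient_id, fellow_lat)]
    if (is.null(fellow_cnv) || length(fellow_cnv) == 0) fellow_cnv <- NA
    v <- evaluate_eye(
      list(area_mm2 = row$area_mm2, central_ga = row$central_ga,
           fovea_involving = row$fovea_involving),
      ga_flag = row$ga_flag, cnv_flag = row$cnv_flag,
      fellow_cnv_flag = unname(fellow_cnv),
      age = ages[[row$patient_id]], criteria = criteria)
    out$eligible[i] <- v$eligible
    out$failed[i] <- paste(v$failed, collapse = ";")
  }
  pe <- tapply(out$eligible, out$patient_id, any)
  out$patient_eligible <- as.logical(pe[out$patient_id])
  out
}

#' Shortlist patients for a trial
#'
#' Three shortlisting modes mirror the screening strategies compared in the
#' pipeline: `"ai"` selects patients for whom at least one eye passes the
#' imaging criteria; `"ehr"` selects patients whose letters matched the
#' keyword search; `"combined"` applies the imaging criteria only to the
#' EHR-matched patients (the intersection). Output is sorted by patient id.
#'
#' @param cohort A `cohort`.
#' @param profiles Per-eye profiles from [profile_cohort()].
#' @param criteria A [trial_criteria()].
#' @param mode One of `"ai"`, `"ehr"`, `"combined"`.
#' @param ehr_flags Optional precomputed [ehr_search_cohort()] result.
#' @return Character vector of shortlisted patient ids, sorted.
#' @export
shortlist <- function(cohort, profiles, criteria,
                      mode = c("ai", "ehr", "combined"), ehr_flags = NULL) {
  mode <- tryCatch(match.arg(mode),
                   error = function(e) stop("unknown shortlist mode",
                                            call. = FALSE))
  need_ehr <- mode %in% c("ehr", "combined")
  if (need_ehr && is.null(ehr_flags)) ehr_flags <- ehr_search_cohort(cohort)
  ai_ids <- function() {
    verdicts <- evaluate_cohort(cohort, profiles, criteria)
    unique(verdicts$patient_id[verdicts$patient_eligible])
  }
  ids <- switch(mode,
    ai = ai_ids(),
    ehr = ehr_flags$patient_id[ehr_flags$matched],
    combined = intersect(ehr_flags$patient_id[ehr_flags$matched], ai_ids()))
  sort(ids)
}

#' Read trial criteria from a JSON configuration file
#'
#' The JSON schema mirrors the [trial_criteria()] arguments. Files shipped
#' under `inst/extdata/criteria/` provide HORIZON plus structurally distinct
#' configurations for DERBY, GATHER2 and the Janssen trial; the latter three
#' carry placeholder values flagged `"unverified": true` because only the
#' HORIZON numbers are fully public.
#'
#' @param path Path to a criteria JSON file.
#' @return A [trial_criteria()].
#' @export
read_criteria <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- "trial_id"
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop(sprintf("criteria file %s missing field(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  raw$unverified <- NULL
  args <- raw[names(raw) %in% names(formals(trial_criteria))]
  do.call(trial_criteria, args)
}

#' Path to a bundled example criteria file
#'
#' @param trial One of `"horizon"`, `"derby"`, `"gather2"`, `"janssen"`.
#' @return File path inside the installed package.
#' @export
example_criteria_path <- function(trial = c("horizon", "derby", "gather2",
                                            "janssen")) {
  trial <- match.arg(trial)
  system.file("extdata", "criteria", paste0(trial, ".json"),
              package = "gascreenr", mustWork = TRUE)
}
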