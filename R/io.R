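# Cohort serialisation. All files are plain text: patients.csv
# (demographics), eyes/<pid>_<L|R>_{rpe,thickness}.txt (whitespace-separated
# matrices, one row per B-scan), eyes/geometry.json (grid and field-of-view
# sidecar stating the value scale), letters.jsonl (one JSON letter per
# line), faf_gradings.csv, ground_truth.csv. Dates ISO-8601, laterality
# "L"/"R", areas written with 4 decimals, decimal point fixed (no locale
# dependence).

#' Write a cohort to a directory
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(file.path(dir, "eyes"), recursive = TRUE, showWarnings = FALSE)

  pats <- do.call(rbind, lapply(cohort$patients, function(p) {
    data.frame(patient_id = p$patient_id,
               age_years = sprintf("%.4f", p$age_years),
               sex = p$sex, ethnicity = p$ethnicity,
               imd_decile = p$imd_decile, stringsAsFactors = FALSE)
  }))
  utils::write.csv(pats, file.path(dir, "patients.csv"), row.names = FALSE)

  geom <- cohort$geometry
  jsonlite::write_json(
    list(n_bscans = geom$n_bscans, n_ascans = geom$n_ascans,
         width_mm = geom$width_mm, height_mm = geom$height_mm,
         rpe_scale = "0/1 integer, 1 = RPE present",
         thickness_scale = "micrometres, 4 decimals"),
    file.path(dir, "eyes", "geometry.json"), auto_unbox = TRUE, digits = NA)

  eye_rows <- list(); grading_rows <- list()
  con <- file(file.path(dir, "letters.jsonl"), open = "wt")
  on.exit(close(con), add = TRUE)
  for (p in cohort$patients) {
    for (eye in p$eyes) {
      stem <- file.path(dir, "eyes", paste0(p$patient_id, "_", eye$laterality))
      utils::write.table(matrix(as.integer(eye$rpe_present),
                                nrow(eye$rpe_present)),
                         paste0(stem, "_rpe.txt"),
                         row.names = FALSE, col.names = FALSE)
      utils::write.table(matrix(sprintf("%.4f", eye$nsr_thickness),
                                nrow(eye$nsr_thickness)),
                         paste0(stem, "_thickness.txt"),
                         row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
      eye_rows[[length(eye_rows) + 1L]] <- data.frame(
        patient_id = p$patient_id, laterality = eye$laterality,
        ga_flag = eye$ga_flag, cnv_flag = eye$cnv_flag,
        drusen_flag = eye$drusen_flag,
        oct_date = format(eye$oct_date, "%Y-%m-%d"),
        faf_date = format(eye$faf_date, "%Y-%m-%d"),
        true_fovea_row = eye$true_fovea_px[1],
        true_fovea_col = eye$true_fovea_px[2],
        true_area_mm2 = sprintf("%.4f", eye$true_area_mm2),
        stringsAsFactors = FALSE)
    }
    for (l in p$letters) {
      writeLines(jsonlite::toJSON(
        list(patient_id = p$patient_id,
             date = format(as.Date(l$date), "%Y-%m-%d"), text = l$text),
        auto_unbox = TRUE), con)
    }
    g <- p$faf_gradings
    if (!is.null(g) && nrow(g)) {
      g2 <- g
      g2$patient_id <- p$patient_id
      g2$area_mm2 <- sprintf("%.4f", g$area_mm2)
      grading_rows[[length(grading_rows) + 1L]] <-
        g2[, c("patient_id", "laterality", "grader_id", "area_mm2")]
    }
  }
  utils::write.csv(do.call(rbind, eye_rows), file.path(dir, "eyes.csv"),
                   row.names = FALSE)
  gr <- if (length(grading_rows)) do.call(rbind, grading_rows) else
    data.frame(patient_id = character(0), laterality = character(0),
               grader_id = character(0), area_mm2 = character(0))
  utils::write.csv(gr, file.path(dir, "faf_gradings.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth_eyes, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth_patients,
                   file.path(dir, "ground_truth_patients.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Round-trips all fields used downstream; areas and thickness values are
#' restored at the serialised 4-decimal precision.
#'
#' @param dir Cohort directory.
#' @return A `cohort` (without the generating `config`).
#' @export
read_cohort <- function(dir) {
  pats <- utils::read.csv(file.path(dir, "patients.csv"),
                          stringsAsFactors = FALSE)
  eyes_meta <- utils::read.csv(file.path(dir, "eyes.csv"),
                               stringsAsFactors = FALSE)
  gj <- jsonlite::read_json(file.path(dir, "eyes", "geometry.json"),
                            simplifyVector = TRUE)
  geom <- scan_geometry(gj$n_bscans, gj$n_ascans, gj$width_mm, gj$height_mm)

  letters_path <- file.path(dir, "letters.jsonl")
  letters_by_pid <- list()
  lines <- readLines(letters_path)
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e)
                      stop(sprintf("letters.jsonl line %d: malformed JSON (%s)",
                                   i, conditionMessage(e)), call. = FALSE))
    letters_by_pid[[rec$patient_id]] <-
      c(letters_by_pid[[rec$patient_id]],
        list(list(date = as.Date(rec$date), text = rec$text)))
  }
  gradings <- utils::read.csv(file.path(dir, "faf_gradings.csv"),
                              stringsAsFactors = FALSE)

  patients <- vector("list", nrow(pats))
  for (i in seq_len(nrow(pats))) {
    pid <- pats$patient_id[i]
    em <- eyes_meta[eyes_meta$patient_id == pid, ]
    eyes <- list()
    for (j in seq_len(nrow(em))) {
      lat <- em$laterality[j]
      stem <- file.path(dir, "eyes", paste0(pid, "_", lat))
      rpe <- as.matrix(utils::read.table(paste0(stem, "_rpe.txt"))) == 1L
      dimnames(rpe) <- NULL
      thick <- as.matrix(utils::read.table(paste0(stem, "_thickness.txt")))
      dimnames(thick) <- NULL
      eyes[[lat]] <- structure(
        list(laterality = lat, rpe_present = rpe, nsr_thickness = thick,
             ga_flag = em$ga_flag[j], cnv_flag = em$cnv_flag[j],
             drusen_flag = em$drusen_flag[j],
             oct_date = as.Date(em$oct_date[j]),
             faf_date = as.Date(em$faf_date[j]),
             true_fovea_px = c(em$true_fovea_row[j], em$true_fovea_col[j]),
             true_area_mm2 = em$true_area_mm2[j]),
        class = "eye_record")
    }
    g <- gradings[gradings$patient_id == pid,
                  c("laterality", "grader_id", "area_mm2")]
    patients[[i]] <- structure(
      list(patient_id = pid, age_years = pats$age_years[i],
           sex = pats$sex[i], ethnicity = pats$ethnicity[i],
           imd_decile = pats$imd_decile[i], eyes = eyes,
           letters = letters_by_pid[[pid]] %||% list(),
           faf_gradings = g),
      class = "patient_record")
  }
  truth_eyes <- utils::read.csv(file.path(dir, "ground_truth.csv"),
                                stringsAsFactors = FALSE)
  truth_pat <- utils::read.csv(file.path(dir, "ground_truth_patients.csv"),
                               stringsAsFactors = FALSE)
  structure(list(patients = patients, geometry = geom, config = NULL,
                 truth_eyes = truth_eyes, truth_patients = truth_pat),
            class = "cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
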