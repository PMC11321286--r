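#' Configuration of a synthetic screening cohort
#'
#' The generator emulates the structure of a retrospective hospital OCT
#' cohort: patients with up to two eyes, planted RPE-loss lesions of known
#' area and location, CNV/drusen flags, clinical letters that may contain
#' the literal keyword "geographic atrophy", FAF acquisition dates offset
#' from the OCT date, and two simulated FAF graders whose area measurements
#' are truth plus grader-specific bias and Gaussian noise.
#'
#' Defaults encode the stated world: lesion areas are log-normal with median
#' 8.5 mm^2 truncated to [0.25, 35] mm^2 (exercising every trial's area
#' bounds); grader noise sd is 1.5 mm^2; fixation error (preferred retinal
#' locus vs anatomical fovea) translates the scan grid by up to 0.75 mm.
#'
#' @param n_patients Number of patients (> 0).
#' @param p_ga,p_cnv,p_drusen Per-eye prevalence of GA / CNV / drusen.
#' @param area_meanlog,area_sdlog Log-normal lesion-area parameters
#'   (meanlog defaults to log(8.5), i.e. median 8.5 mm^2).
#' @param area_range_mm2 Truncation range for planted areas, mm^2.
#' @param p_keyword_given_ga Fraction of GA patients whose letters contain
#'   the keyword.
#' @param p_keyword_given_no_ga Keyword rate among patients without GA
#'   (EHR false positives).
#' @param grader_sd_mm2 Per-measurement grader noise sd, mm^2.
#' @param grader_bias_mm2 Length-2 numeric, fixed bias of each grader, mm^2.
#' @param faf_offset_max_days FAF date offsets are uniform on
#'   [-max, max] days around the OCT date.
#' @param misfixation_max_mm Fixation offset: the true fovea is displaced
#'   from the grid center by a uniform offset within +/- this value (each
#'   axis). Set 0 for perfectly fixated scans.
#' @param pit_depth_um,pit_sigma_mm Foveal pit depth and width of the
#'   planted thickness depression.
#' @param baseline_thickness_um Baseline neurosensory retina thickness.
#' @param thickness_noise_um Additive noise sd on the thickness map.
#' @param n_speckles Isolated single-pixel RPE dropouts per eye (segmentation
#'   noise removed by the speckle filter).
#' @param age_mean,age_sd Patient age distribution (years), clipped to
#'   [50, 100].
#' @param geometry A [scan_geometry()].
#' @param seed Master seed for the cohort substream.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100L,
                          p_ga = 0.35, p_cnv = 0.15, p_drusen = 0.4,
                          area_meanlog = log(8.5), area_sdlog = 0.9,
                          area_range_mm2 = c(0.25, 35),
                          p_keyword_given_ga = 0.6,
                          p_keyword_given_no_ga = 0.02,
                          grader_sd_mm2 = 1.5,
                          grader_bias_mm2 = c(0.3, -0.3),
                          faf_offset_max_days = 120L,
                          misfixation_max_mm = 0.75,
                          pit_depth_um = 120, pit_sigma_mm = 0.35,
                          baseline_thickness_um = 250,
                          thickness_noise_um = 5,
                          n_speckles = 10L,
                          age_mean = 73, age_sd = 10,
                          geometry = scan_geometry(),
                          seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients <= 0L)
    stop("invalid config: n_patients must be a positive integer", call. = FALSE)
  probs <- c(p_ga, p_cnv, p_drusen, p_keyword_given_ga, p_keyword_given_no_ga)
  if (any(probs < 0 | probs > 1))
    stop("invalid config: prevalences must lie in [0, 1]", call. = FALSE)
  if (grader_sd_mm2 < 0)
    stop("invalid config: grader noise sd must be >= 0", call. = FALSE)
  stopifnot(inherits(geometry, "scan_geometry"))
  structure(
    list(n_patients = n_patients, p_ga = p_ga, p_cnv = p_cnv,
         p_drusen = p_drusen, area_meanlog = area_meanlog,
         area_sdlog = area_sdlog, area_range_mm2 = area_range_mm2,
         p_keyword_given_ga = p_keyword_given_ga,
         p_keyword_given_no_ga = p_keyword_given_no_ga,
         grader_sd_mm2 = grader_sd_mm2, grader_bias_mm2 = grader_bias_mm2,
         faf_offset_max_days = as.integer(faf_offset_max_days),
         misfixation_max_mm = misfixation_max_mm,
         pit_depth_um = pit_depth_um, pit_sigma_mm = pit_sigma_mm,
         baseline_thickness_um = baseline_thickness_um,
         thickness_noise_um = thickness_noise_um,
         n_speckles = as.integer(n_speckles),
         age_mean = age_mean, age_sd = age_sd,
         geometry = geometry, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a seeded synthetic cohort with ground truth
#'
#' Draws a cohort of patients with two eyes each under the supplied
#' [cohort_config()]. Every downstream quantity is planted and recorded in
#' a ground-truth table: per eye the true lesion area, true fovea pixel,
#' central / fovea-involving status (computed exhaustively from the planted
#' mask and true fovea) and CNV flag; per patient the letter-keyword status
#' and, when `criteria` are supplied, true eligibility under each trial.
#'
#' Generation is deterministic for a fixed config (the seed is part of the
#' config): identical configs produce identical cohorts.
#'
#' @param config A [cohort_config()].
#' @param criteria Optional list of [trial_criteria()] for which true
#'   eligibility columns are added to the patient ground truth.
#' @return An object of class `cohort`: list with `patients` (list of
#'   patient records), `geometry`, `config`, `truth_eyes` (per-eye ground
#'   truth data frame) and `truth_patients` (per-patient ground truth).
#' @examples
#' co <- generate_cohort(cohort_config(n_patients = 5, seed = 42))
#' head(co$truth_eyes)
#' @export
generate_cohort <- function(config, criteria = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  geom <- config$geometry
  rng <- substream_rng(config$seed, "cohort")
  on.exit(rng$restore(), add = TRUE)

  base_date <- as.Date("2020-01-01")
  shapes <- c("disc", "ellipse", "ring", "multifocal")
  patients <- vector("list", config$n_patients)
  truth_eyes <- list()
  truth_pat <- list()

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%05d", i)
    age <- min(100, max(50, stats::rnorm(1, config$age_mean, config$age_sd)))
    sex <- sample(c("female", "male"), 1, prob = c(0.55, 0.45))
    ethnicity <- sample(c("white", "asian", "black", "mixed", "other", "unknown"),
                        1, prob = c(0.30, 0.16, 0.08, 0.15, 0.01, 0.30))
    imd_decile <- sample(1:10, 1)
    oct_date <- base_date + sample.int(1000L, 1)

    has_ga_patient <- FALSE
    eyes <- list()
    for (lat in c("L", "R")) {
      ga <- stats::runif(1) < config$p_ga
      cnv <- stats::runif(1) < config$p_cnv
      drusen <- stats::runif(1) < config$p_drusen
      if (ga) has_ga_patient <- TRUE

      # fixation offset displaces the true fovea from the grid center
      off_r <- stats::runif(1, -config$misfixation_max_mm,
                            config$misfixation_max_mm) / row_pitch_mm(geom)
      off_c <- stats::runif(1, -config$misfixation_max_mm,
                            config$misfixation_max_mm) / col_pitch_mm(geom)
      fovea_px <- c(round(geom$n_bscans / 2 + off_r),
                    round(geom$n_ascans / 2 + off_c))
      fovea_px <- pmin(pmax(fovea_px, c(1L, 1L)),
                       c(geom$n_bscans - 2L, geom$n_ascans - 2L))

      if (ga) {
        area <- draw_truncated_lognormal(1, config$area_meanlog,
                                         config$area_sdlog,
                                         config$area_range_mm2)
        shape <- sample(shapes, 1)
        # lesion center offset from fovea: mixture of foveal and extrafoveal
        ctr <- stats::rnorm(2, 0, 0.8)
        spec <- lesion_spec(shape, target_area_mm2 = area,
                            center_mm = ctr,
                            n_foci = sample(2:4, 1))
      } else {
        area <- 0
        spec <- lesion_spec("disc", 0)
      }
      absent <- render_lesion(spec, geom, fovea_px)
      true_area <- sum(absent) * pixel_area_mm2(geom)

      rpe <- !absent
      # isolated single-pixel segmentation dropouts (speckle noise)
      if (config$n_speckles > 0) {
        sp <- sample.int(geom$n_bscans * geom$n_ascans, config$n_speckles)
        rpe[sp] <- FALSE
      }

      thick <- synth_thickness(geom, fovea_px, config)

      faf_off <- sample.int(2L * config$faf_offset_max_days + 1L, 1) -
        config$faf_offset_max_days - 1L
      loc <- location_truth(absent, fovea_px, geom)

      eyes[[lat]] <- structure(
        list(laterality = lat, rpe_present = rpe, nsr_thickness = thick,
             ga_flag = ga, cnv_flag = cnv, drusen_flag = drusen,
             oct_date = oct_date, faf_date = oct_date + faf_off,
             true_fovea_px = fovea_px, true_area_mm2 = true_area),
        class = "eye_record")

      truth_eyes[[length(truth_eyes) + 1L]] <- data.frame(
        patient_id = pid, laterality = lat,
        true_area_mm2 = true_area,
        fovea_row = fovea_px[1], fovea_col = fovea_px[2],
        central_ga = loc$central_ga, fovea_involving = loc$fovea_involving,
        ga_flag = ga, cnv_flag = cnv, drusen_flag = drusen,
        stringsAsFactors = FALSE)
    }

    keyword <- if (has_ga_patient) {
      stats::runif(1) < config$p_keyword_given_ga
    } else {
      stats::runif(1) < config$p_keyword_given_no_ga
    }
    letter_date <- oct_date - sample.int(200L, 1)

    pat <- structure(
      list(patient_id = pid, age_years = age, sex = sex,
           ethnicity = ethnicity, imd_decile = imd_decile,
           eyes = eyes, letters = list(), faf_gradings = NULL),
      class = "patient_record")
    pat <- synthesize_letters(pat, include_keyword = keyword,
                              date = letter_date)

    # two simulated FAF graders measure each GA eye
    gradings <- list()
    for (lat in names(eyes)) {
      if (!eyes[[lat]]$ga_flag) next
      for (g in 1:2) {
        meas <- eyes[[lat]]$true_area_mm2 + config$grader_bias_mm2[g] +
          stats::rnorm(1, 0, config$grader_sd_mm2)
        gradings[[length(gradings) + 1L]] <- data.frame(
          laterality = lat, grader_id = paste0("G", g),
          area_mm2 = max(0, meas), stringsAsFactors = FALSE)
      }
    }
    pat$faf_gradings <- if (length(gradings)) do.call(rbind, gradings) else
      data.frame(laterality = character(0), grader_id = character(0),
                 area_mm2 = numeric(0), stringsAsFactors = FALSE)

    patients[[i]] <- pat
    truth_pat[[i]] <- data.frame(
      patient_id = pid, age_years = age, keyword_in_letters = keyword,
      stringsAsFactors = FALSE)
  }

  truth_eyes <- do.call(rbind, truth_eyes)
  truth_pat <- do.call(rbind, truth_pat)

  cohort <- structure(
    list(patients = patients, geometry = geom, config = config,
         truth_eyes = truth_eyes, truth_patients = truth_pat),
    class = "cohort")

  if (!is.null(criteria)) {
    if (inherits(criteria, "trial_criteria")) criteria <- list(criteria)
    for (cr in criteria) {
      cohort$truth_patients[[paste0("eligible_", cr$trial_id)]] <-
        true_eligibility(cohort, cr)
    }
  }
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d patients, %d eyes (%d GA, %d CNV)\n",
              length(x$patients), nrow(x$truth_eyes),
              sum(x$truth_eyes$ga_flag), sum(x$truth_eyes$cnv_flag)))
  invisible(x)
}

# truncated log-normal by rejection; deterministic under the active RNG
draw_truncated_lognormal <- function(n, meanlog, sdlog, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n * 4, meanlog, sdlog)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

# thickness map: baseline + Gaussian foveal pit + noise, all in micrometres
synth_thickness <- function(geom, fovea_px, config) {
  ctr <- pixel_center_mm(geom)
  fy <- (fovea_px[1] + 0.5) * row_pitch_mm(geom)
  fx <- (fovea_px[2] + 0.5) * col_pitch_mm(geom)
  pit <- config$pit_depth_um *
    exp(-outer((ctr$y - fy)^2, (ctr$x - fx)^2, `+`) /
          (2 * config$pit_sigma_mm^2))
  noise <- matrix(stats::rnorm(geom$n_bscans * geom$n_ascans,
                               0, config$thickness_noise_um),
                  geom$n_bscans, geom$n_ascans)
  pmax(config$baseline_thickness_um - pit + noise, 0)
}

# ground-truth location flags by exhaustive distance scan over every absent
# pixel (independent of classify_location's early exits)
location_truth <- function(absent, fovea_px, geom, radius_um = 1500) {
  if (!any(absent))
    return(list(central_ga = FALSE, fovea_involving = FALSE))
  rp <- row_pitch_mm(geom); cp <- col_pitch_mm(geom)
  idx <- which(absent, arr.ind = TRUE)
  dy <- (idx[, 1] - 1L - fovea_px[1]) * rp
  dx <- (idx[, 2] - 1L - fovea_px[2]) * cp
  list(central_ga = min(dy^2 + dx^2) <= (radius_um / 1000)^2,
       fovea_involving = isTRUE(absent[fovea_px[1] + 1L, fovea_px[2] + 1L]))
}

# eligibility from planted truth (true areas, true location flags, flags),
# bypassing the imaging pipeline entirely
true_eligibility <- function(cohort, criteria) {
  te <- cohort$truth_eyes
  out <- logical(length(cohort$patients))
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    rows <- te[te$patient_id == p$patient_id, ]
    elig <- FALSE
    for (j in seq_len(nrow(rows))) {
      fellow <- rows[-j, ]
      fellow_cnv <- if (nrow(fellow)) any(fellow$cnv_flag) else NA
      v <- check_criteria(
        age = p$age_years, ga = rows$ga_flag[j], cnv = rows$cnv_flag[j],
        fellow_cnv = fellow_cnv, area = rows$true_area_mm2[j],
        central = rows$central_ga[j],
        fovea_involving = rows$fovea_involving[j], criteria = criteria)
      if (v$eligible) { elig <- TRUE; break }
    }
    out[i] <- elig
  }
  out
}

#' Attach synthetic clinical letters to a patient
#'
#' Writes a small set of plausible clinic letters. When `include_keyword` is
#' TRUE, exactly one letter (dated `date`) contains the literal phrase
#' "geographic atrophy" (mixed case, exercising case-insensitive search);
#' the remaining letters are decoys with near-miss wording ("atrophic
#' changes", "macular atrophy") that a plain keyword search must not match.
#'
#' @param patient A `patient_record`.
#' @param include_keyword Whether any letter should contain the keyword.
#' @param date Date of the keyword letter (and anchor for decoy dates).
#' @return The patient with its `letters` field replaced; letters are
#'   sorted by ascending date.
#' @export
synthesize_letters <- function(patient, include_keyword, date) {
  date <- as.Date(date)
  letters <- list(
    list(date = date - 300,
         text = "Review in clinic. Early drusen noted at the macula; no atrophic changes seen today."),
    list(date = date - 150,
         text = "Fundus examination shows macular atrophy of indeterminate cause; continue observation.")
  )
  if (isTRUE(include_keyword)) {
    letters[[length(letters) + 1L]] <- list(
      date = date,
      text = "OCT today confirms areas of Geographic Atrophy in the macula; discussed prognosis with the patient.")
  } else {
    letters[[length(letters) + 1L]] <- list(
      date = date,
      text = "Stable appearance; atrophic changes at the fovea without definite progression.")
  }
  ord <- order(vapply(letters, function(l) as.numeric(l$date), numeric(1)))
  patient$letters <- letters[ord]
  patient
}
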