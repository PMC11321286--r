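# Trial-criteria engine and shortlisting.

horizon <- read_criteria(example_criteria_path("horizon"))
prof <- function(area, central = TRUE, fovea = FALSE)
  list(area_mm2 = area, central_ga = central, fovea_involving = fovea)

test_that("HORIZON area bounds are inclusive and age is strict", {
  v <- evaluate_eye(prof(1.25), TRUE, FALSE, FALSE, 70, horizon)
  expect_true(v$eligible)
  expect_true(evaluate_eye(prof(17.5), TRUE, FALSE, FALSE, 70,
                           horizon)$eligible)
  expect_false(evaluate_eye(prof(1.2499), TRUE, FALSE, FALSE, 70,
                            horizon)$eligible)
  # "aged >55": 55 exactly fails, 55.01 passes
  expect_false(evaluate_eye(prof(5), TRUE, FALSE, FALSE, 55,
                            horizon)$eligible)
  expect_true(evaluate_eye(prof(5), TRUE, FALSE, FALSE, 55.01,
                           horizon)$eligible)
})

test_that("an area below another trial's 2.5 mm^2 floor still passes HORIZON", {
  derby <- read_criteria(example_criteria_path("derby"))
  v_h <- evaluate_eye(prof(2.0), TRUE, FALSE, FALSE, 70, horizon)
  v_d <- evaluate_eye(prof(2.0), TRUE, FALSE, FALSE, 70, derby)
  expect_true(v_h$eligible)
  expect_false(v_d$eligible)
  expect_true("area_below_min" %in% v_d$failed)
})

test_that("fellow-eye CNV excludes from trials that require its absence", {
  gather2 <- read_criteria(example_criteria_path("gather2"))
  # central, non-fovea-involving GA but fellow-eye CNV
  v <- evaluate_eye(prof(5, central = TRUE, fovea = FALSE),
                    TRUE, FALSE, TRUE, 70, gather2)
  expect_false(v$eligible)
  expect_true("fellow_eye_cnv" %in% v$failed)
  # HORIZON ignores the fellow eye
  expect_true(evaluate_eye(prof(5), TRUE, FALSE, TRUE, 70,
                           horizon)$eligible)
  # missing fellow data: strict policy marks ineligible
  v2 <- evaluate_eye(prof(5), TRUE, FALSE, NA, 70, gather2)
  expect_false(v2$eligible)
  expect_true("fellow_eye_missing" %in% v2$failed)
})

test_that("location requirements are enforced", {
  gather2 <- read_criteria(example_criteria_path("gather2"))
  expect_false(evaluate_eye(prof(5, central = FALSE), TRUE, FALSE, FALSE,
                            70, gather2)$eligible)
  expect_false(evaluate_eye(prof(5, central = TRUE, fovea = TRUE),
                            TRUE, FALSE, FALSE, 70, gather2)$eligible)
  expect_true(evaluate_eye(prof(5, central = TRUE, fovea = FALSE),
                           TRUE, FALSE, FALSE, 70, gather2)$eligible)
})

test_that("criteria JSON validation names the offending field", {
  bad <- tempfile(fileext = ".json")
  writeLines('{"trial_id":"X","area_min_mm2":5,"area_max_mm2":2}', bad)
  expect_error(read_criteria(bad), "area_min_mm2")
})

make_cohort <- function(n = 20, seed = 21)
  generate_cohort(cohort_config(n_patients = n, seed = seed,
                                geometry = scan_geometry(48, 96, 6, 6)))

test_that("shortlists obey set algebra and match planted eligibility", {
  co <- make_cohort()
  profiles <- profile_cohort(co)
  ehr <- ehr_search_cohort(co)
  ai <- shortlist(co, profiles, horizon, "ai", ehr_flags = ehr)
  eh <- shortlist(co, profiles, horizon, "ehr", ehr_flags = ehr)
  comb <- shortlist(co, profiles, horizon, "combined", ehr_flags = ehr)
  expect_true(all(comb %in% ai))
  expect_true(all(comb %in% eh))
  expect_lte(length(comb), min(length(ai), length(eh)))
  expect_equal(ai, sort(ai))
  expect_error(shortlist(co, profiles, horizon, "nonsense"), "mode")
  # per-patient verdict: eligible patient <=> >= 1 eligible eye
  verdicts <- evaluate_cohort(co, profiles, horizon)
  for (pid in unique(verdicts$patient_id)) {
    rows <- verdicts[verdicts$patient_id == pid, ]
    expect_equal(unique(rows$patient_eligible), any(rows$eligible))
  }
})

test_that("relaxing criteria never shrinks the shortlist", {
  co <- make_cohort(30, seed = 4)
  profiles <- profile_cohort(co)
  strict <- trial_criteria("S", min_age_years = 55, area_min_mm2 = 2.5,
                           area_max_mm2 = 12, require_no_study_eye_cnv = TRUE,
                           require_central_ga = TRUE)
  relaxed <- trial_criteria("R", min_age_years = 55, area_min_mm2 = 1.0,
                            area_max_mm2 = 20, require_no_study_eye_cnv = TRUE,
                            require_central_ga = FALSE)
  s1 <- shortlist(co, profiles, strict, "ai")
  s2 <- shortlist(co, profiles, relaxed, "ai")
  expect_true(all(s1 %in% s2))
})

test_that("shortlists are deterministic across repeated evaluation", {
  co <- make_cohort(10, seed = 6)
  profiles <- profile_cohort(co)
  expect_identical(shortlist(co, profiles, horizon, "ai"),
                   shortlist(co, profiles, horizon, "ai"))
})
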