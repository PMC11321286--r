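# GA area quantification, fovea localisation, location classification.

test_that("area is absent-pixel count times pixel area", {
  geom <- scan_geometry(128, 512, 6, 6)
  all_present <- matrix(TRUE, 128, 512)
  expect_equal(compute_ga_area(all_present, geom)$area_mm2, 0)
  all_absent <- matrix(FALSE, 128, 512)
  expect_equal(compute_ga_area(all_absent, geom)$area_mm2, 36)

  # frozen: 5243 absent pixels on the default grid, pixel area
  # (6/512)(6/128) mm^2, so 5243 * 36 / 65536 = 2.88 mm^2
  rpe <- matrix(TRUE, 128, 512)
  rpe[1:64, 1:81] <- FALSE          # 64*81 = 5184
  rpe[65, 1:59] <- FALSE            # + 59 -> 5243, one connected block
  got <- compute_ga_area(rpe, geom, min_component_mm2 = 0)$area_mm2
  expect_equal(got, 5243 * (6 / 512) * (6 / 128))
  expect_equal(round(got, 2), 2.88)
})

test_that("dimension mismatch raises a geometry error", {
  geom <- scan_geometry(32, 32, 6, 6)
  expect_error(compute_ga_area(matrix(TRUE, 16, 16), geom), "dimensions")
})

test_that("the speckle filter removes sub-threshold components only", {
  geom <- scan_geometry(128, 512, 6, 6)
  rpe <- matrix(TRUE, 128, 512)
  rpe[60:70, 200:300] <- FALSE                   # large block, ~0.61 mm^2
  rpe[cbind(c(5, 20, 120), c(10, 400, 50))] <- FALSE  # isolated speckles
  res <- compute_ga_area(rpe, geom)
  expect_equal(res$area_mm2, 11 * 101 * pixel_area_mm2(geom))
  # filter off keeps the speckles
  res0 <- compute_ga_area(rpe, geom, min_component_mm2 = 0)
  expect_equal(res0$area_mm2, (11 * 101 + 3) * pixel_area_mm2(geom))
})

test_that("area is monotone in added absent pixels", {
  geom <- small_geometry()
  set.seed(42)
  rpe <- matrix(runif(32 * 32) > 0.3, 32, 32)
  a1 <- compute_ga_area(rpe, geom, min_component_mm2 = 0)$area_mm2
  rpe2 <- rpe
  rpe2[sample(which(rpe2), 20)] <- FALSE
  a2 <- compute_ga_area(rpe2, geom, min_component_mm2 = 0)$area_mm2
  expect_gte(a2, a1)
})

test_that("fovea is recovered from a planted pit", {
  geom <- scan_geometry(128, 512, 6, 6)
  cfg <- cohort_config(geometry = geom)
  set.seed(1)
  thick <- gascreenr:::synth_thickness(geom, c(64, 256), cfg)
  got <- locate_fovea(thick, geom)
  expect_lte(abs(got[1] - 64), 3)
  expect_lte(abs(got[2] - 256), 3)

  # translated pit: +0.5 mm laterally = +42.7 columns
  set.seed(1)
  thick2 <- gascreenr:::synth_thickness(geom, c(64, 299), cfg)
  got2 <- locate_fovea(thick2, geom)
  expect_lte(abs(got2[2] - 299), 3)
})

test_that("constant thickness map degenerates to the window center with a warning", {
  geom <- small_geometry()
  expect_warning(got <- locate_fovea(matrix(100, 32, 32), geom), "degenerate")
  expect_true(all(got >= 8 & got <= 24))
})

test_that("location classification matches the geometric oracle on key shapes", {
  geom <- scan_geometry(256, 256, 6, 6)
  fovea <- c(128L, 128L)
  # foveal disc
  disc <- render_lesion(lesion_spec("disc", 3), geom, fovea)
  expect_equal(classify_location(disc, fovea, geom),
               list(central_ga = TRUE, fovea_involving = TRUE))
  # perifoveal ring 0.8-1.2 mm: central but not fovea-involving
  ring <- render_lesion(lesion_spec("ring", inner_radius_mm = 0.8,
                                    outer_radius_mm = 1.2), geom, fovea)
  expect_equal(classify_location(ring, fovea, geom),
               list(central_ga = TRUE, fovea_involving = FALSE))
  # distant lesion beyond 1.6 mm: neither
  far <- render_lesion(lesion_spec("disc", 0.5, center_mm = c(2.2, 0)),
                       geom, fovea)
  expect_equal(classify_location(far, fovea, geom),
               list(central_ga = FALSE, fovea_involving = FALSE))
})

test_that("translating mask and fovea together preserves area and flags", {
  geom <- scan_geometry(64, 64, 6, 6)
  m <- render_lesion(lesion_spec("disc", 1.5, center_mm = c(0.4, 0.2)),
                     geom, c(30, 30))
  base <- classify_location(m, c(30L, 30L), geom)
  shifted <- matrix(FALSE, 64, 64)
  shifted[6:64, 6:64] <- m[1:59, 1:59]
  expect_equal(sum(shifted), sum(m))   # no edge clipping at this offset
  expect_equal(classify_location(shifted, c(35L, 35L), geom), base)
})

test_that("profile_eye composes the metrics consistently", {
  geom <- scan_geometry(64, 128, 6, 6)
  cfg <- cohort_config(geometry = geom)
  set.seed(2)
  thick <- gascreenr:::synth_thickness(geom, c(32, 64), cfg)
  # non-GA eye, intact RPE
  eye <- structure(list(laterality = "L",
                        rpe_present = matrix(TRUE, 64, 128),
                        nsr_thickness = thick, ga_flag = FALSE,
                        cnv_flag = FALSE), class = "eye_record")
  pr <- profile_eye(eye, geom)
  expect_equal(pr$area_mm2, 0)
  expect_false(pr$central_ga)
  expect_false(pr$fovea_involving)
  # 3 mm^2 foveal disc
  m <- render_lesion(lesion_spec("disc", 3), geom, c(32, 64))
  eye$rpe_present <- !m
  eye$ga_flag <- TRUE
  pr2 <- profile_eye(eye, geom)
  expect_lt(abs(pr2$area_mm2 - 3), rendering_tolerance_mm2(m, geom))
  expect_true(pr2$central_ga && pr2$fovea_involving)
  # invariant: fovea_involving implies central
  expect_true(!pr2$fovea_involving || pr2$central_ga)
  # missing map errors
  eye$nsr_thickness <- NULL
  expect_error(profile_eye(eye, geom), "incomplete")
})

test_that("multifocal extrafoveal lesions 2 mm out are not central", {
  geom <- scan_geometry(256, 256, 8, 8)
  fovea <- c(128L, 128L)
  mask <- matrix(FALSE, 256, 256)
  for (ang in c(0, 2 * pi / 3, 4 * pi / 3)) {
    m <- render_lesion(lesion_spec("disc", 0.3,
                                   center_mm = 2.2 * c(cos(ang), sin(ang))),
                       geom, fovea)
    mask <- mask | m
  }
  loc <- classify_location(mask, fovea, geom)
  expect_false(loc$central_ga)
})
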