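# Stratified validation statistics: strata, PPV, yield, agreement measures.

test_that("strata partition the union of shortlists", {
  ids <- sprintf("P%02d", 1:50)
  ai <- ids[c(1:20, 31:35)]
  ehr <- ids[c(10:25, 40:45)]
  st <- assign_strata(ids, ai, ehr)
  expect_equal(st$stratum[st$patient_id %in% intersect(ai, ehr)],
               rep("A1", length(intersect(ai, ehr))))
  expect_equal(st$stratum[st$patient_id %in% setdiff(ai, ehr)],
               rep("A2", length(setdiff(ai, ehr))))
  expect_equal(st$stratum[st$patient_id %in% setdiff(ehr, ai)],
               rep("B1", length(setdiff(ehr, ai))))
  # disjoint cover of ai U ehr, nothing else labeled
  labeled <- st$patient_id[!is.na(st$stratum)]
  expect_setequal(labeled, union(ai, ehr))
  expect_false(anyDuplicated(labeled) > 0)
})

test_that("validation sampling honours the 90-day FAF window inclusively", {
  co <- generate_cohort(cohort_config(n_patients = 12, seed = 31,
                                      faf_offset_max_days = 150,
                                      geometry = scan_geometry(24, 48, 6, 6)))
  # force known offsets: patient 1 exactly 90 days (in), patient 2 at 91 (out)
  co$patients[[1]]$eyes$L$faf_date <- co$patients[[1]]$eyes$L$oct_date + 90
  co$patients[[1]]$eyes$R$faf_date <- co$patients[[1]]$eyes$R$oct_date - 90
  co$patients[[2]]$eyes$L$faf_date <- co$patients[[2]]$eyes$L$oct_date + 91
  ids <- c("P00001", "P00002")
  ok <- sample_for_validation(co, ids, 1, seed = 1)
  expect_equal(ok, "P00001")
  expect_error(sample_for_validation(co, ids, 2, seed = 1), "shortfall")
  # seeded determinism on a larger pool
  all_ids <- vapply(co$patients, `[[`, character(1), "patient_id")
  pool_ids <- all_ids[vapply(co$patients, function(p)
    all(vapply(p$eyes, function(e)
      abs(as.numeric(e$faf_date - e$oct_date)) <= 90, logical(1))),
    logical(1))]
  if (length(pool_ids) >= 3) {
    s1 <- sample_for_validation(co, pool_ids, 3, seed = 99)
    s2 <- sample_for_validation(co, pool_ids, 3, seed = 99)
    expect_identical(s1, s2)
  }
})

test_that("PPV point estimates and edge cases", {
  expect_error(ppv(stratum_sample("A1", 0, 0)), "undefined")
  z <- ppv(stratum_sample("A1", 50, 0), seed = 1)
  expect_equal(z$percent, 0)
  expect_equal(unname(z$ci_percent), c(0, 0))
  expect_error(stratum_sample("A1", 10, 11), "n_eligible")
})

test_that("yield saturates when every stratum PPV is 1", {
  vt <- validation_table(list(
    stratum_sample("A1", 10, 10, population = 100),
    stratum_sample("A2", 10, 10, population = 200),
    stratum_sample("B1", 10, 10, population = 50)))
  y <- estimate_cohort_yield(vt, "ai", n_boot = 100, seed = 1)
  expect_equal(y$estimate, 300)
  expect_equal(y$rate, 1)
  # missing stratum raises a coverage error
  vt2 <- validation_table(list(stratum_sample("A1", 10, 5, population = 100)))
  expect_error(estimate_cohort_yield(vt2, "ai", n_boot = 10), "stratum")
})

test_that("Bland-Altman limits match hand computation", {
  expect_error(bland_altman(1, 1), "insufficient|equal length")
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)
  expect_equal(unname(same$loa), c(0, 0))
  off <- bland_altman(c(3, 4, 5), c(1, 2, 3))
  expect_equal(off$mean_diff, 2)
  expect_equal(unname(off$loa), c(2, 2))
  tri <- bland_altman(c(0, 1, 2), c(1, 1, 1))  # differences -1, 0, 1
  expect_equal(tri$mean_diff, 0)
  expect_equal(tri$sd_diff, 1)                  # sd with n-1 denominator
  expect_equal(unname(tri$loa), c(-1.96, 1.96))
})

test_that("Bland-Altman limits contain ~95% of Gaussian differences", {
  set.seed(123)
  n <- 1000
  truth <- runif(n, 1, 20)
  a <- truth + rnorm(n, 0.5, 1.2)
  b <- truth + rnorm(n, 0, 1.0)
  ba <- bland_altman(a, b)
  inside <- mean(ba$differences >= ba$loa[1] & ba$differences <= ba$loa[2])
  expect_gte(inside, 0.93)
  expect_lte(inside, 0.97)
})

test_that("ICC(A,1) matches the ANOVA oracle and known limits", {
  # identical raters: perfect agreement
  set.seed(7)
  x <- rnorm(10, 10, 3)
  expect_equal(icc_agreement(cbind(x, x), n_boot = 50, seed = 1)$icc, 1)
  # large constant bias with tiny subject variance: near zero (agreement form)
  y <- rnorm(8, 10, 0.01)
  biased <- icc_agreement(cbind(y, y + 50), n_boot = 50, seed = 1)$icc
  expect_lt(abs(biased), 0.01)
  # hand-checkable 4-subject fixture
  m <- matrix(c(9, 6, 8, 7, 8, 4, 9, 8), ncol = 2)
  expect_equal(icc_agreement(m, n_boot = 50, seed = 1)$icc, oracle_icc(m),
               tolerance = 1e-9)
  # constant matrix degenerates with a warning
  expect_warning(z <- icc_agreement(matrix(5, 4, 2), n_boot = 10, seed = 1),
                 "degenerate")
  expect_equal(z$icc, 0)
  expect_error(icc_agreement(matrix(1:2, 1, 2)), "subjects")
})

test_that("bootstrap group comparison behaves at the extremes", {
  set.seed(11)
  a <- rnorm(200, 5, 1)
  same <- bootstrap_group_compare(a, a, "mean", n_boot = 500, seed = 3)
  expect_gt(same$p_value, 0.5)
  sep <- bootstrap_group_compare(rnorm(100, 0, 1), rnorm(100, 10, 1),
                                 "mean", n_boot = 500, seed = 3)
  expect_lte(sep$p_value, 2 / 500)
  # determinism
  p1 <- bootstrap_group_compare(a, a + 0.1, "mean", n_boot = 200, seed = 5)
  p2 <- bootstrap_group_compare(a, a + 0.1, "mean", n_boot = 200, seed = 5)
  expect_identical(p1$p_value, p2$p_value)
  # proportions
  g1 <- rep(c(0, 1), c(20, 80))
  g2 <- rep(c(0, 1), c(80, 20))
  expect_lt(bootstrap_group_compare(g1, g2, "proportion", n_boot = 500,
                                    seed = 2)$p_value, 0.01)
  expect_error(bootstrap_group_compare(numeric(0), g2), "non-empty")
})

test_that("agreement pairs average the two graders against the AI area", {
  co <- generate_cohort(cohort_config(n_patients = 10, seed = 13,
                                      geometry = scan_geometry(48, 96, 6, 6)))
  profiles <- profile_cohort(co)
  pairs <- agreement_pairs(co, profiles)
  if (nrow(pairs)) {
    expect_equal(pairs$faf_mean_mm2,
                 (pairs$grader_G1 + pairs$grader_G2) / 2)
    expect_true(all(pairs$ai_mm2 >= 0))
  }
  expect_true(nrow(pairs) == sum(co$truth_eyes$ga_flag))
})
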