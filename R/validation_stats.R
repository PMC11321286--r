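#' Assign clinical-validation strata
#'
#' Patients flagged by either screening route are split into three disjoint
#' strata for validation sampling: A1 (AI-shortlisted with an affirmative
#' EHR result), A2 (AI-shortlisted, negative EHR) and B1 (affirmative EHR
#' but not AI-shortlisted). Patients in neither route are unlabeled (`NA`).
#'
#' @param patient_ids Character vector of all patient ids in the cohort.
#' @param ai_shortlist Ids shortlisted by the imaging pipeline.
#' @param ehr_shortlist Ids with an affirmative EHR keyword result.
#' @return Data frame with `patient_id` and `stratum`
#'   (`"A1"`/`"A2"`/`"B1"`/`NA`).
#' @export
assign_strata <- function(patient_ids, ai_shortlist, ehr_shortlist) {
  stratum <- rep(NA_character_, length(patient_ids))
  in_ai <- patient_ids %in% ai_shortlist
  in_ehr <- patient_ids %in% ehr_shortlist
  stratum[in_ai & in_ehr] <- "A1"
  stratum[in_ai & !in_ehr] <- "A2"
  stratum[!in_ai & in_ehr] <- "B1"
  data.frame(patient_id = patient_ids, stratum = stratum,
             stringsAsFactors = FALSE)
}

#' Sample patients for clinical validation
#'
#' Uniform random sampling without replacement from a stratum, restricted
#' to patients for whom an FAF image was acquired within `faf_window_days`
#' on either side of the OCT for both eyes (inclusive at exactly the window
#' edge). Seeded and deterministic.
#'
#' @param cohort A `cohort`.
#' @param member_ids Patient ids of the stratum.
#' @param n Sample size.
#' @param seed Seed for the sampling substream.
#' @param faf_window_days Maximum |FAF date - OCT date| in days.
#' @return Character vector of `n` sampled patient ids.
#' @export
sample_for_validation <- function(cohort, member_ids, n, seed,
                                  faf_window_days = 90) {
  pool <- Filter(function(pid) {
    p <- cohort$patients[[match(pid, vapply(cohort$patients,
                                            `[[`, character(1),
                                            "patient_id"))]]
    all(vapply(p$eyes, function(e) {
      !is.null(e$faf_date) && !is.na(e$faf_date) &&
        abs(as.numeric(e$faf_date - e$oct_date)) <= faf_window_days
    }, logical(1)))
  }, member_ids)
  if (length(pool) < n)
    stop(sprintf("validation pool shortfall: %d available after the %d-day FAF window, %d requested",
                 length(pool), faf_window_days, n), call. = FALSE)
  rng <- substream_rng(seed, "validation_sampling")
  on.exit(rng$restore(), add = TRUE)
  sort(sample(pool, n))
}

#' Stratum sample of validation outcomes
#'
#' @param stratum Stratum label (`"A1"`, `"A2"`, `"B1"`).
#' @param n_sampled Number of patients graded.
#' @param n_eligible Number judged truly eligible.
#' @param population Stratum size in the full cohort (optional here,
#'   required for yield inference).
#' @return A `stratum_sample`.
#' @export
stratum_sample <- function(stratum, n_sampled, n_eligible,
                           population = NA_integer_) {
  if (n_sampled < 0 || n_eligible < 0 || n_eligible > n_sampled)
    stop("require 0 <= n_eligible <= n_sampled", call. = FALSE)
  if (!is.na(population) && population < n_sampled)
    stop("stratum population smaller than its sample", call. = FALSE)
  structure(list(stratum = stratum, n_sampled = as.integer(n_sampled),
                 n_eligible = as.integer(n_eligible),
                 population = as.integer(population)),
            class = "stratum_sample")
}

#' Positive predictive value with a percentile-bootstrap CI
#'
#' Point estimate `n_eligible / n_sampled`; the CI resamples the graded
#' binary outcomes with replacement (equivalently, binomial resampling)
#' and takes percentile limits.
#'
#' @param sample A [stratum_sample()], or `n_eligible` when `n_sampled`
#'   is given.
#' @param n_sampled Optional; sample size when `sample` is a count.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Seed for the bootstrap substream.
#' @param conf Confidence level.
#' @return List with `estimate` (proportion), `percent` (whole-percent,
#'   half-up), `ci` (length-2 proportion scale), `ci_percent`, `n_sampled`,
#'   `n_eligible`.
#' @examples
#' ppv(stratum_sample("A1", 98, 84))$percent  # 86
#' @export
ppv <- function(sample, n_sampled = NULL, n_boot = 10000, seed = 1,
                conf = 0.95) {
  if (!inherits(sample, "stratum_sample")) {
    sample <- stratum_sample("?", n_sampled, sample)
  }
  if (sample$n_sampled == 0)
    stop("PPV undefined for an empty sample", call. = FALSE)
  phat <- sample$n_eligible / sample$n_sampled
  rng <- substream_rng(seed, "ppv_bootstrap")
  on.exit(rng$restore(), add = TRUE)
  boot <- stats::rbinom(n_boot, sample$n_sampled, phat) / sample$n_sampled
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  list(estimate = phat,
       percent = round_half_up(100 * phat),
       ci = ci,
       ci_percent = round_half_up(100 * ci),
       n_sampled = sample$n_sampled,
       n_eligible = sample$n_eligible)
}

#' Build a validation table from stratum samples
#'
#' @param samples List of [stratum_sample()] objects, one per stratum
#'   (A1/A2/B1), each carrying its population size.
#' @return A `validation_table`.
#' @export
validation_table <- function(samples) {
  labs <- vapply(samples, `[[`, character(1), "stratum")
  if (anyDuplicated(labs)) stop("duplicate strata", call. = FALSE)
  structure(stats::setNames(samples, labs), class = "validation_table")
}

#' Infer the eligible yield of a shortlist by stratified weighting
#'
#' The number of truly eligible patients among those shortlisted is
#' estimated as a weighted sum over the strata the shortlist covers:
#' `sum(population_s * PPV_s)`. The AI shortlist covers strata A1 and A2,
#' the EHR shortlist A1 and B1, and the combined AI-EHR shortlist A1 alone.
#' The rate divides by the shortlist size (the summed populations). The CI
#' resamples each stratum's validation outcomes independently (binomial
#' bootstrap) and propagates through the weighted sum, matching the
#' stratified design.
#'
#' @param table A [validation_table()] with populations.
#' @param target One of `"ai"`, `"ehr"`, `"combined"`.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap substream.
#' @param conf Confidence level.
#' @return List with `estimate` (expected eligible count), `rate`
#'   (proportion), `rate_percent` (whole-percent, half-up), `ci_count`,
#'   `ci_rate`, `ci_rate_percent`, `shortlist_size`.
#' @export
estimate_cohort_yield <- function(table, target = c("ai", "ehr", "combined"),
                                  n_boot = 10000, seed = 1, conf = 0.95) {
  stopifnot(inherits(table, "validation_table"))
  target <- match.arg(target)
  cover <- switch(target, ai = c("A1", "A2"), ehr = c("A1", "B1"),
                  combined = "A1")
  missing <- setdiff(cover, names(table))
  if (length(missing))
    stop(sprintf("validation table does not cover stratum %s required for target '%s'",
                 paste(missing, collapse = ", "), target), call. = FALSE)
  strata <- table[cover]
  pops <- vapply(strata, `[[`, integer(1), "population")
  if (any(is.na(pops)))
    stop("population sizes required for yield inference", call. = FALSE)
  phat <- vapply(strata, function(s) s$n_eligible / s$n_sampled, numeric(1))
  est <- sum(pops * phat)
  size <- sum(pops)
  rng <- substream_rng(seed, "yield_bootstrap")
  on.exit(rng$restore(), add = TRUE)
  boot <- numeric(n_boot)
  ns <- vapply(strata, `[[`, integer(1), "n_sampled")
  boot_mat <- mapply(function(n, p) stats::rbinom(n_boot, n, p) / n,
                     ns, phat)
  boot <- as.numeric(boot_mat %*% pops)
  alpha <- (1 - conf) / 2
  ci_count <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  list(estimate = est,
       rate = est / size,
       rate_percent = round_half_up(100 * est / size),
       ci_count = ci_count,
       ci_rate = ci_count / size,
       ci_rate_percent = round_half_up(100 * ci_count / size),
       shortlist_size = size,
       target = target)
}

#' Bland-Altman agreement analysis
#'
#' Mean difference between paired measurements (a - b) and 95% limits of
#' agreement, mean +/- 1.96 standard deviations of the differences
#' (sample sd, n-1 denominator).
#'
#' @param a,b Paired measurements (e.g. averaged FAF grader area and
#'   AI-derived OCT area), mm^2.
#' @return List with `mean_diff`, `sd_diff`, `loa` (lower, upper) and the
#'   differences.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired inputs of equal length required",
                                   call. = FALSE)
  if (length(a) < 2)
    stop("insufficient data: at least 2 pairs required", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("measurements must be finite", call. = FALSE)
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       loa = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
       differences = d)
}

#' Intraclass correlation, two-way mixed effects, absolute agreement
#'
#' Single-measurement ICC for agreement, ICC(A,1), from the two-way ANOVA
#' decomposition with subjects as random rows and raters as fixed columns:
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))}
#' where MS_R, MS_C and MS_E are the subject, rater and residual mean
#' squares. Unlike the consistency form, a constant rater bias lowers this
#' ICC. The CI is a subject-level percentile bootstrap.
#'
#' @param ratings Numeric matrix, one row per subject, one column per
#'   rater; no missing cells.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Seed for the bootstrap substream.
#' @param conf Confidence level.
#' @return List with `icc`, `ci`, and the mean squares `ms_rows`,
#'   `ms_cols`, `ms_error`. Zero between-subject variance yields ICC 0
#'   with a warning.
#' @export
icc_agreement <- function(ratings, n_boot = 10000, seed = 1, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2)
    stop("need >= 2 subjects and >= 2 raters", call. = FALSE)
  if (anyNA(ratings)) stop("missing cells are not supported", call. = FALSE)

  icc_point <- function(x) {
    n <- nrow(x); k <- ncol(x)
    gm <- mean(x)
    rm_ <- rowMeans(x); cm <- colMeans(x)
    msr <- k * sum((rm_ - gm)^2) / (n - 1)
    msc <- n * sum((cm - gm)^2) / (k - 1)
    resid <- x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm
    mse <- sum(resid^2) / ((n - 1) * (k - 1))
    denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
    if (abs(denom) < .Machine$double.eps * 100) return(NA_real_)
    (msr - mse) / denom
  }

  point <- icc_point(ratings)
  gm <- mean(ratings)
  rm_ <- rowMeans(ratings); cm <- colMeans(ratings)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  resid <- ratings - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm
  mse <- sum(resid^2) / ((n - 1) * (k - 1))

  if (is.na(point)) {
    warning("degenerate ratings (zero variance); ICC reported as 0")
    point <- 0
  }
  rng <- substream_rng(seed, "icc_bootstrap")
  on.exit(rng$restore(), add = TRUE)
  boot <- vapply(seq_len(n_boot), function(b) {
    xb <- ratings[sample.int(n, n, replace = TRUE), , drop = FALSE]
    v <- icc_point(xb)
    if (is.na(v)) 0 else v
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(icc = point,
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       ms_rows = msr, ms_cols = msc, ms_error = mse,
       n_subjects = n, n_raters = k)
}

#' Two-sided bootstrap comparison of two groups
#'
#' Tests the difference in a summary statistic (mean, or proportion for
#' binary data) between two groups under a bootstrap null of zero
#' difference. For means, both groups are shifted to the pooled mean and
#' resampled with replacement (shifted null); for proportions, both groups
#' are resampled from the pooled data. The p-value is the proportion of
#' null resamples whose |difference| is at least the observed |difference|,
#' with a +1/(n_boot+1) continuity adjustment so p is never exactly 0.
#'
#' @param group_a,group_b Numeric vectors (0/1 for proportions).
#' @param statistic `"mean"` or `"proportion"`.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Seed for the bootstrap substream.
#' @return List with `p_value`, `observed_diff`, `statistic`.
#' @export
bootstrap_group_compare <- function(group_a, group_b,
                                    statistic = c("mean", "proportion"),
                                    n_boot = 10000, seed = 1) {
  statistic <- match.arg(statistic)
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty", call. = FALSE)
  stat <- mean  # proportion of a 0/1 vector is its mean
  obs <- stat(group_a) - stat(group_b)
  na <- length(group_a); nb <- length(group_b)
  rng <- substream_rng(seed, "group_compare_bootstrap")
  on.exit(rng$restore(), add = TRUE)
  if (statistic == "mean") {
    pooled_mean <- mean(c(group_a, group_b))
    a0 <- group_a - mean(group_a) + pooled_mean
    b0 <- group_b - mean(group_b) + pooled_mean
    diffs <- vapply(seq_len(n_boot), function(i) {
      mean(a0[sample.int(na, na, replace = TRUE)]) -
        mean(b0[sample.int(nb, nb, replace = TRUE)])
    }, numeric(1))
  } else {
    pooled <- c(group_a, group_b)
    np <- length(pooled)
    diffs <- vapply(seq_len(n_boot), function(i) {
      mean(pooled[sample.int(np, na, replace = TRUE)]) -
        mean(pooled[sample.int(np, nb, replace = TRUE)])
    }, numeric(1))
  }
  p <- (sum(abs(diffs) >= abs(obs)) + 1) / (n_boot + 1)
  list(p_value = p, observed_diff = obs, statistic = statistic)
}

#' Average each eye's FAF gradings and pair with the AI area
#'
#' Builds the agreement pairs used for Bland-Altman / ICC: per GA eye, the
#' mean of the graders' FAF areas against the AI-derived OCT area.
#'
#' @param cohort A `cohort` with `faf_gradings`.
#' @param profiles Per-eye profiles from [profile_cohort()].
#' @return Data frame with `patient_id`, `laterality`, `faf_mean_mm2`,
#'   `ai_mm2`, plus per-grader columns `grader_G1`, `grader_G2`.
#' @export
agreement_pairs <- function(cohort, profiles) {
  rows <- list()
  for (p in cohort$patients) {
    g <- p$faf_gradings
    if (is.null(g) || !nrow(g)) next
    for (lat in unique(g$laterality)) {
      gl <- g[g$laterality == lat, ]
      ai <- profiles$area_mm2[profiles$patient_id == p$patient_id &
                                profiles$laterality == lat]
      if (!length(ai)) next
      by_grader <- stats::setNames(gl$area_mm2, gl$grader_id)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p$patient_id, laterality = lat,
        faf_mean_mm2 = mean(gl$area_mm2), ai_mm2 = ai,
        grader_G1 = unname(by_grader["G1"]),
        grader_G2 = unname(by_grader["G2"]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(patient_id = character(0), laterality = character(0),
                      faf_mean_mm2 = numeric(0), ai_mm2 = numeric(0),
                      grader_G1 = numeric(0), grader_G2 = numeric(0)))
  do.call(rbind, rows)
}
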