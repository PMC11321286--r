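#' Quantify geographic atrophy area from an en-face RPE-presence mask
#'
#' GA is operationalised as loss of the RPE: the atrophy mask is the logical
#' complement of the RPE-presence mask, cleaned with a speckle filter that
#' discards connected absence components smaller than `min_component_mm2`
#' (raw columnwise absence is noise-sensitive). The area is the absent-pixel
#' count summed over B-scans and converted to mm^2 via the pixel area.
#'
#' The diagnosis flag gates downstream eligibility, not the computation:
#' the area is always computed, and the profile is simply marked non-GA when
#' `ga_flag` is FALSE.
#'
#' @param rpe_present Logical matrix, TRUE where the RPE is segmented.
#' @param geometry A [scan_geometry()] matching the mask.
#' @param ga_flag Diagnosis flag from the classification stand-in.
#' @param min_component_mm2 Speckle filter threshold; connected absence
#'   components (4-connectivity) strictly smaller than this are dropped.
#' @return List with `area_mm2`, `atrophy_mask` (filtered absence mask) and
#'   `ga_flag`.
#' @examples
#' geom <- scan_geometry(32, 32, 6, 6)
#' rpe <- matrix(TRUE, 32, 32); rpe[10:20, 10:20] <- FALSE
#' compute_ga_area(rpe, geom)$area_mm2
#' @export
compute_ga_area <- function(rpe_present, geometry, ga_flag = TRUE,
                            min_component_mm2 = 0.05) {
  check_mask_geometry(rpe_present, geometry, "rpe_present mask")
  if (!is.logical(rpe_present))
    stop("rpe_present must be a logical matrix", call. = FALSE)
  absent <- !rpe_present
  px_area <- pixel_area_mm2(geometry)
  if (min_component_mm2 > 0 && any(absent)) {
    comp <- label_components(absent)
    sizes <- tabulate(comp$labels[comp$labels > 0L], comp$n)
    keep <- which(sizes * px_area >= min_component_mm2)
    absent <- matrix(comp$labels %in% keep, nrow(absent), ncol(absent))
  }
  list(area_mm2 = sum(absent) * px_area,
       atrophy_mask = absent,
       ga_flag = isTRUE(ga_flag))
}

# Connected-component labelling, 4-connectivity, via row-run union-find.
# Runs of TRUE within each row get provisional labels; runs in adjacent rows
# whose column ranges overlap are merged. O(n) with small constants; avoids
# per-pixel flood fill in R.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  runs_row <- integer(0); runs_start <- integer(0); runs_end <- integer(0)
  row_first <- integer(nr); row_count <- integer(nr)
  nruns <- 0L
  for (r in seq_len(nr)) {
    v <- mask[r, ]
    row_first[r] <- nruns + 1L
    if (any(v)) {
      rl <- rle(v)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      idx <- which(rl$values)
      for (i in idx) {
        nruns <- nruns + 1L
        runs_row[nruns] <- r
        runs_start[nruns] <- starts[i]
        runs_end[nruns] <- ends[i]
      }
    }
    row_count[r] <- nruns - row_first[r] + 1L
  }
  if (nruns == 0L) return(list(labels = labels, n = 0L))

  parent <- seq_len(nruns)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nr - 1L)) {
    if (row_count[r] <= 0L || row_count[r + 1L] <= 0L) next
    a <- seq.int(row_first[r], length.out = row_count[r])
    b <- seq.int(row_first[r + 1L], length.out = row_count[r + 1L])
    for (i in a) for (j in b) {
      if (runs_start[j] <= runs_end[i] && runs_end[j] >= runs_start[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(nruns), find, integer(1))
  comp_id <- match(roots, unique(roots))
  for (k in seq_len(nruns)) {
    labels[runs_row[k], runs_start[k]:runs_end[k]] <- comp_id[k]
  }
  list(labels = labels, n = length(unique(roots)))
}

#' Locate the fovea on a neurosensory-retina thickness map
#'
#' The anatomical fovea appears as a local thickness minimum (the foveal
#' pit). Because Topcon scans fixate on the preferred retinal locus, which
#' may not coincide with the anatomical fovea in macular disease, the pit is
#' searched for rather than assumed at the grid center: the map is smoothed
#' with a Gaussian kernel (default sigma 0.25 mm, anisotropic pitch
#' respected) and the minimum is taken within the central 50% window of the
#' grid. Ties break to the smallest (row, col) in lexicographic order.
#'
#' @param nsr_thickness Numeric matrix of neurosensory retina thickness (um),
#'   finite and non-negative.
#' @param geometry A [scan_geometry()].
#' @param sigma_mm Gaussian smoothing bandwidth in mm.
#' @return Length-2 integer, 0-based (row, col) of the fovea pixel. A
#'   constant (degenerate) map returns the window center with a warning.
#' @export
locate_fovea <- function(nsr_thickness, geometry, sigma_mm = 0.25) {
  check_mask_geometry(nsr_thickness, geometry, "thickness map")
  if (!all(is.finite(nsr_thickness)) || any(nsr_thickness < 0))
    stop("thickness map must be finite and non-negative", call. = FALSE)
  nr <- geometry$n_bscans; nc <- geometry$n_ascans
  # central 50% search window
  r_lo <- floor(nr / 4) + 1L; r_hi <- nr - floor(nr / 4)
  c_lo <- floor(nc / 4) + 1L; c_hi <- nc - floor(nc / 4)
  if (diff(range(nsr_thickness)) < .Machine$double.eps * 100) {
    warning("degenerate (constant) thickness map; returning window center")
    return(c((r_lo + r_hi) %/% 2 - 1L, (c_lo + c_hi) %/% 2 - 1L))
  }
  sm <- gaussian_smooth(nsr_thickness, geometry, sigma_mm)
  win <- sm[r_lo:r_hi, c_lo:c_hi]
  # which.min is column-major: first minimum has the smallest column, then
  # row; enforce (row, col) lexicographic tie-break explicitly
  idx <- which(win == min(win), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2])[1], , drop = TRUE]
  c(r_lo + idx[1] - 2L, c_lo + idx[2] - 2L)  # 0-based
}

# separable Gaussian smoothing with edge renormalisation (kernel truncated
# at the grid border keeps unit mass)
gaussian_smooth <- function(x, geometry, sigma_mm) {
  smooth_axis <- function(n, pitch) {
    sigma_px <- sigma_mm / pitch
    if (sigma_px < 1e-8) return(diag(n))
    half <- max(1L, ceiling(3 * sigma_px))
    offs <- (-half):half
    k <- exp(-0.5 * (offs / sigma_px)^2)
    K <- matrix(0, n, n)
    for (o in seq_along(offs)) {
      j <- seq_len(n) + offs[o]
      ok <- j >= 1 & j <= n
      K[cbind(which(ok), j[ok])] <- K[cbind(which(ok), j[ok])] + k[o]
    }
    K / rowSums(K)
  }
  Kr <- smooth_axis(nrow(x), row_pitch_mm(geometry))
  Kc <- smooth_axis(ncol(x), col_pitch_mm(geometry))
  Kr %*% x %*% t(Kc)
}

#' Classify lesion location relative to the fovea
#'
#' Two criteria used by GA trials: "central" GA, any atrophy within
#' `radius_um` (default 1500 um) of the foveal center, and "fovea involving"
#' GA, atrophy at the foveal center point itself. Distance is pixel-center
#' to pixel-center Euclidean distance in mm with anisotropic pitch.
#'
#' @param atrophy_mask Logical absence mask.
#' @param fovea_px Length-2 integer, 0-based (row, col) of the fovea pixel;
#'   must lie inside the grid.
#' @param geometry A [scan_geometry()].
#' @param radius_um Radius of the central zone in micrometres.
#' @return List with logicals `central_ga` and `fovea_involving`.
#' @export
classify_location <- function(atrophy_mask, fovea_px, geometry,
                              radius_um = 1500) {
  check_mask_geometry(atrophy_mask, geometry, "atrophy mask")
  if (fovea_px[1] < 0 || fovea_px[1] >= geometry$n_bscans ||
      fovea_px[2] < 0 || fovea_px[2] >= geometry$n_ascans)
    stop("fovea_px outside the grid", call. = FALSE)
  fovea_involving <- isTRUE(atrophy_mask[fovea_px[1] + 1L, fovea_px[2] + 1L])
  central <- fovea_involving
  if (!central && any(atrophy_mask)) {
    rp <- row_pitch_mm(geometry); cp <- col_pitch_mm(geometry)
    idx <- which(atrophy_mask, arr.ind = TRUE)
    dy <- (idx[, 1] - 1L - fovea_px[1]) * rp
    dx <- (idx[, 2] - 1L - fovea_px[2]) * cp
    central <- any(dy * dy + dx * dx <= (radius_um / 1000)^2)
  }
  list(central_ga = central, fovea_involving = fovea_involving)
}

#' Imaging profile of one eye
#'
#' Composes area quantification, fovea localisation and location
#' classification into the per-eye profile consumed by the eligibility
#' engine: GA area (A_AI), the central / fovea-involving flags, the fovea
#' coordinate and the filtered atrophy mask.
#'
#' @param eye An `eye_record` (see [generate_cohort()]) holding both maps.
#' @param geometry A [scan_geometry()].
#' @param min_component_mm2 Speckle filter threshold, see
#'   [compute_ga_area()].
#' @return An object of class `imaging_profile` with fields `area_mm2`,
#'   `central_ga`, `fovea_involving`, `fovea_px`, `atrophy_mask`, `ga_flag`.
#'   `area_mm2 = 0` forces both location flags FALSE; `fovea_involving`
#'   implies `central_ga`.
#' @export
profile_eye <- function(eye, geometry, min_component_mm2 = 0.05) {
  if (is.null(eye$rpe_present) || is.null(eye$nsr_thickness))
    stop("incomplete eye record: both the RPE mask and the thickness map are required",
         call. = FALSE)
  ga <- compute_ga_area(eye$rpe_present, geometry, eye$ga_flag,
                        min_component_mm2 = min_component_mm2)
  fovea <- locate_fovea(eye$nsr_thickness, geometry)
  if (ga$area_mm2 > 0) {
    loc <- classify_location(ga$atrophy_mask, fovea, geometry)
  } else {
    loc <- list(central_ga = FALSE, fovea_involving = FALSE)
  }
  structure(
    list(area_mm2 = ga$area_mm2,
         central_ga = loc$central_ga,
         fovea_involving = loc$fovea_involving,
         fovea_px = fovea,
         atrophy_mask = ga$atrophy_mask,
         ga_flag = ga$ga_flag),
    class = "imaging_profile"
  )
}

#' Profile every eye of a cohort
#'
#' @param cohort A `cohort` from [generate_cohort()] or [read_cohort()].
#' @param min_component_mm2 Speckle filter threshold.
#' @return Data frame with one row per eye: `patient_id`, `laterality`,
#'   `area_mm2`, `central_ga`, `fovea_involving`, `fovea_row`, `fovea_col`,
#'   `ga_flag`, `cnv_flag`.
#' @export
profile_cohort <- function(cohort, min_component_mm2 = 0.05) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- list()
  for (p in cohort$patients) {
    for (eye in p$eyes) {
      pr <- profile_eye(eye, cohort$geometry,
                        min_component_mm2 = min_component_mm2)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p$patient_id,
        laterality = eye$laterality,
        area_mm2 = pr$area_mm2,
        central_ga = pr$central_ga,
        fovea_involving = pr$fovea_involving,
        fovea_row = pr$fovea_px[1],
        fovea_col = pr$fovea_px[2],
        ga_flag = eye$ga_flag,
        cnv_flag = eye$cnv_flag,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
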