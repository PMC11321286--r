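#' Scan geometry of an OCT volume's en-face grid
#'
#' Describes the physical field of view and grid dimensions of a macular OCT
#' volume. The en-face grid has one row per B-scan (slow axis) and one column
#' per A-scan (fast axis); the geometry converts between pixel indices and
#' physical millimetres. The default mirrors a typical Topcon macular cube:
#' 128 B-scans of 512 A-scans over a 6 x 6 mm field.
#'
#' @param n_bscans Number of B-scans (rows of the en-face grid).
#' @param n_ascans Number of A-scans per B-scan (columns).
#' @param width_mm Lateral field width spanned by the A-scans, in mm.
#' @param height_mm Field height spanned across B-scans, in mm.
#'
#' @return An object of class `scan_geometry` with fields `n_bscans`,
#'   `n_ascans`, `width_mm`, `height_mm`.
#' @examples
#' geom <- scan_geometry()
#' pixel_area_mm2(geom)  # ~0.000549 mm^2 per en-face pixel
#' @export
scan_geometry <- function(n_bscans = 128L, n_ascans = 512L,
                          width_mm = 6, height_mm = 6) {
  n_bscans <- as.integer(n_bscans)
  n_ascans <- as.integer(n_ascans)
  if (any(is.na(c(n_bscans, n_ascans))) || n_bscans <= 0L || n_ascans <= 0L)
    stop("invalid geometry: grid dimensions must be positive integers",
         call. = FALSE)
  if (!is.finite(width_mm) || !is.finite(height_mm) ||
      width_mm <= 0 || height_mm <= 0)
    stop("invalid geometry: physical field dimensions must be positive",
         call. = FALSE)
  structure(
    list(n_bscans = n_bscans, n_ascans = n_ascans,
         width_mm = as.numeric(width_mm), height_mm = as.numeric(height_mm)),
    class = "scan_geometry"
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("scan_geometry: %d B-scans x %d A-scans over %.2f x %.2f mm\n",
              x$n_bscans, x$n_ascans, x$height_mm, x$width_mm))
  cat(sprintf("  pixel pitch: %.4f mm (rows) x %.4f mm (cols); pixel area %.3g mm^2\n",
              row_pitch_mm(x), col_pitch_mm(x), pixel_area_mm2(x)))
  invisible(x)
}

#' Physical area of one en-face pixel
#'
#' @param geometry A [scan_geometry()].
#' @return Pixel area in mm^2.
#' @export
pixel_area_mm2 <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  (geometry$width_mm / geometry$n_ascans) *
    (geometry$height_mm / geometry$n_bscans)
}

# pitch along the slow (B-scan / row) axis, mm per pixel
row_pitch_mm <- function(geometry) geometry$height_mm / geometry$n_bscans

# pitch along the fast (A-scan / column) axis, mm per pixel
col_pitch_mm <- function(geometry) geometry$width_mm / geometry$n_ascans

# physical (y, x) coordinates in mm of all pixel centers, as two matrices.
# 0-based pixel (r, c) has center ((r + 0.5) * row_pitch, (c + 0.5) * col_pitch).
pixel_center_mm <- function(geometry) {
  rp <- row_pitch_mm(geometry)
  cp <- col_pitch_mm(geometry)
  y <- (seq_len(geometry$n_bscans) - 0.5) * rp
  x <- (seq_len(geometry$n_ascans) - 0.5) * cp
  list(y = y, x = x)
}

check_mask_geometry <- function(mask, geometry, what = "mask") {
  if (!is.matrix(mask) ||
      nrow(mask) != geometry$n_bscans || ncol(mask) != geometry$n_ascans)
    stop(sprintf("%s dimensions (%s) do not match geometry (%d x %d)",
                 what, paste(dim(mask), collapse = " x "),
                 geometry$n_bscans, geometry$n_ascans), call. = FALSE)
  invisible(TRUE)
}
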