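#' Specification of a planted atrophic lesion
#'
#' Describes a synthetic region of RPE loss to be rendered onto an en-face
#' grid. Shapes are parameterised by a target area; the renderer solves for
#' the radii that achieve it. `center_mm` is the (x, y) offset of the lesion
#' center from the fovea, in mm (x along A-scans, y along B-scans).
#'
#' For `shape = "ring"` the annulus is `inner_frac * outer_radius` by default;
#' explicit `inner_radius_mm` / `outer_radius_mm` override the target area.
#' For `shape = "multifocal"`, `n_foci` equal discs (total area
#' `target_area_mm2`) are placed on a circle around the center, spaced so
#' they never overlap.
#'
#' @param shape One of `"disc"`, `"ellipse"`, `"ring"`, `"multifocal"`.
#' @param target_area_mm2 Planted lesion area in mm^2 (>= 0).
#' @param center_mm Length-2 numeric, (x, y) offset from the fovea in mm.
#' @param n_foci Number of foci (multifocal only).
#' @param aspect Major/minor axis ratio for ellipses.
#' @param inner_frac Inner/outer radius ratio for rings.
#' @param inner_radius_mm,outer_radius_mm Optional explicit ring radii (mm);
#'   when both are given they take precedence over `target_area_mm2`.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(shape = c("disc", "ellipse", "ring", "multifocal"),
                        target_area_mm2 = 0, center_mm = c(0, 0),
                        n_foci = 1L, aspect = 1.5, inner_frac = 0.5,
                        inner_radius_mm = NULL, outer_radius_mm = NULL) {
  shape <- match.arg(shape)
  if (!is.finite(target_area_mm2) || target_area_mm2 < 0)
    stop("target_area_mm2 must be a non-negative number", call. = FALSE)
  n_foci <- as.integer(n_foci)
  if (is.na(n_foci) || n_foci < 1L)
    stop("n_foci must be a positive integer", call. = FALSE)
  if (shape == "ring" && !is.null(inner_radius_mm) && !is.null(outer_radius_mm)) {
    if (inner_radius_mm < 0 || outer_radius_mm <= inner_radius_mm)
      stop("ring radii must satisfy 0 <= inner < outer", call. = FALSE)
    target_area_mm2 <- pi * (outer_radius_mm^2 - inner_radius_mm^2)
  }
  structure(
    list(shape = shape, target_area_mm2 = as.numeric(target_area_mm2),
         center_mm = as.numeric(center_mm), n_foci = n_foci,
         aspect = aspect, inner_frac = inner_frac,
         inner_radius_mm = inner_radius_mm, outer_radius_mm = outer_radius_mm),
    class = "lesion_spec"
  )
}

#' Render a planted lesion as an en-face RPE-absence mask
#'
#' Rasterises a [lesion_spec()] onto the en-face grid: a pixel is marked
#' absent (TRUE) when its physical center falls inside the lesion. Pixel
#' pitch is anisotropic (B-scan spacing is much coarser than A-scan spacing
#' on the default grid), so all distances are evaluated in mm. The
#' pixel-counted area of the result differs from `target_area_mm2` by at
#' most one boundary-pixel band (see [rendering_tolerance_mm2()]).
#'
#' @param spec A [lesion_spec()].
#' @param geometry A [scan_geometry()].
#' @param fovea_px Length-2 integer, 0-based (row, col) of the fovea pixel;
#'   the lesion center is `fovea + center_mm`.
#' @return Logical matrix (`n_bscans` x `n_ascans`), TRUE where the RPE is
#'   absent.
#' @examples
#' geom <- scan_geometry(64, 64, 6, 6)
#' m <- render_lesion(lesion_spec("disc", 3), geom, c(32, 32))
#' sum(m) * pixel_area_mm2(geom)  # close to 3 mm^2
#' @export
render_lesion <- function(spec, geometry, fovea_px) {
  stopifnot(inherits(spec, "lesion_spec"))
  stopifnot(inherits(geometry, "scan_geometry"))
  mask <- matrix(FALSE, geometry$n_bscans, geometry$n_ascans)
  if (spec$target_area_mm2 <= 0) return(mask)

  ctr <- pixel_center_mm(geometry)
  # lesion center in physical mm from the grid origin
  cy <- (fovea_px[1] + 0.5) * row_pitch_mm(geometry) + spec$center_mm[2]
  cx <- (fovea_px[2] + 0.5) * col_pitch_mm(geometry) + spec$center_mm[1]
  dy <- ctr$y - cy                       # length n_bscans
  dx <- ctr$x - cx                       # length n_ascans
  d2 <- outer(dy^2, dx^2, `+`)           # squared distance to lesion center

  if (spec$shape == "disc") {
    r <- sqrt(spec$target_area_mm2 / pi)
    mask <- d2 <= r^2
  } else if (spec$shape == "ellipse") {
    # semi-axes a (x) and b (y) with a = aspect * b, pi*a*b = area
    b <- sqrt(spec$target_area_mm2 / (pi * spec$aspect))
    a <- spec$aspect * b
    mask <- outer((dy / b)^2, (dx / a)^2, `+`) <= 1
  } else if (spec$shape == "ring") {
    if (!is.null(spec$inner_radius_mm) && !is.null(spec$outer_radius_mm)) {
      ri <- spec$inner_radius_mm
      ro <- spec$outer_radius_mm
    } else {
      # area = pi * ro^2 * (1 - inner_frac^2)
      ro <- sqrt(spec$target_area_mm2 / (pi * (1 - spec$inner_frac^2)))
      ri <- spec$inner_frac * ro
    }
    mask <- d2 <= ro^2 & d2 > ri^2
  } else {                               # multifocal
    r <- sqrt(spec$target_area_mm2 / (pi * spec$n_foci))
    if (spec$n_foci == 1L) {
      mask <- d2 <= r^2
    } else {
      # foci on a circle with chord spacing 2.6r (> 2r) so discs never merge
      ring_r <- 1.3 * r / sin(pi / spec$n_foci)
      ang <- 2 * pi * (seq_len(spec$n_foci) - 1) / spec$n_foci
      for (k in seq_len(spec$n_foci)) {
        fy <- cy + ring_r * sin(ang[k])
        fx <- cx + ring_r * cos(ang[k])
        mask <- mask | (outer((ctr$y - fy)^2, (ctr$x - fx)^2, `+`) <= r^2)
      }
    }
  }
  mask
}

#' Rendering tolerance of a rasterised mask
#'
#' One boundary-pixel band: the number of absent pixels with at least one
#' 4-neighbour that is present (or that lie on the grid edge) times the
#' pixel area. Rasterisation cannot displace the pixel-counted area from the
#' target by more than this band.
#'
#' @param mask Logical absence mask.
#' @param geometry A [scan_geometry()].
#' @return Tolerance in mm^2.
#' @export
rendering_tolerance_mm2 <- function(mask, geometry) {
  check_mask_geometry(mask, geometry)
  sum(boundary_pixels(mask)) * pixel_area_mm2(geometry)
}

# absent pixels adjacent (4-connectivity) to a present pixel or the grid edge
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- function(shift_r, shift_c) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + shift_r
    cs <- seq_len(nc) + shift_c
    ok_r <- rs >= 1 & rs <= nr
    ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- mask[rs[ok_r], cs[ok_c]]
    out
  }
  neigh_all_absent <- pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  # edge pixels have a missing neighbour, counted as boundary when absent
  edge <- matrix(FALSE, nr, nc)
  edge[c(1, nr), ] <- TRUE
  edge[, c(1, nc)] <- TRUE
  mask & (!neigh_all_absent | edge)
}
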