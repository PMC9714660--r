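#' Viewing geometry of the eye-tracking setup
#'
#' Describes the screen and the observer's position, which together map
#' on-screen pixel distances to visual angles. Defaults correspond to a
#' 23-inch 1920 x 1080 display viewed from 65 cm, a typical remote
#' eye-tracker arrangement.
#'
#' @param screen_w_px,screen_h_px Screen resolution in pixels.
#' @param screen_w_mm,screen_h_mm Physical screen size in millimetres.
#' @param distance_mm Eye-to-screen distance in millimetres.
#'
#' @return An object of class `viewing_geometry` (a named list).
#' @details The pixel and physical aspect ratios must agree within 5%,
#'   i.e. pixels are assumed (near-)square.
#' @export
#' @examples
#' geom <- viewing_geometry()
#' visual_angle(c(960, 540), c(1060, 540), geom)
viewing_geometry <- function(screen_w_px = 1920, screen_h_px = 1080,
                             screen_w_mm = 509.8, screen_h_mm = 286.7,
                             distance_mm = 650) {
  vals <- c(screen_w_px, screen_h_px, screen_w_mm, screen_h_mm, distance_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all viewing_geometry dimensions must be strictly positive", call. = FALSE)
  }
  aspect_px <- screen_w_px / screen_h_px
  aspect_mm <- screen_w_mm / screen_h_mm
  if (abs(aspect_px / aspect_mm - 1) > 0.05) {
    stop("pixel and physical aspect ratios disagree by more than 5%", call. = FALSE)
  }
  structure(
    list(
      screen_w_px = screen_w_px, screen_h_px = screen_h_px,
      screen_w_mm = screen_w_mm, screen_h_mm = screen_h_mm,
      distance_mm = distance_mm,
      mm_per_px_x = screen_w_mm / screen_w_px,
      mm_per_px_y = screen_h_mm / screen_h_px
    ),
    class = "viewing_geometry"
  )
}

#' @export
print.viewing_geometry <- function(x, ...) {
  cat(sprintf(
    "<viewing_geometry> %d x %d px (%.1f x %.1f mm) at %.0f mm\n",
    x$screen_w_px, x$screen_h_px, x$screen_w_mm, x$screen_h_mm, x$distance_mm
  ))
  invisible(x)
}

assert_geometry <- function(geometry) {
  if (!inherits(geometry, "viewing_geometry")) {
    stop("`geometry` must be created with viewing_geometry()", call. = FALSE)
  }
  invisible(geometry)
}

#' Visual angle between two on-screen points
#'
#' Computes the angle subtended at the eye between two gaze points on the
#' screen, assuming the screen is orthogonal to the gaze axis and centred
#' on it. Inputs are screen-pixel coordinates (origin top-left, y down).
#'
#' @param p1,p2 Numeric length-2 vectors `c(x, y)` in pixels, or two-column
#'   matrices of points (vectorised row-wise).
#' @param geometry A [viewing_geometry()] object.
#'
#' @return Angle(s) in degrees; `0` iff `p1 == p2`. Symmetric in its
#'   arguments.
#' @export
visual_angle <- function(p1, p2, geometry) {
  assert_geometry(geometry)
  p1 <- rbind(p1); p2 <- rbind(p2)
  # pixel -> mm, relative to screen centre
  cx <- geometry$screen_w_px / 2
  cy <- geometry$screen_h_px / 2
  a <- cbind((p1[, 1] - cx) * geometry$mm_per_px_x,
             (p1[, 2] - cy) * geometry$mm_per_px_y,
             geometry$distance_mm)
  b <- cbind((p2[, 1] - cx) * geometry$mm_per_px_x,
             (p2[, 2] - cy) * geometry$mm_per_px_y,
             geometry$distance_mm)
  dot <- rowSums(a * b)
  cosang <- dot / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  # exact zero for identical points (guards acos rounding)
  ang[rowSums(abs(p1 - p2)) == 0] <- 0
  ang
}

#' Convert a small visual angle to an on-screen pixel distance
#'
#' Small-angle approximation at the screen centre; used by the synthetic
#' generator to express jitter and amplitudes given in degrees.
#'
#' @param deg Angle in degrees.
#' @param geometry A [viewing_geometry()] object.
#' @return Distance in pixels (horizontal mm-per-px scale).
#' @export
deg_to_px <- function(deg, geometry) {
  assert_geometry(geometry)
  mm <- tan(deg * pi / 180) * geometry$distance_mm
  mm / geometry$mm_per_px_x
}
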