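#' Rasterize a polygon into its interior pixel set
#'
#' Enumerates the integer pixel coordinates inside (or on the boundary
#' of) a polygon given as a vertex list, matching the AOI-mask semantics
#' of stimulus-annotation tools where an AOI is the set of screen pixels
#' the drawn outline encloses.
#'
#' @param vertices Two-column matrix (or list of `c(x, y)`) of polygon
#'   vertices in screen pixels.
#' @return Two-column matrix of pixel points inside the polygon.
#' @export
rasterize_polygon <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  xs <- seq(floor(min(v[, 1])), ceiling(max(v[, 1])))
  ys <- seq(floor(min(v[, 2])), ceiling(max(v[, 2])))
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  inside <- pracma::inpolygon(grid[, 1], grid[, 2], v[, 1], v[, 2],
                              boundary = TRUE)
  grid[inside, , drop = FALSE]
}

as_vertex_matrix <- function(vertices) {
  if (is.list(vertices) && !is.data.frame(vertices)) {
    vertices <- do.call(rbind, lapply(vertices, function(p) as.numeric(p)))
  }
  v <- as.matrix(vertices)
  if (ncol(v) != 2 || nrow(v) < 1 || any(!is.finite(v))) {
    stop("polygon vertices must be a finite two-column set of points", call. = FALSE)
  }
  v
}

#' Centre of an AOI region
#'
#' The arithmetic mean of the coordinates of all points within the
#' region: the rasterized interior pixel set of the drawn polygon
#' (default), or the vertex set alone in `"vertex"` mode.
#'
#' @param region Polygon vertices (two-column matrix) or, in
#'   `mode = "points"`, an explicit point set.
#' @param mode `"raster"` (interior pixels), `"vertex"` (vertices only),
#'   or `"points"` (region is already a point set).
#' @return Length-2 numeric `c(x, y)`.
#' @export
aoi_center <- function(region, mode = c("raster", "vertex", "points")) {
  mode <- match.arg(mode)
  pts <- region_points(region, mode)
  c(mean(pts[, 1]), mean(pts[, 2]))
}

#' Radius of an AOI region
#'
#' The maximum Euclidean distance from the centre to the region's edge:
#' the boundary pixels of the rasterized region (default) or the polygon
#' vertices in `"vertex"` mode. For convex polygons the two agree at the
#' farthest vertex.
#'
#' @inheritParams aoi_center
#' @param center Optional centre; computed with [aoi_center()] if omitted.
#' @return Radius in pixels; a degenerate single-point region gives 0.
#' @export
aoi_radius <- function(region, center = NULL, mode = c("raster", "vertex", "points")) {
  mode <- match.arg(mode)
  pts <- region_points(region, mode)
  if (is.null(center)) center <- c(mean(pts[, 1]), mean(pts[, 2]))
  edge <- if (mode == "raster") boundary_points(pts) else pts
  max(sqrt((edge[, 1] - center[1])^2 + (edge[, 2] - center[2])^2))
}

region_points <- function(region, mode) {
  pts <- switch(mode,
    raster = rasterize_polygon(region),
    vertex = as_vertex_matrix(region),
    points = as_vertex_matrix(region)
  )
  if (nrow(pts) == 0) stop("AOI region is empty", call. = FALSE)
  pts
}

# pixels with at least one 4-neighbour outside the set
boundary_points <- function(pts) {
  x0 <- min(pts[, 1]) - 1L; y0 <- min(pts[, 2]) - 1L
  h <- max(pts[, 2]) - y0 + 2L
  enc <- function(x, y) (x - x0) * h + (y - y0)
  key <- enc(pts[, 1], pts[, 2])
  has <- function(dx, dy) enc(pts[, 1] + dx, pts[, 2] + dy) %in% key
  interior <- has(1, 0) & has(-1, 0) & has(0, 1) & has(0, -1)
  out <- pts[!interior, , drop = FALSE]
  if (nrow(out) == 0) pts else out
}

#' Angle between a vector and the benchmark vector
#'
#' The intersection angle in `[0, 180]` degrees between a
#' fixation-to-fixation movement vector and the face-to-target benchmark
#' vector, from the arc-cosine of the normalised dot product. A
#' zero-length movement vector is assigned 0 degrees: a stationary step
#' carries no directional evidence against the benchmark.
#'
#' @param v Length-2 vector or two-column matrix of vectors (row-wise).
#' @param benchmark Length-2 non-zero vector.
#' @return Angle(s) in degrees in `[0, 180]`.
#' @export
vector_angle <- function(v, benchmark) {
  b <- as.numeric(benchmark)
  nb <- sqrt(sum(b^2))
  if (!is.finite(nb) || nb == 0) stop("benchmark vector must be non-zero", call. = FALSE)
  v <- rbind(v)
  nv <- sqrt(rowSums(v^2))
  cosang <- (v[, 1] * b[1] + v[, 2] * b[2]) / (nv * nb)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ang[nv == 0] <- 0
  ang
}

#' Geometric primitives of an AOI set
#'
#' Derives from the face / target / non-target polygons of one clip the
#' quantities the detector consumes: the three centres F, T, N, the
#' radii R_F, R_T, R_N (maximum centre-to-edge distance), and the
#' face-to-target benchmark vector F -> T.
#'
#' @param aoi_set One clip's AOI set (an element of [read_aoi_specs()]'s
#'   result, or any list with `clip_id`, `face`, `target`, `nontarget`
#'   vertex matrices).
#' @param mode Region semantics passed to [aoi_center()]/[aoi_radius()].
#' @return An `aoi_geometry` list: `clip_id`, `F`, `T`, `N`, `R_F`,
#'   `R_T`, `R_N`, `benchmark`.
#' @export
aoi_geometry <- function(aoi_set, mode = c("raster", "vertex", "points")) {
  mode <- match.arg(mode)
  Fc <- aoi_center(aoi_set$face, mode)
  Tc <- aoi_center(aoi_set$target, mode)
  Nc <- aoi_center(aoi_set$nontarget, mode)
  geom <- list(
    clip_id = aoi_set$clip_id,
    F = Fc, T = Tc, N = Nc,
    R_F = aoi_radius(aoi_set$face, Fc, mode),
    R_T = aoi_radius(aoi_set$target, Tc, mode),
    R_N = aoi_radius(aoi_set$nontarget, Nc, mode),
    benchmark = Tc - Fc
  )
  if (geom$R_F <= 0 || geom$R_T <= 0 || geom$R_N <= 0) {
    warning("degenerate AOI with zero radius", call. = FALSE)
  }
  if (sqrt(sum(geom$benchmark^2)) == 0) {
    stop("face and target AOI centres coincide; benchmark vector undefined",
         call. = FALSE)
  }
  structure(geom, class = "aoi_geometry")
}

#' @export
print.aoi_geometry <- function(x, ...) {
  cat(sprintf(
    "<aoi_geometry %s> F=(%.1f,%.1f) R_F=%.1f  T=(%.1f,%.1f) R_T=%.1f  N=(%.1f,%.1f) R_N=%.1f\n",
    x$clip_id %||% "?", x$F[1], x$F[2], x$R_F, x$T[1], x$T[2], x$R_T,
    x$N[1], x$N[2], x$R_N
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
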