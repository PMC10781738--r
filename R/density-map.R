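#' Construct a density map
#'
#' A `density_map` holds a 3-D scalar grid together with its real-space
#' geometry. The array is stored in canonical x-fastest order, i.e.
#' `values[ix, iy, iz]` with `ix` running along the x axis. The centre of
#' voxel `(0, 0, 0)` (zero-based) sits at `origin`, and voxel indices map to
#' real-space coordinates (in angstrom) as `index * voxel_size + origin`.
#'
#' @param values 3-D numeric array of intensities (arbitrary map units).
#' @param voxel_size voxel edge lengths in angstrom; scalar or length-3
#'   (anisotropic voxels are supported).
#' @param origin real-space position (angstrom) of the centre of voxel
#'   `(0, 0, 0)`.
#' @param resolution optional global resolution of the map in angstrom.
#' @return An object of class `density_map` with fields `values`,
#'   `voxel_size`, `origin` and `resolution`.
#' @export
density_map <- function(values, voxel_size = 1, origin = c(0, 0, 0),
                        resolution = NULL) {
  if (length(dim(values)) != 3L)
    stop_cf("'values' must be a 3-D array")
  if (any(dim(values) < 2L))
    stop_cf("density map needs at least 2 voxels per axis")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop_cf("voxel_size components must be positive and finite")
  if (any(!is.finite(values)))
    stop_cf("density map values must be finite (no NA/NaN/Inf)")
  structure(
    list(values = values, voxel_size = voxel_size,
         origin = rep_len(as.numeric(origin), 3L),
         resolution = resolution),
    class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_map: %d x %d x %d voxels, voxel %s A, origin (%s) A\n",
              d[1], d[2], d[3],
              paste(format(x$voxel_size, digits = 4), collapse = " x "),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  if (!is.null(x$resolution))
    cat(sprintf("  stated global resolution: %.2f A\n", x$resolution))
  invisible(x)
}

#' Grid geometry helpers
#'
#' `grid_dim()` returns the number of voxels per axis; `voxel_coords()`
#' converts zero-based voxel indices to real-space coordinates;
#' `grid_axis_coords()` returns the voxel-centre coordinates along one axis.
#'
#' @param map a `density_map`.
#' @param index integer matrix (n x 3) of zero-based voxel indices.
#' @param axis axis number 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector/matrix of coordinates in angstrom.
#' @keywords internal
grid_dim <- function(map) dim(map$values)

#' @rdname grid_dim
#' @keywords internal
voxel_coords <- function(map, index) {
  sweep(sweep(index, 2L, map$voxel_size, "*"), 2L, map$origin, "+")
}

#' @rdname grid_dim
#' @keywords internal
grid_axis_coords <- function(map, axis) {
  (seq_len(dim(map$values)[axis]) - 1) * map$voxel_size[axis] +
    map$origin[axis]
}

#' Trilinear interpolation of map values
#'
#' Evaluates the map at arbitrary real-space positions by trilinear
#' interpolation of the eight surrounding voxel values. Points outside the
#' grid are either clamped to the edge (default, logged) or raise an error.
#'
#' @param map a `density_map`.
#' @param points numeric matrix (n x 3) or length-3 vector of positions (A).
#' @param outside `"clamp"` (default) to clamp out-of-grid points to the edge
#'   of the bounding box, or `"error"`.
#' @return Numeric vector of interpolated intensities.
#' @export
trilinear_value <- function(map, points, outside = c("clamp", "error")) {
  outside <- match.arg(outside)
  w <- .trilinear_setup(map, points, outside)
  v <- map$values
  n <- dim(v)
  i0 <- w$i0; i1 <- w$i1; f <- w$f
  val <- 0
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    ix <- if (bx == 0) i0[, 1] else i1[, 1]
    iy <- if (by == 0) i0[, 2] else i1[, 2]
    iz <- if (bz == 0) i0[, 3] else i1[, 3]
    wt <- (if (bx == 0) 1 - f[, 1] else f[, 1]) *
          (if (by == 0) 1 - f[, 2] else f[, 2]) *
          (if (bz == 0) 1 - f[, 3] else f[, 3])
    val <- val + wt * v[cbind(ix, iy, iz)]
  }
  val
}

#' Gradient of the trilinear interpolant
#'
#' Analytic spatial gradient of [trilinear_value()] with respect to the query
#' position, derived from the interpolation weights. Used by the
#' density-guided force during ensemble relaxation.
#'
#' @inheritParams trilinear_value
#' @return n x 3 matrix of gradients (map units per angstrom).
#' @export
trilinear_gradient <- function(map, points, outside = c("clamp", "error")) {
  outside <- match.arg(outside)
  w <- .trilinear_setup(map, points, outside)
  v <- map$values
  i0 <- w$i0; i1 <- w$i1; f <- w$f
  g <- matrix(0, nrow(i0), 3)
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    ix <- if (bx == 0) i0[, 1] else i1[, 1]
    iy <- if (by == 0) i0[, 2] else i1[, 2]
    iz <- if (bz == 0) i0[, 3] else i1[, 3]
    wx <- if (bx == 0) 1 - f[, 1] else f[, 1]
    wy <- if (by == 0) 1 - f[, 2] else f[, 2]
    wz <- if (bz == 0) 1 - f[, 3] else f[, 3]
    dx <- if (bx == 0) -1 else 1
    dy <- if (by == 0) -1 else 1
    dz <- if (bz == 0) -1 else 1
    vv <- v[cbind(ix, iy, iz)]
    g[, 1] <- g[, 1] + dx * wy * wz * vv / map$voxel_size[1]
    g[, 2] <- g[, 2] + wx * dy * wz * vv / map$voxel_size[2]
    g[, 3] <- g[, 3] + wx * wy * dz * vv / map$voxel_size[3]
  }
  ## clamped points sit on a flat extension: zero gradient along the
  ## clamped axis
  if (any(w$clamped)) g[w$clamped] <- 0
  g
}

.trilinear_setup <- function(map, points, outside) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  n <- dim(map$values)
  u <- sweep(sweep(points, 2L, map$origin, "-"), 2L, map$voxel_size, "/")
  lim <- matrix(n - 1, nrow(u), 3, byrow = TRUE)
  out <- u < 0 | u > lim
  if (any(out)) {
    if (outside == "error")
      stop_cf("point(s) outside the map bounding box")
    cf_log(sum(rowSums(out) > 0), " point(s) clamped to the grid edge")
    u <- clamp(u, 0, lim)
  }
  i0 <- pmin(floor(u), lim - 1)
  f <- u - i0
  list(i0 = i0 + 1, i1 = i0 + 2, f = f, clamped = out)
}

#' Resample a map onto another grid
#'
#' Trilinearly interpolates `map` at the voxel centres of `grid`. Voxel
#' centres of `grid` that fall outside `map` receive `fill`.
#'
#' @param map source `density_map`.
#' @param grid `density_map` supplying the target geometry (values ignored).
#' @param fill value for target voxels outside the source box.
#' @return A `density_map` on the geometry of `grid`.
#' @export
resample_map <- function(map, grid, fill = 0) {
  n <- grid_dim(grid)
  idx <- as.matrix(expand.grid(ix = 0:(n[1] - 1), iy = 0:(n[2] - 1),
                               iz = 0:(n[3] - 1)))
  pts <- voxel_coords(grid, idx)
  vals <- trilinear_value(map, pts, outside = "clamp")
  lo <- map$origin
  hi <- map$origin + (grid_dim(map) - 1) * map$voxel_size
  outside <- pts[, 1] < lo[1] | pts[, 2] < lo[2] | pts[, 3] < lo[3] |
    pts[, 1] > hi[1] | pts[, 2] > hi[2] | pts[, 3] > hi[3]
  vals[outside] <- fill
  density_map(array(vals, n), grid$voxel_size, grid$origin, grid$resolution)
}

#' Empty map on a model's bounding box
#'
#' Convenience constructor of a zero-filled grid enclosing a set of points
#' with a margin on every side.
#'
#' @param points n x 3 coordinate matrix (A).
#' @param voxel_size voxel edge length(s), angstrom.
#' @param margin margin beyond the point bounding box, angstrom.
#' @param resolution optional stated resolution, angstrom.
#' @return A `density_map` of zeros.
#' @export
empty_grid <- function(points, voxel_size = 1, margin = 8, resolution = NULL) {
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  lo <- apply(points, 2, min) - margin
  hi <- apply(points, 2, max) + margin
  n <- pmax(2L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L)
  density_map(array(0, n), voxel_size, lo, resolution)
}
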