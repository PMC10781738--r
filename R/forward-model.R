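#' Gaussian-mixture state
#'
#' Bundles an atomic model with the scalar uniform background term `E` (map
#' units) and the voxel-inclusion cutoff. Together these define the full
#' mixture: each atom contributes a Gaussian
#' \eqn{P_i(v) = A_i \exp(-|v - x_i|^2 / B_i^2)} and the simulated map is
#' \eqn{M_s(v) = \sum_i P_i(v) + E}. The width convention: `bwidth` enters
#' the exponent as \eqn{B^2} directly (no factor 2), so the per-coordinate
#' variance of the component is \eqn{B^2/2}.
#'
#' Two amplitude conventions are supported. The default,
#' `normalise = TRUE`, sets \eqn{A_i = Z_i / (\pi^{3/2} B_i^3)} so that
#' each atom's integrated density equals its atomic number regardless of
#' its width — blurring redistributes an atom's mass without creating or
#' destroying it. This mass-preserving form is what makes the
#' expectation-maximisation width update well behaved: a too-wide start
#' pays an amplitude penalty and contracts back to the data. With
#' `normalise = FALSE` the amplitude is the bare \eqn{Z_i} (the peak
#' intensity is Z, whatever the width); that form is retained for
#' reference but its width update is not reliably convergent from distant
#' starts, because a wide component claims background and neighbour
#' density without penalty (see the methods vignette).
#'
#' @param model an [atomic_model()].
#' @param background the uniform background intensity E, `>= 0`.
#' @param cutoff_sigma dimensionless support cutoff: each atom's Gaussian is
#'   evaluated only within `cutoff_sigma * bwidth` of its centre (exactly 0
#'   outside). Default 4; values below 3 trigger a warning.
#' @param normalise use mass-preserving component amplitudes (default) or
#'   bare-Z amplitudes.
#' @return Object of class `gmm_state`.
#' @export
gmm_state <- function(model, background = 0, cutoff_sigma = 4,
                      normalise = TRUE) {
  stopifnot(inherits(model, "atomic_model"))
  if (!is.finite(background) || background < 0)
    stop_cf("background must be finite and >= 0")
  if (cutoff_sigma < 3)
    warning("cutoff_sigma below 3 truncates a noticeable fraction of ",
            "each atom's density", call. = FALSE)
  structure(list(model = model, background = background,
                 cutoff_sigma = cutoff_sigma, normalise = normalise),
            class = "gmm_state")
}

#' @export
print.gmm_state <- function(x, ...) {
  cat(sprintf("gmm_state: %d atoms, background E = %.4g, cutoff %g sigma\n",
              n_atoms(x$model), x$background, x$cutoff_sigma))
  invisible(x)
}

#' Single-atom Gaussian intensity
#'
#' Evaluates \eqn{A \exp(-|v - x|^2 / B^2)} at arbitrary points, with no
#' cutoff. By default the amplitude is the bare atomic number
#' (`normalise = FALSE`: the intensity at the atom centre is exactly Z);
#' with `normalise = TRUE` the mass-preserving amplitude
#' \eqn{Z/(\pi^{3/2}B^3)} used by [simulate_map()]'s default is applied.
#' `atom` may be a one-row slice of `model$atoms` or any list with fields
#' `x`, `y`, `z`, `bwidth` and `atomic_number`.
#'
#' @param atom atom record (see above).
#' @param points n x 3 matrix or length-3 vector of positions (angstrom).
#' @param normalise amplitude convention, see [gmm_state()].
#' @return Numeric vector of intensities.
#' @export
atom_intensity <- function(atom, points, normalise = FALSE) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  d2 <- (points[, 1] - atom$x)^2 + (points[, 2] - atom$y)^2 +
    (points[, 3] - atom$z)^2
  amp <- if (normalise) atom$atomic_number / (pi^1.5 * atom$bwidth^3)
         else atom$atomic_number
  amp * exp(-d2 / atom$bwidth^2)
}

## Sparse voxel block of one atom: linear indices and squared distances of
## all voxels within `cutoff * b` of `pos` on the grid of `map`.
.atom_block <- function(map, pos, b, cutoff) {
  n <- dim(map$values)
  vs <- map$voxel_size
  or <- map$origin
  rc <- cutoff * b
  lo <- pmax(ceiling((pos - rc - or) / vs), 0)
  hi <- pmin(floor((pos + rc - or) / vs), n - 1)
  if (any(lo > hi))
    return(list(idx = integer(0), r2 = numeric(0)))
  i1 <- lo[1]:hi[1]; i2 <- lo[2]:hi[2]; i3 <- lo[3]:hi[3]
  d1 <- i1 * vs[1] + or[1] - pos[1]
  d2 <- i2 * vs[2] + or[2] - pos[2]
  d3 <- i3 * vs[3] + or[3] - pos[3]
  l1 <- length(i1); l2 <- length(i2); l3 <- length(i3)
  r2 <- rep(d1^2, times = l2 * l3) +
    rep(rep(d2^2, each = l1), times = l3) +
    rep(d3^2, each = l1 * l2)
  ix <- rep(i1, times = l2 * l3)
  iy <- rep(rep(i2, each = l1), times = l3)
  iz <- rep(i3, each = l1 * l2)
  keep <- r2 <= rc * rc
  list(idx = (1 + ix + n[1] * (iy + n[2] * iz))[keep], r2 = r2[keep])
}

## All per-atom blocks plus the accumulated simulated map (float64).
.gmm_fields <- function(state, grid) {
  a <- state$model$atoms
  n <- dim(grid$values)
  ms <- array(state$background, n)
  blocks <- vector("list", nrow(a))
  norm <- if (is.null(state$normalise)) TRUE else isTRUE(state$normalise)
  for (i in seq_len(nrow(a))) {
    bl <- .atom_block(grid, c(a$x[i], a$y[i], a$z[i]), a$bwidth[i],
                      state$cutoff_sigma)
    amp <- if (norm) a$atomic_number[i] / (pi^1.5 * a$bwidth[i]^3)
           else a$atomic_number[i]
    bl$p <- amp * exp(-bl$r2 / a$bwidth[i]^2)
    ms[bl$idx] <- ms[bl$idx] + bl$p
    blocks[[i]] <- bl
  }
  list(ms = ms, blocks = blocks)
}

#' Simulate a density map from a mixture state
#'
#' Evaluates \eqn{M_s(v) = \sum_i P_i(v) + E} on the geometry of `grid`
#' (its values are ignored). Each atom contributes only within
#' `cutoff_sigma * bwidth` of its centre; outside, its contribution is
#' exactly zero. Atoms outside the grid contribute only where in range.
#' Accumulation is double precision; the result is deterministic.
#'
#' @param state a [gmm_state()].
#' @param grid a [density_map()] supplying the target geometry.
#' @return A [density_map()] of the simulated intensities.
#' @export
simulate_map <- function(state, grid) {
  f <- .gmm_fields(state, grid)
  density_map(f$ms, grid$voxel_size, grid$origin, grid$resolution)
}

#' Per-atom and background responsibilities
#'
#' For every voxel in the support (within `cutoff_sigma * bwidth` of at
#' least one atom) computes the responsibility of each atom,
#' \eqn{\gamma_i(v) = P_i(v) / M_s(v)}, and of the background,
#' \eqn{\gamma_{err}(v) = E / M_s(v)}. At every supported voxel the
#' responsibilities sum to 1. Voxels where \eqn{M_s(v) = 0} (possible only
#' when `E = 0`) are excluded from the support and logged.
#'
#' @param state a [gmm_state()].
#' @param grid a [density_map()] supplying the geometry.
#' @return Object of class `responsibility_field`: a list with `support`
#'   (sorted linear voxel indices), `gamma_err` (background weight per
#'   supported voxel), `atom_idx` and `atom_gamma` (per-atom sparse voxel
#'   index/weight lists) and `dim`.
#' @export
responsibilities <- function(state, grid) {
  f <- .gmm_fields(state, grid)
  sup <- sort(unique(unlist(lapply(f$blocks, `[[`, "idx"))))
  dead <- sup[f$ms[sup] == 0]
  if (length(dead)) {
    cf_log(length(dead), " supported voxel(s) with zero simulated ",
           "intensity excluded")
    sup <- setdiff(sup, dead)
  }
  atom_gamma <- vector("list", length(f$blocks))
  atom_idx <- vector("list", length(f$blocks))
  for (i in seq_along(f$blocks)) {
    bl <- f$blocks[[i]]
    ok <- f$ms[bl$idx] > 0
    atom_idx[[i]] <- bl$idx[ok]
    atom_gamma[[i]] <- bl$p[ok] / f$ms[bl$idx[ok]]
  }
  structure(list(support = sup,
                 gamma_err = state$background / f$ms[sup],
                 atom_idx = atom_idx, atom_gamma = atom_gamma,
                 dim = dim(grid$values)),
            class = "responsibility_field")
}

## real-space coordinates of linear voxel indices
.idx_coords <- function(map, idx) {
  n <- dim(map$values)
  i0 <- idx - 1
  ix <- i0 %% n[1]
  iy <- (i0 %/% n[1]) %% n[2]
  iz <- i0 %/% (n[1] * n[2])
  cbind(ix * map$voxel_size[1] + map$origin[1],
        iy * map$voxel_size[2] + map$origin[2],
        iz * map$voxel_size[3] + map$origin[3])
}

#' Voxel support of a model
#'
#' Logical mask of the voxels lying within `cutoff * bwidth` of at least one
#' atom — the voxel set used for the background update and for
#' support-restricted correlation scores.
#'
#' @param state a [gmm_state()] (or [atomic_model()], taken with cutoff 4).
#' @param grid a [density_map()] supplying the geometry.
#' @param cutoff overrides the state's `cutoff_sigma` if given.
#' @return Logical array of the grid's dimensions.
#' @export
model_support <- function(state, grid, cutoff = NULL) {
  if (inherits(state, "atomic_model")) state <- gmm_state(state)
  cutoff <- cutoff %||% state$cutoff_sigma
  a <- state$model$atoms
  mask <- array(FALSE, dim(grid$values))
  for (i in seq_len(nrow(a))) {
    bl <- .atom_block(grid, c(a$x[i], a$y[i], a$z[i]), a$bwidth[i], cutoff)
    mask[bl$idx] <- TRUE
  }
  mask
}
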