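## Maximisation-step updates. Each atom's responsibility-weighted
## experimental map is W_i(v) = M_e(v) * gamma_i(v); new positions are the
## W-weighted mean of voxel coordinates, new widths come from the W-weighted
## variance, and the background is re-estimated from its own responsibility
## over the support voxels.

## shared worker: per-atom sums over the atom's supported voxels
.mstep_atom <- function(fields, exp_map, map, i, pos) {
  bl <- fields$blocks[[i]]
  if (!length(bl$idx))
    return(list(sw = 0, mean = pos, var = NA_real_))
  gamma <- bl$p / fields$ms[bl$idx]
  w <- exp_map$values[bl$idx] * gamma
  sw <- sum(w)
  if (!is.finite(sw) || sw <= 0)
    return(list(sw = sw, mean = pos, var = NA_real_))
  r <- .idx_coords(map, bl$idx)
  xm <- colSums(w * r) / sw
  v <- sum(w * ((r[, 1] - pos[1])^2 + (r[, 2] - pos[2])^2 +
                  (r[, 3] - pos[3])^2)) / sw
  list(sw = sw, mean = xm, var = v)
}

#' Maximisation update of atomic positions
#'
#' For each atom, the target position is the responsibility-weighted
#' real-space mean of the experimental map over the atom's supported
#' voxels: \eqn{x_i' = \sum_v W_i(v) r(v) / \sum_v W_i(v)} with
#' \eqn{W_i(v) = M_e(v)\gamma_i(v)}. Atoms whose total weight is zero or
#' negative (sitting in empty or negative density) keep their current
#' position and are flagged.
#'
#' @param state a [gmm_state()].
#' @param exp_map experimental [density_map()] on the target grid.
#' @return n x 3 matrix of target positions with a logical attribute
#'   `"flagged"` marking atoms that could not be updated.
#' @export
maximise_positions <- function(state, exp_map) {
  fields <- .gmm_fields(state, exp_map)
  a <- state$model$atoms
  out <- matrix(NA_real_, nrow(a), 3)
  flagged <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    pos <- c(a$x[i], a$y[i], a$z[i])
    m <- .mstep_atom(fields, exp_map, exp_map, i, pos)
    out[i, ] <- m$mean
    flagged[i] <- !(is.finite(m$sw) && m$sw > 0)
  }
  if (any(flagged)) cf_log(sum(flagged), " atom(s) kept in place: ",
                           "non-positive total weight")
  structure(out, flagged = flagged)
}

#' Maximisation update of atomic widths
#'
#' The responsibility-weighted variance of the experimental density about
#' the atom's current position,
#' \eqn{\mathrm{var}_i = \sum_v W_i(v)|r(v)-x_i|^2 / \sum_v W_i(v)}, is
#' mapped to the stored width convention. With the component form
#' \eqn{Z\exp(-r^2/B^2)}, the 3-D second moment at the fixed point equals
#' \eqn{1.5\,B^2}, so the stored width is the maximum-likelihood value
#' \eqn{B' = \sqrt{(2/3)\,\mathrm{var}_i}}, which makes the update an exact
#' fixed point when the experimental map is the model's own simulated map.
#' Results are clamped to `[b_floor, b_cap]`. Atoms with non-positive total
#' weight keep their current width and are flagged.
#'
#' @inheritParams maximise_positions
#' @param b_floor,b_cap clamp bounds on the width, angstrom.
#' @return numeric vector of target widths with attribute `"flagged"`.
#' @export
maximise_bfactors <- function(state, exp_map, b_floor = 0.25, b_cap = 2.5) {
  fields <- .gmm_fields(state, exp_map)
  a <- state$model$atoms
  out <- numeric(nrow(a))
  flagged <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    pos <- c(a$x[i], a$y[i], a$z[i])
    m <- .mstep_atom(fields, exp_map, exp_map, i, pos)
    if (is.finite(m$sw) && m$sw > 0 && is.finite(m$var)) {
      out[i] <- sqrt(2 / 3 * m$var)
    } else {
      out[i] <- a$bwidth[i]
      flagged[i] <- TRUE
    }
  }
  structure(clamp(out, b_floor, b_cap), flagged = flagged)
}

#' Maximisation update of the uniform background
#'
#' Averages the background-weighted experimental map
#' \eqn{W_{err}(v) = M_e(v)\,E/M_s(v)} over the support voxels (within
#' `cutoff_sigma * bwidth` of the atoms):
#' \eqn{E' = |V|^{-1}\sum_{v\in V} W_{err}(v)}. The result is floored at
#' `1e-6 * max(exp_map)` so that the absorbing state `E = 0` (whose
#' responsibility could never recover) is avoided.
#'
#' @inheritParams maximise_positions
#' @return Updated background scalar `E'`.
#' @export
update_background <- function(state, exp_map) {
  fields <- .gmm_fields(state, exp_map)
  sup <- sort(unique(unlist(lapply(fields$blocks, `[[`, "idx"))))
  eps <- 1e-6 * max(exp_map$values)
  if (!length(sup)) return(max(state$background, eps))
  ok <- fields$ms[sup] > 0
  werr <- exp_map$values[sup[ok]] * state$background / fields$ms[sup[ok]]
  max(sum(werr) / length(sup), eps)
}

#' Residue-average restraint on widths
#'
#' Blends each atom's width with the mean width of its residue
#' (grouped by `(chain_id, residue_index)`):
#' `B <- (1 - blend) * B + blend * mean(residue B)`, then re-applies the
#' floor/cap clamp. `blend = 0` is the identity; `blend = 1` flattens every
#' residue to its mean.
#'
#' @param model an [atomic_model()].
#' @param blend blending weight in `[0, 1]`.
#' @param b_floor,b_cap clamp bounds, angstrom.
#' @return The model with restrained widths.
#' @export
restrain_bfactors <- function(model, blend = 0.5, b_floor = 0.25,
                              b_cap = 2.5) {
  stopifnot(blend >= 0, blend <= 1)
  if (blend == 0) return(model)
  key <- residue_key(model)
  resmean <- stats::ave(model$atoms$bwidth, key)
  model$atoms$bwidth <- clamp((1 - blend) * model$atoms$bwidth +
                                blend * resmean, b_floor, b_cap)
  model
}

## one full maximisation pass sharing a single field evaluation;
## returns updated state (and position targets when update_positions)
.em_iterate <- function(state, exp_map, config, update_positions) {
  fields <- .gmm_fields(state, exp_map)
  a <- state$model$atoms
  np <- nrow(a)
  targets <- matrix(NA_real_, np, 3)
  newb <- numeric(np)
  for (i in seq_len(np)) {
    pos <- c(a$x[i], a$y[i], a$z[i])
    m <- .mstep_atom(fields, exp_map, exp_map, i, pos)
    if (is.finite(m$sw) && m$sw > 0) {
      targets[i, ] <- m$mean
      newb[i] <- sqrt(2 / 3 * m$var)
    } else {
      targets[i, ] <- pos
      newb[i] <- a$bwidth[i]
    }
  }
  state$model$atoms$bwidth <- clamp(newb, config$b_floor, config$b_cap)
  state$model <- restrain_bfactors(state$model, config$residue_blend,
                                   config$b_floor, config$b_cap)
  ## background update from the same fields
  sup <- sort(unique(unlist(lapply(fields$blocks, `[[`, "idx"))))
  eps <- 1e-6 * max(exp_map$values)
  if (length(sup)) {
    ok <- fields$ms[sup] > 0
    werr <- exp_map$values[sup[ok]] * state$background / fields$ms[sup[ok]]
    state$background <- max(sum(werr) / length(sup), eps)
  } else state$background <- max(state$background, eps)
  list(state = state, targets = if (update_positions) targets else NULL)
}
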