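#' A set of pre-aligned component maps with fitted models
#'
#' Each component pairs an atomic model with its (pre-aligned) experimental
#' map; all are blended on a shared consensus grid. Atom correspondence
#' across components is resolved by exact `(chain_id, residue_index,
#' atom_name)` match; atoms present in only one component are always
#' retained.
#'
#' @param components list of `list(model = atomic_model, map = density_map)`.
#' @param consensus_grid [density_map()] supplying the target geometry;
#'   defaults to the first component's map grid.
#' @param background numeric background E per component (recycled);
#'   defaults to 0.
#' @return Object of class `component_set`.
#' @export
component_set <- function(components, consensus_grid = NULL,
                          background = 0) {
  if (length(components) < 1) stop_cf("need at least one component")
  for (cmp in components) {
    if (!inherits(cmp$model, "atomic_model") ||
        !inherits(cmp$map, "density_map"))
      stop_cf("each component must be list(model = , map = )")
    if (n_atoms(cmp$model) == 0) stop_cf("component models must be non-empty")
  }
  structure(list(components = components,
                 consensus_grid = consensus_grid %||% components[[1]]$map,
                 background = rep_len(background, length(components))),
            class = "component_set")
}

## atom keys of one model
.atom_keys <- function(model)
  paste(model$atoms$chain_id, model$atoms$residue_index,
        model$atoms$atom_name, sep = "|")

## which atoms of component ci keep their Z: an atom is zeroed when a
## corresponding atom in another component has a strictly lower width
## (ties keep the atom in the earliest component by input order)
.retained_atoms <- function(set, ci) {
  keys <- .atom_keys(set$components[[ci]]$model)
  b <- set$components[[ci]]$model$atoms$bwidth
  keep <- rep(TRUE, length(keys))
  for (cj in seq_along(set$components)) {
    if (cj == ci) next
    mj <- set$components[[cj]]$model
    hit <- match(keys, .atom_keys(mj))
    found <- !is.na(hit)
    bj <- mj$atoms$bwidth[hit[found]]
    lose <- bj < b[found] | (bj == b[found] & cj < ci)
    keep[found][lose] <- FALSE
  }
  keep
}

#' Simulated map of one component
#'
#' Simulates the mixture of component `c`'s atoms (plus its background) on
#' the consensus grid, with the atomic number set to 0 for any atom whose
#' corresponding atom in another component has a strictly lower width —
#' only the sharpest copy of a shared atom contributes. Width ties keep the
#' atom in the first component by input order (logged).
#'
#' @param set a [component_set()].
#' @param c component index.
#' @return A [density_map()] on the consensus grid.
#' @export
component_simulated_map <- function(set, c) {
  model <- set$components[[c]]$model
  keep <- .retained_atoms(set, c)
  if (!all(keep))
    cf_log(sum(!keep), " atom(s) of component ", c,
           " zeroed (sharper copy elsewhere)")
  model$atoms$atomic_number[!keep] <- 0
  simulate_map(gmm_state(model, set$background[c]), set$consensus_grid)
}

#' Component responsibility maps
#'
#' Normalises each component's simulated map against the sum over
#' components: \eqn{\gamma_c(v) = M_c(v) / \sum_c M_c(v)}. Voxels where the
#' denominator is zero get \eqn{\gamma_c = 0} for every component and are
#' excluded from the support.
#'
#' @param set a [component_set()].
#' @return List with `gamma` (list of arrays, one per component) and
#'   `included` (logical array of voxels with non-zero denominator).
#' @export
component_responsibilities <- function(set) {
  sims <- lapply(seq_along(set$components),
                 function(ci) component_simulated_map(set, ci)$values)
  denom <- Reduce(`+`, sims)
  included <- denom > 0
  gamma <- lapply(sims, function(s) {
    g <- array(0, dim(s))
    g[included] <- s[included] / denom[included]
    g
  })
  list(gamma = gamma, included = included)
}

#' Compose pre-aligned component maps
#'
#' Resamples each component's experimental map onto the consensus grid
#' (trilinear interpolation) and blends them by their component
#' responsibilities: \eqn{M_C(v) = \sum_c \gamma_c(v)\,M_{e,c}(v)}. At each
#' included voxel the composite is a convex combination of the component
#' experimental values, so overlapping components merge without seams.
#'
#' @param set a [component_set()].
#' @return A [density_map()] on the consensus grid, with the logical
#'   `included` support attached as attribute `"included"`.
#' @export
compose_maps <- function(set) {
  resp <- component_responsibilities(set)
  grid <- set$consensus_grid
  acc <- array(0, grid_dim(grid))
  for (ci in seq_along(set$components)) {
    me <- resample_map(set$components[[ci]]$map, grid)
    acc <- acc + resp$gamma[[ci]] * me$values
  }
  out <- density_map(acc, grid$voxel_size, grid$origin, grid$resolution)
  attr(out, "included") <- resp$included
  out
}
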