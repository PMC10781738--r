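#' Ensemble configuration
#'
#' Constants of the width-driven ensemble generator. Defaults follow the
#' published settings: anchoring constant `k_ens = 1000`; density-force
#' constant `k_dens = 50` (the useful range is roughly 5-200 and is
#' map-dependent); shifted-width floor 0.25 angstrom; 2000-step relaxation
#' budget (nominal 0.1 fs per step, metadata for external engines).
#'
#' @param k_ens anchoring-energy constant.
#' @param k_dens density-force constant.
#' @param b_shift_floor minimum of the shifted widths, angstrom.
#' @param relax_steps iteration budget of the member minimiser.
#' @param step_time nominal time step in femtoseconds (metadata only).
#' @param max_models maximum ensemble size for [select_ensemble_size()].
#' @param plateau_tol CCC gain below which ensemble growth stops.
#' @param seed integer base seed; member `j` uses `seed + j`.
#' @param variance_convention `"variance"` (default): the shifted width is
#'   the per-coordinate sampling variance in square angstrom;
#'   `"sd"`: it is the standard deviation.
#' @return Object of class `ensemble_config`.
#' @export
ensemble_config <- function(k_ens = 1000, k_dens = 50, b_shift_floor = 0.25,
                            relax_steps = 2000, step_time = 0.1,
                            max_models = 30, plateau_tol = 1e-4, seed = 1,
                            variance_convention = c("variance", "sd")) {
  if (k_ens <= 0 || b_shift_floor <= 0 || max_models < 1)
    stop_cf("need k_ens > 0, b_shift_floor > 0, max_models >= 1")
  structure(list(k_ens = k_ens, k_dens = k_dens,
                 b_shift_floor = b_shift_floor, relax_steps = relax_steps,
                 step_time = step_time, max_models = max_models,
                 plateau_tol = plateau_tol, seed = as.integer(seed),
                 variance_convention = match.arg(variance_convention)),
            class = "ensemble_config")
}

#' Shifted widths
#'
#' Rigid shift of the per-atom widths so that their minimum equals `floor`:
#' `b - min(b) + floor`.
#'
#' @param b numeric widths.
#' @param floor target minimum, angstrom (default 0.25).
#' @return shifted widths.
#' @export
shifted_bwidth <- function(b, floor = 0.25) b - min(b) + floor

## run `expr` under a private RNG stream without disturbing the caller's
with_member_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Perturb a model into an ensemble member
#'
#' Samples each atom's position from an isotropic Gaussian centred on the
#' anchor position. The per-coordinate variance is the atom's shifted width
#' (widths shifted so their minimum equals `b_shift_floor`); with
#' `variance_convention = "sd"` the shifted width is used as the standard
#' deviation instead. Deterministic given `member_seed`; atom ordering and
#' topology are preserved exactly.
#'
#' @param anchor the anchor [atomic_model()].
#' @param config an [ensemble_config()].
#' @param member_seed integer seed for this member.
#' @return A perturbed [atomic_model()].
#' @export
perturb_model <- function(anchor, config = ensemble_config(),
                          member_seed = config$seed) {
  sb <- shifted_bwidth(anchor$atoms$bwidth, config$b_shift_floor)
  sdev <- if (config$variance_convention == "variance") sqrt(sb) else sb
  n <- n_atoms(anchor)
  noise <- with_member_seed(member_seed,
                            matrix(stats::rnorm(3 * n), n, 3)) * sdev
  set_atom_positions(anchor, atom_positions(anchor) + noise)
}

#' Relax an ensemble member against the density
#'
#' Minimises the member's total energy — per-atom anchoring energy
#' ([ensemble_energy()]) plus the density-guided term
#' \eqn{-k_{dens} M_e(x_i)} (trilinearly interpolated, analytic gradient)
#' plus harmonic bond restraints about the anchor's bond lengths — with a
#' limited-memory quasi-Newton minimiser (`stats::optim` L-BFGS-B), for at
#' most `relax_steps` iterations.
#'
#' @param member perturbed [atomic_model()].
#' @param anchor the anchor [atomic_model()] (same atom ordering).
#' @param exp_map experimental [density_map()]; `NULL` drops the density
#'   term.
#' @param config an [ensemble_config()].
#' @return The relaxed member.
#' @export
refine_member <- function(member, anchor, exp_map = NULL,
                          config = ensemble_config()) {
  x0 <- atom_positions(member)
  xa <- atom_positions(anchor)
  sb <- shifted_bwidth(anchor$atoms$bwidth, config$b_shift_floor)
  bonds <- anchor$bonds
  r0 <- if (is.null(bonds) || nrow(bonds) == 0) numeric(0) else {
    d <- xa[bonds[, 1], , drop = FALSE] - xa[bonds[, 2], , drop = FALSE]
    sqrt(rowSums(d * d))
  }
  n <- nrow(x0)
  kb <- 1e3   # stiff relative to the k_ens / k_dens force scale
  fn <- function(p) {
    x <- matrix(p, n, 3)
    e <- ensemble_energy(x, xa, sb, config$k_ens)$energy +
      .bond_energy(x, bonds, r0, kb)$energy
    if (!is.null(exp_map) && config$k_dens != 0)
      e <- e - config$k_dens * sum(trilinear_value(exp_map, x))
    e
  }
  gr <- function(p) {
    x <- matrix(p, n, 3)
    g <- ensemble_energy(x, xa, sb, config$k_ens)$gradient +
      .bond_energy(x, bonds, r0, kb)$gradient
    if (!is.null(exp_map) && config$k_dens != 0)
      g <- g - config$k_dens * trilinear_gradient(exp_map, x)
    as.vector(g)
  }
  fit <- stats::optim(as.vector(x0), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = config$relax_steps))
  set_atom_positions(member, matrix(fit$par, n, 3))
}

#' Build an ensemble
#'
#' Draws `n` perturbed members around the anchor and, unless
#' `relax = FALSE`, relaxes each against the map with [refine_member()].
#'
#' @param anchor the anchor [atomic_model()].
#' @param n number of members.
#' @param exp_map experimental [density_map()] (may be `NULL` when
#'   `relax = FALSE`).
#' @param config an [ensemble_config()].
#' @param relax relax members after perturbation?
#' @return Object of class `model_ensemble`: list with `anchor`, `members`
#'   and per-member `seeds`.
#' @export
make_ensemble <- function(anchor, n, exp_map = NULL,
                          config = ensemble_config(), relax = TRUE) {
  seeds <- config$seed + seq_len(n)
  members <- lapply(seeds, function(s) {
    m <- perturb_model(anchor, config, member_seed = s)
    if (relax) m <- refine_member(m, anchor, exp_map, config)
    m
  })
  structure(list(anchor = anchor, members = members, seeds = seeds),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("model_ensemble: %d members, %d atoms each\n",
              length(x$members), n_atoms(x$anchor)))
  invisible(x)
}

#' Ensemble-average map
#'
#' Voxelwise mean of the maps simulated from every member (each with its
#' own widths, shared background).
#'
#' @param ensemble a `model_ensemble`.
#' @param grid [density_map()] supplying the geometry.
#' @param background shared background E.
#' @return A [density_map()].
#' @export
ensemble_map <- function(ensemble, grid, background = 0) {
  stopifnot(length(ensemble$members) >= 1)
  acc <- array(0, grid_dim(grid))
  for (m in ensemble$members)
    acc <- acc + simulate_map(gmm_state(m, background), grid)$values
  density_map(acc / length(ensemble$members), grid$voxel_size, grid$origin,
              grid$resolution)
}

#' Choose the ensemble size by CCC plateau
#'
#' Grows the ensemble one member at a time, each time recomputing the CCC
#' between the ensemble-average map and the experimental map over the
#' anchor's support, and stops as soon as the gain drops to
#' `plateau_tol` or `max_models` is reached. If the final member decreased
#' the CCC it is dropped (the returned size never scores below an earlier
#' accepted size).
#'
#' @param anchor the anchor [atomic_model()].
#' @param exp_map experimental [density_map()].
#' @param config an [ensemble_config()].
#' @param relax relax members against the map?
#' @param background shared background for member simulation.
#' @return List with `n`, `ensemble` (a `model_ensemble`) and `ccc_history`
#'   (CCC at each size).
#' @export
select_ensemble_size <- function(anchor, exp_map,
                                 config = ensemble_config(), relax = TRUE,
                                 background = 0) {
  support <- model_support(gmm_state(anchor), exp_map)
  members <- list()
  acc <- array(0, grid_dim(exp_map))
  hist <- numeric(0)
  repeat {
    j <- length(members) + 1L
    m <- perturb_model(anchor, config, member_seed = config$seed + j)
    if (relax) m <- refine_member(m, anchor, exp_map, config)
    members[[j]] <- m
    acc <- acc + simulate_map(gmm_state(m, background), exp_map)$values
    avg <- density_map(acc / j, exp_map$voxel_size, exp_map$origin)
    hist[j] <- ccc(avg, exp_map, support)
    if (j >= 2 && (hist[j] - hist[j - 1] <= config$plateau_tol ||
                   j >= config$max_models)) {
      if (hist[j] < hist[j - 1] && j > 2) {
        members <- members[seq_len(j - 1)]
        hist <- hist[seq_len(j - 1)]
      }
      break
    }
    if (j >= config$max_models) break
  }
  n <- length(members)
  list(n = n,
       ensemble = structure(list(anchor = anchor, members = members,
                                 seeds = config$seed + seq_len(n)),
                            class = "model_ensemble"),
       ccc_history = hist)
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF about the ensemble mean structure:
#' \eqn{RMSF_i = \sqrt{N^{-1}\sum_j |x_i(j) - \langle x_i\rangle|^2}} per
#' C-alpha (C1' for nucleotides). Residues without an anchor atom are
#' skipped and logged.
#'
#' @param ensemble a `model_ensemble` with at least 2 members.
#' @return Data frame with `chain_id`, `residue_index`, `rmsf` (angstrom).
#' @export
rmsf <- function(ensemble) {
  if (length(ensemble$members) < 2)
    stop_cf("rmsf needs at least 2 ensemble members")
  anchors <- .residue_anchors(ensemble$anchor)
  if (nrow(anchors) == 0)
    stop_cf("no CA/C1' anchor atoms; residues skipped")
  rows <- match(paste(anchors$chain_id, anchors$residue_index,
                      anchors$atom_name),
                paste(ensemble$anchor$atoms$chain_id,
                      ensemble$anchor$atoms$residue_index,
                      ensemble$anchor$atoms$atom_name))
  nm <- length(ensemble$members)
  coords <- array(NA_real_, c(length(rows), 3, nm))
  for (j in seq_len(nm))
    coords[, , j] <- atom_positions(ensemble$members[[j]])[rows, ,
                                                           drop = FALSE]
  mean_xyz <- apply(coords, c(1, 2), mean)
  dev2 <- sapply(seq_len(nm), function(j)
    rowSums((coords[, , j] - mean_xyz)^2))
  data.frame(chain_id = anchors$chain_id,
             residue_index = anchors$residue_index,
             rmsf = sqrt(rowMeans(dev2)))
}
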