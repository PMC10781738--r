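#' Specification of a synthetic toy system
#'
#' Parameters of the fixture generator: a self-avoiding bonded polymer
#' chain with per-atom widths drawn uniformly from `b_range`, rendered on a
#' grid of `grid_voxel`-angstrom voxels with a uniform background of
#' `noise_level` times the peak intensity. Everything is deterministic per
#' `seed`.
#'
#' @param n_residues number of residues (>= 1).
#' @param atoms_per_residue atoms per residue, bonded linearly (default 4:
#'   named N, CA, C, O so that C-alpha-based scores apply).
#' @param bond_length bond length, angstrom.
#' @param b_range width range `(min, max)` within `(0, 5]`, angstrom.
#' @param grid_voxel voxel edge, angstrom.
#' @param noise_level uniform background as a fraction of the peak
#'   intensity (>= 0).
#' @param seed integer seed.
#' @return Object of class `toy_spec`.
#' @export
toy_spec <- function(n_residues = 20, atoms_per_residue = 4,
                     bond_length = 1.5, b_range = c(0.5, 2),
                     grid_voxel = 1, noise_level = 0.05, seed = 1) {
  if (n_residues < 1) stop_cf("n_residues must be >= 1")
  if (b_range[1] <= 0 || b_range[2] > 5 || b_range[1] > b_range[2])
    stop_cf("b_range must lie within (0, 5]")
  if (noise_level < 0) stop_cf("noise_level must be >= 0")
  structure(list(n_residues = n_residues,
                 atoms_per_residue = atoms_per_residue,
                 bond_length = bond_length, b_range = b_range,
                 grid_voxel = grid_voxel, noise_level = noise_level,
                 seed = as.integer(seed)),
            class = "toy_spec")
}

.atom_name_set <- function(k) {
  base <- c("N", "CA", "C", "O", "CB", "CG", "CD", "CE")
  if (k == 1) return("CA")
  if (k <= length(base)) return(base[seq_len(k)])
  c(base, paste0("X", seq_len(k - length(base))))
}

#' Generate a toy polymer model
#'
#' Grows a self-avoiding 3-D random walk with fixed bond length, one bond
#' between consecutive atoms. Atomic numbers alternate 6/7/8 (C/N/O);
#' widths are drawn uniformly from `b_range`. Deterministic per seed. New
#' atoms are rejected while any non-bonded distance falls below 1.6 times
#' the bond length (2.4 angstrom at the default bond length — about the
#' closest van der Waals contact seen between non-bonded atoms in real
#' structures); repeated placement failure raises an error.
#'
#' @param spec a [toy_spec()].
#' @return An [atomic_model()] with bonds.
#' @export
make_toy_model <- function(spec = toy_spec()) {
  n <- spec$n_residues * spec$atoms_per_residue
  names_per_res <- .atom_name_set(spec$atoms_per_residue)
  with_member_seed(spec$seed, {
    pos <- matrix(NA_real_, n, 3)
    pos[1, ] <- c(0, 0, 0)
    min_sep <- 1.6 * spec$bond_length   # non-bonded exclusion, vdW-like
    for (i in seq_len(n)[-1]) {
      placed <- FALSE
      for (try in seq_len(500)) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- pos[i - 1, ] + spec$bond_length * u
        prev <- pos[seq_len(max(i - 2, 1)), , drop = FALSE]
        d2 <- rowSums(sweep(prev, 2, cand)^2)
        ## the bonded predecessor (excluded above) sits at bond_length
        if (i == 2 || all(d2 > min_sep^2)) {
          pos[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop_cf("self-avoiding walk failed to place atom ", i,
                "; try a different seed or a larger system")
    }
    b <- stats::runif(n, spec$b_range[1], spec$b_range[2])
    z <- c(6L, 7L, 8L)[(seq_len(n) - 1) %% 3 + 1]
    atoms <- data.frame(
      serial = seq_len(n),
      element = c("C", "N", "O")[(seq_len(n) - 1) %% 3 + 1],
      atomic_number = z,
      chain_id = "A",
      residue_index = rep(seq_len(spec$n_residues),
                          each = spec$atoms_per_residue),
      residue_name = "ALA",
      atom_name = rep(names_per_res, times = spec$n_residues),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      bwidth = b)
    bonds <- if (n > 1) cbind(seq_len(n - 1), 2:n) else NULL
    atomic_model(atoms, bonds)
  })
}

#' Ground-truth map for a model
#'
#' Simulates the model's mixture on a grid enclosing it with a
#' `4 * max(width)` margin, adds a uniform background
#' `E = noise_level * peak` (peak = maximum atom-only intensity) and,
#' optionally, seeded voxelwise Gaussian noise. The generating state is
#' returned alongside the map for parameter-recovery assertions.
#'
#' @param model an [atomic_model()].
#' @param spec a [toy_spec()] (voxel size, noise level, seed).
#' @param gauss_sd standard deviation of optional additive Gaussian voxel
#'   noise, as a fraction of the peak intensity (default 0).
#' @param resolution stated global resolution attached to the map; default
#'   `2.5 * grid_voxel`.
#' @return List with `map` (a [density_map()]) and `truth` (the generating
#'   [gmm_state()]).
#' @export
make_ground_truth_map <- function(model, spec = toy_spec(), gauss_sd = 0,
                                  resolution = NULL) {
  margin <- 4 * max(model$atoms$bwidth) + 2
  grid <- empty_grid(atom_positions(model), spec$grid_voxel, margin,
                     resolution %||% (2.5 * spec$grid_voxel))
  bare <- simulate_map(gmm_state(model, 0), grid)
  peak <- max(bare$values)
  e <- spec$noise_level * peak
  truth <- gmm_state(model, e)
  vals <- bare$values + e
  if (gauss_sd > 0)
    vals <- vals + with_member_seed(spec$seed + 7L,
      array(stats::rnorm(length(vals), 0, gauss_sd * peak), dim(vals)))
  list(map = density_map(vals, grid$voxel_size, grid$origin,
                         grid$resolution),
       truth = truth)
}

#' Two-conformer heterogeneous map
#'
#' Displaces a contiguous residue segment of the model by `displacement`
#' and returns the `fraction`-weighted voxel average of the maps simulated
#' from the original and displaced conformers — a minimal stand-in for
#' discrete conformational heterogeneity.
#'
#' @param model an [atomic_model()].
#' @param displacement displacement vector (angstrom); a scalar means
#'   `c(d, 0, 0)`.
#' @param fraction weight of the displaced conformer, in `(0, 1)`.
#' @param spec a [toy_spec()].
#' @param segment residue indices to displace; default the middle third.
#' @return List with `map` (the blended [density_map()]), `model_a`
#'   (original), `model_b` (displaced conformer), `map_a`, `map_b` and
#'   `segment`.
#' @export
make_two_conformer_map <- function(model, displacement = 2, fraction = 0.5,
                                   spec = toy_spec(), segment = NULL) {
  if (fraction <= 0 || fraction >= 1)
    stop_cf("fraction must be in (0, 1)")
  if (length(displacement) == 1) displacement <- c(displacement, 0, 0)
  resi <- sort(unique(model$atoms$residue_index))
  segment <- segment %||%
    resi[seq(floor(length(resi) / 3) + 1, ceiling(2 * length(resi) / 3))]
  move <- model$atoms$residue_index %in% segment
  model_b <- model
  xyz <- atom_positions(model_b)
  xyz[move, ] <- sweep(xyz[move, , drop = FALSE], 2, displacement, "+")
  model_b <- set_atom_positions(model_b, xyz)
  margin <- 4 * max(model$atoms$bwidth) + 2
  grid <- empty_grid(rbind(atom_positions(model), xyz), spec$grid_voxel,
                     margin, 2.5 * spec$grid_voxel)
  e <- spec$noise_level * max(simulate_map(gmm_state(model, 0), grid)$values)
  map_a <- simulate_map(gmm_state(model, e), grid)
  map_b <- simulate_map(gmm_state(model_b, e), grid)
  blended <- density_map((1 - fraction) * map_a$values +
                           fraction * map_b$values,
                         grid$voxel_size, grid$origin, grid$resolution)
  list(map = blended, model_a = model, model_b = model_b,
       map_a = map_a, map_b = map_b, segment = segment)
}

#' Overlapping component set fixture
#'
#' Splits the chain into `n_components` overlapping residue windows. Each
#' component receives its window's atoms (atoms in overlaps are duplicated
#' across components) and a map simulated with a per-component width
#' profile that is sharpest at the window centre (width scaled up towards
#' the window edges), plus the background. The full-model ground-truth map
#' is returned for comparison.
#'
#' @param model an [atomic_model()].
#' @param n_components number of components (>= 2).
#' @param overlap_fraction fraction of the window length shared with each
#'   neighbour, in `[0, 0.9]`.
#' @param spec a [toy_spec()].
#' @param edge_blur width multiplier reached at the window edge (default
#'   2.5; 1 = flat profile).
#' @return List with `set` (a [component_set()]), `truth_map` (full-model
#'   map on the consensus grid) and `windows` (residue index ranges).
#' @export
make_component_set <- function(model, n_components = 2,
                               overlap_fraction = 0.25, spec = toy_spec(),
                               edge_blur = 2.5) {
  if (n_components < 2) stop_cf("n_components must be >= 2")
  resi <- sort(unique(model$atoms$residue_index))
  nr <- length(resi)
  span <- nr / (n_components - (n_components - 1) * overlap_fraction)
  step <- span * (1 - overlap_fraction)
  margin <- 4 * max(model$atoms$bwidth) * edge_blur + 2
  grid <- empty_grid(atom_positions(model), spec$grid_voxel, margin,
                     2.5 * spec$grid_voxel)
  e <- spec$noise_level * max(simulate_map(gmm_state(model, 0),
                                           grid)$values)
  windows <- list()
  components <- list()
  for (ci in seq_len(n_components)) {
    lo <- max(1, round((ci - 1) * step) + 1)
    hi <- min(nr, round((ci - 1) * step + span))
    if (ci == n_components) hi <- nr
    win <- resi[lo:hi]
    windows[[ci]] <- range(win)
    rows <- model$atoms$residue_index %in% win
    sub <- model$atoms[rows, , drop = FALSE]
    ## sharpen towards the window centre, blur towards the edges
    ctr <- mean(range(win))
    relpos <- if (hi > lo) abs(sub$residue_index - ctr) / (diff(range(win)) / 2)
              else 0
    submod <- atomic_model(transform(sub,
      bwidth = bwidth * (1 + (edge_blur - 1) * pmin(relpos, 1))))
    cmap <- simulate_map(gmm_state(submod, e), grid)
    components[[ci]] <- list(model = submod, map = cmap)
  }
  truth <- simulate_map(gmm_state(model, e), grid)
  list(set = component_set(components, consensus_grid = grid,
                           background = e),
       truth_map = truth, windows = windows)
}
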