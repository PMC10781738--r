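#' GMM fitting potential
#'
#' The energy biasing an atom towards its maximisation-step target,
#' \eqn{E_{gmm} = k_{gmm}(1 - \exp(-|x - x'|^2 / (2 B^3)))}, with `B` the
#' atom's width. The energy is bounded by `k_gmm` for large displacements.
#' Vectorised over atoms.
#'
#' @param x n x 3 matrix (or length-3 vector) of current positions.
#' @param target n x 3 matrix (or length-3 vector) of target positions.
#' @param bwidth per-atom widths, angstrom.
#' @param k_gmm energy constant (default `1e5`).
#' @return List with `energy` (scalar total) and `gradient` (n x 3, with
#'   respect to `x`).
#' @export
gmm_energy <- function(x, target, bwidth, k_gmm = 1e5) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  if (is.null(dim(target))) target <- matrix(target, ncol = 3)
  d <- x - target
  d2 <- rowSums(d * d)
  s <- 2 * bwidth^3
  e <- exp(-d2 / s)
  list(energy = sum(k_gmm * (1 - e)),
       gradient = (2 * k_gmm * e / s) * d)
}

#' Ensemble anchoring potential
#'
#' The per-atom energy tethering an ensemble member to its anchor position,
#' \eqn{E_{ens} = k_{ens} / \sqrt{2\pi^3 B^3}\,(1 - \exp(-|x - x'|^2 / B^3))}.
#' Vectorised over atoms.
#'
#' @param x n x 3 matrix of member positions.
#' @param anchor n x 3 matrix of anchor positions.
#' @param bwidth per-atom widths, angstrom.
#' @param k_ens energy constant (default 1000).
#' @return List with `energy` and `gradient` as in [gmm_energy()].
#' @export
ensemble_energy <- function(x, anchor, bwidth, k_ens = 1000) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  if (is.null(dim(anchor))) anchor <- matrix(anchor, ncol = 3)
  d <- x - anchor
  d2 <- rowSums(d * d)
  b3 <- bwidth^3
  pref <- k_ens / sqrt(2 * pi^3 * b3)
  e <- exp(-d2 / b3)
  list(energy = sum(pref * (1 - e)),
       gradient = (2 * pref * e / b3) * d)
}

## harmonic bond restraints about reference lengths r0; the default constant
## keeps bonds quasi-rigid against a saturated fitting potential (k_gmm 1e5)
.bond_energy <- function(x, bonds, r0, k_bond = 1e6) {
  if (is.null(bonds) || nrow(bonds) == 0)
    return(list(energy = 0, gradient = 0 * x))
  d <- x[bonds[, 1], , drop = FALSE] - x[bonds[, 2], , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  dr <- r - r0
  g <- matrix(0, nrow(x), 3)
  gi <- (2 * k_bond * dr / pmax(r, 1e-12)) * d
  for (k in seq_len(nrow(bonds))) {
    g[bonds[k, 1], ] <- g[bonds[k, 1], ] + gi[k, ]
    g[bonds[k, 2], ] <- g[bonds[k, 2], ] - gi[k, ]
  }
  list(energy = sum(k_bond * dr^2), gradient = g)
}

## soft-sphere repulsion between non-bonded pairs closer than r_min
.repulsion_energy <- function(x, bonds, r_min = 2, k_rep = 1e4) {
  n <- nrow(x)
  if (n < 3) return(list(energy = 0, gradient = 0 * x))
  bonded <- if (is.null(bonds)) character(0) else
    paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  dd <- as.matrix(stats::dist(x))
  e <- 0
  g <- matrix(0, n, 3)
  close <- which(dd < r_min & upper.tri(dd), arr.ind = TRUE)
  for (k in seq_len(nrow(close))) {
    i <- close[k, 1]; j <- close[k, 2]
    if (paste(min(i, j), max(i, j)) %in% bonded) next
    r <- max(dd[i, j], 1e-9)
    e <- e + k_rep * (r_min - r)^2
    gi <- (-2 * k_rep * (r_min - r) / r) * (x[i, ] - x[j, ])
    g[i, ] <- g[i, ] + gi
    g[j, ] <- g[j, ] - gi
  }
  list(energy = e, gradient = g)
}

#' Relax a model towards maximisation targets
#'
#' In `direct` mode positions are set to the targets exactly. In `relaxer`
#' mode a built-in minimiser takes up to `relax_steps` gradient-descent
#' steps (with backtracking halving on energy increase) on the total energy
#' `gmm_energy + harmonic bond restraints (equilibrium = input lengths) +
#' soft-sphere repulsion`. Third-party engines can stand in for this step
#' through the callable contract `function(model, targets, config) -> model`
#' accepted by [gmm_refine()]'s `relaxer` argument.
#'
#' @param model an [atomic_model()].
#' @param targets n x 3 matrix of target positions.
#' @param config a [refinement_config()] (fields `mode`, `relax_steps`,
#'   `k_gmm` are used).
#' @return The relaxed model. If the step size collapses below `1e-10`
#'   before the step budget is exhausted, relaxation stops there and a
#'   diagnostic attribute `"relax_stalled"` is attached.
#' @export
relax <- function(model, targets, config = refinement_config()) {
  if (config$mode == "direct")
    return(set_atom_positions(model, targets))
  x <- atom_positions(model)
  bonds <- model$bonds
  r0 <- if (is.null(bonds) || nrow(bonds) == 0) numeric(0) else {
    d <- x[bonds[, 1], , drop = FALSE] - x[bonds[, 2], , drop = FALSE]
    sqrt(rowSums(d * d))
  }
  b <- model$atoms$bwidth
  etot <- function(x) {
    gmm_energy(x, targets, b, config$k_gmm)$energy +
      .bond_energy(x, bonds, r0)$energy +
      .repulsion_energy(x, bonds)$energy
  }
  gtot <- function(x) {
    gmm_energy(x, targets, b, config$k_gmm)$gradient +
      .bond_energy(x, bonds, r0)$gradient +
      .repulsion_energy(x, bonds)$gradient
  }
  e <- etot(x)
  step <- 1e-3
  stalled <- FALSE
  for (it in seq_len(config$relax_steps)) {
    g <- gtot(x)
    gn <- sqrt(sum(g * g))
    if (gn < 1e-10) break
    repeat {
      xn <- x - step * g / max(gn, 1)
      en <- etot(xn)
      if (en <= e + 1e-12) break
      step <- step / 2
      if (step < 1e-10) { stalled <- TRUE; break }
    }
    if (stalled) {
      warning("relaxer stalled: step size collapsed below 1e-10 at step ",
              it, call. = FALSE)
      break
    }
    x <- xn
    if (e - en < 1e-12 * max(1, abs(e))) { e <- en; break }
    e <- en
    step <- step * 1.5
  }
  out <- set_atom_positions(model, x)
  if (stalled) attr(out, "relax_stalled") <- TRUE
  out
}
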