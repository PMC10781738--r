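#' Refinement configuration
#'
#' Collects the tunable constants of the EM refinement loop. Defaults follow
#' the method's published settings: fitting-potential constant
#' `k_gmm = 1e5`; width cap 2.5 angstrom (1.5 in membrane-protein mode);
#' width floor 0.25 angstrom; 25 width-only iterations before any positional
#' update; a 2000-step relaxation budget per iteration; convergence patience
#' of 5 iterations; hard stop at 300 iterations.
#'
#' @param k_gmm fitting-potential energy constant.
#' @param b_cap maximum allowed width, angstrom (ignored if `membrane`).
#' @param b_floor minimum allowed width, angstrom.
#' @param b_only_iterations number of width-only iterations before
#'   positional refinement.
#' @param relax_steps step budget of the built-in relaxer per iteration.
#' @param patience stop after this many consecutive iterations without CCC
#'   improvement (improvement means a CCC gain greater than `1e-6`).
#' @param max_iterations hard cap on positional iterations.
#' @param residue_blend weight in `[0, 1]` of the residue-average width
#'   restraint (0 = none, 1 = flat residues).
#' @param mode `"direct"` (positions set to their maximisation targets) or
#'   `"relaxer"` (built-in minimiser biased by the fitting potential).
#' @param membrane use the membrane-protein width cap of 1.5 angstrom.
#' @param cutoff_sigma voxel-inclusion cutoff in units of the width.
#' @param seed integer seed (only the ensemble machinery draws random
#'   numbers; refinement itself is deterministic).
#' @return Object of class `refinement_config`.
#' @export
refinement_config <- function(k_gmm = 1e5, b_cap = 2.5, b_floor = 0.25,
                              b_only_iterations = 25, relax_steps = 2000,
                              patience = 5, max_iterations = 300,
                              residue_blend = 0.5,
                              mode = c("direct", "relaxer"),
                              membrane = FALSE, cutoff_sigma = 4, seed = 1) {
  if (membrane) b_cap <- 1.5
  if (!(b_floor > 0 && b_floor < b_cap))
    stop_cf("need 0 < b_floor < b_cap")
  if (patience < 1 || max_iterations < 1)
    stop_cf("patience and max_iterations must be >= 1")
  structure(list(k_gmm = k_gmm, b_cap = b_cap, b_floor = b_floor,
                 b_only_iterations = b_only_iterations,
                 relax_steps = relax_steps, patience = patience,
                 max_iterations = max_iterations,
                 residue_blend = residue_blend, mode = match.arg(mode),
                 membrane = membrane, cutoff_sigma = cutoff_sigma,
                 seed = as.integer(seed)),
            class = "refinement_config")
}

## initial background: mean intensity outside the model's support, or 10%
## of the map mean if the support covers the whole grid
.initial_background <- function(model, exp_map, cutoff) {
  mask <- model_support(gmm_state(model, 0, cutoff), exp_map)
  out <- exp_map$values[!mask]
  e0 <- if (length(out)) mean(out) else 0.1 * mean(exp_map$values)
  max(e0, 1e-6 * max(exp_map$values))
}

## convergence CCC: zero-mean Pearson between the experimental map and a map
## simulated with a single global width equal to the stated resolution,
## over that scoring model's support
.convergence_ccc <- function(model, exp_map, resolution, cutoff) {
  sm <- model
  sm$atoms$bwidth <- rep(resolution, nrow(sm$atoms))
  st <- gmm_state(sm, 0, cutoff)
  sim <- simulate_map(st, exp_map)
  ccc(sim, exp_map, support = model_support(st, exp_map))
}

## CCC of the state's own simulated map over its own support
.state_ccc <- function(state, exp_map) {
  sim <- simulate_map(state, exp_map)
  ccc(sim, exp_map, support = model_support(state, exp_map))
}

#' Refine an atomic model against a density map
#'
#' Expectation-maximisation refinement of per-atom Gaussian widths,
#' positions and the uniform background against an experimental map. The
#' run has two phases: (1) `b_only_iterations` width-only iterations
#' (positions fixed; widths, residue restraint and background updated each
#' pass); (2) the positional loop — expectation, maximisation of positions,
#' widths and background, relaxation towards the position targets, then
#' scoring by the convergence CCC (computed from a map simulated with one
#' global width equal to the stated resolution). The loop stops when the
#' CCC has not improved for `patience` consecutive iterations, or after
#' `max_iterations`; the returned model is the best-scoring one, not the
#' last.
#'
#' @param model an [atomic_model()].
#' @param exp_map experimental [density_map()]; the model and map must
#'   overlap spatially.
#' @param resolution global map resolution in angstrom; defaults to
#'   `exp_map$resolution` and is required.
#' @param config a [refinement_config()].
#' @param b_only if `TRUE`, stop after the width-only phase.
#' @param scorer optional replacement for the convergence score, a
#'   `function(state, exp_map)` returning a scalar (used mostly for
#'   convergence-bookkeeping tests).
#' @param relaxer optional external relaxation engine with signature
#'   `function(model, targets, config) -> model`, replacing [relax()].
#' @return Object of class `gmm_refit` with components `final_model`,
#'   `final_background`, `ccc_history` (one entry per scored iteration,
#'   both phases), `b_history` (per-iteration width/background summary),
#'   `iterations_run`, `stop_reason` (`"converged"` or
#'   `"max_iterations"`), `config`, `resolution` and the input map.
#' @seealso [coef.gmm_refit()], [fitted.gmm_refit()], [simulate.gmm_refit()]
#' @export
gmm_refine <- function(model, exp_map, resolution = exp_map$resolution,
                       config = refinement_config(), b_only = FALSE,
                       scorer = NULL, relaxer = NULL) {
  stopifnot(inherits(model, "atomic_model"), inherits(exp_map, "density_map"))
  if (is.null(resolution))
    stop_cf("a global map resolution is required (argument 'resolution' ",
            "or exp_map$resolution)")
  model$atoms$bwidth <- clamp(model$atoms$bwidth, config$b_floor,
                              config$b_cap)
  e0 <- .initial_background(model, exp_map, config$cutoff_sigma)
  state <- gmm_state(model, e0, config$cutoff_sigma)

  ccc_hist <- numeric(0)
  b_hist <- list()
  note <- function(phase, it, score) {
    b <- state$model$atoms$bwidth
    b_hist[[length(b_hist) + 1L]] <<- data.frame(
      phase = phase, iteration = it, ccc = score,
      background = state$background, b_mean = mean(b),
      b_median = stats::median(b), b_min = min(b), b_max = max(b))
    ccc_hist <<- c(ccc_hist, score)
  }

  ## phase 1: width-only
  for (it in seq_len(config$b_only_iterations)) {
    state <- .em_iterate(state, exp_map, config, update_positions = FALSE)$state
    note("b_only", it, .state_ccc(state, exp_map))
  }

  stop_reason <- "converged"
  best_state <- state
  best_score <- -Inf
  n2 <- 0L
  if (!b_only) {
    score_fun <- scorer %||% function(st, mp)
      .convergence_ccc(st$model, mp, resolution, config$cutoff_sigma)
    relax_fun <- relaxer %||% relax
    stall <- 0L
    stop_reason <- "max_iterations"
    for (it in seq_len(config$max_iterations)) {
      up <- .em_iterate(state, exp_map, config, update_positions = TRUE)
      state <- up$state
      state$model <- relax_fun(state$model, up$targets, config)
      sc <- score_fun(state, exp_map)
      n2 <- it
      note("positional", it, sc)
      if (sc > best_score + 1e-6) {
        best_score <- sc
        best_state <- state
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) { stop_reason <- "converged"; break }
      }
    }
  } else best_state <- state

  structure(list(
    final_model = best_state$model,
    final_background = best_state$background,
    ccc_history = ccc_hist,
    b_history = do.call(rbind, b_hist),
    iterations_run = length(ccc_hist),
    n_positional = n2,
    stop_reason = stop_reason,
    config = config, resolution = resolution, exp_map = exp_map),
    class = "gmm_refit")
}

#' @export
print.gmm_refit <- function(x, ...) {
  cat("Gaussian-mixture density refinement\n")
  cat(sprintf("  %d atoms, %d iterations (%d width-only + %d positional), %s\n",
              n_atoms(x$final_model), x$iterations_run,
              x$iterations_run - x$n_positional, x$n_positional,
              x$stop_reason))
  nb <- x$iterations_run - x$n_positional
  if (nb > 0)
    cat(sprintf("  width-phase CCC (model widths): %.4f -> %.4f\n",
                x$ccc_history[1], x$ccc_history[nb]))
  if (x$n_positional > 0) {
    ph2 <- x$ccc_history[(nb + 1):x$iterations_run]
    cat(sprintf("  convergence CCC (global width): %.4f -> best %.4f\n",
                ph2[1], max(ph2)))
  }
  cat(sprintf("  background E = %.4g, width range [%.3g, %.3g] A\n",
              x$final_background, min(x$final_model$atoms$bwidth),
              max(x$final_model$atoms$bwidth)))
  invisible(x)
}

#' Summary of a refinement
#'
#' @param object a `gmm_refit`.
#' @param ... unused.
#' @return The object, invisibly, after printing per-phase CCC and
#'   per-residue width statistics.
#' @export
summary.gmm_refit <- function(object, ...) {
  print(object)
  h <- object$b_history
  if (!is.null(h)) {
    cat("\nPer-phase summary:\n")
    for (ph in unique(h$phase)) {
      hh <- h[h$phase == ph, ]
      cat(sprintf("  %-10s %3d iterations, CCC %.4f -> %.4f, E %.4g -> %.4g\n",
                  ph, nrow(hh), hh$ccc[1], hh$ccc[nrow(hh)],
                  hh$background[1], hh$background[nrow(hh)]))
    }
  }
  b <- object$final_model$atoms$bwidth
  cat(sprintf("\nRefined widths (A): mean %.3f, median %.3f, IQR [%.3f, %.3f]\n",
              mean(b), stats::median(b), stats::quantile(b, .25),
              stats::quantile(b, .75)))
  invisible(object)
}

#' @export
coef.gmm_refit <- function(object, ...) {
  a <- object$final_model$atoms
  stats::setNames(a$bwidth, paste(a$chain_id, a$residue_index, a$atom_name,
                                  sep = "."))
}

#' @export
fitted.gmm_refit <- function(object, ...) {
  simulate_map(gmm_state(object$final_model, object$final_background,
                         object$config$cutoff_sigma), object$exp_map)
}

#' @export
residuals.gmm_refit <- function(object, ...) {
  f <- fitted(object)
  density_map(object$exp_map$values - f$values, f$voxel_size, f$origin,
              f$resolution)
}

#' @export
plot.gmm_refit <- function(x, ...) {
  graphics::plot(seq_along(x$ccc_history), x$ccc_history, type = "b",
                 xlab = "scored iteration", ylab = "CCC",
                 main = "Refinement convergence", ...)
  nb <- x$iterations_run - x$n_positional
  if (nb > 0 && x$n_positional > 0)
    graphics::abline(v = nb + 0.5, lty = 2)
  invisible(x)
}

#' Draw perturbed ensemble members from a refinement
#'
#' Samples `nsim` members around the refined model from isotropic Gaussians
#' whose per-coordinate variance is the shifted refined width (see
#' [perturb_model()]); members are not relaxed.
#'
#' @param object a `gmm_refit`.
#' @param nsim number of members.
#' @param seed integer seed; defaults to the refinement config seed.
#' @param ... passed to [ensemble_config()].
#' @return List of [atomic_model()] members.
#' @export
simulate.gmm_refit <- function(object, nsim = 1, seed = NULL, ...) {
  cfg <- ensemble_config(seed = seed %||% object$config$seed, ...)
  lapply(seq_len(nsim), function(j)
    perturb_model(object$final_model, cfg, member_seed = cfg$seed + j))
}
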