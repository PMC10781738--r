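test_that("refining an already-optimal model converges without moving it", {
  spec <- toy_spec(n_residues = 8, b_range = c(0.6, 1.2), seed = 4,
                   noise_level = 0)
  m <- make_toy_model(spec)
  gt <- make_ground_truth_map(m, spec)
  fit <- gmm_refine(m, gt$map, resolution = 2.5,
                    config = refinement_config(mode = "direct",
                                               b_only_iterations = 5))
  expect_equal(fit$stop_reason, "converged")
  ## the best-scoring model (the one returned) never scores below the
  ## first positional iteration; individual later entries may dip within
  ## the 1e-6 patience guard
  ph2 <- tail(fit$ccc_history, fit$n_positional)
  expect_gte(max(ph2) + 1e-9, ph2[1])
  expect_lt(max(abs(atom_positions(fit$final_model) - atom_positions(m))),
            0.1)
})

test_that("the refit object keeps consistent bookkeeping", {
  spec <- toy_spec(n_residues = 5, seed = 6)
  m <- make_toy_model(spec)
  gt <- make_ground_truth_map(m, spec)
  fit <- gmm_refine(m, gt$map, resolution = 2.5,
                    config = refinement_config(b_only_iterations = 3,
                                               max_iterations = 4,
                                               patience = 2,
                                               mode = "direct"))
  expect_s3_class(fit, "gmm_refit")
  expect_length(fit$ccc_history, fit$iterations_run)
  expect_equal(nrow(fit$b_history), fit$iterations_run)
  expect_true(all(fit$final_model$atoms$bwidth >= fit$config$b_floor))
  expect_true(all(fit$final_model$atoms$bwidth <= fit$config$b_cap))
  expect_gt(fit$final_background, 0)
  ## methods are exercised
  expect_output(print(fit), "Gaussian-mixture")
  expect_named(coef(fit))
  expect_s3_class(fitted(fit), "density_map")
  expect_s3_class(residuals(fit), "density_map")
  expect_equal(residuals(fit)$values,
               gt$map$values - fitted(fit)$values, tolerance = 1e-12)
  ## simulate() draws seed-stable perturbed members
  mem <- simulate(fit, nsim = 2, seed = 4)
  expect_length(mem, 2)
  expect_identical(mem, simulate(fit, nsim = 2, seed = 4))
  expect_equal(n_atoms(mem[[1]]), n_atoms(fit$final_model))
})

test_that("a missing global resolution is a required-argument error", {
  m <- fx_toy(3)
  g <- empty_grid(atom_positions(m), 1, 6)   # resolution NULL
  expect_error(gmm_refine(m, g), "resolution")
})

test_that("patience semantics: a never-improving scorer stops after patience + 1", {
  m <- fx_model(rbind(c(0, 0, 0), c(3, 0, 0)), b = 1)
  g <- empty_grid(atom_positions(m), 1, 5)
  exp_map <- simulate_map(gmm_state(m, 0.1), g)
  exp_map$resolution <- 2
  calls <- 0
  stub <- function(state, mp) {
    calls <<- calls + 1
    0.5   # constant: the first call improves over -Inf, none after
  }
  fit <- gmm_refine(m, exp_map,
                    config = refinement_config(b_only_iterations = 0,
                                               patience = 5, mode = "direct"),
                    scorer = stub)
  expect_equal(calls, 6)          # 1 improvement + 5 stalls
  expect_equal(fit$n_positional, 6)
  expect_equal(fit$stop_reason, "converged")
})

test_that("an always-improving scorer runs to the iteration cap", {
  m <- fx_model(rbind(c(0, 0, 0), c(3, 0, 0)), b = 1)
  g <- empty_grid(atom_positions(m), 1, 5)
  exp_map <- simulate_map(gmm_state(m, 0.1), g)
  exp_map$resolution <- 2
  calls <- 0
  stub <- function(state, mp) {
    calls <<- calls + 1
    calls * 1e-3  # strictly improving beyond the 1e-6 tie guard
  }
  fit <- gmm_refine(m, exp_map,
                    config = refinement_config(b_only_iterations = 0,
                                               patience = 5,
                                               max_iterations = 17,
                                               mode = "direct"),
                    scorer = stub)
  expect_equal(calls, 17)
  expect_equal(fit$stop_reason, "max_iterations")
})

test_that("the returned model is the best-scoring one, not the last", {
  m <- fx_model(rbind(c(0, 0, 0), c(3, 0, 0)), b = 1)
  g <- empty_grid(atom_positions(m), 1, 5)
  exp_map <- simulate_map(gmm_state(m, 0.1), g)
  exp_map$resolution <- 2
  calls <- 0
  scores <- c(0.2, 0.9, 0.4, 0.3, 0.25, 0.22, 0.21, 0.2)
  marks <- numeric(0)
  stub <- function(state, mp) {
    calls <<- calls + 1
    marks <<- c(marks, state$background)
    scores[calls]
  }
  fit <- gmm_refine(m, exp_map,
                    config = refinement_config(b_only_iterations = 0,
                                               patience = 5, mode = "direct"),
                    scorer = stub)
  ## stopped after 5 stalls following the improvement at call 2
  expect_equal(calls, 7)
  expect_equal(fit$final_background, marks[2])
})

test_that("width-only refinement honours b_only and the membrane cap", {
  spec <- toy_spec(n_residues = 4, seed = 9)
  m <- make_toy_model(spec)
  gt <- make_ground_truth_map(m, spec)
  fit <- gmm_refine(m, gt$map, resolution = 2.5, b_only = TRUE,
                    config = refinement_config(b_only_iterations = 4,
                                               membrane = TRUE))
  expect_equal(fit$iterations_run, 4)
  expect_equal(fit$n_positional, 0)
  expect_lte(max(fit$final_model$atoms$bwidth), 1.5)
  expect_equal(atom_positions(fit$final_model), atom_positions(m))
})

test_that("an external relaxer attaches through the callable contract", {
  spec <- toy_spec(n_residues = 3, seed = 5)
  m <- make_toy_model(spec)
  gt <- make_ground_truth_map(m, spec)
  seen <- FALSE
  ext <- function(model, targets, config) {
    seen <<- TRUE
    set_atom_positions(model, targets)
  }
  fit <- gmm_refine(m, gt$map, resolution = 2.5,
                    config = refinement_config(b_only_iterations = 0,
                                               max_iterations = 2,
                                               mode = "relaxer"),
                    relaxer = ext)
  expect_true(seen)
  expect_s3_class(fit$final_model, "atomic_model")
})
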