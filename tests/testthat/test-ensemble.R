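test_that("width shifting anchors the minimum at the floor", {
  expect_equal(shifted_bwidth(c(0.5, 1.0)), c(0.25, 0.75))
  expect_equal(min(shifted_bwidth(runif(20, 0.3, 3))), 0.25)
  expect_equal(shifted_bwidth(c(2, 3), floor = 0.1), c(0.1, 1.1))
})

test_that("perturbation is seed-deterministic and topology-preserving", {
  m <- fx_toy(4)
  cfg <- ensemble_config(seed = 3)
  p1 <- perturb_model(m, cfg, member_seed = 11)
  p2 <- perturb_model(m, cfg, member_seed = 11)
  expect_identical(p1, p2)
  p3 <- perturb_model(m, cfg, member_seed = 12)
  expect_false(identical(atom_positions(p1), atom_positions(p3)))
  expect_identical(p1$atoms$atom_name, m$atoms$atom_name)
  expect_identical(p1$bonds, m$bonds)
  expect_identical(p1$atoms$bwidth, m$atoms$bwidth)
})

test_that("per-coordinate sampling variance matches the shifted width", {
  at <- fx_atom(b = 1.3)
  two <- atomic_model(rbind(at$atoms,
                            transform(at$atoms, residue_index = 2,
                                      x = 5, bwidth = 0.6)))
  cfg <- ensemble_config(seed = 1)
  sb <- shifted_bwidth(two$atoms$bwidth)   # (0.95, 0.25)
  draws <- vapply(seq_len(10000), function(j)
    atom_positions(perturb_model(two, cfg, member_seed = j))[, 1],
    numeric(2))
  expect_equal(var(draws[1, ]), sb[1], tolerance = 0.05)
  expect_equal(var(draws[2, ]), sb[2], tolerance = 0.05)
  ## sd convention scales differently
  cfg2 <- ensemble_config(variance_convention = "sd")
  d2 <- vapply(seq_len(2000), function(j)
    atom_positions(perturb_model(two, cfg2, member_seed = j))[1, 1],
    numeric(1))
  expect_equal(sd(d2), sb[1], tolerance = 0.1)
})

test_that("member relaxation is stationary on flat maps and contracts to the anchor", {
  m <- fx_toy(3)
  flat <- density_map(array(1, c(20, 20, 20)), 1.5, c(-12, -12, -12))
  cfg <- ensemble_config(seed = 2, relax_steps = 300)
  ## unperturbed member on a flat map: stays put
  r0 <- refine_member(m, m, flat, cfg)
  expect_lt(max(abs(atom_positions(r0) - atom_positions(m))), 1e-4)
  ## k_dens = 0: a perturbed member moves strictly closer to the anchor
  cfg0 <- ensemble_config(seed = 2, k_dens = 0, relax_steps = 300)
  p <- perturb_model(m, cfg0, member_seed = 4)
  r <- refine_member(p, m, NULL, cfg0)
  rmsd <- function(a, b) sqrt(mean(rowSums((atom_positions(a) -
                                              atom_positions(b))^2)))
  expect_lt(rmsd(r, m), rmsd(p, m))
})

test_that("member relaxation does not increase the total energy", {
  spec <- toy_spec(n_residues = 4, seed = 6)
  m <- make_toy_model(spec)
  gt <- make_ground_truth_map(m, spec)
  cfg <- ensemble_config(seed = 8, k_dens = 50, relax_steps = 500)
  p <- perturb_model(m, cfg, member_seed = 2)
  r <- refine_member(p, m, gt$map, cfg)
  sb <- shifted_bwidth(m$atoms$bwidth, cfg$b_shift_floor)
  xa <- atom_positions(m)
  bonds <- m$bonds
  r0 <- sqrt(rowSums((xa[bonds[, 1], ] - xa[bonds[, 2], ])^2))
  etot <- function(mod) {
    x <- atom_positions(mod)
    ensemble_energy(x, xa, sb, cfg$k_ens)$energy +
      cryofit:::.bond_energy(x, bonds, r0, 1e3)$energy -
      cfg$k_dens * sum(trilinear_value(gt$map, x))
  }
  expect_lte(etot(r), etot(p) + 1e-6)
})

test_that("the ensemble map averages member maps voxelwise", {
  m <- fx_toy(3)
  g <- empty_grid(atom_positions(m), 1, 6)
  ens <- structure(list(anchor = m, members = list(m, m, m), seeds = 1:3),
                   class = "model_ensemble")
  em <- ensemble_map(ens, g, background = 0.2)
  single <- simulate_map(gmm_state(m, 0.2), g)
  expect_equal(em$values, single$values, tolerance = 1e-12)
  ## linearity over two distinct members
  m2 <- set_atom_positions(m, atom_positions(m) + 0.7)
  ens2 <- structure(list(anchor = m, members = list(m, m2), seeds = 1:2),
                    class = "model_ensemble")
  em2 <- ensemble_map(ens2, g, background = 0)
  expect_equal(em2$values,
               (simulate_map(gmm_state(m, 0), g)$values +
                  simulate_map(gmm_state(m2, 0), g)$values) / 2,
               tolerance = 1e-12)
})

test_that("degenerate sampling plateaus the size selection at two members", {
  m <- fx_toy(3)
  m$atoms$bwidth[] <- 1   # flat widths: shifting collapses all variances
  spec <- toy_spec(n_residues = 3, seed = 2)
  gt <- make_ground_truth_map(m, spec)
  ## b_shift_floor ~ 0 then makes every member coincide with the anchor
  cfg <- ensemble_config(seed = 5, b_shift_floor = 1e-9, max_models = 10,
                         k_dens = 0)
  sel <- select_ensemble_size(m, gt$map, cfg, relax = FALSE,
                              background = gt$truth$background)
  expect_equal(sel$n, 2)
  expect_equal(sel$ccc_history[2], sel$ccc_history[1], tolerance = 1e-9)
})

test_that("heterogeneous maps select more than one member without losing CCC", {
  spec <- toy_spec(n_residues = 6, b_range = c(0.5, 1), seed = 7,
                   noise_level = 0.02)
  m <- make_toy_model(spec)
  tc <- make_two_conformer_map(m, 2, 0.5, spec)
  cfg <- ensemble_config(seed = 4, max_models = 8, k_dens = 0,
                         plateau_tol = 1e-4)
  sel <- select_ensemble_size(m, tc$map, cfg, relax = FALSE)
  expect_gte(sel$n, 2)
  expect_gte(tail(sel$ccc_history, 1), sel$ccc_history[1] - 1e-9)
})

test_that("rmsf matches closed forms and an independent two-pass oracle", {
  m <- fx_toy(4)
  ## identical members: zero fluctuation
  ensA <- structure(list(anchor = m, members = list(m, m, m)),
                    class = "model_ensemble")
  expect_true(all(rmsf(ensA)$rmsf == 0))
  ## two members at x +/- d: RMSF = d
  d <- 0.8
  shift <- cbind(rep(d, n_atoms(m)), 0, 0)
  mp <- set_atom_positions(m, atom_positions(m) + shift)
  mm <- set_atom_positions(m, atom_positions(m) - shift)
  ensB <- structure(list(anchor = m, members = list(mp, mm)),
                    class = "model_ensemble")
  expect_equal(rmsf(ensB)$rmsf, rep(d, 4), tolerance = 1e-12)
  ## random ensemble vs scalar two-pass implementation
  cfg <- ensemble_config(seed = 6)
  members <- lapply(1:5, function(j) perturb_model(m, cfg, member_seed = j))
  ensC <- structure(list(anchor = m, members = members),
                    class = "model_ensemble")
  got <- rmsf(ensC)
  ca <- which(m$atoms$atom_name == "CA")
  for (k in seq_along(ca)) {
    xs <- sapply(members, function(mem) atom_positions(mem)[ca[k], ])
    mu <- rowMeans(xs)
    expected <- sqrt(mean(colSums((xs - mu)^2)))
    expect_equal(got$rmsf[k], expected, tolerance = 1e-12)
  }
  expect_error(rmsf(structure(list(anchor = m, members = list(m)),
                              class = "model_ensemble")), "2")
})

test_that("sampled fluctuations rank with the widths that generated them", {
  spec <- toy_spec(n_residues = 30, b_range = c(0.5, 2), seed = 13)
  m <- make_toy_model(spec)
  ens <- make_ensemble(m, 50, NULL, ensemble_config(seed = 9), relax = FALSE)
  rf <- rmsf(ens)
  sb <- shifted_bwidth(m$atoms$bwidth)[m$atoms$atom_name == "CA"]
  expect_gt(cor(rf$rmsf, sb, method = "spearman"), 0.9)
})
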