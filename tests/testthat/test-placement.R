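test_that("align_axis applies the minimal rotation onto the target", {
  m <- make_helix(6)
  same <- align_axis(m, c(0, 0, 1), target = c(0, 0, 1))
  expect_equal(model_xyz(same), model_xyz(m))
  # z -> (theta = 70, phi = 0)
  al <- align_axis(m, c(0, 0, 1), theta = 70, phi = 0)
  R <- attr(al, "rot")
  expect_equal(as.vector(R %*% c(0, 0, 1)),
               c(sin(70 * pi / 180), 0, cos(70 * pi / 180)),
               tolerance = 1e-8)
  # idempotent: aligning again with the same target changes nothing
  al2 <- align_axis(al, as.vector(R %*% c(0, 0, 1)), theta = 70, phi = 0)
  expect_equal(model_xyz(al2), model_xyz(al), tolerance = 1e-10)
  # antiparallel case resolves deterministically
  flip <- align_axis(m, c(0, 0, 1), target = c(0, 0, -1))
  expect_equal(as.vector(attr(flip, "rot") %*% c(0, 0, 1)), c(0, 0, -1),
               tolerance = 1e-10)
})

test_that("the full truth ring is placed at the true position", {
  case <- tiny_case()
  ring <- expand_cn(case$partial_monomer,
                    cn_operators(5, c(0, 0, 1), c(0, 0, 0)))
  # use the FULL protomer ring: the clean-model control
  full_ring <- case$em_model
  pol <- vec_to_polar(case$axis)
  pl <- search_placement(full_ring, case$refl_obs, theta = pol[1],
                         phi = pol[2], order = 5, psi_step = 6,
                         d_max = 15, d_min = 3.8, refine_top = 2)
  expect_gt(pl$cor[1], 0.95)
  placed <- apply_placement(full_ring, pl)
  fc_p <- calc_structure_factors(placed, case$cell, case$sg, d_min = 3.8)
  fc_t <- resolution_window(case$refl_truth, d_min = 3.8)
  expect_gt(refl_map_cc(fc_p, fc_t)$cc, 0.95)
})

test_that("a decoy model does not produce a confident solution", {
  case <- tiny_case()
  # decoy: same size, different internal arrangement
  decoy_mono <- make_protomer(16, 2, seed = 99)
  decoy_mono <- transform_model(decoy_mono, diag(3), c(10, 0, 0))
  decoy <- expand_cn(decoy_mono, cn_operators(5, c(0, 0, 1), c(0, 0, 0)))
  pol <- vec_to_polar(case$axis)
  pl_true <- search_placement(case$em_model, case$refl_obs, theta = pol[1],
                              phi = pol[2], order = 5, psi_step = 6,
                              d_max = 15, d_min = 3.8, refine_top = 1)
  pl_decoy <- search_placement(decoy, case$refl_obs, theta = pol[1],
                               phi = pol[2], order = 5, psi_step = 6,
                               d_max = 15, d_min = 3.8, refine_top = 1)
  expect_lt(pl_decoy$cor[1], 0.6 * pl_true$cor[1])
})

test_that("rigid-body refinement recovers perturbed protomers", {
  case <- tiny_case()
  truth <- case$truth_model
  set.seed(5)
  pert <- truth
  n_at <- nrow(truth) / 5
  for (k in 1:5) {
    rows <- (k - 1) * n_at + seq_len(n_at)
    sub <- atomic_model(truth[rows, ])
    ctr <- model_centroid(sub)
    R <- rotation_about_axis(rnorm(3), runif(1, 1, 2.5))
    sub <- transform_model(sub, diag(3), -ctr)
    sub <- transform_model(sub, R, ctr + runif(3, -1.2, 1.2))
    pert[rows, c("x", "y", "z")] <- model_xyz(sub)
  }
  rb <- rigid_body_refine(pert, case$refl_obs, axis = case$axis,
                          center = case$center, d_max = 15, d_min = 3.8,
                          max_refl = 1500)
  expect_gte(rb$score, rb$score0)    # monotone acceptance
  rms <- function(m) sqrt(mean(rowSums((model_xyz(m) -
                                        model_xyz(truth))^2)))
  expect_lt(rms(rb$model), 0.5)
  expect_lt(rms(rb$model), rms(pert))
})

test_that("an already-optimal model barely moves", {
  case <- tiny_case()
  rb <- rigid_body_refine(case$truth_model, case$refl_obs, axis = case$axis,
                          center = case$center, d_max = 15, d_min = 3.8,
                          max_refl = 1500)
  expect_lt(max(rb$report$shift), 0.05)
  expect_equal(rb$s, 1, tolerance = 2e-3)
})

test_that("magnification diagnostic arithmetic", {
  expect_equal(magnification_diagnostic(1, 200), 0)
  expect_equal(magnification_diagnostic(1.1, 10), 1)
  expect_equal(magnification_diagnostic(1.42 / 1.37, 180), 6.569,
               tolerance = 1e-3)
  expect_error(magnification_diagnostic(-1, 10), "positive")
})
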