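test_that("ideal helices have the canonical backbone geometry", {
  h <- make_helix(20)
  ca <- model_xyz(h[h$name == "CA", ])
  dd <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(dd - 3.8) < 0.1))       # consecutive CA-CA
  # 20 residues rise about 30 A along the axis
  expect_equal(diff(range(ca[, 3])), 1.5 * 19, tolerance = 0.01)
  expect_true(all(h$res_name == "ALA"))
  expect_identical(unique(h$name), c("N", "CA", "C", "O", "CB"))
  # arbitrary direction: length preserved
  h2 <- make_helix(20, direction = c(1, 1, 0))
  ca2 <- model_xyz(h2[h2$name == "CA", ])
  expect_equal(sqrt(sum((ca2[20, ] - ca2[1, ])^2)),
               sqrt(sum((ca[20, ] - ca[1, ])^2)), tolerance = 1e-6)
  expect_error(make_helix(3), "at least 4")
})

test_that("protomers carry the requested residue count in n_helices pieces", {
  p <- make_protomer(66, 6, seed = 12)
  r <- attr(p, "helix_ranges")
  expect_equal(nrow(r), 6)
  expect_equal(sum(r$n_res), 66)
  expect_equal(nrow(unique(p[, c("chain", "res_seq")])), 66)
  expect_equal(unname(model_centroid(p)), c(0, 0, 0), tolerance = 1e-9)
})

test_that("ring cases are fully reproducible from (parameters, seed)", {
  a <- do.call(make_ring_case, c(ring_preset("tiny-c5"), list(seed = 3)))
  b <- do.call(make_ring_case, c(ring_preset("tiny-c5"), list(seed = 3)))
  expect_identical(model_xyz(a$truth_model), model_xyz(b$truth_model))
  expect_identical(a$refl_obs$f, b$refl_obs$f)
  expect_identical(a$truth_placement, b$truth_placement)
  # another seed gives a different crystal
  c3 <- do.call(make_ring_case, c(ring_preset("tiny-c5"), list(seed = 4)))
  expect_false(isTRUE(all.equal(a$refl_obs$f[1:50],
                                c3$refl_obs$f[1:50])))
})

test_that("the ring case honours its construction contracts", {
  case <- tiny_case()
  p <- case$params
  expect_equal(nrow(unique(case$truth_model[, c("chain", "res_seq")])),
               p$n * p$n_res)
  # delivered partial fraction within one helix of the request
  r <- attr(make_protomer(p$n_res, p$n_helices, seed = p$seed),
            "helix_ranges")
  expect_lte(abs(p$delivered_fraction - p$partial_fraction) * p$n_res,
             max(r$n_res))
  # symmetry copies keep their distance
  ca <- model_xyz(case$truth_model[case$truth_model$name == "CA", ])
  expect_gte(cyclophase:::min_copy_distance(ca, case$cell, case$sg), 4)
  # noiseless amplitudes derive exactly from the truth model
  fc <- calc_structure_factors(case$truth_model, case$cell, case$sg,
                               d_min = min(case$refl_obs$d))
  expect_equal(case$refl_obs$f, fc$f, tolerance = 1e-12)
  # the truth model is exactly Cn-symmetric about the stored operators
  op <- case$ops_truth$ops[[2]]
  n_at <- nrow(case$truth_model) / p$n
  img <- sweep(model_xyz(case$truth_model)[seq_len(n_at), ] %*% t(op$R), 2,
               op$t, "+")
  expect_equal(unname(img),
               unname(model_xyz(case$truth_model)[n_at + seq_len(n_at), ]),
               tolerance = 1e-8)
})

test_that("amplitude noise follows the target signal-to-noise", {
  noisy <- do.call(make_ring_case,
                   c(ring_preset("tiny-c5"),
                     list(seed = 3, i_over_sigma = 9.1)))
  clean <- tiny_case()
  rel <- (noisy$refl_obs$f^2 - clean$refl_obs$f^2) / clean$refl_obs$f^2
  expect_equal(stats::sd(rel), 1 / 9.1, tolerance = 0.15)
  expect_true(all(noisy$refl_obs$sigf > 0))
})

test_that("simulated EM maps are band-limited rod pictures of the model", {
  case <- tiny_case()
  em <- tiny_em()
  expect_false(em$periodic)
  # density concentrates on the model: atom sites are far above background
  at <- interpolate_map(em, model_xyz(case$em_model), cartesian = TRUE)
  expect_gt(mean(at), mean(em$values) + 2 * stats::sd(em$values))
  # doubling the pixel size halves the grid counts for the same box
  em2 <- simulate_em_map(case$em_model, resolution = 6, pixel_size = 2 * 1.37,
                         pad = 10)
  expect_equal(dim(em2$values)[1] / dim(em$values)[1], 0.5, tolerance = 0.15)
  # a magnification error dilates the EM-frame model
  pre <- ring_preset("tiny-c5")
  pre$em_map <- NULL
  mag <- do.call(make_ring_case,
                 c(pre, list(seed = 3, mag_error = 1.42 / 1.37,
                             em_map = FALSE)))
  r_em <- sqrt(rowSums(model_xyz(mag$em_model)[, 1:2]^2))
  r_tr <- sqrt(rowSums(model_xyz(case$em_model)[, 1:2]^2))
  expect_equal(mean(r_em) / mean(r_tr), 1.42 / 1.37, tolerance = 1e-6)
  expect_error(simulate_em_map(case$em_model, resolution = 2,
                               pixel_size = 1.37), "Nyquist")
})
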