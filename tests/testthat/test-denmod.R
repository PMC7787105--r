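test_that("EM masks cover the requested volume fraction and the model", {
  em <- tiny_em()
  m1 <- mask_from_em(em, 1)
  expect_true(all(m1$values == 1))
  # two-level map: fraction 0.5 selects exactly the high level
  two <- map_grid(array(rep(c(0, 4), each = 500), c(10, 10, 10)),
                  unit_cell(10, 10, 10))
  m <- mask_from_em(two, 0.5)
  expect_equal(m$values, array(rep(c(0, 1), each = 500), c(10, 10, 10)))
  # a generous mask of the tiny ring encloses nearly all its atoms
  case <- tiny_case()
  frac <- min(0.5, 3 * nrow(case$em_model) * 18 /
                (prod(pixel_size(em)) * length(em$values)))
  mk <- mask_from_em(em, frac)
  inside <- interpolate_map(mk, model_xyz(case$em_model), cartesian = TRUE)
  expect_gt(mean(inside > 0.25), 0.99)
  expect_error(mask_from_em(map_grid(array(1, c(4, 4, 4)),
                                     unit_cell(4, 4, 4)), 0.5), "constant")
})

test_that("wedge masks tile the full mask", {
  case <- tiny_case()
  grid_n <- c(36, 40, 45)
  tr <- list(R = case$truth_placement$R, t = case$truth_placement$t,
             pre_center = c(0, 0, 0))
  copy1 <- resample_mask_to_crystal(mask_from_em(tiny_em(), 0.12), tr,
                                    case$cell, grid_n)
  ops <- case$ops_truth
  wedge <- wedge_mask(copy1, ops)
  expect_equal(wedge$values * copy1$values, wedge$values)  # subset
  # half for a twofold
  half <- wedge_mask(copy1, cn_operators(2, ops$axis, ops$center))
  expect_equal(sum(half$values) / sum(copy1$values), 0.5, tolerance = 0.05)
  # the n rotated wedge copies cover (almost) the whole mask
  x <- voxel_centers(copy1)[copy1$values > 0.5, , drop = FALSE]
  covered <- rep(FALSE, nrow(x))
  for (k in seq_len(ops$n)) {
    op <- ops$ops[[k]]
    xk <- sweep(x %*% op$R, 2, as.vector(op$t %*% op$R), "+")
    # rotate each masked voxel BACK by op k and test wedge membership
    xk <- sweep((x - matrix(op$t, nrow(x), 3, byrow = TRUE)) %*% op$R, 2,
                c(0, 0, 0), "+")
    covered <- covered | (interpolate_map(wedge, xk, cartesian = TRUE) > 0.05)
  }
  # losses are confined to discretized wedge boundaries
  expect_gt(mean(covered), 0.9)
})

test_that("solvent flattening zeroes the solvent variance only", {
  case <- tiny_case()
  mp <- synthesize_map(case$refl_truth, grid_n = c(36, 40, 45))
  prot <- mp
  prot$values <- array(as.numeric(mp$values > stats::quantile(mp$values, 0.7)),
                       dim(mp$values))
  fl <- solvent_flatten(mp, prot)
  sel <- prot$values < 0.5
  expect_equal(stats::var(fl$values[sel]), 0)
  expect_identical(fl$values[!sel], mp$values[!sel])
  # flattening a flat solvent region changes nothing
  expect_identical(solvent_flatten(fl, prot)$values, fl$values)
})

test_that("histogram matching imposes the reference distribution", {
  set.seed(1)
  mp <- map_grid(array(rnorm(4000), c(20, 20, 10)), unit_cell(20, 20, 10))
  mask <- mp; mask$values <- array(1, dim(mp$values))
  ref <- rgamma(4000, shape = 2)
  out <- histogram_match(mp, mask, ref)
  # output distribution equals the reference to bin resolution
  expect_lt(suppressWarnings(stats::ks.test(out$values, ref))$statistic, 0.02)
  # rank order preserved exactly
  expect_identical(order(out$values), order(mp$values))
  # matching a map to its own histogram is (near) identity
  self <- histogram_match(mp, mask, as.vector(mp$values))
  expect_lt(max(abs(self$values - mp$values)), 0.01)
})

test_that("NCS averaging is a fixed point on symmetric maps and cuts noise", {
  case <- tiny_case()
  grid_n <- c(36, 40, 45)
  mp <- synthesize_map(case$refl_truth, grid_n = grid_n)
  tr <- list(R = case$truth_placement$R, t = case$truth_placement$t,
             pre_center = c(0, 0, 0))
  copy1 <- resample_mask_to_crystal(mask_from_em(tiny_em(), 0.12), tr,
                                    case$cell, grid_n)
  av <- ncs_average(mp, case$ops_truth, copy1)
  expect_gt(av$ncs_cc, 0.95)
  sel <- copy1$values > 0.5
  expect_gt(stats::cor(av$map$values[sel], mp$values[sel]), 0.98)
  # independent voxel noise is reduced about n-fold in variance
  set.seed(7)
  noisy <- mp
  noise <- array(rnorm(length(mp$values), sd = stats::sd(mp$values)),
                 dim(mp$values))
  noisy$values <- mp$values + noise
  avn <- ncs_average(noisy, case$ops_truth, copy1)
  resid <- avn$map$values[sel] - av$map$values[sel]
  ratio <- stats::var(resid) / stats::var(noise[sel])
  expect_lt(ratio, 2.5 / case$ops_truth$n)
  expect_gt(ratio, 0.3 / case$ops_truth$n)
  # a random map has no NCS: correlation near zero
  rnd <- map_grid(array(rnorm(prod(grid_n)), grid_n), case$cell)
  expect_lt(abs(ncs_average(rnd, case$ops_truth, copy1)$ncs_cc), 0.1)
})

test_that("phase recombination keeps amplitudes and weights by agreement", {
  case <- tiny_case()
  fo <- case$refl_obs
  fdm <- case$refl_truth
  out <- phase_recombine(fo, fdm)
  expect_identical(out$f, fo$f)            # amplitudes never modified
  expect_gt(mean(out$fom), 0.98)           # F_dm = F_o: certainty
  # random F_dm: weak weights
  set.seed(2)
  bad <- fdm
  bad$f <- sample(bad$f)
  bad$phi <- runif(nrow(bad), 0, 360)
  out2 <- phase_recombine(fo, bad)
  expect_lt(mean(out2$fom), 0.2)
})

test_that("DM from true phases is a fixed point and never alters amplitudes", {
  case <- tiny_case()
  start <- case$refl_truth
  start$fom <- 1
  cfg <- dm_config(d_start = 5, total_cycles = 12, n_steps = 4,
                   solvent_update = 100, ncs_update = 100,
                   solvent_fraction = 0.85, refine_ops = FALSE)
  grid_n <- grid_for_cell(case$cell, min(start$d))
  tr <- list(R = case$truth_placement$R, t = case$truth_placement$t,
             pre_center = c(0, 0, 0))
  copy1 <- resample_mask_to_crystal(mask_from_em(tiny_em(), 0.12), tr,
                                    case$cell, grid_n)
  st <- start
  st$phi[st$d < 5] <- NA; st$fom[st$d < 5] <- NA
  dm <- run_dm(st, cfg, ops = case$ops_truth, masks = list(copy1 = copy1),
               hist_ref = case$refl_truth)
  expect_identical(dm$refl$f, start$f)
  expect_true(all(dm$trace$ncs_cc > 0.9))
  expect_false(dm$aborted)
  # extended phases stay essentially true
  pe <- mean_phase_error(dm$refl, case$refl_truth)
  expect_lt(pe$mean_error, 15)
  cc <- refl_map_cc(dm$refl, case$refl_truth)
  expect_gt(cc$cc, 0.95)
  # trace bookkeeping: d cutoff non-increasing, within [d_final, d_start]
  expect_true(all(diff(dm$trace$d_cut) < 1e-9))
  expect_true(all(dm$trace$ncs_cc >= -1 & dm$trace$ncs_cc <= 1))
})

test_that("dm_config validates the protocol constants", {
  cfg <- dm_config()
  expect_equal(cfg$d_start, 7.9)
  expect_equal(cfg$total_cycles, 104)
  expect_equal(cfg$solvent_update, 50)
  expect_equal(cfg$ncs_update, 20)
  expect_error(dm_config(d_start = 3, d_final = 4), "d_start")
  expect_error(dm_config(total_cycles = 5, n_steps = 10), "total_cycles")
  expect_error(dm_config(ncs_update = 0), "cadences")
})
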