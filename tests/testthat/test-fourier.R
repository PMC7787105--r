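test_that("a single atom at the origin scatters with zero phase", {
  m <- toy_model()[1, ]
  m$x <- 0; m$y <- 0; m$z <- 0
  fc <- calc_structure_factors(m, toy_cell(), space_group("P1"), d_min = 3,
                               method = "direct")
  dphi <- pmin(fc$phi %% 360, 360 - fc$phi %% 360)
  expect_true(all(dphi < 1e-6))
})

test_that("translation applies the Fourier shift theorem", {
  cell <- toy_cell(); sg <- space_group("P1")
  m <- toy_model()[1:10, ]
  t_frac <- c(0.11, 0.23, 0.31)
  mt <- transform_model(m, diag(3), as.vector(frac_to_orth(t_frac, cell)))
  f0 <- calc_structure_factors(m, cell, sg, d_min = 3.5, method = "direct")
  f1 <- calc_structure_factors(mt, cell, sg, d_min = 3.5, method = "direct")
  expect_equal(f1$f, f0$f, tolerance = 1e-8)
  h <- as.matrix(f0[, c("h", "k", "l")])
  expected <- (f0$phi + 360 * as.vector(h %*% t_frac)) %% 360
  dphi <- (f1$phi - expected) %% 360
  expect_true(all(pmin(dphi, 360 - dphi) < 1e-6))
})

test_that("FFT structure factors agree with direct summation to <1%", {
  cell <- toy_cell(); sg <- space_group("P212121")
  m <- toy_model()
  fd <- calc_structure_factors(m, cell, sg, d_min = 2.5, method = "direct")
  ff <- calc_structure_factors(m, cell, sg, d_min = 2.5, method = "fft")
  expect_identical(as.matrix(fd[, 1:3]), as.matrix(ff[, 1:3]))
  rel <- abs(ff$f - fd$f) / mean(fd$f)
  expect_lt(max(rel), 0.01)
  strong <- fd$f > 0.2 * mean(fd$f)
  dphi <- (ff$phi - fd$phi) %% 360
  expect_lt(max(pmin(dphi, 360 - dphi)[strong]), 1)
})

test_that("map synthesis and inversion round-trip to 1e-6", {
  cell <- toy_cell(); sg <- space_group("P212121")
  fc <- calc_structure_factors(toy_model(), cell, sg, d_min = 3)
  mp <- synthesize_map(fc)
  expect_lt(abs(mean(mp$values)), 1e-10 * stats::sd(mp$values))  # F000 absent
  back <- invert_map(mp, sg, d_min = 3, hkl = as.matrix(fc[, 1:3]))
  expect_lt(max(abs(back$f - fc$f)) / mean(fc$f), 1e-6)
  dphi <- (back$phi - fc$phi) %% 360
  expect_lt(max(pmin(dphi, 360 - dphi)[fc$f > 1e-6 * mean(fc$f)]), 1e-4)
  # Parseval: sum over the full sphere of |F|^2 = V^2 <rho^2>
  ex <- cyclophase:::refl_expand_full(fc)
  v <- cell_volume(cell)
  expect_equal(sum(ex$f^2) / v^2, mean(mp$values^2), tolerance = 1e-6)
  expect_error(invert_map(synthesize_map(fc, grid_n = c(8, 8, 8)), sg,
                          d_min = 3), "aliasing")
})

test_that("difference map coefficients behave algebraically", {
  cell <- toy_cell(); sg <- space_group("P212121")
  fc <- calc_structure_factors(toy_model(), cell, sg, d_min = 3.2)
  # Fo = Fc: the Fo-Fc map is identically zero
  z <- synthesize_map(map_coefficients(fc, fc, "fo-fc"),
                      grid_n = c(30, 32, 36))
  expect_lt(max(abs(z$values)), 1e-9)
  # and 2Fo-Fc equals the Fo synthesis
  m1 <- synthesize_map(map_coefficients(fc, fc, "2fo-fc"),
                       grid_n = c(30, 32, 36))
  m2 <- synthesize_map(map_coefficients(fc, fc, "fo"), grid_n = c(30, 32, 36))
  expect_equal(m1$values, m2$values, tolerance = 1e-9)
  expect_error(synthesize_map(tiny_case()$refl_obs), "phases")
})

test_that("Patterson maps are centrosymmetric with interatomic-vector peaks", {
  cell <- unit_cell(18, 20, 22)
  sg <- space_group("P1")
  two <- atomic_model(data.frame(serial = 1:2, name = "CA", res_name = "ALA",
                                 chain = "A", res_seq = 1:2,
                                 x = c(4, 9), y = c(5, 8), z = c(6, 11),
                                 occ = 1, b = 15, element = "C"))
  fc <- calc_structure_factors(two, cell, sg, d_min = 2, method = "direct")
  p <- patterson_map(fc, normalize = FALSE)
  v <- p$values
  d <- dim(v)
  # P(u) = P(-u): compare with the index-reversed array
  rev_idx <- function(n) c(1, n:2)
  expect_equal(v, v[rev_idx(d[1]), rev_idx(d[2]), rev_idx(d[3])],
               tolerance = 1e-8 * max(abs(v)))
  # origin is the global maximum
  expect_equal(which.max(v), 1)
  # peaks at +-(interatomic vector)
  u <- c(5, 3, 5) / c(18, 20, 22)
  pk <- interpolate_map(p, rbind(u, -u))
  expect_true(all(pk > 0.35 * max(v)))
  # everything far from 0 and +-u is small
  away <- interpolate_map(p, rbind(c(0.5, 0.5, 0.5), c(0.25, 0.08, 0.4)))
  expect_true(all(away < 0.15 * max(v)))
  expect_error(patterson_map(resolution_window(fc, d_min = 50)), "empty")
})

test_that("trilinear interpolation is exact at nodes and linear between", {
  cell <- unit_cell(10, 10, 10)
  vals <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  mp <- map_grid(vals, cell)
  expect_equal(interpolate_map(mp, c(3 / 8, 5 / 8, 7 / 8)), vals[4, 6, 8])
  # midpoint between two nodes on a ramp is the mean
  ramp <- map_grid(array(rep(1:8, 64), c(8, 8, 8)), cell)
  expect_equal(interpolate_map(ramp, c(2.5 / 8, 0, 0)),
               mean(c(ramp$values[3, 1, 1], ramp$values[4, 1, 1])))
  cm <- map_grid(array(2.5, c(4, 4, 4)), cell)
  expect_equal(interpolate_map(cm, matrix(runif(30), ncol = 3)),
               rep(2.5, 10))
})

test_that("map correlation behaves like a Pearson correlation", {
  a <- map_grid(array(rnorm(4^3), c(4, 4, 4)), unit_cell(5, 5, 5))
  b <- a; b$values <- -a$values
  expect_equal(map_correlation(a, a), 1)
  expect_equal(map_correlation(a, b), -1)
  b$values <- a$values + 7
  expect_equal(map_correlation(a, b), 1)
  expect_error(map_correlation(a, map_grid(array(1, c(4, 4, 4)) + 0 *
    a$values, unit_cell(5, 5, 5))), "zero variance")
  mask <- a; mask$values <- array(as.numeric(a$values > 0), dim(a$values))
  expect_equal(map_correlation(a, a, mask), 1)
})

test_that("MRC maps round-trip through the mode-2 format", {
  em <- tiny_em()
  f <- tempfile(fileext = ".mrc")
  write_mrc(em, f)
  back <- read_mrc(f, periodic = FALSE)
  expect_equal(dim(back$values), dim(em$values))
  expect_equal(back$cell$a, em$cell$a, tolerance = 1e-4)
  expect_equal(back$origin, em$origin, tolerance = 1e-5)
  rng <- max(em$values) - min(em$values)
  expect_lt(max(abs(back$values - em$values)), 1e-6 * rng)  # float32
})
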