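test_that("PDB files round-trip to format precision", {
  one <- atomic_model(data.frame(serial = 1, name = "CA", res_name = "ALA",
                                 chain = "A", res_seq = 1,
                                 x = 1, y = 2, z = 3, occ = 1, b = 20,
                                 element = "C"))
  f <- tempfile(fileext = ".pdb")
  write_pdb(one, f)
  back <- read_pdb(f)
  expect_equal(nrow(back), 1)
  expect_equal(unlist(back[1, c("x", "y", "z")]), c(x = 1, y = 2, z = 3))

  five <- make_helix(4)[1:5, ]
  five$x <- five$x + 0.0004   # force rounding to 3 decimals
  write_pdb(five, f)
  back <- read_pdb(f)
  expect_equal(unname(model_xyz(back)), unname(model_xyz(five)),
               tolerance = 6e-4)
  expect_identical(back$name, five$name)
  expect_identical(back$element, five$element)
  expect_identical(back$chain, five$chain)
})

test_that("a written ring contains one chain id per protomer", {
  ring <- expand_cn(make_helix(6), cn_operators(13, c(0, 0, 1), c(20, 0, 0)))
  f <- tempfile(fileext = ".pdb")
  write_pdb(ring, f)
  expect_equal(length(unique(read_pdb(f)$chain)), 13)
})

test_that("malformed PDB records raise an error naming the line", {
  f <- tempfile(fileext = ".pdb")
  good <- "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00 20.00           C"
  bad <- sub("   3.000", "   x.000", good)
  writeLines(c("REMARK test", good, bad), f)
  expect_error(read_pdb(f), "line 3")
})

test_that("PDB writer agrees with an independent reader", {
  # bio3d parses the same fixed-width columns; cross-check coordinates
  ring <- expand_cn(make_helix(5), cn_operators(3, c(0, 0, 1), c(10, 0, 0)))
  f <- tempfile(fileext = ".pdb")
  write_pdb(ring, f)
  ref <- bio3d::read.pdb(f)
  expect_equal(matrix(ref$xyz, ncol = 3, byrow = TRUE), unname(model_xyz(ring)),
               tolerance = 6e-4)
  expect_identical(ref$atom$chain, ring$chain)
})

test_that("Cn operators satisfy the group axioms", {
  ops <- cn_operators(13, c(0, 0, 1), c(5, 5, 0))
  expect_equal(length(ops$ops), 13)
  gen <- ops$ops[[2]]$R
  # generator angle 2*pi/13
  expect_equal(acos((sum(diag(gen)) - 1) / 2) * 180 / pi, 360 / 13,
               tolerance = 1e-10)
  for (op in ops$ops) {
    expect_equal(t(op$R) %*% op$R, diag(3), tolerance = 1e-10)
    expect_equal(det(op$R), 1, tolerance = 1e-10)
  }
  # applying the generator 13 times returns any point to itself
  p <- c(11, -3, 7)
  for (k in 1:13) p <- as.vector(gen %*% p) + ops$ops[[2]]$t
  expect_equal(p, c(11, -3, 7), tolerance = 1e-8)
  # single identity operator for n = 1
  expect_equal(cn_operators(1, c(0, 0, 1))$ops[[1]]$R, diag(3))
  expect_error(cn_operators(5, c(0, 0, 0)), "nonzero")
})

test_that("operators preserve pairwise distances", {
  ops <- cn_operators(7, c(1, 2, 2), c(3, -1, 4))
  xyz <- matrix(rnorm(30, sd = 10), ncol = 3)
  d0 <- dist(xyz)
  for (op in ops$ops) {
    xk <- sweep(xyz %*% t(op$R), 2, op$t, "+")
    expect_equal(as.vector(dist(xk)), as.vector(d0), tolerance = 1e-8)
  }
})

test_that("Cn expansion builds the ring the operators describe", {
  mono <- make_protomer(30, 3, seed = 2)
  mono <- transform_model(mono, diag(3), c(12, 0, 0))
  ops <- cn_operators(5, c(0, 0, 1), c(0, 0, 0))
  ring <- expand_cn(mono, ops)
  expect_equal(nrow(ring), 5 * nrow(mono))
  expect_identical(unique(ring$chain), LETTERS[1:5])
  n_at <- nrow(mono)
  for (k in 1:5) {
    copy_k <- model_xyz(ring)[(k - 1) * n_at + seq_len(n_at), ]
    ref <- sweep(model_xyz(mono) %*% t(ops$ops[[k]]$R), 2, ops$ops[[k]]$t, "+")
    expect_equal(max(abs(copy_k - ref)), 0, tolerance = 1e-8)
  }
  # n = 1 is the identity up to renaming
  r1 <- expand_cn(mono, cn_operators(1, c(0, 0, 1)))
  expect_equal(model_xyz(r1), model_xyz(mono))
  # ring positions invariant under post-rotation by the generator
  rot <- transform_model(ring, ops$ops[[2]]$R, ops$ops[[2]]$t)
  a <- model_xyz(ring); b <- model_xyz(rot)
  reord <- rbind(a[-seq_len(n_at), ], a[seq_len(n_at), ])
  expect_equal(max(abs(b - reord)), 0, tolerance = 1e-8)
})

test_that("a 194-residue monomer expands to 2522 residues as a tridecamer", {
  mono <- make_protomer(194, 9, seed = 1)
  mono <- transform_model(mono, diag(3), c(62, 0, 0))
  ring <- expand_cn(mono, cn_operators(13, c(0, 0, 1), c(0, 0, 0)))
  expect_equal(nrow(unique(ring[, c("chain", "res_seq")])), 13 * 194)
})

test_that("magnification rescaling scales distances exactly and composes", {
  mono <- make_protomer(24, 2, seed = 4)
  f <- 1.42 / 1.37
  sc <- rescale_magnification(mono, f, center = c(0, 0, 0))
  expect_equal(as.vector(dist(model_xyz(sc)[1:20, ])),
               f * as.vector(dist(model_xyz(mono)[1:20, ])), tolerance = 1e-12)
  expect_equal(model_xyz(rescale_magnification(mono, 1)), model_xyz(mono))
  ab <- rescale_magnification(rescale_magnification(mono, 1.1, c(1, 2, 3)),
                              1.2, c(1, 2, 3))
  once <- rescale_magnification(mono, 1.32, c(1, 2, 3))
  expect_equal(model_xyz(ab), model_xyz(once), tolerance = 1e-10)
  expect_error(rescale_magnification(mono, 0), "positive")
})

test_that("pixel-size error arithmetic matches the portal-scale numbers", {
  # ring of CA atoms at radius 90 A: mean radial shift under 1.42/1.37
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  ring <- atomic_model(data.frame(
    serial = seq_along(th), name = "CA", res_name = "ALA", chain = "A",
    res_seq = seq_along(th), x = 90 * cos(th), y = 90 * sin(th), z = 0,
    occ = 1, b = 20, element = "C"))
  sc <- rescale_magnification(ring, 1.42 / 1.37, center = c(0, 0, 0))
  shift <- sqrt(rowSums(model_xyz(sc)^2)) - 90
  expect_equal(mean(shift), 90 * (1.42 / 1.37 - 1), tolerance = 1e-9)
  expect_equal(mean(shift), 3.285, tolerance = 0.005)
  # the same error on a 180 A particle changes its diameter by > 6.5 A
  expect_gt(magnification_diagnostic(1.42 / 1.37, 180), 6.5)
  expect_equal(magnification_diagnostic(1.42 / 1.37, 180), 6.57,
               tolerance = 0.005)
})
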