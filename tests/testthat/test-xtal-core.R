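test_that("cell volume follows the triclinic formula", {
  expect_equal(cell_volume(unit_cell(1, 1, 1)), 1)
  expect_equal(cell_volume(unit_cell(2, 3, 4)), 24)
  # portal-crystal-sized orthorhombic cell: volume = a*b*c
  expect_equal(cell_volume(unit_cell(119.85, 238.57, 265.61)),
               119.85 * 238.57 * 265.61, tolerance = 1e-12)
  # triclinic against the closed form
  tc <- unit_cell(10, 12, 14, 80, 95, 103)
  ca <- cos(80 * pi / 180); cb <- cos(95 * pi / 180); cg <- cos(103 * pi / 180)
  expect_equal(cell_volume(tc),
               10 * 12 * 14 * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
  expect_error(unit_cell(-1, 1, 1), "positive")
  expect_error(unit_cell(1, 1, 1, gamma = 180), "angles")
})

test_that("cell volume is invariant under cyclic permutation of axes", {
  cells <- list(unit_cell(7, 11, 13, 85, 92, 99),
                unit_cell(11, 13, 7, 92, 99, 85),
                unit_cell(13, 7, 11, 99, 85, 92))
  vols <- vapply(cells, cell_volume, numeric(1))
  expect_equal(max(vols) - min(vols), 0, tolerance = 1e-9)
})

test_that("d-spacings match axial values and Friedel symmetry", {
  big <- unit_cell(119.85, 238.57, 265.61)
  expect_equal(d_spacing(c(0, 0, 2), big), 265.61 / 2)
  expect_equal(d_spacing(c(0, 3, 0), big), 238.57 / 3)
  expect_equal(d_spacing(c(1, 0, 0), unit_cell(10, 11, 12)), 10)
  # monotone decreasing along an axis
  dd <- d_spacing(cbind(0, 0, 1:6), big)
  expect_true(all(diff(dd) < 0))
  # d(h) = d(-h) exactly, also for triclinic cells
  tc <- unit_cell(10, 12, 14, 80, 95, 103)
  h <- matrix(c(1, 2, 3, -2, 5, 1, 4, -1, -3), ncol = 3, byrow = TRUE)
  expect_identical(d_spacing(h, tc), d_spacing(-h, tc))
  expect_error(d_spacing(c(0, 0, 0), big), "0,0,0")
})

test_that("chi sections for candidate ring orders match the SRF convention", {
  expect_identical(chi_for_order(c(11, 12, 13, 14)), c(32.7, 30, 27.7, 25.7))
  expect_identical(chi_for_order(2), 180)
  # n * chi = 360 within the one-decimal reporting rounding
  n <- 2:30
  expect_true(all(abs(chi_for_order(n) * n - 360) <= n * 0.05))
  expect_error(chi_for_order(0), "integer")
})

test_that("Matthews coefficient and solvent content", {
  cell <- unit_cell(119.85, 238.57, 265.61)
  sg <- space_group("P212121")
  # one tridecamer of 59 kDa protomers per asymmetric unit
  mt <- matthews_coefficient(cell, sg, 13 * 59000)
  expect_equal(mt$vm, cell_volume(cell) / (4 * 13 * 59000))
  expect_equal(mt$vm, 2.475, tolerance = 0.001)
  expect_equal(mt$solvent_fraction, 1 - 1.23 / mt$vm)
  expect_equal(mt$solvent_fraction, 0.503, tolerance = 0.002)
  # definition: vm = 2.46 exactly when volume = 2.46 * z * mass
  c2 <- unit_cell(10, 10, 2.46 * 4 * 1000 / 100)
  expect_equal(matthews_coefficient(c2, sg, 1000)$vm, 2.46)
  # doubling the mass halves vm; solvent strictly decreasing in mass
  expect_equal(matthews_coefficient(cell, sg, 2 * 13 * 59000)$vm, mt$vm / 2)
  masses <- seq(5e5, 9e5, length.out = 5)
  solv <- vapply(masses, function(m)
    matthews_coefficient(cell, sg, m)$solvent_fraction, numeric(1))
  expect_true(all(diff(solv) < 0))
  expect_error(matthews_coefficient(cell, sg, -1), "positive")
})

test_that("symmetry-equivalent reflections", {
  p1 <- space_group("P1"); p212121 <- space_group("P212121")
  expect_equal(nrow(sym_equivalents(c(1, 2, 3), p1)), 2)   # Friedel only
  eq <- sym_equivalents(c(1, 2, 3), p212121)
  expect_equal(nrow(eq), 8)
  # axis reflection collapses onto 2 distinct indices
  expect_equal(nrow(sym_equivalents(c(0, 0, 4), p212121)), 2)
  # idempotence: the orbit of any member is the same set
  key <- function(m) m[, 1] * 1e6 + m[, 2] * 1e3 + m[, 3]
  for (i in seq_len(nrow(eq))) {
    eq2 <- sym_equivalents(eq[i, ], p212121)
    expect_identical(eq2[order(key(eq2)), ], eq[order(key(eq)), ])
  }
  expect_error(space_group("C2"), "unsupported")
})

test_that("space-group operators form a closed group with identity", {
  sg <- space_group("P212121")
  expect_equal(sg$ops[[1]]$R, diag(3L))
  # closure of rotation parts
  rots <- lapply(sg$ops, `[[`, "R")
  for (a in rots) for (b in rots) {
    prod <- a %*% b
    expect_true(any(vapply(rots, function(r) all(r == prod), logical(1))))
  }
})
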