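test_that("rotation overlap is normalized to 100 at the identity", {
  eng <- tiny_srf()$eng
  expect_equal(rotation_overlap(eng, diag(3)), 100)
  # score(R) = score(R^T): Patterson centrosymmetry (equal up to the
  # interpolation noise of the shell sampling, on the origin = 100 scale)
  for (i in 1:3) {
    R <- rotation_about_axis(c(i, 1 + i / 2, 2 - i), 50 + 17 * i)
    expect_lt(abs(rotation_overlap(eng, R) - rotation_overlap(eng, t(R))), 1)
  }
})

test_that("the chi = 0 section is uniformly 100", {
  sec <- srf_section(tiny_srf()$eng, chi = 0, step = 30)
  expect_true(all(abs(sec$values - 100) < 1e-9))
  pk <- find_srf_peaks(sec, refine = FALSE)
  expect_lte(nrow(pk), 1)   # a constant section holds no real peaks
})

test_that("the ring order and axis are recovered on a C5 crystal", {
  case <- tiny_case()
  det <- tiny_srf()$det
  expect_equal(det$n, 5L)
  expect_false(det$ambiguous)
  # axis within 2 degrees of construction, modulo the mmm Patterson mates
  found <- polar_to_vec(det$peak$theta, det$peak$phi)
  mates <- rbind(case$axis,
                 case$axis * c(1, -1, -1),
                 case$axis * c(-1, 1, -1),
                 case$axis * c(-1, -1, 1))
  errs <- apply(mates, 1, axis_angle, v = found)
  expect_lt(min(errs), 2)
})

test_that("an asymmetric (no-NCS) crystal yields no confident order", {
  # a single protomer per asymmetric unit: chi sections for 4..6 should not
  # single out any order the way the true ring does
  case <- tiny_case()
  mono <- case$partial_monomer
  cell <- unit_cell(40, 44, 48)
  mono <- transform_model(mono, diag(3),
                          as.vector(frac_to_orth(c(0.25, 0.25, 0.25), cell)) -
                            model_centroid(mono))
  refl <- calc_structure_factors(mono, cell, space_group("P212121"),
                                 d_min = 3.5)
  det <- detect_ncs_order(refl, candidates = 4:6, tol = 0.02,
                          sharpen_axis = FALSE)
  ring_det <- tiny_srf()$det
  # relative margin of the winning order is far smaller without NCS
  margin <- function(d) {
    h <- d$table$height
    (h[1] - h[2]) / abs(h[1])
  }
  expect_true(det$ambiguous || margin(det) < 0.5 * margin(ring_det))
})

test_that("stereographic projection maps the hemisphere onto the disk", {
  sec <- srf_section(tiny_srf()$eng, chi = 180, step = 45)
  pr <- stereographic_projection(sec)
  expect_equal(pr$x[pr$theta == 0], rep(0, sum(pr$theta == 0)))
  expect_equal(pr$y[pr$theta == 0], rep(0, sum(pr$theta == 0)))
  rim <- pr[pr$theta == 90 & pr$phi == 0, ]
  expect_equal(c(rim$x, rim$y), c(1, 0), tolerance = 1e-12)
  # projection radius is monotone in theta
  r <- sqrt(pr$x^2 + pr$y^2)
  expect_true(all(diff(tapply(r, pr$theta, mean)) > 0))
})

test_that("equatorial twofold counting flags the dihedral comb", {
  # synthetic profile: comb of 13 peaks + weak half-period ripples
  beta <- seq(0, 179, by = 1)
  comb <- function(centers, h, w = 2) {
    rowSums(vapply(centers, function(c0) {
      d <- pmin(abs(beta - c0), 180 - abs(beta - c0))
      h * exp(-d^2 / (2 * w^2))
    }, numeric(length(beta))))
  }
  prof <- data.frame(beta = beta,
                     score = comb((0:12) * 180 / 13, 30) +
                       comb((0:12) * 180 / 13 + 90 / 13, 12) + 50)
  class(prof) <- c("srf_equator", "data.frame")
  prof$score <- prof$score - min(prof$score)
  expect_equal(count_equatorial_twofolds(prof, expected_order = 13)$count, 13)
  flat <- prof; flat$score <- rep(1, nrow(flat))
  expect_equal(count_equatorial_twofolds(flat)$count, 0)
})
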