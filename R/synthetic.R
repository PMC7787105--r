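#' Ideal polyalanine alpha-helix
#'
#' Backbone + CB helix built on the standard alpha-helical cylinder: CA
#' radius 2.3 A, rise 1.5 A per residue, twist 100 degrees per residue
#' (consecutive CA-CA distance 3.8 A). N, C, O and CB are placed at fixed
#' cylindrical offsets from the CA path; the geometry is idealized, which is
#' all the synthetic fixtures require.
#'
#' @param n_res Number of residues (>= 4).
#' @param start Cartesian position of the helix start (first residue,
#'   Angstrom).
#' @param direction Helix axis direction.
#' @param chain Chain id.
#' @param res_start First residue number.
#' @param phase0 Azimuthal phase of the first residue (degrees).
#' @return An [atomic_model()] of `n_res` ALA residues with atoms
#'   N, CA, C, O, CB.
#' @export
make_helix <- function(n_res, start = c(0, 0, 0), direction = c(0, 0, 1),
                       chain = "A", res_start = 1, phase0 = 0) {
  if (n_res < 4) stop("a helix needs at least 4 residues")
  i <- seq_len(n_res) - 1
  th <- (phase0 + 100 * i) * pi / 180
  z <- 1.5 * i
  cyl <- function(r, dth, dz) cbind(r * cos(th + dth * pi / 180),
                                    r * sin(th + dth * pi / 180), z + dz)
  pos <- rbind(cyl(1.56, -26, -0.87),  # N
               cyl(2.30, 0, 0),        # CA
               cyl(1.62, 21.5, 0.74),  # C
               cyl(2.04, 23, 1.95),    # O (carbonyl pointing up the axis)
               cyl(3.30, -8, -0.50))   # CB
  names4 <- c("N", "CA", "C", "O", "CB")
  ord <- as.vector(t(matrix(seq_len(5 * n_res), nrow = n_res)))  # by residue
  pos <- pos[ord, ]
  R <- rotation_between(c(0, 0, 1), direction)
  pos <- pos %*% t(R)
  pos <- sweep(pos, 2, start, "+")
  atomic_model(data.frame(
    serial = seq_len(5 * n_res),
    name = rep(names4, n_res),
    res_name = "ALA",
    chain = chain,
    res_seq = rep(res_start + i, each = 5),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    occ = 1, b = 20,
    element = rep(c("N", "C", "C", "O", "C"), n_res)))
}

# deterministic helix lengths: n_res split into n_helices parts with a
# seeded +-25% spread, always summing exactly to n_res
helix_lengths <- function(n_res, n_helices, seed) {
  base <- n_res / n_helices
  r <- withr_seed(seed + 101, stats::runif(n_helices, -0.25, 0.25))
  len <- round(base * (1 + r - mean(r)))
  len[len < 4] <- 4
  # fix rounding drift on the longest helix
  len[which.max(len)] <- len[which.max(len)] + (n_res - sum(len))
  len
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthetic protomer: a compact, asymmetric alpha-helix bundle
#'
#' Helices run roughly parallel to the eventual ring axis (z), stacked on a
#' radial x vertical grid, with seeded jitter on positions and axis tilts.
#' The bundle is deliberately narrow in the tangential (y) direction so that
#' a ring of such protomers keeps clear inter-protomer gaps -- it is those
#' gaps that carry the n-fold Patterson modulation a self-rotation function
#' detects. Shape realism is not a goal; size, asymmetry, symmetry order and
#' residue counts are.
#'
#' @param n_res Total residues in the protomer.
#' @param n_helices Number of helices.
#' @param seed Seed controlling the deterministic length spread, jitter and
#'   tilts.
#' @param spacing Helix packing distance (A).
#' @return An [atomic_model()] (single chain "A") with attribute
#'   `helix_ranges`: data.frame(helix, res_start, res_end, n_res).
#' @export
make_protomer <- function(n_res, n_helices, seed = 1, spacing = 9) {
  len <- helix_lengths(n_res, n_helices, seed)
  n_rad <- ceiling(n_helices / 2)
  # positional jitter (x, y) and a larger vertical stagger (z): the stagger
  # breaks the approximate two-layer translational/flip symmetry a regular
  # helix stack would have, which no real protomer possesses
  jit <- withr_seed(seed + 77, cbind(matrix(stats::runif(n_helices * 2,
                                                         -2.5, 2.5), ncol = 2),
                                     stats::runif(n_helices, -5, 5)))
  col_shift <- withr_seed(seed + 79, stats::runif(n_rad, -4, 4))
  tilt <- withr_seed(seed + 78, matrix(stats::runif(n_helices * 2,
                                                    -0.25, 0.25), ncol = 2))
  pieces <- vector("list", n_helices)
  ranges <- data.frame(helix = seq_len(n_helices), res_start = NA,
                       res_end = NA, n_res = len)
  res0 <- 1
  for (hx in seq_len(n_helices)) {
    ir <- (hx - 1) %% n_rad          # radial (x) slot
    iv <- (hx - 1) %/% n_rad         # vertical (z) slot
    up <- hx %% 2 == 1
    h_len <- 1.5 * (len[hx] - 1)
    ctr <- c((ir - (n_rad - 1) / 2) * spacing + jit[hx, 1],
             jit[hx, 2],
             (iv - (n_helices / n_rad - 1) / 2) * (h_len + 4) +
               jit[hx, 3] + col_shift[ir + 1])
    dir <- c(tilt[hx, 1], tilt[hx, 2], if (up) 1 else -1)
    dir <- dir / sqrt(sum(dir^2))
    start <- ctr - dir * h_len / 2
    pieces[[hx]] <- make_helix(len[hx], start = start, direction = dir,
                               res_start = res0, phase0 = 40 * hx)
    ranges$res_start[hx] <- res0
    ranges$res_end[hx] <- res0 + len[hx] - 1
    res0 <- res0 + len[hx] + 2   # numbering gap between helices
  }
  out <- do.call(rbind, pieces)
  out$serial <- seq_len(nrow(out))
  out <- atomic_model(out)
  out <- transform_model(out, diag(3), -model_centroid(out))
  attr(out, "helix_ranges") <- ranges
  out
}

# residue numbers of the partial model: whole helices, visited in a seeded
# order, accumulated while the total stays closest to the requested fraction
select_partial_residues <- function(ranges, fraction, seed) {
  target <- fraction * sum(ranges$n_res)
  ord <- withr_seed(seed + 202, sample.int(nrow(ranges)))
  res <- integer(0)
  for (hx in ord) {
    new_total <- length(res) + ranges$n_res[hx]
    if (abs(new_total - target) <= abs(length(res) - target))
      res <- c(res, seq(ranges$res_start[hx], length.out = ranges$n_res[hx]))
  }
  if (!length(res))
    res <- seq(ranges$res_start[ord[1]], length.out = ranges$n_res[ord[1]])
  sort(res)
}

#' Simulate a cryo-EM style density map
#'
#' Gaussian-atom density in an orthogonal box, low-pass filtered to the
#' stated resolution with a cosine-edged Fourier cutoff. The box is
#' non-periodic and centred on the model centroid.
#'
#' @param model An [atomic_model()].
#' @param resolution Nominal resolution in Angstrom (> 2 * pixel_size).
#' @param pixel_size Angstrom per voxel.
#' @param pad Padding around the model (A) on each side.
#' @param edge Fractional width of the cosine filter edge.
#' @return A non-periodic [map_grid()] with origin at the box centre.
#' @export
simulate_em_map <- function(model, resolution, pixel_size = 1.37,
                            pad = 15, edge = 0.2) {
  if (resolution <= 2 * pixel_size)
    stop("resolution must exceed 2 * pixel_size (Nyquist)")
  xyz <- model_xyz(model)
  ctr <- colMeans(xyz)
  ext <- apply(xyz, 2, function(v) diff(range(v)))
  n <- vapply(ext + 2 * pad,
              function(len) good_fft_size(len / pixel_size), integer(1))
  n <- rep(max(n), 3)                       # cubic box
  box_len <- n * pixel_size
  if (any(ext + 2 > box_len)) stop("box too small for model")
  cellbox <- unit_cell(box_len[1], box_len[2], box_len[3])
  shifted <- transform_model(model, diag(3), box_len / 2 - ctr)
  rho <- density_from_model(shifted, cellbox, space_group("P1"), n,
                            b_extra = 30)
  # cosine-edge low-pass at 1/resolution
  s_axis <- function(nn, len) {
    h <- c(0:(nn %/% 2), -((nn - 1) %/% 2):-1)
    (h / len)^2
  }
  s2 <- outer(outer(s_axis(n[1], box_len[1]), s_axis(n[2], box_len[2]), "+"),
              s_axis(n[3], box_len[3]), "+")
  s <- sqrt(s2)
  sc <- 1 / resolution
  filt <- ifelse(s <= sc * (1 - edge), 1,
                 ifelse(s >= sc, 0,
                        0.5 + 0.5 * cos(pi * (s - sc * (1 - edge)) / (sc * edge))))
  sm <- Re(fft(fft(rho$values) * filt, inverse = TRUE)) / prod(n)
  map_grid(sm, cellbox, periodic = FALSE, origin = c(-0.5, -0.5, -0.5))
}

#' Named fixture presets
#'
#' `portal`: full-size tridecamer emulation (536-residue protomer of nine
#' helices, ~180 A ring, data to 3.74 A, amplitude noise at <I/sigma> = 9.1).
#' `portal-mini`: scaled-down C13 ring (66-residue protomer of six helices,
#' ~90 A ring, noiseless data to 4 A) used throughout the test-suite;
#' `portal-mini-c12`: its C12 counterpart; `tiny-c5`: a minimal C5 ring for
#' fast unit tests.
#'
#' @param name Preset name.
#' @return Named list of [make_ring_case()] arguments.
#' @export
ring_preset <- function(name = c("portal-mini", "portal", "portal-mini-c12",
                                 "tiny-c5")) {
  name <- match.arg(name)
  switch(name,
    "portal" = list(n = 13, n_res = 536, n_helices = 9, ring_radius = 62,
                    d_min = 3.74, em_resolution = 7.8, pixel_size = 1.37,
                    partial_fraction = 194 / 536, i_over_sigma = 9.1),
    "portal-mini" = list(n = 13, n_res = 66, n_helices = 6, ring_radius = 31,
                         d_min = 4, em_resolution = 7.8, pixel_size = 1.37,
                         partial_fraction = 0.36),
    "portal-mini-c12" = list(n = 12, n_res = 66, n_helices = 6,
                             ring_radius = 31, d_min = 4,
                             em_resolution = 7.8, pixel_size = 1.37,
                             partial_fraction = 0.36),
    "tiny-c5" = list(n = 5, n_res = 16, n_helices = 2, ring_radius = 10,
                     d_min = 3.5, em_resolution = 7.8, pixel_size = 1.37,
                     partial_fraction = 0.5, em_map = FALSE))
}

#' Generate a synthetic Cn ring "crystal"
#'
#' Builds a fully known test case emulating a portal-protein-style problem:
#' a Cn ring of polyalanine helix bundles placed in a P212121 cell with the
#' ring axis at (theta, phi), observed amplitudes computed from the truth
#' model, an EM-style map of the ring (optionally with a magnification
#' error), and a partial monomer model "built in" the EM frame.
#'
#' The crystal truth never carries the magnification error; the EM map and
#' the partial model do, exactly as when a microscope's nominal pixel size
#' is miscalibrated by `mag_error`.
#'
#' @param n Ring order.
#' @param n_res Residues per protomer.
#' @param n_helices Helices per protomer.
#' @param ring_radius Radius of the protomer centroid circle (A).
#' @param axis_theta,axis_phi Crystal-frame ring-axis direction (degrees).
#' @param partial_fraction Fraction of protomer residues in the partial
#'   model (delivered within one helix of the request).
#' @param i_over_sigma Target amplitude signal-to-noise; NULL = noiseless.
#' @param mag_error Pixel-size calibration error factor applied to the EM
#'   frame (1 = calibrated).
#' @param em_resolution,pixel_size EM map parameters (A).
#' @param d_min X-ray resolution limit (A).
#' @param clearance Minimum allowed distance between symmetry copies (A);
#'   the cell is grown until satisfied.
#' @param center_frac Fractional position of the ring centre in the cell.
#' @param psi_truth Spin of the ring about its own axis (degrees); NULL
#'   draws it from the seed.
#' @param em_map Generate the EM map (set FALSE to skip, for speed).
#' @param seed Integer seed; every stochastic choice derives from it and the
#'   case is bit-identical for equal (parameters, seed).
#' @return Object of class `synthetic_case`; see Details.
#' @details Fields: `truth_model` (crystal frame), `partial_monomer` and
#'   `em_model` (EM frame), `em_map`, `refl_obs`, `cell`, `sg`, `ops_truth`
#'   (crystal frame), `axis`, `center` (Cartesian), `truth_placement`
#'   (list R, t, psi mapping EM frame to crystal), `params`.
#' @export
make_ring_case <- function(n = 13, n_res = 66, n_helices = 6,
                           ring_radius = 31, axis_theta = 70, axis_phi = 0,
                           partial_fraction = 0.36, i_over_sigma = NULL,
                           mag_error = 1, em_resolution = 7.8,
                           pixel_size = 1.37, d_min = 4, clearance = 4,
                           center_frac = c(0.2, 0.3, 0.25),
                           psi_truth = NULL, em_map = TRUE, seed = 1) {
  if (n < 2) stop("ring order must be >= 2")
  if (partial_fraction <= 0 || partial_fraction > 1)
    stop("partial_fraction must be in (0, 1]")
  sg <- space_group("P212121")
  protomer <- make_protomer(n_res, n_helices, seed = seed)
  protomer <- transform_model(protomer, diag(3), c(ring_radius, 0, 0))
  ops_em <- cn_operators(n, c(0, 0, 1), c(0, 0, 0))
  ring_em <- expand_cn(protomer, ops_em)

  # partial model "built into" the EM map: helices (the last one trimmed to
  # the requested residue total), EM scale
  ranges <- attr(protomer, "helix_ranges")
  sel_res <- select_partial_residues(ranges, partial_fraction, seed)
  partial <- atomic_model(protomer[protomer$res_seq %in% sel_res, ])
  partial$serial <- seq_len(nrow(partial))
  partial <- rescale_magnification(partial, mag_error, center = c(0, 0, 0))
  em_model <- rescale_magnification(ring_em, mag_error, center = c(0, 0, 0))

  # crystal placement: axis to (theta, phi), seeded spin about the axis
  if (is.null(psi_truth))
    psi_truth <- withr_seed(seed + 303, stats::runif(1, 0, 360 / n))
  axis <- polar_to_vec(axis_theta, axis_phi)
  R_place <- rotation_between(c(0, 0, 1), axis) %*%
    rotation_about_axis(c(0, 0, 1), psi_truth)
  rot_ring <- transform_model(ring_em, R_place, c(0, 0, 0))

  # size the cell: start from the rotated extent, grow until no two
  # symmetry copies come closer than `clearance`
  ext <- apply(model_xyz(rot_ring), 2, function(v) diff(range(v)))
  lens <- ext + clearance + c(0, 4, 8)
  ca <- model_xyz(rot_ring[rot_ring$name == "CA", ])
  for (iter in 1:40) {
    cell <- unit_cell(round(lens[1], 1), round(lens[2], 1), round(lens[3], 1))
    ctr <- frac_to_orth(center_frac, cell)
    if (min_copy_distance(sweep(ca, 2, ctr, "+"), cell, sg) >= clearance)
      break
    lens <- lens * 1.06
  }
  ctr <- as.vector(frac_to_orth(center_frac, cell))
  truth <- transform_model(rot_ring, diag(3), ctr)

  refl_truth <- calc_structure_factors(truth, cell, sg, d_min = d_min)
  refl <- refl_truth
  if (!is.null(i_over_sigma)) {
    eps <- withr_seed(seed + 404, stats::rnorm(nrow(refl)) / i_over_sigma)
    ii <- pmax(refl$f^2 * (1 + eps), 0)
    refl$f <- sqrt(ii)
    refl$sigf <- refl$f / (2 * i_over_sigma)
  }
  refl$phi <- NA_real_; refl$fom <- NA_real_   # observed data are unphased

  em <- if (em_map) simulate_em_map(em_model, em_resolution, pixel_size)
        else NULL

  out <- list(truth_model = truth,
              partial_monomer = partial,
              em_model = em_model,
              em_map = em,
              refl_obs = refl,
              refl_truth = refl_truth,   # phased ground truth, for validation
              cell = cell, sg = sg,
              ops_truth = cn_operators(n, axis, ctr),
              axis = axis, center = ctr,
              truth_placement = list(R = R_place, t = ctr, psi = psi_truth),
              params = list(n = n, n_res = n_res, n_helices = n_helices,
                            ring_radius = ring_radius,
                            axis_theta = axis_theta, axis_phi = axis_phi,
                            partial_fraction = partial_fraction,
                            delivered_fraction = length(sel_res) / n_res,
                            i_over_sigma = i_over_sigma,
                            mag_error = mag_error,
                            em_resolution = em_resolution,
                            pixel_size = pixel_size, d_min = d_min,
                            psi_truth = psi_truth, seed = seed))
  class(out) <- "synthetic_case"
  out
}

#' @export
print.synthetic_case <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("synthetic C%d ring crystal: %d res/protomer, ",
                     "cell %.1f x %.1f x %.1f, d_min %.2f A, axis (%.0f, %.0f), ",
                     "partial %.0f%%, mag %.4f, seed %d\n"),
              p$n, p$n_res, x$cell$a, x$cell$b, x$cell$c, p$d_min,
              p$axis_theta, p$axis_phi, 100 * p$delivered_fraction,
              p$mag_error, p$seed))
  invisible(x)
}

# minimum minimal-image distance between distinct symmetry copies of a
# point set (CA-level is enough; same-copy lattice clashes are excluded by
# construction because the cell always exceeds the model extent)
min_copy_distance <- function(pts, cell, sg) {
  frac <- orth_to_frac(pts, cell)
  copies <- lapply(sg$ops, function(op)
    (sweep(frac %*% t(op$R), 2, op$t, "+")) %% 1)
  o <- orth_matrix(cell)
  sub <- function(a) a[seq(1, nrow(a), length.out = min(500, nrow(a))), ,
                       drop = FALSE]
  dmin <- Inf
  np <- length(copies)
  if (np < 2) return(dmin)
  for (i in seq_len(np - 1)) {
    sa <- sub(copies[[i]])
    for (j in (i + 1):np) {
      sb <- sub(copies[[j]])
      for (k in seq_len(nrow(sa))) {
        d <- sweep(sb, 2, sa[k, ], "-")
        d <- d - round(d)
        dc <- d %*% t(o)
        dmin <- min(dmin, sqrt(min(rowSums(dc * dc))))
      }
    }
  }
  dmin
}
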