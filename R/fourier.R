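# Atomic scattering factors: Cromer-Mann 4-Gaussian coefficients
# (International Tables for Crystallography Vol. C), f0(s) =
# sum_g a_g exp(-b_g s^2/4) + c with s = 1/d. The constant c is treated as a
# fifth Gaussian with b = 0.
.cm_coeff <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 10.5109, 22.3966, 2.57575), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.56870, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900)
)

# per-element Gaussian terms, falling back to carbon with a warning
cm_terms <- function(element) {
  el <- toupper(element)
  if (is.null(.cm_coeff[[el]])) {
    warning("unknown element '", element, "': using carbon form factor")
    el <- "C"
  }
  cf <- .cm_coeff[[el]]
  list(a = c(cf$a, cf$c), b = c(cf$b, 0))
}

# f0(s) * exp(-B s^2 / 4) for a vector of s^2 values
form_factor <- function(element, s2, b_iso = 0) {
  tm <- cm_terms(element)
  out <- numeric(length(s2))
  for (g in seq_along(tm$a))
    out <- out + tm$a[g] * exp(-(tm$b[g] + b_iso) * s2 / 4)
  out
}

# expand model atoms by the space group into fractional coordinates of the
# whole cell; returns data.frame(xf, yf, zf, occ, b, element)
expand_atoms_p1 <- function(model, cell, sg) {
  frac <- orth_to_frac(model_xyz(model), cell)
  out <- vector("list", length(sg$ops))
  for (i in seq_along(sg$ops)) {
    op <- sg$ops[[i]]
    f <- frac %*% t(op$R)
    f <- sweep(f, 2, op$t, "+") %% 1
    out[[i]] <- data.frame(xf = f[, 1], yf = f[, 2], zf = f[, 3],
                           occ = model$occ, b = model$b,
                           element = model$element)
  }
  do.call(rbind, out)
}

# Sample Gaussian-atom density on a periodic cell grid. b_extra smears every
# atom (sharpened back in reciprocal space by the caller) so that the density
# is effectively band-limited on the grid and aliasing stays negligible.
density_from_model <- function(model, cell, sg, dims, b_extra = 0) {
  atoms <- expand_atoms_p1(model, cell, sg)
  O <- orth_matrix(cell)
  spacing <- c(cell$a, cell$b, cell$c) / dims
  rho <- array(0, dims)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  groups <- split(seq_len(nrow(atoms)),
                  paste(atoms$element, round(atoms$b, 1)))
  for (gi in groups) {
    el <- atoms$element[gi[1]]
    btot <- atoms$b[gi[1]] + b_extra
    tm <- cm_terms(el)
    bg <- tm$b + btot
    amp <- tm$a * (4 * pi / bg)^1.5
    kg <- 4 * pi^2 / bg
    # cutoff where the widest Gaussian has fallen to exp(-12)
    r_cut <- sqrt(12 / min(kg))
    n_off <- pmin(ceiling(r_cut / spacing) + 1L, floor((dims - 1) / 2))
    offs <- as.matrix(expand.grid(-n_off[1]:n_off[1],
                                  -n_off[2]:n_off[2],
                                  -n_off[3]:n_off[3]))
    offs_cart <- (offs %*% diag(1 / dims)) %*% t(O)
    keep <- rowSums(offs_cart^2) <= (r_cut + max(spacing))^2
    offs <- offs[keep, , drop = FALSE]
    offs_cart <- offs_cart[keep, , drop = FALSE]
    gf <- cbind(atoms$xf[gi], atoms$yf[gi], atoms$zf[gi])
    gv <- sweep(gf, 2, dims, "*")          # voxel-unit position
    g0 <- round(gv)
    dcart <- (gv - g0) %*% diag(1 / dims) %*% t(O)  # subvoxel shift, cart
    occ <- atoms$occ[gi]
    for (j in seq_along(gi)) {
      d <- sweep(offs_cart, 2, dcart[j, ], "-")
      r2 <- rowSums(d * d)
      val <- numeric(length(r2))
      for (g in seq_along(amp)) val <- val + amp[g] * exp(-kg[g] * r2)
      ix <- (offs[, 1] + g0[j, 1]) %% nx
      iy <- (offs[, 2] + g0[j, 2]) %% ny
      iz <- (offs[, 3] + g0[j, 3]) %% nz
      idx <- 1 + ix + nx * (iy + ny * iz)
      rho[idx] <- rho[idx] + occ[j] * val
    }
  }
  map_grid(rho, cell, periodic = TRUE)
}

# enumerate symmetry-unique Miller indices in a resolution window
unique_hkl <- function(cell, sg, d_min, d_max = Inf) {
  hmax <- ceiling(c(cell$a, cell$b, cell$c) / d_min) + 1L
  h <- as.matrix(expand.grid(-hmax[1]:hmax[1], 0:hmax[2], -hmax[3]:hmax[3]))
  # k >= 0 half space is enough: canonical representatives have k >= 0 in
  # P1/P212121 (diagonal rotation parts); saves half the enumeration
  h <- h[rowSums(abs(h)) > 0, ]
  d <- d_spacing(h, cell)
  h <- h[d >= d_min & d <= d_max, , drop = FALSE]
  can <- hkl_canonical(h, sg)
  rep <- can$rep[!duplicated(hkl_key(can$rep)), , drop = FALSE]
  storage.mode(rep) <- "integer"
  rep
}

# map Miller indices to 1-based linear indices in an FFT array of dims
hkl_grid_index <- function(hkl, dims) {
  1 + (hkl[, 1] %% dims[1]) +
    dims[1] * ((hkl[, 2] %% dims[2]) + dims[2] * (hkl[, 3] %% dims[3]))
}

#' Structure factors from an atomic model
#'
#' Gaussian-atom scattering (Cromer-Mann coefficients for H/C/N/O/S, unknown
#' elements fall back to carbon with a warning) summed over all space-group
#' mates. The default FFT route samples artificially smeared atomic density
#' on a grid of spacing `d_min/3` and sharpens back in reciprocal space,
#' keeping amplitudes within a fraction of a percent of direct summation;
#' `method = "direct"` is the exact (slow) reference summation.
#'
#' F(000) is excluded: all maps synthesized from these sets are mean-zero.
#'
#' @param model An [atomic_model()] (one asymmetric unit).
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @param d_min High-resolution limit in Angstrom.
#' @param d_max Optional low-resolution limit.
#' @param method "fft" (default) or "direct".
#' @param b_extra Artificial smearing B (A^2) for the FFT route; chosen
#'   automatically from `d_min` and the model B range when NULL.
#' @param hkl Optional n x 3 matrix restricting which unique indices to
#'   return (default: all in the window).
#' @return A [reflection_set()] with calculated amplitudes (`f`) and phases
#'   (`phi`, degrees).
#' @export
calc_structure_factors <- function(model, cell, sg, d_min, d_max = Inf,
                                   method = c("fft", "direct"),
                                   b_extra = NULL, hkl = NULL) {
  method <- match.arg(method)
  if (nrow(model) == 0) stop("empty model")
  if (d_min <= 0) stop("d_min must be positive")
  if (is.null(hkl)) hkl <- unique_hkl(cell, sg, d_min, d_max)
  if (method == "direct") {
    fc <- sf_direct(model, cell, sg, hkl)
  } else {
    if (is.null(b_extra))
      b_extra <- max(0, 7.7 * d_min^2 - min(model$b))
    dims <- grid_for_cell(cell, d_min, rate = 3)
    rho <- density_from_model(model, cell, sg, dims, b_extra = b_extra)
    v <- cell_volume(cell)
    fgrid <- fft(rho$values, inverse = TRUE) * (v / prod(dims))
    fc <- fgrid[hkl_grid_index(hkl, dims)]
    s2 <- 1 / d_spacing(hkl, cell)^2
    fc <- fc * exp(b_extra * s2 / 4)   # undo the artificial smearing
  }
  reflection_set(hkl, f = Mod(fc), phi = (Arg(fc) * 180 / pi) %% 360,
                 cell = cell, sg = sg, reduce = FALSE)
}

# direct structure-factor summation (oracle path; O(n_refl * n_atoms))
sf_direct <- function(model, cell, sg, hkl) {
  atoms <- expand_atoms_p1(model, cell, sg)
  s2 <- 1 / d_spacing(hkl, cell)^2
  fc <- complex(length(s2))
  for (grp in split(seq_len(nrow(atoms)),
                    paste(atoms$element, round(atoms$b, 4)))) {
    ff <- form_factor(atoms$element[grp[1]], s2, b_iso = atoms$b[grp[1]])
    xf <- as.matrix(atoms[grp, c("xf", "yf", "zf")])
    ph <- 2 * pi * (hkl %*% t(xf))
    fc <- fc + ff * as.vector((cos(ph) %*% atoms$occ[grp]) +
                              1i * (sin(ph) %*% atoms$occ[grp]))
  }
  fc
}

# fill a complex FFT grid from a unique reflection set (symmetry + Friedel
# expansion with phase transfer); weights multiply amplitudes
refl_to_grid <- function(refl, dims, f = refl$f, phi = refl$phi,
                         weights = NULL) {
  if (all(is.na(phi))) stop("phases are required for map synthesis")
  cplx <- f * exp(1i * phi * pi / 180)
  if (!is.null(weights)) cplx <- cplx * weights
  tmp <- refl
  tmp$f <- Mod(cplx); tmp$phi <- (Arg(cplx) * 180 / pi)
  ex <- refl_expand_full(tmp)
  grid <- array(complex(real = 0), dims)
  idx <- hkl_grid_index(ex$hkl, dims)
  grid[idx] <- ex$f[] * exp(1i * ex$phi * pi / 180)
  grid
}

#' Synthesize a real-space map from phased reflections
#'
#' Inverse Fourier synthesis of `F = weight * f * exp(i phi)` expanded to the
#' full sphere. With F(000) excluded the map mean is ~0 by construction.
#'
#' @param refl A phased [reflection_set()].
#' @param grid_n Grid dimensions; default sampling `min(d)/3`.
#' @param weights NULL, the string "fom" (use the set's figure-of-merit
#'   column), or a numeric vector of per-reflection weights.
#' @param d_min Optionally restrict synthesis to `d >= d_min`.
#' @return A periodic [map_grid()].
#' @export
synthesize_map <- function(refl, grid_n = NULL, weights = NULL, d_min = NULL) {
  cell <- refl_cell(refl)
  if (!is.null(d_min)) refl <- resolution_window(refl, d_min = d_min)
  if (is.null(grid_n)) grid_n <- grid_for_cell(cell, min(refl$d), rate = 3)
  w <- if (identical(weights, "fom")) ifelse(is.na(refl$fom), 1, refl$fom)
       else weights
  grid <- refl_to_grid(refl, grid_n, weights = w)
  rho <- Re(fft(grid)) / cell_volume(cell)
  map_grid(rho, cell, periodic = TRUE)
}

#' Invert a map to structure factors
#'
#' Forward FFT reduced to the symmetry-unique reflection list. Friedel
#' symmetry holds exactly because the input is real. Errors if the grid is
#' too coarse to represent `d_min`.
#'
#' @param map A periodic [map_grid()].
#' @param sg A [space_group()].
#' @param d_min,d_max Resolution window in Angstrom.
#' @param hkl Optional precomputed unique index matrix (from repeated calls).
#' @return A [reflection_set()] with amplitudes and phases.
#' @export
invert_map <- function(map, sg, d_min, d_max = Inf, hkl = NULL) {
  cell <- map$cell
  dims <- dim(map$values)
  spacing <- max(c(cell$a, cell$b, cell$c) / dims)
  if (spacing > d_min / 2)
    stop(sprintf("grid too coarse for d_min = %.2f A (spacing %.2f A): aliasing",
                 d_min, spacing))
  if (is.null(hkl)) hkl <- unique_hkl(cell, sg, d_min, d_max)
  fgrid <- fft(map$values, inverse = TRUE) * (cell_volume(cell) / prod(dims))
  fc <- fgrid[hkl_grid_index(hkl, dims)]
  reflection_set(hkl, f = Mod(fc), phi = (Arg(fc) * 180 / pi) %% 360,
                 cell = cell, sg = sg, reduce = FALSE)
}

#' Patterson map
#'
#' Fourier synthesis with |F|^2 coefficients and zero phases. With
#' `normalize = TRUE` the coefficients are sharpened to `|F|^2 / <|F|^2> - 1`
#' in resolution shells, which removes the origin ramp and the steep
#' resolution falloff (common practice for rotation functions).
#'
#' @param refl A [reflection_set()] (phases not required).
#' @param d_max,d_min Resolution window used (Angstrom).
#' @param grid_n Grid dimensions (default `d_min/3` sampling).
#' @param normalize Shell-normalize the squared amplitudes.
#' @param n_shells Number of resolution shells for normalization.
#' @return A periodic [map_grid()] with the origin peak at voxel (0,0,0).
#' @export
patterson_map <- function(refl, d_max = Inf, d_min = NULL,
                          grid_n = NULL, normalize = TRUE, n_shells = 20) {
  if (nrow(refl) == 0) stop("empty resolution window")
  if (is.null(d_min)) d_min <- min(refl$d)
  refl <- resolution_window(refl, d_max = d_max, d_min = d_min)
  if (nrow(refl) == 0) stop("empty resolution window")
  cell <- refl_cell(refl)
  if (is.null(grid_n)) grid_n <- grid_for_cell(cell, min(refl$d), rate = 3)
  io <- refl$f^2
  if (normalize) {
    shell <- shell_bins(refl$d, n_shells)
    io <- io / stats::ave(io, shell, FUN = mean) - 1
  }
  tmp <- refl
  tmp$f <- io
  # |F|^2 coefficients are real and identical for all equivalents: expand
  # without phase transfer (phases are identically zero)
  ex <- refl_expand_full(tmp, with_phase = FALSE)
  grid <- array(complex(real = 0), grid_n)
  grid[hkl_grid_index(ex$hkl, grid_n)] <- ex$f
  p <- Re(fft(grid)) / cell_volume(cell)
  map_grid(p, cell, periodic = TRUE)
}

# resolution shell assignment with roughly equal reflection counts
shell_bins <- function(d, n_shells) {
  s3 <- 1 / d^3
  br <- stats::quantile(s3, probs = seq(0, 1, length.out = n_shells + 1))
  br[1] <- -Inf; br[length(br)] <- Inf
  findInterval(s3, br, rightmost.closed = TRUE)
}

#' Difference / combined map coefficients
#'
#' Builds the coefficient set for standard map types from an observed and a
#' calculated reflection set on matching indices: `fo` (Fo amplitudes, Fc
#' phases), `2fo-fc`, `fo-fc`. Negative combined amplitudes are stored as
#' positive with the phase flipped by 180 degrees.
#'
#' @param fo Observed [reflection_set()] (amplitudes used).
#' @param fc Calculated [reflection_set()] (amplitudes and phases used).
#' @param type One of "fo", "2fo-fc", "fo-fc".
#' @return A phased [reflection_set()] on the common indices.
#' @export
map_coefficients <- function(fo, fc, type = c("fo", "2fo-fc", "fo-fc")) {
  type <- match.arg(type)
  key_o <- hkl_key(as.matrix(fo[, c("h", "k", "l")]))
  key_c <- hkl_key(as.matrix(fc[, c("h", "k", "l")]))
  m <- match(key_o, key_c)
  ok <- !is.na(m)
  fo_f <- fo$f[ok]; fc_f <- fc$f[m[ok]]; phi <- fc$phi[m[ok]]
  amp <- switch(type, "fo" = fo_f, "2fo-fc" = 2 * fo_f - fc_f,
                "fo-fc" = fo_f - fc_f)
  flip <- amp < 0
  reflection_set(as.matrix(fo[ok, c("h", "k", "l")]),
                 f = abs(amp), phi = (phi + 180 * flip) %% 360,
                 cell = refl_cell(fo), sg = refl_sg(fo), reduce = FALSE)
}
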