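#' Self-rotation function engine
#'
#' Precomputes the shared state for SRF evaluations: a shell of Patterson
#' sample points around (but excluding) the origin. The rotation overlap for
#' a rotation R is `sum_u P(u) P(Ru)` over the shell, with P(Ru) obtained by
#' trilinear interpolation; dividing by the identity score
#' (`sum_u P(u)^2`) and scaling by 100 gives the conventional
#' "origin = 100" normalization.
#'
#' @param refl A [reflection_set()] of observed amplitudes.
#' @param d_max,d_min Resolution window for the Patterson (default 10-4 A;
#'   `d_min` is clamped to the data limit). Sharp data matter: the angular
#'   width of SRF features scales with d_min / shell radius.
#' @param r_min,r_max Patterson shell radii in Angstrom. `r_max` defaults to
#'   45% of the shortest cell edge (capped at 50 A) so the shell stays within
#'   the minimal image; `r_min` defaults to 45% of `r_max`, which both
#'   excludes the origin peak and drops the small-radius region that carries
#'   little angular discrimination.
#' @param max_points Cap on the number of shell sample points (a
#'   deterministic stride subsample keeps evaluation time bounded; overlap
#'   scores are sums over tens of thousands of voxels and are insensitive to
#'   this).
#' @return An object of class `srf_engine`.
#' @export
srf_engine <- function(refl, d_max = 10, d_min = 4,
                       r_min = NULL, r_max = NULL, max_points = 24000) {
  cell <- refl_cell(refl)
  if (is.null(r_max))
    r_max <- min(50, 0.45 * min(cell$a, cell$b, cell$c))
  if (is.null(r_min)) r_min <- 0.45 * r_max
  if (r_max <= r_min) stop("empty Patterson shell (r_max <= r_min)")
  d_min <- max(d_min, min(refl$d))
  patt <- patterson_map(refl, d_max = d_max, d_min = d_min)
  dims <- dim(patt$values)
  # minimal-image Cartesian coordinates of every voxel
  fr <- cbind(rep((seq_len(dims[1]) - 1) / dims[1], times = dims[2] * dims[3]),
              rep(rep((seq_len(dims[2]) - 1) / dims[2], each = dims[1]),
                  times = dims[3]),
              rep((seq_len(dims[3]) - 1) / dims[3], each = dims[1] * dims[2]))
  fr <- fr - (fr >= 0.5)
  cart <- frac_to_orth(fr, cell)
  r2 <- rowSums(cart * cart)
  sel <- which(r2 >= r_min^2 & r2 <= r_max^2)
  if (length(sel) > max_points)
    sel <- sel[seq(1, length(sel), length.out = max_points)]
  eng <- list(patt = patt, cell = cell, refl = refl,
              points = cart[sel, , drop = FALSE],
              values = as.vector(patt$values)[sel],
              d_max = d_max, d_min = d_min, r_min = r_min, r_max = r_max)
  eng$norm <- sum(eng$values^2)
  class(eng) <- "srf_engine"
  eng
}

#' @export
print.srf_engine <- function(x, ...) {
  cat(sprintf("SRF engine: %d shell points, r = %.1f-%.1f A, data %.1f-%.1f A\n",
              nrow(x$points), x$r_min, x$r_max, x$d_max, x$d_min))
  invisible(x)
}

as_srf_engine <- function(x, ...) {
  if (inherits(x, "srf_engine")) x else srf_engine(x, ...)
}

#' Patterson rotation overlap
#'
#' `sum_u P(u) P(Ru)` over the engine's spherical shell, normalized to 100
#' at the identity rotation.
#'
#' @param engine An [srf_engine()] (or a [reflection_set()], from which one
#'   is built with default parameters).
#' @param rot 3x3 rotation matrix.
#' @return Normalized overlap score (identity = 100).
#' @export
rotation_overlap <- function(engine, rot) {
  engine <- as_srf_engine(engine)
  v <- interpolate_map(engine$patt, engine$points %*% t(rot), cartesian = TRUE)
  100 * sum(engine$values * v) / engine$norm
}

#' Self-rotation function section at fixed rotation angle chi
#'
#' Evaluates the rotation overlap for all rotations by `chi` about axes on a
#' (theta, phi) grid over the hemisphere (theta from the c axis in
#' \[0, 90\], phi from a in \[0, 360)).
#'
#' @param refl A [reflection_set()] or a prebuilt [srf_engine()].
#' @param chi Rotation angle of the section in degrees.
#' @param step Angular grid step in degrees (must divide 90; adjusted with a
#'   warning otherwise).
#' @param ... Passed to [srf_engine()] when `refl` is a reflection set.
#' @return Object of class `srf_section`: list with `chi`, `theta`, `phi`,
#'   and the score matrix `values` (theta x phi, identity = 100).
#' @export
srf_section <- function(refl, chi, step = 5, ...) {
  engine <- as_srf_engine(refl, ...)
  if (90 %% step != 0) {
    step <- 90 / ceiling(90 / step)
    warning("angular step adjusted to ", step, " deg to divide 90")
  }
  theta <- seq(0, 90, by = step)
  phi <- seq(0, 360 - step, by = step)
  vals <- matrix(NA_real_, length(theta), length(phi))
  for (i in seq_along(theta)) {
    if (theta[i] == 0) {
      # pole: all azimuths give the same axis
      vals[i, ] <- rotation_overlap(engine,
                                    rotation_about_axis(c(0, 0, 1), chi))
      next
    }
    for (j in seq_along(phi)) {
      ax <- polar_to_vec(theta[i], phi[j])
      vals[i, j] <- rotation_overlap(engine, rotation_about_axis(ax, chi))
    }
  }
  out <- list(chi = chi, theta = theta, phi = phi, values = vals,
              step = step, engine = engine)
  class(out) <- "srf_section"
  out
}

#' @export
print.srf_section <- function(x, ...) {
  cat(sprintf("SRF section chi = %.1f deg, %d x %d grid (step %.1f deg), max %.1f\n",
              x$chi, length(x$theta), length(x$phi), x$step, max(x$values)))
  invisible(x)
}

#' Locate peaks in an SRF section
#'
#' Grid local maxima (phi wraps around; antipodal rim directions are merged)
#' above a height threshold, with directions within one grid step of each
#' other merged into the higher peak. Directions along the crystallographic
#' dyads a, b, c are flagged `crystallographic` (meaningful for chi = 180 in
#' P212121).
#'
#' @param section An [srf_section()].
#' @param min_height_fraction Peaks below this fraction of the section
#'   maximum are dropped (default 0.25).
#' @param refine Re-optimize each peak position on a local 2-degree grid.
#' @param refine_step Step of the local refinement grid (degrees).
#' @param max_refine Refine at most this many of the highest peaks.
#' @return data.frame with columns theta, phi, chi, height, crystallographic.
#' @export
find_srf_peaks <- function(section, min_height_fraction = 0.25,
                           refine = TRUE, refine_step = 2, max_refine = 6) {
  v <- section$values
  nt <- nrow(v); np <- ncol(v)
  thr <- min_height_fraction * max(v)
  peaks <- list()
  for (i in seq_len(nt)) {
    for (j in seq_len(np)) {
      if (v[i, j] < thr) next
      jm <- if (j == 1) np else j - 1
      jp <- if (j == np) 1 else j + 1
      nb <- c(v[i, jm], v[i, jp],
              if (i > 1) v[i - 1, c(jm, j, jp)],
              if (i < nt) v[i + 1, c(jm, j, jp)])
      if (v[i, j] >= max(nb) && v[i, j] > min(nb))
        peaks[[length(peaks) + 1]] <-
          c(theta = section$theta[i], phi = section$phi[j], h = v[i, j])
    }
  }
  if (!length(peaks))
    return(data.frame(theta = numeric(), phi = numeric(), chi = numeric(),
                      height = numeric(), crystallographic = logical()))
  pk <- as.data.frame(do.call(rbind, peaks))
  pk <- pk[order(-pk$h), ]
  # merge peaks within ~1.5 grid steps (axis directions, +-v identified)
  dirs <- t(apply(pk, 1, function(r) polar_to_vec(r[1], r[2])))
  keep <- rep(TRUE, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (!keep[i]) next
    if (i < nrow(pk)) {
      for (j in (i + 1):nrow(pk)) {
        ang <- acos(pmin(1, abs(sum(dirs[i, ] * dirs[j, ])))) * 180 / pi
        if (ang < 1.5 * section$step) keep[j] <- FALSE
      }
    }
  }
  pk <- pk[keep, , drop = FALSE]
  dirs <- dirs[keep, , drop = FALSE]
  if (refine && !is.null(section$engine)) {
    for (i in seq_len(min(nrow(pk), max_refine))) {
      r <- refine_srf_peak(section$engine, section$chi,
                           pk$theta[i], pk$phi[i],
                           span = section$step, step = refine_step)
      pk$theta[i] <- r["theta"]; pk$phi[i] <- r["phi"]; pk$h[i] <- r["height"]
      dirs[i, ] <- polar_to_vec(r["theta"], r["phi"])
    }
  }
  dyad <- apply(dirs, 1, function(u) {
    max(abs(u)) > cos(1.5 * section$step * pi / 180)
  })
  data.frame(theta = pk$theta, phi = pk$phi, chi = section$chi,
             height = pk$h, crystallographic = dyad)
}

# local grid refinement of a single SRF peak position
refine_srf_peak <- function(engine, chi, theta, phi, span = 5, step = 2) {
  best <- c(theta = theta, phi = phi, height = -Inf)
  u0 <- polar_to_vec(theta, phi)
  for (dt in seq(-span, span, by = step)) {
    th <- theta + dt
    if (th < 0 || th > 90) next
    # keep the azimuthal arc length comparable near the pole
    sc <- max(sin(th * pi / 180), 0.2)
    for (dp in seq(-span, span, by = step) / sc) {
      sc_score <- rotation_overlap(engine,
        rotation_about_axis(polar_to_vec(th, phi + dp), chi))
      if (sc_score > best["height"])
        best <- c(theta = th, phi = (phi + dp) %% 360, height = sc_score)
    }
  }
  best
}

#' Determine the NCS order from chi sections
#'
#' Computes the SRF section at chi = 360/n for every candidate order,
#' takes the best non-crystallographic peak of each, and returns the order
#' whose section peaks highest, with its axis refined on a finer local grid.
#' If the two best candidates agree within `tol` the result is flagged
#' ambiguous and `n` is NA: the score table is returned for the user to
#' judge (no guess is made).
#'
#' @param refl A [reflection_set()] or [srf_engine()].
#' @param candidates Candidate orders (default 11:14).
#' @param step Grid step in degrees for the sections.
#' @param tol Relative height tolerance for declaring a tie.
#' @param sharpen_axis Re-localize the winning axis on a 0.5-degree local
#'   grid using a sharp high-resolution engine (narrow window at the data
#'   limit, wide shell). The broad default engine is best for ranking the
#'   candidate orders but its peak position is biased by up to ~1.5 degrees
#'   where the ridges of symmetry-mate axis directions overlap; the sharp
#'   engine removes that bias.
#' @param ... Passed to [srf_engine()].
#' @return List with `n` (NA when ambiguous), `peak` (best peak row),
#'   `table` (per-candidate scores), `ambiguous`.
#' @export
detect_ncs_order <- function(refl, candidates = 11:14, step = 5,
                             tol = 0.02, sharpen_axis = TRUE, ...) {
  if (length(candidates) < 2) stop("need at least two candidate orders")
  engine <- as_srf_engine(refl, ...)
  rows <- list(); best_pk <- list()
  for (n in candidates) {
    sec <- srf_section(engine, chi_for_order(n), step = step)
    pk <- find_srf_peaks(sec)
    pk <- pk[!pk$crystallographic, , drop = FALSE]
    if (nrow(pk) == 0) {
      rows[[length(rows) + 1]] <- data.frame(n = n, chi = chi_for_order(n),
                                             theta = NA, phi = NA, height = -Inf)
      next
    }
    rows[[length(rows) + 1]] <- data.frame(n = n, chi = chi_for_order(n),
                                           theta = pk$theta[1], phi = pk$phi[1],
                                           height = pk$height[1])
    best_pk[[as.character(n)]] <- pk[1, ]
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$height), ]
  rownames(tab) <- NULL
  ambiguous <- nrow(tab) >= 2 && is.finite(tab$height[2]) &&
    (tab$height[1] - tab$height[2]) < tol * abs(tab$height[1])
  peak <- if (ambiguous) NULL else best_pk[[as.character(tab$n[1])]]
  if (!ambiguous && sharpen_axis) {
    sharp <- sharp_axis_engine(engine)
    r <- refine_srf_peak(sharp, chi_for_order(tab$n[1]),
                         peak$theta, peak$phi, span = 3, step = 0.5)
    peak$theta <- unname(r["theta"]); peak$phi <- unname(r["phi"])
  }
  list(n = if (ambiguous) NA_integer_ else tab$n[1],
       peak = peak, table = tab, ambiguous = ambiguous)
}

# high-resolution wide-shell engine for precise axis localization
sharp_axis_engine <- function(engine) {
  cell <- engine$cell
  d_lo <- engine$d_min
  r_max <- 0.42 * min(cell$a, cell$b, cell$c)
  srf_engine_from_patterson(engine, d_max = 1.5 * d_lo, d_min = d_lo,
                            r_min = 0.44 * r_max, r_max = r_max)
}

# rebuild an engine with different window/shell from the stored reflections
srf_engine_from_patterson <- function(engine, ...) {
  srf_engine(engine$refl, ...)
}

#' Twofold (chi = 180) profile on the equator of an NCS axis
#'
#' Scores chi = 180 rotations about axes in the plane perpendicular to a
#' given NCS axis, parameterized by the angle beta in \[0, 180) measured
#' from a deterministic in-plane reference (the projection of the
#' crystallographic b axis, or of a when b is parallel to the NCS axis).
#' For a Cn ring perpendicular to a crystal dyad the profile shows exactly n
#' peaks per 180 degrees -- the paper-style count of "peaks perpendicular to
#' the n-fold axis" (one of which coincides with the crystal dyad itself).
#'
#' @param refl A [reflection_set()] or [srf_engine()].
#' @param axis NCS axis: length-3 vector or c(theta, phi) via `theta`/`phi`.
#' @param theta,phi Alternative axis specification in degrees.
#' @param step Profile step in degrees (default 1).
#' @param ... Passed to [srf_engine()].
#' @return data.frame with columns beta, score, theta, phi (axis direction of
#'   each twofold), class `srf_equator`.
#' @export
equatorial_twofold_profile <- function(refl, axis = NULL, theta = NULL,
                                       phi = NULL, step = 1, ...) {
  engine <- as_srf_engine(refl, ...)
  if (is.null(axis)) axis <- polar_to_vec(theta, phi)
  m <- axis / sqrt(sum(axis^2))
  ref <- c(0, 1, 0)
  if (abs(sum(ref * m)) > 0.99) ref <- c(1, 0, 0)
  e1 <- ref - sum(ref * m) * m
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(m[2] * e1[3] - m[3] * e1[2],
          m[3] * e1[1] - m[1] * e1[3],
          m[1] * e1[2] - m[2] * e1[1])
  beta <- seq(0, 180 - step, by = step)
  out <- data.frame(beta = beta, score = NA_real_,
                    theta = NA_real_, phi = NA_real_)
  for (i in seq_along(beta)) {
    u <- cos(beta[i] * pi / 180) * e1 + sin(beta[i] * pi / 180) * e2
    out$score[i] <- rotation_overlap(engine, rotation_about_axis(u, 180))
    pol <- vec_to_polar(if (u[3] < 0) -u else u)
    out$theta[i] <- pol[1]; out$phi[i] <- pol[2]
  }
  class(out) <- c("srf_equator", "data.frame")
  out
}

#' Count equatorial twofold peaks
#'
#' Circular local maxima of an equatorial profile above a height threshold,
#' with maxima closer than `min_sep` merged into the higher one. On a Cn
#' ring crystal with the ring axis perpendicular to a crystallographic dyad
#' this count equals n: the dihedral family of twofolds spaced 180/n apart,
#' one member of which coincides with the crystal dyad itself.
#'
#' When the candidate order is known (the count is used as a consistency
#' check of an order detected from the chi sections), pass it as
#' `expected_order`: the merge window is then set just above half the
#' expected 180/n spacing, which absorbs the weak half-period ripples the
#' Patterson mirror symmetry can produce between the true peaks.
#'
#' @param profile An `srf_equator` data frame from
#'   [equatorial_twofold_profile()].
#' @param min_height_fraction Threshold as a fraction of the profile maximum.
#' @param min_sep Minimum peak separation in degrees.
#' @param expected_order Candidate ring order n; overrides `min_sep` with
#'   0.55 * 180/n.
#' @return List with `count` and `peaks` (data frame of beta, score).
#' @export
count_equatorial_twofolds <- function(profile, min_height_fraction = 0.25,
                                      min_sep = 4, expected_order = NULL) {
  if (!is.null(expected_order)) min_sep <- 0.55 * 180 / expected_order
  sc <- profile$score
  n <- length(sc)
  thr <- min_height_fraction * max(sc)
  prev <- sc[c(n, seq_len(n - 1))]
  nxt <- sc[c(seq_len(n - 1) + 1, 1)]
  is_pk <- sc >= prev & sc > nxt & sc >= thr
  idx <- which(is_pk)
  if (length(idx) > 1) {
    ord <- idx[order(-sc[idx])]
    span <- 180
    keep <- logical(0)
    for (i in ord) {
      d <- abs(profile$beta[i] - profile$beta[keep])
      d <- pmin(d, span - d)
      if (!length(keep) || all(d >= min_sep)) keep <- c(keep, i)
    }
    idx <- sort(keep)
  }
  list(count = length(idx),
       peaks = data.frame(beta = profile$beta[idx], score = sc[idx]))
}

#' Stereographic projection of an SRF section
#'
#' Equal-angle projection of the theta in \[0, 90\] hemisphere onto the unit
#' disk: radius tan(theta/2) (0 at the pole, 1 on the rim), azimuth phi
#' measured from +x.
#'
#' @param section An [srf_section()].
#' @return data.frame with x, y, value, theta, phi.
#' @export
stereographic_projection <- function(section) {
  g <- expand.grid(ti = seq_along(section$theta), pj = seq_along(section$phi))
  th <- section$theta[g$ti]; ph <- section$phi[g$pj]
  r <- tan(th / 2 * pi / 180)
  data.frame(x = r * cos(ph * pi / 180), y = r * sin(ph * pi / 180),
             value = section$values[cbind(g$ti, g$pj)], theta = th, phi = ph)
}

#' Plot an SRF section as a stereographic projection
#'
#' @param section An [srf_section()].
#' @param file Optional PNG path; plots to the active device when NULL.
#' @param ... Passed to [graphics::points()].
#' @return The projected data frame, invisibly.
#' @export
plot_srf_section <- function(section, file = NULL, ...) {
  pr <- stereographic_projection(section)
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 700)
    on.exit(grDevices::dev.off())
  }
  rng <- range(pr$value)
  shade <- if (diff(rng) > 0) (pr$value - rng[1]) / diff(rng) else pr$value * 0
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 xlab = "", ylab = "",
                 main = sprintf("SRF chi = %.1f", section$chi))
  ang <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(ang), sin(ang))
  graphics::points(pr$x, pr$y, pch = 16,
                   col = grDevices::gray(1 - shade), cex = 0.8, ...)
  invisible(pr)
}
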