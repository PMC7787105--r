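#' Density-modification configuration
#'
#' Protocol constants for [run_dm()]. The defaults are the protocol that
#' proved optimal on the portal-type problem: phase extension starting at
#' 7.9 A, solvent and NCS averaging masks updated every 50 and 20 cycles
#' respectively, 104 cycles in total.
#'
#' @param d_start Resolution (A) at which the starting phases end and the
#'   extension begins.
#' @param d_final Final resolution (A); NULL = the data limit.
#' @param total_cycles Total number of DM cycles.
#' @param solvent_update,ncs_update Mask update cadences (cycles).
#' @param solvent_fraction Solvent fraction of the cell; used to size the
#'   solvent mask when masks are derived from a map.
#' @param n_steps Number of equal 1/d phase-extension steps.
#' @param weights Phase-combination weighting scheme id ("sim").
#' @param refine_ops Refine the NCS operators against the starting map
#'   before the first cycle (see [refine_ncs_ops()]). Placement-derived
#'   operators carry degree-scale errors that phase extension does not
#'   tolerate, so this defaults to TRUE.
#' @param anchor_weight Weight on the starting-phase probability recombined
#'   with the DM phase each cycle (1 = full Sim concentration of the
#'   starting set; 0 = pure DM phases).
#' @return A list of class `dm_config`.
#' @export
dm_config <- function(d_start = 7.9, d_final = NULL, total_cycles = 104,
                      solvent_update = 50, ncs_update = 20,
                      solvent_fraction = 0.5, n_steps = 13,
                      weights = "sim", refine_ops = TRUE,
                      anchor_weight = 1) {
  if (!is.null(d_final) && d_start < d_final)
    stop("d_start must be >= d_final")
  if (solvent_update < 1 || ncs_update < 1) stop("update cadences must be >= 1")
  if (total_cycles < n_steps) stop("total_cycles must be >= n_steps")
  out <- list(d_start = d_start, d_final = d_final,
              total_cycles = total_cycles,
              solvent_update = solvent_update, ncs_update = ncs_update,
              solvent_fraction = solvent_fraction, n_steps = n_steps,
              weights = weights, refine_ops = refine_ops,
              anchor_weight = anchor_weight)
  class(out) <- "dm_config"
  out
}

#' Mask from an EM map
#'
#' Thresholds the map so that the mask covers exactly the target fraction of
#' voxels, highest density first.
#'
#' @param em_map A [map_grid()].
#' @param volume_fraction Fraction of voxels inside the mask, in (0, 1\].
#' @return A [map_grid()] mask with values in {0, 1}.
#' @export
mask_from_em <- function(em_map, volume_fraction) {
  if (volume_fraction <= 0 || volume_fraction > 1)
    stop("volume_fraction must be in (0, 1]")
  v <- em_map$values
  if (max(v) == min(v)) stop("cannot threshold a constant map")
  if (volume_fraction == 1) {
    thr <- -Inf
  } else {
    thr <- stats::quantile(as.vector(v), probs = 1 - volume_fraction,
                           names = FALSE)
  }
  map_grid(array(as.numeric(v > thr | (volume_fraction == 1)), dim(v)),
           em_map$cell, periodic = em_map$periodic, origin = em_map$origin)
}

#' Resample an EM-frame mask onto the crystal grid
#'
#' Maps every crystal voxel centre back into the EM frame through the
#' placement transform and samples the mask (nearest by thresholded
#' trilinear interpolation). The result covers one ring copy (the placed
#' one).
#'
#' @param mask EM-frame mask ([map_grid()], non-periodic).
#' @param transform Placement transform: list (R, t, pre_center) as attached
#'   to a `placement_list`, mapping EM coordinates to crystal Cartesian.
#' @param cell Crystal [unit_cell()].
#' @param grid_n Crystal grid dimensions.
#' @return A periodic crystal-frame [map_grid()] mask.
#' @export
resample_mask_to_crystal <- function(mask, transform, cell, grid_n) {
  tmp <- map_grid(array(0, grid_n), cell, periodic = TRUE)
  x <- voxel_centers(tmp)
  pc <- if (is.null(transform$pre_center)) c(0, 0, 0) else transform$pre_center
  xe <- sweep(x, 2, transform$t, "-") %*% transform$R  # R^{-1} = t(R)
  xe <- sweep(xe, 2, pc, "+")
  v <- interpolate_map(mask, xe, cartesian = TRUE, fill = 0)
  map_grid(array(as.numeric(v > 0.5), grid_n), cell, periodic = TRUE)
}

#' Angular wedge of a mask about an NCS axis
#'
#' Intersects a mask with the azimuthal wedge \[0, 360/n) about the operator
#' set's axis: the asymmetric unit of the Cn group. The n rotated copies of
#' the wedge tile the full mask (overlaps only at wedge boundaries).
#'
#' @param mask A crystal-frame [map_grid()] mask.
#' @param ops An [cn_operators()] set (crystal frame).
#' @return The wedge mask, same grid.
#' @export
wedge_mask <- function(mask, ops) {
  if (ops$n < 2) stop("wedge requires order >= 2")
  x <- voxel_centers(mask)
  m <- ops$axis
  ref <- c(0, 1, 0)
  if (abs(sum(ref * m)) > 0.99) ref <- c(1, 0, 0)
  e1 <- ref - sum(ref * m) * m; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(m[2] * e1[3] - m[3] * e1[2],
          m[3] * e1[1] - m[1] * e1[3],
          m[1] * e1[2] - m[2] * e1[1])
  v <- sweep(x, 2, ops$center, "-")
  ang <- (atan2(v %*% e2, v %*% e1) * 180 / pi) %% 360
  inside <- as.numeric(ang < 360 / ops$n) * as.vector(mask$values)
  map_grid(array(inside, dim(mask$values)), mask$cell, periodic = mask$periodic,
           origin = mask$origin)
}

#' Solvent flattening
#'
#' Sets every voxel outside the protein mask to the solvent mean; protein
#' voxels are untouched.
#'
#' @param map A [map_grid()].
#' @param protein_mask Mask of the protein region (all copies).
#' @return The flattened map.
#' @export
solvent_flatten <- function(map, protein_mask) {
  v <- map$values
  sel <- protein_mask$values < 0.5
  v[sel] <- mean(v[sel])
  map$values <- v
  map
}

#' Histogram matching
#'
#' Rank-preserving transform of the masked densities onto the distribution
#' of a reference sample (the density histogram of a well-phased map at the
#' same resolution). Values outside the mask are untouched.
#'
#' @param map A [map_grid()].
#' @param mask Region to transform.
#' @param reference Numeric vector of reference densities.
#' @return The matched map.
#' @export
histogram_match <- function(map, mask, reference) {
  sel <- which(mask$values > 0.5)
  if (!length(sel)) stop("empty protein region")
  v <- map$values[sel]
  n <- length(v)
  ref <- sort(reference)
  q <- (rank(v, ties.method = "first") - 0.5) / n
  map$values[sel] <- ref[pmax(1, pmin(length(ref), ceiling(q * length(ref))))]
  map
}

#' NCS averaging
#'
#' Replaces every voxel of the mask by the mean of its density over all n
#' NCS images (trilinear interpolation, periodic). Also returns the average
#' NCS correlation: the mean pairwise Pearson correlation between the n
#' images of the masked region before averaging -- the map-quality statistic
#' density-modification protocols are tuned on.
#'
#' @param map A periodic [map_grid()].
#' @param ops [cn_operators()] in the crystal frame.
#' @param mask Averaging mask (one ring copy).
#' @return List: `map` (averaged), `ncs_cc`.
#' @export
ncs_average <- function(map, ops, mask) {
  sel <- which(mask$values > 0.5)
  if (!length(sel)) stop("empty NCS mask")
  dims <- dim(map$values)
  x <- voxel_centers(map)[sel, , drop = FALSE]
  n <- ops$n
  imgs <- matrix(NA_real_, length(sel), n)
  for (k in seq_len(n)) {
    xk <- sweep(x %*% t(ops$ops[[k]]$R), 2, ops$ops[[k]]$t, "+")
    imgs[, k] <- interpolate_map(map, xk, cartesian = TRUE)
  }
  z <- scale(imgs)   # standardize each image
  ssum <- rowSums(z)
  npairs_sum <- (sum(ssum^2) / (nrow(imgs) - 1) - n)
  ncs_cc <- npairs_sum / (n * (n - 1))
  map$values[sel] <- rowMeans(imgs)
  list(map = map, ncs_cc = ncs_cc)
}

#' Sim-weighted phase recombination
#'
#' Keeps the observed amplitudes, adopts the phases of the
#' density-modified structure factors, and stores a Sim-style figure of
#' merit `m = I1(X)/I0(X)` with `X = 2 Fo Fc / sigma_Delta^2` evaluated in
#' resolution shells after shell-wise scaling of Fc to Fo. Shells are
#' quantile-based, so thin shells are automatically merged with neighbours.
#'
#' @param f_obs Observed [reflection_set()].
#' @param f_dm Modified-map [reflection_set()] (from [invert_map()]).
#' @param n_shells Number of resolution shells.
#' @return A [reflection_set()]: Fo amplitudes, DM phases, Sim FOM.
#' @export
phase_recombine <- function(f_obs, f_dm, n_shells = 15) {
  sx <- sim_x(f_obs, f_dm, n_shells)
  out <- f_obs
  out$phi[sx$ok] <- sx$phi
  out$fom[sx$ok] <- bessel_ratio(sx$x)
  out
}

# I1(X)/I0(X), capped against overflow (m(500) is 1 to 3 decimals anyway)
bessel_ratio <- function(x) {
  x <- pmin(x, 500)
  besselI(x, 1, expon.scaled = TRUE) / besselI(x, 0, expon.scaled = TRUE)
}

# Sim phase-probability concentration X = 2 D Fo Fc / sigma_Delta^2 per
# matched reflection, with shell-wise scaling of Fc. The shell amplitude
# correlation D damps the weight where the map carries no real information
# about the data (plain Sim weights are notoriously overconfident there:
# shell scaling alone gives uninformative maps a nonzero X).
sim_x <- function(f_obs, f_dm, n_shells = 15) {
  ko <- hkl_key(as.matrix(f_obs[, c("h", "k", "l")]))
  kd <- hkl_key(as.matrix(f_dm[, c("h", "k", "l")]))
  m <- match(ko, kd)
  ok <- !is.na(m)
  fo <- f_obs$f[ok]; fd <- f_dm$f[m[ok]]
  shell <- shell_bins(f_obs$d[ok], min(n_shells, max(1, sum(ok) %/% 10)))
  x <- numeric(length(fo))
  for (b in unique(shell)) {
    i <- shell == b
    sc <- sum(fo[i] * fd[i]) / max(sum(fd[i]^2), 1e-12)
    fds <- sc * fd[i]
    dcor <- if (sum(i) > 3 && stats::sd(fo[i]) > 0 && stats::sd(fds) > 0)
      max(0, stats::cor(fo[i], fds)) else 0
    sig <- mean((fo[i] - fds)^2)
    sig <- max(sig, 1e-8 * mean(fo[i]^2) + 1e-30)
    x[i] <- 2 * dcor * fo[i] * fds / sig
  }
  list(ok = ok, x = x, phi = f_dm$phi[m[ok]])
}

# numeric inverse of the Sim figure of merit m = I1(X)/I0(X)
fom_to_x <- local({
  xs <- c(seq(0, 20, by = 0.05), seq(21, 500, by = 1))
  ms <- besselI(xs, 1, expon.scaled = TRUE) / besselI(xs, 0, expon.scaled = TRUE)
  fn <- stats::approxfun(ms, xs, rule = 2)
  function(m) fn(pmin(m, max(ms)))
})

#' Density modification with NCS averaging and phase extension
#'
#' The full cycle engine: synthesize a figure-of-merit weighted map from the
#' current phase set, NCS-average the placed ring copy, histogram-match its
#' protein region, rebuild the other crystal copies from the modified one,
#' flatten the solvent, invert, and recombine phases with Sim weights --
#' while the resolution cutoff is extended from `d_start` to the data limit
#' in equal 1/d steps. Newly admitted reflections take their phases from the
#' inverted modified map. Amplitudes are never altered.
#'
#' Masks are regenerated from the current map on the configured cadences
#' (the EM-derived footprint is kept as a static prior region).
#'
#' @param refl Observed [reflection_set()] whose `phi`/`fom` columns hold
#'   the starting phase set to `d_start` (NA beyond).
#' @param config A [dm_config()].
#' @param ops Crystal-frame [cn_operators()] of the ring.
#' @param em_map EM-frame map used to generate masks (with `placement`).
#' @param placement Placement transform (list R, t, pre_center) or
#'   `placement_list`.
#' @param masks Optional explicit masks: list(copy1 = crystal-frame mask),
#'   replacing the EM route.
#' @param hist_ref Optional phased [reflection_set()] providing the
#'   reference histogram (e.g. calculated from a refined structure at
#'   matching resolution); NULL skips histogram matching.
#' @param protein_volume Protein volume of ONE ring copy in A^3 (sizes the
#'   EM mask); default estimated from the mask region.
#' @param verbose Print per-cycle progress.
#' @return List of class `dm_result`: `trace` (per-cycle data.frame:
#'   cycle, d_cut, ncs_cc, mean_fom, solvent_var), `refl` (final phase set),
#'   `map` (final weighted map), `ncs_cc` (final), `aborted`.
#' @export
run_dm <- function(refl, config = dm_config(), ops, em_map = NULL,
                   placement = NULL, masks = NULL, hist_ref = NULL,
                   protein_volume = NULL, verbose = FALSE) {
  cell <- refl_cell(refl); sg <- refl_sg(refl)
  d_final <- if (is.null(config$d_final)) min(refl$d) else config$d_final
  d_start <- config$d_start
  if (!any(!is.na(refl$phi) & refl$d >= d_start))
    stop("no starting phases at or below d_start")
  grid_n <- grid_for_cell(cell, d_final, rate = 3)
  hkl_all <- as.matrix(refl[, c("h", "k", "l")])

  # masks: one ring copy (copy 1), then the symmetry-expanded protein mask
  if (is.null(masks)) {
    if (is.null(em_map) || is.null(placement))
      stop("run_dm needs either masks or an em_map + placement")
    tr <- if (inherits(placement, "placement_list"))
      attr(placement, "transform") else placement
    if (is.null(protein_volume))
      protein_volume <- (1 - config$solvent_fraction) * cell_volume(cell) /
        length(sg$ops)
    em_vox <- prod(pixel_size(em_map))
    frac_em <- min(1, protein_volume / (em_vox * length(em_map$values)))
    copy1 <- resample_mask_to_crystal(mask_from_em(em_map, frac_em),
                                      tr, cell, grid_n)
  } else {
    copy1 <- masks$copy1
    if (!identical(dim(copy1$values), as.integer(grid_n)))
      stop("masks$copy1 grid does not match the DM grid (",
           paste(grid_n, collapse = "x"), ")")
  }
  mk <- build_dm_masks(copy1, cell, sg, grid_n)

  # phase-extension schedule: equal 1/d steps, cycles split evenly; the
  # first block runs at d_start (pure DM before any extension)
  s_cuts <- seq(1 / d_start, 1 / d_final, length.out = config$n_steps)
  per <- rep(config$total_cycles %/% config$n_steps, config$n_steps)
  per[config$n_steps] <- per[config$n_steps] +
    config$total_cycles %% config$n_steps
  d_cut_cycle <- rep(1 / s_cuts, per)

  ref_cache <- list()
  trace <- vector("list", config$total_cycles)
  cur <- refl
  # admission bookkeeping: newly extended reflections enter the synthesis
  # with a ramped weight over one extension block, so a freshly admitted
  # shell cannot destabilize the map before its phases have settled
  adm_cycle <- ifelse(!is.na(refl$phi), 0L, NA_integer_)
  ramp_len <- max(1, config$total_cycles %/% config$n_steps)
  # starting-phase anchor: the MR phase probability is recombined with the
  # DM phase every cycle, which prevents the iteration from drifting away
  # from the molecular-replacement frame
  has_anchor <- !is.na(refl$phi)
  aw <- if (is.null(config$anchor_weight)) 1 else config$anchor_weight
  x_anchor <- aw * ifelse(has_anchor,
                          fom_to_x(ifelse(is.na(refl$fom), 0.8, refl$fom)), 0)
  phi_anchor <- ifelse(has_anchor, refl$phi, 0) * pi / 180
  bad_streak <- 0; last_cc <- -Inf; aborted <- FALSE
  for (cyc in seq_len(config$total_cycles)) {
    d_cut <- d_cut_cycle[cyc]
    active <- cur$d >= d_cut & !is.na(cur$phi)
    adm_cycle[active & is.na(adm_cycle)] <- cyc
    sub <- cur[active, ]
    attributes(sub)[c("cell", "sg")] <- attributes(cur)[c("cell", "sg")]
    class(sub) <- class(cur)
    ramp <- pmin(1, (cyc - adm_cycle[active] + 1) / ramp_len)
    w <- ifelse(is.na(sub$fom), 1, sub$fom) * ramp
    map <- synthesize_map(sub, grid_n = grid_n, weights = w)
    solvent_var <- stats::var(map$values[mk$solvent_idx])

    if (isTRUE(config$refine_ops) && cyc == 1) {
      # refine once against the starting map; refining again later would
      # pull the operators toward the partial model's bias
      ops <- refine_ncs_ops(map, ops, mk$copy1)
      if (verbose)
        message(sprintf("cycle %3d  operators refined: ncs_cc %.4f",
                        cyc, attr(ops, "ncs_cc")))
    }
    av <- ncs_average_fast(map, ops, mk)
    map <- av$map
    if (!is.null(hist_ref)) {
      key <- sprintf("%.4f", d_cut)
      if (is.null(ref_cache[[key]])) {
        # reference histogram = distribution over the reference map's own
        # protein region, taken as its densest voxels (frame-invariant:
        # the reference need not share the working map's origin)
        rr <- resolution_window(hist_ref, d_min = d_cut)
        rv <- synthesize_map(rr, grid_n = grid_n)$values
        n_prot <- min(length(rv),
                      length(mk$copy1_idx) * length(sg$ops))
        ref_cache[[key]] <- sort(rv, decreasing = TRUE)[seq_len(n_prot)]
      }
      v <- map$values[mk$copy1_idx]
      ref <- sort(ref_cache[[key]])
      q <- (rank(v, ties.method = "first") - 0.5) / length(v)
      map$values[mk$copy1_idx] <-
        ref[pmax(1, pmin(length(ref), ceiling(q * length(ref))))]
    }
    map <- rebuild_copies(map, mk)
    map$values[mk$solvent_idx] <- mean(map$values[mk$solvent_idx])

    fdm <- invert_map(map, sg, d_min = d_final, hkl = hkl_all)
    sx <- sim_x(cur, fdm)
    z <- sx$x * exp(1i * sx$phi * pi / 180) +
      (x_anchor * exp(1i * phi_anchor))[sx$ok]
    nxt <- cur
    nxt$phi[sx$ok] <- (Arg(z) * 180 / pi) %% 360
    nxt$fom[sx$ok] <- bessel_ratio(Mod(z))
    # only phases within the next cycle's cutoff are considered "phased"
    d_next <- d_cut_cycle[min(cyc + 1, config$total_cycles)]
    nxt$phi[nxt$d < d_next] <- NA_real_
    nxt$fom[nxt$d < d_next] <- NA_real_
    cur <- nxt

    trace[[cyc]] <- data.frame(cycle = cyc, d_cut = d_cut, ncs_cc = av$ncs_cc,
                               mean_fom = mean(cur$fom[cur$d >= d_next],
                                               na.rm = TRUE),
                               solvent_var = solvent_var)
    if (verbose && (cyc %% 10 == 0 || cyc == 1))
      message(sprintf("cycle %3d  d = %.2f  ncs_cc = %.4f  <fom> = %.3f",
                      cyc, d_cut, av$ncs_cc,
                      trace[[cyc]]$mean_fom))
    # mask updates on the configured cadences
    if (cyc < config$total_cycles &&
        (cyc %% config$solvent_update == 0 || cyc %% config$ncs_update == 0)) {
      mk <- update_dm_masks(map, mk, cell, sg, grid_n,
                            update_solvent = cyc %% config$solvent_update == 0)
    }
    if (av$ncs_cc < last_cc - 1e-6) {
      if (bad_streak == 0) streak_start <- last_cc
      bad_streak <- bad_streak + 1
    } else bad_streak <- 0
    last_cc <- av$ncs_cc
    # abort on a sustained, material degradation; a slow sub-0.02 sag while
    # newly admitted shells settle is part of normal extension
    if (bad_streak >= 10 && streak_start - av$ncs_cc > 0.02) {
      warning("NCS correlation decreased for 10 consecutive cycles: aborting")
      aborted <- TRUE
      trace <- trace[seq_len(cyc)]
      break
    }
  }
  trace <- do.call(rbind, trace)
  final_map <- synthesize_map(local_set(cur, !is.na(cur$phi)),
                              grid_n = grid_n, weights = "fom")
  out <- list(trace = trace, refl = cur, map = final_map,
              ncs_cc = trace$ncs_cc[nrow(trace)], masks = mk,
              config = config, aborted = aborted)
  class(out) <- "dm_result"
  out
}

#' @export
print.dm_result <- function(x, ...) {
  cat(sprintf("DM run: %d cycles, d %.2f -> %.2f A, final NCS cc = %.3f%s\n",
              nrow(x$trace), x$trace$d_cut[1], x$trace$d_cut[nrow(x$trace)],
              x$ncs_cc, if (x$aborted) " (ABORTED)" else ""))
  invisible(x)
}

# subset a reflection_set preserving attributes
local_set <- function(refl, sel) {
  out <- refl[sel, ]
  attributes(out)[c("cell", "sg")] <- attributes(refl)[c("cell", "sg")]
  class(out) <- class(refl)
  out
}

# precompute voxel index sets and NCS/crystal image coordinates;
# `footprint` is the static dilated region (EM-derived) inside which mask
# updates are allowed to re-threshold
build_dm_masks <- function(copy1, cell, sg, grid_n, footprint = NULL) {
  tmp <- map_grid(array(0, grid_n), cell, periodic = TRUE)
  x_all <- voxel_centers(tmp)
  copy1_idx <- which(copy1$values > 0.5)
  # crystal copies of the mask: voxels whose preimage under op j is in copy1
  o <- orth_matrix(cell); oi <- solve(o)
  prot <- copy1$values > 0.5
  copy_idx <- list()
  copy_pre <- list()
  for (j in seq_along(sg$ops)) {
    if (j == 1) next
    op <- sg$ops[[j]]
    # inverse op in fractional coordinates: x = R^{-1} (x' - t)
    Rinv <- solve(op$R)
    fr <- orth_to_frac(x_all, cell)
    pre <- sweep(fr, 2, op$t, "-") %*% t(Rinv)
    pre_cart <- frac_to_orth(pre %% 1, cell)
    inside <- interpolate_map(copy1, pre %% 1) > 0.5
    copy_idx[[j]] <- which(inside)
    copy_pre[[j]] <- pre_cart[inside, , drop = FALSE]
    prot <- prot | inside
  }
  if (is.null(footprint)) footprint <- dilate_mask(copy1$values > 0.5, 2)
  list(copy1 = copy1, copy1_idx = copy1_idx,
       copy1_x = x_all[copy1_idx, , drop = FALSE],
       copy_idx = copy_idx, copy_pre = copy_pre,
       protein = prot, solvent_idx = which(!prot),
       footprint = footprint,
       cell = cell, sg = sg, grid_n = grid_n)
}

# binary dilation by `by` voxels along each axis (periodic)
dilate_mask <- function(cand, by = 1) {
  shift_axis <- function(a, ax, k) {
    idx <- lapply(dim(a), seq_len)
    idx[[ax]] <- ((idx[[ax]] - 1 - k) %% dim(a)[ax]) + 1
    do.call(`[`, c(list(a), idx))
  }
  dil <- cand
  for (r in seq_len(by)) {
    prev <- dil
    for (ax in 1:3)
      dil <- dil | shift_axis(prev, ax, 1) | shift_axis(prev, ax, -1)
  }
  dil
}

#' Refine NCS operators against a map
#'
#' Maximizes the average NCS correlation over small perturbations of the
#' axis direction (two tilt angles) and the centre position, by cyclic
#' coordinate descent with step halving. Molecular-replacement placements
#' are typically good to 1-2 degrees and 1-2 Angstrom; at the resolutions
#' phase extension reaches, that residual error destroys the averaging
#' signal unless the operators are re-refined against the map.
#'
#' @param map A periodic [map_grid()].
#' @param ops Starting [cn_operators()].
#' @param mask Averaging mask (one ring copy).
#' @param max_tilt,max_shift Bounds on the perturbation (degrees/Angstrom).
#' @param step0,tol Initial/final coordinate-descent steps.
#' @param subsample Number of mask voxels used during refinement.
#' @return Refined `ncs_operator_set` with attribute `ncs_cc`.
#' @export
refine_ncs_ops <- function(map, ops, mask, max_tilt = 2, max_shift = 2,
                           step0 = 0.5, tol = 0.02, subsample = 6000) {
  sel <- which(mask$values > 0.5)
  if (length(sel) > subsample)
    sel <- sel[seq(1, length(sel), length.out = subsample)]
  x <- voxel_centers(map)[sel, , drop = FALSE]
  m0 <- ops$axis; c0 <- ops$center
  # two tilt directions perpendicular to the axis
  ref <- if (abs(m0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * m0) * m0; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(m0[2] * e1[3] - m0[3] * e1[2],
          m0[3] * e1[1] - m0[1] * e1[3],
          m0[1] * e1[2] - m0[2] * e1[1])
  cc_of <- function(p) {
    ax <- as.vector(rotation_about_axis(e1, p[1]) %*%
                    rotation_about_axis(e2, p[2]) %*% m0)
    oo <- cn_operators(ops$n, ax, c0 + p[3] * e1 + p[4] * e2 + p[5] * m0)
    imgs <- matrix(NA_real_, nrow(x), oo$n)
    for (k in seq_len(oo$n)) {
      xk <- sweep(x %*% t(oo$ops[[k]]$R), 2, oo$ops[[k]]$t, "+")
      imgs[, k] <- interpolate_map(map, xk, cartesian = TRUE)
    }
    z <- scale(imgs)
    (sum(rowSums(z)^2) / (nrow(imgs) - 1) - oo$n) / (oo$n * (oo$n - 1))
  }
  p <- rep(0, 5)
  best <- cc_of(p)
  step <- step0
  lim <- c(max_tilt, max_tilt, max_shift, max_shift, max_shift)
  while (step >= tol) {
    improved <- FALSE
    for (i in 1:5) {
      for (sgn in c(1, -1)) {
        q <- p
        q[i] <- max(-lim[i], min(lim[i], q[i] + sgn * step))
        if (identical(q, p)) next
        v <- cc_of(q)
        if (v > best + 1e-9) { p <- q; best <- v; improved <- TRUE }
      }
    }
    if (!improved) step <- step / 2
  }
  ax <- as.vector(rotation_about_axis(e1, p[1]) %*%
                  rotation_about_axis(e2, p[2]) %*% m0)
  out <- cn_operators(ops$n, ax, c0 + p[3] * e1 + p[4] * e2 + p[5] * m0)
  attr(out, "ncs_cc") <- best
  out
}

# NCS averaging using the precomputed mask state
ncs_average_fast <- function(map, ops, mk) {
  n <- ops$n
  x <- mk$copy1_x
  imgs <- matrix(NA_real_, nrow(x), n)
  for (k in seq_len(n)) {
    xk <- sweep(x %*% t(ops$ops[[k]]$R), 2, ops$ops[[k]]$t, "+")
    imgs[, k] <- interpolate_map(map, xk, cartesian = TRUE)
  }
  z <- scale(imgs)
  ssum <- rowSums(z)
  ncs_cc <- (sum(ssum^2) / (nrow(imgs) - 1) - n) / (n * (n - 1))
  map$values[mk$copy1_idx] <- rowMeans(imgs)
  list(map = map, ncs_cc = ncs_cc)
}

# overwrite crystal copies 2..z with the (modified) copy-1 density
rebuild_copies <- function(map, mk) {
  for (j in seq_along(mk$copy_idx)) {
    if (is.null(mk$copy_idx[[j]])) next
    map$values[mk$copy_idx[[j]]] <-
      interpolate_map(map, mk$copy_pre[[j]], cartesian = TRUE)
  }
  map
}

# mask update: re-threshold the current map inside the static EM-derived
# footprint (the footprint anchors the mask so it cannot drift toward the
# partial model's features and lose the unmodelled protein)
update_dm_masks <- function(map, mk, cell, sg, grid_n, update_solvent = TRUE) {
  target <- length(mk$copy1_idx)
  v <- map$values
  d <- dim(v)
  dil <- mk$footprint
  vals <- v[dil]
  thr <- sort(vals, decreasing = TRUE)[min(target, length(vals))]
  newmask <- dil & (v >= thr)
  copy1 <- map_grid(array(as.numeric(newmask), d), cell, periodic = TRUE)
  build_dm_masks(copy1, cell, sg, grid_n, footprint = mk$footprint)
}
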