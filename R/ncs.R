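#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues formula; right-handed rotation by `angle_deg` about `axis`.
#'
#' @param axis Length-3 direction (need not be normalized, must be nonzero).
#' @param angle_deg Rotation angle in degrees.
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation axis must be nonzero")
  u <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Polar direction (theta, phi) to a Cartesian unit vector
#'
#' theta is the polar angle from the crystal c axis, phi the azimuth from a
#' in the ab plane (the convention in which an axis at theta = 70, phi = 0
#' lies in the ac plane, 70 degrees from c).
#'
#' @param theta_deg,phi_deg Angles in degrees.
#' @return Length-3 unit vector.
#' @export
polar_to_vec <- function(theta_deg, phi_deg) {
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

#' @rdname polar_to_vec
#' @param v Length-3 vector (need not be normalized).
#' @return `vec_to_polar`: c(theta, phi) in degrees, theta in \[0, 180\],
#'   phi in \[0, 360).
#' @export
vec_to_polar <- function(v) {
  v <- v / sqrt(sum(v^2))
  c(theta = acos(max(-1, min(1, v[3]))) * 180 / pi,
    phi = (atan2(v[2], v[1]) * 180 / pi) %% 360)
}

#' Cn non-crystallographic symmetry operators
#'
#' Ordered rotation+translation operators generating a cyclic group of order
#' n about the line through `center` along `axis`; the identity comes first,
#' operator k rotates by 2*pi*k/n. Each operator acts on Cartesian Angstrom
#' coordinates as `x' = R %*% x + t` with `t = center - R %*% center`.
#'
#' @param n Order of the axis (>= 1).
#' @param axis Length-3 axis direction (nonzero).
#' @param center Point on the axis (Cartesian Angstrom).
#' @return Object of class `ncs_operator_set`: list with `n`, `axis` (unit),
#'   `center`, and `ops` (list of `list(R, t)`).
#' @export
cn_operators <- function(n, axis = c(0, 0, 1), center = c(0, 0, 0)) {
  if (n < 1 || n != round(n)) stop("order n must be an integer >= 1")
  if (sqrt(sum(axis^2)) == 0) stop("axis must be nonzero")
  u <- axis / sqrt(sum(axis^2))
  ops <- lapply(seq_len(n) - 1L, function(k) {
    R <- rotation_about_axis(u, 360 * k / n)
    list(R = R, t = as.vector(center - R %*% center))
  })
  out <- list(n = as.integer(n), axis = u, center = center, ops = ops)
  class(out) <- "ncs_operator_set"
  out
}

#' @export
print.ncs_operator_set <- function(x, ...) {
  pol <- vec_to_polar(x$axis)
  cat(sprintf("C%d operators about axis (theta=%.1f, phi=%.1f) through (%.1f, %.1f, %.1f)\n",
              x$n, pol[1], pol[2], x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Apply a rigid transform to a model
#'
#' @param model An [atomic_model()].
#' @param R 3x3 rotation matrix.
#' @param t Length-3 translation (Angstrom).
#' @return The transformed model.
#' @export
transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  xyz <- model_xyz(model) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  set_model_xyz(model, xyz)
}

# conjugate an operator set by a rigid transform (x -> A x + b):
# used to express EM-frame NCS operators in the crystal frame
transform_ops <- function(ops, A, b) {
  out <- cn_operators(ops$n, as.vector(A %*% ops$axis),
                      as.vector(A %*% ops$center + b))
  out
}

#' Expand a monomer into a Cn ring
#'
#' Applies each operator to a copy of the monomer and renames chains: copy k
#' (0-based) of a single-chain monomer becomes chain `LETTERS[k+1]`; for
#' multi-chain monomers every copy consumes one id per chain, cycling through
#' A-Z, a-z, 0-9. Atom serial numbers are renumbered sequentially.
#'
#' @param monomer An [atomic_model()].
#' @param ops An [cn_operators()] set (or any `ncs_operator_set`).
#' @return An [atomic_model()] with `ops$n` times the atoms of `monomer`.
#' @export
expand_cn <- function(monomer, ops) {
  alphabet <- c(LETTERS, letters, as.character(0:9))
  mon_chains <- unique(monomer$chain)
  need <- length(mon_chains) * ops$n
  if (need > length(alphabet))
    stop("chain-id alphabet exhausted: need ", need, " ids")
  copies <- vector("list", ops$n)
  for (k in seq_len(ops$n)) {
    cp <- transform_model(monomer, ops$ops[[k]]$R, ops$ops[[k]]$t)
    ids <- alphabet[(k - 1) * length(mon_chains) + seq_along(mon_chains)]
    cp$chain <- ids[match(cp$chain, mon_chains)]
    copies[[k]] <- cp
  }
  out <- do.call(rbind, copies)
  out$serial <- seq_len(nrow(out))
  atomic_model(out)
}

#' Rescale a model about a center (magnification correction)
#'
#' Uniformly scales all coordinates about `center`: the transform a
#' pixel-size (magnification) calibration error applies to any model built
#' in a cryo-EM map. Inter-atomic distances scale exactly by `factor`.
#'
#' @param model An [atomic_model()].
#' @param factor Scale factor (> 0); e.g. 1.42/1.37 to emulate a map scaled
#'   with the wrong pixel size.
#' @param center Fixed point of the scaling (default: model centroid).
#' @return The rescaled model.
#' @export
rescale_magnification <- function(model, factor, center = model_centroid(model)) {
  if (!is.finite(factor) || factor <= 0) stop("scale factor must be positive")
  xyz <- model_xyz(model)
  xyz <- sweep(sweep(xyz, 2, center, "-") * factor, 2, center, "+")
  set_model_xyz(model, xyz)
}

#' Rotate a model so its symmetry axis points along a target direction
#'
#' Applies, about `center`, the minimal rotation taking `model_axis` to the
#' direction (theta, phi). In the antiparallel degenerate case the rotation
#' axis is chosen deterministically as the first Cartesian basis vector
#' perpendicular to `model_axis`.
#'
#' @param model An [atomic_model()].
#' @param model_axis Current axis direction of the model.
#' @param theta,phi Target direction in degrees (see [polar_to_vec()]), or
#' @param target Target direction as a vector (overrides theta/phi).
#' @param center Rotation center; default the model centroid.
#' @return The rotated model, with the rotation matrix in attribute `rot`.
#' @export
align_axis <- function(model, model_axis, theta = NULL, phi = NULL,
                       target = NULL, center = model_centroid(model)) {
  if (is.null(target)) target <- polar_to_vec(theta, phi)
  R <- rotation_between(model_axis, target)
  out <- transform_model(model,
                         R, as.vector(center - R %*% center))
  attr(out, "rot") <- R
  out
}

# minimal rotation mapping vector u onto v (both nonzero)
rotation_between <- function(u, v) {
  if (sqrt(sum(u^2)) == 0 || sqrt(sum(v^2)) == 0)
    stop("axes must be nonzero")
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  d <- sum(u * v)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    # antiparallel: rotate 180 deg about the smallest-index basis vector
    # not parallel to u
    for (i in 1:3) {
      e <- c(0, 0, 0); e[i] <- 1
      w <- e - sum(e * u) * u
      if (sqrt(sum(w^2)) > 1e-6) return(rotation_about_axis(w, 180))
    }
  }
  ax <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  rotation_about_axis(ax, acos(max(-1, min(1, d))) * 180 / pi)
}
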