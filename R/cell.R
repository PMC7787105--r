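#' Construct a crystallographic unit cell
#'
#' @param a,b,c Cell edge lengths in Angstrom. Must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#'   Default 90 (orthorhombic/orthogonal box).
#'
#' @return An object of class `unit_cell`.
#' @examples
#' unit_cell(119.85, 238.57, 265.61)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("unit cell lengths must be positive and finite")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("unit cell angles must lie in (0, 180) degrees")
  cell <- list(a = unname(a), b = unname(b), c = unname(c),
               alpha = unname(alpha), beta = unname(beta),
               gamma = unname(gamma))
  class(cell) <- "unit_cell"
  if (cell_volume(cell) <= 0) stop("degenerate unit cell (non-positive volume)")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f (A, deg)\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Unit-cell volume
#'
#' Triclinic volume formula; reduces to `a*b*c` for orthorhombic cells.
#'
#' @param cell A [unit_cell()].
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  cell$a * cell$b * cell$c *
    sqrt(max(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
}

#' Orthogonalization matrix (fractional -> Cartesian, Angstrom)
#'
#' Standard PDB convention: `a` along x, `b` in the xy plane.
#' Cartesian coordinates are `O %*% x_frac`.
#'
#' @param cell A [unit_cell()].
#' @return A 3x3 matrix.
#' @export
orth_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  v <- cell_volume(cell) / (cell$a * cell$b * cell$c)
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           cell$c * v / sg),
         nrow = 3, byrow = TRUE)
}

#' Convert between fractional and Cartesian coordinates
#'
#' @param x An n x 3 matrix (or length-3 vector) of coordinates.
#' @param cell A [unit_cell()].
#' @return An n x 3 matrix.
#' @export
frac_to_orth <- function(x, cell) {
  x <- rbind3(x)
  x %*% t(orth_matrix(cell))
}

#' @rdname frac_to_orth
#' @export
orth_to_frac <- function(x, cell) {
  x <- rbind3(x)
  x %*% t(solve(orth_matrix(cell)))
}

# coerce a length-3 vector to a 1x3 matrix, pass matrices through
rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

#' Resolution (d-spacing) of reflections
#'
#' Reciprocal-metric d-spacing, valid for any triclinic cell.
#'
#' @param hkl Integer Miller indices: a length-3 vector or an n x 3 matrix.
#' @param cell A [unit_cell()].
#' @return d in Angstrom (vector of length n). Errors on (0,0,0).
#' @examples
#' d_spacing(c(0, 0, 2), unit_cell(119.85, 238.57, 265.61)) # = c/2
#' @export
d_spacing <- function(hkl, cell) {
  h <- rbind3(hkl)
  if (any(rowSums(abs(h)) == 0))
    stop("d-spacing undefined for the (0,0,0) reflection")
  o <- orth_matrix(cell)
  gstar <- solve(t(o) %*% o)  # reciprocal metric tensor
  1 / sqrt(rowSums((h %*% gstar) * h))
}

#' Rotation angle of the generator of a Cn axis
#'
#' The self-rotation function section in which an n-fold axis peaks:
#' chi = 360/n degrees, reported to one decimal (27.7 for n = 13,
#' 30.0 for n = 12, 25.7 for n = 14, 32.7 for n = 11).
#'
#' @param n Rotational order (integer >= 1); vectorized.
#' @return chi in degrees, rounded to one decimal.
#' @export
chi_for_order <- function(n) {
  if (any(n < 1) || any(n != round(n))) stop("order n must be an integer >= 1")
  round(360 / n, 1)
}

#' Matthews coefficient and solvent content
#'
#' Vm = V_cell / (z * mass_au) with z the number of space-group symmetry
#' operators (one assembly per asymmetric unit). Solvent fraction uses the
#' classic protein packing constant: solvent = 1 - 1.23/Vm.
#'
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @param mass_au Molecular mass of the asymmetric-unit contents in Dalton.
#' @param z Number of asymmetric units per cell; defaults to the number of
#'   space-group operators.
#' @return A list of class `matthews_result` with fields `vm` (A^3/Da),
#'   `solvent_fraction`, `z` and `mass_au`.
#' @export
matthews_coefficient <- function(cell, sg, mass_au, z = length(sg$ops)) {
  if (!is.finite(mass_au) || mass_au <= 0) stop("mass_au must be positive")
  vm <- cell_volume(cell) / (z * mass_au)
  res <- list(vm = vm, solvent_fraction = 1 - 1.23 / vm, z = z, mass_au = mass_au)
  class(res) <- "matthews_result"
  res
}

#' @export
print.matthews_result <- function(x, ...) {
  cat(sprintf("Vm = %.2f A^3/Da  (z = %d, mass = %.0f Da)  solvent = %.1f%%\n",
              x$vm, x$z, x$mass_au, 100 * x$solvent_fraction))
  invisible(x)
}
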