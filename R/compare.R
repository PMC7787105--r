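#' Map correlation between two phased reflection sets
#'
#' The real-space Pearson correlation between the two maps the sets would
#' synthesize, evaluated exactly in reciprocal space (Parseval) over the
#' matched indices. Because a molecular-replacement solution is only defined
#' up to the space group's permissible origin shifts, the correlation can be
#' maximized over those shifts (`origin_search = TRUE`), which is how
#' synthetic solutions are compared with their ground truth.
#'
#' @param a,b Phased [reflection_set()]s on the same cell/space group.
#' @param origin_search Maximize over permissible origin shifts.
#' @param weights_a,weights_b Optional amplitude weights (e.g. FOM columns).
#' @return List: `cc` (correlation), `shift` (fractional origin shift
#'   applied to `b`).
#' @export
refl_map_cc <- function(a, b, origin_search = TRUE,
                        weights_a = NULL, weights_b = NULL) {
  a <- local_set(a, !is.na(a$phi))
  b <- local_set(b, !is.na(b$phi))
  ea <- refl_expand_full(local_weighted(a, weights_a))
  eb <- refl_expand_full(local_weighted(b, weights_b))
  m <- match(hkl_key(ea$hkl), hkl_key(eb$hkl))
  ok <- !is.na(m)
  fa <- ea$f[ok] * exp(1i * ea$phi[ok] * pi / 180)
  fb <- eb$f[m[ok]] * exp(1i * eb$phi[m[ok]] * pi / 180)
  h <- ea$hkl[ok, , drop = FALSE]
  norm <- sqrt(sum(Mod(fa)^2) * sum(Mod(fb)^2))
  shifts <- origin_shifts(refl_sg(a))
  if (!origin_search || is.null(shifts)) shifts <- matrix(0, 1, 3)
  best <- c(cc = -Inf)
  best_shift <- c(0, 0, 0)
  for (i in seq_len(nrow(shifts))) {
    ph <- exp(-2i * pi * as.vector(h %*% shifts[i, ]))
    cc <- Re(sum(fa * Conj(fb * ph))) / norm
    if (cc > best["cc"]) { best["cc"] <- cc; best_shift <- shifts[i, ] }
  }
  list(cc = unname(best["cc"]), shift = unname(best_shift))
}

# apply a weight column to the amplitudes of a set (internal)
local_weighted <- function(x, w) {
  if (is.null(w)) return(x)
  if (identical(w, "fom")) w <- ifelse(is.na(x$fom), 1, x$fom)
  x$f <- x$f * w
  x
}

#' Shift the origin of a phased reflection set
#'
#' Applies the phase shift corresponding to moving the whole structure by a
#' fractional translation: phi(h) += 360 h.shift. Used to bring a solution
#' expressed on an alternative permissible origin onto a reference origin.
#'
#' @param refl A phased [reflection_set()].
#' @param shift Fractional translation (length 3).
#' @return The shifted set.
#' @export
shift_origin <- function(refl, shift) {
  h <- as.matrix(refl[, c("h", "k", "l")])
  refl$phi <- (refl$phi + 360 * as.vector(h %*% shift)) %% 360
  refl
}

#' Mean phase error between two phased sets
#'
#' Amplitude-weighted mean absolute phase difference (degrees) over matched
#' indices, minimized over permissible origin shifts.
#'
#' @param a,b Phased [reflection_set()]s.
#' @param d_min Restrict the comparison to d >= d_min.
#' @return List: `mean_error` (degrees), `shift`.
#' @export
mean_phase_error <- function(a, b, d_min = 0) {
  a <- resolution_window(a, d_min = d_min)
  ka <- hkl_key(as.matrix(a[, c("h", "k", "l")]))
  kb <- hkl_key(as.matrix(b[, c("h", "k", "l")]))
  m <- match(ka, kb)
  ok <- !is.na(m) & !is.na(a$phi) & !is.na(b$phi[m])
  h <- as.matrix(a[ok, c("h", "k", "l")])
  w <- a$f[ok] * b$f[m[ok]]
  dphi0 <- a$phi[ok] - b$phi[m[ok]]
  shifts <- origin_shifts(refl_sg(a))
  if (is.null(shifts)) shifts <- matrix(0, 1, 3)
  best <- Inf; best_shift <- c(0, 0, 0)
  for (i in seq_len(nrow(shifts))) {
    d <- (dphi0 + 360 * as.vector(h %*% shifts[i, ])) %% 360
    d <- pmin(d, 360 - d)
    e <- sum(w * d) / sum(w)
    if (e < best) { best <- e; best_shift <- shifts[i, ] }
  }
  list(mean_error = best, shift = best_shift)
}
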