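#' Space-group operators
#'
#' Supported groups: P1 and P212121 (the only group needed for ring crystals
#' of the kind this package targets). Operators are stored as pairs of an
#' integer 3x3 rotation part and a fractional translation; they act on
#' fractional coordinates as `x' = R %*% x + t`.
#'
#' @param symbol Hermann-Mauguin symbol; "P1", "P212121" (also accepted:
#'   "P 21 21 21", "P2(1)2(1)2(1)").
#' @return An object of class `space_group` with fields `symbol` and `ops`.
#' @export
space_group <- function(symbol) {
  key <- toupper(gsub("[ ()]", "", symbol))
  ops <- switch(key,
    "P1" = list(list(R = diag(3L), t = c(0, 0, 0))),
    "P212121" = list(
      list(R = diag(c(1L, 1L, 1L)),   t = c(0,   0,   0)),
      list(R = diag(c(-1L, -1L, 1L)), t = c(0.5, 0,   0.5)),
      list(R = diag(c(-1L, 1L, -1L)), t = c(0,   0.5, 0.5)),
      list(R = diag(c(1L, -1L, -1L)), t = c(0.5, 0.5, 0))
    ),
    stop("unsupported space group: ", symbol,
         " (supported: P1, P212121)")
  )
  sg <- list(symbol = if (key == "P1") "P1" else "P212121", ops = ops)
  class(sg) <- "space_group"
  sg
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("space group %s (%d operators)\n", x$symbol, length(x$ops)))
  invisible(x)
}

#' Symmetry-equivalent reflections
#'
#' All indices equivalent to `hkl` under the space-group rotation parts plus
#' Friedel inversion. The set is closed under the group action and contains
#' `hkl` itself.
#'
#' @param hkl Length-3 integer vector.
#' @param sg A [space_group()].
#' @return An m x 3 integer matrix of distinct equivalent indices.
#' @export
sym_equivalents <- function(hkl, sg) {
  h <- matrix(as.integer(hkl), nrow = 1)
  eq <- do.call(rbind, lapply(sg$ops, function(op) h %*% op$R))
  eq <- rbind(eq, -eq)
  unique(eq)
}

# Canonical representative of the orbit of each reflection under
# symmetry + Friedel: the lexicographically largest (h, then k, then l).
# hkl: n x 3 integer matrix. Returns list(rep = n x 3 matrix of
# representatives, phase_shift = phase to ADD (degrees) to transform a phase
# on hkl into a phase on the representative, i.e.
# phi(rep) = s * phi(hkl) + shift with s = +-1 for Friedel parity).
hkl_canonical <- function(hkl, sg) {
  hkl <- rbind3(hkl)
  n <- nrow(hkl)
  nop <- length(sg$ops)
  best <- hkl
  best_key <- hkl_key(hkl)
  best_shift <- rep(0, n)
  best_flip <- rep(1, n)
  for (i in seq_len(nop)) {
    R <- sg$ops[[i]]$R; tr <- sg$ops[[i]]$t
    for (fr in c(1, -1)) {
      cand <- fr * (hkl %*% R)
      # phase on h' = hR is phi(h) - 360 h.t ; Friedel flips the sign
      shift <- -360 * (hkl %*% tr)
      key <- hkl_key(cand)
      take <- key > best_key
      if (any(take)) {
        best[take, ] <- cand[take, , drop = FALSE]
        best_key[take] <- key[take]
        best_shift[take] <- fr * shift[take]
        best_flip[take] <- fr
      }
    }
  }
  list(rep = best, phase_shift = best_shift, friedel = best_flip)
}

# strictly ordering scalar key for lexicographic (h,k,l) comparison
hkl_key <- function(h) {
  (h[, 1] * 4096 + h[, 2]) * 4096 + h[, 3]
}

#' Alternative permissible origins
#'
#' For P212121 the origin may be shifted by any combination of half cell
#' edges; two molecular-replacement solutions differing by such a shift are
#' equivalent. For P1 any shift is permissible (returns NULL).
#'
#' @param sg A [space_group()].
#' @return An 8 x 3 matrix of fractional shifts, or NULL for P1.
#' @export
origin_shifts <- function(sg) {
  if (sg$symbol == "P1") return(NULL)
  as.matrix(expand.grid(c(0, 0.5), c(0, 0.5), c(0, 0.5)))
}
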