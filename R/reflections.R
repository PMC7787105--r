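#' Create a reflection set
#'
#' A reflection set stores one record per symmetry-unique Miller index
#' (Friedel mates merged), together with its unit cell and space group.
#' Amplitude-only workflow: intensities are never stored, anomalous pairs are
#' out of scope.
#'
#' @param hkl n x 3 integer matrix of Miller indices.
#' @param f Observed (or calculated) amplitudes, arbitrary scale, >= 0.
#' @param sigf Amplitude standard uncertainties (>= 0); defaults to 0.
#' @param phi Phases in degrees, or NA when unphased.
#' @param fom Figures of merit in \[0,1\], or NA.
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @param reduce Reduce indices to the canonical symmetry-unique
#'   representative and merge duplicates (mean amplitude)? Default TRUE.
#' @return An object of class `reflection_set`: a data frame with columns
#'   `h,k,l,f,sigf,phi,fom,d` and attributes `cell`, `sg`.
#' @export
reflection_set <- function(hkl, f, sigf = 0, phi = NA_real_, fom = NA_real_,
                           cell, sg, reduce = TRUE) {
  hkl <- rbind3(hkl)
  storage.mode(hkl) <- "integer"
  n <- nrow(hkl)
  if (any(rowSums(abs(hkl)) == 0)) stop("(0,0,0) is not a working reflection")
  if (any(f < 0, na.rm = TRUE)) stop("amplitudes must be >= 0")
  sigf <- rep_len(sigf, n); phi <- rep_len(phi, n); fom <- rep_len(fom, n)
  if (any(sigf < 0, na.rm = TRUE)) stop("sigmas must be >= 0")
  if (reduce) {
    can <- hkl_canonical(hkl, sg)
    phi <- ifelse(is.na(phi), NA_real_,
                  (can$friedel * phi + can$phase_shift) %% 360)
    hkl <- can$rep
    key <- hkl_key(hkl)
    keep <- !duplicated(key)
    if (any(!keep)) {
      f <- as.vector(tapply(f, key, mean)[as.character(key[keep])])
      sigf <- sigf[keep]; phi <- phi[keep]; fom <- fom[keep]
      hkl <- hkl[keep, , drop = FALSE]
    }
  }
  rs <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                   f = f, sigf = sigf, phi = phi, fom = fom,
                   d = d_spacing(hkl, cell))
  rs <- rs[order(-rs$d, rs$h, rs$k, rs$l), ]
  rownames(rs) <- NULL
  attr(rs, "cell") <- cell
  attr(rs, "sg") <- sg
  class(rs) <- c("reflection_set", "data.frame")
  rs
}

#' @export
print.reflection_set <- function(x, ...) {
  cell <- attr(x, "cell"); sg <- attr(x, "sg")
  cat(sprintf("reflection set: %d unique reflections, %.2f-%.2f A, %s\n",
              nrow(x), max(x$d), min(x$d), sg$symbol))
  invisible(x)
}

#' Cell / space group accessors
#' @param refl A [reflection_set()].
#' @return The [unit_cell()] or [space_group()] carried by the set.
#' @export
refl_cell <- function(refl) attr(refl, "cell")

#' @rdname refl_cell
#' @export
refl_sg <- function(refl) attr(refl, "sg")

#' Restrict a reflection set to a resolution window
#'
#' @param refl A [reflection_set()].
#' @param d_max,d_min Low- and high-resolution limits in Angstrom
#'   (`d_max >= d >= d_min`); either may be Inf/0 to leave open.
#' @export
resolution_window <- function(refl, d_max = Inf, d_min = 0) {
  out <- refl[refl$d <= d_max & refl$d >= d_min, ]
  rownames(out) <- NULL
  attributes(out)[c("cell", "sg")] <- attributes(refl)[c("cell", "sg")]
  class(out) <- class(refl)
  out
}

# Expand a unique set to the full sphere (all symmetry equivalents and
# Friedel mates) with correctly transformed phases. Internal; returns a list
# of matrices/vectors, deduplicated on the expanded index.
refl_expand_full <- function(refl, with_phase = TRUE) {
  sg <- refl_sg(refl)
  hkl <- as.matrix(refl[, c("h", "k", "l")])
  out_h <- list(); out_f <- list(); out_phi <- list(); out_src <- list()
  i <- 0L
  for (op in sg$ops) {
    for (fr in c(1, -1)) {
      i <- i + 1L
      out_h[[i]] <- fr * (hkl %*% op$R)
      out_f[[i]] <- refl$f
      if (with_phase)
        out_phi[[i]] <- fr * (refl$phi - 360 * as.vector(hkl %*% op$t))
      out_src[[i]] <- seq_len(nrow(hkl))
    }
  }
  h <- do.call(rbind, out_h)
  f <- unlist(out_f)
  phi <- if (with_phase) unlist(out_phi) %% 360 else NULL
  src <- unlist(out_src)
  keep <- !duplicated(hkl_key(h))
  list(hkl = h[keep, , drop = FALSE], f = f[keep],
       phi = phi[keep], src = src[keep])
}

#' Read / write the reflection text table
#'
#' Whitespace-separated columns `h k l F SIGF [PHI] [FOM]`; lines starting
#' with `#` are comments. The writer embeds the cell and space group as
#' comment lines which the reader recovers, so round trips need no extra
#' arguments. Numeric columns are written with `%.6g` so that write/read/
#' write round trips are bit-identical.
#'
#' @param path File path.
#' @param cell,sg Required if the file lacks `# cell` / `# spacegroup`
#'   comment lines.
#' @return `read_hkl` returns a [reflection_set()]; `write_hkl` returns
#'   `path` invisibly.
#' @export
read_hkl <- function(path, cell = NULL, sg = NULL) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  cm <- grep("^#\\s*cell\\b", meta, value = TRUE)
  if (is.null(cell) && length(cm)) {
    v <- as.numeric(strsplit(trimws(sub("^#\\s*cell", "", cm[1])), "\\s+")[[1]])
    cell <- unit_cell(v[1], v[2], v[3], v[4], v[5], v[6])
  }
  sm <- grep("^#\\s*spacegroup\\b", meta, value = TRUE)
  if (is.null(sg) && length(sm))
    sg <- space_group(trimws(sub("^#\\s*spacegroup", "", sm[1])))
  if (is.null(cell) || is.null(sg))
    stop("cell/space group neither given nor found in file header")
  fields <- strsplit(trimws(body), "\\s+")
  ncol <- lengths(fields)
  if (any(ncol < 5))
    stop("malformed reflection line ", which(ncol < 5)[1], ": expected >= 5 columns")
  m <- matrix(NA_real_, nrow = length(fields), ncol = max(ncol))
  for (i in seq_along(fields))
    m[i, seq_len(ncol[i])] <- suppressWarnings(as.numeric(fields[[i]]))
  if (any(is.na(m[, 1:5])))
    stop("non-numeric field on reflection line ",
         which(apply(is.na(m[, 1:5, drop = FALSE]), 1, any))[1])
  reflection_set(m[, 1:3], f = m[, 4], sigf = m[, 5],
                 phi = if (max(ncol) >= 6) m[, 6] else NA_real_,
                 fom = if (max(ncol) >= 7) m[, 7] else NA_real_,
                 cell = cell, sg = sg, reduce = FALSE)
}

#' @rdname read_hkl
#' @param refl A [reflection_set()] to write.
#' @export
write_hkl <- function(refl, path) {
  cell <- refl_cell(refl); sg <- refl_sg(refl)
  hdr <- c(sprintf("# cell %.6g %.6g %.6g %.6g %.6g %.6g",
                   cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma),
           sprintf("# spacegroup %s", sg$symbol),
           "# h k l F SIGF PHI FOM")
  has_phi <- any(!is.na(refl$phi))
  fmt_num <- function(x) sprintf("%.6g", x)
  rows <- paste(refl$h, refl$k, refl$l, fmt_num(refl$f), fmt_num(refl$sigf))
  if (has_phi)
    rows <- paste(rows, fmt_num(ifelse(is.na(refl$phi), 0, refl$phi)),
                  fmt_num(ifelse(is.na(refl$fom), 1, refl$fom)))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
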