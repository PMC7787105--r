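#' Real-space density grids
#'
#' A `map_grid` samples a scalar field on a regular 3D grid over a unit cell
#' (crystal maps, periodic) or an orthogonal box (EM maps, non-periodic).
#' Voxel `(i,j,k)` (0-based) is centred at fractional coordinate
#' `origin + (i/nx, j/ny, k/nz)`. Boolean masks reuse the same container with
#' values in {0,1}.
#'
#' @param values 3D numeric array (nx, ny, nz); each dimension >= 2.
#' @param cell A [unit_cell()] (for EM maps: the box edge lengths).
#' @param periodic Does the grid wrap (crystal map) or not (EM box)?
#' @param origin Fractional coordinate of voxel (0,0,0). EM boxes centred on
#'   the coordinate origin use `c(-0.5, -0.5, -0.5)`.
#' @return Object of class `map_grid`.
#' @export
map_grid <- function(values, cell, periodic = TRUE, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3 || any(dim(values) < 2))
    stop("map values must be a 3D array with each dimension >= 2")
  m <- list(values = values, cell = cell, periodic = periodic, origin = origin)
  class(m) <- "map_grid"
  m
}

#' @export
print.map_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("map grid %d x %d x %d (%s), pixel %.3f x %.3f x %.3f A, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], if (x$periodic) "periodic" else "box",
              x$cell$a / d[1], x$cell$b / d[2], x$cell$c / d[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Pixel size of a map
#' @param map A [map_grid()].
#' @return Length-3 vector of Angstrom per voxel along each axis.
#' @export
pixel_size <- function(map) {
  d <- dim(map$values)
  c(map$cell$a / d[1], map$cell$b / d[2], map$cell$c / d[3])
}

# smallest 2,3,5-smooth integer >= n (efficient FFT sizes)
good_fft_size <- function(n) {
  n <- as.integer(ceiling(n))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# grid dimensions sampling the cell at <= d_min/rate Angstrom
grid_for_cell <- function(cell, d_min, rate = 3) {
  vapply(c(cell$a, cell$b, cell$c),
         function(len) good_fft_size(rate * len / d_min), integer(1))
}

#' Trilinear interpolation in a map
#'
#' Exact at grid nodes. Periodic maps wrap; box maps return `fill` outside.
#'
#' @param map A [map_grid()].
#' @param points n x 3 matrix of fractional coordinates (or a length-3
#'   vector); use `cartesian = TRUE` to pass orthogonal Angstrom instead.
#' @param cartesian Interpret `points` as Cartesian Angstrom.
#' @param fill Value returned outside a non-periodic box.
#' @return Numeric vector of interpolated values.
#' @export
interpolate_map <- function(map, points, cartesian = FALSE, fill = 0) {
  pts <- rbind3(points)
  if (cartesian) pts <- orth_to_frac(pts, map$cell)
  dims <- dim(map$values)
  # grid coordinate of each point (0-based voxel units)
  g <- sweep(pts, 2, map$origin, "-")
  g <- sweep(g, 2, dims, "*")
  i0 <- floor(g)
  fr <- g - i0
  v <- map$values
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  if (map$periodic) {
    ix0 <- i0[, 1] %% nx; iy0 <- i0[, 2] %% ny; iz0 <- i0[, 3] %% nz
    ix1 <- (ix0 + 1) %% nx; iy1 <- (iy0 + 1) %% ny; iz1 <- (iz0 + 1) %% nz
    inside <- TRUE
  } else {
    inside <- g[, 1] >= 0 & g[, 1] <= nx - 1 &
              g[, 2] >= 0 & g[, 2] <= ny - 1 &
              g[, 3] >= 0 & g[, 3] <= nz - 1
    ix0 <- pmin(pmax(i0[, 1], 0), nx - 1); iy0 <- pmin(pmax(i0[, 2], 0), ny - 1)
    iz0 <- pmin(pmax(i0[, 3], 0), nz - 1)
    ix1 <- pmin(ix0 + 1, nx - 1); iy1 <- pmin(iy0 + 1, ny - 1)
    iz1 <- pmin(iz0 + 1, nz - 1)
  }
  idx <- function(i, j, k) 1 + i + nx * (j + ny * k)
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  out <-
    v[idx(ix0, iy0, iz0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    v[idx(ix1, iy0, iz0)] * fx * (1 - fy) * (1 - fz) +
    v[idx(ix0, iy1, iz0)] * (1 - fx) * fy * (1 - fz) +
    v[idx(ix1, iy1, iz0)] * fx * fy * (1 - fz) +
    v[idx(ix0, iy0, iz1)] * (1 - fx) * (1 - fy) * fz +
    v[idx(ix1, iy0, iz1)] * fx * (1 - fy) * fz +
    v[idx(ix0, iy1, iz1)] * (1 - fx) * fy * fz +
    v[idx(ix1, iy1, iz1)] * fx * fy * fz
  if (!map$periodic && any(!inside)) out[!inside] <- fill
  out
}

#' Pearson correlation between two maps
#'
#' @param a,b [map_grid()]s on the same grid.
#' @param mask Optional mask (a `map_grid` of {0,1} or logical array);
#'   correlation is computed over voxels where the mask is 1.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
map_correlation <- function(a, b, mask = NULL) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("maps are on different grids")
  va <- as.vector(a$values); vb <- as.vector(b$values)
  if (!is.null(mask)) {
    mv <- if (inherits(mask, "map_grid")) mask$values else mask
    sel <- as.vector(mv) > 0.5
    va <- va[sel]; vb <- vb[sel]
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("map correlation undefined: zero variance")
  stats::cor(va, vb)
}

#' Cartesian coordinates of all voxel centres
#' @param map A [map_grid()].
#' @return n_voxel x 3 matrix in the storage order of `map$values`.
#' @export
voxel_centers <- function(map) {
  d <- dim(map$values)
  fr <- cbind(rep((seq_len(d[1]) - 1) / d[1], times = d[2] * d[3]),
              rep(rep((seq_len(d[2]) - 1) / d[2], each = d[1]), times = d[3]),
              rep((seq_len(d[3]) - 1) / d[3], each = d[1] * d[2]))
  fr <- sweep(fr, 2, map$origin, "+")
  frac_to_orth(fr, map$cell)
}

#' Read / write CCP4-MRC density maps
#'
#' Mode-2 (32-bit float) maps with X,Y,Z as fast-to-slow axes (MAPC/R/S =
#' 1,2,3), MRC2014 Angstrom origin words. `write_mrc` refuses maps that are
#' not in that axis order; `read_mrc` rejects other modes/orders rather than
#' permuting silently.
#'
#' @param path File path.
#' @param map A [map_grid()] (for writing).
#' @param periodic Periodicity flag to set on the map read back (the format
#'   does not record it); default TRUE for full-cell maps.
#' @return `read_mrc`: a [map_grid()]. `write_mrc`: `path`, invisibly.
#' @export
read_mrc <- function(path, periodic = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", 10, size = 4, endian = "little")
  nx <- hdr_i[1]; ny <- hdr_i[2]; nz <- hdr_i[3]; mode <- hdr_i[4]
  if (mode != 2) stop("unsupported MRC mode ", mode, " (only mode 2)")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported MRC axis order (MAPC/MAPR/MAPS must be 1,2,3)")
  seek(con, 4 * 49)  # words 50-52: MRC2014 origin in Angstrom
  orig <- readBin(con, "numeric", 3, size = 4, endian = "little")
  seek(con, 1024)
  vals <- readBin(con, "numeric", nx * ny * nz, size = 4, endian = "little")
  cell <- unit_cell(cella[1], cella[2], cella[3], cellb[1], cellb[2], cellb[3])
  map_grid(array(vals, c(nx, ny, nz)), cell, periodic = periodic,
           origin = orig / cella)
}

#' @rdname read_mrc
#' @export
write_mrc <- function(map, path) {
  d <- dim(map$values)
  cell <- map$cell
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(d, 2L))                       # NX NY NZ MODE
  wi(c(0L, 0L, 0L))                  # NXSTART..
  wi(d)                              # MX MY MZ
  wf(c(cell$a, cell$b, cell$c))      # CELLA
  wf(c(cell$alpha, cell$beta, cell$gamma))
  wi(c(1L, 2L, 3L))                  # MAPC MAPR MAPS
  v <- map$values
  wf(c(min(v), max(v), mean(v)))     # DMIN DMAX DMEAN
  wi(c(1L, 0L))                      # ISPG NSYMBT
  wi(rep(0L, 25))                    # EXTRA (words 25-49)
  wf(map$origin * c(cell$a, cell$b, cell$c))  # ORIGIN (A, words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(v)))        # RMS
  wi(0L)                             # NLABL
  writeBin(raw(800), con)            # empty labels
  wf(as.vector(v))
  invisible(path)
}
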