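#' Atomic models
#'
#' An atomic model is a data frame of class `atomic_model` with one row per
#' atom and columns `serial`, `name` (atom label, e.g. "CA"), `res_name`
#' (3-letter code), `chain` (single character), `res_seq` (integer),
#' `x`, `y`, `z` (orthogonal Angstrom), `occ`, `b` (isotropic B, A^2) and
#' `element`.
#'
#' @param atoms A data frame with (at least) the columns above.
#' @return The data frame, validated, with class `atomic_model`.
#' @export
atomic_model <- function(atoms) {
  req <- c("serial", "name", "res_name", "chain", "res_seq",
           "x", "y", "z", "occ", "b", "element")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("missing atom columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$element))) stop("empty element symbols")
  atoms <- as.data.frame(atoms)[, req]
  rownames(atoms) <- NULL
  class(atoms) <- c("atomic_model", "data.frame")
  atoms
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic model: %d atoms, %d residues, chains %s\n",
              nrow(x), nrow(unique(x[, c("chain", "res_seq")])),
              paste(unique(x$chain), collapse = "")))
  invisible(x)
}

#' Coordinate helpers
#' @param model An [atomic_model()].
#' @return `model_xyz`: n x 3 coordinate matrix. `model_centroid`: length-3
#'   vector. `set_model_xyz`: the model with replaced coordinates.
#' @export
model_xyz <- function(model) as.matrix(model[, c("x", "y", "z")])

#' @rdname model_xyz
#' @param xyz Replacement n x 3 coordinate matrix.
#' @export
set_model_xyz <- function(model, xyz) {
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

#' @rdname model_xyz
#' @param ca_only Use CA atoms only.
#' @export
model_centroid <- function(model, ca_only = FALSE) {
  if (ca_only) model <- model[model$name == "CA", ]
  colMeans(model_xyz(model))
}

#' Read a PDB file
#'
#' Fixed-width parser for ATOM/HETATM records (wwPDB v3.3 columns). Other
#' record types are ignored. Coordinates, occupancy, B factor, chain and
#' element columns are preserved; a malformed numeric field raises an error
#' naming the offending line.
#'
#' @param path Path to a PDB file.
#' @return An [atomic_model()].
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  sel <- which(rec == "ATOM  " | rec == "HETATM")
  if (!length(sel)) stop("no ATOM/HETATM records in ", path)
  ln <- lines[sel]
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(ln, from, to)))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed %s field in PDB line %d: '%s'",
                   what, sel[bad[1]], lines[sel[bad[1]]]))
    v
  }
  element <- trimws(substr(ln, 77, 78))
  # infer element from the atom-name column when absent (old files)
  name <- trimws(substr(ln, 13, 16))
  element[!nzchar(element)] <- substr(gsub("[^A-Za-z].*", "",
                                           name[!nzchar(element)]), 1, 1)
  atomic_model(data.frame(
    serial = as.integer(num(7, 11, "serial")),
    name = name,
    res_name = trimws(substr(ln, 18, 20)),
    chain = substr(ln, 22, 22),
    res_seq = as.integer(num(23, 26, "residue number")),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occ = num(55, 60, "occupancy"), b = num(61, 66, "B factor"),
    element = element))
}

#' Write a PDB file
#'
#' Fixed-width ATOM records; coordinates to 3 decimals (the format's
#' precision), occupancy/B to 2. A TER record closes each chain.
#'
#' @param model An [atomic_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  # atom-name column convention: names of 1-3 chars for 1-letter elements
  # start in column 14
  nm <- ifelse(nchar(model$name) >= 4 | nchar(model$element) == 2,
               sprintf("%-4s", model$name), sprintf(" %-3s", model$name))
  recs <- sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  model$serial %% 100000L, nm, model$res_name, model$chain,
                  model$res_seq, model$x, model$y, model$z,
                  model$occ, model$b, model$element)
  # interleave TER records at chain ends
  last <- cumsum(rle(model$chain)$lengths)
  out <- character(length(recs) + length(last) + 1)
  j <- 1
  for (i in seq_along(recs)) {
    out[j] <- recs[i]; j <- j + 1
    if (i %in% last) { out[j] <- "TER"; j <- j + 1 }
  }
  out[j] <- "END"
  writeLines(out[seq_len(j)], path)
  invisible(path)
}
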