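#' Molecular structure container
#'
#' A molecular structure is an ordered list of atoms with element symbols and
#' 3D Cartesian coordinates in Angstrom. Atom order is stable and meaningful:
#' label schemes and atom-group definitions index into it.
#'
#' @param elements Character vector of element symbols.
#' @param xyz Numeric matrix, one row per atom, columns x, y, z (Angstrom).
#' @param name Optional structure name.
#' @return An object of class `mol_structure` with fields `elements`, `Z`,
#'   `xyz` and `name`.
#' @examples
#' co <- molecular_structure(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.128)))
#' internuclear_distances(co)
#' @export
molecular_structure <- function(elements, xyz, name = "") {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (length(elements) < 1L) stop("structure must contain at least one atom")
  if (nrow(xyz) != length(elements) || ncol(xyz) != 3L) {
    stop("xyz must be a length(elements) x 3 matrix")
  }
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  structure(
    list(elements = as.character(elements), Z = element_to_z(elements),
         xyz = unname(xyz), name = as.character(name)[1L]),
    class = "mol_structure"
  )
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("<mol_structure> %s: %d atoms (%s)\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              length(x$elements),
              paste(unique(x$elements), collapse = ", ")))
  invisible(x)
}

n_atoms <- function(structure) length(structure$elements)

#' All pairwise internuclear distances
#'
#' Returns the N(N-1)/2 distances R_ij (i < j) in Angstrom. The
#' orientation-averaged scattering signal of a molecule depends on its
#' geometry only through this distance multiset.
#'
#' @param structure A [molecular_structure()].
#' @return Numeric vector of distances (empty for a single atom), ordered as
#'   the rows of `t(combn(N, 2))`.
#' @export
internuclear_distances <- function(structure) {
  stopifnot(inherits(structure, "mol_structure"))
  n <- n_atoms(structure)
  if (n < 2L) return(numeric(0))
  d <- stats::dist(structure$xyz)
  # stats::dist orders pairs (1,2),(1,3),...,(1,n),(2,3),... = combn order
  as.numeric(d)
}

# Index pairs (i, j), i < j, in the same order as internuclear_distances().
atom_pairs <- function(n) {
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i, j)
}

# Centroid (unweighted mean position) of a structure, Angstrom.
centroid <- function(structure) colMeans(structure$xyz)

# Translate coordinates so the centroid sits at the origin.
center_structure <- function(structure) {
  structure$xyz <- sweep(structure$xyz, 2L, centroid(structure))
  structure
}

#' Read a molecular structure from an XYZ file
#'
#' Standard XYZ dialect: an atom-count line, a comment line, then one
#' `element x y z` row per atom with coordinates in Angstrom.
#'
#' @param path Path to an XYZ file.
#' @return A [molecular_structure()]; the comment line is kept as `name`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines)))))]
  if (length(lines) < 3L) stop("XYZ file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) stop("malformed atom-count line in ", path)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    stop(sprintf("XYZ count line says %d atoms but %d atom rows found in %s",
                 n, length(body), path))
  }
  tok <- strsplit(trimws(body), "\\s+")
  if (any(lengths(tok) < 4L)) stop("malformed atom row in ", path)
  elements <- vapply(tok, `[[`, "", 1L)
  xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("non-numeric coordinate in ", path)
  molecular_structure(elements, xyz, name = trimws(lines[2L]))
}

#' Write a molecular structure to an XYZ file
#'
#' @param structure A [molecular_structure()].
#' @param path Output path.
#' @param comment Comment line; defaults to the structure name.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path, comment = structure$name) {
  stopifnot(inherits(structure, "mol_structure"))
  rows <- sprintf("%-2s %15.8f %15.8f %15.8f", structure$elements,
                  structure$xyz[, 1L], structure$xyz[, 2L], structure$xyz[, 3L])
  writeLines(c(as.character(n_atoms(structure)), comment, rows), path)
  invisible(path)
}
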