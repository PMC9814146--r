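#' Label schemes: structures as real-valued label vectors
#'
#' A label scheme is the fixed, bidirectional mapping between a molecular
#' geometry and the vector of real numbers the CNN regresses. Distances are
#' in Angstrom and angles in degrees, unnormalized (min-max scaling happens
#' inside training, using training-split statistics only).
#'
#' Three kinds are provided:
#' \describe{
#'   \item{`scheme_c2h2()`}{symmetric linear acetylene H-C-C-H, labels
#'     `(R_CC, R_CH)` in Angstrom; atoms ordered H, C, C, H along +z.}
#'   \item{`scheme_cs2()`}{carbon disulfide S-C-S, polar labels
#'     `(R_CS, theta_SCS)` in Angstrom and degrees; the molecule bends in
#'     the xz-plane with the angle bisector along +z.}
#'   \item{`scheme_cartesian()`}{the flattened `(x, y, z)` Cartesian
#'     coordinates of a set of tracked atoms of a base structure; untracked
#'     atoms keep their base-structure positions when a structure is rebuilt
#'     from labels.}
#' }
#'
#' All reconstructed structures are centered at their centroid, with linear
#' molecules along +z: orientation-averaged scattering only sees pair
#' distances, so the convention is fixed purely for reproducible labels.
#'
#' @param tracked_atoms Integer indices of the atoms whose coordinates form
#'   the label vector (`scheme_cartesian`).
#' @param base_structure A [molecular_structure()] supplying elements and the
#'   positions of untracked atoms (`scheme_cartesian`).
#' @return An object of class `label_scheme`.
#' @name label_scheme
NULL

new_label_scheme <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "label_scheme")
}

#' @rdname label_scheme
#' @export
scheme_c2h2 <- function() {
  new_label_scheme("c2h2", label_names = c("R_CC", "R_CH"))
}

#' @rdname label_scheme
#' @export
scheme_cs2 <- function() {
  new_label_scheme("cs2", label_names = c("R_CS", "theta_SCS"))
}

#' @rdname label_scheme
#' @export
scheme_cartesian <- function(base_structure, tracked_atoms = seq_along(base_structure$elements)) {
  stopifnot(inherits(base_structure, "mol_structure"))
  tracked_atoms <- as.integer(tracked_atoms)
  if (length(tracked_atoms) < 1L ||
      any(tracked_atoms < 1L | tracked_atoms > n_atoms(base_structure)) ||
      anyDuplicated(tracked_atoms)) {
    stop("tracked_atoms must be distinct valid atom indices")
  }
  nm <- as.vector(t(outer(tracked_atoms, c("x", "y", "z"),
                          function(i, a) paste0(a, i))))
  new_label_scheme("cartesian", base_structure = base_structure,
                   tracked_atoms = tracked_atoms, label_names = nm)
}

#' @export
print.label_scheme <- function(x, ...) {
  cat(sprintf("<label_scheme> kind = %s, %d label(s): %s\n", x$kind,
              label_dim(x), paste(x$label_names, collapse = ", ")))
  invisible(x)
}

#' Number of labels in a scheme
#' @param scheme A `label_scheme`.
#' @return Integer label-vector length.
#' @export
label_dim <- function(scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  length(scheme$label_names)
}

#' Build a structure from a label vector
#'
#' Inverse of [structure_labels()]: reconstructs the molecular geometry that
#' a label vector describes, following the scheme's coordinate convention.
#'
#' @param scheme A `label_scheme`.
#' @param params Numeric label vector (Angstrom / degrees).
#' @return A [molecular_structure()].
#' @examples
#' s <- structure_from_params(scheme_c2h2(), c(1.20, 1.06))
#' internuclear_distances(s)
#' @export
structure_from_params <- function(scheme, params) {
  stopifnot(inherits(scheme, "label_scheme"))
  params <- as.numeric(params)
  if (length(params) != label_dim(scheme)) {
    stop(sprintf("expected %d label(s), got %d", label_dim(scheme),
                 length(params)))
  }
  if (!all(is.finite(params))) stop("labels must be finite")
  switch(scheme$kind,
    c2h2 = {
      r_cc <- params[1L]; r_ch <- params[2L]
      if (r_cc <= 0 || r_ch <= 0) stop("distances must be positive")
      z <- c(-(r_cc / 2 + r_ch), -r_cc / 2, r_cc / 2, r_cc / 2 + r_ch)
      molecular_structure(c("H", "C", "C", "H"),
                          cbind(0, 0, z), name = "C2H2")
    },
    cs2 = {
      r_cs <- params[1L]; th <- params[2L]
      if (r_cs <= 0) stop("distances must be positive")
      if (th <= 0 || th > 180) stop("angle must lie in (0, 180] degrees")
      half <- th / 2 * pi / 180
      xyz <- rbind(c(r_cs * sin(half), 0, r_cs * cos(half)),
                   c(0, 0, 0),
                   c(-r_cs * sin(half), 0, r_cs * cos(half)))
      center_structure(molecular_structure(c("S", "C", "S"), xyz,
                                           name = "CS2"))
    },
    cartesian = {
      s <- scheme$base_structure
      s$xyz[scheme$tracked_atoms, ] <- matrix(params, ncol = 3L, byrow = TRUE)
      s
    },
    stop("unknown scheme kind: ", scheme$kind)
  )
}

#' Extract the label vector of a structure
#'
#' @param scheme A `label_scheme`.
#' @param structure A [molecular_structure()] compatible with the scheme.
#' @return Numeric label vector; `structure_labels(scheme,
#'   structure_from_params(scheme, v))` recovers `v` to 1e-9 in label units.
#' @export
structure_labels <- function(scheme, structure) {
  stopifnot(inherits(scheme, "label_scheme"),
            inherits(structure, "mol_structure"))
  switch(scheme$kind,
    c2h2 = {
      if (!identical(structure$elements, c("H", "C", "C", "H"))) {
        stop("c2h2 scheme expects atoms ordered H, C, C, H")
      }
      x <- structure$xyz
      r_cc <- sqrt(sum((x[2L, ] - x[3L, ])^2))
      r_ch <- (sqrt(sum((x[1L, ] - x[2L, ])^2)) +
               sqrt(sum((x[4L, ] - x[3L, ])^2))) / 2
      c(r_cc, r_ch)
    },
    cs2 = {
      if (!identical(structure$elements, c("S", "C", "S"))) {
        stop("cs2 scheme expects atoms ordered S, C, S")
      }
      x <- structure$xyz
      v1 <- x[1L, ] - x[2L, ]; v2 <- x[3L, ] - x[2L, ]
      r_cs <- (sqrt(sum(v1^2)) + sqrt(sum(v2^2))) / 2
      cr <- c(v1[2L] * v2[3L] - v1[3L] * v2[2L],
              v1[3L] * v2[1L] - v1[1L] * v2[3L],
              v1[1L] * v2[2L] - v1[2L] * v2[1L])
      # atan2 form is accurate for near-linear geometries where acos is not
      th <- atan2(sqrt(sum(cr^2)), sum(v1 * v2)) * 180 / pi
      c(r_cs, th)
    },
    cartesian = as.vector(t(structure$xyz[scheme$tracked_atoms, , drop = FALSE])),
    stop("unknown scheme kind: ", scheme$kind)
  )
}
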