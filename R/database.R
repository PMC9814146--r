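#' Deformation specification for structure databases
#'
#' Defines how a database of candidate structures is generated. Two modes:
#' \describe{
#'   \item{`"parameter-grid"`}{deform along the internal coordinates of a
#'     label scheme. Each parameter has a `(min, max)` range and either a
#'     step count (regular grid, database size = product of step counts) or
#'     uniform random sampling of `count` structures.}
#'   \item{`"group-deformation"`}{rigid translations of a few atom groups of
#'     a base structure plus a molecule-wide global scale, sampled uniformly;
#'     the mode used for large molecules where a full internal-coordinate
#'     grid is intractable.}
#' }
#'
#' @param mode `"parameter-grid"` or `"group-deformation"`.
#' @param scheme The [label_scheme] that converts sampled structures to label
#'   vectors (and, in grid mode, parameter vectors to structures).
#' @param parameters Grid mode: a named list, one entry per label, each a
#'   list with `min`, `max` and optionally `n_steps` (regular grid).
#' @param sampling `"grid"` (requires `n_steps` everywhere) or `"uniform"`
#'   (requires `count`).
#' @param count Number of structures for random sampling modes.
#' @param base_structure Group mode: the [molecular_structure()] being
#'   deformed.
#' @param groups Group mode: list of disjoint atom-index vectors.
#' @param shift_range Group mode: `(min, max)` of each per-axis rigid group
#'   shift, Angstrom.
#' @param global_scale `(min, max)` of the molecule-wide multiplicative
#'   scale factor applied about the centroid.
#' @param seed Integer seed making the database reproducible.
#' @return An object of class `deformation_spec`.
#' @export
deformation_spec <- function(mode = c("parameter-grid", "group-deformation"),
                             scheme,
                             parameters = NULL,
                             sampling = c("grid", "uniform"),
                             count = NULL,
                             base_structure = NULL,
                             groups = NULL,
                             shift_range = c(-0.3, 0.3),
                             global_scale = c(0.9, 1.1),
                             seed = 1L) {
  mode <- match.arg(mode)
  sampling <- match.arg(sampling)
  stopifnot(inherits(scheme, "label_scheme"))
  if (mode == "parameter-grid") {
    if (is.null(parameters) || length(parameters) == 0L) {
      stop("parameter-grid mode requires a non-empty parameter list")
    }
    if (length(parameters) != label_dim(scheme)) {
      stop("need one parameter definition per scheme label")
    }
    for (p in parameters) {
      if (p$min > p$max) stop("parameter range must have min <= max")
      if (sampling == "grid" && (is.null(p$n_steps) || p$n_steps < 1L)) {
        stop("grid sampling requires n_steps >= 1 for every parameter")
      }
    }
    if (sampling == "uniform" && (is.null(count) || count <= 0L)) {
      stop("uniform sampling requires a positive count")
    }
  } else {
    stopifnot(inherits(base_structure, "mol_structure"))
    if (is.null(groups) || length(groups) == 0L) stop("groups must be given")
    idx <- unlist(groups)
    if (any(idx < 1L | idx > n_atoms(base_structure))) {
      stop("group indices out of range")
    }
    if (anyDuplicated(idx)) stop("atom groups must be disjoint")
    if (is.null(count) || count <= 0L) {
      stop("group-deformation mode requires a positive count")
    }
    if (shift_range[1L] > shift_range[2L] ||
        global_scale[1L] > global_scale[2L] || global_scale[1L] <= 0) {
      stop("invalid shift_range or global_scale")
    }
  }
  structure(list(mode = mode, scheme = scheme, parameters = parameters,
                 sampling = sampling, count = count,
                 base_structure = base_structure,
                 groups = lapply(groups, as.integer),
                 shift_range = as.numeric(shift_range),
                 global_scale = as.numeric(global_scale),
                 seed = as.integer(seed)),
            class = "deformation_spec")
}

#' Apply rigid group shifts and a global scale to a structure
#'
#' Each atom group is rigidly translated by its shift vector; afterwards all
#' coordinates are scaled by `scale` about the centroid of the shifted
#' structure. Atoms outside every group move only through the global scale.
#'
#' @param spec A group-deformation [deformation_spec()] (supplies the base
#'   structure and groups).
#' @param group_shifts List (or 3-column matrix) of one xyz shift vector per
#'   group, Angstrom.
#' @param scale Positive global scale factor.
#' @return The deformed [molecular_structure()].
#' @export
apply_group_deformation <- function(spec, group_shifts, scale = 1) {
  stopifnot(inherits(spec, "deformation_spec"))
  if (spec$mode != "group-deformation") {
    stop("apply_group_deformation needs a group-deformation spec")
  }
  deform_structure(spec$base_structure, spec$groups, group_shifts, scale)
}

deform_structure <- function(structure, groups, group_shifts, scale = 1) {
  if (is.matrix(group_shifts)) {
    group_shifts <- lapply(seq_len(nrow(group_shifts)),
                           function(i) group_shifts[i, ])
  }
  if (length(group_shifts) != length(groups)) {
    stop("need exactly one shift vector per group")
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("scale must be a positive scalar")
  }
  xyz <- structure$xyz
  for (g in seq_along(groups)) {
    sh <- as.numeric(group_shifts[[g]])
    if (length(sh) != 3L || !all(is.finite(sh))) {
      stop("each group shift must be a finite 3-vector")
    }
    xyz[groups[[g]], ] <- sweep(xyz[groups[[g]], , drop = FALSE], 2L, -sh)
  }
  ctr <- colMeans(xyz)
  xyz <- sweep(sweep(xyz, 2L, ctr) * scale, 2L, -ctr)
  structure$xyz <- xyz
  structure
}

#' Generate a structure database
#'
#' Produces the set of candidate structures and their label vectors that the
#' CNN is trained on: a coarse but representative sweep of the solution
#' space from which the network learns (and interpolates) the map between
#' interference patterns and geometry.
#'
#' @param spec A [deformation_spec()].
#' @return A list with `structures` (list of [molecular_structure()]),
#'   `labels` (matrix, one row per structure, columns named after the scheme
#'   labels) and `scheme`. Deterministic for a fixed `spec$seed`.
#' @examples
#' spec <- deformation_spec("parameter-grid", scheme_c2h2(),
#'   parameters = list(R_CC = list(min = 1.0, max = 1.4, n_steps = 5),
#'                     R_CH = list(min = 0.86, max = 1.26, n_steps = 5)))
#' db <- generate_database(spec)
#' nrow(db$labels)  # 25
#' @export
generate_database <- function(spec) {
  stopifnot(inherits(spec, "deformation_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  if (spec$mode == "parameter-grid") {
    if (spec$sampling == "grid") {
      axes <- lapply(spec$parameters, function(p) {
        if (p$n_steps == 1L) (p$min + p$max) / 2
        else seq(p$min, p$max, length.out = p$n_steps)
      })
      labels <- as.matrix(do.call(expand.grid, axes))
    } else {
      labels <- vapply(spec$parameters,
                       function(p) stats::runif(spec$count, p$min, p$max),
                       numeric(spec$count))
      if (spec$count == 1L) labels <- matrix(labels, nrow = 1L)
    }
    colnames(labels) <- spec$scheme$label_names
    structures <- lapply(seq_len(nrow(labels)), function(i) {
      structure_from_params(spec$scheme, labels[i, ])
    })
  } else {
    ng <- length(spec$groups)
    n <- spec$count
    shifts <- array(stats::runif(n * ng * 3L, spec$shift_range[1L],
                                 spec$shift_range[2L]),
                    dim = c(n, ng, 3L))
    scales <- stats::runif(n, spec$global_scale[1L], spec$global_scale[2L])
    structures <- vector("list", n)
    labels <- matrix(0, n, label_dim(spec$scheme),
                     dimnames = list(NULL, spec$scheme$label_names))
    for (i in seq_len(n)) {
      s <- deform_structure(spec$base_structure, spec$groups,
                            lapply(seq_len(ng), function(g) shifts[i, g, ]),
                            scales[i])
      # centroid frame: group shifts also translate the molecule as a
      # whole, but orientation-averaged scattering is blind to rigid
      # translation, so absolute-coordinate labels would carry an
      # unlearnable offset; the package convention reports structures
      # centered at their centroid
      s <- center_structure(s)
      structures[[i]] <- s
      labels[i, ] <- structure_labels(spec$scheme, s)
    }
  }
  list(structures = structures, labels = unname(labels) |>
         `colnames<-`(spec$scheme$label_names), scheme = spec$scheme)
}

# Save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
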