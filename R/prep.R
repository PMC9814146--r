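#' Normalize a DCS map to unit sum
#'
#' Division by the map total puts simulated and measured maps on the same
#' scale (removing any overall fitting factor) and makes difference maps
#' integrate to zero. Scale-invariant: `normalize_map(c * M) ==
#' normalize_map(M)` for any `c > 0`.
#'
#' @param values Numeric matrix with a positive total.
#' @return Matrix of the same shape summing to 1.
#' @export
normalize_map <- function(values) {
  if (inherits(values, "dcs_map")) values <- values$values
  if (!any(values > 0)) stop("map has no strictly positive entry")
  tot <- sum(values)
  if (!is.finite(tot) || tot <= 0) stop("map total must be positive")
  values / tot
}

#' Equilibrium-difference map
#'
#' Subtracts the normalized reference (equilibrium-structure) map from the
#' normalized input map. The smooth atomic background cancels, leaving the
#' interference fringe pattern that encodes the structural deformation; this
#' is the image the CNN consumes.
#'
#' @param map,reference `dcs_map` objects (or plain matrices) on identical
#'   grids.
#' @return Object of class `dcs_diff` with `grid`, signed `values` summing
#'   to 0, and `reference_name`.
#' @export
difference_map <- function(map, reference) {
  if (inherits(map, "dcs_map") && inherits(reference, "dcs_map")) {
    if (!grids_identical(map$grid, reference$grid)) {
      stop("map and reference are on different grids")
    }
    grid <- map$grid
    ref_name <- reference$structure_name
    m <- map$values; r <- reference$values
  } else {
    m <- as.matrix(map); r <- as.matrix(reference)
    if (!all(dim(m) == dim(r))) stop("map and reference shapes differ")
    grid <- NULL; ref_name <- ""
  }
  structure(list(grid = grid, values = normalize_map(m) - normalize_map(r),
                 reference_name = ref_name),
            class = "dcs_diff")
}

#' Assemble a training dataset from a structure database
#'
#' Simulates the 2D-DCS of every database structure, forms its
#' equilibrium-difference map, and splits the (input image, label vector)
#' pairs into training / validation / test sets with a seeded shuffle.
#' Label min-max statistics are computed from the training split only.
#'
#' @param database Result of [generate_database()].
#' @param reference A [molecular_structure()] used as the subtraction
#'   reference (conventionally the equilibrium geometry).
#' @param grid A [dcs_grid()].
#' @param model An [amplitude_model()].
#' @param fractions Positive train/validation/test fractions summing to 1.
#' @param seed Integer seed for the split shuffle.
#' @param progress Print a note every 1000 simulated maps?
#' @return Object of class `dcs_dataset`: `inputs` (pixels x n matrix of
#'   flattened difference maps), `labels` (n x d matrix), `scheme`, `grid`,
#'   `splits` (disjoint index sets covering all entries), `label_stats`
#'   (train-split per-dimension min/max) and `reference_name`.
#' @export
assemble_dataset <- function(database, reference, grid, model,
                             fractions = c(0.8, 0.1, 0.1), seed = 1L,
                             progress = FALSE) {
  stopifnot(inherits(reference, "mol_structure"), inherits(grid, "dcs_grid"))
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three positive values that sum to 1")
  }
  n <- length(database$structures)
  ref_norm <- normalize_map(dcs_map(reference, model, grid)$values)
  npx <- length(ref_norm)
  inputs <- matrix(0, npx, n)
  for (i in seq_len(n)) {
    m <- dcs_map(database$structures[[i]], model, grid)
    inputs[, i] <- as.vector(normalize_map(m$values) - ref_norm)
    if (progress && i %% 1000L == 0L) message("  simulated ", i, "/", n)
  }
  labels <- database$labels
  splits <- split_indices(n, fractions, seed)
  if (any(lengths(splits) == 0L)) {
    stop("database too small: an assigned split is empty")
  }
  tr <- labels[splits$train, , drop = FALSE]
  structure(list(inputs = inputs, labels = labels, scheme = database$scheme,
                 grid = grid, splits = splits,
                 label_stats = list(min = apply(tr, 2L, min),
                                    max = apply(tr, 2L, max)),
                 reference_name = reference$name),
            class = "dcs_dataset")
}

split_indices <- function(n, fractions, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- floor(fractions[1L] * n)
  n_val <- floor(fractions[2L] * n)
  list(train = sort(idx[seq_len(n_train)]),
       validation = sort(idx[n_train + seq_len(n_val)]),
       test = sort(idx[(n_train + n_val + 1L):n][seq_len(n - n_train - n_val)]))
}

#' @export
print.dcs_dataset <- function(x, ...) {
  cat(sprintf("<dcs_dataset> %d maps (%d px), %d label(s); split %d/%d/%d\n",
              ncol(x$inputs), nrow(x$inputs), ncol(x$labels),
              length(x$splits$train), length(x$splits$validation),
              length(x$splits$test)))
  invisible(x)
}

#' Synthesize a counting-statistics measurement of a DCS map
#'
#' Emulates a detector accumulating a finite number of rescattering events:
#' each pixel draws from a Poisson distribution whose mean is the normalized
#' map intensity times `total_counts`.
#'
#' @param map A `dcs_map`.
#' @param total_counts Expected total number of detected events (> 0).
#' @param seed Integer seed; fixed seed gives identical counts.
#' @return Object of class `counts_map` with `grid`, integer `counts` and
#'   `total_counts` (the realized sum of the drawn counts).
#' @export
poissonize <- function(map, total_counts, seed = 1L) {
  stopifnot(inherits(map, "dcs_map"))
  if (total_counts <= 0) stop("total_counts must be positive")
  p <- normalize_map(map$values)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  counts <- matrix(stats::rpois(length(p), p * total_counts),
                   nrow(p), ncol(p))
  structure(list(grid = map$grid, counts = counts,
                 total_counts = sum(counts)),
            class = "counts_map")
}

#' Poisson error extrema of a counts map
#'
#' The one-standard-error envelope of a counting measurement: per pixel the
#' lower map is `counts - sqrt(counts)` (clipped at zero) and the upper map
#' is `counts + sqrt(counts)`. Feeding both extrema through the retrieval
#' bounds the structural uncertainty induced by shot noise.
#'
#' @param counts A `counts_map`.
#' @return List of two `dcs_map` objects, `lower` and `upper`, on the counts
#'   grid.
#' @export
poisson_extrema <- function(counts) {
  stopifnot(inherits(counts, "counts_map"))
  s <- sqrt(counts$counts)
  mk <- function(v, nm) {
    structure(list(grid = counts$grid, values = v, atom = NULL,
                   coherent = NULL, structure_name = nm), class = "dcs_map")
  }
  list(lower = mk(pmax(counts$counts - s, 0), "poisson-lower"),
       upper = mk(counts$counts + s, "poisson-upper"))
}

#' Convert a counts map to a DCS map
#'
#' @param counts A `counts_map`.
#' @return A `dcs_map` whose values are the raw counts (normalization
#'   happens downstream in [difference_map()]).
#' @export
counts_to_map <- function(counts) {
  stopifnot(inherits(counts, "counts_map"))
  structure(list(grid = counts$grid, values = counts$counts + 0,
                 atom = NULL, coherent = NULL,
                 structure_name = "poisson-counts"), class = "dcs_map")
}
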