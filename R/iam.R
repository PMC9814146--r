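#' Momentum transfer of an elastic rescattering event
#'
#' For an electron that returns to its parent ion with kinetic energy `E_r`
#' (eV) and is elastically deflected by `theta_r` (degrees), the momentum
#' transfer is `q = 2 k sin(theta_r / 2)` with `k = sqrt(2 E_r)` in Hartree
#' atomic units. `q` is the Fourier conjugate of internuclear distance.
#'
#' @param E_r Return energy, eV (vectorized).
#' @param theta_r Rescattering angle, degrees in `[0, 180]` (vectorized).
#' @return Momentum transfer in inverse bohr.
#' @examples
#' momentum_transfer(100, 180)  # backscattering, ~5.42 a.u.
#' @export
momentum_transfer <- function(E_r, theta_r) {
  if (any(E_r <= 0)) stop("return energy must be positive")
  if (any(theta_r < 0 | theta_r > 180)) {
    stop("rescattering angle must lie in [0, 180] degrees")
  }
  k <- sqrt(2 * E_r / HARTREE_EV)
  2 * k * sin(theta_r / 2 * pi / 180)
}

#' Atomic scattering-amplitude model
#'
#' The independent atomic model needs an elastic scattering amplitude
#' `f(Z, q)` per element. The default, self-contained provider is the
#' screened-Born single-Yukawa form `f(q) = 2 Z / (q^2 + alpha_Z^2)` with the
#' Thomas-Fermi screening constant `alpha_Z = Z^(1/3) / 0.88534` (inverse
#' bohr): real, strictly positive, strictly decreasing in `q`, and tending to
#' the Rutherford limit `2 Z / q^2`. A `"tabulated"` provider accepts
#' user-supplied multi-Yukawa fits `f(q) = sum_j A_j / (q^2 + b_j^2)` per
#' element for fidelity upgrades; providers returning complex amplitudes are
#' out of scope (the interference term below needs `Re(f_i f_j*)`, which for
#' the packaged real-valued providers is just the product).
#'
#' @param kind `"screened-born"` (default) or `"tabulated"`.
#' @param table For `"tabulated"`: named list keyed by atomic number, each
#'   entry a list with numeric vectors `A` and `b`.
#' @return An object of class `amplitude_model`.
#' @export
amplitude_model <- function(kind = c("screened-born", "tabulated"),
                            table = NULL) {
  kind <- match.arg(kind)
  if (kind == "tabulated") {
    if (is.null(table) || is.null(names(table))) {
      stop("tabulated provider requires a table keyed by atomic number")
    }
    for (el in table) stopifnot(length(el$A) == length(el$b), all(el$b > 0))
  }
  structure(list(kind = kind, table = table), class = "amplitude_model")
}

#' Atomic scattering amplitude f(Z, q)
#'
#' @param model An [amplitude_model()].
#' @param Z Atomic number (scalar).
#' @param q Momentum transfer, inverse bohr (vectorized), `q >= 0`.
#' @return Amplitude in atomic units.
#' @examples
#' atomic_amplitude(amplitude_model(), Z = 1, q = 0)  # 2 * 0.88534^2
#' @export
atomic_amplitude <- function(model, Z, q) {
  stopifnot(inherits(model, "amplitude_model"))
  if (any(q < 0)) stop("q must be non-negative")
  if (model$kind == "screened-born") {
    alpha <- Z^(1 / 3) / 0.88534
    2 * Z / (q^2 + alpha^2)
  } else {
    el <- model$table[[as.character(Z)]]
    if (is.null(el)) stop("no tabulated amplitude for Z = ", Z)
    f <- 0
    for (j in seq_along(el$A)) f <- f + el$A[j] / (q^2 + el$b[j]^2)
    f
  }
}

# sin(x)/x with the limit value 1 at x = 0.
sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

#' Independent-atomic-model DCS at one kinematic point
#'
#' Orientation-averaged elastic differential cross-section of a molecule:
#' an incoherent atomic background `sigma_atom = sum_i f_i^2` plus the
#' structure-encoding two-center interference term
#' `sigma_coherent = sum_{i != j} f_i f_j sin(q R_ij) / (q R_ij)`
#' (distances in bohr). The total `sigma_tot = sigma_atom + sigma_coherent`
#' depends on the geometry only through the pair-distance multiset.
#'
#' @param structure A [molecular_structure()].
#' @param model An [amplitude_model()].
#' @param E_r Return energy, eV (scalar).
#' @param theta_r Rescattering angle, degrees (scalar).
#' @return Named list `sigma_tot`, `sigma_atom`, `sigma_coherent` (atomic
#'   units).
#' @export
iam_dcs <- function(structure, model, E_r, theta_r) {
  stopifnot(inherits(structure, "mol_structure"))
  q <- momentum_transfer(E_r, theta_r)
  f <- vapply(structure$Z, function(z) atomic_amplitude(model, z, q),
              numeric(1))
  sigma_atom <- sum(f^2)
  sigma_coherent <- 0
  n <- n_atoms(structure)
  if (n > 1L) {
    pr <- atom_pairs(n)
    r_bohr <- internuclear_distances(structure) * BOHR_PER_ANGSTROM
    sigma_coherent <- 2 * sum(f[pr[, 1L]] * f[pr[, 2L]] * sinc(q * r_bohr))
  }
  list(sigma_tot = sigma_atom + sigma_coherent, sigma_atom = sigma_atom,
       sigma_coherent = sigma_coherent)
}

#' Kinematic grid of a 2D-DCS map
#'
#' @param energies Ascending return energies, eV (> 0).
#' @param angles Ascending rescattering angles, degrees in `(0, 180]`.
#' @return Object of class `dcs_grid`. The default 64 x 64 grid spans
#'   50-300 eV and 30-180 degrees, a typical rescattering window for
#'   mid-infrared LIED.
#' @export
dcs_grid <- function(energies = seq(50, 300, length.out = 64),
                     angles = seq(30, 180, length.out = 64)) {
  energies <- as.numeric(energies); angles <- as.numeric(angles)
  if (length(energies) < 1L || length(angles) < 1L) {
    stop("grid axes must be non-empty")
  }
  if (any(energies <= 0) || is.unsorted(energies, strictly = TRUE)) {
    stop("energies must be positive and strictly ascending")
  }
  if (any(angles <= 0 | angles > 180) || is.unsorted(angles, strictly = TRUE)) {
    stop("angles must lie in (0, 180] and be strictly ascending")
  }
  structure(list(energies = energies, angles = angles), class = "dcs_grid")
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$energies, b$energies, tolerance = 1e-12)) &&
    isTRUE(all.equal(a$angles, b$angles, tolerance = 1e-12))
}

# Momentum transfer over a grid, as an nE x nA matrix.
grid_q <- function(grid) {
  outer(sqrt(2 * grid$energies / HARTREE_EV),
        2 * sin(grid$angles / 2 * pi / 180))
}

#' Simulate a 2D-DCS map
#'
#' Evaluates [iam_dcs()] over a whole `(return energy x rescattering angle)`
#' grid, vectorized over pixels and with pair terms grouped by element pair.
#'
#' @param structure A [molecular_structure()].
#' @param model An [amplitude_model()].
#' @param grid A [dcs_grid()].
#' @param components Keep the `sigma_atom` / `sigma_coherent` decomposition
#'   in the result?
#' @return Object of class `dcs_map`: `grid`, `values` (nE x nA matrix of
#'   `sigma_tot`, atomic units), optional `atom` and `coherent` matrices,
#'   and `structure_name`.
#' @export
dcs_map <- function(structure, model, grid = dcs_grid(), components = FALSE) {
  stopifnot(inherits(structure, "mol_structure"), inherits(grid, "dcs_grid"))
  qv <- as.vector(grid_q(grid))
  zs <- sort(unique(structure$Z))
  fz <- vapply(zs, function(z) atomic_amplitude(model, z, qv),
               numeric(length(qv)))
  colnames(fz) <- as.character(zs)
  counts <- table(factor(structure$Z, levels = zs))
  sigma_atom <- as.vector(fz^2 %*% as.numeric(counts))
  sigma_coh <- numeric(length(qv))
  n <- n_atoms(structure)
  if (n > 1L) {
    pr <- atom_pairs(n)
    r_bohr <- internuclear_distances(structure) * BOHR_PER_ANGSTROM
    z1 <- structure$Z[pr[, 1L]]; z2 <- structure$Z[pr[, 2L]]
    key <- paste(pmin(z1, z2), pmax(z1, z2))
    for (k in unique(key)) {
      sel <- key == k
      zz <- as.integer(strsplit(k, " ")[[1L]])
      s <- sinc(outer(qv, r_bohr[sel]))
      ff <- fz[, as.character(zz[1L])] * fz[, as.character(zz[2L])]
      sigma_coh <- sigma_coh + 2 * ff * rowSums(s)
    }
  }
  nE <- length(grid$energies); nA <- length(grid$angles)
  out <- list(grid = grid,
              values = matrix(sigma_atom + sigma_coh, nE, nA),
              atom = if (components) matrix(sigma_atom, nE, nA),
              coherent = if (components) matrix(sigma_coh, nE, nA),
              structure_name = structure$name)
  class(out) <- "dcs_map"
  out
}

#' @export
print.dcs_map <- function(x, ...) {
  cat(sprintf("<dcs_map> %s: %d x %d (%.4g..%.4g a.u.)\n",
              if (nzchar(x$structure_name)) x$structure_name else "(unnamed)",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Persist / load a DCS map as plain-text CSV
#'
#' Long-format CSV with columns `energy_eV`, `angle_deg`, `value` (and the
#' `sigma_atom` / `sigma_coherent` components when present), suitable for
#' inspection with any table tool.
#'
#' @param map A `dcs_map`.
#' @param path Output path.
#' @return `write_dcs_csv()` returns `path` invisibly; `read_dcs_csv()`
#'   returns the reconstructed `dcs_map`.
#' @export
write_dcs_csv <- function(map, path) {
  stopifnot(inherits(map, "dcs_map"))
  df <- data.frame(
    energy_eV = rep(map$grid$energies, times = length(map$grid$angles)),
    angle_deg = rep(map$grid$angles, each = length(map$grid$energies)),
    value = as.vector(map$values))
  if (!is.null(map$atom)) {
    df$sigma_atom <- as.vector(map$atom)
    df$sigma_coherent <- as.vector(map$coherent)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dcs_csv
#' @export
read_dcs_csv <- function(path) {
  df <- utils::read.csv(path)
  energies <- sort(unique(df$energy_eV)); angles <- sort(unique(df$angle_deg))
  grid <- dcs_grid(energies, angles)
  nE <- length(energies); nA <- length(angles)
  ord <- order(match(df$angle_deg, angles), match(df$energy_eV, energies))
  df <- df[ord, ]
  out <- list(grid = grid, values = matrix(df$value, nE, nA),
              atom = if ("sigma_atom" %in% names(df)) {
                matrix(df$sigma_atom, nE, nA)
              },
              coherent = if ("sigma_coherent" %in% names(df)) {
                matrix(df$sigma_coherent, nE, nA)
              },
              structure_name = "")
  class(out) <- "dcs_map"
  out
}
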