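#' Packaged fenchone example geometry and atom groups
#'
#' A 27-atom (+)-fenchone (C10H16O) geometry for the large-molecule
#' retrieval example. The packaged coordinates are a computed conformer
#' (distance-geometry embedding followed by MMFF94 force-field relaxation),
#' not an experimental structure; it stands in for the equilibrium geometry
#' when exercising the group-deformation database machinery.
#'
#' `fenchone_groups()` returns the packaged example partition of all 27
#' atoms into four chemically motivated rigid groups: the carbonyl C=O, the
#' gem-dimethyl bridge, the methyl-bearing bridgehead, and the remaining
#' ring atoms (each carbon keeps its hydrogens). `fenchone_tracked()`
#' returns the default seven tracked heavy atoms whose Cartesian
#' coordinates form the label vector.
#'
#' @return `fenchone_structure()`: a [molecular_structure()];
#'   `fenchone_groups()`: a list of four integer vectors partitioning
#'   `1:27`; `fenchone_tracked()`: an integer vector of seven atom indices.
#' @export
fenchone_structure <- function() {
  read_xyz(system.file("extdata", "fenchone_c10h16o_synthetic.xyz",
                       package = "dcsnet", mustWork = TRUE))
}

#' @rdname fenchone_structure
#' @export
fenchone_groups <- function() {
  list(
    carbonyl = c(10L, 11L),                         # C=O
    gem_dimethyl = c(1L, 2L, 3L, 12L:17L),          # C(CH3)2 bridge
    methyl_bridgehead = c(7L, 8L, 9L, 23L:27L),     # C(CH3) + CH2 bridge
    ring = c(4L, 5L, 6L, 18L:22L)                   # remaining ring CH/CH2
  )
}

#' @rdname fenchone_structure
#' @export
fenchone_tracked <- function() c(2L, 4L, 5L, 7L, 8L, 10L, 11L)
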