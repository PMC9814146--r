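# Physical constants pinned in one place; interfaces use eV and Angstrom,
# scattering internals use Hartree atomic units.
HARTREE_EV <- 27.211386
BOHR_PER_ANGSTROM <- 1.8897261

# Element symbols for Z = 1..36, enough for organic and second-row sulfur
# chemistry; extendable without touching callers.
PERIODIC_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr"
)

#' Atomic number for an element symbol
#'
#' @param element Character vector of element symbols (e.g. `"C"`, `"S"`).
#' @return Integer vector of atomic numbers.
#' @examples
#' element_to_z(c("H", "C", "O", "S"))
#' @export
element_to_z <- function(element) {
  z <- match(element, PERIODIC_SYMBOLS)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(z)]), collapse = ", "))
  }
  as.integer(z)
}
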