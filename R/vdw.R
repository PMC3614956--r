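# Element handling: inference from PDB atom names and van der Waals radii.

# Bondi-like van der Waals radii (Angstrom).  The choice is conventional,
# not derived from any particular pore-profiling program; it is configurable
# wherever radii enter a computation.
VDW_TABLE <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
VDW_DEFAULT <- 1.70

#' Van der Waals radius for an element symbol
#'
#' Unknown elements fall back to 1.70 A (carbon-like) with a warning.
#'
#' @param element character vector of element symbols.
#' @param table named numeric vector of radii in Angstrom.
#' @return numeric vector of radii.
#' @export
vdw_radius <- function(element, table = VDW_TABLE) {
  el <- toupper(trimws(element))
  r <- unname(table[el])
  unknown <- is.na(r) | el == ""
  if (any(unknown)) {
    warning("unknown element(s) ",
            paste(unique(el[unknown]), collapse = ", "),
            "; using default vdW radius ", VDW_DEFAULT, " A")
    r[unknown] <- VDW_DEFAULT
  }
  r
}

#' Infer an element symbol from a PDB atom name
#'
#' Follows the usual PDB conventions: a leading digit marks a hydrogen
#' (e.g. "1HG1"), otherwise the first alphabetic character is the element
#' ("NE2" -> N, "CD1" -> C, "OH2" -> O).
#'
#' @param atom_name character vector of atom names.
#' @return character vector of element symbols.
#' @export
infer_element <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  vapply(nm, function(x) {
    if (x == "") return("")
    if (grepl("^[0-9]", x)) return("H")
    first <- regmatches(x, regexpr("[A-Z]", x))
    if (length(first) == 0) "" else first
  }, character(1), USE.NAMES = FALSE)
}
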