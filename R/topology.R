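# Topology: the ordered atom table that defines the canonical frame order.

#' Build a topology
#'
#' A topology is an ordered atom table; the row order is the canonical
#' coordinate order for every frame of a trajectory built on it.
#'
#' @param atom_name,residue_name character vectors.
#' @param residue_number integer vector.
#' @param chain_id character vector (single letters typically).
#' @param element character vector; inferred from `atom_name` when `NULL`.
#' @param vdw numeric vector of van der Waals radii (Angstrom); assigned
#'   from the element table when `NULL`.
#' @param serial integer atom serial numbers; defaults to 1..n.
#' @return an object of class `topology` (a data.frame).
#' @export
topology <- function(atom_name, residue_name, residue_number,
                     chain_id = "A", element = NULL, vdw = NULL,
                     serial = NULL) {
  n <- length(atom_name)
  if (n == 0L) stop("empty topology: no atoms", call. = FALSE)
  residue_name <- rep_len(as.character(residue_name), n)
  residue_number <- rep_len(as.integer(residue_number), n)
  chain_id <- rep_len(as.character(chain_id), n)
  if (is.null(element)) element <- infer_element(atom_name)
  element <- rep_len(as.character(element), n)
  if (is.null(vdw)) vdw <- suppressWarnings(vdw_radius(element))
  vdw <- rep_len(as.numeric(vdw), n)
  if (any(!is.na(vdw) & vdw <= 0))
    stop("vdw radii must be > 0 when set", call. = FALSE)
  if (is.null(serial)) serial <- seq_len(n)
  key <- paste(chain_id, residue_number, atom_name, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (chain, residue_number, atom_name) triplet in topology",
         call. = FALSE)
  top <- data.frame(serial = as.integer(serial),
                    atom_name = as.character(atom_name),
                    residue_name = residue_name,
                    residue_number = residue_number,
                    chain_id = chain_id,
                    element = element,
                    vdw = vdw,
                    stringsAsFactors = FALSE)
  class(top) <- c("topology", "data.frame")
  top
}

#' Number of atoms in a topology
#' @param top a `topology`.
#' @export
n_atoms <- function(top) nrow(top)

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", nrow(x), " atoms, ",
      length(unique(paste(x$chain_id, x$residue_number))), " residues\n",
      sep = "")
  invisible(x)
}

#' Select atoms by residue / atom name
#'
#' All given criteria must match.  An empty selection is valid (downstream
#' operations reject empties where it matters).  For isoleucine the delta
#' carbon is matched under both the "CD" and "CD1" dialects.
#'
#' @param top a `topology`.
#' @param residue_name,atom_name optional character scalars.
#' @param residue_number optional integer scalar.
#' @param chain optional chain id.
#' @return an `atom_selection`: sorted unique integer atom indices.
#' @export
select_atoms <- function(top, residue_name = NULL, residue_number = NULL,
                         atom_name = NULL, chain = NULL) {
  keep <- rep(TRUE, nrow(top))
  if (!is.null(residue_name))
    keep <- keep & toupper(top$residue_name) == toupper(residue_name)
  if (!is.null(residue_number))
    keep <- keep & top$residue_number == as.integer(residue_number)
  if (!is.null(chain))
    keep <- keep & top$chain_id == chain
  if (!is.null(atom_name)) {
    want <- toupper(atom_name)
    names_up <- toupper(top$atom_name)
    match_name <- names_up == want
    # PDB v2/v3 dialect tolerance for the Ile delta carbon
    ile <- toupper(top$residue_name) == "ILE"
    if (want == "CD")  match_name <- match_name | (ile & names_up == "CD1")
    if (want == "CD1") match_name <- match_name | (ile & names_up == "CD")
    keep <- keep & match_name
  }
  atom_selection(which(keep))
}

#' Construct an atom selection from indices
#' @param indices integer atom indices (1-based topology positions).
#' @export
atom_selection <- function(indices) {
  idx <- sort(unique(as.integer(indices)))
  if (length(idx) && (any(is.na(idx)) || any(idx < 1L)))
    stop("invalid atom indices in selection", call. = FALSE)
  structure(idx, class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("<atom_selection> ", length(x), " atom(s)\n", sep = "")
  invisible(x)
}

# Resolve a selection to exactly one atom index (for order-parameter specs)
resolve_one <- function(sel, what = "selection") {
  if (length(sel) == 0L)
    stop("empty selection for ", what, call. = FALSE)
  if (length(sel) > 1L)
    stop("ambiguous selection for ", what, " (", length(sel), " atoms)",
         call. = FALSE)
  as.integer(sel[1L])
}
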