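# Fixed-width PDB reader/writer (ATOM/HETATM/MODEL/ENDMDL/CRYST1).
# Only orthorhombic cells are supported; triclinic CRYST1 records are
# rejected so that minimum-image arithmetic stays exact.

num_field <- function(lines, from, to, lineno, what) {
  s <- trimws(substr(lines, from, to))
  v <- suppressWarnings(as.numeric(s))
  bad <- is.na(v) & s != ""
  if (any(bad))
    stop("malformed PDB record (", what, ") at line ", lineno[bad][1L],
         call. = FALSE)
  v
}

#' Read a (multi-model) PDB file
#'
#' One frame is produced per MODEL block; a file without MODEL records
#' yields a single frame.  Elements are taken from columns 77-78 when
#' present, otherwise inferred from the atom name; van der Waals radii are
#' assigned from the element table.
#'
#' @param path file path.
#' @param dt_ns frame stride (ns) used to synthesize frame times
#'   (PDB carries no time information).
#' @param box orthorhombic box lengths used when no CRYST1 record is
#'   present (default 100 A cube).
#' @return list with elements `topology` and `trajectory`.
#' @export
read_pdb <- function(path, dt_ns = 0.1, box = c(100, 100, 100)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  cryst <- which(rec == "CRYST1")
  if (length(cryst)) {
    ln <- cryst[1L]
    abc <- c(num_field(lines[ln], 7, 15, ln, "CRYST1 a"),
             num_field(lines[ln], 16, 24, ln, "CRYST1 b"),
             num_field(lines[ln], 25, 33, ln, "CRYST1 c"))
    ang <- c(num_field(lines[ln], 34, 40, ln, "CRYST1 alpha"),
             num_field(lines[ln], 41, 47, ln, "CRYST1 beta"),
             num_field(lines[ln], 48, 54, ln, "CRYST1 gamma"))
    if (any(abs(ang - 90) > 1e-3))
      stop("triclinic unit cell not supported (CRYST1 angles ",
           paste(ang, collapse = ", "), ")", call. = FALSE)
    box <- abc
  }
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path, call. = FALSE)

  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) == 0L) {
    frames_idx <- list(which(is_atom))
  } else {
    model_ends <- which(rec == "ENDMDL")
    if (length(model_ends) < length(model_starts))
      model_ends <- c(model_ends, length(lines))
    frames_idx <- lapply(seq_along(model_starts), function(k) {
      span <- seq(model_starts[k], model_ends[k])
      span[is_atom[span]]
    })
    frames_idx <- frames_idx[vapply(frames_idx, length, 1L) > 0L]
    if (length(frames_idx) == 0L)
      stop("MODEL blocks contain no atoms in ", path, call. = FALSE)
  }

  n <- length(frames_idx[[1L]])
  counts <- vapply(frames_idx, length, 1L)
  if (any(counts != n))
    stop("MODEL blocks differ in atom count (", paste(unique(counts),
         collapse = ", "), ")", call. = FALSE)

  first <- frames_idx[[1L]]
  l1 <- lines[first]
  serial <- as.integer(num_field(l1, 7, 11, first, "serial"))
  atom_name <- trimws(substr(l1, 13, 16))
  residue_name <- trimws(substr(l1, 18, 21))
  chain_id <- trimws(substr(l1, 22, 22))
  chain_id[chain_id == ""] <- "A"
  residue_number <- as.integer(num_field(l1, 23, 26, first, "resSeq"))
  element <- trimws(substr(l1, 77, 78))
  missing_el <- element == "" | is.na(element)
  element[missing_el] <- infer_element(atom_name[missing_el])
  top <- topology(atom_name, residue_name, residue_number, chain_id,
                  element = element, serial = serial)

  coords <- array(NA_real_, dim = c(n, 3L, length(frames_idx)))
  for (k in seq_along(frames_idx)) {
    lk <- lines[frames_idx[[k]]]
    coords[, 1, k] <- num_field(lk, 31, 38, frames_idx[[k]], "x")
    coords[, 2, k] <- num_field(lk, 39, 46, frames_idx[[k]], "y")
    coords[, 3, k] <- num_field(lk, 47, 54, frames_idx[[k]], "z")
  }
  if (anyNA(coords)) stop("missing coordinates in ", path, call. = FALSE)
  traj <- trajectory(top, coords, box, dt_ns = dt_ns)
  list(topology = top, trajectory = traj)
}

format_pdb_name <- function(nm) {
  # Standard alignment: names shorter than 4 characters start in column 14
  ifelse(nchar(nm) >= 4L, substr(nm, 1, 4), sprintf(" %-3s", nm))
}

#' Write a (multi-model) PDB file
#'
#' @param top a `topology`.
#' @param traj a `trajectory` on that topology (multi-frame trajectories
#'   are written as MODEL blocks).
#' @param path output path.
#' @export
write_pdb <- function(top, traj, path) {
  if (n_frames(traj) == 0L) stop("cannot write a 0-frame PDB", call. = FALSE)
  if (n_atoms(top) != dim(traj$coords)[1])
    stop("topology/trajectory atom counts differ", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  b <- traj$box[, 1L]
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    b[1], b[2], b[3], 90, 90, 90), con)
  nf <- n_frames(traj)
  nm <- format_pdb_name(top$atom_name)
  el <- sprintf("%2s", substr(top$element, 1, 2))
  for (k in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- frame_coords(traj, k)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      top$serial %% 100000L, nm, substr(top$residue_name, 1, 4),
      substr(top$chain_id, 1, 1), top$residue_number %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, el), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
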