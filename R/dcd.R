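# CHARMM/NAMD DCD binary trajectory codec (single precision, Fortran
# record framing, native little-endian).  Orthorhombic unit cells only.

read_record <- function(con, what, size, n = NULL, label = "record") {
  len <- readBin(con, "integer", n = 1L, size = 4L)
  if (length(len) == 0L) return(NULL)
  payload <- readBin(con, what, n = if (is.null(n)) len %/% size else n,
                     size = size)
  trailer <- readBin(con, "integer", n = 1L, size = 4L)
  if (length(trailer) == 0L || trailer != len)
    stop("corrupt DCD ", label, " (record framing mismatch)", call. = FALSE)
  payload
}

write_record <- function(con, data, what, size) {
  nbytes <- length(data) * size
  writeBin(as.integer(nbytes), con, size = 4L)
  if (what == "character") writeBin(data, con, size = size, useBytes = TRUE)
  else writeBin(data, con, size = size)
  writeBin(as.integer(nbytes), con, size = 4L)
}

#' Read a CHARMM/NAMD DCD trajectory
#'
#' The unit cell is taken from the file when the header's crystal flag is
#' set (orthorhombic cells only); otherwise `box` must be supplied.  DCD
#' carries no physical time unit; times are synthesized from `dt_ns` when
#' given, else from the header timestep (interpreted as ns per saved frame,
#' the dialect written by [write_dcd()]), else from a 0.1 ns default.
#'
#' @param path file path.
#' @param top a `topology`; its atom count must match the file.
#' @param dt_ns optional frame stride in ns.
#' @param box optional length-3 orthorhombic box (required when the file
#'   has no unit-cell records).
#' @return a `trajectory`.
#' @export
read_dcd <- function(path, top, dt_ns = NULL, box = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  len <- readBin(con, "integer", n = 1L, size = 4L)
  if (length(len) == 0L || len != 84L)
    stop("not a DCD file (bad header length): ", path, call. = FALSE)
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "CORD"))
    stop("not a coordinate DCD (magic '", magic, "')", call. = FALSE)
  icntrl_raw <- readBin(con, "raw", n = 80L)
  trailer <- readBin(con, "integer", n = 1L, size = 4L)
  if (trailer != 84L) stop("corrupt DCD header framing", call. = FALSE)
  icntrl <- readBin(icntrl_raw, "integer", n = 20L, size = 4L)
  delta <- readBin(icntrl_raw[37:40], "numeric", n = 1L, size = 4L)
  nsavc <- icntrl[3L]
  has_cell <- icntrl[11L] != 0L

  # title block, ignored
  tlen <- readBin(con, "integer", n = 1L, size = 4L)
  invisible(readBin(con, "raw", n = tlen))
  if (readBin(con, "integer", n = 1L, size = 4L) != tlen)
    stop("corrupt DCD title record", call. = FALSE)
  natom <- read_record(con, "integer", 4L, label = "natom")[1L]
  if (natom != n_atoms(top))
    stop("DCD atom count (", natom, ") does not match topology (",
         n_atoms(top), ")", call. = FALSE)

  frames <- list()
  boxes <- list()
  repeat {
    if (has_cell) {
      cell <- read_record(con, "numeric", 8L, label = "unit cell")
      if (is.null(cell)) break
      if (length(cell) != 6L)
        stop("corrupt DCD unit-cell record after frame ", length(frames),
             call. = FALSE)
      # XTLABC layout: a, cos(gamma), b, cos(beta), cos(alpha), c
      off <- cell[c(2, 4, 5)]
      ortho <- all(abs(off) < 1e-6) || all(abs(off - 90) < 1e-6)
      if (!ortho)
        stop("triclinic DCD unit cell not supported", call. = FALSE)
      boxes[[length(boxes) + 1L]] <- cell[c(1, 3, 6)]
    }
    x <- read_record(con, "numeric", 4L, n = natom, label = "x coordinates")
    if (is.null(x)) break
    y <- read_record(con, "numeric", 4L, n = natom, label = "y coordinates")
    z <- read_record(con, "numeric", 4L, n = natom, label = "z coordinates")
    if (is.null(y) || is.null(z) || length(x) != natom ||
        length(y) != natom || length(z) != natom)
      stop("truncated DCD file: last complete frame is ", length(frames),
           call. = FALSE)
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
  }
  nf <- length(frames)
  if (nf == 0L) stop("empty trajectory: DCD contains no frames",
                     call. = FALSE)
  coords <- array(unlist(frames), dim = c(natom, 3L, nf))
  if (has_cell) {
    boxm <- do.call(cbind, boxes[seq_len(nf)])
  } else {
    if (is.null(box))
      stop("DCD has no unit-cell records; supply `box`", call. = FALSE)
    boxm <- matrix(box, 3L, nf)
  }
  stride <- dt_ns %||% (if (is.finite(delta) && delta > 0)
    delta * max(1L, nsavc) else 0.1)
  trajectory(top, coords, boxm, dt_ns = stride)
}

#' Write a CHARMM/NAMD-dialect DCD trajectory
#'
#' Coordinates are stored in single precision; the orthorhombic unit cell
#' is written per frame; the header timestep slot stores the frame stride
#' in ns.
#'
#' @param traj a `trajectory`.
#' @param path output path.
#' @export
write_dcd <- function(traj, path) {
  nf <- n_frames(traj)
  if (nf == 0L) stop("cannot write a 0-frame DCD", call. = FALSE)
  natom <- dim(traj$coords)[1]
  con <- file(path, "wb")
  on.exit(close(con))

  dt <- frame_dt(traj)
  if (!is.finite(dt)) dt <- 0.1
  icntrl <- integer(20L)
  icntrl[1L] <- nf       # NSET
  icntrl[2L] <- 0L       # ISTART
  icntrl[3L] <- 1L       # NSAVC
  icntrl[4L] <- nf       # NSTEP
  icntrl[11L] <- 1L      # crystal flag
  icntrl[20L] <- 24L     # CHARMM version tag
  hdr_raw <- writeBin(icntrl, raw(), size = 4L)
  hdr_raw[37:40] <- writeBin(as.numeric(dt), raw(), size = 4L)
  writeBin(84L, con, size = 4L)
  writeChar("CORD", con, nchars = 4L, eos = NULL, useBytes = TRUE)
  writeBin(hdr_raw, con)
  writeBin(84L, con, size = 4L)

  title <- sprintf("%-80s", "Created by aquaflux")
  writeBin(c(4L + 80L), con, size = 4L)
  writeBin(1L, con, size = 4L)
  writeChar(title, con, nchars = 80L, eos = NULL, useBytes = TRUE)
  writeBin(c(4L + 80L), con, size = 4L)

  write_record(con, as.integer(natom), "integer", 4L)

  for (k in seq_len(nf)) {
    b <- traj$box[, k]
    cell <- c(b[1], 0, b[2], 0, 0, b[3])
    write_record(con, as.numeric(cell), "numeric", 8L)
    xyz <- frame_coords(traj, k)
    write_record(con, as.numeric(xyz[, 1]), "numeric", 4L)
    write_record(con, as.numeric(xyz[, 2]), "numeric", 4L)
    write_record(con, as.numeric(xyz[, 3]), "numeric", 4L)
  }
  invisible(path)
}
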