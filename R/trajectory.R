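# Trajectory container: coordinates in Angstrom on an orthorhombic box.

#' Build a trajectory
#'
#' @param top a `topology`.
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom), or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param box orthorhombic box lengths: length-3 vector (constant) or a
#'   `3 x n_frames` matrix.
#' @param times frame times in ns; strictly increasing.  Defaults to
#'   `(0:(n_frames-1)) * dt_ns`.
#' @param dt_ns frame stride used when `times` is `NULL` (default 0.1 ns).
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(top, coords, box, times = NULL, dt_ns = 0.1) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  nf <- dim(coords)[3]
  if (nf == 0L) stop("trajectory must contain at least one frame",
                     call. = FALSE)
  if (dim(coords)[1] != n_atoms(top))
    stop("coordinate count (", dim(coords)[1],
         ") does not match topology atom count (", n_atoms(top), ")",
         call. = FALSE)
  if (is.null(dim(box))) {
    stopifnot(length(box) == 3L)
    box <- matrix(as.numeric(box), nrow = 3L, ncol = nf)
  }
  stopifnot(nrow(box) == 3L, ncol(box) == nf)
  if (any(box <= 0)) stop("box lengths must be > 0", call. = FALSE)
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt_ns
  times <- as.numeric(times)
  stopifnot(length(times) == nf)
  if (nf > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  structure(list(topology = top, coords = coords, box = box, times = times),
            class = "trajectory")
}

#' Number of frames
#' @param traj a `trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#' @param traj a `trajectory`.
#' @param i frame index.
#' @return `n_atoms x 3` numeric matrix.
#' @export
frame_coords <- function(traj, i) {
  m <- traj$coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Frame stride in ns (median of time differences; equals the stride for
#' uniformly sampled trajectories)
#' @param traj a `trajectory`.
#' @export
frame_dt <- function(traj) {
  if (n_frames(traj) < 2L) return(NA_real_)
  stats::median(diff(traj$times))
}

#' Subset frames of a trajectory
#' @param traj a `trajectory`.
#' @param frames integer frame indices (increasing).
#' @export
traj_subset <- function(traj, frames) {
  frames <- as.integer(frames)
  stopifnot(all(frames >= 1L), all(frames <= n_frames(traj)))
  trajectory(traj$topology,
             traj$coords[, , frames, drop = FALSE],
             traj$box[, frames, drop = FALSE],
             times = traj$times[frames])
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_atoms(x$topology), " atoms x ", n_frames(x),
      " frames, t = [", format(x$times[1]), ", ",
      format(x$times[n_frames(x)]), "] ns\n", sep = "")
  invisible(x)
}
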