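# Maximal-sphere pore radius profiles along z (HOLE-style), computed with
# a deterministic coarse grid plus local grid refinement rather than
# simulated annealing, for bit-reproducibility.

#' Maximal-sphere pore radius of one z slice
#'
#' Maximizes `r(x, y) = min_i(||(x, y, z) - a_i|| - vdw_i)` over (x, y) at
#' fixed z by a deterministic compass (pattern) search ascending from the
#' seed point: steps start at the coarse spacing (0.5 A) and halve down to
#' the requested tolerance, confined to the search cylinder.  The search
#' is local by construction -- it finds the pore-interior maximum in the
#' basin connected to the seed, where the unconstrained global maximum
#' would escape through the pore mouth.  The result is clamped at 0.
#'
#' @param coords `n x 3` atom coordinate matrix.
#' @param vdw per-atom van der Waals radii.
#' @param z slice height.
#' @param seed_xy search center `c(x, y)`.
#' @param search_radius half-width of the coarse search square (default
#'   10 A).
#' @param coarse coarse grid spacing (default 0.5 A).
#' @param tol refinement tolerance on the optimum position (default 1e-3).
#' @return list: radius (A), xy (optimal center).
#' @export
slice_radius <- function(coords, vdw, z, seed_xy = c(0, 0),
                         search_radius = 10, coarse = 0.5, tol = 1e-3) {
  stopifnot(ncol(coords) == 3L, nrow(coords) == length(vdw))
  near <- abs(coords[, 1] - seed_xy[1]) <= 2 * search_radius &
    abs(coords[, 2] - seed_xy[2]) <= 2 * search_radius
  if (!any(near))
    stop("no atoms near the search cylinder at z = ", z, call. = FALSE)
  ax <- coords[, 1]; ay <- coords[, 2]
  dz2 <- (coords[, 3] - z)^2
  obj <- function(px, py) {
    # candidates x atoms; returns per-candidate clearance
    d2 <- outer(px, ax, "-")^2 + outer(py, ay, "-")^2
    d2 <- sweep(d2, 2L, dz2, "+")
    apply(sqrt(d2) - rep(vdw, each = length(px)), 1L, min)
  }
  # Deterministic compass/pattern search ascending from the seed: the
  # maximal-sphere objective diverges outside the pore mouth, so the
  # search must stay in the local basin connected to the seed axis rather
  # than scan the whole slice.  Steps start at the coarse spacing and are
  # halved down to the tolerance; moves are confined to the search
  # cylinder around the seed.
  nb <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
              c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  pos <- seed_xy
  v <- obj(pos[1], pos[2])
  step <- coarse
  while (step > tol / 4) {
    moves <- 0L
    repeat {
      px <- pos[1] + nb[, 1] * step
      py <- pos[2] + nb[, 2] * step
      ok <- (px - seed_xy[1])^2 + (py - seed_xy[2])^2 <= search_radius^2
      ok[1] <- TRUE
      val <- rep(-Inf, nrow(nb))
      val[ok] <- obj(px[ok], py[ok])
      j <- which.max(val)
      if (j == 1L || val[j] <= v || moves > 8 * search_radius / step) break
      pos <- c(px[j], py[j]); v <- val[j]
      moves <- moves + 1L
    }
    step <- step / 2
  }
  list(radius = max(0, v), xy = pos)
}

#' Pore radius profile along z
#'
#' [slice_radius()] on a uniform z grid for every frame, each slice seeded
#' by the previous slice's optimum (continuation); waters and other
#' excluded residues are removed so the profile characterizes the protein
#' pore.
#'
#' @param traj a `trajectory`.
#' @param top its `topology` (defaults to `traj$topology`).
#' @param z_lo,z_hi profile span.
#' @param spacing slice spacing (default 0.25 A).
#' @param seed_xy axis seed for the first slice.
#' @param exclude_resnames residues to drop (default common water names).
#' @param frames frame indices to include (default all).
#' @param ... passed to [slice_radius()].
#' @return a `radius_profile`: data.frame (z, radius_mean, radius_sd) with
#'   the per-frame matrix in `attr(, "per_frame")`.
#' @export
pore_radius_profile <- function(traj, top = NULL, z_lo, z_hi,
                                spacing = 0.25, seed_xy = c(0, 0),
                                exclude_resnames = c("HOH", "TIP3", "WAT",
                                                     "SOL"),
                                frames = NULL, ...) {
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  if (z_hi <= z_lo) stop("need z_hi > z_lo", call. = FALSE)
  top <- top %||% traj$topology
  keep <- !(toupper(top$residue_name) %in% toupper(exclude_resnames))
  if (!any(keep)) stop("no atoms left after exclusion", call. = FALSE)
  frames <- frames %||% seq_len(n_frames(traj))
  zg <- seq(z_lo, z_hi, by = spacing)
  per_frame <- matrix(NA_real_, nrow = length(zg), ncol = length(frames))
  vdw <- top$vdw[keep]
  for (fi in seq_along(frames)) {
    xyz <- frame_coords(traj, frames[fi])[keep, , drop = FALSE]
    seed <- seed_xy
    for (zi in seq_along(zg)) {
      sr <- slice_radius(xyz, vdw, zg[zi], seed_xy = seed, ...)
      per_frame[zi, fi] <- sr$radius
      seed <- sr$xy
    }
  }
  out <- data.frame(z = zg,
                    radius_mean = rowMeans(per_frame),
                    radius_sd = if (length(frames) > 1L)
                      apply(per_frame, 1L, stats::sd) else 0)
  attr(out, "per_frame") <- per_frame
  class(out) <- c("radius_profile", "data.frame")
  out
}

#' Call gating states from a radius profile
#'
#' The selectivity filter is wide when its minimal radius exceeds
#' `sf_cut` (1.1 A), narrow otherwise; the cytoplasmic end is closed below
#' `ce_closed` (1 A), open above `ce_open` (1.4 A), intermediate between.
#'
#' @param profile a `radius_profile`.
#' @param sf_z_range,ce_z_range z windows `c(lo, hi)` over which the
#'   minimal radius is taken (figure-defined regions; mandatory).
#' @param sf_cut,ce_closed,ce_open thresholds in Angstrom.
#' @return list: sf_state, ce_state, sf_min_radius, ce_min_radius.
#' @export
call_states_from_profile <- function(profile, sf_z_range, ce_z_range,
                                     sf_cut = 1.1, ce_closed = 1.0,
                                     ce_open = 1.4) {
  min_in <- function(rng) {
    sel <- profile$z >= rng[1] & profile$z <= rng[2]
    if (!any(sel))
      stop("empty z range [", rng[1], ", ", rng[2], "] in profile",
           call. = FALSE)
    min(profile$radius_mean[sel])
  }
  sf_min <- min_in(sf_z_range)
  ce_min <- min_in(ce_z_range)
  list(sf_state = if (sf_min > sf_cut) "wide" else "narrow",
       ce_state = if (ce_min < ce_closed) "closed"
                  else if (ce_min > ce_open) "open" else "intermediate",
       sf_min_radius = sf_min, ce_min_radius = ce_min)
}
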