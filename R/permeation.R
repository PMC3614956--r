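# Water permeation: region tracking, complete-transit event detection,
# one-directional permeation rate q0, and diffusive permeability
# p_d = v_w * q0.

REGION_BELOW <- 0L
REGION_INSIDE <- 1L
REGION_ABOVE <- 2L
REGION_OUTSIDE <- 3L

# Channel-local coordinates: z and xy displacement are minimum-imaged
# about the channel center each frame, so labels are stateless and a
# periodic wrap far from the channel appears as a direct below <-> above
# jump that never passes "inside" (the event automaton ignores those).
channel_local <- function(traj, channel, waters) {
  nf <- n_frames(traj)
  zc <- (channel$z_lo + channel$z_hi) / 2
  z <- traj$coords[waters, 3L, , drop = FALSE]
  dim(z) <- c(length(waters), nf)
  x <- traj$coords[waters, 1L, , drop = FALSE]
  dim(x) <- c(length(waters), nf)
  y <- traj$coords[waters, 2L, , drop = FALSE]
  dim(y) <- c(length(waters), nf)
  if (!is.null(channel$center_selection)) {
    sel <- as.integer(channel$center_selection)
    if (length(sel) == 0L) stop("empty center_selection", call. = FALSE)
    cx <- apply(traj$coords[sel, 1L, , drop = FALSE], 3, mean)
    cy <- apply(traj$coords[sel, 2L, , drop = FALSE], 3, mean)
  } else {
    cx <- rep(channel$center[1], nf)
    cy <- rep(channel$center[2], nf)
  }
  Lx <- traj$box[1, ]; Ly <- traj$box[2, ]; Lz <- traj$box[3, ]
  wrap <- function(d, L) d - rep(L, each = nrow(d)) *
    round(d / rep(L, each = nrow(d)))
  dz <- wrap(sweep(z, 2, zc), Lz)
  dx <- wrap(sweep(x, 2, cx), Lx)
  dy <- wrap(sweep(y, 2, cy), Ly)
  list(z = dz + zc, r = sqrt(dx^2 + dy^2), waters = waters)
}

#' Track per-water channel regions
#'
#' Labels every water oxygen at every frame as below (`z < z_lo - buffer`),
#' inside (z within the channel span and radially within the cutoff),
#' above (`z > z_hi + buffer`), or outside (in the buffer zone or radially
#' excluded).
#'
#' @param traj a `trajectory`.
#' @param channel a `channel_spec`.
#' @return integer matrix `n_waters x n_frames` with values 0 below,
#'   1 inside, 2 above, 3 outside; attributes `waters` (atom indices),
#'   `z` (channel-local z matrix), and `times`.
#' @export
track_regions <- function(traj, channel) {
  waters <- water_oxygens(traj$topology, channel)
  loc <- channel_local(traj, channel, waters)
  z <- loc$z; r <- loc$r
  reg <- matrix(REGION_OUTSIDE, nrow = nrow(z), ncol = ncol(z))
  reg[z < channel$z_lo - channel$buffer] <- REGION_BELOW
  reg[z > channel$z_hi + channel$buffer] <- REGION_ABOVE
  inside <- z >= channel$z_lo & z <= channel$z_hi & r <= channel$radial_cutoff
  reg[inside] <- REGION_INSIDE
  attr(reg, "waters") <- waters
  attr(reg, "z") <- z
  attr(reg, "times") <- traj$times
  reg
}

#' Detect complete permeation events
#'
#' An event is a transit below -> (inside ...) -> above (direction +1) or
#' the reverse (-1), without touching the opposite bulk in between;
#' partial entries and mouth recrossings count zero.  Implemented as a
#' per-water automaton over the region series (vectorized with
#' last-visit bookkeeping).
#'
#' @param regions region matrix from [track_regions()].
#' @return data.frame (class `permeation_events`) with columns water_id
#'   (topology atom index), direction (+1/-1), entry_frame (last frame in
#'   the originating bulk), exit_frame (first frame in the destination
#'   bulk); attribute `times`.
#' @export
count_events <- function(regions) {
  waters <- attr(regions, "waters") %||% seq_len(nrow(regions))
  times <- attr(regions, "times")
  nf <- ncol(regions)
  out <- vector("list", nrow(regions))
  for (w in seq_len(nrow(regions))) {
    r <- regions[w, ]
    if (nf < 3L) next
    idx <- seq_len(nf)
    last_below <- cummax(ifelse(r == REGION_BELOW, idx, 0L))
    last_above <- cummax(ifelse(r == REGION_ABOVE, idx, 0L))
    last_inside <- cummax(ifelse(r == REGION_INSIDE, idx, 0L))
    enter_above <- which(r == REGION_ABOVE & c(REGION_ABOVE, r[-nf]) !=
                           REGION_ABOVE)
    enter_below <- which(r == REGION_BELOW & c(REGION_BELOW, r[-nf]) !=
                           REGION_BELOW)
    enter_above <- enter_above[enter_above > 1L]
    enter_below <- enter_below[enter_below > 1L]
    pos <- enter_above[last_below[enter_above - 1L] >
                         last_above[enter_above - 1L] &
                       last_inside[enter_above - 1L] >
                         last_below[enter_above - 1L] &
                       last_below[enter_above - 1L] > 0L]
    neg <- enter_below[last_above[enter_below - 1L] >
                         last_below[enter_below - 1L] &
                       last_inside[enter_below - 1L] >
                         last_above[enter_below - 1L] &
                       last_above[enter_below - 1L] > 0L]
    if (length(pos) || length(neg)) {
      out[[w]] <- data.frame(
        water_id = waters[w],
        direction = c(rep(1L, length(pos)), rep(-1L, length(neg))),
        entry_frame = c(last_below[pmax(pos - 1L, 1L)],
                        last_above[pmax(neg - 1L, 1L)]),
        exit_frame = c(pos, neg))
    }
  }
  ev <- do.call(rbind, out)
  if (is.null(ev))
    ev <- data.frame(water_id = integer(0), direction = integer(0),
                     entry_frame = integer(0), exit_frame = integer(0))
  ev <- ev[order(ev$exit_frame, ev$water_id), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "times") <- times
  class(ev) <- c("permeation_events", "data.frame")
  ev
}

#' Cumulative permeation curve
#'
#' Number of completed events up to each frame, per direction and averaged
#' over the two directions (the form plotted in permeation-rate figures).
#'
#' @param events events from [count_events()].
#' @param times frame times (defaults to the attribute on `events`).
#' @return data.frame: frame, time_ns, n_pos, n_neg, n_mean.
#' @export
cumulative_curve <- function(events, times = NULL) {
  times <- times %||% attr(events, "times")
  nf <- length(times)
  n_pos <- cumsum(tabulate(events$exit_frame[events$direction > 0], nf))
  n_neg <- cumsum(tabulate(events$exit_frame[events$direction < 0], nf))
  data.frame(frame = seq_len(nf), time_ns = times,
             n_pos = n_pos, n_neg = n_neg, n_mean = (n_pos + n_neg) / 2)
}

#' One-directional permeation rate q0
#'
#' `q0` is the event count per direction averaged over the two directions,
#' divided by the window length; additionally the linear-fit slope of the
#' direction-averaged cumulative curve over the window is returned.
#'
#' @param events events from [count_events()].
#' @param t0,t1 time window (ns), `t1 > t0`.
#' @param times frame times (defaults to the attribute on `events`).
#' @return list with q0 (1/ns), slope (1/ns), n_pos, n_neg.
#' @export
permeation_rate <- function(events, t0, t1, times = NULL) {
  times <- times %||% attr(events, "times")
  if (is.null(times)) stop("frame times required", call. = FALSE)
  if (t1 <= t0) stop("undefined rate: empty window (t1 <= t0)",
                     call. = FALSE)
  tev <- times[events$exit_frame]
  in_win <- tev >= t0 & tev <= t1
  n_pos <- sum(events$direction[in_win] > 0)
  n_neg <- sum(events$direction[in_win] < 0)
  q0 <- mean(c(n_pos, n_neg)) / (t1 - t0)
  cc <- cumulative_curve(events, times)
  sel <- cc$time_ns >= t0 & cc$time_ns <= t1
  slope <- if (sum(sel) >= 2L)
    unname(coef(lm(cc$n_mean[sel] ~ cc$time_ns[sel]))[2L]) else NA_real_
  if (is.na(slope)) slope <- 0
  list(q0 = q0, slope = slope, n_pos = n_pos, n_neg = n_neg)
}

#' Specific volume of a water molecule
#'
#' `v_w = V_m / N_A` with Avogadro's number `N_A = 6.02214e23 / mol`.
#'
#' @param molar_volume molar volume of water in cm^3/mol (default 18.0).
#' @return v_w in cm^3.
#' @export
water_specific_volume <- function(molar_volume = 18.0) {
  if (!is.numeric(molar_volume) || molar_volume <= 0)
    stop("molar_volume must be > 0", call. = FALSE)
  molar_volume / AVOGADRO
}

#' Diffusive single-channel permeability p_d
#'
#' `p_d = v_w * q0`, converted from 1/ns to 1/s and reported in units of
#' 1e-14 cm^3/s (the conventional single-channel unit).
#'
#' @param q0 one-directional permeation rate (1/ns), `>= 0`.
#' @param v_w water specific volume (cm^3).
#' @return p_d in 1e-14 cm^3/s.
#' @export
diffusive_permeability <- function(q0, v_w = water_specific_volume()) {
  if (any(q0 < 0)) stop("q0 must be >= 0", call. = FALSE)
  v_w * q0 * 1e9 / 1e-14
}
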