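# Collective water-displacement coordinate n(t), windowed-MSD diffusion
# coefficient D_n, osmotic permeability p_f = v_w * D_n, channel occupancy
# N(t), per-state permeability estimates, and the single-file CTRW
# consistency check p_f/p_d = N + 1.

#' Collective water-displacement coordinate n(t)
#'
#' Per step, `dn = sum_i dz_i / L` over waters inside the channel during
#' that step; `n` is the cumulative sum with `n(0) = 0`.  A water
#' entering/leaving mid-step contributes only the displacement accrued
#' while inside: each step's contribution is the signed change of its
#' channel-local z clamped to `[z_lo, z_hi]` (steps are minimum-imaged so
#' periodic wraps cannot fake displacement), gated on radial membership.
#' One complete single-water transit advances n by exactly 1.
#'
#' @param traj a `trajectory`.
#' @param channel a `channel_spec`.
#' @param window_ns MSD window length carried as metadata (default 2 ns).
#' @return a `collective_series`: list with n (length n_frames, first
#'   element 0),
#'   N (per-frame inside-water count), times, window_ns, L.
#' @export
collective_coordinate <- function(traj, channel, window_ns = 2) {
  if (channel$L <= 0) stop("zero-length channel", call. = FALSE)
  waters <- water_oxygens(traj$topology, channel)
  loc <- channel_local(traj, channel, waters)
  z <- loc$z; r <- loc$r
  nf <- ncol(z)
  inside <- z >= channel$z_lo & z <= channel$z_hi &
    r <= channel$radial_cutoff
  N <- colSums(inside)
  if (nf == 1L) {
    n <- 0
  } else {
    Lz <- traj$box[3L, -1L]
    step <- z[, -1L, drop = FALSE] - z[, -nf, drop = FALSE]
    step <- step - rep(Lz, each = nrow(z)) *
      round(step / rep(Lz, each = nrow(z)))
    z0 <- z[, -nf, drop = FALSE]
    z1 <- z0 + step
    clamp <- function(m) pmin(pmax(m, channel$z_lo), channel$z_hi)
    contrib <- clamp(z1) - clamp(z0)
    member <- (r[, -nf, drop = FALSE] <= channel$radial_cutoff) |
      (r[, -1L, drop = FALSE] <= channel$radial_cutoff)
    contrib[!member] <- 0
    n <- c(0, cumsum(colSums(contrib) / channel$L))
  }
  structure(list(n = n, N = as.numeric(N), times = traj$times,
                 window_ns = window_ns, L = channel$L),
            class = "collective_series")
}

#' @export
print.collective_series <- function(x, ...) {
  cat("<collective_series> ", length(x$n), " frames, n(final) = ",
      format(x$n[length(x$n)], digits = 4), ", <N> = ",
      format(mean(x$N), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Windowed mean square displacement of n(t)
#'
#' The series is cut into non-overlapping windows of `window_ns`; within
#' each window MSD(tau) is computed over all time origins for lags up to
#' `max_lag_fraction` of the window, and `D_n` is half the OLS slope of
#' MSD(tau) versus tau (free intercept).  A quadratic-term diagnostic
#' flags super-diffusive curvature (e.g. drift, for which MSD ~ t^2).
#'
#' @param series a `collective_series` (or plain numeric n with `dt_ns`).
#' @param window_ns window length in ns (default from the series, 2 ns).
#' @param max_lag_fraction largest lag as a fraction of the window (0.5).
#' @param dt_ns frame stride override.
#' @return list: tau_ns, msd (lag x window matrix), D_n_windows, D_n
#'   (mean), D_n_se (SE over windows), n_windows, superdiffusive flag.
#' @export
msd_of_n <- function(series, window_ns = NULL, max_lag_fraction = 0.5,
                     dt_ns = NULL) {
  if (inherits(series, "collective_series")) {
    n <- series$n
    dt <- dt_ns %||% stats::median(diff(series$times))
    window_ns <- window_ns %||% series$window_ns
  } else {
    n <- as.numeric(series)
    dt <- dt_ns %||% stop("dt_ns required for a plain vector")
    window_ns <- window_ns %||% 2
  }
  W <- max(2L, floor(window_ns / dt))
  nf <- length(n)
  if (nf < W)
    stop("insufficient data: trajectory shorter than one MSD window",
         call. = FALSE)
  nw <- nf %/% W
  mat <- matrix(n[seq_len(nw * W)], nrow = W, ncol = nw)
  max_lag <- max(1L, floor(W * max_lag_fraction))
  msd <- matrix(NA_real_, nrow = max_lag, ncol = nw)
  for (tau in seq_len(max_lag)) {
    d <- mat[(tau + 1L):W, , drop = FALSE] - mat[seq_len(W - tau), ,
                                                 drop = FALSE]
    msd[tau, ] <- colMeans(d * d)
  }
  tau_ns <- seq_len(max_lag) * dt
  Dw <- apply(msd, 2L, function(m)
    unname(coef(lm(m ~ tau_ns))[2L]) / 2)
  msd_bar <- rowMeans(msd)
  fit2 <- lm(msd_bar ~ tau_ns + I(tau_ns^2))
  quad <- coef(fit2)[[3L]]
  lin <- coef(fit2)[[2L]]
  superdiff <- is.finite(quad) && quad > 0 &&
    abs(quad) * max(tau_ns) > 0.5 * abs(lin)
  list(tau_ns = tau_ns, msd = msd, D_n_windows = Dw,
       D_n = mean(Dw), D_n_se = stats::sd(Dw) / sqrt(nw),
       n_windows = nw, superdiffusive = superdiff)
}

#' Osmotic single-channel permeability p_f
#'
#' `p_f = v_w * D_n`, converted from 1/ns to 1/s and reported in units of
#' 1e-14 cm^3/s; the uncertainty of `D_n` propagates linearly.
#'
#' @param D_n collective diffusion coefficient (1/ns), `>= 0`.
#' @param v_w water specific volume (cm^3).
#' @param D_n_se optional standard error of `D_n`.
#' @return p_f in 1e-14 cm^3/s (with attribute `se` when `D_n_se` given).
#' @export
osmotic_permeability <- function(D_n, v_w = water_specific_volume(),
                                 D_n_se = NULL) {
  if (any(D_n < 0)) stop("D_n must be >= 0", call. = FALSE)
  pf <- v_w * D_n * 1e9 / 1e-14
  if (!is.null(D_n_se)) attr(pf, "se") <- v_w * D_n_se * 1e9 / 1e-14
  pf
}

#' Channel occupancy N(t) and its blocked mean
#'
#' @param traj a `trajectory`.
#' @param channel a `channel_spec`.
#' @param block_ns block length for the blocked standard error (default
#'   2 ns, the MSD window).
#' @return list: N (per frame), N_bar, N_se, times.
#' @export
occupancy <- function(traj, channel, block_ns = 2) {
  cs <- collective_coordinate(traj, channel)
  occupancy_from_series(cs$N, cs$times, block_ns)
}

occupancy_from_series <- function(N, times, block_ns = 2) {
  dt <- if (length(times) > 1L) stats::median(diff(times)) else 1
  B <- max(1L, floor(block_ns / dt))
  nb <- max(1L, length(N) %/% B)
  blocks <- vapply(seq_len(nb), function(b)
    mean(N[((b - 1L) * B + 1L):min(b * B, length(N))]), numeric(1))
  list(N = N, N_bar = mean(N),
       N_se = if (nb > 1L) stats::sd(blocks) / sqrt(nb) else NA_real_,
       times = times)
}

#' Per-state permeability estimates (Table-1-analog rows)
#'
#' For each homogeneous gating segment, q0/p_d (event counting), D_n/p_f
#' (windowed MSD of n), and the occupancy N_bar are estimated
#' independently on that segment's frames.  Segments shorter than two MSD
#' windows report p_f as unavailable.
#'
#' @param traj a `trajectory`.
#' @param channel a `channel_spec`.
#' @param segments data.frame from [state_segments()] (columns state,
#'   start, end half-open).
#' @param window_ns MSD window (default 2 ns).
#' @param molar_volume water molar volume, cm^3/mol.
#' @param max_lag_fraction see [msd_of_n()].
#' @return data.frame (class `permeability_estimates`): state, t0, t1,
#'   q0, D_n, D_n_se, p_f, p_f_se, p_d, ratio, N_bar, N_se, n_windows,
#'   n_events.
#' @export
per_state_estimates <- function(traj, channel, segments, window_ns = 2,
                                molar_volume = 18.0,
                                max_lag_fraction = 0.5) {
  nf <- n_frames(traj)
  if (any(segments$start < 1L) || any(segments$end > nf + 1L) ||
      any(segments$end <= segments$start))
    stop("segment outside trajectory", call. = FALSE)
  v_w <- water_specific_volume(molar_volume)
  regions <- track_regions(traj, channel)
  cs <- collective_coordinate(traj, channel, window_ns)
  dt <- frame_dt(traj)
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    fr <- segments$start[i]:(segments$end[i] - 1L)
    times <- traj$times[fr]
    sub <- regions[, fr, drop = FALSE]
    attr(sub, "waters") <- attr(regions, "waters")
    attr(sub, "times") <- times
    ev <- count_events(sub)
    t0 <- times[1L]
    t1 <- times[length(times)]
    dur <- if (length(fr) > 1L) t1 - t0 + dt else dt
    q0 <- mean(c(sum(ev$direction > 0), sum(ev$direction < 0))) / dur
    p_d <- diffusive_permeability(q0, v_w)
    nsub <- cs$n[fr] - cs$n[fr[1L]]
    W <- max(2L, floor(window_ns / dt))
    if (length(fr) >= 2L * W) {
      m <- msd_of_n(nsub, window_ns = window_ns,
                    max_lag_fraction = max_lag_fraction, dt_ns = dt)
      D_n <- max(0, m$D_n); D_se <- m$D_n_se; nwin <- m$n_windows
      p_f <- osmotic_permeability(D_n, v_w)
      p_f_se <- v_w * D_se * 1e9 / 1e-14
    } else {
      D_n <- NA_real_; D_se <- NA_real_; nwin <- 0L
      p_f <- NA_real_; p_f_se <- NA_real_
    }
    occ <- occupancy_from_series(cs$N[fr], times, window_ns)
    data.frame(state = segments$state[i], t0 = t0, t1 = t1, q0 = q0,
               D_n = D_n, D_n_se = D_se, p_f = p_f, p_f_se = p_f_se,
               p_d = p_d,
               ratio = if (!is.na(p_f) && p_d > 0) p_f / p_d else NA_real_,
               N_bar = occ$N_bar, N_se = occ$N_se,
               n_windows = nwin, n_events = nrow(ev),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("permeability_estimates", "data.frame")
  out
}

#' Single-file CTRW consistency check
#'
#' For ideal single-file transport the continuous-time random-walk model
#' predicts `p_f / p_d = N + 1` with `N` the mean channel occupancy.  The
#' ratio is reported to 2 decimals; when `p_d = 0` it is undefined and
#' flagged (never infinity).
#'
#' @param p_f,p_d permeabilities (same units).
#' @param N_bar mean channel occupancy.
#' @return list: ratio (2 decimals, NA when undefined), predicted
#'   (`N_bar + 1`), deviation (ratio - predicted), defined (logical).
#' @export
ctrw_check <- function(p_f, p_d, N_bar = NA_real_) {
  defined <- is.finite(p_d) && p_d > 0 && is.finite(p_f)
  ratio <- if (defined) round(p_f / p_d, 2) else NA_real_
  predicted <- N_bar + 1
  list(ratio = ratio, predicted = predicted,
       deviation = if (defined) ratio - predicted else NA_real_,
       defined = defined)
}
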