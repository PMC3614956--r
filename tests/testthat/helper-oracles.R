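# Independent oracles used against the package implementations.  These are
# deliberately naive (brute force / alternative formulas) and share no code
# with the functions they check.

# distance by explicit minimum over all 27 periodic images
oracle_min_image_distance <- function(p, q, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- p - (q + c(ix, iy, iz) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# torsion via the projection ("Praxeolitic") formulation
oracle_dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b2 <- p4 - p3
  b1 <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  cr <- c(b1[2] * v[3] - b1[3] * v[2],
          b1[3] * v[1] - b1[1] * v[3],
          b1[1] * v[2] - b1[2] * v[1])
  y <- sum(cr * w)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# exhaustive per-frame scan of one water's region series
# regions coded 0 below, 1 inside, 2 above, 3 outside
oracle_events_one <- function(r) {
  dirs <- integer(0); entries <- integer(0); exits <- integer(0)
  origin <- NA_character_; origin_last <- NA_integer_; passed <- FALSE
  for (t in seq_along(r)) {
    reg <- r[t]
    if (reg == 1L) passed <- TRUE
    if (reg == 0L) {
      if (identical(origin, "above") && passed) {
        dirs <- c(dirs, -1L); entries <- c(entries, origin_last)
        exits <- c(exits, t)
      }
      passed <- FALSE; origin <- "below"; origin_last <- t
    } else if (reg == 2L) {
      if (identical(origin, "below") && passed) {
        dirs <- c(dirs, 1L); entries <- c(entries, origin_last)
        exits <- c(exits, t)
      }
      passed <- FALSE; origin <- "above"; origin_last <- t
    }
  }
  data.frame(direction = dirs, entry_frame = entries, exit_frame = exits)
}

oracle_events <- function(regions) {
  waters <- attr(regions, "waters")
  if (is.null(waters)) waters <- seq_len(nrow(regions))
  out <- do.call(rbind, lapply(seq_len(nrow(regions)), function(w) {
    e <- oracle_events_one(regions[w, ])
    if (nrow(e)) cbind(water_id = waters[w], e) else NULL
  }))
  if (is.null(out))
    out <- data.frame(water_id = integer(0), direction = integer(0),
                      entry_frame = integer(0), exit_frame = integer(0))
  out <- out[order(out$exit_frame, out$water_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive xy-grid maximal-sphere radius at resolution `res`
oracle_slice_radius <- function(coords, vdw, z, half_width = 8, res = 0.01) {
  g <- seq(-half_width, half_width, by = res)
  dz2 <- (z - coords[, 3])^2
  best <- -Inf
  for (x in g) {
    dx2 <- (x - coords[, 1])^2
    rowmin <- rep(Inf, length(g))
    for (a in seq_len(nrow(coords))) {
      rowmin <- pmin(rowmin,
                     sqrt((g - coords[a, 2])^2 + dx2[a] + dz2[a]) - vdw[a])
    }
    best <- max(best, max(rowmin))
  }
  max(0, best)
}

# direct band lookup with no smoothing/hysteresis
oracle_band <- function(v, cutoffs, labels) {
  labels[findInterval(v, cutoffs) + 1L]
}

# build a plain water-only trajectory from a z-position matrix
# (waters x frames), all on the channel axis
make_z_trajectory <- function(zmat, box = c(40, 40, 200), dt_ns = 0.1,
                              x = 0, y = 0) {
  M <- nrow(zmat); F <- ncol(zmat)
  top <- topology(rep("OH2", M), "TIP3", seq_len(M), "W", element = "O")
  coords <- array(0, dim = c(M, 3L, F))
  coords[, 1L, ] <- x
  coords[, 2L, ] <- y
  coords[, 3L, ] <- zmat
  trajectory(top, coords, box, dt_ns = dt_ns)
}
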