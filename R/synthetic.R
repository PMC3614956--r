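# Ground-truth synthetic data: single-file water columns (hopping CTRW and
# collective Brownian modes), telegraph order-parameter series, toy pore
# geometries with analytic radius profiles, and a minimal gating fixture
# containing the four key residues (His67, Ile165, His173, Ser183).

#' Generate a single-file water trajectory with known transport truth
#'
#' Waters are evenly spaced along a z-aligned cylindrical channel of length
#' `L`, with reservoir waters (2x the channel occupancy per side) in bulk
#' slabs beyond both mouths so entry/exit logic is exercised.
#'
#' In `"ctrw"` mode the water file performs collective hops of one site
#' spacing `a = L / n_waters` as a Poisson process of rate `k` per
#' direction: each hop pushes the end water into the destination bulk slab
#' and feeds a reservoir water in at the opposite mouth.  One hop advances
#' the collective coordinate n by exactly 1, so the collective diffusion
#' coefficient is `D_n = k`; a water entering at the first site completes a
#' full transit with probability `1/(n_waters+1)` (gambler's ruin), so the
#' one-directional transit rate is `q0 = k/(n_waters+1)` and the ideal
#' single-file relation `p_f/p_d = n_waters + 1` holds exactly.  Completed
#' ground-truth transits are logged.
#'
#' In `"brownian"` mode the column (a periodic ring of waters) undergoes
#' rigid Gaussian displacements calibrated so that the collective
#' coordinate has `Var(dn) = 2 * D_n_true * dt` per step.
#'
#' @param n_waters channel occupancy (>= 1).
#' @param L channel length in Angstrom (default 20).
#' @param mode `"ctrw"` or `"brownian"`.
#' @param k CTRW hop rate per direction, 1/ns (>= 0).
#' @param D_n_true Brownian collective diffusion coefficient, 1/ns.
#' @param duration_ns,dt_ns total time and frame stride
#'   (`duration_ns >= 100 * dt_ns`).
#' @param seed integer seed; same seed gives bitwise-identical output.
#' @return list with `trajectory` and `truth` (class `single_file_truth`):
#'   n_waters, L, mode, rates, expected_pf/expected_pd (1e-14 cm^3/s),
#'   events (ground-truth transit log), seed.
#' @export
gen_single_file <- function(n_waters = 7, L = 20,
                            mode = c("ctrw", "brownian"),
                            k = 0.5, D_n_true = NULL,
                            duration_ns = 100, dt_ns = 0.1, seed = 1) {
  mode <- match.arg(mode)
  if (n_waters < 1) stop("n_waters must be >= 1", call. = FALSE)
  if (duration_ns < 100 * dt_ns)
    stop("duration_ns must be >= 100 * dt_ns", call. = FALSE)
  if (mode == "ctrw" && (!is.numeric(k) || k < 0))
    stop("hop rate k must be >= 0", call. = FALSE)
  if (mode == "brownian" && (is.null(D_n_true) || D_n_true < 0))
    stop("D_n_true must be >= 0 in brownian mode", call. = FALSE)

  N <- as.integer(n_waters)
  a <- L / N
  z_lo <- -L / 2; z_hi <- L / 2
  n_res <- 2L * N                      # reservoir waters per side
  M <- N + 2L * n_res
  tf <- seq(0, duration_ns, by = dt_ns)
  F <- length(tf)
  v_w <- water_specific_volume()

  res <- with_private_seed(seed, {
    if (mode == "ctrw") gen_ctrw_column(N, a, z_lo, z_hi, n_res, k,
                                        duration_ns, tf)
    else gen_brownian_column(N, a, z_lo, z_hi, n_res, D_n_true, tf)
  })

  top <- topology(atom_name = rep("OH2", M), residue_name = "TIP3",
                  residue_number = seq_len(M), chain_id = "W",
                  element = "O")
  coords <- array(0, dim = c(M, 3L, F))
  coords[, 3L, ] <- res$z
  traj <- trajectory(top, coords, box = c(40, 40, res$Lz), times = tf)

  truth <- structure(list(
    n_waters = N, L = L, mode = mode,
    k = if (mode == "ctrw") k else NA_real_,
    D_n_true = if (mode == "ctrw") k else D_n_true,
    expected_pf = osmotic_permeability(if (mode == "ctrw") k else D_n_true,
                                       v_w),
    expected_pd = if (mode == "ctrw")
      osmotic_permeability(k, v_w) / (N + 1) else NA_real_,
    expected_ratio = if (mode == "ctrw") N + 1 else NA_real_,
    events = res$events, seed = seed,
    z_lo = z_lo, z_hi = z_hi),
    class = "single_file_truth")
  list(trajectory = traj, truth = truth)
}

# Collective hopping column (CTRW mode).  Runs the exact event-time chain,
# then snapshots positions at the frame times.
gen_ctrw_column <- function(N, a, z_lo, z_hi, n_res, k, T, tf) {
  depth0 <- 3                          # first bulk slot beyond the buffer
  M <- N + 2L * n_res
  # enough bulk slots per side to hold every water (net drift can pile the
  # reservoir up on one side)
  slot_z_below <- z_lo - depth0 - (seq_len(M) - 1L) * a
  slot_z_above <- z_hi + depth0 + (seq_len(M) - 1L) * a
  Lz <- 2 * (z_hi + depth0 + M * a + 2)

  # hop times: merged Poisson process of rate 2k, fair signs
  if (k > 0) {
    gaps <- rexp(ceiling(4 * 2 * k * T + 50), rate = 2 * k)
    ht <- cumsum(gaps)
    while (ht[length(ht)] < T) {
      gaps <- rexp(length(gaps), rate = 2 * k)
      ht <- c(ht, ht[length(ht)] + cumsum(gaps))
    }
    ht <- ht[ht <= T]
    sign <- sample(c(1L, -1L), length(ht), replace = TRUE)
  } else {
    ht <- numeric(0); sign <- integer(0)
  }
  nh <- length(ht)

  site_water <- seq_len(N)             # water id at channel sites 1..N
  below_q <- (N + 1L):(N + n_res)      # FIFO, head enters next
  above_q <- (N + n_res + 1L):M
  slot_below <- seq_len(n_res)         # slot index per queue position
  slot_above <- seq_len(n_res)
  origin <- rep(NA_character_, M)
  origin[below_q] <- "below"
  origin[above_q] <- "above"

  zpos <- numeric(M)
  zpos[site_water] <- z_lo + (seq_len(N) - 0.5) * a
  zpos[below_q] <- slot_z_below[slot_below]
  zpos[above_q] <- slot_z_above[slot_above]

  snaps <- matrix(0, nrow = M, ncol = nh + 1L)
  snaps[, 1L] <- zpos
  ev_time <- numeric(0); ev_dir <- integer(0); ev_water <- integer(0)

  pop_front <- function(q) list(x = q[1L], q = q[-1L])
  for (h in seq_len(nh)) {
    if (sign[h] > 0) {
      if (length(below_q) == 0L) {     # recycle across the periodic box
        last <- length(above_q)
        w <- above_q[last]; s <- slot_above[last]
        above_q <- above_q[-last]; slot_above <- slot_above[-last]
        sfree <- setdiff(seq_len(length(slot_z_below)), slot_below)[1L]
        below_q <- c(below_q, w); slot_below <- c(slot_below, sfree)
        origin[w] <- "below"
        zpos[w] <- slot_z_below[sfree]
      }
      entrant <- below_q[1L]; sfreed <- slot_below[1L]
      below_q <- below_q[-1L]; slot_below <- slot_below[-1L]
      leaver <- site_water[N]
      site_water <- c(entrant, site_water[-N])
      if (identical(origin[leaver], "below")) {
        ev_time <- c(ev_time, ht[h]); ev_dir <- c(ev_dir, 1L)
        ev_water <- c(ev_water, leaver)
      }
      origin[leaver] <- "above"
      sfree <- setdiff(seq_len(length(slot_z_above)), slot_above)[1L]
      above_q <- c(above_q, leaver); slot_above <- c(slot_above, sfree)
      zpos[leaver] <- slot_z_above[sfree]
      zpos[site_water] <- z_lo + (seq_len(N) - 0.5) * a
    } else {
      if (length(above_q) == 0L) {
        last <- length(below_q)
        w <- below_q[last]; s <- slot_below[last]
        below_q <- below_q[-last]; slot_below <- slot_below[-last]
        sfree <- setdiff(seq_len(length(slot_z_above)), slot_above)[1L]
        above_q <- c(above_q, w); slot_above <- c(slot_above, sfree)
        origin[w] <- "above"
        zpos[w] <- slot_z_above[sfree]
      }
      entrant <- above_q[1L]
      above_q <- above_q[-1L]; slot_above <- slot_above[-1L]
      leaver <- site_water[1L]
      site_water <- c(site_water[-1L], entrant)
      if (identical(origin[leaver], "above")) {
        ev_time <- c(ev_time, ht[h]); ev_dir <- c(ev_dir, -1L)
        ev_water <- c(ev_water, leaver)
      }
      origin[leaver] <- "below"
      sfree <- setdiff(seq_len(length(slot_z_below)), slot_below)[1L]
      below_q <- c(below_q, leaver); slot_below <- c(slot_below, sfree)
      zpos[leaver] <- slot_z_below[sfree]
      zpos[site_water] <- z_lo + (seq_len(N) - 0.5) * a
    }
    snaps[, h + 1L] <- zpos
  }
  idx <- findInterval(tf, ht) + 1L
  list(z = snaps[, idx, drop = FALSE], Lz = Lz,
       events = data.frame(time_ns = ev_time, direction = ev_dir,
                           water_id = ev_water))
}

# Rigid Brownian ring column (brownian mode)
gen_brownian_column <- function(N, a, z_lo, z_hi, n_res, D_n, tf) {
  M <- N + 2L * n_res
  P <- M * a                           # ring period; equals the box length
  u0 <- -P / 2 + (seq_len(M) - 0.5) * a
  dt <- tf[2L] - tf[1L]
  sd_z <- sqrt(2 * D_n * dt) * (z_hi - z_lo) / N
  s <- c(0, cumsum(rnorm(length(tf) - 1L, 0, sd_z)))
  z <- outer(u0, s, "+")
  z <- z - P * round(z / P)            # wrap onto the ring
  list(z = z, Lz = P,
       events = data.frame(time_ns = numeric(0), direction = integer(0),
                           water_id = integer(0)))
}

#' @export
print.single_file_truth <- function(x, ...) {
  cat("<single_file_truth> ", x$mode, ": N = ", x$n_waters, ", L = ", x$L,
      " A, D_n = ", format(x$D_n_true), "/ns, ", nrow(x$events),
      " ground-truth transits\n", sep = "")
  invisible(x)
}

#' Generate a telegraph (Markov-switching) order-parameter series
#'
#' A continuous-time Markov chain switches between emission regimes; frame
#' values are Gaussian around the state mean.  The generated labels are
#' returned as ground truth for classifier-recovery tests.
#'
#' @param state_means,state_sds per-state emission mean/sd (Angstrom).
#' @param switch_rates rate of leaving each state (1/ns); scalar or
#'   per-state.  The next state is uniform over the other states.
#' @param duration_ns,dt_ns total time and frame stride.
#' @param seed integer seed.
#' @param name series name (default "D2").
#' @return list: `op` (an `op_series`) and `truth` (class
#'   `telegraph_truth`): labels (state index per frame), switch_times,
#'   means, sds, rates, seed.
#' @export
gen_two_state_op <- function(state_means, state_sds, switch_rates,
                             duration_ns = 100, dt_ns = 0.1, seed = 1,
                             name = "D2") {
  S <- length(state_means)
  stopifnot(S >= 1L, length(state_sds) %in% c(1L, S))
  state_sds <- rep_len(state_sds, S)
  if (any(state_sds <= 0)) stop("state sds must be > 0", call. = FALSE)
  rates <- rep_len(switch_rates, S)
  if (any(rates < 0)) stop("switch_rates must be >= 0", call. = FALSE)
  tf <- seq(0, duration_ns, by = dt_ns)
  res <- with_private_seed(seed, {
    st <- 1L; t <- 0
    sw_t <- numeric(0); sw_s <- integer(0)
    if (S > 1L) repeat {
      r <- rates[st]
      if (r <= 0) break
      t <- t + rexp(1L, r)
      if (t > duration_ns) break
      st <- sample(setdiff(seq_len(S), st), 1L)
      sw_t <- c(sw_t, t); sw_s <- c(sw_s, st)
    }
    labels <- c(1L, sw_s)[findInterval(tf, sw_t) + 1L]
    values <- rnorm(length(tf), state_means[labels], state_sds[labels])
    list(labels = labels, values = values, switch_times = sw_t)
  })
  op <- new_op_series(name, res$values, tf, units = "A",
                      kind = "distance", atoms = integer(0))
  truth <- structure(list(labels = res$labels,
                          switch_times = res$switch_times,
                          means = state_means, sds = state_sds,
                          rates = rates, seed = seed),
                     class = "telegraph_truth")
  list(op = op, truth = truth)
}

#' Generate a toy pore geometry with an analytic radius profile
#'
#' Pseudo-atoms are placed on rings around the z axis densely enough that
#' the maximal-sphere pore radius matches the analytic envelope.
#'
#' * `"ring"`: a single ring of atom centers at `ring_radius`; the pore
#'   radius at the ring plane is `ring_radius - vdw`.
#' * `"cylinder"`: constant pore radius `radius` (centers at
#'   `radius + vdw`).
#' * `"hourglass"`: pore radius `waist + curvature * z^2`.
#'
#' @param kind `"cylinder"`, `"hourglass"` or `"ring"`.
#' @param radius,waist,curvature,ring_radius geometry parameters (A).
#' @param half_length half-extent of the pore along z (A).
#' @param vdw van der Waals radius of the pseudo-atoms.
#' @param ring_spacing z spacing of atom rings.
#' @param n_ring atoms per ring.
#' @param center xyz offset applied to the whole geometry.
#' @return list: `topology`, `trajectory` (one frame), and
#'   `analytic_radius`, a function of z (in the untranslated frame).
#' @export
gen_toy_pore <- function(kind = c("cylinder", "hourglass", "ring"),
                         radius = 4, waist = 1, curvature = 0.05,
                         ring_radius = 5, half_length = 10, vdw = 1.5,
                         ring_spacing = 0.25, n_ring = 64,
                         center = c(0, 0, 0)) {
  kind <- match.arg(kind)
  if (vdw <= 0 || half_length <= 0 || n_ring < 8)
    stop("invalid toy-pore geometry parameters", call. = FALSE)
  if (kind == "ring") {
    if (ring_radius <= vdw) stop("ring_radius must exceed vdw",
                                 call. = FALSE)
    zj <- 0
    Rc <- ring_radius
  } else {
    zj <- seq(-half_length, half_length, by = ring_spacing)
    Rc <- if (kind == "cylinder") rep(radius + vdw, length(zj))
          else waist + curvature * zj^2 + vdw
    if (any(Rc <= vdw)) stop("pore radius must be > 0 everywhere",
                             call. = FALSE)
  }
  ang <- (seq_len(n_ring) - 1L) * 2 * pi / n_ring
  xyz <- do.call(rbind, lapply(seq_along(zj), function(j)
    cbind(Rc[j] * cos(ang), Rc[j] * sin(ang), zj[j])))
  xyz <- sweep(xyz, 2L, center, "+")
  n <- nrow(xyz)
  top <- topology(atom_name = rep("C", n), residue_name = "POR",
                  residue_number = seq_len(n), chain_id = "P",
                  element = "C", vdw = rep(vdw, n))
  traj <- trajectory(top, xyz, box = c(200, 200, 200))
  zj_loc <- zj; Rc_loc <- Rc; vdw_loc <- vdw
  analytic <- function(z) {
    vapply(z, function(zz)
      max(0, min(sqrt((zz - zj_loc)^2 + Rc_loc^2)) - vdw_loc), numeric(1))
  }
  list(topology = top, trajectory = traj, analytic_radius = analytic)
}

# NeRF placement: position p4 given p1..p3, bond length r (p3-p4), bond
# angle theta (p2-p3-p4) and torsion tau (p1-p2-p3-p4), degrees.
place_atom_nerf <- function(p1, p2, p3, r, theta, tau) {
  th <- theta * pi / 180; ta <- tau * pi / 180
  bc <- p3 - p2; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(p2 - p1, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- c(-r * cos(th), r * sin(th) * cos(ta), r * sin(th) * sin(ta))
  p3 + d[1] * bc + d[2] * m + d[3] * n
}

#' Generate a minimal gating fixture (His67, Ile165, His173, Ser183)
#'
#' Builds a PDB-writable single-frame system in which the selectivity
#' filter distance D1 (His173:NE2 -- Ser183:O), the cytoplasmic-end
#' distance D2 (His67:CB -- Ile165:CD) and the two sidechain dihedrals
#' (His173 CA-CG-CD2-NE2; His67 CG-CB-CA-C) equal the requested values
#' exactly.
#'
#' @param d1,d2 requested distances in Angstrom (>= 0).
#' @param chi_sf His173 ring dihedral CA-CG-CD2-NE2 (degrees).
#' @param chi_ce His67 sidechain dihedral CG-CB-CA-C (degrees).
#' @param ile_cd_name atom name used for the Ile165 delta carbon ("CD" or
#'   "CD1"; both PDB dialects occur).
#' @return list: `topology`, `trajectory` (one frame).
#' @export
gen_gating_fixture <- function(d1 = 4, d2 = 8, chi_sf = 180, chi_ce = 60,
                               ile_cd_name = "CD") {
  if (!is.numeric(d1) || !is.numeric(d2) || d1 < 0 || d2 < 0)
    stop("requested distances must be >= 0", call. = FALSE)
  if (!ile_cd_name %in% c("CD", "CD1"))
    stop("ile_cd_name must be 'CD' or 'CD1'", call. = FALSE)
  build_quad <- function(tau) {
    p1 <- c(0, 0, 0)
    p2 <- c(1.5, 0, 0)
    p3 <- p2 + 1.4 * c(cos(pi / 3), sin(pi / 3), 0)
    p4 <- place_atom_nerf(p1, p2, p3, 1.35, 111, tau)
    rbind(p1, p2, p3, p4)
  }
  # His173 chain CA-CG-CD2-NE2, anchored so NE2 sits at (d1, 0, 0);
  # Ser183's backbone O sits at the origin -> D1 = d1 exactly.
  q_sf <- build_quad(chi_sf)
  q_sf <- sweep(q_sf, 2L, q_sf[4L, ] - c(d1, 0, 0), "-")
  o_ser <- c(0, 0, 0)
  # His67 chain CG-CB-CA-C, anchored so CB (2nd atom) sits at
  # (d2, 25, 0); Ile165:CD at (0, 25, 0) -> D2 = d2 exactly.
  q_ce <- build_quad(chi_ce)
  q_ce <- sweep(q_ce, 2L, q_ce[2L, ] - c(d2, 25, 0), "-")
  cd_ile <- c(0, 25, 0)

  atom_name <- c("CG", "CB", "CA", "C", ile_cd_name,
                 "CA", "CG", "CD2", "NE2", "O")
  residue_name <- c(rep("HIS", 4), "ILE", rep("HIS", 4), "SER")
  residue_number <- c(rep(67L, 4), 165L, rep(173L, 4), 183L)
  xyz <- rbind(q_ce, cd_ile, q_sf, o_ser)
  top <- topology(atom_name, residue_name, residue_number, chain_id = "A")
  traj <- trajectory(top, xyz, box = c(60, 60, 60))
  list(topology = top, trajectory = traj)
}
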