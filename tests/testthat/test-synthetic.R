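# Synthetic-data generators: determinism, ground-truth bookkeeping and
# agreement with independent oracles on the generated paths.

test_that("generators are bitwise deterministic under a fixed seed", {
  a <- gen_single_file(duration_ns = 20, dt_ns = 0.1, k = 0.5, seed = 9)
  b <- gen_single_file(duration_ns = 20, dt_ns = 0.1, k = 0.5, seed = 9)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$truth$events, b$truth$events)
  c <- gen_single_file(duration_ns = 20, dt_ns = 0.1, k = 0.5, seed = 10)
  expect_false(identical(a$trajectory$coords, c$trajectory$coords))

  t1 <- gen_two_state_op(c(5.5, 8), 0.3, 0.05, duration_ns = 50, seed = 4)
  t2 <- gen_two_state_op(c(5.5, 8), 0.3, 0.05, duration_ns = 50, seed = 4)
  expect_identical(t1$op$values, t2$op$values)

  # generator must not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_single_file(duration_ns = 15, seed = 2))
  expect_identical(rnorm(1), before)
})

test_that("CTRW mode with k = 0 is static with zero permeations", {
  g <- gen_single_file(n_waters = 7, k = 0, duration_ns = 10,
                       dt_ns = 0.1, seed = 1)
  expect_equal(n_frames(g$trajectory), 101L)
  expect_equal(nrow(g$truth$events), 0L)
  rng <- apply(g$trajectory$coords, c(1, 2), function(v)
    max(v) - min(v))
  expect_equal(max(rng), 0)
  ch <- channel_spec(g$truth$z_lo, g$truth$z_hi)
  expect_equal(nrow(count_events(track_regions(g$trajectory, ch))), 0L)
})

test_that("CTRW truth records pf/pd ratio n_waters + 1 and the event log matches the path", {
  g <- gen_single_file(n_waters = 7, k = 0.5, duration_ns = 400,
                       dt_ns = 0.05, seed = 11)
  expect_equal(g$truth$expected_pf / g$truth$expected_pd, 8)

  # event-count oracle on the generated path (not theory): the pipeline's
  # region automaton and the exhaustive scan must agree, and both must be
  # close to the generator's own transit log (snapshot aliasing can hide
  # a transit that completes between two frames, so exact equality with
  # the log is not required)
  ch <- channel_spec(g$truth$z_lo, g$truth$z_hi)
  reg <- track_regions(g$trajectory, ch)
  ev <- count_events(reg)
  orc <- oracle_events(reg)
  expect_equal(as.data.frame(ev), orc, ignore_attr = TRUE)
  n_log <- nrow(g$truth$events)
  expect_lt(abs(nrow(ev) - n_log), max(5, 0.15 * n_log))

  # long-run one-directional rate vs the k/(N+1) construction
  q0 <- permeation_rate(ev, 0, 400)$q0
  expect_lt(abs(q0 - 0.5 / 8) / (0.5 / 8), 0.35)
})

test_that("brownian mode MSD slope recovers D_n_true", {
  Dhat <- vapply(1:2, function(s) {
    g <- gen_single_file(n_waters = 7, mode = "brownian", D_n_true = 0.2,
                         duration_ns = 100, dt_ns = 0.01, seed = s)
    cs <- collective_coordinate(g$trajectory,
                                channel_spec(g$truth$z_lo, g$truth$z_hi))
    msd_of_n(cs, window_ns = 2)$D_n
  }, numeric(1))
  expect_lt(abs(mean(Dhat) - 0.2) / 0.2, 0.30)
})

test_that("generator rejects invalid parameters", {
  expect_error(gen_single_file(n_waters = 0), "n_waters")
  expect_error(gen_single_file(k = -1), "k must be")
  expect_error(gen_single_file(mode = "brownian", D_n_true = -0.1),
               "D_n_true")
  expect_error(gen_single_file(duration_ns = 1, dt_ns = 0.1),
               "duration")
  expect_error(gen_two_state_op(c(5, 8), c(0.3, -1), 0.1), "sds")
  expect_error(gen_two_state_op(c(5, 8), 0.3, -0.1), "switch_rates")
})

test_that("telegraph generator honors degenerate and three-state setups", {
  g0 <- gen_two_state_op(c(5.5, 8), 0.3, switch_rates = 0,
                         duration_ns = 50, seed = 2)
  expect_true(all(g0$truth$labels == 1L))

  g3 <- gen_two_state_op(c(5.5, 7.0, 8.5), 0.3, 0.05, duration_ns = 200,
                         dt_ns = 0.1, seed = 6)
  mid <- g3$op$values[g3$truth$labels == 2L]
  expect_gt(length(mid), 50)
  expect_gt(mean(mid > 6.5 & mid < 7.5), 0.9)   # occupies the printed band
})

test_that("toy pores match their analytic radii", {
  ring <- gen_toy_pore("ring", ring_radius = 5, vdw = 1.5, n_ring = 64)
  expect_equal(ring$analytic_radius(0), 3.5)
  sr <- slice_radius(frame_coords(ring$trajectory, 1), ring$topology$vdw,
                     z = 0)
  expect_equal(sr$radius, 3.5, tolerance = 1e-6)

  hg <- gen_toy_pore("hourglass", waist = 1.0, curvature = 0.05,
                     half_length = 8)
  zg <- seq(-5, 5, by = 0.5)
  expect_equal(which.min(hg$analytic_radius(zg)), which(zg == 0))
  expect_equal(hg$analytic_radius(0), 1.0, tolerance = 1e-6)

  # randomized cylinder against the dense-grid brute force
  withr::local_seed(55)
  r0 <- runif(1, 3, 5)
  cyl <- gen_toy_pore("cylinder", radius = r0, half_length = 3,
                      ring_spacing = 0.5, n_ring = 32)
  xyz <- frame_coords(cyl$trajectory, 1)
  for (z in c(-1.3, 0.7)) {
    grid <- oracle_slice_radius(xyz, cyl$topology$vdw, z,
                                half_width = r0 / 2, res = 0.01)
    fast <- slice_radius(xyz, cyl$topology$vdw, z)$radius
    expect_lt(abs(fast - grid), 0.02)
  }
  expect_error(gen_toy_pore("ring", ring_radius = 1, vdw = 1.5),
               "exceed")
})

test_that("gating fixture realizes requested geometry exactly", {
  g <- gen_gating_fixture(d1 = 4.0, d2 = 7.0, chi_sf = 180, chi_ce = 60)
  top <- g$topology
  xyz <- frame_coords(g$trajectory, 1)
  box <- g$trajectory$box[, 1]
  i <- function(rn, an) as.integer(select_atoms(top, residue_number = rn,
                                                atom_name = an))
  expect_equal(min_image_distance(xyz[i(173, "NE2"), ],
                                  xyz[i(183, "O"), ], box), 4.0,
               tolerance = 1e-6)
  expect_equal(min_image_distance(xyz[i(67, "CB"), ],
                                  xyz[i(165, "CD"), ], box), 7.0,
               tolerance = 1e-6)
  expect_equal(dihedral_angle(xyz[i(173, "CA"), ], xyz[i(173, "CG"), ],
                              xyz[i(173, "CD2"), ], xyz[i(173, "NE2"), ]),
               180, tolerance = 1e-6)
  expect_equal(dihedral_angle(xyz[i(67, "CG"), ], xyz[i(67, "CB"), ],
                              xyz[i(67, "CA"), ], xyz[i(67, "C"), ]),
               60, tolerance = 1e-6)

  # D2 = 7.0 falls in the intermediate band
  d2 <- op_series(g$trajectory,
                  list(select_atoms(top, "HIS", 67, "CB"),
                       select_atoms(top, "ILE", 165, "CD")), "distance")
  st <- classify_states(d2, c(6.5, 7.5),
                        c("closed", "intermediate", "open"),
                        hysteresis = 0, smoothing_window = 1)
  expect_equal(st$labels, "intermediate")

  expect_error(gen_gating_fixture(d1 = -1), ">= 0")
})
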