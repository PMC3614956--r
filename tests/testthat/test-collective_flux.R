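# Collective coordinate n(t), windowed MSD, p_f, occupancy, per-state
# estimates and the CTRW check.

test_that("one full transit advances n by exactly 1; static systems give n = 0", {
  # water crossing z_lo -> z_hi while inside, plus an idle bulk water
  z <- rbind(seq(-10, 10, length.out = 21), rep(-20, 21))
  tr <- make_z_trajectory(z)
  ch <- channel_spec(-10, 10)
  cs <- collective_coordinate(tr, ch)
  expect_equal(cs$n[1], 0)
  expect_equal(cs$n[length(cs$n)], 1.0)

  static <- make_z_trajectory(matrix(3, 2, 50))
  expect_true(all(collective_coordinate(static, ch)$n == 0))
})

test_that("full crossing in one step still contributes exactly 1", {
  z <- rbind(c(-15, -11, 15, 15))
  cs <- collective_coordinate(make_z_trajectory(z), channel_spec(-10, 10))
  expect_equal(cs$n[length(cs$n)], 1.0)
})

test_that("final n matches the generator's net transit count up to boundary terms", {
  g <- gen_single_file(n_waters = 7, k = 0.5, duration_ns = 300,
                       dt_ns = 0.05, seed = 31)
  cs <- collective_coordinate(g$trajectory, channel_spec(-10, 10))
  net <- sum(g$truth$events$direction)
  expect_lte(abs(cs$n[length(cs$n)] - net), 8)   # waters still in transit
})

test_that("msd_of_n recovers a simple random walk and flags drift", {
  withr::local_seed(19)
  # fair +/-1 coin flip per frame: MSD(tau) = tau frames, D = 0.5/frame
  n <- cumsum(sample(c(-1, 1), 20000, replace = TRUE))
  m <- msd_of_n(n, window_ns = 200, dt_ns = 1)   # windows of 200 frames
  # the mean MSD curve is MSD(tau) = tau to Monte-Carlo error ...
  msd_bar <- rowMeans(m$msd)
  expect_lt(max(abs(msd_bar[1:20] - m$tau_ns[1:20]) / m$tau_ns[1:20]),
            0.10)
  # ... and the windowed OLS slope gives D = 0.5/frame
  expect_lt(abs(m$D_n - 0.5) / 0.5, 0.15)
  expect_false(m$superdiffusive)
  expect_equal(m$n_windows, 100L)

  drift <- msd_of_n((1:4000) * 0.05, window_ns = 200, dt_ns = 1)
  expect_true(drift$superdiffusive)

  expect_error(msd_of_n(rnorm(10), window_ns = 100, dt_ns = 1),
               "insufficient")
})

test_that("osmotic_permeability arithmetic and linearity", {
  v <- water_specific_volume(18.0)
  expect_equal(osmotic_permeability(0, v), 0)
  expect_equal(osmotic_permeability(1.161, v), 3.47, tolerance = 1e-3)
  expect_equal(osmotic_permeability(2.5, v),
               2.5 * osmotic_permeability(1, v))
  pf <- osmotic_permeability(1.0, v, D_n_se = 0.1)
  expect_equal(attr(pf, "se"), 0.1 * osmotic_permeability(1, v))
  expect_error(osmotic_permeability(-0.1, v), ">= 0")
})

test_that("occupancy counts inside waters with a blocked SE", {
  z <- matrix(rep(seq(-7.5, 7.5, length.out = 7), 40), 7, 40)
  tr <- make_z_trajectory(z)
  occ <- occupancy(tr, channel_spec(-10, 10), block_ns = 1)
  expect_equal(occ$N_bar, 7.0)
  expect_equal(occ$N_se, 0)

  empty <- make_z_trajectory(matrix(-30, 2, 40))
  expect_equal(occupancy(empty, channel_spec(-10, 10))$N_bar, 0)
})

test_that("p_f is invariant under rigid translation of system + channel", {
  g <- gen_single_file(n_waters = 7, k = 0.5, duration_ns = 100,
                       dt_ns = 0.05, seed = 41)
  cs0 <- collective_coordinate(g$trajectory, channel_spec(-10, 10))
  tr2 <- g$trajectory
  tr2$coords[, 1, ] <- tr2$coords[, 1, ] + 5
  tr2$coords[, 2, ] <- tr2$coords[, 2, ] - 3
  tr2$coords[, 3, ] <- tr2$coords[, 3, ] + 11.7
  cs1 <- collective_coordinate(tr2, channel_spec(-10 + 11.7, 10 + 11.7,
                                                 center = c(5, -3)))
  expect_equal(cs1$n, cs0$n, tolerance = 1e-9)
  expect_equal(cs1$N, cs0$N)
})

test_that("doubling L with the same hop dynamics leaves p_f unchanged (scaled property)", {
  # same hopping physics, channel twice as long holding twice the waters:
  # per-hop dn stays 1, so D_n (and p_f) is unchanged while occupancy
  # doubles
  g1 <- gen_single_file(n_waters = 7, L = 20, k = 0.4, duration_ns = 300,
                        dt_ns = 0.05, seed = 51)
  g2 <- gen_single_file(n_waters = 14, L = 40, k = 0.4, duration_ns = 300,
                        dt_ns = 0.05, seed = 52)
  m1 <- msd_of_n(collective_coordinate(g1$trajectory,
                                       channel_spec(-10, 10)))
  m2 <- msd_of_n(collective_coordinate(g2$trajectory,
                                       channel_spec(-20, 20)))
  expect_lt(abs(m1$D_n - 0.4) / 0.4, 0.25)
  expect_lt(abs(m2$D_n - 0.4) / 0.4, 0.25)
  o1 <- occupancy(g1$trajectory, channel_spec(-10, 10))
  o2 <- occupancy(g2$trajectory, channel_spec(-20, 20))
  expect_equal(o2$N_bar / o1$N_bar, 2, tolerance = 0.05)
})

test_that("per_state_estimates conditions on segments", {
  g <- gen_single_file(n_waters = 7, k = 0.5, duration_ns = 200,
                       dt_ns = 0.05, seed = 61)
  ch <- channel_spec(-10, 10)
  nf <- n_frames(g$trajectory)
  whole <- data.frame(state = "WO", start = 1L, end = nf + 1L)
  est <- per_state_estimates(g$trajectory, ch, whole)
  expect_equal(nrow(est), 1L)
  expect_gt(est$p_f, 0); expect_gt(est$p_d, 0)
  expect_equal(est$N_bar, 7, tolerance = 0.01)
  expect_equal(est$ratio, est$p_f / est$p_d)

  # single segment covering everything equals whole-trajectory estimates
  m <- msd_of_n(collective_coordinate(g$trajectory, ch))
  expect_equal(est$D_n, m$D_n, tolerance = 1e-9)

  # splitting into conducting + static halves recovers each regime
  g0 <- gen_single_file(n_waters = 7, k = 0, duration_ns = 200,
                        dt_ns = 0.05, seed = 62)
  both <- g$trajectory
  both$coords <- array(c(g$trajectory$coords[, , 1:2000],
                         g0$trajectory$coords[, , 1:2000]),
                       dim = c(dim(g$trajectory$coords)[1], 3, 4000))
  both$box <- cbind(g$trajectory$box[, 1:2000], g0$trajectory$box[, 1:2000])
  both$times <- (0:3999) * 0.05
  segs <- data.frame(state = c("WO", "WC"), start = c(1L, 2001L),
                     end = c(2001L, 4001L))
  est2 <- per_state_estimates(both, ch, segs)
  expect_gt(est2$q0[1], 0.02)
  expect_equal(est2$q0[2], 0)
  expect_equal(est2$p_d[2], 0)
  expect_true(is.na(est2$ratio[2]))
  expect_error(per_state_estimates(both, ch,
                                   data.frame(state = "X", start = 1L,
                                              end = 5000L)),
               "outside")
})

test_that("ctrw_check reproduces the worked ratio examples", {
  expect_equal(ctrw_check(3.47, 0.69)$ratio, 5.03)
  expect_equal(ctrw_check(1.52, 0.47)$ratio, 3.23)
  expect_equal(ctrw_check(0.33, 0.12)$ratio, 2.75)
  expect_equal(ctrw_check(1.7, 1.7)$ratio, 1.00)
  chk <- ctrw_check(3.47, 0.69, N_bar = 7.1)
  expect_equal(chk$predicted, 8.1)
  expect_equal(chk$deviation, 5.03 - 8.1)
  und <- ctrw_check(0.29, 0)
  expect_false(und$defined)
  expect_true(is.na(und$ratio))
})
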