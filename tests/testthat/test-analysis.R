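# Search-mode classification and nonspecific-search observables, validated
# against generator ground truth and brute-force oracles.

fix_mode_bundle <- function() memo("mode_bundle", {
  plan <- data.frame(mode = c("S", "H", "D"), length = c(40, 40, 20))
  synthetic_mode_trajectory(plan, fix_bound_asm(), seed = 5)
})

test_that("classifier recovers generator ground truth (mid-band poses)", {
  b <- fix_mode_bundle()
  labs <- classify_frames(b$traj)
  agree <- mean(labs$label == b$labels$label)
  expect_gte(agree, 0.99)
  expect_equal(unname(mode_propensities(b$labels)), c(0.4, 0.4, 0.2))
  # far-from-DNA pose is 3D diffusion; near pose with 150 deg offset hops
  plan2 <- data.frame(mode = c("D", "H", "S"), length = c(5, 5, 5),
                      radial_out = c(60, 3.5, 0), theta_off = c(0, 150, 0),
                      step_bp_sd = 0)
  b2 <- synthetic_mode_trajectory(plan2, fix_bound_asm(), seed = 6)
  labs2 <- classify_frames(b2$traj)
  expect_equal(labs2$label, b2$labels$label)
  expect_true(all(labs2$min_dist[1:5] > 30))
})

test_that("frames within 30 A are S or H, never D", {
  b <- fix_mode_bundle()
  labs <- classify_frames(b$traj)
  expect_true(all(labs$label[labs$min_dist <= 30] %in% c("S", "H")))
  near <- labs[labs$min_dist <= 30, ]
  expect_equal(sum(mode_propensities(near)[c("S", "H")]), 1)
})

test_that("propensities count frames and live on the simplex", {
  expect_equal(mode_propensities(rep("S", 7)), c(S = 1, H = 0, D = 0))
  expect_equal(mode_propensities(c("S", "S", "H", "D")),
               c(S = 0.5, H = 0.25, D = 0.25))
  expect_error(mode_propensities(character(0)), "empty")
  set.seed(1)
  for (i in 1:5) {
    v <- sample(c("S", "H", "D"), 50, replace = TRUE)
    expect_equal(sum(mode_propensities(v)), 1)
  }
})

test_that("event segmentation matches run-length ground truth", {
  ev <- segment_events(c("S", "S", "H", "S"))
  s <- ev$summary[ev$summary$mode == "S", ]
  expect_equal(s$n_events, 2)
  expect_equal(s$mean_duration, 1.5)
  ev1 <- segment_events(rep("H", 9))
  expect_equal(nrow(ev1$events), 1)
  expect_equal(ev1$events$duration, 9)
  # generator plan defines the events exactly
  b <- fix_mode_bundle()
  evp <- segment_events(b$labels)
  expect_equal(evp$events$mode, c("S", "H", "D"))
  expect_equal(evp$events$duration, c(40, 40, 20))
})

test_that("label smoothing removes single-frame flicker only", {
  v <- c("S", "S", "H", "S", "S", "D", "D", "D")
  expect_equal(smooth_labels(v)[3], "S")
  expect_equal(smooth_labels(v)[6:8], c("D", "D", "D"))
  expect_equal(smooth_labels(c("S", "H")), c("S", "H"))
})

test_that("positions probed counts distinct nearest base pairs in 1D modes", {
  lab <- data.frame(label = rep("S", 5), nearest_bp = rep(20L, 5))
  expect_equal(positions_probed(lab), 1)
  lab2 <- data.frame(label = rep(c("S", "H"), length.out = 21),
                     nearest_bp = 10:30)
  expect_equal(positions_probed(lab2), 21)
  lab3 <- data.frame(label = c("S", "D", "D"), nearest_bp = c(5L, 9L, 12L))
  expect_equal(positions_probed(lab3), 1)
  # random-walk generator: classifier assignment equals brute-force recount
  plan <- data.frame(mode = "S", length = 60, step_bp_sd = 1)
  b <- synthetic_mode_trajectory(plan, fix_bound_asm(), seed = 9)
  labs <- classify_frames(b$traj)
  expect_equal(labs$nearest_bp, nearest_bp_oracle(b$traj))
  expect_equal(positions_probed(labs),
               length(unique(nearest_bp_oracle(b$traj))))
})

test_that("helical coordinates follow the stated conventions", {
  # a point on the +x side at z = 100: theta = 0
  hc <- helix_coordinates(rbind(c(10, 0, 100), c(10, 0, 101)))
  expect_equal(hc$theta, c(0, 0))
  expect_equal(hc$z[1], 100)
  expect_equal(hc$r[1], 10)
  expect_error(helix_coordinates(rbind(c(0, 0, 5))), "degenerate")
  # full counter-clockwise turn unwraps to -360, not 0
  ang <- seq(0, 2 * pi, length.out = 73)
  turn <- cbind(10 * cos(ang), 10 * sin(ang), 0)
  hc2 <- helix_coordinates(turn)
  expect_equal(hc2$theta[73], -360, tolerance = 1e-9)
  # ideal helical path: dz/dtheta = -pitch/360 per degree
  pitch <- 3.4 * 360 / 34.3
  z <- seq(0, 60, by = 3.4)
  hel <- cbind(10 * cos(z * 34.3 / 3.4 * pi / 180),
               10 * sin(z * 34.3 / 3.4 * pi / 180), z)
  hc3 <- helix_coordinates(hel)
  slopes <- diff(hc3$z) / diff(hc3$theta)
  expect_equal(slopes, rep(-pitch / 360, length(slopes)), tolerance = 1e-9)
})

test_that("D1 recovers the diffusion coefficient of a Gaussian walk", {
  b <- helical_walk_trajectory(D1_target = 0.5, coupling = 1,
                               n_frames = 30000, seed = 3)
  fit <- d1_coefficient(b$coords)
  expect_equal(fit$D1, 0.5, tolerance = 0.05)
  expect_false(fit$flagged)
  # stride invariance after time rescaling
  sub <- b$coords[seq(1, nrow(b$coords), by = 2), ]
  fit2 <- d1_coefficient(sub)
  expect_equal(fit2$D1, fit$D1, tolerance = 0.1)
  # ballistic motion is flagged as a poor linear fit
  ball <- structure(data.frame(frame = 1:300, time = 0:299,
                               z = 0.5 * (0:299), theta = 0, r = 9),
                    class = c("helix_coords", "data.frame"))
  expect_true(d1_coefficient(ball)$flagged)
  # no qualifying segment
  short <- b$coords[1:5, ]
  expect_warning(res <- d1_coefficient(short, min_seg = 10), "no 1D segment")
  expect_true(is.na(res$D1))
})

test_that("z-theta correlation: coupled, uncoupled and mixed walks", {
  b1 <- helical_walk_trajectory(0.5, 1, 3000, seed = 4)
  expect_equal(as.numeric(z_theta_correlation(b1$coords)), -1,
               tolerance = 1e-6)
  b0 <- helical_walk_trajectory(0.5, 0, 3000, seed = 5)
  expect_lt(abs(z_theta_correlation(b0$coords)), 0.1)
  # mixture: with segment-wise centring, E[R] = -coupling
  bm <- helical_walk_trajectory(0.5, 0.6, 20000, seed = 6)
  expect_lt(abs(as.numeric(z_theta_correlation(bm$coords)) - (-0.6)), 0.05)
  # degenerate input flagged
  flat <- structure(data.frame(frame = 1:20, time = 0:19, z = 1:20,
                               theta = 5, r = 9),
                    class = c("helix_coords", "data.frame"))
  expect_warning(r <- z_theta_correlation(flat), "constant")
  expect_true(is.na(r))
  expect_error(z_theta_correlation(flat[1:3, ]), "fewer than")
})

test_that("depletion width follows the surface-to-surface convention", {
  asm <- toy_system(n_bp = 40, phi = 0.01, seed = 1, protein = FALSE)
  # one crowder 25 A from the centre of bp 20 (0-based), others removed
  bp <- crowdsearch:::.base_pair_indices(asm$dna)
  ctr <- (asm$dna$beads[bp$i[21], ] + asm$dna$beads[bp$j[21], ]) / 2
  asm$crowders$positions <- matrix(ctr + c(25, 0, 0), 1)
  asm$crowders$n <- 1L
  nd <- nrow(asm$dna$beads)
  asm$index$crowder <- nd + 1L
  asm$positions <- rbind(asm$dna$beads, asm$crowders$positions)
  attr(asm, "ff_tables") <- NULL
  ld <- depletion_width(static_traj(asm))
  per_bp <- attr(ld, "per_bp")
  expect_equal(per_bp[21], 25 - 10 - 3, tolerance = 1e-9)
  expect_gt(min(per_bp), 11)                  # nothing sits below the shell
  expect_gt(per_bp[40], per_bp[26])           # the gap grows away from it
  # no crowders -> flagged undefined
  asm0 <- toy_system(n_bp = 40, phi = 0, seed = 1, protein = FALSE)
  expect_warning(v <- depletion_width(static_traj(asm0)), "no crowders")
  expect_true(is.na(v))
})

test_that("crowder gap measures nearest-neighbour surface separations", {
  g <- crowder_gas(0.01, box = simulation_box(c(200, 200, 200)), seed = 1)
  g$crowders$positions <- rbind(c(0, 0, 0), c(24, 0, 0), c(0, 52, 0))
  g$crowders$n <- 3L
  g$index$crowder <- 1:3
  g$positions <- g$crowders$positions
  attr(g, "ff_tables") <- NULL
  # nearest-neighbour distances: 24, 24, 52 -> gaps 4, 4, 32; mean 40/3
  expect_equal(crowder_gap(static_traj(g)), 40 / 3, tolerance = 1e-9)
})
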