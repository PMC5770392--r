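# Integrator-level checks: limits, thermostat, determinism, boundaries.

run_tab <- function(pos, vel, tab, dt, gamma, kT, n, stride, seed = 1) {
  set.seed(seed)
  crowdsearch:::cg_run_cpp(pos, vel, tab, dt, gamma, kT, as.integer(n),
                           as.integer(stride), 3)
}

test_that("gamma = 0 reduces to velocity Verlet with tiny energy drift", {
  pos <- rbind(c(0, 0, 0), c(21, 0, 0))       # stretched 20 A bond, k = 100
  tab <- make_tab(pos, bonds_ij = matrix(c(0L, 1L), 1),
                  bonds_r0k = matrix(c(20, 100), 1))
  vel <- matrix(0, 2, 3)
  etot <- function(p, v)
    crowdsearch:::cg_energy_cpp(p, tab)$total + 0.5 * sum(v^2)
  e0 <- etot(pos, vel)
  res <- run_tab(pos, vel, tab, dt = 0.002, gamma = 0, kT = 1,
                 n = 10000, stride = 10000)
  e1 <- etot(res$pos, res$vel)
  expect_lt(abs(e1 - e0) / abs(e0), 1e-4)
})

test_that("equipartition: free-particle velocities thermalise to kT/m", {
  n <- 3000
  pos <- as.matrix(expand.grid(x = 1:15, y = 1:15, z = 1:14))[1:n, ] * 10
  tab <- make_tab(pos, box = c(160, 160, 150))
  vel <- matrix(0, n, 3)                      # start cold
  res <- run_tab(pos, vel, tab, dt = 0.01, gamma = 1, kT = 1,
                 n = 3000, stride = 3000, seed = 11)
  expect_equal(mean(res$vel^2), 1, tolerance = 0.02)
  # and at a different temperature
  res2 <- run_tab(pos, vel, tab, dt = 0.01, gamma = 1, kT = 0.5,
                  n = 8000, stride = 8000, seed = 12)
  expect_equal(mean(res2$vel^2), 0.5, tolerance = 0.02)
})

test_that("harmonically tethered coordinates have variance kT/k", {
  n <- 12; k <- 1
  pos <- cbind(0, 0, seq_len(n) * 50)
  tab <- make_tab(pos, box = c(1000, 1000, 1000),
                  xy_idx = seq_len(n) - 1L, xy_ref = pos[, 1:2], k_xy = k)
  vel <- matrix(0, n, 3)
  res <- run_tab(pos, vel, tab, dt = 0.01, gamma = 1, kT = 1,
                 n = 150000, stride = 50, seed = 13)
  xy <- res$frames[, 1:2, -(1:200)]           # drop equilibration frames
  expect_equal(mean(xy^2), 1 / k, tolerance = 0.03)
})

test_that("identical seeds give bitwise-identical trajectories", {
  asm <- toy_system(n_bp = 12, phi = 0.05, box = simulation_box(c(60, 60, 60)),
                    seed = 2)
  pr <- sim_protocol(n_steps = 500, record_stride = 50, seed = 99)
  t1 <- run_simulation(asm, pr)
  t2 <- run_simulation(asm, pr)
  expect_identical(t1$frames, t2$frames)
  pr2 <- sim_protocol(n_steps = 500, record_stride = 50, seed = 100)
  t3 <- run_simulation(asm, pr2)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("a zero-step protocol stores exactly the initial frame", {
  asm <- fix_bound_asm()
  tr <- run_simulation(asm, sim_protocol(n_steps = 0, record_stride = 10))
  expect_equal(n_frames(tr), 1L)
  expect_equal(tr$frames[, , 1], asm$positions, ignore_attr = TRUE)
  expect_equal(tr$times, 0)
})

test_that("minimum image maps components into (-L/2, L/2]", {
  box <- simulation_box(c(150, 150, 400))
  expect_equal(minimum_image(c(0, 0, 0), box), c(0, 0, 0))
  expect_equal(minimum_image(c(149, 0, 0), box), c(-1, 0, 0))
  expect_equal(minimum_image(c(75, 75, 200), box), c(75, 75, 200))
  set.seed(5)
  d <- matrix(runif(300, -900, 900), ncol = 3)
  w <- minimum_image(d, box)
  L <- rep(box$lengths, each = 100)
  expect_true(all(w > -L / 2 - 1e-9 & w <= L / 2 + 1e-9))
  lat <- (d - w) / matrix(box$lengths, 100, 3, byrow = TRUE)
  expect_equal(lat, round(lat), tolerance = 1e-9)
})

test_that("equilibrated runs: species temperatures, DNA centring, overlaps", {
  asm <- toy_system(n_bp = 40, phi = 0.2, seed = 1)
  pr <- sim_protocol(n_steps = 12000, record_stride = 400,
                     equil_steps = 4000, seed = 31)
  tr <- run_simulation(asm, pr)
  v <- tr$final$velocities
  for (sp in c("dna", "protein", "crowder")) {
    kT_sp <- mean(v[asm$index[[sp]], ]^2)
    expect_equal(kT_sp, 1, tolerance = 4 / sqrt(length(asm$index[[sp]])),
                 label = paste("kinetic temperature of", sp))
  }
  # weak COM restraint keeps the DNA centred
  com_xy <- t(crowdsearch:::.subset_com(tr$frames, asm$index$dna))
  expect_lt(max(sqrt(rowSums(com_xy^2))), 5)
  # crowder gas: no pair below 0.9 sigma after equilibration
  last <- crowdsearch:::frame_coords(tr, n_frames(tr))[asm$index$crowder, ]
  dmin <- min(vapply(seq_len(nrow(last) - 1), function(i) {
    d <- minimum_image(sweep(last[(i + 1):nrow(last), , drop = FALSE],
                             2, last[i, ]), asm$box)
    min(rowSums(d^2))
  }, numeric(1)))
  expect_gt(sqrt(dmin), 0.9 * 20)
})

test_that("langevin_step advances one step deterministically", {
  asm <- fix_bound_asm()
  pr <- sim_protocol(n_steps = 1, record_stride = 1, seed = 41)
  set.seed(41)
  v0 <- matrix(rnorm(length(asm$positions)), ncol = 3)
  set.seed(42)
  s1 <- langevin_step(asm$positions, v0, asm, pr)
  set.seed(42)
  s2 <- langevin_step(asm$positions, v0, asm, pr)
  expect_identical(s1, s2)
  expect_false(identical(s1$positions, asm$positions))
})
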