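# Specific-complex formation: contact counting, first-passage statistics,
# DNA deformation and landscape ruggedness.

test_that("specific contact counting matches a brute-force recount", {
  asm <- fix_bound_asm()
  expect_equal(specific_contact_count(asm$positions, asm), 18)
  # protein pulled far into the bulk: none
  far <- asm$positions
  far[asm$index$protein, 1] <- far[asm$index$protein, 1] + 55
  expect_equal(specific_contact_count(far, asm), 0)
  # half-engaged scripted pose: oracle recount
  part <- asm$positions
  part[asm$index$protein, 1:2] <- part[asm$index$protein, 1:2] + 2.2
  sc <- asm$protein$specific_contacts
  nd <- nrow(asm$dna$beads)
  d <- sqrt(rowSums((part[sc$res + nd, ] - part[sc$dna_bead, ])^2))
  want <- sum(d <= sc$r0 * 1.2)
  expect_equal(specific_contact_count(part, asm), want)
  expect_true(want > 0 && want < 18)
  # bounded between 0 and the total
  cs <- contact_series(static_traj(asm))
  expect_true(all(cs$n_s >= 0 & cs$n_s <= attr(cs, "total_contacts")))
})

test_that("time-to-fraction handles exact hits, means and censoring", {
  mk <- function(times, ns, total = 18)
    structure(data.frame(time = times, n_s = ns),
              class = c("contact_series", "data.frame"),
              total_contacts = total)
  s1 <- mk(0:200, c(rep(0, 100), rep(15, 101)))
  expect_equal(time_to_fraction(list(s1), 0.8)$t_f, 100)
  s2 <- mk(0:400, c(rep(0, 300), rep(18, 101)))
  tf <- time_to_fraction(list(s1, s2), 0.8)
  expect_equal(tf$t_f, 200)
  expect_equal(tf$threshold, 15)              # ceil(0.8 * 18)
  expect_equal(tf$censored_fraction, 0)
  # censored series excluded and reported
  s3 <- mk(0:400, rep(3, 401))
  tf2 <- time_to_fraction(list(s1, s3), 0.8)
  expect_equal(tf2$t_f, 100)
  expect_equal(tf2$censored_fraction, 0.5)
  expect_warning(time_to_fraction(list(s3), 0.8), "censored")
  # synthetic ramp ensemble: recovery equals a brute-force scan
  ens <- kinetic_ramp_ensemble(25, list("fixed", 120), list("exp", 1e-3),
                               total_contacts = 18, t_max = 20000, seed = 2)
  tf3 <- time_to_fraction(ens, 0.8)
  brute <- vapply(ens, function(s) {
    hit <- which(s$n_s >= 15)
    if (length(hit)) s$time[hit[1]] else NA_real_
  }, numeric(1))
  expect_equal(tf3$times, brute)
  expect_equal(tf3$t_f, mean(brute, na.rm = TRUE))
})

test_that("association and orientation rates from scripted ensembles", {
  a <- association_rate(c(500, 300, 700))
  expect_equal(a$tau, 500)
  expect_equal(a$rate, 1 / 500)
  # immediate association handled
  a0 <- association_rate(c(0, 0))
  expect_equal(a0$tau, 0)
  expect_true(is.infinite(a0$rate))
  expect_warning(association_rate(c(NA_real_, NA_real_)), "censored")
  o <- orientation_rate(t_f = c(400, 900), t_assoc = c(100, 300))
  expect_equal(o$tau, 450)
  expect_equal(o$rate, 1 / 450)
  o0 <- orientation_rate(t_f = c(100), t_assoc = c(100))
  expect_equal(o0$tau, 0)
  # exponential completion at rate lambda: k_O recovers lambda within 10%
  lam <- 1e-3
  ens <- kinetic_ramp_ensemble(200, list("fixed", 100), list("exp", lam),
                               total_contacts = 18, t_max = 30000, seed = 7)
  tf <- time_to_fraction(ens, 1.0)
  truth <- attr(ens, "truth")
  ko <- orientation_rate(tf$times, rep(100, 200))
  expect_equal(ko$rate, lam, tolerance = 0.1)
  # f = 1 threshold sits at arrival + completion by construction
  expect_true(all(abs(tf$times - ceiling(truth$arrival + truth$completion))
                  <= 1))
})

test_that("first association time is found from labels and from contacts", {
  # scripted sweep entering the window (bp 16-24) from below
  plan <- data.frame(mode = "S", length = 30, step_bp_sd = 0,
                     step_bp_mean = 0.5)
  b <- synthetic_mode_trajectory(plan, fix_bound_asm(), seed = 3)
  # walk starts at the window centre, so association is immediate
  expect_equal(first_association(b$traj, b$labels), b$labels$time[1])
  # push the labels outside the window artificially and find the crossing
  lab <- b$labels
  lab$nearest_bp <- 5L + round(cumsum(rep(0.7, 30)))
  hit <- which(lab$nearest_bp %in% 16:24)[1]
  expect_equal(first_association(b$traj, lab), lab$time[hit])
  lab$nearest_bp <- rep(2L, 30)
  expect_true(is.na(first_association(b$traj, lab)))
})

test_that("deformation profile: zero baseline, localisation, rigid motions", {
  asm <- fix_bound_asm()
  base <- deformation_profile(static_traj(asm), normalize = FALSE)
  expect_true(all(abs(base$raw) < 1e-10))
  # displace both base beads of bp 30 by 3 A: profile peaks there at ds = 1
  bp <- crowdsearch:::.base_pair_indices(asm$dna)
  pos <- asm$positions
  pos[c(bp$i[31], bp$j[31]), 1] <- pos[c(bp$i[31], bp$j[31]), 1] + 3
  arr <- array(pos, dim = c(nrow(pos), 3, 1))
  prof <- deformation_profile(static_traj(asm, frames = arr))
  expect_equal(which.max(prof$ds) - 1L, 30L)
  expect_equal(max(prof$ds), 1)
  # a rigidly moved copy of the reference superposes to zero
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- sweep(asm$positions %*% R, 2, c(5, -3, 8), "+")
  arr2 <- array(moved, dim = c(nrow(moved), 3, 1))
  prof2 <- deformation_profile(static_traj(asm, frames = arr2),
                               normalize = FALSE)
  expect_true(all(abs(prof2$raw) < 1e-8))
  expect_error(deformation_profile(static_traj(asm), frames = integer()),
               "empty")
  # joint normalisation across ensembles uses the global maximum
  p1 <- list(bp = 0:39, raw = rep(1, 40))
  p2 <- list(bp = 0:39, raw = rep(4, 40))
  nn <- ds_normalize(list(p1, p2))
  expect_equal(max(nn[[1]]$ds), 0.25)
  expect_equal(max(nn[[2]]$ds), 1)
})

test_that("ruggedness is the per-bp population SD of energy samples", {
  r <- ruggedness_from_samples(bp = rep(0:1, each = 4),
                               energy = c(rep(2, 4), -1, 1, -1, 1),
                               n_bp = 3, direction = "5to3")
  expect_equal(r$sigma, c(0, 1, NA))
  expect_equal(r$n, c(4L, 4L, 0L))
  rev <- ruggedness_from_samples(rep(0:1, each = 4),
                                 c(rep(2, 4), -1, 1, -1, 1), 3)
  expect_equal(rev$bp, c(2L, 1L, 0L))         # 3' -> 5' ordering
  # Gaussian samples of known sigma recovered within 10% at n = 100
  set.seed(8)
  sig_true <- c(0.5, 2, 1)
  bp <- rep(0:2, each = 100)
  en <- rnorm(300, 0, rep(sig_true, each = 100))
  rg <- ruggedness_from_samples(bp, en, 3, direction = "5to3")
  expect_equal(rg$sigma, sig_true, tolerance = 0.1)
})

test_that("ruggedness at the engaged target window exceeds baseline", {
  # bound-state run: specific-energy fluctuations at the window are larger
  # than excluded-volume fluctuations at untouched positions
  asm <- fix_bound_asm()
  pr <- sim_protocol(n_steps = 6000, record_stride = 100, seed = 17)
  tr <- run_simulation(asm, pr)
  rug <- ruggedness_profile(tr, direction = "5to3")
  win <- attr(rug, "window")
  in_win <- rug$sigma[rug$bp %in% win]
  expect_true(any(!is.na(in_win)))
  expect_gt(max(in_win, na.rm = TRUE), 0)
})
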