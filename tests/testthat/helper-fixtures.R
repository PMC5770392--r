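# Shared fixtures (memoised so expensive objects are built once per session)
# and small independent oracles used across the test files.

.fix_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fix_env)) assign(key, force(expr), envir = .fix_env)
  get(key, envir = .fix_env)
}

fix_dna40 <- function() memo("dna40", {
  build_ideal_bdna(random_dna_sequence(40, seed = 2))
})

fix_protein <- function() memo("protein", toy_protein())

fix_docked <- function() memo("docked", dock_protein(fix_protein(), fix_dna40()))

fix_bound_asm <- function() memo("bound_asm", {
  toy_system(n_bp = 40, phi = 0, seed = 1, placement = "bound")
})

# a single-frame trajectory wrapping an assembly's current coordinates
static_traj <- function(asm, frames = NULL) {
  pos <- asm$positions
  if (is.null(frames)) frames <- array(pos, dim = c(nrow(pos), 3, 1))
  structure(list(frames = frames, times = seq_len(dim(frames)[3]) - 1,
                 protocol = sim_protocol(n_steps = 0, record_stride = 1),
                 assembly = asm, final = NULL),
            class = "cg_trajectory")
}

# hand-built interaction tables for bespoke micro-systems (free particles,
# tethered beads, a lone bond) used to probe the integrator directly
make_tab <- function(pos, box = c(1000, 1000, 1000), radius = 0.01,
                     bonds_ij = matrix(0L, 0, 2), bonds_r0k = matrix(0, 0, 2),
                     xy_idx = integer(), xy_ref = matrix(0, 0, 2),
                     k_xy = 0) {
  n <- nrow(pos)
  list(n = n, box = box,
       radius = rep(radius, n), charge = rep(0, n), mass = rep(1, n),
       group = rep(2L, n),
       bonds_ij = bonds_ij, bonds_r0k = bonds_r0k,
       angles_ijk = matrix(0L, 0, 3), angles_t0k = matrix(0, 0, 2),
       cont_ij = matrix(0L, 0, 2), cont_r0eps = matrix(0, 0, 2),
       cont_spec = integer(),
       charged_ij = matrix(0L, 0, 2),
       excl_ij = if (nrow(bonds_ij)) bonds_ij else matrix(0L, 0, 2),
       lB = 7.14, kappa = 0.123, rc_elec = 32, eps_ev = 1,
       sigma_pp = 4, sigma_pd = 3.5,
       com_idx = integer(), k_com = 0, com_target = c(0, 0, 0),
       xy_idx = as.integer(xy_idx), xy_x0 = xy_ref[, 1], xy_y0 = xy_ref[, 2],
       k_xy = k_xy)
}

# independent all-pairs R oracle for the full potential of an assembly:
# same physics, no neighbor list, plain R arithmetic
energy_oracle <- function(asm, pos = asm$positions) {
  tab <- crowdsearch:::ff_tables(crowdsearch:::with_tables(asm))
  L <- tab$box
  mi <- function(d) sweep(d, 2, L, function(x, l) x - l * ceiling(x / l - 0.5))
  pd <- function(i, j) {
    d <- mi(pos[i, , drop = FALSE] - pos[j, , drop = FALSE])
    sqrt(rowSums(d^2))
  }
  e <- c(bonded = 0, native = 0, specific = 0, electrostatic = 0,
         excluded_volume = 0)
  if (nrow(tab$bonds_ij)) {
    r <- pd(tab$bonds_ij[, 1] + 1, tab$bonds_ij[, 2] + 1)
    e["bonded"] <- sum(0.5 * tab$bonds_r0k[, 2] * (r - tab$bonds_r0k[, 1])^2)
  }
  if (nrow(tab$angles_ijk)) {
    for (m in seq_len(nrow(tab$angles_ijk))) {
      i <- tab$angles_ijk[m, 1] + 1; j <- tab$angles_ijk[m, 2] + 1
      k <- tab$angles_ijk[m, 3] + 1
      v1 <- drop(mi(pos[i, , drop = FALSE] - pos[j, , drop = FALSE]))
      v2 <- drop(mi(pos[k, , drop = FALSE] - pos[j, , drop = FALSE]))
      th <- acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
      e["bonded"] <- e["bonded"] +
        0.5 * tab$angles_t0k[m, 2] * (th - tab$angles_t0k[m, 1])^2
    }
  }
  if (length(tab$com_idx) && tab$k_com > 0) {
    cm <- colMeans(pos[tab$com_idx + 1, , drop = FALSE])
    e["bonded"] <- e["bonded"] +
      0.5 * tab$k_com * sum((cm - tab$com_target)^2)
  }
  if (length(tab$xy_idx)) {
    dx <- pos[tab$xy_idx + 1, 1] - tab$xy_x0
    dy <- pos[tab$xy_idx + 1, 2] - tab$xy_y0
    e["bonded"] <- e["bonded"] + 0.5 * tab$k_xy * sum(dx^2 + dy^2)
  }
  if (nrow(tab$cont_ij)) {
    r <- pd(tab$cont_ij[, 1] + 1, tab$cont_ij[, 2] + 1)
    u <- tab$cont_r0eps[, 2] *
      (5 * (tab$cont_r0eps[, 1] / r)^12 - 6 * (tab$cont_r0eps[, 1] / r)^10)
    e["native"] <- sum(u[tab$cont_spec == 0])
    e["specific"] <- sum(u[tab$cont_spec == 1])
  }
  if (nrow(tab$charged_ij)) {
    i <- tab$charged_ij[, 1] + 1; j <- tab$charged_ij[, 2] + 1
    r <- pd(i, j)
    rc <- tab$rc_elec
    qq <- tab$charge[i] * tab$charge[j]
    u <- tab$lB * qq * exp(-tab$kappa * r) / r
    urc <- tab$lB * qq * exp(-tab$kappa * rc) / rc
    durc <- -tab$lB * qq * exp(-tab$kappa * rc) * (1 + tab$kappa * rc) / rc^2
    us <- u - urc - (r - rc) * durc
    e["electrostatic"] <- sum(us[r < rc])
  }
  # all-pairs WCA with the pair-class sigma rules
  n <- tab$n
  excl_key <- character(0)
  if (nrow(tab$excl_ij))
    excl_key <- paste(pmin(tab$excl_ij[, 1], tab$excl_ij[, 2]),
                      pmax(tab$excl_ij[, 1], tab$excl_ij[, 2]))
  sig_of <- function(i, j) {   # 1-based
    gi <- tab$group[i]; gj <- tab$group[j]
    if (gi == 1 && gj == 1) return(tab$sigma_pp)
    if ((gi == 1 && gj == 0) || (gi == 0 && gj == 1)) return(tab$sigma_pd)
    tab$radius[i] + tab$radius[j]
  }
  for (i in seq_len(n - 1)) {
    d <- mi(sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ]))
    r <- sqrt(rowSums(d^2))
    for (o in seq_along(r)) {
      j <- i + o
      if (paste(i - 1, j - 1) %in% excl_key) next
      sig <- sig_of(i, j)
      if (r[o] <= 2^(1 / 6) * sig) {
        s6 <- (sig / r[o])^6
        e["excluded_volume"] <- e["excluded_volume"] + 4 * (s6^2 - s6) + 1
      }
    }
  }
  e["excluded_volume"] <- e["excluded_volume"] * tab$eps_ev
  c(e, total = sum(e))
}

# brute-force nearest-bp assignment of the recognition-helix COM, per frame
nearest_bp_oracle <- function(traj) {
  a <- traj$assembly
  bp <- crowdsearch:::.base_pair_indices(a$dna)
  rh <- a$index$protein[a$protein$recognition_helix]
  vapply(seq_len(n_frames(traj)), function(f) {
    X <- traj$frames[, , f]
    com <- colMeans(X[rh, , drop = FALSE])
    ctr <- (X[bp$i, ] + X[bp$j, ]) / 2
    which.min(rowSums(sweep(ctr, 2, com)^2)) - 1L
  }, integer(1))
}
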