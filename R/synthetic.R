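## Synthetic fixtures: a toy folded protein with a charged recognition
## helix, a docked bound pose, mode-labelled synthetic trajectories and
## kinetic contact ramps with known ground truth. Everything is
## seed-deterministic and regenerable from its parameters.

#' Toy three-helix-bundle protein
#'
#' Builds a compact three-helix bundle from ideal alpha-helix geometry
#' (rise 1.5 A, 100 deg/residue, C-alpha radius 2.3 A). The last helix is
#' the DNA-recognition helix: its axis runs along local +z through the
#' origin, the bundle body sits on the +x side, and the DNA-facing (-x)
#' face of the recognition helix carries the positive charges. The default
#' charge plan places 6 Arg/Lys on that face and 4 Glu/Asp on the body
#' (net +2 e).
#'
#' @param n_residues total residue count (>= 30; default 60).
#' @param charge_plan optional list with integer vectors `positive` and
#'   `negative` (residue indices) overriding the default plan.
#' @param seed integer seed (a tiny coordinate jitter keeps the build free
#'   of exact degeneracies).
#' @param params force-field parameters.
#' @return a `protein_model` in the local (undocked) frame.
#' @export
toy_protein <- function(n_residues = 60, charge_plan = NULL, seed = 1,
                        params = forcefield_params()) {
  if (n_residues < 30) stop("need at least 30 residues")
  set.seed(seed)
  h <- (n_residues - 6) %/% 3
  segA <- 1:h
  segB <- (h + 4):(2 * h + 3)
  segC <- (2 * h + 7):n_residues
  loops <- setdiff(seq_len(n_residues), c(segA, segB, segC))

  helix <- function(n, axis_xy, z0, up = TRUE, phase = 0) {
    i <- seq_len(n) - 1
    ang <- (phase + i * 100) * pi / 180
    z <- z0 + (if (up) i else -i) * 1.5
    cbind(axis_xy[1] + 2.3 * cos(ang), axis_xy[2] + 2.3 * sin(ang), z)
  }
  nC <- length(segC)
  zC <- -(nC - 1) * 1.5 / 2                     # recognition helix centred
  xyA <- c(9.1, 5.25); xyB <- c(9.1, -5.25); xyC <- c(0, 0)
  beads <- matrix(NA_real_, n_residues, 3)
  beads[segA, ] <- helix(length(segA), xyA, zC, up = TRUE)
  beads[segB, ] <- helix(length(segB), xyB,
                         zC + (length(segA) - 1) * 1.5, up = FALSE)
  beads[segC, ] <- helix(nC, xyC, zC, up = TRUE, phase = 180)
  # short connecting loops: quadratic Bezier bowed away from the bundle so
  # loop beads neither pierce the helices nor each other
  centroid <- c(mean(c(xyA[1], xyB[1], xyC[1])),
                mean(c(xyA[2], xyB[2], xyC[2])), 0)
  for (g in split(loops, cumsum(c(1, diff(loops) != 1)))) {
    a <- min(g) - 1; b <- max(g) + 1
    mid <- (beads[a, ] + beads[b, ]) / 2
    out <- mid - centroid; out[3] <- 0
    out <- if (sqrt(sum(out^2)) > 1e-6) out / sqrt(sum(out^2)) else c(1, 0, 0)
    ctrl <- mid + 5 * out + c(0, 0, 3 * sign(mid[3]))
    w <- seq_along(g) / (length(g) + 1)
    beads[g, ] <- outer((1 - w)^2, beads[a, ]) + outer(2 * w * (1 - w), ctrl) +
      outer(w^2, beads[b, ])
  }
  beads <- beads + matrix(rnorm(3 * n_residues, 0, 0.01), n_residues, 3)

  residues <- rep("ALA", n_residues)
  if (is.null(charge_plan)) {
    # positives on the DNA-facing (-x) side of the recognition helix
    facing <- segC[order(beads[segC, 1])]
    pos <- sort(facing[1:6])
    body <- c(segA, segB)
    neg <- body[round(seq(2, length(body) - 1, length.out = 4))]
    charge_plan <- list(positive = pos, negative = neg)
  }
  if (!length(charge_plan$positive))
    stop("infeasible charge plan: recognition helix needs positive charges")
  residues[charge_plan$positive] <- rep(c("ARG", "LYS"),
                                        length.out = length(charge_plan$positive))
  residues[charge_plan$negative] <- rep(c("GLU", "ASP"),
                                        length.out = length(charge_plan$negative))
  p <- .new_protein(beads, residues, recognition_helix = segC, params)
  p$helices <- list(A = segA, B = segB, C = segC)
  p
}

#' Dock a toy protein into the DNA major groove
#'
#' Rigidly places the recognition helix along the major-groove track at the
#' centre of the target window, then scans the insertion depth until the
#' specific-contact count (recognition residues within `cutoff` of
#' target-window DNA beads) equals `target_contacts`, rejecting depths that
#' produce steric clashes. The resulting pose defines the specific-contact
#' reference distances.
#'
#' @param protein a `protein_model` from [toy_protein()] (recognition helix
#'   along local z, body on +x).
#' @param dna a `dna_model`.
#' @param cutoff specific-contact cutoff in Angstrom.
#' @param target_contacts desired contact count (default 18; must lie in
#'   16-20 for the bound pose to be accepted).
#' @return the protein with docked coordinates, `specific_contacts`, and a
#'   `dock` descriptor (window centre bp, insertion depth).
#' @export
dock_protein <- function(protein, dna,
                         cutoff = forcefield_params()$specific_cutoff,
                         target_contacts = 18) {
  w <- dna$target_window[ceiling(length(dna$target_window) / 2)]
  fr <- .groove_frame(dna, w)
  Xl <- protein$beads
  best <- NULL
  for (d in seq(14, 3, by = -0.1)) {
    X <- Xl %*% t(fr$R)
    # translate so the recognition-helix COM sits d Angstrom out in the groove
    ctr <- fr$center + d * fr$g
    rc <- colMeans(X[protein$recognition_helix, , drop = FALSE])
    X <- sweep(X, 2, ctr - rc, "+")
    cand <- protein; cand$beads <- X
    sc <- tryCatch(derive_specific_contacts(cand, dna, cutoff),
                   error = function(e) NULL)
    cnt <- if (is.null(sc)) 0L else nrow(sc)
    dmin <- min(.cross_dist(X, dna$beads, simulation_box(c(1e6, 1e6, 1e6))))
    if (dmin < 3.5) next                       # steric clash with the duplex
    if (cnt == target_contacts) { best <- list(X = X, sc = sc, d = d); break }
    if (cnt >= 16 && cnt <= 20 && is.null(best))
      best <- list(X = X, sc = sc, d = d)
  }
  if (is.null(best))
    stop("docking failed: no clash-free depth gives 16-20 specific contacts")
  protein$beads <- best$X
  protein$specific_contacts <- best$sc
  protein$dock <- list(bp = w, depth = best$d,
                       n_contacts = nrow(best$sc))
  protein
}

# local frame of the major groove at bp w: g = outward groove direction,
# t = groove tangent, center = bp centre
.groove_frame <- function(dna, w) {
  bp <- .base_pair_indices(dna); sg <- .sugar_pair_indices(dna)
  bpc <- (dna$beads[bp$i, ] + dna$beads[bp$j, ]) / 2
  smid <- (dna$beads[sg$i, ] + dna$beads[sg$j, ]) / 2
  k <- w + 1                                   # 0-based bp -> row
  g <- bpc[k, ] - smid[k, ]; g[3] <- 0; g <- g / sqrt(sum(g^2))
  track <- function(i) {
    gg <- bpc[i, ] - smid[i, ]; gg[3] <- 0; gg <- gg / sqrt(sum(gg^2))
    bpc[i, ] + 6 * gg
  }
  t <- track(k + 1) - track(k - 1); t <- t / sqrt(sum(t^2))
  gp <- g - sum(g * t) * t; gp <- gp / sqrt(sum(gp^2))
  y <- .cross3(t, gp)
  list(R = cbind(gp, y, t), g = gp, t = t, center = bpc[k, ])
}

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

#' Assemble the default toy search system
#'
#' Convenience constructor used throughout the tests: a seeded random DNA
#' duplex (centred 9-bp window), the docked 60-residue toy protein, and a
#' crowder field at the requested volume fraction.
#'
#' @param n_bp DNA length in bp (default 40).
#' @param phi crowder volume fraction.
#' @param box a `simulation_box` (default 120 x 120 x 180 A).
#' @param seed integer seed.
#' @param protein include the protein at all?
#' @param placement protein placement preset (see [assemble_system()]).
#' @param params force-field parameters.
#' @param ... passed to [assemble_system()].
#' @return a `system_assembly`.
#' @export
toy_system <- function(n_bp = 40, phi = 0,
                       box = simulation_box(c(120, 120, 180)), seed = 1,
                       protein = TRUE, placement = "bound",
                       params = forcefield_params(), ...) {
  seq <- random_dna_sequence(n_bp, seed = seed)
  dna <- build_ideal_bdna(seq, params = params)
  prot <- NULL
  if (protein) prot <- dock_protein(toy_protein(params = params), dna,
                                    cutoff = params$specific_cutoff)
  assemble_system(dna, prot, phi = phi, box = box, params = params,
                  seed = seed + 1,
                  protein_placement = if (protein) placement else "as-is", ...)
}

#' Synthetic mode-labelled trajectory
#'
#' Generates a protein path whose frames realise a prescribed sequence of
#' search modes unambiguously (poses are placed mid-band of the classifier
#' criteria), with the ground-truth labels attached. DNA and crowders stay
#' at their assembly positions; the protein is screw-transformed from its
#' bound pose.
#'
#' Default pose bands: sliding = bound depth, 0 deg groove offset; hopping =
#' bound depth + 8 A, 120 deg offset; 3D = 48 A radially out in bulk.
#'
#' @param plan data frame with columns `mode` ("S"/"H"/"D") and `length`
#'   (frames); optional columns `step_bp_sd` (axial random-walk step, bp per
#'   frame), `step_bp_mean` (drift), `radial_out`, `theta_off` override the
#'   per-mode defaults.
#' @param assembly a `system_assembly` with a docked (bound) protein.
#' @param seed integer seed.
#' @param frame_stride nominal MD steps between frames (metadata only).
#' @return list of class `fixture_bundle`: `traj` (a `cg_trajectory`),
#'   `labels` (ground truth, incl. planned nearest bp), `plan`, `seed`.
#' @export
synthetic_mode_trajectory <- function(plan, assembly, seed = 1,
                                      frame_stride = 100) {
  stopifnot(all(plan$mode %in% c("S", "H", "D")), all(plan$length >= 1))
  a <- assembly
  if (is.null(a$protein$dock))
    stop("assembly's protein must be docked (bound pose)")
  set.seed(seed)
  defaults <- list(
    S = list(radial_out = 0, theta_off = 0, step_bp_sd = 0.3, step_bp_mean = 0),
    H = list(radial_out = 8, theta_off = 120, step_bp_sd = 0.5, step_bp_mean = 0),
    D = list(radial_out = 48, theta_off = 0, step_bp_sd = 0, step_bp_mean = 0))
  dna <- a$dna
  w <- a$protein$dock$bp
  n_tot <- sum(plan$length)
  nb <- nrow(a$positions)
  frames <- array(rep(a$positions, n_tot), dim = c(nb, 3, n_tot))
  lab <- character(n_tot); planned_bp <- integer(n_tot)
  s <- 0                                        # bp offset from window centre
  f <- 0
  max_off <- (dna$n_bp - 5) / 2 - abs(w - (dna$n_bp - 1) / 2)
  for (r in seq_len(nrow(plan))) {
    md <- plan$mode[r]
    par <- defaults[[md]]
    for (nm in c("step_bp_sd", "step_bp_mean", "radial_out", "theta_off"))
      if (!is.null(plan[[nm]]) && !is.na(plan[[nm]][r])) par[[nm]] <- plan[[nm]][r]
    for (k in seq_len(plan$length[r])) {
      f <- f + 1
      s <- s + par$step_bp_mean + rnorm(1, 0, par$step_bp_sd)
      s <- max(-max_off, min(max_off, s))
      pp <- screw_place(a$protein, dna, ds_bp = s,
                        radial_out = par$radial_out,
                        theta_off = par$theta_off)
      frames[a$index$protein, , f] <- pp$beads
      lab[f] <- md
      planned_bp[f] <- max(0, min(dna$n_bp - 1, w + round(s)))
    }
  }
  proto <- sim_protocol(n_steps = n_tot * frame_stride,
                        record_stride = frame_stride, seed = seed)
  traj <- structure(list(frames = frames,
                         times = seq_len(n_tot) * frame_stride,
                         protocol = proto, assembly = a,
                         final = NULL, synthetic = TRUE),
                    class = "cg_trajectory")
  labels <- data.frame(frame = seq_len(n_tot), time = traj$times,
                       label = lab, nearest_bp = planned_bp)
  structure(list(traj = traj, labels = labels, plan = plan, seed = seed),
            class = "fixture_bundle")
}

#' Helical-walk coordinate fixture
#'
#' A 1D Gaussian random walk in z with per-frame variance `2 * D1_target`;
#' within each segment the azimuth either follows the groove
#' (`theta = -z * twist / rise`, probability `coupling`) or performs an
#' independent random walk with the matched step size. With segment-wise
#' centring the expected pooled z-theta correlation is `-coupling`.
#'
#' @param D1_target 1D diffusion coefficient, A^2 per frame.
#' @param coupling probability that a segment is groove-coupled, in [0, 1].
#' @param n_frames total frames.
#' @param seed integer seed.
#' @param seg_len frames per segment (default 50).
#' @param rise,twist helical geometry (defaults 3.4 A, 34.3 deg).
#' @return list of class `fixture_bundle`: `coords` (a `helix_coords` frame
#'   with a `segment` column), `labels` (all sliding), `segments`, `seed`.
#' @export
helical_walk_trajectory <- function(D1_target, coupling, n_frames, seed = 1,
                                    seg_len = 50, rise = 3.4, twist = 34.3) {
  stopifnot(D1_target > 0, coupling >= 0, coupling <= 1, n_frames >= 2)
  set.seed(seed)
  step_sd <- sqrt(2 * D1_target)
  c_slope <- twist / rise                     # deg per Angstrom
  dz <- rnorm(n_frames, 0, step_sd)
  seg <- rep(seq_len(ceiling(n_frames / seg_len)), each = seg_len)[1:n_frames]
  coupled <- runif(max(seg)) < coupling
  dth <- numeric(n_frames)
  for (si in seq_len(max(seg))) {
    i <- which(seg == si)
    dth[i] <- if (coupled[si]) -c_slope * dz[i]
              else rnorm(length(i), 0, c_slope * step_sd)
  }
  z <- cumsum(dz); th <- cumsum(dth)
  coords <- structure(data.frame(frame = seq_len(n_frames),
                                 time = seq_len(n_frames) - 1,
                                 z = z, theta = th, r = 9,
                                 segment = seg),
                      class = c("helix_coords", "data.frame"))
  labels <- data.frame(frame = seq_len(n_frames),
                       time = seq_len(n_frames) - 1, label = "S",
                       nearest_bp = pmax(0, round(z / rise)))
  structure(list(coords = coords, labels = labels,
                 segments = data.frame(segment = seq_len(max(seg)),
                                       coupled = coupled),
                 D1_target = D1_target, coupling = coupling, seed = seed),
            class = "fixture_bundle")
}

.draw_law <- function(law, n) {
  type <- law[[1]]
  switch(type,
         fixed = rep(law[[2]], n),
         exp = stats::rexp(n, rate = law[[2]]),
         stop("unknown law type '", type, "'"))
}

#' Synthetic kinetic contact-ramp ensemble
#'
#' Contact time series with known arrival and completion times: `N_s` is 0
#' before the arrival time, jumps to 1 at arrival (first specific contact),
#' ramps linearly to `total_contacts` over the completion duration, and
#' stays saturated. Laws are `list("fixed", value)` or
#' `list("exp", rate)`.
#'
#' @param n_series ensemble size.
#' @param arrival arrival-time law (MD steps).
#' @param completion completion-duration law (MD steps).
#' @param total_contacts total specific contacts (default 18).
#' @param t_max series length in MD steps.
#' @param dt_frame sampling interval in MD steps.
#' @param seed integer seed.
#' @return list of `contact_series`, with attribute `truth` (data frame of
#'   per-series arrival/completion times).
#' @export
kinetic_ramp_ensemble <- function(n_series, arrival, completion,
                                  total_contacts = 18, t_max = 5000,
                                  dt_frame = 1, seed = 1) {
  set.seed(seed)
  A <- .draw_law(arrival, n_series)
  C <- .draw_law(completion, n_series)
  tgrid <- seq(0, t_max, by = dt_frame)
  out <- vector("list", n_series)
  for (s in seq_len(n_series)) {
    ns <- ifelse(tgrid < A[s], 0,
                 pmin(total_contacts,
                      1 + floor((total_contacts - 1) *
                                pmax(0, tgrid - A[s]) / max(C[s], 1e-12))))
    out[[s]] <- structure(data.frame(time = tgrid, n_s = as.integer(ns)),
                          class = c("contact_series", "data.frame"),
                          total_contacts = total_contacts)
  }
  attr(out, "truth") <- data.frame(series = seq_len(n_series),
                                   arrival = A, completion = C)
  out
}
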