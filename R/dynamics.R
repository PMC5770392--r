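## Langevin propagation (BAOAB) of an assembled system and the trajectory
## container.

#' Simulation protocol
#'
#' Time step and friction are in reduced units (bead mass = 1, k_B.T at
#' 300 K = 1; the reduced time unit follows from these). Temperatures other
#' than 300 K rescale the thermostat target `kT` accordingly.
#'
#' @param n_steps number of MD steps.
#' @param record_stride store a frame every `record_stride` steps.
#' @param dt reduced time step (default 0.01).
#' @param gamma Langevin friction coefficient (default 0.05).
#' @param temperature temperature in K (default 300).
#' @param seed integer seed; fixes the whole trajectory bitwise.
#' @param equil_steps steps run (and discarded) before recording starts.
#' @param skin neighbor-list skin in Angstrom.
#' @return object of class `sim_protocol`.
#' @export
sim_protocol <- function(n_steps, record_stride = 100, dt = 0.01,
                         gamma = 0.05, temperature = 300, seed = 1,
                         equil_steps = 0, skin = 3) {
  stopifnot(dt > 0, n_steps >= 0, record_stride >= 1, gamma >= 0,
            temperature > 0, equil_steps >= 0)
  structure(list(n_steps = as.integer(n_steps),
                 record_stride = as.integer(record_stride),
                 dt = dt, gamma = gamma, temperature = temperature,
                 kT = temperature / 300,
                 seed = as.integer(seed),
                 equil_steps = as.integer(equil_steps),
                 skin = skin), class = "sim_protocol")
}

#' Run a Langevin dynamics simulation
#'
#' Propagates the assembly with the BAOAB integrator under periodic boundary
#' conditions. Initial velocities are Maxwell-Boltzmann at the protocol
#' temperature. Coordinates are stored unwrapped (interactions use the
#' minimum-image convention), so diffusive observables can be computed
#' directly. An optional equilibration phase runs before recording.
#'
#' @param assembly a `system_assembly`.
#' @param protocol a `sim_protocol`.
#' @param velocities optional starting velocity matrix (defaults to a fresh
#'   Maxwell-Boltzmann draw).
#' @param positions optional starting coordinates (defaults to the
#'   assembly's).
#' @param stop_at_contacts if > 0, end the run early once this many specific
#'   contacts are simultaneously formed (checked at recording strides);
#'   useful for first-passage ensembles.
#' @return object of class `cg_trajectory`: `frames` (beads x 3 x n_frames
#'   array, Angstrom), `times` (MD-step index of each frame), `protocol`,
#'   `assembly`, and the final phase-space state.
#' @export
run_simulation <- function(assembly, protocol, velocities = NULL,
                           positions = NULL, stop_at_contacts = 0) {
  stopifnot(inherits(assembly, "system_assembly"),
            inherits(protocol, "sim_protocol"))
  assembly <- with_tables(assembly)
  tab <- attr(assembly, "ff_tables")
  set.seed(protocol$seed)
  if (is.null(positions)) positions <- assembly$positions
  if (is.null(velocities))
    velocities <- matrix(rnorm(3 * tab$n, 0, sqrt(protocol$kT)), tab$n, 3)

  if (protocol$equil_steps > 0) {
    eq <- cg_run_cpp(positions, velocities, tab, protocol$dt, protocol$gamma,
                     protocol$kT, protocol$equil_steps,
                     protocol$equil_steps, protocol$skin)
    positions <- eq$pos
    velocities <- eq$vel
  }
  res <- cg_run_cpp(positions, velocities, tab, protocol$dt, protocol$gamma,
                    protocol$kT, protocol$n_steps, protocol$record_stride,
                    protocol$skin, as.integer(stop_at_contacts),
                    assembly$params$contact_tol)
  structure(list(
    frames = res$frames, times = as.numeric(res$times),
    protocol = protocol, assembly = assembly,
    final = list(positions = res$pos, velocities = res$vel)
  ), class = "cg_trajectory")
}

#' Single Langevin (BAOAB) update
#'
#' One integrator step; mainly useful for integrator-level checks. With
#' `gamma = 0` the update reduces to velocity Verlet.
#'
#' @param positions,velocities current state matrices.
#' @param assembly a `system_assembly`.
#' @param protocol a `sim_protocol`.
#' @return list with updated `positions` and `velocities`.
#' @export
langevin_step <- function(positions, velocities, assembly, protocol) {
  assembly <- with_tables(assembly)
  tab <- attr(assembly, "ff_tables")
  res <- cg_run_cpp(positions, velocities, tab, protocol$dt, protocol$gamma,
                    protocol$kT, 1L, 1L, protocol$skin)
  list(positions = res$pos, velocities = res$vel)
}

#' @export
print.cg_trajectory <- function(x, ...) {
  nf <- dim(x$frames)[3]
  cat("Trajectory:", nf, "frames of", dim(x$frames)[1], "beads;",
      "steps 0 -", max(x$times), "(stride", x$protocol$record_stride, ")\n")
  cat("  dt", x$protocol$dt, ", gamma", x$protocol$gamma, ", T",
      x$protocol$temperature, "K, seed", x$protocol$seed, "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cg_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

# coordinates of one frame as a beads x 3 matrix
frame_coords <- function(traj, f) {
  traj$frames[, , f, drop = TRUE]
}

#' Save / load a trajectory store
#'
#' The on-disk store is an RDS archive of the full trajectory object
#' (frames, protocol with seed, assembly reference) and is therefore
#' self-describing.
#'
#' @param traj a `cg_trajectory`.
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  saveRDS(traj, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) readRDS(path)

#' Export a trajectory to plain XYZ for visualization
#'
#' @param traj a `cg_trajectory`.
#' @param path output file.
#' @param which frame indices (default all).
#' @export
export_xyz <- function(traj, path, which = seq_len(n_frames(traj))) {
  a <- traj$assembly
  lab <- c(paste0("D", a$dna$info$type),
           rep("CA", length(a$index$protein)),
           rep("CR", length(a$index$crowder)))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in which) {
    x <- frame_coords(traj, f)
    writeLines(c(as.character(nrow(x)),
                 paste("step", traj$times[f])), con)
    writeLines(sprintf("%s %.3f %.3f %.3f", lab, x[, 1], x[, 2], x[, 3]), con)
  }
  invisible(path)
}
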