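## Spherical crowders: counting from the volume fraction and non-overlapping
## initial placement in the periodic box.

#' Simulation box
#'
#' @param lengths box edge lengths (Lx, Ly, Lz) in Angstrom; default
#'   150 x 150 x 400.
#' @param periodic logical flags per axis.
#' @return object of class `simulation_box`. Coordinates are centred: each
#'   component lives in (-L/2, L/2].
#' @export
simulation_box <- function(lengths = c(150, 150, 400),
                           periodic = c(TRUE, TRUE, TRUE)) {
  stopifnot(length(lengths) == 3, all(lengths > 0))
  structure(list(lengths = as.numeric(lengths), periodic = periodic),
            class = "simulation_box")
}

#' Number of crowders at a requested volume fraction
#'
#' Inverts `Phi = 4 Nc pi R^3 / (3 Lx Ly Lz)`, rounding half away from zero.
#' The realized volume fraction recomputed from the integer count is attached
#' as an attribute.
#'
#' @param phi requested volume fraction in `[0, 0.64)`.
#' @param radius crowder radius in Angstrom.
#' @param box a `simulation_box`.
#' @return integer crowder count with attributes `phi_requested` and
#'   `phi_realized`.
#' @examples
#' count_crowders(0.2, 10, simulation_box())  # 430
#' @export
count_crowders <- function(phi, radius = 10, box = simulation_box()) {
  stopifnot(phi >= 0, radius > 0)
  if (phi >= 0.64)
    stop("phi = ", phi, " exceeds the random-close-packing bound (0.64)")
  v <- prod(box$lengths)
  n <- floor(abs(phi * 3 * v / (4 * pi * radius^3)) + 0.5) # half away from 0
  structure(as.integer(n),
            phi_requested = phi,
            phi_realized = 4 * n * pi * radius^3 / (3 * v))
}

#' Place non-overlapping crowders in the box
#'
#' Crowder centres are drawn uniformly in the periodic box, rejecting any
#' candidate closer than `2 R` (minimum image) to an accepted crowder or
#' closer than `R + bead radius` to an exclusion bead. Above the jamming
#' density of random sequential placement (around volume fraction 0.38)
#' rejection sampling stalls, so a seeded, shuffled cubic-lattice fallback
#' (site spacing >= 2 R, small jitter) is used; the subsequent Langevin
#' equilibration melts the lattice.
#'
#' @param n number of crowders.
#' @param radius crowder radius in Angstrom.
#' @param box a `simulation_box`.
#' @param exclusions optional bead coordinate matrix to avoid.
#' @param exclusion_radius bead radii (scalar or per-bead) for the exclusion
#'   distance.
#' @param seed integer seed; placement is reproducible.
#' @param max_tries rejection attempts per crowder before the fallback.
#' @return object of class `crowder_field` with fields `positions`, `radius`,
#'   `phi` (realized), `n`, `method`.
#' @export
place_crowders <- function(n, radius = 10, box = simulation_box(),
                           exclusions = NULL, exclusion_radius = 3,
                           seed = NULL, max_tries = 200) {
  n <- as.integer(n)                      # strip count_crowders attributes
  stopifnot(n >= 0, radius > 0)
  if (!is.null(seed)) set.seed(seed)
  L <- box$lengths
  if (!is.null(exclusions)) {
    exclusions <- as.matrix(exclusions)
    if (length(exclusion_radius) == 1)
      exclusion_radius <- rep(exclusion_radius, nrow(exclusions))
  }
  pos <- matrix(numeric(0), 0, 3)
  method <- "rejection"
  ok_candidate <- function(p, pos) {
    if (nrow(pos)) {
      d <- minimum_image(sweep(pos, 2, p), box)
      if (min(rowSums(d^2)) < (2 * radius)^2) return(FALSE)
    }
    if (!is.null(exclusions)) {
      d <- minimum_image(sweep(exclusions, 2, p), box)
      if (any(rowSums(d^2) < (radius + exclusion_radius)^2)) return(FALSE)
    }
    TRUE
  }
  if (n > 0) {
    failed <- FALSE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        p <- runif(3, -L / 2, L / 2)
        if (ok_candidate(p, pos)) {
          pos <- rbind(pos, p)
          placed <- TRUE
          break
        }
      }
      if (!placed) { failed <- TRUE; break }
    }
    if (failed) {
      # lattice fallback for dense packings
      method <- "lattice"
      nxyz <- pmax(1L, floor(L / (2 * radius)))
      a <- L / nxyz
      sites <- as.matrix(expand.grid(
        x = (seq_len(nxyz[1]) - 0.5) * a[1] - L[1] / 2,
        y = (seq_len(nxyz[2]) - 0.5) * a[2] - L[2] / 2,
        z = (seq_len(nxyz[3]) - 0.5) * a[3] - L[3] / 2))
      keep <- rep(TRUE, nrow(sites))
      if (!is.null(exclusions)) {
        for (s in seq_len(nrow(sites))) {
          d <- minimum_image(sweep(exclusions, 2, sites[s, ]), box)
          if (any(rowSums(d^2) < (radius + exclusion_radius)^2))
            keep[s] <- FALSE
        }
      }
      sites <- sites[keep, , drop = FALSE]
      if (nrow(sites) < n)
        stop("placement failed: only ", nrow(sites),
             " non-overlapping sites available for ", n, " crowders")
      sites <- sites[sample.int(nrow(sites), n), , drop = FALSE]
      jit <- pmin(1, (a - 2 * radius) / 2)
      jitm <- matrix(runif(3 * n, -1, 1), n, 3)
      pos <- sites + sweep(jitm, 2, jit, "*")
    }
  }
  dimnames(pos) <- NULL
  structure(list(positions = pos, radius = radius, n = n,
                 phi = 4 * n * pi * radius^3 / (3 * prod(L)),
                 method = method),
            class = "crowder_field")
}

#' @export
print.crowder_field <- function(x, ...) {
  cat("Crowder field:", x$n, "spheres of radius", x$radius,
      "A (phi =", signif(x$phi, 3), ",", x$method, "placement)\n")
  invisible(x)
}

#' Minimum-image displacement
#'
#' Maps each displacement component into `(-L/2, L/2]`.
#'
#' @param d displacement vector or matrix (columns x, y, z).
#' @param box a `simulation_box` (or length-3 numeric).
#' @return object of the same shape as `d`.
#' @export
minimum_image <- function(d, box) {
  L <- if (inherits(box, "simulation_box")) box$lengths else as.numeric(box)
  vec <- is.null(dim(d))
  d <- matrix(d, ncol = 3)
  out <- cg_minimum_image_cpp(d, L)
  if (vec) out <- drop(out)
  out
}
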