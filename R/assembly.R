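## System assembly: DNA + protein + crowders in a periodic box, plus the
## flattened interaction tables consumed by the compiled kernels.

#' Assemble a simulation system
#'
#' Combines a DNA duplex (centred in the box, axis along z), an optional
#' protein and a crowder field at a requested volume fraction into one
#' periodic system. Crowders are placed avoiding all DNA/protein beads.
#'
#' Protein placement presets:
#' * `"as-is"` / `"bound"`: keep the supplied (docked) pose;
#' * `"kinetic"`: start close to the DNA surface but axially displaced from
#'   the target window (screw-translated by `kinetic_offset_bp`, pushed
#'   `kinetic_radial_out` Angstrom off the bound depth, rotated
#'   `kinetic_theta_off` degrees out of the groove);
#' * `"nonspecific"`: random orientation, placed in bulk more than
#'   `bulk_min_dist` Angstrom from the DNA surface.
#'
#' Specific protein-DNA contacts are active for `"bound"` and `"kinetic"`
#' presets and inactive for `"nonspecific"` (override with
#' `include_specific`).
#'
#' @param dna a `dna_model`.
#' @param protein optional `protein_model` in its bound pose (see
#'   [dock_protein()]).
#' @param phi requested crowder volume fraction.
#' @param box a `simulation_box`.
#' @param params force-field parameters.
#' @param salt molar ionic strength (overrides `params`).
#' @param seed integer seed for crowder placement and protein orientation.
#' @param protein_placement placement preset, see Details.
#' @param include_specific logical; activate the specific-contact potential.
#' @param kinetic_offset_bp axial offset (bp) from the window centre for the
#'   kinetic preset.
#' @param kinetic_radial_out radial push (Angstrom) off the bound depth.
#' @param kinetic_theta_off azimuthal offset (degrees) out of the groove.
#' @param bulk_min_dist minimum protein-DNA bead distance (Angstrom) for the
#'   nonspecific preset.
#' @return object of class `system_assembly`.
#' @export
assemble_system <- function(dna, protein = NULL, phi = 0,
                            box = simulation_box(),
                            params = forcefield_params(),
                            salt = NULL, seed = NULL,
                            protein_placement = c("as-is", "bound", "kinetic",
                                                  "nonspecific"),
                            include_specific = NULL,
                            kinetic_offset_bp = 10, kinetic_radial_out = 4,
                            kinetic_theta_off = 60, bulk_min_dist = 30) {
  protein_placement <- match.arg(protein_placement)
  stopifnot(is.null(dna) || inherits(dna, "dna_model"))
  if (!is.null(salt)) {
    params$ionic_strength <- salt
    tmp <- forcefield_params(temperature = params$temperature,
                             dielectric = params$dielectric,
                             ionic_strength = salt)
    params$kappa <- tmp$kappa
    params$elec_cutoff <- tmp$elec_cutoff
  }
  if (!is.null(dna) && (dna$n_bp - 1) * dna$rise > box$lengths[3])
    stop("DNA is longer than the box z edge")
  if (is.null(dna) && !is.null(protein))
    stop("a protein requires a DNA model")
  if (!is.null(seed)) set.seed(seed)

  if (!is.null(protein)) {
    if (protein_placement == "kinetic") {
      base <- protein
      ro <- kinetic_radial_out
      repeat {
        protein <- screw_place(base, dna, ds_bp = kinetic_offset_bp,
                               radial_out = ro,
                               theta_off = kinetic_theta_off)
        dmin <- min(.cross_dist(protein$beads, dna$beads, box))
        if (dmin >= 0.95 * params$sigma_pd || ro > kinetic_radial_out + 20)
          break
        ro <- ro + 0.5                      # back off until sterically clean
      }
    } else if (protein_placement == "nonspecific") {
      protein <- .place_in_bulk(protein, dna, box, bulk_min_dist)
    }
    if (is.null(include_specific))
      include_specific <- protein_placement %in% c("as-is", "bound", "kinetic")
    if (include_specific && is.null(protein$specific_contacts))
      stop("include_specific = TRUE but the protein has no specific contacts; ",
           "dock it first (see dock_protein)")
  } else include_specific <- FALSE

  crowders <- NULL
  if (phi > 0) {
    nc <- count_crowders(phi, params$crowder_radius, box)
    excl <- rbind(if (!is.null(dna)) dna$beads,
                  if (!is.null(protein)) protein$beads)
    excl_r <- c(if (!is.null(dna)) dna$info$radius,
                if (!is.null(protein)) rep(params$bead_radius$CA, protein$n_res))
    crowders <- place_crowders(nc, params$crowder_radius, box,
                               exclusions = excl, exclusion_radius = excl_r)
  } else {
    crowders <- place_crowders(0, params$crowder_radius, box)
  }

  nd <- if (!is.null(dna)) nrow(dna$beads) else 0L
  np <- if (!is.null(protein)) protein$n_res else 0L
  nc <- crowders$n
  asm <- structure(list(
    dna = dna, protein = protein, crowders = crowders, box = box,
    params = params, salt = params$ionic_strength,
    include_specific = include_specific,
    placement = protein_placement,
    index = list(dna = seq_len(nd),
                 protein = if (np) nd + seq_len(np) else integer(),
                 crowder = if (nc) nd + np + seq_len(nc) else integer()),
    positions = rbind(if (!is.null(dna)) dna$beads,
                      if (!is.null(protein)) protein$beads,
                      crowders$positions)
  ), class = "system_assembly")
  asm
}

# random rigid placement in bulk, > min_dist from every DNA bead
.place_in_bulk <- function(protein, dna, box, min_dist, max_tries = 2000) {
  b <- protein$beads
  b <- sweep(b, 2, colMeans(b))
  for (t in seq_len(max_tries)) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    cand <- b %*% t(R)
    ctr <- runif(3, -box$lengths / 2, box$lengths / 2)
    cand <- sweep(cand, 2, ctr, "+")
    dmin <- min(.cross_dist(cand, dna$beads, box))
    ext <- max(sqrt(rowSums(sweep(cand, 2, ctr)^2)))
    inside <- all(abs(ctr) < box$lengths / 2 - 1)
    if (dmin > min_dist && dmin < min_dist + 25 && inside) {
      protein$beads <- cand
      return(protein)
    }
  }
  stop("could not place the protein in bulk after ", max_tries, " tries")
}

.cross_dist <- function(a, b, box) {
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    d <- minimum_image(sweep(b, 2, a[i, ]), box)
    out[i, ] <- sqrt(rowSums(d^2))
  }
  out
}

#' Screw-translate a bound protein along the DNA helix
#'
#' Moves a docked protein `ds_bp` base pairs along the helix (rotating with
#' the helical twist so the groove registration is preserved), optionally
#' pushes it radially outward and rotates it about the DNA axis out of the
#' groove. Used to construct kinetic-run starting poses and synthetic
#' trajectory fixtures.
#'
#' @param protein docked `protein_model`.
#' @param dna the `dna_model` it is docked on.
#' @param ds_bp axial displacement in bp (may be fractional).
#' @param radial_out extra radial distance from the DNA axis in Angstrom.
#' @param theta_off additional rotation about the axis in degrees.
#' @return the protein with transformed coordinates.
#' @export
screw_place <- function(protein, dna, ds_bp = 0, radial_out = 0,
                        theta_off = 0) {
  b <- protein$beads
  ang <- (ds_bp * dna$twist + theta_off) * pi / 180
  Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  b <- b %*% t(Rz)
  b[, 3] <- b[, 3] + ds_bp * dna$rise
  if (radial_out != 0) {
    com <- colMeans(b[protein$recognition_helix, , drop = FALSE])
    u <- com[1:2] / sqrt(sum(com[1:2]^2))
    b[, 1] <- b[, 1] + radial_out * u[1]
    b[, 2] <- b[, 2] + radial_out * u[2]
  }
  protein$beads <- b
  protein
}

#' Crowder-only gas
#'
#' Assembles a periodic box containing nothing but crowders at the requested
#' volume fraction; crowders interact through excluded volume only.
#'
#' @param phi crowder volume fraction.
#' @param box a `simulation_box`.
#' @param params force-field parameters.
#' @param seed integer placement seed.
#' @return a `system_assembly` without DNA or protein.
#' @export
crowder_gas <- function(phi, box = simulation_box(c(120, 120, 180)),
                        params = forcefield_params(), seed = 1) {
  assemble_system(dna = NULL, protein = NULL, phi = phi, box = box,
                  params = params, seed = seed)
}

#' @export
print.system_assembly <- function(x, ...) {
  cat("System assembly in box", paste(x$box$lengths, collapse = " x "), "A\n")
  if (!is.null(x$dna)) print(x$dna)
  if (!is.null(x$protein)) print(x$protein)
  print(x$crowders)
  cat("  salt:", x$salt, "M; specific contacts",
      if (x$include_specific) "ACTIVE" else "inactive", "\n")
  invisible(x)
}

# ---- flattened tables for the compiled kernels --------------------------

# 0-based interaction tables; cached on the assembly via attribute
ff_tables <- function(assembly) {
  tab <- attr(assembly, "ff_tables")
  if (!is.null(tab)) return(tab)
  p <- assembly$params
  dna <- assembly$dna; prot <- assembly$protein; cr <- assembly$crowders
  nd <- if (!is.null(dna)) nrow(dna$beads) else 0L
  np <- if (!is.null(prot)) prot$n_res else 0L
  nc <- cr$n
  n <- nd + np + nc

  radius <- c(if (nd) dna$info$radius, rep(p$bead_radius$CA, np),
              rep(cr$radius, nc))
  charge <- c(if (nd) dna$charges, if (np) prot$charges, rep(0, nc))
  group <- c(rep(0L, nd), rep(1L, np), rep(2L, nc))

  if (nd) {
    bonds_ij <- cbind(dna$topology$i, dna$topology$j)
    bonds_r0k <- cbind(dna$topology$r0, dna$topology$k)
  } else {
    bonds_ij <- matrix(0L, 0, 2); bonds_r0k <- matrix(0, 0, 2)
  }
  if (np) {
    bonds_ij <- rbind(bonds_ij, cbind(prot$bonds$i + nd, prot$bonds$j + nd))
    bonds_r0k <- rbind(bonds_r0k, cbind(prot$bonds$r0, prot$bonds$k))
  }
  if (np && nrow(prot$angles)) {
    angles_ijk <- cbind(prot$angles$i, prot$angles$j, prot$angles$k) + nd
    angles_t0k <- cbind(prot$angles$theta0, prot$angles$kang)
  } else {
    angles_ijk <- matrix(0L, 0, 3); angles_t0k <- matrix(0, 0, 2)
  }

  cont_ij <- matrix(0L, 0, 2); cont_r0eps <- matrix(0, 0, 2)
  cont_spec <- integer()
  if (np && nrow(prot$native_contacts)) {
    ncn <- prot$native_contacts
    cont_ij <- rbind(cont_ij, cbind(ncn$i + nd, ncn$j + nd))
    cont_r0eps <- rbind(cont_r0eps, cbind(ncn$r0, p$eps_native))
    cont_spec <- c(cont_spec, rep(0L, nrow(ncn)))
  }
  if (np && assembly$include_specific && !is.null(prot$specific_contacts)) {
    sc <- prot$specific_contacts
    cont_ij <- rbind(cont_ij, cbind(sc$res + nd, sc$dna_bead))
    cont_r0eps <- rbind(cont_r0eps, cbind(sc$r0, p$eps_specific))
    cont_spec <- c(cont_spec, rep(1L, nrow(sc)))
  }

  # pairs excluded from the excluded-volume term: networked/bonded pairs,
  # angle 1-3 pairs, and all 12-10 contact pairs
  excl <- rbind(bonds_ij,
                if (nrow(angles_ijk)) angles_ijk[, c(1, 3), drop = FALSE],
                cont_ij)
  excl <- excl[excl[, 1] != excl[, 2], , drop = FALSE]

  # electrostatics: charged protein residues with each other and with DNA
  # phosphates (no DNA-internal electrostatics: the elastic network already
  # encodes the duplex geometry)
  qi <- which(charge != 0)
  charged_ij <- matrix(0L, 0, 2)
  if (length(qi) > 1) {
    grid <- t(utils::combn(qi, 2))
    keep <- !(group[grid[, 1]] == 0 & group[grid[, 2]] == 0)
    grid <- grid[keep, , drop = FALSE]
    if (nrow(grid) && nrow(excl)) {
      key <- paste(pmin(grid[, 1], grid[, 2]), pmax(grid[, 1], grid[, 2]))
      ekey <- paste(pmin(excl[, 1], excl[, 2]), pmax(excl[, 1], excl[, 2]))
      grid <- grid[!key %in% ekey, , drop = FALSE]
    }
    charged_ij <- grid
  }

  # terminal sugar xy restraints (two bp at each end, both strands)
  if (nd) {
    info <- dna$info
    term_bp <- c(0, 1, dna$n_bp - 2, dna$n_bp - 1)
    xy_idx <- which(info$type == "S" & info$bp %in% term_bp)
    xy_ref <- dna$reference$beads[xy_idx, , drop = FALSE]
  } else {
    xy_idx <- integer()
    xy_ref <- matrix(0, 0, 3)
  }

  list(
    n = n, box = assembly$box$lengths,
    radius = radius, charge = charge, mass = rep(1, n),
    group = group,
    bonds_ij = .zero_based(bonds_ij), bonds_r0k = bonds_r0k,
    angles_ijk = .zero_based(angles_ijk), angles_t0k = angles_t0k,
    cont_ij = .zero_based(cont_ij), cont_r0eps = cont_r0eps,
    cont_spec = as.integer(cont_spec),
    charged_ij = .zero_based(charged_ij),
    excl_ij = .zero_based(excl),
    lB = p$lB, kappa = p$kappa, rc_elec = p$elec_cutoff,
    eps_ev = p$eps_ev, sigma_pp = p$sigma_pp, sigma_pd = p$sigma_pd,
    com_idx = seq_len(nd) - 1L, k_com = p$k_com,
    com_target = c(0, 0, 0),
    xy_idx = as.integer(xy_idx - 1L),
    xy_x0 = xy_ref[, 1], xy_y0 = xy_ref[, 2], k_xy = p$k_xy
  )
}

.zero_based <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (nrow(m)) m - 1L else m
}

with_tables <- function(assembly) {
  if (is.null(attr(assembly, "ff_tables")))
    attr(assembly, "ff_tables") <- ff_tables(assembly)
  assembly
}

# ---- serialization ------------------------------------------------------

#' Write / read an assembly archive
#'
#' Serializes an assembly to a self-describing, versioned JSON archive and
#' rebuilds it through the package constructors on read.
#'
#' @param assembly a `system_assembly`.
#' @param path file path.
#' @return `read_assembly` returns the rebuilt `system_assembly`.
#' @export
write_assembly <- function(assembly, path) {
  a <- assembly
  payload <- list(
    format = "crowdsearch/assembly", version = 1L,
    sequence = paste(a$dna$sequence, collapse = ""),
    rise = a$dna$rise, twist = a$dna$twist,
    box = a$box$lengths, salt = a$salt,
    include_specific = a$include_specific,
    crowder_radius = a$crowders$radius,
    crowder_positions = a$crowders$positions,
    protein = if (!is.null(a$protein)) list(
      beads = a$protein$beads,
      residues = a$protein$residues,
      recognition_helix = a$protein$recognition_helix,
      specific_contacts = a$protein$specific_contacts
    ),
    positions = a$positions
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_assembly
#' @export
read_assembly <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "crowdsearch/assembly"))
    stop("not a crowdsearch assembly archive")
  dna <- build_ideal_bdna(p$sequence, rise = p$rise, twist = p$twist)
  prot <- NULL
  if (!is.null(p$protein) && length(p$protein)) {
    prot <- .new_protein(p$protein$beads, p$protein$residues,
                         p$protein$recognition_helix)
    if (!is.null(p$protein$specific_contacts))
      prot$specific_contacts <- as.data.frame(p$protein$specific_contacts)
  }
  asm <- assemble_system(dna, prot, phi = 0,
                         box = simulation_box(p$box), salt = p$salt,
                         include_specific = isTRUE(p$include_specific))
  if (!is.null(p$crowder_positions) && length(p$crowder_positions)) {
    cr <- matrix(p$crowder_positions, ncol = 3)
    asm$crowders <- structure(list(positions = cr, radius = p$crowder_radius,
                                   n = nrow(cr),
                                   phi = 4 * nrow(cr) * pi * p$crowder_radius^3 /
                                     (3 * prod(p$box)),
                                   method = "restored"),
                              class = "crowder_field")
    nd <- nrow(asm$dna$beads)
    np <- if (!is.null(prot)) prot$n_res else 0L
    asm$index$crowder <- nd + np + seq_len(nrow(cr))
  }
  asm$positions <- matrix(p$positions, ncol = 3)
  asm
}
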