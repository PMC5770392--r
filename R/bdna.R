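## Ideal B-DNA builder: 3 beads per nucleotide (phosphate, sugar, base) on a
## right-handed double helix with the axis along +z. The as-built geometry is
## the reference for all deformation measurements.

# cylindrical placement of the three bead types: radial distance (Angstrom)
# and azimuthal offset (degrees) from the base-pair reference angle. Strand B
# mirrors strand A so the sugars flank the minor groove; the major-groove
# bisector of bp i then points along (reference angle + 180 deg).
.bdna_geom <- list(
  r_P = 8.9, r_S = 6.9, r_B = 3.0,
  az_S = 60, az_B = 25
)

#' Generate a random DNA sequence
#'
#' @param n_bp number of base pairs.
#' @param seed integer seed (optional).
#' @return character scalar of A/C/G/T letters.
#' @export
random_dna_sequence <- function(n_bp, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n_bp, replace = TRUE), collapse = "")
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Build an ideal B-form DNA duplex
#'
#' Constructs a three-beads-per-nucleotide double helix with the helical axis
#' along +z, centred at the origin. Each nucleotide carries a phosphate (P,
#' charge -1 e), sugar (S) and base (B) bead; the 5'-terminal nucleotide of
#' each strand carries no phosphate, so a duplex of `N` bp has `6N - 2`
#' beads. A harmonic elastic network fit to the as-built geometry (all
#' intra-DNA bead pairs closer than `params$enm_cutoff`) supplies the bonded
#' topology. The 9-bp target window is centred on the duplex.
#'
#' @param sequence base letters (character scalar or vector) of strand A,
#'   read 5' to 3' along +z.
#' @param rise helical rise per bp in Angstrom (default 3.4).
#' @param twist helical twist per bp in degrees (default 34.3, ~10.5 bp/turn).
#' @param params force-field parameter list from [forcefield_params()]; used
#'   for bead radii and elastic-network constants.
#' @return an object of class `dna_model`.
#' @export
build_ideal_bdna <- function(sequence, rise = 3.4, twist = 34.3,
                             params = forcefield_params()) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(sequence)
  bad <- which(!sequence %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop("non-ACGT character at position ", bad[1], ": '", sequence[bad[1]], "'")
  n_bp <- length(sequence)
  if (n_bp < 10) stop("sequence must be at least 10 bp")
  stopifnot(rise > 0, twist > 0)

  g <- .bdna_geom
  phi <- (seq_len(n_bp) - 1) * twist          # bp reference angle, degrees
  z <- (seq_len(n_bp) - 1) * rise
  z <- z - mean(z)                            # centre on the origin
  d2r <- pi / 180

  cyl <- function(r, az_deg, z) cbind(r * cos(az_deg * d2r), r * sin(az_deg * d2r), z)

  beads <- list(); info <- list()
  add <- function(strand, bp, type, xyz) {
    beads[[length(beads) + 1]] <<- xyz
    info[[length(info) + 1]] <<- data.frame(strand = strand, bp = bp, type = type)
  }
  for (s in c("A", "B")) {
    sgn <- if (s == "A") 1 else -1
    for (i in seq_len(n_bp)) {
      # strand A runs 5'->3' along +z; strand B is antiparallel
      has_p <- if (s == "A") i > 1 else i < n_bp
      if (has_p) {
        azP <- phi[i] + sgn * (g$az_S - twist / 2 * 1)
        zP <- z[i] - sgn * rise / 2
        add(s, i - 1, "P", cyl(g$r_P, azP, zP))
      }
      add(s, i - 1, "S", cyl(g$r_S, phi[i] + sgn * g$az_S, z[i]))
      add(s, i - 1, "B", cyl(g$r_B, phi[i] + sgn * g$az_B, z[i]))
    }
  }
  beads <- do.call(rbind, beads)
  info <- do.call(rbind, info)
  rownames(beads) <- NULL

  radii <- unname(unlist(params$bead_radius[c(P = "P", S = "S", B = "B")]))
  info$radius <- radii[match(info$type, c("P", "S", "B"))]
  info$charge <- ifelse(info$type == "P", -1, 0)

  # elastic network on the ideal geometry
  topo <- .build_enm(beads, params$enm_cutoff, params$enm_k)

  win0 <- ceiling((n_bp - 9) / 2)             # 0-based start, centred window
  dna <- structure(list(
    sequence = sequence,
    sequence_b = unname(.complement[sequence]),
    n_bp = n_bp,
    beads = beads,
    info = info,
    charges = info$charge,
    topology = topo,
    target_window = win0:(win0 + 8),
    rise = rise, twist = twist,
    reference = list(beads = beads,
                     bp_centers = .bp_centers_from(beads, info, n_bp),
                     phi = phi)
  ), class = "dna_model")
  dna
}

# all intra-DNA pairs within cutoff get a spring at the build distance
.build_enm <- function(beads, cutoff, k) {
  d <- as.matrix(stats::dist(beads))
  idx <- which(d > 0 & d <= cutoff & upper.tri(d), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             r0 = d[idx], k = k)
}

# bp centers = midpoints of the paired base beads
.bp_centers_from <- function(beads, info, n_bp) {
  ia <- match(paste0("A", 0:(n_bp - 1)),
              paste0(info$strand, info$bp)[seq_len(nrow(info))] )
  bi <- which(info$strand == "A" & info$type == "B")
  bj <- which(info$strand == "B" & info$type == "B")
  bi <- bi[order(info$bp[bi])]
  bj <- bj[order(info$bp[bj])]
  (beads[bi, , drop = FALSE] + beads[bj, , drop = FALSE]) / 2
}

# indices of the paired base beads (for C++ analysis kernels), bp-ordered
.base_pair_indices <- function(dna) {
  info <- dna$info
  bi <- which(info$strand == "A" & info$type == "B")
  bj <- which(info$strand == "B" & info$type == "B")
  list(i = bi[order(info$bp[bi])], j = bj[order(info$bp[bj])])
}

# indices of the two sugar beads of bp k (for the groove direction)
.sugar_pair_indices <- function(dna) {
  info <- dna$info
  si <- which(info$strand == "A" & info$type == "S")
  sj <- which(info$strand == "B" & info$type == "S")
  list(i = si[order(info$bp[si])], j = sj[order(info$bp[sj])])
}

#' @export
print.dna_model <- function(x, ...) {
  cat("Ideal B-DNA duplex:", x$n_bp, "bp,", nrow(x$beads), "beads\n")
  cat("  rise", x$rise, "A, twist", x$twist, "deg,",
      "length", round((x$n_bp - 1) * x$rise, 1), "A along z\n")
  cat("  target window (0-based bp):", min(x$target_window), "-",
      max(x$target_window), "\n")
  cat("  elastic network:", nrow(x$topology), "springs\n")
  invisible(x)
}
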