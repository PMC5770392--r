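## Force-field parameters and the elementary interaction forms. Energies are
## in reduced units (k_B.T at 300 K = 1), lengths in Angstrom, charges in e.

# e^2 / (4 pi eps0 k_B) = 1.671009e5 Angstrom Kelvin
.COULOMB_AK <- 1.671009e5
# ions per cubic Angstrom for a 1 mol/L solution
.MOLAR_PER_A3 <- 6.02214076e-4

#' Force-field parameter set
#'
#' Returns the full parameter list used by the energy and dynamics kernels.
#' All energy scales are in units of k_B.T at 300 K. The Debye screening
#' constant `kappa` and Bjerrum length `lB` are derived from the ionic
#' strength, temperature and dielectric constant.
#'
#' @param temperature temperature in K (default 300).
#' @param dielectric relative dielectric constant (default 78).
#' @param ionic_strength molar ionic strength (default 0.140 M).
#' @param eps_ev excluded-volume (WCA) energy scale.
#' @param eps_native native-contact well depth (12-10 potential).
#' @param eps_specific specific protein-DNA contact well depth; defaults to
#'   twice the excluded-volume scale so the specifically bound protein cannot
#'   fully dissociate at 300 K.
#' @param bond_k,angle_k protein bond and angle force constants
#'   (kT/A^2, kT/rad^2).
#' @param enm_cutoff,enm_k DNA elastic-network cutoff (A) and spring constant.
#' @param native_cutoff C-alpha distance cutoff for native contacts (A).
#' @param specific_cutoff residue-to-DNA-bead cutoff for specific contacts (A).
#' @param contact_tol a specific contact counts as formed when the pair
#'   distance is below `r0 * (1 + contact_tol)`.
#' @param bead_radius list of half-diameters for the WCA terms (A); additive
#'   radii apply to every pair involving a crowder and within the DNA.
#' @param sigma_pp,sigma_pd fixed WCA contact diameters for protein-protein
#'   nonbonded and protein-DNA cross pairs (A). These are deliberately
#'   slimmer than the additive radii so the recognition helix can insert
#'   into the major groove without steric strain.
#' @param crowder_radius crowder radius in A (default 10).
#' @param k_com harmonic restraint on the DNA centre of mass (kT/A^2).
#' @param k_xy weak xy restraint on terminal sugar beads, keeping the helix
#'   axis aligned with z for the helical-coordinate analyses.
#' @param elec_cutoff_factor electrostatic cutoff in Debye lengths.
#' @return a named list of class `forcefield_params`.
#' @export
forcefield_params <- function(temperature = 300, dielectric = 78,
                              ionic_strength = 0.140,
                              eps_ev = 1, eps_native = 2, eps_specific = 2,
                              bond_k = 100, angle_k = 20,
                              enm_cutoff = 12, enm_k = 5,
                              native_cutoff = 8, specific_cutoff = 7,
                              contact_tol = 0.2,
                              bead_radius = list(P = 2, S = 3, B = 3, CA = 2.5),
                              sigma_pp = 4.0, sigma_pd = 3.5,
                              crowder_radius = 10,
                              k_com = 1, k_xy = 0.2,
                              elec_cutoff_factor = 4) {
  stopifnot(temperature > 0, ionic_strength >= 0, eps_ev > 0)
  lB <- .COULOMB_AK / (dielectric * temperature)
  kappa <- if (ionic_strength > 0)
    sqrt(8 * pi * lB * ionic_strength * .MOLAR_PER_A3) else 0
  # reduced energy unit is kT at 300 K; lB above is in kT(T) units, convert
  lB_red <- lB * temperature / 300
  structure(list(
    temperature = temperature, dielectric = dielectric,
    ionic_strength = ionic_strength,
    lB = lB_red, kappa = kappa,
    elec_cutoff = if (kappa > 0) elec_cutoff_factor / kappa else Inf,
    eps_ev = eps_ev, eps_native = eps_native, eps_specific = eps_specific,
    bond_k = bond_k, angle_k = angle_k,
    enm_cutoff = enm_cutoff, enm_k = enm_k,
    native_cutoff = native_cutoff, specific_cutoff = specific_cutoff,
    contact_tol = contact_tol,
    bead_radius = bead_radius, sigma_pp = sigma_pp, sigma_pd = sigma_pd,
    crowder_radius = crowder_radius,
    k_com = k_com, k_xy = k_xy
  ), class = "forcefield_params")
}

#' Debye screening length
#'
#' Computes the Debye length `1/kappa = sqrt(eps eps0 kB T / (2 NA e^2 I))`
#' for a 1:1 salt, in Angstrom.
#'
#' @param ionic_strength molar ionic strength (> 0).
#' @param temperature temperature in K.
#' @param dielectric relative dielectric constant.
#' @return Debye length in Angstrom.
#' @examples
#' debye_length(0.140, 300, 78)   # ~8.1 A at physiological salt
#' @export
debye_length <- function(ionic_strength, temperature = 300, dielectric = 78) {
  if (ionic_strength <= 0)
    stop("ionic strength must be > 0 (use unscreened Coulomb instead)")
  lB <- .COULOMB_AK / (dielectric * temperature)
  1 / sqrt(8 * pi * lB * ionic_strength * .MOLAR_PER_A3)
}

#' Screened (Debye-Hueckel) pair energy
#'
#' `U = lB qi qj exp(-kappa r) / r` in reduced units. With `shifted = TRUE`
#' the shifted-force form used by the simulation kernels (energy and force
#' both continuous at the cutoff) is returned.
#'
#' @param qi,qj charges in e.
#' @param r separation in Angstrom (> 0).
#' @param params force-field parameters.
#' @param shifted apply the force-shift at the electrostatic cutoff.
#' @return energy in kT units.
#' @export
debye_huckel_energy <- function(qi, qj, r, params = forcefield_params(),
                                shifted = FALSE) {
  if (any(r <= 0)) stop("r must be > 0")
  u <- params$lB * qi * qj * exp(-params$kappa * r) / r
  if (!shifted) return(u)
  rc <- params$elec_cutoff
  urc <- params$lB * qi * qj * exp(-params$kappa * rc) / rc
  durc <- -params$lB * qi * qj * exp(-params$kappa * rc) *
    (1 + params$kappa * rc) / rc^2
  out <- u - urc - (r - rc) * durc
  out[r >= rc] <- 0
  out
}

#' Purely repulsive excluded-volume (WCA) energy
#'
#' Truncated-shifted Lennard-Jones: `4 eps [(sigma/r)^12 - (sigma/r)^6] + eps`
#' for `r <= 2^(1/6) sigma`, zero beyond.
#'
#' @param r separation in Angstrom (> 0).
#' @param sigma contact diameter in Angstrom.
#' @param eps energy scale in kT.
#' @return energy in kT units.
#' @export
excluded_volume_energy <- function(r, sigma, eps = 1) {
  if (any(r <= 0)) stop("r must be > 0")
  s6 <- (sigma / r)^6
  u <- 4 * eps * (s6^2 - s6) + eps
  u[r > 2^(1 / 6) * sigma] <- 0
  u
}

#' 12-10 contact energy
#'
#' Structure-based contact potential `eps [5 (r0/r)^12 - 6 (r0/r)^10]` with
#' minimum `-eps` at `r = r0`; used for both native (intra-protein) and
#' specific (protein-DNA) contacts.
#'
#' @param r separation in Angstrom (> 0).
#' @param r0 native distance in Angstrom.
#' @param eps well depth in kT.
#' @return energy in kT units.
#' @export
contact_energy <- function(r, r0, eps = 1) {
  if (any(r <= 0)) stop("r must be > 0")
  s <- r0 / r
  eps * (5 * s^12 - 6 * s^10)
}

#' Full energy breakdown of an assembled system
#'
#' Evaluates every term of the potential at the supplied coordinates, with
#' the minimum-image convention. Crowders contribute only excluded volume;
#' electrostatics acts between charged protein residues and between protein
#' charges and DNA phosphates.
#'
#' @param assembly a `system_assembly`.
#' @param positions bead coordinate matrix (defaults to the assembly's own);
#'   row count must match the assembly.
#' @param forces also return the analytic forces.
#' @return list of class `energy_breakdown` with components `bonded`,
#'   `native`, `specific`, `electrostatic`, `excluded_volume` (plus the
#'   protein-crowder and protein-DNA shares), and `total`, in kT units.
#' @export
total_energy <- function(assembly, positions = NULL, forces = FALSE) {
  stopifnot(inherits(assembly, "system_assembly"))
  tab <- ff_tables(assembly)
  if (is.null(positions)) positions <- assembly$positions
  if (nrow(positions) != tab$n)
    stop("positions have ", nrow(positions), " rows; assembly has ", tab$n, " beads")
  res <- cg_energy_cpp(positions, tab)
  out <- res[c("bonded", "native", "specific", "electrostatic",
               "excluded_volume", "ev_protein_crowder", "ev_protein_dna",
               "total")]
  if (forces) out$forces <- res$forces
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("Energy breakdown (kT units):\n")
  for (nm in c("bonded", "native", "specific", "electrostatic",
               "excluded_volume", "total"))
    cat(sprintf("  %-16s %12.4f\n", nm, x[[nm]]))
  invisible(x)
}
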