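## C-alpha protein model: one bead per residue, charges from residue
## identity, structure-based (Go-type) contacts from the build-time pose.

.positive_res <- c("ARG", "LYS")
.negative_res <- c("GLU", "ASP")

.residue_charge <- function(resid) {
  ifelse(resid %in% .positive_res, 1, ifelse(resid %in% .negative_res, -1, 0))
}

.new_protein <- function(beads, residues, recognition_helix,
                         params = forcefield_params()) {
  beads <- as.matrix(beads)
  rownames(beads) <- NULL
  n <- nrow(beads)
  stopifnot(length(residues) == n)
  if (length(recognition_helix) == 0) stop("recognition_helix must be nonempty")
  p <- structure(list(
    beads = beads,
    n_res = n,
    residues = residues,
    charges = .residue_charge(residues),
    recognition_helix = as.integer(recognition_helix),
    native_contacts = NULL,
    specific_contacts = NULL,
    bonds = .protein_bonds(beads, params),
    angles = .protein_angles(beads, params)
  ), class = "protein_model")
  p$native_contacts <- derive_native_contacts(p, params$native_cutoff)
  p
}

.protein_bonds <- function(beads, params) {
  n <- nrow(beads)
  i <- seq_len(n - 1); j <- i + 1
  r0 <- sqrt(rowSums((beads[i, , drop = FALSE] - beads[j, , drop = FALSE])^2))
  data.frame(i = i, j = j, r0 = r0, k = params$bond_k)
}

.protein_angles <- function(beads, params) {
  n <- nrow(beads)
  if (n < 3) return(data.frame(i = integer(), j = integer(), k = integer(),
                               theta0 = numeric(), kang = numeric()))
  i <- seq_len(n - 2); j <- i + 1; k <- i + 2
  v1 <- beads[i, , drop = FALSE] - beads[j, , drop = FALSE]
  v2 <- beads[k, , drop = FALSE] - beads[j, , drop = FALSE]
  ct <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  data.frame(i = i, j = j, k = k,
             theta0 = acos(pmin(1, pmax(-1, ct))), kang = params$angle_k)
}

#' Load a C-alpha protein model from a PDB structure
#'
#' Extracts one bead per residue at the C-alpha position of a single chain,
#' assigns charges from residue identity (Arg/Lys +1 e, Glu/Asp -1 e) and
#' derives the native contact map from the crystal pose.
#'
#' @param pdb path to a PDB file, or a `pdb` object from [bio3d::read.pdb()].
#' @param chain chain identifier (default: first chain in the file).
#' @param recognition_helix integer vector of residue indices (1-based, in
#'   order of appearance) forming the DNA-recognition helix.
#' @param params force-field parameters.
#' @return an object of class `protein_model`.
#' @export
load_protein <- function(pdb, chain = NULL, recognition_helix,
                         params = forcefield_params()) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain & at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("empty chain '", chain, "'")
  res_keys <- unique(paste(at$resno, at$insert))
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca_keys <- paste(ca$resno, ca$insert)
  missing <- setdiff(res_keys, ca_keys)
  if (length(missing))
    warning(length(missing), " residue(s) without a C-alpha atom skipped")
  ca <- ca[!duplicated(ca_keys), , drop = FALSE]
  if (nrow(ca) == 0) stop("no C-alpha atoms in chain '", chain, "'")
  .new_protein(as.matrix(ca[, c("x", "y", "z")]), ca$resid,
               recognition_helix, params)
}

#' Native (intra-protein) contact map
#'
#' All residue pairs at least 4 apart in sequence whose C-alpha distance in
#' the build-time structure is within `cutoff`; the build distance becomes
#' the 12-10 contact minimum `r0`.
#'
#' @param protein a `protein_model`.
#' @param cutoff distance cutoff in Angstrom.
#' @return data frame with columns `i`, `j`, `r0`.
#' @export
derive_native_contacts <- function(protein, cutoff) {
  stopifnot(inherits(protein, "protein_model"), cutoff >= 0)
  n <- protein$n_res
  if (n < 5) stop("protein must have at least 5 residues")
  d <- as.matrix(stats::dist(protein$beads))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  idx <- which(upper.tri(d) & sep >= 4 & d <= cutoff, arr.ind = TRUE)
  out <- data.frame(i = idx[, 1], j = idx[, 2], r0 = d[idx])
  out[order(out$i, out$j), , drop = FALSE]
}

#' Specific protein-DNA contact list
#'
#' From a bound pose, all (recognition-helix residue, DNA bead) pairs within
#' `cutoff`, restricted to DNA beads of the 9-bp target window. The bound
#' distance becomes the 12-10 minimum `r0`.
#'
#' @param protein `protein_model` positioned in its bound pose.
#' @param dna a `dna_model`.
#' @param cutoff distance cutoff in Angstrom.
#' @param flank how many residues on each side of the recognition helix may
#'   also contact the DNA (default 1).
#' @return data frame with columns `res`, `dna_bead`, `r0`.
#' @export
derive_specific_contacts <- function(protein, dna, cutoff, flank = 1) {
  stopifnot(inherits(protein, "protein_model"), inherits(dna, "dna_model"))
  rh <- protein$recognition_helix
  res_ok <- sort(unique(pmax(1, pmin(protein$n_res,
    c(outer(rh, -flank:flank, "+"))))))
  win_beads <- which(dna$info$bp %in% dna$target_window)
  pr <- protein$beads[res_ok, , drop = FALSE]
  db <- dna$beads[win_beads, , drop = FALSE]
  d <- sqrt(outer(rowSums(pr^2), rep(1, nrow(db))) +
            outer(rep(1, nrow(pr)), rowSums(db^2)) - 2 * pr %*% t(db))
  idx <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop("no specific contacts within ", cutoff, " A: protein not bound")
  out <- data.frame(res = res_ok[idx[, 1]],
                    dna_bead = win_beads[idx[, 2]],
                    r0 = d[idx])
  out[order(out$res, out$dna_bead), , drop = FALSE]
}

#' @export
print.protein_model <- function(x, ...) {
  cat("C-alpha protein model:", x$n_res, "residues, net charge",
      sum(x$charges), "e\n")
  cat("  recognition helix: residues", min(x$recognition_helix), "-",
      max(x$recognition_helix), "\n")
  cat("  native contacts:", nrow(x$native_contacts), "\n")
  if (!is.null(x$specific_contacts))
    cat("  specific contacts:", nrow(x$specific_contacts), "(bound pose)\n")
  invisible(x)
}
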