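## Specific-complex formation: contact counting, first-passage kinetics,
## DNA deformation and binding-landscape ruggedness.

#' Count formed specific contacts in one frame
#'
#' A contact is formed when the current pair distance is at most
#' `r0 * (1 + tolerance)`.
#'
#' @param positions full bead coordinate matrix for one frame.
#' @param assembly a `system_assembly` with a docked protein.
#' @param tolerance relative distance tolerance (default from the
#'   force-field parameters, 0.2).
#' @return integer count of formed contacts.
#' @export
specific_contact_count <- function(positions, assembly,
                                   tolerance = assembly$params$contact_tol) {
  sc <- assembly$protein$specific_contacts
  if (is.null(sc)) stop("assembly's protein has no specific contacts")
  nd <- nrow(assembly$dna$beads)
  pi <- sc$res + nd; pj <- sc$dna_bead
  d <- positions[pi, , drop = FALSE] - positions[pj, , drop = FALSE]
  d <- .wrap_mat(d, assembly$box$lengths)
  sum(sqrt(rowSums(d^2)) <= sc$r0 * (1 + tolerance))
}

#' Specific-contact time series of a trajectory
#'
#' @param traj a `cg_trajectory` from a kinetic-preset run.
#' @param tolerance relative distance tolerance.
#' @return data frame of class `contact_series` (`time` in MD steps, `n_s`),
#'   with attribute `total_contacts`.
#' @export
contact_series <- function(traj,
                           tolerance = traj$assembly$params$contact_tol) {
  a <- traj$assembly
  sc <- a$protein$specific_contacts
  if (is.null(sc)) stop("assembly's protein has no specific contacts")
  nf <- n_frames(traj)
  ns <- vapply(seq_len(nf), function(f)
    specific_contact_count(frame_coords(traj, f), a, tolerance), integer(1))
  structure(data.frame(time = traj$times, n_s = ns),
            class = c("contact_series", "data.frame"),
            total_contacts = nrow(sc))
}

#' Mean first time to a fraction of specific contacts
#'
#' Per series, the first time the contact count reaches
#' `ceiling(f * total)`; series that never reach it are right-censored and
#' excluded from the mean, with the censoring fraction reported.
#'
#' @param ensemble list of `contact_series`.
#' @param f target fraction in (0, 1] (default 0.8).
#' @return list of class `tfrac`: `t_f` (mean), `se`, `times` (per series,
#'   NA = censored), `threshold`, `censored_fraction`.
#' @export
time_to_fraction <- function(ensemble, f = 0.8) {
  stopifnot(f > 0, f <= 1, length(ensemble) >= 1)
  if (inherits(ensemble, "contact_series")) ensemble <- list(ensemble)
  times <- vapply(ensemble, function(s) {
    thr <- ceiling(f * attr(s, "total_contacts"))
    hit <- which(s$n_s >= thr)
    if (length(hit)) s$time[hit[1]] else NA_real_
  }, numeric(1))
  ok <- !is.na(times)
  if (!any(ok))
    warning("no series reached the ", f, " contact fraction (all censored)")
  thr <- ceiling(f * attr(ensemble[[1]], "total_contacts"))
  structure(list(
    t_f = if (any(ok)) mean(times[ok]) else NA_real_,
    se = if (sum(ok) > 1) sd(times[ok]) / sqrt(sum(ok)) else NA_real_,
    times = times, threshold = thr, f = f,
    censored_fraction = mean(!ok)), class = "tfrac")
}

#' First association time with the target window
#'
#' The first time the protein's nearest base pair lies inside the 9-bp
#' target window while the protein is in a 1D mode (S or H). With
#' `from = "contact"` the first formation of any specific contact is used
#' instead.
#'
#' @param traj a `cg_trajectory`.
#' @param labels `mode_labels` for the trajectory (computed if omitted).
#' @param from `"arrival"` (nearest-bp in window, default) or `"contact"`.
#' @param series optional precomputed `contact_series` (for
#'   `from = "contact"`).
#' @return first time in MD steps, or `NA` if never.
#' @export
first_association <- function(traj, labels = NULL,
                              from = c("arrival", "contact"),
                              series = NULL) {
  from <- match.arg(from)
  if (from == "contact") {
    if (is.null(series)) series <- contact_series(traj)
    hit <- which(series$n_s >= 1)
    return(if (length(hit)) series$time[hit[1]] else NA_real_)
  }
  if (is.null(labels)) labels <- classify_frames(traj)
  win <- traj$assembly$dna$target_window
  hit <- which(labels$label %in% c("S", "H") & labels$nearest_bp %in% win)
  if (length(hit)) labels$time[hit[1]] else NA_real_
}

#' Association rate from an ensemble of first-arrival times
#'
#' `tau_1` is the mean first time the protein reaches the target window
#' (while scanning in a 1D mode); `k_A = 1/tau_1`. A run starting inside
#' the window contributes 0 (immediate association).
#'
#' @param times numeric vector of first-association times in MD steps
#'   (NA = censored run).
#' @return list of class `rate_estimate`: `tau`, `rate`, `n`,
#'   `censored_fraction`.
#' @export
association_rate <- function(times) {
  ok <- !is.na(times)
  if (!any(ok)) warning("all runs censored; association rate undefined")
  tau <- if (any(ok)) mean(times[ok]) else NA_real_
  structure(list(tau = tau,
                 rate = if (!is.na(tau)) (if (tau > 0) 1 / tau else Inf)
                        else NA_real_,
                 n = sum(ok), censored_fraction = mean(!ok),
                 kind = "association"), class = "rate_estimate")
}

#' Orientation rate from association and completion times
#'
#' `tau_2` is the mean additional time between first association and
#' reaching the target contact fraction; `k_O = 1/tau_2`.
#'
#' @param t_f per-run times to the contact fraction (NA = censored).
#' @param t_assoc per-run first-association times (NA = censored).
#' @return list of class `rate_estimate`.
#' @export
orientation_rate <- function(t_f, t_assoc) {
  stopifnot(length(t_f) == length(t_assoc))
  ok <- !is.na(t_f) & !is.na(t_assoc)
  if (!any(ok)) warning("all runs censored; orientation rate undefined")
  tau <- if (any(ok)) mean(t_f[ok] - t_assoc[ok]) else NA_real_
  structure(list(tau = tau,
                 rate = if (!is.na(tau)) (if (tau > 0) 1 / tau else Inf)
                        else NA_real_,
                 n = sum(ok), censored_fraction = mean(!ok),
                 kind = "orientation"), class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(x$kind, "rate: tau =", signif(x$tau, 4), "steps, k =",
      signif(x$rate, 4), "/step (n =", x$n, ", censored",
      signif(100 * x$censored_fraction, 3), "%)\n")
  invisible(x)
}

# optimal rigid superposition (Kabsch); returns P aligned onto Q
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(Pc %*% t(R), 2, cq, "+")
}

#' Per-base-pair DNA deformation profile
#'
#' For each frame the full DNA is rigidly superposed onto the ideal
#' reference geometry; the deformation of bp `i` is the mean displacement of
#' its local coordinate (the midpoint of the paired base beads) from the
#' reference position. `D_s` is the profile normalised by its maximum so
#' the most deformed position maps to 1; to normalise jointly across
#' several ensembles (e.g. different crowder fractions) use
#' [ds_normalize()] on the raw profiles.
#'
#' @param traj a `cg_trajectory` (or a beads x 3 x frames array of full
#'   system coordinates laid out like the assembly).
#' @param assembly required when `traj` is a bare array.
#' @param frames frame indices to use (default: all).
#' @param normalize return the max-normalised profile.
#' @return list of class `deformation_profile`: `bp`, `raw` (Angstrom),
#'   `ds` (normalised, when requested).
#' @export
deformation_profile <- function(traj, assembly = NULL, frames = NULL,
                                normalize = TRUE) {
  if (inherits(traj, "cg_trajectory")) {
    assembly <- traj$assembly
    arr <- traj$frames
  } else arr <- traj
  if (is.null(assembly)) stop("assembly required")
  if (is.null(frames)) frames <- seq_len(dim(arr)[3])
  if (length(frames) == 0) stop("empty frame set")
  dna <- assembly$dna
  idxD <- assembly$index$dna
  ref <- dna$reference$beads
  bp <- .base_pair_indices(dna)
  refc <- (ref[bp$i, ] + ref[bp$j, ]) / 2
  acc <- numeric(dna$n_bp)
  for (f in frames) {
    X <- arr[idxD, , f]
    Xal <- .kabsch(X, ref)
    cc <- (Xal[bp$i, ] + Xal[bp$j, ]) / 2
    acc <- acc + sqrt(rowSums((cc - refc)^2))
  }
  raw <- acc / length(frames)
  out <- list(bp = seq_len(dna$n_bp) - 1L, raw = raw,
              ds = if (normalize && max(raw) > 0) raw / max(raw)
                   else if (normalize) raw else NULL)
  class(out) <- "deformation_profile"
  out
}

#' Jointly normalise deformation profiles
#'
#' Divides every raw profile by the maximum over all supplied profiles, so
#' ensembles sampled at different crowder fractions share one D_s scale.
#'
#' @param profiles list of `deformation_profile` objects.
#' @return the list with `ds` replaced by jointly normalised values.
#' @export
ds_normalize <- function(profiles) {
  mx <- max(vapply(profiles, function(p) max(p$raw), numeric(1)))
  lapply(profiles, function(p) { p$ds <- p$raw / mx; p })
}

# population standard deviation
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Ruggedness profile from energy samples
#'
#' Per-bp population standard deviation of the supplied energy samples.
#' Base pairs with fewer than `min_samples` samples are reported as `NA`.
#'
#' @param bp integer nearest-bp assignment per sample (0-based).
#' @param energy energy sample per observation, in kT units.
#' @param n_bp total number of base pairs.
#' @param min_samples minimum samples per bp (default 2).
#' @param direction `"3to5"` (default, reversed bp order as conventionally
#'   plotted) or `"5to3"`.
#' @return data frame: `bp`, `sigma`, `n`.
#' @export
ruggedness_from_samples <- function(bp, energy, n_bp, min_samples = 2,
                                    direction = c("3to5", "5to3")) {
  direction <- match.arg(direction)
  stopifnot(length(bp) == length(energy))
  sig <- rep(NA_real_, n_bp); cnt <- integer(n_bp)
  for (k in seq_len(n_bp)) {
    x <- energy[bp == k - 1]
    cnt[k] <- length(x)
    if (length(x) >= min_samples) sig[k] <- .pop_sd(x)
  }
  out <- data.frame(bp = seq_len(n_bp) - 1L, sigma = sig, n = cnt)
  if (direction == "3to5") out <- out[rev(seq_len(n_bp)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binding-energy-landscape ruggedness along the DNA
#'
#' Assigns every frame to the protein's nearest base pair and collects the
#' specific interaction energy at target-window positions and the
#' protein-DNA excluded-volume energy elsewhere; the per-bp population
#' standard deviation of those samples is the landscape ruggedness.
#'
#' @param traj a `cg_trajectory`.
#' @param labels `mode_labels` (computed if omitted); only 1D (S/H) frames
#'   contribute samples.
#' @param min_samples minimum samples per bp.
#' @param direction bp ordering of the output, `"3to5"` or `"5to3"`.
#' @return data frame: `bp`, `sigma`, `n`, plus attribute `window`.
#' @export
ruggedness_profile <- function(traj, labels = NULL, min_samples = 2,
                               direction = "3to5") {
  if (is.null(labels)) labels <- classify_frames(traj)
  a <- traj$assembly
  en <- frame_energies(traj)
  use <- labels$label %in% c("S", "H")
  bp <- labels$nearest_bp[use]
  in_win <- bp %in% a$dna$target_window
  e <- ifelse(in_win & a$include_specific,
              en[use, "specific"], en[use, "ev_protein_dna"])
  out <- ruggedness_from_samples(bp, e, a$dna$n_bp, min_samples, direction)
  attr(out, "window") <- a$dna$target_window
  out
}
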