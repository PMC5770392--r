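## Search-mode classification and nonspecific-search observables.

#' Classify trajectory frames into sliding / hopping / 3D diffusion
#'
#' A frame is 3D diffusion (`D`) when the minimum protein-bead to DNA-bead
#' distance exceeds `d_bulk`. Otherwise it is sliding (`S`) when the
#' recognition-helix centre of mass lies within `r_slide` of the DNA axis
#' AND its azimuth is within `dtheta_groove` degrees of the major-groove
#' bisector of the nearest base pair; any remaining near-DNA frame is
#' hopping (`H`). Sliding and hopping are therefore complementary within the
#' 1D regime.
#'
#' @param traj a `cg_trajectory` whose assembly contains a protein.
#' @param d_bulk bulk cutoff in Angstrom (default 30).
#' @param r_slide maximal axis distance of the recognition-helix COM for
#'   sliding (default 13 A).
#' @param dtheta_groove half-width of the groove azimuth band in degrees
#'   (default 60).
#' @return data frame of class `mode_labels`: `frame`, `time`, `label`
#'   (S/H/D), `min_dist`, `radial`, `theta_off`, `nearest_bp` (0-based).
#' @export
classify_frames <- function(traj, d_bulk = 30, r_slide = 13,
                            dtheta_groove = 60) {
  a <- traj$assembly
  if (is.null(a$protein)) stop("assembly has no protein")
  L <- a$box$lengths
  nf <- n_frames(traj)
  idxP <- a$index$protein
  idxD <- a$index$dna
  mind <- cg_min_dist_cpp(traj$frames, idxP, idxD, L)

  rh <- a$index$protein[a$protein$recognition_helix]
  hcom <- .subset_com(traj$frames, rh)                    # 3 x nf
  axis_xy <- .subset_com(traj$frames, idxD)[1:2, , drop = FALSE]

  bp <- .base_pair_indices(a$dna)
  sg <- .sugar_pair_indices(a$dna)
  bpc <- (traj$frames[bp$i, , , drop = FALSE] +
          traj$frames[bp$j, , , drop = FALSE]) / 2        # nbp x 3 x nf
  smid <- (traj$frames[sg$i, , , drop = FALSE] +
           traj$frames[sg$j, , , drop = FALSE]) / 2

  nbp <- a$dna$n_bp
  nearest <- integer(nf); theta_off <- numeric(nf); radial <- numeric(nf)
  for (f in seq_len(nf)) {
    d <- sweep(bpc[, , f, drop = TRUE], 2, hcom[, f], "-")
    d <- .wrap_mat(d, L)
    k <- which.min(rowSums(d^2))
    nearest[f] <- k - 1L
    g <- bpc[k, 1:2, f] - smid[k, 1:2, f]                 # major-groove dir
    v <- .wrap_vec(hcom[1:2, f] - bpc[k, 1:2, f], L[1:2])
    ang <- atan2(v[2], v[1]) - atan2(g[2], g[1])
    theta_off[f] <- abs(((ang * 180 / pi + 180) %% 360) - 180)
    rxy <- .wrap_vec(hcom[1:2, f] - axis_xy[, f], L[1:2])
    radial[f] <- sqrt(sum(rxy^2))
  }
  lab <- ifelse(mind > d_bulk, "D",
                ifelse(radial <= r_slide & theta_off <= dtheta_groove,
                       "S", "H"))
  structure(data.frame(frame = seq_len(nf), time = traj$times, label = lab,
                       min_dist = mind, radial = radial,
                       theta_off = theta_off, nearest_bp = nearest),
            class = c("mode_labels", "data.frame"),
            thresholds = list(d_bulk = d_bulk, r_slide = r_slide,
                              dtheta_groove = dtheta_groove))
}

.subset_com <- function(frames, idx) {
  sub <- frames[idx, , , drop = FALSE]
  apply(sub, c(2, 3), mean)
}

.wrap_mat <- function(d, L) {
  for (c in 1:ncol(d)) d[, c] <- d[, c] - L[c] * ceiling(d[, c] / L[c] - 0.5)
  d
}
.wrap_vec <- function(d, L) d - L * ceiling(d / L - 0.5)

.label_vec <- function(labels) {
  if (is.data.frame(labels)) as.character(labels$label) else as.character(labels)
}

#' Search-mode propensities
#'
#' Fraction of frames spent in each mode; sums to one.
#'
#' @param labels a `mode_labels` frame or character vector of S/H/D labels.
#' @return named numeric vector `c(S = , H = , D = )`.
#' @export
mode_propensities <- function(labels) {
  v <- .label_vec(labels)
  if (length(v) == 0) stop("empty label sequence")
  c(S = mean(v == "S"), H = mean(v == "H"), D = mean(v == "D"))
}

#' Majority-filter smoothing of mode labels
#'
#' Removes single-frame label flicker with a centred majority filter; used
#' before event segmentation so stride-level noise does not fragment events.
#' Raw labels should be kept for propensities.
#'
#' @param labels a `mode_labels` frame or character vector.
#' @param window odd window size (default 3).
#' @return object of the same type with smoothed labels.
#' @export
smooth_labels <- function(labels, window = 3) {
  v <- .label_vec(labels)
  n <- length(v)
  h <- window %/% 2
  out <- v
  if (n >= window) {
    for (i in seq_len(n)) {
      lo <- max(1, i - h); hi <- min(n, i + h)
      tb <- table(v[lo:hi])
      if (max(tb) > (hi - lo + 1) / 2) out[i] <- names(tb)[which.max(tb)]
    }
  }
  if (is.data.frame(labels)) { labels$label <- out; labels } else out
}

#' Segment a label track into contiguous search events
#'
#' Maximal runs of identical labels become events; the summary reports the
#' event count and mean duration per mode (in frames).
#'
#' @param labels a `mode_labels` frame or character vector.
#' @return list of class `event_table` with `events` (mode, start, end,
#'   duration) and `summary` (mode, n_events, mean_duration).
#' @export
segment_events <- function(labels) {
  v <- .label_vec(labels)
  if (length(v) == 0) stop("empty label sequence")
  r <- rle(v)
  end <- cumsum(r$lengths)
  events <- data.frame(mode = r$values,
                       start = end - r$lengths + 1L,
                       end = end, duration = r$lengths)
  smry <- do.call(rbind, lapply(split(events, events$mode), function(e)
    data.frame(mode = e$mode[1], n_events = nrow(e),
               mean_duration = mean(e$duration))))
  rownames(smry) <- NULL
  structure(list(events = events, summary = smry), class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("Search events:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Number of distinct DNA positions probed
#'
#' Counts the distinct base pairs that were the protein's nearest bp during
#' any sliding or hopping frame.
#'
#' @param labels a `mode_labels` frame (must carry `nearest_bp`).
#' @return integer bp count.
#' @export
positions_probed <- function(labels) {
  stopifnot(is.data.frame(labels), "nearest_bp" %in% names(labels))
  length(unique(labels$nearest_bp[labels$label %in% c("S", "H")]))
}

#' Helical (cylindrical) coordinates of the searching protein
#'
#' Axial position `z`, unwrapped azimuth `theta` (degrees) and axis distance
#' `r` of the recognition-helix centre of mass about the DNA axis. The
#' azimuth is defined so that tracking the major groove towards +z
#' *decreases* theta; an ideal groove-following path therefore has slope
#' `dz/dtheta = -pitch/360` and a z-theta correlation of -1.
#'
#' @param x a `cg_trajectory`, or a path matrix (n x 3) of positions.
#' @param ... passed on to methods.
#' @return data frame of class `helix_coords`: `frame`, `time`, `z`,
#'   `theta`, `r`.
#' @export
helix_coordinates <- function(x, ...) UseMethod("helix_coordinates")

#' @rdname helix_coordinates
#' @param axis_xy for the matrix method: xy position of the helix axis.
#' @param times optional frame times.
#' @export
helix_coordinates.matrix <- function(x, axis_xy = c(0, 0), times = NULL, ...) {
  dx <- x[, 1] - axis_xy[1]; dy <- x[, 2] - axis_xy[2]
  if (any(dx^2 + dy^2 < 1e-12)) stop("degenerate axis: point on the axis")
  th <- -atan2(dy, dx) * 180 / pi
  structure(data.frame(frame = seq_len(nrow(x)),
                       time = if (is.null(times)) seq_len(nrow(x)) - 1 else times,
                       z = x[, 3], theta = .unwrap_deg(th),
                       r = sqrt(dx^2 + dy^2)),
            class = c("helix_coords", "data.frame"))
}

#' @rdname helix_coordinates
#' @export
helix_coordinates.cg_trajectory <- function(x, ...) {
  a <- x$assembly
  if (is.null(a$protein)) stop("assembly has no protein")
  rh <- a$index$protein[a$protein$recognition_helix]
  hcom <- t(.subset_com(x$frames, rh))
  axis_xy <- colMeans(t(.subset_com(x$frames, a$index$dna))[, 1:2, drop = FALSE])
  helix_coordinates(hcom, axis_xy = axis_xy, times = x$times)
}

.unwrap_deg <- function(th) {
  d <- diff(th)
  d <- d - 360 * ceiling(d / 360 - 0.5)
  c(th[1], th[1] + cumsum(d))
}

# contiguous 1D (S/H) segments as index ranges
.oned_segments <- function(labels, modes = c("S", "H")) {
  v <- .label_vec(labels)
  r <- rle(v %in% modes)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  keep <- r$values
  data.frame(start = start[keep], end = end[keep])
}

#' 1D diffusion coefficient along the DNA contour
#'
#' Mean-squared displacement of the axial coordinate over lag times pooled
#' within contiguous 1D (sliding/hopping) segments; `D_1` is half the
#' least-squares slope of MSD versus lag, in A^2 per MD step. Lags span
#' 10-50% of the shortest qualifying segment, additionally capped at 5-25
#' frames so that very long segments still yield well-averaged MSD points
#' (at lags comparable to the segment length only a handful of independent
#' displacement intervals exist and the slope estimate degrades). The fit
#' is flagged when the MSD is visibly nonlinear (R^2 < 0.98), e.g. for
#' ballistic motion.
#'
#' @param coords a `helix_coords` frame.
#' @param labels optional `mode_labels`; when omitted, the whole track is
#'   treated as one 1D segment.
#' @param min_seg minimal qualifying segment length in frames.
#' @return list of class `d1_fit`: `D1`, `slope`, `r_squared`, `flagged`,
#'   `n_segments`, `msd` (lag table).
#' @export
d1_coefficient <- function(coords, labels = NULL, min_seg = 10) {
  segs <- if (is.null(labels))
    data.frame(start = 1L, end = nrow(coords))
  else .oned_segments(labels)
  segs <- segs[segs$end - segs$start + 1 >= min_seg, , drop = FALSE]
  if (nrow(segs) == 0) {
    warning("no 1D segment of at least ", min_seg, " frames; D1 undefined")
    return(structure(list(D1 = NA_real_, slope = NA_real_,
                          r_squared = NA_real_, flagged = TRUE,
                          n_segments = 0L, msd = NULL), class = "d1_fit"))
  }
  shortest <- min(segs$end - segs$start + 1)
  lo <- max(1L, min(floor(0.1 * shortest), 5L))
  hi <- max(lo + 4L, min(floor(0.5 * shortest), 25L))
  lags <- lo:hi
  dtf <- if (nrow(coords) > 1) diff(coords$time)[1] else 1
  msd <- vapply(lags, function(L) {
    acc <- 0; cnt <- 0
    for (s in seq_len(nrow(segs))) {
      i <- segs$start[s]:segs$end[s]
      z <- coords$z[i]
      if (length(z) > L) {
        dz <- z[(1 + L):length(z)] - z[seq_len(length(z) - L)]
        acc <- acc + sum(dz^2); cnt <- cnt + length(dz)
      }
    }
    acc / cnt
  }, numeric(1))
  lag_steps <- lags * dtf
  fit <- lm(msd ~ lag_steps)
  r2 <- if (length(lags) > 2) summary(fit)$r.squared else 1
  structure(list(D1 = unname(coef(fit)[2]) / 2,
                 slope = unname(coef(fit)[2]),
                 r_squared = r2, flagged = r2 < 0.98,
                 n_segments = nrow(segs),
                 msd = data.frame(lag = lags, lag_steps = lag_steps,
                                  msd = msd)),
            class = "d1_fit")
}

#' @export
print.d1_fit <- function(x, ...) {
  cat("D1 =", signif(x$D1, 4), "A^2/step over", x$n_segments,
      "segment(s); R^2 =", signif(x$r_squared, 4),
      if (x$flagged) "(FLAGGED: poor linear fit)" else "", "\n")
  invisible(x)
}

#' Correlation of axial and rotational motion during sliding
#'
#' Pearson correlation of the (z, theta) pairs pooled over sliding segments,
#' each segment centred before pooling so that offsets between separate
#' sliding events do not contribute. Rotation-coupled groove tracking gives
#' R = -1; decoupled motion gives R near 0.
#'
#' @param coords a `helix_coords` frame (a `segment` column, if present,
#'   overrides label-derived segmentation).
#' @param labels optional `mode_labels`; only sliding (S) frames are used.
#' @param min_frames minimum number of pooled frames (default 10).
#' @return correlation coefficient with attribute `n` (frames used);
#'   `NA` (with a warning) when z or theta is constant.
#' @export
z_theta_correlation <- function(coords, labels = NULL, min_frames = 10) {
  if (!is.null(coords$segment)) {
    seg_id <- coords$segment
    use <- rep(TRUE, nrow(coords))
  } else if (!is.null(labels)) {
    v <- .label_vec(labels)
    use <- v == "S"
    r <- rle(use)
    seg_id <- rep(seq_along(r$lengths), r$lengths)
  } else {
    use <- rep(TRUE, nrow(coords))
    seg_id <- rep(1L, nrow(coords))
  }
  z <- coords$z[use]; th <- coords$theta[use]; sid <- seg_id[use]
  if (length(z) < min_frames)
    stop("fewer than ", min_frames, " sliding frames")
  zc <- z - stats::ave(z, sid); tc <- th - stats::ave(th, sid)
  if (sd(zc) == 0 || sd(tc) == 0) {
    warning("constant z or theta; correlation undefined")
    return(structure(NA_real_, n = length(z)))
  }
  structure(stats::cor(zc, tc), n = length(z))
}

#' Width of the crowder-DNA depletion layer
#'
#' For every frame and base pair, the distance from the bp centre (midpoint
#' of the paired base beads) to the surface of the nearest crowder, minus
#' the base-bead radius: a surface-to-surface convention. `l_d` is the
#' average over base pairs, frames and (by pooling) seeds.
#'
#' @param traj a `cg_trajectory` with crowders.
#' @param frames frame indices to use (default: all).
#' @return mean depletion width in Angstrom, with attributes `per_bp`
#'   (bp-resolved means) and `n_frames`; `NA` with a warning when the system
#'   has no crowders.
#' @export
depletion_width <- function(traj, frames = NULL) {
  a <- traj$assembly
  if (length(a$index$crowder) == 0) {
    warning("no crowders in the system; depletion width undefined")
    return(structure(NA_real_, per_bp = NULL, n_frames = 0L))
  }
  bp <- .base_pair_indices(a$dna)
  d <- cg_bp_crowder_dist_cpp(traj$frames, bp$i, bp$j,
                              as.integer(a$index$crowder), a$box$lengths)
  if (!is.null(frames)) d <- d[frames, , drop = FALSE]
  r_base <- a$params$bead_radius$B
  ld <- d - a$crowders$radius - r_base
  structure(mean(ld), per_bp = colMeans(ld), n_frames = nrow(ld))
}

#' Mean nearest-neighbour crowder-crowder surface gap
#'
#' Per frame, each crowder's centre distance to its nearest neighbour minus
#' one crowder diameter; averaged over crowders and frames.
#'
#' @param traj a `cg_trajectory` with at least two crowders.
#' @param frames frame indices to use (default: all).
#' @return mean surface-to-surface gap in Angstrom.
#' @export
crowder_gap <- function(traj, frames = NULL) {
  a <- traj$assembly
  if (length(a$index$crowder) < 2) stop("need at least two crowders")
  g <- cg_nn_gap_cpp(traj$frames, as.integer(a$index$crowder), a$box$lengths)
  if (!is.null(frames)) g <- g[frames]
  mean(g) - 2 * a$crowders$radius
}

#' Per-frame energy breakdown along a trajectory
#'
#' @param traj a `cg_trajectory`.
#' @param frames frame indices (default: all).
#' @return matrix (frames x components) of energies in kT units.
#' @export
frame_energies <- function(traj, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  a <- with_tables(traj$assembly)
  tab <- attr(a, "ff_tables")
  comp <- c("bonded", "native", "specific", "electrostatic",
            "excluded_volume", "ev_protein_crowder", "ev_protein_dna",
            "total")
  out <- matrix(NA_real_, length(frames), length(comp),
                dimnames = list(NULL, comp))
  for (k in seq_along(frames)) {
    e <- cg_energy_cpp(frame_coords(traj, frames[k]), tab)
    out[k, ] <- unlist(e[comp])
  }
  out
}

#' Summary of a nonspecific search trajectory
#'
#' Runs the full analysis chain: raw-label propensities, event table on
#' majority-smoothed labels, positions probed, 1D diffusion coefficient,
#' z-theta coupling, and (when crowders are present) the depletion width
#' and mean protein-crowder excluded-volume energy.
#'
#' @param traj a `cg_trajectory`.
#' @param d_bulk,r_slide,dtheta_groove classifier thresholds, see
#'   [classify_frames()].
#' @param energy_stride compute energies every this many frames.
#' @return list of class `search_summary`.
#' @export
analyze_search <- function(traj, d_bulk = 30, r_slide = 13,
                           dtheta_groove = 60, energy_stride = 5) {
  labels <- classify_frames(traj, d_bulk, r_slide, dtheta_groove)
  sm <- smooth_labels(labels)
  coords <- helix_coordinates(traj)
  prop <- mode_propensities(labels)
  ev <- segment_events(sm)
  d1 <- suppressWarnings(d1_coefficient(coords, sm))
  R <- tryCatch(suppressWarnings(z_theta_correlation(coords, sm)),
                error = function(e) NA_real_)
  has_cr <- length(traj$assembly$index$crowder) > 0
  ld <- if (has_cr) suppressWarnings(depletion_width(traj)) else NA_real_
  eev <- if (has_cr) {
    en <- frame_energies(traj, seq(1, n_frames(traj), by = energy_stride))
    mean(en[, "ev_protein_crowder"])
  } else 0
  structure(list(propensities = prop, events = ev,
                 positions_probed = positions_probed(labels),
                 D1 = d1, R = as.numeric(R),
                 l_d = as.numeric(ld), E_ev = eev,
                 labels = labels, thresholds = attr(labels, "thresholds")),
            class = "search_summary")
}

#' @export
print.search_summary <- function(x, ...) {
  cat("Search summary\n  propensities: S", signif(x$propensities["S"], 3),
      " H", signif(x$propensities["H"], 3),
      " D", signif(x$propensities["D"], 3), "\n")
  cat("  positions probed:", x$positions_probed, "bp\n")
  cat("  D1:", signif(x$D1$D1, 4), "A^2/step; R:", signif(x$R, 3), "\n")
  if (!is.na(x$l_d)) cat("  l_d:", signif(x$l_d, 4), "A; <E_ev(p-c)>:",
                         signif(x$E_ev, 4), "kT\n")
  invisible(x)
}
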