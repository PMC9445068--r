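## Intrapersonal kinematic and postural features.
##
## All per-agent operations take a frames x 15 x 3 trajectory array (mm) and
## return a list with the per-frame series and the per-agent scalar; the
## scene-level reducer averages scalars over the two agents. Unless stated
## otherwise, features use the 13 anatomical markers (sternum and sacrum
## excluded) and are in mm-based units; the bounding-box volume is reported
## in m^3.

anat_idx <- function(markers = marker_set()) match(markers$anatomical_13, markers$names)

marker_cols <- function(a, labels) a[, labels, , drop = FALSE]

#' Per-marker speed (velocity feature)
#'
#' Forward-difference Euclidean displacement of each anatomical marker
#' between consecutive frames, times the sampling rate.
#'
#' @param agent frames x 15 x 3 trajectory array (mm).
#' @param fps sampling rate, Hz.
#' @param markers a \code{\link{marker_set}}.
#' @return list(series = (frames-1) x 13 matrix of speeds in mm/s,
#'   scalar = mean over steps and markers).
#' @export
velocity <- function(agent, fps, markers = marker_set()) {
  if (!is_scalar_number(fps) || fps <= 0) stop_dyadkin("fps must be positive")
  nf <- dim(agent)[1]
  if (nf < 2) stop_dyadkin("velocity needs frames >= 2")
  a <- agent[, markers$anatomical_13, , drop = FALSE]
  d <- a[-1, , , drop = FALSE] - a[-nf, , , drop = FALSE]
  sp <- sqrt(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2) * fps
  sp <- matrix(sp, nrow = nf - 1)
  colnames(sp) <- markers$anatomical_13
  list(series = sp, scalar = mean(sp))
}

#' Per-marker acceleration (derivative of speed)
#'
#' Absolute forward difference of the speed series, times the sampling rate.
#'
#' @inheritParams velocity
#' @return list(series = (frames-2) x 13 matrix in mm/s^2, scalar = mean).
#' @export
acceleration <- function(agent, fps, markers = marker_set()) {
  if (dim(agent)[1] < 3) stop_dyadkin("acceleration needs frames >= 3")
  sp <- velocity(agent, fps, markers)$series
  ac <- abs(sp[-1, , drop = FALSE] - sp[-nrow(sp), , drop = FALSE]) * fps
  list(series = ac, scalar = mean(ac))
}

#' Vertical movement
#'
#' Cumulative absolute vertical (z) displacement of each anatomical marker
#' over the clip, averaged over the 13 markers.
#'
#' @inheritParams velocity
#' @return list(series = (frames-1) x 13 matrix of |dz| per step (mm),
#'   scalar = mean over markers of the per-marker path sums).
#' @export
vertical_movement <- function(agent, markers = marker_set()) {
  nf <- dim(agent)[1]
  if (nf < 2) stop_dyadkin("vertical_movement needs frames >= 2")
  z <- agent[, markers$anatomical_13, 3, drop = TRUE]
  z <- matrix(z, nrow = nf)
  dz <- abs(z[-1, , drop = FALSE] - z[-nf, , drop = FALSE])
  list(series = dz, scalar = mean(colSums(dz)))
}

#' Bounding-box volume and its variability
#'
#' Per frame, the product of the anatomical point cloud's extents along the
#' agent's own body axes, converted to m^3. The body frame uses the
#' horizontal left-right axis (average of the shoulder and hip lines), the
#' horizontal axis perpendicular to it, and the vertical, which makes the
#' volume invariant under rotation of the scene about the vertical axis;
#' frames with a degenerate left-right axis fall back to the world axes.
#'
#' @inheritParams velocity
#' @return list(series = per-frame volumes (m^3), scalar = time mean,
#'   scalar_sd = time SD).
#' @export
body_volume <- function(agent, markers = marker_set()) {
  nf <- dim(agent)[1]
  a <- agent[, markers$anatomical_13, , drop = FALSE]
  lr <- (agent[, "r_shoulder", ] - agent[, "l_shoulder", ] +
           agent[, "r_hip", ] - agent[, "l_hip", ]) / 2
  lr <- matrix(lr, nrow = nf)
  lr[, 3] <- 0
  nrm <- sqrt(rowSums(lr^2))
  bad <- nrm < 1e-6
  lr[bad, 1] <- 1; lr[bad, 2] <- 0
  nrm[bad] <- 1
  u1x <- lr[, 1] / nrm
  u1y <- lr[, 2] / nrm
  ax <- matrix(a[, , 1], nrow = nf)
  ay <- matrix(a[, , 2], nrow = nf)
  az <- matrix(a[, , 3], nrow = nf)
  p1 <- ax * u1x + ay * u1y          # left-right
  p2 <- ay * u1x - ax * u1y          # fore-aft (horizontal, perpendicular)
  ext <- function(m) apply(m, 1, max) - apply(m, 1, min)
  v <- ext(p1) * ext(p2) * ext(az) / 1e9
  list(series = v, scalar = mean(v), scalar_sd = stats::sd(v))
}

#' Left/right posture symmetry (asymmetry score)
#'
#' For each of the six left/right marker pairs and each frame, three
#' deviations from the body's sagittal midline plane (the vertical plane
#' through the hip-pair and shoulder-pair midpoints, normal to the
#' left-right axis): the height difference |z_L - z_R|, the difference of
#' the two perpendicular distances to the plane, and the angular offset of
#' the pair's chord from the plane normal expressed as an arc length at half
#' the chord. All three are in mm; 0 means perfect mirror symmetry.
#'
#' @inheritParams velocity
#' @param weights length-3 aggregation weights for (height, distance, arc);
#'   default equal.
#' @return list(components = frames x 3 matrix of pair-averaged components,
#'   scalar = weighted mean over components and frames).
#' @export
symmetry <- function(agent, markers = marker_set(), weights = rep(1, 3)) {
  stopifnot(length(weights) == 3, all(weights >= 0), sum(weights) > 0)
  nf <- dim(agent)[1]
  pairs <- markers$pairs
  mid_sh <- (agent[, "l_shoulder", ] + agent[, "r_shoulder", ]) / 2
  mid_hip <- (agent[, "l_hip", ] + agent[, "r_hip", ]) / 2
  centre <- (mid_sh + mid_hip) / 2
  centre <- matrix(centre, nrow = nf)
  ## left-right axis (horizontal projection) = plane normal
  lr <- (agent[, "r_shoulder", ] - agent[, "l_shoulder", ] +
           agent[, "r_hip", ] - agent[, "l_hip", ]) / 2
  lr <- matrix(lr, nrow = nf)
  lr[, 3] <- 0
  nrm <- sqrt(rowSums(lr^2))
  if (any(nrm < 1e-6))
    stop_dyadkin("collapsed midline: left-right axis degenerate at frame %d",
                 which(nrm < 1e-6)[1])
  lr <- lr / nrm
  comp <- matrix(0, nf, 3,
                 dimnames = list(NULL, c("height", "distance", "arc")))
  for (p in seq_len(nrow(pairs))) {
    pl <- matrix(agent[, pairs[p, "left"], ], nrow = nf)
    pr <- matrix(agent[, pairs[p, "right"], ], nrow = nf)
    dz <- abs(pl[, 3] - pr[, 3])
    dl <- abs(rowSums((pl - centre) * lr))
    dr <- abs(rowSums((pr - centre) * lr))
    chord <- pr - pl
    clen <- sqrt(rowSums(chord^2))
    cosang <- ifelse(clen < 1e-9, 1,
                     pmin(1, abs(rowSums(chord * lr)) / pmax(clen, 1e-9)))
    ang <- acos(cosang)
    comp[, 1] <- comp[, 1] + dz
    comp[, 2] <- comp[, 2] + abs(dl - dr)
    comp[, 3] <- comp[, 3] + ang * clen / 2
  }
  comp <- comp / nrow(pairs)
  w <- weights / sum(weights)
  list(components = comp, scalar = sum(colMeans(comp) * w))
}

#' Mean limb joint angle
#'
#' Interior angles at the 8 limb joints (left/right shoulder, elbow, hip,
#' knee), in degrees, averaged over joints and frames.
#'
#' @inheritParams velocity
#' @return list(series = frames x 8 matrix (degrees), scalar = mean).
#' @export
limb_angles <- function(agent, markers = marker_set()) {
  nf <- dim(agent)[1]
  joints <- list(
    shoulder = c("shoulder", "elbow", "hip"),
    elbow = c("elbow", "shoulder", "wrist"),
    hip = c("hip", "shoulder", "knee"),
    knee = c("knee", "hip", "ankle"))
  out <- matrix(0, nf, 8)
  cn <- character(8)
  j <- 0L
  for (side in c("l", "r")) for (jn in names(joints)) {
    j <- j + 1L
    at <- paste0(side, "_", joints[[jn]][1])
    to1 <- paste0(side, "_", joints[[jn]][2])
    to2 <- paste0(side, "_", joints[[jn]][3])
    v1 <- matrix(agent[, to1, ] - agent[, at, ], nrow = nf)
    v2 <- matrix(agent[, to2, ] - agent[, at, ], nrow = nf)
    n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
    bad <- which(n1 < 1e-9 | n2 < 1e-9)
    if (length(bad))
      stop_dyadkin("zero-length segment at joint '%s_%s', frame %d",
                   side, jn, bad[1])
    cosang <- clip(rowSums(v1 * v2) / (n1 * n2), -1, 1)
    out[, j] <- acos(cosang) * 180 / pi
    cn[j] <- paste0(side, "_", jn)
  }
  colnames(out) <- cn
  list(series = out, scalar = mean(out))
}

#' Limb contraction
#'
#' Mean Euclidean distance from the head to the two wrists and two ankles;
#' larger values = more extended posture.
#'
#' @inheritParams velocity
#' @return list(series = per-frame means (mm), scalar = time mean).
#' @export
limb_contraction <- function(agent, markers = marker_set()) {
  nf <- dim(agent)[1]
  head <- matrix(agent[, "head", ], nrow = nf)
  d <- sapply(c("l_wrist", "r_wrist", "l_ankle", "r_ankle"), function(m) {
    v <- matrix(agent[, m, ], nrow = nf) - head
    sqrt(rowSums(v^2))
  })
  d <- matrix(d, nrow = nf)
  series <- rowMeans(d)
  list(series = series, scalar = mean(series))
}

#' Reduce a scene to its 8 intrapersonal scalars
#'
#' Applies the six intrapersonal operations to both agents and averages the
#' scalars over agents (the volume SD averages the per-agent SDs).
#'
#' @param sc a \code{\link{scene}}.
#' @param sm_weights passed to \code{\link{symmetry}}.
#' @return Named numeric: VEL, ACC, VM, VOL, VOL_STD, SM, LA, LC.
#' @export
reduce_intrapersonal <- function(sc, sm_weights = rep(1, 3)) {
  validate_scene(sc)
  ms <- sc$markers
  per_agent <- vapply(sc$agents, function(a) {
    vol <- body_volume(a, ms)
    c(VEL = velocity(a, sc$fps, ms)$scalar,
      ACC = acceleration(a, sc$fps, ms)$scalar,
      VM = vertical_movement(a, ms)$scalar,
      VOL = vol$scalar, VOL_STD = vol$scalar_sd,
      SM = symmetry(a, ms, sm_weights)$scalar,
      LA = limb_angles(a, ms)$scalar,
      LC = limb_contraction(a, ms)$scalar)
  }, numeric(8))
  rowMeans(per_agent)
}

#' Collection-level rescaling of symmetry components
#'
#' Alternative aggregation of the symmetry composite: z-scores each of the
#' three per-scene component means across a scene collection before
#' averaging them, removing the unit mismatch by standardisation instead of
#' the default arc-length construction.
#'
#' @param component_means n_scenes x 3 matrix of per-scene component means.
#' @param weights length-3 nonnegative weights.
#' @return Numeric vector of per-scene standardised symmetry scores.
#' @export
scale_symmetry_components <- function(component_means, weights = rep(1, 3)) {
  stopifnot(is.matrix(component_means), ncol(component_means) == 3)
  z <- scale(component_means)
  z[is.nan(z)] <- 0
  w <- weights / sum(weights)
  as.numeric(z %*% w)
}
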