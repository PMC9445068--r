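## Interpersonal features of the dyad.
##
## Centroids are the mean of each agent's 13 anatomical markers. Distance
## correlations and synchronisation are zero-lag Pearson correlations on
## per-frame profiles; profiles produced by differencing are aligned by
## truncating the distance profile to the differenced length.

# Per-frame centroid of agent i (frames x 3).
agent_centroid <- function(sc, i) {
  a <- anat_coords(sc, i)
  nf <- dim(a)[1]
  cbind(rowMeans(matrix(a[, , 1], nf)), rowMeans(matrix(a[, , 2], nf)),
        rowMeans(matrix(a[, , 3], nf)))
}

#' Interpersonal distance
#'
#' @param sc a \code{\link{scene}}.
#' @return list(IPD = time mean (mm), IPD_STD = time SD, ipd_t = per-frame
#'   centroid distances).
#' @export
interpersonal_distance <- function(sc) {
  validate_scene(sc)
  d <- agent_centroid(sc, 1) - agent_centroid(sc, 2)
  ipd_t <- sqrt(rowSums(d^2))
  list(IPD = mean(ipd_t), IPD_STD = stats::sd(ipd_t), ipd_t = ipd_t)
}

# Mean arm length (shoulder->elbow + elbow->wrist) over arms, agents, time.
mean_arm_length <- function(sc) {
  seg <- function(a, from, to) {
    v <- matrix(a[, to, ] - a[, from, ], nrow = dim(a)[1])
    sqrt(rowSums(v^2))
  }
  arms <- vapply(sc$agents, function(a) {
    mean(seg(a, "l_shoulder", "l_elbow") + seg(a, "l_elbow", "l_wrist")) / 2 +
      mean(seg(a, "r_shoulder", "r_elbow") + seg(a, "r_elbow", "r_wrist")) / 2
  }, numeric(1))
  mean(arms)
}

#' Personal space occupancy
#'
#' Percentage of frames in which the centroid separation is below one arm
#' length. The arm length is estimated from the scene itself (time-mean
#' shoulder-elbow plus elbow-wrist segment lengths, averaged over arms and
#' agents); \code{min_marker} switches the separation measure to the minimum
#' inter-agent marker distance instead of centroids.
#'
#' @param sc a \code{\link{scene}}.
#' @param arm_length override the estimated arm length (mm).
#' @param min_marker use minimum pairwise marker distance instead of
#'   centroid distance (default FALSE).
#' @return PS, a percentage in [0, 100].
#' @export
personal_space <- function(sc, arm_length = NULL, min_marker = FALSE) {
  validate_scene(sc)
  arm <- arm_length %||% mean_arm_length(sc)
  if (min_marker) {
    a1 <- anat_coords(sc, 1); a2 <- anat_coords(sc, 2)
    nf <- dim(a1)[1]
    dmin <- rep(Inf, nf)
    for (m in seq_len(dim(a1)[2])) for (k in seq_len(dim(a2)[2])) {
      v <- matrix(a1[, m, ] - a2[, k, ], nrow = nf)
      dmin <- pmin(dmin, sqrt(rowSums(v^2)))
    }
    sep <- dmin
  } else {
    sep <- interpersonal_distance(sc)$ipd_t
  }
  100 * mean(sep < arm)
}

#' Interpersonal orientation
#'
#' An agent faces its partner when the horizontal outward normal of its
#' shoulder line (front disambiguated by the horizontal head offset) lies
#' within \code{cone_half_angle} of the horizontal direction to the
#' partner's centroid. IPO is the mean of the two agents' facing-time
#' percentages (equivalently: mutual facing plus half of each one-sided
#' facing share); \code{mode = "mutual"} restricts it to frames where both
#' face. IPO_BAL = 1 - |t1 - t2| / (t1 + t2), 0 when neither agent ever
#' faces.
#'
#' @param sc a \code{\link{scene}}.
#' @param cone_half_angle facing cone half-angle, degrees (default 45).
#' @param mode \code{"mean"} (default) or \code{"mutual"}.
#' @return list(IPO (percent), IPO_BAL in [0,1], facing_1, facing_2
#'   per-frame logicals).
#' @export
orientation <- function(sc, cone_half_angle = 45, mode = c("mean", "mutual")) {
  validate_scene(sc)
  mode <- match.arg(mode)
  nf <- n_frames(sc)
  cents <- list(agent_centroid(sc, 1), agent_centroid(sc, 2))
  facing <- function(i) {
    a <- sc$agents[[i]]
    sh_l <- matrix(a[, "l_shoulder", ], nrow = nf)
    sh_r <- matrix(a[, "r_shoulder", ], nrow = nf)
    line <- sh_r - sh_l
    line[, 3] <- 0
    ln <- sqrt(rowSums(line^2))
    if (any(ln < 1e-6))
      stop_dyadkin("coincident shoulder markers (agent %d, frame %d)",
                   i, which(ln < 1e-6)[1])
    line <- line / ln
    ## two horizontal normals of the shoulder line; pick the frontal one by
    ## the horizontal head offset from the shoulder midpoint
    n1 <- cbind(-line[, 2], line[, 1], 0)
    mid <- (sh_l + sh_r) / 2
    headv <- matrix(a[, "head", ], nrow = nf) - mid
    headv[, 3] <- 0
    sgn <- sign(rowSums(n1 * headv))
    sgn[sgn == 0] <- 1
    fwd <- n1 * sgn
    to_partner <- cents[[if (i == 1) 2 else 1]] - cents[[i]]
    to_partner[, 3] <- 0
    tn <- sqrt(rowSums(to_partner^2))
    tn[tn < 1e-9] <- 1
    cosang <- clip(rowSums(fwd * to_partner) / tn, -1, 1)
    acos(cosang) * 180 / pi < cone_half_angle
  }
  f1 <- facing(1); f2 <- facing(2)
  t1 <- sum(f1); t2 <- sum(f2)
  ipo <- if (mode == "mutual") 100 * mean(f1 & f2) else 50 * (t1 + t2) / nf
  bal <- if (t1 + t2 == 0) 0 else 1 - abs(t1 - t2) / (t1 + t2)
  list(IPO = ipo, IPO_BAL = bal, facing_1 = f1, facing_2 = f2)
}

## ---- per-frame dyad profiles -------------------------------------------

# Agent-averaged per-frame profiles used by the distance correlations and
# synchronisation: VEL/ACC (differenced), VOL, LC (full length).
dyad_profiles <- function(sc) {
  ms <- sc$markers
  vel <- lapply(sc$agents, function(a) rowMeans(velocity(a, sc$fps, ms)$series))
  acc <- lapply(vel, function(v) abs(diff(v)) * sc$fps)
  vol <- lapply(sc$agents, function(a) body_volume(a, ms)$series)
  lc <- lapply(sc$agents, function(a) limb_contraction(a, ms)$series)
  list(speed_1 = vel[[1]], speed_2 = vel[[2]],
       acc_1 = acc[[1]], acc_2 = acc[[2]],
       VEL = (vel[[1]] + vel[[2]]) / 2, ACC = (acc[[1]] + acc[[2]]) / 2,
       VOL = (vol[[1]] + vol[[2]]) / 2, LC = (lc[[1]] + lc[[2]]) / 2,
       ipd_t = interpersonal_distance(sc)$ipd_t)
}

# Pearson correlation with NA-on-degenerate handling.
safe_cor <- function(x, y, what) {
  if (length(x) != length(y)) stop_dyadkin("profile length mismatch")
  if (length(x) < 3) stop_dyadkin("need >= 3 aligned frames for %s", what)
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    warning(sprintf("%s undefined: zero-variance profile", what), call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Distance correlation features
#'
#' Pearson correlation between the per-frame interpersonal distance and an
#' agent-averaged intrapersonal profile; differenced profiles are aligned by
#' truncating the distance profile.
#'
#' @param sc a \code{\link{scene}}.
#' @param profile one of \code{"VEL"}, \code{"ACC"}, \code{"VOL"},
#'   \code{"LC"}.
#' @param profiles optional precomputed \code{dyad_profiles} result.
#' @return Pearson r (NA with a warning when degenerate).
#' @export
distance_correlation <- function(sc, profile = c("VEL", "ACC", "VOL", "LC"),
                                 profiles = NULL) {
  profile <- match.arg(profile)
  pr <- profiles %||% dyad_profiles(sc)
  y <- pr[[profile]]
  x <- pr$ipd_t[seq_along(y)]
  safe_cor(x, y, paste0("DC_", profile))
}

#' Velocity / acceleration synchronisation
#'
#' Zero-lag Pearson correlation between the two agents' per-frame speed
#' (or speed-derivative) profiles.
#'
#' @param sc a \code{\link{scene}}.
#' @param profile \code{"VEL"} or \code{"ACC"}.
#' @param profiles optional precomputed \code{dyad_profiles} result.
#' @return Pearson r (NA with a warning when a profile is constant).
#' @export
synchronization <- function(sc, profile = c("VEL", "ACC"), profiles = NULL) {
  profile <- match.arg(profile)
  pr <- profiles %||% dyad_profiles(sc)
  if (profile == "VEL") safe_cor(pr$speed_1, pr$speed_2, "SYNC_VEL")
  else safe_cor(pr$acc_1, pr$acc_2, "SYNC_ACC")
}

#' Motion-energy balance
#'
#' E_i is agent i's summed mean-marker inter-frame displacement;
#' ME_BAL = 1 - |E1 - E2| / (E1 + E2), so 1 means both agents move equally
#' much and 0 means one agent is static.
#'
#' @param sc a \code{\link{scene}}.
#' @return ME_BAL in [0, 1].
#' @export
motion_energy_balance <- function(sc) {
  validate_scene(sc)
  ms <- sc$markers
  e <- vapply(sc$agents, function(a) {
    sum(rowMeans(velocity(a, sc$fps, ms)$series)) / sc$fps
  }, numeric(1))
  if (sum(e) == 0) return(0)
  1 - abs(e[1] - e[2]) / sum(e)
}

#' Reduce a scene to its 12 interpersonal scalars
#'
#' @param sc a \code{\link{scene}}.
#' @param cone_half_angle facing cone half-angle, degrees.
#' @return Named numeric: IPD, IPD_STD, PS, IPO, IPO_BAL, DC_VEL, DC_ACC,
#'   DC_VOL, DC_LC, SYNC_VEL, SYNC_ACC, ME_BAL. Degenerate correlations are
#'   NA (with warnings).
#' @export
reduce_interpersonal <- function(sc, cone_half_angle = 45) {
  validate_scene(sc)
  ipd <- interpersonal_distance(sc)
  ori <- orientation(sc, cone_half_angle)
  pr <- dyad_profiles(sc)
  c(IPD = ipd$IPD, IPD_STD = ipd$IPD_STD,
    PS = personal_space(sc),
    IPO = ori$IPO, IPO_BAL = ori$IPO_BAL,
    DC_VEL = distance_correlation(sc, "VEL", profiles = pr),
    DC_ACC = distance_correlation(sc, "ACC", profiles = pr),
    DC_VOL = distance_correlation(sc, "VOL", profiles = pr),
    DC_LC = distance_correlation(sc, "LC", profiles = pr),
    SYNC_VEL = synchronization(sc, "VEL", profiles = pr),
    SYNC_ACC = synchronization(sc, "ACC", profiles = pr),
    ME_BAL = motion_energy_balance(sc))
}
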