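## Synthetic dyadic scenes and simulated raters.
##
## Each agent is a fixed 15-marker template posed between a contracted and an
## extended posture, animated by (i) a root path implementing the programmed
## centroid-separation schedule plus vertical bounce, (ii) a yaw schedule
## holding the facing-time target, and (iii) smooth envelope-modulated
## per-marker noise whose overall amplitude is solved by bisection so that
## the realised mean marker speed equals the programmed target exactly.
## Agent 2's speed target is energy_ratio times agent 1's, which pins the
## motion-energy balance, and the two speed envelopes are linear mixtures of
## smooth latents with mixing weight sync_level, which pins the velocity
## synchronisation.

#' Archetype parameters for one emotion's motion style
#'
#' @param speed_scale target mean marker speed, mm/s.
#' @param bounce_amp amplitude of the whole-body vertical oscillation, mm.
#' @param start_ipd,end_ipd centroid-separation schedule endpoints, mm.
#' @param facing_frac mean fraction of time the agents are oriented toward
#'   each other, in [0, 1].
#' @param facing_balance ratio of agent 2's to agent 1's facing time,
#'   in (0, 1]; together with \code{facing_frac} it fixes the
#'   orientation-balance feature (1 = both agents face equally long).
#' @param energy_ratio agent-2 / agent-1 motion-energy ratio, in (0, 1].
#' @param posture_openness limb-extension scalar in [0, 1] (0 = crouched,
#'   1 = fully extended template).
#' @param sync_level target correlation of the two agents' speed envelopes,
#'   in [-1, 1].
#' @return An object of class \code{archetype_params}.
#' @export
archetype_params <- function(speed_scale, bounce_amp, start_ipd, end_ipd,
                             facing_frac, facing_balance = 1,
                             energy_ratio = 1, posture_openness = 0.7,
                             sync_level = 0.3) {
  p <- list(speed_scale = speed_scale, bounce_amp = bounce_amp,
            start_ipd = start_ipd, end_ipd = end_ipd,
            facing_frac = facing_frac, facing_balance = facing_balance,
            energy_ratio = energy_ratio, posture_openness = posture_openness,
            sync_level = sync_level)
  stopifnot(speed_scale > 0, bounce_amp >= 0, start_ipd > 0, end_ipd > 0,
            facing_frac >= 0, facing_frac <= 1,
            facing_balance > 0, facing_balance <= 1,
            energy_ratio > 0, energy_ratio <= 1,
            posture_openness >= 0, posture_openness <= 1,
            sync_level >= -1, sync_level <= 1)
  structure(p, class = "archetype_params")
}

#' Default per-emotion archetype table
#'
#' Calibrated once against the feature extractor so that the programmed
#' contrasts (fast, bouncy happiness; close, mutually oriented affection;
#' slow sadness; distant, unbalanced anger) reproduce the qualitative
#' ANOVA orderings of the features across emotions.
#'
#' @return Named list of \code{\link{archetype_params}}, one per emotion.
#' @export
default_archetypes <- function() {
  list(
    happiness = archetype_params(374, 40, 1200, 850, 0.40,
                                 facing_balance = 0.38, energy_ratio = 0.87,
                                 posture_openness = 0.80, sync_level = 0.45),
    affection = archetype_params(205, 12, 560, 400, 0.80,
                                 facing_balance = 0.74, energy_ratio = 0.82,
                                 posture_openness = 0.55, sync_level = 0.55),
    sadness   = archetype_params(124, 8, 950, 880, 0.32,
                                 facing_balance = 0.09, energy_ratio = 0.64,
                                 posture_openness = 0.35, sync_level = 0.15),
    anger     = archetype_params(335, 25, 1250, 1130, 0.25,
                                 facing_balance = 0.18, energy_ratio = 0.61,
                                 posture_openness = 0.70, sync_level = 0.05)
  )
}

## ---- template skeleton -------------------------------------------------

# Extended and contracted 15-marker poses (mm), facing +x, left side +y.
# Segment lengths are generic adult anthropometry; nothing downstream
# depends on their exact values.
template_pose <- function(openness = 0.7, markers = marker_set()) {
  open <- rbind(
    head = c(80, 0, 1680), sternum = c(60, 0, 1430), sacrum = c(0, 0, 1010),
    l_shoulder = c(0, 190, 1450), r_shoulder = c(0, -190, 1450),
    l_elbow = c(30, 250, 1160), r_elbow = c(30, -250, 1160),
    l_wrist = c(60, 280, 900), r_wrist = c(60, -280, 900),
    l_hip = c(0, 95, 980), r_hip = c(0, -95, 980),
    l_knee = c(20, 105, 500), r_knee = c(20, -105, 500),
    l_ankle = c(0, 110, 80), r_ankle = c(0, -110, 80))
  closed <- rbind(
    head = c(60, 0, 1380), sternum = c(40, 0, 1200), sacrum = c(0, 0, 840),
    l_shoulder = c(0, 165, 1220), r_shoulder = c(0, -165, 1220),
    l_elbow = c(100, 190, 1010), r_elbow = c(100, -190, 1010),
    l_wrist = c(160, 120, 1120), r_wrist = c(160, -120, 1120),
    l_hip = c(0, 90, 820), r_hip = c(0, -90, 820),
    l_knee = c(120, 100, 450), r_knee = c(120, -100, 450),
    l_ankle = c(0, 105, 70), r_ankle = c(0, -105, 70))
  pose <- closed + openness * (open - closed)
  pose[markers$names, , drop = FALSE]
}

## ---- single-scene generator --------------------------------------------

#' Generate one synthetic dyadic scene
#'
#' Deterministic given \code{seed}. The realised mean marker speed of agent 1
#' over the 13 anatomical markers equals \code{params$speed_scale} (agent 2:
#' \code{energy_ratio} times that) up to bisection tolerance.
#'
#' @param emotion emotion label; with \code{params = NULL} it selects the
#'   matching \code{\link{default_archetypes}} entry. An emotion outside the
#'   default table requires explicit \code{params}.
#' @param params an \code{\link{archetype_params}} or NULL.
#' @param seed integer RNG seed.
#' @param frames,fps scene geometry (defaults 400 frames at 100 Hz = 4 s).
#' @param scene_id identifier; defaults to \code{"<emotion>_s<seed>"}.
#' @return A \code{\link{scene}}.
#' @export
generate_scene <- function(emotion, params = NULL, seed = 1L,
                           frames = 400L, fps = 100,
                           scene_id = NULL) {
  if (is.null(params)) {
    arch <- default_archetypes()
    if (!emotion %in% names(arch))
      stop_dyadkin("unknown emotion '%s' and no explicit params given", emotion)
    params <- arch[[emotion]]
  }
  stopifnot(inherits(params, "archetype_params"), frames >= 2)
  ms <- marker_set()
  with_seed(seed, {
    nf <- as.integer(frames)
    tt <- seq_len(nf)
    dt <- 1 / fps

    ## centroid-separation schedule with a little smooth wobble
    ipd <- params$start_ipd +
      (params$end_ipd - params$start_ipd) * (tt - 1) / (nf - 1) +
      15 * smooth_noise(nf, smooth = 30)
    ipd <- pmax(ipd, 60)

    ## root paths: agents approach along x, slight lateral wander, bounce in z
    bounce_f <- 1.1
    root <- lapply(1:2, function(i) {
      sgn <- if (i == 1) -1 else 1
      phase <- stats::runif(1, 0, 2 * pi)
      amp <- params$bounce_amp * (if (i == 1) 1 else params$energy_ratio)
      cbind(x = sgn * ipd / 2,
            y = 20 * smooth_noise(nf, smooth = 40),
            z = amp * sin(2 * pi * bounce_f * (tt - 1) * dt + phase))
    })

    ## yaw schedules holding the facing-time targets
    t1 <- clip(2 * params$facing_frac / (1 + params$facing_balance), 0, 1)
    t2 <- clip(t1 * params$facing_balance, 0, 1)
    gate <- function(frac) {
      ## 1 = averted; facing during a contiguous (wrapped) window of `frac`
      n_face <- round(frac * nf)
      g <- rep(1, nf)
      if (n_face > 0) {
        start <- sample.int(nf, 1)
        idx <- ((start - 1 + seq_len(n_face) - 1) %% nf) + 1
        g[idx] <- 0
      }
      ## smooth the transition so the yaw ramp is physical
      as.numeric(stats::filter(c(rep(g[1], 40), g, rep(g[nf], 40)),
                               rep(1 / 41, 41), sides = 2)[41:(40 + nf)])
    }
    base1 <- atan2(root[[2]][, "y"] - root[[1]][, "y"],
                   root[[2]][, "x"] - root[[1]][, "x"])
    base2 <- atan2(root[[1]][, "y"] - root[[2]][, "y"],
                   root[[1]][, "x"] - root[[2]][, "x"])
    avert <- stats::runif(2, 60, 100) * sample(c(-1, 1), 2, replace = TRUE) *
      pi / 180
    theta <- list(base1 + gate(t1) * avert[1] +
                    (4 * pi / 180) * smooth_noise(nf, 25),
                  base2 + gate(t2) * avert[2] +
                    (4 * pi / 180) * smooth_noise(nf, 25))

    ## synchrony: speed envelopes from linearly mixed smooth latents
    rho <- params$sync_level
    lat1 <- smooth_noise(nf - 1, smooth = 18)
    raw2 <- smooth_noise(nf - 1, smooth = 18)
    ## residualise against lat1 so the sample correlation of the latents is
    ## exactly sync_level (the envelopes only deviate via rare clipping)
    resid <- raw2 - lat1 * sum(raw2 * lat1) / sum(lat1^2)
    if (stats::sd(resid) > 1e-12)
      resid <- (resid - mean(resid)) / stats::sd(resid)
    lat2 <- rho * lat1 + sqrt(max(0, 1 - rho^2)) * resid
    env <- list(pmax(0.15, 1 + 0.35 * lat1), pmax(0.15, 1 + 0.35 * lat2))

    ## per-marker unit direction fields and amplitude weights
    amp_w <- c(head = 0.6, sternum = 0.4, sacrum = 0.4,
               l_shoulder = 0.6, r_shoulder = 0.6,
               l_elbow = 1.0, r_elbow = 1.0, l_wrist = 1.3, r_wrist = 1.3,
               l_hip = 0.4, r_hip = 0.4, l_knee = 1.0, r_knee = 1.0,
               l_ankle = 1.3, r_ankle = 1.3)[ms$names]
    z_w <- 0.35
    local_field <- function(e) {
      ## returns frames x 15 x 3 cumulative local offsets with per-step
      ## magnitude e(t) * amp_w[m] (before the global scale factor)
      out <- array(0, c(nf, 15L, 3L))
      for (m in 1:15) {
        d <- cbind(smooth_noise(nf - 1, 10), smooth_noise(nf - 1, 10),
                   z_w * smooth_noise(nf - 1, 10))
        len <- sqrt(rowSums(d^2))
        len[len < 1e-12] <- 1
        d <- d / len * (e * amp_w[m])
        out[, m, ] <- rbind(c(0, 0, 0), apply(d, 2, cumsum))
      }
      out
    }
    locals <- list(local_field(env[[1]]), local_field(env[[2]]))

    pose <- template_pose(params$posture_openness, ms)
    anat <- match(ms$anatomical_13, ms$names)

    compose <- function(i, cc) {
      co <- cos(theta[[i]]); si <- sin(theta[[i]])
      px <- matrix(pose[, 1], nf, 15, byrow = TRUE) + cc * locals[[i]][, , 1]
      py <- matrix(pose[, 2], nf, 15, byrow = TRUE) + cc * locals[[i]][, , 2]
      pz <- matrix(pose[, 3], nf, 15, byrow = TRUE) + cc * locals[[i]][, , 3]
      a <- array(0, c(nf, 15L, 3L),
                 dimnames = list(NULL, ms$names, c("x", "y", "z")))
      a[, , 1] <- co * px - si * py + root[[i]][, "x"]
      a[, , 2] <- si * px + co * py + root[[i]][, "y"]
      a[, , 3] <- pz + root[[i]][, "z"]
      a
    }
    mean_speed <- function(a) {
      d <- a[-1, anat, , drop = FALSE] - a[-nf, anat, , drop = FALSE]
      mean(sqrt(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)) * fps
    }
    calibrate <- function(i, target) {
      f <- function(cc) mean_speed(compose(i, cc)) - target
      if (f(0) >= 0) return(0)
      hi <- 1
      while (f(hi) < 0 && hi < 64) hi <- hi * 2
      lo <- 0
      for (k in 1:45) {
        mid <- (lo + hi) / 2
        if (f(mid) < 0) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
    ## a small deformation floor keeps posture profiles non-degenerate even
    ## when root motion alone already exceeds the speed target
    c_floor <- 0.05
    c1 <- max(c_floor, calibrate(1, params$speed_scale))
    c2 <- max(c_floor, calibrate(2, params$energy_ratio * params$speed_scale))

    scene(compose(1, c1), compose(2, c2), fps = fps, emotion = emotion,
          scene_id = scene_id %||% sprintf("%s_s%d", emotion, as.integer(seed)),
          markers = ms)
  })
}

## ---- dataset generator -------------------------------------------------

#' Generate a labelled dataset of synthetic scenes
#'
#' Per-scene parameters are jittered around each emotion's archetype
#' (relative Gaussian jitter, SD \code{jitter_sd}, bounded parameters
#' clipped to their valid ranges) and every scene receives a child seed
#' derived deterministically from \code{seed}.
#'
#' @param archetypes named list of \code{\link{archetype_params}} (default
#'   \code{\link{default_archetypes}}).
#' @param n_scenes_per_emotion scenes per emotion (default 12, i.e. 48 total).
#' @param seed master RNG seed.
#' @param jitter_sd relative jitter SD (default 0.08).
#' @param frames,fps passed to \code{\link{generate_scene}}.
#' @return List of \code{\link{scene}} objects, grouped by emotion.
#' @export
generate_dataset <- function(archetypes = default_archetypes(),
                             n_scenes_per_emotion = 12L, seed = 1L,
                             jitter_sd = 0.08, frames = 400L, fps = 100) {
  stopifnot(n_scenes_per_emotion >= 1)
  emotions <- names(archetypes)
  n_total <- length(emotions) * n_scenes_per_emotion
  child <- derive_seeds(seed, n_total)
  jit <- with_seed(seed + 1L,
                   matrix(stats::rnorm(n_total * 8), n_total, 8))
  scenes <- vector("list", n_total)
  k <- 0L
  for (e in emotions) for (j in seq_len(n_scenes_per_emotion)) {
    k <- k + 1L
    p <- archetypes[[e]]
    g <- jit[k, ]
    pj <- archetype_params(
      speed_scale = p$speed_scale * exp(jitter_sd * g[1]),
      bounce_amp = p$bounce_amp * exp(jitter_sd * g[2]),
      start_ipd = p$start_ipd * exp(jitter_sd * g[3]),
      end_ipd = p$end_ipd * exp(jitter_sd * g[4]),
      facing_frac = clip(p$facing_frac + 0.06 * g[5], 0.02, 0.97),
      facing_balance = clip(p$facing_balance * exp(1.5 * jitter_sd * g[6]),
                            0.02, 1),
      energy_ratio = clip(p$energy_ratio + 0.05 * g[7], 0.05, 1),
      posture_openness = clip(p$posture_openness + 0.05 * g[8], 0.05, 1),
      sync_level = p$sync_level)
    scenes[[k]] <- generate_scene(e, pj, seed = child[k], frames = frames,
                                  fps = fps,
                                  scene_id = sprintf("%s_%02d", e, j))
  }
  scenes
}

## ---- simulated raters --------------------------------------------------

#' Simulated-rater model
#'
#' Stands in for a human rating cohort: each rater draws an emotion response
#' from the confusion row of the scene's true label and a valence rating
#' from a Gaussian around the label's mean valence, rounded and clipped to
#' the integer scale -5..+5.
#'
#' @param n_raters cohort size (default 31).
#' @param confusion 4x4 row-stochastic matrix, rows/cols in emotion order
#'   happiness, affection, sadness, anger. The default encodes the typical
#'   confusion structure of dyadic emotion ratings: affection is most often
#'   confused with happiness, anger least often with happiness, and
#'   per-emotion recognition orders anger >= happiness >= sadness >=
#'   affection.
#' @param valence_mean named per-emotion mean valence on the -5..+5 scale.
#' @param valence_sd rating noise SD (default 1.2).
#' @param seed RNG seed.
#' @return Object of class \code{rater_model}.
#' @export
rater_model <- function(n_raters = 31L, confusion = NULL,
                        valence_mean = c(happiness = 3.5, affection = 3.0,
                                         sadness = -2.5, anger = -3.5),
                        valence_sd = 1.2, seed = 1L) {
  if (is.null(confusion)) {
    confusion <- rbind(
      happiness = c(0.906, 0.055, 0.014, 0.025),
      affection = c(0.130, 0.804, 0.050, 0.016),
      sadness   = c(0.020, 0.060, 0.876, 0.044),
      anger     = c(0.008, 0.020, 0.053, 0.919))
    colnames(confusion) <- EMOTIONS
  }
  stopifnot(is.matrix(confusion), nrow(confusion) == 4, ncol(confusion) == 4,
            all(abs(rowSums(confusion) - 1) < 1e-8), all(confusion >= 0),
            all(EMOTIONS %in% rownames(confusion)),
            all(EMOTIONS %in% names(valence_mean)),
            n_raters >= 1, valence_sd >= 0)
  structure(list(n_raters = as.integer(n_raters), confusion = confusion,
                 valence_mean = valence_mean, valence_sd = valence_sd,
                 seed = as.integer(seed)),
            class = "rater_model")
}

#' Simulate per-rater emotion and valence ratings
#'
#' @param scenes list of labelled scenes.
#' @param model a \code{\link{rater_model}}.
#' @return A data frame of class \code{rating_set} with columns
#'   \code{rater}, \code{scene_id}, \code{emotion_true}, \code{response},
#'   \code{valence} (integer in -5..+5). Deterministic under
#'   \code{model$seed}.
#' @export
simulate_ratings <- function(scenes, model = rater_model()) {
  labels <- vapply(scenes, function(s) s$emotion, character(1))
  if (anyNA(labels) || any(labels == "NA"))
    stop_dyadkin("simulate_ratings requires every scene to be labelled")
  ids <- vapply(scenes, function(s) s$scene_id, character(1))
  ns <- length(scenes)
  with_seed(model$seed, {
    out <- vector("list", model$n_raters)
    for (r in seq_len(model$n_raters)) {
      resp <- vapply(labels, function(l) {
        sample(EMOTIONS, 1, prob = model$confusion[l, EMOTIONS])
      }, character(1))
      val <- round(model$valence_mean[labels] +
                     stats::rnorm(ns, 0, model$valence_sd))
      out[[r]] <- data.frame(rater = r, scene_id = ids, emotion_true = labels,
                             response = unname(resp),
                             valence = as.integer(clip(val, -5, 5)),
                             stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    class(res) <- c("rating_set", "data.frame")
    res
  })
}
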