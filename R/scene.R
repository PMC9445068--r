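## Scene data model: one 4-s dyadic interaction.
##
## An agent trajectory is a frames x 15 x 3 numeric array in mm; dimension 2
## carries the canonical marker labels, dimension 3 the axes c("x","y","z")
## with z vertical (up-positive). Frames are stored at `fps` Hz.

EMOTIONS <- c("happiness", "affection", "sadness", "anger")

#' Construct a dyadic point-light scene
#'
#' @param agent1,agent2 frames x 15 x 3 numeric arrays (mm) with marker
#'   labels on dimension 2 and axes \code{c("x","y","z")} on dimension 3.
#' @param fps sampling rate in Hz (default 100).
#' @param emotion one of \code{"happiness"}, \code{"affection"},
#'   \code{"sadness"}, \code{"anger"}, or \code{NA} for unlabeled scenes.
#' @param scene_id identifier string.
#' @param markers a \code{\link{marker_set}}.
#' @return Object of class \code{dyad_scene}.
#' @export
scene <- function(agent1, agent2, fps = 100, emotion = NA_character_,
                  scene_id = "scene", markers = marker_set()) {
  agents <- list(as_agent(agent1, markers), as_agent(agent2, markers))
  sc <- structure(list(agents = agents, fps = fps,
                       emotion = as.character(emotion),
                       scene_id = as.character(scene_id),
                       markers = markers),
                  class = "dyad_scene")
  validate_scene(sc)
}

as_agent <- function(a, markers = marker_set()) {
  if (!is.array(a) || length(dim(a)) != 3L || dim(a)[3] != 3L)
    stop_dyadkin("agent trajectory must be a frames x markers x 3 array")
  labs <- dimnames(a)[[2]]
  if (is.null(labs))
    stop_dyadkin("agent trajectory must carry marker labels on dimension 2")
  labs <- resolve_markers(labs, markers)
  missing <- setdiff(markers$names, labs)
  if (length(missing))
    stop_dyadkin("missing marker label(s): %s", paste(missing, collapse = ", "))
  a <- a[, match(markers$names, labs), , drop = FALSE]
  dimnames(a) <- list(NULL, markers$names, c("x", "y", "z"))
  storage.mode(a) <- "double"
  a
}

validate_scene <- function(sc) {
  stopifnot(inherits(sc, "dyad_scene"))
  if (length(sc$agents) != 2L)
    stop_dyadkin("agent count must be 2, got %d", length(sc$agents))
  f <- vapply(sc$agents, function(a) dim(a)[1], integer(1))
  if (f[1] != f[2])
    stop_dyadkin("both agents must share the frame count (%d vs %d)", f[1], f[2])
  if (f[1] < 2L) stop_dyadkin("a scene needs frames >= 2, got %d", f[1])
  if (!is_scalar_number(sc$fps) || sc$fps <= 0)
    stop_dyadkin("fps must be a positive number")
  for (a in sc$agents)
    if (any(!is.finite(a)))
      stop_dyadkin("non-finite coordinates in scene '%s'", sc$scene_id)
  if (!is.na(sc$emotion) && !(sc$emotion %in% EMOTIONS))
    stop_dyadkin("unknown emotion label '%s'", sc$emotion)
  sc
}

#' @export
print.dyad_scene <- function(x, ...) {
  cat(sprintf("<dyad_scene '%s'> %d frames @ %g Hz, emotion: %s\n",
              x$scene_id, n_frames(x), x$fps,
              ifelse(is.na(x$emotion), "unlabeled", x$emotion)))
  invisible(x)
}

n_frames <- function(sc) dim(sc$agents[[1]])[1]

# Coordinates of the 13 anatomical markers for agent i.
anat_coords <- function(sc, i) {
  sc$agents[[i]][, sc$markers$anatomical_13, , drop = FALSE]
}

## ---- rigid / affine transforms (exported: used by invariance checks) ----

#' Geometric transforms of a scene
#'
#' Utility transforms used mainly for invariance testing: rigid translation,
#' rotation about the vertical axis, uniform scaling about the origin, agent
#' relabelling and time reversal.
#'
#' @param sc a \code{dyad_scene}.
#' @param offset length-3 numeric (mm) for translation.
#' @param angle rotation angle about z, radians.
#' @param s positive scale factor.
#' @return The transformed \code{dyad_scene}.
#' @name scene-transforms
NULL

transform_agents <- function(sc, f) {
  sc$agents <- lapply(sc$agents, f)
  sc
}

#' @rdname scene-transforms
#' @export
scene_translate <- function(sc, offset) {
  stopifnot(length(offset) == 3L)
  transform_agents(sc, function(a) {
    for (k in 1:3) a[, , k] <- a[, , k] + offset[k]
    a
  })
}

#' @rdname scene-transforms
#' @export
scene_rotate_z <- function(sc, angle) {
  co <- cos(angle); si <- sin(angle)
  transform_agents(sc, function(a) {
    x <- a[, , 1]; y <- a[, , 2]
    a[, , 1] <- co * x - si * y
    a[, , 2] <- si * x + co * y
    a
  })
}

#' @rdname scene-transforms
#' @export
scene_scale <- function(sc, s) {
  stopifnot(is_scalar_number(s), s > 0)
  transform_agents(sc, function(a) a * s)
}

#' @rdname scene-transforms
#' @export
scene_swap_agents <- function(sc) {
  sc$agents <- sc$agents[c(2L, 1L)]
  sc
}

#' @rdname scene-transforms
#' @export
scene_reverse_time <- function(sc) {
  transform_agents(sc, function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE])
}

# Mirror a scene across the xz-plane (y -> -y), swapping left/right labels.
scene_mirror <- function(sc) {
  ms <- sc$markers
  swap <- ms$names
  idx_l <- match(ms$pairs[, "left"], swap)
  idx_r <- match(ms$pairs[, "right"], swap)
  perm <- seq_along(swap)
  perm[idx_l] <- idx_r
  perm[idx_r] <- idx_l
  transform_agents(sc, function(a) {
    a[, , 2] <- -a[, , 2]
    a <- a[, perm, , drop = FALSE]
    dimnames(a)[[2]] <- ms$names
    a
  })
}
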