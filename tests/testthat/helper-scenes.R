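# Toy scene builders used across the suite. Poses are defined here,
# independently of the package's internal template.

MS <- marker_set()

# A plain standing pose (mm), facing +x, left side at +y.
toy_pose <- function() {
  p <- rbind(
    head = c(70, 0, 1650), sternum = c(50, 0, 1420), sacrum = c(0, 0, 1000),
    l_shoulder = c(0, 185, 1440), r_shoulder = c(0, -185, 1440),
    l_elbow = c(25, 245, 1150), r_elbow = c(25, -245, 1150),
    l_wrist = c(50, 275, 890), r_wrist = c(50, -275, 890),
    l_hip = c(0, 92, 975), r_hip = c(0, -92, 975),
    l_knee = c(15, 102, 495), r_knee = c(15, -102, 495),
    l_ankle = c(0, 108, 75), r_ankle = c(0, -108, 75))
  p[MS$names, ]
}

# Static agent: same pose every frame, optionally offset.
static_agent <- function(frames = 5, pose = toy_pose(), offset = c(0, 0, 0)) {
  a <- array(0, c(frames, 15, 3),
             dimnames = list(NULL, MS$names, c("x", "y", "z")))
  for (k in 1:3) a[, , k] <- matrix(pose[, k] + offset[k], frames, 15,
                                    byrow = TRUE)
  a
}

# Agent from a per-frame pose function f(t) -> 15 x 3 (t = 1..frames).
agent_from_fn <- function(frames, f) {
  a <- array(0, c(frames, 15, 3),
             dimnames = list(NULL, MS$names, c("x", "y", "z")))
  for (t in seq_len(frames)) a[t, , ] <- f(t)
  a
}

# Random smooth-ish small scene for oracle comparisons.
random_agent <- function(frames = 8, scale = 40) {
  base <- toy_pose()
  agent_from_fn(frames, function(t) base + matrix(stats::rnorm(45, 0, scale),
                                                  15, 3))
}

toy_scene <- function(a1, a2 = NULL, fps = 100, emotion = NA, id = "toy") {
  if (is.null(a2)) a2 <- a1 + rep(c(2000, 0, 0), each = dim(a1)[1] * 15)
  sc <- scene(a1, a2, fps = fps, emotion = emotion, scene_id = id)
  sc
}

# Rotate agent2 of a scene by 180 deg about its own vertical axis.
turn_agent_away <- function(a) {
  ctr <- colMeans(a[1, , 1:2])
  b <- a
  b[, , 1] <- 2 * ctr[1] - a[, , 1]
  b[, , 2] <- 2 * ctr[2] - a[, , 2]
  b
}
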