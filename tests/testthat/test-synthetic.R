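test_that("dataset generation counts, labels and determinism", {
  sc <- generate_dataset(n_scenes_per_emotion = 1, seed = 5, frames = 60)
  expect_length(sc, 4)
  expect_setequal(vapply(sc, function(s) s$emotion, character(1)),
                  c("happiness", "affection", "sadness", "anger"))
  sc2 <- generate_dataset(n_scenes_per_emotion = 1, seed = 5, frames = 60)
  for (i in 1:4) {
    expect_identical(sc[[i]]$agents[[1]], sc2[[i]]$agents[[1]])
    expect_identical(sc[[i]]$agents[[2]], sc2[[i]]$agents[[2]])
  }
  sc3 <- generate_dataset(n_scenes_per_emotion = 1, seed = 6, frames = 60)
  expect_false(identical(sc[[1]]$agents[[1]], sc3[[1]]$agents[[1]]))
})

test_that("unknown emotion without params errors; labelled scene geometry", {
  expect_error(generate_scene("boredom", seed = 1), "unknown emotion")
  sc <- generate_scene("affection", seed = 3, frames = 150)
  expect_equal(dim(sc$agents[[1]]), c(150L, 15L, 3L))
  expect_equal(sc$fps, 100)
})

test_that("speed calibration hits the programmed target", {
  sc <- generate_scene("happiness", seed = 1)
  target <- default_archetypes()$happiness$speed_scale
  ## finite-difference mean marker speed, computed here not via the package
  sp <- sapply(1:2, function(i) {
    a <- sc$agents[[i]][, MS$anatomical_13, ]
    d <- a[-1, , ] - a[-400, , ]
    mean(sqrt(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)) * sc$fps
  })
  expect_lt(abs(mean(sp) - target) / target, 0.20)
  ## agent 1 is calibrated to the target itself
  expect_lt(abs(sp[1] - target) / target, 0.01)
})

test_that("archetype contrasts: sadness slower and flatter than happiness", {
  hap <- reduce_intrapersonal(generate_scene("happiness", seed = 7))
  sad <- reduce_intrapersonal(generate_scene("sadness", seed = 7))
  expect_lt(sad[["VEL"]], hap[["VEL"]])
  expect_lt(sad[["VM"]], hap[["VM"]])
})

test_that("energy ratio propagates to motion-energy balance", {
  ## facing_frac = 1 suppresses yaw-aversion root motion, so the calibrated
  ## local motion dominates and the programmed energy ratio is realised
  p1 <- archetype_params(250, 5, 900, 900, 1, energy_ratio = 1)
  s1 <- generate_scene("anger", p1, seed = 2, frames = 200)
  expect_gt(motion_energy_balance(s1), 0.98)
  p2 <- archetype_params(250, 5, 900, 900, 1, energy_ratio = 0.5)
  s2 <- generate_scene("anger", p2, seed = 2, frames = 200)
  expect_equal(motion_energy_balance(s2), 2 / 3, tolerance = 0.02)
})

test_that("synchrony target is recovered from controlled archetypes", {
  for (rho in c(0.6, -0.5)) {
    p <- archetype_params(300, 0, 800, 800, 1, sync_level = rho)
    r <- vapply(1:3, function(s) {
      suppressWarnings(synchronization(generate_scene("happiness", p,
                                                      seed = s)))
    }, numeric(1))
    expect_true(all(abs(r - rho) < 0.15))
  }
})

test_that("degenerate rater model reproduces the labels exactly", {
  scenes <- generate_dataset(n_scenes_per_emotion = 2, seed = 9, frames = 40)
  ident <- diag(4)
  dimnames(ident) <- list(c("happiness", "affection", "sadness", "anger"),
                          c("happiness", "affection", "sadness", "anger"))
  rm0 <- rater_model(n_raters = 5, confusion = ident, valence_sd = 0, seed = 2)
  rt <- simulate_ratings(scenes, rm0)
  expect_true(all(rt$response == rt$emotion_true))
  expect_true(all(tapply(rt$valence, rt$scene_id, stats::sd) == 0))
})

test_that("uniform confusion converges to 25% accuracy", {
  scenes <- generate_dataset(n_scenes_per_emotion = 3, seed = 10, frames = 40)
  unif <- matrix(0.25, 4, 4,
                 dimnames = list(c("happiness", "affection", "sadness", "anger"),
                                 c("happiness", "affection", "sadness", "anger")))
  rt <- simulate_ratings(scenes, rater_model(n_raters = 100, confusion = unif,
                                             seed = 3))
  expect_equal(mean(rt$response == rt$emotion_true), 0.25, tolerance = 0.05)
})

test_that("default confusion reproduces its recognition ordering", {
  cm <- rater_model()$confusion
  d <- diag(cm[c("anger", "happiness", "sadness", "affection"),
               c("anger", "happiness", "sadness", "affection")])
  expect_true(all(diff(d) < 0))  # anger >= happiness >= sadness >= affection
  ## Monte-Carlo per-emotion accuracy matches the configured diagonal
  scenes <- generate_dataset(n_scenes_per_emotion = 3, seed = 11, frames = 40)
  rt <- simulate_ratings(scenes, rater_model(n_raters = 400, seed = 4))
  acc <- tapply(rt$response == rt$emotion_true, rt$emotion_true, mean)
  expect_equal(as.vector(acc[rownames(cm)]), unname(diag(cm)),
               tolerance = 0.03)
  ## and the rating simulator is deterministic under the model seed
  rt2 <- simulate_ratings(scenes, rater_model(n_raters = 400, seed = 4))
  expect_identical(rt, rt2)
})

test_that("unlabeled scenes cannot be rated", {
  sc <- toy_scene(static_agent(4), static_agent(4, offset = c(1500, 0, 0)))
  expect_error(simulate_ratings(list(sc)), "labelled")
})
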