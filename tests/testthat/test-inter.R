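test_that("interpersonal distance closed forms", {
  sc <- toy_scene(static_agent(5), static_agent(5, offset = c(1000, 0, 0)))
  d <- interpersonal_distance(sc)
  expect_equal(d$IPD, 1000)
  expect_equal(d$IPD_STD, 0)
  expect_equal(d$ipd_t, rep(1000, 5))

  ## linear approach 2000 -> 200: mean of the ramp
  nf <- 101
  appr <- agent_from_fn(nf, function(t) {
    p <- toy_pose(); p[, 1] <- p[, 1] + 2000 - 1800 * (t - 1) / (nf - 1); p
  })
  sc2 <- scene(static_agent(nf), appr, scene_id = "appr")
  expect_equal(interpersonal_distance(sc2)$IPD, 1100, tolerance = 1e-9)
})

test_that("personal space boundary cases", {
  far <- toy_scene(static_agent(4), static_agent(4, offset = c(3000, 0, 0)))
  expect_equal(personal_space(far), 0)
  near <- toy_scene(static_agent(4), static_agent(4, offset = c(300, 0, 0)))
  expect_equal(personal_space(near), 100)
  ## explicit arm length override and min-marker variant stay in range
  expect_equal(personal_space(far, arm_length = 5000), 100)
  expect_true(personal_space(near, min_marker = TRUE) %in% c(0, 100))
})

test_that("orientation: mutual, one-sided, and balance boundaries", {
  a1 <- static_agent(10)                                    # faces +x
  a2 <- turn_agent_away(static_agent(10, offset = c(1500, 0, 0)))  # faces -x
  sc <- scene(a1, a2, scene_id = "face")
  o <- orientation(sc)
  expect_equal(o$IPO, 100)
  expect_equal(o$IPO_BAL, 1)
  expect_true(all(o$facing_1 & o$facing_2))

  ## agent 2 keeps facing +x (away from agent 1's side? no: away from 1)
  sc1 <- scene(a1, static_agent(10, offset = c(1500, 0, 0)), scene_id = "one")
  o1 <- orientation(sc1)
  expect_true(all(o1$facing_1))
  expect_false(any(o1$facing_2))
  expect_equal(o1$IPO, 50)
  expect_equal(o1$IPO_BAL, 0)
  expect_equal(orientation(sc1, mode = "mutual")$IPO, 0)

  degen <- a1
  degen[, "r_shoulder", ] <- degen[, "l_shoulder", ]
  expect_error(orientation(scene(degen, a2)), "shoulder")
})

test_that("distance correlations equal the textbook Pearson formula", {
  set.seed(31)
  sc <- toy_scene(random_agent(12), random_agent(12))
  pr <- dyadkin:::dyad_profiles(sc)
  for (p in c("VEL", "ACC", "VOL", "LC")) {
    y <- pr[[p]]
    x <- pr$ipd_t[seq_along(y)]
    expect_equal(distance_correlation(sc, p), oracle_pearson(x, y),
                 tolerance = 1e-9, info = p)
  }
  ## a scene built so limb contraction tracks distance perfectly
  nf <- 60
  open <- agent_from_fn(nf, function(t) {
    p <- toy_pose()
    g <- (t - 1) / (nf - 1)
    for (m in c("l_wrist", "r_wrist"))
      p[m, ] <- p["head", ] + (p[m, ] - p["head", ]) * (1 + g)
    p[, 1] <- p[, 1] + 1000 * g   # drift apart while opening
    p
  })
  sc2 <- scene(static_agent(nf), open, scene_id = "open")
  expect_gt(distance_correlation(sc2, "LC"), 0.99)
})

test_that("synchronisation: mirrored and anti-phase constructions", {
  nf <- 80; fps <- 100
  osc <- function(phase) agent_from_fn(nf, function(t) {
    p <- toy_pose()
    ## per-frame step magnitude c + A sin(...) along x
    steps <- 5 + 3 * sin(2 * pi * 3 * (0:(nf - 2)) / fps + phase)
    p[, 1] <- p[, 1] + c(0, cumsum(steps))[t]
    p
  })
  same <- scene(osc(0), {
    a <- osc(0); a[, , 1] <- a[, , 1] + 2500; a
  }, scene_id = "same")
  expect_equal(synchronization(same, "VEL"), 1, tolerance = 1e-9)

  anti <- scene(osc(0), {
    a <- osc(pi); a[, , 1] <- a[, , 1] + 2500; a
  }, scene_id = "anti")
  expect_equal(synchronization(anti, "VEL"), -1, tolerance = 1e-6)

  ## oracle equality on irregular motion
  set.seed(32)
  sc <- toy_scene(random_agent(10), random_agent(10))
  pr <- dyadkin:::dyad_profiles(sc)
  expect_equal(synchronization(sc, "VEL"), oracle_pearson(pr$speed_1, pr$speed_2),
               tolerance = 1e-9)
  expect_equal(synchronization(sc, "ACC"), oracle_pearson(pr$acc_1, pr$acc_2),
               tolerance = 1e-9)
})

test_that("motion-energy balance boundaries and exact ratio", {
  set.seed(33)
  a <- random_agent(8)
  b <- a; b[, , 1] <- b[, , 1] + 2000
  expect_equal(motion_energy_balance(scene(a, b)), 1, tolerance = 1e-12)

  stat <- static_agent(8, offset = c(2000, 0, 0))
  expect_equal(motion_energy_balance(scene(a, stat)), 0)

  ## halve agent 2's displacements -> E2 = E1 / 2 -> 1 - (1/3) = 2/3
  half <- a
  for (k in 1:3) {
    d <- apply(a[, , k], 2, diff) / 2
    half[, , k] <- rbind(a[1, , k],
                         sweep(apply(d, 2, cumsum), 2, a[1, , k], "+"))
  }
  half[, , 1] <- half[, , 1] + 2000
  expect_equal(motion_energy_balance(scene(a, half)), 2 / 3,
               tolerance = 1e-12)
})

test_that("interpersonal reduction: completeness, degenerate scenes, invariances", {
  set.seed(34)
  sc <- toy_scene(random_agent(8), random_agent(8))
  f <- reduce_interpersonal(sc)
  expect_named(f, interpersonal_features(), ignore.order = FALSE)
  expect_true(all(is.finite(f)))

  stat <- scene(static_agent(6), static_agent(6, offset = c(1500, 0, 0)))
  fs <- suppressWarnings(reduce_interpersonal(stat))
  expect_equal(unname(fs["IPD"]), 1500)
  expect_equal(unname(fs["ME_BAL"]), 0)
  expect_true(all(is.na(fs[c("DC_VEL", "DC_ACC", "SYNC_VEL", "SYNC_ACC")])))
  expect_warning(synchronization(stat, "VEL"), "zero-variance")

  ## rigid motion of the whole dyad and agent swap
  moved <- scene_rotate_z(scene_translate(sc, c(-200, 640, 90)), 1.1)
  expect_equal(reduce_interpersonal(moved), f, tolerance = 1e-8)
  swapped <- reduce_interpersonal(scene_swap_agents(sc))
  expect_equal(swapped, f, tolerance = 1e-10)
})
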