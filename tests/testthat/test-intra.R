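test_that("velocity and acceleration closed forms", {
  a <- static_agent(6)
  expect_equal(velocity(a, 100)$scalar, 0)
  expect_equal(acceleration(a, 100)$scalar, 0)

  ## one marker stepping 1 mm/frame along x at 100 Hz -> 100 mm/s
  b <- static_agent(6)
  b[, "l_wrist", 1] <- b[, "l_wrist", 1] + (0:5)
  v <- velocity(b, 100)
  expect_equal(unname(v$series[, "l_wrist"]), rep(100, 5))
  expect_equal(v$scalar, 100 / 13)
  expect_equal(acceleration(b, 100)$scalar, 0)   # constant velocity

  ## quadratic fall z = a t^2 / 2 with a = 1000 mm/s^2
  fps <- 100
  cfall <- agent_from_fn(8, function(t) {
    p <- toy_pose()
    p[, 3] <- p[, 3] + 0.5 * 1000 * ((t - 1) / fps)^2
    p
  })
  acc <- acceleration(cfall, fps)
  expect_equal(unname(acc$series[, 1]), rep(1000, 6), tolerance = 1e-6)
  expect_error(velocity(a, fps = 0), "fps")
})

test_that("vertical movement: z-invariance and sinusoid arc", {
  ## pure horizontal translation -> 0
  hor <- agent_from_fn(10, function(t) {
    p <- toy_pose(); p[, 1] <- p[, 1] + 7 * t; p
  })
  expect_equal(vertical_movement(hor)$scalar, 0)

  ## whole-body sinusoid: total |dz| path ~ 4 A f T
  A <- 50; f <- 2; fps <- 100; nf <- 400
  sine <- agent_from_fn(nf, function(t) {
    p <- toy_pose(); p[, 3] <- p[, 3] + A * sin(2 * pi * f * (t - 1) / fps); p
  })
  vm <- vertical_movement(sine)$scalar
  expect_equal(vm, 4 * A * f * (nf / fps), tolerance = 0.02)
  ## and it equals the explicit discrete sum
  z <- A * sin(2 * pi * f * (0:(nf - 1)) / fps)
  expect_equal(vm, sum(abs(diff(z))), tolerance = 1e-9)
})

test_that("bounding-box volume closed forms and s^3 homogeneity", {
  ## an axis-aligned 1 m cube of anatomical points
  cube <- static_agent(4)
  corners <- as.matrix(expand.grid(c(0, 1000), c(0, 1000), c(0, 1000)))
  pts <- corners[c(1:8, 1:5), ]   # 13 anatomical points spanning the cube
  for (k in 1:3) cube[, MS$anatomical_13, k] <-
    matrix(pts[, k], 4, 13, byrow = TRUE)
  v <- body_volume(cube)
  expect_equal(v$scalar, 1)
  expect_equal(v$scalar_sd, 0)

  set.seed(21)
  r <- random_agent(5)
  expect_equal(body_volume(r * 2)$scalar, 8 * body_volume(r)$scalar,
               tolerance = 1e-12)
})

test_that("symmetry: mirrored posture scores zero, asymmetries localise", {
  sym <- static_agent(3)               # toy pose is left/right mirrored
  expect_equal(symmetry(sym)$scalar, 0, tolerance = 1e-9)

  up <- static_agent(3)
  up[, "l_wrist", 3] <- up[, "l_wrist", 3] + 100
  comp <- symmetry(up)$components
  ## height component: 100 mm at one of six pairs
  expect_equal(unname(comp[1, "height"]), 100 / 6, tolerance = 1e-9)
  expect_gt(symmetry(up)$scalar, 0)

  flat <- static_agent(3)
  flat[, , 1:2] <- 0                   # all markers on the vertical axis
  expect_error(symmetry(flat), "midline")
})

test_that("limb angles: collinear and orthogonal constructions", {
  a <- static_agent(2)
  ## straighten the left arm along -z below the shoulder
  sh <- a[1, "l_shoulder", ]
  a[, "l_elbow", ] <- matrix(sh + c(0, 0, -300), 2, 3, byrow = TRUE)
  a[, "l_wrist", ] <- matrix(sh + c(0, 0, -600), 2, 3, byrow = TRUE)
  la <- limb_angles(a)
  expect_equal(unname(la$series[1, "l_elbow"]), 180)
  ## right-angle elbow
  a[, "l_wrist", ] <- matrix(sh + c(300, 0, -300), 2, 3, byrow = TRUE)
  expect_equal(unname(limb_angles(a)$series[1, "l_elbow"]), 90)
  ## degenerate segment errors with the joint named
  a[, "l_elbow", ] <- a[, "l_shoulder", ]
  expect_error(limb_angles(a), "l_shoulder")
})

test_that("limb contraction: zero case and homogeneity", {
  a <- static_agent(3)
  for (m in c("l_wrist", "r_wrist", "l_ankle", "r_ankle"))
    a[, m, ] <- a[, "head", ]
  expect_equal(limb_contraction(a)$scalar, 0)
  set.seed(22)
  r <- random_agent(4)
  expect_equal(limb_contraction(r * 2)$scalar,
               2 * limb_contraction(r)$scalar, tolerance = 1e-12)
})

test_that("intrapersonal reduction matches the brute-force oracle", {
  set.seed(23)
  for (rep in 1:3) {
    sc <- toy_scene(random_agent(7), random_agent(7, scale = 25))
    got <- reduce_intrapersonal(sc)
    want <- oracle_intrapersonal(sc)
    expect_equal(got, want, tolerance = 1e-9)
  }
  ## two identical agents equal the single-agent value
  a <- random_agent(6)
  sc2 <- scene(a, a, scene_id = "dup")
  expect_equal(unname(reduce_intrapersonal(sc2)["LC"]),
               limb_contraction(a)$scalar, tolerance = 1e-12)
})

test_that("rigid-motion, scaling, reflection and time-reversal invariances", {
  set.seed(24)
  sc <- toy_scene(random_agent(6), random_agent(6))
  base <- reduce_intrapersonal(sc)
  moved <- scene_rotate_z(scene_translate(sc, c(500, -300, 120)), 0.7)
  expect_equal(reduce_intrapersonal(moved), base, tolerance = 1e-8)

  s <- 1.7
  scaled <- reduce_intrapersonal(scene_scale(sc, s))
  expo <- c(VEL = 1, ACC = 1, VM = 1, VOL = 3, VOL_STD = 3, SM = 1, LA = 0,
            LC = 1)
  expect_equal(scaled, base * s^expo[names(base)], tolerance = 1e-8)

  mir <- dyadkin:::scene_mirror(sc)
  expect_equal(reduce_intrapersonal(mir), base, tolerance = 1e-8)

  rev <- reduce_intrapersonal(scene_reverse_time(sc))
  still <- c("VEL", "VM", "VOL", "VOL_STD", "SM", "LA", "LC")
  expect_equal(rev[still], base[still], tolerance = 1e-8)
})
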