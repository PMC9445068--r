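# Independent brute-force oracles, written with explicit loops and kept
# deliberately separate from the package implementation paths.

MS <- marker_set()
ANAT <- MS$anatomical_13

oracle_velocity <- function(a, fps) {
  nf <- dim(a)[1]
  sp <- c()
  for (t in 1:(nf - 1)) for (m in ANAT) {
    sp <- c(sp, sqrt(sum((a[t + 1, m, ] - a[t, m, ])^2)) * fps)
  }
  mean(sp)
}

oracle_acceleration <- function(a, fps) {
  nf <- dim(a)[1]
  acc <- c()
  for (m in ANAT) {
    sp <- sapply(1:(nf - 1), function(t)
      sqrt(sum((a[t + 1, m, ] - a[t, m, ])^2)) * fps)
    acc <- c(acc, abs(diff(sp)) * fps)
  }
  mean(acc)
}

oracle_vm <- function(a) {
  nf <- dim(a)[1]
  per_marker <- sapply(ANAT, function(m) {
    s <- 0
    for (t in 1:(nf - 1)) s <- s + abs(a[t + 1, m, 3] - a[t, m, 3])
    s
  })
  mean(per_marker)
}

oracle_volume <- function(a) {
  nf <- dim(a)[1]
  v <- sapply(1:nf, function(t) {
    lr <- (a[t, "r_shoulder", ] - a[t, "l_shoulder", ] +
             a[t, "r_hip", ] - a[t, "l_hip", ]) / 2
    lr[3] <- 0
    if (sqrt(sum(lr^2)) < 1e-6) lr <- c(1, 0, 0)
    u1 <- lr / sqrt(sum(lr^2))
    u2 <- c(-u1[2], u1[1], 0)
    pts <- a[t, ANAT, ]
    proj <- cbind(pts %*% u1, pts %*% u2, pts[, 3])
    prod(apply(proj, 2, function(col) max(col) - min(col))) / 1e9
  })
  c(mean(v), stats::sd(v))
}

oracle_symmetry <- function(a) {
  nf <- dim(a)[1]
  sides <- rownames(MS$pairs)
  comp <- matrix(0, nf, 3)
  for (t in 1:nf) {
    mid_sh <- (a[t, "l_shoulder", ] + a[t, "r_shoulder", ]) / 2
    mid_hip <- (a[t, "l_hip", ] + a[t, "r_hip", ]) / 2
    centre <- (mid_sh + mid_hip) / 2
    lr <- (a[t, "r_shoulder", ] - a[t, "l_shoulder", ] +
             a[t, "r_hip", ] - a[t, "l_hip", ]) / 2
    lr[3] <- 0
    lr <- lr / sqrt(sum(lr^2))
    acc <- c(0, 0, 0)
    for (s in sides) {
      pl <- a[t, paste0("l_", s), ]
      pr <- a[t, paste0("r_", s), ]
      dz <- abs(pl[3] - pr[3])
      dl <- abs(sum((pl - centre) * lr))
      dr <- abs(sum((pr - centre) * lr))
      chord <- pr - pl
      clen <- sqrt(sum(chord^2))
      ang <- if (clen < 1e-9) 0 else acos(min(1, abs(sum(chord * lr)) / clen))
      acc <- acc + c(dz, abs(dl - dr), ang * clen / 2)
    }
    comp[t, ] <- acc / length(sides)
  }
  mean(colMeans(comp))
}

oracle_limb_angles <- function(a) {
  nf <- dim(a)[1]
  triples <- list(c("shoulder", "elbow", "hip"), c("elbow", "shoulder", "wrist"),
                  c("hip", "shoulder", "knee"), c("knee", "hip", "ankle"))
  angles <- c()
  for (t in 1:nf) for (s in c("l", "r")) for (tr in triples) {
    at <- a[t, paste0(s, "_", tr[1]), ]
    v1 <- a[t, paste0(s, "_", tr[2]), ] - at
    v2 <- a[t, paste0(s, "_", tr[3]), ] - at
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    angles <- c(angles, acos(max(-1, min(1, cosang))) * 180 / pi)
  }
  mean(angles)
}

oracle_lc <- function(a) {
  nf <- dim(a)[1]
  d <- c()
  for (t in 1:nf) for (m in c("l_wrist", "r_wrist", "l_ankle", "r_ankle")) {
    d <- c(d, sqrt(sum((a[t, m, ] - a[t, "head", ])^2)))
  }
  mean(d)
}

oracle_intrapersonal <- function(sc) {
  vals <- sapply(sc$agents, function(a) {
    vol <- oracle_volume(a)
    c(VEL = oracle_velocity(a, sc$fps), ACC = oracle_acceleration(a, sc$fps),
      VM = oracle_vm(a), VOL = vol[1], VOL_STD = vol[2],
      SM = oracle_symmetry(a), LA = oracle_limb_angles(a), LC = oracle_lc(a))
  })
  rowMeans(vals)
}

# Textbook Pearson formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  num / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Kendall tau-A by full pair enumeration.
oracle_tau_a <- function(x, y) {
  m <- length(x)
  cd <- 0
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    cd <- cd + sign(x[j] - x[i]) * sign(y[j] - y[i])
  }
  cd / (m * (m - 1) / 2)
}
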