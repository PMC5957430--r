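# V_KT / A_KT / D_KT and spindle-frame estimation.

test_that("V_KT is displacement over the frame interval", {
  tr <- data.frame(frame = 0:1, x_um = c(0, 1), y_um = 0, z_um = 0)
  expect_equal(compute_vkt(tr, 10), 0.1)
  still <- data.frame(frame = 0:5, x_um = 1, y_um = 2, z_um = 3)
  expect_equal(compute_vkt(still, 10), rep(0, 5))
  expect_error(compute_vkt(still[1, ], 10), "single-sample")
})

test_that("V_KT matches the closed-form arc speed of a helix", {
  # helix of radius r, pitch b: speed = omega * sqrt(r^2 + b^2)
  r <- 2; b <- 0.5; omega <- 0.01
  t <- seq(0, 1000, by = 10)
  tr <- data.frame(frame = seq_along(t) - 1, x_um = r * cos(omega * t),
                   y_um = r * sin(omega * t), z_um = b * omega * t)
  v <- compute_vkt(tr, 10)
  v_true <- omega * sqrt(r^2 + b^2)
  # chord underestimates arc by O((omega dt)^2 / 24)
  expect_lt(max(abs(v - v_true)) / v_true, (omega * 10)^2 / 8)
})

test_that("gap-flagged samples give missing velocities, never zeros", {
  tr <- data.frame(frame = 0:4, x_um = c(0, 1, 2, 3, 4), y_um = 0, z_um = 0,
                   gap = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  v <- compute_vkt(tr, 10)
  expect_true(all(is.na(v[2:3])))
  expect_equal(v[c(1, 4)], c(0.1, 0.1))
})

test_that("A_KT follows the closed forms and stays in [0, 90]", {
  p1 <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(0, 0, 0))
  p2 <- matrix(0, 4, 3)
  a <- compute_akt(p1, p2, c(1, 0, 0))
  expect_equal(a[1], 0)
  expect_equal(a[2], 90)
  expect_equal(a[3], 45)
  expect_true(is.na(a[4]))   # coincident points: undefined
})

test_that("A_KT is invariant under member exchange and axis sign flip", {
  set.seed(4)
  p1 <- matrix(rnorm(30), 10, 3)
  p2 <- matrix(rnorm(30), 10, 3)
  ax <- rnorm(3)
  expect_equal(compute_akt(p1, p2, ax), compute_akt(p2, p1, ax))
  expect_equal(compute_akt(p1, p2, ax), compute_akt(p1, p2, -ax))
})

test_that("D_KT is a Euclidean distance, rigid-motion invariant", {
  expect_equal(compute_dkt(matrix(c(0, 0, 0), 1), matrix(c(3, 4, 0), 1)), 5)
  expect_equal(compute_dkt(matrix(1:3, 1), matrix(1:3, 1)), 0)
  set.seed(5)
  p1 <- matrix(rnorm(30), 10, 3)
  p2 <- matrix(rnorm(30), 10, 3)
  d0 <- compute_dkt(p1, p2)
  # random rigid transform
  qr_r <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_r) < 0) qr_r[, 1] <- -qr_r[, 1]
  shift <- rnorm(3)
  tf <- function(p) p %*% qr_r + matrix(shift, nrow(p), 3, byrow = TRUE)
  expect_equal(compute_dkt(tf(p1), tf(p2)), d0)
  # V_KT scale covariance
  tr <- data.frame(frame = 0:9, x_um = cumsum(rnorm(10)),
                   y_um = cumsum(rnorm(10)), z_um = cumsum(rnorm(10)))
  tr3 <- tr
  tr3[, 2:4] <- tr3[, 2:4] * 3
  expect_equal(compute_vkt(tr3, 10), 3 * compute_vkt(tr, 10))
})

test_that("spindle axis estimation recovers exact constructed geometries", {
  mk <- function(vecs, n_frames = 10) {
    do.call(rbind, lapply(seq_along(vecs), function(p) {
      v <- vecs[[p]]
      base <- c(p, 0, 0)
      do.call(rbind, lapply(1:2, function(m) {
        sgn <- if (m == 1) 0.5 else -0.5
        data.frame(kt_id = sprintf("p%d_m%d", p, m), pair_id = p, member = m,
                   frame = 0:(n_frames - 1), t_s = (0:(n_frames - 1)) * 10,
                   x_um = base[1] + sgn * v[1], y_um = base[2] + sgn * v[2],
                   z_um = base[3] + sgn * v[3])
      }))
    }))
  }
  # all pair vectors along +x
  tr <- mk(list(c(1, 0, 0), c(1, 0, 0)))
  sp <- estimate_spindle_axis(tr, 0:9)
  expect_equal(abs(sp$axis), c(1, 0, 0), tolerance = 1e-8)
  # symmetric +/-10 degrees about x: axis along x
  a <- 10 * pi / 180
  tr2 <- mk(list(c(cos(a), sin(a), 0), c(cos(a), -sin(a), 0)))
  sp2 <- estimate_spindle_axis(tr2, 0:9)
  expect_equal(abs(sp2$axis[1]), 1, tolerance = 1e-8)
  expect_false(sp2$oriented)   # no anaphase info: PCA fallback, flagged
  expect_error(estimate_spindle_axis(tr2, 500:520), "window")
})

test_that("the estimated axis is within 5 degrees of the true pole axis", {
  for (seed in c(3, 11)) {
    res <- simulate_cell(make_preset("control"), seed = seed)
    ann <- score_phases(res$bundle$positions, res$bundle$proxies, 10)
    sp <- attr(ann, "spindle")
    expect_true(sp$oriented)
    ang <- acos(min(1, abs(sum(sp$axis * res$truth$spindle_axis)))) * 180 / pi
    expect_lt(ang, 5)
  }
})

test_that("control kinematics show the published metaphase/anaphase signature", {
  res <- cached_cell("control", seed = 6)
  ann <- score_phases(res$bundle$positions, res$bundle$proxies, 10)
  kin <- kinematic_series(res$bundle$positions, attr(ann, "spindle"), 10)
  ph <- res$truth$phases
  meta <- kin$t_s > ph["metaphase_onset"] + 60 & kin$t_s < ph["anaphase_onset"]
  expect_lt(median(kin$a_kt_deg[meta], na.rm = TRUE), 15)
  # D_KT increases abruptly at anaphase onset: the first large step of the
  # median inter-KT distance falls at the onset, after an essentially flat
  # metaphase
  med_d <- tapply(kin$d_kt_um, kin$t_s, median)
  tt <- as.numeric(names(med_d))
  first_big <- tt[which(diff(med_d) > 0.3)[1] + 1L]
  expect_lt(abs(first_big - ph["anaphase_onset"]), 30)
  pre <- diff(med_d)[tt[-1] > ph["metaphase_onset"] + 60 &
                       tt[-1] < ph["anaphase_onset"] - 30]
  expect_lt(max(abs(pre)), 0.3)
})
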