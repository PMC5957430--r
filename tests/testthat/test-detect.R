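# Spot detection and the sub-resolution sister-separation estimator.

opt <- optics_config()

test_that("well-separated KTs are each detected within 150 nm", {
  set.seed(21)
  pts <- cbind(runif(8, -4, 4), runif(8, -4, 4), runif(8, -1.5, 1.5))
  while (min(dist(pts)) < 2) {
    pts <- cbind(runif(8, -4, 4), runif(8, -4, 4), runif(8, -1.5, 1.5))
  }
  st <- render_stack(pts, opt)
  sp <- detect_spots(st)
  expect_equal(nrow(sp), 8L)
  errs <- apply(pts, 1, function(p) {
    min(sqrt(rowSums((as.matrix(sp[, 1:3]) -
                        matrix(p, nrow(sp), 3, byrow = TRUE))^2)))
  })
  expect_true(all(errs < 0.150))
  # sorted by decreasing intensity
  expect_true(all(diff(sp$intensity) <= 0))
})

test_that("noise-only frames produce no spots and bad input errors", {
  set.seed(3)
  blank <- optics_config(photon_scale = 1e-9, stack_dim = c(64L, 64L, 10L))
  st <- render_stack(matrix(0, 1, 3), blank)
  expect_equal(nrow(detect_spots(st)), 0L)
  st2 <- render_stack(matrix(0, 1, 3), opt)
  attr(st2, "voxel_nm") <- NULL
  expect_error(detect_spots(st2), "calibrated")
  expect_error(detect_spots(st2, voxel_nm = c(300, 300, 300),
                            diameter_nm = 500), "diameter")
})

test_that("a single noiseless KT localizes within one voxel", {
  pos <- matrix(c(0.55, -1.23, 0.4), 1, 3)
  st <- render_stack(pos, optics_config(background = 0), noise = FALSE)
  sp <- detect_spots(st)
  expect_equal(nrow(sp), 1L)
  expect_lt(abs(sp$x_um - 0.55), 0.1)
  expect_lt(abs(sp$y_um + 1.23), 0.1)
  expect_lt(abs(sp$z_um - 0.4), 0.3)
})

test_that("localization error is sub-100 nm and improves with photons", {
  set.seed(11)
  pts <- cbind(runif(6, -3, 3), runif(6, -3, 3), runif(6, -1, 1))
  while (min(dist(pts)) < 2.2) {
    pts <- cbind(runif(6, -3, 3), runif(6, -3, 3), runif(6, -1, 1))
  }
  # photon ladder from starved to the default budget; the detection
  # threshold is relaxed so the starved condition still yields spots and the
  # error (capped at 1 um for gross failures) reflects localization quality
  mean_err <- vapply(c(40, 150, 2000), function(ph) {
    oo <- optics_config(photon_scale = ph)
    errs <- c()
    for (rep in 1:8) {
      st <- render_stack(pts, oo)
      sp <- detect_spots(st, nsigma = 5, threshold_rel = 0.12)
      if (nrow(sp) == 0) next
      errs <- c(errs, apply(pts, 1, function(p) {
        min(sqrt(rowSums((as.matrix(sp[, 1:3]) -
                            matrix(p, nrow(sp), 3, byrow = TRUE))^2)))
      }))
    }
    mean(pmin(errs, 1))
  }, numeric(1))
  expect_true(all(diff(mean_err) < 0))   # monotone improvement
  # default budget: median localization error below 100 nm
  st <- render_stack(pts, optics_config())
  sp <- detect_spots(st)
  med <- median(apply(pts, 1, function(p) {
    min(sqrt(rowSums((as.matrix(sp[, 1:3]) -
                        matrix(p, nrow(sp), 3, byrow = TRUE))^2)))
  }))
  expect_lt(med, 0.100)
})

test_that("spot counts are conserved on metaphase frames of control renders", {
  # condition of the check: all pairs separated by more than 1 um, so pin
  # the configured metaphase bivalent stretch safely above that
  cfg <- make_preset("control")
  cfg$bivalent_nm$metaphase <- c(1250, 60)
  res <- simulate_cell(cfg, seed = 3)
  pos <- res$bundle$positions
  ph <- res$truth$phases
  frames <- unique(pos$frame[pos$t_s > ph["metaphase_onset"] + 60 &
                               pos$t_s < ph["anaphase_onset"] - 60])
  # restrict to frames where every pair is separated by more than 1 um
  usable <- Filter(function(f) {
    sub <- pos[pos$frame == f, ]
    min(compute_dkt(
      as.matrix(sub[sub$member == 1, c("x_um", "y_um", "z_um")]),
      as.matrix(sub[sub$member == 2, c("x_um", "y_um", "z_um")]))) > 1
  }, frames)
  expect_gte(length(usable), 10L)
  usable <- usable[seq(1, length(usable), length.out = min(20, length(usable)))]
  set.seed(77)
  hits <- 0L
  for (f in usable) {
    sub <- pos[pos$frame == f, ]
    st <- render_stack(as.matrix(sub[, c("x_um", "y_um", "z_um")]), opt)
    if (nrow(detect_spots(st)) == nrow(sub)) hits <- hits + 1L
  }
  expect_gte(hits / length(usable), 0.95)
})

test_that("resolved sister blobs are measured from their two maxima", {
  set.seed(5)
  est <- replicate(12, {
    img <- render_pair_region(950, opt)
    e <- estimate_pair_separation(img)
    expect_true(e$resolved)
    e$distance_nm
  })
  expect_lt(abs(mean(est) - 950), 100)
})

test_that("a single point source reports the censored floor and no elongation", {
  set.seed(6)
  img <- render_pair_region(0, opt)
  e <- estimate_pair_separation(img)
  expect_false(e$resolved)
  expect_true(e$censored)
  expect_equal(e$distance_nm, 150)
  expect_lt(e$elongation, 1.25)
})

test_that("sub-resolution separations near 300 nm are recovered on average", {
  set.seed(8)
  est <- replicate(51, estimate_pair_separation(
    render_pair_region(300, opt))$distance_nm)
  expect_lt(abs(mean(est) - 300), 100)
})

test_that("the separation estimate is monotone in the true separation", {
  set.seed(9)
  ladder <- c(0, 200, 400, 600, 800, 1000, 1200)
  means <- vapply(ladder, function(d) {
    mean(replicate(12, estimate_pair_separation(
      render_pair_region(d, opt))$distance_nm))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("multi-blob regions are rejected", {
  set.seed(10)
  # three emitters spread far apart: three components at half-max
  vx <- 0.1
  n <- 41L
  cc <- (seq_len(n) - (n + 1) / 2) * vx
  img <- matrix(0, n, n)
  for (p in list(c(-1.5, -1.5), c(1.5, 1.5), c(-1.5, 1.5))) {
    img <- img + 1000 * exp(-outer((cc - p[1])^2, (cc - p[2])^2, `+`) /
                              (2 * 0.12^2))
  }
  attr(img, "voxel_nm") <- c(100, 100)
  expect_error(estimate_pair_separation(img), "more than one object")
})

test_that("integrated KT intensity is linear and additive", {
  set.seed(12)
  one <- matrix(c(-2, 0, 0), 1, 3)
  two <- rbind(c(-2, 0, 0), c(2, 0.5, 0.3))
  oo <- optics_config(background = 0, camera_sd = 0)
  st1 <- render_stack(one, oo, noise = FALSE)
  sp1 <- detect_spots(st1)
  i1 <- quantify_kt_intensity(st1, sp1)
  # doubling voxel intensities doubles the total (background 0)
  st_twice <- st1 * 2
  attr(st_twice, "voxel_nm") <- attr(st1, "voxel_nm")
  expect_equal(quantify_kt_intensity(st_twice, sp1), 2 * i1)
  # two identical non-overlapping spots give twice the single-spot value
  st2 <- render_stack(two, oo, noise = FALSE)
  sp2 <- detect_spots(st2)
  expect_equal(nrow(sp2), 2L)
  i2 <- quantify_kt_intensity(st2, sp2)
  expect_lt(abs(i2 - 2 * i1) / (2 * i1), 0.01)
  # no spots: zero with a warning
  expect_warning(z <- quantify_kt_intensity(st1, sp1[0, ]), "no spots")
  expect_equal(z, 0)
})
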