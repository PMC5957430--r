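# Phase scoring and event detection.

test_that("all six boundaries are recovered within 60 s on control cells", {
  hits <- c()
  for (seed in 1:20) {
    res <- simulate_cell(make_preset("control"), seed = seed)
    ann <- score_phases(res$bundle$positions, res$bundle$proxies, 10)
    sc <- setNames(ann$t_s, ann$boundary)
    err <- abs(sc[names(res$truth$phases)] - res$truth$phases)
    hits <- rbind(hits, !is.na(err) & err <= 60)
  }
  # each boundary within 60 s of ground truth in at least 90% of cells
  expect_true(all(colMeans(hits) >= 0.9))
})

test_that("boundaries are monotone and never silently defaulted", {
  res <- cached_cell("colcemid", seed = 4)
  ann <- score_phases(res$bundle$positions, res$bundle$proxies, 10)
  # colcemid: no jump ever crosses the threshold, so the A->B boundary is
  # explicitly unscored
  expect_true(is.na(ann$t_s[ann$boundary == "pm_b_onset"]))
  expect_equal(ann$method[ann$boundary == "pm_b_onset"], "unscored")
  scored <- ann$t_s[!is.na(ann$t_s)]
  expect_true(all(diff(scored) > 0))
})

test_that("APC/C-depleted cells stay in metaphase for more than four hours", {
  res <- cached_cell("fzy_rnai", seed = 2)
  ann <- score_phases(res$bundle$positions, res$bundle$proxies, 10)
  meta <- ann$t_s[ann$boundary == "anaphase_onset"] -
    ann$t_s[ann$boundary == "metaphase_onset"]
  expect_gt(meta / 60, 240)
})

test_that("excursion counting matches a hand-built trajectory", {
  # a KT oscillating 7 times between a pole and the plate
  sp <- structure(list(axis = c(1, 0, 0), center = c(0, 0, 0),
                       oriented = TRUE, window = c(0, 1)),
                  class = "spindle_frame")
  proj <- c(4, 4, 0, 0, 4, 0, 4, 0, 4)   # P E P E P E P -> 7 transits? count:
  # P->E,E->P,P->E,E->P,P->E,E->P = walk: 4(P),4,0(E:1),0,4(P:2),0(3),4(4),0(5),4(6)
  proj <- c(4, 0, 4, 0, 4, 0, 4, 0)       # 7 transits
  tr <- data.frame(t_s = seq_along(proj) * 10, x_um = proj, y_um = 0, z_um = 0)
  got <- detect_excursions(tr, sp)
  expect_equal(got$count, 7L)
  expect_equal(got$count,
               oracle_count_transits(proj, 1.5, 3))
  # plate-resident track: zero
  tr0 <- data.frame(t_s = 1:20 * 10, x_um = 0.3, y_um = 0, z_um = 0)
  expect_equal(detect_excursions(tr0, sp)$count, 0L)
  # leaves the band but never reaches the polar zone: zero
  tr1 <- data.frame(t_s = 1:5 * 10, x_um = c(0, 2.4, 2.0, 0.5, 0), y_um = 0,
                    z_um = 0)
  expect_equal(detect_excursions(tr1, sp)$count, 0L)
  # overlapping zones rejected
  bad <- phase_config(plate_halfwidth_um = 4, polar_inner_um = 3)
  expect_error(detect_excursions(tr0, sp, bad), "geometry")
})

test_that("excursion detector equals the state-machine oracle on simulations", {
  for (seed in c(1, 4)) {
    res <- simulate_cell(make_preset("control"), seed = seed)
    ana <- analyze_cell(res$bundle, ground_truth = res$truth)
    sp <- ana$spindle
    ph <- res$truth$phases
    pos <- res$bundle$positions
    for (p in unique(pos$pair_id)) {
      sub <- pos[pos$pair_id == p, ]
      cen <- aggregate(sub[, c("x_um", "y_um", "z_um")],
                       by = list(frame = sub$frame, t_s = sub$t_s), mean)
      cen <- cen[order(cen$frame), ]
      w <- cen$t_s >= ph["nebd"] & cen$t_s <= ph["anaphase_onset"]
      proj <- as.matrix(cen[w, c("x_um", "y_um", "z_um")]) %*% sp$axis -
        sum(sp$center * sp$axis)
      expect_equal(
        detect_excursions(cen, sp,
                          window_s = unname(ph[c("nebd", "anaphase_onset")]))$count,
        oracle_count_transits(as.numeric(proj), 1.5, 3))
    }
  }
})

test_that("re-orientation events require antagonistic poleward jumps", {
  sp <- structure(list(axis = c(1, 0, 0), center = c(0, 0, 0),
                       oriented = TRUE, window = c(0, 1)),
                  class = "spindle_frame")
  mk_tracks <- function(proj1) {
    n <- length(proj1)
    rbind(
      data.frame(kt_id = "a", pair_id = 1, member = 1, frame = seq_len(n) - 1,
                 t_s = (seq_len(n) - 1) * 10, x_um = proj1, y_um = 0, z_um = 0),
      data.frame(kt_id = "b", pair_id = 1, member = 2, frame = seq_len(n) - 1,
                 t_s = (seq_len(n) - 1) * 10, x_um = 0.4, y_um = 0.4, z_um = 0))
  }
  # jump toward +pole then toward -pole
  proj <- c(0.2, 0.2, 0.2, 1.4, 2.6, 2.6, 2.6, 1.2, -0.6, -2.4, -2.4, -2.4)
  ev <- detect_reorientations(mk_tracks(proj), sp, 10,
                              jump_threshold_um_s = 0.08)
  expect_equal(nrow(ev), 1L)
  # jumps all toward the same pole: nothing
  proj2 <- c(0.2, 0.2, 1.6, 3.0, 3.0, 1.2, 1.2, 2.6, 4.0, 4.0)
  ev2 <- detect_reorientations(mk_tracks(proj2), sp, 10,
                               jump_threshold_um_s = 0.08)
  expect_equal(nrow(ev2), 0L)
})

test_that("scheduled re-orientations are detected about once per control cell", {
  n_det <- 0; n_true <- 0
  for (seed in 1:5) {
    res <- simulate_cell(make_preset("control"), seed = seed + 30)
    ana <- analyze_cell(res$bundle, ground_truth = res$truth)
    n_det <- n_det + nrow(ana$reorientations)
    n_true <- n_true + nrow(res$truth$reorientations)
  }
  expect_equal(n_true, 5L)
  expect_lt(abs(n_det / 5 - 1), 0.5)
})

test_that("breathing events need the configured minimal run of resolved frames", {
  never <- data.frame(frame = 0:99, distance_nm = 150, resolved = FALSE,
                      censored = TRUE)
  got <- detect_breathing(list(never), 10)
  expect_equal(got$n_events, 0L)
  one_frame <- never
  one_frame$resolved[50] <- TRUE
  expect_equal(detect_breathing(list(one_frame), 10)$n_events, 0L)
  two_frames <- never
  two_frames$resolved[50:51] <- TRUE
  two_frames$distance_nm[50:51] <- c(500, 540)
  got2 <- detect_breathing(list(two_frames), 10)
  expect_equal(got2$n_events, 1L)
  expect_equal(got2$events$duration_s, 20)
  expect_equal(got2$events$max_separation_nm, 540)
  expect_error(detect_breathing(list(never)), "cadence|frame_interval")
})

test_that("the breathing detector has no false positives at rate zero", {
  cfg <- make_preset("control", stage = "IK", n_cells = 1L)
  cfg$breathing$rate_per_dot_hour <- 1e-9
  opt <- optics_config()
  n_ev <- 0; dot_hours <- 0
  k <- 0
  series <- list()
  for (seed in 1:28) {
    res <- simulate_cell(cfg, seed = 7000 + seed)
    dot_hours <- dot_hours + res$truth$dot_hours
    pos <- res$bundle$positions
    expect_equal(nrow(res$truth$breathing), 0L)
    for (p in 1:4) {
      sub <- pos[pos$pair_id == p, ]
      m1 <- sub[sub$member == 1, ]; m2 <- sub[sub$member == 2, ]
      sep <- sqrt((m1$x_um - m2$x_um)^2 + (m1$y_um - m2$y_um)^2 +
                    (m1$z_um - m2$z_um)^2)
      k <- k + 1
      series[[k]] <- pair_separation_series(sep, opt,
                                            seed = child_seed(seed, p))
    }
    if (dot_hours >= 100) break
  }
  expect_gte(dot_hours, 100)
  got <- detect_breathing(series, 10)
  expect_equal(got$n_events, 0L)
})

test_that("univalent classification follows the class rules", {
  sp <- structure(list(axis = c(1, 0, 0), center = c(0, 0, 0),
                       oriented = TRUE, window = c(0, 1)),
                  class = "spindle_frame")
  t_telo <- 3000
  t_ma <- t_telo - 600
  tt <- seq(0, 3600, by = 10)
  mk_uni <- function(pair, center_x, sep_nm_series) {
    do.call(rbind, lapply(1:2, function(m) {
      sgn <- if (m == 1) 0.5 else -0.5
      data.frame(kt_id = sprintf("u%d_%d", pair, m), pair_id = pair,
                 member = m, frame = seq_along(tt) - 1, t_s = tt,
                 x_um = center_x + sgn * sep_nm_series / 1000,
                 y_um = 0, z_um = 0)
    }))
  }
  # class I: plate-resident, splits 2 min after the inferred m/a transition
  sep1 <- ifelse(tt >= t_ma + 120, 900, 200)
  # class III: departs poleward 5 min before m/a, never splits
  x3 <- ifelse(tt >= t_ma - 300, 4.5, 0.3)
  # class II: plate-resident, never resolved
  u3 <- mk_uni(3, 0, rep(150, length(tt)))
  u3$x_um <- rep(x3, 2) + rep(c(0.075, -0.075), each = length(tt))
  tracks <- rbind(mk_uni(1, 0.3, sep1),
                  mk_uni(2, 0.2, rep(180, length(tt))),
                  u3)
  cls <- classify_univalents(tracks, t_telo, sp)
  expect_equal(cls$class[cls$pair_id == 1], "I")
  expect_equal(cls$class[cls$pair_id == 2], "II")
  expect_equal(cls$class[cls$pair_id == 3], "III")
  expect_true(cls$split_after_ma[cls$pair_id == 1])
  expect_true(cls$departure_before_ma[cls$pair_id == 3])
  expect_error(classify_univalents(tracks, NA, sp), "telophase")
})

test_that("classification is deterministic and order-independent", {
  res <- cached_cell("mnm", seed = 5)
  ana <- analyze_cell(res$bundle, ground_truth = res$truth)
  expect_false(is.null(ana$classes))
  tracks <- res$bundle$positions
  t_telo <- res$truth$phases["telophase_onset"]
  c1 <- classify_univalents(tracks, t_telo, ana$spindle)
  # permute row order of the input
  set.seed(1)
  c2 <- classify_univalents(tracks[sample.int(nrow(tracks)), ], t_telo,
                            ana$spindle)
  expect_identical(c1$class, c2$class)
})

test_that("genotype summaries aggregate cells correctly", {
  cells <- lapply(1:2, function(seed) {
    res <- cached_cell("control", seed = 2)   # identical cells
    analyze_cell(res$bundle, ground_truth = res$truth)
  })
  s <- summarize_genotypes(cells)
  # two identical cells: zero dispersion on every scored duration
  expect_true(all(s$phases$sd_min == 0, na.rm = TRUE))
  expect_true(all(s$phases$n == 2))
  expect_error(summarize_genotypes(list()), "no analyzed cells")
})

test_that("univalent cells shuttle more than controls", {
  mnm <- analyze_cell(cached_cell("mnm", seed = 6)$bundle,
                      ground_truth = cached_cell("mnm", seed = 6)$truth)
  ctl <- analyze_cell(cached_cell("control", seed = 6)$bundle,
                      ground_truth = cached_cell("control", seed = 6)$truth)
  expect_gt(mean(mnm$excursions$count), mean(ctl$excursions$count))
})
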