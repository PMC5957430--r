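# Track linking, gap closing, and pair assignment.

test_that("noise-free detections yield 8 perfectly identified tracks", {
  res <- cached_cell("control", seed = 3)
  sbf <- spots_from_bundle(res$bundle, noise_sd_um = 0, seed = 1)
  ts <- link_spots(sbf, frame_interval_s = 10)
  expect_equal(length(unique(ts$tracks$track_id)), 8L)
  acc <- track_identity_accuracy(ts, sbf)
  expect_equal(acc$accuracy, 1)
})

test_that("short detection dropouts are gap-closed, not split", {
  # one spot missing for 2 consecutive frames in a clean 12-frame sequence
  frames <- lapply(0:11, function(f) {
    df <- data.frame(x_um = c(0 + 0.01 * f, 5), y_um = c(0, 0), z_um = c(0, 0))
    if (f %in% c(5, 6)) df <- df[2, , drop = FALSE]
    df
  })
  ts <- link_spots(frames, frame_interval_s = 10)
  expect_equal(length(unique(ts$tracks$track_id)), 2L)
  moving <- ts$tracks[abs(ts$tracks$x_um) < 1, ]
  expect_equal(nrow(moving), 12L)           # gap closed
  expect_equal(sum(moving$gap), 2L)
  expect_true(all(moving$frame == 0:11))
})

test_that("stationary spots keep their identities", {
  frames <- lapply(1:10, function(f) {
    data.frame(x_um = c(0, 5), y_um = c(0, 0), z_um = c(0, 0))
  })
  ts <- link_spots(frames, frame_interval_s = 10)
  expect_equal(length(unique(ts$tracks$track_id)), 2L)
  for (id in 1:2) {
    s <- ts$tracks[ts$tracks$track_id == id, ]
    expect_equal(length(unique(s$x_um)), 1L)
  }
  expect_error(link_spots(frames, search_radius_um = 0), "radius")
  expect_error(link_spots(frames[1]), "2 frames")
})

test_that("linking accuracy exceeds 95% on seeded control cells", {
  accs <- c()
  pmb_fail <- 0; other_fail <- 0
  for (seed in 1:20) {
    res <- simulate_cell(make_preset("control"), seed = seed)
    sbf <- spots_from_bundle(res$bundle, noise_sd_um = 0.03, seed = seed + 500)
    ts <- link_spots(sbf, frame_interval_s = 10)
    acc <- track_identity_accuracy(ts, sbf)
    accs <- c(accs, acc$accuracy)
  }
  expect_gte(mean(accs), 0.95)
})

test_that("pair assignment equals the brute-force matching oracle", {
  for (seed in c(2, 5, 9)) {
    res <- simulate_cell(make_preset("control"), seed = seed)
    pos <- res$bundle$positions
    pos$track_id <- as.integer(factor(pos$kt_id))
    tr <- data.frame(track_id = pos$track_id, frame = pos$frame,
                     t_s = pos$t_s, x_um = pos$x_um, y_um = pos$y_um,
                     z_um = pos$z_um, gap = FALSE)
    tset <- structure(list(tracks = tr, frame_interval_s = 10),
                      class = "track_set")
    win <- unname(res$truth$phases[c("pm_b_onset", "anaphase_onset")])
    got <- assign_pairs(tset, window_s = win,
                        anaphase_onset_s = res$truth$phases["anaphase_onset"])
    # oracle: exhaustive enumeration of all 105 matchings
    plist <- split(tr, tr$track_id)
    oracle <- oracle_best_matching(plist, win)
    for (pair in oracle) {
      ids <- as.integer(pair)
      p1 <- got$pairing$pair_id[got$pairing$track_id == ids[1]]
      p2 <- got$pairing$pair_id[got$pairing$track_id == ids[2]]
      expect_equal(p1, p2)
    }
    # and the matching agrees with the simulator's true pairing
    map <- unique(data.frame(tid = pos$track_id, true_pair = pos$pair_id))
    m <- merge(got$pairing, map, by.x = "track_id", by.y = "tid")
    grp <- split(m$pair_id, m$true_pair)
    expect_true(all(vapply(grp, function(x) length(unique(x)) == 1L, TRUE)))
  }
})

test_that("ground-truth pairing mode copies the simulator map exactly", {
  res <- cached_cell("control", seed = 2)
  pos <- res$bundle$positions
  pos$track_id <- as.integer(factor(pos$kt_id))
  tr <- data.frame(track_id = pos$track_id, frame = pos$frame, t_s = pos$t_s,
                   x_um = pos$x_um, y_um = pos$y_um, z_um = pos$z_um,
                   gap = FALSE)
  tset <- structure(list(tracks = tr, frame_interval_s = 10),
                    class = "track_set")
  gt <- unique(data.frame(track_id = pos$track_id, pair_id = pos$pair_id))
  got <- assign_pairs(tset, ground_truth = gt)
  expect_identical(got$pairing$pair_id[order(got$pairing$track_id)],
                   gt$pair_id[order(gt$track_id)])
})

test_that("odd track counts are rejected with the deficit named", {
  frames <- lapply(1:10, function(f) {
    data.frame(x_um = c(0, 5, -5), y_um = c(0, 0, 0), z_um = c(0, 0, 0))
  })
  ts <- link_spots(frames, frame_interval_s = 10)
  expect_error(assign_pairs(ts), "even track count.*3")
})
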