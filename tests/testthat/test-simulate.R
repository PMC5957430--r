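test_that("identical config and seed reproduce trajectories bit for bit", {
  cfg <- make_preset("control")
  r1 <- simulate_cell(cfg, seed = 7)
  r2 <- simulate_cell(cfg, seed = 7)
  expect_identical(r1$bundle$positions, r2$bundle$positions)
  expect_identical(r1$truth$phases, r2$truth$phases)
  r3 <- simulate_cell(cfg, seed = 8)
  expect_false(identical(r1$bundle$positions, r3$bundle$positions))
})

test_that("pinned phase durations conserve the total M I length", {
  ph <- sim_config()$phase_minutes
  for (nm in names(ph$mi)) ph$mi[[nm]][2] <- 0
  cfg <- sim_config(phase_minutes = ph)
  res <- simulate_cell(cfg, seed = 3)
  total_s <- res$truth$phases["interphase_onset"] - res$truth$phases["nebd"]
  expect_equal(unname(total_s),
               60 * sum(vapply(ph$mi, `[`, numeric(1), 1L)))
})

test_that("phase boundaries are strictly increasing in every ground truth", {
  for (g in c("control", "mad2", "mnm", "fzy_rnai")) {
    res <- cached_cell(g, seed = 2)
    ph <- res$truth$phases[!is.na(res$truth$phases)]
    expect_true(all(diff(ph) > 0), info = g)
  }
})

test_that("every KT belongs to exactly one pair", {
  res <- cached_cell("control", seed = 1)
  pm <- res$truth$pairing
  expect_equal(anyDuplicated(pm$kt_id), 0L)
  expect_true(all(table(pm$pair_id) == 2L))
})

test_that("mnm cells carry 8 sister pairs (univalents), controls 4 bivalents", {
  ctrl <- cached_cell("control", seed = 1)
  expect_equal(length(unique(ctrl$truth$pairing$pair_id)), 4L)
  mnm <- cached_cell("mnm", seed = 1)
  expect_equal(length(unique(mnm$truth$pairing$pair_id)), 8L)
  expect_equal(nrow(mnm$truth$pairing), 16L)
  expect_equal(nrow(mnm$truth$classes), 8L)
})

test_that("speeds respect the jump scale: slow in prometaphase A, exceeded in B", {
  cfg <- make_preset("control")
  for (seed in 1:5) {
    res <- simulate_cell(cfg, seed = seed)
    tr <- res$truth
    kin <- kinematic_series(res$bundle$positions, frame_interval_s = 10)
    v <- pmax(kin$v_kt_a, kin$v_kt_b)
    pma <- kin$t_s > tr$phases["nebd"] & kin$t_s <= tr$phases["pm_b_onset"]
    expect_lt(max(v[pma], na.rm = TRUE), cfg$kinematics$jump_speed_um_s)
    pmb <- kin$t_s > tr$phases["pm_b_onset"] &
      kin$t_s <= tr$phases["metaphase_onset"]
    for (p in unique(kin$pair_id)) {
      expect_gt(max(v[pmb & kin$pair_id == p], na.rm = TRUE),
                cfg$kinematics$jump_speed_um_s)
    }
  }
})

test_that("true pair distance never decreases from anaphase to telophase", {
  for (seed in 1:5) {
    res <- simulate_cell(make_preset("control"), seed = seed)
    kin <- kinematic_series(res$bundle$positions, frame_interval_s = 10)
    win <- kin$t_s >= res$truth$phases["anaphase_onset"] &
      kin$t_s <= res$truth$phases["telophase_onset"]
    for (p in unique(kin$pair_id)) {
      d <- kin$d_kt_um[win & kin$pair_id == p]
      expect_true(all(diff(d) >= -1e-9))
    }
  }
})

test_that("breathing events obey the configured Poisson rate over 500+ dot-hours", {
  cfg <- make_preset("control", stage = "IK", n_cells = 1L)
  n_ev <- 0
  dot_hours <- 0
  for (seed in 1:140) {
    res <- simulate_cell(cfg, seed = 4000 + seed)
    n_ev <- n_ev + nrow(res$truth$breathing)
    dot_hours <- dot_hours + res$truth$dot_hours
  }
  expect_gte(dot_hours, 500)
  expected <- cfg$breathing$rate_per_dot_hour * dot_hours
  expect_lt(abs(n_ev - expected), 3 * sqrt(expected))
  # event times inside the simulated interval
  res <- simulate_cell(cfg, seed = 4001)
  ev <- res$truth$breathing
  if (nrow(ev)) {
    expect_true(all(ev$t_start >= res$truth$phases["ik_start"]))
    expect_true(all(ev$t_start + ev$duration_s <= res$truth$phases["ik_end"]))
  }
})

test_that("cysts are near-synchronous with a configurable jitter bound", {
  cfg <- make_preset("control", n_cells = 16L)
  cells <- simulate_cyst(cfg, seed = 5)
  expect_length(cells, 16L)
  nebd <- vapply(cells, function(cl) cl$truth$phases[["nebd"]], numeric(1))
  expect_lt(diff(range(nebd)), 4 * cfg$cyst_jitter_min * 60 + 1e-9)

  cfg0 <- make_preset("control", n_cells = 3L, cyst_jitter_min = 0)
  cells0 <- simulate_cyst(cfg0, seed = 5)
  expect_identical(cells0[[1]]$truth$phases, cells0[[2]]$truth$phases)
  expect_identical(cells0[[2]]$truth$phases, cells0[[3]]$truth$phases)

  one <- simulate_cyst(make_preset("control", n_cells = 1L), seed = 5)
  expect_length(one, 1L)
  cfgbad <- make_preset("control")
  cfgbad$n_cells <- 0L
  expect_error(simulate_cyst(cfgbad, seed = 1), "n_cells")
})

test_that("colcemid cells neither jump nor congress", {
  res <- cached_cell("colcemid", seed = 3)
  expect_true(is.na(res$truth$phases["pm_b_onset"]))
  kin <- kinematic_series(res$bundle$positions, frame_interval_s = 10)
  expect_lt(max(pmax(kin$v_kt_a, kin$v_kt_b), na.rm = TRUE), 0.06)
})

test_that("M II sister separation follows the measured time course", {
  seps <- sapply(1:8, function(seed) {
    res <- simulate_cell(make_preset("control", stage = "MII"), seed = seed)
    kin <- kinematic_series(res$bundle$positions, frame_interval_s = 10)
    ph <- res$truth$phases
    t18 <- ph["nebd"] + 18 * 60
    c(start = mean(kin$d_kt_um[abs(kin$t_s - ph["nebd"]) < 30]),
      t18 = mean(kin$d_kt_um[abs(kin$t_s - t18) < 30]))
  })
  # ~300 nm at NEBD II rising to ~950 nm once all dyads are bi-oriented
  expect_lt(abs(mean(seps["start", ]) - 0.30), 0.12)
  expect_lt(abs(mean(seps["t18", ]) - 0.95), 0.12)
})
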