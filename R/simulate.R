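# Phase-switched stochastic model of kinetochore motion in spermatocyte
# meiosis. Units of motion are "KT pairs": a bivalent (two homolog KT dots)
# in M I, a conjoined sister-KT dot in interkinesis, a dyad (two sister KTs)
# in M II, or a univalent (conjoined sisters) in mnm/tef-like cells. Each
# unit has an anchor path made of scripted legs (Poisson-like timed ballistic
# jumps toward a pole, slower congression moves back to the metaphase plate)
# with Ornstein-Uhlenbeck jitter superimposed, plus an intra-pair axis and
# separation model that produces the published V/A/D signatures.

# ---- timeline ---------------------------------------------------------------

# Phase-duration variance is split between a cyst-shared component and a
# per-cell component (fractions cyst_var_frac / 1 - cyst_var_frac of the
# configured variance), reflecting that cells of one cyst progress almost
# synchronously while the published dispersions are per-cell. With
# cyst_jitter_min = 0 the per-cell component is dropped, so all cells of a
# cyst share identical boundaries.
cyst_var_frac <- 0.3

draw_phase_durations <- function(cfg, stage, sd_scale = 1, base = NULL) {
  ph <- cfg$phase_minutes[[if (stage == "MII") "mii" else "mi"]]
  d <- vapply(seq_along(ph), function(i) {
    m <- ph[[i]][1]; s <- ph[[i]][2] * sd_scale
    mu <- if (is.null(base)) m else base[[i]] / 60
    if (s == 0) return(mu * 60)
    60 * rnorm_trunc(1, mu, s, lower = max(0.2 * m, mu - 2.5 * s),
                     upper = mu + 2.5 * s)
  }, numeric(1))
  stats::setNames(d, names(ph))
}

draw_ik_duration <- function(cfg, sd_scale = 1, base = NULL) {
  ik_ms <- cfg$phase_minutes$ik
  m <- ik_ms[1]; s <- ik_ms[2] * sd_scale
  mu <- if (is.null(base)) m else base / 60
  if (s == 0) return(mu * 60)
  60 * rnorm_trunc(1, mu, s, lower = max(0.2 * m, mu - 2.5 * s),
                   upper = mu + 2.5 * s)
}

# boundaries in seconds on the recording clock (t = 0 at first frame)
make_boundaries <- function(cfg, stage, offset_min = 0, durations = NULL,
                            ik_duration = NULL) {
  pre <- max(30, (cfg$pre_nebd_min + offset_min) * 60)
  if (stage == "IK") {
    dur <- ik_duration %||% draw_ik_duration(cfg)
    return(list(ik_start = pre, ik_end = pre + dur,
                t_end = pre + dur + 60 * cfg$post_min))
  }
  d <- durations %||% draw_phase_durations(cfg, stage)
  b <- list(nebd = pre,
            pm_b_onset = pre + d[["pm_a"]],
            metaphase_onset = pre + d[["pm_a"]] + d[["pm_b"]],
            anaphase_onset = pre + d[["pm_a"]] + d[["pm_b"]] + d[["metaphase"]],
            telophase_onset = pre + sum(d[c("pm_a", "pm_b", "metaphase",
                                            "anaphase")]),
            interphase_onset = pre + sum(d))
  b$t_end <- b$interphase_onset + 60 * cfg$post_min
  b
}

# ---- unit scripts -----------------------------------------------------------

polar_target <- function(sign, geom) {
  c(sign * stats::runif(1, 3.5, 0.8 * geom$pole_distance_um / 2),
    stats::runif(1, -2.2, 2.2), stats::runif(1, -2.2, 2.2))
}

plate_target <- function(geom) {
  hw <- geom$plate_halfwidth_um
  c(stats::runif(1, -0.55, 0.55) * hw,
    stats::runif(1, -1.5, 1.5), stats::runif(1, -1.5, 1.5))
}

# Build the scripted anchor path of one unit between its first jump and its
# settling into the plate. `loops` = number of extra pole-and-back trips;
# `reor` marks the unit carrying the scheduled re-orientation event.
build_unit_legs <- function(p0, sign, first_jump, settle, loops, reor,
                            cfg, geom, final_plate = NULL) {
  kin <- cfg$kinematics
  jump_v <- function() kin$jump_speed_um_s * stats::runif(1, 1.25, 1.6)
  # univalents keep shuttling rapidly in both directions; bivalents return
  # to the plate at the slower congression speed
  ret_v <- function() if (cfg$univalents) {
    kin$jump_speed_um_s * stats::runif(1, 0.95, 1.2)
  } else kin$congression_speed_um_s
  legs <- list()       # each: list(target, speed, kind)
  if (isTRUE(reor)) {
    # move to the plate first, then jump beyond the band on the far side and
    # later back past the plate toward the home pole: two antagonistically
    # directed supra-threshold jumps that add no completed zone transits,
    # followed by the normal itinerary
    legs[[length(legs) + 1L]] <- list(target = plate_target(geom),
                                      speed = kin$congression_speed_um_s,
                                      kind = "congress")
    legs[[length(legs) + 1L]] <- list(
      target = c(-sign * stats::runif(1, 2.0, 2.5),
                 stats::runif(1, -1, 1), stats::runif(1, -1, 1)),
      speed = jump_v(), kind = "reor1")
    legs[[length(legs) + 1L]] <- list(
      target = c(sign * stats::runif(1, 2.2, 2.7),
                 stats::runif(1, -1, 1), stats::runif(1, -1, 1)),
      speed = jump_v(), kind = "reor2")
    for (k in seq_len(loops)) {
      legs[[length(legs) + 1L]] <- list(target = polar_target(sign, geom),
                                        speed = jump_v(), kind = "jump")
      legs[[length(legs) + 1L]] <- list(target = plate_target(geom),
                                        speed = ret_v(), kind = "congress")
    }
    if (loops == 0L) {
      legs[[length(legs) + 1L]] <- list(target = final_plate %||%
                                          plate_target(geom),
                                        speed = kin$congression_speed_um_s,
                                        kind = "congress")
    }
  } else {
    # the first jump must span at least two full frame intervals at a speed
    # above the jump scale, or it would be invisible at the acquisition
    # cadence: draw a sufficiently distant target and fit the speed
    tgt <- polar_target(sign, geom)
    for (try in 1:40) {
      if (vec_norm(tgt - p0) >= 2.8) break
      tgt <- polar_target(sign, geom)
    }
    v1 <- min(kin$jump_speed_um_s * 1.6,
              max(kin$jump_speed_um_s * 1.06, vec_norm(tgt - p0) / 21))
    legs[[length(legs) + 1L]] <- list(target = tgt, speed = v1,
                                      kind = "jump")
    if (loops > 0) {
      for (k in seq_len(loops)) {
        legs[[length(legs) + 1L]] <- list(target = plate_target(geom),
                                          speed = ret_v(), kind = "congress")
        legs[[length(legs) + 1L]] <- list(target = polar_target(sign, geom),
                                          speed = jump_v(), kind = "jump")
      }
    }
    legs[[length(legs) + 1L]] <- list(target = plate_target(geom),
                                      speed = kin$congression_speed_um_s,
                                      kind = "congress")
  }

  leg_time <- function(lg) {
    p <- p0
    tot <- 0
    for (l in lg) {
      tot <- tot + vec_norm(l$target - p) / l$speed
      p <- l$target
    }
    tot
  }
  avail <- settle - first_jump
  # drop pole-and-back loops that no longer fit in a short prometaphase B
  while (leg_time(legs) > avail && length(legs) > 2L) {
    kinds <- vapply(legs, function(l) l$kind, "")
    cand <- which(kinds[-length(kinds)] == "congress" & kinds[-1] == "jump")
    if (!length(cand)) {
      cand <- which(kinds[-length(kinds)] == "jump" & kinds[-1] == "congress")
    }
    if (!length(cand)) break
    legs <- legs[-c(cand[1], cand[1] + 1L)]
  }
  if (legs[[length(legs)]]$kind != "congress") {
    # never leave a pair stranded off the plate
    legs[[length(legs) + 1L]] <- list(target = plate_target(geom),
                                      speed = kin$congression_speed_um_s,
                                      kind = "congress")
  }
  if (!is.null(final_plate)) legs[[length(legs)]]$target <- final_plate
  # a residual overrun (short prometaphase B) is absorbed by moving faster,
  # so every pair still settles on schedule
  overrun <- leg_time(legs) / avail
  if (is.finite(overrun) && overrun > 1) {
    legs <- lapply(legs, function(l) {
      l$speed <- l$speed * overrun * 1.02
      l
    })
  }
  tot <- leg_time(legs)
  n_gap <- length(legs) - 1L
  dwell <- if (n_gap > 0) max(0, (avail - tot)) / n_gap else 0

  # assemble waypoints
  wp_t <- first_jump
  wp <- list(list(t = first_jump, p = p0))
  jumps <- list()
  p <- p0
  for (i in seq_along(legs)) {
    l <- legs[[i]]
    dur <- vec_norm(l$target - p) / l$speed
    if (i == length(legs) && n_gap == 0L) {
      dur <- max(dur, avail)   # single-leg script stretched to fit
    }
    t1 <- wp_t + dur
    wp[[length(wp) + 1L]] <- list(t = t1, p = l$target)
    if (l$kind != "congress") {
      jumps[[length(jumps) + 1L]] <- data.frame(
        t0 = wp_t, t1 = t1, kind = l$kind,
        dx = l$target[1] - p[1], dy = l$target[2] - p[2],
        dz = l$target[3] - p[3])
    }
    p <- l$target
    wp_t <- t1
    if (i < length(legs)) {
      # the two antagonistic re-orientation jumps must stay distinct events
      gd <- if (l$kind == "reor1") max(dwell, 30) else dwell
      if (gd > 0) {
        wp_t <- wp_t + gd
        wp[[length(wp) + 1L]] <- list(t = wp_t, p = p)
      }
    }
  }
  list(waypoints = wp, jumps = if (length(jumps)) do.call(rbind, jumps) else NULL,
       final = p)
}

ou_path <- function(n, sigma, dt, tau = 30) {
  # AR(1) discretization of an OU process; sigma may be per-frame
  if (n < 2L) return(numeric(n))
  rho <- exp(-dt / tau)
  innov_sd <- rep(sigma, length.out = n) * sqrt(1 - rho^2)
  x <- numeric(n)
  e <- stats::rnorm(n)
  for (i in 2:n) x[i] <- rho * x[i - 1] + innov_sd[i] * e[i]
  x
}

# ---- single cell ------------------------------------------------------------

#' Simulate one spermatocyte
#'
#' Generates ground-truth kinetochore trajectories for a single cell
#' progressing through one stage (M I, interkinesis, or M II) under the
#' given configuration. The motion model is phase-switched: concerted slow
#' drift with OU jitter during prometaphase A, ballistic poleward jumps and
#' slower plate-directed congression moves during prometaphase B,
#' low-amplitude jitter with the intra-pair axis aligned to the spindle
#' during metaphase, deterministic poleward separation during anaphase.
#' Sister-centromere breathing events are injected during interkinesis at
#' the configured Poisson rate.
#'
#' @param config a [sim_config()]
#' @param seed integer; fixes all randomness (same config + seed gives
#'   bitwise-identical output)
#' @param cell_id identifier stored in the output tables
#' @return a list with components `bundle` (class `kt_bundle`: per-frame
#'   true KT positions, proxy signals, calibration) and `truth` (class
#'   `kt_truth`: phase boundaries, pairing map, event log)
#' @export
simulate_cell <- function(config, seed, cell_id = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  bnd <- make_boundaries(config, config$stage)
  simulate_cell_impl(config, bnd, cell_id, seed)
}

#' Simulate a cyst of near-synchronous spermatocytes
#'
#' Cells within a cyst progress almost synchronously: phase durations are
#' drawn once per cyst and shared by its cells, while each cell receives a
#' small clock offset (s.d. `cyst_jitter_min` minutes, clamped to twice the
#' s.d.) and its own independent trajectory noise. With
#' `cyst_jitter_min = 0` all cells share identical phase boundaries.
#'
#' @param config a [sim_config()]; `n_cells` sets the cyst size
#' @param seed integer root seed; per-cell child seeds are derived with
#'   [child_seed()]
#' @return a list of length `n_cells`; each element as in [simulate_cell()]
#' @export
simulate_cyst <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  set.seed(child_seed(seed, 0L))
  jit <- config$cyst_jitter_min
  ik_stage <- config$stage == "IK"
  base_d <- if (ik_stage) NULL else {
    draw_phase_durations(config, config$stage, sd_scale = sqrt(cyst_var_frac))
  }
  base_ik <- if (ik_stage) {
    draw_ik_duration(config, sd_scale = sqrt(cyst_var_frac))
  } else NULL
  offsets <- if (jit > 0) {
    rnorm_trunc(config$n_cells, 0, jit, lower = -2 * jit, upper = 2 * jit)
  } else rep(0, config$n_cells)
  offsets <- offsets - min(offsets)    # keep the pre-NEBD pad non-negative
  lapply(seq_len(config$n_cells), function(i) {
    set.seed(child_seed(seed, i))
    if (jit > 0) {
      d <- if (ik_stage) NULL else {
        draw_phase_durations(config, config$stage,
                             sd_scale = sqrt(1 - cyst_var_frac), base = base_d)
      }
      ikd <- if (ik_stage) {
        draw_ik_duration(config, sd_scale = sqrt(1 - cyst_var_frac),
                         base = base_ik)
      } else NULL
    } else {
      d <- base_d
      ikd <- base_ik
    }
    bnd <- make_boundaries(config, config$stage, offset_min = offsets[i],
                           durations = d, ik_duration = ikd)
    simulate_cell_impl(config, bnd, cell_id = i, seed = child_seed(seed, i))
  })
}

simulate_cell_impl <- function(cfg, bnd, cell_id, seed) {
  if (cfg$stage == "IK") return(simulate_ik_cell(cfg, bnd, cell_id, seed))
  geom <- cfg$geometry
  kin <- cfg$kinematics
  dt <- cfg$frame_interval_s
  n_frames <- floor(bnd$t_end / dt) + 1L
  tt <- (seq_len(n_frames) - 1L) * dt

  n_units <- if (cfg$univalents && cfg$stage == "MI") 8L else 4L
  member_kind <- if (cfg$stage == "MI" && !cfg$univalents) "homolog" else "sister"

  # unit classes (univalent cells only)
  classes <- rep(NA_character_, n_units)
  if (cfg$univalents) {
    classes <- sample(names(cfg$class_fractions), n_units, replace = TRUE,
                      prob = cfg$class_fractions)
  }

  signs <- rep(c(1, -1), length.out = n_units)[sample.int(n_units)]
  v_drift <- normalize(stats::rnorm(3)) * kin$drift_speed_um_s

  # timing of first jumps and plate settling
  do_jumps <- kin$jumps_enabled
  do_congress <- kin$congression_enabled
  pm_b0 <- bnd$pm_b_onset
  t_meta <- bnd$metaphase_onset

  # excursion loop counts; plate-enders do 1 + 2*loops completed transits,
  # pole-enders (class III univalents) 2 + 2*loops
  pole_ender <- cfg$univalents & classes == "III"
  loops_target <- ifelse(pole_ender, (cfg$excursions_mean - 2) / 2,
                         (cfg$excursions_mean - 1) / 2)
  loops <- stats::rpois(n_units, pmax(0, loops_target))

  n_reor <- if (do_jumps) min(cfg$reorientations_per_cell, n_units - 1L) else 0L
  reor_units <- if (n_reor > 0) sample.int(n_units, n_reor) else integer(0)

  # pairs with more pole-and-back trips start jumping earlier and settle
  # later, so their itineraries are not squeezed out of prometaphase B
  busy_first <- order(loops, stats::runif(n_units), decreasing = TRUE)
  first_jump <- numeric(n_units)
  first_jump[busy_first] <- pm_b0 +
    sort(stats::runif(n_units, 0, min(60, 0.2 * (t_meta - pm_b0))))
  # a non-reorientation unit jumps right at the boundary (the reorientation
  # itinerary starts with a slow congression move, not a jump)
  non_reor <- setdiff(busy_first, reor_units)
  first_jump[non_reor[1L]] <- pm_b0
  settle_gap <- stats::runif(n_units, 25, 55)
  offsets <- cumsum(settle_gap) - settle_gap[1]
  settle <- numeric(n_units)
  settle[busy_first] <- t_meta - offsets
  settle[which.max(settle)] <- t_meta            # last pair defines onset

  # starting positions near the nuclear envelope, on the home-pole side;
  # bivalents start widely spaced, so draw jointly with a minimal spacing
  starts <- matrix(NA_real_, n_units, 3)
  for (i in seq_len(n_units)) {
    for (try in 1:60) {
      cand <- c(signs[i] * stats::runif(1, 3.2, 4.4),
                stats::runif(1, -2.0, 2.0), stats::runif(1, -2.0, 2.0))
      if (i == 1L) break
      dmin <- min(sqrt(rowSums((starts[seq_len(i - 1L), , drop = FALSE] -
                                matrix(cand, i - 1L, 3, byrow = TRUE))^2)))
      if (dmin >= 1.8) break
    }
    starts[i, ] <- cand
  }

  # final plate positions are drawn jointly with a minimal spacing, so that
  # congressed pairs spread across the plate as in real cells instead of
  # crowding below optical resolution
  plate_slots <- matrix(NA_real_, n_units, 3)
  for (i in seq_len(n_units)) {
    for (try in 1:60) {
      cand <- c(stats::runif(1, -0.55, 0.55) * geom$plate_halfwidth_um,
                stats::runif(1, -2.2, 2.2), stats::runif(1, -2.2, 2.2))
      if (i == 1L) break
      dmin <- min(sqrt(rowSums((plate_slots[seq_len(i - 1L), , drop = FALSE] -
                                matrix(cand, i - 1L, 3, byrow = TRUE))^2)))
      if (dmin >= 1.5) break
    }
    plate_slots[i, ] <- cand
  }

  unit_scripts <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    p_drift <- starts[i, ] + v_drift * (first_jump[i] - bnd$nebd)
    wps <- list(list(t = 0, p = starts[i, ]),
                list(t = bnd$nebd, p = starts[i, ]))
    jumps <- NULL
    final <- p_drift
    if (do_jumps) {
      sc <- build_unit_legs(p_drift, signs[i], first_jump[i], settle[i],
                            loops[i], i %in% reor_units, cfg, geom,
                            final_plate = plate_slots[i, ])
      wps <- c(wps, sc$waypoints)
      jumps <- sc$jumps
      final <- sc$final
    } else if (do_congress) {
      tgt <- plate_slots[i, ]
      t_go <- max(bnd$nebd + 60,
                  settle[i] - vec_norm(tgt - p_drift) / kin$congression_speed_um_s)
      p_go <- starts[i, ] + v_drift * (t_go - bnd$nebd)
      wps <- c(wps, list(list(t = t_go, p = p_go), list(t = settle[i], p = tgt)))
      final <- tgt
    } else {
      # no congression: limited concerted drift, then positional jitter only
      t_stop <- bnd$pm_b_onset
      p_stop <- starts[i, ] + v_drift * (t_stop - bnd$nebd)
      wps <- c(wps, list(list(t = t_stop, p = p_stop)))
      final <- p_stop
    }
    # class III univalents leave the plate for a pole before the inferred
    # metaphase-to-anaphase transition
    dep_time <- NA_real_
    if (cfg$univalents && classes[i] == "III" && do_jumps) {
      t_ma <- bnd$telophase_onset - cfg$ma_offset_min * 60
      dep_time <- t_ma - 60 * stats::runif(1, 3, 8)
      dep_tgt <- polar_target(signs[i], geom)
      dep_dur <- vec_norm(dep_tgt - final) / kin$congression_speed_um_s
      wps <- c(wps, list(list(t = max(dep_time, settle[i] + 30), p = final),
                         list(t = max(dep_time, settle[i] + 30) + dep_dur,
                              p = dep_tgt)))
      final <- dep_tgt
    }
    wps <- c(wps, list(list(t = bnd$t_end + dt, p = final)))
    unit_scripts[[i]] <- list(wp = wps, jumps = jumps, final = final,
                              dep_time = dep_time)
  }

  # per-unit separation (um) and axis model -----------------------------------
  has_anaphase <- !cfg$univalents &&
    !(cfg$genotype %in% c("colcemid", "spc105_rnai"))
  sep_model <- draw_separations(cfg, bnd, n_units, classes, first_jump, settle)

  positions <- vector("list", n_units)
  excursion_counts <- integer(n_units)
  reor_log <- list()

  for (i in seq_len(n_units)) {
    sc <- unit_scripts[[i]]
    wt <- vapply(sc$wp, function(w) w$t, numeric(1))
    wpm <- t(vapply(sc$wp, function(w) w$p, numeric(3)))
    keep <- !duplicated(wt)
    anchor <- cbind(
      stats::approx(wt[keep], wpm[keep, 1], xout = tt, rule = 2)$y,
      stats::approx(wt[keep], wpm[keep, 2], xout = tt, rule = 2)$y,
      stats::approx(wt[keep], wpm[keep, 3], xout = tt, rule = 2)$y)

    # OU jitter, phase dependent; frozen from anaphase onset so that true
    # pair separation grows monotonically while poleward movement lasts
    sig <- rep(kin$jitter_prometaphase_um, n_frames)
    sig[tt >= settle[i]] <- kin$jitter_metaphase_um
    if (has_anaphase) sig[tt >= bnd$anaphase_onset] <- 0
    jit <- cbind(ou_path(n_frames, sig, dt), ou_path(n_frames, sig, dt),
                 ou_path(n_frames, sig, dt))
    jit[sig == 0, ] <- 0
    anchor <- anchor + jit

    # intra-pair axis: misaligned before bi-orientation, aligned (with small
    # wobble) afterwards; during jumps the axis follows the motion direction
    ax <- unit_axis_series(tt, settle[i], sc$jumps, kin)

    sep <- sep_model$series[[i]]
    p1 <- anchor + 0.5 * sep * ax
    p2 <- anchor - 0.5 * sep * ax

    # scheduled re-orientation: between the two antagonistic jumps the
    # partner KT may be pulled slightly toward the opposite pole
    if (i %in% reor_units && !is.null(sc$jumps)) {
      j1 <- sc$jumps[sc$jumps$kind == "reor1", , drop = FALSE]
      j2 <- sc$jumps[sc$jumps$kind == "reor2", , drop = FALSE]
      if (nrow(j1) && nrow(j2)) {
        biorient <- stats::runif(1) < cfg$reorientation_biorient_frac
        if (biorient) {
          win <- tt > j1$t1[1] & tt < j2$t0[1]
          p2[win, 1] <- p2[win, 1] + signs[i] * 0.3
        }
        reor_log[[length(reor_log) + 1L]] <- data.frame(
          pair_id = i, kt_member = 1L, t_jump1 = j1$t0[1], t_jump2 = j2$t0[1],
          transient_biorientation = biorient)
      }
    }

    # anaphase: members move deterministically to opposite poles
    if (has_anaphase) {
      ia <- which(tt >= bnd$anaphase_onset)
      if (length(ia)) {
        i0 <- ia[1]
        pole_x <- geom$pole_distance_um / 2 - 0.8
        # the intra-pair axis points into the +x hemisphere, so member 1 is
        # the pole-facing KT on the + side and segregates to the + pole
        for (mm in 1:2) {
          pm <- if (mm == 1) p1 else p2
          dest_sign <- if (mm == 1) 1 else -1
          x0 <- pm[i0, 1]
          trav <- pmin(kin$anaphase_speed_um_s * (tt[ia] - tt[i0]),
                       abs(dest_sign * pole_x - x0))
          pm[ia, 1] <- x0 + sign(dest_sign * pole_x - x0) * trav
          pm[ia, 2] <- pm[i0, 2]
          pm[ia, 3] <- pm[i0, 3]
          if (mm == 1) p1 <- pm else p2 <- pm
        }
      }
    }

    # excursions are counted through the (metaphase-like) congressed period:
    # up to metaphase onset for pairs that settle, up to the inferred
    # metaphase-to-anaphase transition for univalent cells where class III
    # univalents still depart poleward late
    exc_end <- if (cfg$univalents) {
      bnd$telophase_onset - cfg$ma_offset_min * 60
    } else t_meta + 1
    excursion_counts[i] <- count_zone_transits(anchor[, 1],
                                               geom$plate_halfwidth_um,
                                               geom$pole_distance_um / 4,
                                               tt, c(bnd$nebd, exc_end))
    positions[[i]] <- list(p1 = p1, p2 = p2)
  }

  bundle <- assemble_bundle(cfg, bnd, cell_id, tt, positions, member_kind)
  phases <- c(nebd = bnd$nebd,
              pm_b_onset = if (do_jumps) pm_b0 else NA_real_,
              metaphase_onset = if (do_jumps && do_congress && !cfg$univalents)
                t_meta else if (cfg$univalents) t_meta else NA_real_,
              anaphase_onset = if (has_anaphase) bnd$anaphase_onset else NA_real_,
              telophase_onset = bnd$telophase_onset,
              interphase_onset = bnd$interphase_onset)
  truth <- structure(list(
    phases = phases,
    stage = cfg$stage,
    genotype = cfg$genotype,
    cell_id = cell_id,
    seed = seed,
    pairing = bundle$pairing,
    excursions = data.frame(pair_id = seq_len(n_units),
                            count = excursion_counts),
    reorientations = if (length(reor_log)) do.call(rbind, reor_log) else
      data.frame(pair_id = integer(0), kt_member = integer(0),
                 t_jump1 = numeric(0), t_jump2 = numeric(0),
                 transient_biorientation = logical(0)),
    breathing = data.frame(pair_id = integer(0), t_start = numeric(0),
                           duration_s = numeric(0), amplitude_nm = numeric(0)),
    classes = if (cfg$univalents)
      data.frame(pair_id = seq_len(n_units), class = classes) else NULL,
    separation = sep_model$truth,
    spindle_axis = c(1, 0, 0),
    pole_distance_um = geom$pole_distance_um
  ), class = "kt_truth")
  list(bundle = bundle, truth = truth)
}

# separation (member-to-member distance) series per unit, in um
draw_separations <- function(cfg, bnd, n_units, classes, first_jump, settle) {
  dt <- cfg$frame_interval_s
  n_frames <- floor(bnd$t_end / dt) + 1L
  tt <- (seq_len(n_frames) - 1L) * dt
  series <- vector("list", n_units)
  truth <- list()
  wob <- function(sd_um) ou_path(n_frames, sd_um, dt, tau = 60)

  for (i in seq_len(n_units)) {
    if (cfg$stage == "MI" && !cfg$univalents) {
      rest <- rnorm_trunc(1, cfg$bivalent_nm$rest[1], cfg$bivalent_nm$rest[2],
                          lower = 200) / 1000
      meta <- rnorm_trunc(1, cfg$bivalent_nm$metaphase[1],
                          cfg$bivalent_nm$metaphase[2], lower = 600) / 1000
      base <- stats::approx(c(0, settle[i] - 90, settle[i], bnd$t_end + dt),
                            c(rest, rest, meta, meta), xout = tt, rule = 2)$y
      series[[i]] <- pmax(0.15, base + wob(0.03))
      truth[[i]] <- list(rest_um = rest, metaphase_um = meta)
    } else if (cfg$stage == "MII") {
      s0 <- rnorm_trunc(1, cfg$separation_nm$nebd2[1],
                        cfg$separation_nm$nebd2[2], lower = 50) / 1000
      s5 <- max(s0, rnorm_trunc(1, cfg$separation_nm$five_min[1],
                                cfg$separation_nm$five_min[2], lower = 60) / 1000)
      pl <- rnorm_trunc(1, cfg$separation_nm$plateau[1],
                        cfg$separation_nm$plateau[2], lower = 500) / 1000
      base <- stats::approx(
        c(0, bnd$nebd, bnd$nebd + 300, first_jump[i], settle[i], bnd$t_end + dt),
        c(s0, s0, s5, s5, pl, pl), xout = tt, rule = 2)$y
      series[[i]] <- pmax(0.05, base + wob(0.02))
      truth[[i]] <- list(nebd2_um = s0, five_min_um = s5, plateau_um = pl)
    } else {
      # univalent (conjoined sisters) in M I
      cls <- classes[i]
      t_ma <- bnd$telophase_onset - cfg$ma_offset_min * 60
      baseline <- rnorm_trunc(1, 0.15, 0.04, lower = 0.05)
      if (cls == "I") {
        stretch <- rnorm_trunc(1, 0.33, 0.05, lower = 0.2)  # elongated dot
        t_split <- t_ma + 60 * stats::runif(1, 0, 5)
        amp <- stats::runif(1, 0.8, 1.3)
        base <- stats::approx(
          c(0, settle[i], settle[i] + 60, t_split, t_split + 180,
            t_split + 480, min(t_split + 720, bnd$t_end), bnd$t_end + dt),
          c(baseline, baseline, stretch, stretch, amp, amp, baseline, baseline),
          xout = tt, rule = 2)$y
        truth[[i]] <- list(class = "I", t_split = t_split, amplitude_um = amp)
      } else {
        base <- rep(baseline, n_frames)
        truth[[i]] <- list(class = cls, t_split = NA_real_)
      }
      series[[i]] <- pmax(0.03, base + wob(0.015))
    }
  }
  list(series = series, truth = truth)
}

# intra-pair axis unit vectors over time, n x 3
unit_axis_series <- function(tt, settle, jumps, kin) {
  n <- length(tt)
  dt <- if (n > 1) tt[2] - tt[1] else 10
  theta_pre <- stats::runif(1, kin$precapture_min_angle_deg, 85) * pi / 180
  phi_pre <- stats::runif(1, 0, 2 * pi)
  theta_meta <- (2 + 6 * abs(stats::rnorm(1))) * pi / 180
  phi_meta <- stats::runif(1, 0, 2 * pi)
  w_pre <- tan(theta_pre) * c(cos(phi_pre), sin(phi_pre))
  w_meta <- tan(theta_meta) * c(cos(phi_meta), sin(phi_meta))
  wy <- stats::approx(c(0, settle - 90, settle, max(tt) + dt),
                      c(w_pre[1], w_pre[1], w_meta[1], w_meta[1]),
                      xout = tt, rule = 2)$y
  wz <- stats::approx(c(0, settle - 90, settle, max(tt) + dt),
                      c(w_pre[2], w_pre[2], w_meta[2], w_meta[2]),
                      xout = tt, rule = 2)$y
  wob_sd <- ifelse(tt < settle, 0.15, 0.05)
  wy <- wy + ou_path(n, wob_sd, dt, tau = 60)
  wz <- wz + ou_path(n, wob_sd, dt, tau = 60)
  ax <- cbind(1, wy, wz)
  ax <- ax / sqrt(rowSums(ax^2))
  # during jumps the axis rotates into the motion direction (the leading KT
  # pulls the pair around) and relaxes back afterwards; the rotation is
  # blended over ~25 s so member paths stay smooth
  if (!is.null(jumps)) {
    for (k in seq_len(nrow(jumps))) {
      d <- c(jumps$dx[k], jumps$dy[k], jumps$dz[k])
      d <- normalize(d) * sign(d[1] + 1e-12)
      w <- pmin(1, pmax(0, (tt - jumps$t0[k] + 10) / 25)) *
        pmin(1, pmax(0, (jumps$t1[k] + 15 - tt) / 25))
      blend <- w > 0
      if (any(blend)) {
        m <- ax[blend, , drop = FALSE] * (1 - w[blend]) +
          matrix(d, sum(blend), 3, byrow = TRUE) * w[blend]
        ax[blend, ] <- m / sqrt(rowSums(m^2))
      }
    }
  }
  ax
}

# completed transits between the equatorial band and the polar zones,
# evaluated on axial positions sampled at frames (the simulator-side truth
# uses the same state machine the detector is tested against)
count_zone_transits <- function(x_axial, plate_halfwidth, polar_inner,
                                tt, window) {
  use <- tt >= window[1] & tt <= window[2]
  x <- x_axial[use]
  zone <- ifelse(abs(x) <= plate_halfwidth, 1L,
                 ifelse(abs(x) >= polar_inner, 2L, 0L))
  state <- 0L
  count <- 0L
  for (z in zone) {
    if (z == 0L) next
    if (state != 0L && z != state) count <- count + 1L
    state <- z
  }
  count
}

# interkinesis cell: four conjoined sister-centromere dots with breathing
simulate_ik_cell <- function(cfg, bnd, cell_id, seed) {
  dt <- cfg$frame_interval_s
  n_frames <- floor(bnd$t_end / dt) + 1L
  tt <- (seq_len(n_frames) - 1L) * dt
  n_units <- 4L
  br <- cfg$breathing
  ik_hours <- (bnd$ik_end - bnd$ik_start) / 3600

  positions <- vector("list", n_units)
  ev_log <- list()
  for (i in seq_len(n_units)) {
    anchor0 <- c(stats::runif(1, -2.5, 2.5), stats::runif(1, -2.5, 2.5),
                 stats::runif(1, -1.5, 1.5))
    jit <- cbind(ou_path(n_frames, 0.04, dt), ou_path(n_frames, 0.04, dt),
                 ou_path(n_frames, 0.04, dt))
    anchor <- matrix(anchor0, n_frames, 3, byrow = TRUE) + jit

    baseline <- rnorm_trunc(1, br$baseline_nm[1], br$baseline_nm[2],
                            lower = 20) / 1000
    sep <- rep(baseline, n_frames)

    # Poisson-timed breathing events, non-overlapping
    n_ev <- stats::rpois(1, br$rate_per_dot_hour * ik_hours)
    taken <- matrix(numeric(0), ncol = 2)
    for (k in seq_len(n_ev)) {
      dur <- if (stats::runif(1) < br$long_frac) {
        stats::runif(1, br$duration_range_s[2], br$long_max_s)
      } else stats::runif(1, br$duration_range_s[1], br$duration_range_s[2])
      ok <- FALSE
      for (try in 1:20) {
        t0 <- stats::runif(1, bnd$ik_start, bnd$ik_end - dur)
        if (!nrow(taken) ||
            all(t0 + dur < taken[, 1] - 30 | t0 > taken[, 2] + 30)) {
          ok <- TRUE; break
        }
      }
      if (!ok) next
      taken <- rbind(taken, c(t0, t0 + dur))
      amp <- br$max_amplitude_nm * stats::runif(1, 0.7, 1.0) / 1000
      win <- tt >= t0 & tt < t0 + dur
      sep[win] <- amp
      ev_log[[length(ev_log) + 1L]] <- data.frame(
        pair_id = i, t_start = t0, duration_s = dur, amplitude_nm = amp * 1000)
    }

    phi <- stats::runif(1, 0, 2 * pi)
    u <- c(cos(phi), sin(phi), 0)   # breathing axis kept in-plane
    p1 <- anchor + 0.5 * matrix(sep, n_frames, 3) * matrix(u, n_frames, 3, byrow = TRUE)
    p2 <- anchor - 0.5 * matrix(sep, n_frames, 3) * matrix(u, n_frames, 3, byrow = TRUE)
    positions[[i]] <- list(p1 = p1, p2 = p2)
  }

  bundle <- assemble_bundle(cfg, bnd, cell_id, tt, positions, "sister")
  truth <- structure(list(
    phases = c(ik_start = bnd$ik_start, ik_end = bnd$ik_end),
    stage = "IK", genotype = cfg$genotype, cell_id = cell_id, seed = seed,
    pairing = bundle$pairing,
    excursions = data.frame(pair_id = integer(0), count = integer(0)),
    reorientations = data.frame(),
    breathing = if (length(ev_log)) do.call(rbind, ev_log) else
      data.frame(pair_id = integer(0), t_start = numeric(0),
                 duration_s = numeric(0), amplitude_nm = numeric(0)),
    classes = NULL,
    separation = NULL,
    spindle_axis = c(1, 0, 0),
    pole_distance_um = cfg$geometry$pole_distance_um,
    dot_hours = n_units * (bnd$ik_end - bnd$ik_start) / 3600
  ), class = "kt_truth")
  list(bundle = bundle, truth = truth)
}

assemble_bundle <- function(cfg, bnd, cell_id, tt, positions, member_kind) {
  n_units <- length(positions)
  n_frames <- length(tt)
  rows <- vector("list", 2L * n_units)
  for (i in seq_len(n_units)) {
    for (mm in 1:2) {
      pm <- if (mm == 1) positions[[i]]$p1 else positions[[i]]$p2
      rows[[(i - 1L) * 2L + mm]] <- data.frame(
        cell_id = cell_id,
        kt_id = sprintf("p%d_%s%d", i, substr(member_kind, 1, 1), mm),
        pair_id = i, member = mm,
        frame = seq_len(n_frames) - 1L, t_s = tt,
        x_um = pm[, 1], y_um = pm[, 2], z_um = pm[, 3])
    }
  }
  pos <- do.call(rbind, rows)
  proxies <- make_proxies(bnd, tt)
  pairing <- unique(pos[, c("kt_id", "pair_id", "member")])
  rownames(pairing) <- NULL
  structure(list(positions = pos, proxies = proxies,
                 frame_interval_s = cfg$frame_interval_s,
                 stage = cfg$stage, genotype = cfg$genotype,
                 cell_id = cell_id, pairing = pairing,
                 geometry = cfg$geometry),
            class = "kt_bundle")
}

# nucleoplasmic signal (drops precipitously at NEBD) and chromatin
# decondensation proxy (steps up at telophase onset and again when chromatin
# is fully round at interphase onset); both carry mild measurement noise
make_proxies <- function(bnd, tt) {
  nuc <- rep(1, length(tt))
  dec <- rep(0, length(tt))
  if (!is.null(bnd$nebd)) {
    nuc <- 0.2 + 0.8 / (1 + exp((tt - bnd$nebd - 15) / 8))
    dec <- ifelse(tt >= bnd$interphase_onset, 1,
                  ifelse(tt >= bnd$telophase_onset, 0.5, 0))
  }
  data.frame(frame = seq_along(tt) - 1L, t_s = tt,
             nucleoplasmic = nuc + stats::rnorm(length(tt), 0, 0.015),
             decondensation = dec + stats::rnorm(length(tt), 0, 0.015))
}

#' Draw true sister-KT separations at a canonical M II time point
#'
#' Samples from the configured separation distribution: `"nebd2"` (about
#' 300 +/- 160 nm), `"five_min"`, or `"plateau"` (the bi-oriented value
#' 18 min after NEBD II, about 950 +/- 100 nm). Draws are truncated at
#' 50 nm.
#'
#' @param config a [sim_config()]
#' @param timepoint one of "nebd2", "five_min", "plateau"
#' @param n number of draws
#' @return numeric vector of separations in nm
#' @export
sample_sister_separation <- function(config, timepoint = c("plateau", "nebd2",
                                                           "five_min"), n = 1L) {
  timepoint <- match.arg(timepoint)
  ms <- config$separation_nm[[timepoint]]
  rnorm_trunc(n, ms[1], ms[2], lower = 50)
}

#' @export
print.kt_bundle <- function(x, ...) {
  cat(sprintf("<kt_bundle> cell %s, stage %s (%s): %d KTs x %d frames, dt=%gs\n",
              x$cell_id, x$stage, x$genotype,
              length(unique(x$positions$kt_id)),
              max(x$positions$frame) + 1L, x$frame_interval_s))
  invisible(x)
}

#' @export
print.kt_truth <- function(x, ...) {
  cat(sprintf("<kt_truth> cell %s, stage %s (%s)\n", x$cell_id, x$stage,
              x$genotype))
  ph <- x$phases
  cat("  phases (s): ",
      paste(sprintf("%s=%s", names(ph), signif(ph, 4)), collapse = " "), "\n")
  invisible(x)
}
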