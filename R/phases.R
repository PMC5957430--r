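# Rule-based scoring of division-phase boundaries and detection of the
# behavioral events: polar-equatorial excursions, kinetochore
# re-orientations, sister-centromere breathing, and univalent classes.

#' Thresholds for phase scoring and event detection
#'
#' All tunables in one place, echoed into analysis reports.
#'
#' @param jump_fallback_um_s absolute fallback jump-speed threshold
#' @param jump_quantile,jump_mult adaptive jump threshold: `jump_mult`
#'   times this quantile of prometaphase-A speeds of the same cell
#' @param angle_max_deg maximal A_KT counted as aligned (metaphase rule)
#' @param mobility_max_um_s maximal V_KT counted as immobile
#' @param persistence_frames frames of joint stability required to call
#'   metaphase onset (default 6 frames = 60 s at 10 s cadence)
#' @param dkt_step_um minimal abrupt single-step increase of median D_KT
#'   at anaphase onset
#' @param proxy_min_step minimal proxy-signal step for a changepoint call
#' @param smooth_frames running-mean window for proxy signals
#' @param plate_halfwidth_um metaphase-plate band half-width (the band is
#'   3 um wide, about one quarter of the pole-to-pole distance)
#' @param polar_inner_um distance from the spindle equator beyond which a
#'   KT is in the polar zone (outer quarter of the pole-to-pole axis)
#' @param breathing_min_frames minimal run of resolved frames for a
#'   breathing event (2 frames, about 20 s at 10 s cadence)
#' @param split_min_nm minimal separation counted as a conspicuous sister
#'   split in univalent classification
#' @param ma_offset_min inferred metaphase-to-anaphase transition: this
#'   many minutes before telophase onset
#' @param plate_resident_frac minimal fraction of metaphase-like frames in
#'   the plate band for plate residency
#' @return a named list of class `phase_config`
#' @export
phase_config <- function(jump_fallback_um_s = 0.06,
                         jump_quantile = 0.95,
                         jump_mult = 3,
                         angle_max_deg = 30,
                         mobility_max_um_s = 0.03,
                         persistence_frames = 6L,
                         dkt_step_um = 0.3,
                         proxy_min_step = 0.15,
                         smooth_frames = 3L,
                         plate_halfwidth_um = 1.5,
                         polar_inner_um = 3,
                         breathing_min_frames = 2L,
                         split_min_nm = 600,
                         ma_offset_min = 10,
                         plate_resident_frac = 0.6) {
  structure(as.list(environment()), class = "phase_config")
}

run_mean <- function(x, k) {
  if (k <= 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
}

# changepoint of the steepest sustained drop of a signal; returns the time
# (s) or NA when no drop of at least min_step is sustained
steepest_drop <- function(t_s, sig, k, min_step) {
  n <- length(sig)
  if (n < 3 * k) return(NA_real_)
  before <- after <- rep(NA_real_, n)
  for (i in (k + 1):(n - k)) {
    before[i] <- mean(sig[(i - k):(i - 1)])
    after[i] <- mean(sig[i:(i + k - 1)])
  }
  drop <- before - after
  i <- which.max(drop)
  if (!length(i) || is.na(drop[i]) || drop[i] < min_step) return(NA_real_)
  # sustained: the later level must stay down
  tail_lvl <- mean(sig[min(n, i + k):min(n, i + 3 * k)])
  if (tail_lvl > before[i] - min_step / 2) return(NA_real_)
  t_s[i]
}

# upward steps of a proxy signal: returns times of the `m` largest sustained
# increases, in time order
proxy_steps <- function(t_s, sig, k, min_step, m = 2L) {
  n <- length(sig)
  if (n < 3 * k) return(rep(NA_real_, m))
  before <- after <- rep(NA_real_, n)
  for (i in (k + 1):(n - k)) {
    before[i] <- mean(sig[(i - k):(i - 1)])
    after[i] <- mean(sig[i:(i + k - 1)])
  }
  inc <- after - before
  inc[is.na(inc)] <- -Inf
  picks <- integer(0)
  for (j in seq_len(m)) {
    i <- which.max(inc)
    if (!is.finite(inc[i]) || inc[i] < min_step) break
    picks <- c(picks, i)
    lo <- max(1, i - 2 * k); hi <- min(n, i + 2 * k)
    inc[lo:hi] <- -Inf
  }
  out <- rep(NA_real_, m)
  if (length(picks)) out[seq_along(picks)] <- sort(t_s[picks])
  out
}

#' Score division-phase boundaries for one cell
#'
#' Applies the scoring rules used on the live recordings: NEBD is the
#' changepoint of the steepest sustained drop of the nucleoplasmic signal;
#' the prometaphase A-to-B boundary is the first frame at which any KT
#' speed exceeds the jump threshold (adaptive: `jump_mult` times the
#' `jump_quantile` of the cell's own prometaphase-A speeds, with an
#' absolute fallback); metaphase onset is the first frame after which every
#' pair simultaneously sits inside the plate band with A_KT below
#' `angle_max_deg` and V_KT below `mobility_max_um_s` for at least
#' `persistence_frames`; anaphase onset is the frame of the maximal abrupt
#' increase of median D_KT (scored when the majority of pairs starts to
#' separate); telophase and interphase onsets are the two sustained upward
#' steps of the chromatin-decondensation proxy. Every boundary is either
#' scored or explicitly NA with method tag "unscored" — never a guess.
#'
#' @param tracks long data.frame: `kt_id`, `pair_id`, `member`, `frame`,
#'   `t_s`, `x_um`, `y_um`, `z_um`
#' @param proxies data.frame with `t_s`, `nucleoplasmic`,
#'   `decondensation`; may be NULL if `nebd_s` is supplied
#' @param frame_interval_s frame interval (s)
#' @param config a [phase_config()]
#' @param nebd_s externally supplied NEBD time (optional; used when no
#'   nucleoplasmic signal is available)
#' @return a `phase_annotation`: data.frame with `boundary`, `t_s`,
#'   `method`; plus attributes `spindle` (the estimated `spindle_frame` or
#'   NULL) and `jump_threshold_um_s`
#' @export
score_phases <- function(tracks, proxies = NULL, frame_interval_s = 10,
                         config = phase_config(), nebd_s = NULL) {
  cfg <- config
  dt <- frame_interval_s
  kin <- kinematic_series(tracks, spindle = NULL, frame_interval_s = dt)
  out <- data.frame(boundary = c("nebd", "pm_b_onset", "metaphase_onset",
                                 "anaphase_onset", "telophase_onset",
                                 "interphase_onset"),
                    t_s = NA_real_, method = "unscored",
                    stringsAsFactors = FALSE)
  set_b <- function(out, b, t, m) {
    out[out$boundary == b, c("t_s", "method")] <- list(t, m)
    out
  }

  # --- NEBD ---
  t_nebd <- NA_real_
  if (!is.null(nebd_s)) {
    t_nebd <- nebd_s
    out <- set_b(out, "nebd", t_nebd, "external")
  } else if (!is.null(proxies) && "nucleoplasmic" %in% names(proxies)) {
    sig <- run_mean(proxies$nucleoplasmic, cfg$smooth_frames)
    ok <- !is.na(sig)
    t_nebd <- steepest_drop(proxies$t_s[ok], sig[ok], k = 6L,
                            min_step = cfg$proxy_min_step)
    if (!is.na(t_nebd)) out <- set_b(out, "nebd", t_nebd, "signal")
  }

  # --- prometaphase A -> B: first supra-threshold jump ---
  t_pmb <- NA_real_
  jump_thr <- cfg$jump_fallback_um_s
  if (!is.na(t_nebd)) {
    v_long <- rbind(
      data.frame(t_s = kin$t_s, v = kin$v_kt_a),
      data.frame(t_s = kin$t_s, v = kin$v_kt_b))
    v_long <- v_long[!is.na(v_long$v) & v_long$t_s > t_nebd, ]
    v_long <- v_long[order(v_long$t_s), ]
    first_cross <- function(thr) {
      i <- which(v_long$v > thr)
      if (length(i)) v_long$t_s[i[1]] else NA_real_
    }
    t1 <- first_cross(cfg$jump_fallback_um_s)
    if (!is.na(t1)) {
      pma <- v_long$v[v_long$t_s < t1]
      if (length(pma) >= 10L) {
        adapt <- cfg$jump_mult *
          stats::quantile(pma, cfg$jump_quantile, names = FALSE)
        jump_thr <- min(cfg$jump_fallback_um_s, max(adapt, 0.02))
        t1 <- first_cross(jump_thr)
      }
      t_pmb <- t1
      out <- set_b(out, "pm_b_onset", t_pmb, "kinematics")
    }
  }

  # --- anaphase onset: abrupt sustained increase of D_KT, majority rule ---
  t_ana <- NA_real_
  pair_ids <- sort(unique(kin$pair_id))
  onset_of_pair <- function(p) {
    s <- kin[kin$pair_id == p, ]
    dd <- diff(s$d_kt_um)
    cand <- which(dd > cfg$dkt_step_um)
    for (i in cand) {
      lvl <- s$d_kt_um[i]
      hi <- min(nrow(s), i + 6L)
      if (all(s$d_kt_um[(i + 1):hi] > lvl + cfg$dkt_step_um / 2)) {
        return(s$t_s[i + 1L])
      }
    }
    NA_real_
  }
  onsets <- vapply(pair_ids, onset_of_pair, numeric(1))
  scored <- sort(onsets[!is.na(onsets)])
  if (length(scored) >= ceiling(length(pair_ids) / 2)) {
    t_ana <- scored[ceiling(length(pair_ids) / 2)]
    out <- set_b(out, "anaphase_onset", t_ana, "kinematics")
  }

  # --- telophase / interphase from the decondensation proxy ---
  t_telo <- t_inter <- NA_real_
  if (!is.null(proxies) && "decondensation" %in% names(proxies)) {
    sig <- run_mean(proxies$decondensation, cfg$smooth_frames)
    ok <- !is.na(sig)
    st <- proxy_steps(proxies$t_s[ok], sig[ok], k = 6L,
                      min_step = cfg$proxy_min_step, m = 2L)
    t_telo <- st[1]; t_inter <- st[2]
    if (!is.na(t_telo)) out <- set_b(out, "telophase_onset", t_telo, "signal")
    if (!is.na(t_inter)) {
      out <- set_b(out, "interphase_onset", t_inter, "signal")
    }
  }

  # --- spindle frame: metaphase window before anaphase (or late fallback) ---
  spindle <- NULL
  frames <- sort(unique(tracks$frame))
  ref_t <- if (!is.na(t_ana)) t_ana else if (!is.na(t_telo)) {
    t_telo - cfg$ma_offset_min * 60
  } else max(tracks$t_s)
  win_end <- max(frames[1] + 5L, floor(ref_t / dt) - 1L)
  win <- seq(max(frames[1], win_end - 34L), win_end)
  spindle <- tryCatch(
    estimate_spindle_axis(tracks, win, anaphase_onset_s = t_ana,
                          frame_interval_s = dt),
    error = function(e) NULL)

  # --- metaphase onset: joint congression + alignment + immobility ---
  if (!is.null(spindle) && !is.na(t_pmb)) {
    axis <- spindle$axis; ctr <- spindle$center
    t_hi <- if (!is.na(t_ana)) t_ana else max(tracks$t_s)
    ok_frame <- NULL
    for (p in pair_ids) {
      s <- kin[kin$pair_id == p, ]
      sub <- tracks[tracks$pair_id == p, ]
      m1 <- sub[sub$member == 1L, ][order(sub$frame[sub$member == 1L]), ]
      m2 <- sub[sub$member == 2L, ][order(sub$frame[sub$member == 2L]), ]
      common <- intersect(m1$frame, m2$frame)
      m1 <- m1[match(common, m1$frame), ]; m2 <- m2[match(common, m2$frame), ]
      cen <- (as.matrix(m1[, c("x_um", "y_um", "z_um")]) +
              as.matrix(m2[, c("x_um", "y_um", "z_um")])) / 2
      proj <- as.numeric((cen - matrix(ctr, nrow(cen), 3, byrow = TRUE)) %*%
                           axis)
      a <- compute_akt(as.matrix(m1[, c("x_um", "y_um", "z_um")]),
                       as.matrix(m2[, c("x_um", "y_um", "z_um")]), axis)
      vmax <- pmax(c(NA, compute_vkt(m1, dt)), c(NA, compute_vkt(m2, dt)))
      good <- abs(proj) <= cfg$plate_halfwidth_um &
        a < cfg$angle_max_deg & !is.na(vmax) & vmax < cfg$mobility_max_um_s
      good[is.na(good)] <- FALSE
      ok_frame <- if (is.null(ok_frame)) good else ok_frame & good
    }
    tvec <- kin$t_s[kin$pair_id == pair_ids[1]]
    usable <- tvec > t_pmb & tvec < t_hi
    run <- 0L
    t_meta <- NA_real_
    for (i in seq_along(ok_frame)) {
      if (usable[i] && ok_frame[i]) {
        run <- run + 1L
        if (run == cfg$persistence_frames) {
          t_meta <- tvec[i - cfg$persistence_frames + 1L]
          break
        }
      } else run <- 0L
    }
    if (!is.na(t_meta)) out <- set_b(out, "metaphase_onset", t_meta,
                                     "kinematics")
  }

  structure(out, spindle = spindle, jump_threshold_um_s = jump_thr,
            class = c("phase_annotation", "data.frame"))
}

#' @export
print.phase_annotation <- function(x, ...) {
  cat("<phase_annotation>\n")
  print.data.frame(x)
  invisible(x)
}

phase_time <- function(annotation, boundary) {
  annotation$t_s[annotation$boundary == boundary]
}

#' Count polar-equatorial excursions of one KT (pair) track
#'
#' Positions are projected onto the spindle axis; the equatorial zone is
#' the metaphase-plate band (3 um wide by default) and the polar zones are
#' the outer quarters of the pole-to-pole axis. An excursion is one
#' completed transit from one zone into the other (both directions count);
#' leaving a zone without reaching the other one does not count.
#'
#' @param track data.frame with `t_s`, `x_um`, `y_um`, `z_um` (typically a
#'   pair-center track)
#' @param spindle a `spindle_frame`
#' @param config a [phase_config()]
#' @param window_s length-2 time window (s) over which transits are
#'   counted (typically NEBD to anaphase onset or to the inferred
#'   metaphase-to-anaphase transition)
#' @return list with `count` and `events` (data.frame `t_s`, `from`, `to`)
#' @export
detect_excursions <- function(track, spindle, config = phase_config(),
                              window_s = range(track$t_s)) {
  cfg <- config
  if (cfg$plate_halfwidth_um >= cfg$polar_inner_um) {
    stop("equatorial band and polar zones overlap: bad geometry",
         call. = FALSE)
  }
  use <- track$t_s >= window_s[1] & track$t_s <= window_s[2]
  p <- as.matrix(track[use, c("x_um", "y_um", "z_um")])
  proj <- as.numeric((p - matrix(spindle$center, nrow(p), 3, byrow = TRUE)) %*%
                       spindle$axis)
  zone <- ifelse(abs(proj) <= cfg$plate_halfwidth_um, "equatorial",
                 ifelse(abs(proj) >= cfg$polar_inner_um, "polar", NA))
  state <- NA_character_
  events <- list()
  tt <- track$t_s[use]
  for (i in seq_along(zone)) {
    z <- zone[i]
    if (is.na(z)) next
    if (!is.na(state) && z != state) {
      events[[length(events) + 1L]] <- data.frame(t_s = tt[i], from = state,
                                                  to = z)
    }
    state <- z
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(t_s = numeric(0), from = character(0), to = character(0))
  list(count = nrow(events), events = events)
}

#' Detect kinetochore re-orientation events
#'
#' A re-orientation is a supra-threshold poleward jump of one KT toward one
#' spindle pole followed later by a poleward jump of the same KT toward the
#' opposite pole. Jumps are maximal runs of frames with speed above the
#' jump threshold whose net axial displacement moves the KT beyond the
#' plate band on the side it is heading to; plate-directed moves are not
#' jumps toward a pole and are ignored. Each sign-alternating pair of
#' consecutive poleward jumps of one KT yields one event, annotated with
#' whether the partner KT was displaced toward the opposite pole in
#' between (transient bi-orientation).
#'
#' @param tracks long data.frame as in [score_phases()] (needs `member`)
#' @param spindle a `spindle_frame`
#' @param frame_interval_s frame interval (s)
#' @param jump_threshold_um_s speed threshold; use the value reported by
#'   [score_phases()]
#' @param config a [phase_config()]
#' @param min_jump_um minimal net axial displacement of a jump
#' @return data.frame: `pair_id`, `kt_id`, `t_jump1`, `t_jump2`,
#'   `transient_biorientation`
#' @export
detect_reorientations <- function(tracks, spindle, frame_interval_s = 10,
                                  jump_threshold_um_s = 0.06,
                                  config = phase_config(),
                                  min_jump_um = 0.8) {
  cfg <- config
  axis <- spindle$axis; ctr <- spindle$center
  out <- list()
  for (id in unique(tracks$kt_id)) {
    s <- tracks[tracks$kt_id == id, ]
    s <- s[order(s$frame), ]
    if (nrow(s) < 3L) next
    p <- as.matrix(s[, c("x_um", "y_um", "z_um")])
    proj <- as.numeric((p - matrix(ctr, nrow(p), 3, byrow = TRUE)) %*% axis)
    v <- compute_vkt(s, frame_interval_s)
    fast <- !is.na(v) & v > jump_threshold_um_s
    if (!any(fast)) next
    r <- rle(fast)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    jumps <- list()
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k] + 1L   # sample indices spanned
      dproj <- proj[i1] - proj[i0]
      sgn <- sign(dproj)
      if (abs(dproj) < min_jump_um) next
      # must end beyond the plate band on the side it is heading to
      if (sgn * proj[i1] <= cfg$plate_halfwidth_um) next
      jumps[[length(jumps) + 1L]] <- list(t0 = s$t_s[i0], t1 = s$t_s[i1],
                                          sgn = sgn)
    }
    if (length(jumps) < 2L) next
    partner <- tracks[tracks$pair_id == s$pair_id[1] &
                        tracks$kt_id != id, ]
    partner <- partner[order(partner$frame), ]
    pproj <- if (nrow(partner)) {
      as.numeric((as.matrix(partner[, c("x_um", "y_um", "z_um")]) -
                    matrix(ctr, nrow(partner), 3, byrow = TRUE)) %*% axis)
    } else NULL
    for (k in 2:length(jumps)) {
      if (jumps[[k]]$sgn != jumps[[k - 1]]$sgn) {
        bi <- FALSE
        if (!is.null(pproj)) {
          w <- partner$t_s > jumps[[k - 1]]$t1 & partner$t_s < jumps[[k]]$t0
          if (sum(w) >= 2L) {
            dp <- pproj[which(w)[sum(w)]] - pproj[which(w)[1]]
            # partner pulled toward the pole opposite to the first jump
            bi <- (-jumps[[k - 1]]$sgn) * dp > 0.15
          }
        }
        out[[length(out) + 1L]] <- data.frame(
          pair_id = s$pair_id[1], kt_id = id,
          t_jump1 = jumps[[k - 1]]$t0, t_jump2 = jumps[[k]]$t0,
          transient_biorientation = bi)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(pair_id = integer(0), kt_id = character(0),
                      t_jump1 = numeric(0), t_jump2 = numeric(0),
                      transient_biorientation = logical(0)))
  }
  ev <- do.call(rbind, out)
  # one event per pair: when the partner KT is dragged along, both members
  # register the same antagonistic jump pair; merge events of one pair with
  # near-coincident jump times
  keep <- rep(TRUE, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(ev)) > i & ev$pair_id == ev$pair_id[i] &
                 abs(ev$t_jump1 - ev$t_jump1[i]) < 60 &
                 abs(ev$t_jump2 - ev$t_jump2[i]) < 60)
    if (length(j)) {
      ev$transient_biorientation[i] <- ev$transient_biorientation[i] ||
        any(ev$transient_biorientation[j])
      keep[j] <- FALSE
    }
  }
  ev[keep, , drop = FALSE]
}

#' Detect sister-centromere breathing events
#'
#' A breathing event is a maximal run of at least `min_frames` consecutive
#' frames in which a nominally single centromere dot is resolved into two
#' distinct maxima. The rate is events per dot-hour observed.
#'
#' @param series_list list of per-dot separation series (data.frames with
#'   `frame`, `resolved`, `distance_nm`, as produced by
#'   [pair_separation_series()])
#' @param frame_interval_s frame interval (s); required (the rate is
#'   undefined without the cadence)
#' @param min_frames minimal run length (default 2 frames, about 20 s)
#' @return list with `events` (data.frame `dot`, `t_start_s`,
#'   `duration_s`, `max_separation_nm`), `n_events`, `dot_hours`, `rate`
#'   (events per dot per hour)
#' @export
detect_breathing <- function(series_list, frame_interval_s,
                             min_frames = 2L) {
  if (missing(frame_interval_s) || is.null(frame_interval_s) ||
      !is.finite(frame_interval_s)) {
    stop("frame_interval_s is required: the event rate is undefined ",
         "without the acquisition cadence", call. = FALSE)
  }
  events <- list()
  dot_hours <- 0
  for (d in seq_along(series_list)) {
    s <- series_list[[d]]
    dot_hours <- dot_hours + nrow(s) * frame_interval_s / 3600
    r <- rle(as.logical(s$resolved))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_frames)) {
      events[[length(events) + 1L]] <- data.frame(
        dot = d,
        t_start_s = s$frame[starts[k]] * frame_interval_s,
        duration_s = r$lengths[k] * frame_interval_s,
        max_separation_nm = max(s$distance_nm[starts[k]:ends[k]]))
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(dot = integer(0), t_start_s = numeric(0),
               duration_s = numeric(0), max_separation_nm = numeric(0))
  list(events = events, n_events = nrow(events), dot_hours = dot_hours,
       rate = nrow(events) / dot_hours)
}

#' Classify univalents into classes I / II / III
#'
#' Class I univalents sit within the metaphase plate with sister KTs
#' stretched apart and show a conspicuous sister-splitting event at or
#' after the inferred metaphase-to-anaphase (m/a) transition; class II
#' univalents are plate-resident but never resolve; class III univalents
#' have unresolved sister KTs and depart toward a spindle pole before the
#' inferred m/a transition. The m/a transition is inferred as telophase
#' onset minus `ma_offset_min` minutes; classification is refused when
#' telophase onset is unscored.
#'
#' @param tracks long data.frame (sister members per univalent, `pair_id`
#'   marks the univalent)
#' @param telophase_onset_s scored telophase onset (s)
#' @param spindle a `spindle_frame`
#' @param config a [phase_config()]
#' @param metaphase_like_start_s start of the metaphase-like period used
#'   for plate residency (default: m/a minus 15 min)
#' @return data.frame per univalent: `pair_id`, `class`,
#'   `plate_resident_frac`, `max_separation_nm`, `t_max_separation_s`,
#'   `split_after_ma`, `departure_before_ma`
#' @export
classify_univalents <- function(tracks, telophase_onset_s, spindle,
                                config = phase_config(),
                                metaphase_like_start_s = NULL) {
  cfg <- config
  if (is.na(telophase_onset_s)) {
    stop("telophase onset unscored: the inferred m/a anchor is required ",
         "for classification", call. = FALSE)
  }
  t_ma <- telophase_onset_s - cfg$ma_offset_min * 60
  if (is.null(metaphase_like_start_s)) {
    metaphase_like_start_s <- t_ma - 15 * 60
  }
  axis <- spindle$axis; ctr <- spindle$center
  out <- lapply(sort(unique(tracks$pair_id)), function(p) {
    sub <- tracks[tracks$pair_id == p, ]
    m1 <- sub[sub$member == 1L, ][order(sub$frame[sub$member == 1L]), ]
    m2 <- sub[sub$member == 2L, ][order(sub$frame[sub$member == 2L]), ]
    common <- intersect(m1$frame, m2$frame)
    m1 <- m1[match(common, m1$frame), ]; m2 <- m2[match(common, m2$frame), ]
    p1 <- as.matrix(m1[, c("x_um", "y_um", "z_um")])
    p2 <- as.matrix(m2[, c("x_um", "y_um", "z_um")])
    sep_nm <- compute_dkt(p1, p2) * 1000
    cen <- (p1 + p2) / 2
    proj <- as.numeric((cen - matrix(ctr, nrow(cen), 3, byrow = TRUE)) %*%
                         axis)
    tt <- m1$t_s
    meta_win <- tt >= metaphase_like_start_s & tt < t_ma
    plate_frac <- if (any(meta_win)) {
      mean(abs(proj[meta_win]) <= cfg$plate_halfwidth_um)
    } else NA_real_
    # conspicuous splitting: sustained separation above the split threshold
    split_run <- sep_nm > cfg$split_min_nm
    r <- rle(split_run)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    split_t <- NA_real_
    for (k in which(r$values & r$lengths >= cfg$breathing_min_frames)) {
      if (tt[starts[k]] >= t_ma - 60) { split_t <- tt[starts[k]]; break }
    }
    split_after_ma <- !is.na(split_t)
    # poleward departure before m/a: sustained polar-zone residency during
    # the metaphase-like period (prometaphase wandering does not count)
    w <- which(tt >= metaphase_like_start_s & tt < t_ma)
    dep_before_ma <- FALSE
    if (length(w) > 6L) {
      pol <- abs(proj[w]) >= cfg$polar_inner_um
      rr <- rle(pol)
      dep_before_ma <- any(rr$values & rr$lengths >= 6L)
    }
    plate_res <- !is.na(plate_frac) && plate_frac >= cfg$plate_resident_frac
    cls <- if (split_after_ma && plate_res) "I"
      else if (dep_before_ma && !split_after_ma) "III"
      else "II"
    data.frame(pair_id = p, class = cls,
               plate_resident_frac = plate_frac,
               max_separation_nm = max(sep_nm),
               t_max_separation_s = tt[which.max(sep_nm)],
               split_after_ma = split_after_ma,
               departure_before_ma = dep_before_ma)
  })
  do.call(rbind, out)
}

#' Summarize analyzed cells by genotype
#'
#' Aggregates per-cell analysis results into per-genotype tables: phase
#' durations (mean, s.d., n), excursion counts, breathing statistics,
#' univalent class fractions, and the sister-separation time course at the
#' canonical M II sampling times.
#'
#' @param cells list of per-cell summaries as produced by [analyze_cell()]
#' @return list of data.frames: `phases`, `excursions`, `breathing`,
#'   `classes`
#' @export
summarize_genotypes <- function(cells) {
  if (!length(cells)) stop("no analyzed cells supplied", call. = FALSE)
  genos <- vapply(cells, function(cl) cl$genotype, "")
  per_geno <- split(cells, genos)

  phase_rows <- list()
  exc_rows <- list()
  class_rows <- list()
  for (g in names(per_geno)) {
    cl <- per_geno[[g]]
    durs <- lapply(cl, function(x) x$durations_min)
    all_names <- unique(unlist(lapply(durs, names)))
    for (nm in all_names) {
      vals <- vapply(durs, function(d) d[nm] %||% NA_real_, numeric(1))
      vals <- vals[!is.na(vals)]
      if (!length(vals)) next
      phase_rows[[length(phase_rows) + 1L]] <- data.frame(
        genotype = g, interval = nm, mean_min = mean(vals),
        sd_min = stats::sd(vals), n = length(vals))
    }
    exc <- unlist(lapply(cl, function(x) x$excursions$count))
    if (length(exc)) {
      exc_rows[[length(exc_rows) + 1L]] <- data.frame(
        genotype = g, mean_excursions_per_pair = mean(exc),
        sd = stats::sd(exc), n_pairs = length(exc),
        n_cells = length(cl))
    }
    cls <- unlist(lapply(cl, function(x) {
      if (!is.null(x$classes)) as.character(x$classes$class) else character(0)
    }))
    if (length(cls)) {
      tab <- table(factor(cls, levels = c("I", "II", "III")))
      class_rows[[length(class_rows) + 1L]] <- data.frame(
        genotype = g, class = names(tab), n = as.integer(tab),
        fraction = as.numeric(tab) / sum(tab))
    }
  }
  list(
    phases = if (length(phase_rows)) do.call(rbind, phase_rows) else NULL,
    excursions = if (length(exc_rows)) do.call(rbind, exc_rows) else NULL,
    classes = if (length(class_rows)) do.call(rbind, class_rows) else NULL
  )
}
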