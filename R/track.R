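# Track linking (constant-velocity motion model, gap closing) and pair
# assignment. Commercial autoregressive trackers fit higher-order motion
# models; a constant-velocity prediction is the stand-in here, with
# deterministic tie-breaking (nearest predicted-position match wins, equal
# distances broken by lower track id).

#' Link per-frame detections into tracks
#'
#' Each live track predicts its next position by constant velocity and
#' claims the nearest unclaimed detection within `search_radius_um`
#' (candidate pairs assigned greedily in order of increasing predicted
#' distance; ties broken by lower track id). Tracks missing a detection
#' coast for up to `max_gap` frames (gaps are closed by linear
#' interpolation and flagged); unlinked detections start new tracks.
#'
#' @param spots_by_frame list of data.frames with columns `x_um`, `y_um`,
#'   `z_um` (one element per frame, in frame order; empty data.frames are
#'   allowed)
#' @param frame_interval_s frame interval (s)
#' @param search_radius_um association gate (default 2 um)
#' @param max_gap maximal number of consecutive missed frames closed by
#'   interpolation (default 3, matching the observation that unresolvable
#'   stretches usually last less than four time points)
#' @param repair_swaps run a trajectory-smoothness pass that un-crosses
#'   identity swaps created by near-collinear rapid jumps (default TRUE)
#' @return a `track_set`: list with `tracks` (long data.frame: `track_id`,
#'   `frame`, `t_s`, `x_um`, `y_um`, `z_um`, `gap`), `frame_interval_s`
#' @export
link_spots <- function(spots_by_frame, frame_interval_s = 10,
                       search_radius_um = 3, max_gap = 3L,
                       repair_swaps = TRUE) {
  if (search_radius_um <= 0) stop("search radius must be > 0", call. = FALSE)
  n_frames <- length(spots_by_frame)
  if (n_frames < 2L) stop("need detections from at least 2 frames",
                          call. = FALSE)

  # track state: positions in a growing (n_tracks x n_frames x 3) structure
  max_tracks <- 16L
  pos_arr <- array(NA_real_, c(max_tracks, n_frames, 3))
  vel <- matrix(0, max_tracks, 3)
  last_frame <- rep(NA_integer_, max_tracks)
  missed <- rep(0L, max_tracks)
  n_tracks <- 0L

  grow <- function() {
    new_max <- max_tracks * 2L
    pa <- array(NA_real_, c(new_max, n_frames, 3))
    pa[seq_len(max_tracks), , ] <- pos_arr
    pos_arr <<- pa
    vel <<- rbind(vel, matrix(0, max_tracks, 3))
    last_frame <<- c(last_frame, rep(NA_integer_, max_tracks))
    missed <<- c(missed, rep(0L, max_tracks))
    max_tracks <<- new_max
  }

  for (f in seq_len(n_frames)) {
    det <- spots_by_frame[[f]]
    det <- if (is.null(det) || nrow(det) == 0L) {
      matrix(numeric(0), ncol = 3)
    } else unname(as.matrix(det[, c("x_um", "y_um", "z_um")]))
    live <- which(!is.na(last_frame[seq_len(n_tracks)]) &
                    missed[seq_len(n_tracks)] <= max_gap)
    claimed <- rep(FALSE, nrow(det))
    matched <- rep(FALSE, length(live))
    if (length(live) && nrow(det)) {
      lf <- last_frame[live]
      pred <- cbind(
        pos_arr[cbind(live, lf, 1)] + vel[live, 1] * (f - lf),
        pos_arr[cbind(live, lf, 2)] + vel[live, 2] * (f - lf),
        pos_arr[cbind(live, lf, 3)] + vel[live, 3] * (f - lf))
      dmat <- outer(seq_along(live), seq_len(nrow(det)),
                    Vectorize(function(i, j) sqrt(sum((pred[i, ] -
                                                       det[j, ])^2))))
      assign <- assign_min_cost(dmat, search_radius_um)
      for (ti in which(!is.na(assign))) {
        di <- assign[ti]
        if (claimed[di]) next
        matched[ti] <- TRUE; claimed[di] <- TRUE
        id <- live[ti]
        lf0 <- last_frame[id]
        gap_len <- f - lf0 - 1L
        if (gap_len > 0L) {
          af <- seq_len(gap_len) / (gap_len + 1L)
          for (ax in 1:3) {
            pos_arr[id, lf0 + seq_len(gap_len), ax] <-
              pos_arr[id, lf0, ax] + af * (det[di, ax] - pos_arr[id, lf0, ax])
          }
        }
        pos_arr[id, f, ] <- det[di, ]
        vel[id, ] <- (det[di, ] - pos_arr[id, lf0, ]) / (f - lf0)
        last_frame[id] <- f
        missed[id] <- 0L
      }
    }
    missed[live[!matched]] <- missed[live[!matched]] + 1L
    for (di in which(!claimed)) {
      if (n_tracks == max_tracks) grow()
      n_tracks <- n_tracks + 1L
      pos_arr[n_tracks, f, ] <- det[di, ]
      last_frame[n_tracks] <- f
    }
  }

  # stitch fragments: a rapid jump can out-run the search gate, ending one
  # track and starting another at the landing point
  if (n_tracks >= 2L) {
    repeat {
      ends <- vapply(seq_len(n_tracks), function(id) {
        w <- which(!is.na(pos_arr[id, , 1]))
        if (length(w)) max(w) else NA_integer_
      }, integer(1))
      starts <- vapply(seq_len(n_tracks), function(id) {
        w <- which(!is.na(pos_arr[id, , 1]))
        if (length(w)) min(w) else NA_integer_
      }, integer(1))
      best <- NULL
      for (i in seq_len(n_tracks)) {
        if (is.na(ends[i]) || ends[i] == n_frames) next
        for (j in seq_len(n_tracks)) {
          if (i == j || is.na(starts[j])) next
          dt_f <- starts[j] - ends[i]
          if (dt_f < 1L || dt_f > max_gap + 1L) next
          d <- sqrt(sum((pos_arr[i, ends[i], ] - pos_arr[j, starts[j], ])^2))
          if (d > 2.5 * search_radius_um) next
          score <- dt_f * 100 + d
          if (is.null(best) || score < best$score) {
            best <- list(i = i, j = j, score = score)
          }
        }
      }
      if (is.null(best)) break
      i <- best$i; j <- best$j
      f0 <- ends[i]; f1 <- starts[j]
      if (f1 - f0 > 1L) {
        af <- seq_len(f1 - f0 - 1L) / (f1 - f0)
        for (ax in 1:3) {
          pos_arr[i, (f0 + 1L):(f1 - 1L), ax] <-
            pos_arr[i, f0, ax] + af * (pos_arr[j, f1, ax] - pos_arr[i, f0, ax])
        }
      }
      w <- which(!is.na(pos_arr[j, , 1]))
      pos_arr[i, w, ] <- pos_arr[j, w, ]
      pos_arr[j, , ] <- NA_real_
    }
    keep <- which(vapply(seq_len(n_tracks), function(id) {
      any(!is.na(pos_arr[id, , 1]))
    }, TRUE))
    pos_arr <- pos_arr[keep, , , drop = FALSE]
    n_tracks <- length(keep)
  }

  if (repair_swaps && n_tracks >= 2L) {
    pos_arr <- repair_identity_swaps(pos_arr, n_tracks, n_frames)
  }

  # interpolated (gap-closed) samples are positions matching no detection
  det_used <- lapply(seq_len(n_frames), function(f) {
    d <- spots_by_frame[[f]]
    if (is.null(d) || nrow(d) == 0L) matrix(numeric(0), ncol = 3) else
      unname(as.matrix(d[, c("x_um", "y_um", "z_um")]))
  })
  gap_flag <- matrix(FALSE, n_tracks, n_frames)
  for (id in seq_len(n_tracks)) {
    for (f in which(!is.na(pos_arr[id, , 1]))) {
      d <- det_used[[f]]
      if (!nrow(d) || min(abs(d[, 1] - pos_arr[id, f, 1]) +
                          abs(d[, 2] - pos_arr[id, f, 2])) > 1e-12) {
        gap_flag[id, f] <- TRUE
      }
    }
  }

  rows <- lapply(seq_len(n_tracks), function(id) {
    fr <- which(!is.na(pos_arr[id, , 1]))
    data.frame(track_id = id, frame = fr - 1L,
               t_s = (fr - 1L) * frame_interval_s,
               x_um = pos_arr[id, fr, 1], y_um = pos_arr[id, fr, 2],
               z_um = pos_arr[id, fr, 3], gap = gap_flag[id, fr])
  })
  long <- do.call(rbind, rows)
  rownames(long) <- NULL
  structure(list(tracks = long, frame_interval_s = frame_interval_s),
            class = "track_set")
}

# Globally optimal gated assignment of tracks to detections: minimizes the
# total predicted-position distance (unmatched tracks pay the gate penalty).
# Contention clusters (connected components of the candidate graph) are tiny
# in practice — one KT pair, occasionally two crossing pairs — so each
# component is solved exactly by recursive enumeration; singletons take the
# nearest match directly. Deterministic: ties resolve toward lower indices.
assign_min_cost <- function(dmat, gate) {
  nt <- nrow(dmat); nd <- ncol(dmat)
  assign <- rep(NA_integer_, nt)
  if (nt == 0L || nd == 0L) return(assign)
  cand <- dmat <= gate
  if (!any(cand)) return(assign)
  # connected components over the bipartite candidate graph
  t_comp <- rep(0L, nt); d_comp <- rep(0L, nd)
  ncomp <- 0L
  for (t0 in seq_len(nt)) {
    if (t_comp[t0] != 0L || !any(cand[t0, ])) next
    ncomp <- ncomp + 1L
    tq <- t0
    while (length(tq)) {
      ti <- tq[1]; tq <- tq[-1]
      if (t_comp[ti] != 0L) next
      t_comp[ti] <- ncomp
      for (di in which(cand[ti, ] & d_comp == 0L)) {
        d_comp[di] <- ncomp
        tq <- c(tq, which(cand[, di] & t_comp == 0L))
      }
    }
  }
  skip_pen <- gate * 1.0001
  for (cc in seq_len(ncomp)) {
    ts <- which(t_comp == cc); ds <- which(d_comp == cc)
    if (length(ts) == 1L) {
      assign[ts] <- ds[which.min(dmat[ts, ds])]
      next
    }
    if (length(ts) > 7L) {
      # very large contention cluster: nearest-first greedy
      sub <- dmat[ts, ds, drop = FALSE]
      used <- rep(FALSE, length(ds))
      for (o in order(sub)) {
        if (sub[o] > gate) break
        i <- (o - 1L) %% length(ts) + 1L
        j <- (o - 1L) %/% length(ts) + 1L
        if (is.na(assign[ts[i]]) && !used[j]) {
          assign[ts[i]] <- ds[j]; used[j] <- TRUE
        }
      }
      next
    }
    best_cost <- Inf
    best_sel <- NULL
    rec <- function(k, used, sel, acc) {
      if (acc >= best_cost) return()
      if (k > length(ts)) {
        best_cost <<- acc; best_sel <<- sel
        return()
      }
      for (j in seq_along(ds)) {
        if (used[j] || dmat[ts[k], ds[j]] > gate) next
        used[j] <- TRUE
        rec(k + 1L, used, c(sel, j), acc + dmat[ts[k], ds[j]])
        used[j] <- FALSE
      }
      rec(k + 1L, used, c(sel, NA_integer_), acc + skip_pen)
    }
    rec(1L, rep(FALSE, length(ds)), integer(0), 0)
    if (!is.null(best_sel)) {
      for (k in seq_along(ts)) {
        if (!is.na(best_sel[k])) assign[ts[k]] <- ds[best_sel[k]]
      }
    }
  }
  assign
}

# Identity swaps arise when a KT jumps nearly along the axis through its
# neighbor: the two assignments have almost equal instantaneous cost. The
# true continuation is smoother, so for every track pair and frame, swap the
# tails if that reduces the summed squared acceleration around the frame.
repair_identity_swaps <- function(pos_arr, n_tracks, n_frames) {
  accsum <- function(p) {
    if (nrow(p) < 3L) return(0)
    a <- p[3:nrow(p), , drop = FALSE] - 2 * p[2:(nrow(p) - 1), , drop = FALSE] +
      p[1:(nrow(p) - 2), , drop = FALSE]
    sum(a^2)
  }
  for (sweep in 1:8) {
    changed <- FALSE
    for (f in 3:(n_frames - 2L)) {
      for (i in seq_len(n_tracks - 1L)) {
        if (anyNA(pos_arr[i, (f - 2):(f + 2), 1])) next
        for (j in (i + 1L):n_tracks) {
          if (anyNA(pos_arr[j, (f - 2):(f + 2), 1])) next
          # only consider nearby tracks
          if (sum((pos_arr[i, f, ] - pos_arr[j, f, ])^2) > 9) next
          wi <- pos_arr[i, (f - 2):(f + 2), ]
          wj <- pos_arr[j, (f - 2):(f + 2), ]
          cur <- accsum(wi) + accsum(wj)
          alt <- accsum(rbind(wi[1:2, ], wj[3:5, ])) +
            accsum(rbind(wj[1:2, ], wi[3:5, ]))
          if (alt < cur - 1e-9) {
            tmp <- pos_arr[i, f:n_frames, ]
            pos_arr[i, f:n_frames, ] <- pos_arr[j, f:n_frames, ]
            pos_arr[j, f:n_frames, ] <- tmp
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  pos_arr
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks, frames %d..%d, dt=%gs\n",
              length(unique(x$tracks$track_id)), min(x$tracks$frame),
              max(x$tracks$frame), x$frame_interval_s))
  invisible(x)
}

# enumerate all perfect matchings of 1..n (n even); 105 matchings for n = 8
perfect_matchings <- function(n) {
  if (n == 0L) return(list(integer(0)))
  rec <- function(items) {
    if (!length(items)) return(list(matrix(integer(0), ncol = 2)))
    a <- items[1]
    out <- list()
    for (b in items[-1]) {
      rest <- setdiff(items, c(a, b))
      for (m in rec(rest)) out[[length(out) + 1L]] <- rbind(c(a, b), m)
    }
    out
  }
  rec(seq_len(n))
}

#' Assign sister/homolog pair structure to tracks
#'
#' In evaluation mode (`ground_truth` supplied) pair ids are copied from
#' the simulator map. Otherwise the pairing minimizing the summed mean
#' intra-pair distance over the prometaphase-metaphase window is found by
#' exhaustive enumeration of all perfect matchings (105 matchings for 8
#' tracks). If anaphase information is supplied, the matching is validated
#' by anaphase divergence: paired tracks must separate toward opposite
#' poles after anaphase onset. A second matching within `ambiguity_tol` of
#' the optimum triggers a warning on the affected pairs.
#'
#' @param track_set a `track_set` from [link_spots()]
#' @param window_s length-2 numeric: time window (s) over which pair
#'   distance is accumulated (default: full recording)
#' @param anaphase_onset_s optional anaphase onset (s) for validation
#' @param ground_truth optional data.frame `track_id`, `pair_id`
#' @param ambiguity_tol relative cost tolerance for ambiguity warnings
#' @return the `track_set` with a `pair_id` column added and a `pairing`
#'   data.frame (`track_id`, `pair_id`)
#' @export
assign_pairs <- function(track_set, window_s = NULL, anaphase_onset_s = NA,
                         ground_truth = NULL, ambiguity_tol = 0.05) {
  tr <- track_set$tracks
  ids <- sort(unique(tr$track_id))
  n <- length(ids)
  if (!is.null(ground_truth)) {
    map <- ground_truth[match(tr$track_id, ground_truth$track_id), "pair_id"]
    track_set$tracks$pair_id <- map
    track_set$pairing <- unique(data.frame(track_id = tr$track_id,
                                           pair_id = map))
    return(track_set)
  }
  if (n %% 2L != 0L) {
    stop(sprintf("pair assignment needs an even track count, got %d", n),
         call. = FALSE)
  }
  if (is.null(window_s)) window_s <- range(tr$t_s)
  win <- tr[tr$t_s >= window_s[1] & tr$t_s <= window_s[2], ]
  # mean pairwise distance over common frames
  cost <- matrix(Inf, n, n)
  pos <- split(win, win$track_id)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- pos[[as.character(ids[i])]]
    b <- pos[[as.character(ids[j])]]
    common <- intersect(a$frame, b$frame)
    if (length(common) < 3L) next
    pa <- as.matrix(a[match(common, a$frame), c("x_um", "y_um", "z_um")])
    pb <- as.matrix(b[match(common, b$frame), c("x_um", "y_um", "z_um")])
    cost[i, j] <- cost[j, i] <- mean(sqrt(rowSums((pa - pb)^2)))
  }
  matchings <- perfect_matchings(n)
  costs <- vapply(matchings, function(m) {
    sum(cost[cbind(m[, 1], m[, 2])])
  }, numeric(1))
  best <- which.min(costs)
  second <- sort(costs)[2]
  if (is.finite(second) && second - costs[best] < ambiguity_tol * costs[best]) {
    warning("ambiguous pairing: an alternative matching lies within ",
            "tolerance of the optimum")
  }
  m <- matchings[[best]]
  pair_of <- integer(n)
  for (k in seq_len(nrow(m))) pair_of[m[k, ]] <- k
  # anaphase-divergence validation
  if (is.finite(anaphase_onset_s)) {
    for (k in seq_len(nrow(m))) {
      a <- pos_after(tr, ids[m[k, 1]], anaphase_onset_s)
      b <- pos_after(tr, ids[m[k, 2]], anaphase_onset_s)
      if (!is.null(a) && !is.null(b) && sum(a * b) > 0 &&
          vec_norm(a) > 0.5 && vec_norm(b) > 0.5) {
        warning(sprintf(
          "pair %d does not diverge toward opposite poles after anaphase", k))
      }
    }
  }
  map <- data.frame(track_id = ids, pair_id = pair_of)
  track_set$tracks$pair_id <- map$pair_id[match(tr$track_id, map$track_id)]
  track_set$pairing <- map
  track_set
}

pos_after <- function(tr, id, t0) {
  s <- tr[tr$track_id == id, ]
  i0 <- which.min(abs(s$t_s - t0))
  i1 <- which.min(abs(s$t_s - (t0 + 150)))
  if (i1 <= i0) return(NULL)
  c(s$x_um[i1] - s$x_um[i0], s$y_um[i1] - s$y_um[i0], s$z_um[i1] - s$z_um[i0])
}

#' Build per-frame detection lists from a simulated bundle
#'
#' Converts true KT positions into the per-frame spot-list format consumed
#' by [link_spots()], optionally adding isotropic Gaussian localization
#' noise — the "perfect detection" evaluation mode for the linker.
#'
#' @param bundle a `kt_bundle`
#' @param noise_sd_um localization noise s.d. per axis (default 0.03)
#' @param seed integer seed for the noise
#' @return list of data.frames, one per frame, plus attribute
#'   `true_kt_id` per row for identity scoring
#' @export
spots_from_bundle <- function(bundle, noise_sd_um = 0.03, seed = 1L) {
  set.seed(as.integer(seed))
  pos <- bundle$positions
  frames <- sort(unique(pos$frame))
  lapply(frames, function(f) {
    sub <- pos[pos$frame == f, ]
    n <- nrow(sub)
    df <- data.frame(x_um = sub$x_um + stats::rnorm(n, 0, noise_sd_um),
                     y_um = sub$y_um + stats::rnorm(n, 0, noise_sd_um),
                     z_um = sub$z_um + stats::rnorm(n, 0, noise_sd_um),
                     true_kt_id = sub$kt_id)
    df
  })
}

#' Score track identity against simulator ground truth
#'
#' Fraction of non-gap track samples carrying the same true KT identity as
#' the majority identity of their track.
#'
#' @param track_set a `track_set` built from [spots_from_bundle()] output
#' @param spots_by_frame the same detection lists (with `true_kt_id`)
#' @return list with `accuracy` (overall) and `per_track`
#' @export
track_identity_accuracy <- function(track_set, spots_by_frame) {
  tr <- track_set$tracks[!track_set$tracks$gap, ]
  truth <- character(nrow(tr))
  for (r in seq_len(nrow(tr))) {
    det <- spots_by_frame[[tr$frame[r] + 1L]]
    j <- which(abs(det$x_um - tr$x_um[r]) < 1e-9 &
               abs(det$y_um - tr$y_um[r]) < 1e-9)
    truth[r] <- if (length(j) == 1L) det$true_kt_id[j] else NA_character_
  }
  tr$truth <- truth
  per <- vapply(split(tr, tr$track_id), function(s) {
    tab <- table(s$truth)
    max(tab) / nrow(s)
  }, numeric(1))
  total <- sum(vapply(split(tr, tr$track_id), function(s) {
    max(table(s$truth))
  }, numeric(1)))
  list(accuracy = total / nrow(tr), per_track = per)
}
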