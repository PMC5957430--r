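# Per-pair kinematic parameters: V_KT (frame-to-frame KT speed), A_KT (angle
# between the intra-pair axis and the spindle axis) and D_KT (intra-pair
# KT-KT distance), plus estimation of the spindle reference frame.

#' Frame-to-frame kinetochore speed
#'
#' Raw Euclidean 3D displacement between consecutive frames divided by the
#' frame interval; no temporal smoothing by default (an optional 3-frame
#' running median is available behind `smooth`). Gap-flagged samples yield
#' missing values, never zeros.
#'
#' @param track data.frame with columns `frame`, `x_um`, `y_um`, `z_um` and
#'   optionally `gap` (logical, interpolated samples)
#' @param frame_interval_s frame interval in seconds
#' @param smooth apply a 3-frame running median (default FALSE)
#' @return numeric vector of length `nrow(track) - 1`, um/s
#' @export
compute_vkt <- function(track, frame_interval_s, smooth = FALSE) {
  if (nrow(track) < 2L) {
    stop("a single-sample track has no defined velocity", call. = FALSE)
  }
  if (is.unsorted(track$frame, strictly = TRUE)) {
    stop("track frames must be strictly increasing", call. = FALSE)
  }
  stop_if_not_positive(frame_interval_s, "frame_interval_s")
  d <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2 + diff(track$z_um)^2)
  v <- d / (diff(track$frame) * frame_interval_s)
  if (!is.null(track$gap)) {
    bad <- track$gap[-1] | track$gap[-nrow(track)]
    v[bad] <- NA_real_
  }
  if (smooth && length(v) >= 3L) {
    v <- stats::runmed(v, 3L, endrule = "keep")
  }
  v
}

#' Angle between the pair axis and the spindle axis
#'
#' Unsigned acute angle, degrees in \[0, 90\]. Invariant under exchange of
#' the two KTs and under a sign flip of the spindle axis. Coincident KT
#' positions give a missing value (the angle is undefined).
#'
#' @param p1,p2 n x 3 matrices (or data.frames) of the two KT positions, um
#' @param axis spindle axis vector (need not be normalized)
#' @return numeric vector of angles in degrees
#' @export
compute_akt <- function(p1, p2, axis) {
  p1 <- as.matrix(p1); p2 <- as.matrix(p2)
  stopifnot(ncol(p1) == 3L, ncol(p2) == 3L, nrow(p1) == nrow(p2))
  v <- p1 - p2
  nv <- sqrt(rowSums(v^2))
  na <- vec_norm(axis)
  cosang <- abs(v %*% axis) / (nv * na)
  ang <- acos(pmin(1, pmax(0, cosang))) * 180 / pi
  ang[nv == 0] <- NA_real_
  as.numeric(ang)
}

#' Distance between the two KTs of a pair
#'
#' Euclidean 3D distance in um; missing positions propagate to missing
#' values.
#'
#' @inheritParams compute_akt
#' @return numeric vector, um
#' @export
compute_dkt <- function(p1, p2) {
  p1 <- as.matrix(p1); p2 <- as.matrix(p2)
  stopifnot(ncol(p1) == 3L, ncol(p2) == 3L, nrow(p1) == nrow(p2))
  sqrt(rowSums((p1 - p2)^2))
}

#' Estimate the spindle reference frame
#'
#' The spindle axis is the average direction of all intra-pair KT vectors
#' over a metaphase window (about 35 frames by default). Vector origins are
#' chosen so that all origins migrate to the same spindle pole during
#' anaphase: the post-anaphase displacement of each KT decides which member
#' of a pair is the origin. If no anaphase information is available the
#' first principal component of the metaphase pair vectors is used instead
#' and the frame is flagged (`oriented = FALSE`, arbitrary sign).
#'
#' @param tracks data.frame with columns `kt_id`, `pair_id`, `member`,
#'   `frame`, `t_s`, `x_um`, `y_um`, `z_um` (two members per pair)
#' @param metaphase_window integer vector of frames inside metaphase
#' @param anaphase_onset_s anaphase onset time (s), or NA when unknown
#' @param frame_interval_s frame interval (s)
#' @return an object of class `spindle_frame`: list with `axis` (unit
#'   vector), `center` (um), `poles` (2 x 3 matrix or NULL), `oriented`,
#'   `window`
#' @export
estimate_spindle_axis <- function(tracks, metaphase_window,
                                  anaphase_onset_s = NA,
                                  frame_interval_s = 10) {
  frames_avail <- sort(unique(tracks$frame))
  metaphase_window <- intersect(metaphase_window, frames_avail)
  if (length(metaphase_window) < 5L) {
    stop("metaphase window must cover at least 5 available frames",
         call. = FALSE)
  }
  pairs <- sort(unique(tracks$pair_id))
  if (length(pairs) < 1L) stop("need at least one pair", call. = FALSE)

  win <- tracks[tracks$frame %in% metaphase_window, ]
  pair_vec <- function(df) {
    m1 <- df[df$member == 1L, c("x_um", "y_um", "z_um")]
    m2 <- df[df$member == 2L, c("x_um", "y_um", "z_um")]
    as.matrix(m1) - as.matrix(m2)
  }

  oriented <- FALSE
  orient_sign <- stats::setNames(rep(1, length(pairs)), pairs)
  if (is.finite(anaphase_onset_s)) {
    # which member of each pair migrates toward the reference pole?
    t_max <- max(tracks$t_s)
    a0 <- anaphase_onset_s
    a1 <- min(a0 + 150, t_max)
    disp <- lapply(split(tracks, tracks$kt_id), function(df) {
      i0 <- which.min(abs(df$t_s - a0)); i1 <- which.min(abs(df$t_s - a1))
      c(df$x_um[i1] - df$x_um[i0], df$y_um[i1] - df$y_um[i0],
        df$z_um[i1] - df$z_um[i0])
    })
    ref <- NULL
    for (d in disp) if (vec_norm(d) > 0.5) { ref <- normalize(d); break }
    if (!is.null(ref)) {
      oriented <- TRUE
      for (p in pairs) {
        sub <- tracks[tracks$pair_id == p, ]
        d1 <- disp[[unique(sub$kt_id[sub$member == 1L])[1]]]
        # member 1 is the origin when it migrates with the reference pole
        orient_sign[as.character(p)] <- if (sum(d1 * ref) >= 0) -1 else 1
      }
    }
  }

  vs <- do.call(rbind, lapply(pairs, function(p) {
    v <- pair_vec(win[win$pair_id == p, ])
    v * orient_sign[as.character(p)]
  }))
  vs <- vs[rowSums(vs^2) > 0, , drop = FALSE]
  un <- vs / sqrt(rowSums(vs^2))

  if (oriented) {
    axis <- normalize(colMeans(un))
  } else {
    # PCA fallback, arbitrary sign
    axis <- normalize(stats::prcomp(un, center = FALSE)$rotation[, 1])
  }
  # robust plate center: median over per-KT mean positions, so that a few
  # pole-parked KTs (e.g. class III univalents) do not drag the equator
  per_kt <- t(vapply(split(win, win$kt_id), function(df) {
    colMeans(as.matrix(df[, c("x_um", "y_um", "z_um")]))
  }, numeric(3)))
  center <- apply(per_kt, 2, stats::median)
  structure(list(axis = as.numeric(axis), center = as.numeric(center),
                 poles = NULL, oriented = oriented,
                 window = range(metaphase_window)),
            class = "spindle_frame")
}

#' @export
print.spindle_frame <- function(x, ...) {
  cat(sprintf("<spindle_frame> axis=(%.3f, %.3f, %.3f) %s, frames %d..%d\n",
              x$axis[1], x$axis[2], x$axis[3],
              if (x$oriented) "oriented by anaphase destinations"
              else "PCA fallback (arbitrary sign)",
              x$window[1], x$window[2]))
  invisible(x)
}

#' Per-pair kinematic series for a cell
#'
#' Computes V_KT for each KT, and A_KT / D_KT for each pair, from a long
#' track table.
#'
#' @inheritParams estimate_spindle_axis
#' @param spindle a `spindle_frame` (for A_KT); NULL skips A_KT
#' @return data.frame with one row per pair per frame: `pair_id`, `frame`,
#'   `t_s`, `v_kt_a`, `v_kt_b` (um/s, NA at the first frame), `a_kt_deg`,
#'   `d_kt_um`
#' @export
kinematic_series <- function(tracks, spindle = NULL, frame_interval_s = 10) {
  out <- lapply(sort(unique(tracks$pair_id)), function(p) {
    sub <- tracks[tracks$pair_id == p, ]
    m1 <- sub[sub$member == 1L, ][order(sub$frame[sub$member == 1L]), ]
    m2 <- sub[sub$member == 2L, ][order(sub$frame[sub$member == 2L]), ]
    common <- intersect(m1$frame, m2$frame)
    m1 <- m1[m1$frame %in% common, ]
    m2 <- m2[m2$frame %in% common, ]
    p1 <- as.matrix(m1[, c("x_um", "y_um", "z_um")])
    p2 <- as.matrix(m2[, c("x_um", "y_um", "z_um")])
    v1 <- c(NA, compute_vkt(m1, frame_interval_s))
    v2 <- c(NA, compute_vkt(m2, frame_interval_s))
    a <- if (!is.null(spindle)) compute_akt(p1, p2, spindle$axis) else NA_real_
    data.frame(pair_id = p, frame = m1$frame, t_s = m1$t_s,
               v_kt_a = v1, v_kt_b = v2, a_kt_deg = a,
               d_kt_um = compute_dkt(p1, p2))
  })
  do.call(rbind, out)
}
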