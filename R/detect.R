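# Kinetochore spot detection and sub-resolution sister separation.
#
# Detection is scale-matched blob detection: a Laplacian-of-Gaussian filter
# at the sigma implied by the nominal spot diameter (500 nm for Cid/Mis12
# dots), local-maximum extraction with a noise-adaptive threshold, and
# intensity-weighted sub-voxel refinement.

# separable 3D Gaussian smoothing, sigma in voxels per axis
gauss_smooth3d <- function(arr, sigma_vox) {
  k <- function(s) {
    if (s <= 0) return(1)
    r <- max(1L, ceiling(3 * s))
    w <- exp(-(seq(-r, r))^2 / (2 * s^2))
    w / sum(w)
  }
  convolve_axis <- function(a, w, axis) {
    if (length(w) == 1L) return(a)
    d <- dim(a)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    r <- (length(w) - 1L) / 2L
    # replicate-pad and filter columns
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
                m[rep(nrow(m), r), , drop = FALSE])
    out <- stats::filter(mp, w, sides = 2)
    out <- matrix(out[(r + 1L):(r + nrow(m)), ], nrow = nrow(m))
    out[is.na(out)] <- 0
    ao <- array(out, dp)
    aperm(ao, order(perm))
  }
  for (ax in 1:3) arr <- convolve_axis(arr, k(sigma_vox[ax]), ax)
  arr
}

# 26-connected local maxima of a 3D array above a threshold
local_maxima3d <- function(arr, threshold) {
  d <- dim(arr)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  is_max <- array(TRUE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- pad[(2:(d[1] + 1)) + dx, (2:(d[2] + 1)) + dy, (2:(d[3] + 1)) + dz]
    is_max <- is_max & (arr >= nb)
  }
  which(is_max & arr > threshold, arr.ind = TRUE)
}

#' Detect kinetochore spots in one 3D stack
#'
#' Scale-matched Laplacian-of-Gaussian detection: the stack is smoothed at
#' the sigma implied by the nominal spot diameter (sigma = d / (2 sqrt(3)),
#' the LoG radius-matching relation), the negative discrete Laplacian is
#' taken as blob response, and responses that are 26-connected local maxima
#' above a noise-adaptive threshold (`nsigma` response s.d., combined with
#' `threshold_rel` of the strongest response) become spots. Positions are
#' refined by an intensity-weighted centroid and reported in um with the
#' voxel-center convention (0-based voxel origin).
#'
#' @param stack 3D array with attribute `voxel_nm`, or pass `voxel_nm`
#' @param voxel_nm voxel size (x, y, z) in nm
#' @param diameter_nm nominal spot diameter (default 500 nm)
#' @param threshold_rel fraction of the maximal blob response below which
#'   maxima are discarded (default 0.25)
#' @param nsigma absolute noise floor in response s.d. units (default 8)
#' @return data.frame sorted by decreasing intensity: `x_um`, `y_um`,
#'   `z_um`, `intensity` (integrated, background-subtracted), `elongation`
#'   (x-y principal-axis ratio >= 1), `response`
#' @export
detect_spots <- function(stack, voxel_nm = attr(stack, "voxel_nm"),
                         diameter_nm = 500, threshold_rel = 0.25,
                         nsigma = 8) {
  if (is.null(voxel_nm)) {
    stop("stack is not calibrated: voxel_nm is required", call. = FALSE)
  }
  if (length(stack) == 0) return(empty_spots())
  if (diameter_nm <= 2 * min(voxel_nm[1:2])) {
    stop("diameter must exceed twice the voxel size", call. = FALSE)
  }
  d <- dim(stack)
  sigma_nm <- diameter_nm / (2 * sqrt(3))
  sigma_vox <- pmax(0.5, sigma_nm / voxel_nm)
  sm <- gauss_smooth3d(stack, sigma_vox)

  # negative 6-neighbour Laplacian of the smoothed stack as blob response
  resp <- array(0, d)
  core <- sm * 6
  shift <- function(a, ax, by) {
    idx <- lapply(dim(a), seq_len)
    idx[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), dim(a)[ax])
    do.call(`[`, c(list(a), idx))
  }
  for (ax in 1:3) {
    core <- core - shift(sm, ax, 1L) - shift(sm, ax, -1L)
  }
  resp <- core
  thr <- max(threshold_rel * max(resp), nsigma * stats::sd(resp))
  mx <- local_maxima3d(resp, thr)
  if (nrow(mx) == 0L) return(empty_spots())

  vx <- voxel_nm / 1000
  bg <- stats::median(stack)
  rwin <- pmax(1L, round(2.5 * sigma_vox))
  spots <- lapply(seq_len(nrow(mx)), function(k) {
    ijk <- mx[k, ]
    i0 <- pmax(ijk - rwin, 1L); i1 <- pmin(ijk + rwin, d)
    sub <- stack[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
    w <- pmax(sub - bg, 0)
    if (sum(w) == 0) return(NULL)
    gx <- voxel_centers(d[1], vx[1])[i0[1]:i1[1]]
    gy <- voxel_centers(d[2], vx[2])[i0[2]:i1[2]]
    gz <- voxel_centers(d[3], vx[3])[i0[3]:i1[3]]
    sw <- sum(w)
    cxw <- sum(apply(w, 1, sum) * gx) / sw
    cyw <- sum(apply(w, 2, sum) * gy) / sw
    czw <- sum(apply(w, 3, sum) * gz) / sw
    # x-y principal-axis ratio from second moments
    wxy <- apply(w, c(1, 2), sum)
    mux <- sum(rowSums(wxy) * gx) / sw
    muy <- sum(colSums(wxy) * gy) / sw
    vxx <- sum(wxy * outer((gx - mux)^2, rep(1, length(gy)))) / sw
    vyy <- sum(wxy * outer(rep(1, length(gx)), (gy - muy)^2)) / sw
    vxy <- sum(wxy * outer(gx - mux, gy - muy)) / sw
    ev <- eigen(matrix(c(vxx, vxy, vxy, vyy), 2), symmetric = TRUE)$values
    elong <- sqrt(max(ev[1], 1e-12) / max(ev[2], 1e-12))
    data.frame(x_um = cxw, y_um = cyw, z_um = czw, intensity = sw,
               elongation = elong, response = resp[ijk[1], ijk[2], ijk[3]])
  })
  spots <- do.call(rbind, spots[!vapply(spots, is.null, TRUE)])
  if (is.null(spots) || nrow(spots) == 0L) return(empty_spots())
  # merge duplicate maxima closer than half the nominal diameter
  ord <- order(spots$response, decreasing = TRUE)
  spots <- spots[ord, ]
  keep <- rep(TRUE, nrow(spots))
  for (i in seq_len(nrow(spots))) {
    if (!keep[i]) next
    if (i < nrow(spots)) {
      for (j in (i + 1):nrow(spots)) {
        if (!keep[j]) next
        dd <- sqrt((spots$x_um[i] - spots$x_um[j])^2 +
                   (spots$y_um[i] - spots$y_um[j])^2 +
                   (spots$z_um[i] - spots$z_um[j])^2)
        if (dd * 1000 < diameter_nm / 2) keep[j] <- FALSE
      }
    }
  }
  spots <- spots[keep, ]
  spots <- spots[order(spots$intensity, decreasing = TRUE), ]
  rownames(spots) <- NULL
  spots
}

empty_spots <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
             intensity = numeric(0), elongation = numeric(0),
             response = numeric(0))
}

# connected components (4/8-neighbour, 2D) of a logical mask; returns count
count_blobs2d <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  cur <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      i <- (q - 1L) %% d[1] + 1L
      j <- (q - 1L) %/% d[1] + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || jj < 1 || ii > d[1] || jj > d[2]) next
        p <- (jj - 1L) * d[1] + ii
        if (mask[p] && lab[p] == 0L) {
          lab[p] <- cur
          queue <- c(queue, p)
        }
      }
    }
  }
  cur
}

#' Estimate sister-KT separation inside one blob
#'
#' Emulates the manual two-sphere procedure for a single (possibly
#' elongated) kinetochore blob. If two distinct intensity maxima are
#' resolvable, their sub-voxel peak positions are returned
#' (`resolved = TRUE`). Otherwise the blob is analyzed along its longest
#' in-plane principal axis: for a symmetric two-emitter model the
#' intensity-weighted variance along the major axis exceeds the variance
#' along the minor axis by (d/2)^2, so the separation is estimated as
#' `2 * sqrt(var_major - var_minor)` (`resolved = FALSE`). The minor-axis
#' variance doubles as an internal PSF-width calibration, which makes the
#' estimate robust to the exact PSF width, pixelation and uniform noise.
#' Because an unresolved blob constrains the separation only from above,
#' the value is an approximate upper-bound-style estimate; separations
#' below `floor_nm` are reported as censored at the floor rather than as a
#' point estimate.
#'
#' @param region 2D matrix (x-y view) or 3D array containing exactly one
#'   above-threshold blob, with attribute `voxel_nm` (or pass `voxel_nm`)
#' @param voxel_nm voxel size in nm
#' @param floor_nm reporting floor (default 150 nm)
#' @param peak_frac threshold, as a fraction of the blob peak, used for
#'   blob segmentation (default 0.5)
#' @return list with `distance_nm`, `resolved`, `censored`, `centers`
#'   (2 x 2 matrix, um), `elongation` (major/minor axis s.d. ratio)
#' @export
estimate_pair_separation <- function(region,
                                     voxel_nm = attr(region, "voxel_nm"),
                                     floor_nm = 150, peak_frac = 0.5) {
  if (is.null(voxel_nm)) {
    stop("region is not calibrated: voxel_nm is required", call. = FALSE)
  }
  img <- if (length(dim(region)) == 3L) {
    apply(region, c(1, 2), sum)          # x-y view; z not used for pairing
  } else as.matrix(region)
  vx <- voxel_nm[1] / 1000
  vy <- voxel_nm[2] / 1000
  d <- dim(img)
  gx <- voxel_centers(d[1], vx)
  gy <- voxel_centers(d[2], vy)

  # light smoothing stabilizes maxima detection without washing out peaks
  sm <- gauss_smooth2d(img, 0.8)
  bg <- stats::median(sm)
  peak <- max(sm)
  mask <- sm - bg >= peak_frac * (peak - bg)
  nb <- count_blobs2d(mask)
  if (nb == 0L) stop("no above-threshold blob in region", call. = FALSE)
  if (nb > 2L) stop("region contains more than one object (", nb,
                    " components); pass a single-blob region", call. = FALSE)

  w <- pmax(img - bg, 0)
  sw <- sum(w)
  mux <- sum(rowSums(w) * gx) / sw
  muy <- sum(colSums(w) * gy) / sw
  vxx <- sum(w * outer((gx - mux)^2, rep(1, d[2]))) / sw
  vyy <- sum(w * outer(rep(1, d[1]), (gy - muy)^2)) / sw
  vxy <- sum(w * outer(gx - mux, gy - muy)) / sw
  eg <- eigen(matrix(c(vxx, vxy, vxy, vyy), 2), symmetric = TRUE)
  elong <- sqrt(max(eg$values[1], 1e-12) / max(eg$values[2], 1e-12))

  # are two maxima resolvable?
  mx <- local_maxima2d(sm, bg + 0.35 * (peak - bg))
  resolved <- FALSE
  centers <- NULL
  if (nrow(mx) >= 2L) {
    ord <- order(sm[mx], decreasing = TRUE)
    mx <- mx[ord[1:2], , drop = FALSE]
    sep_vox <- sqrt(sum((mx[1, ] - mx[2, ])^2))
    if (sep_vox >= 2) {
      resolved <- TRUE
      centers <- t(apply(mx, 1, function(ij) refine_peak2d(img, bg, ij, gx, gy)))
    }
  }
  if (resolved) {
    dist_um <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  } else {
    dist_um <- 2 * sqrt(max(0, eg$values[1] - eg$values[2]))
    u <- eg$vectors[, 1]
    centers <- rbind(c(mux, muy) + 0.5 * dist_um * u,
                     c(mux, muy) - 0.5 * dist_um * u)
  }
  censored <- dist_um * 1000 < floor_nm
  list(distance_nm = if (censored) floor_nm else dist_um * 1000,
       resolved = resolved, censored = censored,
       centers = centers, elongation = elong)
}

gauss_smooth2d <- function(img, sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  pad_filter <- function(m) {
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
                m[rep(nrow(m), r), , drop = FALSE])
    out <- stats::filter(mp, w, sides = 2)   # column-wise
    matrix(out[(r + 1L):(r + nrow(m)), ], nrow = nrow(m))
  }
  t(pad_filter(t(pad_filter(img))))
}

local_maxima2d <- function(img, threshold) {
  d <- dim(img)
  pad <- matrix(-Inf, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- img
  is_max <- matrix(TRUE, d[1], d[2])
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    is_max <- is_max & (img >= pad[(2:(d[1] + 1)) + dx, (2:(d[2] + 1)) + dy])
  }
  which(is_max & img > threshold, arr.ind = TRUE)
}

# parabolic sub-voxel refinement of a 2D peak on the raw image
refine_peak2d <- function(img, bg, ij, gx, gy) {
  d <- dim(img)
  i <- ij[1]; j <- ij[2]
  sub1 <- function(v, c0) {
    # 3-point parabola vertex offset in voxel units
    if (any(!is.finite(v)) || (v[1] - 2 * v[2] + v[3]) >= 0) return(0)
    0.5 * (v[1] - v[3]) / (v[1] - 2 * v[2] + v[3])
  }
  oi <- 0; oj <- 0
  if (i > 1 && i < d[1]) oi <- sub1(img[(i - 1):(i + 1), j])
  if (j > 1 && j < d[2]) oj <- sub1(img[i, (j - 1):(j + 1)])
  c(gx[i] + oi * (gx[2] - gx[1]), gy[j] + oj * (gy[2] - gy[1]))
}

#' Integrated kinetochore signal per frame
#'
#' Segments each detected spot at a fraction of its local peak and sums the
#' voxel intensities over the union of segmented volumes, one scalar per
#' frame.
#'
#' @param stack 3D array with `voxel_nm` attribute
#' @param spots data.frame from [detect_spots()]
#' @param voxel_nm voxel size in nm
#' @param peak_frac segmentation threshold as a fraction of each spot's
#'   peak (default 0.5)
#' @param radius_nm maximal segmentation radius around each spot
#' @return scalar total intensity; 0 (with a warning) when `spots` is empty
#' @export
quantify_kt_intensity <- function(stack, spots,
                                  voxel_nm = attr(stack, "voxel_nm"),
                                  peak_frac = 0.5, radius_nm = 600) {
  if (is.null(voxel_nm)) {
    stop("stack is not calibrated: voxel_nm is required", call. = FALSE)
  }
  if (nrow(spots) == 0L) {
    warning("no spots supplied; total KT intensity is 0")
    return(0)
  }
  d <- dim(stack)
  vx <- voxel_nm / 1000
  sel <- array(FALSE, d)
  rw <- pmax(1L, round(radius_nm / voxel_nm))
  for (k in seq_len(nrow(spots))) {
    ijk <- round(c(spots$x_um[k] / vx[1] + (d[1] + 1) / 2,
                   spots$y_um[k] / vx[2] + (d[2] + 1) / 2,
                   spots$z_um[k] / vx[3] + (d[3] + 1) / 2))
    i0 <- pmax(ijk - rw, 1L); i1 <- pmin(ijk + rw, d)
    sub <- stack[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
    thr <- peak_frac * max(sub)
    selsub <- sel[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
    sel[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- selsub | (sub >= thr)
  }
  sum(stack[sel])
}

#' Per-frame sister-separation series for one kinetochore dot
#'
#' Renders the x-y region around a conjoined sister-KT dot at every frame
#' from its two true emitter positions and runs
#' [estimate_pair_separation()] on each, producing the per-frame series
#' that the breathing detector consumes.
#'
#' @param sep_um numeric vector of true separations per frame (um)
#' @param optics an [optics_config()]
#' @param seed integer seed
#' @param floor_nm passed to the estimator
#' @return data.frame: `frame` (0-based), `distance_nm`, `resolved`,
#'   `censored`
#' @export
pair_separation_series <- function(sep_um, optics, seed, floor_nm = 150) {
  set.seed(as.integer(seed))
  angles <- stats::runif(length(sep_um), 0, pi)
  out <- lapply(seq_along(sep_um), function(i) {
    img <- render_pair_region(sep_um[i] * 1000, optics,
                              axis_angle_rad = angles[i])
    est <- estimate_pair_separation(img)
    data.frame(frame = i - 1L, distance_nm = est$distance_nm,
               resolved = est$resolved, censored = est$censored)
  })
  do.call(rbind, out)
}
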