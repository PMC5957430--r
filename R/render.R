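# Fluorescence rendering: each kinetochore is a 3D Gaussian blob (the PSF
# dominates a sub-resolution emitter) sampled on a calibrated voxel grid with
# Poisson photon noise plus Gaussian camera noise.

# voxel-center coordinate of voxel i (1-based) along an axis with n voxels:
# ((i - (n + 1) / 2)) * voxel_size; the stack is centered on the origin.
voxel_centers <- function(n, step_um) (seq_len(n) - (n + 1) / 2) * step_um

#' Render one 3D stack from point emitters
#'
#' @param points_um matrix (n x 3) of emitter positions in um, origin at the
#'   stack center
#' @param optics an [optics_config()]
#' @param amplitudes per-emitter peak photon counts (default
#'   `optics$photon_scale`)
#' @param noise add Poisson photon noise and Gaussian camera noise
#' @return 3D array (x, y, z) with attributes `voxel_nm`
#' @export
render_stack <- function(points_um, optics, amplitudes = NULL, noise = TRUE) {
  stopifnot(inherits(optics, "optics_config"))
  points_um <- matrix(as.numeric(points_um), ncol = 3)
  dims <- optics$stack_dim
  vx <- optics$voxel_nm / 1000
  cx <- voxel_centers(dims[1], vx[1])
  cy <- voxel_centers(dims[2], vx[2])
  cz <- voxel_centers(dims[3], vx[3])
  half <- c(max(abs(cx)) + vx[1] / 2, max(abs(cy)) + vx[2] / 2,
            max(abs(cz)) + vx[3] / 2)
  out_of_volume <- abs(points_um[, 1]) > half[1] |
    abs(points_um[, 2]) > half[2] | abs(points_um[, 3]) > half[3]
  if (any(out_of_volume)) {
    stop("emitter position(s) outside the rendered volume: rows ",
         paste(which(out_of_volume), collapse = ", "), call. = FALSE)
  }
  sl <- optics$psf_sigma_nm[1] / 1000
  sa <- optics$psf_sigma_nm[2] / 1000
  if (is.null(amplitudes)) amplitudes <- rep(optics$photon_scale,
                                             nrow(points_um))
  arr <- array(0, dims)
  for (k in seq_len(nrow(points_um))) {
    gx <- exp(-(cx - points_um[k, 1])^2 / (2 * sl^2))
    gy <- exp(-(cy - points_um[k, 2])^2 / (2 * sl^2))
    gz <- exp(-(cz - points_um[k, 3])^2 / (2 * sa^2))
    arr <- arr + amplitudes[k] * (gx %o% gy %o% gz)
  }
  arr <- arr + optics$background
  if (noise) {
    n <- length(arr)
    arr[] <- stats::rpois(n, arr) + stats::rnorm(n, 0, optics$camera_sd)
  }
  attr(arr, "voxel_nm") <- optics$voxel_nm
  arr
}

#' Render a two-channel movie from a simulated cell
#'
#' Channel 1 carries the kinetochore blobs (one Gaussian per true KT
#' position; unresolved sister pairs merge naturally), channel 2 a chromatin
#' / nucleoplasm proxy: a broad central blob whose diffuse component follows
#' the nucleoplasmic proxy signal, so that NEBD is visible as a precipitous
#' drop.
#'
#' @param bundle a `kt_bundle` from [simulate_cell()]
#' @param optics an [optics_config()]
#' @param seed integer seed for the rendering noise
#' @param frames integer vector of frame indices to render (default all)
#' @return object of class `kt_movie`: list of per-frame lists with
#'   elements `kt` and `chromatin` (3D arrays), plus calibration metadata
#' @export
render_movie <- function(bundle, optics, seed, frames = NULL) {
  stopifnot(inherits(bundle, "kt_bundle"))
  set.seed(as.integer(seed))
  pos <- bundle$positions
  if (is.null(frames)) frames <- sort(unique(pos$frame))
  prox <- bundle$proxies
  nuc_blob_sigma <- optics_config(psf_sigma_nm = c(2500, 1500),
                                  voxel_nm = optics$voxel_nm,
                                  photon_scale = optics$photon_scale / 4,
                                  background = optics$background,
                                  camera_sd = optics$camera_sd,
                                  stack_dim = optics$stack_dim)
  out <- lapply(frames, function(f) {
    sub <- pos[pos$frame == f, ]
    pts <- as.matrix(sub[, c("x_um", "y_um", "z_um")])
    kt <- render_stack(pts, optics, noise = TRUE)
    nuc_level <- prox$nucleoplasmic[match(f, prox$frame)]
    chrom <- render_stack(matrix(0, 1, 3), nuc_blob_sigma,
                          amplitudes = nuc_blob_sigma$photon_scale *
                            max(0.05, nuc_level), noise = TRUE)
    list(kt = kt, chromatin = chrom)
  })
  structure(list(frames = out, frame_index = frames,
                 frame_interval_s = bundle$frame_interval_s,
                 optics = optics, cell_id = bundle$cell_id),
            class = "kt_movie")
}

#' Write / read a movie as multi-page TIFF
#'
#' Pages are ordered T, then Z, then C (dimension order TZCYX). Intensities
#' are scaled to \[0, 1\] floats; the scale, channel order, voxel
#' calibration and frame interval are stored in a JSON sidecar file
#' (`<path>.json`) because the installed TIFF writer does not expose the
#' description tag.
#'
#' @param movie a `kt_movie`
#' @param path output file
#' @return `read_movie_tiff` returns a list of per-frame channel arrays and
#'   metadata
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "kt_movie"))
  pages <- list()
  mx <- max(vapply(movie$frames, function(fr) max(fr$kt, fr$chromatin),
                   numeric(1)))
  for (fr in movie$frames) {
    for (z in seq_len(dim(fr$kt)[3])) {
      for (ch in c("kt", "chromatin")) {
        # transpose: TIFF pages are row-major (y, x)
        pages[[length(pages) + 1L]] <- t(pmax(fr[[ch]][, , z], 0)) / mx
      }
    }
  }
  meta <- list(
    dimension_order = "TZCYX",
    n_t = length(movie$frames), n_z = dim(movie$frames[[1]]$kt)[3],
    n_c = 2L, channels = c("kt", "chromatin"),
    voxel_nm = movie$optics$voxel_nm,
    frame_interval_s = movie$frame_interval_s,
    intensity_scale = mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param path TIFF file written by [write_movie_tiff()]
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  nz <- meta$n_z; nc <- meta$n_c; nt <- meta$n_t
  frames <- vector("list", nt)
  i <- 1L
  for (tix in seq_len(nt)) {
    chans <- list(kt = NULL, chromatin = NULL)
    planes <- list(kt = list(), chromatin = list())
    for (z in seq_len(nz)) {
      for (ch in meta$channels) {
        planes[[ch]][[z]] <- t(pages[[i]]) * meta$intensity_scale
        i <- i + 1L
      }
    }
    for (ch in meta$channels) {
      chans[[ch]] <- array(unlist(planes[[ch]]),
                           dim = c(dim(planes[[ch]][[1]]), nz))
      attr(chans[[ch]], "voxel_nm") <- meta$voxel_nm
    }
    frames[[tix]] <- chans
  }
  list(frames = frames, meta = meta)
}

#' Render an x-y region containing one sister-KT blob
#'
#' Fast 2D render used for per-frame sister-separation estimation: two point
#' emitters `separation_nm` apart along an in-plane axis, imaged with the
#' lateral PSF, with Poisson-Gaussian noise. This emulates the
#' maximum-intensity view in which the manual two-sphere procedure operates;
#' the axial direction is not rendered because sister resolution along z is
#' not attempted.
#'
#' @param separation_nm true emitter separation
#' @param optics an [optics_config()]
#' @param axis_angle_rad in-plane orientation of the pair axis
#' @param window_um half-width of the square region
#' @param noise logical
#' @return 2D matrix with attribute `voxel_nm`
#' @export
render_pair_region <- function(separation_nm, optics,
                               axis_angle_rad = stats::runif(1, 0, pi),
                               window_um = 1.0, noise = TRUE) {
  vx <- optics$voxel_nm[1] / 1000
  n <- 2L * floor(window_um / vx) + 1L
  cc <- voxel_centers(n, vx)
  sl <- optics$psf_sigma_nm[1] / 1000
  d <- separation_nm / 1000
  u <- c(cos(axis_angle_rad), sin(axis_angle_rad))
  p1 <- 0.5 * d * u
  p2 <- -0.5 * d * u
  img <- matrix(0, n, n)
  for (p in list(p1, p2)) {
    gx <- exp(-(cc - p[1])^2 / (2 * sl^2))
    gy <- exp(-(cc - p[2])^2 / (2 * sl^2))
    img <- img + optics$photon_scale / 2 * (gx %o% gy)
  }
  img <- img + optics$background
  if (noise) {
    img[] <- stats::rpois(length(img), img) +
      stats::rnorm(length(img), 0, optics$camera_sd)
  }
  attr(img, "voxel_nm") <- optics$voxel_nm[1:2]
  img
}
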