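#' Simulation configuration for spermatocyte meiosis
#'
#' Builds the full parameter set driving the trajectory simulator. Defaults
#' are the control condition: phase durations (minutes, mean and s.d.) match
#' the live-imaging measurements for Drosophila spermatocytes (M I, IK and
#' M II each close to one hour; prometaphase A 5 +/- 1.5 min, prometaphase B
#' 9.75 +/- 3 min in M I and 7 +/- 2 min in M II; metaphase 18 min; anaphase
#' 10 min, matching the convention that the metaphase-to-anaphase transition
#' precedes telophase onset by about 10 minutes). Geometry places the two
#' spindle poles 12 um apart with a 3 um wide metaphase-plate band (one
#' quarter of the pole-to-pole distance) and a 5 um nuclear radius.
#'
#' Sister-centromere "breathing" defaults: 0.17 events per centromere dot per
#' hour, 20-40 s typical duration with a minority up to 3 min, and maximal
#' separation around 550 nm. Sister-KT separations (nm) for M II follow the
#' measured time course: about 300 +/- 160 nm at NEBD II rising to a
#' bi-oriented plateau of 950 +/- 100 nm.
#'
#' @param genotype label, one of the presets known to [make_preset()]
#' @param stage one of "MI", "IK", "MII"
#' @param n_cells cells per cyst
#' @param frame_interval_s acquisition cadence in seconds (default 10 s)
#' @param ... named overrides for any top-level field
#' @return an object of class `sim_config` (a validated named list)
#' @seealso [make_preset()], [simulate_cell()], [simulate_cyst()]
#' @export
sim_config <- function(genotype = "control", stage = "MI", n_cells = 3L,
                       frame_interval_s = 10, ...) {
  cfg <- list(
    genotype = genotype,
    stage = stage,
    n_cells = as.integer(n_cells),
    frame_interval_s = frame_interval_s,
    pre_nebd_min = 2,
    post_min = 2,
    cyst_jitter_min = 1.5,
    geometry = list(
      nuclear_radius_um = 5,
      pole_distance_um = 12,
      plate_halfwidth_um = 1.5
    ),
    phase_minutes = list(
      mi = list(pm_a = c(5, 1.5), pm_b = c(9.75, 3), metaphase = c(18, 3),
                anaphase = c(10, 2), telophase = c(15.25, 3)),
      ik = c(54, 8),
      mii = list(pm_a = c(5, 1.5), pm_b = c(7, 2), metaphase = c(18, 3),
                 anaphase = c(10, 2), telophase = c(16, 3))
    ),
    kinematics = list(
      jump_speed_um_s = 0.12,       # scale; actual jumps exceed it
      drift_speed_um_s = 0.003,     # concerted prometaphase-A drift
      jitter_prometaphase_um = 0.08,  # OU positional s.d.
      jitter_metaphase_um = 0.05,
      congression_speed_um_s = 0.035,
      anaphase_speed_um_s = 0.03,
      jumps_enabled = TRUE,
      congression_enabled = TRUE,
      tension_stabilization = TRUE,
      stabilization_onset_min = NA_real_,  # time-dependent fallback (mnm)
      precapture_min_angle_deg = 35
    ),
    excursions_mean = 2,            # completed polar<->equatorial transits per KT pair
    reorientations_per_cell = 1,
    reorientation_biorient_frac = 0.2,
    breathing = list(
      rate_per_dot_hour = 0.17,
      duration_range_s = c(20, 40),
      long_frac = 0.15,
      long_max_s = 180,
      max_amplitude_nm = 550,
      baseline_nm = c(100, 40)      # conjoined sister separation mean, sd
    ),
    separation_nm = list(           # sister-KT separation (mean, sd)
      nebd2 = c(300, 160),
      five_min = c(420, 160),
      plateau = c(950, 100)
    ),
    bivalent_nm = list(             # homolog KT-KT distance in M I (mean, sd)
      rest = c(400, 50),
      metaphase = c(1100, 80)
    ),
    univalents = FALSE,
    class_fractions = c(I = 0.30, II = 0.38, III = 0.32),
    ma_offset_min = 10
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    stop("unknown sim_config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  cfg <- validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stop_if_not_positive(cfg$frame_interval_s, "frame_interval_s")
  if (!is.finite(cfg$n_cells) || cfg$n_cells < 1L) {
    stop("n_cells must be >= 1", call. = FALSE)
  }
  if (!cfg$stage %in% c("MI", "IK", "MII")) {
    stop("stage must be one of 'MI', 'IK', 'MII'", call. = FALSE)
  }
  g <- cfg$geometry
  stop_if_not_positive(unlist(g), "geometry")
  if (2 * g$plate_halfwidth_um > g$pole_distance_um) {
    stop("metaphase-plate band width exceeds the pole-to-pole distance",
         call. = FALSE)
  }
  for (div in c("mi", "mii")) {
    ph <- cfg$phase_minutes[[div]]
    means <- vapply(ph, `[`, numeric(1), 1L)
    sds <- vapply(ph, `[`, numeric(1), 2L)
    stop_if_not_positive(means, paste0("phase_minutes$", div, " means"))
    if (any(sds < 0)) stop("phase s.d. must be non-negative", call. = FALSE)
  }
  stop_if_not_positive(cfg$phase_minutes$ik[1], "phase_minutes$ik mean")
  stop_if_not_positive(cfg$breathing$rate_per_dot_hour + 1e-12,
                       "breathing$rate_per_dot_hour")
  if (any(cfg$breathing$duration_range_s <= 0) ||
      diff(cfg$breathing$duration_range_s) < 0) {
    stop("breathing duration range must be positive and increasing",
         call. = FALSE)
  }
  if (abs(sum(cfg$class_fractions) - 1) > 1e-6) {
    stop("class_fractions must sum to 1", call. = FALSE)
  }
  cfg
}

#' Genotype presets for the simulator
#'
#' Returns a fully populated [sim_config()] for one of the genotypes or
#' treatments whose kinetochore phenomenology the simulator emulates.
#' Perturbed presets differ from `control` only in the documented fields:
#'
#' * `control`: all defaults.
#' * `mad2`: spindle-checkpoint null; the NEBD-to-anaphase interval is
#'   shortened by about 10 minutes (metaphase duration 18 -> 8 min).
#' * `mnm` / `tef`: homolog conjunction lost; eight univalents instead of
#'   four bivalents, tension-dependent attachment stabilization disabled
#'   with time-dependent stabilization setting in about 25 minutes after
#'   NEBD, about 7 excursions per KT pair, delayed M I exit, univalent
#'   classes I/II/III at fractions 30/38/32 percent.
#' * `spc105_rnai`: kinetochore-null; rapid KT jumps abolished, residual
#'   KT-independent congression, accelerated division (as in mad2).
#' * `colcemid`: microtubules depolymerized; no jumps and no congression,
#'   long checkpoint-imposed delay before exit.
#' * `fzy_rnai`: APC/C activator depleted; metaphase arrest lasting more
#'   than four hours.
#'
#' @param genotype preset label
#' @param stage,n_cells,... passed on to [sim_config()]
#' @return a `sim_config`
#' @export
make_preset <- function(genotype = "control", stage = "MI", n_cells = 3L, ...) {
  presets <- c("control", "mad2", "mnm", "tef", "spc105_rnai", "colcemid",
               "fzy_rnai")
  if (!is.character(genotype) || length(genotype) != 1L ||
      !genotype %in% presets) {
    stop("unknown genotype preset; valid presets: ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  cfg <- sim_config(genotype = genotype, stage = stage, n_cells = n_cells, ...)
  if (genotype == "mad2") {
    cfg$phase_minutes$mi$metaphase <- c(8, 3)
    cfg$phase_minutes$mii$metaphase <- c(8, 3)
  } else if (genotype %in% c("mnm", "tef")) {
    cfg$univalents <- TRUE
    cfg$kinematics$tension_stabilization <- FALSE
    cfg$kinematics$stabilization_onset_min <- 25
    # jump period runs to the stabilization onset; exit from M I is delayed
    cfg$phase_minutes$mi$pm_b <- c(20, 3)
    cfg$phase_minutes$mi$metaphase <- c(17, 3)
    cfg$excursions_mean <- 7
  } else if (genotype == "spc105_rnai") {
    cfg$kinematics$jumps_enabled <- FALSE
    cfg$phase_minutes$mi$metaphase <- c(8, 3)
    cfg$phase_minutes$mii$metaphase <- c(8, 3)
    cfg$excursions_mean <- 0
    cfg$reorientations_per_cell <- 0
  } else if (genotype == "colcemid") {
    cfg$kinematics$jumps_enabled <- FALSE
    cfg$kinematics$congression_enabled <- FALSE
    cfg$phase_minutes$mi$metaphase <- c(90, 10)  # checkpoint-imposed delay
    cfg$excursions_mean <- 0
    cfg$reorientations_per_cell <- 0
  } else if (genotype == "fzy_rnai") {
    cfg$phase_minutes$mi$metaphase <- c(260, 20)
    cfg$phase_minutes$mii$metaphase <- c(260, 20)
  }
  cfg
}

#' Optics configuration for the movie renderer
#'
#' Emulates spinning-disc confocal acquisition: 300 nm z-spacing at the
#' highest-resolution imaging mode, ~100 nm lateral sampling, a Gaussian
#' point-spread function, Poisson photon noise and Gaussian camera noise.
#'
#' @param voxel_nm voxel size (x, y, z) in nm
#' @param psf_sigma_nm PSF sigma (lateral, axial) in nm
#' @param photon_scale expected photon count at a kinetochore blob peak
#' @param background mean background level (photons)
#' @param camera_sd Gaussian read-noise s.d. (counts)
#' @param stack_dim stack size in voxels (nx, ny, nz)
#' @return an object of class `optics_config`
#' @export
optics_config <- function(voxel_nm = c(100, 100, 300),
                          psf_sigma_nm = c(120, 350),
                          photon_scale = 2000,
                          background = 100,
                          camera_sd = 5,
                          stack_dim = c(128L, 128L, 20L)) {
  stop_if_not_positive(voxel_nm, "voxel_nm")
  stop_if_not_positive(psf_sigma_nm, "psf_sigma_nm")
  stop_if_not_positive(photon_scale, "photon_scale")
  if (background < 0 || camera_sd < 0) {
    stop("background and camera_sd must be non-negative", call. = FALSE)
  }
  structure(list(voxel_nm = voxel_nm, psf_sigma_nm = psf_sigma_nm,
                 photon_scale = photon_scale, background = background,
                 camera_sd = camera_sd, stack_dim = as.integer(stack_dim)),
            class = "optics_config")
}

#' Write / read a simulation configuration as YAML
#' @param cfg a `sim_config`
#' @param path file path
#' @return `read_sim_config` returns a validated `sim_config`
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  required <- c("genotype", "stage", "n_cells", "frame_interval_s")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("config is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  base <- sim_config(genotype = raw$genotype, stage = raw$stage,
                     n_cells = raw$n_cells,
                     frame_interval_s = raw$frame_interval_s)
  merge_rec <- function(a, b) {
    for (nm in names(b)) {
      if (is.list(a[[nm]]) && is.list(b[[nm]])) {
        a[[nm]] <- merge_rec(a[[nm]], b[[nm]])
      } else {
        a[[nm]] <- if (is.list(b[[nm]])) b[[nm]] else unlist(b[[nm]])
      }
    }
    a
  }
  cfg <- merge_rec(unclass(base), raw)
  cfg$class_fractions <- stats::setNames(as.numeric(cfg$class_fractions),
                                         c("I", "II", "III"))
  cfg <- validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> genotype=%s stage=%s n_cells=%d dt=%gs\n",
              x$genotype, x$stage, x$n_cells, x$frame_interval_s))
  ph <- x$phase_minutes$mi
  cat(sprintf("  M I phases (min): %s\n",
              paste(sprintf("%s=%g+/-%g", names(ph),
                            vapply(ph, `[`, 0, 1), vapply(ph, `[`, 0, 2)),
                    collapse = " ")))
  invisible(x)
}
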