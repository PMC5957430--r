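# Pipeline glue: trajectory-table readers/writers, ground-truth JSON,
# per-cell analysis, run manifests, and the programmatic entry points the
# command-line wrapper calls.

#' Write / read a trajectory table as CSV
#'
#' Columns carry explicit units: `cell_id`, `kt_id`, `pair_id`, `member`,
#' `frame`, `t_seconds`, `x_um`, `y_um`, `z_um` (plus `gap` for tracked
#' data). The same schema is accepted for externally produced track tables
#' (`member` and `pair_id` may be absent).
#'
#' @param positions data.frame in the internal layout (`t_s` column)
#' @param path file path
#' @return `read_tracks_csv` returns a data.frame in the internal layout
#' @export
write_tracks_csv <- function(positions, path) {
  df <- positions
  names(df)[names(df) == "t_s"] <- "t_seconds"
  # 17 significant digits: doubles survive the round trip bit-exactly
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("kt_id", "frame", "t_seconds", "x_um", "y_um", "z_um")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("track CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  names(df)[names(df) == "t_seconds"] <- "t_s"
  for (nm in c("t_s", "x_um", "y_um", "z_um")) df[[nm]] <- as.double(df[[nm]])
  # frames must increase within each track
  for (id in unique(df$kt_id)) {
    fr <- df$frame[df$kt_id == id]
    if (is.unsorted(fr, strictly = TRUE)) {
      bad <- which(df$kt_id == id)[which(diff(fr) <= 0)[1] + 1L]
      stop(sprintf("non-monotone frames for track '%s' at row %d", id, bad),
           call. = FALSE)
    }
  }
  df
}

#' Write / read simulator ground truth as JSON
#' @param truth a `kt_truth`
#' @param path file path
#' @return `read_truth_json` returns a `kt_truth`
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  x$phases <- as.list(x$phases)   # keep boundary names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  raw <- jsonlite::fromJSON(path)
  raw$phases <- unlist(raw$phases)
  structure(raw, class = "kt_truth")
}

#' Analyze one cell
#'
#' Runs the trajectory-level pipeline on a simulated bundle or an external
#' track table: pair assignment (heuristic, or copied from ground truth in
#' evaluation mode), kinematics, phase scoring, excursion and
#' re-orientation detection, and univalent classification where the
#' pairing map marks univalents.
#'
#' @param x a `kt_bundle` or a track data.frame (internal layout with
#'   `pair_id` and `member`)
#' @param ground_truth optional `kt_truth` for evaluation-mode pairing
#' @param config a [phase_config()]
#' @param proxies proxy-signal data.frame (taken from the bundle when `x`
#'   is a bundle)
#' @param frame_interval_s frame interval (s)
#' @param genotype genotype label for reporting
#' @param univalents treat pairs as univalents (classification enabled)
#' @return list: `phases`, `spindle`, `kinematics`, `excursions`,
#'   `reorientations`, `classes`, `durations_min`, `genotype`, `config`
#' @export
analyze_cell <- function(x, ground_truth = NULL, config = phase_config(),
                         proxies = NULL, frame_interval_s = NULL,
                         genotype = "unknown", univalents = FALSE) {
  if (inherits(x, "kt_bundle")) {
    tracks <- x$positions
    proxies <- proxies %||% x$proxies
    frame_interval_s <- frame_interval_s %||% x$frame_interval_s
    genotype <- x$genotype
    univalents <- univalents ||
      (!is.null(ground_truth) && !is.null(ground_truth$classes))
  } else {
    tracks <- x
    if (is.null(frame_interval_s)) {
      stop("frame_interval_s is required for plain track tables",
           call. = FALSE)
    }
  }
  ann <- score_phases(tracks, proxies = proxies,
                      frame_interval_s = frame_interval_s, config = config)
  spindle <- attr(ann, "spindle")
  jump_thr <- attr(ann, "jump_threshold_um_s")
  kin <- kinematic_series(tracks, spindle = spindle,
                          frame_interval_s = frame_interval_s)

  t_nebd <- phase_time(ann, "nebd")
  t_ana <- phase_time(ann, "anaphase_onset")
  t_telo <- phase_time(ann, "telophase_onset")
  exc_end <- if (!is.na(t_ana)) t_ana else if (!is.na(t_telo)) {
    t_telo - config$ma_offset_min * 60
  } else max(tracks$t_s)
  exc_start <- if (!is.na(t_nebd)) t_nebd else min(tracks$t_s)

  excursions <- NULL
  reor <- NULL
  classes <- NULL
  if (!is.null(spindle)) {
    pair_ids <- sort(unique(tracks$pair_id))
    exc <- vapply(pair_ids, function(p) {
      sub <- tracks[tracks$pair_id == p, ]
      cen <- stats::aggregate(sub[, c("x_um", "y_um", "z_um")],
                              by = list(frame = sub$frame, t_s = sub$t_s),
                              FUN = mean)
      detect_excursions(cen, spindle, config,
                        window_s = c(exc_start, exc_end))$count
    }, numeric(1))
    excursions <- data.frame(pair_id = pair_ids, count = exc)
    reor <- detect_reorientations(tracks, spindle,
                                  frame_interval_s = frame_interval_s,
                                  jump_threshold_um_s = jump_thr,
                                  config = config)
    if (univalents && !is.na(t_telo)) {
      classes <- classify_univalents(tracks, t_telo, spindle, config)
    }
  }

  durations <- cell_durations_min(ann)
  list(phases = ann, spindle = spindle, kinematics = kin,
       excursions = excursions, reorientations = reor, classes = classes,
       durations_min = durations, genotype = genotype,
       jump_threshold_um_s = jump_thr, config = config)
}

# named intervals (minutes) from a phase annotation
cell_durations_min <- function(ann) {
  tm <- function(b) phase_time(ann, b)
  iv <- c(
    m_total = tm("interphase_onset") - tm("nebd"),
    prometaphase_a = tm("pm_b_onset") - tm("nebd"),
    prometaphase_b = tm("metaphase_onset") - tm("pm_b_onset"),
    metaphase = tm("anaphase_onset") - tm("metaphase_onset"),
    nebd_to_anaphase = tm("anaphase_onset") - tm("nebd"),
    anaphase_to_telophase = tm("telophase_onset") - tm("anaphase_onset"))
  iv / 60
}

#' Simulate to files (programmatic CLI entry point)
#'
#' Writes per-cell trajectory CSVs, ground-truth JSONs, the configuration
#' snapshot and a run manifest into `out_dir`. With `movie = TRUE` also a
#' rendered two-channel TIFF per cell.
#'
#' @param config a `sim_config`, or the path of a YAML config
#' @param out_dir output directory (created if needed)
#' @param seed integer root seed
#' @param movie render TIFF movies (default FALSE)
#' @param optics an [optics_config()] for movie rendering
#' @return invisibly, the manifest list
#' @export
cli_simulate <- function(config, out_dir, seed, movie = FALSE,
                         optics = optics_config()) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cells <- simulate_cyst(config, seed)
  files <- character(0)
  for (i in seq_along(cells)) {
    fcsv <- file.path(out_dir, sprintf("cell%02d_tracks.csv", i))
    fjson <- file.path(out_dir, sprintf("cell%02d_truth.json", i))
    write_tracks_csv(cells[[i]]$bundle$positions, fcsv)
    write_truth_json(cells[[i]]$truth, fjson)
    fprox <- file.path(out_dir, sprintf("cell%02d_proxies.csv", i))
    utils::write.csv(cells[[i]]$bundle$proxies, fprox, row.names = FALSE)
    files <- c(files, fcsv, fjson, fprox)
    if (movie) {
      ftif <- file.path(out_dir, sprintf("cell%02d_movie.tif", i))
      mov <- render_movie(cells[[i]]$bundle, optics,
                          seed = child_seed(seed, 1000L + i))
      write_movie_tiff(mov, ftif)
      files <- c(files, ftif)
    }
  }
  fcfg <- file.path(out_dir, "config.yaml")
  write_sim_config(config, fcfg)
  manifest <- write_manifest(out_dir, config = fcfg, seed = seed,
                             files = c(files, fcfg))
  invisible(manifest)
}

#' Analyze simulated or external data to files
#'
#' Reads every `*_tracks.csv` in `in_dir` (using the matching
#' `*_truth.json` for evaluation-mode pairing if present and
#' `use_ground_truth_pairing` is TRUE), runs [analyze_cell()] on each, and
#' writes per-cell kinematics CSVs, phase-annotation JSONs, a genotype
#' summary and a manifest.
#'
#' @param in_dir directory with track CSVs (as written by
#'   [cli_simulate()])
#' @param out_dir output directory
#' @param config a [phase_config()]
#' @param use_ground_truth_pairing copy pair ids from the simulator map
#'   instead of using them as stored in the CSV
#' @return invisibly, the list of per-cell analysis results
#' @export
cli_analyze <- function(in_dir, out_dir, config = phase_config(),
                        use_ground_truth_pairing = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  track_files <- sort(list.files(in_dir, pattern = "_tracks\\.csv$",
                                 full.names = TRUE))
  if (!length(track_files)) {
    stop("no *_tracks.csv files in ", in_dir, call. = FALSE)
  }
  results <- list()
  files <- character(0)
  for (f in track_files) {
    tag <- sub("_tracks\\.csv$", "", basename(f))
    tr <- read_tracks_csv(f)
    truth_file <- file.path(in_dir, paste0(tag, "_truth.json"))
    truth <- if (file.exists(truth_file)) read_truth_json(truth_file) else NULL
    proxy_file <- file.path(in_dir, paste0(tag, "_proxies.csv"))
    proxies <- if (file.exists(proxy_file)) {
      utils::read.csv(proxy_file)
    } else NULL
    dt <- if (nrow(tr) > 1) {
      fr1 <- tr[tr$kt_id == tr$kt_id[1], ]
      (fr1$t_s[2] - fr1$t_s[1]) / (fr1$frame[2] - fr1$frame[1])
    } else 10
    geno <- if (!is.null(truth)) truth$genotype else "unknown"
    uni <- !is.null(truth) && !is.null(truth$classes)
    res <- analyze_cell(tr, ground_truth = truth, config = config,
                        proxies = proxies, frame_interval_s = dt,
                        genotype = geno, univalents = uni)
    results[[tag]] <- res
    fk <- file.path(out_dir, paste0(tag, "_kinematics.csv"))
    utils::write.csv(res$kinematics, fk, row.names = FALSE)
    fp <- file.path(out_dir, paste0(tag, "_phases.json"))
    jsonlite::write_json(list(
      boundaries = res$phases,
      jump_threshold_um_s = res$jump_threshold_um_s,
      thresholds = unclass(config)), fp, auto_unbox = TRUE, digits = NA,
      na = "null", dataframe = "rows")
    files <- c(files, fk, fp)
  }
  summary <- summarize_genotypes(results)
  fs <- file.path(out_dir, "summary_phases.csv")
  if (!is.null(summary$phases)) {
    utils::write.csv(summary$phases, fs, row.names = FALSE)
    files <- c(files, fs)
  }
  write_manifest(out_dir, config = NA, seed = NA, files = files)
  invisible(results)
}

# run manifest: config snapshot reference, seeds, package version, file
# digests, timestamp
write_manifest <- function(out_dir, config, seed, files) {
  digests <- vapply(files, function(f) {
    as.character(tools::md5sum(f))
  }, "")
  manifest <- list(
    package = "ktmeiosis",
    version = as.character(utils::packageVersion("ktmeiosis")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    files = data.frame(path = basename(files), md5 = unname(digests))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(manifest)
}
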