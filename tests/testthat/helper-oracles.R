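# Independent oracles used across the suite.

# brute-force zone-sequence state machine for excursion counting: operates
# on raw axial positions, written independently of the package detector
oracle_count_transits <- function(proj, plate_hw, polar_inner) {
  zone <- function(p) {
    if (abs(p) <= plate_hw) return("E")
    if (abs(p) >= polar_inner) return("P")
    "N"
  }
  state <- "N"
  n <- 0L
  for (p in proj) {
    z <- zone(p)
    if (z == "N") next
    if (state != "N" && z != state) n <- n + 1L
    state <- z
  }
  n
}

# brute-force enumeration of all perfect matchings of track ids, returning
# the matching with minimal summed mean pair distance
oracle_best_matching <- function(pos_list, window) {
  ids <- names(pos_list)
  n <- length(ids)
  pairdist <- function(a, b) {
    pa <- pos_list[[a]]; pb <- pos_list[[b]]
    w <- pa$t_s >= window[1] & pa$t_s <= window[2]
    mean(sqrt((pa$x_um[w] - pb$x_um[w])^2 + (pa$y_um[w] - pb$y_um[w])^2 +
                (pa$z_um[w] - pb$z_um[w])^2))
  }
  enum <- function(items) {
    if (!length(items)) return(list(list()))
    a <- items[1]
    out <- list()
    for (b in items[-1]) {
      for (rest in enum(setdiff(items, c(a, b)))) {
        out[[length(out) + 1L]] <- c(list(c(a, b)), rest)
      }
    }
    out
  }
  ms <- enum(ids)
  costs <- vapply(ms, function(m) {
    sum(vapply(m, function(p) pairdist(p[1], p[2]), numeric(1)))
  }, numeric(1))
  ms[[which.min(costs)]]
}

# brute-force scan for distinct local maxima in a rendered stack
oracle_count_maxima <- function(arr, rel_threshold = 0.3) {
  d <- dim(arr)
  thr <- rel_threshold * max(arr)
  n <- 0L
  coords <- NULL
  for (i in 2:(d[1] - 1)) for (j in 2:(d[2] - 1)) for (k in 2:(d[3] - 1)) {
    v <- arr[i, j, k]
    if (v <= thr) next
    nb <- arr[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)]
    if (v >= max(nb)) {
      # require separation from previously found maxima
      if (is.null(coords) ||
          min(sqrt(rowSums((coords - matrix(c(i, j, k), nrow(coords), 3,
                                            byrow = TRUE))^2))) > 2) {
        n <- n + 1L
        coords <- rbind(coords, c(i, j, k))
      }
    }
  }
  n
}

# shared simulated fixtures (computed once per test run)
sim_cache <- new.env(parent = emptyenv())
cached_cell <- function(genotype = "control", stage = "MI", seed = 1L) {
  key <- paste(genotype, stage, seed, sep = "_")
  if (is.null(sim_cache[[key]])) {
    sim_cache[[key]] <- simulate_cell(make_preset(genotype, stage = stage),
                                      seed = seed)
  }
  sim_cache[[key]]
}

# tracks data.frame from a bundle (truth-level, already in tracks layout)
bundle_tracks <- function(bundle) bundle$positions
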