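#' Configuration for the synthetic landscape and forager generator
#'
#' The generator draws forager GPS fixes from a known resource-selection
#' structure: a point is used with probability proportional to
#' `exp(selection[category] + decay[distance bin])` over a fine lattice of
#' candidate locations, which is the generative counterpart of the
#' use-availability logistic model fitted by [fit_rsf()]. Defaults describe a
#' colony of 17 birds with around 250 usable fixes each on a 2-km farmland
#' mosaic of five foraging categories plus c. 10% non-foraging cover, with
#' selection strengths and a distance-to-nest decay typical of a breeding
#' colony of starlings on a dairy farm.
#'
#' @param seed integer RNG seed; all generator randomness derives from it.
#' @param n_birds number of tracked birds.
#' @param fixes_per_bird GPS fixes recorded per bird (before contamination).
#' @param habitat_proportions named fractions over foraging plus excluded
#'   categories; must sum to 1.
#' @param true_selection named log selection strengths relative to the
#'   reference category `Grazed` (which must be exactly 0). Categories absent
#'   from this map are never used (zero weight).
#' @param distance_decay either a numeric vector of length 10 giving the log
#'   selection of each 100-m distance bin relative to the 0-99 m bin (first
#'   element must be 0), or a single negative rate per metre.
#' @param contamination named fractions `flying`, `imprecise`, `night` of
#'   fixes flagged with positive speed, HDOP above 2.5, or a night timestamp.
#' @param bird_sd standard deviation of zero-mean Gaussian per-bird deviations
#'   added to each bird's category log-strengths (between-bird heterogeneity
#'   in selection; 0 disables).
#' @param landscape_extent_m side of the square landscape (m).
#' @param field_size_m typical field diameter (m); controls the number of
#'   Voronoi cells.
#' @param classification_radius_m radius of habitat classification (m).
#' @param start_date first tracking day (used for timestamps).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_birds = 17L,
    fixes_per_bird = 250L,
    habitat_proportions = c(
      Grazed = 0.18, ShortGrass = 0.20, BareGround = 0.22,
      Meadow = 0.13, WinterCrops = 0.166,
      Building = 0.034, Garden = 0.02, Forest = 0.04, Lake = 0.01),
    true_selection = c(
      Grazed = 0, ShortGrass = -0.94, BareGround = -1.83,
      Meadow = -2.55, WinterCrops = -3.87),
    distance_decay = c(0, -0.27, -1.05, -2.16, -3.02,
                       -4.06, -4.57, -5.61, -5.82, -4.81),
    contamination = c(flying = 0.10, imprecise = 0.10, night = 0.10),
    bird_sd = 0.5,
    landscape_extent_m = 2000,
    field_size_m = 200,
    classification_radius_m = 1000,
    start_date = "2015-05-10") {
  stopifnot(length(seed) == 1, is.finite(seed),
            n_birds >= 1, fixes_per_bird > 0,
            landscape_extent_m > 0, field_size_m > 0,
            classification_radius_m > 0, bird_sd >= 0)
  if (is.null(names(habitat_proportions)) ||
      !all(names(habitat_proportions) %in% all_categories())) {
    stop("habitat_proportions must be named with known categories",
         call. = FALSE)
  }
  if (any(habitat_proportions < 0) || any(habitat_proportions > 1) ||
      abs(sum(habitat_proportions) - 1) > 1e-9) {
    stop("habitat_proportions must lie in [0, 1] and sum to 1",
         call. = FALSE)
  }
  if (!reference_category() %in% names(true_selection) ||
      true_selection[[reference_category()]] != 0) {
    stop("true_selection must give the reference category ",
         reference_category(), " a log-strength of exactly 0", call. = FALSE)
  }
  if (length(distance_decay) == 10) {
    if (distance_decay[1] != 0) {
      stop("distance_decay[1] (bin 0-99 m) must be 0", call. = FALSE)
    }
  } else if (length(distance_decay) != 1) {
    stop("distance_decay must be length 10 (per bin) or 1 (rate per metre)",
         call. = FALSE)
  }
  stopifnot(all(c("flying", "imprecise", "night") %in% names(contamination)),
            all(contamination >= 0 & contamination < 1))
  structure(
    list(seed = as.integer(seed), n_birds = as.integer(n_birds),
         fixes_per_bird = as.integer(fixes_per_bird),
         habitat_proportions = habitat_proportions,
         true_selection = true_selection,
         distance_decay = distance_decay,
         contamination = contamination,
         bird_sd = bird_sd,
         landscape_extent_m = landscape_extent_m,
         field_size_m = field_size_m,
         classification_radius_m = classification_radius_m,
         start_date = start_date),
    class = "simulation_config")
}

#' Build the candidate-location lattice used to draw fixes
#'
#' Discretises the disc around the colony into a 10-m lattice (finer than the
#' 50-m availability grid so that availability sampling stays decoupled from
#' generation) and annotates every lattice point with habitat category and
#' distance bin. Computing this once and passing it to [simulate_fixes()]
#' avoids repeating the point-in-polygon work across replicate simulations.
#'
#' @param landscape a [landscape_map()].
#' @param spacing_m lattice spacing in metres.
#' @param max_distance_m lattice points at or beyond this distance from the
#'   colony are dropped (bins are only defined below 1000 m).
#' @return tibble with columns `x`, `y`, `category`, `distance_m`, `bin`.
#' @export
build_sampling_lattice <- function(landscape, spacing_m = 10,
                                   max_distance_m = 1000) {
  r <- min(landscape$classification_radius_m, max_distance_m)
  cx <- landscape$colony_centre[1]
  cy <- landscape$colony_centre[2]
  k <- floor((r - 1e-9) / spacing_m)
  g <- seq(-k, k) * spacing_m
  pts <- expand.grid(x = cx + g, y = cy + g)
  d <- sqrt((pts$x - cx)^2 + (pts$y - cy)^2)
  keep <- d < r
  pts <- pts[keep, ]
  d <- d[keep]
  cat <- assign_habitat(pts, landscape)
  tibble::tibble(x = pts$x, y = pts$y, category = cat,
                 distance_m = d, bin = distance_bin_index(d))
}

decay_at <- function(config, bin, distance_m) {
  if (length(config$distance_decay) == 10) {
    config$distance_decay[bin + 1L]
  } else {
    config$distance_decay * distance_m
  }
}

#' Simulate central-place forager GPS fixes
#'
#' Draws fix locations from the lattice with weight
#' `exp(selection[category] + decay[bin])` (habitat selection times
#' distance-to-nest decay), then contaminates the configured fractions of
#' fixes with flight speeds, imprecise HDOP values, or night timestamps so
#' that the QC filters of [apply_qc_filters()] have realistic work to do.
#' Clean fixes have speed exactly 0 and HDOP drawn below 2.5; flying fixes
#' draw speed uniformly on (1, 15) m/s; imprecise fixes draw HDOP on
#' (2.6, 6). Daylight fixes run at 1-minute cadence from 05:30; night fixes
#' are re-timed into the 20:00-05:30 window.
#'
#' @param landscape a [landscape_map()].
#' @param config a [simulation_config()].
#' @param lattice optional pre-built [build_sampling_lattice()] result.
#' @return tibble of raw fixes with columns `bird_id`, `timestamp`, `x_m`,
#'   `y_m`, `speed_mps`, `hdop` (plus hidden truth columns `true_category`,
#'   `true_bin` for validation).
#' @export
simulate_fixes <- function(landscape, config, lattice = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(lattice)) lattice <- build_sampling_lattice(landscape)
  sel <- config$true_selection
  known <- !is.na(lattice$category) & lattice$category %in% names(sel)
  base_w <- numeric(nrow(lattice))
  base_w[known] <- exp(sel[lattice$category[known]] +
                         decay_at(config, lattice$bin[known],
                                  lattice$distance_m[known]))
  if (!any(base_w > 0)) {
    stop("degenerate support: no lattice point has positive sampling weight",
         call. = FALSE)
  }
  withr::with_seed(config$seed * 2L + 1L, {
    per_bird <- lapply(seq_len(config$n_birds), function(b) {
      bird_id <- sprintf("S%02d", b)
      w <- base_w
      if (config$bird_sd > 0) {
        dev <- stats::rnorm(length(sel), 0, config$bird_sd)
        names(dev) <- names(sel)
        w[known] <- w[known] * exp(dev[lattice$category[known]])
      }
      n <- config$fixes_per_bird
      idx <- sample.int(nrow(lattice), n, replace = TRUE, prob = w)
      # contamination flags, independently per fix
      fly <- stats::runif(n) < config$contamination[["flying"]]
      bad <- stats::runif(n) < config$contamination[["imprecise"]]
      night <- stats::runif(n) < config$contamination[["night"]]
      # 1-minute cadence through the 05:30-20:00 daylight span, rolling over
      # to the next day; night-contaminated fixes re-timed into 20:00-05:30
      minute_of_day <- 330L + (seq_len(n) - 1L) %% 870L
      night_minutes <- c(1200:1439, 0:329)
      minute_of_day[night] <- sample(night_minutes, sum(night),
                                     replace = TRUE)
      day <- (seq_len(n) - 1L) %/% 870L
      ts <- as.POSIXct(config$start_date, tz = "UTC") +
        day * 86400 + (minute_of_day %% 1440) * 60
      tibble::tibble(
        bird_id = bird_id,
        timestamp = ts,
        x_m = lattice$x[idx],
        y_m = lattice$y[idx],
        speed_mps = ifelse(fly, stats::runif(n, 1, 15), 0),
        hdop = ifelse(bad, stats::runif(n, 2.6, 6), stats::runif(n, 0.8, 2.5)),
        true_category = lattice$category[idx],
        true_bin = lattice$bin[idx])
    })
    dplyr::bind_rows(per_bird)
  })
}

#' Write per-bird GPS logger files
#'
#' Writes one comma-delimited `.txt` file per bird with columns `bird_id`,
#' `iso_timestamp_local`, `x_m`, `y_m`, `speed_mps`, `hdop`, the format
#' consumed by [parse_logger_file()]. Coordinates are written with enough
#' digits to round-trip losslessly at sub-millimetre precision.
#'
#' @param fixes tibble of fixes as produced by [simulate_fixes()].
#' @param directory output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_logger_files <- function(fixes, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  header <- "bird_id,iso_timestamp_local,x_m,y_m,speed_mps,hdop"
  birds <- unique(fixes$bird_id)
  if (length(birds) == 0) birds <- character(0)
  paths <- vapply(birds, function(b) {
    f <- fixes[fixes$bird_id == b, ]
    path <- file.path(directory, paste0(b, ".txt"))
    lines <- sprintf("%s,%s,%.10g,%.10g,%.10g,%.10g",
                     f$bird_id,
                     format(f$timestamp, "%Y-%m-%dT%H:%M:%S"),
                     f$x_m, f$y_m, f$speed_mps, f$hdop)
    writeLines(c(header, lines), path)
    path
  }, character(1))
  if (length(birds) == 0) {
    path <- file.path(directory, "empty.txt")
    writeLines(header, path)
    paths <- path
  }
  invisible(paths)
}
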