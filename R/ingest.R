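#' Parse a GPS logger file
#'
#' Reads a delimited logger file (one per bird) with columns `bird_id`,
#' `iso_timestamp_local`, `x_m`, `y_m`, `speed_mps`, `hdop`. Rows that fail to
#' parse (unreadable timestamp or non-numeric fields) are counted and
#' reported via the `malformed` attribute and a warning, never silently
#' dropped without accounting.
#'
#' @param path path to a logger text file.
#' @param drop_first_day if `TRUE`, drop all fixes from the first calendar day
#'   in the file (a start-up exclusion for behavioural effects of capture and
#'   tagging); off by default, appropriate for synthetic data.
#' @return tibble of raw fixes (`bird_id`, `timestamp`, `x_m`, `y_m`,
#'   `speed_mps`, `hdop`) with attribute `malformed` (row count).
#' @export
parse_logger_file <- function(path, drop_first_day = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  required <- c("bird_id", "iso_timestamp_local", "x_m", "y_m",
                "speed_mps", "hdop")
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("logger file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ts <- as.POSIXct(raw$iso_timestamp_local, format = "%Y-%m-%dT%H:%M:%S",
                   tz = "UTC")
  out <- tibble::tibble(
    bird_id = raw$bird_id,
    timestamp = ts,
    x_m = suppressWarnings(as.numeric(raw$x_m)),
    y_m = suppressWarnings(as.numeric(raw$y_m)),
    speed_mps = suppressWarnings(as.numeric(raw$speed_mps)),
    hdop = suppressWarnings(as.numeric(raw$hdop)))
  bad <- is.na(out$timestamp) | is.na(out$x_m) | is.na(out$y_m) |
    is.na(out$speed_mps) | is.na(out$hdop) | is.na(out$bird_id)
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) in ", basename(path),
            call. = FALSE)
    out <- out[!bad, ]
  }
  if (drop_first_day && nrow(out) > 0) {
    first_day <- min(as.Date(out$timestamp))
    out <- out[as.Date(out$timestamp) != first_day, ]
  }
  attr(out, "malformed") <- sum(bad)
  out
}

#' Read all logger files in a directory
#'
#' @param directory directory of `.txt` logger files.
#' @param ... passed to [parse_logger_file()].
#' @return a single tibble of raw fixes.
#' @export
read_logger_directory <- function(directory, ...) {
  files <- sort(list.files(directory, pattern = "\\.txt$", full.names = TRUE))
  if (length(files) == 0) stop("no .txt logger files in ", directory,
                               call. = FALSE)
  dplyr::bind_rows(lapply(files, parse_logger_file, ...))
}

#' Quality-control filter rules for GPS fixes
#'
#' The defaults encode the foraging-fix selection rules of the analysis:
#' exclude fixes of flying birds (speed > 0.0 m/s), imprecise fixes
#' (HDOP > 2.5, roughly worse than 10 m), fixes between 20:00 and 05:30 local
#' time (movements to and from night roosts), fixes in non-foraging habitat
#' (buildings, gardens, forest, lakes), fixes at or beyond 999 m from the
#' colony centre, and finally whole birds with 50 or fewer surviving fixes
#' ("more than 50 observations" is strict). Speed and HDOP thresholds are
#' inclusive-keep: equality is retained. The night window is half-open
#' \[20:00, 05:30): 20:00 exactly is excluded, 05:30 exactly retained.
#'
#' @param max_speed_inclusive keep fixes with speed <= this (m/s).
#' @param max_hdop_inclusive keep fixes with HDOP <= this.
#' @param night_start,night_end local clock times (\"HH:MM\") bounding the
#'   excluded night window \[night_start, night_end).
#' @param excluded_categories habitat categories excluded from the analysis.
#' @param max_distance_m exclude fixes at distance >= this from the colony.
#' @param min_fixes_per_bird_exclusive drop birds with <= this many fixes
#'   after all per-fix rules.
#' @return an object of class `filter_rules`.
#' @export
filter_rules <- function(max_speed_inclusive = 0.0,
                         max_hdop_inclusive = 2.5,
                         night_start = "20:00",
                         night_end = "05:30",
                         excluded_categories = cpforage::excluded_categories(),
                         max_distance_m = 999,
                         min_fixes_per_bird_exclusive = 50L) {
  to_min <- function(s) {
    p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
    p[1] * 60L + p[2]
  }
  structure(
    list(max_speed_inclusive = max_speed_inclusive,
         max_hdop_inclusive = max_hdop_inclusive,
         night_start_min = to_min(night_start),
         night_end_min = to_min(night_end),
         excluded_categories = excluded_categories,
         max_distance_m = max_distance_m,
         min_fixes_per_bird_exclusive = as.integer(min_fixes_per_bird_exclusive)),
    class = "filter_rules")
}

in_night_window <- function(timestamp, rules) {
  m <- as.integer(format(timestamp, "%H")) * 60L +
    as.integer(format(timestamp, "%M"))
  s <- rules$night_start_min
  e <- rules$night_end_min
  if (s <= e) m >= s & m < e else m >= s | m < e
}

#' Apply the QC filters to raw fixes
#'
#' Annotates each fix with habitat category and distance to the colony, then
#' applies the exclusion rules in a fixed order — speed, HDOP, time of day,
#' excluded habitat, distance, per-bird minimum — attributing every excluded
#' fix to the first rule that rejects it. Each rule is a pure predicate, so
#' the retained set does not depend on the order; only the attribution does.
#' Fixes that fall outside every polygon are counted under the distance rule
#' (they cannot be assigned a foraging habitat).
#'
#' @param fixes tibble of raw fixes ([parse_logger_file()] /
#'   [simulate_fixes()]).
#' @param rules a [filter_rules()].
#' @param landscape a [landscape_map()].
#' @return list with elements `fixes` (retained foraging fixes, annotated
#'   with `category`, `distance_m`, `bin`) and `report` (class
#'   `filter_report`: per-rule exclusion counts, birds dropped, retained).
#' @export
apply_qc_filters <- function(fixes, rules, landscape) {
  stopifnot(inherits(rules, "filter_rules"),
            inherits(landscape, "landscape_map"))
  n_in <- nrow(fixes)
  cat <- assign_habitat(fixes[, c("x_m", "y_m")], landscape)
  db <- distance_and_bin(fixes[, c("x_m", "y_m")], landscape$colony_centre)
  ann <- dplyr::mutate(fixes, category = cat,
                       distance_m = db$distance_m, bin = db$bin)

  excl_speed <- ann$speed_mps > rules$max_speed_inclusive
  excl_hdop <- !excl_speed & ann$hdop > rules$max_hdop_inclusive
  excl_night <- !excl_speed & !excl_hdop & in_night_window(ann$timestamp, rules)
  known_excluded <- !is.na(ann$category) &
    ann$category %in% rules$excluded_categories
  excl_habitat <- !excl_speed & !excl_hdop & !excl_night & known_excluded
  too_far <- ann$distance_m >= rules$max_distance_m | is.na(ann$category) |
    !(ann$category %in% c(foraging_categories(), rules$excluded_categories))
  excl_distance <- !excl_speed & !excl_hdop & !excl_night & !excl_habitat &
    too_far
  surviving <- !(excl_speed | excl_hdop | excl_night | excl_habitat |
                   excl_distance)

  kept <- ann[surviving, ]
  per_bird <- table(kept$bird_id)
  drop_birds <- names(per_bird)[per_bird <= rules$min_fixes_per_bird_exclusive]
  excl_min <- sum(kept$bird_id %in% drop_birds)
  kept <- kept[!kept$bird_id %in% drop_birds, ]

  report <- structure(
    list(input = n_in,
         excluded = c(speed = sum(excl_speed),
                      hdop = sum(excl_hdop),
                      night = sum(excl_night),
                      habitat = sum(excl_habitat),
                      distance = sum(excl_distance),
                      min_fixes = excl_min),
         birds_dropped = drop_birds,
         retained = nrow(kept)),
    class = "filter_report")
  list(fixes = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cat("  input fixes:   ", x$input, "\n")
  for (r in names(x$excluded)) {
    cat(sprintf("  excluded %-10s %d\n", paste0(r, ":"), x$excluded[[r]]))
  }
  cat("  birds dropped: ",
      if (length(x$birds_dropped)) paste(x$birds_dropped, collapse = ", ")
      else "none", "\n")
  cat("  retained:      ", x$retained, "\n")
  invisible(x)
}
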