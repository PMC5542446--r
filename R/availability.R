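#' Assign a habitat category to points
#'
#' Looks up the land-cover polygon containing each point. Points on a shared
#' boundary are resolved deterministically: the polygon with the lowest id
#' wins. Points inside no polygon get `NA` (a sentinel, never an error).
#'
#' @param points a two-column matrix or data frame of planar coordinates
#'   (metres), columns x then y.
#' @param landscape a [landscape_map()].
#' @return character vector of category names, `NA` where unclassified.
#' @export
assign_habitat <- function(points, landscape) {
  points <- as.matrix(as.data.frame(points)[, 1:2, drop = FALSE])
  out <- rep(NA_character_, nrow(points))
  todo <- rep(TRUE, nrow(points))
  for (p in landscape$polygons) {       # polygons are sorted by id
    if (!any(todo)) break
    idx <- which(todo)
    hit <- points_in_polygon(points[idx, 1], points[idx, 2], p$coords)
    out[idx[hit]] <- p$category
    todo[idx[hit]] <- FALSE
  }
  out
}

#' Distance to the colony centre and 100-m distance bin
#'
#' Euclidean distance in the plane from each point to the colony centre, and
#' the half-open 100-m bin it falls into (bin 0 is 0-99 m). Distances of
#' 1000 m or more return bin `NA`; callers treat that as out of range.
#'
#' @inheritParams assign_habitat
#' @param colony_centre numeric length-2 (x, y) in metres.
#' @return tibble with columns `distance_m` and `bin`.
#' @examples
#' distance_and_bin(cbind(300, 400), c(0, 0))  # 500 m, bin 5
#' @export
distance_and_bin <- function(points, colony_centre) {
  points <- as.matrix(as.data.frame(points)[, 1:2, drop = FALSE])
  d <- sqrt((points[, 1] - colony_centre[1])^2 +
              (points[, 2] - colony_centre[2])^2)
  tibble::tibble(distance_m = d, bin = distance_bin_index(d))
}

#' Generate the systematic availability sample (RAPs)
#'
#' Relative availability points are the intersections of a square grid
#' (default spacing 50 m, i.e. 4 points per hectare) superimposed on the
#' land-cover map and anchored at the colony centre. Grid points are retained
#' when they lie strictly within `radius_m` of the colony and fall in a
#' foraging category; points in excluded cover (buildings, gardens, forest,
#' lakes) or unclassified are dropped, mirroring their exclusion from use.
#'
#' @param landscape a [landscape_map()].
#' @param spacing_m grid spacing in metres (> 0).
#' @param radius_m retention radius in metres (999 by default: the analysis
#'   uses locations within 999 m of the colony centre).
#' @return tibble with columns `x`, `y`, `category`, `distance_m`, `bin`.
#' @export
generate_raps <- function(landscape, spacing_m = 50, radius_m = 999) {
  if (spacing_m <= 0) stop("spacing_m must be positive", call. = FALSE)
  cx <- landscape$colony_centre[1]
  cy <- landscape$colony_centre[2]
  k <- floor(radius_m / spacing_m)
  g <- seq(-k, k) * spacing_m
  pts <- expand.grid(x = cx + g, y = cy + g)
  db <- distance_and_bin(pts, landscape$colony_centre)
  keep <- db$distance_m < radius_m
  pts <- pts[keep, ]
  db <- db[keep, ]
  cat <- assign_habitat(pts, landscape)
  ok <- !is.na(cat) & cat %in% foraging_categories()
  tibble::tibble(x = pts$x[ok], y = pts$y[ok], category = cat[ok],
                 distance_m = db$distance_m[ok], bin = db$bin[ok])
}

#' Availability frequency table
#'
#' Counts of availability points by habitat category and distance bin (the
#' systematic estimate of how much of each cover type is available at each
#' distance from the colony).
#'
#' @param raps tibble from [generate_raps()].
#' @return tibble with columns `category`, `bin`, `n`, `proportion`.
#' @export
availability_table <- function(raps) {
  out <- dplyr::count(raps, .data$category, .data$bin, name = "n")
  out$proportion <- out$n / sum(out$n)
  out
}
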