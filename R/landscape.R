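#' Construct a land-cover map
#'
#' A `landscape_map` holds labelled habitat polygons (planar metre
#' coordinates), the colony-centre point used as the common central place for
#' all nests, and the radius out to which habitat classification is valid
#' (1 km by default, beyond the maximum foraging distance of the birds).
#'
#' @param polygons list of polygons, each a list with elements `coords`
#'   (two-column numeric matrix of vertices, unclosed), `category` (a category
#'   name from [all_categories()]) and optionally `id` (integer; assigned from
#'   list position when missing). Polygon ids define the deterministic
#'   tie-break used by [assign_habitat()].
#' @param colony_centre numeric length-2, colony centre (x, y) in metres.
#' @param classification_radius_m radius (m) of validity of the habitat
#'   classification around the colony centre.
#' @return an object of class `landscape_map`.
#' @seealso [generate_landscape()], [write_landscape_geojson()]
#' @export
landscape_map <- function(polygons, colony_centre = c(0, 0),
                          classification_radius_m = 1000) {
  stopifnot(is.list(polygons), length(colony_centre) == 2,
            classification_radius_m > 0)
  known <- all_categories()
  polygons <- lapply(seq_along(polygons), function(i) {
    p <- polygons[[i]]
    stopifnot(is.matrix(p$coords), ncol(p$coords) == 2, nrow(p$coords) >= 3)
    if (!p$category %in% known) {
      stop("unknown habitat category: ", p$category, call. = FALSE)
    }
    if (is.null(p$id)) p$id <- i
    p
  })
  ids <- vapply(polygons, function(p) p$id, numeric(1))
  polygons <- polygons[order(ids)]
  structure(
    list(polygons = polygons,
         colony_centre = as.numeric(colony_centre),
         classification_radius_m = classification_radius_m),
    class = "landscape_map")
}

#' @export
print.landscape_map <- function(x, ...) {
  cats <- table(vapply(x$polygons, function(p) p$category, character(1)))
  cat("<landscape_map>", length(x$polygons), "polygons,",
      "colony at (", x$colony_centre[1], ",", x$colony_centre[2], "),",
      "classification radius", x$classification_radius_m, "m\n")
  print(cats)
  invisible(x)
}

# Areal proportion of each category within the classification disc.
landscape_disc_proportions <- function(landscape, ngon = 256L) {
  disc <- disc_polygon(landscape$colony_centre,
                       landscape$classification_radius_m, ngon)
  areas <- vapply(landscape$polygons, function(p) {
    polygon_area(clip_convex(p$coords, disc))
  }, numeric(1))
  cats <- vapply(landscape$polygons, function(p) p$category, character(1))
  tot <- sum(areas)
  prop <- tapply(areas, cats, sum) / tot
  out <- stats::setNames(rep(0, length(all_categories())), all_categories())
  out[names(prop)] <- prop
  out
}

#' Generate a synthetic field mosaic around a colony
#'
#' Builds a field-like landscape by Voronoi tessellation of uniformly placed
#' seed points over a square extent centred on the colony, then labels cells
#' greedily so that realised areal proportions inside the classification disc
#' track the requested category proportions. Convex Voronoi cells with a
#' typical diameter of `field_size_m` emulate an agricultural parcel mosaic.
#'
#' @param config a [simulation_config()].
#' @return a [landscape_map()] whose colony centre is the origin.
#' @details Deterministic for a given `config$seed`. The realised proportion
#'   of every category within the classification disc is within about one
#'   cell area of the requested proportion (well under 5 percentage points at
#'   the default field size), and every category with positive requested
#'   proportion receives at least one polygon.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  props <- config$habitat_proportions
  extent <- config$landscape_extent_m
  radius <- config$classification_radius_m
  if (extent < 2 * radius) {
    stop("landscape_extent_m must be at least twice the classification radius",
         call. = FALSE)
  }
  withr::with_seed(config$seed, {
    n_seed <- max(length(props), round((extent / config$field_size_m)^2))
    sx <- stats::runif(n_seed, -extent / 2, extent / 2)
    sy <- stats::runif(n_seed, -extent / 2, extent / 2)
    bbox <- cbind(c(-1, 1, 1, -1) * extent / 2, c(-1, -1, 1, 1) * extent / 2)
    cells <- lapply(seq_len(n_seed), function(i) {
      poly <- bbox
      for (j in seq_len(n_seed)) {
        if (j == i) next
        dx <- sx[j] - sx[i]; dy <- sy[j] - sy[i]
        mx <- (sx[i] + sx[j]) / 2; my <- (sy[i] + sy[j]) / 2
        poly <- clip_halfplane(poly, dx, dy, dx * mx + dy * my)
        if (nrow(poly) == 0) break
      }
      poly
    })
    keep <- vapply(cells, function(p) nrow(p) >= 3, logical(1))
    cells <- cells[keep]
    disc <- disc_polygon(c(0, 0), radius, 256L)
    disc_area <- vapply(cells, function(p) {
      polygon_area(clip_convex(p, disc))
    }, numeric(1))
    total <- sum(disc_area)

    # Greedy labelling: visit cells in random order, give each to the
    # category with the largest remaining area deficit inside the disc.
    cats <- names(props)[props > 0]
    target <- props[cats] * total
    got <- stats::setNames(rep(0, length(cats)), cats)
    ord <- sample.int(length(cells))
    label <- character(length(cells))
    for (i in ord) {
      deficit <- target - got
      pick <- cats[which.max(deficit)]
      label[i] <- pick
      got[pick] <- got[pick] + disc_area[i]
    }
    # guarantee representation of every requested category
    for (cat in cats) {
      if (!any(label == cat)) {
        donor_cat <- names(which.max(table(label)))
        donors <- which(label == donor_cat & disc_area > 0)
        i <- donors[which.min(disc_area[donors])]
        label[i] <- cat
      }
    }
    polys <- lapply(seq_along(cells), function(i) {
      list(coords = cells[[i]], category = label[i], id = i)
    })
    landscape_map(polys, colony_centre = c(0, 0),
                  classification_radius_m = radius)
  })
}

#' Read and write landscapes as GeoJSON
#'
#' The interchange format is a GeoJSON `FeatureCollection` in planar metre
#' coordinates: one `Polygon` feature per field with a `category` property
#' (and `id`), plus a single `Point` feature with `role: "colony_centre"`
#' carrying the classification radius.
#'
#' @param landscape a [landscape_map()].
#' @param path file path.
#' @return `read_landscape_geojson()` returns a [landscape_map()];
#'   `write_landscape_geojson()` returns `path` invisibly.
#' @export
write_landscape_geojson <- function(landscape, path) {
  feats <- lapply(landscape$polygons, function(p) {
    ring <- rbind(p$coords, p$coords[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(category = p$category, id = p$id),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(ring))))
  })
  centre <- list(type = "Feature",
                 properties = list(
                   role = "colony_centre",
                   classification_radius_m = landscape$classification_radius_m),
                 geometry = list(type = "Point",
                                 coordinates = landscape$colony_centre))
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = "local-planar-metres")),
             features = c(feats, list(centre)))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landscape_geojson
#' @export
read_landscape_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  polys <- list()
  centre <- NULL
  radius <- 1000
  for (f in fc$features) {
    geom <- f$geometry
    if (geom$type == "Point") {
      centre <- as.numeric(unlist(geom$coordinates))
      if (!is.null(f$properties$classification_radius_m)) {
        radius <- f$properties$classification_radius_m
      }
    } else if (geom$type == "Polygon") {
      ring <- do.call(rbind, lapply(geom$coordinates[[1]], function(v) {
        as.numeric(unlist(v))
      }))
      # drop the repeated closing vertex
      if (all(ring[1, ] == ring[nrow(ring), ])) {
        ring <- ring[-nrow(ring), , drop = FALSE]
      }
      polys[[length(polys) + 1L]] <- list(
        coords = ring,
        category = f$properties$category,
        id = f$properties$id %||% (length(polys) + 1L))
    }
  }
  if (is.null(centre)) stop("no colony_centre point feature in ", path,
                            call. = FALSE)
  landscape_map(polys, colony_centre = centre,
                classification_radius_m = radius)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
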