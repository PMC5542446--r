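# Shared fixtures and independent oracles, all built in code.

# axis-aligned rectangle polygon
rect_poly <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# Four-quadrant landscape: 1-km-radius disc fully covered by four 2x2-km
# quadrant squares with known categories; colony at the origin.
quadrant_landscape <- function(cats = c("Grazed", "ShortGrass",
                                        "BareGround", "Meadow")) {
  polys <- list(
    list(coords = rect_poly(0, 0, 1100, 1100), category = cats[1], id = 1),
    list(coords = rect_poly(-1100, 0, 0, 1100), category = cats[2], id = 2),
    list(coords = rect_poly(-1100, -1100, 0, 0), category = cats[3], id = 3),
    list(coords = rect_poly(0, -1100, 1100, 0), category = cats[4], id = 4))
  landscape_map(polys, colony_centre = c(0, 0),
                classification_radius_m = 1000)
}

# Two-half-plane landscape: x < 0 one category, x >= 0 another; equal
# availability at every distance by symmetry.
halves_landscape <- function(left = "Grazed", right = "ShortGrass") {
  polys <- list(
    list(coords = rect_poly(-1100, -1100, 0, 1100), category = left, id = 1),
    list(coords = rect_poly(0, -1100, 1100, 1100), category = right, id = 2))
  landscape_map(polys, colony_centre = c(0, 0),
                classification_radius_m = 1000)
}

# Independent ray-casting point-in-polygon oracle: counts proper
# intersections of the segment from the point to a far outside anchor with
# each polygon edge, using signed-orientation tests. Written independently
# of the package's crossing-number implementation.
pip_ray_oracle <- function(px, py, poly) {
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  far <- c(max(poly[, 1]) + 7919.77, max(poly[, 2]) + 104729.13)
  n <- nrow(poly)
  crossings <- 0L
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    a <- poly[k, ]; b <- poly[k2, ]
    o1 <- orient(px, py, far[1], far[2], a[1], a[2])
    o2 <- orient(px, py, far[1], far[2], b[1], b[2])
    o3 <- orient(a[1], a[2], b[1], b[2], px, py)
    o4 <- orient(a[1], a[2], b[1], b[2], far[1], far[2])
    if (o1 != o2 && o3 != o4) crossings <- crossings + 1L
  }
  crossings %% 2L == 1L
}

# Hand-made raw-fix tibble
make_fix <- function(bird_id, time, x, y, speed = 0, hdop = 1.2,
                     date = "2015-05-10") {
  tibble::tibble(
    bird_id = bird_id,
    timestamp = as.POSIXct(paste0(date, "T", time, ":00"),
                           format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    x_m = x, y_m = y, speed_mps = speed, hdop = hdop)
}

# Use-availability table for calibration simulations: fixes from the
# generator's truth columns, availability drawn as an independent random
# sample of the generation lattice for each bird (so that the availability
# class is genuinely a random sample and model-based/cluster-robust
# inference is calibrated; the systematic 50-m grid is exercised by its own
# oracle tests).
calibration_table <- function(fx, forage_lattice, n_rap_per_bird = 1250) {
  birds <- unique(fx$bird_id)
  use <- tibble::tibble(
    bird_id = fx$bird_id, response = 1L, category = fx$true_category,
    bin = fx$true_bin, distance_m = sqrt(fx$x_m^2 + fx$y_m^2))
  avail <- dplyr::bind_rows(lapply(birds, function(b) {
    i <- sample.int(nrow(forage_lattice), n_rap_per_bird, replace = TRUE)
    tibble::tibble(bird_id = b, response = 0L,
                   category = forage_lattice$category[i],
                   bin = forage_lattice$bin[i],
                   distance_m = forage_lattice$distance_m[i])
  }))
  dplyr::bind_rows(use, avail)
}

# foraging-category subset of a sampling lattice
forage_lattice_of <- function(landscape) {
  lat <- build_sampling_lattice(landscape)
  lat[!is.na(lat$category) & lat$category %in% foraging_categories(), ]
}
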