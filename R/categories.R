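#' Land-cover categories
#'
#' The analysis condenses the landscape into five foraging crop categories
#' plus four non-foraging ("excluded") categories. `Grazed` (grazed grass) is
#' the reference level against which selection coefficients are expressed;
#' the excluded categories (farm buildings, gardens, forest, open water) are
#' associated with roosting, singing, drinking and other non-foraging
#' behaviour and are removed from both use and availability.
#'
#' @return `foraging_categories()` and `excluded_categories()` return
#'   character vectors of category names; `all_categories()` their union;
#'   `reference_category()` the single reference level (`"Grazed"`).
#' @export
foraging_categories <- function() {
  c("Grazed", "ShortGrass", "BareGround", "Meadow", "WinterCrops")
}

#' @rdname foraging_categories
#' @export
excluded_categories <- function() {
  c("Building", "Garden", "Forest", "Lake")
}

#' @rdname foraging_categories
#' @export
all_categories <- function() {
  c(foraging_categories(), excluded_categories())
}

#' @rdname foraging_categories
#' @export
reference_category <- function() "Grazed"

#' Distance-to-nest bins
#'
#' Distances to the colony centre are aggregated into ten half-open 100-m
#' bins: \[0, 100) is bin 0 ("0-99 m"), \[100, 200) is bin 1, and so on up to
#' bin 9 ("900-999 m"). Distances of 1000 m or more fall outside the analysis
#' radius and map to `NA`.
#'
#' @param distance_m numeric vector of non-negative distances in metres.
#' @return `distance_bin_index()` returns integer bin indices (0-9, `NA`
#'   beyond 999 m); `distance_bin_labels()` the ten ordered labels.
#' @examples
#' distance_bin_index(c(0, 99.99, 100, 500))
#' @export
distance_bin_index <- function(distance_m) {
  stopifnot(is.numeric(distance_m), all(distance_m >= 0, na.rm = TRUE))
  idx <- floor(distance_m / 100)
  idx[idx > 9] <- NA_integer_
  as.integer(idx)
}

#' @rdname distance_bin_index
#' @export
distance_bin_labels <- function() {
  paste0(seq(0, 900, by = 100), "-", seq(99, 999, by = 100), " m")
}

# Factor constructors with the documented reference levels first.
category_factor <- function(x, levels = foraging_categories()) {
  factor(as.character(x), levels = levels)
}

bin_factor <- function(bin_index) {
  factor(distance_bin_labels()[bin_index + 1L], levels = distance_bin_labels())
}
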