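#' Provisioning-flight energetics parameters
#'
#' Defaults describe a provisioning starling: up to 250 feeding roundtrips
#' per day, a mean flight speed of 10 m/s close to the minimum-power optimum
#' at a metabolic power of 9.4 W, nestlings consuming about 40 g of fresh
#' food per day as invertebrate prey (cranefly larvae) of mean wet mass
#' 0.25 g and energy density 4 kJ/g.
#'
#' @param roundtrips_per_day feeding roundtrips per day.
#' @param flight_speed_mps mean flight speed (m/s).
#' @param flight_power_w metabolic power in flight (W).
#' @param nestling_food_g fresh food consumed per nestling per day (g).
#' @param prey_mass_g mean wet mass of one prey item (g).
#' @param prey_energy_kj_per_g energy density of prey (kJ/g).
#' @return an object of class `energetics_params`.
#' @export
energetics_params <- function(roundtrips_per_day = 250,
                              flight_speed_mps = 10,
                              flight_power_w = 9.4,
                              nestling_food_g = 40,
                              prey_mass_g = 0.25,
                              prey_energy_kj_per_g = 4) {
  vals <- c(roundtrips_per_day, flight_speed_mps, flight_power_w,
            nestling_food_g, prey_mass_g, prey_energy_kj_per_g)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all energetics parameters must be strictly positive",
         call. = FALSE)
  }
  structure(list(roundtrips_per_day = roundtrips_per_day,
                 flight_speed_mps = flight_speed_mps,
                 flight_power_w = flight_power_w,
                 nestling_food_g = nestling_food_g,
                 prey_mass_g = prey_mass_g,
                 prey_energy_kj_per_g = prey_energy_kj_per_g),
            class = "energetics_params")
}

#' Daily distance travelled provisioning at a given one-way foraging distance
#'
#' `roundtrips * 2 * one_way_m / 1000`: a 100-m one-way distance at 250
#' roundtrips/day means 50 km of commuting flight per day.
#'
#' @param one_way_m one-way nest-to-patch distance (m, >= 0).
#' @param params an [energetics_params()].
#' @return distance in km/day.
#' @export
daily_travel_km <- function(one_way_m, params = energetics_params()) {
  stopifnot(all(one_way_m >= 0))
  params$roundtrips_per_day * 2 * one_way_m / 1000
}

#' Energy spent flying a given distance
#'
#' Time aloft (distance / speed) times metabolic power: 50 km at 10 m/s and
#' 9.4 W is 47 kJ.
#'
#' @param distance_km distance flown (km, >= 0).
#' @inheritParams daily_travel_km
#' @return energy in kJ.
#' @export
flight_energy_kj <- function(distance_km, params = energetics_params()) {
  stopifnot(all(distance_km >= 0))
  (distance_km * 1000 / params$flight_speed_mps) *
    params$flight_power_w / 1000
}

#' Daily energy demand of one nestling
#'
#' Fresh-food intake times prey energy density, and the equivalent number of
#' prey items: with the defaults, 40 g/day at 4 kJ/g is 160 kJ/day, or 160
#' larvae of 0.25 g.
#'
#' @inheritParams daily_travel_km
#' @return list `demand_kj` and `larvae_equivalent`.
#' @export
nestling_demand_kj <- function(params = energetics_params()) {
  list(demand_kj = params$nestling_food_g * params$prey_energy_kj_per_g,
       larvae_equivalent = params$nestling_food_g / params$prey_mass_g)
}

#' Marginal cost of extra foraging distance as a share of nestling demand
#'
#' The flight energy of the extra daily commuting caused by foraging
#' `extra_one_way_m` further from the nest, expressed as a fraction of one
#' nestling's daily energy demand: an extra 100 m costs 47/160 = 0.294,
#' i.e. roughly 30%.
#'
#' @param extra_one_way_m additional one-way distance (m, >= 0).
#' @inheritParams daily_travel_km
#' @return fraction (dimensionless).
#' @export
marginal_cost_share <- function(extra_one_way_m,
                                params = energetics_params()) {
  flight_energy_kj(daily_travel_km(extra_one_way_m, params), params) /
    nestling_demand_kj(params)$demand_kj
}
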