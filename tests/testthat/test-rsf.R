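# Use-availability RSF fitting

# expanded-row table from cell counts
make_rows <- function(bird, response, category, bin, count,
                      distance_m = bin * 100 + 50) {
  tibble::tibble(bird_id = bird, response = as.integer(response),
                 category = category, bin = as.integer(bin),
                 distance_m = distance_m)[rep(1, count), ]
}

test_that("use-availability stacking replicates RAPs per bird", {
  fixes <- dplyr::bind_rows(
    make_rows("S01", 1, "Grazed", 0, 60),
    make_rows("S02", 1, "Grazed", 0, 40))
  raps <- tibble::tibble(x = 0, y = 0, category = "Grazed",
                         distance_m = 50, bin = 0L)[rep(1, 100), ]
  tab <- build_use_availability(fixes, raps)
  expect_equal(nrow(tab), 300L)
  expect_equal(sum(tab$response[tab$bird_id == "S01"]), 60L)
  expect_equal(sum(tab$bird_id == "S01"), 160L)
  expect_equal(mean(tab$response), 100 / (100 + 2 * 100))
  expect_error(build_use_availability(fixes, raps[0, ]), "availability")
})

test_that("a perfectly balanced table gives all-zero coefficients", {
  cells <- list(c("Grazed", 0, 30), c("Grazed", 1, 20),
                c("ShortGrass", 0, 10), c("ShortGrass", 1, 40))
  tab <- dplyr::bind_rows(lapply(cells, function(cl) {
    dplyr::bind_rows(
      make_rows("S01", 1, cl[1], as.integer(cl[2]), as.integer(cl[3])),
      make_rows("S01", 0, cl[1], as.integer(cl[2]), as.integer(cl[3])))
  }))
  fit <- fit_rsf(tab, "cover_plus_distance", method = "fixed")
  est <- fit$coefficients
  expect_true(all(abs(est$B) < 1e-6))
})

test_that("two-category one-bird coefficient equals the closed-form 2x2
           log-odds ratio", {
  tab <- dplyr::bind_rows(
    make_rows("S01", 1, "Grazed", 0, 30),
    make_rows("S01", 1, "ShortGrass", 0, 10),
    make_rows("S01", 0, "Grazed", 0, 50),
    make_rows("S01", 0, "ShortGrass", 0, 50))
  fit <- fit_rsf(tab, "cover_only", method = "fixed")
  B <- fit$coefficients$B[fit$coefficients$level == "ShortGrass" &
                            !fit$coefficients$reference]
  expect_equal(B, log((10 / 50) / (30 / 50)), tolerance = 1e-6)
})

test_that("doubling availability replication moves only the intercept", {
  L <- quadrant_landscape()
  cfg <- simulation_config(
    seed = 19, n_birds = 4, fixes_per_bird = 300, bird_sd = 0,
    habitat_proportions = c(Grazed = 0.25, ShortGrass = 0.25,
                            BareGround = 0.25, Meadow = 0.25),
    true_selection = c(Grazed = 0, ShortGrass = -0.5, BareGround = -1,
                       Meadow = -1.5),
    contamination = c(flying = 0, imprecise = 0, night = 0))
  fx <- simulate_fixes(L, cfg)
  fixes <- tibble::tibble(bird_id = fx$bird_id, category = fx$true_category,
                          bin = fx$true_bin,
                          distance_m = sqrt(fx$x_m^2 + fx$y_m^2))
  raps <- generate_raps(L)
  tab1 <- build_use_availability(fixes, raps)
  tab2 <- dplyr::bind_rows(tab1, tab1[tab1$response == 0L, ])
  f1 <- fit_rsf(tab1, "cover_only", method = "fixed")
  f2 <- fit_rsf(tab2, "cover_only", method = "fixed")
  c1 <- f1$coefficients
  c2 <- f2$coefficients
  sel <- c1$factor == "cover" & !c1$reference
  expect_true(all(abs(c1$B[sel] - c2$B[sel]) < 0.01))
  i1 <- c1$B[c1$factor == "intercept"]
  i2 <- c2$B[c2$factor == "intercept"]
  expect_equal(i2 - i1, -log(2), tolerance = 0.02)
})

test_that("changing the reference level is a pure re-expression", {
  tab <- dplyr::bind_rows(
    make_rows("S01", 1, "Grazed", 0, 30),
    make_rows("S01", 1, "ShortGrass", 0, 25),
    make_rows("S01", 1, "Meadow", 0, 12),
    make_rows("S01", 0, "Grazed", 0, 40),
    make_rows("S01", 0, "ShortGrass", 0, 40),
    make_rows("S01", 0, "Meadow", 0, 40))
  fg <- fit_rsf(tab, "cover_only", method = "fixed",
                reference_cat = "Grazed")
  fs <- fit_rsf(tab, "cover_only", method = "fixed",
                reference_cat = "ShortGrass")
  getB <- function(f, lv) {
    cf <- f$coefficients
    cf$B[cf$level == lv & cf$factor == "cover"]
  }
  contrast_g <- getB(fg, "Meadow") - getB(fg, "ShortGrass")
  contrast_s <- getB(fs, "Meadow") - getB(fs, "ShortGrass")
  expect_equal(contrast_g, contrast_s, tolerance = 1e-8)
})

test_that("overall effect test reduces to t-squared for one coefficient and
           is null on balanced data", {
  tab <- dplyr::bind_rows(
    make_rows("S01", 1, "Grazed", 0, 30),
    make_rows("S01", 1, "ShortGrass", 0, 10),
    make_rows("S01", 0, "Grazed", 0, 50),
    make_rows("S01", 0, "ShortGrass", 0, 50))
  fit <- fit_rsf(tab, "cover_only", method = "fixed")
  cf <- fit$coefficients[fit$coefficients$level == "ShortGrass" &
                           !fit$coefficients$reference, ]
  tst <- overall_effect_test(fit, "cover")
  expect_equal(unname(tst["F"]), cf$t^2, tolerance = 1e-8)
  expect_equal(unname(tst["num_df"]), 1)
  # balanced null
  tab0 <- dplyr::bind_rows(
    make_rows("S01", 1, "Grazed", 0, 40),
    make_rows("S01", 1, "ShortGrass", 0, 40),
    make_rows("S01", 0, "Grazed", 0, 40),
    make_rows("S01", 0, "ShortGrass", 0, 40))
  fit0 <- fit_rsf(tab0, "cover_only", method = "fixed")
  tst0 <- overall_effect_test(fit0, "cover")
  expect_lt(unname(tst0["F"]), 1e-10)
  expect_gt(unname(tst0["p"]), 0.99)
})

test_that("a never-used category is flagged non-estimable, not huge", {
  tab <- dplyr::bind_rows(
    make_rows("S01", 1, "Grazed", 0, 50),
    make_rows("S01", 0, "Grazed", 0, 60),
    make_rows("S01", 0, "ShortGrass", 0, 60))
  fit <- suppressWarnings(fit_rsf(tab, "cover_only", method = "fixed"))
  row <- fit$coefficients[fit$coefficients$level == "ShortGrass" &
                            !fit$coefficients$reference, ]
  expect_false(row$estimable)
  expect_true(is.na(row$p))
  expect_warning(overall_effect_test(fit, "cover"), "non-estimable")
})

test_that("zone subsetting drops under-sampled birds and unused categories", {
  # zone C = 400-999 m: S1 has 25+10 use fixes, S2 has 21, S3 exactly 20
  # (dropped: strictly more than 20 required); WinterCrops available but
  # never used in the zone
  use <- dplyr::bind_rows(
    make_rows("S1", 1, "Grazed", 4, 25),
    make_rows("S1", 1, "ShortGrass", 5, 10),
    make_rows("S2", 1, "Grazed", 5, 21),
    make_rows("S3", 1, "Grazed", 4, 20),
    make_rows("S1", 1, "Grazed", 0, 30),     # outside zone C
    make_rows("S2", 1, "WinterCrops", 1, 5)) # WC used only near the nest
  avail <- dplyr::bind_rows(lapply(c("S1", "S2", "S3"), function(b) {
    dplyr::bind_rows(
      make_rows(b, 0, "Grazed", 5, 40),
      make_rows(b, 0, "ShortGrass", 5, 40),
      make_rows(b, 0, "WinterCrops", 5, 40),
      make_rows(b, 0, "Grazed", 0, 40),
      make_rows(b, 0, "WinterCrops", 0, 40))
  }))
  tab <- dplyr::bind_rows(use, avail)
  zf <- fit_zone_rsfs(tab, zone_spec(), method = "fixed")
  zc <- zf[[3]]
  expect_false(zc$skipped)
  expect_true("S3" %in% zc$birds_dropped)
  expect_true("WinterCrops" %in% zc$categories_dropped)
  lv <- zc$fit$coefficients$level[zc$fit$coefficients$factor == "cover"]
  expect_false("WinterCrops" %in% lv)
  expect_setequal(lv, c("Grazed", "ShortGrass"))
  # zone A retains only birds with > 20 fixes there: S1 only
  za <- zf[[1]]
  expect_true(za$skipped)   # only Grazed used in zone A by S1 -> < 2 cats
})

test_that("distance-invariant selection yields mutually consistent zone
           coefficients", {
  cfg <- simulation_config(
    seed = 23, n_birds = 8, fixes_per_bird = 400, bird_sd = 0,
    true_selection = c(Grazed = 0, ShortGrass = -0.9, BareGround = -0.9,
                       Meadow = -0.9, WinterCrops = -0.9),
    distance_decay = 0,
    contamination = c(flying = 0, imprecise = 0, night = 0))
  L <- generate_landscape(cfg)
  lat <- build_sampling_lattice(L)
  fx <- simulate_fixes(L, cfg, lat)
  withr::with_seed(101, {
    tab <- calibration_table(fx, forage_lattice_of(L))
  })
  zf <- fit_zone_rsfs(tab, zone_spec(), method = "fixed")
  fits <- Filter(function(z) !z$skipped, zf)
  expect_gte(length(fits), 2)
  getrow <- function(z, lv) {
    cf <- z$fit$coefficients
    cf[cf$level == lv & !cf$reference & cf$factor == "cover", ]
  }
  for (lv in c("ShortGrass", "BareGround")) {
    a <- getrow(fits[[1]], lv)
    b <- getrow(fits[[length(fits)]], lv)
    d <- coef_difference_test(a$B, a$SE, a$df, b$B, b$SE, b$df)
    expect_gt(d$p, 0.01)
  }
})

test_that("mixed and cluster-robust fits agree on mildly heterogeneous
           data", {
  cfg <- simulation_config(seed = 29, n_birds = 8, fixes_per_bird = 200,
                           bird_sd = 0.2,
                           contamination = c(flying = 0, imprecise = 0,
                                             night = 0))
  L <- generate_landscape(cfg)
  lat <- build_sampling_lattice(L)
  fx <- simulate_fixes(L, cfg, lat)
  withr::with_seed(55, {
    tab <- calibration_table(fx, forage_lattice_of(L), 1000)
  })
  fm <- fit_rsf(tab, "cover_plus_distance", method = "mixed")
  fr <- fit_rsf(tab, "cover_plus_distance", method = "fixed_robust")
  expect_equal(fm$method, "mixed")
  expect_named(fm$variance_components)
  for (lv in c("ShortGrass", "BareGround", "Meadow", "WinterCrops")) {
    bm <- fm$coefficients$B[fm$coefficients$level == lv &
                              !fm$coefficients$reference]
    br <- fr$coefficients$B[fr$coefficients$level == lv &
                              !fr$coefficients$reference]
    expect_lt(abs(bm - br), 0.1)
  }
})

test_that("both response classes are required", {
  tab <- make_rows("S01", 1, "Grazed", 0, 10)
  expect_error(fit_rsf(tab, "cover_only"), "both response classes")
})
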