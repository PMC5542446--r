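# Selection ratios, continuity-corrected coefficients, difference tests

test_that("selection-ratio display follows the field convention", {
  expect_equal(odds_ratio(-0.94)$display, "1:2.6")
  expect_equal(odds_ratio(0)$display, "1:1")
  expect_equal(odds_ratio(-3.87)$display, "1:48")
  expect_equal(odds_ratio(-3.87)$ratio, exp(3.87))
  expect_equal(odds_ratio(1.2)$display, "3.3:1")
  # anti-log of a log ratio is the ratio
  for (r in c(1.01, 2.6, 9.99, 13, 48)) {
    expect_equal(odds_ratio(log(r))$ratio, r, tolerance = 1e-12)
  }
})

test_that("coefficient contrasts reproduce between-category ratios", {
  ct <- coefficient_contrast(-1.83, -3.87, 0.32, 0.43)
  expect_equal(ct$contrast, 2.04)
  expect_equal(round(ct$ratio), 8)
  # lower bound 3 as reported; the upper bound from independent SEs is 22
  # (a within-model covariance between the two coefficients would shrink it)
  expect_equal(round(ct$ci_ratio),
               round(exp(2.04 + c(-1, 1) * 1.96 * sqrt(0.32^2 + 0.43^2))))
  expect_equal(round(ct$ci_ratio[1]), 3)
  expect_equal(coefficient_contrast(-1.5, -1.5)$ratio, 1)
})

test_that("continuity correction turns zero counts into 0.5-count
           proportions", {
  counts <- tibble::tibble(
    bird_id = "S1", category = c("WinterCrops", "Grazed"),
    use = c(0L, 10L), use_total = 24L,
    avail = c(20L, 30L), avail_total = 100L)
  out <- continuity_sc(counts, "WinterCrops", "Grazed")
  expect_true(out$corrected)
  expect_equal(out$sc,
               log((0.5 / 24) / (20 / 100)) - log((10 / 24) / (30 / 100)))
  expect_equal(round(0.5 / 24, 3), 0.021)
  # no zeros: plain log ratio difference, flagged uncorrected
  counts2 <- tibble::tibble(
    bird_id = "S1", category = c("ShortGrass", "Grazed"),
    use = c(6L, 12L), use_total = 24L,
    avail = c(30L, 30L), avail_total = 100L)
  out2 <- continuity_sc(counts2, "ShortGrass", "Grazed")
  expect_false(out2$corrected)
  expect_equal(out2$sc, log(0.25 / 0.3) - log(0.5 / 0.3))
  # equal selection
  counts3 <- tibble::tibble(
    bird_id = "S1", category = c("Meadow", "Grazed"),
    use = c(10L, 10L), use_total = 40L,
    avail = c(25L, 25L), avail_total = 100L)
  expect_equal(continuity_sc(counts3, "Meadow")$sc, 0)
})

test_that("continuity-corrected coefficient converges to the closed-form
           log odds ratio at large counts", {
  base <- c(u_f = 7, u_r = 19, a_f = 31, a_r = 52)
  scaled <- tibble::tibble(
    bird_id = "S1", category = c("Meadow", "Grazed"),
    use = as.integer(base[c("u_f", "u_r")] * 1000),
    use_total = as.integer(sum(base[c("u_f", "u_r")]) * 1000),
    avail = as.integer(base[c("a_f", "a_r")] * 1000),
    avail_total = as.integer(sum(base[c("a_f", "a_r")]) * 1000))
  closed <- log((base["u_f"] / base["a_f"]) / (base["u_r"] / base["a_r"]))
  expect_lt(abs(continuity_sc(scaled, "Meadow")$sc - unname(closed)), 1e-6)
})

test_that("selection counts aggregate fixes and availability per bird", {
  fixes <- tibble::tibble(bird_id = rep(c("S1", "S2"), c(3, 2)),
                          category = c("Grazed", "Grazed", "Meadow",
                                       "Grazed", "Grazed"))
  raps <- tibble::tibble(category = rep(c("Grazed", "Meadow"), c(30, 20)))
  sc <- selection_counts(fixes, raps)
  expect_equal(sc$use[sc$bird_id == "S1" & sc$category == "Grazed"], 2L)
  expect_equal(unique(sc$use_total[sc$bird_id == "S1"]), 3L)
  expect_equal(unique(sc$avail[sc$category == "Meadow"]), 20L)
  expect_equal(unique(sc$avail_total), 50L)
})

test_that("mean selection coefficient uses simple normal statistics", {
  sc <- tibble::tibble(bird_id = c("a", "b"), sc = c(0, 2))
  m <- mean_sc(sc)
  expect_equal(m$mean, 1)
  expect_equal(m$se, 1)
  expect_equal(m$ci, c(1 - 1.96, 1 + 1.96))
  same <- tibble::tibble(bird_id = letters[1:4], sc = rep(-2.5, 4))
  expect_equal(mean_sc(same)$se, 0)
  expect_equal(mean_sc(same)$ci, c(-2.5, -2.5))
  expect_true(is.na(mean_sc(sc[1, ])$se))
  # sampling oracle: many birds around a known mean
  withr::with_seed(7, {
    big <- tibble::tibble(bird_id = as.character(1:1000),
                          sc = stats::rnorm(1000, -5, 1))
  })
  mb <- mean_sc(big)
  expect_lt(abs(mb$mean - (-5)), 3 * mb$se)
})

test_that("coefficient-difference t-test matches the summed-variance
           formula", {
  d <- coef_difference_test(-1.56, 0.32, 50.0, -0.94, 0.33, 59.1,
                            ordering = "cover-only-minus-combined")
  expect_equal(d$delta_B, -0.62)
  expect_equal(d$SE, sqrt(0.32^2 + 0.33^2))
  expect_equal(round(d$SE, 2), 0.46)
  expect_equal(d$df, 109.1)
  expect_equal(round(d$t, 2), -1.35)
  expect_gt(d$p, 0.1)
  # identical estimates
  d0 <- coef_difference_test(-1, 0.2, 10, -1, 0.2, 10)
  expect_equal(d0$delta_B, 0)
  expect_equal(d0$t, 0)
  # 3-4-5 standard errors
  d2 <- coef_difference_test(1.0, 0.3, 10, 0.0, 0.4, 10)
  expect_equal(d2$t, 2.0)
  # antisymmetry
  fwd <- coef_difference_test(0.7, 0.25, 30, -0.2, 0.35, 40)
  rev <- coef_difference_test(-0.2, 0.35, 40, 0.7, 0.25, 30)
  expect_equal(fwd$delta_B, -rev$delta_B)
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$SE, rev$SE)
  expect_equal(fwd$df, rev$df)
  expect_equal(fwd$p, rev$p)
  # zero SE -> undefined sentinel
  expect_true(is.na(coef_difference_test(1, 0, 10, 0, 0.3, 10)$t))
})

test_that("distance-use summary averages per-bird bin proportions", {
  fixes <- dplyr::bind_rows(
    tibble::tibble(bird_id = "S1", bin = rep(0L, 12)),
    tibble::tibble(bird_id = "S2", bin = rep(c(0L, 1L), c(6, 4))))
  du <- distance_use_summary(fixes)
  expect_equal(du$mean[1], mean(c(1, 0.6)))
  expect_equal(du$mean[2], mean(c(0, 0.4)))
  expect_equal(sum(du$mean), 1, tolerance = 1e-12)
  expect_true(all(du$ci_lo_display >= 0 & du$ci_hi_display <= 1))
})

test_that("per-bird bin proportions sum to one for simulated fleets and
           track the generative decay", {
  cfg <- simulation_config(seed = 37, n_birds = 10, fixes_per_bird = 300,
                           bird_sd = 0,
                           contamination = c(flying = 0, imprecise = 0,
                                             night = 0))
  L <- generate_landscape(cfg)
  lat <- build_sampling_lattice(L)
  fx <- simulate_fixes(L, cfg, lat)
  fixes <- tibble::tibble(bird_id = fx$bird_id, bin = fx$true_bin)
  du <- distance_use_summary(fixes)
  expect_equal(sum(du$mean), 1, tolerance = 1e-12)
  # generative bin distribution from the lattice weights
  sel <- cfg$true_selection
  keep <- !is.na(lat$category) & lat$category %in% names(sel)
  w <- exp(sel[lat$category[keep]] + cfg$distance_decay[lat$bin[keep] + 1])
  gen <- tapply(w, lat$bin[keep], sum) / sum(w)
  # heavily used bins fall inside the across-bird CI
  for (b in 0:3) {
    expect_gt(gen[[as.character(b)]], du$ci_lo[b + 1] - 0.02)
    expect_lt(gen[[as.character(b)]], du$ci_hi[b + 1] + 0.02)
  }
})
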