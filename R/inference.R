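#' Selection (odds) ratio from a log selection coefficient
#'
#' The anti-log of an RSF coefficient is the approximate odds ratio by which
#' a level is used relative to the reference at equal availability. The
#' display string follows the field's reporting convention: `"1:x"` when the
#' coefficient is negative (used x times less than the reference), `"x:1"`
#' when positive; x shown to one decimal below 10 and as an integer from 10
#' up.
#'
#' @param B log selection coefficient (finite).
#' @return list with `ratio` (`exp(abs(B))`) and `display` (character).
#' @examples
#' odds_ratio(-0.94)  # 1:2.6
#' odds_ratio(-3.87)  # 1:48
#' @export
odds_ratio <- function(B) {
  stopifnot(is.finite(B))
  ratio <- exp(abs(B))
  if (B == 0) return(list(ratio = 1, display = "1:1"))
  x <- if (ratio < 10) format(round(ratio, 1), nsmall = 1) else
    format(round(ratio))
  display <- if (B < 0) paste0("1:", x) else paste0(x, ":1")
  list(ratio = ratio, display = display)
}

#' Contrast two coefficients that share a reference level
#'
#' For two levels expressed against the same reference, the difference of
#' their log coefficients is the log selection ratio between the two levels
#' themselves; its anti-log says how many times more the first is selected
#' than the second. A normal 95% CI uses the summed squared standard errors,
#' treating the two estimates as independent (any positive within-model
#' covariance between them would narrow the interval).
#'
#' @param B_a,B_b log coefficients (same reference level).
#' @param SE_a,SE_b their standard errors (optional; `NA` omits the CI).
#' @return list with `contrast` (`B_a - B_b`), `ratio` (`exp(contrast)`),
#'   `ci_ratio` (length-2, ratio scale) when SEs are supplied.
#' @examples
#' coefficient_contrast(-1.83, -3.87, 0.32, 0.43)  # ~8x, CI ~(3, 22)
#' @export
coefficient_contrast <- function(B_a, B_b, SE_a = NA, SE_b = NA) {
  contrast <- B_a - B_b
  out <- list(contrast = contrast, ratio = exp(contrast), ci_ratio = NULL)
  if (is.finite(SE_a) && is.finite(SE_b)) {
    se <- sqrt(SE_a^2 + SE_b^2)
    out$ci_ratio <- exp(contrast + c(-1, 1) * 1.96 * se)
  }
  out
}

#' Per-bird use and availability counts by category
#'
#' @param fixes filtered foraging fixes (columns `bird_id`, `category`).
#' @param raps availability points (column `category`).
#' @return a `selection_counts` tibble: one row per (bird, category) over all
#'   foraging categories, with columns `use`, `use_total`, `avail`,
#'   `avail_total` (availability identical across birds: the shared RAP set).
#' @export
selection_counts <- function(fixes, raps) {
  cats <- foraging_categories()
  birds <- sort(unique(fixes$bird_id))
  a <- table(factor(raps$category, levels = cats))
  grid <- tidyr::expand_grid(bird_id = birds, category = cats)
  u <- dplyr::count(fixes, .data$bird_id, .data$category, name = "use")
  out <- dplyr::left_join(grid, u, by = c("bird_id", "category"))
  out$use[is.na(out$use)] <- 0L
  totals <- tapply(out$use, out$bird_id, sum)
  out$use_total <- as.integer(totals[out$bird_id])
  out$avail <- as.integer(a[out$category])
  out$avail_total <- sum(a)
  out
}

#' Continuity-corrected per-bird selection coefficient
#'
#' For one bird, the log ratio of use proportion to availability proportion
#' of a focal category, minus the same quantity for the reference category:
#' `sc = ln((U_f/U_tot)/(A_f/A_tot)) - ln((U_r/U_tot)/(A_r/A_tot))`. Any zero
#' count among the four (use or availability, focal or reference) is replaced
#' by 0.5 before forming proportions, so the coefficient stays finite — e.g.
#' 0 use out of 24 fixes becomes the proportion 0.5/24 = 0.021.
#'
#' @param counts a [selection_counts()] table (or any tibble with the same
#'   columns).
#' @param focal,reference category names.
#' @return tibble with one row per bird: `bird_id`, `focal`, `reference`,
#'   `sc` (log scale), `corrected` (whether a 0.5 substitution was applied).
#'   Birds for which both categories are entirely absent from availability
#'   get `sc = NA`.
#' @export
continuity_sc <- function(counts, focal, reference = reference_category()) {
  stopifnot(all(c("bird_id", "category", "use", "use_total", "avail",
                  "avail_total") %in% names(counts)))
  f <- counts[counts$category == focal, ]
  r <- counts[counts$category == reference, ]
  stopifnot(nrow(f) > 0, nrow(r) > 0)
  m <- dplyr::inner_join(f, r, by = "bird_id", suffix = c("_f", "_r"))
  corrected <- m$use_f == 0 | m$use_r == 0 | m$avail_f == 0 | m$avail_r == 0
  half <- function(x) ifelse(x == 0, 0.5, x)
  sc <- log((half(m$use_f) / m$use_total_f) /
              (half(m$avail_f) / m$avail_total_f)) -
    log((half(m$use_r) / m$use_total_r) /
          (half(m$avail_r) / m$avail_total_r))
  undefined <- m$avail_f == 0 & m$avail_r == 0
  sc[undefined] <- NA_real_
  tibble::tibble(bird_id = m$bird_id, focal = focal, reference = reference,
                 sc = sc, corrected = corrected)
}

#' Mean selection coefficient across birds with simple normal statistics
#'
#' @param sc_table tibble from [continuity_sc()] (needs >= 2 birds with
#'   finite `sc`).
#' @return list `mean`, `se` (sd/sqrt(n)), `ci` (mean +/- 1.96 se), `n`.
#' @export
mean_sc <- function(sc_table) {
  x <- sc_table$sc[is.finite(sc_table$sc)]
  n <- length(x)
  if (n < 2) {
    return(list(mean = if (n == 1) x else NA_real_, se = NA_real_,
                ci = c(NA_real_, NA_real_), n = n))
  }
  m <- mean(x)
  se <- stats::sd(x) / sqrt(n)
  list(mean = m, se = se, ci = m + c(-1, 1) * 1.96 * se, n = n)
}

#' t-test for the difference of two selection coefficients
#'
#' Compares a coefficient for the same level estimated by two different
#' models (e.g. cover-only versus cover-plus-distance):
#' `t = (B_1 - B_2) / sqrt(SE_1^2 + SE_2^2)` on `df_1 + df_2` degrees of
#' freedom, two-sided. The ordering (which estimate is subtracted from
#' which) is recorded explicitly; swapping the arguments flips the signs of
#' the difference and t but leaves SE, df and p unchanged.
#'
#' @param B_a,SE_a,df_a first estimate, its SE and df.
#' @param B_b,SE_b,df_b second estimate, its SE and df.
#' @param ordering label naming the subtraction, default
#'   `"first-minus-second"`.
#' @return tibble with `delta_B`, `SE`, `df`, `t`, `p`, `ordering`.
#' @examples
#' coef_difference_test(-1.56, 0.32, 50.0, -0.94, 0.33, 59.1)
#' @export
coef_difference_test <- function(B_a, SE_a, df_a, B_b, SE_b, df_b,
                                 ordering = "first-minus-second") {
  if (!is.finite(SE_a) || !is.finite(SE_b) || SE_a <= 0 || SE_b <= 0) {
    return(tibble::tibble(delta_B = NA_real_, SE = NA_real_, df = NA_real_,
                          t = NA_real_, p = NA_real_, ordering = ordering))
  }
  delta <- B_a - B_b
  se <- sqrt(SE_a^2 + SE_b^2)
  df <- df_a + df_b
  t <- delta / se
  tibble::tibble(delta_B = delta, SE = se, df = df, t = t,
                 p = 2 * stats::pt(-abs(t), df), ordering = ordering)
}

#' Mean proportional use of distance bins across birds
#'
#' Each bird contributes a vector of proportions of its fixes over the ten
#' 100-m distance bins (summing to 1); the summary is the arithmetic mean and
#' a normal 95% CI per bin across birds. CIs are truncated to \[0, 1\] for
#' display only (`ci_lo_display`, `ci_hi_display`).
#'
#' @param fixes filtered foraging fixes (columns `bird_id`, `bin`).
#' @return tibble per bin: `bin`, `label`, `mean`, `se`, `ci_lo`, `ci_hi`,
#'   `ci_lo_display`, `ci_hi_display`, `n_birds`.
#' @export
distance_use_summary <- function(fixes) {
  birds <- unique(fixes$bird_id)
  props <- vapply(birds, function(b) {
    x <- fixes$bin[fixes$bird_id == b]
    as.numeric(table(factor(x, levels = 0:9)) / length(x))
  }, numeric(10))
  m <- rowMeans(props)
  n <- length(birds)
  se <- apply(props, 1, stats::sd) / sqrt(n)
  lo <- m - 1.96 * se
  hi <- m + 1.96 * se
  tibble::tibble(bin = 0:9, label = distance_bin_labels(), mean = m,
                 se = se, ci_lo = lo, ci_hi = hi,
                 ci_lo_display = pmax(0, lo), ci_hi_display = pmin(1, hi),
                 n_birds = n)
}
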