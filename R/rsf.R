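#' Build the stacked use-availability table
#'
#' Stacks GPS fixes (response 1, "use") against the systematic availability
#' sample (response 0), replicating the full RAP set once per bird under that
#' bird's id so that every bird contributes both use and availability rows.
#' Category and distance bin are carried for both; raw distance is kept so
#' that distance-zone subsets remain possible downstream.
#'
#' @param fixes filtered, annotated foraging fixes (from
#'   [apply_qc_filters()]): columns `bird_id`, `category`, `distance_m`,
#'   `bin`.
#' @param raps availability points (from [generate_raps()]).
#' @return tibble with columns `bird_id`, `response` (1 use / 0 availability),
#'   `category`, `bin`, `distance_m`.
#' @export
build_use_availability <- function(fixes, raps) {
  if (nrow(raps) == 0) stop("no availability points", call. = FALSE)
  birds <- unique(fixes$bird_id)
  empty <- setdiff(birds, unique(fixes$bird_id[!is.na(fixes$category)]))
  if (length(empty) > 0) {
    warning("bird(s) with no usable fixes excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
    birds <- setdiff(birds, empty)
  }
  if (length(birds) == 0) stop("no birds with fixes", call. = FALSE)
  use <- tibble::tibble(bird_id = fixes$bird_id, response = 1L,
                        category = fixes$category, bin = fixes$bin,
                        distance_m = fixes$distance_m)
  avail <- dplyr::bind_rows(lapply(birds, function(b) {
    tibble::tibble(bird_id = b, response = 0L, category = raps$category,
                   bin = raps$bin, distance_m = raps$distance_m)
  }))
  dplyr::bind_rows(use, avail)
}

rsf_fixed_formula <- function(model_form) {
  switch(model_form,
         cover_only = response ~ category_f,
         distance_only = response ~ bin_f,
         cover_plus_distance = response ~ category_f + bin_f,
         stop("unknown model_form: ", model_form, call. = FALSE))
}

# Aggregate the 0/1 table to weighted cells; identical binomial likelihood,
# orders of magnitude fewer rows.
rsf_aggregate <- function(table, reference_cat, reference_bin_label) {
  cats <- intersect(foraging_categories(), unique(table$category))
  if (!reference_cat %in% cats) {
    stop("reference category '", reference_cat, "' absent from the table",
         call. = FALSE)
  }
  cats <- c(reference_cat, setdiff(cats, reference_cat))
  agg <- dplyr::count(table, .data$bird_id, .data$category, .data$bin,
                      .data$response, name = "n")
  agg$category_f <- factor(agg$category, levels = cats)
  labs <- distance_bin_labels()
  labs_present <- labs[sort(unique(agg$bin)) + 1L]
  if (reference_bin_label %in% labs_present) {
    labs_present <- c(reference_bin_label,
                      setdiff(labs_present, reference_bin_label))
  }
  agg$bin_f <- factor(labs[agg$bin + 1L], levels = labs_present)
  agg
}

#' Fit a use-availability resource selection function
#'
#' Logistic regression of use (1) versus availability (0) on habitat
#' category and/or 100-m distance-to-nest bin, with treatment coding against
#' the reference levels `Grazed` and "0-99 m". Coefficients are log selection
#' ratios: how often a level is used relative to the reference at equal
#' availability.
#'
#' Three estimation methods are available. `"mixed"` is a binomial GLMM
#' (logit link) with independent Gaussian random intercepts for bird,
#' bird-by-category level and bird-by-bin level (the grouping structure that
#' absorbs unequal use/availability ratios between birds and per-bird
#' variation in selection). `"fixed_robust"` is a fixed-effects logistic fit
#' with cluster-robust (by bird) standard errors and t-statistics on
#' (birds - 1) degrees of freedom; it is the mandatory fallback when the
#' mixed fit fails to converge, and is also the recommended estimator for
#' large simulation studies. `"fixed"` is plain maximum-likelihood logistic
#' regression with model-based standard errors, appropriate when observations
#' are independent (e.g. data simulated without per-bird heterogeneity).
#' `"auto"` tries `"mixed"` and falls back to `"fixed_robust"`.
#'
#' @param table a [build_use_availability()] table.
#' @param model_form one of `"cover_only"`, `"distance_only"`,
#'   `"cover_plus_distance"`.
#' @param method estimation method, see Details.
#' @param reference_cat reference habitat category.
#' @param reference_bin_label reference distance-bin label.
#' @return an `rsf_fit` object: tibble `coefficients` (term, factor, level,
#'   B, SE, df, t, p, reference, estimable), `vcov`, `variance_components`,
#'   `effect_tests`, `converged`, `method`, `model_form`, `n_use`, `n_avail`,
#'   `n_birds`.
#' @export
fit_rsf <- function(table,
                    model_form = c("cover_plus_distance", "cover_only",
                                   "distance_only"),
                    method = c("auto", "mixed", "fixed_robust", "fixed"),
                    reference_cat = reference_category(),
                    reference_bin_label = distance_bin_labels()[1]) {
  model_form <- match.arg(model_form)
  method <- match.arg(method)
  if (!all(c(0L, 1L) %in% table$response)) {
    stop("both response classes (use and availability) must be present",
         call. = FALSE)
  }
  agg <- rsf_aggregate(table, reference_cat, reference_bin_label)
  fixed <- rsf_fixed_formula(model_form)

  fit <- NULL
  used_method <- method
  converged <- TRUE
  varcomp <- numeric(0)
  if (method %in% c("auto", "mixed")) {
    re <- switch(model_form,
                 cover_only = "(1 | bird_id) + (1 | bird_id:category_f)",
                 distance_only = "(1 | bird_id) + (1 | bird_id:bin_f)",
                 cover_plus_distance = paste(
                   "(1 | bird_id) + (1 | bird_id:category_f)",
                   "+ (1 | bird_id:bin_f)"))
    form <- stats::as.formula(paste(deparse(fixed), "+", re))
    mixed_ok <- TRUE
    fit <- withCallingHandlers(
      tryCatch(
        lme4::glmer(form, data = agg, family = stats::binomial("logit"),
                    weights = n, nAGQ = 0L,
                    control = lme4::glmerControl(
                      check.conv.singular = "ignore")),
        error = function(e) { mixed_ok <<- FALSE; NULL }),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
          mixed_ok <<- FALSE
        }
        invokeRestart("muffleWarning")
      })
    if (mixed_ok && !is.null(fit)) {
      used_method <- "mixed"
      vc <- lme4::VarCorr(fit)
      varcomp <- vapply(vc, function(m) m[1, 1], numeric(1))
      B <- lme4::fixef(fit)
      V <- as.matrix(stats::vcov(fit))
    } else if (method == "mixed") {
      stop("mixed-model fit failed to converge; use method = 'auto' for ",
           "the cluster-robust fallback", call. = FALSE)
    } else {
      used_method <- "fixed_robust"
      converged <- FALSE   # records that the mixed route was abandoned
      fit <- NULL
    }
  }
  if (is.null(fit)) {
    fit <- stats::glm(fixed, data = agg, family = stats::binomial("logit"),
                      weights = n)
    B <- stats::coef(fit)
    if (identical(method, "fixed")) {
      used_method <- "fixed"
      V <- stats::vcov(fit)
    } else {
      used_method <- "fixed_robust"
      # CR3 (jackknife-type) cluster correction: with tens of birds rather
      # than hundreds, the plain CR1 cluster estimator is anti-conservative.
      # CR3 is undefined when a cluster fits itself perfectly (singular
      # leverage adjustment); degrade gracefully to CR2 then CR1.
      V <- NULL
      if (length(unique(agg$bird_id)) >= 2) {
        for (type in c("HC3", "HC2", "HC1")) {
          V <- tryCatch(
            suppressWarnings(sandwich::vcovCL(fit, cluster = agg$bird_id,
                                              type = type)),
            error = function(e) NULL)
          if (!is.null(V) && all(is.finite(diag(V)))) break
          V <- NULL
        }
      }
      # a single bird (or a degenerate meat matrix) leaves nothing to
      # cluster on; fall back to model-based covariance
      if (is.null(V)) V <- stats::vcov(fit)
    }
  }

  n_birds <- length(unique(agg$bird_id))
  den_df <- if (used_method == "fixed_robust" && n_birds >= 2) {
    n_birds - 1
  } else {
    sum(agg$n) - length(B)
  }
  SE <- sqrt(diag(V))
  estimable <- is.finite(B) & is.finite(SE) & abs(B) < 15 & SE < 50
  tval <- ifelse(estimable, B / SE, NA_real_)
  pval <- ifelse(estimable, 2 * stats::pt(-abs(tval), den_df), NA_real_)

  term_info <- function(nm) {
    if (nm == "(Intercept)") return(c("intercept", "(Intercept)"))
    if (startsWith(nm, "category_f")) {
      return(c("cover", sub("^category_f", "", nm)))
    }
    if (startsWith(nm, "bin_f")) return(c("distance", sub("^bin_f", "", nm)))
    c("other", nm)
  }
  info <- t(vapply(names(B), term_info, character(2)))
  coefs <- tibble::tibble(
    term = names(B), factor = info[, 1], level = info[, 2],
    B = unname(B), SE = unname(SE), df = den_df, t = unname(tval),
    p = unname(pval), reference = FALSE, estimable = unname(estimable))
  # reference rows, Table-style: B exactly 0, no SE
  refs <- tibble::tibble(term = character(0), factor = character(0),
                         level = character(0), B = numeric(0),
                         SE = numeric(0), df = numeric(0), t = numeric(0),
                         p = numeric(0), reference = logical(0),
                         estimable = logical(0))
  if (model_form != "distance_only") {
    refs <- dplyr::bind_rows(refs, tibble::tibble(
      term = paste0("category_f", reference_cat), factor = "cover",
      level = reference_cat, B = 0, SE = NA_real_, df = NA_real_,
      t = NA_real_, p = NA_real_, reference = TRUE, estimable = TRUE))
  }
  if (model_form != "cover_only") {
    refs <- dplyr::bind_rows(refs, tibble::tibble(
      term = paste0("bin_f", reference_bin_label), factor = "distance",
      level = reference_bin_label, B = 0, SE = NA_real_, df = NA_real_,
      t = NA_real_, p = NA_real_, reference = TRUE, estimable = TRUE))
  }
  coefs <- dplyr::bind_rows(coefs, refs)

  out <- structure(
    list(model_form = model_form, method = used_method,
         converged = converged, coefficients = coefs, vcov = V,
         variance_components = varcomp, den_df = den_df,
         n_use = sum(agg$n[agg$response == 1L]),
         n_avail = sum(agg$n[agg$response == 0L]),
         n_birds = n_birds, effect_tests = NULL),
    class = "rsf_fit")
  factors <- setdiff(unique(coefs$factor[!coefs$reference]),
                     c("intercept", "other"))
  out$effect_tests <- dplyr::bind_rows(lapply(factors, function(f) {
    tst <- overall_effect_test(out, f)
    tibble::tibble(factor = f, F = tst["F"], num_df = tst["num_df"],
                   den_df = tst["den_df"], p = tst["p"])
  }))
  out
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat("<rsf_fit>", x$model_form, "| method:", x$method,
      if (!x$converged) "(mixed fit did not converge; fell back)", "\n")
  cat("  use:", x$n_use, " availability:", x$n_avail,
      " birds:", x$n_birds, "\n")
  print(as.data.frame(x$coefficients[, c("factor", "level", "B", "SE",
                                         "df", "t", "p")]),
        digits = 3, row.names = FALSE)
  if (length(x$variance_components)) {
    cat("  variance components:\n")
    print(round(x$variance_components, 3))
  }
  if (!is.null(x$effect_tests) && nrow(x$effect_tests)) {
    cat("  overall (type-III) effect tests:\n")
    print(as.data.frame(x$effect_tests), digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Joint (type-III style) test that all coefficients of a factor are zero
#'
#' Wald test of the joint null that every non-reference coefficient of the
#' factor is zero, given the other terms in the model: F = b' V^-1 b / q on
#' (q, denominator-df) degrees of freedom, where V is the fitted covariance
#' of the q coefficients (cluster-robust when the fit used the robust
#' method). For a single-coefficient factor this reduces to F = t^2.
#'
#' @param fit an [fit_rsf()] result.
#' @param factor `"cover"` or `"distance"`.
#' @return named numeric vector `F`, `num_df`, `den_df`, `p` (all `NA` when
#'   any coefficient of the factor is non-estimable).
#' @export
overall_effect_test <- function(fit, factor) {
  cf <- fit$coefficients
  rows <- cf[!cf$reference & cf$factor == factor, ]
  if (nrow(rows) == 0) stop("factor '", factor, "' not in fit", call. = FALSE)
  if (!all(rows$estimable)) {
    warning("non-estimable coefficient(s) in factor '", factor,
            "'; overall test skipped", call. = FALSE)
    return(c(F = NA_real_, num_df = NA_real_, den_df = NA_real_,
             p = NA_real_))
  }
  idx <- match(rows$term, colnames(fit$vcov))
  b <- rows$B
  V <- fit$vcov[idx, idx, drop = FALSE]
  # rank-aware inverse: a cluster-robust covariance has rank at most the
  # number of clusters, so a joint test of more coefficients than birds must
  # drop the null directions rather than crash
  e <- eigen(V, symmetric = TRUE)
  tol <- max(e$values) * length(b) * .Machine$double.eps * 1e3
  pos <- e$values > tol
  q <- sum(pos)
  if (q == 0) {
    return(c(F = NA_real_, num_df = NA_real_, den_df = NA_real_,
             p = NA_real_))
  }
  z <- crossprod(e$vectors[, pos, drop = FALSE], b)
  Fstat <- sum(z^2 / e$values[pos]) / q
  p <- stats::pf(Fstat, q, fit$den_df, lower.tail = FALSE)
  c(F = Fstat, num_df = q, den_df = fit$den_df, p = p)
}

#' Distance-zone specification for subset RSFs
#'
#' @param intervals list of inclusive metre intervals (matched to whole
#'   100-m bins) defining the zones; defaults to 0-199, 200-399 and
#'   400-999 m.
#' @param min_fixes_per_bird birds with this many GPS fixes or fewer inside a
#'   zone are dropped from that zone's fit (strictly more than
#'   `min_fixes_per_bird` fixes are required).
#' @return an object of class `zone_spec`.
#' @export
zone_spec <- function(intervals = list(c(0, 199), c(200, 399), c(400, 999)),
                      min_fixes_per_bird = 20L) {
  lo <- vapply(intervals, `[`, numeric(1), 1)
  hi <- vapply(intervals, `[`, numeric(1), 2)
  stopifnot(all(lo < hi), !is.unsorted(lo), all(hi[-length(hi)] < lo[-1]))
  structure(list(intervals = intervals,
                 min_fixes_per_bird = as.integer(min_fixes_per_bird)),
            class = "zone_spec")
}

#' Cover-type RSFs within distance zones
#'
#' Fits a cover-only RSF separately on the rows of each distance zone.
#' Within a zone, birds with too few GPS fixes there are dropped (both their
#' use and availability rows), and categories never used in the zone are
#' dropped from the design and reported, mirroring how sparse distant zones
#' are handled in practice. A zone left with fewer than two categories is
#' skipped with a report entry.
#'
#' @param table a [build_use_availability()] table (with `distance_m`).
#' @param zones a [zone_spec()].
#' @param method passed to [fit_rsf()].
#' @return list of per-zone entries: `zone` (label), `fit` (an `rsf_fit` or
#'   `NULL`), `birds_dropped`, `categories_dropped`, `skipped`.
#' @export
fit_zone_rsfs <- function(table, zones = zone_spec(), method = "auto") {
  lapply(zones$intervals, function(iv) {
    label <- paste0(iv[1], "-", iv[2], " m")
    sub <- table[table$distance_m >= iv[1] & table$distance_m < iv[2] + 1, ]
    use_per_bird <- table(sub$bird_id[sub$response == 1L])
    keep_birds <- names(use_per_bird)[use_per_bird > zones$min_fixes_per_bird]
    dropped_birds <- setdiff(unique(sub$bird_id), keep_birds)
    sub <- sub[sub$bird_id %in% keep_birds, ]
    used_cats <- unique(sub$category[sub$response == 1L])
    dropped_cats <- setdiff(unique(sub$category), used_cats)
    sub <- sub[sub$category %in% used_cats, ]
    if (length(used_cats) < 2 || length(keep_birds) == 0 ||
        !all(c(0L, 1L) %in% sub$response)) {
      return(list(zone = label, fit = NULL, birds_dropped = dropped_birds,
                  categories_dropped = dropped_cats, skipped = TRUE))
    }
    ref <- if (reference_category() %in% used_cats) reference_category() else
      intersect(foraging_categories(), used_cats)[1]
    fit <- fit_rsf(sub, model_form = "cover_only", method = method,
                   reference_cat = ref)
    list(zone = label, fit = fit, birds_dropped = dropped_birds,
         categories_dropped = dropped_cats, skipped = FALSE)
  })
}
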