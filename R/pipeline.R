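#' Configuration of an end-to-end pipeline run
#'
#' A run either ingests real data (`loggers_dir` + `landscape_file`) or
#' generates synthetic data from a [simulation_config()]. All stage outputs
#' (filter report, availability sample, use-availability table, model fits,
#' inference tables, figures, run log) land in `output_dir`.
#'
#' @param output_dir run directory (created; contents overwritten).
#' @param loggers_dir directory of per-bird logger `.txt` files, or `NULL`.
#' @param landscape_file GeoJSON land-cover map, or `NULL`.
#' @param simulation a [simulation_config()] used when `loggers_dir` is
#'   `NULL`.
#' @param rules a [filter_rules()].
#' @param rap_spacing_m,rap_radius_m availability grid spacing and retention
#'   radius (m).
#' @param zones a [zone_spec()].
#' @param method estimation method passed to [fit_rsf()].
#' @param figures write diagnostic figures (PDF)?
#' @return an object of class `run_config`.
#' @export
run_config <- function(output_dir,
                       loggers_dir = NULL,
                       landscape_file = NULL,
                       simulation = simulation_config(),
                       rules = filter_rules(),
                       rap_spacing_m = 50,
                       rap_radius_m = 999,
                       zones = zone_spec(),
                       method = "auto",
                       figures = TRUE) {
  structure(list(output_dir = output_dir, loggers_dir = loggers_dir,
                 landscape_file = landscape_file, simulation = simulation,
                 rules = rules, rap_spacing_m = rap_spacing_m,
                 rap_radius_m = rap_radius_m, zones = zones,
                 method = method, figures = figures),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Maps a YAML key-value file onto [run_config()]. Recognised top-level
#' keys: `output_dir`, `loggers_dir`, `landscape_file`, `rap_spacing_m`,
#' `rap_radius_m`, `method`, `figures`, plus nested maps `simulation`
#' (arguments to [simulation_config()]) and `rules` (arguments to
#' [filter_rules()]). Unspecified values keep their defaults.
#'
#' @param path YAML file path.
#' @param output_dir overrides the file's `output_dir` when non-`NULL`.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, output_dir = NULL) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  for (nm in c("habitat_proportions", "true_selection", "contamination")) {
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  }
  if (!is.null(sim_args$distance_decay)) {
    sim_args$distance_decay <- as.numeric(unlist(sim_args$distance_decay))
  }
  run_config(
    output_dir = output_dir %||% y$output_dir %||%
      stop("output_dir missing from ", path, call. = FALSE),
    loggers_dir = y$loggers_dir,
    landscape_file = y$landscape_file,
    simulation = do.call(simulation_config, sim_args),
    rules = do.call(filter_rules, y$rules %||% list()),
    rap_spacing_m = y$rap_spacing_m %||% 50,
    rap_radius_m = y$rap_radius_m %||% 999,
    method = y$method %||% "auto",
    figures = y$figures %||% TRUE)
}

write_fit_outputs <- function(fit, stem, out) {
  readr::write_csv(fit$coefficients, file.path(out, paste0(stem, ".csv")))
  meta <- list(model_form = fit$model_form, method = fit$method,
               converged = fit$converged,
               variance_components = as.list(fit$variance_components),
               effect_tests = fit$effect_tests,
               n_use = fit$n_use, n_avail = fit$n_avail,
               n_birds = fit$n_birds)
  jsonlite::write_json(meta, file.path(out, paste0(stem, "_meta.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full habitat-selection pipeline
#'
#' Orchestrates every stage: data acquisition (ingest or simulate), QC
#' filtering, availability sampling, use-availability table construction,
#' the three full RSFs (cover only, distance only, cover plus distance),
#' the distance-zone cover RSFs, coefficient-difference tests between the
#' single-factor and combined models, selection-ratio reporting, the
#' distance-use summary, and figures. Deterministic given the simulation
#' seed: re-running with the same config reproduces all CSV outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the main in-memory artifacts (`landscape`,
#'   `fixes`, `report`, `raps`, `table`, `fits`, `zone_fits`,
#'   `difference_tests`, `distance_use`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  logline <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), ..., "\n",
        file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  logline("cpforage", as.character(utils::packageVersion("cpforage")),
          "| R", paste(R.version$major, R.version$minor, sep = "."))

  landscape <- pipeline_stage("landscape", {
    if (!is.null(config$landscape_file)) {
      read_landscape_geojson(config$landscape_file)
    } else {
      l <- generate_landscape(config$simulation)
      write_landscape_geojson(l, file.path(out, "landscape.geojson"))
      l
    }
  })
  fixes <- pipeline_stage("fixes", {
    if (!is.null(config$loggers_dir)) {
      read_logger_directory(config$loggers_dir)
    } else {
      logline("simulating fixes, seed", config$simulation$seed)
      f <- simulate_fixes(landscape, config$simulation)
      write_logger_files(f, file.path(out, "loggers"))
      f
    }
  })

  filtered <- pipeline_stage("filter", {
    res <- apply_qc_filters(fixes, config$rules, landscape)
    readr::write_csv(res$fixes, file.path(out, "foraging_fixes.csv"))
    jsonlite::write_json(
      list(input = res$report$input,
           excluded = as.list(res$report$excluded),
           birds_dropped = res$report$birds_dropped,
           retained = res$report$retained),
      file.path(out, "filter_report.json"),
      auto_unbox = TRUE, pretty = TRUE)
    logline("retained", res$report$retained, "of", res$report$input, "fixes")
    res
  })

  raps <- pipeline_stage("availability", {
    r <- generate_raps(landscape, config$rap_spacing_m, config$rap_radius_m)
    if (nrow(r) == 0) stop("no availability points (all habitat excluded?)")
    readr::write_csv(r, file.path(out, "raps.csv"))
    readr::write_csv(availability_table(r),
                     file.path(out, "availability_table.csv"))
    r
  })

  table <- pipeline_stage("use_availability", {
    tab <- build_use_availability(filtered$fixes, raps)
    readr::write_csv(tab, file.path(out, "use_availability.csv"))
    tab
  })

  forms <- c("cover_only", "distance_only", "cover_plus_distance")
  fits <- pipeline_stage("rsf", {
    fits <- lapply(forms, function(f) {
      fit <- fit_rsf(table, model_form = f, method = config$method)
      write_fit_outputs(fit, paste0("rsf_", f), out)
      logline("fitted", f, "via", fit$method)
      fit
    })
    names(fits) <- forms
    fits
  })

  zone_fits <- pipeline_stage("zones", {
    zf <- fit_zone_rsfs(table, config$zones, method = config$method)
    for (z in zf) {
      stem <- paste0("rsf_zone_", gsub("[^0-9]+", "_", z$zone))
      if (!z$skipped) write_fit_outputs(z$fit, stem, out)
      logline("zone", z$zone, if (z$skipped) "skipped" else "fitted",
              "| birds dropped:", length(z$birds_dropped),
              "| categories dropped:",
              paste(z$categories_dropped, collapse = ","))
    }
    zf
  })

  inference <- pipeline_stage("inference", {
    # single-factor vs combined-model coefficient differences, Table-style
    diffs <- dplyr::bind_rows(lapply(c("cover", "distance"), function(fac) {
      single <- if (fac == "cover") fits$cover_only else fits$distance_only
      comb <- fits$cover_plus_distance
      a <- single$coefficients
      b <- comb$coefficients
      lv <- intersect(a$level[a$factor == fac & !a$reference],
                      b$level[b$factor == fac & !b$reference])
      dplyr::bind_rows(lapply(lv, function(l) {
        ea <- a[a$factor == fac & a$level == l, ]
        eb <- b[b$factor == fac & b$level == l, ]
        d <- coef_difference_test(ea$B, ea$SE, ea$df, eb$B, eb$SE, eb$df,
                                  ordering = "single-factor-minus-combined")
        dplyr::mutate(d, factor = fac, level = l, .before = 1)
      }))
    }))
    readr::write_csv(diffs, file.path(out, "coefficient_differences.csv"))

    cf <- fits$cover_plus_distance$coefficients
    cov_rows <- cf[cf$factor == "cover" & !cf$reference & cf$estimable, ]
    ratios <- vapply(cov_rows$B, function(b) odds_ratio(b)$display,
                     character(1))
    writeLines(c("Selection ratios relative to Grazed (cover+distance model):",
                 sprintf("  %-12s B = %6.2f  ratio %s", cov_rows$level,
                         cov_rows$B, ratios)),
               file.path(out, "selection_ratios.txt"))

    du <- distance_use_summary(filtered$fixes)
    readr::write_csv(du, file.path(out, "distance_use_summary.csv"))
    list(difference_tests = diffs, distance_use = du)
  })

  if (isTRUE(config$figures)) {
    pipeline_stage("figures", {
      av <- availability_table(raps)
      use <- dplyr::count(filtered$fixes, .data$category, .data$bin,
                          name = "n")
      use$proportion <- use$n / sum(use$n)
      both <- dplyr::bind_rows(
        dplyr::mutate(av, source = "availability"),
        dplyr::mutate(use, source = "use"))
      p1 <- ggplot2::ggplot(both,
                            ggplot2::aes(x = .data$bin, y = .data$proportion,
                                         fill = .data$category)) +
        ggplot2::geom_col() +
        ggplot2::facet_wrap(~source) +
        ggplot2::scale_x_continuous(breaks = 0:9) +
        ggplot2::labs(x = "distance bin (100 m)", y = "proportion")
      ggplot2::ggsave(file.path(out, "use_vs_availability.pdf"), p1,
                      width = 9, height = 4)
      cf <- dplyr::bind_rows(lapply(fits, function(f) {
        dplyr::mutate(f$coefficients, model = f$model_form)
      }))
      cf <- cf[!cf$reference & cf$factor %in% c("cover", "distance"), ]
      p2 <- ggplot2::ggplot(cf, ggplot2::aes(x = .data$level, y = .data$B,
                                             colour = .data$model)) +
        ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$B - 1.96 * .data$SE,
                                              ymax = .data$B + 1.96 * .data$SE),
                                 position = ggplot2::position_dodge(0.5)) +
        ggplot2::facet_wrap(~factor, scales = "free_x") +
        ggplot2::labs(x = NULL, y = "selection coefficient (log ratio)") +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
      ggplot2::ggsave(file.path(out, "coefficients.pdf"), p2,
                      width = 9, height = 4.5)
    })
  }
  logline("run complete")
  invisible(list(landscape = landscape, fixes = fixes,
                 report = filtered$report, raps = raps, table = table,
                 fits = fits, zone_fits = zone_fits,
                 difference_tests = inference$difference_tests,
                 distance_use = inference$distance_use))
}
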