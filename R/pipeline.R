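# Pipeline orchestration: one entry point running the stages
# foi-score -> availability -> ship density -> satellite densities ->
# comparison report, with pre-flight input validation and a run manifest.

#' Run the full density-comparison pipeline
#'
#' The configuration (a YAML file or an equivalent list) supplies the survey
#' geometry, the ship-survey summary, and the satellite/tag inputs — either
#' as file paths (`foi`, `tag_summaries` or `tag_depths`) or as inline
#' values (`counts:` with the three class counts, `availability:` with
#' `a_hat` and `cv`). All referenced files are checked before any stage
#' runs; any stage failure aborts with the stage name attached.
#'
#' @param config path to a YAML configuration or a list with the same keys.
#' @param out_dir directory for the outputs (`table2.csv`, `ratios.csv`,
#'   `estimates.json`, `manifest.json`); created if missing. `NULL` skips
#'   writing.
#' @param seed integer seed recorded in the manifest and applied before any
#'   stochastic stage.
#' @return a list with `report` (a `comparison_report`), `estimates`,
#'   `counts`, `availability` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = 1L) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    if (!file.exists(config)) schema_error(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = c("whaledens_pipeline_error", "whaledens_error")))
    })
  }

  # --- pre-flight ------------------------------------------------------
  inputs <- stage("preflight", {
    paths <- unlist(config[c("foi", "tag_summaries", "tag_depths")])
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      schema_error(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")))
    }
    for (key in c("image_area_total", "area_calmer", "area_rougher")) {
      if (is.null(config[[key]])) schema_error(sprintf("config key '%s' missing", key))
    }
    if (is.null(config$ship)) schema_error("config key 'ship' missing")
    if (is.null(config$foi) && is.null(config$counts)) {
      schema_error("config needs either 'foi' (a scored table) or inline 'counts'")
    }
    if (is.null(config$tag_summaries) && is.null(config$tag_depths) &&
        is.null(config$availability)) {
      schema_error("config needs 'tag_summaries', 'tag_depths' or inline 'availability'")
    }
    paths
  })
  svy <- survey_config(config$image_area_total, config$area_calmer,
                       config$area_rougher,
                       surface_threshold = config$surface_threshold %||% 1)
  set.seed(seed)

  # --- FOI scoring -----------------------------------------------------
  foi <- NULL
  strat <- NULL
  counts <- stage("foi_score", {
    if (!is.null(config$foi)) {
      foi <<- read_foi_table(config$foi)
      strat <<- stratify_counts(foi)
      classified_counts(foi$label)
    } else {
      structure(list(n_definite = config$counts$definite,
                     n_probable = config$counts$probable,
                     n_unclassified = config$counts$unclassified,
                     n_total = config$counts$definite + config$counts$probable +
                       config$counts$unclassified),
                class = "classified_counts")
    }
  })

  # --- availability ----------------------------------------------------
  avail <- stage("availability", {
    if (!is.null(config$tag_summaries)) {
      estimate_availability(read_tag_summaries(config$tag_summaries))
    } else if (!is.null(config$tag_depths)) {
      estimate_availability(summarise_tags(read_tag_depths(config$tag_depths),
                                           threshold = svy$surface_threshold))
    } else {
      structure(list(a_hat = config$availability$a_hat, se = NA_real_,
                     cv = config$availability$cv, n_tags = NA_integer_,
                     weighting = "supplied"),
                class = "availability_estimate")
    }
  })

  # --- ship density ----------------------------------------------------
  ship <- stage("ship_density", {
    sh <- config$ship
    mgs <- if (!is.null(sh$mean_group_size)) sh$mean_group_size else
      sh$n_individuals / sh$n_groups
    ship_density(sh$n_groups, mgs, esw = sh$esw, effort_L = sh$effort_km,
                 cv_components = c(reported = sh$cv %||% 0))
  })

  # --- satellite densities + comparison --------------------------------
  sats <- stage("satellite_density", {
    out <- list(
      "definite" = satellite_density(counts, svy$image_area_total, "definite"),
      "probable" = satellite_density(counts, svy$image_area_total, "probable"),
      "unclassified" = satellite_density(counts, svy$image_area_total, "unclassified"),
      "definite+probable" = satellite_density(counts, svy$image_area_total,
                                              "definite+probable")
    )
    if (!is.null(strat)) {
      for (st in c("calmer", "rougher")) {
        row <- strat[strat$stratum == st, ]
        cc <- structure(list(n_definite = row$n_definite,
                             n_probable = row$n_probable,
                             n_unclassified = row$n_unclassified,
                             n_total = row$n_total),
                        class = "classified_counts")
        ar <- if (st == "calmer") svy$area_calmer else svy$area_rougher
        out[[paste0("definite+probable (", st, ")")]] <-
          satellite_density(cc, ar, "definite+probable", stratum = st)
      }
    }
    out
  })
  report <- stage("report", build_comparison(ship, sats, avail))

  manifest <- list(
    tool = "whaledens",
    version = as.character(utils::packageVersion("whaledens")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_digest = if (!is.null(config_path)) unname(tools::md5sum(config_path)) else
      digest_object(config),
    input_digests = if (length(inputs)) as.list(tools::md5sum(inputs)) else list(),
    stages = list(
      list(stage = "foi_score", weights = foi_weights(),
           thresholds = c(definite_gt = 9, probable_ge = 7)),
      list(stage = "availability", threshold_m = svy$surface_threshold,
           weighting = avail$weighting,
           cv_formula = "duration-weighted between-tag sd / a_hat"),
      list(stage = "ship_density", estimator = "n*E[s]/(2*ESW*L)"),
      list(stage = "satellite_density", area_km2 = svy$image_area_total),
      list(stage = "report", rounding = "half-up, 2 d.p.")
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(report$table[c("class", "stratum", "density", "cv",
                                   "density_adjusted", "cv_adjusted")],
                    file.path(out_dir, "table2.csv"))
    write_table_csv(report$ratios, file.path(out_dir, "ratios.csv"))
    jsonlite::write_json(
      list(ship = unclass(ship), availability = unclass(avail),
           counts = unclass(counts),
           satellite = lapply(sats, unclass)),
      file.path(out_dir, "estimates.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(report = report, estimates = sats, ship = ship, counts = counts,
       availability = avail, stratified = strat, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of a canonical serialisation, for inline configs
digest_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(x), tf)
  unname(tools::md5sum(tf))
}
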