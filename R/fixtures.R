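# Packaged study inputs: the published Gerlache Strait summary data.

#' Gerlache Strait study inputs
#'
#' The published desk-scale inputs of the Gerlache Strait ship-vs-satellite
#' comparison: the 21 tag dive summaries (daylight seconds above/below the
#' 1 m surface threshold per deployment), the FOI class counts from the
#' principal observer (18 definite, 21 probable, 146 unclassified), the
#' image areas (971 km^2 total including overlaps; 635 calmer / 336
#' rougher), and the ship-survey summary (90 groups, 185 individuals of
#' which 177 humpback, ESW 3.1 km, effort 90.7 km, overall CV 0.09).
#'
#' @return a list with elements `tag_summaries` (data frame), `config`
#'   (a `survey_config`), `counts` (a `classified_counts`), `ship` (a list
#'   of the ship summary statistics) and `config_path` (the packaged YAML).
#' @export
gerlache_study <- function() {
  yaml_path <- system.file("extdata", "gerlache_survey.yaml",
                           package = "whaledens", mustWork = TRUE)
  csv_path <- system.file("extdata", "gerlache_tag_summaries.csv",
                          package = "whaledens", mustWork = TRUE)
  cfg <- yaml::read_yaml(yaml_path)
  list(
    tag_summaries = read_tag_summaries(csv_path),
    tag_summaries_path = csv_path,
    config = survey_config(cfg$image_area_total, cfg$area_calmer,
                           cfg$area_rougher, cfg$surface_threshold),
    counts = structure(list(n_definite = cfg$counts$definite,
                            n_probable = cfg$counts$probable,
                            n_unclassified = cfg$counts$unclassified,
                            n_total = cfg$counts$definite + cfg$counts$probable +
                              cfg$counts$unclassified),
                       class = "classified_counts"),
    ship = cfg$ship,
    config_path = yaml_path
  )
}

#' Pipeline configuration for the packaged Gerlache inputs
#'
#' Convenience wrapper building the [run_pipeline()] configuration list
#' that points at the packaged tag summaries and inline class counts.
#'
#' @return a configuration list.
#' @export
gerlache_pipeline_config <- function() {
  st <- gerlache_study()
  yaml_cfg <- yaml::read_yaml(st$config_path)
  yaml_cfg$tag_summaries <- st$tag_summaries_path
  yaml_cfg
}
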