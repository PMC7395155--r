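# CSV schemas and run configuration.
#
# Single source of truth for column names, units and validation rules.
# Units are fixed package-wide: distances km, depths m, times s, areas km^2,
# densities whales/km^2.

VISIBILITY_LEVELS  <- c("Good", "Fair", "Poor")
SEA_STATE_LEVELS   <- c("ideal", "good", "average", "sub-average", "poor")
CALMER_SEA_STATES  <- c("ideal", "good", "average")
STRATUM_LEVELS     <- c("calmer", "rougher")
PSI_COLS           <- paste0("psi", 1:13)

#' Raise a schema error (missing/misnamed column)
#' @noRd
schema_error <- function(msg) {
  stop(errorCondition(msg, class = c("whaledens_schema_error", "whaledens_error")))
}

#' Raise a validation error (well-formed file, invalid values)
#' @noRd
validation_error <- function(msg) {
  stop(errorCondition(msg, class = c("whaledens_validation_error", "whaledens_error")))
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    schema_error(sprintf("%s: missing column(s): %s", what,
                         paste(missing, collapse = ", ")))
  }
  invisible(df)
}

row_report <- function(bad_rows, msg) {
  validation_error(sprintf("%s (row%s %s)", msg,
                           if (length(bad_rows) > 1L) "s" else "",
                           paste(bad_rows, collapse = ", ")))
}

#' Read a ship-survey sightings table
#'
#' Expects a comma-separated UTF-8 file with a header row and columns
#' `perp_distance` (km), `group_size` (integer >= 1), `species`,
#' `beaufort` (ordinal 0-5), `visibility` (Good/Fair/Poor) and
#' `sightability` (ordinal 0-3, 0 = excellent).
#'
#' @param path path to the CSV file.
#' @return a validated `data.frame` of sightings.
#' @export
read_sightings <- function(path) {
  df <- read_csv_strict(path)
  validate_sightings(df)
}

#' @rdname read_sightings
#' @param df a data frame holding the sightings columns.
#' @export
validate_sightings <- function(df) {
  check_columns(df, c("perp_distance", "group_size", "species",
                      "beaufort", "visibility", "sightability"), "sightings")
  df$perp_distance <- as.numeric(df$perp_distance)
  df$group_size    <- as.integer(df$group_size)
  bad <- which(!is.finite(df$perp_distance) | df$perp_distance < 0)
  if (length(bad)) row_report(bad, "sightings: perp_distance must be finite and >= 0")
  bad <- which(is.na(df$group_size) | df$group_size < 1L)
  if (length(bad)) row_report(bad, "sightings: group_size must be an integer >= 1")
  bad <- which(!(df$beaufort %in% 0:5))
  if (length(bad)) row_report(bad, "sightings: beaufort must be an integer in 0..5")
  bad <- which(!(df$visibility %in% VISIBILITY_LEVELS))
  if (length(bad)) row_report(bad, "sightings: visibility must be one of Good/Fair/Poor")
  bad <- which(!(df$sightability %in% 0:3))
  if (length(bad)) row_report(bad, "sightings: sightability must be an integer in 0..3")
  df
}

#' Read a survey effort table
#'
#' Columns: `transect_id`, `length` (km, > 0).
#'
#' @param path path to the CSV file.
#' @return a validated `data.frame` with one row per transect.
#' @export
read_effort <- function(path) {
  df <- read_csv_strict(path)
  check_columns(df, c("transect_id", "length"), "effort")
  df$length <- as.numeric(df$length)
  bad <- which(!is.finite(df$length) | df$length <= 0)
  if (length(bad)) row_report(bad, "effort: transect length must be > 0")
  df
}

#' Read a feature-of-interest (FOI) criterion-score table
#'
#' Expects columns `foi_id`, `psi1`..`psi13` (each 0, 1 or 2), `sea_state`
#' (ideal/good/average/sub-average/poor), `stratum` (calmer/rougher) and
#' `observer`. The weighted total score and class label are recomputed from
#' the criterion scores on read; a stored `C_s` column is ignored (a message
#' notes any mismatch).
#'
#' @param path path to the CSV file.
#' @param weights criterion weight vector, see [score_foi()].
#' @return a `data.frame` of FOI records with `C_s` and `label` columns.
#' @export
read_foi_table <- function(path, weights = foi_weights()) {
  df <- read_csv_strict(path)
  validate_foi_table(df, weights)
}

#' @rdname read_foi_table
#' @param df a data frame holding the FOI columns.
#' @export
validate_foi_table <- function(df, weights = foi_weights()) {
  check_columns(df, c("foi_id", PSI_COLS, "sea_state", "stratum", "observer"),
                "foi_table")
  for (col in PSI_COLS) {
    v <- df[[col]]
    bad <- which(!(v %in% 0:2))
    if (length(bad)) {
      row_report(bad, sprintf("foi_table: %s must be 0, 1 or 2", col))
    }
    df[[col]] <- as.integer(v)
  }
  bad <- which(!(df$sea_state %in% SEA_STATE_LEVELS))
  if (length(bad)) row_report(bad, "foi_table: unknown sea_state label")
  bad <- which(!(df$stratum %in% STRATUM_LEVELS))
  if (length(bad)) row_report(bad, "foi_table: stratum must be calmer or rougher")
  scores <- apply(as.matrix(df[PSI_COLS]), 1L, score_foi, weights = weights)
  if ("C_s" %in% names(df)) {
    mism <- which(!is.na(df$C_s) & df$C_s != scores)
    if (length(mism)) {
      message(sprintf("foi_table: recomputed C_s overrides stored total in %d row(s): %s",
                      length(mism), paste(utils::head(mism, 10L), collapse = ", ")))
    }
  }
  df$C_s   <- scores
  df$label <- vapply(scores, classify_foi, character(1L))
  df
}

#' Read tag depth records
#'
#' Columns: `deployment_id`, `t` (s, strictly increasing within deployment),
#' `depth` (m) and `daylight` (logical/0-1). Negative depths (pressure-sensor
#' offsets above the surface) are clamped to 0 so that they can never be
#' classified as submerged.
#'
#' @param path path to the CSV file.
#' @return a named list of per-deployment data frames with columns
#'   `t`, `depth`, `daylight`.
#' @export
read_tag_depths <- function(path) {
  df <- read_csv_strict(path)
  check_columns(df, c("deployment_id", "t", "depth", "daylight"), "tag_depths")
  df$t       <- as.numeric(df$t)
  df$depth   <- pmax(as.numeric(df$depth), 0)
  df$daylight <- as.logical(df$daylight)
  if (anyNA(df$daylight)) validation_error("tag_depths: daylight must be logical")
  split_df <- split(df[c("t", "depth", "daylight")], df$deployment_id)
  for (id in names(split_df)) {
    tt <- split_df[[id]]$t
    if (any(diff(tt) <= 0)) {
      validation_error(sprintf("tag_depths: time not strictly increasing in deployment %s", id))
    }
  }
  split_df
}

#' Read per-tag dive summaries
#'
#' Alternative to raw depth series: one row per deployment holding the
#' pre-summarised daylight seconds above and below the surface threshold
#' (the layout tag manufacturers and field reports usually print).
#' Columns: `deployment_id`, `surface_s`, `dive_s`, `total_s`.
#'
#' @param path path to the CSV file.
#' @return a `data.frame` of tag summaries with a recomputed `proportion`.
#' @export
read_tag_summaries <- function(path) {
  df <- read_csv_strict(path)
  check_columns(df, c("deployment_id", "surface_s", "dive_s", "total_s"),
                "tag_summaries")
  for (col in c("surface_s", "dive_s", "total_s")) df[[col]] <- as.numeric(df[[col]])
  bad <- which(abs(df$surface_s + df$dive_s - df$total_s) > 0.2)
  if (length(bad)) row_report(bad, "tag_summaries: surface_s + dive_s must equal total_s")
  bad <- which(df$total_s <= 0 | df$surface_s < 0 | df$dive_s < 0)
  if (length(bad)) row_report(bad, "tag_summaries: durations must be non-negative with total > 0")
  df$proportion <- df$surface_s / df$total_s
  df
}

#' Read the survey-geometry configuration
#'
#' A flat-key YAML file with `image_area_total`, `area_calmer`,
#' `area_rougher` (km^2), `surface_threshold` (m) and optional
#' `esw_override` and `truncation_distance` (km).
#'
#' @param path path to the YAML file.
#' @return a validated list of class `survey_config`.
#' @export
read_survey_config <- function(path) {
  if (!file.exists(path)) schema_error(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  survey_config(
    image_area_total  = cfg$image_area_total,
    area_calmer       = cfg$area_calmer,
    area_rougher      = cfg$area_rougher,
    surface_threshold = if (is.null(cfg$surface_threshold)) 1 else cfg$surface_threshold,
    esw_override      = cfg$esw_override,
    truncation_distance = cfg$truncation_distance
  )
}

#' Construct and validate a survey configuration
#'
#' @param image_area_total total scanned image area including overlaps (km^2).
#' @param area_calmer,area_rougher stratum areas (km^2); must sum to the total.
#' @param surface_threshold depth (m) above which a whale counts as available;
#'   default 1 m, a deliberately conservative instantaneous threshold.
#' @param esw_override optional effective half strip width (km) to use instead
#'   of a fitted one.
#' @param truncation_distance optional right-truncation distance (km).
#' @return a list of class `survey_config`.
#' @export
survey_config <- function(image_area_total, area_calmer, area_rougher,
                          surface_threshold = 1, esw_override = NULL,
                          truncation_distance = NULL) {
  for (nm in c("image_area_total", "area_calmer", "area_rougher")) {
    v <- get(nm)
    if (is.null(v) || !is.finite(v) || v <= 0) {
      validation_error(sprintf("survey_config: %s must be a positive number", nm))
    }
  }
  if (abs(area_calmer + area_rougher - image_area_total) > 1e-6) {
    validation_error("survey_config: area_calmer + area_rougher must equal image_area_total")
  }
  if (!is.finite(surface_threshold) || surface_threshold <= 0) {
    validation_error("survey_config: surface_threshold must be > 0")
  }
  structure(list(image_area_total = image_area_total,
                 area_calmer = area_calmer, area_rougher = area_rougher,
                 surface_threshold = surface_threshold,
                 esw_override = esw_override,
                 truncation_distance = truncation_distance),
            class = "survey_config")
}

#' Write any of the package's tables as CSV
#'
#' One dialect throughout: comma separator, "." decimal, header row, UTF-8,
#' no quoting beyond what base R requires, no row names — so that a write
#' followed by a read reproduces the table exactly.
#'
#' @param df the table to write.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

read_csv_strict <- function(path) {
  if (!file.exists(path)) schema_error(sprintf("file not found: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
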