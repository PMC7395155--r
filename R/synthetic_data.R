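# Synthetic survey generator.
#
# Generates every input the pipeline consumes with known ground truth: whale
# groups as a spatial Poisson process, dive cycles as an alternating renewal
# process, ship detections thinned by a chosen detection function, and FOI
# criterion-score vectors emitted from per-sea-state probability tables.

#' Default whale criterion-emission tables, one per sea state
#'
#' Two blocks of criteria: the four double-weighted diagnostic criteria
#' (fluke, fins, footprint, blow) score high only when the feature is
#' sharply resolved, while the nine generic body criteria (shape, length,
#' contrast, ...) are scored more readily. Each entry gives `(P0, P1, P2)`
#' for one criterion. Worsening sea state shifts mass towards 0, which is
#' what degrades classification in rough water. Under these tables a
#' surfaced whale in calm water is classified definite-or-probable about
#' 84% of the time (definite roughly half of those), falling to about 34%
#' in rough water.
#'
#' @return a named list (one element per sea state) of lists with
#'   `primary` and `secondary` probability vectors.
#' @export
default_whale_emission <- function() {
  mk <- function(p1p, p2p, p1s, p2s) {
    list(primary = c(1 - p1p - p2p, p1p, p2p),
         secondary = c(1 - p1s - p2s, p1s, p2s))
  }
  list(
    "ideal"       = mk(0.12, 0.06, 0.60, 0.14),
    "good"        = mk(0.12, 0.05, 0.60, 0.12),
    "average"     = mk(0.10, 0.04, 0.58, 0.10),
    "sub-average" = mk(0.10, 0.02, 0.48, 0.06),
    "poor"        = mk(0.08, 0.01, 0.38, 0.04)
  )
}

#' Perfect whale emission: every criterion fully met
#'
#' Used to isolate availability from classification error: all whale FOIs
#' score the maximum and classify definite.
#'
#' @return emission tables as in [default_whale_emission()].
#' @export
perfect_emission <- function() {
  tab <- list(primary = c(0, 0, 1), secondary = c(0, 0, 1))
  stats::setNames(rep(list(tab), 5L), SEA_STATE_LEVELS)
}

#' Build a simulation scenario
#'
#' Defaults emulate the Gerlache Strait study conditions: a 971 km^2 image
#' footprint split 635/336 km^2 into calmer/rougher strata, individual whale
#' density 0.18 km^-2 (the level at which the default emission tables yield
#' about 18 definite, 21 probable and 146 unclassified FOIs in expectation),
#' group sizes zero-truncated Poisson with mean 2.06, exponential
#' surface/dive bouts of mean 60 s / 117 s (long-run surface fraction
#' 60/177 = 0.339), a half-normal ship detection function with sigma 1.5 km
#' truncated at 6 km, and clutter FOIs at 0.13 km^-2.
#'
#' @param true_density individual whales per km^2.
#' @param region_length,region_width region rectangle, km (length runs along
#'   the ship trackline; area = length x width).
#' @param calmer_fraction fraction of the region (by area, split along the
#'   length axis) in the calmer stratum.
#' @param mean_group_size mean of the zero-truncated Poisson group sizes.
#' @param surface_mean_s,dive_mean_s mean surface/dive bout durations, s.
#' @param bout_model `"exponential"` (default) or `"lognormal"`
#'   (log-sd 0.5, means preserved).
#' @param detection_key,detection_sigma,detection_b,truncation_w ship
#'   detection function: key, scale (km), hazard-rate shape, truncation (km).
#' @param sample_hz depth sampling rate, Hz.
#' @param emission_whale per-sea-state criterion tables
#'   ([default_whale_emission()] or [perfect_emission()]).
#' @param emission_noise `(P0, P1, P2)` for every criterion of a clutter FOI.
#' @param noise_rate clutter FOIs per km^2.
#' @param n_transects number of equal sub-transects the trackline is split
#'   into for the effort table.
#' @param seed integer seed recorded on the scenario; every generator resets
#'   the RNG from it (plus a fixed per-stage offset) so a scenario is fully
#'   reproducible.
#' @return a list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(true_density = 0.18,
                                region_length = 97.1,
                                region_width = 10,
                                calmer_fraction = 635 / 971,
                                mean_group_size = 2.06,
                                surface_mean_s = 60,
                                dive_mean_s = 117,
                                bout_model = c("exponential", "lognormal"),
                                detection_key = "hn",
                                detection_sigma = 1.5,
                                detection_b = 2.5,
                                truncation_w = 6,
                                sample_hz = 10,
                                emission_whale = default_whale_emission(),
                                emission_noise = c(0.92, 0.08, 0),
                                noise_rate = 0.13,
                                n_transects = 6,
                                seed = 1L) {
  bout_model <- match.arg(bout_model)
  stopifnot(true_density >= 0, region_length > 0, region_width > 0,
            calmer_fraction >= 0, calmer_fraction <= 1,
            mean_group_size >= 1, surface_mean_s >= 0, dive_mean_s >= 0,
            noise_rate >= 0, sample_hz > 0,
            abs(sum(emission_noise) - 1) < 1e-8,
            all(vapply(emission_whale,
                       function(e) abs(sum(e$primary) - 1) < 1e-8 &&
                         abs(sum(e$secondary) - 1) < 1e-8, logical(1L))))
  structure(as.list(environment()), class = "simulation_scenario")
}

# per-stage RNG reset: deterministic and stage-independent
scenario_seed <- function(scenario, stage_offset) {
  set.seed((scenario$seed + stage_offset) %% .Machine$integer.max)
}

# zero-truncated Poisson with a given mean (> 1): solve for lambda, then
# invert the truncated CDF
rztpois <- function(n, mean) {
  if (n == 0L) return(integer(0))
  if (mean <= 1) return(rep(1L, n))
  lambda <- stats::uniroot(function(l) l / (1 - exp(-l)) - mean,
                           c(1e-8, 10 * mean))$root
  u <- stats::runif(n, min = stats::dpois(0, lambda), max = 1)
  stats::qpois(u, lambda)
}

#' Simulate the whale population
#'
#' Groups are a homogeneous Poisson process with intensity
#' `true_density / mean_group_size` over the region rectangle, and each
#' group draws a zero-truncated Poisson size, so the expected number of
#' individuals equals `true_density * area`.
#'
#' @param scenario a `simulation_scenario`.
#' @return a data frame of groups: `x`, `y` (km), `group_size`, `stratum`.
#' @export
simulate_population <- function(scenario) {
  scenario_seed(scenario, 101L)
  area <- scenario$region_length * scenario$region_width
  n_groups <- stats::rpois(1L, scenario$true_density / scenario$mean_group_size * area)
  x <- stats::runif(n_groups, 0, scenario$region_length)
  y <- stats::runif(n_groups, 0, scenario$region_width)
  sizes <- rztpois(n_groups, scenario$mean_group_size)
  data.frame(
    x = x, y = y, group_size = as.integer(sizes),
    stratum = ifelse(x < scenario$calmer_fraction * scenario$region_length,
                     "calmer", "rougher"),
    stringsAsFactors = FALSE
  )
}

# draw alternating bout durations covering at least `duration` seconds
draw_bouts <- function(n, mean_s, model) {
  if (mean_s <= 0) return(rep(0, n))
  if (model == "exponential") {
    stats::rexp(n, rate = 1 / mean_s)
  } else {
    sdlog <- 0.5
    stats::rlnorm(n, meanlog = log(mean_s) - sdlog^2 / 2, sdlog = sdlog)
  }
}

#' Simulate tag dive profiles
#'
#' Each tag alternates surface bouts (depth drawn in [0, 0.6] m) and dive
#' bouts (depth in [5, 60] m) with the configured bout-duration
#' distributions, sampled at `sample_hz`. The long-run surface fraction is
#' `surface_mean_s / (surface_mean_s + dive_mean_s)` by the renewal-reward
#' theorem.
#'
#' @param scenario a `simulation_scenario`.
#' @param n_tags number of deployments.
#' @param duration_s record length per tag, s.
#' @param daylight_fraction leading fraction of each record flagged as
#'   daylight (default all of it).
#' @return a named list of per-deployment data frames (`t`, `depth`,
#'   `daylight`), the shape [read_tag_depths()] returns.
#' @export
simulate_dive_profiles <- function(scenario, n_tags = 21L, duration_s = 72000,
                                   daylight_fraction = 1) {
  scenario_seed(scenario, 202L)
  dt <- 1 / scenario$sample_hz
  out <- lapply(seq_len(n_tags), function(i) {
    t <- seq(0, duration_s - dt, by = dt)
    n <- length(t)
    if (scenario$dive_mean_s <= 0) {
      depth <- stats::runif(n, 0, 0.6)
    } else if (scenario$surface_mean_s <= 0) {
      depth <- stats::runif(n, 5, 60)
    } else {
      # enough bouts to cover the record with margin
      n_bouts <- ceiling(2.5 * duration_s /
                           (scenario$surface_mean_s + scenario$dive_mean_s)) + 20L
      surf <- draw_bouts(n_bouts, scenario$surface_mean_s, scenario$bout_model)
      dive <- draw_bouts(n_bouts, scenario$dive_mean_s, scenario$bout_model)
      # stationary start: begin in a surface bout with prob = surface fraction
      bouts <- as.vector(rbind(surf, dive))
      is_surface <- rep(c(TRUE, FALSE), n_bouts)
      if (stats::runif(1L) > scenario$surface_mean_s /
          (scenario$surface_mean_s + scenario$dive_mean_s)) {
        bouts <- bouts[-1L]
        is_surface <- is_surface[-1L]
      }
      ends <- cumsum(bouts)
      while (ends[length(ends)] < duration_s) {
        extra_s <- draw_bouts(20L, scenario$surface_mean_s, scenario$bout_model)
        extra_d <- draw_bouts(20L, scenario$dive_mean_s, scenario$bout_model)
        nxt <- !is_surface[length(is_surface)]
        add <- if (nxt) as.vector(rbind(extra_s, extra_d)) else as.vector(rbind(extra_d, extra_s))
        add_f <- if (nxt) rep(c(TRUE, FALSE), 20L) else rep(c(FALSE, TRUE), 20L)
        bouts <- c(bouts, add)
        is_surface <- c(is_surface, add_f)
        ends <- cumsum(bouts)
      }
      idx <- findInterval(t, c(0, ends), rightmost.closed = FALSE)
      surface_now <- is_surface[idx]
      depth <- ifelse(surface_now, stats::runif(n, 0, 0.6), stats::runif(n, 5, 60))
    }
    data.frame(t = t, depth = depth,
               daylight = seq_len(n) <= ceiling(daylight_fraction * n))
  })
  stats::setNames(out, sprintf("sim-%02d", seq_len(n_tags)))
}

#' Simulate the ship line-transect survey
#'
#' The trackline runs along the region's length axis at mid-width, split
#' into equal sub-transects for the effort table. Each group within the
#' truncation distance is detected with probability `g(perpendicular
#' distance)`; optionally thinned further by instantaneous availability at
#' passage (off by default, mirroring an analysis that takes g(0) = 1 for a
#' conspicuous surface-active species).
#'
#' @param scenario a `simulation_scenario`.
#' @param population the group table from [simulate_population()].
#' @param availability_at_passage detection is additionally thinned by this
#'   probability; default 1 (no thinning).
#' @return a list with `sightings` (a valid sightings table) and `effort`.
#' @export
simulate_ship_survey <- function(scenario, population,
                                 availability_at_passage = 1) {
  scenario_seed(scenario, 303L)
  y0 <- scenario$region_width / 2
  perp <- abs(population$y - y0)
  in_strip <- perp <= scenario$truncation_w
  g <- detection_g(perp, scenario$detection_key, scenario$detection_sigma,
                   scenario$detection_b)
  detected <- in_strip &
    stats::runif(nrow(population)) < g * availability_at_passage
  det <- population[detected, , drop = FALSE]
  sightings <- data.frame(
    perp_distance = abs(det$y - y0),
    group_size = det$group_size,
    species = "humpback",
    beaufort = sample(0:3, nrow(det), replace = TRUE),
    visibility = "Good",
    sightability = sample(0:1, nrow(det), replace = TRUE),
    stringsAsFactors = FALSE
  )
  k <- scenario$n_transects
  effort <- data.frame(
    transect_id = sprintf("T%02d", seq_len(k)),
    length = rep(scenario$region_length / k, k),
    stringsAsFactors = FALSE
  )
  # remember which transect each sighting fell on for encounter-rate variance
  sightings$transect_id <- effort$transect_id[
    pmin(k, 1L + floor(det$x / (scenario$region_length / k)))]
  list(sightings = sightings, effort = effort)
}

# draw one criterion block: n_foi x n_crit matrix of scores 0/1/2
draw_scores <- function(n_foi, n_crit, probs) {
  matrix(sample(0:2, n_foi * n_crit, replace = TRUE, prob = probs),
         nrow = n_foi, ncol = n_crit)
}

#' Simulate the satellite FOI criterion-score table
#'
#' At the snapshot instant each individual whale is available (above the
#' surface threshold) with the stationary probability
#' `surface_mean_s / (surface_mean_s + dive_mean_s)`; available whales emit
#' a 13-criterion score vector from the whale table for their local sea
#' state, clutter FOIs are a Poisson process at `noise_rate` emitting from
#' the noise table. Sea state is drawn among the calm classes in the calmer
#' stratum and the rough classes in the rougher stratum. The ground-truth
#' flag is kept in an `is_whale` column.
#'
#' @param scenario a `simulation_scenario`.
#' @param population the group table from [simulate_population()].
#' @return a validated FOI table with extra ground-truth columns.
#' @export
simulate_foi_table <- function(scenario, population) {
  scenario_seed(scenario, 404L)
  p_avail <- if (scenario$dive_mean_s <= 0) 1 else
    scenario$surface_mean_s / (scenario$surface_mean_s + scenario$dive_mean_s)
  # individuals inherit their group's position/stratum
  strat_ind <- rep(population$stratum, population$group_size)
  n_ind <- length(strat_ind)
  avail <- stats::runif(n_ind) < p_avail
  strat_whale <- strat_ind[avail]

  area <- scenario$region_length * scenario$region_width
  n_noise <- stats::rpois(1L, scenario$noise_rate * area)
  x_noise <- stats::runif(n_noise, 0, scenario$region_length)
  strat_noise <- ifelse(x_noise < scenario$calmer_fraction * scenario$region_length,
                        "calmer", "rougher")

  stratum <- c(strat_whale, strat_noise)
  is_whale <- c(rep(TRUE, length(strat_whale)), rep(FALSE, n_noise))
  n_foi <- length(stratum)
  if (n_foi == 0L) {
    return(cbind(data.frame(foi_id = character(0)),
                 stats::setNames(as.data.frame(matrix(integer(0), 0, 13)), PSI_COLS),
                 data.frame(sea_state = character(0), stratum = character(0),
                            observer = character(0), is_whale = logical(0))))
  }
  sea_state <- ifelse(stratum == "calmer",
                      sample(CALMER_SEA_STATES, n_foi, replace = TRUE),
                      sample(setdiff(SEA_STATE_LEVELS, CALMER_SEA_STATES),
                             n_foi, replace = TRUE))
  psi <- matrix(0L, n_foi, 13L)
  for (i in seq_len(n_foi)) {
    if (is_whale[i]) {
      em <- scenario$emission_whale[[sea_state[i]]]
      psi[i, 1:4]  <- sample(0:2, 4L, replace = TRUE, prob = em$primary)
      psi[i, 5:13] <- sample(0:2, 9L, replace = TRUE, prob = em$secondary)
    } else {
      psi[i, ] <- sample(0:2, 13L, replace = TRUE, prob = scenario$emission_noise)
    }
  }
  df <- data.frame(foi_id = sprintf("FOI-%04d", seq_len(n_foi)),
                   stringsAsFactors = FALSE)
  df[PSI_COLS] <- as.data.frame(psi)
  df$sea_state <- sea_state
  df$stratum <- stratum
  df$observer <- "O1"
  df <- validate_foi_table(df)
  df$is_whale <- is_whale
  df
}
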