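# Surface availability from tag depth records.
#
# A whale is "available" to an overhead platform when it sits above a shallow
# depth threshold (default 1 m — deliberately conservative, well inside the
# conventional 4-5 m dive definition, because the depth to which a whale stays
# visible in imagery is uncertain). Availability a-hat is the proportion of
# daylight time spent above the threshold, pooled over tags by duration.

#' Summarise one tag deployment's depth series
#'
#' Counts daylight samples above (`depth < threshold`, strict) and at/below
#' the threshold and converts to seconds using the series' sample interval.
#' Gaps longer than 1 s are excluded from the totals rather than
#' interpolated. Negative depths have already been clamped to 0 on read.
#'
#' @param series a data frame with columns `t` (s), `depth` (m),
#'   `daylight` (logical).
#' @param threshold surface threshold, m (> 0). Default 1.
#' @param deployment_id label carried into the summary.
#' @return a one-row data frame: `deployment_id`, `surface_s`, `dive_s`,
#'   `total_s`, `proportion`.
#' @export
summarise_tag <- function(series, threshold = 1, deployment_id = "tag") {
  stopifnot(threshold > 0)
  day <- series[series$daylight, , drop = FALSE]
  if (nrow(day) == 0L) {
    validation_error(sprintf("summarise_tag: no daylight samples in deployment %s",
                             deployment_id))
  }
  dts <- diff(series$t)
  dt <- if (length(dts)) stats::median(dts) else 1
  # each retained sample contributes one sample period; samples after a gap
  # > 1 s contribute dt, the gap itself is dropped
  surface <- sum(pmax(day$depth, 0) < threshold) * dt
  dive <- sum(pmax(day$depth, 0) >= threshold) * dt
  data.frame(deployment_id = deployment_id,
             surface_s = surface, dive_s = dive, total_s = surface + dive,
             proportion = surface / (surface + dive),
             stringsAsFactors = FALSE)
}

#' Summarise every deployment in a set of depth series
#'
#' @param series_list named list of depth series as returned by
#'   [read_tag_depths()].
#' @inheritParams summarise_tag
#' @return a data frame of tag summaries, one row per deployment.
#' @export
summarise_tags <- function(series_list, threshold = 1) {
  do.call(rbind, lapply(names(series_list), function(id) {
    summarise_tag(series_list[[id]], threshold, deployment_id = id)
  }))
}

#' Estimate surface availability from per-tag summaries
#'
#' Duration weighting pools the tags: `a_hat = sum(surface_s) / sum(total_s)`,
#' identical to the tag-duration-weighted mean of the per-tag proportions.
#' The SE reported is the plain between-tag `sd(proportion)/sqrt(n)` of the
#' unweighted proportions. The CV is the duration-weighted between-tag
#' standard deviation of the proportions (with the unbiased frequency-weight
#' correction) divided by a_hat: availability varies strongly between
#' individuals, and that dispersion — not the SE of the mean — is what
#' propagates into a density corrected by a single shared a_hat.
#'
#' @param summaries a data frame of tag summaries (columns `surface_s`,
#'   `dive_s`, `total_s`; see [read_tag_summaries()] / [summarise_tags()]).
#' @param weighting `"duration"` (default) or `"none"` (plain mean of
#'   proportions).
#' @return a list of class `availability_estimate` with `a_hat`, `se`, `cv`,
#'   `n_tags`, `weighting`.
#' @export
estimate_availability <- function(summaries, weighting = c("duration", "none")) {
  weighting <- match.arg(weighting)
  n <- nrow(summaries)
  if (is.null(n) || n == 0L) validation_error("estimate_availability: no tag summaries")
  p <- summaries$surface_s / summaries$total_s
  w <- summaries$total_s
  a_hat <- if (weighting == "duration") sum(summaries$surface_s) / sum(w) else mean(p)
  if (n == 1L) {
    se <- NA_real_
    cv <- NA_real_
  } else {
    se <- stats::sd(p) / sqrt(n)
    if (weighting == "duration") {
      # weighted between-tag sd with unbiased reliability-weight denominator
      wsd <- sqrt(sum(w * (p - a_hat)^2) / (sum(w) - sum(w^2) / sum(w)))
    } else {
      wsd <- stats::sd(p)
    }
    cv <- wsd / a_hat
  }
  structure(list(a_hat = a_hat, se = se, cv = cv, n_tags = n,
                 weighting = weighting),
            class = "availability_estimate")
}

#' @export
print.availability_estimate <- function(x, ...) {
  cat(sprintf("Availability a_hat = %.4f (SE %.3f, CV %.3f) from %d tags, %s-weighted\n",
              x$a_hat, x$se, x$cv, x$n_tags, x$weighting))
  invisible(x)
}

#' Correct a density estimate for availability bias
#'
#' Instantaneous overhead sampling only sees whales above the surface
#' threshold, so the raw density underestimates truth by the factor a_hat:
#' the correction is `d_hat / a_hat`, with the CVs combined in quadrature
#' (delta method for a ratio of independent estimates).
#'
#' @param d_hat a `density_estimate`.
#' @param a an `availability_estimate` (requires `a_hat > 0`).
#' @return the adjusted `density_estimate` with the availability CV recorded
#'   among its components.
#' @export
adjust_density <- function(d_hat, a) {
  if (!is.finite(a$a_hat) || a$a_hat <= 0) {
    validation_error("adjust_density: availability must be > 0")
  }
  comps <- c(d_hat$components, availability = unname(a$cv))
  density_estimate(
    density = d_hat$density / a$a_hat,
    cv = sqrt(d_hat$cv^2 + (if (is.finite(a$cv)) a$cv else 0)^2),
    platform = d_hat$platform, stratum = d_hat$stratum,
    adjusted = TRUE, components = comps
  )
}
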