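# Satellite-side density estimates and the ship-vs-satellite comparison.

#' Satellite snapshot density for a class of FOIs
#'
#' `density = count / area`. The CV is the binomial CV of the class
#' proportion (SE/p with n = total FOIs scored): the count is treated as
#' n draws of a class label, so classification uncertainty is the only
#' stochastic component of the unadjusted estimate.
#'
#' @param counts a `classified_counts` object.
#' @param area surveyed image area, km^2 (> 0).
#' @param class_selector one of `"definite"`, `"probable"`, `"unclassified"`,
#'   `"definite+probable"`.
#' @param n_total denominator for the class proportion; defaults to the
#'   total in `counts`.
#' @param stratum label recorded on the estimate.
#' @return a `density_estimate` (platform `"satellite"`, unadjusted).
#' @export
satellite_density <- function(counts, area, class_selector = "definite+probable",
                              n_total = counts$n_total, stratum = "whole") {
  if (area <= 0) validation_error("satellite_density: area must be > 0")
  k <- switch(class_selector,
              "definite" = counts$n_definite,
              "probable" = counts$n_probable,
              "unclassified" = counts$n_unclassified,
              "definite+probable" = counts$n_definite + counts$n_probable,
              validation_error(sprintf("satellite_density: unknown class '%s'",
                                       class_selector)))
  d <- k / area
  cv <- if (k > 0) proportion_se(k, n_total)$cv else 0
  density_estimate(d, cv = cv, platform = "satellite", stratum = stratum,
                   adjusted = FALSE,
                   components = c(classification = cv))
}

#' Assemble the ship-vs-satellite comparison report
#'
#' Builds the per-class/per-stratum density table (unadjusted and
#' availability-adjusted side by side) and the ship/satellite density
#' ratios. Ratios are computed from unrounded values; rounding (half-up,
#' 2 d.p. for densities and CVs, 1 d.p. for ratios) happens only in the
#' presentation columns. The report is a pure function of its inputs.
#'
#' @param ship the ship-platform `density_estimate`.
#' @param satellite a named list of unadjusted satellite `density_estimate`s.
#' @param availability an `availability_estimate` used to adjust each
#'   satellite row.
#' @return a list of class `comparison_report` with `table` (one row per
#'   satellite estimate) and `ratios` (ship density over adjusted satellite
#'   density, unrounded and rounded).
#' @export
build_comparison <- function(ship, satellite, availability) {
  stopifnot(inherits(ship, "density_estimate"), length(satellite) >= 1L)
  rows <- lapply(names(satellite), function(nm) {
    s <- satellite[[nm]]
    adj <- adjust_density(s, availability)
    data.frame(class = nm, stratum = s$stratum,
               density = round_half_up(s$density, 2),
               cv = round_half_up(s$cv, 2),
               density_adjusted = round_half_up(adj$density, 2),
               cv_adjusted = round_half_up(adj$cv, 2),
               density_unrounded = s$density,
               density_adjusted_unrounded = adj$density,
               cv_adjusted_unrounded = adj$cv,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ratios <- vapply(seq_len(nrow(tab)), function(i) {
    da <- tab$density_adjusted_unrounded[i]
    if (da == 0) Inf else ship$density / da
  }, numeric(1L))
  structure(list(
    table = tab,
    ship = ship,
    availability = availability,
    ratios = data.frame(class = tab$class, stratum = tab$stratum,
                        ratio = ratios,
                        ratio_rounded = round_half_up(ratios, 1),
                        stringsAsFactors = FALSE)
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Ship vs satellite density comparison\n")
  print(x$ship)
  cat(sprintf("Availability adjustment: %.4f (CV %.2f)\n",
              x$availability$a_hat, x$availability$cv))
  print(x$table[c("class", "stratum", "density", "cv",
                  "density_adjusted", "cv_adjusted")])
  cat("Ship / adjusted-satellite ratios:\n")
  print(x$ratios)
  invisible(x)
}

#' Round half away from zero
#'
#' Tabular presentation rounding; base `round()` rounds half to even, which
#' would print 0.125 as 0.12 rather than 0.13.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
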