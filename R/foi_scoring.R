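# Scoring and classification of satellite features of interest (FOIs).
#
# Each candidate whale-like feature is scored against 13 criteria, each
# 0 (not met) / 1 (partial) / 2 (met). The first four criteria — fluke,
# fins, footprint, blow — are the strongly whale-indicative ones and carry
# double weight in the total. Class thresholds sit on the weighted total.

#' Default criterion weights
#'
#' Weight 2 on criteria 1-4 (fluke, fins, footprint, blow), weight 1 on the
#' remaining nine. Exposed so alternative weightings can be explored.
#'
#' @return a numeric vector of length 13.
#' @export
foi_weights <- function() {
  c(2, 2, 2, 2, rep(1, 9))
}

#' Weighted criterion-sum score of one FOI
#'
#' `C_s = 2*(psi1 + psi2 + psi3 + psi4) + psi5 + ... + psi13` under the
#' default weights.
#'
#' @param psi integer vector of 13 criterion scores, each 0, 1 or 2.
#' @param weights criterion weights, default [foi_weights()].
#' @return the integer total score.
#' @export
score_foi <- function(psi, weights = foi_weights()) {
  if (length(psi) != 13L) validation_error("score_foi: expected 13 criterion scores")
  if (!all(psi %in% 0:2)) validation_error("score_foi: criterion scores must be 0, 1 or 2")
  sum(weights * psi)
}

#' Classify an FOI from its total score
#'
#' Definite if `C_s > 9`; probable if `7 <= C_s <= 9`; unclassified if
#' `C_s < 7`. Thresholds are compared with exact integer arithmetic.
#'
#' @param C_s the weighted total score (>= 0).
#' @return `"definite"`, `"probable"` or `"unclassified"`.
#' @export
classify_foi <- function(C_s) {
  stopifnot(C_s >= 0)
  if (C_s > 9) "definite" else if (C_s >= 7) "probable" else "unclassified"
}

#' Binomial proportion with its standard error
#'
#' `p = k/n`, `SE = sqrt(p (1 - p) / n)`; the CV is `SE/p` where defined.
#'
#' @param k successes (class count).
#' @param n trials (total FOIs).
#' @return a list with `p`, `se` and `cv` (`NA` when `p = 0`).
#' @export
proportion_se <- function(k, n) {
  if (n <= 0) validation_error("proportion_se: n must be > 0")
  if (k < 0 || k > n) validation_error("proportion_se: need 0 <= k <= n")
  p <- k / n
  se <- sqrt(p * (1 - p) / n)
  list(p = p, se = se, cv = if (p > 0) se / p else NA_real_)
}

#' Count FOIs per class
#'
#' @param labels character vector of class labels.
#' @return a list of class `classified_counts` with `n_definite`,
#'   `n_probable`, `n_unclassified` and `n_total`.
#' @export
classified_counts <- function(labels) {
  stopifnot(all(labels %in% c("definite", "probable", "unclassified")))
  structure(list(
    n_definite = sum(labels == "definite"),
    n_probable = sum(labels == "probable"),
    n_unclassified = sum(labels == "unclassified"),
    n_total = length(labels)
  ), class = "classified_counts")
}

#' Per-stratum classified counts and definite+probable proportions
#'
#' @param foi a validated FOI table (see [read_foi_table()]).
#' @return a data frame, one row per stratum plus a `whole` row, with class
#'   counts and the definite-or-probable proportion and its binomial SE.
#' @export
stratify_counts <- function(foi) {
  if (!all(foi$stratum %in% STRATUM_LEVELS)) {
    validation_error("stratify_counts: unknown stratum label")
  }
  one <- function(sub, name) {
    cc <- classified_counts(sub$label)
    dp <- cc$n_definite + cc$n_probable
    ps <- if (cc$n_total > 0) proportion_se(dp, cc$n_total) else list(p = NA, se = NA)
    data.frame(stratum = name, n_definite = cc$n_definite,
               n_probable = cc$n_probable, n_unclassified = cc$n_unclassified,
               n_total = cc$n_total, p_def_prob = ps$p, se_def_prob = ps$se,
               stringsAsFactors = FALSE)
  }
  rbind(one(foi, "whole"),
        one(foi[foi$stratum == "calmer", , drop = FALSE], "calmer"),
        one(foi[foi$stratum == "rougher", , drop = FALSE], "rougher"))
}

#' Fit a negative-binomial distribution to the FOI score totals
#'
#' Maximum-likelihood fit of the integer scores (via `fitdistrplus`),
#' summarising the overall shape/overdispersion of the score distribution.
#'
#' @param scores integer total scores, at least 10 of them.
#' @return a list with `size`, `mu`, `log_lik`, `aic` and `degenerate`
#'   (TRUE when the scores are constant, in which case no fit is attempted).
#' @export
fit_score_distribution <- function(scores) {
  if (length(scores) < 10L) validation_error("fit_score_distribution: need >= 10 scores")
  if (any(scores != round(scores)) || any(scores < 0)) {
    validation_error("fit_score_distribution: scores must be non-negative integers")
  }
  if (stats::sd(scores) == 0) {
    return(list(size = NA_real_, mu = mean(scores), log_lik = NA_real_,
                aic = NA_real_, degenerate = TRUE))
  }
  fit <- fitdistrplus::fitdist(as.integer(scores), "nbinom")
  list(size = unname(fit$estimate["size"]), mu = unname(fit$estimate["mu"]),
       log_lik = fit$loglik, aic = fit$aic, degenerate = FALSE)
}

#' Compare the principal observer's scores against independent reviewers
#'
#' On the FOIs reviewed by every party, computes the per-FOI deviation
#' (principal total score minus the mean of the reviewers' total scores),
#' its mean and median, and each observer's definite-or-probable proportion
#' with binomial SE. An adjustment to the principal's scores is flagged
#' when the absolute mean deviation reaches 1 (one full criterion step).
#'
#' @param principal validated FOI table from the principal observer.
#' @param reviewers a list of validated FOI tables, one per reviewer, whose
#'   `foi_id`s must reference the principal's.
#' @return a list of class `observer_comparison`.
#' @export
compare_observers <- function(principal, reviewers) {
  stopifnot(is.list(reviewers), length(reviewers) >= 1L)
  common <- Reduce(intersect, c(list(principal$foi_id),
                                lapply(reviewers, `[[`, "foi_id")))
  if (length(common) == 0L) {
    validation_error("compare_observers: no FOIs shared by principal and all reviewers")
  }
  p_scores <- principal$C_s[match(common, principal$foi_id)]
  r_scores <- vapply(reviewers, function(r) r$C_s[match(common, r$foi_id)],
                     numeric(length(common)))
  r_mean <- rowMeans(r_scores)
  dev <- p_scores - r_mean
  prop_dp <- function(tab, ids) {
    sub <- tab[tab$foi_id %in% ids, , drop = FALSE]
    ps <- proportion_se(sum(sub$label %in% c("definite", "probable")), nrow(sub))
    c(p = ps$p, se = ps$se)
  }
  props <- rbind(principal = prop_dp(principal, common),
                 t(vapply(reviewers, prop_dp, numeric(2L), ids = common)))
  rownames(props)[-1L] <- paste0("reviewer", seq_along(reviewers))
  structure(list(
    n_common = length(common),
    deviations = stats::setNames(dev, common),
    mean_deviation = mean(dev),
    median_deviation = stats::median(dev),
    proportions = props,
    adjust = abs(mean(dev)) >= 1
  ), class = "observer_comparison")
}

#' @export
print.observer_comparison <- function(x, ...) {
  cat(sprintf("Observer comparison on %d shared FOIs\n", x$n_common))
  cat(sprintf("  score deviation: mean %.2f, median %.2f -> %s\n",
              x$mean_deviation, x$median_deviation,
              if (x$adjust) "ADJUSTMENT FLAGGED" else "no adjustment"))
  print(round(x$proportions, 3))
  invisible(x)
}
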