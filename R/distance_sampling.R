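# Line-transect detection-function fitting and density estimation.
#
# Multiple-covariate distance sampling (MCDS) on perpendicular distances:
# the detection function g(x) is half-normal or hazard-rate with the scale
# modelled as sigma_i = exp(beta0 + sum_j beta_j z_ij); g(0) = 1 holds by
# construction of both keys, and no series adjustment terms are used.

#' Detection function evaluated at perpendicular distance x
#'
#' Half-normal: `g(x) = exp(-x^2 / (2 sigma^2))`.
#' Hazard-rate: `g(x) = 1 - exp(-(x/sigma)^-b)`.
#' Both satisfy `g(0) = 1` exactly.
#'
#' @param x perpendicular distance(s), km.
#' @param key `"hn"` (half-normal) or `"hr"` (hazard-rate).
#' @param sigma scale parameter, km (recycled against `x`).
#' @param b hazard-rate shape parameter (> 0); ignored for half-normal.
#' @return detection probabilities in (0, 1].
#' @export
detection_g <- function(x, key = c("hn", "hr"), sigma, b = NULL) {
  key <- match.arg(key)
  if (key == "hn") {
    exp(-x^2 / (2 * sigma^2))
  } else {
    stopifnot(!is.null(b), b > 0)
    ifelse(x <= 0, 1, 1 - exp(-(x / sigma)^(-b)))
  }
}

# integral of g over [0, w] for a vector of sigmas (one per observation)
integral_g <- function(key, sigma, b, w) {
  if (key == "hn") {
    # closed form: sigma * sqrt(2*pi) * (Phi(w/sigma) - 1/2)
    sigma * sqrt(2 * pi) * (stats::pnorm(w / sigma) - 0.5)
  } else {
    us <- unique(sigma)
    vals <- vapply(us, function(s) {
      stats::integrate(function(x) detection_g(x, "hr", s, b), 0, w,
                       rel.tol = 1e-9)$value
    }, numeric(1L))
    vals[match(sigma, us)]
  }
}

# numeric covariates on the log-scale: ordinal Beaufort and sightability as
# their numeric levels, visibility as linear scores Good=0, Fair=1, Poor=2
covariate_matrix <- function(covariates, data) {
  if (length(covariates) == 0L) {
    return(matrix(numeric(0), nrow = if (is.null(data)) 0L else nrow(data), ncol = 0L))
  }
  cols <- lapply(covariates, function(nm) {
    v <- data[[nm]]
    if (is.null(v)) schema_error(sprintf("covariate '%s' not found in sightings", nm))
    if (nm == "visibility") {
      as.numeric(factor(v, levels = VISIBILITY_LEVELS)) - 1
    } else {
      as.numeric(v)
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

#' Fit a line-transect detection function by maximum likelihood
#'
#' Maximises the standard conditional-on-detection perpendicular-distance
#' likelihood `prod_i g_i(x_i) / int_0^w g_i(u) du` over the scale
#' coefficients (and the hazard-rate shape). The optimiser is a quasi-Newton
#' search on log-transformed parameters with three fixed starting points to
#' guard against the hazard-rate key's occasional multimodality.
#'
#' @param distances perpendicular distances, km.
#' @param covariates character vector of covariate names to place on the
#'   log-scale of sigma (subset of `beaufort`, `visibility`, `sightability`),
#'   or `NULL` for none.
#' @param data the sightings table carrying the covariate columns; only
#'   needed when `covariates` is non-empty.
#' @param key `"hn"` or `"hr"`.
#' @param truncation_w right-truncation distance w, km. `NULL` uses the
#'   maximum observed distance. Observations beyond w are discarded.
#' @return an object of class `detection_fit`: the fitted key, coefficient
#'   estimates, average detectability `P_a_hat` with standard error,
#'   effective half strip width `esw = P_a_hat * w`, log-likelihood and AIC.
#' @export
fit_detection <- function(distances, covariates = NULL, data = NULL,
                          key = c("hn", "hr"), truncation_w = NULL) {
  key <- match.arg(key)
  distances <- as.numeric(distances)
  if (is.null(truncation_w)) truncation_w <- max(distances)
  keep <- distances <= truncation_w
  x <- distances[keep]
  if (length(unique(x)) < 2L) {
    validation_error("fit_detection: need at least 2 distinct distances within the truncation")
  }
  Z <- covariate_matrix(covariates, data)
  if (ncol(Z) > 0L) Z <- Z[keep, , drop = FALSE]
  n <- length(x)
  w <- truncation_w
  p_cov <- ncol(Z)
  k <- 1L + p_cov + if (key == "hr") 1L else 0L

  # theta = (beta0, beta_1..beta_p[, log b])
  negloglik <- function(theta) {
    beta <- theta[seq_len(1L + p_cov)]
    b <- if (key == "hr") exp(theta[length(theta)]) else NULL
    eta <- beta[1L] + if (p_cov > 0L) drop(Z %*% beta[-1L]) else 0
    sigma <- rep(exp(eta), length.out = n)
    g <- detection_g(x, key, sigma, b)
    mu <- integral_g(key, sigma, b, w)
    if (any(!is.finite(g)) || any(g <= 0) || any(!is.finite(mu)) || any(mu <= 0)) {
      return(1e10)
    }
    -(sum(log(g)) - sum(log(mu)))
  }

  s0 <- log(stats::sd(x))
  starts <- lapply(c(0, log(0.5), log(2)), function(shift) {
    th <- c(s0 + shift, rep(0, p_cov))
    if (key == "hr") th <- c(th, log(2.5))
    th
  })
  fits <- lapply(starts, function(th) {
    tryCatch(stats::optim(th, negloglik, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-10)),
             error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value) && f$value < 1e9, fits)
  if (length(fits) == 0L) {
    validation_error(sprintf("fit_detection: optimizer failed to converge (%s key)", key))
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "value"))]]
  theta <- best$par
  if (key == "hn" && p_cov == 0L) {
    # the covariate-free half-normal MLE solves a smooth 1-d score equation;
    # polish the quasi-Newton solution to root-finding precision
    theta[1L] <- log(hn_sigma_mle(x, w, exp(theta[1L])))
  }
  ll <- -negloglik(theta)

  beta <- theta[seq_len(1L + p_cov)]
  b <- if (key == "hr") exp(theta[length(theta)]) else NULL
  eta <- beta[1L] + if (p_cov > 0L) drop(Z %*% beta[-1L]) else 0
  sigma <- rep(exp(eta), length.out = n)
  mu <- integral_g(key, sigma, b, w)
  P_a <- mean(mu) / w

  # delta-method SE of P_a from the numerically differentiated Hessian
  P_a_of <- function(th) {
    bb <- th[seq_len(1L + p_cov)]
    bbb <- if (key == "hr") exp(th[length(th)]) else NULL
    ss <- rep(exp(bb[1L] + if (p_cov > 0L) drop(Z %*% bb[-1L]) else 0),
              length.out = n)
    mean(integral_g(key, ss, bbb, w)) / w
  }
  se_P_a <- tryCatch({
    H <- stats::optimHess(theta, negloglik)
    V <- solve(H)
    gr <- grad_fd(P_a_of, theta)
    v <- drop(t(gr) %*% V %*% gr)
    if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  }, error = function(e) NA_real_)

  structure(list(
    key = key,
    covariate_formula = if (is.null(covariates)) character(0) else covariates,
    scale_params = stats::setNames(beta, c("(Intercept)",
                                           if (p_cov > 0L) colnames(Z))),
    shape_param = b,
    sigma = if (p_cov == 0L) exp(beta[1L]) else NULL,
    truncation_w = w,
    n = n,
    P_a_hat = P_a,
    se_P_a = se_P_a,
    esw = P_a * w,
    log_lik = ll,
    k = k,
    AIC = 2 * k - 2 * ll,
    distances = x,
    Z = Z
  ), class = "detection_fit")
}

# exact MLE for the covariate-free half-normal key: root of
# dl/dsigma = sum(x^2)/sigma^3 - n * mu'(sigma)/mu(sigma), with
# mu(sigma) = sigma*sqrt(2*pi)*(Phi(w/sigma) - 1/2)
hn_sigma_mle <- function(x, w, sigma0) {
  n <- length(x)
  sx2 <- sum(x^2)
  score <- function(s) {
    z <- w / s
    mu <- s * sqrt(2 * pi) * (stats::pnorm(z) - 0.5)
    dmu <- sqrt(2 * pi) * (stats::pnorm(z) - 0.5) - z * sqrt(2 * pi) * stats::dnorm(z)
    sx2 / s^3 - n * dmu / mu
  }
  lo <- sigma0 / 3
  hi <- sigma0 * 3
  if (score(lo) * score(hi) > 0) return(sigma0)
  stats::uniroot(score, c(lo, hi), tol = 1e-12)$root
}

# central finite-difference gradient
grad_fd <- function(f, theta, h = 1e-5) {
  vapply(seq_along(theta), function(j) {
    tp <- tm <- theta
    tp[j] <- tp[j] + h
    tm[j] <- tm[j] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1L))
}

#' @export
print.detection_fit <- function(x, ...) {
  form <- if (length(x$covariate_formula)) {
    paste("~", paste(x$covariate_formula, collapse = " + "))
  } else "~ 1"
  cat(sprintf("Detection fit: %s %s\n",
              c(hn = "half-normal", hr = "hazard-rate")[x$key], form))
  cat(sprintf("  n = %d, w = %.3g km\n", x$n, x$truncation_w))
  cat(sprintf("  P_a = %.3f (se %.3f), ESW = %.3f km\n",
              x$P_a_hat, x$se_P_a, x$esw))
  cat(sprintf("  logLik = %.3f, k = %d, AIC = %.3f\n", x$log_lik, x$k, x$AIC))
  invisible(x)
}

#' Rank candidate detection fits by AIC and select the best
#'
#' Produces the usual model-comparison table (key, covariate formula, CvM
#' goodness-of-fit p-value, average detectability with its SE, delta-AIC)
#' sorted by AIC, flags fits with implausible parameter estimates
#' (`P_a_hat <= 0.01` or an undefined SE), and returns the minimum-AIC
#' unflagged fit.
#'
#' @param fits a list of `detection_fit` objects.
#' @return a list with `best` (the selected fit) and `table` (a data frame,
#'   one row per candidate, ordered by AIC).
#' @export
select_model <- function(fits) {
  if (length(fits) == 0L) validation_error("select_model: no fits supplied")
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(
      key = c(hn = "half-normal", hr = "hazard-rate")[f$key],
      formula = if (length(f$covariate_formula)) {
        paste("~", paste(f$covariate_formula, collapse = " + "))
      } else "~ 1",
      cvm_p = tryCatch(cvm_test(f)$p_value, error = function(e) NA_real_),
      P_a = f$P_a_hat,
      se_P_a = f$se_P_a,
      log_lik = f$log_lik,
      k = f$k,
      AIC = f$AIC,
      stringsAsFactors = FALSE
    )
  }))
  tab$flagged <- tab$P_a <= 0.01 | !is.finite(tab$se_P_a)
  ord <- order(tab$AIC)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  tab$delta_AIC <- tab$AIC - min(tab$AIC)
  rownames(tab) <- NULL
  pick <- which(!tab$flagged)
  best_idx <- if (length(pick)) pick[1L] else 1L
  list(best = fits[[best_idx]], table = tab)
}

#' Mean group size with the CV of its mean
#'
#' @param group_sizes integer group sizes, one per detected group.
#' @return a list with `mean`, `cv` (= standard error of the mean divided by
#'   the mean) and `n_groups`.
#' @export
mean_group_size <- function(group_sizes) {
  group_sizes <- as.numeric(group_sizes)
  if (length(group_sizes) == 0L) validation_error("mean_group_size: no groups")
  m <- mean(group_sizes)
  cv <- if (length(group_sizes) > 1L) (stats::sd(group_sizes) / sqrt(length(group_sizes))) / m else 0
  list(mean = m, cv = cv, n_groups = length(group_sizes))
}

#' Empirical encounter-rate CV from per-transect counts
#'
#' Standard between-transect estimator of `var(n/L)` with transect lengths
#' as weights.
#'
#' @param counts detected groups per transect.
#' @param lengths transect lengths, km.
#' @return CV of the encounter rate n/L.
#' @export
encounter_rate_cv <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths), all(lengths > 0))
  K <- length(counts)
  if (K < 2L) validation_error("encounter_rate_cv: need >= 2 transects")
  L <- sum(lengths)
  n <- sum(counts)
  er <- n / L
  if (er == 0) return(0)
  v <- K / (L^2 * (K - 1)) * sum(lengths^2 * (counts / lengths - er)^2)
  sqrt(v) / er
}

#' Along-track ship-survey density
#'
#' `D = n * E[s] / (2 * ESW * L)`: detected groups times mean group size over
#' the effectively searched area, the strip of half-width ESW either side of
#' L km of trackline. The CV combines the supplied component CVs in
#' quadrature (delta method on a product/quotient of independent factors).
#'
#' @param n_groups number of detected groups.
#' @param mean_group_size mean individuals per group.
#' @param esw effective half strip width, km.
#' @param effort_L total on-effort trackline length, km.
#' @param cv_components named numeric vector of component CVs (typically
#'   `encounter`, `detection`, `group_size`); may be empty.
#' @param stratum label recorded on the estimate.
#' @return a `density_estimate` (whales per km^2).
#' @export
ship_density <- function(n_groups, mean_group_size, esw, effort_L,
                         cv_components = numeric(0), stratum = "whole") {
  if (effort_L <= 0) validation_error("ship_density: effort must be > 0")
  if (esw <= 0) validation_error("ship_density: esw must be > 0")
  if (n_groups < 0 || mean_group_size <= 0) {
    validation_error("ship_density: counts and group size must be non-negative")
  }
  d <- n_groups * mean_group_size / (2 * esw * effort_L)
  density_estimate(d, cv = cv_quadrature(cv_components), platform = "ship",
                   stratum = stratum, adjusted = FALSE,
                   components = cv_components)
}

#' Combine CV components in quadrature
#' @param components named numeric vector of CVs.
#' @return `sqrt(sum(components^2))`.
#' @export
cv_quadrature <- function(components) {
  if (length(components) == 0L) return(0)
  sqrt(sum(as.numeric(components)^2))
}

#' Construct a density estimate
#'
#' @param density whales per km^2.
#' @param cv coefficient of variation.
#' @param platform `"ship"` or `"satellite"`.
#' @param stratum stratum label.
#' @param adjusted whether an availability correction has been applied.
#' @param components named CV components entering `cv` by quadrature.
#' @return an object of class `density_estimate`.
#' @export
density_estimate <- function(density, cv, platform, stratum = "whole",
                             adjusted = FALSE, components = numeric(0)) {
  stopifnot(density >= 0, cv >= 0)
  structure(list(density = density, cv = cv, platform = platform,
                 stratum = stratum, adjusted = adjusted,
                 components = components),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("%s density (%s%s): %.4f whales/km^2, CV = %.3f\n",
              x$platform, x$stratum, if (x$adjusted) ", availability-adjusted" else "",
              x$density, x$cv))
  invisible(x)
}
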