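test_that("half-normal fit recovers the generating scale", {
  set.seed(101)
  x <- rhn(2000, sigma = 1.5, w = 6)
  fit <- fit_detection(x, key = "hn", truncation_w = 6)
  # asymptotic SE from the observed information of the fit's own 1-d problem
  nll <- function(s) {
    mu <- s * sqrt(2 * pi) * (pnorm(6 / s) - 0.5)
    -(sum(-x^2 / (2 * s^2)) - length(x) * log(mu))
  }
  h <- 1e-4
  info <- (nll(fit$sigma + h) - 2 * nll(fit$sigma) + nll(fit$sigma - h)) / h^2
  se <- 1 / sqrt(info)
  expect_lt(abs(fit$sigma - 1.5), 3 * se)
})

test_that("score equation holds at the half-normal MLE", {
  set.seed(7)
  x <- rhn(400, sigma = 1.2, w = 5)
  fit <- fit_detection(x, key = "hn", truncation_w = 5)
  s <- fit$sigma
  z <- 5 / s
  mu <- s * sqrt(2 * pi) * (pnorm(z) - 0.5)
  dmu <- sqrt(2 * pi) * (pnorm(z) - 0.5) - z * sqrt(2 * pi) * dnorm(z)
  score <- sum(x^2) / s^3 - length(x) * dmu / mu
  expect_lt(abs(score), 1e-6)
})

test_that("average detectability equals the quadrature of g over the strip", {
  set.seed(21)
  x <- rhn(600, sigma = 1.5, w = 6)
  for (key in c("hn", "hr")) {
    fit <- fit_detection(x, key = key, truncation_w = 6)
    sigma <- exp(fit$scale_params[["(Intercept)"]])
    q <- integrate(function(u) detection_g(u, key, sigma, fit$shape_param),
                   0, 6, rel.tol = 1e-10)$value / 6
    expect_equal(fit$P_a_hat, q, tolerance = 1e-6)
    expect_equal(fit$esw / fit$truncation_w, fit$P_a_hat)
  }
})

test_that("covariate fits recover a positive Beaufort effect on the scale", {
  set.seed(33)
  n <- 1500
  dat <- data.frame(beaufort = sample(0:4, n, replace = TRUE))
  sigma <- exp(log(1.2) + 0.2 * dat$beaufort)
  x <- abs(rnorm(n, 0, sigma))
  keep <- x <= 6
  fit <- fit_detection(x[keep], covariates = "beaufort",
                       data = dat[keep, , drop = FALSE],
                       key = "hn", truncation_w = 6)
  expect_equal(unname(fit$scale_params["beaufort"]), 0.2, tolerance = 0.25)
  # per-observation quadrature oracle for the MCDS average detectability
  sig_i <- exp(fit$scale_params[1] + fit$scale_params[2] * dat$beaufort[keep])
  q <- mean(vapply(sig_i, function(s) {
    integrate(function(u) detection_g(u, "hn", s), 0, 6)$value / 6
  }, numeric(1)))
  expect_equal(fit$P_a_hat, q, tolerance = 1e-6)
})

test_that("ESW approaches sigma * sqrt(pi/2) as the truncation grows", {
  set.seed(5)
  x <- rhn(1500, sigma = 1.0, w = 20)
  fit <- fit_detection(x, key = "hn", truncation_w = 20)
  expect_equal(fit$esw, fit$sigma * sqrt(pi / 2), tolerance = 1e-6)
})

test_that("degenerate distance data are rejected", {
  expect_error(fit_detection(rep(1.5, 30), key = "hn", truncation_w = 6),
               "distinct", class = "whaledens_validation_error")
})

test_that("AIC ranking follows the arithmetic and flags implausible fits", {
  f1 <- make_hn_fit(1.5, 6)
  f1$log_lik <- -100; f1$k <- 1L; f1$AIC <- 2 * 1 - 2 * -100
  f1$se_P_a <- 0.03
  f2 <- f1
  f2$k <- 2L; f2$AIC <- 2 * 2 - 2 * -100
  sel <- select_model(list(f2, f1))
  expect_equal(sel$table$delta_AIC, c(0, 2))
  expect_equal(sel$best$k, 1L)

  single <- select_model(list(f1))
  expect_equal(single$table$delta_AIC, 0)
  expect_identical(single$best, f1)

  f3 <- f1
  f3$P_a_hat <- 0.005; f3$AIC <- f1$AIC - 5
  sel2 <- select_model(list(f1, f3))
  expect_true(sel2$table$flagged[1])
  expect_equal(sel2$best$P_a_hat, f1$P_a_hat)

  expect_error(select_model(list()), class = "whaledens_validation_error")
})

test_that("half-normal is preferred by AIC on half-normal data", {
  set.seed(55)
  wins <- 0L
  for (r in 1:30) {
    x <- rhn(300, sigma = 1.5, w = 6)
    fh <- fit_detection(x, key = "hn", truncation_w = 6)
    fr <- fit_detection(x, key = "hr", truncation_w = 6)
    wins <- wins + (fh$AIC < fr$AIC)
  }
  expect_gt(wins, 15)
})

test_that("ship density follows n E[s] / (2 ESW L) with CVs in quadrature", {
  d <- ship_density(90, 2.06, esw = 3.1, effort_L = 90.7,
                    cv_components = c(encounter = 0.05, detection = 0.07,
                                      group_size = 0.01))
  expect_equal(round_half_up(d$density, 2), 0.33)
  expect_equal(d$cv, sqrt(0.05^2 + 0.07^2 + 0.01^2))
  expect_true(all(d$cv^2 >= d$components^2))

  expect_equal(ship_density(0, 2, 3.1, 90.7)$density, 0)
  expect_equal(ship_density(90, 2.06, 3.1, 2 * 90.7)$density, d$density / 2)
  expect_error(ship_density(90, 2.06, 3.1, 0),
               class = "whaledens_validation_error")

  # invariant to how the effort is split into transects: only total L enters
  expect_equal(ship_density(90, 2.06, 3.1, sum(c(30, 40.7, 20)))$density,
               d$density)
})

test_that("mean group size and its CV are the sample mean and CV of the mean", {
  sizes <- c(rep(1L, 30), rep(2L, 30), rep(3L, 25), rep(4L, 5))
  stopifnot(length(sizes) == 90, sum(sizes) == 185)
  m <- mean_group_size(sizes)
  expect_equal(round_half_up(m$mean, 2), 2.06)
  expect_equal(m$cv, (sd(sizes) / sqrt(90)) / mean(sizes))

  expect_equal(mean_group_size(rep(1, 10)), list(mean = 1, cv = 0, n_groups = 10L))
  expect_equal(mean_group_size(c(1, 3))$mean, 2)
})

test_that("encounter-rate CV responds to between-transect variability", {
  expect_equal(encounter_rate_cv(c(5, 5, 5, 5), rep(10, 4)), 0, tolerance = 1e-12)
  cv_var <- encounter_rate_cv(c(2, 9, 1, 8), rep(10, 4))
  expect_gt(cv_var, 0.2)
  expect_error(encounter_rate_cv(5, 10), class = "whaledens_validation_error")
})
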