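test_that("criterion totals apply double weight to the four diagnostic criteria", {
  expect_equal(score_foi(rep(0L, 13)), 0)
  expect_equal(score_foi(psi_vec(psi4 = 2L)), 4)
  expect_equal(score_foi(psi_vec(psi1 = 2L, psi5 = 2L, psi6 = 1L)), 7)
  expect_equal(score_foi(rep(2L, 13)), 2 * 8 + 9 * 2)
  expect_error(score_foi(c(3L, rep(0L, 12))), class = "whaledens_validation_error")
  expect_error(score_foi(rep(0L, 12)), class = "whaledens_validation_error")
  # custom weights are honoured
  expect_equal(score_foi(psi_vec(psi1 = 1L), weights = rep(1, 13)), 1)
})

test_that("class thresholds sit at 7 and above 9 with exact integer comparison", {
  expect_equal(classify_foi(10), "definite")
  expect_equal(classify_foi(9), "probable")
  expect_equal(classify_foi(7), "probable")
  expect_equal(classify_foi(6), "unclassified")
  expect_equal(classify_foi(0), "unclassified")
})

test_that("score/classify is total and the label partition is disjoint on sampled vectors", {
  set.seed(3)
  psi <- matrix(sample(0:2, 13 * 500, replace = TRUE), ncol = 13)
  scores <- apply(psi, 1, score_foi)
  labels <- vapply(scores, classify_foi, character(1))
  expect_true(all(labels %in% c("definite", "probable", "unclassified")))
  expect_true(all((scores > 9) == (labels == "definite")))
  expect_true(all((scores >= 7 & scores <= 9) == (labels == "probable")))
  expect_true(all((scores < 7) == (labels == "unclassified")))
})

test_that("binomial SE matches sqrt(p(1-p)/n) and its monotonicity properties", {
  r <- proportion_se(21, 185)
  expect_equal(round(r$se, 3), 0.023)
  expect_equal(proportion_se(0, 50)$se, 0)
  expect_equal(proportion_se(50, 100)$se, 0.05)
  expect_error(proportion_se(1, 0), class = "whaledens_validation_error")
  expect_error(proportion_se(5, 3), class = "whaledens_validation_error")

  # maximal at p = 1/2 for fixed n; decreasing in n for fixed p
  ses <- vapply(0:100, function(k) proportion_se(k, 100)$se, numeric(1))
  expect_equal(which.max(ses), 51L)
  se_n <- vapply(c(50, 100, 200, 400),
                 function(n) proportion_se(n / 2, n)$se, numeric(1))
  expect_true(all(diff(se_n) < 0))
})

test_that("negative-binomial score fit recovers parameters and detects limits", {
  set.seed(42)
  pois <- rpois(5000, 3)
  fp <- fit_score_distribution(pois)
  expect_false(fp$degenerate)
  expect_gt(fp$size, 20)            # Poisson limit: vanishing overdispersion
  expect_equal(fp$mu, 3, tolerance = 0.1)

  nb <- rnbinom(5000, size = 1, mu = 3)
  fn <- fit_score_distribution(nb)
  expect_equal(fn$size, 1, tolerance = 0.1)
  expect_equal(fn$mu, 3, tolerance = 0.1)

  expect_true(fit_score_distribution(rep(4L, 20))$degenerate)
  expect_error(fit_score_distribution(c(rep(1.5, 20))),
               class = "whaledens_validation_error")
  expect_error(fit_score_distribution(1:5), class = "whaledens_validation_error")
})

test_that("observer comparison measures deviations on the shared subset", {
  set.seed(8)
  psi <- matrix(sample(0:2, 37 * 13, replace = TRUE,
                       prob = c(0.4, 0.35, 0.25)), 37, 13)
  principal <- make_foi(psi)

  same <- compare_observers(principal, list(principal, principal))
  expect_equal(unname(same$deviations), rep(0, 37))
  expect_false(same$adjust)

  # reviewers uniformly half a point below the principal: no adjustment
  lower <- principal
  lower$C_s <- principal$C_s - 0.5
  cmp <- compare_observers(principal, list(lower))
  expect_equal(cmp$mean_deviation, 0.5)
  expect_false(cmp$adjust)

  # a full criterion step triggers the adjustment flag
  lower$C_s <- principal$C_s - 1.2
  expect_true(compare_observers(principal, list(lower))$adjust)

  # stochastic reviewer deviations around -0.3 are recovered
  revs <- lapply(1:3, function(i) {
    r <- principal
    r$C_s <- principal$C_s + rnorm(37, 0.3, 0.4)
    r
  })
  cmp2 <- compare_observers(principal, revs)
  expect_equal(cmp2$mean_deviation, -0.3, tolerance = 3 * 0.4 / sqrt(3 * 37))

  other <- principal
  other$foi_id <- paste0("X", other$foi_id)
  expect_error(compare_observers(principal, list(other)),
               class = "whaledens_validation_error")
})

test_that("stratified counts conserve totals and recover class probabilities", {
  psi_hi <- matrix(2L, 10, 13)
  psi_lo <- matrix(0L, 27, 13)
  foi <- rbind(make_foi(psi_hi, sea_state = "good", stratum = "calmer"),
               make_foi(psi_lo, sea_state = "poor", stratum = "rougher"))
  strat <- stratify_counts(foi)
  expect_equal(strat$n_total[strat$stratum == "whole"], 37)
  expect_equal(sum(strat$n_total[strat$stratum != "whole"]), 37)
  expect_equal(strat$p_def_prob[strat$stratum == "calmer"], 1)
  expect_equal(strat$p_def_prob[strat$stratum == "rougher"], 0)

  only <- stratify_counts(make_foi(psi_hi, stratum = "calmer"))
  expect_equal(only$n_total[only$stratum == "rougher"], 0)

  bad <- foi
  bad$stratum[1] <- "offshore"
  expect_error(stratify_counts(bad), class = "whaledens_validation_error")

  # simulated stratum-dependent classification probabilities
  set.seed(12)
  n <- 400
  p_by <- c(calmer = 0.6, rougher = 0.2)
  stratum <- sample(names(p_by), n, replace = TRUE)
  hit <- runif(n) < p_by[stratum]
  psi <- matrix(0L, n, 13)
  psi[hit, ] <- matrix(2L, sum(hit), 13)
  foi2 <- make_foi(psi, sea_state = ifelse(stratum == "calmer", "good", "poor"),
                   stratum = stratum)
  s2 <- stratify_counts(foi2)
  for (st in names(p_by)) {
    row <- s2[s2$stratum == st, ]
    expect_lt(abs(row$p_def_prob - p_by[[st]]), 3 * row$se_def_prob + 0.02)
  }
})
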