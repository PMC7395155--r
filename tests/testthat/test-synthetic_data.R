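test_that("the population process hits the target individual density", {
  counts <- vapply(1:300, function(r) {
    scn <- simulation_scenario(true_density = 0.33, region_length = 100,
                               region_width = 10, seed = r)
    sum(simulate_population(scn)$group_size)
  }, numeric(1))
  # E[individuals] = D * A = 330; MC error of the mean over 300 replicates
  expect_equal(mean(counts), 330, tolerance = 3 * sd(counts) / sqrt(300) / 330)

  empty <- simulation_scenario(true_density = 0, seed = 1)
  expect_equal(nrow(simulate_population(empty)), 0)
})

test_that("generators are deterministic given the scenario seed", {
  scn <- simulation_scenario(seed = 77)
  expect_identical(simulate_population(scn), simulate_population(scn))
  pop <- simulate_population(scn)
  expect_identical(simulate_ship_survey(scn, pop), simulate_ship_survey(scn, pop))
  expect_identical(simulate_foi_table(scn, pop), simulate_foi_table(scn, pop))
  expect_identical(simulate_dive_profiles(scn, 2, 600),
                   simulate_dive_profiles(scn, 2, 600))
  # a different seed changes the draw
  scn2 <- simulation_scenario(seed = 78)
  expect_false(identical(simulate_population(scn2), pop))
})

test_that("dive profiles honour degenerate bout settings", {
  scn <- simulation_scenario(dive_mean_s = 0, sample_hz = 1, seed = 3)
  prof <- simulate_dive_profiles(scn, 1, 600)
  expect_equal(summarise_tag(prof[[1]])$proportion, 1)
  scn2 <- simulation_scenario(surface_mean_s = 0, sample_hz = 1, seed = 3)
  prof2 <- simulate_dive_profiles(scn2, 1, 600)
  expect_equal(summarise_tag(prof2[[1]])$proportion, 0)
})

test_that("ship survey detects every in-strip group when g is flat", {
  scn <- simulation_scenario(true_density = 0.5, detection_sigma = 1e6,
                             region_width = 8, truncation_w = 4, seed = 5)
  pop <- simulate_population(scn)
  survey <- simulate_ship_survey(scn, pop)
  expect_equal(nrow(survey$sightings), nrow(pop))
  expect_equal(sum(survey$effort$length), scn$region_length)
})

test_that("detected distances follow the detection function shape", {
  scn <- simulation_scenario(true_density = 2, region_length = 600,
                             region_width = 12, detection_sigma = 1.5,
                             truncation_w = 6, seed = 8)
  pop <- simulate_population(scn)
  survey <- simulate_ship_survey(scn, pop)
  x <- survey$sightings$perp_distance
  expect_gt(length(x), 1500)
  breaks <- c(seq(0, 3, by = 0.5), 4, 6)   # pooled tail keeps expected counts > 5
  observed <- table(cut(x, breaks))
  p <- diff(vapply(breaks, function(b) {
    integrate(function(u) detection_g(u, "hn", 1.5), 0, max(b, 1e-12))$value
  }, numeric(1)))
  expect_gt(chisq.test(observed, p = p / sum(p))$p.value, 0.01)
})

test_that("available whale FOIs thin the population by the surface fraction", {
  reps <- 60
  counts <- numeric(reps); expected <- numeric(reps)
  for (r in seq_len(reps)) {
    scn <- simulation_scenario(true_density = 0.4, noise_rate = 0,
                               emission_whale = perfect_emission(),
                               seed = 4000 + r)
    pop <- simulate_population(scn)
    foi <- simulate_foi_table(scn, pop)
    expect_true(all(foi$label == "definite"))
    counts[r] <- nrow(foi)
    expected[r] <- sum(pop$group_size) * 60 / 177
  }
  expect_equal(mean(counts), mean(expected),
               tolerance = 3 * sd(counts - expected) / sqrt(reps) / mean(expected))
})

test_that("rough-water degradation lowers the definite+probable proportion", {
  worse <- 0L
  valid <- 0L
  for (r in 1:40) {
    scn <- simulation_scenario(seed = 9000 + r)
    foi <- simulate_foi_table(scn, simulate_population(scn))
    strat <- stratify_counts(foi)
    pc <- strat$p_def_prob[strat$stratum == "calmer"]
    pr <- strat$p_def_prob[strat$stratum == "rougher"]
    if (!is.na(pc) && !is.na(pr)) {
      valid <- valid + 1L
      worse <- worse + (pc > pr)
    }
  }
  expect_gt(worse / valid, 0.5)
})

test_that("simulated outputs pass the package's own validation on disk", {
  scn <- simulation_scenario(seed = 13)
  pop <- simulate_population(scn)
  survey <- simulate_ship_survey(scn, pop)
  foi <- simulate_foi_table(scn, pop)
  sp <- withr::local_tempfile(fileext = ".csv")
  fp <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(survey$sightings, sp)
  write_table_csv(foi[setdiff(names(foi), "is_whale")], fp)
  expect_silent(read_sightings(sp))
  back <- read_foi_table(fp)
  expect_equal(back$C_s, foi$C_s)
})

test_that("the reference scenario yields the expected class mix", {
  # expectation at the defaults: roughly 18 definite, 21 probable,
  # 146 unclassified per realisation of the 971 km^2 footprint
  tot <- c(definite = 0, probable = 0, unclassified = 0)
  reps <- 25
  for (r in seq_len(reps)) {
    scn <- simulation_scenario(seed = 600 + r)
    foi <- simulate_foi_table(scn, simulate_population(scn))
    tot <- tot + table(factor(foi$label,
                              c("definite", "probable", "unclassified"))) / reps
  }
  expect_equal(unname(tot["definite"]), 18, tolerance = 0.25)
  expect_equal(unname(tot["probable"]), 21, tolerance = 0.25)
  expect_equal(unname(tot["unclassified"]), 146, tolerance = 0.15)
})
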