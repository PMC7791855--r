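test_that("discretisation counts boundaries strictly below the latent value", {
  cp <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(discretize(0.0, cp), 1L)
  expect_equal(discretize(0.99, cp), 5L)
  expect_equal(discretize(0.5, cp), 3L)
  # a value exactly on a cutpoint falls in the lower category
  expect_equal(discretize(0.4, cp), 2L)
  expect_equal(discretize(c(0.1, 0.3, 0.7), cp), c(1L, 2L, 4L))
  expect_error(discretize(0.5, c(0.4, 0.2)), "strictly increasing")
})

small_config <- function(seed = 1, ...) {
  simulation_config(
    n_outcomes = 5,
    group_sizes = c(clinician = 8L, clinician_researcher = 6L, patient = 8L,
                    researcher = 5L, service_provider_policy_maker = 4L),
    seed = seed, ...)
}

test_that("identical seeds give bitwise-identical panels", {
  a <- simulate_panel(small_config(seed = 11))
  b <- simulate_panel(small_config(seed = 11))
  expect_identical(a$roster, b$roster)
  expect_identical(a$ratings, b$ratings)
  c <- simulate_panel(small_config(seed = 12))
  expect_false(identical(a$ratings, c$ratings))
})

test_that("simulated data satisfy conservation and monotone dropout", {
  sim <- simulate_panel(small_config(seed = 3))
  # record count per round = active participants x candidate outcomes, per arm
  for (r in 1:3) {
    active <- sim$roster[sim$roster$last_round >= r, ]
    for (a in c("5pt", "9pt")) {
      n_expect <- sum(active$arm == a) * length(sim$candidates[[a]][[r]])
      n_got <- sum(sim$ratings$round == r & sim$ratings$arm == a)
      expect_equal(n_got, n_expect)
    }
    # active sets shrink weakly
    if (r > 1) {
      expect_lte(nrow(active), sum(sim$roster$last_round >= r - 1))
    }
  }
  # simulated output flows through the validators unchanged
  expect_equal(nrow(validate_ratings(sim$ratings)), nrow(sim$ratings))
  expect_equal(nrow(validate_roster(sim$roster)), nrow(sim$roster))
})

test_that("zero noise and zero dropout behave degenerately", {
  nodrop <- default_dropout()
  nodrop$prob <- 0
  cfg <- small_config(seed = 5, sigma = 0, dropout = nodrop)
  sim <- simulate_panel(cfg)
  expect_true(all(sim$roster$last_round == 3))
  expect_true(all(attrition_rates(sim$roster)$percent == 0))
  # sigma = 0: every rater in a group gives the identical rating, so each
  # group's importance proportion is exactly 0 or 100
  gp <- group_percentages(sim$ratings, 1, "5pt")
  expect_true(all(gp$percent %in% c(0, 100)))
  # and the analytic importance probability is 0/1 accordingly
  s5 <- cfg$scales[["5pt"]]
  for (i in seq_len(nrow(gp))) {
    th <- cfg$theta[gp$outcome_id[i], gp$group[i]]
    expect_equal(gp$percent[i] / 100, importance_probability(th, 0, s5))
  }
})

test_that("group importance probabilities are recovered within binomial error", {
  s5 <- delphi_scales()[["5pt"]]
  theta <- 0.55; sigma <- 0.15; n <- 5000
  p_true <- importance_probability(theta, sigma, s5)
  inside <- 0
  for (k in 1:100) {
    cfg <- simulation_config(
      n_outcomes = 1, group_sizes = c(patient = n), sigma = sigma,
      theta = matrix(theta, 1, dimnames = list(NULL, "patient")),
      rounds = 1, seed = 5000 + k)
    sim <- simulate_panel(cfg)
    p_hat <- estimate_importance_probability(sim$ratings, "outcome_01",
                                             "patient", s5)
    n_arm <- sum(sim$ratings$arm == "5pt")
    se <- sqrt(p_true * (1 - p_true) / n_arm)
    if (abs(p_hat - p_true) <= 2 * se) inside <- inside + 1
  }
  # ~95% of replicates should land within 2 standard errors
  expect_gte(inside, 90)
})

test_that("theta exactly at the cutoff boundary recovers one half", {
  s5 <- delphi_scales()[["5pt"]]
  cut <- s5$cutpoints[s5$importance_cutoff - 1]
  cfg <- simulation_config(
    n_outcomes = 1, group_sizes = c(patient = 20000), sigma = 0.2,
    theta = matrix(cut, 1, dimnames = list(NULL, "patient")),
    rounds = 1, seed = 77)
  sim <- simulate_panel(cfg)
  p_hat <- estimate_importance_probability(sim$ratings, "outcome_01",
                                           "patient", s5)
  expect_equal(p_hat, 0.5, tolerance = 0.02)
})

test_that("matched cutoff boundaries give equivalent consensus counts", {
  # a 5-point (cutoff 4) and a 3-point (cutoff 3) scale whose importance
  # boundaries coincide at 0.6 on the latent axis measure the same event
  scales <- list(
    `5pt` = rating_scale("5pt", 5, 4),
    `3pt` = rating_scale("3pt", 3, 3, cutpoints = c(0.3, 0.6))
  )
  cfg <- simulation_config(
    n_outcomes = 6,
    group_sizes = c(clinician = 10L, clinician_researcher = 10L,
                    patient = 10L, researcher = 10L,
                    service_provider_policy_maker = 10L),
    sigma = 0.2, scales = scales, rounds = 1, seed = 2718)
  res <- run_scale_experiment(cfg, replicates = 200)
  m <- res$summary
  d5 <- m$mean_in[m$arm == "5pt"]
  d3 <- m$mean_in[m$arm == "3pt"]
  # paired Monte-Carlo error on the mean of 200 replicates of counts in 0..6
  wide <- tidyr::pivot_wider(res$draws[c("replicate", "arm", "in_n")],
                             names_from = "arm", values_from = "in_n")
  se_diff <- stats::sd(wide$`5pt` - wide$`3pt`) / sqrt(nrow(wide))
  expect_lt(abs(d5 - d3), 4 * se_diff + 1e-9)
})

test_that("a lower cutoff boundary admits at least as many outcomes", {
  scales <- list(
    lenient = rating_scale("lenient", 5, 4,
                           cutpoints = c(0.125, 0.25, 0.5, 0.75)),
    strict = rating_scale("strict", 5, 4)  # boundary 0.6 > 0.5
  )
  cfg <- simulation_config(
    n_outcomes = 6,
    group_sizes = c(clinician = 10L, clinician_researcher = 10L,
                    patient = 10L, researcher = 10L,
                    service_provider_policy_maker = 10L),
    sigma = 0.2, scales = scales, rounds = 1, seed = 31415)
  res <- run_scale_experiment(cfg, replicates = 200)
  m <- res$summary
  expect_gte(m$mean_in[m$arm == "lenient"], m$mean_in[m$arm == "strict"])
})

test_that("zero replicates give an empty experiment summary", {
  res <- run_scale_experiment(small_config(), replicates = 0)
  expect_equal(nrow(res$draws), 0)
  expect_equal(nrow(res$summary), 0)
  expect_error(run_scale_experiment(
    simulation_config(scales = delphi_scales()["5pt"]), replicates = 1),
    "two scales")
})
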