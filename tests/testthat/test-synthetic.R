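test_that("sample_cohort is seeded, validated and matches its configured rates", {
  world <- synthetic_world()
  expect_identical(nrow(sample_cohort(world, 0, seed = 1)), 0L)

  a <- sample_cohort(world, 100, seed = 4)
  b <- sample_cohort(world, 100, seed = 4)
  expect_identical(a, b)                       # bit-identical under one seed
  expect_false(identical(a, sample_cohort(world, 100, seed = 5)))
  expect_silent(validate_cohort(a))

  # empirical hypertension rate within a 99% binomial CI of p = 0.6
  big <- sample_cohort(world, 10000, seed = 6)
  ci <- 0.6 + c(-1, 1) * qnorm(0.995) * sqrt(0.6 * 0.4 / 10000)
  expect_gte(mean(big$hypertension), ci[1])
  expect_lte(mean(big$hypertension), ci[2])
  # truncation bounds respected
  expect_true(all(big$age >= 35 & big$age <= 95))
  expect_true(all(big$resting_hr >= 40 & big$resting_hr <= 180))
})

test_that("deterministic-expert labels are exactly argmax of the ground-truth scores", {
  world <- synthetic_world(expert_mode = "argmax")
  co <- sample_cohort(world, 500, seed = 9)
  X <- encode_cohort(co, world$ref_scaler)
  S <- X %*% t(world$expert_weights)
  expect_identical(co$expert_action, actions()[max.col(S, ties.method = "first")])
})

test_that("sample_outcomes draws from the configured outcome model", {
  world <- synthetic_world()
  rec <- valid_record()

  # degenerate endpoints: all probabilities 0, then all 1
  zero_om <- lapply(world$outcome_model, function(m) {
    m$feat[] <- 0
    m$feat[["intercept"]] <- -50
    m$action[] <- 0
    m
  })
  w0 <- synthetic_world(outcome_model = zero_om)
  expect_identical(unlist(sample_outcomes(w0, rec, "AAM", seed = 2)),
                   c(stroke = 0L, hospitalization = 0L,
                     symptomatic_recurrence = 0L))
  one_om <- lapply(zero_om, function(m) { m$feat[["intercept"]] <- 50; m })
  w1 <- synthetic_world(outcome_model = one_om)
  o1 <- sample_outcomes(w1, rec, "AAM", seed = 2)
  expect_identical(unlist(o1), c(stroke = 1L, hospitalization = 1L,
                                 symptomatic_recurrence = 1L))
  expect_identical(compute_reward(o1), -4)

  # discrete world: empirical frequencies near the table at n = 10,000
  dw <- world_suboptimal_expert()
  co <- sample_cohort(dw, 10000, seed = 13)
  take <- "EXC"
  O <- aflearn:::draw_outcomes_matrix(dw, co,
                                      rep(take, nrow(co)))
  for (k in 1:4) {
    sel <- co$context == k
    p <- dw$recurrence_rates[k, take]
    half <- qnorm(0.995) * sqrt(p * (1 - p) / sum(sel))
    expect_lt(abs(mean(O$symptomatic_recurrence[sel]) - p), half + 1e-9)
  }
})

test_that("expected_reward: enumeration and linearity agree, and match hand arithmetic", {
  dw <- world_suboptimal_expert()
  # hand case: rates (.1, .3, .5) -> -2(.1) - .3 - .5 = -1.0
  custom <- dw
  custom$stroke_rates[1, 1] <- 0.1
  custom$hosp_rates[1, 1] <- 0.3
  custom$recurrence_rates[1, 1] <- 0.5
  expect_equal(expected_reward(custom, 1, "RAC"), -1.0)
  expect_equal(expected_reward(custom, 1, "RAC", method = "enumeration"), -1.0)

  zero <- dw
  zero$stroke_rates[, ] <- 0
  zero$hosp_rates[, ] <- 0
  zero$recurrence_rates[, ] <- 0
  expect_identical(expected_reward(zero, 2, "AAM"), 0)

  # two independent routes agree on randomized tables
  set.seed(44)
  for (i in 1:25) {
    rnd <- dw
    rnd$stroke_rates[, ] <- runif(16)
    rnd$hosp_rates[, ] <- runif(16)
    rnd$recurrence_rates[, ] <- runif(16)
    k <- sample(4, 1)
    a <- sample(actions(), 1)
    lin <- expected_reward(rnd, k, a, method = "linearity")
    enu <- expected_reward(rnd, k, a, method = "enumeration")
    expect_lt(abs(lin - enu), 1e-12)
    expect_lt(abs(lin - enum_expected_reward(rnd$stroke_rates[k, action_index(a)],
                                             rnd$hosp_rates[k, action_index(a)],
                                             rnd$recurrence_rates[k, action_index(a)])),
              1e-12)
  }

  expect_error(expected_reward(synthetic_world(), 1, "RAC"),
               class = "aflearn_continuous_world")
})

test_that("the initialization cohort has exactly 100 labelled valid records", {
  co <- make_initialization_cohort(seed = 3)
  expect_identical(nrow(co), 100L)
  expect_true(all(co$expert_action %in% actions()))
  expect_silent(validate_cohort(co))
  expect_identical(co, make_initialization_cohort(seed = 3))
})

test_that("worlds serialize to JSON and back without changing behaviour", {
  tmp <- withr::local_tempfile(fileext = ".json")
  world_to_json(synthetic_world(expert_mode = "argmax"), tmp)
  w2 <- world_from_json(tmp)
  expect_identical(sample_cohort(w2, 50, seed = 8),
                   sample_cohort(synthetic_world(expert_mode = "argmax"),
                                 50, seed = 8))

  tmp2 <- withr::local_tempfile(fileext = ".json")
  world_to_json(world_suboptimal_expert(), tmp2)
  dw2 <- world_from_json(tmp2)
  expect_equal(dw2$recurrence_rates, world_suboptimal_expert()$recurrence_rates)
  expect_identical(optimal_policy(dw2), optimal_policy(world_suboptimal_expert()))

  expect_error(world_from_json(tmp3 <- {
    f <- withr::local_tempfile(fileext = ".json")
    writeLines('{"format_version": "9.9", "kind": "discrete"}', f)
    f
  }), class = "aflearn_version_mismatch")
})

test_that("the suboptimal-expert fixture has the designed improvement gap", {
  dw <- world_suboptimal_expert()
  opt <- optimal_policy(dw)
  expect_identical(opt, c("RAC", "EXC", "AFA", "AAM"))
  expect_identical(dw$expert_actions, c("RAC", "EXC", "AAM", "AAM"))
  # expert suboptimal exactly in context 3, with a material reward gap
  gap <- expected_reward(dw, 3, "AFA") - expected_reward(dw, 3, "AAM")
  expect_gt(gap, 0.2)
})
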