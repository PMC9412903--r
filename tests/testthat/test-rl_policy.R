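sc <- fit_scaler(tiny_cohort(8))
x0 <- c(1, rep(0, 8))  # intercept-only context

test_that("q_predict is the per-action linear value and greedy breaks ties low", {
  expect_equal(unname(q_predict(q_model(sc), x0)), rep(0, 4))

  V <- matrix(0, 4, 9)
  V[3, 1] <- -2
  q <- q_model(sc, weights = V)
  expect_equal(unname(q_predict(q, x0)), c(0, 0, -2, 0))
  expect_identical(greedy_action(q_model(sc), x0), "RAC")  # all-tie

  V2 <- matrix(0, 4, 9)
  V2[, 1] <- c(-1, -0.2, -3, -0.5)
  expect_identical(greedy_action(q_model(sc, weights = V2), x0), "EXC")

  # random instances against a hand matrix product
  set.seed(5)
  for (i in 1:20) {
    V3 <- matrix(rnorm(36), 4, 9)
    x <- c(1, rnorm(8))
    expect_equal(unname(q_predict(q_model(sc, weights = V3), x)),
                 as.numeric(V3 %*% x))
  }
  expect_error(q_predict(q_model(sc), 1:3), class = "aflearn_dimension")
})

test_that("q_single_delta is the sparse TD step", {
  q <- q_model(sc)

  # 0.01 * (-2 - 0) * 1 on the taken action's intercept, zero elsewhere
  d <- q_single_delta(q, experience(x0, "RAC", -2), lr = 0.01)
  expect_equal(d[1, 1], -0.02)
  d[1, 1] <- 0
  expect_equal(unname(d), matrix(0, 4, 9))

  # zero TD error -> zero matrix
  V <- matrix(0, 4, 9)
  V[2, 1] <- -1.5
  qf <- q_model(sc, weights = V)
  expect_equal(unname(q_single_delta(qf, experience(x0, "EXC", -1.5), 0.01)),
               matrix(0, 4, 9))

  # only the taken row moves, on arbitrary instances
  set.seed(31)
  for (i in 1:20) {
    qr <- q_model(sc, weights = matrix(rnorm(36), 4, 9))
    x <- c(1, rnorm(8))
    a <- sample(4, 1)
    d <- q_single_delta(qr, experience(x, a, rnorm(1)), lr = 0.05)
    expect_true(all(d[-a, ] == 0))
  }

  # closed-form geometric convergence of repeated single updates:
  # after n steps on intercept-only x, Q = r * (1 - (1 - lr)^n)
  lr <- 0.1
  r <- -3
  q2 <- q_model(sc)
  for (n in 1:25) {
    q2$weights <- q2$weights + q_single_delta(q2, experience(x0, "AFA", r), lr)
    expect_equal(q_predict(q2, x0)[["AFA"]], r * (1 - (1 - lr)^n))
  }
})

test_that("single-step contraction: TD error never grows when lr*||x||^2 < 2", {
  set.seed(8)
  for (i in 1:40) {
    q <- q_model(sc, weights = matrix(rnorm(36), 4, 9))
    x <- c(1, rnorm(4), rbinom(4, 1, 0.5))
    lr <- runif(1, 0.001, 1.9 / sum(x^2))
    a <- sample(4, 1)
    r <- runif(1, -4, 0)
    before <- abs(r - q_predict(q, x)[a])
    q$weights <- q$weights + q_single_delta(q, experience(x, a, r), lr)
    expect_lte(abs(r - q_predict(q, x)[a]), before + 1e-12)
  }
})

test_that("q_batch_update matches the fixed-weights oracle and is permutation invariant", {
  set.seed(21)
  cfg <- rl_config()
  for (i in 1:10) {
    q <- q_model(sc, weights = matrix(rnorm(36), 4, 9))
    X <- cbind(1, matrix(rnorm(8 * 8), 8, 8))
    batch <- experience_set(X, sample(4, 8, replace = TRUE),
                            runif(8, -4, 0))
    got <- q_batch_update(q, batch, cfg)
    expect_equal(got$weights, oracle_batch_update(q, batch, cfg))
    expect_identical(got$updates_applied, 1L)
    expect_identical(got$experiences_seen, 8L)

    perm <- sample(8)
    shuffled <- experience_set(X[perm, ], batch$action[perm],
                               batch$reward[perm])
    expect_equal(q_batch_update(q, shuffled, cfg)$weights, got$weights)
  }

  # batch of identical experiences under mean aggregation == one single delta
  q <- q_model(sc)
  e8 <- experience_set(matrix(rep(x0, 8), 8, byrow = TRUE), rep(2L, 8),
                       rep(-1, 8))
  got <- q_batch_update(q, e8, cfg)
  expect_equal(got$weights,
               q_model(sc)$weights + q_single_delta(q, experience(x0, 2L, -1),
                                                    cfg$learning_rate))

  # rewards equal to current Q-values -> no change
  V <- matrix(rnorm(36), 4, 9)
  qv <- q_model(sc, weights = V)
  X <- cbind(1, matrix(rnorm(64), 8, 8))
  a <- sample(4, 8, replace = TRUE)
  rew <- (X %*% t(V))[cbind(1:8, a)]
  expect_equal(q_batch_update(qv, experience_set(X, a, rew), cfg)$weights,
               qv$weights)

  expect_error(q_batch_update(q, experience_set(matrix(x0, 1), 1L, 0), cfg),
               class = "aflearn_dimension")
})

test_that("rl_train consumes full batches of 8 and buffers the remainder", {
  set.seed(12)
  X <- cbind(1, matrix(rnorm(19 * 8), 19, 8))
  es <- experience_set(X, sample(4, 19, replace = TRUE), runif(19, -4, 0))
  q <- rl_train(q_model(sc), es, rl_config())
  expect_identical(q$updates_applied, 2L)      # 19 = 2 full batches + 3
  expect_identical(q$experiences_seen, 16L)
  expect_identical(n_experiences(q$pending), 3L)

  # 16 experiences -> exactly 2 updates, nothing pending
  q16 <- rl_train(q_model(sc), slice_16 <- aflearn:::slice_experiences(es, 1:16),
                  rl_config())
  expect_identical(q16$updates_applied, 2L)
  expect_identical(n_experiences(q16$pending), 0L)

  # feeding the pending buffer later continues seamlessly: 19 then 5 more
  # equals 24 in one stream
  more <- experience_set(cbind(1, matrix(rnorm(5 * 8), 5, 8)),
                         sample(4, 5, replace = TRUE), runif(5, -4, 0))
  q_cont <- rl_train(q, more, rl_config())
  q_once <- rl_train(q_model(sc), bind_experiences(es, more), rl_config())
  expect_equal(q_cont$weights, q_once$weights)
  expect_identical(q_cont$updates_applied, 3L)

  # flush_partial applies the short tail with mean aggregation
  qf <- rl_train(q_model(sc), es, rl_config(), flush_partial = TRUE)
  expect_identical(qf$updates_applied, 3L)
  expect_identical(n_experiences(qf$pending), 0L)

  # empty stream: untouched
  q0 <- rl_train(q_model(sc), aflearn:::empty_experience_set(), rl_config())
  expect_identical(q0$updates_applied, 0L)
  expect_equal(q0$weights, q_model(sc)$weights)
})

test_that("Q-learning converges to the enumeration oracle on the tabulated bandit", {
  world <- world_tabulated_bandit()
  scaler <- fit_scaler(sample_cohort(world, 200, seed = 101))
  es <- generate_experiences(world, n = 0, scaler = scaler, seed = 1,
                             behavior = "balanced", per_pair = 5000)
  expect_identical(n_experiences(es), 80000L)
  q <- rl_train(q_model(scaler), es, rl_config())
  expect_identical(q$updates_applied, 10000L)

  # oracle expected rewards by independent exhaustive enumeration
  for (k in 1:4) for (a in 1:4) {
    oracle <- enum_expected_reward(world$stroke_rates[k, a],
                                   world$hosp_rates[k, a],
                                   world$recurrence_rates[k, a])
    x <- encode_features(c(as.list(world$templates[k, ]), context = k),
                         scaler)
    expect_lt(abs(q_predict(q, x)[a] - oracle), 0.05)
  }
  expect_identical(greedy_per_context(q, world), optimal_policy(world))
})

test_that("warm start from the supervised stage reproduces its argmax", {
  co <- separable_cohort()
  m <- sl_train(co, sl_config(epochs = 30, shuffle_seed = 3))
  q <- q_from_sl(m)
  X <- encode_cohort(co, m$scaler)
  for (i in seq(1, nrow(X), by = 7)) {
    expect_identical(greedy_action(q, X[i, ]),
                     actions()[which.max(sl_predict(m, X[i, ]))])
  }
})
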