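# Shared fixtures and independent oracles used across the suite.

# one fully valid record
valid_record <- function(...) {
  rec <- list(age = 65, af_duration_months = 24, heart_failure = 0,
              la_enlargement = 1, resting_hr = 88, hypertension = 1,
              bmi = 29, symptomatic = 1)
  mods <- list(...)
  rec[names(mods)] <- mods
  rec
}

# tiny hand-built cohort with feature variance in every continuous column
tiny_cohort <- function(n = 6) {
  data.frame(
    patient_id = sprintf("T%02d", seq_len(n)),
    age = seq(50, 80, length.out = n),
    af_duration_months = seq(2, 60, length.out = n),
    heart_failure = rep(c(0, 1), length.out = n),
    la_enlargement = rep(c(1, 0), length.out = n),
    resting_hr = seq(60, 120, length.out = n),
    hypertension = rep(c(0, 0, 1), length.out = n),
    bmi = seq(22, 36, length.out = n),
    symptomatic = rep(c(1, 0, 0), length.out = n),
    stringsAsFactors = FALSE)
}

# linearly separable two-context cohort: symptomatic young patients are
# always ablated, asymptomatic old patients always rate-controlled
separable_cohort <- function(n_per = 20) {
  young <- tiny_cohort(n_per)
  young$age <- seq(42, 55, length.out = n_per)
  young$symptomatic <- 1
  young$expert_action <- "AFA"
  old <- tiny_cohort(n_per)
  old$age <- seq(75, 92, length.out = n_per)
  old$symptomatic <- 0
  old$expert_action <- "RAC"
  out <- rbind(young, old)
  out$patient_id <- sprintf("S%03d", seq_len(nrow(out)))
  out
}

# independent finite-difference gradient of the per-record loss wrt W
fd_gradient <- function(model, x, chosen_idx, h = 1e-6) {
  loss_at <- function(W) {
    scores <- drop(W %*% x)
    if (model$loss_mode == "softmax_ce") {
      m <- max(scores)
      (m + log(sum(exp(scores - m)))) - scores[chosen_idx]
    } else {
      y <- numeric(4); y[chosen_idx] <- 1
      0.5 * sum((scores - y)^2)
    }
  }
  G <- matrix(0, 4, 9)
  for (i in 1:4) for (j in 1:9) {
    Wp <- model$weights; Wp[i, j] <- Wp[i, j] + h
    Wm <- model$weights; Wm[i, j] <- Wm[i, j] - h
    G[i, j] <- (loss_at(Wp) - loss_at(Wm)) / (2 * h)
  }
  G
}

# sequential-at-fixed-weights oracle for a batched Q update: every delta
# from the same starting weights, then aggregated
oracle_batch_update <- function(model, batch, config) {
  deltas <- lapply(seq_len(n_experiences(batch)), function(i) {
    e <- experience(batch$X[i, ], batch$action[i], batch$reward[i])
    q_single_delta(model, e, config$learning_rate)
  })
  agg <- Reduce(`+`, deltas)
  if (config$batch_aggregation == "mean") agg <- agg / length(deltas)
  model$weights + agg
}

# exact expected reward by exhaustive enumeration, written independently
# of the package's own enumeration path
enum_expected_reward <- function(p_stroke, p_hosp, p_rec, spec = reward_spec()) {
  grid <- expand.grid(s = 0:1, h = 0:1, r = 0:1)
  total <- 0
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    pr <- (if (g$s) p_stroke else 1 - p_stroke) *
      (if (g$h) p_hosp else 1 - p_hosp) *
      (if (g$r) p_rec else 1 - p_rec)
    total <- total + pr * (spec$weights[["stroke"]] * g$s +
                             spec$weights[["hospitalization"]] * g$h +
                             spec$weights[["symptomatic_recurrence"]] * g$r)
  }
  total
}

# greedy actions of a Q model over a discrete world's contexts
greedy_per_context <- function(q, world) {
  vapply(seq_len(nrow(world$templates)), function(k) {
    rec <- as.list(world$templates[k, , drop = FALSE])
    rec$context <- k
    greedy_policy_fn(q)(rec)
  }, character(1))
}
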