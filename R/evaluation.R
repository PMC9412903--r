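# Evaluation: agreement with the expert labeler, Q-estimation error
# against the tabulated oracle, policy value (expected reward per
# decision) and regret (gap to the brute-force optimal policy).  Discrete
# worlds admit exact values; continuous worlds are scored by seeded
# Monte-Carlo with reported standard errors.

#' Agreement between a mimicry model and the expert labels
#'
#' @param model trained \code{sl_policy} model.
#' @param cohort labelled cohort data.frame.
#' @return Fraction in [0, 1] of records where the model's top action
#'   (lowest-index tie-break) equals \code{expert_action}.
#' @export
policy_agreement <- function(model, cohort) {
  stopifnot(inherits(model, "sl_policy"))
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    af_error("aflearn_empty_cohort", "agreement needs a nonempty cohort")
  if (is.null(cohort$expert_action) || anyNA(cohort$expert_action))
    af_error("aflearn_unlabeled", "agreement needs labelled records")
  X <- encode_cohort(cohort, model$scaler)
  S <- X %*% t(model$weights)
  # argmax of the frequency equals argmax of the scores in both loss modes
  pred <- AF_ACTIONS[max.col(S, ties.method = "first")]
  mean(pred == cohort$expert_action)
}

# resolve a "policy": an action-choosing function(record) -> code, or a
# model object wrapped by its natural policy function
as_policy_fn <- function(policy) {
  if (is.function(policy)) return(policy)
  if (inherits(policy, "sl_policy")) return(sl_policy_fn(policy))
  if (inherits(policy, "q_policy")) return(greedy_policy_fn(policy))
  af_error("aflearn_validation",
           "policy must be a function, sl_policy or q_policy")
}

policy_actions_per_context <- function(policy, world) {
  fn <- as_policy_fn(policy)
  K <- nrow(world$templates)
  vapply(seq_len(K), function(k) {
    rec <- as.list(world$templates[k, , drop = FALSE])
    rec$context <- k
    fn(rec)
  }, character(1))
}

#' Expected reward per decision under a policy
#'
#' Exact in discrete worlds (context-probability-weighted
#' \code{\link{expected_reward}}); Monte-Carlo otherwise, with the
#' standard error of the mean reported alongside.
#'
#' @param policy function(record) -> action code, or an \code{sl_policy} /
#'   \code{q_policy} model (wrapped by its natural policy).
#' @param world a world object.
#' @param n Monte-Carlo rollouts (ignored in exact mode).
#' @param seed integer seed for the rollouts.
#' @param spec a \code{\link{reward_spec}}.
#' @param method \code{"exact"} (discrete worlds only), \code{"mc"}, or
#'   \code{"auto"} (exact when available).
#' @return List with \code{$value}, \code{$se} (NA in exact mode) and
#'   \code{$n}.
#' @export
policy_value <- function(policy, world, n = 10000L, seed = 1L,
                         spec = reward_spec(),
                         method = c("auto", "exact", "mc")) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (inherits(world, "discrete_world")) "exact" else "mc"
  if (method == "exact") {
    if (!inherits(world, "discrete_world"))
      af_error("aflearn_continuous_world",
               "exact policy value needs a discrete world")
    acts <- policy_actions_per_context(policy, world)
    er <- vapply(seq_along(acts), function(k)
      expected_reward(world, k, acts[k], spec), numeric(1))
    return(list(value = sum(world$probs * er), se = NA_real_, n = NA_integer_))
  }
  if (n < 1) af_error("aflearn_validation", "n must be >= 1")
  fn <- as_policy_fn(policy)
  cohort <- sample_cohort(world, n, seed = seed)
  acts <- vapply(seq_len(n), function(i)
    fn(as.list(cohort[i, , drop = FALSE])), character(1))
  r <- with_seed(seed + 1L, {
    O <- draw_outcomes_matrix(world, cohort, acts)
    compute_reward(O, spec)
  })
  list(value = mean(r), se = sd(r) / sqrt(n), n = n)
}

#' Regret of a policy against the brute-force optimum
#'
#' @inheritParams policy_value
#' @return List with \code{$regret} (optimal value minus policy value;
#'   >= 0 in exact mode, up to Monte-Carlo error otherwise),
#'   \code{$optimal_value} and \code{$policy_value}.
#' @export
regret <- function(policy, world, n = 10000L, seed = 1L,
                   spec = reward_spec(), method = c("auto", "exact", "mc")) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (inherits(world, "discrete_world")) "exact" else "mc"
  if (method == "exact") {
    opt <- policy_value(function(rec) optimal_policy(world, spec)[rec$context],
                        world, spec = spec, method = "exact")
  } else {
    if (!inherits(world, "discrete_world"))
      af_error("aflearn_continuous_world",
               "regret for continuous worlds needs a reference policy; not provided")
    opt <- policy_value(function(rec) optimal_policy(world, spec)[rec$context],
                        world, n = n, seed = seed + 7L, spec = spec,
                        method = "mc")
  }
  pv <- policy_value(policy, world, n = n, seed = seed, spec = spec,
                     method = method)
  list(regret = opt$value - pv$value, optimal_value = opt$value,
       policy_value = pv$value, se = pv$se)
}

#' Maximum absolute Q-estimation error against the tabulated oracle
#'
#' @param model \code{q_policy} model.
#' @param world a \code{discrete_world}.
#' @param spec a \code{\link{reward_spec}}.
#' @return max over (context, action) of \code{|Q(x, a) - E[reward]|},
#'   where the expectation is exact from the rate tables.
#' @export
q_max_abs_error <- function(model, world, spec = reward_spec()) {
  stopifnot(inherits(model, "q_policy"))
  if (!inherits(world, "discrete_world"))
    af_error("aflearn_continuous_world",
             "Q-error against the oracle needs a discrete world")
  X <- encode_cohort(world$templates, model$scaler)
  Q <- X %*% t(model$weights)
  ER <- outer(seq_len(nrow(X)), seq_along(AF_ACTIONS),
              Vectorize(function(k, a)
                expected_reward(world, k, AF_ACTIONS[a], spec)))
  max(abs(Q - ER))
}

#' Q-learning curve on a world
#'
#' Streams experiences under a behavior policy, pausing at each checkpoint
#' to score the current model: Q-error versus the oracle (discrete worlds),
#' exact or Monte-Carlo policy value of the greedy policy, and regret.
#'
#' @param world a world object (metrics are exact for discrete worlds).
#' @param checkpoints increasing non-negative experience counts at which
#'   to evaluate.
#' @param seed integer seed; the full curve is reproducible.
#' @param config an \code{\link{rl_config}}.
#' @param scaler \code{feature_scaler} for the learner (default: fitted to
#'   a world sample).
#' @param behavior,model,epsilon behavior policy passed to
#'   \code{\link{generate_experiences}} (default \code{"uniform"}).
#' @param spec a \code{\link{reward_spec}}.
#' @param n_eval Monte-Carlo size for continuous-world metrics.
#' @return data.frame with one row per checkpoint: \code{checkpoint},
#'   \code{q_max_abs_error} (NA for continuous worlds),
#'   \code{policy_value}, \code{regret}, \code{n_eval}, \code{seed}.
#' @export
learning_curve <- function(world, checkpoints, seed = 1L,
                           config = rl_config(), scaler = NULL,
                           behavior = "uniform", model = NULL, epsilon = 0.1,
                           spec = reward_spec(), n_eval = 5000L) {
  checkpoints <- as.integer(checkpoints)
  if (is.unsorted(checkpoints, strictly = FALSE) || any(checkpoints < 0))
    af_error("aflearn_validation",
             "checkpoints must be nondecreasing and >= 0")
  if (is.null(scaler))
    scaler <- fit_scaler(sample_cohort(world, 200L, seed = seed))
  q <- model %||% q_model(scaler, id = sprintf("q-curve-s%d", seed))
  discrete <- inherits(world, "discrete_world")
  rows <- vector("list", length(checkpoints))
  consumed <- 0L
  for (i in seq_along(checkpoints)) {
    need <- checkpoints[i] - consumed
    if (need > 0L) {
      es <- generate_experiences(world, need, scaler,
                                 seed = seed + 1000L + i,
                                 behavior = behavior, model = q,
                                 epsilon = epsilon, spec = spec)
      q <- rl_train(q, es, config)
      consumed <- consumed + need
    }
    val <- policy_value(q, world, n = n_eval, seed = seed + 2000L + i,
                        spec = spec)
    reg <- regret(q, world, n = n_eval, seed = seed + 2000L + i, spec = spec)
    rows[[i]] <- data.frame(
      checkpoint = checkpoints[i],
      q_max_abs_error = if (discrete) q_max_abs_error(q, world, spec)
                        else NA_real_,
      policy_value = val$value,
      regret = reg$regret,
      n_eval = if (discrete) NA_integer_ else as.integer(n_eval),
      seed = as.integer(seed))
  }
  do.call(rbind, rows)
}
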