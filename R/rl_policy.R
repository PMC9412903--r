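# Stage two: linear Q-learning in a contextual-bandit framing.  One
# treatment decision and one terminal reward per patient, so the TD target
# is the reward itself.  Only the taken action's weight row is updated;
# updates are delivered in batches of 8 patients (the follow-up constant),
# aggregated as the mean of per-example deltas computed at the pre-batch
# weights.

#' Construct a Q-value model
#'
#' Row \eqn{a} of the 4 x 9 weight matrix gives the linear value estimate
#' \eqn{Q(x, a) = V_a \cdot x}.
#'
#' @param scaler fitted \code{feature_scaler}.
#' @param weights optional 4 x 9 matrix (default zeros).
#' @param id optional identifier echoed into recommendations and files.
#' @return Object of class \code{q_policy} with counters
#'   \code{updates_applied} (batch updates so far) and
#'   \code{experiences_seen} (experiences consumed by applied updates) and
#'   a \code{pending} buffer of experiences awaiting a full batch.
#' @export
q_model <- function(scaler, weights = NULL, id = "q-unversioned") {
  stopifnot(inherits(scaler, "feature_scaler"))
  V <- new_weight_matrix()
  if (!is.null(weights)) {
    if (!is.matrix(weights) || !all(dim(weights) == dim(V)))
      af_error("aflearn_dimension", "weights must be a 4 x 9 matrix")
    if (any(!is.finite(weights)))
      af_error("aflearn_validation", "weights must be finite")
    V[, ] <- weights
  }
  structure(list(weights = V, scaler = scaler,
                 updates_applied = 0L, experiences_seen = 0L,
                 pending = empty_experience_set(), id = id),
            class = "q_policy")
}

#' @export
print.q_policy <- function(x, ...) {
  cat(sprintf("<q_policy> id=%s updates_applied=%d experiences_seen=%d pending=%d\n",
              x$id, x$updates_applied, x$experiences_seen,
              n_experiences(x$pending)))
  print(round(x$weights, 4))
  invisible(x)
}

#' Warm-start a Q model from the supervised stage
#'
#' Copies the mimicry model's weights (scaled by \code{scale}) so that the
#' initial greedy action agrees with the supervised argmax in every
#' context -- the "scaffold" reading of the SL-to-RL hand-off.  Because
#' rewards are non-positive, the copied values are optimistic and get
#' pulled down by training.
#'
#' @param sl trained \code{sl_policy} model.
#' @param scale multiplier applied to the copied weights (default 1).
#' @return A \code{q_policy} sharing the supervised model's scaler.
#' @export
q_from_sl <- function(sl, scale = 1) {
  stopifnot(inherits(sl, "sl_policy"))
  q_model(sl$scaler, weights = scale * sl$weights,
          id = sprintf("q-warm-%s", sl$id))
}

#' Predict per-action Q-values
#'
#' @param model \code{q_policy} model.
#' @param x encoded feature vector.
#' @return Named numeric vector of 4 unbounded value estimates.
#' @export
q_predict <- function(model, x) {
  stopifnot(inherits(model, "q_policy"))
  check_x(x)
  q <- drop(model$weights %*% x)
  names(q) <- AF_ACTIONS
  q
}

#' Greedy action under a Q model
#'
#' @param model \code{q_policy} model.
#' @param x encoded feature vector.
#' @return Action code maximizing Q; ties broken by lowest action index
#'   (RAC < EXC < AAM < AFA).
#' @export
greedy_action <- function(model, x) {
  AF_ACTIONS[which.max(q_predict(model, x))]
}

#' Epsilon-greedy action
#'
#' With probability \code{epsilon} a uniformly random action, otherwise the
#' greedy one.  Draws from the current RNG stream; seed it at the caller.
#'
#' @param model \code{q_policy} model.
#' @param x encoded feature vector.
#' @param epsilon exploration rate in [0, 1] (default 0.1).
#' @return Action code.
#' @export
epsilon_greedy_action <- function(model, x, epsilon = 0.1) {
  if (runif(1) < epsilon) sample(AF_ACTIONS, 1) else greedy_action(model, x)
}

# ---- experience sets -------------------------------------------------------

#' Experience sets
#'
#' Column-oriented container for (context, action, reward) training
#' triples: an encoded design matrix, taken-action indices and scalar
#' rewards.
#'
#' @param X numeric matrix, one encoded feature vector per row.
#' @param action integer indices 1--4 or action codes, length nrow(X).
#' @param reward finite numeric rewards, length nrow(X).
#' @return Object of class \code{experience_set}.
#' @export
experience_set <- function(X, action, reward) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(FEATURE_ORDER))
    af_error("aflearn_dimension",
             sprintf("X must have %d columns", length(FEATURE_ORDER)))
  a <- if (is.character(action)) action_index(action) else as.integer(action)
  if (any(a < 1 | a > length(AF_ACTIONS)))
    af_error("aflearn_invalid_action", "action indices must be in 1..4")
  if (length(a) != nrow(X) || length(reward) != nrow(X))
    af_error("aflearn_dimension", "X, action and reward lengths differ")
  if (any(!is.finite(reward)))
    af_error("aflearn_validation", "rewards must be finite")
  colnames(X) <- FEATURE_ORDER
  structure(list(X = X, action = a, reward = as.numeric(reward)),
            class = "experience_set")
}

empty_experience_set <- function() {
  structure(list(X = matrix(numeric(0), 0, length(FEATURE_ORDER),
                            dimnames = list(NULL, FEATURE_ORDER)),
                 action = integer(0), reward = numeric(0)),
            class = "experience_set")
}

#' A single training experience
#'
#' @param x encoded feature vector.
#' @param action action code or index of the treatment actually taken.
#' @param reward scalar reward from \code{\link{compute_reward}}.
#' @return A length-1 \code{\link{experience_set}}.
#' @export
experience <- function(x, action, reward) {
  experience_set(matrix(check_x(x), 1), action, reward)
}

#' Number of experiences in a set
#' @param es an \code{experience_set}.
#' @return Integer count.
#' @export
n_experiences <- function(es) nrow(es$X)

#' Concatenate experience sets
#' @param ... \code{experience_set} objects.
#' @return Combined \code{experience_set}.
#' @export
bind_experiences <- function(...) {
  sets <- list(...)
  experience_set(do.call(rbind, lapply(sets, `[[`, "X")),
                 unlist(lapply(sets, `[[`, "action")),
                 unlist(lapply(sets, `[[`, "reward")))
}

slice_experiences <- function(es, idx) {
  structure(list(X = es$X[idx, , drop = FALSE], action = es$action[idx],
                 reward = es$reward[idx]),
            class = "experience_set")
}

#' Build experiences from a cohort with recorded actions and outcomes
#'
#' @param cohort data.frame with the 8 features, an \code{action_taken}
#'   column (falls back to \code{expert_action}) and the three outcome
#'   flags.
#' @param scaler fitted \code{feature_scaler} used to encode the contexts.
#' @param spec \code{\link{reward_spec}} converting outcomes to rewards.
#' @return An \code{experience_set} in cohort row order.
#' @export
experiences_from_cohort <- function(cohort, scaler, spec = reward_spec()) {
  act <- cohort$action_taken
  if (is.null(act)) act <- cohort$expert_action
  if (is.null(act) || anyNA(act) || any(act == ""))
    af_error("aflearn_unlabeled",
             "every record needs an action_taken (or expert_action)")
  out <- validate_outcomes(cohort[, OUTCOME_FLAGS])
  experience_set(encode_cohort(cohort, scaler), act,
                 compute_reward(out, spec))
}

# ---- updates ---------------------------------------------------------------

#' Reinforcement-learning training configuration
#'
#' Defaults are the outcome-learning constants: learning rate 0.01 (one
#' order of magnitude below the supervised stage) and batches of 8
#' patients per weight update.
#'
#' @param learning_rate TD step size (default 0.01).
#' @param batch_size experiences consumed per weight update (default 8).
#' @param batch_aggregation \code{"mean"} (default; step size independent
#'   of batch size) or \code{"sum"} of per-example deltas.
#' @param seed seed echoed into artifacts for reproducibility.
#' @return Object of class \code{rl_config}.
#' @export
rl_config <- function(learning_rate = 0.01, batch_size = 8L,
                      batch_aggregation = c("mean", "sum"), seed = 1L) {
  batch_aggregation <- match.arg(batch_aggregation)
  if (!is.finite(learning_rate) || learning_rate <= 0)
    af_error("aflearn_validation", "learning_rate must be > 0")
  if (batch_size < 1) af_error("aflearn_validation", "batch_size must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 batch_aggregation = batch_aggregation,
                 seed = as.integer(seed)),
            class = "rl_config")
}

#' Single-experience Q update matrix
#'
#' Pure function returning the 4 x 9 delta of one temporal-difference
#' step: zero except in the taken action's row, which equals
#' \eqn{\mathrm{lr}\,(r - Q(x, a))\,x}.
#'
#' @param model \code{q_policy} model (not mutated).
#' @param e a length-1 \code{\link{experience_set}} (see
#'   \code{\link{experience}}).
#' @param lr learning rate.
#' @return 4 x 9 numeric matrix.
#' @export
q_single_delta <- function(model, e, lr = 0.01) {
  stopifnot(inherits(model, "q_policy"), inherits(e, "experience_set"))
  if (n_experiences(e) != 1L)
    af_error("aflearn_dimension", "q_single_delta takes exactly one experience")
  x <- drop(e$X[1, ])
  a <- e$action[1]
  td <- e$reward[1] - sum(model$weights[a, ] * x)
  D <- new_weight_matrix()
  D[a, ] <- lr * td * x
  D
}

#' Apply one batched Q update
#'
#' Every per-experience delta is computed at the pre-batch weights, the
#' deltas are aggregated (mean by default), and the aggregate is applied
#' once -- so the result is invariant to the order of experiences within
#' the batch.
#'
#' @param model \code{q_policy} model.
#' @param batch \code{experience_set}; length must equal
#'   \code{config$batch_size} (partial batches are handled by
#'   \code{\link{rl_train}}'s pending buffer).
#' @param config an \code{\link{rl_config}}.
#' @param allow_partial internal: permit a short final batch when flushing.
#' @return Updated model with \code{updates_applied} incremented and
#'   \code{experiences_seen} advanced by the batch length.
#' @export
q_batch_update <- function(model, batch, config = rl_config(),
                           allow_partial = FALSE) {
  stopifnot(inherits(model, "q_policy"), inherits(batch, "experience_set"),
            inherits(config, "rl_config"))
  B <- n_experiences(batch)
  if (B == 0L) af_error("aflearn_empty_batch", "empty experience batch")
  if (!allow_partial && B != config$batch_size)
    af_error("aflearn_dimension",
             sprintf("batch length %d != batch_size %d", B, config$batch_size))
  Q <- batch$X %*% t(model$weights)             # B x 4, pre-batch weights
  td <- batch$reward - Q[cbind(seq_len(B), batch$action)]
  D <- new_weight_matrix()
  for (a in unique(batch$action)) {
    rows <- which(batch$action == a)
    D[a, ] <- config$learning_rate *
      colSums(batch$X[rows, , drop = FALSE] * td[rows])
  }
  if (config$batch_aggregation == "mean") D <- D / B
  model$weights <- model$weights + D
  model$updates_applied <- model$updates_applied + 1L
  model$experiences_seen <- model$experiences_seen + B
  model
}

#' Train the Q model on a stream of experiences
#'
#' Consumes experiences in arrival order (after any previously pending
#' ones), grouping into consecutive batches of \code{batch_size} and
#' applying \code{\link{q_batch_update}} per group.  A final partial batch
#' is held in the model's pending buffer -- updates are only delivered in
#' full batches -- unless \code{flush_partial = TRUE}.
#'
#' @param model \code{q_policy} model.
#' @param experiences an \code{\link{experience_set}}.
#' @param config an \code{\link{rl_config}}.
#' @param flush_partial apply a trailing short batch (mean aggregation)
#'   instead of buffering it.
#' @return Updated model.
#' @export
rl_train <- function(model, experiences, config = rl_config(),
                     flush_partial = FALSE) {
  stopifnot(inherits(model, "q_policy"),
            inherits(experiences, "experience_set"))
  es <- bind_experiences(model$pending, experiences)
  n <- n_experiences(es)
  B <- config$batch_size
  n_full <- n %/% B
  for (b in seq_len(n_full)) {
    idx <- ((b - 1L) * B + 1L):(b * B)
    model$pending <- empty_experience_set()
    model <- q_batch_update(model, slice_experiences(es, idx), config)
  }
  rest <- if (n_full * B < n) slice_experiences(es, (n_full * B + 1L):n)
          else empty_experience_set()
  if (flush_partial && n_experiences(rest) > 0L) {
    model <- q_batch_update(model, rest, config, allow_partial = TRUE)
    rest <- empty_experience_set()
  }
  model$pending <- rest
  model
}

#' Wrap a Q model as an action-choosing policy function
#'
#' @param model \code{q_policy} model.
#' @return Function mapping a validated record to the greedy action code.
#' @export
greedy_policy_fn <- function(model) {
  stopifnot(inherits(model, "q_policy"))
  function(record) greedy_action(model, encode_features(record, model$scaler))
}
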