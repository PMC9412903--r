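# Stage one: supervised expert mimicry.  A linear score per action,
# trained by per-record stochastic gradient descent to predict the
# clinician's chosen strategy.  Two loss modes share one update rule:
#   softmax_ce  - softmax of the scores, cross-entropy against the label
#                 (the default: proper for frequency outputs);
#   mse_onehot  - raw linear outputs, squared error against the one-hot
#                 label (the literal linear-regression reading), with
#                 clip-and-renormalize only at prediction time.

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

new_weight_matrix <- function() {
  matrix(0, length(AF_ACTIONS), length(FEATURE_ORDER),
         dimnames = list(AF_ACTIONS, FEATURE_ORDER))
}

check_x <- function(x) {
  if (!is.numeric(x) || length(x) != length(FEATURE_ORDER))
    af_error("aflearn_dimension",
             sprintf("feature vector must have length %d (got %d)",
                     length(FEATURE_ORDER), length(x)))
  x
}

#' Construct a supervised mimicry model
#'
#' @param scaler fitted \code{feature_scaler} the model's inputs must be
#'   encoded with.
#' @param loss_mode \code{"softmax_ce"} (default) or \code{"mse_onehot"};
#'   fixed at construction.
#' @param weights 4 x 9 numeric matrix (rows in action order); defaults to
#'   zeros, which predicts the uniform distribution.
#' @param id optional model identifier echoed into recommendations and
#'   serialized files.
#' @return Object of class \code{sl_policy}.
#' @export
sl_model <- function(scaler, loss_mode = c("softmax_ce", "mse_onehot"),
                     weights = NULL, id = "sl-unversioned") {
  loss_mode <- match.arg(loss_mode)
  stopifnot(inherits(scaler, "feature_scaler"))
  W <- new_weight_matrix()
  if (!is.null(weights)) {
    if (!is.matrix(weights) || !all(dim(weights) == dim(W)))
      af_error("aflearn_dimension", "weights must be a 4 x 9 matrix")
    if (any(!is.finite(weights)))
      af_error("aflearn_validation", "weights must be finite")
    W[, ] <- weights
  }
  structure(list(weights = W, loss_mode = loss_mode, scaler = scaler,
                 id = id),
            class = "sl_policy")
}

#' @export
print.sl_policy <- function(x, ...) {
  cat(sprintf("<sl_policy> loss_mode=%s id=%s\n", x$loss_mode, x$id))
  print(round(x$weights, 4))
  invisible(x)
}

#' Predict the expert strategy-choice frequencies
#'
#' In \code{softmax_ce} mode returns \code{softmax(W x)}.  In
#' \code{mse_onehot} mode the raw linear outputs are clipped at zero and
#' renormalized (uniform fallback when everything clips to zero).
#'
#' @param model \code{sl_policy} model.
#' @param x encoded feature vector (see \code{\link{encode_features}}).
#' @return Named numeric vector: 4 non-negative frequencies summing to 1.
#' @export
sl_predict <- function(model, x) {
  stopifnot(inherits(model, "sl_policy"))
  check_x(x)
  scores <- drop(model$weights %*% x)
  if (model$loss_mode == "softmax_ce") {
    p <- softmax(scores)
  } else {
    p <- pmax(scores, 0)
    s <- sum(p)
    p <- if (s > 0) p / s else rep(1 / length(p), length(p))
  }
  names(p) <- AF_ACTIONS
  p
}

# raw per-record loss gradient wrt W: (prediction - onehot) outer x,
# where "prediction" is softmax(Wx) for CE and Wx itself for the
# half-squared-error mode.
sl_gradient <- function(model, x, chosen_idx) {
  scores <- drop(model$weights %*% x)
  pred <- if (model$loss_mode == "softmax_ce") softmax(scores) else scores
  err <- pred
  err[chosen_idx] <- err[chosen_idx] - 1
  tcrossprod(err, x)
}

#' One stochastic-gradient step on a labelled record
#'
#' Applies \eqn{W \leftarrow W - \mathrm{lr}\,(p - e_a) x^\top} where
#' \eqn{p} is the model prediction and \eqn{e_a} the one-hot label:
#' the gradient of cross-entropy-after-softmax, or of half the squared
#' error in \code{mse_onehot} mode.
#'
#' @param model \code{sl_policy} model.
#' @param x encoded feature vector.
#' @param chosen the expert's action code.
#' @param lr learning rate (default 0.1, the supervised-stage constant).
#' @param ridge optional L2 penalty coefficient (default 0, i.e. none).
#' @return Updated model (functional: the input is not mutated).
#' @export
sl_update <- function(model, x, chosen, lr = 0.1, ridge = 0) {
  stopifnot(inherits(model, "sl_policy"))
  check_x(x)
  a <- action_index(chosen)
  g <- sl_gradient(model, x, a)
  if (ridge > 0) g <- g + ridge * model$weights
  model$weights <- model$weights - lr * g
  model
}

#' Supervised training configuration
#'
#' @param learning_rate SGD step size; default 0.1, the supervised-stage
#'   constant.
#' @param epochs full passes over the cohort.
#' @param shuffle_seed seed driving the per-epoch record shuffles.
#' @param loss_mode see \code{\link{sl_model}}.
#' @param ridge optional L2 penalty (default 0).
#' @return Object of class \code{sl_config}.
#' @export
sl_config <- function(learning_rate = 0.1, epochs = 50L, shuffle_seed = 1L,
                      loss_mode = c("softmax_ce", "mse_onehot"), ridge = 0) {
  loss_mode <- match.arg(loss_mode)
  if (!is.finite(learning_rate) || learning_rate <= 0)
    af_error("aflearn_validation", "learning_rate must be > 0")
  if (epochs < 1) af_error("aflearn_validation", "epochs must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 shuffle_seed = as.integer(shuffle_seed),
                 loss_mode = loss_mode, ridge = ridge),
            class = "sl_config")
}

#' Train the supervised mimicry model by SGD
#'
#' Fits the scaler on the cohort, initializes weights at zero (both losses
#' are convex in W, so the start point only affects the path), then runs
#' \code{epochs} shuffled passes of per-record updates.  Fully reproducible
#' from \code{shuffle_seed}.
#'
#' @param cohort data.frame of validated records, every row labelled with
#'   \code{expert_action}.
#' @param config an \code{\link{sl_config}}.
#' @return Trained \code{sl_policy} model.
#' @export
sl_train <- function(cohort, config = sl_config()) {
  stopifnot(inherits(config, "sl_config"))
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    af_error("aflearn_empty_cohort", "cannot train on an empty cohort")
  if (is.null(cohort$expert_action) || anyNA(cohort$expert_action) ||
      any(cohort$expert_action == ""))
    af_error("aflearn_unlabeled",
             "every record must carry an expert_action label")
  scaler <- fit_scaler(cohort)
  X <- encode_cohort(cohort, scaler)
  y <- action_index(cohort$expert_action)
  model <- sl_model(scaler, loss_mode = config$loss_mode)
  n <- nrow(X)
  lr <- config$learning_rate
  ridge <- config$ridge
  ce <- config$loss_mode == "softmax_ce"
  W <- model$weights
  with_seed(config$shuffle_seed, {
    for (ep in seq_len(config$epochs)) {
      for (i in sample.int(n)) {
        x <- X[i, ]
        scores <- drop(W %*% x)
        err <- if (ce) softmax(scores) else scores
        err[y[i]] <- err[y[i]] - 1
        if (ridge > 0) W <- W - lr * ridge * W
        W <- W - lr * tcrossprod(err, x)
      }
    }
  })
  model$weights <- W
  model$id <- sprintf("sl-%s-n%d-e%d-s%d", config$loss_mode, n,
                      config$epochs, config$shuffle_seed)
  model
}

#' Mean per-record training loss
#'
#' Cross-entropy (\code{softmax_ce}) or half squared error against the
#' one-hot label (\code{mse_onehot}); zero only for a perfect mimic.
#'
#' @param model \code{sl_policy} model.
#' @param cohort labelled cohort data.frame.
#' @return Non-negative scalar.
#' @export
sl_loss <- function(model, cohort) {
  stopifnot(inherits(model, "sl_policy"))
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    af_error("aflearn_empty_cohort", "loss needs a nonempty cohort")
  if (is.null(cohort$expert_action) || anyNA(cohort$expert_action))
    af_error("aflearn_unlabeled", "loss needs labelled records")
  X <- encode_cohort(cohort, model$scaler)
  y <- action_index(cohort$expert_action)
  S <- X %*% t(model$weights)            # n x 4 scores
  if (model$loss_mode == "softmax_ce") {
    m <- apply(S, 1, max)
    logZ <- m + log(rowSums(exp(S - m)))
    mean(logZ - S[cbind(seq_len(nrow(S)), y)])
  } else {
    Y <- matrix(0, nrow(S), ncol(S))
    Y[cbind(seq_len(nrow(S)), y)] <- 1
    mean(0.5 * rowSums((S - Y)^2))
  }
}

#' Wrap a mimicry model as an action-choosing policy function
#'
#' @param model \code{sl_policy} model.
#' @return Function mapping a validated record to the action code with the
#'   highest predicted frequency (ties broken by lowest action index).
#' @export
sl_policy_fn <- function(model) {
  stopifnot(inherits(model, "sl_policy"))
  function(record) {
    p <- sl_predict(model, encode_features(record, model$scaler))
    AF_ACTIONS[which.max(p)]
  }
}
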