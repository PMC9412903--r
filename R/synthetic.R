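# Synthetic patient worlds.  No public cohort exists for this problem, so
# training and evaluation run against simulators with a *known*
# ground-truth expert policy and outcome model:
#
#   synthetic_world - continuous covariate distributions, a linear expert
#     score matrix W*, and logistic outcome models; emulates the
#     100-patient chart-review cohort used to initialize the supervised
#     stage.  All distribution parameters are artifact defaults chosen to
#     be clinically plausible for an AF clinic population; none is an
#     empirical estimate.
#
#   discrete_world - K fixed patient templates with tabulated Bernoulli
#     outcome rates per (context, action); expected rewards are available
#     in closed form, making it the brute-force oracle for Q-learning
#     convergence and regret.

default_expert_weights <- function() {
  W <- new_weight_matrix()
  # textbook-leaning tendencies on the standardized scale: older,
  # asymptomatic, long-standing AF -> rate control; recent-onset
  # symptomatic -> cardioversion; younger symptomatic without marked LA
  # enlargement -> ablation.  Tests never rely on these clinical choices,
  # only on recovery of whatever W* is configured.
  W["RAC", ] <- c( 0.2,  1.0,  0.8, 0.3,  0.2,  0.5,  0.8,  0.3, -1.5)
  W["EXC", ] <- c(-0.5, -0.2, -1.2, 0.5,  0.0,  0.3, -0.3,  0.0,  0.8)
  W["AAM", ] <- c( 0.3,  0.0, -0.3, 0.0, -0.2, -0.5,  0.0,  0.2,  0.7)
  W["AFA", ] <- c(-0.3, -1.0, -0.4, 0.0, -0.3,  0.2, -0.8, -0.2,  1.2)
  W
}

default_outcome_model <- function() {
  feat <- function(...) {
    v <- stats::setNames(numeric(length(FEATURE_ORDER)), FEATURE_ORDER)
    args <- list(...)
    v[names(args)] <- unlist(args)
    v
  }
  act <- function(RAC, EXC, AAM, AFA)
    c(RAC = RAC, EXC = EXC, AAM = AAM, AFA = AFA)
  list(
    # log-odds on the world's reference-standardized features plus an
    # additive per-action effect; stroke rare, recurrence common under
    # pure rate control in symptomatic long-duration disease
    stroke = list(
      feat = feat(intercept = -3.5, age = 0.5, hypertension = 0.4,
                  heart_failure = 0.3, la_enlargement = 0.2),
      action = act(0, 0.2, 0.1, -0.2)),
    hospitalization = list(
      feat = feat(intercept = -1.5, heart_failure = 0.8, age = 0.2),
      action = act(0.2, 0.4, 0.3, -0.3)),
    symptomatic_recurrence = list(
      feat = feat(intercept = -0.5, af_duration_months = 0.5,
                  la_enlargement = 0.6, symptomatic = 0.3),
      action = act(0.8, 0.5, 0.2, -0.8))
  )
}

#' Continuous synthetic AF world
#'
#' Defines covariate distributions, a ground-truth expert policy
#' (softmax or argmax of \code{expert_weights \%*\% x}) and per-outcome
#' logistic models.  Every parameter is explicit, so a world plus a seed
#' fully determines every sampled record and outcome.
#'
#' @param age,resting_hr,bmi lists \code{(mean, sd, min, max)} of truncated
#'   normals.  Defaults: age N(68, 10) on [35, 95]; HR N(88, 15) on
#'   [40, 180]; BMI N(29, 5) on [16, 55].
#' @param af_duration list \code{(meanlog, sdlog)} of a log-normal in
#'   months; default meanlog = log 24, sdlog = 0.8.
#' @param p_hf,p_lae,p_htn,p_sympt Bernoulli rates of the binary features
#'   (defaults 0.3, 0.4, 0.6, 0.55).
#' @param expert_weights ground-truth 4 x 9 score matrix W*.
#' @param outcome_model per-outcome logistic coefficients (feature vector
#'   on the reference-standardized scale plus an additive per-action
#'   effect).
#' @param expert_mode \code{"softmax"} (labels drawn from softmax(W* x))
#'   or \code{"argmax"} (deterministic expert; used as the mimicry
#'   recovery ceiling).
#' @return Object of class \code{c("synthetic_world", "af_world")}.
#' @export
synthetic_world <- function(age = list(mean = 68, sd = 10, min = 35, max = 95),
                            af_duration = list(meanlog = log(24), sdlog = 0.8),
                            resting_hr = list(mean = 88, sd = 15, min = 40, max = 180),
                            bmi = list(mean = 29, sd = 5, min = 16, max = 55),
                            p_hf = 0.3, p_lae = 0.4, p_htn = 0.6, p_sympt = 0.55,
                            expert_weights = default_expert_weights(),
                            outcome_model = default_outcome_model(),
                            expert_mode = c("softmax", "argmax")) {
  expert_mode <- match.arg(expert_mode)
  if (!is.matrix(expert_weights) ||
      !all(dim(expert_weights) == c(length(AF_ACTIONS), length(FEATURE_ORDER))))
    af_error("aflearn_validation", "expert_weights must be a 4 x 9 matrix")
  for (p in c(p_hf, p_lae, p_htn, p_sympt))
    if (p < 0 || p > 1)
      af_error("aflearn_validation", "Bernoulli rates must lie in [0, 1]")
  # reference scaler: the nominal location/scale of each continuous
  # feature, on which W* and the outcome coefficients are expressed
  # (log-normal moments give AF duration mean exp(mu + s^2/2))
  dur_mean <- exp(af_duration$meanlog + af_duration$sdlog^2 / 2)
  dur_sd <- dur_mean * sqrt(exp(af_duration$sdlog^2) - 1)
  ref_scaler <- structure(
    list(means = c(age = age$mean, af_duration_months = dur_mean,
                   resting_hr = resting_hr$mean, bmi = bmi$mean),
         sds = c(age = age$sd, af_duration_months = dur_sd,
                 resting_hr = resting_hr$sd, bmi = bmi$sd)),
    class = "feature_scaler")
  structure(list(age = age, af_duration = af_duration,
                 resting_hr = resting_hr, bmi = bmi,
                 p_hf = p_hf, p_lae = p_lae, p_htn = p_htn,
                 p_sympt = p_sympt,
                 expert_weights = expert_weights,
                 outcome_model = outcome_model,
                 expert_mode = expert_mode,
                 ref_scaler = ref_scaler),
            class = c("synthetic_world", "af_world"))
}

# exact truncated-normal draws by inverse-CDF (deterministic under seed)
rtruncnorm <- function(n, mean, sd, min, max) {
  lo <- pnorm(min, mean, sd)
  hi <- pnorm(max, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Sample a patient cohort from a world
#'
#' @param world a \code{synthetic_world} or \code{discrete_world}.
#' @param n number of records (>= 0).
#' @param seed integer seed; the same (world, n, seed) yields a
#'   bit-identical cohort.
#' @return data.frame in the patient CSV schema, with expert labels; for
#'   discrete worlds an extra \code{context} column records the template
#'   index.
#' @export
sample_cohort <- function(world, n, seed = 1L) UseMethod("sample_cohort")

#' @export
sample_cohort.synthetic_world <- function(world, n, seed = 1L) {
  if (n < 0) af_error("aflearn_validation", "n must be >= 0")
  with_seed(seed, {
    cohort <- data.frame(
      patient_id = if (n > 0) sprintf("P%05d", seq_len(n)) else character(0),
      age = rtruncnorm(n, world$age$mean, world$age$sd,
                       world$age$min, world$age$max),
      af_duration_months = rlnorm(n, world$af_duration$meanlog,
                                  world$af_duration$sdlog),
      heart_failure = rbinom(n, 1, world$p_hf),
      la_enlargement = rbinom(n, 1, world$p_lae),
      resting_hr = rtruncnorm(n, world$resting_hr$mean, world$resting_hr$sd,
                              world$resting_hr$min, world$resting_hr$max),
      hypertension = rbinom(n, 1, world$p_htn),
      bmi = rtruncnorm(n, world$bmi$mean, world$bmi$sd,
                       world$bmi$min, world$bmi$max),
      symptomatic = rbinom(n, 1, world$p_sympt),
      stringsAsFactors = FALSE)
    if (n > 0) {
      X <- encode_cohort(cohort, world$ref_scaler)
      S <- X %*% t(world$expert_weights)
      cohort$expert_action <- if (world$expert_mode == "argmax") {
        AF_ACTIONS[max.col(S, ties.method = "first")]
      } else {
        vapply(seq_len(n), function(i) {
          sample(AF_ACTIONS, 1, prob = softmax(S[i, ]))
        }, character(1))
      }
    } else {
      cohort$expert_action <- character(0)
    }
    validate_cohort(cohort)
  })
}

# n x 3 matrix of outcome probabilities for encoded contexts X and action
# indices a (vectorized core shared by sampling and Monte-Carlo evaluation)
outcome_probs_synthetic <- function(world, X, a) {
  sapply(OUTCOME_FLAGS, function(o) {
    m <- world$outcome_model[[o]]
    plogis(drop(X %*% m$feat) + m$action[a])
  })
}

#' Sample follow-up outcomes for one treated patient
#'
#' @param world a world object.
#' @param record validated patient record (for discrete worlds it must
#'   carry its \code{context} index).
#' @param action action code actually taken.
#' @param seed integer seed.
#' @return Named list of 0/1 flags \code{stroke}, \code{hospitalization},
#'   \code{symptomatic_recurrence}.
#' @export
sample_outcomes <- function(world, record, action, seed = 1L)
  UseMethod("sample_outcomes")

#' @export
sample_outcomes.synthetic_world <- function(world, record, action, seed = 1L) {
  record <- validate_record(record)
  x <- encode_features(record, world$ref_scaler)
  p <- outcome_probs_synthetic(world, matrix(x, 1), action_index(action))
  with_seed(seed, {
    flags <- rbinom(3, 1, as.numeric(p))
  })
  stats::setNames(as.list(flags), OUTCOME_FLAGS)
}

# vectorized outcome sampling used by simulation helpers; draws from the
# current RNG stream (callers seed it)
draw_outcomes_matrix <- function(world, cohort, actions_taken) {
  a <- action_index(actions_taken)
  P <- if (inherits(world, "discrete_world")) {
    k <- cohort$context
    cbind(stroke = world$stroke_rates[cbind(k, a)],
          hospitalization = world$hosp_rates[cbind(k, a)],
          symptomatic_recurrence = world$recurrence_rates[cbind(k, a)])
  } else {
    outcome_probs_synthetic(world, encode_cohort(cohort, world$ref_scaler), a)
  }
  O <- matrix(rbinom(length(P), 1, P), nrow(P), 3,
              dimnames = list(NULL, OUTCOME_FLAGS))
  as.data.frame(O)
}

#' The initialization cohort
#'
#' Draws the 100-record labelled cohort that seeds the supervised stage,
#' mirroring the chart-review initialization of the deployed tool.
#'
#' @param seed integer seed.
#' @param world world to draw from (default \code{synthetic_world()}).
#' @return data.frame of exactly 100 validated, labelled records.
#' @export
make_initialization_cohort <- function(seed = 1L, world = synthetic_world()) {
  sample_cohort(world, 100L, seed = seed)
}

# ---- discrete worlds -------------------------------------------------------

#' Discrete (tabulated) bandit world
#'
#' K fixed patient templates sampled with given probabilities; each
#' (context, action) has tabulated Bernoulli rates for the three outcomes,
#' so expected rewards -- and the optimal policy -- are exact.
#'
#' @param templates data.frame of K validated records (the contexts).
#' @param probs sampling probabilities over contexts (default uniform).
#' @param stroke_rates,hosp_rates,recurrence_rates K x 4 matrices of
#'   Bernoulli rates, columns in action order.
#' @param expert_actions length-K character vector: the deterministic
#'   expert's choice per context.
#' @return Object of class \code{c("discrete_world", "af_world")}.
#' @export
discrete_world <- function(templates, probs = NULL, stroke_rates, hosp_rates,
                           recurrence_rates, expert_actions) {
  K <- nrow(templates)
  validate_cohort(templates)
  if (is.null(probs)) probs <- rep(1 / K, K)
  if (length(probs) != K || any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    af_error("aflearn_validation", "probs must be a length-K distribution")
  for (M in list(stroke_rates, hosp_rates, recurrence_rates)) {
    if (!all(dim(M) == c(K, length(AF_ACTIONS))) ||
        any(M < 0) || any(M > 1))
      af_error("aflearn_validation",
               "rate tables must be K x 4 with entries in [0, 1]")
  }
  action_index(expert_actions)
  if (length(expert_actions) != K)
    af_error("aflearn_validation", "need one expert action per context")
  dn <- list(NULL, AF_ACTIONS)
  structure(list(templates = templates, probs = probs,
                 stroke_rates = `dimnames<-`(stroke_rates, dn),
                 hosp_rates = `dimnames<-`(hosp_rates, dn),
                 recurrence_rates = `dimnames<-`(recurrence_rates, dn),
                 expert_actions = expert_actions),
            class = c("discrete_world", "af_world"))
}

#' @export
sample_cohort.discrete_world <- function(world, n, seed = 1L) {
  if (n < 0) af_error("aflearn_validation", "n must be >= 0")
  with_seed(seed, {
    k <- sample.int(nrow(world$templates), n, replace = TRUE,
                    prob = world$probs)
    cohort <- world$templates[k, , drop = FALSE]
    rownames(cohort) <- NULL
    cohort$patient_id <- if (n > 0) sprintf("P%05d", seq_len(n)) else character(0)
    cohort$expert_action <- world$expert_actions[k]
    cohort$context <- k
    cohort
  })
}

#' @export
sample_outcomes.discrete_world <- function(world, record, action, seed = 1L) {
  k <- record$context
  if (is.null(k))
    af_error("aflearn_validation",
             "discrete-world records must carry their context index")
  a <- action_index(action)
  with_seed(seed, {
    flags <- rbinom(3, 1, c(world$stroke_rates[k, a], world$hosp_rates[k, a],
                            world$recurrence_rates[k, a]))
  })
  stats::setNames(as.list(flags), OUTCOME_FLAGS)
}

#' Exact expected reward of (context, action) in a discrete world
#'
#' @param world a \code{discrete_world}.
#' @param context context index 1..K.
#' @param action action code.
#' @param spec a \code{\link{reward_spec}}.
#' @param method \code{"linearity"} (spec-weighted sum of the three
#'   Bernoulli rates) or \code{"enumeration"} (sum over the 8 outcome
#'   combinations); the two agree to machine precision and serve as
#'   mutual checks.
#' @return Scalar expected reward.
#' @export
expected_reward <- function(world, context, action, spec = reward_spec(),
                            method = c("linearity", "enumeration")) {
  method <- match.arg(method)
  if (!inherits(world, "discrete_world"))
    af_error("aflearn_continuous_world",
             "exact expected reward needs a discrete world; use policy_value() Monte-Carlo for continuous worlds")
  a <- action_index(action)
  p <- c(world$stroke_rates[context, a], world$hosp_rates[context, a],
         world$recurrence_rates[context, a])
  w <- spec$weights
  if (method == "linearity") return(sum(w * p))
  total <- 0
  for (s in 0:1) for (h in 0:1) for (r in 0:1) {
    flags <- c(s, h, r)
    prob <- prod(ifelse(flags == 1, p, 1 - p))
    total <- total + prob * sum(w * flags)
  }
  total
}

#' Exact per-context optimal actions of a discrete world
#'
#' @param world a \code{discrete_world}.
#' @param spec a \code{\link{reward_spec}}.
#' @return Character vector of length K (ties broken by lowest action
#'   index).
#' @export
optimal_policy <- function(world, spec = reward_spec()) {
  K <- nrow(world$templates)
  vapply(seq_len(K), function(k) {
    er <- vapply(AF_ACTIONS, function(a) expected_reward(world, k, a, spec),
                 numeric(1))
    AF_ACTIONS[which.max(er)]
  }, character(1))
}

#' The shipped suboptimal-expert fixture world
#'
#' Four clinically themed contexts with tabulated outcome rates.  The
#' deterministic expert is optimal in contexts 1, 2 and 4 but prescribes
#' antiarrhythmic medication in context 3 (younger, symptomatic,
#' long-standing AF) where ablation is substantially better -- the gap a
#' trained outcome-driven policy must find.  Doubles as the 4-context x
#' 4-action tabulated bandit used for Q-convergence checks.
#'
#' @return A \code{discrete_world}.
#' @export
world_suboptimal_expert <- function() {
  templates <- data.frame(
    age = c(82, 58, 49, 67),
    af_duration_months = c(48, 2, 36, 24),
    heart_failure = c(0, 0, 0, 1),
    la_enlargement = c(1, 0, 0, 1),
    resting_hr = c(72, 110, 95, 88),
    hypertension = c(1, 0, 1, 1),
    bmi = c(27, 31, 29, 33),
    symptomatic = c(0, 1, 1, 1))
  #                      RAC   EXC   AAM   AFA
  stroke <- rbind(c(0.05, 0.10, 0.08, 0.07),
                  c(0.04, 0.03, 0.04, 0.05),
                  c(0.03, 0.04, 0.04, 0.02),
                  c(0.06, 0.07, 0.05, 0.06))
  hosp   <- rbind(c(0.10, 0.30, 0.25, 0.20),
                  c(0.30, 0.15, 0.20, 0.25),
                  c(0.25, 0.25, 0.30, 0.10),
                  c(0.35, 0.40, 0.25, 0.30))
  recur  <- rbind(c(0.10, 0.40, 0.35, 0.25),
                  c(0.60, 0.20, 0.30, 0.25),
                  c(0.55, 0.45, 0.40, 0.15),
                  c(0.50, 0.45, 0.30, 0.35))
  discrete_world(templates, stroke_rates = stroke, hosp_rates = hosp,
                 recurrence_rates = recur,
                 expert_actions = c("RAC", "EXC", "AAM", "AAM"))
}

#' The tabulated-bandit oracle fixture
#'
#' Four contexts by four actions with small Bernoulli outcome rates and a
#' distinct optimal action per context (RAC, EXC, AFA, AAM).  Event rates
#' are deliberately low (a short, low-event follow-up window) so the
#' fixed-step learner's stochastic noise floor sits well inside the
#' convergence tolerance used against the enumeration oracle; the
#' optimal-vs-runner-up reward gap (about 0.06) stays an order of
#' magnitude above that floor.  The expert here equals the optimal
#' policy; use \code{\link{world_suboptimal_expert}} to exercise policy
#' improvement.
#'
#' @return A \code{discrete_world}.
#' @export
world_tabulated_bandit <- function() {
  # orthogonal +/- (Hadamard) layout of the continuous features and
  # constant binaries: minimizes and equalizes the encoded context norm,
  # so the fixed-step learner is perfectly conditioned and its noise
  # floor is as small as the stated constants allow
  templates <- data.frame(
    age = c(72, 56, 72, 56),
    af_duration_months = c(36, 36, 10, 10),
    heart_failure = 0,
    la_enlargement = 0,
    resting_hr = c(100, 76, 76, 100),
    hypertension = 0,
    bmi = c(32, 26, 26, 32),
    symptomatic = 0)
  opt <- c(1L, 2L, 4L, 3L)     # RAC, EXC, AFA, AAM
  s <- matrix(0.002, 4, 4)
  h <- matrix(0, 4, 4)
  r <- matrix(0, 4, 4)
  for (k in 1:4) for (a in 1:4) {
    if (a == opt[k]) { s[k, a] <- 0.001; h[k, a] <- 0.003; r[k, a] <- 0.004 }
    else             { h[k, a] <- 0.012 + 0.002 * a; r[k, a] <- 0.060 + 0.003 * a }
  }
  discrete_world(templates, stroke_rates = s, hosp_rates = h,
                 recurrence_rates = r, expert_actions = AF_ACTIONS[opt])
}

# ---- experience generation -------------------------------------------------

#' Simulate treatment experiences from a world
#'
#' Samples patients, chooses actions under a behavior policy, draws
#' outcomes and converts them to rewards -- the stream consumed by
#' \code{\link{rl_train}}.
#'
#' @param world a world object.
#' @param n number of experiences (ignored for \code{"balanced"}).
#' @param scaler \code{feature_scaler} used to encode contexts for the
#'   learner.
#' @param seed integer seed.
#' @param behavior \code{"uniform"} (uniformly random actions),
#'   \code{"expert"} (the world's expert labels),
#'   \code{"epsilon_greedy"} (requires \code{model}), or
#'   \code{"balanced"} (discrete worlds only: exactly
#'   \code{per_pair} experiences for every (context, action) pair, in
#'   shuffled order).
#' @param model \code{q_policy} model for epsilon-greedy behavior.
#' @param epsilon exploration rate for epsilon-greedy (default 0.1).
#' @param per_pair experiences per (context, action) pair for
#'   \code{"balanced"}.
#' @param spec a \code{\link{reward_spec}}.
#' @return An \code{\link{experience_set}}.
#' @export
generate_experiences <- function(world, n, scaler, seed = 1L,
                                 behavior = c("uniform", "expert",
                                              "epsilon_greedy", "balanced"),
                                 model = NULL, epsilon = 0.1,
                                 per_pair = 1000L, spec = reward_spec()) {
  behavior <- match.arg(behavior)
  if (behavior == "balanced") {
    if (!inherits(world, "discrete_world"))
      af_error("aflearn_continuous_world",
               "balanced behavior requires a discrete world")
    K <- nrow(world$templates)
    grid <- expand.grid(context = seq_len(K),
                        action = seq_along(AF_ACTIONS))
    k <- rep(grid$context, each = per_pair)
    a <- rep(grid$action, each = per_pair)
    return(with_seed(seed, {
      ord <- sample.int(length(k))
      k <- k[ord]; a <- a[ord]
      cohort <- world$templates[k, , drop = FALSE]
      cohort$context <- k
      O <- draw_outcomes_matrix(world, cohort, AF_ACTIONS[a])
      experience_set(encode_cohort(cohort, scaler), a,
                     compute_reward(O, spec))
    }))
  }
  with_seed(seed, {
    cohort <- sample_cohort(world, n, seed = sample.int(2^31 - 1, 1))
    acts <- switch(behavior,
      uniform = sample(AF_ACTIONS, n, replace = TRUE),
      expert = cohort$expert_action,
      epsilon_greedy = {
        if (is.null(model))
          af_error("aflearn_validation",
                   "epsilon_greedy behavior needs a q_policy model")
        Xm <- encode_cohort(cohort, model$scaler)
        vapply(seq_len(n), function(i) {
          if (runif(1) < epsilon) sample(AF_ACTIONS, 1)
          else AF_ACTIONS[which.max(drop(model$weights %*% Xm[i, ]))]
        }, character(1))
      })
    O <- draw_outcomes_matrix(world, cohort, acts)
    experience_set(encode_cohort(cohort, scaler), acts,
                   compute_reward(O, spec))
  })
}

# ---- world serialization ---------------------------------------------------

#' Serialize a world to JSON
#'
#' @param world a world object.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
world_to_json <- function(world, path = NULL) {
  kind <- if (inherits(world, "discrete_world")) "discrete" else "synthetic"
  payload <- unclass(world)
  if (kind == "synthetic") payload$ref_scaler <- unclass(payload$ref_scaler)
  js <- jsonlite::toJSON(list(format_version = "1.0", kind = kind,
                              world = payload),
                         auto_unbox = TRUE, digits = I(17), dataframe = "columns")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Load a world from JSON
#'
#' @param path file produced by \code{\link{world_to_json}}.
#' @return A world object.
#' @export
world_from_json <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e)
                    af_error("aflearn_corrupt_file",
                             sprintf("cannot parse world file: %s",
                                     conditionMessage(e))))
  if (!identical(obj$format_version, "1.0"))
    af_error("aflearn_version_mismatch",
             sprintf("unsupported world format_version: %s",
                     obj$format_version %||% "<missing>"))
  w <- obj$world
  if (identical(obj$kind, "discrete")) {
    discrete_world(as.data.frame(w$templates), probs = w$probs,
                   stroke_rates = as.matrix(w$stroke_rates),
                   hosp_rates = as.matrix(w$hosp_rates),
                   recurrence_rates = as.matrix(w$recurrence_rates),
                   expert_actions = w$expert_actions)
  } else {
    om <- lapply(w$outcome_model, function(m)
      list(feat = stats::setNames(unlist(m$feat), FEATURE_ORDER),
           action = stats::setNames(unlist(m$action), AF_ACTIONS)))
    EW <- new_weight_matrix()
    EW[, ] <- as.matrix(w$expert_weights)
    synthetic_world(age = w$age, af_duration = w$af_duration,
                    resting_hr = w$resting_hr, bmi = w$bmi,
                    p_hf = w$p_hf, p_lae = w$p_lae, p_htn = w$p_htn,
                    p_sympt = w$p_sympt,
                    expert_weights = EW, outcome_model = om,
                    expert_mode = w$expert_mode)
  }
}

#' Look up a named world fixture
#'
#' @param name \code{"default"} (continuous, softmax expert),
#'   \code{"default_argmax"} (continuous, deterministic expert),
#'   \code{"suboptimal_expert"} or \code{"tabulated_bandit"} (the discrete
#'   fixtures); otherwise treated as a path to a world JSON file.
#' @return A world object.
#' @export
get_world <- function(name) {
  switch(name,
         default = synthetic_world(),
         default_argmax = synthetic_world(expert_mode = "argmax"),
         suboptimal_expert = world_suboptimal_expert(),
         tabulated_bandit = world_tabulated_bandit(),
         {
           if (!file.exists(name))
             af_error("aflearn_validation",
                      sprintf("unknown world '%s' (and no such file)", name))
           world_from_json(name)
         })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
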