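# Domain types shared by every stage: the 4-action space, patient-record
# validation, feature encoding, and the outcome reward.

# Fixed action order; index 1..4 is the canonical order everywhere
# (weight-matrix rows, tie-breaks, serialized files).
AF_ACTIONS <- c("RAC", "EXC", "AAM", "AFA")

AF_ACTION_LABELS <- c(
  RAC = "rate control",
  EXC = "external cardioversion",
  AAM = "antiarrhythmic medication",
  AFA = "AF ablation"
)

CONT_FEATURES <- c("age", "af_duration_months", "resting_hr", "bmi")
BIN_FEATURES  <- c("heart_failure", "la_enlargement", "hypertension", "symptomatic")
FEATURE_ORDER <- c("intercept", CONT_FEATURES, BIN_FEATURES)
OUTCOME_FLAGS <- c("stroke", "hospitalization", "symptomatic_recurrence")

# Plausible clinical ranges; values outside are treated as data errors,
# never silently clipped or imputed.
FEATURE_RANGES <- list(
  age                = c(30, 100),
  af_duration_months = c(0, Inf),
  resting_hr         = c(30, 220),
  bmi                = c(12, 70)
)

#' The action space
#'
#' @return Character vector of the four strategy codes in canonical order:
#'   RAC (rate control), EXC (external cardioversion), AAM (antiarrhythmic
#'   medication), AFA (AF ablation).  This order fixes weight-matrix rows
#'   and the lowest-index tie-break used throughout.
#' @export
actions <- function() AF_ACTIONS

#' Map an action code to its canonical index
#'
#' @param action character vector of codes among \code{actions()}.
#' @return Integer index 1--4 in the fixed order RAC, EXC, AAM, AFA.
#' @export
action_index <- function(action) {
  idx <- match(action, AF_ACTIONS)
  if (anyNA(idx)) {
    af_error("aflearn_invalid_action",
             sprintf("unknown action code(s): %s",
                     paste(unique(action[is.na(idx)]), collapse = ", ")))
  }
  idx
}

# structured conditions so callers/tests can catch by class
af_error <- function(class, message, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "aflearn_error"),
                      call = call))
}

# evaluate `code` under a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Validate a single patient record
#'
#' Checks that all 8 clinical features are present, non-missing and within
#' range.  Missing features are a hard error -- a decision-support tool must
#' not guess clinical inputs.
#'
#' @param record named list (or single-row data.frame) with the 8 features:
#'   \code{age} (years, 30--100), \code{af_duration_months} (>= 0),
#'   \code{resting_hr} (beats/min, 30--220), \code{bmi} (kg/m2, 12--70),
#'   and binary \code{heart_failure}, \code{la_enlargement},
#'   \code{hypertension}, \code{symptomatic} (each 0/1).  May also carry
#'   \code{expert_action} and outcome flags.
#' @return The record as a named list, unchanged (idempotent).
#' @export
validate_record <- function(record) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1L)
      af_error("aflearn_validation", "expected a single-row record")
    record <- as.list(record)
  }
  if (!is.list(record))
    af_error("aflearn_validation", "record must be a named list")
  for (f in c(CONT_FEATURES, BIN_FEATURES)) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v))
      af_error("aflearn_missing_field",
               sprintf("missing or NA clinical feature: '%s'", f))
    if (!is.numeric(v))
      af_error("aflearn_validation",
               sprintf("feature '%s' must be numeric", f))
  }
  for (f in CONT_FEATURES) {
    rng <- FEATURE_RANGES[[f]]
    v <- record[[f]]
    if (v < rng[1] || v > rng[2])
      af_error("aflearn_out_of_range",
               sprintf("feature '%s' = %g outside allowed range [%g, %g]",
                       f, v, rng[1], rng[2]))
  }
  for (f in BIN_FEATURES) {
    if (!record[[f]] %in% c(0, 1))
      af_error("aflearn_out_of_range",
               sprintf("binary feature '%s' must be 0 or 1 (got %g)",
                       f, record[[f]]))
  }
  if (!is.null(record$expert_action) && !is.na(record$expert_action))
    action_index(record$expert_action)
  record
}

#' Validate a cohort data frame
#'
#' @param cohort data.frame with one row per patient, columns as in
#'   \code{\link{validate_record}}.
#' @return The cohort, unchanged.  Errors name the offending row.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort))
    af_error("aflearn_validation", "cohort must be a data.frame")
  for (i in seq_len(nrow(cohort))) {
    tryCatch(validate_record(as.list(cohort[i, , drop = FALSE])),
             aflearn_error = function(e) {
               af_error(class(e)[1],
                        sprintf("row %d: %s", i, conditionMessage(e)))
             })
  }
  cohort
}

#' Fit the continuous-feature scaler
#'
#' Computes training-cohort mean and sample (n-1) standard deviation of the
#' 4 continuous features (age, AF duration, resting HR, BMI).  The fitted
#' scaler travels with every model so encodings stay consistent.
#'
#' @param cohort nonempty data.frame of validated patient records.
#' @return Object of class \code{feature_scaler} with \code{$means} and
#'   \code{$sds} named over the continuous features.
#' @export
fit_scaler <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    af_error("aflearn_empty_cohort", "cannot fit a scaler on an empty cohort")
  validate_cohort(cohort[, c(CONT_FEATURES, BIN_FEATURES)])
  means <- vapply(CONT_FEATURES, function(f) mean(cohort[[f]]), numeric(1))
  sds   <- vapply(CONT_FEATURES, function(f) sd(cohort[[f]]),   numeric(1))
  bad <- is.na(sds) | sds <= 0
  if (any(bad))
    af_error("aflearn_zero_variance",
             sprintf("zero-variance continuous feature(s): %s",
                     paste(CONT_FEATURES[bad], collapse = ", ")))
  structure(list(means = means, sds = sds), class = "feature_scaler")
}

#' @export
print.feature_scaler <- function(x, ...) {
  cat("<feature_scaler>\n")
  print(rbind(mean = x$means, sd = x$sds))
  invisible(x)
}

#' Encode a patient record as a model feature vector
#'
#' Layout is frozen: intercept (1), then z-scored age, AF duration,
#' resting HR, BMI, then the four 0/1 flags (heart failure, LA enlargement,
#' hypertension, symptomatic).
#'
#' @param record validated patient record.
#' @param scaler fitted \code{feature_scaler}.
#' @return Named numeric vector of length 9.
#' @export
encode_features <- function(record, scaler) {
  record <- validate_record(record)
  stopifnot(inherits(scaler, "feature_scaler"))
  cont <- (vapply(CONT_FEATURES, function(f) as.numeric(record[[f]]),
                  numeric(1)) - scaler$means) / scaler$sds
  x <- c(intercept = 1, cont,
         vapply(BIN_FEATURES, function(f) as.numeric(record[[f]]),
                numeric(1)))
  names(x) <- FEATURE_ORDER
  x
}

#' Encode a cohort as an n x 9 design matrix
#'
#' @param cohort validated cohort data.frame.
#' @param scaler fitted \code{feature_scaler}.
#' @return Numeric matrix, one row per record, columns in the frozen
#'   feature order.
#' @export
encode_cohort <- function(cohort, scaler) {
  stopifnot(inherits(scaler, "feature_scaler"))
  validate_cohort(cohort)
  n <- nrow(cohort)
  X <- matrix(0, n, length(FEATURE_ORDER),
              dimnames = list(NULL, FEATURE_ORDER))
  X[, "intercept"] <- 1
  for (f in CONT_FEATURES)
    X[, f] <- (cohort[[f]] - scaler$means[[f]]) / scaler$sds[[f]]
  for (f in BIN_FEATURES)
    X[, f] <- as.numeric(cohort[[f]])
  X
}

#' Reward specification
#'
#' Weights of the composite follow-up outcome.  Defaults encode the fixed
#' clinical reward \eqn{-2\cdot stroke - hospitalization - recurrence}:
#' stroke, as the most severe event, is penalized twice as heavily.
#'
#' @param stroke_weight,hospitalization_weight,recurrence_weight
#'   non-positive reals.
#' @return Object of class \code{reward_spec}.
#' @export
reward_spec <- function(stroke_weight = -2, hospitalization_weight = -1,
                        recurrence_weight = -1) {
  w <- c(stroke = stroke_weight, hospitalization = hospitalization_weight,
         symptomatic_recurrence = recurrence_weight)
  if (any(!is.finite(w)) || any(w > 0))
    af_error("aflearn_validation", "reward weights must be finite and <= 0")
  structure(list(weights = w), class = "reward_spec")
}

validate_outcomes <- function(outcomes) {
  if (is.data.frame(outcomes)) outcomes <- as.list(outcomes)
  for (f in OUTCOME_FLAGS) {
    v <- outcomes[[f]]
    if (is.null(v) || anyNA(v))
      af_error("aflearn_missing_field",
               sprintf("missing outcome flag: '%s'", f))
    if (!all(v %in% c(0, 1)))
      af_error("aflearn_out_of_range",
               sprintf("outcome flag '%s' must be 0 or 1", f))
  }
  outcomes
}

#' Compute the scalar reward of a follow-up episode
#'
#' With the default \code{\link{reward_spec}} this is
#' \eqn{-2\cdot stroke - hospitalization - recurrence}, bounded in
#' \eqn{[-4, 0]}.  Vectorized over equal-length outcome flags.
#'
#' @param outcomes named list/data.frame with 0/1 flags \code{stroke},
#'   \code{hospitalization}, \code{symptomatic_recurrence}.
#' @param spec a \code{\link{reward_spec}}.
#' @return Numeric reward(s).
#' @export
compute_reward <- function(outcomes, spec = reward_spec()) {
  stopifnot(inherits(spec, "reward_spec"))
  outcomes <- validate_outcomes(outcomes)
  w <- spec$weights
  w[["stroke"]] * outcomes$stroke +
    w[["hospitalization"]] * outcomes$hospitalization +
    w[["symptomatic_recurrence"]] * outcomes$symptomatic_recurrence
}
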