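# The two-stage decision surface: a convex blend of the mimicry
# frequencies and a softmax over the Q-values, with blend weight beta
# rising linearly in accumulated outcome experience.  At beta = 0 the
# recommendation is pure expert mimicry; at beta = 1 it is pure value
# maximization (and concentrates on the greedy action as the softmax
# temperature goes to zero).

#' Blend schedule from mimicry to value maximization
#'
#' @param switch_count number of outcome experiences at which the blend
#'   reaches pure RL (default 500; the linear form and default are package
#'   design choices, documented in the methods vignette).
#' @param temperature softmax temperature converting Q-values to a
#'   frequency distribution (default 1).
#' @return Object of class \code{blend_schedule}.
#' @export
blend_schedule <- function(switch_count = 500L, temperature = 1) {
  if (switch_count < 1) af_error("aflearn_validation", "switch_count must be >= 1")
  if (!is.finite(temperature) || temperature <= 0)
    af_error("aflearn_validation", "temperature must be > 0")
  structure(list(switch_count = as.integer(switch_count),
                 temperature = temperature),
            class = "blend_schedule")
}

#' Blend weight at a given experience count
#'
#' @param n_rl_experiences non-negative count of outcome experiences the Q
#'   model has been trained on.
#' @param schedule a \code{\link{blend_schedule}}.
#' @return \code{min(1, n / switch_count)}, in [0, 1] and nondecreasing
#'   in \code{n}.
#' @export
blend_weight <- function(n_rl_experiences, schedule = blend_schedule()) {
  stopifnot(inherits(schedule, "blend_schedule"))
  if (n_rl_experiences < 0)
    af_error("aflearn_validation", "n_rl_experiences must be >= 0")
  min(1, n_rl_experiences / schedule$switch_count)
}

scalers_match <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 0))
}

#' Recommend a rhythm-management strategy for one patient
#'
#' Computes frequencies
#' \eqn{(1-\beta)\,p_{SL} + \beta\,\mathrm{softmax}(Q/\tau)} -- a convex
#' combination of two distributions, hence itself a distribution -- and
#' reports the top strategy with the lowest-index tie-break.
#'
#' @param sl trained \code{sl_policy} model.
#' @param q \code{q_policy} model; must share the supervised model's
#'   scaler.
#' @param record validated patient record.
#' @param schedule a \code{\link{blend_schedule}}.
#' @param n_rl_experiences experience count driving beta; defaults to the
#'   Q model's own \code{experiences_seen} counter.
#' @return Object of class \code{af_recommendation}: \code{$frequencies}
#'   (4 values summing to 1), \code{$best_action}, \code{$beta},
#'   \code{$sl_model_id}, \code{$q_model_id}.
#' @export
recommend <- function(sl, q, record, schedule = blend_schedule(),
                      n_rl_experiences = q$experiences_seen) {
  stopifnot(inherits(sl, "sl_policy"), inherits(q, "q_policy"))
  if (!scalers_match(sl$scaler, q$scaler))
    af_error("aflearn_scaler_mismatch",
             "SL and Q models were fitted with different feature scalers")
  record <- validate_record(record)
  x <- encode_features(record, sl$scaler)
  beta <- blend_weight(n_rl_experiences, schedule)
  p_sl <- sl_predict(sl, x)
  p_rl <- softmax(q_predict(q, x) / schedule$temperature)
  freq <- (1 - beta) * p_sl + beta * p_rl
  names(freq) <- AF_ACTIONS
  structure(list(frequencies = freq,
                 best_action = AF_ACTIONS[which.max(freq)],
                 beta = beta,
                 sl_model_id = sl$id, q_model_id = q$id),
            class = "af_recommendation")
}

#' Render a recommendation as a plain-text report
#'
#' Percentages are rounded half-even to one decimal for display; rounding
#' never changes which action is reported as recommended.  Use
#' \code{\link{recommendation_json}} for the full-precision machine form.
#'
#' @param rec an \code{af_recommendation}.
#' @return Character vector of report lines.
#' @export
format_recommendation <- function(rec) {
  stopifnot(inherits(rec, "af_recommendation"))
  pct <- sprintf("%.1f%%", round(100 * rec$frequencies, 1))
  lines <- c(
    sprintf("Recommended strategy: %s (%s)", rec$best_action,
            AF_ACTION_LABELS[[rec$best_action]]),
    sprintf("  %s  %6s%s", names(rec$frequencies), pct,
            ifelse(names(rec$frequencies) == rec$best_action,
                   "  <- recommended", "")),
    sprintf("  [blend beta = %.3f; sl = %s; q = %s]", rec$beta,
            rec$sl_model_id, rec$q_model_id)
  )
  lines
}

#' @export
print.af_recommendation <- function(x, ...) {
  cat(format_recommendation(x), sep = "\n")
  invisible(x)
}

#' Full-precision JSON rendering of a recommendation
#'
#' @param rec an \code{af_recommendation}.
#' @return JSON string; round-trips losslessly.
#' @export
recommendation_json <- function(rec) {
  stopifnot(inherits(rec, "af_recommendation"))
  jsonlite::toJSON(list(frequencies = as.list(rec$frequencies),
                        best_action = rec$best_action,
                        beta = rec$beta,
                        sl_model_id = rec$sl_model_id,
                        q_model_id = rec$q_model_id),
                   auto_unbox = TRUE, digits = I(17))
}
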