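# File I/O: the patient CSV schema, the experience log, and full-precision
# JSON model serialization.  One CSV dialect only: comma separator, UTF-8,
# required header, "." decimal.  Doubles are written with 17 significant
# digits so save -> load reproduces weights bit-exactly.

COHORT_COLUMNS <- c("patient_id", "age", "af_duration_months", "heart_failure",
                    "la_enlargement", "resting_hr", "hypertension", "bmi",
                    "symptomatic", "expert_action", "stroke", "hospitalization",
                    "symptomatic_recurrence")

MODEL_FORMAT_VERSION <- "1.0"

parse_numeric_col <- function(v, col, allow_empty = FALSE) {
  v <- as.character(v)
  empty <- is.na(v) | v == ""
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!empty & is.na(out))
  if (length(bad))
    af_error("aflearn_parse",
             sprintf("row %d, column '%s': cannot parse '%s' as a number",
                     bad[1], col, v[bad[1]]))
  if (!allow_empty && any(empty))
    af_error("aflearn_parse",
             sprintf("row %d, column '%s': value missing",
                     which(empty)[1], col))
  out
}

parse_binary_col <- function(v, col, allow_empty = FALSE) {
  out <- parse_numeric_col(v, col, allow_empty = allow_empty)
  bad <- which(!is.na(out) & !out %in% c(0, 1))
  if (length(bad))
    af_error("aflearn_parse",
             sprintf("row %d, column '%s': expected 0 or 1, got '%s'",
                     bad[1], col, v[bad[1]]))
  out
}

#' Read a patient cohort CSV
#'
#' Required header (any order): \code{patient_id, age, af_duration_months,
#' heart_failure, la_enlargement, resting_hr, hypertension, bmi,
#' symptomatic, expert_action, stroke, hospitalization,
#' symptomatic_recurrence}.  Labels and outcome flags may be empty; the 8
#' clinical features may not.  Errors name the offending row and column.
#'
#' @param path CSV file path.
#' @return Validated cohort data.frame in schema column order.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    af_error("aflearn_io", sprintf("no such file: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 check.names = FALSE)
  missing <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing))
    af_error("aflearn_header",
             sprintf("cohort CSV is missing column(s): %s",
                     paste(missing, collapse = ", ")))
  out <- data.frame(patient_id = as.character(df$patient_id),
                    stringsAsFactors = FALSE)
  for (f in CONT_FEATURES) out[[f]] <- parse_numeric_col(df[[f]], f)
  for (f in BIN_FEATURES)  out[[f]] <- parse_binary_col(df[[f]], f)
  ea <- as.character(df$expert_action)
  ea[is.na(ea)] <- ""
  bad <- which(ea != "" & !ea %in% AF_ACTIONS)
  if (length(bad))
    af_error("aflearn_parse",
             sprintf("row %d, column 'expert_action': unknown action '%s'",
                     bad[1], ea[bad[1]]))
  out$expert_action <- ifelse(ea == "", NA_character_, ea)
  for (f in OUTCOME_FLAGS)
    out[[f]] <- parse_binary_col(df[[f]], f, allow_empty = TRUE)
  out <- out[, COHORT_COLUMNS]
  for (i in seq_len(nrow(out))) {
    rec <- as.list(out[i, c(CONT_FEATURES, BIN_FEATURES)])
    tryCatch(validate_record(rec), aflearn_error = function(e)
      af_error(class(e)[1], sprintf("row %d: %s", i, conditionMessage(e))))
  }
  out
}

#' Write a patient cohort CSV
#'
#' @param cohort cohort data.frame (missing schema columns are emitted
#'   empty).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- data.frame(row.names = seq_len(nrow(cohort)))
  for (col in COHORT_COLUMNS) {
    v <- cohort[[col]]
    if (is.null(v)) v <- rep(NA, nrow(cohort))
    out[[col]] <- if (is.numeric(v)) sprintf_num(v) else as.character(v)
  }
  out[is.na(out)] <- ""
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# 17 significant digits: lossless for doubles, trims trailing zeros
sprintf_num <- function(v) {
  ifelse(is.na(v), NA_character_,
         vapply(v, function(z) format(z, digits = 17, scientific = FALSE,
                                      trim = TRUE),
                character(1)))
}

#' Read / write an experience log CSV
#'
#' Schema: \code{patient_id, action_taken, stroke, hospitalization,
#' symptomatic_recurrence, reward}.  Contexts live in the companion
#' cohort CSV; the two are joined on \code{patient_id}.
#'
#' @param path CSV file path.
#' @return data.frame of the log.
#' @export
read_experience_csv <- function(path) {
  if (!file.exists(path))
    af_error("aflearn_io", sprintf("no such file: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 check.names = FALSE)
  need <- c("patient_id", "action_taken", OUTCOME_FLAGS, "reward")
  missing <- setdiff(need, names(df))
  if (length(missing))
    af_error("aflearn_header",
             sprintf("experience CSV is missing column(s): %s",
                     paste(missing, collapse = ", ")))
  bad <- which(!df$action_taken %in% AF_ACTIONS)
  if (length(bad))
    af_error("aflearn_parse",
             sprintf("row %d, column 'action_taken': unknown action '%s'",
                     bad[1], df$action_taken[bad[1]]))
  out <- data.frame(patient_id = df$patient_id,
                    action_taken = df$action_taken,
                    stringsAsFactors = FALSE)
  for (f in OUTCOME_FLAGS) out[[f]] <- parse_binary_col(df[[f]], f)
  out$reward <- parse_numeric_col(df$reward, "reward")
  out
}

#' @rdname read_experience_csv
#' @param log experience-log data.frame.
#' @export
write_experience_csv <- function(log, path) {
  out <- log
  out$reward <- sprintf_num(out$reward)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Join an experience log with its cohort into a training set
#'
#' @param cohort cohort data.frame carrying the features.
#' @param log experience-log data.frame (see
#'   \code{\link{read_experience_csv}}).
#' @param scaler \code{feature_scaler} used to encode the contexts.
#' @return An \code{\link{experience_set}} in log order.
#' @export
experiences_from_log <- function(cohort, log, scaler) {
  idx <- match(log$patient_id, cohort$patient_id)
  if (anyNA(idx))
    af_error("aflearn_validation",
             sprintf("experience log row %d: patient_id '%s' not in cohort",
                     which(is.na(idx))[1], log$patient_id[which(is.na(idx))[1]]))
  experience_set(encode_cohort(cohort[idx, , drop = FALSE], scaler),
                 log$action_taken, log$reward)
}

# ---- model JSON ------------------------------------------------------------

model_payload <- function(model) {
  scaler <- list(means = as.list(model$scaler$means),
                 sds = as.list(model$scaler$sds))
  common <- list(format_version = MODEL_FORMAT_VERSION,
                 action_order = AF_ACTIONS, feature_order = FEATURE_ORDER,
                 id = model$id, scaler = scaler,
                 weights = matrix(model$weights, nrow(model$weights)))
  if (inherits(model, "sl_policy")) {
    c(list(model_type = "sl_policy", loss_mode = model$loss_mode), common)
  } else {
    c(list(model_type = "q_policy",
           updates_applied = model$updates_applied,
           experiences_seen = model$experiences_seen,
           pending = list(X = model$pending$X,
                          action = model$pending$action,
                          reward = model$pending$reward)),
      common)
  }
}

#' Save a model to JSON
#'
#' Weights and scaler statistics are written with 17 significant digits,
#' so \code{load_model(save_model(m))} reproduces them bit-exactly.
#'
#' @param model \code{sl_policy} or \code{q_policy} model.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "sl_policy") && !inherits(model, "q_policy"))
    af_error("aflearn_validation", "can only save sl_policy or q_policy models")
  writeLines(jsonlite::toJSON(model_payload(model), auto_unbox = TRUE,
                              digits = I(17), matrix = "rowmajor"),
             path)
  invisible(path)
}

#' Load a model from JSON
#'
#' @param path file produced by \code{\link{save_model}}.
#' @return The model, with predictions identical to the saved one.
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    af_error("aflearn_io", sprintf("no such file: %s", path))
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e)
                    af_error("aflearn_corrupt_file",
                             sprintf("cannot parse model file: %s",
                                     conditionMessage(e))))
  if (!identical(obj$format_version, MODEL_FORMAT_VERSION))
    af_error("aflearn_version_mismatch",
             sprintf("unsupported model format_version: %s",
                     obj$format_version %||% "<missing>"))
  if (!identical(unname(unlist(obj$feature_order)), FEATURE_ORDER) ||
      !identical(unname(unlist(obj$action_order)), AF_ACTIONS))
    af_error("aflearn_corrupt_file",
             "model file feature/action order does not match this package")
  scaler <- structure(list(means = unlist(obj$scaler$means)[CONT_FEATURES],
                           sds = unlist(obj$scaler$sds)[CONT_FEATURES]),
                      class = "feature_scaler")
  W <- new_weight_matrix()
  W[, ] <- as.matrix(obj$weights)
  if (identical(obj$model_type, "sl_policy")) {
    sl_model(scaler, loss_mode = obj$loss_mode, weights = W, id = obj$id)
  } else if (identical(obj$model_type, "q_policy")) {
    m <- q_model(scaler, weights = W, id = obj$id)
    m$updates_applied <- as.integer(obj$updates_applied)
    m$experiences_seen <- as.integer(obj$experiences_seen)
    if (length(obj$pending$action) > 0) {
      PX <- matrix(as.numeric(obj$pending$X), ncol = length(FEATURE_ORDER))
      m$pending <- experience_set(PX, as.integer(obj$pending$action),
                                  as.numeric(obj$pending$reward))
    }
    m
  } else {
    af_error("aflearn_corrupt_file",
             sprintf("unknown model_type: %s", obj$model_type %||% "<missing>"))
  }
}
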