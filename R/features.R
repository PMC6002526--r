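# The 83-feature participant vector: the seven per-trial metrics averaged
# per question type and overall, overall velocity/acceleration means,
# symptom-endorsement counts and control-error counts.

METRIC_NAMES <- c(
  it_ms = "IT", rt_ms = "RT", md_time_ms = "MD-time", md = "MD",
  auc = "AUC", x_flip = "x-flip", y_flip = "y-flip"
)
VELOCITY_NAMES <- c("v_x", "v_y", "a_x", "a_y")

#' The fixed 83-feature schema
#'
#' Enumerates, in canonical order, the feature names of the participant
#' vector: the seven spatio-temporal metrics (IT, RT, MD-time, MD, AUC,
#' x-flip, y-flip) each averaged overall and within the nine question
#' categories (70), the four overall velocity/acceleration means, the six
#' symptom-endorsement counts and the three control-error counts.
#'
#' @return A tibble `name`, `kind` (`metric`/`velocity`/`count`/`error`),
#'   `metric`, `scope`, with exactly 83 rows.
#' @export
feature_schema <- function() {
  metric_rows <- purrr::map_dfr(unname(METRIC_NAMES), function(m) {
    tibble(
      name = c(m, paste(m, CATEGORY_CODES)),
      kind = "metric",
      metric = m,
      scope = c("overall", CATEGORY_CODES)
    )
  })
  bind_rows(
    metric_rows,
    tibble(name = VELOCITY_NAMES, kind = "velocity",
           metric = VELOCITY_NAMES, scope = "overall"),
    tibble(name = SYMPTOM_CATEGORIES, kind = "count",
           metric = "symptoms", scope = SYMPTOM_CATEGORIES),
    tibble(name = CONTROL_CATEGORIES, kind = "error",
           metric = "errors", scope = CONTROL_CATEGORIES)
  )
}

check_one_response_per_question <- function(responses, stimulus_set) {
  missing <- setdiff(stimulus_set$id, responses$question_id)
  if (length(missing) > 0) {
    abort(paste0("missing response for question(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  dup <- responses$question_id[duplicated(responses$question_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicated response for question(s): ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Symptom-endorsement counts per category
#'
#' Number of "yes" responses on the symptom-bearing items of each category.
#'
#' @param responses Tibble with `question_id` and `response` for one
#'   participant.
#' @param stimulus_set Tibble from [build_stimulus_set()].
#' @return Tibble `category`, `count` over the six symptom categories.
#' @export
symptom_counts <- function(responses, stimulus_set) {
  check_one_response_per_question(responses, stimulus_set)
  joined <- stimulus_set %>%
    left_join(responses[, c("question_id", "response")],
              by = c("id" = "question_id"))
  purrr::map_dfr(SYMPTOM_CATEGORIES, function(catg) {
    rows <- joined[joined$category == catg, ]
    tibble(category = catg, count = sum(rows$response == "yes"))
  })
}

#' Control-question error counts per category
#'
#' Number of responses differing from the answer key on the control
#' categories (statements about the experimental situation, whose key does
#' not depend on clinical state).
#'
#' @inheritParams symptom_counts
#' @return Tibble `category`, `count` over the three control categories.
#' @export
control_errors <- function(responses, stimulus_set) {
  check_one_response_per_question(responses, stimulus_set)
  joined <- stimulus_set %>%
    left_join(responses[, c("question_id", "response")],
              by = c("id" = "question_id"))
  purrr::map_dfr(CONTROL_CATEGORIES, function(catg) {
    rows <- joined[joined$category == catg, ]
    tibble(category = catg, count = sum(rows$response != rows$key_healthy))
  })
}

#' Aggregate one participant's trials into the 83-feature vector
#'
#' Means of the seven spatio-temporal metrics within each question category
#' and overall, overall velocity/acceleration means, and the endorsement /
#' error counts. Trials with missing kinematics are dropped from the means
#' with a warning; counts are unaffected.
#'
#' @param trials Tibble of per-trial metrics ([trial_features()] columns
#'   plus `question_id`) for one participant.
#' @param responses Tibble with `question_id`, `response` for the same
#'   participant.
#' @param stimulus_set Tibble from [build_stimulus_set()].
#' @param participant_id,label Carried into the output row.
#' @return A one-row tibble: `participant_id`, `label`, then the 83 schema
#'   columns in schema order.
#' @export
aggregate_features <- function(trials, responses, stimulus_set,
                               participant_id = NA_character_,
                               label = NA_character_) {
  check_one_response_per_question(responses, stimulus_set)
  missing <- setdiff(stimulus_set$id, trials$question_id)
  if (length(missing) > 0) {
    warn(paste0("dropping ", length(missing),
                " question(s) without trial kinematics from the means"))
  }
  trials <- trials %>%
    left_join(stimulus_set[, c("id", "category")],
              by = c("question_id" = "id"))
  if (any(is.na(trials$category))) {
    abort("trial features reference question ids absent from the stimulus set")
  }
  present <- unique(trials$category)
  configured <- unique(stimulus_set$category)
  empty <- setdiff(configured, present)
  if (length(empty) > 0) {
    abort(paste0("no trials for configured categor(ies): ",
                 paste(empty, collapse = ", ")))
  }

  vals <- list()
  for (col in names(METRIC_NAMES)) {
    m <- METRIC_NAMES[[col]]
    vals[[m]] <- mean(trials[[col]])
    for (catg in CATEGORY_CODES) {
      rows <- trials[[col]][trials$category == catg]
      nm <- paste(m, catg)
      vals[[nm]] <- if (length(rows) > 0) mean(rows) else NA_real_
    }
  }
  for (vcol in VELOCITY_NAMES) vals[[vcol]] <- mean(trials[[vcol]])
  sc <- symptom_counts(responses, stimulus_set)
  for (i in seq_len(nrow(sc))) vals[[sc$category[i]]] <- sc$count[i]
  ce <- control_errors(responses, stimulus_set)
  for (i in seq_len(nrow(ce))) vals[[ce$category[i]]] <- ce$count[i]

  schema <- feature_schema()
  keep <- intersect(schema$name, names(vals))
  row <- as_tibble(vals[keep])
  # categories absent from the stimulus set keep an NA column so the
  # 83-name schema is stable
  for (nm in setdiff(schema$name, names(row))) row[[nm]] <- NA_real_
  dplyr::bind_cols(
    tibble(participant_id = participant_id, label = label),
    row[, schema$name]
  )
}

#' Extract the feature table of a whole cohort
#'
#' Runs the kinematic extraction on every trajectory and aggregates each
#' participant into the 83-feature vector.
#'
#' @param cohort A `mouse_cohort` from [generate_cohort()].
#' @param trial_feats Optional precomputed [extract_trial_features()]
#'   output (avoids recomputing).
#' @return A tibble with one row per participant: `participant_id`,
#'   `label`, and the 83 schema columns.
#' @export
extract_features <- function(cohort, trial_feats = NULL) {
  if (is.null(trial_feats)) trial_feats <- extract_trial_features(cohort)
  ids <- cohort$participants$participant_id
  purrr::map_dfr(ids, function(pid) {
    aggregate_features(
      trials = filter(trial_feats, .data$participant_id == pid),
      responses = filter(cohort$responses, .data$participant_id == pid),
      stimulus_set = cohort$stimulus_set,
      participant_id = pid,
      label = cohort$participants$group[
        cohort$participants$participant_id == pid
      ]
    )
  })
}

#' Write / read a participant feature table
#'
#' @param features Feature tibble from [extract_features()].
#' @param path CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` the tibble (schema order restored).
#' @export
write_feature_table <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    participant_id = "c", label = "c", .default = "d"
  ))
  schema <- feature_schema()
  out[, c("participant_id", "label", intersect(schema$name, names(out)))]
}

#' Matrix of feature values over the schema columns
#'
#' @param features Feature tibble.
#' @param subset Optional character vector of feature names.
#' @return Numeric matrix, participants x features.
#' @export
feature_matrix <- function(features, subset = NULL) {
  nm <- subset %||% intersect(feature_schema()$name, names(features))
  bad <- setdiff(nm, names(features))
  if (length(bad) > 0) {
    abort(paste0("unknown feature(s): ", paste(bad, collapse = ", ")))
  }
  m <- as.matrix(features[, nm])
  rownames(m) <- features$participant_id
  m
}
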