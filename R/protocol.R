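# Stimulus protocol: nine question categories, conjunctive answer semantics,
# and the atypical-symptom screening rule.

CATEGORY_CODES <- c(
  "EX", "DS", "VAS", "2DS-d", "2DS-c",
  "DS&EX-d", "DS&EX-c", "2EX-d", "2EX-c"
)

SYMPTOM_CATEGORIES <- c("DS", "2DS-d", "2DS-c", "DS&EX-d", "DS&EX-c", "VAS")
CONTROL_CATEGORIES <- c("EX", "2EX-d", "2EX-c")

# Component propositions of each category: "ex" items are true statements
# about the experimental situation, "ds" items are typical depressive
# symptoms (true only for a depressed respondent), "vas" items are very
# atypical symptoms (true for no one), "ex_false" is a false statement about
# the situation. A question's key is the conjunction of its components.
CATEGORY_COMPONENTS <- list(
  "EX"      = c("ex"),
  "DS"      = c("ds"),
  "VAS"     = c("vas"),
  "2DS-d"   = c("ds", "vas"),
  "2DS-c"   = c("ds", "ds"),
  "DS&EX-d" = c("ds", "ex_false"),
  "DS&EX-c" = c("ds", "ex"),
  "2EX-d"   = c("ex", "ex_false"),
  "2EX-c"   = c("ex", "ex")
)

component_truth <- function(component, depressed) {
  switch(component,
    ex = TRUE,
    ex_false = FALSE,
    vas = FALSE,
    ds = depressed,
    abort(paste0("unknown question component '", component, "'"))
  )
}

category_key <- function(code, depressed) {
  comps <- CATEGORY_COMPONENTS[[code]]
  if (is.null(comps)) {
    abort(paste0("unknown question category '", code, "'"))
  }
  all(vapply(comps, component_truth, logical(1), depressed = depressed))
}

#' Question categories of the double-choice symptom task
#'
#' The task presents nine categories of yes/no questions: simple items about
#' the experimental situation (`EX`), typical depressive symptoms (`DS`) and
#' very atypical symptoms (`VAS`), plus complex (two-proposition) items whose
#' truthful answer is "yes" only when *both* propositions are true. The
#' default item counts give a 76-question set (30 simple, 46 complex).
#'
#' @return A tibble with one row per category: `code`, `complexity`
#'   (`"simple"`/`"complex"`), `default_count`, and the truthful answer keys
#'   `key_healthy` and `key_depressed` (`"yes"`/`"no"`).
#' @examples
#' question_categories()
#' @export
question_categories <- function() {
  tibble(
    code = CATEGORY_CODES,
    complexity = ifelse(
      lengths(CATEGORY_COMPONENTS[CATEGORY_CODES]) > 1, "complex", "simple"
    ),
    default_count = unname(default_question_counts()[CATEGORY_CODES]),
    key_healthy = ifelse(
      vapply(CATEGORY_CODES, category_key, logical(1), depressed = FALSE),
      "yes", "no"
    ),
    key_depressed = ifelse(
      vapply(CATEGORY_CODES, category_key, logical(1), depressed = TRUE),
      "yes", "no"
    )
  )
}

#' Default number of items per question category
#'
#' @return A named integer vector over the nine category codes, summing
#'   to 76.
#' @export
default_question_counts <- function() {
  c(
    "EX" = 5L, "DS" = 10L, "VAS" = 15L, "2DS-d" = 15L, "2DS-c" = 15L,
    "DS&EX-d" = 5L, "DS&EX-c" = 5L, "2EX-d" = 3L, "2EX-c" = 3L
  )
}

#' Build a randomized stimulus set
#'
#' Assembles the question list for one run of the task: the requested number
#' of items per category, answer keys derived from the category's
#' conjunction semantics, and a presentation order shuffled by `seed`.
#'
#' @param counts Named integer vector of items per category code. Defaults
#'   to [default_question_counts()]. Categories omitted from the vector get
#'   zero items; unknown codes are an error.
#' @param seed Integer seed for the presentation-order shuffle.
#' @return A tibble with columns `id`, `category`, `complexity`,
#'   `key_healthy`, `key_depressed`, one row per question, in presentation
#'   order.
#' @examples
#' ss <- build_stimulus_set(seed = 7)
#' nrow(ss) # 76
#' @export
build_stimulus_set <- function(counts = default_question_counts(), seed = 1L) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort("`counts` must be a named vector of per-category item counts")
  }
  unknown <- setdiff(names(counts), CATEGORY_CODES)
  if (length(unknown) > 0) {
    abort(paste0(
      "unknown question category code(s): ",
      paste(unknown, collapse = ", ")
    ))
  }
  if (any(counts < 0)) {
    abort("per-category counts must be non-negative")
  }
  cats <- question_categories()
  rows <- purrr::map(names(counts), function(code) {
    k <- as.integer(counts[[code]])
    if (k == 0) return(NULL)
    info <- cats[cats$code == code, ]
    tibble(
      id = sprintf("%s_%02d", code, seq_len(k)),
      category = code,
      complexity = info$complexity,
      key_healthy = info$key_healthy,
      key_depressed = info$key_depressed
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      id = character(), category = character(), complexity = character(),
      key_healthy = character(), key_depressed = character()
    )
  } else {
    out <- withr::with_seed(seed, out[sample.int(nrow(out)), ])
  }
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Truthful answer key for questions
#'
#' Returns, for each question, the answer a fully truthful respondent in the
#' given clinical state would give. For complex questions this is the
#' conjunction of the component propositions: "yes" only if both are true.
#'
#' @param questions A stimulus-set tibble from [build_stimulus_set()] (or any
#'   data frame with `key_healthy`/`key_depressed` columns).
#' @param depressed Logical flag: answer as a clinically depressed
#'   respondent?
#' @return Character vector of `"yes"`/`"no"`, one per question row.
#' @export
truthful_answer <- function(questions, depressed = FALSE) {
  need <- c("key_healthy", "key_depressed")
  if (!all(need %in% names(questions))) {
    abort("`questions` must carry key_healthy and key_depressed columns")
  }
  if (isTRUE(depressed)) questions$key_depressed else questions$key_healthy
}

#' Atypical-symptom screening flag
#'
#' Screening rule of the atypical-symptom (affective-disorder) scale: a
#' respondent endorsing more than five of the very atypical symptom items is
#' flagged as a suspected malingerer.
#'
#' @param vas_count Number of atypical-symptom ("VAS") items endorsed.
#' @return Logical: `TRUE` iff `vas_count > 5`.
#' @examples
#' sims_af_flag(6) # TRUE
#' sims_af_flag(5) # FALSE
#' @export
sims_af_flag <- function(vas_count) {
  if (any(vas_count < 0)) {
    abort("`vas_count` must be non-negative")
  }
  vas_count > 5
}

#' Write / read a stimulus set as CSV
#'
#' @param stimulus_set Tibble from [build_stimulus_set()].
#' @param path File path.
#' @return `write_stimulus_set()` returns `path` invisibly;
#'   `read_stimulus_set()` returns the stimulus tibble.
#' @export
write_stimulus_set <- function(stimulus_set, path) {
  readr::write_csv(stimulus_set, path)
  invisible(path)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  as_tibble(out)
}
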