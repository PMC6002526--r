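# Correlation-based feature selection (CFS) with greedy stepwise forward
# search, plus the fixed alternative feature subsets used for
# countermeasure-resistant models.

#' Correlation between a feature and the class
#'
#' For a two-level class, the signed Pearson (point-biserial) correlation
#' with a 0/1 class indicator. For three or more levels, where no signed
#' ordering exists, the mean absolute point-biserial correlation over
#' one-vs-rest indicators.
#'
#' @param x Numeric feature values.
#' @param labels Class labels, same length.
#' @return Correlation in \[-1, 1\]; zero-variance features return 0 with
#'   attribute `zero_variance = TRUE`.
#' @export
class_correlation <- function(x, labels) {
  labels <- as.character(labels)
  keep <- complete.cases(x, labels)
  x <- x[keep]
  labels <- labels[keep]
  lv <- sort(unique(labels))
  if (length(lv) < 2) abort("need at least 2 distinct labels")
  if (sd(x) == 0) {
    out <- 0
    attr(out, "zero_variance") <- TRUE
    return(out)
  }
  if (length(lv) == 2) {
    return(cor(x, as.numeric(labels == lv[2])))
  }
  mean(vapply(lv, function(l) abs(cor(x, as.numeric(labels == l))),
              numeric(1)))
}

#' CFS merit of a feature subset
#'
#' Hall's correlation-based merit: for a subset of k features,
#' `merit = k * rcf / sqrt(k + k * (k - 1) * rff)` where `rcf` is the mean
#' absolute feature-class correlation and `rff` the mean absolute
#' feature-feature correlation. Merit grows with class relevance and
#' shrinks with redundancy.
#'
#' @param features Feature tibble (schema columns plus `label`).
#' @param subset Character vector of feature names (non-empty).
#' @param labels Class labels; defaults to `features$label`.
#' @return The merit score (scalar).
#' @export
cfs_merit <- function(features, subset, labels = features$label) {
  if (length(subset) == 0) abort("subset must be non-empty")
  bad <- setdiff(subset, names(features))
  if (length(bad) > 0) {
    abort(paste0("unknown feature(s): ", paste(bad, collapse = ", ")))
  }
  k <- length(subset)
  rcf <- mean(vapply(subset, function(nm) {
    abs(class_correlation(features[[nm]], labels))
  }, numeric(1)))
  if (k == 1) return(rcf)
  m <- as.matrix(features[, subset])
  cm <- suppressWarnings(abs(cor(m)))
  cm[!is.finite(cm)] <- 0
  rff <- mean(cm[upper.tri(cm)])
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Greedy stepwise CFS selection
#'
#' Forward selection over the feature table: starting from the empty set,
#' repeatedly add the feature that maximizes the CFS merit, stopping when
#' no addition improves it. Ties break by schema (column) order, so the
#' selection is deterministic given the table.
#'
#' @inheritParams cfs_merit
#' @param feature_names Candidate features; defaults to every schema
#'   column present.
#' @return A `cfs_result` list: `selected` (in selection order), `merit`,
#'   and `class_correlations` (named, every candidate).
#' @export
cfs_select <- function(features, labels = features$label,
                       feature_names = NULL) {
  feature_names <- feature_names %||%
    intersect(feature_schema()$name, names(features))
  if (length(feature_names) < 1) abort("need at least one candidate feature")
  cors <- vapply(feature_names, function(nm) {
    as.numeric(class_correlation(features[[nm]], labels))
  }, numeric(1))
  selected <- character(0)
  best_merit <- -Inf
  repeat {
    remaining <- setdiff(feature_names, selected)
    if (length(remaining) == 0) break
    merits <- vapply(remaining, function(nm) {
      cfs_merit(features, c(selected, nm), labels)
    }, numeric(1))
    top <- which.max(merits) # which.max takes the first (schema-order) tie
    if (merits[top] > best_merit + 1e-12) {
      selected <- c(selected, remaining[top])
      best_merit <- unname(merits[top])
    } else {
      break
    }
  }
  structure(
    list(selected = selected, merit = best_merit,
         class_correlations = cors),
    class = "cfs_result"
  )
}

#' @export
print.cfs_result <- function(x, ...) {
  cat("<cfs_result> merit ", format(x$merit, digits = 4), "; ",
      length(x$selected), " feature(s): ",
      paste(x$selected, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-feature class correlations of a CFS result
#' @param x A `cfs_result`.
#' @param ... Unused.
#' @return A tibble sorted by class correlation.
#' @method tidy cfs_result
#' @export
tidy.cfs_result <- function(x, ...) {
  tibble(
    feature = names(x$class_correlations),
    class_correlation = unname(x$class_correlations),
    selected = names(x$class_correlations) %in% x$selected
  ) %>%
    arrange(dplyr::desc(.data$class_correlation))
}

#' One-row summary of a CFS result
#' @param x A `cfs_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance cfs_result
#' @export
glance.cfs_result <- function(x, ...) {
  tibble(n_selected = length(x$selected), merit = x$merit)
}

NAMED_SUBSETS <- list(
  three_class_cfs = c(
    "DS", "2DS-c", "2DS-d", "VAS", "MD-time 2DS-d", "MD-time VAS"
  ),
  two_class_cfs = c(
    "DS", "2DS-d", "2DS-c", "VAS", "IT 2EX-d", "IT 2EX-c", "RT 2EX-c",
    "MD-time", "MD-time DS", "MD-time 2DS-d", "MD-time DS&EX-c",
    "MD-time VAS", "a_y", "y-flip DS"
  ),
  top5_correlated = c("DS", "2DS-c", "VAS", "DS&EX-c", "MD-time DS"),
  complex_DS_only = c(
    "2DS-c", "2DS-d",
    "IT 2DS-c", "IT 2DS-d", "RT 2DS-c", "RT 2DS-d",
    "MD-time 2DS-c", "MD-time 2DS-d", "MD 2DS-c", "MD 2DS-d",
    "AUC 2DS-c", "AUC 2DS-d", "x-flip 2DS-c", "x-flip 2DS-d",
    "y-flip 2DS-c", "y-flip 2DS-d"
  )
)

#' Fixed named feature subsets
#'
#' The predictor sets used by the study's models: the three-class CFS
#' selection (6 features), the two-class (liar vs depressed) CFS selection
#' (14 features), the five features most correlated with the class, and the
#' countermeasure-resistant subset restricted to complex depressive-symptom
#' questions (16 features).
#'
#' @param name One of `"three_class_cfs"`, `"two_class_cfs"`,
#'   `"top5_correlated"`, `"complex_DS_only"`.
#' @return Character vector of feature names (all present in
#'   [feature_schema()]).
#' @export
named_subset <- function(name) {
  if (!name %in% names(NAMED_SUBSETS)) {
    abort(paste0(
      "unknown subset '", name, "'; available: ",
      paste(names(NAMED_SUBSETS), collapse = ", ")
    ))
  }
  NAMED_SUBSETS[[name]]
}
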