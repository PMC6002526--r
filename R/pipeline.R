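# End-to-end orchestration: simulate -> extract -> stats -> select ->
# train -> evaluate, with one root seed and plain-text artifacts.

#' Default pipeline configuration
#'
#' @param seed Root seed; per-stage seeds are derived from it.
#' @param n_train,n_test Participants per group for the training and
#'   held-out cohorts (defaults: the study sizes 20/20/20 and 9/9/9).
#' @param counts Stimulus counts per category.
#' @param classifiers Classifier kinds to evaluate.
#' @param k Cross-validation folds.
#' @param write_raw Also write the raw per-participant trajectory CSVs
#'   (large; off by default).
#' @return A named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L,
                            n_train = c(truth_teller = 20, liar = 20,
                                        depressed = 20),
                            n_test = c(truth_teller = 9, liar = 9,
                                       depressed = 9),
                            counts = default_question_counts(),
                            classifiers = c("gaussian_nb", "depth2_tree",
                                            "svm", "random_forest",
                                            "multinom"),
                            k = 10,
                            write_raw = FALSE) {
  list(
    seed = as.integer(seed), n_train = n_train, n_test = n_test,
    counts = counts, classifiers = classifiers, k = k,
    write_raw = write_raw
  )
}

#' Run the full analysis pipeline
#'
#' Simulates seeded training and held-out cohorts, extracts trial and
#' participant features, runs the univariate statistics, the CFS feature
#' selection, cross-validated and held-out classification in both
#' three-class and two-class modes, and writes every artifact (CSV/JSON
#' tables, an average-trajectory figure, and a run manifest) under
#' `out_dir`. One root seed governs the whole run; rerunning with the same
#' configuration reproduces every artifact.
#'
#' @param config A [pipeline_config()] list, or the path of a YAML file
#'   with the same fields.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`train_features`,
#'   `test_features`, `anova`, `selection`, `reports`, paths).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    raw <- yaml::read_yaml(config)
    base <- pipeline_config()
    config <- utils::modifyList(base, raw)
    for (nm in c("n_train", "n_test", "counts")) {
      config[[nm]] <- unlist(config[[nm]])
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  stimulus_set <- stage("protocol", build_stimulus_set(
    counts = config$counts, seed = config$seed
  ))
  write_stimulus_set(stimulus_set, file.path(out_dir, "stimulus_set.csv"))

  train <- stage("simulate", generate_cohort(
    cohort_config(n_per_group = config$n_train, seed = config$seed),
    stimulus_set = stimulus_set
  ))
  test <- stage("simulate", generate_cohort(
    cohort_config(n_per_group = config$n_test, seed = config$seed + 1L),
    stimulus_set = stimulus_set
  ))
  if (isTRUE(config$write_raw)) {
    write_cohort(train, file.path(out_dir, "cohort_train"))
    write_cohort(test, file.path(out_dir, "cohort_test"))
  }

  train_features <- stage("extract", extract_features(train))
  test_features <- stage("extract", extract_features(test))
  write_feature_table(train_features,
                      file.path(out_dir, "features_train.csv"))
  write_feature_table(test_features, file.path(out_dir, "features_test.csv"))

  stage("stats", {
    readr::write_csv(group_summary(train_features),
                     file.path(out_dir, "group_summary.csv"))
    readr::write_csv(anova_all(train_features),
                     file.path(out_dir, "anova.csv"))
    readr::write_csv(tukey_all(train_features),
                     file.path(out_dir, "tukey.csv"))
  })
  anova_tab <- read_csv_quiet(file.path(out_dir, "anova.csv"))

  selection <- stage("select", cfs_select(train_features))
  jsonlite::write_json(
    list(selected = selection$selected, merit = selection$merit,
         class_correlations = as.list(selection$class_correlations)),
    file.path(out_dir, "selection.json"),
    auto_unbox = TRUE, digits = NA
  )

  reports <- list()
  stage("evaluate", {
    for (mode in c("three_class", "two_class")) {
      subset_name <- if (mode == "three_class") "three_class_cfs" else
        "two_class_cfs"
      for (kind in config$classifiers) {
        spec <- classifier_spec(kind, features = subset_name, mode = mode)
        cv <- kfold_cv(train_features, spec, k = config$k,
                       seed = config$seed)
        ho <- evaluate_holdout(spec, train_features, test_features)
        reports[[paste(mode, kind, sep = ".")]] <- list(cv = cv,
                                                        holdout = ho)
      }
      if (mode == "three_class") {
        spec <- classifier_spec("printed_tree", features = "three_class_cfs")
        ho <- evaluate_holdout(spec, train_features, test_features)
        reports[["three_class.printed_tree"]] <- list(holdout = ho)
      }
    }
  })
  acc <- purrr::imap_dfr(reports, function(r, nm) {
    tibble(
      model = nm,
      cv_accuracy = if (!is.null(r$cv)) r$cv$accuracy else NA_real_,
      holdout_accuracy = r$holdout$accuracy
    )
  })
  readr::write_csv(acc, file.path(out_dir, "accuracies.csv"))
  jsonlite::write_json(
    purrr::map(reports, function(r) {
      list(
        cv_accuracy = if (!is.null(r$cv)) r$cv$accuracy else NULL,
        holdout_accuracy = r$holdout$accuracy,
        holdout_confusion = as.data.frame(r$holdout$confusion)
      )
    }),
    file.path(out_dir, "reports.json"),
    auto_unbox = TRUE, digits = NA
  )

  stage("plot", {
    avg <- average_trajectory(train)
    readr::write_csv(avg, file.path(out_dir, "average_trajectory.csv"))
    p <- plot_average_trajectories(avg)
    ggplot2::ggsave(file.path(out_dir, "average_trajectory.pdf"), p,
                    width = 6, height = 5)
  })

  manifest <- list(
    seed = config$seed,
    n_train = as.list(config$n_train),
    n_test = as.list(config$n_test),
    k = config$k,
    classifiers = config$classifiers,
    package_version = as.character(utils::packageVersion("feigndep")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(
    stimulus_set = stimulus_set,
    train_features = train_features,
    test_features = test_features,
    anova = anova_tab,
    selection = selection,
    reports = reports,
    out_dir = out_dir
  ))
}

read_csv_quiet <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
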