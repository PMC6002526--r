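# Classification and evaluation: native Gaussian naive Bayes, the
# two-rule interpretable decision tree, a depth-2 CART-style trainer,
# adapters to standard classifiers, stratified k-fold cross-validation and
# held-out evaluation, in three-class and two-class (liar vs depressed)
# modes.

CLASSIFIER_KINDS <- c(
  "gaussian_nb", "printed_tree", "depth2_tree",
  "svm", "random_forest", "multinom", "memorizer"
)

#' Specify a classifier run
#'
#' @param kind One of `"gaussian_nb"` (native Gaussian naive Bayes),
#'   `"printed_tree"` (the fixed two-rule tree, no training),
#'   `"depth2_tree"` (native depth-2 Gini tree), `"svm"` (linear support
#'   vector machine via e1071, the SMO-family model), `"random_forest"`
#'   (randomForest), `"multinom"` (multinomial logistic regression via
#'   nnet, standing in for the logistic-model-tree family), or
#'   `"memorizer"` (a diagnostic classifier that only recognizes rows it
#'   was trained on — used to prove cross-validation does not leak).
#' @param features Feature names, or the name of a [named_subset()].
#'   Defaults to the three-class CFS selection.
#' @param mode `"three_class"` (all groups) or `"two_class"` (liars vs
#'   depressed only; truth-tellers are excluded from training and scoring).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = CLASSIFIER_KINDS,
                            features = "three_class_cfs",
                            mode = c("three_class", "two_class")) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (length(features) == 1 && features %in% names(NAMED_SUBSETS)) {
    features <- named_subset(features)
  }
  structure(list(kind = kind, features = features, mode = mode),
            class = "classifier_spec")
}

apply_mode <- function(data, mode) {
  if (mode == "two_class") {
    data <- filter(data, .data$label != "truth_teller")
  }
  data
}

#' Fit a Gaussian naive Bayes model
#'
#' Class priors are relative frequencies; each feature gets a per-class
#' mean and variance; prediction is the arg-max of log prior plus summed
#' log normal densities. Zero within-class variances are floored at a small
#' epsilon (flagged in the model).
#'
#' @param x Numeric matrix or data frame of features (rows = samples).
#' @param labels Class labels.
#' @param var_floor Minimum class-conditional variance.
#' @return A `gaussian_nb` model.
#' @export
fit_gaussian_nb <- function(x, labels, var_floor = 1e-9) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("need at least 2 classes")
  if (any(table(labels) < 2)) abort("need at least 2 rows per class")
  floored <- FALSE
  params <- lapply(classes, function(cl) {
    m <- x[labels == cl, , drop = FALSE]
    v <- apply(m, 2, var)
    if (any(v < var_floor)) floored <<- TRUE
    list(
      prior = nrow(m) / nrow(x),
      mean = colMeans(m),
      var = pmax(v, var_floor)
    )
  })
  names(params) <- classes
  structure(
    list(classes = classes, params = params, features = colnames(x),
         variance_floored = floored),
    class = "gaussian_nb"
  )
}

#' @export
predict.gaussian_nb <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  scores <- vapply(object$classes, function(cl) {
    p <- object$params[[cl]]
    log(p$prior) + rowSums(
      -0.5 * log(2 * pi * rep(p$var, each = nrow(x))) -
        sweep(x, 2, p$mean)^2 / (2 * rep(p$var, each = nrow(x)))
    )
  }, numeric(nrow(x)))
  if (nrow(x) == 1) scores <- matrix(scores, nrow = 1)
  object$classes[max.col(scores, ties.method = "first")]
}

#' The two-rule interpretable decision tree
#'
#' Fixed classifier: a participant endorsing fewer than 3.5 symptoms on the
#' concordant complex depressive items (`2DS-c`) is a truth-teller;
#' otherwise, a mean maximum-deviation latency above 4048 ms on the
#' discordant complex items (`MD-time 2DS-d`) marks a depressed patient,
#' else a liar. Both thresholds are strict; values exactly at a threshold
#' fall to the "else" branch.
#'
#' @param features Data frame with columns `2DS-c` and `MD-time 2DS-d`.
#' @return Character vector of predicted labels.
#' @examples
#' printed_tree(tibble::tibble(`2DS-c` = c(2, 10, 10),
#'                             `MD-time 2DS-d` = c(NA, 6000, 3000)))
#' @export
printed_tree <- function(features) {
  need <- c("2DS-c", "MD-time 2DS-d")
  miss <- setdiff(need, names(features))
  if (length(miss) > 0) {
    abort(paste0("printed tree needs feature(s): ",
                 paste(miss, collapse = ", ")))
  }
  ifelse(features[["2DS-c"]] < 3.5, "truth_teller",
         ifelse(features[["MD-time 2DS-d"]] > 4048, "depressed", "liar"))
}

gini_impurity <- function(labels) {
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

best_split <- function(x, labels, feature_names) {
  best <- NULL
  n <- length(labels)
  parent <- gini_impurity(labels)
  for (nm in feature_names) {
    v <- x[[nm]]
    u <- sort(unique(v))
    if (length(u) < 2) next
    thresholds <- (u[-1] + u[-length(u)]) / 2
    for (th in thresholds) {
      left <- v <= th
      nl <- sum(left)
      if (nl == 0 || nl == n) next
      imp <- (nl * gini_impurity(labels[left]) +
                (n - nl) * gini_impurity(labels[!left])) / n
      if (is.null(best) || imp < best$impurity - 1e-12) {
        best <- list(feature = nm, threshold = th, impurity = imp,
                     gain = parent - imp)
      }
    }
  }
  if (!is.null(best) && best$gain <= 1e-12) best <- NULL
  best
}

grow_node <- function(x, labels, feature_names, depth, max_depth) {
  tab <- table(labels)
  majority <- names(tab)[which.max(tab)]
  if (length(tab) == 1 || depth >= max_depth) {
    return(list(leaf = TRUE, class = majority, n = length(labels)))
  }
  sp <- best_split(x, labels, feature_names)
  if (is.null(sp)) {
    return(list(leaf = TRUE, class = majority, n = length(labels)))
  }
  left <- x[[sp$feature]] <= sp$threshold
  list(
    leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
    n = length(labels),
    left = grow_node(x[left, , drop = FALSE], labels[left],
                     feature_names, depth + 1, max_depth),
    right = grow_node(x[!left, , drop = FALSE], labels[!left],
                      feature_names, depth + 1, max_depth)
  )
}

#' Fit a depth-2 decision tree
#'
#' Greedy binary splits minimizing weighted Gini impurity, thresholds at
#' midpoints between observed values, majority-class leaves, maximum depth
#' 2. The chosen features and thresholds are exposed so the learned tree
#' can be compared with the fixed two-rule tree.
#'
#' @param x Data frame of features.
#' @param labels Class labels.
#' @param max_depth Maximum depth (default 2).
#' @return A `depth2_tree` model; `tidy()` lists its splits.
#' @export
fit_depth2_tree <- function(x, labels, max_depth = 2) {
  labels <- as.character(labels)
  root <- grow_node(as_tibble(x), labels, names(x), 0, max_depth)
  structure(list(root = root, features = names(x)), class = "depth2_tree")
}

predict_node <- function(node, row) {
  while (!node$leaf) {
    node <- if (row[[node$feature]] <= node$threshold) node$left else
      node$right
  }
  node$class
}

#' @export
predict.depth2_tree <- function(object, newdata, ...) {
  vapply(seq_len(nrow(newdata)), function(i) {
    predict_node(object$root, newdata[i, , drop = FALSE])
  }, character(1))
}

#' Splits and leaves of a fitted depth-2 tree
#' @param x A `depth2_tree`.
#' @param ... Unused.
#' @return A tibble of nodes.
#' @method tidy depth2_tree
#' @export
tidy.depth2_tree <- function(x, ...) {
  rows <- list()
  walk <- function(node, depth, side) {
    if (node$leaf) {
      rows[[length(rows) + 1]] <<- tibble(
        depth = depth, side = side, feature = NA_character_,
        threshold = NA_real_, leaf_class = node$class, n = node$n
      )
    } else {
      rows[[length(rows) + 1]] <<- tibble(
        depth = depth, side = side, feature = node$feature,
        threshold = node$threshold, leaf_class = NA_character_, n = node$n
      )
      walk(node$left, depth + 1, "left")
      walk(node$right, depth + 1, "right")
    }
  }
  walk(x$root, 0, "root")
  bind_rows(rows)
}

standardize_train <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(ctr = ctr, scl = scl, x = scale(x, center = ctr, scale = scl))
}

#' Fit a classifier according to a spec
#'
#' @param spec A [classifier_spec()].
#' @param data Feature tibble (`label` plus schema columns).
#' @return A `feign_model` that [predict()]s labels for new feature rows.
#' @export
fit_classifier <- function(spec, data) {
  data <- apply_mode(data, spec$mode)
  miss <- setdiff(spec$features, names(data))
  if (length(miss) > 0) {
    abort(paste0("training data lacks feature(s): ",
                 paste(miss, collapse = ", ")))
  }
  labels <- as.character(data$label)
  x <- data[, spec$features, drop = FALSE]
  fit <- switch(spec$kind,
    gaussian_nb = fit_gaussian_nb(x, labels),
    printed_tree = NULL,
    depth2_tree = fit_depth2_tree(x, labels),
    svm = {
      st <- standardize_train(as.matrix(x))
      list(std = st,
           model = e1071::svm(st$x, factor(labels), kernel = "linear",
                              scale = FALSE))
    },
    random_forest = randomForest::randomForest(as.matrix(x),
                                               factor(labels),
                                               ntree = 200),
    multinom = {
      st <- standardize_train(as.matrix(x))
      df <- as.data.frame(st$x)
      names(df) <- paste0("f", seq_along(spec$features))
      df$.label <- factor(labels)
      list(std = st,
           model = nnet::multinom(.label ~ ., data = df, trace = FALSE,
                                  maxit = 300))
    },
    memorizer = {
      keyv <- apply(as.matrix(x), 1, paste, collapse = "|")
      tabm <- table(labels)
      list(map = setNames(labels, keyv),
           majority = names(tabm)[which.max(tabm)])
    }
  )
  structure(list(spec = spec, fit = fit, classes = sort(unique(labels))),
            class = "feign_model")
}

#' @export
predict.feign_model <- function(object, newdata, ...) {
  spec <- object$spec
  if (spec$kind == "printed_tree") return(printed_tree(newdata))
  x <- newdata[, spec$features, drop = FALSE]
  switch(spec$kind,
    gaussian_nb = predict(object$fit, x),
    depth2_tree = predict(object$fit, x),
    svm = {
      xs <- scale(as.matrix(x), object$fit$std$ctr, object$fit$std$scl)
      as.character(predict(object$fit$model, xs))
    },
    random_forest = as.character(predict(object$fit, as.matrix(x))),
    multinom = {
      xs <- scale(as.matrix(x), object$fit$std$ctr, object$fit$std$scl)
      df <- as.data.frame(xs)
      names(df) <- paste0("f", seq_along(spec$features))
      as.character(predict(object$fit$model, df))
    },
    memorizer = {
      keyv <- apply(as.matrix(x), 1, paste, collapse = "|")
      out <- unname(object$fit$map[keyv])
      out[is.na(out)] <- object$fit$majority
      out
    }
  )
}

make_report <- function(truth, pred, classes, fold = NULL, k = NA, seed = NA,
                        spec = NULL) {
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- table(truth = truth, predicted = pred)
  fold_acc <- if (!is.null(fold)) {
    vapply(sort(unique(fold)), function(f) {
      mean(pred[fold == f] == truth[fold == f]) * 100
    }, numeric(1))
  } else {
    mean(pred == truth) * 100
  }
  fold_sizes <- if (!is.null(fold)) as.integer(table(fold)) else sum(!is.na(pred))
  structure(
    list(
      accuracy = sum(diag(cm)) / sum(cm) * 100,
      fold_accuracy = fold_acc,
      fold_sizes = fold_sizes,
      confusion = cm,
      k = k, seed = seed, n = sum(cm), spec = spec
    ),
    class = "cv_report"
  )
}

#' Stratified k-fold cross-validation
#'
#' Partitions the cohort into k folds (stratified by class unless
#' `stratify = FALSE`), trains on k-1 folds and scores the held-out fold,
#' each fold serving once for validation. Deterministic given `seed`.
#'
#' @param data Feature tibble (`label` plus schema columns).
#' @param spec A [classifier_spec()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param stratify Stratify fold assignment by class.
#' @return A `cv_report`: overall accuracy (percent), per-fold accuracies,
#'   pooled confusion matrix, `k`, `seed`.
#' @export
kfold_cv <- function(data, spec, k = 10, seed = 1, stratify = TRUE) {
  data <- apply_mode(data, spec$mode)
  n <- nrow(data)
  if (k > n) abort("k must not exceed the number of scored participants")
  if (k < 2) abort("need at least 2 folds")
  labels <- as.character(data$label)
  fold <- integer(n)
  withr::with_seed(seed, {
    if (stratify) {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold <- sample(rep_len(seq_len(k), n))
    }
  })
  pred <- character(n)
  for (f in seq_len(k)) {
    hold <- fold == f
    model <- fit_classifier(spec, data[!hold, , drop = FALSE])
    pred[hold] <- predict(model, data[hold, , drop = FALSE])
  }
  make_report(labels, pred, sort(unique(labels)), fold = fold, k = k,
              seed = seed, spec = spec)
}

#' Evaluate on a held-out cohort
#'
#' Fits the classifier on the training table and scores a disjoint test
#' table with the same schema.
#'
#' @param spec A [classifier_spec()].
#' @param train,test Feature tibbles with identical schema columns.
#' @return A `cv_report` (with `k = NA`).
#' @export
evaluate_holdout <- function(spec, train, test) {
  test <- apply_mode(test, spec$mode)
  if (nrow(test) == 0) abort("test cohort is empty")
  miss <- setdiff(spec$features, names(test))
  if (length(miss) > 0) {
    abort(paste0("test cohort lacks feature(s): ",
                 paste(miss, collapse = ", ")))
  }
  model <- fit_classifier(spec, train)
  pred <- predict(model, test)
  truth <- as.character(test$label)
  make_report(truth, pred, sort(unique(c(truth, model$classes))),
              spec = spec)
}

#' @export
print.cv_report <- function(x, ...) {
  kind <- if (!is.null(x$spec)) x$spec$kind else "?"
  cv <- if (is.na(x$k)) "held-out" else paste0(x$k, "-fold CV")
  cat("<cv_report> ", kind, ", ", cv, ": accuracy ",
      format(x$accuracy, digits = 4), "% (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Confusion matrix of a report in long form
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A tibble `truth`, `predicted`, `n`.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  as_tibble(as.data.frame(x$confusion)) %>%
    rename(n = "Freq")
}

#' One-row accuracy summary of a report
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble(
    accuracy = x$accuracy,
    k = x$k,
    n = x$n,
    seed = x$seed,
    kind = if (!is.null(x$spec)) x$spec$kind else NA_character_,
    mode = if (!is.null(x$spec)) x$spec$mode else NA_character_
  )
}

#' Confusion-matrix heatmap for a report
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("Confusion matrix (accuracy %.1f%%)", object$accuracy),
      x = "predicted", y = "observed"
    ) +
    ggplot2::theme_minimal()
}
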