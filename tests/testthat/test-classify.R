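test_that("Gaussian NB decision boundary sits midway between equal-variance
           class means", {
  train <- tibble::tibble(x = c(-1, 0, 1, 1, 2, 3))
  labels <- rep(c("a", "b"), each = 3) # means 0 and 2, equal variance
  nb <- fit_gaussian_nb(train, labels)
  expect_equal(predict(nb, tibble::tibble(x = 0.99)), "a")
  expect_equal(predict(nb, tibble::tibble(x = 1.01)), "b")
})

test_that("Gaussian NB follows the larger prior under identical likelihoods", {
  train <- tibble::tibble(x = c(0, 1, 0, 1, 0, 1, 0, 1))
  labels <- c(rep("big", 6), rep("small", 2))
  nb <- fit_gaussian_nb(train, labels)
  expect_true(all(predict(nb, tibble::tibble(x = c(0, 0.5, 1))) == "big"))
})

test_that("Gaussian NB predictions equal a brute-force density oracle", {
  withr::with_seed(55, {
    n <- 90
    labels <- sample(c("a", "b", "c"), n, replace = TRUE)
    x <- tibble::tibble(
      f1 = rnorm(n, as.integer(factor(labels))),
      f2 = rnorm(n, 0, 2)
    )
    nb <- fit_gaussian_nb(x, labels)
    newx <- tibble::tibble(f1 = rnorm(30), f2 = rnorm(30))
    mine <- predict(nb, newx)
    oracle <- vapply(seq_len(nrow(newx)), function(i) {
      post <- vapply(nb$classes, function(cl) {
        p <- nb$params[[cl]]
        log(p$prior) +
          sum(stats::dnorm(as.numeric(newx[i, ]), p$mean, sqrt(p$var),
                           log = TRUE))
      }, numeric(1))
      names(post)[which.max(post)]
    }, character(1))
    expect_equal(mine, oracle)
  })
  # zero-variance features are floored, not fatal
  const <- tibble::tibble(f = c(1, 1, 2, 2))
  nb0 <- fit_gaussian_nb(const, c("a", "a", "b", "b"))
  expect_true(nb0$variance_floored)
})

test_that("the two-rule tree reproduces its decision logic exactly", {
  grid <- tibble::tibble(
    `2DS-c` = c(2, 0, 3, 10, 10, 4, 4),
    `MD-time 2DS-d` = c(9999, 100, 4100, 6000, 3000, 4048, 4049)
  )
  expect_equal(
    printed_tree(grid),
    c("truth_teller", "truth_teller", "truth_teller", "depressed", "liar",
      # exactly at a threshold falls to the "else" branch
      "liar", "depressed")
  )
  expect_equal(printed_tree(tibble::tibble(`2DS-c` = 3.5,
                                           `MD-time 2DS-d` = 5000)),
               "depressed")
  expect_error(printed_tree(tibble::tibble(`2DS-c` = 1)), "MD-time 2DS-d")
})

test_that("the depth-2 trainer recovers a single separating threshold", {
  train <- tibble::tibble(f = c(1, 2, 3, 7, 8, 9))
  labels <- rep(c("lo", "hi"), each = 3)
  tree <- fit_depth2_tree(train, labels)
  td <- tidy(tree)
  root <- td[td$side == "root", ]
  expect_equal(root$feature, "f")
  expect_equal(root$threshold, 5) # midpoint convention
  expect_equal(predict(tree, tibble::tibble(f = c(0, 4.9, 5.1, 10))),
               c("lo", "lo", "hi", "hi"))
  # single-class input collapses to one leaf
  pure <- fit_depth2_tree(train, rep("only", 6))
  expect_true(pure$root$leaf)
  expect_equal(predict(pure, train), rep("only", 6))
})

test_that("cross-validation partitions honestly and reports coherently", {
  feats <- shared_train_features()
  spec <- classifier_spec("gaussian_nb")
  cv <- kfold_cv(feats, spec, k = 10, seed = 5)
  expect_equal(cv$fold_sizes, rep(6L, 10))
  expect_equal(sum(cv$confusion), 60)
  expect_equal(cv$accuracy,
               sum(diag(cv$confusion)) / sum(cv$confusion) * 100)
  expect_length(cv$fold_accuracy, 10)
  # deterministic given the seed
  cv2 <- kfold_cv(feats, spec, k = 10, seed = 5)
  expect_equal(cv$accuracy, cv2$accuracy)
  expect_equal(cv$confusion, cv2$confusion)
  expect_error(kfold_cv(feats, spec, k = 61), "exceed")
})

test_that("a memorizing classifier proves there is no train/test leakage", {
  feats <- shared_train_features()
  spec <- classifier_spec("memorizer")
  # test = train: perfect recall
  full <- evaluate_holdout(spec, feats, feats)
  expect_equal(full$accuracy, 100)
  # under cross-validation the validation rows are never seen in training,
  # so recall collapses to the majority-class rate
  cv <- kfold_cv(feats, spec, k = 10, seed = 1)
  expect_lte(cv$accuracy, 40)
})

test_that("two-class mode scores liars versus depressed only", {
  feats <- shared_train_features()
  spec <- classifier_spec("gaussian_nb", features = "two_class_cfs",
                          mode = "two_class")
  cv <- kfold_cv(feats, spec, k = 10, seed = 2)
  expect_equal(dim(cv$confusion), c(2L, 2L))
  expect_equal(sum(cv$confusion), 40)
  expect_false("truth_teller" %in% rownames(cv$confusion))
  ho <- evaluate_holdout(spec, feats, shared_test_features())
  expect_equal(sum(ho$confusion), 18)
})

test_that("held-out evaluation validates its inputs", {
  feats <- shared_train_features()
  spec <- classifier_spec("gaussian_nb")
  expect_error(evaluate_holdout(spec, feats, feats[0, ]), "empty")
  expect_error(
    evaluate_holdout(spec, feats,
                     feats[, c("participant_id", "label", "DS")]),
    "lacks"
  )
})

test_that("calibrated cohorts are classified far above chance", {
  feats <- shared_train_features()
  test_feats <- shared_test_features()
  for (kind in c("gaussian_nb", "depth2_tree", "svm", "random_forest",
                 "multinom")) {
    cv <- kfold_cv(feats, classifier_spec(kind), k = 10, seed = 7)
    expect_gt(cv$accuracy, 60, label = paste(kind, "cv"))
    ho <- evaluate_holdout(classifier_spec(kind), feats, test_feats)
    expect_gt(ho$accuracy, 60, label = paste(kind, "holdout"))
  }
  # the interpretable two-rule tree also generalizes to the held-out cohort
  ho <- evaluate_holdout(classifier_spec("printed_tree"), feats, test_feats)
  expect_gt(ho$accuracy, 50)
})

test_that("the learned depth-2 root splits on a concordant-complex count", {
  feats <- shared_train_features()
  model <- fit_classifier(classifier_spec("depth2_tree"), feats)
  root <- tidy(model$fit)
  root <- root[root$side == "root", ]
  expect_true(root$feature %in% c("2DS-c", "DS", "VAS", "2DS-d"))
})

test_that("report tidiers expose the confusion matrix", {
  feats <- shared_train_features()
  cv <- kfold_cv(feats, classifier_spec("gaussian_nb"), k = 10, seed = 3)
  td <- tidy(cv)
  expect_equal(sum(td$n), 60)
  gl <- glance(cv)
  expect_equal(gl$k, 10)
  expect_s3_class(autoplot(cv), "ggplot")
})
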