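test_that("trajectory synthesis is deterministic given the RNG state", {
  p <- default_profiles()$depressed
  a <- withr::with_seed(31, synth_trajectory(p, "left"))
  b <- withr::with_seed(31, synth_trajectory(p, "left"))
  expect_identical(a$t_ms, b$t_ms)
  expect_identical(a$x_px, b$x_px)
  expect_identical(a$y_px, b$y_px)
})

test_that("every drawn per-trial target is realized by the extracted features", {
  prof <- default_profiles()
  withr::with_seed(17, {
    for (g in names(prof)) {
      for (i in 1:8) {
        side <- if (i %% 2 == 0) "left" else "right"
        tr <- synth_trajectory(prof[[g]], side)
        tg <- attr(tr, "targets")
        f <- trial_features(tr)
        expect_equal(f$it_ms, tg[["it_ms"]], tolerance = 1e-6)
        expect_equal(f$rt_ms, tg[["rt_ms"]], tolerance = 1e-6)
        expect_equal(f$md, tg[["md"]], tolerance = 1e-6)
        expect_equal(f$auc, tg[["auc"]], tolerance = 5e-3)
        expect_equal(f$md_time_ms, tg[["md_time_ms"]], tolerance = 1e-6)
        # realized flips equal the draw unless the path's own loop already
        # exceeds it (reversals cannot be removed)
        expect_gte(f$x_flip, tg[["x_flip"]])
        expect_lte(f$x_flip - tg[["x_flip"]], 8)
        expect_gte(f$y_flip, tg[["y_flip"]])
      }
    }
  })
})

test_that("a zero-amplitude, zero-flip profile gives a straight silent path", {
  quiet <- group_profile(
    label = "truth_teller",
    endorse_prob = c("DS" = 0, "2DS-c" = 0, "2DS-d" = 0, "VAS" = 0,
                     "DS&EX-c" = 0, "DS&EX-d" = 0),
    error_prob_controls = c("EX" = 0, "2EX-d" = 0, "2EX-c" = 0),
    rt_mean = 3000, rt_sd = 0, it_mean = 500, it_sd = 0,
    mdtime_frac_mean = 0.6, md_mean = 0, md_sd = 0, auc_mean = 0,
    flip_rate_x = 0, flip_sd_x = 0, flip_rate_y = 0, flip_sd_y = 0,
    click_x_sd = 0, click_y_sd = 0
  )
  tr <- withr::with_seed(2, synth_trajectory(quiet, "left"))
  f <- trial_features(tr)
  expect_equal(f$md, 0, tolerance = 1e-9)
  expect_equal(f$auc, 0, tolerance = 1e-9)
  expect_equal(f$x_flip, 0L)
  expect_equal(f$y_flip, 0L)
  expect_equal(f$rt_ms, 3000, tolerance = 1e-6)
})

test_that("raw samples satisfy the trajectory invariants", {
  p <- default_profiles()$liar
  geo <- default_geometry()
  withr::with_seed(9, {
    for (side in c("left", "right")) {
      tr <- synth_trajectory(p, side, geometry = geo)
      expect_true(all(diff(tr$t_ms) > 0))
      expect_equal(tr$t_ms[1], 0)
      expect_equal(tr$x_px[1], geo$start[["x"]], tolerance = 1e-6)
      expect_equal(tr$y_px[1], geo$start[["y"]], tolerance = 1e-6)
      box <- if (side == "left") geo$box_left else geo$box_right
      n <- nrow(tr)
      expect_lte(abs(tr$x_px[n] - box[["x"]]), geo$box_size[["w"]] / 2)
      expect_lte(abs(tr$y_px[n] - box[["y"]]), geo$box_size[["h"]] / 2)
    }
  })
})

test_that("response policies hit their endorsement extremes", {
  ss <- build_stimulus_set(seed = 1)
  prof <- default_profiles()
  saturated <- prof$liar
  saturated$endorse_prob[["VAS"]] <- 1
  sim <- withr::with_seed(4, sample_participant(
    saturated, ss, "li_x", trajectories = FALSE
  ))
  counts <- symptom_counts(sim$responses, ss)
  expect_equal(counts$count[counts$category == "VAS"], 15)

  flawless <- prof$truth_teller
  flawless$error_prob_controls[] <- 0
  sim2 <- withr::with_seed(4, sample_participant(
    flawless, ss, "tt_x", trajectories = FALSE
  ))
  errs <- control_errors(sim2$responses, ss)
  expect_equal(sum(errs$count), 0)
})

test_that("cohort sizes follow the configuration", {
  ss <- shared_stimulus()
  train <- generate_cohort(cohort_config(seed = 1), stimulus_set = ss,
                           trajectories = FALSE)
  expect_equal(nrow(train$participants), 60)
  expect_equal(as.integer(table(train$participants$group)[
    c("truth_teller", "liar", "depressed")
  ]), c(20L, 20L, 20L))
  expect_equal(nrow(train$responses), 60 * 76)

  test <- generate_cohort(
    cohort_config(n_per_group = c(truth_teller = 9, liar = 9,
                                  depressed = 9), seed = 2),
    stimulus_set = ss, trajectories = FALSE
  )
  expect_equal(nrow(test$participants), 27)

  none <- generate_cohort(
    cohort_config(n_per_group = c(truth_teller = 0), seed = 3),
    stimulus_set = ss, trajectories = FALSE
  )
  expect_equal(nrow(none$participants), 0)
})

test_that("identical configuration and seed reproduce the cohort exactly", {
  ss <- shared_stimulus()
  cfg <- cohort_config(n_per_group = c(truth_teller = 2, depressed = 2),
                       seed = 77)
  a <- generate_cohort(cfg, stimulus_set = ss)
  b <- generate_cohort(cfg, stimulus_set = ss)
  expect_identical(a$responses, b$responses)
  expect_identical(a$trajectories, b$trajectories)
})

test_that("group ordering of configured means survives extraction", {
  prof <- default_profiles()
  # configured orderings
  expect_gt(prof$depressed$rt_mean, prof$liar$rt_mean)
  expect_gt(prof$liar$rt_mean, prof$truth_teller$rt_mean)
  # depressed are markedly slower in extracted features too
  withr::with_seed(13, {
    rt_mean_of <- function(p, n = 60) {
      mean(purrr::map_dbl(1:n, function(i) {
        trial_features(synth_trajectory(p, "left"))$rt_ms
      }))
    }
    expect_gt(rt_mean_of(prof$depressed), rt_mean_of(prof$liar) + 1000)
    expect_gt(rt_mean_of(prof$depressed),
              rt_mean_of(prof$truth_teller) + 1000)
  })
  # liars over-endorse atypical symptoms relative to both other groups
  ss <- shared_stimulus()
  coh <- generate_cohort(
    cohort_config(n_per_group = c(truth_teller = 40, liar = 40,
                                  depressed = 40), seed = 5),
    stimulus_set = ss, trajectories = FALSE
  )
  vas <- coh$responses %>%
    dplyr::filter(.data$category == "VAS") %>%
    dplyr::inner_join(coh$participants, by = "participant_id") %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(vas = sum(.data$response == "yes") / 40)
  v <- setNames(vas$vas, vas$group)
  expect_gt(v[["liar"]], v[["depressed"]])
  expect_gt(v[["depressed"]], v[["truth_teller"]])
  # truth-tellers sit below the interpretable-tree threshold on 2DS-c,
  # the other groups above it
  dsc <- coh$responses %>%
    dplyr::filter(.data$category == "2DS-c") %>%
    dplyr::inner_join(coh$participants, by = "participant_id") %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(m = sum(.data$response == "yes") / 40)
  d <- setNames(dsc$m, dsc$group)
  expect_lt(d[["truth_teller"]], 3.5)
  expect_gt(d[["liar"]], 3.5)
  expect_gt(d[["depressed"]], 3.5)
})

test_that("cohorts round-trip through the CSV/JSON dialect", {
  ss <- build_stimulus_set(counts = c("EX" = 2, "DS" = 3), seed = 2)
  coh <- generate_cohort(
    cohort_config(n_per_group = c(truth_teller = 1, liar = 1), seed = 8),
    stimulus_set = ss
  )
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$participants),
               as.data.frame(coh$participants))
  expect_equal(as.data.frame(back$responses),
               as.data.frame(coh$responses))
  expect_equal(
    as.data.frame(back$trajectories[order(back$trajectories$participant_id,
                                          back$trajectories$question_id,
                                          back$trajectories$t_ms), ]),
    as.data.frame(coh$trajectories[order(coh$trajectories$participant_id,
                                         coh$trajectories$question_id,
                                         coh$trajectories$t_ms), ]),
    tolerance = 1e-8
  )
})

test_that("profile validation rejects impossible parameters", {
  expect_error(
    group_profile("x", c("DS" = 1.5), c("EX" = 0), 1000, 1, 100, 1,
                  0.5, 0.3, 0.1, 0.5, 5, 1, 5, 1),
    "probabilities"
  )
  expect_error(
    group_profile("x", c("DS" = 0.5), c("EX" = 0), 100, 1, 1000, 1,
                  0.5, 0.3, 0.1, 0.5, 5, 1, 5, 1),
    "rt_mean"
  )
})
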