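test_that("time normalization yields 101 frames and interpolates linearly", {
  p <- path_through(c(0, -0.5, -1), c(0, 0.75, 1.5))
  st <- time_normalize(p)
  expect_equal(nrow(st), 101)
  expect_equal(st$x[1], 0)
  expect_equal(st$y[1], 0)
  expect_equal(st$x[101], -1)
  expect_equal(st$y[101], 1.5)
  # closed form: frame 50 sits at t = 100 ms, i.e. the middle waypoint
  expect_equal(st$x[51], -0.5, tolerance = 1e-12)
  expect_equal(st$y[51], 0.75, tolerance = 1e-12)

  expect_error(time_normalize(p[1, ]), "at least 2")
})

test_that("a path already on the 101-frame grid is reproduced exactly", {
  withr::with_seed(8, {
    st <- random_standard_path()
    again <- time_normalize(
      tibble::tibble(t_ms = st$frame * 10, x = st$x, y = st$y)
    )
    expect_equal(again$x, st$x, tolerance = 1e-12)
    expect_equal(again$y, st$y, tolerance = 1e-12)
  })
})

test_that("maximum deviation matches the analytic point-to-line oracle", {
  # vertex (0, 1) against the chord (0,0)->(-1,1.5): distance 1/sqrt(3.25)
  st <- time_normalize(path_through(c(0, 0, -1), c(0, 1, 1.5)))
  md <- max_deviation(st)
  expect_equal(md$md, 1 / sqrt(3.25), tolerance = 1e-10)
  expect_gt(md$md, 0) # deviation toward the non-chosen side is positive

  # straight path: zero deviation
  straight <- time_normalize(path_through(c(0, -0.5, -1), c(0, 0.75, 1.5)))
  expect_equal(max_deviation(straight)$md, 0, tolerance = 1e-12)

  # latency: peak at the midpoint of a 4000 ms movement, reported on the
  # trial clock
  hook <- time_normalize(path_through(c(0, 0, -1), c(0, 1, 1.5),
                                      t_step = 2000))
  expect_equal(max_deviation(hook)$md_time_ms, 2000)

  expect_error(
    max_deviation(time_normalize(path_through(c(0, 1, 0), c(0, 1, 0)))),
    "degenerate"
  )
})

test_that("|MD| equals the brute-force max distance on random paths", {
  withr::with_seed(99, {
    for (i in 1:25) {
      st <- random_standard_path()
      expect_equal(abs(max_deviation(st)$md),
                   oracle_max_point_line_distance(st$x, st$y),
                   tolerance = 1e-10)
    }
  })
})

test_that("area under the curve matches the shoelace oracle", {
  # right-angle path vs the direct chord: triangle of area 0.75
  st <- time_normalize(path_through(c(0, 0, -1), c(0, 1.5, 1.5)))
  expect_equal(area_under_curve(st), 0.75, tolerance = 1e-10)

  straight <- time_normalize(path_through(c(0, -1), c(0, 1.5)))
  expect_equal(area_under_curve(straight), 0, tolerance = 1e-12)
})

test_that("MD and AUC are translation invariant and mirror equivariant", {
  withr::with_seed(5, {
    for (i in 1:10) {
      st <- random_standard_path()
      shifted <- time_normalize(tibble::tibble(
        t_ms = st$frame * 10, x = st$x + 0.7, y = st$y - 0.4
      ))
      expect_equal(max_deviation(shifted)$md, max_deviation(st)$md,
                   tolerance = 1e-10)
      expect_equal(area_under_curve(shifted), area_under_curve(st),
                   tolerance = 1e-10)
      mirrored <- time_normalize(tibble::tibble(
        t_ms = st$frame * 10, x = -st$x, y = st$y
      ))
      expect_equal(max_deviation(mirrored)$md, max_deviation(st)$md,
                   tolerance = 1e-10)
      expect_equal(area_under_curve(mirrored), area_under_curve(st),
                   tolerance = 1e-10)
    }
  })
})

test_that("flip counting matches enumeration, skipping zero increments", {
  mk <- function(incs) {
    x <- cumsum(c(0, incs, rep(0, 101 - length(incs) - 1)))
    y <- seq(0, 1.5, length.out = 101)
    time_normalize(tibble::tibble(t_ms = 0:100 * 10, x = x, y = y))
  }
  # alternating increments (-,+,-,+,-): 4 reversals
  st <- mk(c(-0.1, 0.1, -0.1, 0.1, -0.1))
  expect_equal(count_flips(st, "x"), 4L)
  # zeros are skipped: (-,0,+) counts a single reversal
  st0 <- mk(c(-0.1, 0, 0.1))
  expect_equal(count_flips(st0, "x"), 1L)
  expect_equal(count_flips(st0, "x"), oracle_flip_count(st0$x))
  # monotone path: no flips
  mono <- time_normalize(path_through(c(0, -0.5, -1), c(0, 0.75, 1.5)))
  expect_equal(count_flips(mono, "x"), 0L)
  expect_equal(count_flips(mono, "y"), 0L)
  # random paths against the enumeration oracle
  withr::with_seed(12, {
    for (i in 1:20) {
      st <- random_standard_path()
      expect_equal(count_flips(st, "x"), oracle_flip_count(st$x))
      expect_equal(count_flips(st, "y"), oracle_flip_count(st$y))
    }
  })
})

test_that("frame kinematics reduce to closed forms on uniform motion", {
  xs <- seq(0, -1, length.out = 101)
  ys <- seq(0, 1.5, length.out = 101)
  st <- time_normalize(tibble::tibble(t_ms = 0:100 * 40, x = xs, y = ys))
  fk <- frame_kinematics(st)
  expect_equal(fk$v_y, 1.5 / 100, tolerance = 1e-12)
  expect_equal(fk$v_x, -1 / 100, tolerance = 1e-12)
  expect_equal(fk$a_x, 0, tolerance = 1e-12)
  expect_equal(fk$a_y, 0, tolerance = 1e-12)
})

test_that("remapping sends box centres to (-1, 1.5) and mirrors right clicks", {
  geo <- default_geometry()
  # straight two-sample path to the left box centre
  raw_left <- tibble::tibble(
    t_ms = c(0, 500),
    x_px = c(geo$start[["x"]], geo$box_left[["x"]]),
    y_px = c(geo$start[["y"]], geo$box_left[["y"]])
  )
  pl <- remap_trajectory(raw_left, geo)
  expect_equal(pl$x, c(0, -1), tolerance = 1e-12)
  expect_equal(pl$y, c(0, 1.5), tolerance = 1e-12)
  expect_false(attr(pl, "mirrored"))

  raw_right <- tibble::tibble(
    t_ms = c(0, 500),
    x_px = c(geo$start[["x"]], geo$box_right[["x"]]),
    y_px = c(geo$start[["y"]], geo$box_right[["y"]])
  )
  pr <- remap_trajectory(raw_right, geo)
  expect_equal(pr$x[2], -1, tolerance = 1e-12) # mirrored leftward
  expect_true(attr(pr, "mirrored"))

  expect_warning(
    remap_trajectory(tibble::tibble(t_ms = c(0, 1), x_px = c(-5, 100),
                                    y_px = c(500, 500)), geo),
    "clamping"
  )
})

test_that("mirror twins produce identical spatial features", {
  withr::with_seed(77, {
    p <- default_profiles()$liar
    left <- synth_trajectory(p, "left")
  })
  geo <- default_geometry()
  cx <- (geo$box_left[["x"]] + geo$box_right[["x"]]) / 2
  right <- dplyr::mutate(left, x_px = 2 * cx - .data$x_px)
  fl <- trial_features(left)
  fr <- trial_features(right)
  for (nm in c("it_ms", "rt_ms", "md_time_ms", "md", "auc", "x_flip",
               "y_flip", "v_y", "a_y")) {
    expect_equal(fl[[nm]], fr[[nm]], tolerance = 1e-9, label = nm)
  }
  # horizontal velocity tracks the true response direction, so it flips
  expect_equal(fl$v_x, -fr$v_x, tolerance = 1e-9)
})

test_that("initiation time finds the first displacement", {
  idle <- tibble::tibble(
    t_ms = c(0, 250, 500, 600, 700),
    x = c(0, 0, 0, -0.2, -0.5),
    y = c(0, 0, 0, 0.3, 0.8)
  )
  expect_equal(initiation_time(idle), 600)
  moving <- tibble::tibble(t_ms = c(0, 10, 20), x = c(0, -0.1, -0.2),
                           y = c(0, 0.1, 0.2))
  expect_equal(initiation_time(moving), 10)
  frozen <- tibble::tibble(t_ms = c(0, 400), x = c(0, 0), y = c(0, 0))
  it <- initiation_time(frozen)
  expect_equal(as.numeric(it), 400)
  expect_true(attr(it, "no_movement"))
})

test_that("average trajectories are frame-wise means", {
  coh <- generate_cohort(
    cohort_config(n_per_group = c(truth_teller = 1, liar = 1), seed = 4),
    stimulus_set = build_stimulus_set(counts = c("EX" = 3), seed = 1)
  )
  avg <- average_trajectory(coh)
  expect_equal(sort(unique(avg$group)), c("liar", "truth_teller"))
  expect_equal(nrow(avg), 202)
  # mean of N identical paths is that path
  st <- withr::with_seed(3, random_standard_path())
  stack <- dplyr::bind_rows(
    dplyr::mutate(st, participant_id = "a", question_id = "q"),
    dplyr::mutate(st, participant_id = "b", question_id = "q")
  )
  m <- stack %>%
    dplyr::group_by(frame) %>%
    dplyr::summarise(x = mean(x), y = mean(y))
  expect_equal(m$x, st$x, tolerance = 1e-12)
  expect_equal(m$y, st$y, tolerance = 1e-12)
})
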