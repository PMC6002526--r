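# Seeded synthetic cohorts: symptom endorsements and raw mouse trajectories
# whose extracted kinematic features are calibrated to configured group
# statistics.
#
# Each trial draws its own feature targets (RT, IT, MD, AUC, flip counts,
# MD latency) from the group profile and then *constructs* a raw path that
# realizes them: a smooth deviation bump toward the non-chosen side sets the
# maximum deviation, one regressive loop (a backtracking excursion along the
# ideal line) tops the signed area up to the AUC target, and small motor
# reversals are inserted until the per-axis flip counts match. The movement
# phase is emitted on the 101-point equal-time grid, so time normalization
# reproduces it exactly and cohort means of extracted features are unbiased
# estimators of the configured targets.

#' Generative profile for one experimental group
#'
#' Bundles the parameters that drive response simulation for one condition:
#' endorsement probabilities per symptom category, control-question error
#' probabilities, and the kinematic targets (means/SDs of reaction and
#' initiation time in ms, maximum deviation, area under the curve, flip
#' rates, and the maximum-deviation latency as a fraction of RT).
#'
#' @param label One of `"truth_teller"`, `"liar"`, `"depressed"`.
#' @param endorse_prob Named probabilities of a "yes" per symptom category
#'   (`DS`, `2DS-d`, `2DS-c`, `DS&EX-d`, `DS&EX-c`, `VAS`).
#' @param error_prob_controls Named probabilities of a wrong answer per
#'   control category (`EX`, `2EX-d`, `2EX-c`).
#' @param rt_mean,rt_sd Reaction time mean/SD (ms), lognormal.
#' @param it_mean,it_sd Initiation time mean/SD (ms), lognormal.
#' @param mdtime_frac_mean Maximum-deviation latency as a fraction of RT.
#' @param md_mean,md_sd Maximum deviation (normalized units), lognormal.
#' @param auc_mean Mean area under the curve (normalized units squared);
#'   per-trial AUC is coupled proportionally to the trial's MD draw.
#' @param flip_rate_x,flip_sd_x,flip_rate_y,flip_sd_y Mean/SD of direction
#'   changes per trial along each axis.
#' @param click_x_mean,click_x_sd,click_y_mean,click_y_sd Click-point
#'   scatter inside the response box, in normalized units (x as magnitude).
#' @return A `group_profile` list.
#' @export
group_profile <- function(label,
                          endorse_prob,
                          error_prob_controls,
                          rt_mean, rt_sd,
                          it_mean, it_sd,
                          mdtime_frac_mean,
                          md_mean, md_sd,
                          auc_mean,
                          flip_rate_x, flip_sd_x,
                          flip_rate_y, flip_sd_y,
                          click_x_mean = 0.96, click_x_sd = 0.03,
                          click_y_mean = 1.326, click_y_sd = 0.014) {
  probs <- c(endorse_prob, error_prob_controls)
  if (any(probs < 0 | probs > 1)) {
    abort("endorsement and error probabilities must lie in [0, 1]")
  }
  if (!(rt_mean > it_mean && it_mean >= 0)) {
    abort("need rt_mean > it_mean >= 0")
  }
  if (md_mean < 0) abort("md_mean must be non-negative")
  structure(
    list(
      label = label,
      endorse_prob = endorse_prob,
      error_prob_controls = error_prob_controls,
      rt_mean = rt_mean, rt_sd = rt_sd,
      it_mean = it_mean, it_sd = it_sd,
      mdtime_frac_mean = mdtime_frac_mean,
      md_mean = md_mean, md_sd = md_sd,
      auc_mean = auc_mean,
      flip_rate_x = flip_rate_x, flip_sd_x = flip_sd_x,
      flip_rate_y = flip_rate_y, flip_sd_y = flip_sd_y,
      click_x_mean = click_x_mean, click_x_sd = click_x_sd,
      click_y_mean = click_y_mean, click_y_sd = click_y_sd
    ),
    class = "group_profile"
  )
}

#' Default calibrated group profiles
#'
#' Profiles for the three conditions, calibrated so that cohort-level
#' extracted features reproduce the published group statistics: kinematic
#' targets (e.g. mean RT 4018.79 / 6641.81 / 4030.60 ms, MD 0.44 / 0.51 /
#' 0.57, AUC 1.01 / 1.09 / 1.25, x-flips 7.64 / 8.75 / 9.23 for
#' truth-tellers / depressed / liars) and symptom-endorsement anchors chosen
#' to reproduce the published pairwise group differences (liars endorse 6.80
#' more atypical-symptom items than truth-tellers and 2.85 more than
#' depressed patients; truth-tellers average fewer than 3.5 endorsements on
#' concordant complex depressive items while both other groups average
#' more).
#'
#' Absolute endorsement anchors (only differences are published):
#' truth-tellers DS = 1.0, 2DS-c = 1.5, VAS = 0.5, 2DS-d = 6.0,
#' DS&EX-c = 0.5 endorsed items; other groups follow from the differences,
#' divided by the per-category item counts to give probabilities.
#'
#' @return Named list of three [group_profile()] objects
#'   (`truth_teller`, `liar`, `depressed`).
#' @export
default_profiles <- function() {
  list(
    truth_teller = group_profile(
      label = "truth_teller",
      endorse_prob = c(
        "DS" = 1.0 / 10, "2DS-c" = 1.5 / 15, "2DS-d" = 6.0 / 15,
        "VAS" = 0.5 / 15, "DS&EX-c" = 0.5 / 5, "DS&EX-d" = 0.4 / 5
      ),
      error_prob_controls = c("EX" = 0.55 / 5, "2EX-d" = 0.05, "2EX-c" = 0.05),
      rt_mean = 4018.79, rt_sd = 1466.98,
      it_mean = 620.35, it_sd = 491.94,
      mdtime_frac_mean = 2392.37 / 4018.79,
      md_mean = 0.44, md_sd = 0.31,
      auc_mean = 1.01,
      flip_rate_x = 7.64, flip_sd_x = 2.24,
      flip_rate_y = 7.74, flip_sd_y = 2.63
    ),
    liar = group_profile(
      label = "liar",
      endorse_prob = c(
        "DS" = 8.75 / 10, "2DS-c" = 13.35 / 15, "2DS-d" = 0.75 / 15,
        "VAS" = 7.30 / 15, "DS&EX-c" = 2.90 / 5, "DS&EX-d" = 0.6 / 5
      ),
      error_prob_controls = c("EX" = 0.35 / 5, "2EX-d" = 0.05, "2EX-c" = 0.05),
      rt_mean = 4030.60, rt_sd = 1203.67,
      it_mean = 559.57, it_sd = 399.84,
      mdtime_frac_mean = 2297.64 / 4030.60,
      md_mean = 0.57, md_sd = 0.24,
      auc_mean = 1.25,
      flip_rate_x = 9.23, flip_sd_x = 2.72,
      flip_rate_y = 9.20, flip_sd_y = 2.67
    ),
    depressed = group_profile(
      label = "depressed",
      endorse_prob = c(
        "DS" = 6.30 / 10, "2DS-c" = 8.35 / 15, "2DS-d" = 2.90 / 15,
        "VAS" = 4.45 / 15, "DS&EX-c" = 2.70 / 5, "DS&EX-d" = 0.5 / 5
      ),
      error_prob_controls = c("EX" = 0.10 / 5, "2EX-d" = 0.05, "2EX-c" = 0.05),
      rt_mean = 6641.81, rt_sd = 3204.22,
      it_mean = 408.67, it_sd = 332.99,
      mdtime_frac_mean = 4199.85 / 6641.81,
      md_mean = 0.51, md_sd = 0.30,
      auc_mean = 1.09,
      flip_rate_x = 8.75, flip_sd_x = 2.94,
      flip_rate_y = 8.05, flip_sd_y = 2.88
    )
  )
}

#' Expected feature targets implied by a profile
#'
#' The cohort-level means that [generate_cohort()] is calibrated to:
#' kinematic targets straight from the profile and expected endorsement /
#' error counts (probability times item count).
#'
#' @param profile A [group_profile()].
#' @param counts Items per category, defaults to
#'   [default_question_counts()].
#' @return A named numeric vector of expected values.
#' @export
profile_targets <- function(profile, counts = default_question_counts()) {
  endors <- profile$endorse_prob * counts[names(profile$endorse_prob)]
  errs <- profile$error_prob_controls *
    counts[names(profile$error_prob_controls)]
  c(
    rt_ms = profile$rt_mean,
    it_ms = profile$it_mean,
    md_time_ms = profile$mdtime_frac_mean * profile$rt_mean,
    md = profile$md_mean,
    auc = profile$auc_mean,
    x_flip = profile$flip_rate_x,
    y_flip = profile$flip_rate_y,
    setNames(endors, names(profile$endorse_prob)),
    setNames(errs, paste0("err_", names(profile$error_prob_controls)))
  )
}

#' Cohort configuration
#'
#' @param n_per_group Named counts of participants per group label. The
#'   defaults are the published training-cohort sizes (20/20/20); the test
#'   cohort uses 9/9/9.
#' @param seed Integer seed governing the whole cohort draw.
#' @param sampling_rate_hz Sampling rate used for the pre-movement (idle)
#'   phase of the raw logs.
#' @param geometry Screen geometry, see [default_geometry()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = c(truth_teller = 20, liar = 20,
                                          depressed = 20),
                          seed = 1L,
                          sampling_rate_hz = 70,
                          geometry = default_geometry()) {
  if (any(n_per_group < 0)) abort("group sizes must be non-negative")
  if (sampling_rate_hz <= 0) abort("sampling_rate_hz must be positive")
  validate_geometry(geometry)
  structure(
    list(
      n_per_group = n_per_group,
      seed = as.integer(seed),
      sampling_rate_hz = sampling_rate_hz,
      geometry = geometry
    ),
    class = "cohort_config"
  )
}

# lognormal draw parameterized by mean/sd on the natural scale
rlnorm_m <- function(n, m, s) {
  if (m <= 0) return(rep(0, n))
  if (s <= 0) return(rep(m, n))
  sigma2 <- log(1 + (s / m)^2)
  rlnorm(n, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# deviation bump shape: unimodal on (0,1), peak 1 at sp, 0 at the ends
bump_shape <- function(s, sp, kappa) {
  out <- numeric(length(s))
  inside <- s > 0 & s < 1
  si <- s[inside]
  out[inside] <- exp(kappa * (sp * log(si / sp) +
    (1 - sp) * log((1 - si) / (1 - sp))))
  out
}

shoelace_area <- function(x, y) {
  # closed-polygon area of the path plus the straight return segment,
  # oriented so leftward paths count deviation toward the non-chosen side
  # as positive (same convention as area_under_curve())
  a <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  if (x[length(x)] <= x[1]) a else -a
}

count_sign_flips <- function(coords, tol = 1e-9) {
  inc <- diff(coords)
  s <- sign(inc[abs(inc) > tol])
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

# insert a motor reversal (2 sign flips) by reflecting the step into frame j
apply_notch <- function(coords, j) {
  coords[j + 1] <- coords[j + 1] - 1.3 * (coords[j + 1] - coords[j])
  coords
}

# add a single trailing flip: overshoot the endpoint on the penultimate frame
apply_overshoot <- function(coords) {
  n <- length(coords)
  s <- sign(coords[n] - coords[n - 1])
  if (s == 0) s <- sign(coords[n] - coords[n - 2])
  if (s == 0) s <- 1
  coords[n - 1] <- coords[n] + 0.004 * s
  coords
}

adjust_flips <- function(coords, target, candidates) {
  cur <- count_sign_flips(coords)
  ci <- 1
  while (target - cur >= 2 && ci <= length(candidates)) {
    coords2 <- apply_notch(coords, candidates[ci])
    ci <- ci + 1
    cur2 <- count_sign_flips(coords2)
    if (cur2 > cur) {
      coords <- coords2
      cur <- cur2
    }
  }
  if (target - cur == 1) {
    coords2 <- apply_overshoot(coords)
    if (count_sign_flips(coords2) == target) coords <- coords2
  }
  coords
}

#' Synthesize one raw mouse trajectory
#'
#' Draws per-trial targets from the profile (lognormal RT/IT and maximum
#' deviation, Gaussian flip counts, AUC proportional to the MD draw) and
#' constructs a raw pixel path that realizes them: idle at the start button
#' for the initiation time, then a smooth start-to-box movement with a
#' perpendicular deviation bump peaking at the maximum-deviation latency,
#' one regressive loop whose swept area tops the AUC up to its target, and
#' micro-reversals that set the per-axis flip counts. Uses the current RNG
#' state; seed the stream (e.g. `withr::with_seed()`) for reproducibility.
#'
#' @param profile A [group_profile()].
#' @param target_side `"left"` or `"right"` response box.
#' @param geometry Screen geometry.
#' @param sampling_rate_hz Sampling rate of the idle phase; the movement
#'   phase is logged on the 101-point equal-time grid.
#' @return A tibble `t_ms`, `x_px`, `y_px`; attributes `response_side` and
#'   `targets` (the per-trial feature targets that were realized).
#' @export
synth_trajectory <- function(profile, target_side = c("left", "right"),
                             geometry = default_geometry(),
                             sampling_rate_hz = 70) {
  target_side <- match.arg(target_side)
  validate_geometry(geometry)
  gl <- geometry$box_left
  gs <- geometry$start
  if (abs(gl[["x"]] - gs[["x"]]) < 1 && abs(gl[["y"]] - gs[["y"]]) < 1) {
    abort("impossible geometry: response box overlaps the start point")
  }

  it <- rlnorm_m(1, profile$it_mean, profile$it_sd)
  rt <- rlnorm_m(1, profile$rt_mean, profile$rt_sd)
  tries <- 0
  while (rt < it + 200 && tries < 100) {
    rt <- rlnorm_m(1, profile$rt_mean, profile$rt_sd)
    tries <- tries + 1
  }
  if (rt < it + 200) rt <- it + 200

  amp <- min(rlnorm_m(1, profile$md_mean, profile$md_sd), 1.5)
  auc_t <- if (profile$md_mean > 0) {
    profile$auc_mean * amp / profile$md_mean
  } else {
    0
  }
  fx <- max(0L, as.integer(round(rnorm(1, profile$flip_rate_x,
                                       profile$flip_sd_x))))
  fy <- max(0L, as.integer(round(rnorm(1, profile$flip_rate_y,
                                       profile$flip_sd_y))))

  ex <- -max(0.80, min(1.15, profile$click_x_mean +
                         rnorm(1, 0, profile$click_x_sd)))
  ey <- max(1.315, min(1.68, profile$click_y_mean +
                         rnorm(1, 0, profile$click_y_sd)))
  chord_len <- sqrt(ex^2 + ey^2)
  dhat <- c(ex, ey) / chord_len
  nhat <- c(dhat[2], -dhat[1]) # points toward the non-chosen (right) side

  # movement-phase time grid: 101 frames, frame 1 still at the start;
  # onset must stay non-negative, so tiny initiation times are floored
  it <- max(it, rt / 100)
  dt <- (rt - it) / 99
  t0 <- max(it - dt, 0)
  frame_t <- t0 + dt * (0:100)

  # maximum-deviation frame on the trial clock
  md_time <- profile$mdtime_frac_mean * rt
  i_star <- round((md_time - t0) / dt)
  i_star <- min(max(i_star, 12), 92)

  # regressive-loop window (frozen chord progress, loop offsets)
  need_loop <- amp > 0 && auc_t > 0
  loop_len <- if (need_loop) 14L else 0L
  w0 <- if (i_star >= 50) 30L else 58L
  window <- if (loop_len > 0) w0:(w0 + loop_len - 1L) else integer(0)

  ds <- 1 / (100 - loop_len)
  step_is_window <- (1:100) %in% window
  s <- c(0, cumsum(ifelse(step_is_window, 0, ds)))
  s_peak <- s[i_star + 1]
  s_peak <- min(max(s_peak, 0.05), 0.95)

  build_base <- function(kappa) {
    w <- amp * bump_shape(s, s_peak, kappa)
    list(
      x = s * ex + w * nhat[1],
      y = s * ey + w * nhat[2],
      w = w
    )
  }

  kappa <- 3
  base <- build_base(kappa)
  a0 <- if (amp > 0) shoelace_area(base$x, base$y) else 0
  if (amp > 0 && a0 > auc_t) {
    lo <- 3
    hi <- 500
    for (i in 1:40) {
      kappa <- (lo + hi) / 2
      base <- build_base(kappa)
      a0 <- shoelace_area(base$x, base$y)
      if (a0 > auc_t) lo <- kappa else hi <- kappa
    }
    need_loop <- FALSE
  }
  px <- base$x
  py <- base$y

  if (need_loop) {
    delta <- auc_t - a0
    s_w <- s[w0 + 1]
    u_c <- s_w * chord_len
    g_w <- bump_shape(s_w, s_peak, kappa)
    eu_max <- min(0.55, 0.85 * u_c, 0.85 * (chord_len - u_c))
    # keep the loop dip strictly inside the bump amplitude (so the MD
    # argmax stays at the peak) and inside the screen
    ew_cap <- min(amp * (g_w + 0.92) / 2, (amp * g_w + 0.7) / 2)
    winding <- 2L
    eu <- delta / (winding * pi * ew_cap)
    while (eu > eu_max && winding < 8L) {
      winding <- winding + 1L
      eu <- delta / (winding * pi * ew_cap)
    }
    eu <- min(eu, eu_max)
    ew <- min(ew_cap, delta / (winding * pi * max(eu, 1e-9)))
    base_pt <- c(s_w * ex, s_w * ey) + amp * g_w * nhat
    place_loop <- function(eu) {
      theta <- 2 * pi * winding * seq_len(loop_len) / loop_len
      du <- eu * sin(theta)
      dw <- ew * (cos(theta) - 1)
      x2 <- px
      y2 <- py
      x2[window + 1] <- base_pt[1] + du * dhat[1] + dw * nhat[1]
      y2[window + 1] <- base_pt[2] + du * dhat[2] + dw * nhat[2]
      list(x = x2, y = y2)
    }
    for (i in 1:3) {
      pl <- place_loop(eu)
      got <- shoelace_area(pl$x, pl$y) - a0
      if (got > 1e-8) {
        eu <- min(eu * delta / got, 1.15 * eu_max)
      }
    }
    pl <- place_loop(eu)
    px <- pl$x
    py <- pl$y
  }

  # flip calibration: spaced candidate frames away from peak and loop
  # (with a buffer: a notch must never reflect a large loop-entry step)
  wbuf <- if (length(window) > 0) {
    (min(window) - 3L):(max(window) + 3L)
  } else {
    integer(0)
  }
  avail <- setdiff(4:96, c(wbuf, (i_star - 2):(i_star + 2)))
  cand <- avail[seq(1, length(avail), by = 4)]
  px <- adjust_flips(px, fx, cand)
  py <- adjust_flips(py, fy, cand + 1L)

  if (target_side == "right") px <- -px

  pix <- norm_to_px(px, py, geometry)
  scr <- geometry$screen
  x_px <- pmin(pmax(pix$x_px, 1), scr[["width"]] - 1)
  y_px <- pmin(pmax(pix$y_px, 1), scr[["height"]] - 1)

  idle_t <- if (t0 > 1e-9) {
    s <- seq(0, t0, by = 1000 / sampling_rate_hz)
    s[s < t0 - 1e-9]
  } else {
    numeric(0)
  }
  out <- tibble(
    t_ms = c(idle_t, frame_t),
    x_px = c(rep(x_px[1], length(idle_t)), x_px),
    y_px = c(rep(y_px[1], length(idle_t)), y_px)
  )
  attr(out, "response_side") <- target_side
  attr(out, "targets") <- c(
    it_ms = it, rt_ms = rt, md = amp, auc = auc_t,
    x_flip = fx, y_flip = fy, md_time_ms = t0 + (i_star) * dt
  )
  out
}

#' Simulate one participant
#'
#' Draws yes/no responses for every question of the stimulus set under the
#' group's response policy (endorsement probabilities on symptom items,
#' truthful keys perturbed by error probabilities on control items) and
#' synthesizes one raw trajectory toward the chosen response box ("yes" is
#' the left box).
#'
#' @param profile A [group_profile()].
#' @param stimulus_set Tibble from [build_stimulus_set()].
#' @param participant_id Identifier string.
#' @param config A [cohort_config()] (geometry and sampling rate).
#' @param trajectories Synthesize raw paths (`TRUE`) or responses only.
#' @return List with `responses` (tibble: `participant_id`, `question_id`,
#'   `category`, `response`, `response_side`) and `trajectories` (long
#'   tibble of raw samples, or `NULL`).
#' @export
sample_participant <- function(profile, stimulus_set, participant_id,
                               config = cohort_config(),
                               trajectories = TRUE) {
  n <- nrow(stimulus_set)
  cat <- stimulus_set$category
  p_yes <- numeric(n)
  is_symptom <- cat %in% SYMPTOM_CATEGORIES
  p_yes[is_symptom] <- profile$endorse_prob[cat[is_symptom]]
  if (any(!is_symptom)) {
    key_yes <- stimulus_set$key_healthy[!is_symptom] == "yes"
    perr <- profile$error_prob_controls[cat[!is_symptom]]
    p_yes[!is_symptom] <- ifelse(key_yes, 1 - perr, perr)
  }
  response <- ifelse(runif(n) < p_yes, "yes", "no")
  side <- ifelse(response == "yes", "left", "right")

  resp <- tibble(
    participant_id = participant_id,
    question_id = stimulus_set$id,
    category = cat,
    response = response,
    response_side = side
  )
  traj <- NULL
  if (trajectories) {
    traj <- purrr::map2_dfr(stimulus_set$id, side, function(qid, sd) {
      tr <- synth_trajectory(
        profile, sd,
        geometry = config$geometry,
        sampling_rate_hz = config$sampling_rate_hz
      )
      mutate(tr, participant_id = participant_id, question_id = qid,
             .before = 1)
    })
    attr(traj, "response_side") <- NULL
    attr(traj, "targets") <- NULL
  }
  list(responses = resp, trajectories = traj)
}

#' Generate a synthetic cohort
#'
#' Simulates every participant of the configured cohort deterministically
#' under the configuration seed. The default configuration reproduces the
#' study's training-cohort arithmetic (20 participants per condition, 60
#' total); `cohort_config(n_per_group = c(truth_teller = 9, liar = 9,
#' depressed = 9))` gives the 27-participant held-out cohort.
#'
#' @param config A [cohort_config()].
#' @param profiles Named list of [group_profile()]s, one per label in
#'   `config$n_per_group`.
#' @param stimulus_set Tibble from [build_stimulus_set()].
#' @param trajectories Synthesize raw paths (`TRUE`) or responses only
#'   (much faster; sufficient for endorsement-count analyses).
#' @return A `mouse_cohort`: list with `participants`, `responses`,
#'   `trajectories`, `stimulus_set`, `profiles`, `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            profiles = default_profiles(),
                            stimulus_set = build_stimulus_set(),
                            trajectories = TRUE) {
  missing_profiles <- setdiff(names(config$n_per_group), names(profiles))
  if (length(missing_profiles) > 0) {
    abort(paste0("no profile for group(s): ",
                 paste(missing_profiles, collapse = ", ")))
  }
  short <- c(truth_teller = "tt", liar = "li", depressed = "de")
  withr::with_seed(config$seed, {
    parts <- list()
    resps <- list()
    trajs <- list()
    for (grp in names(config$n_per_group)) {
      ng <- config$n_per_group[[grp]]
      if (ng == 0) next
      for (i in seq_len(ng)) {
        pid <- sprintf("%s_%03d", short[[grp]] %||% grp, i)
        sim <- sample_participant(
          profiles[[grp]], stimulus_set, pid, config,
          trajectories = trajectories
        )
        parts[[pid]] <- tibble(participant_id = pid, group = grp)
        resps[[pid]] <- sim$responses
        if (trajectories) trajs[[pid]] <- sim$trajectories
      }
    }
  })
  empty_parts <- tibble(participant_id = character(), group = character())
  structure(
    list(
      participants = if (length(parts)) bind_rows(parts) else empty_parts,
      responses = if (length(resps)) bind_rows(resps) else
        tibble(participant_id = character(), question_id = character(),
               category = character(), response = character(),
               response_side = character()),
      trajectories = if (length(trajs)) bind_rows(trajs) else NULL,
      stimulus_set = stimulus_set,
      profiles = profiles,
      config = config
    ),
    class = "mouse_cohort"
  )
}

#' @export
print.mouse_cohort <- function(x, ...) {
  sizes <- table(x$participants$group)
  cat("<mouse_cohort> ", nrow(x$participants), " participants (",
      paste(names(sizes), sizes, sep = "=", collapse = ", "), "), ",
      nrow(x$stimulus_set), " questions, seed ", x$config$seed, "\n",
      sep = "")
  invisible(x)
}

#' Write / read a cohort as plain-text files
#'
#' One trajectory CSV per participant (`<id>_trajectory.csv`: question_id,
#' t_ms, x_px, y_px), a shared responses CSV, and a JSON manifest carrying
#' the labels, seed and profile parameters.
#'
#' @param cohort A `mouse_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   rebuilds the cohort list (profiles become plain lists).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(
    cohort$responses, file.path(dir, "responses.csv")
  )
  readr::write_csv(cohort$stimulus_set, file.path(dir, "stimulus_set.csv"))
  if (!is.null(cohort$trajectories)) {
    for (pid in unique(cohort$trajectories$participant_id)) {
      readr::write_csv(
        cohort$trajectories %>%
          filter(.data$participant_id == pid) %>%
          select("question_id", "t_ms", "x_px", "y_px"),
        file.path(dir, paste0(pid, "_trajectory.csv"))
      )
    }
  }
  manifest <- list(
    participants = cohort$participants,
    seed = cohort$config$seed,
    sampling_rate_hz = cohort$config$sampling_rate_hz,
    n_per_group = as.list(cohort$config$n_per_group),
    profiles = lapply(cohort$profiles, unclass)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  participants <- as_tibble(manifest$participants)
  responses <- readr::read_csv(
    file.path(dir, "responses.csv"),
    col_types = readr::cols(.default = "c")
  )
  traj_files <- list.files(dir, pattern = "_trajectory\\.csv$",
                           full.names = TRUE)
  trajectories <- NULL
  if (length(traj_files) > 0) {
    trajectories <- purrr::map_dfr(traj_files, function(f) {
      pid <- sub("_trajectory\\.csv$", "", basename(f))
      readr::read_csv(
        f,
        col_types = readr::cols(
          question_id = "c", t_ms = "d", x_px = "d", y_px = "d"
        )
      ) %>%
        mutate(participant_id = pid, .before = 1)
    })
  }
  structure(
    list(
      participants = participants,
      responses = as_tibble(responses),
      trajectories = trajectories,
      stimulus_set = read_stimulus_set(file.path(dir, "stimulus_set.csv")),
      profiles = manifest$profiles,
      config = cohort_config(
        n_per_group = unlist(manifest$n_per_group),
        seed = manifest$seed,
        sampling_rate_hz = manifest$sampling_rate_hz
      )
    ),
    class = "mouse_cohort"
  )
}
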