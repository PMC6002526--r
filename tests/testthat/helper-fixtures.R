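# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

shared_stimulus <- function() {
  memo("stimulus", build_stimulus_set(seed = 11))
}

shared_train_cohort <- function() {
  memo("train_cohort", generate_cohort(
    cohort_config(seed = 101), stimulus_set = shared_stimulus()
  ))
}

shared_train_features <- function() {
  memo("train_features", extract_features(shared_train_cohort()))
}

shared_test_features <- function() {
  memo("test_features", extract_features(generate_cohort(
    cohort_config(
      n_per_group = c(truth_teller = 9, liar = 9, depressed = 9),
      seed = 202
    ),
    stimulus_set = shared_stimulus()
  )))
}

# a raw trajectory running exactly through given normalized waypoints,
# expressed in the trial's own normalized space (no pixel remapping)
path_through <- function(xs, ys, t_step = 100) {
  tibble::tibble(
    t_ms = t_step * (seq_along(xs) - 1),
    x = xs, y = ys
  )
}

# deterministic smooth random 101-frame standardized path
random_standard_path <- function() {
  t <- seq(0, 1, length.out = 101)
  x <- -t + 0.3 * sin(2 * pi * t * runif(1, 1, 3)) * runif(1, 0.1, 1)
  y <- 1.5 * t + 0.2 * sin(2 * pi * t * runif(1, 1, 4)) * runif(1, 0.1, 1)
  time_normalize(tibble::tibble(t_ms = t * 1000, x = x, y = y))
}

# independent brute-force oracles -------------------------------------------

oracle_max_point_line_distance <- function(x, y) {
  n <- length(x)
  x0 <- x[1]; y0 <- y[1]; x1 <- x[n]; y1 <- y[n]
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  max(vapply(seq_len(n), function(i) {
    abs((x1 - x0) * (y[i] - y0) - (y1 - y0) * (x[i] - x0)) / len
  }, numeric(1)))
}

oracle_flip_count <- function(coords) {
  inc <- diff(coords)
  inc <- inc[inc != 0]
  if (length(inc) < 2) return(0L)
  flips <- 0L
  for (i in 2:length(inc)) {
    if (sign(inc[i]) != sign(inc[i - 1])) flips <- flips + 1L
  }
  flips
}

oracle_anova <- function(values, groups) {
  # naive two-pass sums-of-squares
  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  ss_within <- 0
  ss_between <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss_within <- ss_within + sum((v - mean(v))^2)
    ss_between <- ss_between + length(v) * (mean(v) - grand)^2
  }
  k <- length(unique(groups))
  df_b <- k - 1
  df_w <- length(values) - k
  ms_w <- ss_within / df_w
  list(
    F = (ss_between / df_b) / ms_w,
    omega = (ss_between - df_b * ms_w) / (ss_total + ms_w)
  )
}

oracle_cfs_merit <- function(features, subset, labels) {
  # direct transcription of the merit formula, independent of cfs_merit()
  k <- length(subset)
  rcf <- mean(sapply(subset, function(nm) {
    abs(as.numeric(class_correlation(features[[nm]], labels)))
  }))
  if (k == 1) return(rcf)
  rff_vals <- c()
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      rff_vals <- c(rff_vals,
                    abs(cor(features[[subset[i]]], features[[subset[j]]])))
    }
  }
  rff <- mean(rff_vals)
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

exhaustive_cfs_best <- function(features, labels, feature_names) {
  best <- -Inf
  for (size in seq_along(feature_names)) {
    combs <- utils::combn(feature_names, size, simplify = FALSE)
    for (s in combs) {
      m <- cfs_merit(features, s, labels)
      if (m > best) best <- m
    }
  }
  best
}

# features with exactly known class/feature correlations: both features
# correlate 0.5 with the binary class and 0 with each other
exact_cfs_fixture <- function() {
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  g1 <- c(1, -1, 1, -1, 1, -1, 1, -1)
  g2 <- c(1, 1, -1, -1, 1, 1, -1, -1)
  z <- function(v) (v - mean(v)) / sd(v)
  f1 <- 0.5 * z(y) + sqrt(0.75) * z(g1)
  b <- -0.25 / sqrt(0.75)
  f2 <- 0.5 * z(y) + b * z(g1) + sqrt(1 - 0.25 - b^2) * z(g2)
  tibble::tibble(label = ifelse(y == 1, "a", "b"), f1 = f1, f2 = f2)
}
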