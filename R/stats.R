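# Univariate group comparisons: one-way ANOVA with omega-squared effect
# size and Tukey HSD post hoc contrasts, over the 83-feature table.

#' Per-group mean and SD of every feature
#'
#' @param features Feature tibble from [extract_features()] (column `label`
#'   plus schema columns).
#' @param feature_names Features to summarise; defaults to every schema
#'   column present.
#' @return A tidy tibble `feature`, `group`, `n`, `mean`, `sd`,
#'   `sd_degenerate` (TRUE when a single observation forced sd to 0).
#' @export
group_summary <- function(features, feature_names = NULL) {
  feature_names <- feature_names %||%
    intersect(feature_schema()$name, names(features))
  if (any(table(features$label) < 1) || nrow(features) == 0) {
    abort("every group must contain at least one participant")
  }
  features %>%
    select(dplyr::all_of(c("label", feature_names))) %>%
    tidyr::pivot_longer(-"label", names_to = "feature") %>%
    group_by(feature = .data$feature, group = .data$label) %>%
    summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() > 1, sd(.data$value), 0),
      sd_degenerate = dplyr::n() < 2,
      .groups = "drop"
    )
}

#' One-way ANOVA with omega-squared effect size
#'
#' Decomposes the total sum of squares into between- and within-group parts
#' and reports `F = MS_between / MS_within`, the p value from the F
#' distribution, and the omega-squared effect size
#' `(SS_b - df_b * MS_w) / (SS_t + MS_w)`, clamped below at 0 (attribute
#' `omega_clamped` records when the raw estimate was negative).
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length.
#' @param feature Optional feature name carried into the result.
#' @return A one-row tibble `feature`, `F`, `df_between`, `df_within`, `p`,
#'   `omega_sq`.
#' @export
oneway_anova <- function(values, groups, feature = NA_character_) {
  groups <- as.character(groups)
  keep <- complete.cases(values, groups)
  values <- values[keep]
  groups <- groups[keep]
  lv <- unique(groups)
  k <- length(lv)
  if (k < 2) abort("need at least 2 groups")
  if (any(table(groups) < 2)) abort("need at least 2 values per group")
  n <- length(values)
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ss_b <- sum(gn * (gm - grand)^2)
  ss_t <- sum((values - grand)^2)
  ss_w <- ss_t - ss_b
  df_b <- k - 1L
  df_w <- n - k
  ms_w <- ss_w / df_w
  if (ms_w <= 0) {
    f <- if (ss_b > 0) Inf else 0
    p <- if (ss_b > 0) 0 else 1
    omega <- if (ss_b > 0) 1 else 0
  } else {
    f <- (ss_b / df_b) / ms_w
    p <- pf(f, df_b, df_w, lower.tail = FALSE)
    omega <- (ss_b - df_b * ms_w) / (ss_t + ms_w)
  }
  clamped <- omega < 0
  out <- tibble(
    feature = feature, F = f, df_between = df_b, df_within = df_w,
    p = p, omega_sq = max(omega, 0)
  )
  attr(out, "omega_clamped") <- clamped
  out
}

#' ANOVA across every feature of a table
#'
#' @inheritParams group_summary
#' @param adjust Multiplicity adjustment for the p values column
#'   `p_adjusted` (any [stats::p.adjust()] method; `"none"` by default, as
#'   in classical per-feature screening).
#' @return Tibble with one [oneway_anova()] row per feature.
#' @export
anova_all <- function(features, feature_names = NULL, adjust = "none") {
  feature_names <- feature_names %||%
    intersect(feature_schema()$name, names(features))
  out <- purrr::map_dfr(feature_names, function(nm) {
    oneway_anova(features[[nm]], features$label, feature = nm)
  })
  out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
  out
}

#' Tukey HSD post hoc contrasts
#'
#' All unordered pairs of groups with the mean difference, the studentized
#' range statistic `q`, the pooled-variance t-style statistic
#' (`difference / SE(difference)`, i.e. `q / sqrt(2)`), and the adjusted p
#' value from the studentized range distribution.
#'
#' @inheritParams oneway_anova
#' @return Tibble `feature`, `group1`, `group2`, `mean_difference`,
#'   `statistic` (t-style), `q`, `p_adjusted`. The difference is
#'   `mean(group1) - mean(group2)`; swapping the pair flips its sign.
#' @export
tukey_hsd <- function(values, groups, feature = NA_character_) {
  groups <- as.character(groups)
  keep <- complete.cases(values, groups)
  values <- values[keep]
  groups <- groups[keep]
  lv <- sort(unique(groups))
  k <- length(lv)
  if (k < 2) abort("need at least 2 groups")
  if (any(table(groups) < 2)) abort("need at least 2 values per group")
  n <- length(values)
  gm <- tapply(values, groups, mean)[lv]
  gn <- tapply(values, groups, length)[lv]
  ss_w <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df_w <- n - k
  ms_w <- ss_w / df_w
  pairs <- utils::combn(lv, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]
    g2 <- pairs[2, j]
    diffm <- gm[[g1]] - gm[[g2]]
    se_q <- sqrt(ms_w / 2 * (1 / gn[[g1]] + 1 / gn[[g2]]))
    se_t <- sqrt(ms_w * (1 / gn[[g1]] + 1 / gn[[g2]]))
    q <- if (se_q > 0) abs(diffm) / se_q else if (diffm == 0) 0 else Inf
    p <- if (is.finite(q)) ptukey(q, k, df_w, lower.tail = FALSE) else 0
    tibble(
      feature = feature, group1 = g1, group2 = g2,
      mean_difference = diffm,
      statistic = if (se_t > 0) diffm / se_t else sign(diffm) * Inf,
      q = q, p_adjusted = p
    )
  })
}

#' Tukey contrasts across every feature of a table
#'
#' @inheritParams group_summary
#' @return Tibble of [tukey_hsd()] rows for every feature.
#' @export
tukey_all <- function(features, feature_names = NULL) {
  feature_names <- feature_names %||%
    intersect(feature_schema()$name, names(features))
  purrr::map_dfr(feature_names, function(nm) {
    tukey_hsd(features[[nm]], features$label, feature = nm)
  })
}

#' Internal consistency of three pairwise differences
#'
#' For three groups A, B, C the pairwise mean differences must satisfy
#' `diff(A,B) = diff(A,C) - diff(B,C)`. Checks a set of published or
#' computed differences for that identity.
#'
#' @param diff_ab,diff_ac,diff_bc The three pairwise differences, in the
#'   orientation `mean(first) - mean(second)`.
#' @param tol Absolute tolerance.
#' @return Logical flag with attribute `residual`.
#' @examples
#' transitivity_check(-7.75, -5.30, 2.45) # DS row: consistent
#' @export
transitivity_check <- function(diff_ab, diff_ac, diff_bc, tol = 1e-6) {
  if (any(is.na(c(diff_ab, diff_ac, diff_bc)))) {
    abort("all three pairwise differences are required")
  }
  resid <- diff_ab - (diff_ac - diff_bc)
  out <- abs(resid) <= tol
  attr(out, "residual") <- resid
  out
}
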