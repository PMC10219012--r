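# Statistical characterisation of the phenotype clusters.

#' Per-cluster summary statistics
#'
#' Arithmetic mean and n - 1 standard deviation of the requested variables
#' within each cluster, in long format.
#'
#' @param data Cohort data frame.
#' @param vars Variables to summarise.
#' @param cluster Name of the grouping column (default `"cluster"`).
#' @return Tibble with columns `cluster`, `variable`, `n`, `mean`, `sd`.
#' @export
summarize_clusters <- function(data, vars, cluster = "cluster") {
  stopifnot(all(c(vars, cluster) %in% names(data)))
  if (any(is.na(data[[cluster]]))) {
    abort("Cluster assignments contain NA.")
  }
  tibble::as_tibble(data) |>
    tidyr::pivot_longer(dplyr::all_of(vars),
      names_to = "variable", values_to = ".value"
    ) |>
    dplyr::group_by(cluster = .data[[cluster]], .data$variable) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$.value),
      sd = sd(.data$.value),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cluster, match(.data$variable, vars))
}

#' Sex-by-cluster counts
#'
#' @param data Cohort data frame with a `sex` column.
#' @param cluster Name of the grouping column.
#' @return A 2 x k contingency matrix (rows: sexes, columns: clusters).
#' @export
sex_by_cluster <- function(data, cluster = "cluster") {
  stopifnot(all(c("sex", cluster) %in% names(data)))
  as.matrix(table(data$sex, data[[cluster]]))
}

#' Pearson chi-square test with Cramer's V effect size
#'
#' Pearson's chi-square without continuity correction (the Yates correction
#' is a 2 x 2 device and is not applied), with Cramer's V
#' `sqrt(chi2 / (n * (min(dim) - 1)))` as effect size.
#'
#' @param tab Contingency matrix of non-negative counts with positive row
#'   and column margins, e.g. from [sex_by_cluster()].
#' @return A `contingency_result`: list with `observed`, `statistic`, `df`,
#'   `p_value`, `cramers_v`, `n`.
#' @examples
#' chi_square_cramers_v(rbind(female = c(36, 171, 116), male = c(92, 33, 66)))
#' @export
chi_square_cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("Contingency table must contain non-negative integer counts.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Contingency table has a zero margin.")
  }
  n <- sum(tab)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  v <- sqrt(unname(ct$statistic) / (n * (min(dim(tab)) - 1)))
  structure(
    list(
      observed = tab,
      statistic = unname(ct$statistic),
      df = unname(ct$parameter),
      p_value = ct$p.value,
      cramers_v = v,
      n = n
    ),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("Pearson chi-square:", signif(x$statistic, 5), " df:", x$df,
    " p:", format.pval(x$p_value, digits = 3),
    " Cramer's V:", round(x$cramers_v, 3), "\n")
  invisible(x)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Fits a one-way ANOVA of `value` on `group` and runs Tukey's honestly
#' significant difference test on all cluster pairs (Tukey--Kramer for
#' unequal group sizes, via the studentized range distribution).
#'
#' @param data Data frame.
#' @param value Name of the numeric response column.
#' @param group Name of the grouping column.
#' @param alpha Significance level for the `all_pairs_significant` flag.
#' @return A `tukey_result`: list with `f_statistic`, `p_value` (ANOVA),
#'   `pairs` (tibble: `pair`, `diff`, `lwr`, `upr`, `p_adj`) and
#'   `all_pairs_significant`.
#' @export
anova_tukey <- function(data, value, group, alpha = 0.05) {
  stopifnot(all(c(value, group) %in% names(data)))
  df <- tibble::tibble(
    .value = as.numeric(data[[value]]),
    .group = factor(data[[group]])
  )
  if (nlevels(df$.group) < 2 || any(table(df$.group) < 2)) {
    abort("Need at least 2 groups with at least 2 observations each.")
  }
  if (all(tapply(df$.value, df$.group, sd) == 0)) {
    abort("Zero within-group variance in every group; ANOVA is undefined.")
  }
  fit <- aov(.value ~ .group, data = df)
  smry <- summary(fit)[[1]]
  hsd <- TukeyHSD(fit, conf.level = 1 - alpha)$.group
  pairs <- tibble::tibble(
    pair = rownames(hsd),
    diff = hsd[, "diff"],
    lwr = hsd[, "lwr"],
    upr = hsd[, "upr"],
    p_adj = hsd[, "p adj"]
  )
  structure(
    list(
      variable = value,
      f_statistic = smry[["F value"]][1],
      p_value = smry[["Pr(>F)"]][1],
      df = c(smry[["Df"]][1], smry[["Df"]][2]),
      pairs = pairs,
      alpha = alpha,
      all_pairs_significant = all(pairs$p_adj < alpha)
    ),
    class = "tukey_result"
  )
}

#' @export
print.tukey_result <- function(x, ...) {
  cat("One-way ANOVA F =", signif(x$f_statistic, 5),
    " p =", format.pval(x$p_value, digits = 3), "\n")
  print(as.data.frame(x$pairs), digits = 4)
  invisible(x)
}

#' Keep only variables separating every cluster pair
#'
#' The study's selection rule: a variable characterises the phenotypes only
#' if its Tukey-adjusted p-value is below `alpha` for all three cluster
#' pairs; variables separating just two pairs are excluded.
#'
#' @param data Cohort data frame.
#' @param vars Candidate variable names.
#' @param cluster Name of the cluster column.
#' @param alpha Significance level.
#' @return Tibble with one row per variable: `variable`, `f_statistic`,
#'   `anova_p`, `min_pair_p`, `max_pair_p`, `keep`.
#' @export
select_discriminative_variables <- function(data, vars, cluster = "cluster",
                                            alpha = 0.05) {
  purrr::map_dfr(vars, function(v) {
    res <- anova_tukey(data, v, cluster, alpha = alpha)
    tibble::tibble(
      variable = v,
      f_statistic = res$f_statistic,
      anova_p = res$p_value,
      min_pair_p = min(res$pairs$p_adj),
      max_pair_p = max(res$pairs$p_adj),
      keep = res$all_pairs_significant
    )
  })
}

#' Mann-Whitney U test (normal approximation)
#'
#' Rank-sum test with mid-ranks for ties, tie-corrected variance and a 0.5
#' continuity correction, as in common commercial statistics packages. `U`
#' counts, over all pairs, how often a value of `a` exceeds one of `b`
#' (ties count one half). When all values are identical the p-value is 1 by
#' convention.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return One-row tibble with `u`, `z`, `p_value`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) {
    abort("Both groups must be non-empty.")
  }
  na <- length(a)
  nb <- length(b)
  n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(tibble::tibble(u = u, z = 0, p_value = 1, n_a = na, n_b = nb))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  if (abs(u - mu) <= 0.5) z <- 0
  tibble::tibble(
    u = u,
    z = z,
    p_value = min(1, 2 * pnorm(-abs(z))),
    n_a = na,
    n_b = nb
  )
}

#' Compare per-cluster Bonwill-arm and Balkwill-angle values to the norms
#'
#' Summarises the per-patient hinge-axis distance `Ie`--`Ax` (Bonwill-arm
#' analogue, norm 101.6 mm) and Balkwill-angle analogue (norm range 18--25
#' degrees) by cluster and flags agreement with the classical norms: the
#' arm is "within norm" when the norm value lies inside mean +/- SD, the
#' angle when the cluster mean falls inside the norm range.
#'
#' @param data Cohort data frame with `axv_mm`, `axh_mm` and a cluster
#'   column ([derive_articulator_values()] is applied if the derived
#'   columns are absent).
#' @param cluster Name of the cluster column.
#' @return Tibble with per-cluster `n`, means/SDs of `ie_ax_mm` and
#'   `balkwill_deg`, and logical flags `bonwill_within_norm`,
#'   `balkwill_within_norm`.
#' @export
bonwill_balkwill_report <- function(data, cluster = "cluster") {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) {
    return(tibble::tibble(
      cluster = integer(), n = integer(),
      ie_ax_mean = numeric(), ie_ax_sd = numeric(),
      balkwill_mean = numeric(), balkwill_sd = numeric(),
      bonwill_within_norm = logical(), balkwill_within_norm = logical()
    ))
  }
  stopifnot(cluster %in% names(data))
  if (!all(c("ie_ax_mm", "balkwill_deg") %in% names(data))) {
    data <- derive_articulator_values(data)
  }
  data |>
    dplyr::group_by(cluster = .data[[cluster]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      ie_ax_mean = mean(.data$ie_ax_mm),
      ie_ax_sd = sd(.data$ie_ax_mm),
      balkwill_mean = mean(.data$balkwill_deg),
      balkwill_sd = sd(.data$balkwill_deg),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bonwill_within_norm = abs(.data$ie_ax_mean - bonwill_norm_mm) <=
        dplyr::coalesce(.data$ie_ax_sd, 0),
      balkwill_within_norm = .data$balkwill_mean >= balkwill_norm_range_deg[1] &
        .data$balkwill_mean <= balkwill_norm_range_deg[2]
    )
}
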