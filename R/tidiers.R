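# broom-style tidiers for the package's fitted objects.

#' Tidy a phenotype clustering fit
#'
#' One row per cluster with raw-unit centre coordinates, size and (for
#' `k = 3`) phenotype label.
#'
#' @param x A `mounting_clusters` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mounting_clusters <- function(x, ...) {
  x$centers
}

#' @rdname tidy.mounting_clusters
#' @return For `glance()`: a one-row tibble with `k`, `n`, `totss`,
#'   `tot_withinss`, `prop_within` and the seed.
#' @export
glance.mounting_clusters <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n = length(x$cluster),
    totss = x$totss,
    tot_withinss = x$tot_withinss,
    prop_within = x$tot_withinss / x$totss,
    seed = x$seed
  )
}

#' @rdname tidy.mounting_clusters
#' @param data Data frame to augment; defaults to the clustered cohort.
#' @return For `augment()`: `data` with `.cluster` (factor) and, when
#'   available, `.phenotype` columns appended.
#' @export
augment.mounting_clusters <- function(x, data = x$data, ...) {
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    .cluster = factor(x$cluster)
  )
  if ("phenotype" %in% names(x$centers)) {
    out$.phenotype <- x$centers$phenotype[x$cluster]
  }
  out
}

#' Tidy a contingency-table result
#'
#' @param x A `contingency_result` from [chi_square_cramers_v()].
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df`, `p_value`, `cramers_v`,
#'   `n`.
#' @export
tidy.contingency_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    df = x$df,
    p_value = x$p_value,
    cramers_v = x$cramers_v,
    n = x$n
  )
}

#' Tidy ANOVA/Tukey results
#'
#' @param x A `tukey_result` from [anova_tukey()].
#' @param ... Unused.
#' @return `tidy()`: one row per cluster pair (`pair`, `diff`, `lwr`,
#'   `upr`, `p_adj`); `glance()`: the omnibus ANOVA row.
#' @export
tidy.tukey_result <- function(x, ...) {
  x$pairs
}

#' @rdname tidy.tukey_result
#' @export
glance.tukey_result <- function(x, ...) {
  tibble::tibble(
    variable = x$variable,
    f_statistic = x$f_statistic,
    df_between = x$df[1],
    df_within = x$df[2],
    p_value = x$p_value,
    all_pairs_significant = x$all_pairs_significant
  )
}
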