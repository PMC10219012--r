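# Cohort assembly and k-means phenotype clustering of mounting triples.

MOUNTING_VARS <- c("alpha_deg", "axv_mm", "axh_mm")

#' Apply the inclusion filter to a raw planning registry
#'
#' Drops cases flagged with an exclusion reason, then keeps only the most
#' recent plan of each patient who was planned more than once, and reports
#' the accounting.
#'
#' @param registry Data frame with columns `patient_id`, `plan` (integer
#'   plan sequence per patient) and `excluded_reason` (`NA` when not
#'   excluded); further columns are carried through.
#' @return A list with `cohort` (the included rows, one per patient) and
#'   `accounting` (one-row tibble: `eligible`, `excluded`,
#'   `superseded_plans`, `included`).
#' @export
filter_registry <- function(registry) {
  registry <- tibble::as_tibble(registry)
  needed <- c("patient_id", "plan", "excluded_reason")
  stopifnot(all(needed %in% names(registry)))
  dup <- registry |>
    dplyr::count(.data$patient_id, .data$plan) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "Inconsistent registry: duplicated (patient_id, plan) pairs for ",
      paste(head(dup$patient_id, 5), collapse = ", ")
    ))
  }
  eligible <- nrow(registry)
  kept <- dplyr::filter(registry, is.na(.data$excluded_reason))
  excluded <- eligible - nrow(kept)
  cohort <- kept |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_max(.data$plan, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  superseded <- nrow(kept) - nrow(cohort)
  list(
    cohort = cohort,
    accounting = tibble::tibble(
      eligible = eligible,
      excluded = excluded,
      superseded_plans = superseded,
      included = nrow(cohort)
    )
  )
}

#' Z-score cohort variables
#'
#' Centres and scales each variable to mean 0 and SD 1 (n - 1 denominator),
#' keeping the scaling parameters so cluster centres can be mapped back to
#' raw units.
#'
#' @param data Data frame.
#' @param vars Character vector of column names to scale.
#' @return A numeric matrix with attributes `center` and `scale`.
#' @export
scale_variables <- function(data, vars = MOUNTING_VARS) {
  stopifnot(all(vars %in% names(data)))
  if (nrow(data) < 2) {
    abort("Need at least 2 rows to scale variables.")
  }
  x <- as.matrix(dplyr::select(tibble::as_tibble(data), dplyr::all_of(vars)))
  storage.mode(x) <- "double"
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0(
      "Zero variance in variable(s): ",
      paste(vars[sds == 0], collapse = ", ")
    ))
  }
  ctr <- colMeans(x)
  z <- sweep(sweep(x, 2, ctr), 2, sds, `/`)
  attr(z, "center") <- ctr
  attr(z, "scale") <- sds
  z
}

# k-means++ seeding: first centre uniform, subsequent centres drawn with
# probability proportional to squared distance from the nearest chosen one.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- colSums((t(x) - centers[1, ])^2)
    for (j in 2:k) {
      d2[d2 < 0] <- 0
      i <- if (sum(d2) > 0) sample.int(n, 1, prob = d2) else sample.int(n, 1)
      centers[j, ] <- x[i, ]
      d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
    }
  }
  centers
}

#' Fit k-means with k-means++ seeding and restarts
#'
#' Lloyd iterations from k-means++ starting centres, best of `n_restarts`
#' by total within-cluster sum of squares; deterministic for a fixed seed.
#' Exact distance ties in assignment go to the lowest cluster index.
#'
#' @param x Numeric matrix (observations in rows), typically from
#'   [scale_variables()].
#' @param k Number of clusters, `1 <= k <= nrow(x)`.
#' @param seed Integer RNG seed.
#' @param n_restarts Number of independent starts.
#' @return A `stats::kmeans` fit object (the best restart).
#' @export
kmeans_fit <- function(x, k, seed = 20230521, n_restarts = 25) {
  x <- as.matrix(x)
  if (k < 1 || k > nrow(x)) {
    abort("`k` must be between 1 and the number of observations.")
  }
  with_seed(seed, {
    if (nrow(unique(x)) < k) {
      abort("Fewer than `k` distinct observations; cannot place k centres.")
    }
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- kmeanspp_init(x, k)
      tries <- 0
      while (anyDuplicated(init) && tries < 20) {
        init <- kmeanspp_init(x, k)
        tries <- tries + 1
      }
      fit <- suppressWarnings(
        kmeans(x, centers = init, iter.max = 100, algorithm = "Lloyd")
      )
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) {
        best <- fit
      }
    }
    best
  })
}

#' Select the cluster count at the elbow of a WSS curve
#'
#' Operationalises the verbal elbow criterion ("where the curve starts to
#' flatten") as the candidate `k` whose point on the within-cluster
#' sum-of-squares curve lies farthest (perpendicular distance) from the
#' chord joining the curve's first and last points; ties break towards the
#' smallest `k`. Invariant under positive rescaling of the curve.
#'
#' @param wss Numeric vector of total within-cluster sums of squares.
#' @param ks Candidate cluster counts (default `1:length(wss)`).
#' @return The selected integer `k`.
#' @export
elbow_select <- function(wss, ks = seq_along(wss)) {
  stopifnot(length(wss) == length(ks), length(wss) >= 3)
  if (any(diff(wss) > 1e-8 * max(abs(wss)))) {
    warn("WSS curve is not non-increasing; elbow selection may be unreliable.")
  }
  x1 <- ks[1]; y1 <- wss[1]
  x2 <- ks[length(ks)]; y2 <- wss[length(wss)]
  d <- abs((y2 - y1) * ks - (x2 - x1) * wss + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  ks[which.max(d)]
}

#' Assign skeletal-phenotype labels to three cluster centres
#'
#' Encodes the study's reading of the three phenotypes: the cluster with
#' the largest `AxH` is the balanced face, the one with the smallest `AxV`
#' the vertical face with class II, and the one with the smallest `alpha`
#' the horizontal face with class III. An error is raised when the rules
#' collide on one cluster (the centres then do not show the expected
#' structure).
#'
#' @param centers Data frame of raw-unit centres with columns `alpha_deg`,
#'   `axv_mm`, `axh_mm`, one row per cluster.
#' @return Character vector of phenotype labels (`"balanced"`,
#'   `"vertical_II"`, `"horizontal_III"`), one per row of `centers`.
#' @export
label_clusters <- function(centers) {
  stopifnot(all(MOUNTING_VARS %in% names(centers)))
  if (nrow(centers) != 3) {
    abort("Phenotype labelling is defined for exactly 3 clusters.")
  }
  idx <- c(
    balanced = which.max(centers$axh_mm),
    vertical_II = which.min(centers$axv_mm),
    horizontal_III = which.min(centers$alpha_deg)
  )
  if (anyDuplicated(idx)) {
    abort(paste0(
      "Ambiguous phenotype labelling: rules collide on one cluster. Centres:\n",
      paste(utils::capture.output(print(as.data.frame(centers))), collapse = "\n")
    ))
  }
  labels <- character(3)
  labels[idx] <- names(idx)
  labels
}

#' Cluster a cohort of mounting triples into skeletal phenotypes
#'
#' The full clustering stage: z-scores the mounting variables, computes the
#' within-cluster sum-of-squares curve over `1:kmax`, selects `k` by the
#' elbow criterion (unless `k` is given), fits the final k-means model and
#' -- when `k == 3` -- attaches phenotype labels.
#'
#' @param data Cohort data frame containing the mounting variables.
#' @param vars Variables to cluster on (default the mounting triple).
#' @param kmax Largest candidate cluster count for the elbow curve.
#' @param k Optional fixed cluster count, bypassing elbow selection.
#' @param seed Integer RNG seed for the k-means restarts.
#' @param n_restarts Restarts per candidate `k`.
#' @return A `mounting_clusters` object: list with `k`, `cluster`
#'   (assignments), `centers_scaled`, `centers` (raw-unit tibble with
#'   `phenotype`, `n`), `wss_curve`, `totss`, `seed`, `vars`.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' fit <- cluster_mounting(cohort)
#' fit$centers
#' @export
cluster_mounting <- function(data, vars = MOUNTING_VARS, kmax = 10, k = NULL,
                             seed = 20230521, n_restarts = 25) {
  if (!is.null(k) && (k < 1 || k > nrow(data))) {
    abort("`k` must be between 1 and the number of observations.")
  }
  if (kmax < 3) {
    abort("`kmax` must be at least 3.")
  }
  z <- scale_variables(data, vars)
  kmax_eff <- min(kmax, nrow(z))
  wss <- vapply(
    seq_len(kmax_eff),
    function(kk) kmeans_fit(z, kk, seed = seed + kk, n_restarts = n_restarts)$tot.withinss,
    numeric(1)
  )
  k_sel <- if (is.null(k)) elbow_select(wss, seq_len(kmax_eff)) else as.integer(k)
  fit <- kmeans_fit(z, k_sel, seed = seed + k_sel, n_restarts = n_restarts)
  raw <- sweep(
    sweep(fit$centers, 2, attr(z, "scale"), `*`),
    2, attr(z, "center"), `+`
  )
  centers <- tibble::as_tibble(raw) |>
    dplyr::mutate(
      cluster = dplyr::row_number(),
      n = as.integer(fit$size),
      .before = 1
    )
  if (k_sel == 3 && setequal(vars, MOUNTING_VARS)) {
    centers$phenotype <- label_clusters(centers)
  }
  structure(
    list(
      k = k_sel,
      cluster = fit$cluster,
      centers_scaled = fit$centers,
      centers = centers,
      wss_curve = tibble::tibble(k = seq_len(kmax_eff), wss = wss),
      totss = fit$totss,
      tot_withinss = fit$tot.withinss,
      scaling = list(center = attr(z, "center"), scale = attr(z, "scale")),
      seed = seed,
      vars = vars,
      data = tibble::as_tibble(data)
    ),
    class = "mounting_clusters"
  )
}

#' @export
print.mounting_clusters <- function(x, ...) {
  cat("k-means skeletal-phenotype clustering (", x$k, " clusters, n = ",
    length(x$cluster), ")\n", sep = "")
  cat("Raw-unit centres:\n")
  print(as.data.frame(x$centers), digits = 4)
  invisible(x)
}
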