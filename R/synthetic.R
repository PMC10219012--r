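# Synthetic-cohort generator: a 3-component Gaussian mixture over the
# mounting triple with the per-cluster sample sizes, sex compositions, age
# structure and cephalometric profiles of the study cohort, plus known
# ground-truth cluster labels so every pipeline stage can be validated
# without patient data.

CEPH_DISCRIMINATIVE <- c(
  "facial_axis", "facial_depth", "snb", "rel_mand_length", "sna",
  "convexity_point_a", "rel_max_mand_ratio", "sagittal_molar_distance",
  "lower_lip_e_line"
)

CEPH_NONDISCRIMINATIVE <- c(
  "mandibular_plane", "inner_gonion_angle", "maxillary_position",
  "palatal_plane", "rel_max_length", "lower_facial_height",
  "lower_incisor_position", "lower_incisor_inclination",
  "upper_incisor_position", "upper_incisor_inclination",
  "inter_incisor_angle", "vertical_molar_distance", "upper_lip_drape"
)

default_ceph_table <- function() {
  # Nine phenotype-discriminative variables: per-cluster means/SDs as
  # reported for the study cohort. The maxillo-mandibular length ratio is
  # stated at a print precision (1.4/1.3/1.4) at which clusters 1 and 3
  # coincide although their comparison is reported significant; the
  # defaults 1.42/1.30/1.38 stay within that precision while preserving
  # the reported separation.
  disc <- tibble::tribble(
    ~variable,                  ~m1,    ~s1,  ~m2,   ~s2,  ~m3,   ~s3,
    "facial_axis",               89.1,  5.7,  85.7,  5.9,  91.8,  6.5,
    "facial_depth",              89.5,  4.8,  85.7,  5.0,  92.1,  5.3,
    "snb",                       80.2,  5.6,  76.0,  5.2,  82.4,  6.4,
    "rel_mand_length",          118.7, 10.0, 106.3,  9.0, 114.0,  9.2,
    "sna",                       82.4,  4.3,  79.9,  4.3,  81.1,  4.9,
    "convexity_point_a",          1.3,  4.8,   2.8,  5.0,  -2.8,  4.6,
    "rel_max_mand_ratio",        1.42,  0.1,  1.30,  0.1,  1.38,  0.1,
    "sagittal_molar_distance",   20.4,  4.8,  16.9,  4.2,  19.1,  4.5,
    "lower_lip_e_line",          -2.2,  3.6,  -1.3,  3.0,  -3.3,  3.3
  )
  # Thirteen variables that separate only two of three clusters by design:
  # clusters 1 and 2 share the base mean (typical cephalometric norm
  # values), cluster 3 sits 1.5 SD away, so the all-pairs selection rule
  # excludes them.
  nond <- tibble::tribble(
    ~variable,                   ~base,  ~sd,
    "mandibular_plane",            24,    5,
    "inner_gonion_angle",          38,    4,
    "maxillary_position",          90,    3.5,
    "palatal_plane",                1,    3.5,
    "rel_max_length",              85,    5,
    "lower_facial_height",         47,    5,
    "lower_incisor_position",     1.5,    2.5,
    "lower_incisor_inclination",   24,    6,
    "upper_incisor_position",       6,    2.5,
    "upper_incisor_inclination",   30,    6,
    "inter_incisor_angle",        127,   10,
    "vertical_molar_distance",     21,    3,
    "upper_lip_drape",            100,    8
  )
  dplyr::bind_rows(
    purrr::pmap_dfr(disc, function(variable, m1, s1, m2, s2, m3, s3) {
      tibble::tibble(
        variable = variable, cluster = 1:3,
        mean = c(m1, m2, m3), sd = c(s1, s2, s3),
        discriminative = TRUE
      )
    }),
    purrr::pmap_dfr(nond, function(variable, base, sd) {
      tibble::tibble(
        variable = variable, cluster = 1:3,
        mean = c(base, base, base + 1.5 * sd), sd = sd,
        discriminative = FALSE
      )
    })
  )
}

#' Synthetic-cohort generator specification
#'
#' Bundles the parameters of the synthetic surgical cohort: per-cluster
#' sample sizes and sex counts, Gaussian means/SDs of the mounting triple,
#' age distributions by cluster and sex, and per-cluster Gaussians for the
#' 22 cephalometric variables (9 separating all cluster pairs, 13 by
#' design separating only two). Defaults reproduce the published per-cluster
#' summaries of the 514-patient study cohort; variables are independent
#' within cluster (no within-cluster covariances were published).
#'
#' @param clusters Tibble with one row per cluster: `cluster`, `phenotype`,
#'   `n_female`, `n_male`, `alpha_mean`, `alpha_sd`, `axv_mean`, `axv_sd`,
#'   `axh_mean`, `axh_sd`.
#' @param age Tibble with `cluster`, `sex`, `age_mean`, `age_sd`.
#' @param ceph Tibble with `variable`, `cluster`, `mean`, `sd`,
#'   `discriminative`, or `NULL` to omit cephalometric variables.
#' @return A `generator_spec` object.
#' @examples
#' spec <- generator_spec()
#' sum(spec$clusters$n_female + spec$clusters$n_male) # 514
#' @export
generator_spec <- function(clusters = NULL, age = NULL, ceph = default_ceph_table()) {
  if (is.null(clusters)) {
    clusters <- tibble::tribble(
      ~cluster, ~phenotype,       ~n_female, ~n_male,
      ~alpha_mean, ~alpha_sd, ~axv_mean, ~axv_sd, ~axh_mean, ~axh_sd,
      1L, "balanced",       36L,  92L,  7.8, 3.4, 36.2, 4.6, 98.9, 5.5,
      2L, "vertical_II",   171L,  33L, 11.1, 3.3, 26.5, 3.8, 88.1, 5.4,
      3L, "horizontal_III", 116L,  66L,  2.4, 4.0, 35.9, 4.5, 85.6, 5.6
    )
  }
  if (is.null(age)) {
    age <- tibble::tribble(
      ~cluster, ~sex,     ~age_mean, ~age_sd,
      1L, "female", 26.3, 9.2,
      1L, "male",   28.8, 9.0,
      2L, "female", 26.0, 7.9,
      2L, "male",   27.6, 7.0,
      3L, "female", 26.3, 9.7,
      3L, "male",   26.9, 7.9
    )
  }
  if (any(clusters$n_female + clusters$n_male <= 0)) {
    abort("Every cluster must contain at least one patient.")
  }
  sds <- c(clusters$alpha_sd, clusters$axv_sd, clusters$axh_sd, age$age_sd)
  if (!is.null(ceph)) sds <- c(sds, ceph$sd)
  if (any(sds < 0) || !all(is.finite(sds))) {
    abort("All SDs must be finite and >= 0.")
  }
  structure(
    list(clusters = clusters, age = age, ceph = ceph),
    class = "generator_spec"
  )
}

#' @export
print.generator_spec <- function(x, ...) {
  cat("<generator_spec> ", nrow(x$clusters), " clusters, n = ",
    sum(x$clusters$n_female + x$clusters$n_male), " patients, ",
    if (is.null(x$ceph)) 0L else dplyr::n_distinct(x$ceph$variable),
    " cephalometric variables\n", sep = "")
  print(as.data.frame(x$clusters), digits = 3)
  invisible(x)
}

# Truncated-normal draws by resampling (no point mass at the bounds).
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (mean <= lower || mean >= upper) {
      abort("Degenerate draw outside the truncation bounds.")
    }
    return(rep(mean, n))
  }
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  guard <- 0
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower | x[bad] >= upper]
    guard <- guard + 1
    if (guard > 1000) abort("Truncation bounds reject essentially all draws.")
  }
  x
}

#' Generate a synthetic surgical cohort with known cluster labels
#'
#' Draws each cluster's patients from independent per-variable Gaussians
#' (mounting triple truncated to its valid range: `|alpha| < 90`,
#' `AxV > 0`, `AxH > 0`), assigns sexes per the cluster's sex counts and
#' ages from the sex-specific age distributions, and attaches the
#' ground-truth cluster and phenotype of every patient.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer RNG seed; the same seed reproduces the table
#'   exactly.
#' @return Tibble with `patient_id`, `sex`, `age`, `alpha_deg`, `axv_mm`,
#'   `axh_mm`, one column per cephalometric variable, `true_cluster`,
#'   `true_phenotype`.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' nrow(cohort)
#' @export
generate_cohort <- function(spec = generator_spec(), seed = 20230521) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(seed, {
    rows <- purrr::pmap_dfr(spec$clusters, function(cluster, phenotype,
                                                    n_female, n_male,
                                                    alpha_mean, alpha_sd,
                                                    axv_mean, axv_sd,
                                                    axh_mean, axh_sd) {
      n <- n_female + n_male
      sex <- sample(rep(c("female", "male"), c(n_female, n_male)))
      age_par <- dplyr::filter(spec$age, .data$cluster == !!cluster)
      age <- numeric(n)
      for (s in unique(sex)) {
        i <- which(sex == s)
        p <- dplyr::filter(age_par, .data$sex == s)
        age[i] <- rtrunc_norm(length(i), p$age_mean, p$age_sd, lower = 0)
      }
      out <- tibble::tibble(
        sex = sex,
        age = age,
        alpha_deg = rtrunc_norm(n, alpha_mean, alpha_sd, -90, 90),
        axv_mm = rtrunc_norm(n, axv_mean, axv_sd, lower = 0),
        axh_mm = rtrunc_norm(n, axh_mean, axh_sd, lower = 0),
        true_cluster = cluster,
        true_phenotype = phenotype
      )
      if (!is.null(spec$ceph)) {
        cpar <- dplyr::filter(spec$ceph, .data$cluster == !!cluster)
        for (j in seq_len(nrow(cpar))) {
          out[[cpar$variable[j]]] <- rnorm(n, cpar$mean[j], cpar$sd[j])
        }
      }
      out
    })
    rows |>
      dplyr::mutate(
        patient_id = sprintf("P%04d", dplyr::row_number()),
        .before = 1
      ) |>
      dplyr::relocate("true_cluster", "true_phenotype", .after = dplyr::last_col())
  })
}

#' Generate per-patient landmark sets realising a synthetic cohort
#'
#' Draws a cohort with [generate_cohort()] and lays out, per patient, a
#' calibrated landmark set whose [compute_mounting()] reproduces that
#' patient's mounting triple (via [invert_mounting()]). Layout degrees of
#' freedom are jittered per patient so the sets are not congruent.
#'
#' @param spec A [generator_spec()].
#' @param facebow A [facebow_spec()].
#' @param seed Integer RNG seed.
#' @return A list with `landmarks` (long tibble: `patient_id`, `landmark`,
#'   `x`, `y`, `ref_distance_mm`) and `cohort` (the generated cohort
#'   table).
#' @export
generate_landmark_cohort <- function(spec = generator_spec(),
                                     facebow = facebow_spec(d_ns_mm = 23),
                                     seed = 20230521) {
  cohort <- generate_cohort(spec, seed = seed)
  with_seed(seed + 1L, {
    ns_x <- stats::runif(nrow(cohort), 90, 110)
    span <- stats::runif(nrow(cohort), 30, 40)
    landmarks <- purrr::pmap_dfr(
      list(cohort$patient_id, cohort$alpha_deg, cohort$axv_mm, cohort$axh_mm,
        ns_x, span),
      function(id, a, v, h, nsx, sp) {
        lm <- invert_mounting(a, v, h, facebow,
          ns_x_mm = nsx, ie_dc_span_mm = sp
        )
        tibble::tibble(
          patient_id = id, landmark = lm$landmark, x = lm$x, y = lm$y,
          ref_distance_mm = attr(lm, "ref_distance_mm")
        )
      }
    )
    list(landmarks = landmarks, cohort = cohort)
  })
}

#' Generate a raw planning-registry fixture
#'
#' Builds a registry of planning cases for exercising the inclusion filter:
#' `n_eligible` cases of which `n_excluded` carry an exclusion reason and
#' `n_second_plans` patients (among the non-excluded) were planned twice;
#' [filter_registry()] on the result yields
#' `n_eligible - n_excluded - n_second_plans` included patients. Flag
#' positions are randomised by `seed`.
#'
#' @param n_eligible Total number of planning cases.
#' @param n_excluded Cases meeting an exclusion criterion.
#' @param n_second_plans Patients planned twice.
#' @param seed Integer RNG seed.
#' @return Tibble with `patient_id`, `plan`, `excluded_reason`.
#' @examples
#' reg <- generate_registry_fixture(568, 37, 17, seed = 1)
#' filter_registry(reg)$accounting
#' @export
generate_registry_fixture <- function(n_eligible = 568, n_excluded = 37,
                                      n_second_plans = 17, seed = 20230521) {
  if (n_excluded < 0 || n_second_plans < 0 ||
    n_excluded + 2 * n_second_plans > n_eligible) {
    abort("Invalid counts: need n_excluded + 2 * n_second_plans <= n_eligible.")
  }
  with_seed(seed, {
    n_included_cases <- n_eligible - n_excluded
    n_patients <- n_included_cases - n_second_plans
    reasons <- c(
      "orofacial syndrome", "comprehensive prosthetic rehabilitation",
      "distraction osteogenesis"
    )
    twice <- if (n_patients > 0) sample.int(n_patients, n_second_plans) else integer()
    ok <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n_patients)),
      plan = 1L,
      excluded_reason = NA_character_
    )
    second <- tibble::tibble(
      patient_id = sprintf("P%04d", twice),
      plan = 2L,
      excluded_reason = NA_character_
    )
    excl <- tibble::tibble(
      patient_id = sprintf("X%04d", seq_len(n_excluded)),
      plan = 1L,
      excluded_reason = if (n_excluded > 0) {
        sample(reasons, n_excluded, replace = TRUE)
      } else {
        character()
      }
    )
    out <- dplyr::bind_rows(ok, second, excl)
    out[sample.int(nrow(out)), ]
  })
}
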