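# Readers/writers and the umbrella pipeline wiring every stage together.

#' Read a landmark CSV
#'
#' Expects columns `patient_id`, `landmark`, `x`, `y` and optionally
#' `ref_distance_mm` (otherwise supply it as an argument). Coordinates are
#' x anterior-positive, y superior-positive.
#'
#' @param path CSV path (UTF-8, header required).
#' @param ref_distance_mm Scaling distance applied to every patient when
#'   the column is absent.
#' @return A tibble.
#' @export
read_landmarks <- function(path, ref_distance_mm = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("patient_id", "landmark", "x", "y") %in% names(df)))
  if (!"ref_distance_mm" %in% names(df)) {
    if (is.null(ref_distance_mm)) {
      abort("Provide `ref_distance_mm` as a CSV column or argument.")
    }
    df$ref_distance_mm <- ref_distance_mm
  }
  df
}

#' Write a per-patient mounting table
#'
#' Writes `patient_id, alpha_deg, axv_mm, axh_mm, ie_ax_mm, balkwill_deg`
#' (degrees and mm as named), deriving the articulator values if absent.
#'
#' @param mounting Data frame with at least `patient_id`, `alpha_deg`,
#'   `axv_mm`, `axh_mm`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mounting_csv <- function(mounting, path) {
  if (!all(c("ie_ax_mm", "balkwill_deg") %in% names(mounting))) {
    mounting <- derive_articulator_values(mounting)
  }
  readr::write_csv(
    dplyr::select(
      mounting, "patient_id", "alpha_deg", "axv_mm", "axh_mm",
      "ie_ax_mm", "balkwill_deg"
    ),
    path
  )
  invisible(path)
}

#' Run the complete mounting-phenotype analysis
#'
#' Executes the full pipeline on a cohort table: inclusion filtering (when
#' registry columns are present), k-means clustering of the mounting triple
#' with elbow selection, phenotype labelling, per-cluster summaries,
#' sex-by-cluster contingency with Cramer's V, ANOVA/Tukey on the mounting
#' variables, the all-pairs selection rule over any cephalometric columns,
#' Mann--Whitney sex comparisons of the mounting values,
#' Bonwill-arm/Balkwill-angle norm comparison, and integer mounting
#' presets per phenotype.
#'
#' @param cohort Cohort data frame (e.g. from [generate_cohort()], or a raw
#'   registry with `plan`/`excluded_reason` columns).
#' @param kmax,k,seed,n_restarts Passed to [cluster_mounting()].
#' @param alpha Significance level for all tests.
#' @param ceph_vars Cephalometric variable columns to screen with the
#'   selection rule; defaults to any of the generator's 22 names present.
#' @param out_dir Optional directory; when given, CSV/JSON reports are
#'   written there.
#' @return A `mounting_analysis` list: `accounting`, `clusters`
#'   (the [cluster_mounting()] fit), `summary`, `sex_contingency`,
#'   `mounting_tests`, `variable_selection`, `sex_mounting_tests`,
#'   `bonwill_balkwill`, `presets`, `config` (seed, parameters, hash).
#' @examples
#' res <- run_full_analysis(generate_cohort(seed = 1), seed = 1)
#' res$presets
#' @export
run_full_analysis <- function(cohort, kmax = 10, k = NULL, seed = 20230521,
                              n_restarts = 25, alpha = 0.05,
                              ceph_vars = NULL, out_dir = NULL) {
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) == 0) {
    abort("Empty cohort: nothing to filter or cluster.")
  }
  accounting <- NULL
  if (all(c("plan", "excluded_reason") %in% names(cohort))) {
    filt <- filter_registry(cohort)
    cohort <- filt$cohort
    accounting <- filt$accounting
  }
  if (nrow(cohort) == 0) {
    abort("No patients remain after inclusion filtering.")
  }
  fit <- cluster_mounting(cohort,
    kmax = kmax, k = k, seed = seed, n_restarts = n_restarts
  )
  labelled <- dplyr::mutate(cohort, cluster = fit$cluster)
  if ("phenotype" %in% names(fit$centers)) {
    labelled$phenotype <- fit$centers$phenotype[fit$cluster]
  }
  summary_tbl <- summarize_clusters(labelled, c(MOUNTING_VARS, "age"))
  sex_cont <- if ("sex" %in% names(labelled)) {
    chi_square_cramers_v(sex_by_cluster(labelled))
  }
  mounting_tests <- purrr::map_dfr(MOUNTING_VARS, function(v) {
    res <- anova_tukey(labelled, v, "cluster", alpha = alpha)
    tibble::tibble(
      variable = v, f_statistic = res$f_statistic, p_value = res$p_value,
      all_pairs_significant = res$all_pairs_significant
    )
  })
  if (is.null(ceph_vars)) {
    ceph_vars <- intersect(
      c(CEPH_DISCRIMINATIVE, CEPH_NONDISCRIMINATIVE), names(labelled)
    )
  }
  selection <- if (length(ceph_vars) && fit$k >= 2) {
    select_discriminative_variables(labelled, ceph_vars, alpha = alpha)
  }
  sex_mounting <- if ("sex" %in% names(labelled) &&
    dplyr::n_distinct(labelled$sex) == 2) {
    sexes <- sort(unique(labelled$sex))
    purrr::map_dfr(c(MOUNTING_VARS, "age"), function(v) {
      if (!v %in% names(labelled)) {
        return(NULL)
      }
      dplyr::mutate(
        mann_whitney(
          labelled[[v]][labelled$sex == sexes[1]],
          labelled[[v]][labelled$sex == sexes[2]]
        ),
        variable = v, .before = 1
      )
    })
  }
  bb <- bonwill_balkwill_report(labelled)
  presets <- if ("phenotype" %in% names(fit$centers)) {
    round_presets(
      dplyr::select(
        fit$centers, "cluster", "phenotype",
        "alpha_deg", "axv_mm", "axh_mm"
      )
    )
  }
  config <- list(
    kmax = kmax, k = fit$k, seed = seed, n_restarts = n_restarts,
    alpha = alpha, n_patients = nrow(labelled)
  )
  config$hash <- rlang::hash(config)
  out <- structure(
    list(
      accounting = accounting,
      clusters = fit,
      cohort = labelled,
      summary = summary_tbl,
      sex_contingency = sex_cont,
      mounting_tests = mounting_tests,
      variable_selection = selection,
      sex_mounting_tests = sex_mounting,
      bonwill_balkwill = bb,
      presets = presets,
      config = config
    ),
    class = "mounting_analysis"
  )
  if (!is.null(out_dir)) {
    write_analysis_reports(out, out_dir)
  }
  out
}

#' @export
print.mounting_analysis <- function(x, ...) {
  cat("Mounting phenotype analysis: n =", x$config$n_patients,
    "patients, k =", x$config$k, "clusters (seed", paste0(x$config$seed, ")\n"))
  if (!is.null(x$presets)) {
    cat("Phenotype mounting presets:\n")
    print(as.data.frame(x$presets))
  }
  if (!is.null(x$sex_contingency)) {
    print(x$sex_contingency)
  }
  invisible(x)
}

#' Write the report bundle of a full analysis
#'
#' Emits CSV reports (cluster summary, variable selection, norm
#' comparison, presets, per-patient assignments) plus a JSON summary
#' embedding the configuration hash and seed; reruns with the same seed
#' reproduce the files byte-identically.
#'
#' @param analysis A `mounting_analysis` from [run_full_analysis()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_analysis_reports <- function(analysis, out_dir) {
  stopifnot(inherits(analysis, "mounting_analysis"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df)) readr::write_csv(df, file.path(out_dir, name))
  }
  w(analysis$summary, "cluster_summary.csv")
  w(analysis$presets, "phenotype_presets.csv")
  w(analysis$bonwill_balkwill, "bonwill_balkwill.csv")
  w(analysis$variable_selection, "variable_selection.csv")
  w(analysis$mounting_tests, "mounting_anova.csv")
  w(
    dplyr::select(
      analysis$cohort,
      dplyr::any_of(c("patient_id", "cluster", "phenotype"))
    ),
    "assignments.csv"
  )
  json <- list(
    config = analysis$config,
    k = analysis$clusters$k,
    wss_curve = analysis$clusters$wss_curve,
    centers = analysis$clusters$centers,
    accounting = analysis$accounting
  )
  if (!is.null(analysis$sex_contingency)) {
    sc <- analysis$sex_contingency
    json$sex_contingency <- list(
      statistic = sc$statistic, df = sc$df, p_value = sc$p_value,
      cramers_v = sc$cramers_v
    )
  }
  jsonlite::write_json(
    json, file.path(out_dir, "analysis.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(out_dir)
}
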