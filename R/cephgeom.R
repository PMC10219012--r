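# 2D virtual-facebow geometry on a right-lateral cephalogram.
# Coordinate convention throughout: x anterior-positive, y superior-positive.

REQUIRED_LANDMARKS <- c("Pi", "Ns", "Ie", "Dc", "Ref0", "Ref1")

#' Cephalometric landmark set
#'
#' Bundles the four landmarks of the virtual-facebow construction -- porion
#' inferior (`Pi`), nasal facebow support (`Ns`), upper incisor edge (`Ie`)
#' and the distobuccal cusp of the first upper molar (`Dc`) -- together with
#' a scaling marker pair (`Ref0`, `Ref1`) of known physical separation.
#' Coordinates are x anterior-positive, y superior-positive (right-lateral
#' view), in pixels before calibration and millimetres after.
#'
#' @param Pi,Ns,Ie,Dc,Ref0,Ref1 Numeric length-2 vectors `c(x, y)`.
#' @param ref_distance_mm Physical distance (mm, > 0) spanned by
#'   `Ref0`--`Ref1`.
#' @param calibrated Logical; `TRUE` when coordinates are already in mm.
#'
#' @return A `ceph_landmarks` object: a tibble with columns `landmark`,
#'   `x`, `y` and attributes `ref_distance_mm`, `calibrated`.
#' @examples
#' lm <- ceph_landmarks(
#'   Pi = c(0, 0), Ns = c(100, 23), Ie = c(95, -40), Dc = c(60, -38),
#'   Ref0 = c(0, -60), Ref1 = c(50, -60), ref_distance_mm = 50,
#'   calibrated = TRUE
#' )
#' @export
ceph_landmarks <- function(Pi, Ns, Ie, Dc, Ref0, Ref1, ref_distance_mm,
                           calibrated = FALSE) {
  pts <- list(Pi = Pi, Ns = Ns, Ie = Ie, Dc = Dc, Ref0 = Ref0, Ref1 = Ref1)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (length(p) != 2L || !all(is.finite(p))) {
      abort(paste0("Landmark `", nm, "` must be a finite length-2 numeric."))
    }
  }
  if (!is.numeric(ref_distance_mm) || ref_distance_mm <= 0) {
    abort("`ref_distance_mm` must be a positive length.")
  }
  if (identical(pts$Ie, pts$Dc)) {
    abort("`Ie` and `Dc` must differ (they define the upper occlusal plane).")
  }
  if (identical(pts$Ref0, pts$Ref1)) {
    abort("`Ref0` and `Ref1` must differ (they define the image scale).")
  }
  tbl <- tibble::tibble(
    landmark = names(pts),
    x = unname(vapply(pts, `[`, numeric(1), 1L)),
    y = unname(vapply(pts, `[`, numeric(1), 2L))
  )
  structure(tbl,
    ref_distance_mm = as.numeric(ref_distance_mm),
    calibrated = isTRUE(calibrated),
    class = c("ceph_landmarks", class(tbl))
  )
}

# Extract one landmark as c(x, y).
lm_pt <- function(lm, name) {
  i <- match(name, lm$landmark)
  c(lm$x[i], lm$y[i])
}

is_calibrated <- function(lm) isTRUE(attr(lm, "calibrated"))

vnorm <- function(v) sqrt(sum(v^2))
cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]
rot2 <- function(v, theta) {
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2])
}
# Counter-clockwise perpendicular: for an anterior-pointing vector this
# points superiorly.
perp2 <- function(v) c(-v[2], v[1])

#' Calibrate a landmark set to millimetres
#'
#' Rescales every coordinate by `ref_distance_mm / |Ref0 - Ref1|`, the ratio
#' of the known physical separation of the scaling markers to their image
#' separation.
#'
#' @param landmarks A [ceph_landmarks()] set in image units.
#' @return The same set with coordinates in mm, flagged calibrated.
#' @export
calibrate_landmarks <- function(landmarks) {
  stopifnot(inherits(landmarks, "ceph_landmarks"))
  if (is_calibrated(landmarks)) {
    return(landmarks)
  }
  d_px <- vnorm(lm_pt(landmarks, "Ref0") - lm_pt(landmarks, "Ref1"))
  if (d_px == 0) {
    abort("Degenerate scaling: Ref0 and Ref1 coincide.")
  }
  s <- attr(landmarks, "ref_distance_mm") / d_px
  landmarks$x <- landmarks$x * s
  landmarks$y <- landmarks$y * s
  attr(landmarks, "calibrated") <- TRUE
  landmarks
}

#' Construct the axis-orbital line from landmarks and facebow dimensions
#'
#' The axis-orbital plane (AOP) appears on the lateral cephalogram as the
#' line through the porion-derived anchor `Pi` whose perpendicular distance
#' below the nasal facebow support `Ns` equals the facebow's `d_ns_mm`. Two
#' tangent lines satisfy this; the anatomically oriented one is returned --
#' the line whose foot point `b` (perpendicular foot of `Ns`) lies anterior
#' to `Pi` and inferior to `Ns`.
#'
#' @param landmarks A calibrated [ceph_landmarks()] set.
#' @param facebow A [facebow_spec()].
#' @return A list with `point` (the `Pi` anchor), `direction` (unit vector,
#'   anterior-pointing) and `b` (foot of the perpendicular from `Ns`).
#' @export
construct_aop <- function(landmarks, facebow) {
  stopifnot(inherits(landmarks, "ceph_landmarks"), inherits(facebow, "facebow_spec"))
  if (!is_calibrated(landmarks)) {
    abort("Landmarks must be calibrated to mm first; see `calibrate_landmarks()`.")
  }
  anchor <- lm_pt(landmarks, "Pi")
  ns <- lm_pt(landmarks, "Ns")
  u <- ns - anchor
  len <- vnorm(u)
  d <- facebow$d_ns_mm
  if (len < d) {
    abort(paste0(
      "Infeasible facebow: |Ns - Pi| = ", signif(len, 6),
      " mm is smaller than d_ns_mm = ", d, " mm; no tangent line exists."
    ))
  }
  theta <- asin(d / len)
  u_hat <- u / len
  cand <- lapply(c(-theta, theta), function(t) {
    dir <- rot2(u_hat, t)
    b <- anchor + sum(u * dir) * dir
    list(direction = dir, b = b)
  })
  # Prefer the anatomic solution: b anterior to Pi and inferior to Ns.
  ok <- vapply(cand, function(cc) {
    cc$b[1] >= anchor[1] && cc$b[2] <= ns[2]
  }, logical(1))
  pick <- if (any(ok)) {
    which(ok)[which.min(vapply(cand[ok], function(cc) cc$b[2], numeric(1)))]
  } else {
    which.min(vapply(cand, function(cc) cc$b[2], numeric(1)))
  }
  list(point = anchor, direction = cand[[pick]]$direction, b = cand[[pick]]$b)
}

#' Compute the mounting triple from a single landmark set
#'
#' Extracts the arbitrary mounting values: the angle `alpha` between the
#' upper occlusal plane (line `Ie`--`Dc`, uOP) and the axis-orbital plane;
#' the perpendicular distance `AxV` from the arbitrary hinge axis `Ax` to
#' its projection `Ax'` on the uOP; and the along-plane distance `AxH` from
#' `Ie` to `Ax'`. `alpha` is stored signed -- positive when the uOP ascends
#' posteriorly towards the AOP -- so that per-patient values may be
#' averaged without losing information; individual patients can be negative.
#'
#' @param landmarks A calibrated [ceph_landmarks()] set (uncalibrated sets
#'   are calibrated on the fly).
#' @param facebow A [facebow_spec()].
#' @return A one-row tibble with `alpha_deg`, `axv_mm`, `axh_mm`.
#' @seealso [mounting_from_landmarks()] for whole cohorts,
#'   [invert_mounting()] for the inverse construction.
#' @export
compute_mounting <- function(landmarks, facebow) {
  landmarks <- calibrate_landmarks(landmarks)
  aop <- construct_aop(landmarks, facebow)
  ie <- lm_pt(landmarks, "Ie")
  dc <- lm_pt(landmarks, "Dc")
  uop_vec <- ie - dc
  if (vnorm(uop_vec) == 0) {
    abort("Degenerate occlusal plane: Ie and Dc coincide.")
  }
  uop_dir <- uop_vec / vnorm(uop_vec)
  # Signed angle of the uOP against the AOP; positive when the occlusal
  # plane descends anteriorly, i.e. the two planes converge posteriorly.
  alpha <- -atan2(cross2(aop$direction, uop_dir), sum(aop$direction * uop_dir))
  ax <- aop$point +
    facebow$ax_offset_along_mm * aop$direction +
    facebow$ax_offset_perp_mm * perp2(aop$direction)
  ax_proj <- ie + sum((ax - ie) * uop_dir) * uop_dir
  tibble::tibble(
    alpha_deg = alpha * 180 / pi,
    axv_mm = vnorm(ax - ax_proj),
    axh_mm = vnorm(ie - ax_proj)
  )
}

#' Compute mounting values for a cohort of landmark tables
#'
#' Pipe-friendly wrapper over [compute_mounting()]: takes the long landmark
#' table (one row per landmark per patient) produced by
#' [read_landmarks()] or [generate_landmark_cohort()].
#'
#' @param data Data frame with columns `patient_id`, `landmark`, `x`, `y`
#'   and either a `ref_distance_mm` column or a single value passed via the
#'   argument of the same name.
#' @param facebow A [facebow_spec()].
#' @param ref_distance_mm Fallback scaling distance when the column is
#'   absent.
#' @param calibrated Set `TRUE` when coordinates are already in mm.
#' @return A tibble with one row per patient: `patient_id`, `alpha_deg`,
#'   `axv_mm`, `axh_mm`.
#' @export
mounting_from_landmarks <- function(data, facebow, ref_distance_mm = NULL,
                                    calibrated = FALSE) {
  stopifnot(all(c("patient_id", "landmark", "x", "y") %in% names(data)))
  data |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      rd <- if ("ref_distance_mm" %in% names(df)) df$ref_distance_mm[1] else ref_distance_mm
      if (is.null(rd)) {
        abort("Provide `ref_distance_mm` as a column or argument.")
      }
      pts <- setNames(Map(c, df$x, df$y), df$landmark)
      missing <- setdiff(REQUIRED_LANDMARKS, names(pts))
      if (length(missing)) {
        abort(paste0(
          "Patient ", key$patient_id, " is missing landmark(s): ",
          paste(missing, collapse = ", ")
        ))
      }
      lm <- ceph_landmarks(
        Pi = pts$Pi, Ns = pts$Ns, Ie = pts$Ie, Dc = pts$Dc,
        Ref0 = pts$Ref0, Ref1 = pts$Ref1,
        ref_distance_mm = rd, calibrated = calibrated
      )
      compute_mounting(lm, facebow)
    }) |>
    dplyr::ungroup()
}

#' Synthesise a landmark set realising a given mounting triple
#'
#' Inverse of [compute_mounting()]: lays out a calibrated landmark set in a
#' canonical frame (axis-orbital line horizontal through `Pi` at the
#' origin) whose forward computation reproduces the requested triple. The
#' free degrees of freedom -- where the nasal support sits along the line
#' and how long the `Ie`--`Dc` span is -- are layout parameters without
#' influence on the mounting values.
#'
#' @param alpha_deg Signed mounting angle, `|alpha_deg| < 90`.
#' @param axv_mm Perpendicular hinge-axis distance, > 0.
#' @param axh_mm Along-plane distance from `Ie`, > 0.
#' @param facebow A [facebow_spec()].
#' @param ns_x_mm Anterior position of the nasal support (layout, > 0).
#' @param ie_dc_span_mm Occlusal-plane span `Ie`--`Dc` (layout, > 0).
#' @return A calibrated [ceph_landmarks()] set.
#' @export
invert_mounting <- function(alpha_deg, axv_mm, axh_mm, facebow,
                            ns_x_mm = 100, ie_dc_span_mm = 35) {
  if (!all(is.finite(c(alpha_deg, axv_mm, axh_mm)))) {
    abort("Mounting values must be finite.")
  }
  if (abs(alpha_deg) >= 90 || axv_mm <= 0 || axh_mm <= 0) {
    abort(paste0(
      "Infeasible mounting triple (", alpha_deg, ", ", axv_mm, ", ", axh_mm,
      "): need |alpha| < 90, AxV > 0, AxH > 0."
    ))
  }
  if (ns_x_mm <= 0 || ie_dc_span_mm <= 0) {
    abort("Layout parameters must be positive.")
  }
  a <- alpha_deg * pi / 180
  anchor <- c(0, 0)                                  # Pi; AOP is the x-axis
  ns <- c(ns_x_mm, facebow$d_ns_mm)
  ax <- anchor + c(facebow$ax_offset_along_mm, facebow$ax_offset_perp_mm)
  uop_dir <- c(cos(a), -sin(a))                      # anterior, descending for a > 0
  up <- perp2(uop_dir)                               # superior-pointing normal
  ax_proj <- ax - axv_mm * up                        # occlusal plane runs below Ax
  ie <- ax_proj + axh_mm * uop_dir
  dc <- ie - ie_dc_span_mm * uop_dir
  ceph_landmarks(
    Pi = anchor, Ns = ns, Ie = ie, Dc = dc,
    Ref0 = c(0, -60), Ref1 = c(50, -60),
    ref_distance_mm = 50, calibrated = TRUE
  )
}

#' Derive Bonwill-arm and Balkwill-angle equivalents
#'
#' `Ax`, `Ie` and `Ax'` form a right triangle with the right angle at
#' `Ax'`, so the distance `Ie`--`Ax` (the virtual analogue of one Bonwill
#' triangle arm, norm 101.6 mm) is `sqrt(AxH^2 + AxV^2)` and the Balkwill
#' angle analogue (norm range 18--25 degrees) is `atan(AxV / AxH)`.
#'
#' @param data Data frame with columns `axv_mm` and `axh_mm` (e.g. the
#'   output of [mounting_from_landmarks()] or [generate_cohort()]).
#' @return `data` with columns `ie_ax_mm` and `balkwill_deg` appended.
#' @export
derive_articulator_values <- function(data) {
  stopifnot(all(c("axv_mm", "axh_mm") %in% names(data)))
  if (any(data$axh_mm == 0)) {
    abort("Balkwill angle is undefined when `axh_mm` is 0.")
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    ie_ax_mm = sqrt(.data$axh_mm^2 + .data$axv_mm^2),
    balkwill_deg = atan2(.data$axv_mm, .data$axh_mm) * 180 / pi
  )
}

#' Round half-up
#'
#' Commercial rounding to the nearest integer with `.5` always rounding
#' away from zero upwards (26.5 -> 27), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Round cluster-mean mounting values to integer presets
#'
#' Turns per-phenotype mean mounting triples into the integer presets a
#' clinician would dial in, using half-up rounding.
#'
#' @param centers Data frame with columns `alpha_deg`, `axv_mm`, `axh_mm`
#'   (additional columns such as `phenotype` are carried through).
#' @return A tibble with the three mounting columns rounded to integers.
#' @export
round_presets <- function(centers) {
  stopifnot(all(c("alpha_deg", "axv_mm", "axh_mm") %in% names(centers)))
  dplyr::mutate(
    tibble::as_tibble(centers),
    dplyr::across(
      dplyr::all_of(c("alpha_deg", "axv_mm", "axh_mm")),
      round_half_up
    )
  )
}
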