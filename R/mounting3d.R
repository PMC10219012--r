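# 3D arbitrary mounting of an intraoral scan against the virtual hinge axis.
# Frame: x transverse (patient left +), y anterior +, z superior +; the scan
# arrives pre-oriented with the upper occlusal plane on the ground plane
# (z = 0), the midsagittal plane at x = 0 and the upper incisor edge Ie at
# the origin.

#' Build the rigid mounting transform for a mounting triple
#'
#' Places the hinge axis by shifting from `Ie` posteriorly by `AxH` along
#' the midline and superiorly by `AxV`, then rotates the whole scene
#' (scan and axis together) by `alpha` about the transverse axis through
#' `Ie`. The rotation sense moves the posterior side superiorly, matching
#' the cephalometric relation in which the occlusal and axis-orbital planes
#' converge posteriorly; set `posterior_up = FALSE` to flip it.
#'
#' @param alpha_deg,axv_mm,axh_mm The mounting triple.
#' @param posterior_up Rotation sense; default moves the posterior end of
#'   the scan superiorly for positive `alpha_deg`.
#' @return A `mounting_scene`: list with `transform` (4 x 4 homogeneous
#'   rigid matrix), `hinge_axis` (list of `point`, `direction`),
#'   `ie_position` (origin) and `ground_plane` (list of `point`, `normal`).
#' @examples
#' build_mounting_transform(11, 27, 88)
#' @export
build_mounting_transform <- function(alpha_deg, axv_mm, axh_mm,
                                     posterior_up = TRUE) {
  if (!all(is.finite(c(alpha_deg, axv_mm, axh_mm)))) {
    abort("Mounting values must be finite.")
  }
  # Rotation about +x by theta sends (0, -1, 0) to z = -sin(theta); the
  # posterior (-y) side rises for theta = -alpha.
  theta <- (if (posterior_up) -1 else 1) * alpha_deg * pi / 180
  rot <- rbind(
    c(1, 0, 0),
    c(0, cos(theta), -sin(theta)),
    c(0, sin(theta), cos(theta))
  )
  transform <- diag(4)
  transform[1:3, 1:3] <- rot
  axis_point <- drop(rot %*% c(0, -axh_mm, axv_mm))
  structure(
    list(
      transform = transform,
      hinge_axis = list(point = axis_point, direction = c(1, 0, 0)),
      ie_position = c(0, 0, 0),
      ground_plane = list(point = c(0, 0, 0), normal = c(0, 0, 1))
    ),
    class = "mounting_scene"
  )
}

#' @export
print.mounting_scene <- function(x, ...) {
  cat("<mounting_scene>\n")
  cat("  hinge axis point:    ", paste(signif(x$hinge_axis$point, 6), collapse = ", "), "\n")
  cat("  hinge axis direction:", paste(x$hinge_axis$direction, collapse = ", "), "\n")
  cat("  transform:\n")
  print(signif(x$transform, 6))
  invisible(x)
}

#' Apply a mounting scene's rigid transform to 3D points
#'
#' @param scene A `mounting_scene` from [build_mounting_transform()].
#' @param points Data frame (or matrix) with columns/coordinates `x`, `y`,
#'   `z` in mm.
#' @return A tibble of transformed coordinates; other columns are carried
#'   through.
#' @export
apply_transform <- function(scene, points) {
  stopifnot(inherits(scene, "mounting_scene"))
  if (is.matrix(points)) {
    points <- tibble::as_tibble(points, .name_repair = "minimal")
    names(points)[1:3] <- c("x", "y", "z")
  }
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  xyz <- rbind(points$x, points$y, points$z, 1)
  if (!all(is.finite(xyz))) {
    abort("Point coordinates must be finite.")
  }
  out <- scene$transform %*% xyz
  dplyr::mutate(
    tibble::as_tibble(points),
    x = out[1, ], y = out[2, ], z = out[3, ]
  )
}

#' Export a mounting scene as JSON
#'
#' Writes the 4 x 4 transform (16 numbers, row-major), hinge-axis point and
#' direction, suitable for downstream planning tools.
#'
#' @param scene A `mounting_scene`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mounting_scene <- function(scene, path) {
  jsonlite::write_json(
    list(
      transform = as.vector(t(scene$transform)),
      hinge_axis_point = scene$hinge_axis$point,
      hinge_axis_direction = scene$hinge_axis$direction,
      ie_position = scene$ie_position
    ),
    path,
    auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}
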