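# ggplot2 graphics for the clustering results.

#' Plot the within-cluster sum-of-squares (elbow) curve
#'
#' @param fit A `mounting_clusters` object.
#' @return A ggplot: WSS against candidate cluster count with the selected
#'   elbow marked.
#' @export
plot_elbow <- function(fit) {
  stopifnot(inherits(fit, "mounting_clusters"))
  ggplot2::ggplot(fit$wss_curve, ggplot2::aes(x = .data$k, y = .data$wss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = fit$k, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = fit$wss_curve$k) +
    ggplot2::labs(
      x = "number of clusters k",
      y = "total within-cluster sum of squares",
      title = paste0("Elbow criterion selects k = ", fit$k)
    ) +
    ggplot2::theme_minimal()
}

#' Plot clusters in the space of the first two principal components
#'
#' Projects the z-scored mounting triple onto its first two principal
#' components and colours patients by assigned cluster (labelled with
#' phenotypes when available).
#'
#' @param object A `mounting_clusters` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mounting_clusters <- function(object, ...) {
  z <- scale_variables(object$data, object$vars)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  var_expl <- round(100 * pc$sdev[1:2]^2 / sum(pc$sdev^2), 1)
  df <- tibble::tibble(
    dim1 = pc$x[, 1],
    dim2 = pc$x[, 2],
    cluster = factor(object$cluster)
  )
  if ("phenotype" %in% names(object$centers)) {
    df$cluster <- factor(
      object$centers$phenotype[object$cluster],
      levels = object$centers$phenotype
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$dim1, y = .data$dim2, colour = .data$cluster
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_ellipse() +
    ggplot2::labs(
      x = paste0("Dim1 (", var_expl[1], "%)"),
      y = paste0("Dim2 (", var_expl[2], "%)"),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a mounting scene in the sagittal plane
#'
#' Side view (anterior right, superior up) of the mounted occlusal plane,
#' the upper incisor edge and the hinge axis position.
#'
#' @param object A `mounting_scene` from [build_mounting_transform()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mounting_scene <- function(object, ...) {
  # Sagittal (y, z) trace of the occlusal plane: a 100 mm posterior span
  # through Ie, transformed by the scene.
  span <- apply_transform(
    object,
    tibble::tibble(x = 0, y = c(0, -100), z = 0)
  )
  ax <- object$hinge_axis$point
  pts <- tibble::tibble(
    y = c(0, ax[2]), z = c(0, ax[3]),
    what = c("Ie", "hinge axis")
  )
  ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(
      data = tibble::tibble(y = span$y, z = span$z),
      ggplot2::aes(x = .data$y, y = .data$z)
    ) +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$y, y = .data$z, shape = .data$what),
      size = 3
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "anterior (mm)", y = "superior (mm)", shape = NULL,
      title = "Mounted scene, sagittal view"
    ) +
    ggplot2::theme_minimal()
}
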