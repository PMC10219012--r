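#' Facebow dimension specification
#'
#' The virtual-facebow construction needs the physical dimensions of the
#' facebow that was worn when the lateral cephalogram was taken: how far the
#' nasal support sits above the axis-orbital line, and where the arbitrary
#' hinge axis lies relative to the porion-derived anchor of that line. These
#' dimensions are instrument-specific and are therefore explicit
#' configuration, not constants.
#'
#' @param d_ns_mm Perpendicular distance (mm, >= 0) of the nasal support
#'   landmark `Ns` above the axis-orbital line.
#' @param ax_offset_along_mm Displacement (mm) of the hinge axis point `Ax`
#'   from the anchor along the axis-orbital line, anterior positive.
#' @param ax_offset_perp_mm Displacement (mm) of `Ax` perpendicular to the
#'   axis-orbital line, superior positive.
#'
#' @return An object of class `facebow_spec` (a named list).
#' @examples
#' facebow_spec(d_ns_mm = 23)
#' @export
facebow_spec <- function(d_ns_mm, ax_offset_along_mm = 0, ax_offset_perp_mm = 0) {
  vals <- c(d_ns_mm, ax_offset_along_mm, ax_offset_perp_mm)
  if (!all(is.finite(vals))) {
    abort("All facebow dimensions must be finite numbers.")
  }
  if (d_ns_mm < 0) {
    abort("`d_ns_mm` must be >= 0.")
  }
  structure(
    list(
      d_ns_mm = as.numeric(d_ns_mm),
      ax_offset_along_mm = as.numeric(ax_offset_along_mm),
      ax_offset_perp_mm = as.numeric(ax_offset_perp_mm)
    ),
    class = "facebow_spec"
  )
}

#' @export
print.facebow_spec <- function(x, ...) {
  cat("<facebow_spec>\n")
  cat("  d_ns_mm:            ", x$d_ns_mm, "\n")
  cat("  ax_offset_along_mm: ", x$ax_offset_along_mm, "\n")
  cat("  ax_offset_perp_mm:  ", x$ax_offset_perp_mm, "\n")
  invisible(x)
}

#' Read a facebow specification from YAML or JSON
#'
#' Expects keys `d_ns_mm`, `ax_offset_along_mm`, `ax_offset_perp_mm`
#' (offsets default to 0 when absent).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [facebow_spec()].
#' @export
read_facebow_spec <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$d_ns_mm)) {
    abort("Facebow config must contain `d_ns_mm`.")
  }
  facebow_spec(
    d_ns_mm = cfg$d_ns_mm,
    ax_offset_along_mm = cfg$ax_offset_along_mm %||% 0,
    ax_offset_perp_mm = cfg$ax_offset_perp_mm %||% 0
  )
}
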