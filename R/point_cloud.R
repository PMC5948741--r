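#' Point clouds as tibbles
#'
#' Point clouds flow through the pipeline as tibbles with coordinate columns
#' `x`, `y`, `z` (plus optional 8-bit colour columns `r`, `g`, `b` and any
#' provenance columns such as `component`). Two attributes ride along:
#' `unit_state` (`"cm"` or `"uncalibrated"`) and, after calibration,
#' `cm_per_unit`. All filtering verbs preserve row order and extra columns.
#'
#' @param xyz numeric matrix or data frame with three coordinate columns.
#' @param rgb optional integer matrix/data frame of 8-bit colours (one row per
#'   point).
#' @param unit_state `"cm"` or `"uncalibrated"`.
#' @param ... additional per-point columns (recycled by tibble rules).
#' @return A `point_cloud` tibble.
#' @export
point_cloud <- function(xyz, rgb = NULL, unit_state = "cm", ...) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop_input("`xyz` must have 3 columns.")
  if (nrow(xyz) > 0 && any(!is.finite(xyz))) {
    stop_input("Point coordinates must be finite.")
  }
  out <- tibble(x = as.double(xyz[, 1]), y = as.double(xyz[, 2]),
                z = as.double(xyz[, 3]), ...)
  if (!is.null(rgb)) {
    rgb <- as.matrix(rgb)
    if (nrow(rgb) != nrow(xyz) || ncol(rgb) != 3L) {
      stop_input("`rgb` must be an n x 3 matrix matching the points.")
    }
    if (nrow(rgb) > 0 && (min(rgb) < 0 || max(rgb) > 255)) {
      stop_input("RGB values must lie in [0, 255].")
    }
    out$r <- as.integer(rgb[, 1]); out$g <- as.integer(rgb[, 2])
    out$b <- as.integer(rgb[, 3])
  }
  as_point_cloud(out, unit_state = unit_state)
}

#' @rdname point_cloud
#' @param cloud a data frame with `x`, `y`, `z` columns.
#' @export
as_point_cloud <- function(cloud, unit_state = NULL) {
  if (!all(c("x", "y", "z") %in% names(cloud))) {
    stop_input("A point cloud needs `x`, `y`, `z` columns.")
  }
  out <- as_tibble(cloud)
  state <- unit_state %||% attr(cloud, "unit_state") %||% "cm"
  attr(out, "unit_state") <- match.arg(state, c("cm", "uncalibrated"))
  attr(out, "cm_per_unit") <- attr(cloud, "cm_per_unit")
  class(out) <- unique(c("point_cloud", class(out)))
  out
}

#' @rdname point_cloud
#' @export
unit_state <- function(cloud) attr(cloud, "unit_state") %||% "cm"

cloud_xyz <- function(cloud) {
  cbind(cloud$x, cloud$y, cloud$z)
}

# Rebuild a point_cloud from a row subset, preserving attributes.
cloud_subset <- function(cloud, keep) {
  out <- cloud[keep, , drop = FALSE]
  attr(out, "unit_state") <- attr(cloud, "unit_state")
  attr(out, "cm_per_unit") <- attr(cloud, "cm_per_unit")
  class(out) <- unique(c("point_cloud", class(out)))
  out
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("# point_cloud: %d points, units %s\n", nrow(x), unit_state(x)))
  NextMethod()
}
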