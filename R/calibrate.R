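# Metric calibration from graphic scales. Each marker of known physical
# length (10 cm rules in the field protocol) yields one cm-per-unit ratio;
# their unweighted mean calibrates the scene, and the spread across markers is
# reported as a percentage residual -- the same consistency check done when
# comparing real distances on the metric rules against the model.

#' Estimate the metric scale from graphic markers
#'
#' @param markers a data frame with observed endpoint columns `ax, ay, az,
#'   bx, by, bz` (scene units) and optionally `true_length_cm` (defaults to
#'   10 cm, the standard graphic scale).
#' @param true_length_cm fallback true length when the column is absent.
#' @return A `scale_estimate`: `cm_per_unit` (mean of per-marker ratios),
#'   `per_marker_ratios`, and `residual_pct` = max |ratio - mean| / mean x 100.
#' @export
calibrate_scale <- function(markers, true_length_cm = 10) {
  need <- c("ax", "ay", "az", "bx", "by", "bz")
  if (!all(need %in% names(markers))) {
    stop_param("`markers` needs endpoint columns ax..az and bx..bz.")
  }
  if (nrow(markers) < 1L) stop_param("At least one marker is required.")
  tl <- markers[["true_length_cm"]] %||% rep(true_length_cm, nrow(markers))
  if (any(!is.finite(tl)) || any(tl <= 0)) {
    stop_param("Marker true lengths must be positive.")
  }
  sep <- sqrt((markers$ax - markers$bx)^2 + (markers$ay - markers$by)^2 +
                (markers$az - markers$bz)^2)
  if (any(sep < 1e-12)) {
    stop_degenerate("A marker has coincident endpoints; cannot calibrate.")
  }
  ratios <- tl / sep
  m <- mean(ratios)
  structure(
    list(
      cm_per_unit = m,
      per_marker_ratios = ratios,
      residual_pct = max(abs(ratios - m)) / m * 100
    ),
    class = "scale_estimate"
  )
}

#' @export
print.scale_estimate <- function(x, ...) {
  cat(sprintf("<scale_estimate: %.6g cm/unit from %d markers, residual %.3g%%>\n",
              x$cm_per_unit, length(x$per_marker_ratios), x$residual_pct))
  invisible(x)
}

#' Apply a scale estimate to an uncalibrated cloud or mesh
#'
#' Multiplies all coordinates by `cm_per_unit` and marks the object as
#' calibrated; applying a scale twice is an error (the threshold-bearing
#' filters must know their units).
#'
#' @param x an uncalibrated [point_cloud()] or [triangle_mesh()].
#' @param estimate a [calibrate_scale()] result, or a positive number.
#' @return The calibrated object (units cm).
#' @export
apply_scale <- function(x, estimate) {
  s <- if (inherits(estimate, "scale_estimate")) estimate$cm_per_unit else estimate
  check_scalar_number(s, "cm_per_unit", positive = TRUE)
  if (is_triangle_mesh(x)) {
    if (x$unit_state == "cm") {
      stop_unit("Mesh is already calibrated; refusing to scale twice.")
    }
    x$vertices <- x$vertices * s
    x$unit_state <- "cm"
    return(x)
  }
  if (unit_state(x) != "uncalibrated") {
    stop_unit("Cloud is already calibrated; refusing to scale twice.")
  }
  x$x <- x$x * s; x$y <- x$y * s; x$z <- x$z * s
  out <- as_point_cloud(x, unit_state = "cm")
  attr(out, "cm_per_unit") <- s
  out
}
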