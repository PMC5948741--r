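# Point-cloud cleaning: the workflow mirrors how MVS clouds are typically
# post-processed in mesh-editing tools -- (1) statistical outlier removal and a 0.5 cm
# distance-to-surface ("grid") filter, (2) bounding-box isolation of the
# target plant. All filters are pure subsets: they never add or reorder
# points, and the removed row indices are attached as an attribute.

#' Indices removed by the last filter
#'
#' @param cloud a filtered [point_cloud()].
#' @return Integer vector of row indices (into the filter's input) removed.
#' @export
removed_indices <- function(cloud) attr(cloud, "removed_indices") %||% integer(0)

set_removed <- function(cloud, removed) {
  attr(cloud, "removed_indices") <- as.integer(removed)
  cloud
}

#' Statistical outlier removal
#'
#' Computes each point's mean distance to its `k` nearest neighbours and
#' removes points whose mean distance exceeds the global mean by more than
#' `std_ratio` standard deviations -- the standard k-NN statistical filter
#' used to clean individual stray points from dense photogrammetric clouds.
#'
#' @param cloud a [point_cloud()] with more than `k` points.
#' @param k number of nearest neighbours (default 12).
#' @param std_ratio removal threshold in standard deviations above the mean
#'   (default 2).
#' @return The surviving cloud (order preserved); removed row indices are
#'   available via [removed_indices()].
#' @export
remove_statistical_outliers <- function(cloud, k = 12L, std_ratio = 2.0) {
  k <- check_count(k, "k", min = 1L)
  check_scalar_number(std_ratio, "std_ratio", nonneg = TRUE)
  if (nrow(cloud) <= k) {
    stop_input(sprintf("Cloud has %d points; need more than k = %d.", nrow(cloud), k))
  }
  d <- cpp_knn(cloud_xyz(cloud), k)$mean_dist
  # relative epsilon so floating-point jitter on homogeneous clouds (where
  # all mean distances are equal up to rounding) never triggers removal
  thr <- mean(d) + std_ratio * sd(d)
  removed <- which(d > thr * (1 + 1e-12))
  keep <- setdiff(seq_len(nrow(cloud)), removed)
  set_removed(cloud_subset(cloud, keep), removed)
}

#' Grid-distance filter
#'
#' Removes every point lying more than `max_dist_cm` from the reconstructed
#' surface; points at exactly the threshold are kept (the filter removes
#' points *more than* 0.5 cm out, so the interval is closed). The reference
#' surface is either an explicit triangle mesh, or -- when no mesh exists yet,
#' the usual situation straight after dense reconstruction -- a local
#' total-least-squares plane fitted through each point's `k` nearest
#' neighbours (the point itself excluded).
#'
#' @param cloud a calibrated (cm) [point_cloud()]; the threshold is metric, so
#'   an uncalibrated cloud is an error.
#' @param reference optional [triangle_mesh()] reference surface.
#' @param max_dist_cm removal threshold, cm (default 0.5).
#' @param k neighbours for the local-plane reference (default 12).
#' @return The surviving cloud; removed indices via [removed_indices()].
#' @export
grid_distance_filter <- function(cloud, reference = NULL, max_dist_cm = 0.5,
                                 k = 12L) {
  check_scalar_number(max_dist_cm, "max_dist_cm", nonneg = TRUE)
  if (unit_state(cloud) != "cm") {
    stop_unit("The grid filter threshold is metric; calibrate the cloud first.")
  }
  xyz <- cloud_xyz(cloud)
  if (!is.null(reference)) {
    if (!is_triangle_mesh(reference) || nrow(reference$faces) == 0L) {
      stop_input("`reference` must be a non-empty triangle_mesh.")
    }
    d <- cpp_point_mesh_dist(xyz, reference$vertices, reference$faces)
  } else {
    k <- check_count(k, "k", min = 3L)
    if (nrow(cloud) <= k) {
      stop_input(sprintf("Cloud has %d points; need more than k = %d.", nrow(cloud), k))
    }
    d <- cpp_local_plane_dist(xyz, k)
  }
  removed <- which(d > max_dist_cm)
  keep <- setdiff(seq_len(nrow(cloud)), removed)
  set_removed(cloud_subset(cloud, keep), removed)
}

#' Crop a cloud to a closed bounding box
#'
#' Retains points with `box_min <= p <= box_max` componentwise. This is the
#' manual-cleaning stand-in: neighbouring plants cannot be separated by colour
#' or connectivity (the ground joins everything), so the target plant is
#' isolated by a user-chosen box.
#'
#' @param cloud a [point_cloud()].
#' @param box_min,box_max length-3 numeric corners, `box_min < box_max`
#'   componentwise.
#' @return The cropped cloud (possibly empty, with a warning).
#' @export
crop_bounding_box <- function(cloud, box_min, box_max) {
  if (length(box_min) != 3L || length(box_max) != 3L) {
    stop_param("`box_min` and `box_max` must be length-3 numeric.")
  }
  if (any(!is.finite(c(box_min, box_max))) || any(box_min >= box_max)) {
    stop_param("`box_min` must be strictly below `box_max` componentwise.")
  }
  xyz <- cloud_xyz(cloud)
  keep <- which(
    xyz[, 1] >= box_min[1] & xyz[, 1] <= box_max[1] &
    xyz[, 2] >= box_min[2] & xyz[, 2] <= box_max[2] &
    xyz[, 3] >= box_min[3] & xyz[, 3] <= box_max[3]
  )
  if (length(keep) == 0L) warn("Bounding box crop left an empty cloud.")
  set_removed(cloud_subset(cloud, keep), setdiff(seq_len(nrow(cloud)), keep))
}
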