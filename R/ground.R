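# Ground-plane estimation. Plant height is measured normal to the ground, so
# the pipeline needs a robust plane through the soil points that ignores the
# plant sticking out of it: random-consensus hypotheses refined by a
# total-least-squares fit on the best inlier set.

#' Construct a plane
#'
#' Stored as a unit normal `n` and offset `d` with the plane `n . x = d`.
#'
#' @param normal length-3 normal vector (normalised internally).
#' @param offset scalar offset.
#' @return An object of class `plane`.
#' @export
plane <- function(normal, offset) {
  if (length(normal) != 3L || any(!is.finite(normal))) {
    stop_param("`normal` must be a finite length-3 vector.")
  }
  nn <- vec_norm(normal)
  if (nn < 1e-300) stop_param("`normal` must be non-zero.")
  structure(list(normal = normal / nn, offset = offset / nn), class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("<plane: n = (%.4f, %.4f, %.4f), offset = %.4f>\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

#' Signed distance of points to a plane
#'
#' @param pl a [plane()].
#' @param x a [point_cloud()] or an `n x 3` matrix.
#' @return Numeric vector of signed distances (positive on the normal side).
#' @export
signed_distance <- function(pl, x) {
  xyz <- if (is.data.frame(x)) cloud_xyz(x) else as.matrix(x)
  drop(xyz %*% pl$normal) - pl$offset
}

# Total-least-squares plane through a point set (smallest covariance
# eigenvector); also the refinement step of the consensus fit.
tls_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  cc <- crossprod(sweep(xyz, 2, ctr))
  ev <- eigen(cc, symmetric = TRUE)
  n <- ev$vectors[, 3]
  if (ev$values[2] < 1e-12 * max(ev$values[1], 1e-300)) {
    stop_degenerate("Points are collinear; no unique plane.")
  }
  plane(n, sum(n * ctr))
}

#' Robust ground-plane fit
#'
#' Random sample consensus: `n_trials` seeded 3-point plane hypotheses are
#' scored by the number of points within `inlier_dist_cm`, and the winning
#' inlier set is refined by a total-least-squares fit. The normal is oriented
#' so that the plant side of the scene (the majority of off-plane points) has
#' positive signed distance.
#'
#' @param cloud a [point_cloud()] with at least 3 non-collinear points.
#' @param inlier_dist_cm inlier band half-width, cm.
#' @param n_trials number of random hypotheses.
#' @param seed integer seed; fits are deterministic given the seed.
#' @return A [plane()].
#' @export
fit_ground_plane <- function(cloud, inlier_dist_cm = 0.2, n_trials = 200L,
                             seed = 1L) {
  check_scalar_number(inlier_dist_cm, "inlier_dist_cm", positive = TRUE)
  n_trials <- check_count(n_trials, "n_trials", min = 1L)
  xyz <- cloud_xyz(cloud)
  n <- nrow(xyz)
  if (n < 3L) stop_degenerate("At least 3 points are needed to fit a plane.")
  if (n == 3L) {
    nrm <- cross3(xyz[2, ] - xyz[1, ], xyz[3, ] - xyz[1, ])
    if (vec_norm(nrm) < 1e-12) stop_degenerate("The 3 points are collinear.")
    return(orient_plane(plane(nrm, sum(nrm * xyz[1, ])), xyz))
  }
  with_seed_(seed, {
    best_count <- -1L
    best_inliers <- NULL
    for (t in seq_len(n_trials)) {
      idx <- sample.int(n, 3L)
      p <- xyz[idx, , drop = FALSE]
      nrm <- cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
      if (vec_norm(nrm) < 1e-12) next
      nrm <- unit_vec(nrm)
      d <- abs(drop(xyz %*% nrm) - sum(nrm * p[1, ]))
      cnt <- sum(d <= inlier_dist_cm)
      if (cnt > best_count) {
        best_count <- cnt
        best_inliers <- which(d <= inlier_dist_cm)
      }
    }
    if (is.null(best_inliers) || length(best_inliers) < 3L) {
      stop_degenerate("Consensus plane fit failed; are the points collinear?")
    }
    orient_plane(tls_plane(xyz[best_inliers, , drop = FALSE]), xyz)
  })
}

# Flip the normal so most off-plane mass (the plant) is on the positive side;
# for a bare plane default to +z up.
orient_plane <- function(pl, xyz) {
  d <- drop(xyz %*% pl$normal) - pl$offset
  pos <- sum(pmax(d, 0))
  neg <- sum(pmax(-d, 0))
  flip <- if (abs(pos - neg) < 1e-9 * max(pos + neg, 1e-300)) {
    pl$normal[3] < 0
  } else {
    neg > pos
  }
  if (flip) pl <- plane(-pl$normal, -pl$offset)
  pl
}
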