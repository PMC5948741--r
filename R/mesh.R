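#' Triangle mesh
#'
#' A lightweight container for a triangle mesh: an `n x 3` matrix of vertex
#' coordinates (cm once calibrated, right-handed, z-up) and an `m x 3` integer
#' matrix of 1-based face indices. Optional per-vertex metadata carried by the
#' synthetic generator (leaf membership and along-leaf arclength parameter)
#' travels with the mesh so degradation operators can act per leaf.
#'
#' @param vertices numeric matrix, `n x 3`.
#' @param faces integer matrix, `m x 3`, 1-based vertex indices.
#' @param vertex_component optional integer vector, length `n`: `0` for stem
#'   vertices, `k > 0` for vertices of leaf `k`.
#' @param vertex_u optional numeric vector, length `n`: normalised arclength
#'   position along the leaf axis (0 = insertion, 1 = tip); `NA` for stem.
#' @param unit_state `"cm"` or `"uncalibrated"`.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces,
                          vertex_component = NULL, vertex_u = NULL,
                          unit_state = "cm") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L) stop_input("`vertices` must have 3 columns.")
  if (nrow(vertices) > 0 && any(!is.finite(vertices))) {
    stop_input("Mesh vertices must be finite.")
  }
  if (is.null(faces) || length(faces) == 0L) {
    faces <- matrix(integer(0), 0L, 3L)
  }
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(faces) != 3L) stop_input("`faces` must have 3 columns.")
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop_input("Face indices reference missing vertices.")
  }
  unit_state <- match.arg(unit_state, c("cm", "uncalibrated"))
  structure(
    list(
      vertices = vertices, faces = faces,
      vertex_component = vertex_component, vertex_u = vertex_u,
      unit_state = unit_state
    ),
    class = "triangle_mesh"
  )
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf(
    "<triangle_mesh: %d vertices, %d faces, units %s>\n",
    nrow(x$vertices), nrow(x$faces), x$unit_state
  ))
  invisible(x)
}

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

#' Total surface area of a triangle mesh
#'
#' Sums the areas of all triangles, `sum over faces of 0.5 * |(v1 - v0) x
#' (v2 - v0)|`. Leaves in this package are open single sheets, so for a plant
#' mesh the triangle-sum equals one-sided leaf area plus the lateral area of
#' the stem tube. Zero-area (degenerate) faces contribute 0.
#'
#' @param mesh a [triangle_mesh()].
#' @return Surface area (cm^2 for calibrated meshes). An empty mesh returns 0
#'   with a warning.
#' @examples
#' tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                      matrix(c(1L, 2L, 3L), 1))
#' mesh_surface_area(tri) # 0.5
#' @export
mesh_surface_area <- function(mesh) {
  if (!is_triangle_mesh(mesh)) stop_input("`mesh` must be a triangle_mesh.")
  if (nrow(mesh$faces) == 0L) {
    warn("Mesh has no faces; surface area is 0.")
    return(0)
  }
  sum(face_areas(mesh))
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Rigidly transform or uniformly scale a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @param rotation 3x3 rotation matrix applied first.
#' @param translation length-3 offset applied after rotation.
#' @param scale uniform scale factor applied last.
#' @return The transformed mesh (metadata preserved).
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+") * scale
  out <- mesh
  out$vertices <- v
  out
}

# Merge meshes, re-indexing faces; metadata vectors concatenated.
merge_meshes <- function(meshes) {
  meshes <- meshes[vapply(meshes, function(m) nrow(m$vertices) > 0, logical(1))]
  if (length(meshes) == 0L) {
    return(triangle_mesh(matrix(0, 0, 3), matrix(integer(0), 0, 3)))
  }
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices), integer(1))))
  verts <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  faces <- do.call(rbind, Map(function(m, o) m$faces + o, meshes, offs[-length(offs)]))
  comp <- unlist(lapply(meshes, function(m) {
    m$vertex_component %||% rep(NA_integer_, nrow(m$vertices))
  }))
  u <- unlist(lapply(meshes, function(m) {
    m$vertex_u %||% rep(NA_real_, nrow(m$vertices))
  }))
  triangle_mesh(verts, faces, vertex_component = comp, vertex_u = u,
                unit_state = meshes[[1]]$unit_state)
}
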