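# Rendering detached-leaf layouts: the synthetic counterpart of photographing
# a plant's separated leaves on a white surface next to a 100 cm^2 black
# square. Leaves are flattened isometrically (the dicot fold and the monocot
# strap are both developable), so silhouette area equals the leaf's one-sided
# area exactly; only rasterisation error separates pixel counts from truth.

# 2D silhouette polygon (cm) of leaf i of a plant, midrib along +x.
leaf_silhouette <- function(model, i, n_pts = 200L) {
  p <- model$params
  t <- seq(0, 1, length.out = n_pts)
  if (model$morphotype == "dicot") {
    L <- p$leaf_length_cm[i]
    hw <- (p$leaf_width_cm[i] / 2) * dicot_halfwidth(t)
  } else {
    L <- p$leaf_length_cm[i]
    hw <- (p$leaf_width_cm / 2) * (1 - t)^MONO_PROFILE_POW
  }
  cbind(c(t * L, rev(t * L)), c(hw, -rev(hw)))
}

#' Render a detached-leaf layout image
#'
#' Produces a synthetic overhead image: white background, each leaf flattened
#' (area-preserving) and rasterised in seeded green hues, plus one black
#' reference square of exactly `round(square_area_cm2 * px_per_cm^2)` pixels.
#' Silhouettes never overlap (shelf packing with margins). The exact rendered
#' pixel counts are attached as attributes `plant_px` and `square_px`, so the
#' 2D leaf-area pipeline can be validated against the renderer's own truth.
#'
#' @param plant a `plant_model` (a plant with zero leaves yields a
#'   square-only image).
#' @param px_per_cm raster resolution, pixels per cm (>= 5).
#' @param square_area_cm2 reference square area (default 100 cm^2).
#' @param seed integer seed for the hue jitter.
#' @param margin_cm white margin between items.
#' @param canvas_max_px maximum canvas side; exceeding it is a layout error.
#' @return An [rgb_image()] with attributes `plant_px` and `square_px`.
#' @export
render_leaf_layout <- function(plant, px_per_cm, square_area_cm2 = 100,
                               seed = 1L, margin_cm = 1, canvas_max_px = 4000L) {
  check_scalar_number(px_per_cm, "px_per_cm", positive = TRUE)
  if (px_per_cm < 5) stop_param("`px_per_cm` must be at least 5.")
  check_scalar_number(square_area_cm2, "square_area_cm2", positive = TRUE)
  n_leaves <- length(plant$per_leaf_areas_cm2)
  polys <- lapply(seq_len(n_leaves), function(i) leaf_silhouette(plant, i))
  sq_px <- round(square_area_cm2 * px_per_cm^2)
  sq_w <- floor(sqrt(sq_px))
  sq_h <- ceiling(sq_px / sq_w)
  items <- c(
    list(list(kind = "square", w_cm = sq_w / px_per_cm, h_cm = sq_h / px_per_cm)),
    lapply(polys, function(pp) {
      list(kind = "leaf", poly = pp,
           w_cm = diff(range(pp[, 1])), h_cm = diff(range(pp[, 2])))
    })
  )
  # shelf packing: rows of items, row width limited to a square-ish canvas
  widths <- vapply(items, `[[`, numeric(1), "w_cm")
  heights <- vapply(items, `[[`, numeric(1), "h_cm")
  total_area <- sum((widths + margin_cm) * (heights + margin_cm))
  row_limit <- max(sqrt(total_area) * 1.4, max(widths) + 2 * margin_cm)
  x <- margin_cm; y <- margin_cm; row_h <- 0; canvas_w <- 0
  for (i in seq_along(items)) {
    if (x + widths[i] + margin_cm > row_limit && x > margin_cm) {
      x <- margin_cm
      y <- y + row_h + margin_cm
      row_h <- 0
    }
    items[[i]]$x0 <- x
    items[[i]]$y0 <- y
    x <- x + widths[i] + margin_cm
    row_h <- max(row_h, heights[i])
    canvas_w <- max(canvas_w, x)
  }
  canvas_h <- y + row_h + margin_cm
  W <- ceiling(canvas_w * px_per_cm)
  H <- ceiling(canvas_h * px_per_cm)
  if (W > canvas_max_px || H > canvas_max_px) {
    stop_layout(sprintf(
      "Layout needs %d x %d px but the canvas is capped at %d; cannot pack the leaves.",
      W, H, canvas_max_px
    ))
  }
  R <- matrix(255L, H, W); G <- matrix(255L, H, W); B <- matrix(255L, H, W)
  # reference square: first sq_px pixels of its bbox in row-major order
  sq <- items[[1]]
  r0 <- floor(sq$y0 * px_per_cm)
  c0 <- floor(sq$x0 * px_per_cm)
  full_rows <- sq_px %/% sq_w
  rem <- sq_px - full_rows * sq_w
  if (full_rows > 0) {
    rows <- r0 + seq_len(full_rows)
    cols <- c0 + seq_len(sq_w)
    R[rows, cols] <- 0L; G[rows, cols] <- 0L; B[rows, cols] <- 0L
  }
  if (rem > 0) {
    rows <- r0 + full_rows + 1L
    cols <- c0 + seq_len(rem)
    R[rows, cols] <- 0L; G[rows, cols] <- 0L; B[rows, cols] <- 0L
  }
  plant_px <- 0L
  if (n_leaves > 0) {
    hues <- with_seed_(seed, cbind(
      round(runif(n_leaves, 55, 95)),
      round(runif(n_leaves, 135, 190)),
      round(runif(n_leaves, 30, 75))
    ))
    for (i in seq_len(n_leaves)) {
      it <- items[[i + 1L]]
      poly <- it$poly
      px_x <- (poly[, 1] - min(poly[, 1]) + it$x0) * px_per_cm
      px_y <- (poly[, 2] - min(poly[, 2]) + it$y0) * px_per_cm
      cr <- floor(range(px_y)) + c(0L, 1L)
      cc <- floor(range(px_x)) + c(0L, 1L)
      rows <- max(1L, cr[1]):min(H, cr[2])
      cols <- max(1L, cc[1]):min(W, cc[2])
      cx <- rep(cols - 0.5, each = length(rows))
      cy <- rep(rows - 0.5, times = length(cols))
      inside <- pracma::inpolygon(cx, cy, px_x, px_y, boundary = FALSE)
      if (!any(inside)) next
      ri <- rep(rows, times = length(cols))[inside]
      ci <- rep(cols, each = length(rows))[inside]
      lin <- cbind(ri, ci)
      R[lin] <- as.integer(hues[i, 1])
      G[lin] <- as.integer(hues[i, 2])
      B[lin] <- as.integer(hues[i, 3])
      plant_px <- plant_px + sum(inside)
    }
  }
  img <- rgb_image(array(c(R, G, B), c(H, W, 3)))
  attr(img, "plant_px") <- plant_px
  attr(img, "square_px") <- sq_px
  img
}
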