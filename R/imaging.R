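# Image-based ground-truth leaf area: detached leaves photographed on a white
# background with a 100 cm^2 black reference square. Vegetation is segmented
# by a linear combination of the RGB planes (plants come out bright) followed
# by Otsu's threshold; the reference square converts pixel counts to cm^2.

#' Segmentation coefficient presets
#'
#' `"ga2018"` is a genetic-algorithm-optimised linear RGB index
#' (R = -0.884, G = 1.262, B = -0.311); `"exg"` is the classic Excess Green
#' index (2G - R - B).
#'
#' @param preset `"ga2018"` or `"exg"`, or pass explicit coefficients to
#'   [segmentation_coefficients()].
#' @return A named numeric vector `c(cR, cG, cB)` of class
#'   `segmentation_coefficients`.
#' @export
coeffs_preset <- function(preset = c("ga2018", "exg")) {
  preset <- match.arg(preset)
  co <- switch(preset,
    ga2018 = c(-0.884, 1.262, -0.311),
    exg = c(-1, 2, -1)
  )
  segmentation_coefficients(co[1], co[2], co[3])
}

#' @rdname coeffs_preset
#' @param cR,cG,cB channel weights; not all zero.
#' @export
segmentation_coefficients <- function(cR, cG, cB) {
  co <- c(cR = cR, cG = cG, cB = cB)
  if (any(!is.finite(co))) stop_param("Coefficients must be finite.")
  if (all(co == 0)) stop_param("Coefficients must not all be zero.")
  structure(co, class = "segmentation_coefficients")
}

#' RGB image container
#'
#' Images are integer arrays `height x width x 3` with 8-bit channels
#' (0-255), origin top-left, row-major pixel order as read from file.
#'
#' @param pixels numeric array `h x w x 3` with values in [0, 255].
#' @return An `rgb_image` array.
#' @export
rgb_image <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop_input("`pixels` must be an h x w x 3 array.")
  }
  if (any(pixels < 0) || any(pixels > 255)) {
    stop_input("Channel values must lie in [0, 255].")
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, class = c("rgb_image", class(pixels)))
}

#' Read / write an 8-bit RGB image
#'
#' PNG is handled natively; TIFF if the `tiff` package is installed.
#'
#' @param path file path (.png or .tif/.tiff).
#' @return An [rgb_image()].
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop_io("Reading TIFF requires the 'tiff' package.")
    }
    tiff::readTIFF(path)
  } else {
    stop_io(sprintf("Unsupported image format '%s'.", ext))
  }
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  rgb_image(round(arr * 255))
}

#' @rdname read_rgb_image
#' @param image an [rgb_image()].
#' @export
write_rgb_image <- function(image, path) {
  arr <- unclass(image)
  storage.mode(arr) <- "double"
  png::writePNG(arr / 255, target = path)
  invisible(path)
}

#' Linear RGB index image
#'
#' `index(p) = cR * R(p) + cG * G(p) + cB * B(p)`, kept real-valued and
#' unclipped: clipping to 8 bits would destroy the bimodality that Otsu
#' needs when coefficients are negative.
#'
#' @param image an [rgb_image()].
#' @param coeffs a [segmentation_coefficients()] (default the `"ga2018"`
#'   preset).
#' @return A numeric matrix the size of the image.
#' @export
linear_index <- function(image, coeffs = coeffs_preset("ga2018")) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop_input("`image` must be an h x w x 3 array.")
  }
  idx <- coeffs[1] * image[, , 1] + coeffs[2] * image[, , 2] +
    coeffs[3] * image[, , 3]
  if (is.null(dim(idx))) dim(idx) <- dim(image)[1:2]
  unname(idx)
}

#' Otsu's threshold on a real-valued index image
#'
#' Bins the index into `n_bins` equal-width bins spanning its range and
#' returns the bin-edge threshold maximising the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`; class statistics are accumulated from the raw
#' values, so the result equals an exhaustive search over all bin edges.
#' Ties are broken toward the smallest threshold.
#'
#' @param index_image numeric matrix (e.g. from [linear_index()]).
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold (same scale as the index).
#' @export
otsu_threshold <- function(index_image, n_bins = 256L) {
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  v <- as.numeric(index_image)
  if (any(!is.finite(v))) stop_input("Index image must be finite.")
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop_degenerate("Constant image: no threshold separates it.")
  width <- (hi - lo) / n_bins
  bin <- pmin(floor((v - lo) / width), n_bins - 1)  # 0-based bin
  cnt <- tabulate(bin + 1L, nbins = n_bins)
  sums <- vapply(split(v, factor(bin, levels = 0:(n_bins - 1))), sum,
                 numeric(1))
  sums[is.na(sums)] <- 0
  n <- length(v)
  total <- sum(v)
  c0 <- cumsum(cnt)[-n_bins]       # counts below edge j (bins 0..j-1)
  s0 <- cumsum(sums)[-n_bins]
  c1 <- n - c0
  s1 <- total - s0
  valid <- c0 > 0 & c1 > 0
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (c0[valid] / n) * (c1[valid] / n) *
    (s0[valid] / c0[valid] - s1[valid] / c1[valid])^2
  j <- which.max(sigma_b)          # which.max takes the first (smallest) tie
  lo + j * width
}

#' Binarize an index image
#'
#' Foreground (plant) = pixels with index strictly greater than the
#' threshold: the vegetation index is built so green material comes out
#' bright.
#'
#' @param index_image numeric matrix.
#' @param threshold scalar threshold.
#' @return A logical matrix of class `binary_mask` with attribute
#'   `threshold_used`.
#' @export
binarize <- function(index_image, threshold) {
  m <- index_image > threshold
  attr(m, "threshold_used") <- threshold
  class(m) <- c("binary_mask", class(m))
  m
}

#' Detect the black reference square
#'
#' Thresholds the raw image at max-channel <= `darkness_max`, labels
#' 4-connected components, and picks the largest one whose bounding-box fill
#' ratio is at least `squareness_min` (thin dark objects such as scale bars
#' fail the squareness test). Equal-sized candidates are broken by higher
#' fill ratio, then by top-left position.
#'
#' @param image an [rgb_image()] containing a dark square of known area.
#' @param darkness_max 8-bit darkness cut-off (default 40).
#' @param squareness_min minimum bounding-box fill ratio (default 0.9).
#' @param square_area_cm2 physical square area (default 100 cm^2).
#' @return A `reference_square`: list with `px_per_cm2`, `n_pixels`, `mask`
#'   (logical matrix of the square's pixels) and `bbox`.
#' @export
detect_reference_square <- function(image, darkness_max = 40,
                                    squareness_min = 0.9,
                                    square_area_cm2 = 100) {
  check_scalar_number(square_area_cm2, "square_area_cm2", positive = TRUE)
  dark <- pmax(image[, , 1], pmax(image[, , 2], image[, , 3])) <= darkness_max
  if (!any(dark)) stop_detection("No dark pixels: reference square not found.")
  lab <- cpp_label4(dark)
  sizes <- tabulate(lab[lab > 0L])
  stats <- lapply(seq_along(sizes), function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    bb <- c(min(w[, 1]), max(w[, 1]), min(w[, 2]), max(w[, 2]))
    fill <- sizes[id] / ((bb[2] - bb[1] + 1) * (bb[4] - bb[3] + 1))
    list(id = id, size = sizes[id], fill = fill, bbox = bb)
  })
  ok <- Filter(function(s) s$fill >= squareness_min, stats)
  if (length(ok) == 0L) {
    stop_detection("No component is square enough to be the reference.")
  }
  ord <- order(
    -vapply(ok, `[[`, numeric(1), "size"),
    -vapply(ok, `[[`, numeric(1), "fill"),
    vapply(ok, function(s) s$bbox[3], numeric(1)),
    vapply(ok, function(s) s$bbox[1], numeric(1))
  )
  best <- ok[[ord[1]]]
  structure(
    list(
      px_per_cm2 = best$size / square_area_cm2,
      n_pixels = best$size,
      mask = lab == best$id,
      bbox = best$bbox
    ),
    class = "reference_square"
  )
}

#' Leaf area from a detached-leaf image
#'
#' The full 2D procedure: linear RGB index, Otsu threshold, binarization,
#' reference-square detection, and pixel-to-cm^2 conversion. The detected
#' square's pixels are excluded from the foreground count (they sit below the
#' vegetation threshold anyway, but excluding them makes the accounting
#' explicit).
#'
#' @param image an [rgb_image()] of leaves on a white background with a black
#'   reference square.
#' @param coeffs segmentation coefficients (default `"ga2018"` preset).
#' @param exclude_square logical; subtract detected square pixels from the
#'   foreground (default TRUE).
#' In a detached-leaf layout the white background is always the majority
#' class; if the thresholded "bright" class covers more than half of the
#' non-square pixels, the scene contains no vegetation to separate (e.g. a
#' square-only image, where Otsu can only split white from black) and the
#' leaf area is 0.
#'
#' @param n_bins,darkness_max,squareness_min,square_area_cm2 passed through.
#' @return Leaf area in cm^2, with attributes `threshold`, `px_per_cm2` and
#'   `foreground_px`.
#' @export
leaf_area_from_image <- function(image, coeffs = coeffs_preset("ga2018"),
                                 exclude_square = TRUE, n_bins = 256L,
                                 darkness_max = 40, squareness_min = 0.9,
                                 square_area_cm2 = 100) {
  sq <- detect_reference_square(image, darkness_max, squareness_min,
                                square_area_cm2)
  idx <- linear_index(image, coeffs)
  thr <- otsu_threshold(idx, n_bins)
  mask <- binarize(idx, thr)
  fg <- mask
  if (exclude_square) fg <- fg & !sq$mask
  n_fg <- sum(fg)
  if (n_fg > 0.5 * (length(fg) - sq$n_pixels)) {
    n_fg <- 0L  # majority guard: background cannot be the bright class
  }
  area <- n_fg / sq$px_per_cm2
  attr(area, "threshold") <- thr
  attr(area, "px_per_cm2") <- sq$px_per_cm2
  attr(area, "foreground_px") <- n_fg
  area
}
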