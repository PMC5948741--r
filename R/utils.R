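# Shared internal helpers: error signalling, seed handling, small numerics.

stop_param <- function(msg, ...) {
  abort(msg, class = "phenocloud_parameter_error", ...)
}

stop_input <- function(msg, ...) {
  abort(msg, class = "phenocloud_input_error", ...)
}

stop_unit <- function(msg, ...) {
  abort(msg, class = "phenocloud_unit_error", ...)
}

stop_degenerate <- function(msg, ...) {
  abort(msg, class = "phenocloud_degenerate_error", ...)
}

stop_detection <- function(msg, ...) {
  abort(msg, class = "phenocloud_detection_error", ...)
}

stop_layout <- function(msg, ...) {
  abort(msg, class = "phenocloud_layout_error", ...)
}

stop_io <- function(msg, ...) {
  abort(msg, class = "phenocloud_io_error", ...)
}

check_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    stop_param(sprintf("`%s` must be positive (got %g).", name, x))
  }
  if (nonneg && x < 0) {
    stop_param(sprintf("`%s` must be non-negative (got %g).", name, x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop_param(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Derive a child seed from a parent seed and a stream index; kept within
# 32-bit signed range so set.seed() always accepts it.
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483629
  as.integer(s)
}

with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Normalise rows of an n x 3 matrix.
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / n
}

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) v / vec_norm(v)

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Rotation matrix about a unit axis by angle (radians), Rodrigues form.
rotation_about_axis <- function(axis, angle) {
  a <- unit_vec(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
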