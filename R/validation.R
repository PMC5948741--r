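# Validation statistics: estimated traits against ground truth. Estimates are
# regressed on actual values (actual on the x-axis), with Pearson r, R^2,
# RMSE, and signed/absolute mean percentage errors. Signed MPE and absolute
# MAPE are reported separately and labelled distinctly: a signed mean can
# legitimately be negative (systematic underestimation) while the absolute
# mean never is, and conflating the two makes error tables unreadable.

check_pairs <- function(data, actual, estimated, min_n = 2L) {
  a <- dplyr::pull(data, {{ actual }})
  e <- dplyr::pull(data, {{ estimated }})
  if (length(a) != length(e)) stop_input("`actual` and `estimated` lengths differ.")
  if (length(a) < min_n) {
    stop_input(sprintf("Need at least %d pairs, got %d.", min_n, length(a)))
  }
  if (any(!is.finite(a)) || any(!is.finite(e))) {
    stop_input("Paired values must be finite.")
  }
  list(actual = a, estimated = e)
}

#' Pearson product-moment correlation of paired traits
#'
#' @param data a data frame of paired observations.
#' @param actual,estimated columns holding ground truth and model estimates
#'   (defaults `actual`, `estimated`).
#' @return The correlation coefficient.
#' @export
pearson_r <- function(data, actual = actual, estimated = estimated) {
  p <- check_pairs(data, {{ actual }}, {{ estimated }})
  if (sd(p$actual) == 0 || sd(p$estimated) == 0) {
    stop_degenerate("Zero variance: correlation is undefined.")
  }
  cor(p$actual, p$estimated)
}

#' Ordinary least squares of estimated on actual
#'
#' @inheritParams pearson_r
#' @return A list: `slope`, `intercept`, `r_squared` (= squared Pearson r),
#'   `p_value` (slope t-test, descriptive), `significant_p01`.
#' @export
linear_fit <- function(data, actual = actual, estimated = estimated) {
  p <- check_pairs(data, {{ actual }}, {{ estimated }})
  if (sd(p$actual) == 0) {
    stop_degenerate("Zero variance in actual values: regression is undefined.")
  }
  fit <- lm(estimated ~ actual, data = list(actual = p$actual,
                                            estimated = p$estimated))
  cf <- coef(fit)
  r <- if (sd(p$estimated) == 0) 0 else cor(p$actual, p$estimated)
  # p-value is descriptive output; a perfect fit's warning is expected there
  sm <- suppressWarnings(summary(fit))
  pv <- if (nrow(sm$coefficients) > 1L && length(p$actual) > 2L) {
    sm$coefficients[2L, 4L]
  } else {
    NA_real_
  }
  list(
    slope = unname(cf[2L]), intercept = unname(cf[1L]), r_squared = r^2,
    p_value = pv, significant_p01 = isTRUE(pv < 0.01)
  )
}

#' Root mean square error
#'
#' `sqrt(mean((estimated - actual)^2))`, in the units of the trait.
#'
#' @inheritParams pearson_r
#' @export
rmse <- function(data, actual = actual, estimated = estimated) {
  p <- check_pairs(data, {{ actual }}, {{ estimated }}, min_n = 1L)
  sqrt(mean((p$estimated - p$actual)^2))
}

#' Signed and absolute mean percentage errors
#'
#' Per-pair percentage error `e_i = 100 * (estimated_i - actual_i) /
#' actual_i`; MPE is its signed mean (negative = systematic underestimation),
#' MAPE the mean of its absolute values.
#'
#' @inheritParams pearson_r
#' @param label optional column of identifiers used to name offenders when an
#'   actual value is zero.
#' @return A list with `mpe_pct` and `mape_pct`.
#' @export
percentage_errors <- function(data, actual = actual, estimated = estimated,
                              label = NULL) {
  p <- check_pairs(data, {{ actual }}, {{ estimated }}, min_n = 1L)
  lab <- if (rlang::quo_is_null(rlang::enquo(label))) {
    as.character(seq_along(p$actual))
  } else {
    as.character(dplyr::pull(data, {{ label }}))
  }
  zero <- which(p$actual == 0)
  if (length(zero) > 0L) {
    stop_input(sprintf(
      "Percentage error undefined for zero actual value(s): %s.",
      paste(lab[zero], collapse = ", ")
    ))
  }
  e <- 100 * (p$estimated - p$actual) / p$actual
  list(mpe_pct = mean(e), mape_pct = mean(abs(e)))
}

#' Full validation report for one trait
#'
#' Bundles n, Pearson r, R^2, the regression of estimated on actual, RMSE and
#' the signed/absolute mean percentage errors.
#'
#' @inheritParams percentage_errors
#' @param trait optional trait name recorded in the report.
#' @return A `validation_report` object; see [tidy.validation_report()].
#' @export
validation_report <- function(data, actual = actual, estimated = estimated,
                              label = NULL, trait = NA_character_) {
  p <- check_pairs(data, {{ actual }}, {{ estimated }})
  fit <- linear_fit(data, {{ actual }}, {{ estimated }})
  pe <- percentage_errors(data, {{ actual }}, {{ estimated }}, {{ label }})
  r <- pearson_r(data, {{ actual }}, {{ estimated }})
  structure(
    list(
      trait = trait, n = length(p$actual), pearson_r = r,
      r_squared = fit$r_squared, slope = fit$slope,
      intercept = fit$intercept, p_value = fit$p_value,
      significant_p01 = fit$significant_p01,
      rmse = rmse(data, {{ actual }}, {{ estimated }}),
      mpe_pct = pe$mpe_pct, mape_pct = pe$mape_pct,
      data = tibble(actual = p$actual, estimated = p$estimated)
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    paste0("<validation_report%s: n = %d>\n",
           "  r = %.4f  R^2 = %.4f  slope = %.4f  intercept = %.4f\n",
           "  RMSE = %.4g  MPE = %.3f%%  MAPE = %.3f%%\n"),
    if (is.na(x$trait)) "" else paste0(" [", x$trait, "]"),
    x$n, x$pearson_r, x$r_squared, x$slope, x$intercept,
    x$rmse, x$mpe_pct, x$mape_pct
  ))
  invisible(x)
}

#' Tidy a validation report
#'
#' @param x a [validation_report()].
#' @param ... unused.
#' @return A one-row tibble of the report statistics.
#' @export
tidy.validation_report <- function(x, ...) {
  tibble(
    trait = x$trait, n = x$n, pearson_r = x$pearson_r,
    r_squared = x$r_squared, slope = x$slope, intercept = x$intercept,
    p_value = x$p_value, rmse = x$rmse, mpe_pct = x$mpe_pct,
    mape_pct = x$mape_pct
  )
}

#' @rdname tidy.validation_report
#' @export
glance.validation_report <- function(x, ...) tidy(x, ...)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Scatter plot of a validation report
#'
#' Actual values on the x-axis, estimates on the y-axis, with the fitted
#' regression line (solid) and the identity line (dashed).
#'
#' @param object a [validation_report()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.validation_report <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = actual, y = estimated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#2c7fb8") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      title = if (is.na(object$trait)) "Estimated vs actual" else object$trait,
      subtitle = sprintf("R² = %.3f, RMSE = %.3g, MAPE = %.2f%%",
                         object$r_squared, object$rmse, object$mape_pct),
      x = "actual", y = "estimated"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Serialise / restore a validation report
#'
#' @param x a [validation_report()].
#' @param path JSON file path.
#' @return `write_validation_json()` returns the path invisibly;
#'   `read_validation_json()` returns the restored report.
#' @export
write_validation_json <- function(x, path) {
  lst <- x[setdiff(names(x), "data")]
  lst$data <- as.list(x$data)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_validation_json
#' @export
read_validation_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  lst$data <- as_tibble(lst$data)
  lst$trait <- lst$trait %||% NA_character_
  structure(lst, class = "validation_report")
}
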