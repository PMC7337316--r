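# Paired-error statistics comparing calculated against manually measured
# dimensions. Note two deliberate conventions carried over from the
# method's validation protocol: RMSE uses an n - 1 denominator (so it is
# slightly larger than the 1/n convention), and the accuracy rate is the
# arithmetic mean of per-sample rates (1 - |y - x| / x) * 100.

check_pairs <- function(measured, calculated) {
  if (length(measured) != length(calculated))
    abort("`measured` and `calculated` must have equal length")
  if (!length(measured)) abort("empty input")
  invisible(NULL)
}

#' Mean absolute error of paired measurements
#'
#' @param measured,calculated Numeric vectors (reference and computed
#'   values, same units).
#' @return `(1/n) * sum(|measured - calculated|)`.
#' @export
leaf_mae <- function(measured, calculated) {
  check_pairs(measured, calculated)
  mean(abs(measured - calculated))
}

#' Root mean square error with an n - 1 denominator
#'
#' @inheritParams leaf_mae
#' @return `sqrt(sum((measured - calculated)^2) / (n - 1))`; requires
#'   `n >= 2`.
#' @export
leaf_rmse <- function(measured, calculated) {
  check_pairs(measured, calculated)
  n <- length(measured)
  if (n < 2L) abort("RMSE requires at least 2 pairs (n - 1 denominator)")
  sqrt(sum((measured - calculated)^2) / (n - 1))
}

#' Accuracy rate of paired measurements
#'
#' Per-sample accuracy is `(1 - |calculated - measured| / measured) * 100`;
#' the aggregate is the arithmetic mean over samples.
#'
#' @inheritParams leaf_mae
#' @param aggregate If `FALSE`, return the per-sample rates.
#' @return Percentage (scalar, or vector when `aggregate = FALSE`).
#' @export
accuracy_rate <- function(measured, calculated, aggregate = TRUE) {
  check_pairs(measured, calculated)
  if (any(measured == 0)) abort("measured values must be nonzero")
  rates <- (1 - abs(calculated - measured) / abs(measured)) * 100
  if (aggregate) mean(rates) else rates
}

#' Agreement report between measured and calculated values
#'
#' Bundles MAE, RMSE (n - 1 denominator), mean accuracy rate, and the R^2
#' of the ordinary least-squares fit of calculated on measured, together
#' with the paired values for a calculated-vs-measured scatter against the
#' y = x reference line.
#'
#' @inheritParams leaf_mae
#' @param label Optional label (e.g. `"length"`) carried into tidiers.
#' @return A `leaf_agreement` object; see [tidy.leaf_agreement()],
#'   [glance.leaf_agreement()], [autoplot.leaf_agreement()].
#' @export
agreement_report <- function(measured, calculated, label = NULL) {
  check_pairs(measured, calculated)
  if (length(measured) < 2L) abort("agreement report requires n >= 2")
  fit <- lm(calculated ~ measured)
  # summary.lm warns on exact agreement; R^2 = 1 is the right answer there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(mae = leaf_mae(measured, calculated),
                 rmse = leaf_rmse(measured, calculated),
                 accuracy_pct = accuracy_rate(measured, calculated),
                 r_squared = r2, n = length(measured), label = label,
                 data = tibble(measured = measured,
                               calculated = calculated)),
            class = "leaf_agreement")
}

#' @export
print.leaf_agreement <- function(x, ...) {
  cat(sprintf("Agreement%s over %d pairs\n",
              if (is.null(x$label)) "" else paste0(" (", x$label, ")"),
              x$n))
  cat(sprintf("  MAE: %.3f   RMSE (n-1): %.3f   accuracy: %.2f%%   R^2: %.4f\n",
              x$mae, x$rmse, x$accuracy_pct, x$r_squared))
  invisible(x)
}

#' Tidy a leaf agreement report
#'
#' @param x A `leaf_agreement`.
#' @param ... Unused.
#' @return The paired values as a tibble with per-sample accuracy rates.
#' @export
tidy.leaf_agreement <- function(x, ...) {
  d <- x$data
  d$error <- d$calculated - d$measured
  d$accuracy_pct <- accuracy_rate(d$measured, d$calculated,
                                  aggregate = FALSE)
  d
}

#' One-row summary of a leaf agreement report
#'
#' @param x A `leaf_agreement`.
#' @param ... Unused.
#' @return Tibble with `mae`, `rmse`, `accuracy_pct`, `r_squared`, `n`.
#' @export
glance.leaf_agreement <- function(x, ...) {
  tibble(label = x$label %||% NA_character_, mae = x$mae, rmse = x$rmse,
         accuracy_pct = x$accuracy_pct, r_squared = x$r_squared, n = x$n)
}

#' Calculated-versus-measured scatter with y = x reference
#'
#' @param object A `leaf_agreement`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.leaf_agreement <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$measured,
                                  y = .data$calculated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "measured", y = "calculated",
      title = object$label %||% "calculated vs measured",
      subtitle = sprintf("MAE %.3f, RMSE %.3f, accuracy %.2f%%, R² %.3f",
                         object$mae, object$rmse, object$accuracy_pct,
                         object$r_squared)) +
    ggplot2::theme_minimal()
}
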