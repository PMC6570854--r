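#' Standardized major axis (model II) regression
#'
#' Fits the SMA line, the model II regression appropriate when both axes
#' carry sampling error: the slope magnitude is SD(y)/SD(x), signed by the
#' Pearson correlation, and the line passes through the bivariate mean.
#' Significance is the conventional SMA test of zero correlation
#' (t distribution with n - 2 degrees of freedom).
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with positive
#'   variance.
#' @param log Apply a natural-log transform to both axes before fitting
#'   (requires strictly positive data).
#' @return An object of class `sma_fit` with elements `slope`,
#'   `intercept`, `r`, `r_squared`, `p_value`, `n`, and the (transformed)
#'   data for plotting.
#' @export
#' @examples
#' f <- sma_fit(1:10, 2 * (1:10) + 1)
#' f$slope # 2
sma_fit <- function(x, y, log = FALSE) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) {
    abort("SMA needs at least 3 complete observations.",
          class = "leafspectra_sample_size_error")
  }
  if (log) {
    check_positive(x, "x")
    check_positive(y, "y")
    x <- base::log(x)
    y <- base::log(y)
  }
  sx <- sd(x)
  sy <- sd(y)
  if (sx == 0 || sy == 0) {
    abort("SMA is degenerate when either axis has zero variance.",
          class = "leafspectra_degenerate_error")
  }
  r <- cor(x, y)
  slope <- (if (r < 0) -1 else 1) * sy / sx
  intercept <- mean(y) - slope * mean(x)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  structure(
    list(slope = slope, intercept = intercept, r = r, r_squared = r^2,
         p_value = p, n = n, log = log, data = tibble(x = x, y = y)),
    class = "sma_fit"
  )
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("<sma_fit> n = %d, slope = %.4g, intercept = %.4g, r2 = %.3f, p = %.3g\n",
              x$n, x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' @rdname sma_fit
#' @param x An `sma_fit` object.
#' @param ... Unused.
#' @export
tidy.sma_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname sma_fit
#' @export
glance.sma_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r = x$r,
         r.squared = x$r_squared, p.value = x$p_value, n = x$n)
}

#' @rdname sma_fit
#' @param object An `sma_fit` object.
#' @export
autoplot.sma_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "#2c7fb8", linewidth = 0.8) +
    ggplot2::labs(
      subtitle = sprintf("SMA slope = %.3g, r2 = %.3f, p = %.3g",
                         object$slope, object$r_squared, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' All pairwise SMA fits among the seven leaf traits
#'
#' Fits the 21 bivariate standardized-major-axis regressions among the
#' log-transformed leaf traits.
#'
#' @param traits Trait table (see [trait_indices()]).
#' @param log Log-transform traits before fitting (default `TRUE`).
#' @return A tibble with one row per trait pair: `x`, `y`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
sma_all_pairs <- function(traits, log = TRUE) {
  traits <- validate_traits(traits)
  combos <- utils::combn(trait_names(), 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]
    b <- combos[2, i]
    f <- sma_fit(traits[[a]], traits[[b]], log = log)
    tibble(x = a, y = b, slope = f$slope, intercept = f$intercept,
           r_squared = f$r_squared, p_value = f$p_value, n = f$n)
  })
}
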