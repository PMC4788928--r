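#' Confidence interval container
#'
#' Light-weight S3 container used by every interval construction in the
#' package.
#'
#' @param lower,upper Interval limits.
#' @param alpha Nominal non-coverage level (two-sided).
#' @param method Method tag, e.g. `"t1"`, `"ws"`, `"b3"`.
#' @param point Point estimate of the mean difference, when the method
#'   defines one.
#' @param df Degrees of freedom of the reference t distribution, or
#'   `"normal"` for z-based intervals.
#' @return An object of class `"conf_int"`.
#' @export
conf_int <- function(lower, upper, alpha, method, point = NA_real_,
                     df = "normal") {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  if (lower > upper + 1e-12)
    stop("internal error: lower > upper in method ", method, call. = FALSE)
  structure(list(lower = lower, upper = upper, alpha = alpha,
                 method = method, point = point, df = df),
            class = "conf_int")
}

#' @export
print.conf_int <- function(x, digits = 4L, ...) {
  dfs <- if (identical(x$df, "normal")) "z" else
    sprintf("t(%s)", format(x$df, digits = digits))
  cat(sprintf("%s %.0f%% CI [%s]: (%s, %s)  width %s",
              toupper(x$method), 100 * (1 - x$alpha), dfs,
              format(x$lower, digits = digits),
              format(x$upper, digits = digits),
              format(x$upper - x$lower, digits = digits)))
  if (!is.na(x$point))
    cat(sprintf("  point %s", format(x$point, digits = digits)))
  cat("\n")
  invisible(x)
}

#' Interval width
#' @param x A `"conf_int"` object.
#' @export
ci_width <- function(x) x$upper - x$lower

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single number in (0, 1)", call. = FALSE)
  alpha
}
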