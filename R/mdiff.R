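#' Mean-difference intervals for partially paired data
#'
#' The package front-end: computes any subset of the implemented confidence
#' intervals for `delta = mu1 - mu2` on one partially paired sample and
#' returns them as a fitted-model-style object with `print`, `summary`,
#' `coef` and `confint` methods.
#'
#' Method tags: `"t1"` to `"t5"` (estimated-covariance t intervals, see
#' [ci_t1()]), `"tg"` (GEE sandwich, [ci_gee()]), `"ws"`/`"wa"` (hybrid
#' MOVER with Wilson-score / Agresti–Coull marginals, [ci_hybrid()]),
#' `"b1"` to `"b4"` (bootstrap, [bootstrap_cis()]), and — when `sigma` is
#' supplied — `"tw1"`/`"tw2"` (known-covariance z intervals, [ci_tw1()]).
#'
#' @param x An [incomplete_pairs()] object (or anything [pair_summary()]
#'   accepts after conversion with [incomplete_pairs()]).
#' @param methods Character vector of method tags; the default is every
#'   estimated-covariance method.
#' @param alpha Two-sided non-coverage level.
#' @param sigma Optional [known_cov()] enabling `"tw1"`/`"tw2"`.
#' @param G Bootstrap replicate count for `"b1"`–`"b4"`.
#' @param seed Seed for the bootstrap resampling (see [bootstrap_cis()]).
#' @param equiv_margin Optional equivalence margin `delta0 > 0`; when given,
#'   each interval is annotated with whether it lies entirely inside
#'   `(-delta0, delta0)`.
#' @param control A [mdiff_control()] object.
#' @return An object of class `"mdiff"`.
#' @examples
#' fit <- mdiff(fev1_formoterol(), methods = c("t1", "t2", "t5"))
#' fit
#' confint(fit)
#' @export
mdiff <- function(x, methods = c("t1", "t2", "t3", "t4", "t5",
                                 "tg", "ws", "wa", "b1", "b2", "b3", "b4"),
                  alpha = 0.05, sigma = NULL, G = 5000L, seed = NULL,
                  equiv_margin = NULL, control = mdiff_control()) {
  check_alpha(alpha)
  stopifnot(inherits(x, "incomplete_pairs"))
  known <- c("tw1", "tw2", "t1", "t2", "t3", "t4", "t5",
             "tg", "ws", "wa", "b1", "b2", "b3", "b4")
  bad <- setdiff(methods, known)
  if (length(bad))
    stop("unknown method tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(methods %in% c("tw1", "tw2")) && is.null(sigma))
    stop("methods 'tw1'/'tw2' require a known_cov() in 'sigma'",
         call. = FALSE)
  s <- pair_summary(x)
  boot <- if (any(methods %in% c("b1", "b2", "b3", "b4")))
    bootstrap_cis(x, alpha, G, seed) else NULL
  cis <- lapply(methods, function(m) {
    switch(m,
      tw1 = ci_tw1(s, sigma, alpha),
      tw2 = ci_tw2(s, sigma, alpha),
      t1 = ci_t1(s, alpha),
      t2 = ci_t2(s, alpha),
      t3 = ci_t3(s, alpha),
      t4 = ci_t4(s, alpha, control),
      t5 = ci_t5(s, alpha, control),
      tg = ci_gee(x, alpha, control),
      ws = ci_hybrid(x, alpha, "wilson", sigma, control),
      wa = ci_hybrid(x, alpha, "agresti", sigma, control),
      b1 = boot$b1, b2 = boot$b2, b3 = boot$b3, b4 = boot$b4)
  })
  names(cis) <- methods
  out <- list(intervals = cis, summary = s, sample = x, alpha = alpha,
              G = if (is.null(boot)) NA_integer_ else G,
              seed = seed, equiv_margin = equiv_margin,
              control = control, call = match.call())
  class(out) <- "mdiff"
  out
}

#' @export
print.mdiff <- function(x, digits = 4L, ...) {
  cat(sprintf(
    "Mean-difference intervals, %d%% level (n = %d, n1 = %d, n2 = %d)\n\n",
    round(100 * (1 - x$alpha)), x$summary$n, x$summary$n1, x$summary$n2))
  df <- as.data.frame(x)
  print(format(df, digits = digits), row.names = FALSE)
  if (!is.null(x$equiv_margin))
    cat(sprintf("\nequivalence margin: +/- %s\n",
                format(x$equiv_margin, digits = digits)))
  invisible(x)
}

#' @export
as.data.frame.mdiff <- function(x, ...) {
  df <- data.frame(
    method = names(x$intervals),
    lower = vapply(x$intervals, `[[`, numeric(1), "lower"),
    upper = vapply(x$intervals, `[[`, numeric(1), "upper"),
    width = vapply(x$intervals, ci_width, numeric(1)),
    point = vapply(x$intervals, `[[`, numeric(1), "point"),
    df = vapply(x$intervals, function(ci)
      if (identical(ci$df, "normal")) Inf else as.numeric(ci$df), numeric(1)),
    row.names = NULL)
  if (!is.null(x$equiv_margin))
    df$equivalent <- df$lower > -x$equiv_margin & df$upper < x$equiv_margin
  df
}

#' @export
summary.mdiff <- function(object, ...) {
  structure(list(fit = object, table = as.data.frame(object)),
            class = "summary.mdiff")
}

#' @export
print.summary.mdiff <- function(x, digits = 4L, ...) {
  print(x$fit, digits = digits, ...)
  s <- x$fit$summary
  cat(sprintf("\npaired r = %s, lambda = %s\n",
              format(s$r, digits = digits), format(s$lam, digits = digits)))
  invisible(x)
}

#' @export
coef.mdiff <- function(object, ...) {
  vapply(object$intervals, `[[`, numeric(1), "point")
}

#' @export
confint.mdiff <- function(object, parm, level, ...) {
  m <- cbind(
    lower = vapply(object$intervals, `[[`, numeric(1), "lower"),
    upper = vapply(object$intervals, `[[`, numeric(1), "upper"))
  rownames(m) <- names(object$intervals)
  m
}

#' @export
plot.mdiff <- function(x, ...) {
  df <- as.data.frame(x)
  k <- nrow(df)
  graphics::plot(NULL, xlim = range(df$lower, df$upper, 0),
                 ylim = c(0.5, k + 0.5), yaxt = "n",
                 xlab = expression(delta == mu[1] - mu[2]), ylab = "",
                 main = sprintf("%d%% confidence intervals",
                                round(100 * (1 - x$alpha))), ...)
  graphics::axis(2, at = seq_len(k), labels = df$method, las = 1)
  graphics::segments(df$lower, seq_len(k), df$upper, seq_len(k), lwd = 2)
  graphics::points(df$point, seq_len(k), pch = 16)
  graphics::abline(v = 0, lty = 2, col = "grey40")
  if (!is.null(x$equiv_margin))
    graphics::abline(v = c(-1, 1) * x$equiv_margin, lty = 3, col = "red")
  invisible(x)
}
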