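#' Marginal confidence limits for one mean
#'
#' Score-style limits for a single mean from a partially paired sample,
#' used as inputs to the hybrid (MOVER) interval. Both methods center the
#' limits at the shrunken mean
#' \eqn{\tilde\theta_i = (\sum x_{ij} + 0.5 z^2)/(N_i + z^2)}, with
#' \eqn{N_i = n + n_i}, and take deviations from the pooled mean
#' \eqn{\hat\theta_i}:
#' * Wilson score: half-width
#'   \eqn{z/(N_i+z^2)\sqrt{(n/(n-1))\sum_{j=1}^n (x_{ij}-\hat\theta_i)^2
#'   + z^2/4}};
#' * Agresti–Coull: half-width
#'   \eqn{z\sqrt{\sum_{j=1}^n (x_{ij}-\hat\theta_i)^2 /\{(N_i+z^2)(n-1)\}}}.
#'
#' By default the sum of squares runs over the complete-pair block only
#' (deviations from the pooled mean); `marginal_ss = "all"` in
#' [mdiff_control()] extends it to all `N_i` observations (with an
#' `N_i/(N_i-1)` factor in the Wilson form).
#'
#' @param x An [incomplete_pairs()] object.
#' @param which Which mean: 1 or 2.
#' @param alpha Two-sided non-coverage level.
#' @param method `"wilson"` or `"agresti"`.
#' @param control A [mdiff_control()] object.
#' @return A list with `l`, `u`, `theta_hat` (pooled mean), `theta_tilde`
#'   (shrunken center), `method`.
#' @export
marginal_limits <- function(x, which, alpha = 0.05,
                            method = c("wilson", "agresti"),
                            control = mdiff_control()) {
  check_alpha(alpha)
  method <- match.arg(method)
  stopifnot(inherits(x, "incomplete_pairs"), which %in% c(1L, 2L))
  n <- nrow(x$paired)
  xi_paired <- x$paired[, which]
  xi_all <- c(xi_paired, if (which == 1L) x$x1_only else x$x2_only)
  Ni <- length(xi_all)
  z <- stats::qnorm(1 - alpha / 2)
  theta_hat <- mean(xi_all)
  theta_tilde <- (sum(xi_all) + 0.5 * z^2) / (Ni + z^2)
  if (identical(control$marginal_ss, "paired")) {
    ss <- sum((xi_paired - theta_hat)^2)
    fac <- n / (n - 1)
    dfree <- n - 1
  } else {
    ss <- sum((xi_all - theta_hat)^2)
    fac <- Ni / (Ni - 1)
    dfree <- Ni - 1
  }
  hw <- switch(method,
    wilson  = z / (Ni + z^2) * sqrt(fac * ss + z^2 / 4),
    agresti = z * sqrt(ss / ((Ni + z^2) * dfree)))
  list(l = theta_tilde - hw, u = theta_tilde + hw,
       theta_hat = theta_hat, theta_tilde = theta_tilde, method = method)
}

#' Recovered correlation between the two mean estimators
#'
#' The correlation plugged into the MOVER combination. With known covariance
#' the recovery is \eqn{2n\rho/\sqrt{(n+n_1)(n+n_2)}}; with estimated
#' covariance it is \eqn{nr/\{(n+n_1)(n+n_2)-n_1n_2r^2\}} under the default
#' `corr_variant = "printed"`, or
#' \eqn{nr/\sqrt{(n+n_1)(n+n_2)-n_1n_2r^2}} under `"derived"`. Values are
#' clamped to `[-1, 1]` (the known-covariance form can exceed 1 when the
#' unpaired blocks are small) and a `clamped` flag records when that
#' happened.
#'
#' @param summary A [pair_summary()] object.
#' @param cov Optional [known_cov()]; when supplied the known-covariance
#'   recovery is used.
#' @param control A [mdiff_control()] object.
#' @return A list with `value`, `source` (`"known_sigma"` or `"estimated"`),
#'   and `clamped`.
#' @export
recovered_correlation <- function(summary, cov = NULL,
                                  control = mdiff_control()) {
  s <- summary
  N1 <- s$n + s$n1; N2 <- s$n + s$n2
  if (!is.null(cov)) {
    raw <- 2 * s$n * cov$rho / sqrt(N1 * N2)
    src <- "known_sigma"
  } else {
    raw <- if (identical(control$corr_variant, "printed"))
      s$n * s$r / (N1 * N2 - s$n1 * s$n2 * s$r^2)
    else
      s$n * s$r / sqrt(N1 * N2 - s$n1 * s$n2 * s$r^2)
    src <- "estimated"
  }
  list(value = clamp1(raw), source = src, clamped = abs(raw) > 1)
}

#' Hybrid (MOVER) interval for the mean difference
#'
#' Recovers marginal variance estimates from single-mean confidence limits
#' and combines them with the recovered correlation:
#' \deqn{L = \hat\theta_1-\hat\theta_2 - \sqrt{(\hat\theta_1-l_1)^2 +
#'   (u_2-\hat\theta_2)^2 - 2\,\widehat{corr}\,(\hat\theta_1-l_1)
#'   (u_2-\hat\theta_2)},}
#' and symmetrically for `U` with \eqn{(u_1-\hat\theta_1)} and
#' \eqn{(\hat\theta_2-l_2)}. The anchors \eqn{\hat\theta_i} are the pooled
#' means by default (`hybrid_center = "shrunken"` uses the shrunken centers
#' instead). With `|corr| <= 1` both radicands are bounded below by a square,
#' so `L <= theta1 - theta2 <= U` always holds.
#'
#' @param x An [incomplete_pairs()] object.
#' @param alpha Two-sided non-coverage level.
#' @param method Marginal-limit method: `"wilson"` (tag `"ws"`) or
#'   `"agresti"` (tag `"wa"`).
#' @param cov Optional [known_cov()] passed to [recovered_correlation()].
#' @param control A [mdiff_control()] object.
#' @return A [conf_int()] object.
#' @examples
#' ci_hybrid(fev1_formoterol(), method = "wilson")
#' @export
ci_hybrid <- function(x, alpha = 0.05, method = c("wilson", "agresti"),
                      cov = NULL, control = mdiff_control()) {
  check_alpha(alpha)
  method <- match.arg(method)
  s <- pair_summary(x)
  l1 <- marginal_limits(x, 1L, alpha, method, control)
  l2 <- marginal_limits(x, 2L, alpha, method, control)
  corr <- recovered_correlation(s, cov, control)$value
  c1 <- if (identical(control$hybrid_center, "pooled")) l1$theta_hat else
    l1$theta_tilde
  c2 <- if (identical(control$hybrid_center, "pooled")) l2$theta_hat else
    l2$theta_tilde
  point <- c1 - c2
  dl1 <- c1 - l1$l; du2 <- l2$u - c2
  du1 <- l1$u - c1; dl2 <- c2 - l2$l
  L <- point - sqrt(max(dl1^2 + du2^2 - 2 * corr * dl1 * du2, 0))
  U <- point + sqrt(max(du1^2 + dl2^2 - 2 * corr * du1 * dl2, 0))
  conf_int(L, U, alpha, if (method == "wilson") "ws" else "wa", point)
}
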