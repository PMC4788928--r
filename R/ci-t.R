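#' Estimated-covariance t intervals for the mean difference
#'
#' The five t-based intervals for partially paired data when the covariance
#' matrix is estimated. All are of the form `center +/- t_{alpha/2}(df) * se`
#' and differ in estimator, variance estimate, and degrees-of-freedom rule:
#'
#' * `ci_t1()` — weighted estimator with sample-analogue weights
#'   \eqn{A = n(n+n_2+n_1 m_{12}/m_1) h_r},
#'   \eqn{B = n(n+n_1+n_2 m_{12}/m_2) h_r},
#'   \eqn{h_r = 1/\{(n+n_1)(n+n_2)-n_1n_2r^2\}}; variance
#'   \eqn{V_1 = [\{A^2/n+(1-A)^2/n_1\}m_1 + \{B^2/n+(1-B)^2/n_2\}m_2
#'   - 2ABm_{12}/n]/(n-1)}; df = n.
#' * `ci_t2()` — unbiased estimator (difference of pooled means) with a
#'   three-component variance \eqn{h_1+h_2+h_3} and a Welch–Satterthwaite
#'   df \eqn{\nu}.
#' * `ci_t3()` — equal-variance pooled statistic with df
#'   \eqn{n+n_1+n_2-4}; its variance pools \eqn{b_1+c_2} (or \eqn{b_2+c_1}
#'   when \eqn{n_2>n_1}) against \eqn{2n-2nr+n_1+n_2}.
#' * `ci_t4()` — Ekbohm weighted estimator \eqn{\tilde\delta} under equal
#'   variances, with pooled \eqn{\hat\sigma^2} and df = n. See
#'   [mdiff_control()] for the weight variant switch.
#' * `ci_t5()` — unbiased estimator with pooled within/between variance
#'   components \eqn{R_1 = n(m_1+m_2-2m_{12})/(n-1)},
#'   \eqn{R_2 = (n_1+n_2)(b_1+b_2)/(n_1+n_2-2)} and a Welch-type df
#'   \eqn{\nu_\sigma} (variant switch in [mdiff_control()]).
#'
#' @param summary A [pair_summary()] object.
#' @param alpha Two-sided non-coverage level.
#' @param control A [mdiff_control()] object.
#' @return A [conf_int()] object.
#' @examples
#' s <- pair_summary(fev1_formoterol())
#' ci_t1(s)  # (-0.2751, 0.1071)
#' ci_t2(s)  # (-0.4764, 0.5220)
#' @name ci_t
NULL

#' @rdname ci_t
#' @export
ci_t1 <- function(summary, alpha = 0.05) {
  check_alpha(alpha)
  s <- summary
  if (s$n1 < 1L || s$n2 < 1L)
    stop("t1 requires at least one unpaired observation in each block",
         call. = FALSE)
  if (s$degenerate)
    stop("t1 is undefined for a degenerate paired block (m1*m2 = 0)",
         call. = FALSE)
  w <- t1_weights(s)
  point <- w$A * (s$mean_x1_paired - s$mean_x1_extra) -
    w$B * (s$mean_x2_paired - s$mean_x2_extra) +
    s$mean_x1_extra - s$mean_x2_extra
  V1 <- ((w$A^2 / s$n + (1 - w$A)^2 / s$n1) * s$m1 +
           (w$B^2 / s$n + (1 - w$B)^2 / s$n2) * s$m2 -
           2 * w$A * w$B * s$m12 / s$n) / (s$n - 1)
  stopifnot(V1 >= 0)
  hw <- stats::qt(1 - alpha / 2, df = s$n) * sqrt(V1)
  conf_int(point - hw, point + hw, alpha, "t1", point, df = s$n)
}

# sample-analogue weights of the weighted estimator (shared with bootstrap)
t1_weights <- function(s) {
  hr <- 1 / ((s$n + s$n1) * (s$n + s$n2) - s$n1 * s$n2 * s$r^2)
  list(A = s$n * (s$n + s$n2 + s$n1 * s$m12 / s$m1) * hr,
       B = s$n * (s$n + s$n1 + s$n2 * s$m12 / s$m2) * hr)
}

#' @rdname ci_t
#' @export
ci_t2 <- function(summary, alpha = 0.05) {
  check_alpha(alpha)
  s <- summary
  if (s$n1 < 2L || s$n2 < 2L)
    stop("t2 requires n1 >= 2 and n2 >= 2 (its variance components divide ",
         "by n1 - 1 and n2 - 1)", call. = FALSE)
  N1 <- s$n + s$n1; N2 <- s$n + s$n2
  h1 <- s$n * (N2 * s$m1 / N1 + N1 * s$m2 / N2 - 2 * s$m12) /
    ((s$n - 1) * N1 * N2)
  h2 <- s$n1 * s$b1 / ((s$n1 - 1) * N1^2)
  h3 <- s$n2 * s$b2 / ((s$n2 - 1) * N2^2)
  v <- h1 + h2 + h3
  if (v <= 0) stop("t2 variance estimate is not positive", call. = FALSE)
  nu <- v^2 / (h1^2 / (s$n - 1) + h2^2 / (s$n1 - 1) + h3^2 / (s$n2 - 1))
  point <- s$mean_x1_all - s$mean_x2_all
  hw <- stats::qt(1 - alpha / 2, df = nu) * sqrt(v)
  conf_int(point - hw, point + hw, alpha, "t2", point, df = nu)
}

#' @rdname ci_t
#' @export
ci_t3 <- function(summary, alpha = 0.05) {
  check_alpha(alpha)
  s <- summary
  if (s$n + s$n1 + s$n2 <= 4L)
    stop("t3 requires n + n1 + n2 > 4", call. = FALSE)
  pool <- if (s$n2 > s$n1) s$b2 + s$c1 else s$b1 + s$c2
  denom <- 2 * s$n - 2 * s$n * s$r + s$n1 + s$n2
  if (denom <= 0)
    stop("t3 is undefined: 2n(1 - r) + n1 + n2 <= 0", call. = FALSE)
  N1 <- s$n + s$n1; N2 <- s$n + s$n2
  dfree <- s$n + s$n1 + s$n2 - 4
  se <- sqrt(pool * denom / ((s$n + s$n1 + s$n2 - 2) * N1 * N2))
  point <- s$mean_x1_all - s$mean_x2_all
  hw <- stats::qt(1 - alpha / 2, df = dfree) * se
  conf_int(point - hw, point + hw, alpha, "t3", point, df = dfree)
}

#' @rdname ci_t
#' @export
ci_t4 <- function(summary, alpha = 0.05, control = mdiff_control()) {
  check_alpha(alpha)
  s <- summary
  lam <- s$lam
  den <- (s$n + s$n1) * (s$n + s$n2) - s$n1 * s$n2 * lam^2
  if (den <= 0) stop("t4 denominator degenerate", call. = FALSE)
  point <- t4_estimator(s, control)
  sig2 <- (s$m1 + s$m2 + (1 + lam^2) * (s$b1 + s$b2)) /
    (2 * (s$n - 1) + (1 + lam^2) * (s$n1 + s$n2 - 2))
  se <- sqrt(sig2) * sqrt(2 * s$n * (1 - lam) +
                            (s$n1 + s$n2) * (1 - lam^2)) / sqrt(den)
  hw <- stats::qt(1 - alpha / 2, df = s$n) * se
  conf_int(point - hw, point + hw, alpha, "t4", point, df = s$n)
}

t4_estimator <- function(s, control = mdiff_control()) {
  lam <- s$lam
  den <- (s$n + s$n1) * (s$n + s$n2) - s$n1 * s$n2 * lam^2
  if (identical(control$t4_weights, "symmetric")) {
    a <- s$n * (s$n + s$n2 + s$n1 * lam) / den
    b <- s$n * (s$n + s$n1 + s$n2 * lam) / den
    x1e <- if (s$n1 > 0L) s$mean_x1_extra else 0
    x2e <- if (s$n2 > 0L) s$mean_x2_extra else 0
    a * s$mean_x1_paired + (1 - a) * x1e -
      b * s$mean_x2_paired - (1 - b) * x2e
  } else {
    (s$n * (s$n + s$n2 + s$n1 * lam) * s$mean_x1_paired -
       s$n * (s$n + s$n1 + s$n2 * lam) * s$mean_x2_paired +
       (if (s$n1 > 0L)
         s$n1 * (s$n + s$n2 * (1 - lam^2) - s$n * lam) * s$mean_x1_extra
        else 0) -
       (if (s$n2 > 0L)
         s$n2 * (s$n + s$n1 * (1 - lam)^2 - s$n * lam) * s$mean_x2_extra
        else 0)) / den
  }
}

#' @rdname ci_t
#' @export
ci_t5 <- function(summary, alpha = 0.05, control = mdiff_control()) {
  check_alpha(alpha)
  s <- summary
  if (s$n1 + s$n2 < 3L)
    stop("t5 requires n1 + n2 >= 3", call. = FALSE)
  R1 <- s$n * (s$m1 + s$m2 - 2 * s$m12) / (s$n - 1)
  R2 <- (s$n1 + s$n2) * (s$b1 + s$b2) / (s$n1 + s$n2 - 2)
  if (R1 + R2 <= 0)
    stop("t5 variance components are zero", call. = FALSE)
  ndf <- if (identical(control$t5_df, "printed")) s$n + 1 else s$n - 1
  nu <- (R1 + R2)^2 / (R1^2 / ndf + R2^2 / (s$n1 + s$n2)) - 2
  nu <- max(nu, 1)
  point <- s$mean_x1_all - s$mean_x2_all
  se <- sqrt((R1 + R2) / ((s$n + s$n1) * (s$n + s$n2)))
  hw <- stats::qt(1 - alpha / 2, df = nu) * se
  conf_int(point - hw, point + hw, alpha, "t5", point, df = nu)
}
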