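#' Known covariance specification
#'
#' Marginal standard deviations and correlation of the bivariate population,
#' for the known-covariance intervals [ci_tw1()] and [ci_tw2()].
#'
#' @param sigma1,sigma2 Marginal standard deviations (> 0).
#' @param rho Correlation, strictly inside (-1, 1).
#' @export
known_cov <- function(sigma1, sigma2, rho) {
  if (sigma1 <= 0 || sigma2 <= 0)
    stop("standard deviations must be positive", call. = FALSE)
  if (abs(rho) >= 1)
    stop("'rho' must lie strictly inside (-1, 1)", call. = FALSE)
  structure(list(sigma1 = sigma1, sigma2 = sigma2, rho = rho),
            class = "known_cov")
}

#' Known-covariance intervals for the mean difference
#'
#' `ci_tw1()` is the z interval around the weighted maximum-likelihood
#' estimator of the mean difference,
#' \deqn{\hat\delta = a\bar x_1^{(n)} + (1-a)\bar x_1^{(n_1)}
#'       - b\bar x_2^{(n)} - (1-b)\bar x_2^{(n_2)},}
#' with weights \eqn{a = nh(n+n_2+n_1\beta_{21})},
#' \eqn{b = nh(n+n_1+n_2\beta_{12})}, \eqn{\beta_{21}=\rho\sigma_2/\sigma_1},
#' \eqn{\beta_{12}=\rho\sigma_1/\sigma_2},
#' \eqn{h = 1/\{(n+n_1)(n+n_2)-n_1n_2\rho^2\}}, and exact variance
#' \deqn{Var(\hat\delta) = h\{[n+n_2(1-\rho^2)]\sigma_1^2
#'       - 2n\rho\sigma_1\sigma_2 + [n+n_1(1-\rho^2)]\sigma_2^2\}.}
#' `ci_tw2()` is the z interval around the unbiased estimator
#' \eqn{\bar x_1^{(n+n_1)} - \bar x_2^{(n+n_2)}} with variance
#' \deqn{\{(n+n_2)\sigma_1^2 + (n+n_1)\sigma_2^2 - 2n\rho\sigma_1\sigma_2\}
#'       / \{(n+n_1)(n+n_2)\}.}
#' Both estimators are exactly normal under bivariate normal data, so these
#' intervals have exact coverage for every design size.
#'
#' With no unpaired observations on one side (`n1 = 0` or `n2 = 0`) the
#' weights of `ci_tw1()` degenerate; both functions then fall back to the
#' complete-pair z interval
#' \eqn{\bar x_1^{(n)} - \bar x_2^{(n)} \pm z_{\alpha/2}
#'      \sqrt{(\sigma_1^2+\sigma_2^2-2\rho\sigma_1\sigma_2)/n}}.
#'
#' @param summary A [pair_summary()] object.
#' @param cov A [known_cov()] object.
#' @param alpha Two-sided non-coverage level.
#' @return A [conf_int()] object (method tags `"tw1"`, `"tw2"`).
#' @export
ci_tw1 <- function(summary, cov, alpha = 0.05) {
  check_alpha(alpha)
  stopifnot(inherits(summary, "pair_summary"), inherits(cov, "known_cov"))
  s <- summary
  z <- stats::qnorm(1 - alpha / 2)
  if (s$n1 == 0L || s$n2 == 0L)
    return(complete_pair_z(s, cov, alpha, "tw1"))
  s1 <- cov$sigma1; s2 <- cov$sigma2; rho <- cov$rho
  h <- 1 / ((s$n + s$n1) * (s$n + s$n2) - s$n1 * s$n2 * rho^2)
  a <- s$n * h * (s$n + s$n2 + s$n1 * rho * s2 / s1)
  b <- s$n * h * (s$n + s$n1 + s$n2 * rho * s1 / s2)
  point <- a * s$mean_x1_paired + (1 - a) * s$mean_x1_extra -
    b * s$mean_x2_paired - (1 - b) * s$mean_x2_extra
  v <- h * ((s$n + s$n2 * (1 - rho^2)) * s1^2 - 2 * s$n * rho * s1 * s2 +
              (s$n + s$n1 * (1 - rho^2)) * s2^2)
  conf_int(point - z * sqrt(v), point + z * sqrt(v), alpha, "tw1", point)
}

#' @rdname ci_tw1
#' @export
ci_tw2 <- function(summary, cov, alpha = 0.05) {
  check_alpha(alpha)
  stopifnot(inherits(summary, "pair_summary"), inherits(cov, "known_cov"))
  s <- summary
  if (s$n1 == 0L || s$n2 == 0L)
    return(complete_pair_z(s, cov, alpha, "tw2"))
  z <- stats::qnorm(1 - alpha / 2)
  s1 <- cov$sigma1; s2 <- cov$sigma2; rho <- cov$rho
  point <- s$mean_x1_all - s$mean_x2_all
  v <- ((s$n + s$n2) * s1^2 + (s$n + s$n1) * s2^2 -
          2 * s$n * rho * s1 * s2) / ((s$n + s$n1) * (s$n + s$n2))
  conf_int(point - z * sqrt(v), point + z * sqrt(v), alpha, "tw2", point)
}

# complete-pair z interval used when one unpaired block is empty
complete_pair_z <- function(s, cov, alpha, method) {
  z <- stats::qnorm(1 - alpha / 2)
  point <- s$mean_x1_paired - s$mean_x2_paired
  v <- (cov$sigma1^2 + cov$sigma2^2 -
          2 * cov$rho * cov$sigma1 * cov$sigma2) / s$n
  conf_int(point - z * sqrt(v), point + z * sqrt(v), alpha, method, point)
}

# exact variance of the tw1 estimator (exposed for tests/simulation)
var_tw1 <- function(n, n1, n2, sigma1, sigma2, rho) {
  h <- 1 / ((n + n1) * (n + n2) - n1 * n2 * rho^2)
  h * ((n + n2 * (1 - rho^2)) * sigma1^2 - 2 * n * rho * sigma1 * sigma2 +
         (n + n1 * (1 - rho^2)) * sigma2^2)
}

var_tw2 <- function(n, n1, n2, sigma1, sigma2, rho) {
  ((n + n2) * sigma1^2 + (n + n1) * sigma2^2 - 2 * n * rho * sigma1 * sigma2) /
    ((n + n1) * (n + n2))
}
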