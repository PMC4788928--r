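#' Simulation scenario for the Monte-Carlo evaluation
#'
#' Describes one cell of a coverage study: the bivariate population, the
#' design sizes, the nominal level and the replication counts. Scenarios are
#' parameterised by the marginal standard deviations `sigma1`, `sigma2` of
#' the scale matrix (for the `t5` family, the scale matrix — the marginal
#' variance of a bivariate t(5) is `5/3` times the scale).
#'
#' @param family `"normal"` (bivariate normal) or `"t5"` (bivariate t with 5
#'   degrees of freedom, generated as `mu + L z sqrt(5/w)` with `L` the
#'   Cholesky factor of the scale matrix, `z` standard bivariate normal and
#'   `w ~ chi^2_5 / 5`, drawn per subject).
#' @param mu1,mu2 Population means; the estimand is `delta = mu1 - mu2`.
#' @param sigma1,sigma2 Marginal standard deviations (scale) of the two
#'   outcomes.
#' @param rho Correlation of the scale matrix, `|rho| < 1`.
#' @param n,n1,n2 Complete pairs and unpaired block sizes.
#' @param alpha Nominal two-sided non-coverage level.
#' @param M Outer Monte-Carlo replications.
#' @param G Bootstrap replications for bootstrap methods.
#' @return A list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(family = c("normal", "t5"), mu1 = 0, mu2 = 0,
                         sigma1 = 1, sigma2 = 1, rho = 0,
                         n = 5L, n1 = 2L, n2 = 2L,
                         alpha = 0.05, M = 10000L, G = 5000L) {
  family <- match.arg(family)
  if (sigma1 <= 0 || sigma2 <= 0) stop("scales must be positive")
  if (abs(rho) >= 1) stop("'rho' must lie strictly inside (-1, 1)")
  check_alpha(alpha)
  if (M < 1L) stop("'M' must be at least 1")
  structure(list(family = family, mu1 = mu1, mu2 = mu2,
                 sigma1 = sigma1, sigma2 = sigma2, rho = rho,
                 n = as.integer(n), n1 = as.integer(n1), n2 = as.integer(n2),
                 alpha = alpha, M = as.integer(M), G = as.integer(G)),
            class = "sim_scenario")
}

#' Generate one partially paired dataset from a scenario
#'
#' Draws `n + n1 + n2` bivariate vectors from the scenario's family, then
#' deletes `x2` from a random subset of size `n1` and `x1` from a random
#' subset of size `n2` of the remainder. Under MCAR this is equivalent to
#' assigning the three roles by a single random permutation, which is how it
#' is implemented. Uses the current RNG stream.
#'
#' @param scenario A [sim_scenario()] object.
#' @return An [incomplete_pairs()] object with block sizes `(n, n1, n2)`.
#' @export
generate_dataset <- function(scenario) {
  sc <- scenario
  N <- sc$n + sc$n1 + sc$n2
  cv <- sc$rho * sc$sigma1 * sc$sigma2
  L <- chol2x2(sc$sigma1^2, sc$sigma2^2, cv)
  z <- matrix(stats::rnorm(2L * N), nrow = 2L)
  xy <- t(L %*% z)
  if (identical(sc$family, "t5")) {
    w <- stats::rchisq(N, df = 5) / 5
    xy <- xy / sqrt(w)
  }
  xy <- sweep(xy, 2L, c(sc$mu1, sc$mu2), `+`)
  roles <- sample.int(N)   # first n paired, next n1 keep x1, last n2 keep x2
  ip <- roles[seq_len(sc$n)]
  i1 <- roles[sc$n + seq_len(sc$n1)]
  i2 <- roles[sc$n + sc$n1 + seq_len(sc$n2)]
  incomplete_pairs_blocks(xy[ip, , drop = FALSE], xy[i1, 1L], xy[i2, 2L])
}

# lower Cholesky factor of a 2x2 covariance
chol2x2 <- function(v1, v2, cv) {
  l11 <- sqrt(v1)
  l21 <- cv / l11
  l22 <- sqrt(max(v2 - l21^2, 0))
  matrix(c(l11, l21, 0, l22), 2L, 2L)
}

# one interval by tag (shared by evaluate_ci and run_compute)
compute_ci <- function(x, method, alpha, sigma = NULL, G = 1000L,
                       seed = NULL, control = mdiff_control(),
                       boot_cache = NULL) {
  if (method %in% c("b1", "b2", "b3", "b4")) {
    b <- if (is.null(boot_cache)) bootstrap_cis(x, alpha, G, seed) else
      boot_cache
    return(b[[method]])
  }
  s <- pair_summary(x)
  switch(method,
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
    stop("unknown method tag: ", method, call. = FALSE))
}

#' Monte-Carlo evaluation of one interval method
#'
#' Runs `M` independent datasets from the scenario and summarises the method
#' by empirical coverage probability (ECP), empirical confidence width
#' (ECW), mesial and distal non-coverage probabilities (MNP: the true delta
#' falls below the lower limit; DNP: above the upper limit), their ratio
#' RNCP = MNP / (1 - ECP), and power: the percentage of intervals excluding
#' zero. The counts partition, so `ECP + MNP + DNP = 1` exactly.
#'
#' A dataset on which the method errors (e.g. a degenerate configuration) is
#' redrawn and counted; more than `0.1% * M` redraws is an error.
#'
#' @param method A method tag (see [mdiff()]); `"tw1"`/`"tw2"` use the
#'   scenario's true covariance.
#' @param scenario A [sim_scenario()] object.
#' @param seed Integer seed for the whole evaluation.
#' @param control A [mdiff_control()] object.
#' @return An object of class `"evaluation_result"`.
#' @export
evaluate_ci <- function(method, scenario, seed = NULL,
                        control = mdiff_control()) {
  sc <- scenario
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  sigma <- known_cov(sc$sigma1, sc$sigma2, sc$rho)
  delta <- sc$mu1 - sc$mu2
  n_cover <- 0L; n_below <- 0L; n_above <- 0L; n_power <- 0L
  sum_w <- 0
  redraws <- 0L
  max_redraws <- max(10L, ceiling(0.001 * sc$M))
  m <- 0L
  while (m < sc$M) {
    d <- generate_dataset(sc)
    ci <- tryCatch(
      compute_ci(d, method, sc$alpha, sigma, sc$G, seed = NULL,
                 control = control),
      error = function(e) NULL)
    if (is.null(ci)) {
      redraws <- redraws + 1L
      if (redraws > max_redraws)
        stop("method '", method, "' failed on more than 0.1% of datasets",
             call. = FALSE)
      next
    }
    m <- m + 1L
    if (delta < ci$lower) n_below <- n_below + 1L
    else if (delta > ci$upper) n_above <- n_above + 1L
    else n_cover <- n_cover + 1L
    if (ci$lower > 0 || ci$upper < 0) n_power <- n_power + 1L
    sum_w <- sum_w + (ci$upper - ci$lower)
  }
  ecp <- n_cover / sc$M
  mnp <- n_below / sc$M
  dnp <- n_above / sc$M
  structure(list(
    method = method, scenario = sc,
    n_cover = n_cover, n_below = n_below, n_above = n_above,
    ecp = ecp, ecw = sum_w / sc$M, mnp = mnp, dnp = dnp,
    rncp = if (ecp < 1) mnp / (1 - ecp) else NA_real_,
    power = 100 * n_power / sc$M,
    mc_se_ecp = sqrt(ecp * (1 - ecp) / sc$M),
    n_redraws = redraws
  ), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, digits = 4L, ...) {
  cat(sprintf(
    "%s @ %s(n=%d,n1=%d,n2=%d, rho=%s): ECP %.4f (se %.4f), ECW %.4f\n",
    x$method, x$scenario$family, x$scenario$n, x$scenario$n1, x$scenario$n2,
    format(x$scenario$rho), x$ecp, x$mc_se_ecp, x$ecw))
  cat(sprintf("  MNP %.4f  DNP %.4f  RNCP %s  power %.2f%%  (redraws %d)\n",
              x$mnp, x$dnp,
              if (is.na(x$rncp)) "-" else sprintf("%.4f", x$rncp),
              x$power, x$n_redraws))
  invisible(x)
}

#' Evaluate a grid of scenarios and methods
#'
#' @param scenarios A list of [sim_scenario()] objects (a single scenario is
#'   promoted to a list). Names, if any, become scenario ids.
#' @param methods Character vector of method tags.
#' @param seed Integer seed; scenario/method cells get distinct derived
#'   seeds, so the full table is reproducible.
#' @param control A [mdiff_control()] object.
#' @return A long-format data frame: one row per scenario x method x metric,
#'   with columns `scenario`, `method`, `metric`, `value`, `mc_se` (the
#'   binomial standard error, for ECP only).
#' @export
run_grid <- function(scenarios, methods, seed = 1L,
                     control = mdiff_control()) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  if (length(scenarios) == 0L || length(methods) == 0L)
    return(data.frame(scenario = character(), method = character(),
                      metric = character(), value = numeric(),
                      mc_se = numeric()))
  ids <- names(scenarios)
  if (is.null(ids)) ids <- sprintf("scenario%02d", seq_along(scenarios))
  rows <- list()
  cell <- 0L
  for (i in seq_along(scenarios)) for (mth in methods) {
    cell <- cell + 1L
    res <- evaluate_ci(mth, scenarios[[i]],
                       seed = (seed + 1013L * cell) %% .Machine$integer.max,
                       control = control)
    mets <- c(ecp = res$ecp, ecw = res$ecw, mnp = res$mnp, dnp = res$dnp,
              rncp = res$rncp, power = res$power)
    rows[[cell]] <- data.frame(
      scenario = ids[i], method = mth, metric = names(mets),
      value = unname(mets),
      mc_se = c(res$mc_se_ecp, rep(NA_real_, 5L)),
      row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Reshape a long results table to the wide layout of a report table
#'
#' @param grid A data frame from [run_grid()].
#' @param metric Which metric to tabulate.
#' @return A wide data frame: one row per scenario, one column per method.
#' @export
grid_wide <- function(grid, metric = "ecp") {
  g <- grid[grid$metric == metric, c("scenario", "method", "value")]
  stats::reshape(g, idvar = "scenario", timevar = "method",
                 direction = "wide")
}
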