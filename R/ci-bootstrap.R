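#' Block resampling of a partially paired sample
#'
#' Draws one bootstrap dataset: `n` pairs with replacement from the paired
#' block, `n1` values from the `x1`-only block and `n2` from the `x2`-only
#' block. Block sizes are preserved; pairs are resampled jointly so the
#' within-pair dependence is retained. Uses the current RNG stream.
#'
#' @param x An [incomplete_pairs()] object.
#' @return An [incomplete_pairs()] object of the same block sizes.
#' @export
resample_pairs <- function(x) {
  n <- nrow(x$paired)
  n1 <- length(x$x1_only); n2 <- length(x$x2_only)
  incomplete_pairs_blocks(
    x$paired[sample.int(n, n, replace = TRUE), , drop = FALSE],
    if (n1 > 0L) x$x1_only[sample.int(n1, n1, replace = TRUE)] else numeric(),
    if (n2 > 0L) x$x2_only[sample.int(n2, n2, replace = TRUE)] else numeric())
}

#' Point estimators of the mean difference
#'
#' The two estimators resampled by the bootstrap intervals:
#' `"unbiased"` is the difference of pooled means
#' \eqn{\bar x_1^{(n+n_1)} - \bar x_2^{(n+n_2)}}; `"mle_weighted"` is the
#' weighted estimator with the sample-analogue weights of [ci_t1()]. A
#' degenerate paired block (zero `m1` or `m2`) makes the weighted estimator
#' undefined; callers that must not fail (bootstrap replicates) fall back to
#' the unbiased estimator in that case.
#'
#' @param summary A [pair_summary()] object.
#' @param kind `"mle_weighted"` or `"unbiased"`.
#' @return A single number.
#' @examples
#' s <- pair_summary(fev1_formoterol())
#' point_estimator(s, "unbiased")      #  0.0228
#' point_estimator(s, "mle_weighted")  # -0.0840
#' @export
point_estimator <- function(summary, kind = c("unbiased", "mle_weighted")) {
  kind <- match.arg(kind)
  s <- summary
  if (kind == "unbiased") return(s$mean_x1_all - s$mean_x2_all)
  if (s$n1 < 1L || s$n2 < 1L || s$degenerate)
    stop("the weighted estimator requires unpaired observations on both ",
         "sides and a non-degenerate paired block", call. = FALSE)
  w <- t1_weights(s)
  w$A * (s$mean_x1_paired - s$mean_x1_extra) -
    w$B * (s$mean_x2_paired - s$mean_x2_extra) +
    s$mean_x1_extra - s$mean_x2_extra
}

#' Bootstrap intervals for the mean difference
#'
#' Draws `G` block-bootstrap datasets (shared across the four intervals) and
#' computes on each both point estimators; each interval family resamples
#' its own estimator (weighted for B1/B3, unbiased for B2/B4):
#' * `b1`, `b2` — simple bootstrap: original-sample point estimate
#'   `+/- z_{alpha/2} * se`, where `se` is the standard deviation of the `G`
#'   replicate estimates;
#' * `b3`, `b4` — percentile bootstrap: the order statistics at the 1-based
#'   positions `floor(G * alpha/2)` and `floor(G * (1 - alpha/2))` (positions
#'   are clamped to at least 1).
#'
#' Replicates whose paired block is degenerate for the weighted estimator
#' fall back to the unbiased estimator for that replicate; the count is
#' returned as `n_degenerate`.
#'
#' @param x An [incomplete_pairs()] object.
#' @param alpha Two-sided non-coverage level.
#' @param G Number of bootstrap replicates (>= 100).
#' @param seed Optional integer seed; when supplied the RNG state is set for
#'   the resampling and restored afterwards, making the result reproducible.
#' @return A list of class `"bootstrap_cis"` with elements `b1`, `b2`, `b3`,
#'   `b4` ([conf_int()] objects), the sorted replicate vectors
#'   `replicates_weighted` and `replicates_unbiased`, and `n_degenerate`.
#' @examples
#' bootstrap_cis(fev1_formoterol(), G = 500, seed = 1)$b1
#' @export
bootstrap_cis <- function(x, alpha = 0.05, G = 5000L, seed = NULL) {
  check_alpha(alpha)
  stopifnot(inherits(x, "incomplete_pairs"))
  G <- as.integer(G)
  if (G < 100L) stop("G must be at least 100", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  n <- nrow(x$paired)
  n1 <- length(x$x1_only); n2 <- length(x$x2_only)
  x1p <- x$paired[, 1L]; x2p <- x$paired[, 2L]
  ip <- matrix(sample.int(n, n * G, replace = TRUE), nrow = n)
  X1p <- matrix(x1p[ip], nrow = n); X2p <- matrix(x2p[ip], nrow = n)
  o1m <- if (n1 > 0L)
    colMeans(matrix(x$x1_only[sample.int(n1, n1 * G, replace = TRUE)], n1))
  else rep(0, G)
  o2m <- if (n2 > 0L)
    colMeans(matrix(x$x2_only[sample.int(n2, n2 * G, replace = TRUE)], n2))
  else rep(0, G)
  c1m <- colMeans(X1p); c2m <- colMeans(X2p)
  m1 <- colSums(X1p^2) - n * c1m^2
  m2 <- colSums(X2p^2) - n * c2m^2
  m12 <- colSums(X1p * X2p) - n * c1m * c2m
  rep_unb <- (n * c1m + n1 * o1m) / (n + n1) - (n * c2m + n2 * o2m) / (n + n2)
  deg <- (m1 <= 1e-12 * pmax(c1m^2, 1)) | (m2 <= 1e-12 * pmax(c2m^2, 1)) |
    n1 < 1L | n2 < 1L
  r2 <- ifelse(deg, 0, m12^2 / (m1 * m2))
  hr <- 1 / ((n + n1) * (n + n2) - n1 * n2 * r2)
  A <- n * (n + n2 + n1 * m12 / ifelse(deg, 1, m1)) * hr
  B <- n * (n + n1 + n2 * m12 / ifelse(deg, 1, m2)) * hr
  rep_w <- A * (c1m - o1m) - B * (c2m - o2m) + o1m - o2m
  rep_w[deg] <- rep_unb[deg]

  s <- pair_summary(x)
  pt_unb <- point_estimator(s, "unbiased")
  pt_w <- if (n1 >= 1L && n2 >= 1L && !s$degenerate)
    point_estimator(s, "mle_weighted") else pt_unb
  z <- stats::qnorm(1 - alpha / 2)
  se_w <- stats::sd(rep_w); se_u <- stats::sd(rep_unb)
  lo <- max(1L, floor(G * alpha / 2))
  hi <- max(1L, floor(G * (1 - alpha / 2)))
  sw <- sort(rep_w); su <- sort(rep_unb)
  structure(list(
    b1 = conf_int(pt_w - z * se_w, pt_w + z * se_w, alpha, "b1", pt_w),
    b2 = conf_int(pt_unb - z * se_u, pt_unb + z * se_u, alpha, "b2", pt_unb),
    b3 = conf_int(sw[lo], sw[hi], alpha, "b3", pt_w),
    b4 = conf_int(su[lo], su[hi], alpha, "b4", pt_unb),
    replicates_weighted = sw, replicates_unbiased = su,
    se_weighted = se_w, se_unbiased = se_u,
    G = G, n_degenerate = sum(deg)
  ), class = "bootstrap_cis")
}

#' @export
print.bootstrap_cis <- function(x, ...) {
  cat(sprintf("Block-bootstrap intervals (G = %d, %d degenerate replicates)\n",
              x$G, x$n_degenerate))
  for (k in c("b1", "b2", "b3", "b4")) print(x[[k]], ...)
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

# exact variance of the unbiased estimator under block resampling of the
# observed sample (the bootstrap-population plug-in); oracle for the B2 se
bootstrap_plugin_var <- function(s) {
  N1 <- s$n + s$n1; N2 <- s$n + s$n2
  (s$m1 + s$b1) / N1^2 + (s$m2 + s$b2) / N2^2 - 2 * s$m12 / (N1 * N2)
}
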