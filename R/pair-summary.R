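#' Sufficient statistics of a partially paired sample
#'
#' Computes every summary the interval constructions consume: block means,
#' pooled means, corrected sums of squares and cross-products over the
#' complete pairs (`m1`, `m2`, `m12`), over the unpaired blocks (`b1`, `b2`)
#' and over the pooled per-variable samples (`c1`, `c2`), the paired Pearson
#' correlation `r = m12 / sqrt(m1 m2)` and the pooled-variance correlation
#' proxy `lam = 2 m12 / (m1 + m2)`.
#'
#' When the paired block is constant in either variable (`m1 * m2 = 0`) the
#' ratios `r` and `lam` are set to 0 and the summary is flagged degenerate;
#' downstream methods decide whether that is an error. Floating-point error
#' can push `|r|` marginally past 1 for n = 2, so both `r` and `lam` are
#' clamped to `[-1, 1]`.
#'
#' @param x An [incomplete_pairs()] object.
#' @return An object of class `"pair_summary"`.
#' @examples
#' s <- pair_summary(fev1_formoterol())
#' s$mean_x1_all - s$mean_x2_all   # 0.0228, the unbiased estimate
#' @export
pair_summary <- function(x) {
  stopifnot(inherits(x, "incomplete_pairs"))
  x1p <- x$paired[, 1L]; x2p <- x$paired[, 2L]
  n  <- length(x1p)
  n1 <- length(x$x1_only)
  n2 <- length(x$x2_only)
  m1n <- mean(x1p); m2n <- mean(x2p)
  m1e <- if (n1 > 0L) mean(x$x1_only) else NA_real_
  m2e <- if (n2 > 0L) mean(x$x2_only) else NA_real_
  x1a <- c(x1p, x$x1_only); x2a <- c(x2p, x$x2_only)
  m1a <- mean(x1a); m2a <- mean(x2a)
  m1  <- sum((x1p - m1n)^2)
  m2  <- sum((x2p - m2n)^2)
  m12 <- sum((x1p - m1n) * (x2p - m2n))
  b1  <- if (n1 > 0L) sum((x$x1_only - m1e)^2) else 0
  b2  <- if (n2 > 0L) sum((x$x2_only - m2e)^2) else 0
  c1  <- sum((x1a - m1a)^2)
  c2  <- sum((x2a - m2a)^2)
  degenerate <- (m1 * m2) <= 0
  r   <- if (degenerate) 0 else clamp1(m12 / sqrt(m1 * m2))
  lam <- if ((m1 + m2) <= 0) 0 else clamp1(2 * m12 / (m1 + m2))
  structure(list(
    n = n, n1 = n1, n2 = n2,
    mean_x1_paired = m1n, mean_x2_paired = m2n,
    mean_x1_extra = m1e, mean_x2_extra = m2e,
    mean_x1_all = m1a, mean_x2_all = m2a,
    m1 = m1, m2 = m2, m12 = m12, r = r,
    b1 = b1, b2 = b2, c1 = c1, c2 = c2,
    lam = lam, degenerate = degenerate
  ), class = "pair_summary")
}

clamp1 <- function(x) max(-1, min(1, x))

#' @export
print.pair_summary <- function(x, digits = 4L, ...) {
  cat(sprintf("Partially paired summary (n = %d, n1 = %d, n2 = %d)\n",
              x$n, x$n1, x$n2))
  cat(sprintf("  pooled means: %s, %s  (difference %s)\n",
              format(x$mean_x1_all, digits = digits),
              format(x$mean_x2_all, digits = digits),
              format(x$mean_x1_all - x$mean_x2_all, digits = digits)))
  cat(sprintf("  paired correlation r = %s, lambda = %s%s\n",
              format(x$r, digits = digits), format(x$lam, digits = digits),
              if (x$degenerate) "  [degenerate paired block]" else ""))
  invisible(x)
}

#' @export
summary.pair_summary <- function(object, ...) object
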