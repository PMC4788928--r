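# shared helpers: random samples and brute-force oracles

random_sample <- function(n = 7, n1 = 4, n2 = 3, sd1 = 1, sd2 = 2,
                          rho = 0.5, mu1 = 0, mu2 = 0) {
  cv <- rho * sd1 * sd2
  L <- t(chol(matrix(c(sd1^2, cv, cv, sd2^2), 2)))
  xy <- t(L %*% matrix(rnorm(2 * (n + n1 + n2)), 2)) +
    matrix(c(mu1, mu2), n + n1 + n2, 2, byrow = TRUE)
  incomplete_pairs_blocks(xy[seq_len(n), , drop = FALSE],
                          xy[n + seq_len(n1), 1],
                          xy[n + n1 + seq_len(n2), 2])
}

# corrected sum of squares / cross-products by an explicit double loop
# (independent of the one-pass formulas in pair_summary)
brute_css <- function(x, y = x) {
  n <- length(x)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    acc <- acc + (x[i] - x[j]) * (y[i] - y[j])
  acc / (2 * n)
}

# negate-and-reverse an interval, for label-swap antisymmetry checks
neg_ci <- function(ci) c(-ci$upper, -ci$lower)

expect_antisymmetric <- function(fun, x, ..., tol = 1e-10) {
  a <- fun(x, ...)
  b <- fun(swap_labels(x), ...)
  expect_equal(c(a$lower, a$upper), neg_ci(b), tolerance = tol)
}
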