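test_that("marginal limits collapse to the pooled mean as alpha approaches 1", {
  d <- fev1_formoterol()
  for (m in c("wilson", "agresti")) {
    ml <- marginal_limits(d, 1L, alpha = 1 - 1e-12, method = m)
    expect_equal(ml$l, ml$theta_hat, tolerance = 1e-6)
    expect_equal(ml$u, ml$theta_hat, tolerance = 1e-6)
    expect_equal(ml$theta_tilde, ml$theta_hat, tolerance = 1e-6)
  }
})

test_that("marginal limits agree with a direct transcription of the formulas", {
  d <- fev1_formoterol()
  z <- qnorm(0.975)
  for (which in 1:2) {
    xp <- d$paired[, which]
    xa <- c(xp, if (which == 1) d$x1_only else d$x2_only)
    n <- length(xp); Ni <- length(xa)
    th <- mean(xa)
    tt <- (sum(xa) + 0.5 * z^2) / (Ni + z^2)
    hw_w <- z / (Ni + z^2) * sqrt(n / (n - 1) * sum((xp - th)^2) + z^2 / 4)
    hw_a <- z * sqrt(sum((xp - th)^2) / ((Ni + z^2) * (n - 1)))
    mw <- marginal_limits(d, which, 0.05, "wilson")
    ma <- marginal_limits(d, which, 0.05, "agresti")
    expect_equal(c(mw$l, mw$u), c(tt - hw_w, tt + hw_w), tolerance = 1e-12)
    expect_equal(c(ma$l, ma$u), c(tt - hw_a, tt + hw_a), tolerance = 1e-12)
  }
})

test_that("the Wilson and Agresti-Coull half-widths differ by the z^2/4 inflation", {
  set.seed(501)
  z <- qnorm(0.975)
  for (k in 1:10) {
    d <- random_sample(n = sample(3:9, 1), n1 = sample(0:5, 1),
                       n2 = sample(1:5, 1))
    mw <- marginal_limits(d, 1L, 0.05, "wilson")
    ma <- marginal_limits(d, 1L, 0.05, "agresti")
    Ni <- nrow(d$paired) + length(d$x1_only)
    n <- nrow(d$paired)
    hw_w <- (mw$u - mw$l) / 2; hw_a <- (ma$u - ma$l) / 2
    # expanding both formulas: hw_w^2 - (n/((n-1)) ss) z^2/(Ni+z^2)^2 = z^4/4/(Ni+z^2)^2
    lhs <- hw_w^2 - hw_a^2 * (Ni + z^2) * (n - 1) * n / ((n - 1) * (Ni + z^2)^2)
    expect_equal(lhs, z^2 * (z^2 / 4) / (Ni + z^2)^2, tolerance = 1e-10)
  }
})

test_that("recovered correlation matches hand evaluations and clamps", {
  # r = 0 gives 0
  set.seed(502)
  s <- pair_summary(random_sample())
  s$r <- 0
  expect_equal(recovered_correlation(s)$value, 0)
  # printed form, hand value: n=5, n1=n2=2, r=0.8 -> 4/46.44
  s$n <- 5L; s$n1 <- 2L; s$n2 <- 2L; s$r <- 0.8
  expect_equal(recovered_correlation(s)$value,
               5 * 0.8 / (49 - 4 * 0.64), tolerance = 1e-12)  # = 0.08613
  # derived variant carries the square root
  expect_equal(recovered_correlation(s, control = mdiff_control(
    corr_variant = "derived"))$value,
    5 * 0.8 / sqrt(49 - 4 * 0.64), tolerance = 1e-12)
  # known-covariance form exceeds 1 with no unpaired data and is clamped
  s$n1 <- 0L; s$n2 <- 0L
  rc <- recovered_correlation(s, cov = known_cov(1, 1, 0.6))
  expect_equal(rc$value, 1)
  expect_true(rc$clamped)
})

test_that("hybrid worked-example intervals are frozen for the printed formulas", {
  d <- fev1_formoterol()
  ws <- ci_hybrid(d, 0.05, "wilson")
  wa <- ci_hybrid(d, 0.05, "agresti")
  expect_equal(round(c(ws$lower, ws$upper), 4), c(-0.4768, 0.5550))
  expect_equal(round(c(wa$lower, wa$upper), 4), c(-0.5671, 0.6490))
})

test_that("the hybrid interval always contains the estimated difference", {
  set.seed(503)
  for (k in 1:20) {
    d <- random_sample(n = sample(3:8, 1), n1 = sample(1:5, 1),
                       n2 = sample(1:5, 1), rho = runif(1, -0.95, 0.95))
    s <- pair_summary(d)
    diffhat <- s$mean_x1_all - s$mean_x2_all
    for (m in c("wilson", "agresti")) {
      ci <- ci_hybrid(d, 0.05, m)
      expect_lte(ci$lower, diffhat + 1e-12)
      expect_gte(ci$upper, diffhat - 1e-12)
    }
  }
})

test_that("hybrid width is non-increasing in the recovered correlation", {
  # with the shrunken anchoring all four tail radii are the (positive)
  # marginal half-widths, so each tail radius of the combination decreases
  # in the correlation; the pooled anchoring can flip a radius sign when
  # the shrunken and pooled centers differ a lot, breaking monotonicity
  d <- fev1_formoterol()
  l1 <- marginal_limits(d, 1L); l2 <- marginal_limits(d, 2L)
  hw1 <- (l1$u - l1$l) / 2; hw2 <- (l2$u - l2$l) / 2
  widths <- vapply(seq(-0.95, 0.95, by = 0.19), function(cr) {
    2 * sqrt(hw1^2 + hw2^2 - 2 * cr * hw1 * hw2)
  }, numeric(1))
  expect_true(all(diff(widths) <= 1e-12))
})

test_that("at zero correlation with symmetric marginals the tail radii are Pythagorean", {
  set.seed(504)
  d <- random_sample(n = 6, n1 = 3, n2 = 3)
  s <- pair_summary(d)
  s$r <- 0   # force zero recovered correlation
  l1 <- marginal_limits(d, 1L); l2 <- marginal_limits(d, 2L)
  expect_equal(recovered_correlation(s)$value, 0)
  hw1 <- (l1$u - l1$l) / 2; hw2 <- (l2$u - l2$l) / 2
  # with shrunken centers the marginal radii are exactly symmetric, so each
  # tail radius of the zero-correlation combination is sqrt(hw1^2 + hw2^2)
  dl1 <- l1$theta_tilde - l1$l; du2 <- l2$u - l2$theta_tilde
  expect_equal(sqrt(dl1^2 + du2^2), sqrt(hw1^2 + hw2^2), tolerance = 1e-12)
})

test_that("label swap negates and reverses both hybrid intervals", {
  set.seed(505)
  d <- random_sample(n = 7, n1 = 2, n2 = 4, rho = 0.5)
  for (m in c("wilson", "agresti"))
    expect_antisymmetric(function(x, ...) ci_hybrid(x, 0.05, m), d,
                         tol = 1e-10)
})
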