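# closed-form two-pass Butterworth band-pass gain, the independent oracle
# for the filter's pass/stop behaviour
bp_gain <- function(f, lo = 0.01, hi = 0.10, order = 4) {
  x <- (f^2 - lo * hi) / ((hi - lo) * f)
  1 / (1 + x^(2 * order))
}

# amplitude of a sinusoid at frequency f in a series, by regression
sin_amplitude <- function(y, f, tr) {
  t <- (seq_along(y) - 1) * tr
  fit <- lm(y ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
  sqrt(sum(coef(fit)[2:3]^2))
}

test_that("bandpass passes in-band and suppresses out-of-band sinusoids", {
  tr <- 0.8
  nt <- 1520L
  t <- (0:(nt - 1)) * tr
  rows <- rbind(const = rep(3, nt),
                inband = sin(2 * pi * 0.05 * t),
                stop = sin(2 * pi * 0.25 * t))
  ts <- make_ts(rows, tr = tr)
  out <- bandpass(ts)$data

  # DC is removed exactly and every output row is zero-mean
  expect_equal(max(abs(out[1, ])), 0)
  expect_lt(max(abs(rowMeans(out))), 1e-12)

  a_in <- sin_amplitude(out[2, ], 0.05, tr)
  expect_lt(abs(a_in - 1), 0.05)                      # within 5% of input
  expect_lt(abs(a_in - bp_gain(0.05)), 0.02)          # matches the design gain

  a_stop <- sin_amplitude(out[3, ], 0.25, tr)
  expect_lt(a_stop, 0.10)                             # stop-band < 10%
  expect_lt(abs(a_stop - bp_gain(0.25)), 0.02)

  # zero-phase: in-band output stays aligned with the input
  expect_gt(cor(out[2, ], rows[2, ]), 0.99)
})

test_that("bandpass validates its band and commutes with row permutation", {
  ts <- make_ts(matrix(rnorm(5 * 64), 5, 64), tr = 0.8)
  expect_error(bandpass(ts, 0.01, 0.7), "Nyquist")
  expect_error(bandpass(ts, 0.1, 0.01), "invalid")
  expect_error(bandpass(make_ts(matrix(1, 2, 8), tr = 0.8)), "16 frames")

  perm <- sample(5)
  a <- bandpass(ts)$data[perm, ]
  ts_p <- ts; ts_p$data <- ts$data[perm, ]
  expect_equal(bandpass(ts_p)$data, a)
})

test_that("censor_high_motion clears frames above threshold and flags exclusion", {
  ts <- make_ts(matrix(0.0, 2, 3), fd = c(0.1, 0.6, 0.2))
  out <- censor_high_motion(ts, 0.5, 0.5)
  expect_equal(out$frame_mask, c(TRUE, FALSE, TRUE))
  expect_false(out$excluded)

  ts0 <- make_ts(matrix(0.0, 2, 10))              # fd defaults to zeros
  out0 <- censor_high_motion(ts0)
  expect_true(all(out0$frame_mask))
  expect_false(out0$excluded)

  fd <- c(rep(0.7, 6), rep(0.1, 4))               # 40% retained < 50%
  exc <- censor_high_motion(make_ts(matrix(0.0, 2, 10), fd = fd))
  expect_true(exc$excluded)
  expect_equal(attr(exc, "retained_fraction"), 0.4)
})

test_that("residualize_group removes covariates and preserves the grand mean", {
  set.seed(31)
  n <- 80L
  covs <- data.frame(fd = runif(n, 0.05, 0.3),
                     age = rnorm(n, 120, 8),
                     sex = sample(c("F", "M"), n, TRUE))
  y <- 2 * covs$fd + rnorm(n, sd = 0.1)
  r <- residualize_group(y, covs)
  expect_lt(abs(cor(r, covs$fd)), 1e-8)
  expect_lt(abs(cor(r, covs$age)), 1e-8)
  expect_equal(mean(r), mean(y))

  # all-constant covariates: nothing to remove
  expect_equal(residualize_group(y, data.frame(a = rep(1, n), b = "x")), y)

  # single binary covariate: both residual group means equal the grand mean
  g <- rep(c(0, 1), each = 20)
  v <- ifelse(g == 0, 1, 3) + rnorm(40, sd = 0.01)
  rr <- residualize_group(v, data.frame(g = g))
  expect_equal(as.vector(tapply(rr, g, mean)), rep(mean(v), 2),
               tolerance = 1e-10)

  # idempotency
  expect_equal(residualize_group(r, covs), r, tolerance = 1e-10)

  # rank-deficient designs are rejected naming the collinear columns
  expect_error(residualize_group(y, data.frame(a = covs$fd, b = covs$fd)),
               "collinear")
})

test_that("grand_mean_scale equalizes stratum means", {
  v <- c(1, 3, 3, 5)                 # stratum means 2 and 4, grand mean 3
  s <- c("a", "a", "b", "b")
  out <- grand_mean_scale(v, s)
  expect_equal(out, c(1 * 1.5, 3 * 1.5, 3 * 0.75, 5 * 0.75),
               ignore_attr = TRUE)
  expect_equal(as.vector(tapply(out, s, mean)), c(3, 3))

  expect_equal(grand_mean_scale(v, rep("z", 4)), v,   # one stratum: identity
               ignore_attr = TRUE)

  set.seed(32)
  vv <- runif(90, 1, 5)
  ss <- sample(letters[1:3], 90, TRUE)
  oo <- grand_mean_scale(vv, ss)
  expect_lt(diff(range(tapply(oo, ss, mean))), 1e-12)

  expect_error(grand_mean_scale(c(-2, 1, 2, 2), c("a", "a", "b", "b")),
               "stratum mean")
})
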