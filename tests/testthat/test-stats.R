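test_that("two_sample_t_map matches the closed form and t.test oracle", {
  sp <- line_space(0)
  a <- matrix(c(1, 2, 3), 3, 1)
  b <- matrix(c(4, 5, 6), 3, 1)
  res <- two_sample_t_map(a, b, space = sp)
  expect_equal(res$t$values, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)

  # 50-vertex random fixture against stats::t.test per vertex
  set.seed(71)
  nv <- 50L
  spv <- line_space(seq_len(nv))
  A <- matrix(rnorm(8 * nv), 8, nv)
  B <- matrix(rnorm(6 * nv, mean = 0.5), 6, nv)
  res2 <- two_sample_t_map(A, B, space = spv)
  for (v in seq_len(nv)) {
    tt <- t.test(A[, v], B[, v], var.equal = TRUE)
    expect_lt(abs(res2$t$values[v] - unname(tt$statistic)), 1e-10)
    expect_lt(abs(res2$p$values[v] - tt$p.value), 1e-10)
  }

  # permutation invariance over subjects
  res3 <- two_sample_t_map(A[sample(8), ], B[sample(6), ], space = spv)
  expect_equal(res3$t$values, res2$t$values)

  # NaN propagation: zero variance in both groups
  A0 <- matrix(1, 3, 1); B0 <- matrix(1, 3, 1)
  expect_true(is.nan(two_sample_t_map(A0, B0, space = sp)$t$values))
  expect_error(two_sample_t_map(matrix(1, 1, 1), B0, space = sp),
               "2 subjects")
})

test_that("one_sample_t_map handles degenerate vertices as specified", {
  sp <- line_space(1:3)
  M <- rbind(c(0, 1, -1),
             c(0, 1, 0),
             c(0, 1, 1))
  expect_warning(res <- one_sample_t_map(M, space = sp), "1e9")
  expect_equal(res$t$values[1], 0)           # all zeros
  expect_equal(res$t$values[2], 1e9)         # {1,1,1}: zero variance, mean 1
  expect_equal(res$t$values[3], 0)           # {-1,0,1}: mean 0
  expect_equal(res$p$values[3], 1)
})

test_that("fdr_bh implements BH/BY step-up and matches p.adjust", {
  r <- fdr_bh(c(0.01, 0.02, 0.04), 0.05)
  expect_equal(r$mask, rep(TRUE, 3))
  expect_equal(fdr_bh(c(0.5, 0.6), 0.05)$mask, rep(FALSE, 2))
  expect_equal(fdr_bh(0.001, 0.05)$mask, TRUE)

  set.seed(72)
  for (i in 1:20) {
    p <- runif(200)^sample(c(1, 3), 1)
    p[sample(200, 5)] <- NA
    got <- fdr_bh(p, 0.05)
    expect_equal(got$q, p.adjust(p, "BH"))
    expect_equal(got$mask, p.adjust(p, "BH") <= 0.05)
    by <- fdr_bh(p, 0.05, method = "BY")
    expect_equal(by$q, pmin(p.adjust(p, "BY"), 1))
  }
  # q is monotone in sorted p
  p <- sort(runif(100))
  expect_true(all(diff(fdr_bh(p)$q) >= 0))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cohens_d and dice match hand computations", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # hand computation: means 0.5 vs 1.5, unbiased pooled SD = sqrt(1/2)
  expect_equal(cohens_d(c(0, 1), c(1, 2)), -sqrt(2))
  set.seed(73)
  a <- rnorm(2000, 1, 1); b <- rnorm(2000, 0, 1)
  expect_equal(cohens_d(a, b), 1, tolerance = 0.1)

  expect_equal(dice(c(TRUE, TRUE), c(TRUE, TRUE)), 1)
  expect_equal(dice(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_equal(dice(rep(c(TRUE, FALSE), each = 4),
                    c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_message(d0 <- dice(logical(3), logical(3)), "convention")
  expect_equal(d0, 1)
  expect_error(dice(logical(2), logical(3)), "shared space")
})

test_that("roi_group_model reduces to the two-sample t on balanced designs", {
  set.seed(74)
  n <- 40L
  cohort <- data.frame(group = rep(c("A", "B"), each = n / 2),
                       cov1 = rep(1, n))
  y <- rnorm(n) + ifelse(cohort$group == "B", 0.8, 0)
  fit <- roi_group_model(y, cohort, "cov1")   # constant covariate dropped
  tt <- two_sample_t_map(matrix(y[cohort$group == "B"]),
                         matrix(y[cohort$group == "A"]),
                         space = line_space(0))
  expect_lt(abs(fit$pairwise$t[1] - tt$t$values), 1e-10)
  expect_equal(fit$pairwise$contrast[1], "B - A")

  # duplicated covariate: rank error
  cohort2 <- data.frame(group = cohort$group, a = rnorm(n))
  cohort2$b <- cohort2$a
  expect_error(roi_group_model(y, cohort2, c("a", "b")), "rank|aliased")

  # three groups report an overall F plus all pairwise contrasts
  cohort3 <- data.frame(group = rep(c("L", "M", "R"), each = 10),
                        fd = runif(30))
  y3 <- rnorm(30)
  fit3 <- roi_group_model(y3, cohort3, "fd")
  expect_equal(nrow(fit3$pairwise), 3L)
  expect_true(is.finite(fit3$group_f) && is.finite(fit3$group_p))
})

test_that("roi_group_model keeps its size under the null", {
  set.seed(75)
  nsim <- 200L
  rej <- logical(nsim)
  for (i in seq_len(nsim)) {
    cohort <- data.frame(group = rep(c("A", "B"), each = 100),
                         fd = runif(200), age = rnorm(200))
    y <- rnorm(200) + 0.5 * cohort$fd
    rej[i] <- roi_group_model(y, cohort, c("fd", "age"))$group_p < 0.05
  }
  expect_gt(mean(rej), 0.015)
  expect_lt(mean(rej), 0.10)
})
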