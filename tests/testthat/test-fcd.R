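# canonical 4-vertex fixture: v1 == v2 (same hemisphere), v3 = -v1 on the
# other hemisphere, v4 independent noise
four_vertex_fixture <- function(nt = 64L, seed = 41L) {
  set.seed(seed)
  a <- rnorm(nt)
  list(ts = make_ts(rbind(a, a, -a, rnorm(nt))),
       space = surface_space(rbind(c(-10, 0, 0), c(-12, 0, 0),
                                   c(10, 0, 0), c(12, 0, 0)),
                             c("L", "L", "R", "R")))
}

test_that("compute_fcd reproduces the brute-force counts on the 4-vertex example", {
  fx <- four_vertex_fixture()
  pos <- compute_fcd(fx$ts, fx$space, fcd_params(0.6, "positive", "global"))
  expect_equal(pos$counts$values, c(1, 1, 0, 0))

  ipsi <- compute_fcd(fx$ts, fx$space, fcd_params(0.6, "positive", "ipsi"))
  contra <- compute_fcd(fx$ts, fx$space, fcd_params(0.6, "positive", "contra"))
  expect_equal(ipsi$counts$values, c(1, 1, 0, 0))
  expect_equal(contra$counts$values, c(0, 0, 0, 0))

  neg <- compute_fcd(fx$ts, fx$space, fcd_params(0.6, "negative", "global"))
  expect_equal(neg$counts$values,
               oracle_fcd_counts(fx$ts, fx$space, sign = "negative"))
  expect_equal(neg$counts$values[1], 1)   # v1 anticorrelated with v3 only
  expect_equal(neg$counts$values[3], 2)   # v3 anticorrelated with both copies
})

test_that("chunked counts equal the full-correlation oracle for every scope and sign", {
  set.seed(42)
  nv <- 60L
  sp <- surface_space(cbind(rnorm(nv), rnorm(nv), rnorm(nv)),
                      sample(c("L", "R"), nv, TRUE))
  # a mix of coupled blocks and noise so both tails are populated
  f <- rnorm(120)
  X <- matrix(rnorm(nv * 120, sd = 1), nv, 120)
  X[1:15, ] <- X[1:15, ] + 2 * matrix(f, 15, 120, byrow = TRUE)
  X[16:30, ] <- X[16:30, ] - 2 * matrix(f, 15, 120, byrow = TRUE)
  ts <- make_ts(X)
  for (thr in c(0.3, 0.6)) for (sg in c("positive", "negative"))
    for (sc in c("global", "ipsi", "contra")) {
      got <- compute_fcd(ts, sp, fcd_params(thr, sg, sc), chunk_size = 7L)
      expect_equal(got$counts$values,
                   oracle_fcd_counts(ts, sp, thr, sg, sc),
                   info = paste(thr, sg, sc))
    }
})

test_that("counts are bit-identical across chunk sizes and rows subsets", {
  set.seed(43)
  sp <- surface_space(cbind(rnorm(50), 0, 0), rep(c("L", "R"), 25))
  ts <- make_ts(matrix(rnorm(50 * 80), 50, 80))
  ref <- compute_fcd(ts, sp, chunk_size = 50L)$counts$values
  for (cs in c(1L, 7L, 17L))
    expect_identical(compute_fcd(ts, sp, chunk_size = cs)$counts$values, ref)
  sub <- compute_fcd(ts, sp, rows = c(3L, 20L, 44L))$counts$values
  expect_identical(sub[c(3, 20, 44)], ref[c(3, 20, 44)])
  expect_true(all(is.na(sub[-c(3, 20, 44)])))
})

test_that("raising the threshold never increases counts; permutation equivariance", {
  set.seed(44)
  sp <- surface_space(cbind(rnorm(40), 0, 0), rep(c("L", "R"), each = 20))
  ts <- make_ts(matrix(rnorm(40 * 100), 40, 100) +
                  2 * matrix(rnorm(100), 40, 100, byrow = TRUE))
  cnt <- sapply(c(0.3, 0.5, 0.7, 0.9), function(thr)
    compute_fcd(ts, sp, fcd_params(thr))$counts$values)
  expect_true(all(diff(t(cnt)) <= 0))

  perm <- sample(40L)
  sp_p <- surface_space(sp$coords[perm, , drop = FALSE],
                        as.character(sp$hemisphere)[perm])
  ts_p <- ts; ts_p$data <- ts$data[perm, ]
  ref <- compute_fcd(ts, sp)$counts$values
  expect_identical(compute_fcd(ts_p, sp_p)$counts$values, ref[perm])
})

test_that("counts depend only on retained frames", {
  set.seed(45)
  sp <- surface_space(cbind(rnorm(20), 0, 0), rep(c("L", "R"), 10))
  X <- matrix(rnorm(20 * 60), 20, 60)
  mask <- rep(TRUE, 60); mask[c(5, 17, 33)] <- FALSE
  ts1 <- make_ts(X, frame_mask = mask)
  X2 <- X
  X2[, !mask] <- 1e6 * matrix(rnorm(20 * 3), 20, 3)   # junk in masked frames
  ts2 <- make_ts(X2, frame_mask = mask)
  expect_identical(compute_fcd(ts1, sp)$counts$values,
                   compute_fcd(ts2, sp)$counts$values)
})

test_that("zero-variance rows yield count 0 and long noise yields no edges", {
  sp <- surface_space(cbind(rnorm(30), 0, 0), rep(c("L", "R"), 15))
  set.seed(46)
  X <- matrix(rnorm(30 * 2000), 30, 2000)
  X[7, ] <- 5                                   # constant row
  res <- compute_fcd(make_ts(X), sp)
  expect_equal(res$counts$values[7], 0)
  expect_equal(res$counts$values, rep(0, 30))   # white noise: no r > 0.6
  expect_equal(res$gfcd$values, rep(0, 30))
})

test_that("the gFCD log rule is applied as configured", {
  fx <- four_vertex_fixture()
  ln <- compute_fcd(fx$ts, fx$space, fcd_params(0.6, log_base = "natural"))
  expect_equal(ln$gfcd$values, c(log(1), log(1), 0, 0))
  l10 <- compute_fcd(fx$ts, fx$space, fcd_params(0.6, log_base = "log10"))
  expect_equal(l10$gfcd$values, c(0, 0, 0, 0))
  raw <- compute_fcd(fx$ts, fx$space, fcd_params(0.6, log_base = "none"))
  expect_equal(raw$gfcd$values, raw$counts$values)
})

test_that("scope decomposition check passes on synthetic data and catches preconditions", {
  gp <- tiny_gen()
  sg <- generate_space(gp)
  ts <- generate_subject_timeseries(sg, list(subject_id = "d1",
                                             ehis_score = 100), gp)
  ts <- censor_high_motion(bandpass(ts))
  expect_silent(fcd_scope_decomposition_check(ts, sg$space))
  # single-hemisphere space: contralateral counts are all zero
  spL <- line_space(rnorm(10) * 30)
  tsL <- make_ts(matrix(rnorm(10 * 64), 10, 64))
  contra <- compute_fcd(tsL, spL, fcd_params(0.6, scope = "contra"))
  expect_equal(contra$counts$values, rep(0, 10))

  short <- make_ts(matrix(rnorm(8), 4, 2))
  expect_error(compute_fcd(short, four_vertex_fixture()$space),
               "3 retained frames")
  expect_error(fcd_params(1.2), "threshold")
  exc <- censor_high_motion(make_ts(matrix(rnorm(40), 4, 10),
                                    fd = rep(1, 10)))
  expect_error(compute_fcd(exc, four_vertex_fixture()$space), "excluded")
})
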