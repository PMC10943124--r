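test_that("generator is deterministic under the master seed", {
  gp <- tiny_gen(seed = 81L)
  s1 <- generate_space(gp); s2 <- generate_space(gp)
  expect_identical(s1$space$coords, s2$space$coords)
  expect_identical(s1$ml$members, s2$ml$members)

  c1 <- generate_cohort(5L, gp); c2 <- generate_cohort(5L, gp)
  expect_identical(c1, c2)

  sub <- c1[3L, ]
  t1 <- generate_subject_timeseries(s1, sub, gp)
  t2 <- generate_subject_timeseries(s1, sub, gp)
  expect_identical(t1$data, t2$data)
  expect_identical(t1$fd, t2$fd)

  # subjects are regenerable in isolation (named substreams): generating
  # another subject first does not perturb subject 3
  invisible(generate_subject_timeseries(s1, c1[1L, ], gp))
  t3 <- generate_subject_timeseries(s1, sub, gp)
  expect_identical(t3$data, t1$data)

  gp2 <- tiny_gen(seed = 82L)
  expect_false(identical(generate_space(gp2)$space$coords, s1$space$coords))
})

test_that("generated spaces are mirror-symmetric with matched motor patches", {
  gp <- tiny_gen(seed = 83L)
  sg <- generate_space(gp)
  p <- build_homologous_pairing(sg$space)
  expect_equal(p$pairs$left, sg$pairing_truth$left)
  expect_equal(p$pairs$right, sg$pairing_truth$right)
  expect_equal(p$coordinate_correlation, 1.0)
  # ROIs are mirror copies: same member count, mirrored ids
  expect_equal(length(sg$ml$members), length(sg$mr$members))
  expect_equal(sg$mr$members, sg$ml$members + gp$n_vertices_per_hemi)
  # hemisphere labels are honored
  expect_true(all(sg$space$hemisphere[sg$ml$members] == "L"))
  expect_true(all(sg$space$hemisphere[sg$mr$members] == "R"))

  # jittered space still recovers the true twin
  gpj <- tiny_gen(seed = 83L, jitter_sd = 0.1)
  sgj <- generate_space(gpj)
  pj <- build_homologous_pairing(sgj$space)
  expect_equal(pj$pairs$left, sgj$pairing_truth$left)
  expect_equal(pj$pairs$right, sgj$pairing_truth$right)
})

test_that("cohort tables are balanced with group-consistent handedness scores", {
  gp <- tiny_gen(seed = 84L)
  cohort <- generate_cohort(600L, gp)
  expect_equal(nrow(cohort), 1800L)
  expect_equal(unname(table(cohort$group)), rep(600L, 3L),
               ignore_attr = TRUE)
  expect_true(all(cohort$ehis_score[cohort$group == "R"] > 0))
  expect_true(all(cohort$ehis_score[cohort$group == "L"] < 0))
  expect_true(all(abs(cohort$ehis_score[cohort$group == "M"]) <= 50))
  expect_true(all(as.matrix(cohort[, paste0("ehis_item", 1:4)]) %in%
                    c(100, 50, 0, -50, -100)))
  expect_equal(cohort$ehis_score,
               rowMeans(cohort[, paste0("ehis_item", 1:4)]))
  expect_error(generate_cohort(1L, gp), ">= 2")
})

test_that("group labels are exchangeable when the motor effect is off", {
  gp <- tiny_gen(seed = 85L, motor_asymmetry_effect = 0)
  sg <- generate_space(gp)
  tsR <- generate_subject_timeseries(sg, list(subject_id = "X",
                                              ehis_score = 100), gp)
  tsL <- generate_subject_timeseries(sg, list(subject_id = "X",
                                              ehis_score = -100), gp)
  expect_identical(tsR$data, tsL$data)
})

test_that("without homotopic coupling, contralateral counts vanish off the hub set", {
  # at short series the band-pass leaves few effective degrees of freedom
  # and chance |r| > 0.6 is not negligible; 512 frames (~40 in-band bins)
  # makes the null tail bound sharp.  Scaled down from a 200-subject check.
  gp <- tiny_gen(seed = 86L, homotopic_rho = 0, n_frames = 512L)
  sg <- generate_space(gp)
  n_subj <- 10L
  acc <- 0
  n_off <- NULL
  for (i in seq_len(n_subj)) {
    ts <- generate_subject_timeseries(sg, list(subject_id = paste0("h", i),
                                               ehis_score = 0), gp)
    ts <- censor_high_motion(bandpass(ts))
    contra <- compute_fcd(ts, sg$space, fcd_params(0.6, scope = "contra"))
    off_hub <- setdiff(seq_len(sg$space$n),
                       c(sg$hubs, sg$ml$members, sg$mr$members,
                         sg$ml_nbr, sg$mr_nbr))
    n_off <- length(off_hub)
    acc <- acc + mean(contra$counts$values[off_hub])
  }
  expect_lt(acc / n_subj, 0.05)
})

test_that("FD traces mix a plausible baseline with censorable spikes", {
  gp <- tiny_gen(seed = 87L, fd_spike_rate = 0.2, n_frames = 512L)
  sg <- generate_space(gp)
  ts <- generate_subject_timeseries(sg, list(subject_id = "fd1",
                                             ehis_score = 0), gp)
  frac_spike <- mean(ts$fd > 0.5)
  expect_gt(frac_spike, 0.1)
  expect_lt(frac_spike, 0.3)
  expect_true(all(ts$fd >= 0))
  # spikes are censorable: the censored mask drops exactly the > 0.5 frames
  cen <- censor_high_motion(ts)
  expect_equal(cen$frame_mask, ts$fd <= 0.5)
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(generator_params(hub_fraction = 1.2), "\\[0, 1\\]")
  expect_error(generator_params(n_frames = 32L), ">= 64")
  expect_error(generator_params(n_vertices_per_hemi = 10L), ">= 50")
})
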