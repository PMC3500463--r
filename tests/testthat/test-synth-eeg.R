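test_that("montage has 64 unique unit-norm scalp channels incl. the pool", {
  m <- standard_montage()
  sc <- m[m$type == "scalp", ]
  expect_equal(nrow(sc), 64)
  expect_false(anyDuplicated(m$label) > 0)
  expect_true(all(abs(sqrt(sc$x^2 + sc$y^2 + sc$z^2) - 1) < 1e-9))
  expect_true(all(pool_channels() %in% sc$label))
  expect_equal(sum(m$type == "eog"), 4)
})

test_that("ground-truth ERPs respect template support and gains", {
  tm <- erp_templates()
  t_ms <- seq(-200, 500, by = 2)
  expect_true(all(ground_truth_erp("homogenous", "none", tm, t_ms) == 0))
  sf <- ground_truth_erp("stack", "none", tm, t_ms) -
    ground_truth_erp("frame", "none", tm, t_ms)
  expect_true(all(sf[t_ms < 227 | t_ms > 313] == 0))
  expect_true(any(sf != 0))
  # early gain scales the stack-frame difference multiplicatively
  sf_early <- ground_truth_erp("stack", "early", tm, t_ms) -
    ground_truth_erp("frame", "early", tm, t_ms)
  expect_equal(sf_early, sf * tm$surface$gains[["early"]])
  # figure-homogenous support: the shared figural window plus half the
  # stack-only surface component
  fh <- (ground_truth_erp("stack", "none", tm, t_ms) +
           ground_truth_erp("frame", "none", tm, t_ms)) / 2
  expect_true(all(fh[t_ms < 137 | (t_ms > 211 & t_ms < 227)] == 0))
  expect_equal(fh[t_ms >= 137 & t_ms <= 211],
               tm$figural$amplitude *
                 figseg:::hann_bump(t_ms[t_ms >= 137 & t_ms <= 211],
                                    c(137, 211)))
})

test_that("TMS artifact model matches the double-pulse arithmetic", {
  a <- tms_artifact_model()
  expect_equal(a$pulse_gap_ms, 23)
  for (w in a$onsets_ms) expect_equal(diff(w), 23)
  expect_gte(a$peak_uv, 10 * abs(erp_templates()$figural$amplitude) * 100)
  wave <- artifact_waveform(a, 1048)
  expect_true(all(abs(wave) <= a$clip_uv))
  expect_gt(max(abs(wave)), 0.9 * a$peak_uv)
})

test_that("simulated recordings are deterministic in the seed", {
  sch <- build_schedule(1, 12, seed = 4)
  a <- simulate_subject(sch, seed = 77)
  b <- simulate_subject(sch, seed = 77)
  expect_identical(a$data, b$data)
  expect_identical(a$behavior, b$behavior)
  c <- simulate_subject(sch, seed = 78)
  expect_false(identical(a$data, c$data))
})

test_that("with zero noise and no TMS the recording is the clean ERP stream", {
  sch <- build_schedule(1, 12, seed = 4)
  rec <- simulate_subject(sch, noise = quiet_noise(), artifact = NULL,
                          seed = 5)
  expect_identical(rec$data, rec$clean)
  expect_equal(nrow(rec$pulses), 0)
})

test_that("recording minus clean ground truth is exactly the noise stream", {
  sch <- build_schedule(1, 12, seed = 4)
  rec <- simulate_subject(sch, seed = 6, store_components = TRUE)
  expect_equal(rec$data - rec$clean, rec$components, tolerance = 1e-12)
})

test_that("pulse events appear only on TMS trials with the right timing", {
  sch <- build_schedule(1, 24, seed = 8)
  rec <- simulate_subject(sch, seed = 9)
  expect_equal(nrow(rec$pulses), sum(sch$tms != "none"))
  for (r in seq_len(nrow(rec$pulses))) {
    tr <- rec$pulses$trial[r]
    off_ms <- (rec$pulses$sample[r] - rec$events$sample[tr]) / rec$fs * 1000
    expect_equal(off_ms, tms_windows_ms()[[rec$pulses$condition[r]]][1],
                 tolerance = 1)
  }
  expect_true(all(diff(rec$events$sample) > 0))
})

test_that("confusion rows are stochastic and accuracies converge to the diagonal", {
  bm <- behavior_model()
  for (m in bm$confusion) expect_equal(rowSums(m), c(stack = 1, frame = 1,
                                                     homogenous = 1))
  # law of large numbers at ~10k trials: sampled accuracy within 3 binomial
  # SE of the generating diagonal in every cell
  sch <- build_schedule(105, 96, seed = 1) # 840 trials per cell
  beh <- sample_behavior(sch, bm, seed = 31)
  n_cell <- 840
  for (cc in tms_conditions_4) {
    for (k in kinds_3) {
      acc <- mean(beh$correct[beh$kind == k & beh$tms == cc])
      p <- bm$confusion[[cc]][k, k]
      expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / n_cell))
    }
  }
})

test_that("simulated behavior reproduces the condition-dependent deficits", {
  sch <- build_schedule(25, 96, seed = 1) # 200 trials per cell
  beh <- sample_behavior(sch, behavior_model(), seed = 41)
  acc <- with(beh, tapply(correct, list(kind, tms), mean))
  expect_gt(acc["stack", "none"], acc["stack", "late"]) # late TMS hits stacks
  expect_true(all(acc["frame", "early"] <
                    acc["frame", c("none", "intermediate", "late")]))
  # sham: RT slowing without accuracy change in the generating model
  sham <- behavior_model(sham = TRUE)
  beh_s <- sample_behavior(sch, sham, seed = 42)
  rt_means <- with(beh_s, tapply(rt_ms, tms, mean))
  expect_true(all(rt_means[c("early", "intermediate", "late")] >
                    rt_means["none"]))
})

test_that("cohorts share ground truth when between-subject variance is zero", {
  sch <- build_schedule(1, 12, seed = 4)
  co <- simulate_cohort(2, sch, noise = quiet_noise(), artifact = NULL,
                        seed = 3)
  expect_identical(co$recordings[[1]]$clean, co$recordings[[2]]$clean)
  expect_error(simulate_cohort(1, sch), class = "figseg_input_error")
})

test_that("poor subjects fall at or below the exclusion bar", {
  sch <- build_schedule(2, 12, seed = 4)
  co <- simulate_cohort(2, sch, noise = quiet_noise(), artifact = NULL,
                        n_poor = 1, seed = 13)
  beh <- co$behavior
  acc <- tapply(beh$correct, beh$subject, mean)
  expect_lt(acc[["3"]], 0.55) # chance responder, far below 67%
})

test_that("ERP-level cohorts are seeded and carry the injected structure", {
  a <- simulate_erp_cohort(3, seed = 10)
  b <- simulate_erp_cohort(3, seed = 10)
  expect_identical(a$erps, b$erps)
  # noiseless cohort: stack-frame difference is the surface template
  c0 <- simulate_erp_cohort(2, noise_sd = 0, subject_sd = 0, seed = 1)
  dw <- difference_waves(c0, "stack-frame", "none")
  gt <- ground_truth_erp("stack", "none", erp_templates(), c0$times_ms) -
    ground_truth_erp("frame", "none", erp_templates(), c0$times_ms)
  expect_equal(dw$mat[1, ], gt)
  expect_error(simulate_erp_cohort(1), class = "figseg_input_error")
})
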