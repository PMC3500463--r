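test_that("excision recovers polynomials exactly and touches nothing outside", {
  fs <- 1048
  n <- 4000
  line <- matrix(3 + 0.01 * seq_len(n), 1)
  z <- line
  z[1, 2000:2060] <- 0 # corrupted segment inside the excision window
  ex <- excise_and_interpolate(z, fs, 2000)
  expect_lt(max(abs(ex$data - line)), 1e-8)
  expect_equal(sum(ex$mask), diff(excision_spec()$window_ms) / 1000 * fs,
               tolerance = 2)
  # bit-identity outside the window
  expect_identical(ex$data[1, !ex$mask], z[1, !ex$mask])
  # no pulses: identity with empty mask
  ex0 <- excise_and_interpolate(z, fs, integer(0))
  expect_identical(ex0$data, z)
  expect_false(any(ex0$mask))
})

test_that("excision interpolation error on a 5 Hz sinusoid is below 5%", {
  fs <- 1048
  tt <- seq_len(20000) / fs
  s5 <- matrix(sin(2 * pi * 5 * tt), 1)
  ex <- excise_and_interpolate(s5, fs, 10000)
  gap <- which(ex$mask)
  rmse <- sqrt(mean((ex$data[1, gap] - s5[1, gap])^2))
  expect_lt(rmse, 0.05)
})

test_that("excision near the recording edge raises a boundary error", {
  x <- matrix(rnorm(2000), 1)
  expect_error(excise_and_interpolate(x, 1048, 100),
               class = "figseg_boundary_error")
})

test_that("mirror filtering is zero-phase with the designed band behaviour", {
  fs <- 1048
  t <- seq(0, 10, by = 1 / fs)
  mid <- seq(2 * fs, 8 * fs)
  y10 <- mirror_filter(sin(2 * pi * 10 * t), fs)
  expect_equal(max(abs(y10[mid])), 1, tolerance = 0.02) # passband gain
  cc <- stats::ccf(y10[mid], sin(2 * pi * 10 * t)[mid], lag.max = 5,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0) # zero-lag peak
  y50 <- mirror_filter(sin(2 * pi * 50 * t), fs)
  expect_lt(max(abs(y50[mid])), 0.05) # notch residual < 5%
  expect_error(mirror_filter(rnorm(100), fs), class = "figseg_input_error")
})

test_that("mirror filtering rings less at a step than causal filtering", {
  fs <- 1048
  x <- c(rep(0, 8000), rep(50, 8000))
  sp <- filter_spec(highpass = NULL) # keep a DC steady state to compare to
  ym <- mirror_filter(x, fs, sp)
  yc <- causal_filter(x, fs, sp)
  settle <- 8100:9000 # after the step transit
  expect_lt(max(abs(ym[settle] - 50)), max(abs(yc[settle] - 50)))
})

test_that("resampling metadata matches the actual sample spacing", {
  fs <- 1048
  x <- sin(2 * pi * 7 * seq(0, 4, by = 1 / fs))
  rs <- resample_to(x, fs, 256)
  expect_equal(rs$fs, 256)
  expect_equal(length(rs$data), floor(4 * 256) + 1)
  t_new <- (seq_along(rs$data) - 1) / rs$fs
  expect_equal(rs$data[100], sin(2 * pi * 7 * t_new[100]), tolerance = 1e-4)
})

test_that("ocular correction removes injected blinks and skips degenerate EOG", {
  sch <- build_schedule(1, 12, seed = 2)
  nz <- noise_model(blink_rate_per_min = 12)
  rec <- simulate_subject(sch, noise = nz, artifact = NULL, seed = 33)
  oc <- ocular_correct(rec$data, rownames(rec$data), fs = rec$fs)
  veog <- rec$data["VEOG1", ]
  resid_before <- rec$data["Fpz", ] - rec$clean["Fpz", ]
  resid_after <- oc$data["Fpz", ] - rec$clean["Fpz", ]
  b0 <- stats::coef(stats::lm(resid_before ~ veog))[2]
  b1 <- stats::coef(stats::lm(resid_after ~ veog))[2]
  expect_lt(abs(b1), 0.1 * abs(b0)) # residual blink < 10% of injected
  # flat EOG: warning, data untouched
  flat <- rec$data
  flat[grepl("EOG", rownames(flat)), ] <- 0
  expect_warning(oc2 <- ocular_correct(flat, rownames(flat), fs = rec$fs),
                 "flat")
  expect_identical(oc2$data, flat)
})

test_that("ocular coefficients vanish on a blink-free recording", {
  sch <- build_schedule(1, 12, seed = 2)
  rec <- simulate_subject(sch, noise = noise_model(blink_rate_per_min = 0),
                          artifact = NULL, seed = 14)
  oc <- ocular_correct(rec$data, rownames(rec$data), fs = rec$fs)
  # only spurious 1/f correlation left: small weights, and the induced
  # change stays well below the background-noise floor
  expect_lt(max(abs(oc$coefficients)), 0.25)
  ch <- "Oz"
  change_rms <- sqrt(mean((oc$data[ch, ] - rec$data[ch, ])^2))
  expect_lt(change_rms, 0.5 * sd(rec$data[ch, ]))
})

make_epochs <- function(data_arr, mask = NULL, labels) {
  n_tr <- dim(data_arr)[1]
  structure(list(
    data = data_arr,
    mask = mask %||% matrix(FALSE, n_tr, dim(data_arr)[3]),
    meta = data.frame(kind = rep("stack", n_tr), tms = "none",
                      correct = TRUE),
    times_ms = seq_len(dim(data_arr)[3]) / 256 * 1000, fs = 256,
    labels = labels), class = "fg_epochs")
}

test_that("artifact rejection applies the amplitude and step thresholds literally", {
  labs <- c("A", "B")
  arr <- array(0, dim = c(4, 2, 50))
  arr[1, 1, 10] <- 80                    # amplitude violation
  arr[2, 2, ] <- seq(0, 49) * 0.5        # smooth, max 24.5: retained
  arr[3, 1, 25:29] <- c(49, 74, 49, 25, 0) # 74 peak, max step 49: retained
  arr[4, 2, 30] <- 60                    # 60 uV jump from 0: step violation
  rj <- reject_artifacts(make_epochs(arr, labels = labs))
  expect_equal(dim(rj$epochs$data)[1], 2)
  expect_equal(rj$report$reason, c("amplitude", "step"))
  expect_equal(rj$report$trial, c(1L, 4L))
  # interpolated samples are exempt from the step criterion
  mask <- matrix(FALSE, 1, 50); mask[1, 29:31] <- TRUE
  arr2 <- array(0, dim = c(1, 2, 50)); arr2[1, 2, 30] <- 60
  rj2 <- reject_artifacts(make_epochs(arr2, mask, labs))
  expect_equal(nrow(rj2$report), 0)
  # everything rejected -> classed error
  arr3 <- array(100, dim = c(2, 2, 50))
  expect_error(reject_artifacts(make_epochs(arr3, labels = labs)),
               class = "figseg_empty_error")
})

test_that("the surface Laplacian passes its analytic checks", {
  m <- standard_montage()
  lt <- laplacian_transform(m)
  expect_lt(max(abs(lt$L %*% rep(5, 64))), 1e-8) # constant -> 0
  sc <- m[m$type == "scalp", ]
  v <- sc$z # l = 1 zonal spherical harmonic
  lap <- as.numeric(lt$L %*% v)
  interior <- sc$z > 0.15 # away from the spline rim
  rel_err <- abs(lap - (-2 * v)) / max(abs(2 * v))
  expect_lt(max(rel_err[interior]), 0.05) # -l(l+1) eigenrelation
  # reference invariance
  expect_equal(as.numeric(lt$L %*% (v + 7.3)), lap, tolerance = 1e-8)
  # duplicate electrodes -> singular geometry
  m2 <- m
  m2[2, c("x", "y", "z")] <- m2[1, c("x", "y", "z")]
  expect_error(laplacian_transform(m2), class = "figseg_geometry_error")
  expect_error(laplacian_transform(m[1:10, ]), class = "figseg_input_error")
})

test_that("the full chain recovers the injected ERP on a quiet recording", {
  sch <- build_schedule(1, 24, seed = 3)
  rec <- simulate_subject(sch, noise = quiet_noise(), artifact = NULL,
                          seed = 12)
  pp <- run_preprocessing(rec, preproc_config(laplacian = FALSE,
                                              ocular = FALSE,
                                              excision = FALSE))
  e <- pp$erps[["stack.none"]]
  gt <- filtered_template("stack", "none", e$times_ms)
  rel <- sqrt(mean((e$pooled - gt)^2)) / sqrt(mean(gt^2))
  expect_lt(rel, 0.02)
  # every ERP channel is baseline-zero
  bl <- e$times_ms >= -100 & e$times_ms <= 0
  expect_lt(max(abs(rowMeans(e$data[, bl]))), 1e-10)
  # no events -> error
  rec$events <- rec$events[0, ]
  expect_error(run_preprocessing(rec), class = "figseg_input_error")
})

test_that("excision + interpolation brings ERPs closer to ground truth in every TMS condition", {
  sch <- build_schedule(2, 24, seed = 5)
  rec <- simulate_subject(sch, seed = 21)
  base <- preproc_config(reject = FALSE, laplacian = FALSE, ocular = FALSE)
  on <- run_preprocessing(rec, base)
  off_cfg <- base; off_cfg$excision <- FALSE
  off <- run_preprocessing(rec, off_cfg)
  for (cc in c("early", "intermediate", "late")) {
    nm <- paste("stack", cc, sep = ".")
    gt <- filtered_template("stack", cc, on$erps[[nm]]$times_ms)
    rmse_on <- sqrt(mean((on$erps[[nm]]$pooled - gt)^2))
    rmse_off <- sqrt(mean((off$erps[[nm]]$pooled - gt)^2))
    expect_lt(rmse_on, rmse_off)
  }
})

test_that("ERP estimation error shrinks with trial count", {
  errs <- sapply(c(12, 48, 96), function(n_tr) {
    sch <- build_schedule(1, n_tr, seed = 6)
    rec <- simulate_subject(sch, artifact = NULL,
                            noise = noise_model(blink_rate_per_min = 0,
                                                subject_sd = 0),
                            seed = 61)
    pp <- run_preprocessing(rec, preproc_config(laplacian = FALSE,
                                                ocular = FALSE,
                                                excision = FALSE,
                                                trials = "all"))
    err <- 0
    for (k in kinds_3) {
      e <- pp$erps[[paste(k, "none", sep = ".")]]
      gt <- filtered_template(k, "none", e$times_ms)
      err <- err + sqrt(mean((e$pooled - gt)^2))
    }
    err
  })
  expect_true(all(diff(errs) < 0))
})
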