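test_that("behavioral filters apply the RT and accuracy rules exactly", {
  tab <- data.frame(
    subject = rep(1:2, each = 6),
    kind = "stack", tms = "none",
    response = "stack",
    rt_ms = rep(c(99, 100, 500, 1500, 1501, 700), 2),
    correct = TRUE)
  # subject 2 at exactly 67% correct overall -> excluded
  tab$correct[tab$subject == 2] <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  tab$response[!tab$correct] <- "frame"
  out <- filter_behavior(tab)
  lg <- attr(out, "log")
  expect_equal(lg$n_rt_removed, 4) # RT 99 and 1501 per subject
  expect_true(all(out$rt_ms >= 100 & out$rt_ms <= 1500))
  # subject 2 accuracy on retained trials: 2/4 + ... compute explicitly
  expect_true(all(out$subject == 1))
  expect_true("2" %in% lg$subjects_removed)
  # a clean table passes unchanged
  ok <- data.frame(subject = 1, kind = "stack", tms = "none",
                   response = "stack", rt_ms = c(100, 1500, 800),
                   correct = TRUE)
  expect_equal(nrow(filter_behavior(ok)), 3)
})

test_that("subjects at exactly the 67% bar are excluded", {
  tab <- data.frame(subject = rep(1:2, each = 100), kind = "stack",
                    tms = "none", response = "stack", rt_ms = 500,
                    correct = c(rep(TRUE, 100),
                                rep(c(TRUE, FALSE), c(67, 33))))
  out <- filter_behavior(tab)
  expect_true(all(out$subject == 1))
})

test_that("within-subject ANOVA matches the aov error-stratum oracle", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    cells <- expand.grid(subject = 1:4, stimulus = c("a", "b", "c"),
                         tms = c("w", "x", "y", "z"),
                         stringsAsFactors = FALSE)
    cells$value <- rnorm(nrow(cells))
    res <- rm_anova_3x4(cells)
    fit <- stats::aov(value ~ stimulus * tms +
                        Error(factor(subject) / (stimulus * tms)),
                      data = cells)
    s <- summary(fit)
    f_or <- c(s[["Error: factor(subject):stimulus"]][[1]]$`F value`[1],
              s[["Error: factor(subject):tms"]][[1]]$`F value`[1],
              s[["Error: factor(subject):stimulus:tms"]][[1]]$`F value`[1])
    expect_equal(res$F, f_or, tolerance = 1e-10)
    # SS partition closes
    sst <- attr(res, "ss_table")
    expect_equal(sum(sst[-1]), sst[["total"]], tolerance = 1e-8)
  }
})

test_that("ANOVA degrees of freedom and degenerate inputs behave", {
  cells <- expand.grid(subject = 1:11, stimulus = kinds_3,
                       tms = tms_conditions_4, stringsAsFactors = FALSE)
  cells$value <- stats::runif(nrow(cells))
  res <- rm_anova_3x4(cells)
  inter <- res[res$effect == "stimulus:tms", ]
  expect_equal(c(inter$df1, inter$df2), c(6, 60))
  # all cells equal -> all F = 0
  cells$value <- 0.5
  expect_true(all(rm_anova_3x4(cells)$F == 0))
  # missing cell -> error naming it
  expect_error(rm_anova_3x4(cells[-1, ]), "missing cell",
               class = "figseg_input_error")
})

test_that("Benjamini-Hochberg matches the brute-force step-up oracle", {
  p15 <- c(0.0001, 0.0004, 0.0019, 0.0095, 0.0201, 0.0278, 0.0298,
           0.0344, 0.0459, 0.3240, 0.4262, 0.5719, 0.6528, 0.7590, 1.000)
  sel <- bh_select(p15, 0.05)
  expect_equal(which(sel$reject), 1:4) # exactly the 4 smallest
  set.seed(99)
  for (i in 1:300) {
    p <- stats::runif(sample(2:60, 1))^sample(1:3, 1)
    expect_identical(bh_select(p, 0.05)$reject, brute_force_bh(p, 0.05))
  }
})

test_that("sample-wise FDR tests handle nulls, masks and zero variance", {
  times <- seq(-200, 500, length.out = 180)
  zero <- matrix(0, 5, 180)
  expect_warning(r0 <- samplewise_fdr_ttest(zero, c(80, 230),
                                            times_ms = times),
                 "zero-variance")
  expect_false(any(r0$table$sig))
  # masked-out samples never significant; fully masked window errors
  set.seed(1)
  mat <- matrix(rnorm(5 * 180, mean = 3), 5, 180) # strong global effect
  msk <- times >= 100 & times <= 150
  r1 <- samplewise_fdr_ttest(mat, c(80, 230), times_ms = times, mask = msk)
  expect_false(any(r1$table$sig[msk]))
  expect_true(any(r1$table$sig))
  full <- times >= 75 & times <= 235
  expect_error(samplewise_fdr_ttest(mat, c(80, 230), times_ms = times,
                                    mask = full),
               "could not be tested", class = "figseg_masked_error")
  # intervals lie inside the test window
  expect_true(all(r1$intervals$start_ms >= 80 & r1$intervals$end_ms <= 230))
})

test_that("paired-t symmetry: swapping the contrast negates t, keeps p", {
  co <- simulate_erp_cohort(8, seed = 55)
  dw <- difference_waves(co, "stack-frame", "none")
  r1 <- samplewise_fdr_ttest(dw, c(200, 350))
  dw2 <- dw; dw2$mat <- -dw$mat
  r2 <- samplewise_fdr_ttest(dw2, c(200, 350))
  expect_equal(r2$table$t, -r1$table$t)
  expect_equal(r2$table$p, r1$table$p)
  expect_identical(r2$table$sig, r1$table$sig)
})

test_that("the figure difference wave averages stack and frame before subtracting", {
  co <- simulate_erp_cohort(3, noise_sd = 0, subject_sd = 0, seed = 2)
  dw <- difference_waves(co, "figure-homogenous", "none")
  tm <- erp_templates()
  gt <- (ground_truth_erp("stack", "none", tm, co$times_ms) +
           ground_truth_erp("frame", "none", tm, co$times_ms)) / 2
  expect_equal(dw$mat[2, ], gt)
})

test_that("cumulative stack-frame statistics behave on degenerate and scaled input", {
  # identical stack and frame ERPs -> zeros, t = 0
  co <- simulate_erp_cohort(4, noise_sd = 0, subject_sd = 0, seed = 3)
  sets <- figseg:::erp_cohort_sets(co)
  for (s in seq_along(sets)) {
    sets[[s]][["stack.none"]] <- sets[[s]][["frame.none"]]
    sets[[s]][["stack.early"]] <- sets[[s]][["frame.early"]]
    sets[[s]][["stack.intermediate"]] <- sets[[s]][["frame.intermediate"]]
  }
  expect_warning(ct <- cumulative_diff_test(sets), NA)
  expect_true(all(ct$cumulative == 0))
  expect_true(all(ct$comparisons$t == 0))
  # correct-only ERPs carrying the full (unattenuated) signal cumulate
  # at least as much as all-trials ERPs diluted by error trials
  co2 <- simulate_erp_cohort(6, seed = 4)
  all_tr <- figseg:::erp_cohort_sets(co2)
  correct <- all_tr
  for (s in seq_along(all_tr)) {
    for (nm in names(all_tr[[s]])) {
      all_tr[[s]][[nm]]$pooled <- 0.7 * all_tr[[s]][[nm]]$pooled
    }
  }
  c_all <- cumulative_diff_test(all_tr, trial_subset = "all")
  c_cor <- cumulative_diff_test(correct, trial_subset = "correct")
  expect_gte(mean(c_cor$cumulative[, "none"]),
             mean(c_all$cumulative[, "none"]))
})

test_that("early TMS attenuation of the cumulative difference is detected", {
  hits <- 0L
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    co <- simulate_erp_cohort(11, seed = derive_seed(777, r))
    ct <- cumulative_diff_test(co)
    row <- ct$comparisons[ct$comparisons$a == "none" &
                            ct$comparisons$b == "early", ]
    if (row$p < 0.05 &&
        mean(ct$cumulative[, "none"]) > mean(ct$cumulative[, "early"])) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("error-type analysis recovers the generating confusion structure", {
  # perfect responder: all error proportions zero
  perfect <- data.frame(subject = 1, kind = rep(kinds_3, each = 8),
                        tms = rep(tms_conditions_4, 6),
                        response = rep(kinds_3, each = 8),
                        rt_ms = 500, correct = TRUE)
  ea <- error_type_analysis(perfect)
  expect_true(all(ea$proportions$proportion == 0))
  # uniform responder: each error type near 1/3
  sch <- build_schedule(25, 96, seed = 3)
  unif <- lapply(default_confusion(), function(m) { m[] <- 1 / 3; m })
  beh_u <- sample_behavior(sch, behavior_model(confusion = unif), seed = 8)
  ea_u <- error_type_analysis(beh_u)
  se3 <- 3 * sqrt((1 / 3) * (2 / 3) / 200)
  expect_true(all(abs(ea_u$proportions$proportion - 1 / 3) < se3))
  # default model: estimates near the generating off-diagonals (200/cell)
  beh_d <- sample_behavior(sch, behavior_model(), seed = 9)
  ea_d <- error_type_analysis(beh_d)
  cm <- default_confusion()
  for (r in seq_len(nrow(ea_d$proportions))) {
    pr <- ea_d$proportions[r, ]
    gen <- cm[[pr$tms]][pr$kind, pr$response]
    expect_lt(abs(pr$proportion - gen),
              3 * sqrt(max(gen * (1 - gen), 0.01) / 200))
  }
  # error proportions complement accuracy
  acc <- mean(beh_d$correct[beh_d$kind == "stack" & beh_d$tms == "late"])
  errs <- ea_d$proportions
  tot_err <- sum(errs$proportion[errs$kind == "stack" & errs$tms == "late"])
  expect_equal(tot_err, 1 - acc, tolerance = 1e-10)
})

test_that("FDR recovery under the null stays at the nominal level", {
  nullT <- erp_templates(figural_amp = 0, surface_amp = 0)
  n_rep <- 120
  fp <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    co <- simulate_erp_cohort(11, templates = nullT,
                              seed = derive_seed(555, r))
    ts <- samplewise_fdr_ttest(difference_waves(co, "stack-frame", "none"),
                               c(200, 350))
    fp[r] <- any(ts$table$sig)
  }
  expect_lte(mean(fp), 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
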