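#' Filter a behavioral table
#'
#' Removes trials with reaction times below 100 ms or above 1500 ms
#' (strict bounds: 100 and 1500 themselves are retained), then removes
#' every subject whose overall accuracy fails to exceed 67% correct
#' (exactly 67.0% is excluded). A removal log is attached as the
#' `"log"` attribute.
#'
#' @param table behavioral data.frame with columns `subject`, `kind`,
#'   `tms`, `response`, `rt_ms`, `correct`.
#' @param rt_bounds_ms inclusive retention range for RTs.
#' @param accuracy_floor subjects must exceed this overall proportion
#'   correct.
#' @return filtered table with attribute `log` (list: `n_rt_removed`,
#'   `subjects_removed`).
#' @export
filter_behavior <- function(table, rt_bounds_ms = c(100, 1500),
                            accuracy_floor = 0.67) {
  need <- c("subject", "kind", "tms", "response", "rt_ms", "correct")
  fg_assert(all(need %in% names(table)), "input",
            "behavior table lacks columns: %s",
            paste(setdiff(need, names(table)), collapse = ", "))
  keep_rt <- table$rt_ms >= rt_bounds_ms[1] & table$rt_ms <= rt_bounds_ms[2]
  out <- table[keep_rt, , drop = FALSE]
  acc <- tapply(out$correct, out$subject, mean)
  bad <- names(acc)[acc <= accuracy_floor]
  out <- out[!out$subject %in% bad, , drop = FALSE]
  fg_assert(nrow(out) > 0, "empty", "no trials left after filtering")
  attr(out, "log") <- list(n_rt_removed = sum(!keep_rt),
                           subjects_removed = bad,
                           subject_accuracy = acc)
  out
}

#' Two-way within-subject (repeated measures) ANOVA on a 3 x 4 design
#'
#' Sums of squares are computed from scratch by the classical
#' decomposition for a fully crossed within-subject design: each effect
#' is tested against its own effect-by-subject interaction. With the
#' 3-level stimulus factor, the 4-level TMS-window factor and n subjects
#' the interaction has degrees of freedom (6, 6(n-1)) -- (6, 60) at
#' n = 11. No sphericity correction is applied by default (the design's
#' reported dfs are uncorrected); `gg = TRUE` applies Greenhouse-Geisser
#' correction to the p-values.
#'
#' @param cells data.frame with columns `subject`, `stimulus`, `tms`,
#'   `value` -- one row per subject x cell (cell means).
#' @param gg apply Greenhouse-Geisser epsilon to the p-values.
#' @return data.frame with `effect`, `df1`, `df2`, `SS`, `SS_error`, `F`,
#'   `p` (and `epsilon` if `gg`), plus attribute `ss_table` holding the
#'   full decomposition (including subject and total SS).
#' @export
rm_anova_3x4 <- function(cells, gg = FALSE) {
  need <- c("subject", "stimulus", "tms", "value")
  fg_assert(all(need %in% names(cells)), "input",
            "cells must have columns subject, stimulus, tms, value")
  subj <- sort(unique(cells$subject))
  A <- sort(unique(cells$stimulus))
  B <- sort(unique(cells$tms))
  n <- length(subj); a <- length(A); b <- length(B)
  fg_assert(n >= 2, "input", "need >= 2 subjects")
  y <- array(NA_real_, dim = c(n, a, b))
  for (r in seq_len(nrow(cells))) {
    y[match(cells$subject[r], subj), match(cells$stimulus[r], A),
      match(cells$tms[r], B)] <- cells$value[r]
  }
  miss <- which(is.na(y), arr.ind = TRUE)
  if (nrow(miss) > 0) {
    fg_stop("input", "missing cell: subject %s, stimulus %s, tms %s",
            subj[miss[1, 1]], A[miss[1, 2]], B[miss[1, 3]])
  }
  g <- mean(y)
  m_s <- apply(y, 1, mean); m_a <- apply(y, 2, mean); m_b <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean); m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)
  ss_total <- sum((y - g)^2)
  ss_s <- a * b * sum((m_s - g)^2)
  ss_a <- n * b * sum((m_a - g)^2)
  ss_b <- n * a * sum((m_b - g)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + g)^2)
  ss_as <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + g)^2)
  ss_bs <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + g)^2)
  ss_abs <- ss_total - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs
  df <- list(a = a - 1, b = b - 1, ab = (a - 1) * (b - 1),
             as = (a - 1) * (n - 1), bs = (b - 1) * (n - 1),
             abs = (a - 1) * (b - 1) * (n - 1))
  fratio <- function(ss, d1, ss_err, d2) {
    if (ss == 0 && ss_err <= 0) return(0) # degenerate all-equal design
    (ss / d1) / (ss_err / d2)
  }
  f_a <- fratio(ss_a, df$a, ss_as, df$as)
  f_b <- fratio(ss_b, df$b, ss_bs, df$bs)
  f_ab <- fratio(ss_ab, df$ab, ss_abs, df$abs)
  out <- data.frame(
    effect = c("stimulus", "tms", "stimulus:tms"),
    df1 = c(df$a, df$b, df$ab), df2 = c(df$as, df$bs, df$abs),
    SS = c(ss_a, ss_b, ss_ab), SS_error = c(ss_as, ss_bs, ss_abs),
    F = c(f_a, f_b, f_ab))
  if (gg) {
    eps <- c(gg_epsilon(m_sa), gg_epsilon(m_sb), gg_epsilon_inter(y))
    out$epsilon <- eps
    out$p <- pf_safe(out$F, out$df1 * eps, out$df2 * eps)
  } else {
    out$p <- pf_safe(out$F, out$df1, out$df2)
  }
  attr(out, "ss_table") <- c(total = ss_total, subject = ss_s,
                             stimulus = ss_a, tms = ss_b,
                             `stimulus:tms` = ss_ab, `stimulus:subj` = ss_as,
                             `tms:subj` = ss_bs, residual = ss_abs)
  out
}

pf_safe <- function(f, df1, df2) {
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[!is.finite(f)] <- NA_real_
  p
}

# Greenhouse-Geisser epsilon from a subjects x levels score matrix
gg_epsilon <- function(scores) {
  k <- ncol(scores)
  ctr <- stats::contr.helmert(k)
  ctr <- qr.Q(qr(ctr)) # orthonormal contrasts
  S <- stats::cov(scores %*% ctr)
  sum(diag(S))^2 / ((k - 1) * sum(S^2))
}

gg_epsilon_inter <- function(y) {
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  ca <- qr.Q(qr(stats::contr.helmert(a)))
  cb <- qr.Q(qr(stats::contr.helmert(b)))
  M <- kronecker(ca, cb) # (a*b) x (a-1)(b-1) contrasts on vec(cell)
  cells <- sapply(seq_len(a * b), function(j) {
    ai <- ((j - 1) %/% b) + 1; bi <- ((j - 1) %% b) + 1
    y[, ai, bi]
  })
  S <- stats::cov(cells %*% M)
  d <- (a - 1) * (b - 1)
  sum(diag(S))^2 / (d * sum(S^2))
}

#' Benjamini-Hochberg step-up selection
#'
#' Returns the rejection set at FDR level `q` over a vector of p-values
#' (NAs are never rejected and do not count toward the family size).
#'
#' @param p numeric p-values.
#' @param q FDR level.
#' @return list with `reject` (logical), `threshold` (largest rejected
#'   p-value, or 0 if none).
#' @export
bh_select <- function(p, q = 0.05) {
  ok <- which(!is.na(p))
  m <- length(ok)
  reject <- rep(FALSE, length(p))
  if (m == 0) return(list(reject = reject, threshold = 0))
  ord <- order(p[ok])
  ps <- p[ok][ord]
  crit <- q * seq_len(m) / m
  below <- which(ps <= crit)
  if (length(below) > 0) {
    kmax <- max(below)
    reject[ok[ord[seq_len(kmax)]]] <- TRUE
    return(list(reject = reject, threshold = ps[kmax]))
  }
  list(reject = reject, threshold = 0)
}

#' Build per-subject pooled difference waves from a cohort of ERPs
#'
#' `figure - homogenous` averages the stack and frame ERPs before
#' subtracting the homogenous ERP; `stack - frame` subtracts directly.
#' The interpolation mask is the union across the contrasted conditions
#' and subjects.
#'
#' @param erp_sets list over subjects; each element a named list
#'   (`kind.condition`) of ERP objects as produced by
#'   [run_preprocessing()] (fields `pooled`, `mask`, `times_ms`), or an
#'   `fg_erp_cohort` from [simulate_erp_cohort()].
#' @param contrast `"figure-homogenous"` or `"stack-frame"`.
#' @param condition TMS condition.
#' @return list with `mat` (subjects x samples), `times_ms`, `mask`
#'   (logical per sample), `contrast`, `condition`.
#' @export
difference_waves <- function(erp_sets, contrast = c("figure-homogenous",
                                                    "stack-frame"),
                             condition = "none") {
  contrast <- match.arg(contrast)
  if (inherits(erp_sets, "fg_erp_cohort")) {
    erp_sets <- erp_cohort_sets(erp_sets)
  }
  n <- length(erp_sets)
  times_ms <- erp_sets[[1]][[1]]$times_ms
  mat <- matrix(NA_real_, n, length(times_ms))
  mask <- logical(length(times_ms))
  for (s in seq_len(n)) {
    get <- function(kind) {
      e <- erp_sets[[s]][[paste(kind, condition, sep = ".")]]
      fg_assert(!is.null(e) && isTRUE(e$valid %||% TRUE) &&
                  !is.null(e$pooled), "input",
                "missing or invalid ERP %s.%s for subject %d",
                kind, condition, s)
      e
    }
    st <- get("stack"); fr <- get("frame")
    if (contrast == "figure-homogenous") {
      ho <- get("homogenous")
      mat[s, ] <- (st$pooled + fr$pooled) / 2 - ho$pooled
      for (e in list(st, fr, ho)) if (!is.null(e$mask)) mask <- mask | e$mask
    } else {
      mat[s, ] <- st$pooled - fr$pooled
      for (e in list(st, fr)) if (!is.null(e$mask)) mask <- mask | e$mask
    }
  }
  list(mat = mat, times_ms = times_ms, mask = mask, contrast = contrast,
       condition = condition)
}

# adapt an fg_erp_cohort into the per-subject ERP-set shape
erp_cohort_sets <- function(cohort) {
  n <- dim(cohort$erps)[1]
  cells <- dimnames(cohort$erps)[[2]]
  lapply(seq_len(n), function(s) {
    out <- lapply(seq_along(cells), function(j) {
      list(pooled = cohort$erps[s, j, ], mask = NULL,
           times_ms = cohort$times_ms, valid = TRUE)
    })
    names(out) <- cells
    out
  })
}

#' Sample-wise paired t-tests with FDR control over a time window
#'
#' For every non-interpolated sample inside the test window, a two-tailed
#' paired t-test of the subject difference waves against zero; the
#' Benjamini-Hochberg step-up procedure at level `q` over all tested
#' samples in the window; maximal runs of contiguous significant samples
#' reported as intervals in ms (single-sample runs are flagged).
#' Zero-variance samples are reported as non-significant with a warning.
#'
#' @param dw difference-wave set from [difference_waves()], or a plain
#'   subjects x samples matrix (then supply `times_ms`).
#' @param window test window `c(start, end)` in ms.
#' @param q FDR level.
#' @param times_ms required if `dw` is a bare matrix.
#' @param mask optional logical per-sample interpolation mask.
#' @return object of class `fg_sample_test`: list with `table`
#'   (per-sample `time_ms`, `t`, `p`, `sig`, `tested`), `q_star` (BH
#'   threshold), `intervals`, `window`, `df`, `n_subjects`.
#' @export
samplewise_fdr_ttest <- function(dw, window = c(80, 230), q = 0.05,
                                 times_ms = NULL, mask = NULL) {
  if (is.matrix(dw)) {
    fg_assert(!is.null(times_ms), "input",
              "times_ms required for a bare matrix")
    dw <- list(mat = dw, times_ms = times_ms,
               mask = mask %||% logical(length(times_ms)))
  }
  mat <- dw$mat; tms <- dw$times_ms
  msk <- dw$mask %||% logical(length(tms))
  n <- nrow(mat)
  fg_assert(n >= 2, "input", "need >= 2 subjects")
  in_win <- tms >= window[1] & tms <= window[2]
  fg_assert(any(in_win), "input", "window outside the epoch")
  testable <- in_win & !msk
  if (!any(testable)) {
    fg_stop("masked",
            "this time window could not be tested: all samples in [%g, %g] ms are interpolated",
            window[1], window[2])
  }
  mu <- colMeans(mat)
  sdv <- apply(mat, 2, sd)
  tval <- rep(NA_real_, ncol(mat))
  pval <- rep(NA_real_, ncol(mat))
  zerovar <- sdv == 0
  ok <- testable & !zerovar
  tval[ok] <- mu[ok] / (sdv[ok] / sqrt(n))
  pval[ok] <- 2 * pt(abs(tval[ok]), df = n - 1, lower.tail = FALSE)
  if (any(testable & zerovar)) {
    tval[testable & zerovar & mu == 0] <- 0
    pval[testable & zerovar & mu == 0] <- 1
    if (any(testable & zerovar & mu != 0)) {
      warning("zero-variance nonzero-mean samples reported as non-significant")
    } else {
      warning("zero-variance samples in the test window")
    }
  }
  bh <- bh_select(pval[testable], q)
  sig <- logical(ncol(mat))
  sig[testable] <- bh$reject
  intervals <- runs_to_intervals(sig[in_win], tms[in_win])
  structure(list(
    table = data.frame(time_ms = tms, t = tval, p = pval, sig = sig,
                       tested = testable),
    q_star = bh$threshold, q = q, intervals = intervals, window = window,
    df = n - 1, n_subjects = n), class = "fg_sample_test")
}

#' Cumulative stack-frame difference over the surface-segregation window
#'
#' Per subject and TMS condition, the sum of the stack minus frame pooled
#' difference over 227-313 ms (units: signal x samples), compared between
#' TMS conditions with two-tailed paired t-tests. With
#' `trial_subset = "correct"` the caller supplies ERPs computed from
#' correct trials only.
#'
#' @param erp_sets as in [difference_waves()].
#' @param conditions TMS conditions to compare (the late window is
#'   normally excluded: its excision overlaps the test window).
#' @param window cumulation window in ms.
#' @param trial_subset label recorded in the output (`"all"` or
#'   `"correct"`).
#' @return list with `cumulative` (subjects x conditions matrix),
#'   `comparisons` (pairwise paired t-table), `window`, `trial_subset`.
#' @export
cumulative_diff_test <- function(erp_sets,
                                 conditions = c("none", "early",
                                                "intermediate"),
                                 window = c(227, 313),
                                 trial_subset = "all") {
  if (inherits(erp_sets, "fg_erp_cohort")) erp_sets <- erp_cohort_sets(erp_sets)
  cum <- sapply(conditions, function(cc) {
    dw <- difference_waves(erp_sets, "stack-frame", cc)
    sel <- dw$times_ms >= window[1] & dw$times_ms <= window[2]
    rowSums(dw$mat[, sel, drop = FALSE])
  })
  cum <- matrix(cum, ncol = length(conditions),
                dimnames = list(NULL, conditions))
  prs <- utils::combn(conditions, 2)
  comparisons <- data.frame(a = prs[1, ], b = prs[2, ], t = NA_real_,
                            df = nrow(cum) - 1, p = NA_real_)
  for (i in seq_len(ncol(prs))) {
    d <- cum[, prs[1, i]] - cum[, prs[2, i]]
    if (sd(d) == 0) {
      comparisons$t[i] <- 0; comparisons$p[i] <- 1
      if (any(d != 0)) warning("zero-variance paired difference")
      next
    }
    tt <- t.test(cum[, prs[1, i]], cum[, prs[2, i]], paired = TRUE)
    comparisons$t[i] <- unname(tt$statistic)
    comparisons$p[i] <- tt$p.value
  }
  list(cumulative = cum, comparisons = comparisons, window = window,
       trial_subset = trial_subset)
}

#' Error-type analysis of the behavioral confusions
#'
#' Per stimulus kind and TMS condition, the proportion of each
#' misclassification (e.g. stacks reported as frames), estimated per
#' subject and averaged; pairwise TMS-condition comparisons per error
#' type by two-tailed paired t-tests with Benjamini-Hochberg correction
#' across all comparisons.
#'
#' @param table (filtered) behavioral table.
#' @param q FDR level for the pairwise comparisons.
#' @return list with `proportions` (kind x response x tms, long
#'   data.frame incl. per-subject values in attribute), `tests`.
#' @export
error_type_analysis <- function(table, q = 0.05) {
  subj <- sort(unique(table$subject))
  grid <- expand.grid(kind = kinds_3, response = kinds_3,
                      tms = tms_conditions_4, stringsAsFactors = FALSE)
  grid <- grid[grid$kind != grid$response, ]
  per_subj <- lapply(subj, function(s) {
    tb <- table[table$subject == s, ]
    p <- mapply(function(k, r, cc) {
      den <- sum(tb$kind == k & tb$tms == cc)
      if (den == 0) return(NA_real_)
      sum(tb$kind == k & tb$tms == cc & tb$response == r) / den
    }, grid$kind, grid$response, grid$tms)
    p
  })
  pm <- do.call(cbind, per_subj) # error-type rows x subjects
  props <- grid
  props$proportion <- rowMeans(pm, na.rm = TRUE)
  # pairwise condition tests per error type
  prs <- utils::combn(tms_conditions_4, 2)
  err_types <- unique(grid[, c("kind", "response")])
  tests <- do.call(rbind, lapply(seq_len(nrow(err_types)), function(e) {
    k <- err_types$kind[e]; r <- err_types$response[e]
    do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      ra <- which(grid$kind == k & grid$response == r & grid$tms == prs[1, i])
      rb <- which(grid$kind == k & grid$response == r & grid$tms == prs[2, i])
      d <- pm[ra, ] - pm[rb, ]
      d <- d[!is.na(d)]
      if (length(d) < 2 || sd(d) == 0) {
        return(data.frame(kind = k, response = r, a = prs[1, i],
                          b = prs[2, i], t = 0, p = 1))
      }
      tt <- t.test(d)
      data.frame(kind = k, response = r, a = prs[1, i], b = prs[2, i],
                 t = unname(tt$statistic), p = tt$p.value)
    }))
  }))
  tests$sig_fdr <- bh_select(tests$p, q)$reject
  attr(props, "per_subject") <- pm
  list(proportions = props, tests = tests)
}

#' Behavioral summary statistics for the 3 x 4 design
#'
#' Cell means of accuracy and RT, the two within-subject ANOVAs, and the
#' error-type analysis, computed from a filtered behavior table.
#'
#' @param table filtered behavioral table.
#' @return list with `cell_means`, `anova_accuracy`, `anova_rt`,
#'   `error_types`.
#' @export
behavior_stats <- function(table) {
  agg_acc <- aggregate(correct ~ subject + kind + tms, table, mean)
  agg_rt <- aggregate(rt_ms ~ subject + kind + tms, table, mean)
  cells_acc <- data.frame(subject = agg_acc$subject,
                          stimulus = agg_acc$kind, tms = agg_acc$tms,
                          value = agg_acc$correct)
  cells_rt <- data.frame(subject = agg_rt$subject,
                         stimulus = agg_rt$kind, tms = agg_rt$tms,
                         value = agg_rt$rt_ms)
  cm <- aggregate(cbind(accuracy = correct) ~ kind + tms, table, mean)
  cm$rt_ms <- aggregate(rt_ms ~ kind + tms, table, mean)$rt_ms
  list(cell_means = cm,
       anova_accuracy = rm_anova_3x4(cells_acc),
       anova_rt = rm_anova_3x4(cells_rt),
       error_types = error_type_analysis(table))
}
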