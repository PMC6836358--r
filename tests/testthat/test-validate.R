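# Derivation/validation statistics.

make_summaries <- function(n_pat = 8, recs = 3, ratio1 = -0.75,
                           ratio2 = 0.66, noise = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_pat)) {
    for (r in seq_len(recs)) {
      pocc <- -runif(5, 8, 30)
      mp <- mean(pocc)
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient = sprintf("P%02d", p), day = r,
        mean_pmus = -ratio1 * abs(mp) * exp(rnorm(1, 0, noise)),
        mean_delta_pes = ratio2 * mp * exp(rnorm(1, 0, noise)),
        mean_delta_paw = runif(1, 2, 8),
        mean_delta_pl_dyn = -ratio1 * abs(mp) + runif(1, 2, 8),
        mean_ptp_mus = -0.4 * mp,
        mean_delta_pocc = mp,
        pocc_pes_ratio = 1, valid = TRUE,
        n_breaths = 30L, n_occlusions = 5L,
        pocc_values = list(pocc)
      )
    }
  }
  dplyr::bind_rows(rows)
}

test_that("a degenerate cohort with constant ratios is recovered exactly", {
  summ <- make_summaries(noise = 0)
  f <- derive_conversion_factors(summ)
  expect_equal(f$k1, -0.75, tolerance = 1e-10)
  expect_equal(f$k2, 0.66, tolerance = 1e-10)
  expect_lt(diff(f$k1_ci), 1e-8)
  expect_lt(diff(f$k2_ci), 1e-8)
  td <- tidy(f)
  expect_equal(td$estimate, c(-0.75, 0.66), tolerance = 1e-10)
})

test_that("mixed-model derivation is close to the generating ratios under noise", {
  summ <- make_summaries(n_pat = 12, noise = 0.05, seed = 3)
  f <- derive_conversion_factors(summ)
  expect_equal(f$k1, -0.75, tolerance = 0.04)
  expect_equal(f$k2, 0.66, tolerance = 0.04)
  expect_identical(f$method, "lmm")
  expect_true(f$k1_ci[1] < f$k1 && f$k1 < f$k1_ci[2])
})

test_that("identity agreement has zero bias and zero limits everywhere", {
  m <- runif(30, 5, 25)
  ba <- bland_altman_repeated(m, m, rep(letters[1:5], each = 6))
  expect_equal(ba$bias_ratio, 1)
  expect_equal(ba$la_pct_within, 0)
  expect_equal(ba$sd_bias_between, 0)
  expect_equal(ba$total_loa(10), 0)
  expect_equal(ba$total_loa(100), 0)
})

test_that("lognormal disagreement gives the analytic within-patient limits", {
  set.seed(9)
  m <- runif(500, 5, 30)
  p <- m * exp(rnorm(500, 0, 0.1))
  ba <- bland_altman_repeated(p, m)
  # LA%,within = 100 * 1.96 * sigma_log with sigma = 0.1.
  expect_equal(ba$la_pct_within, 19.6, tolerance = 0.1)
  expect_equal(ba$bias_ratio, 1, tolerance = 0.02)
})

test_that("constant multiplicative offsets yield the closed-form between-patient SD", {
  m <- rep(c(10, 20), each = 4)
  p <- m * rep(c(1.2, 1 / 1.2), each = 4)
  ba <- bland_altman_repeated(p, m, rep(c("a", "b"), each = 4))
  expect_equal(ba$sd_bias_between_log, sd(c(log(1.2), -log(1.2))),
               tolerance = 1e-10)
  # Constant within-patient offsets: the total limits reduce to the
  # between-patient term, and are never decreasing in the estimate.
  expect_equal(ba$total_loa(10), 1.96 * ba$sd_bias_between,
               tolerance = 1e-10)
  expect_gte(ba$total_loa(20), ba$total_loa(10))
})

test_that("nonpositive values are refused on the log scale", {
  expect_error(bland_altman_repeated(c(1, -2), c(1, 1)), "positive")
})

test_that("AUROC equals exhaustive concordant-pair counting and is rank-invariant", {
  set.seed(2)
  pred <- round(runif(30), 1)  # ties on purpose
  lab <- runif(30) > 0.5
  oracle <- mean(outer(pred[lab], pred[!lab],
                       function(a, b) (a > b) + 0.5 * (a == b)))
  d <- discrimination(pred, ifelse(lab, 2, 0), 1, n_boot = 100, seed = 1)
  expect_equal(d$auroc, oracle, tolerance = 1e-12)
  # Invariance under a strictly monotone transform.
  d2 <- discrimination(exp(3 * pred), ifelse(lab, 2, 0), 1,
                       n_boot = 100, seed = 1)
  expect_equal(d2$auroc, d$auroc, tolerance = 1e-12)
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  pred <- rnorm(60)
  meas <- pred + rnorm(60)
  d <- discrimination(pred, meas, 0.5, n_boot = 50, seed = 1)
  ref <- suppressMessages(pROC::auc(pROC::roc(meas > 0.5, pred,
                                              quiet = TRUE)))
  expect_equal(d$auroc, as.numeric(ref), tolerance = 1e-12)
})

test_that("separated and uninformative predictions bracket the AUROC range", {
  meas <- c(rep(1, 10), rep(3, 10))
  expect_equal(discrimination(meas * 2, meas, 2, n_boot = 10,
                              seed = 1)$auroc, 1)
  set.seed(7)
  d <- discrimination(rnorm(2000), rep(c(0, 5), 1000), 2, n_boot = 10,
                      seed = 1)
  expect_equal(d$auroc, 0.5, tolerance = 0.05)
  expect_error(discrimination(rnorm(5), rep(1, 5), 2), "both classes")
})

test_that("sensitivity/specificity are computed at the stated cutoffs", {
  pred <- c(1, 2, 3, 4)
  meas <- c(1, 1, 3, 3)
  d <- discrimination(pred, meas, 2, n_boot = 10, seed = 1)
  row <- d$cutoffs[d$cutoffs$cutoff == 2, ]
  expect_equal(row$sensitivity, 100)  # both positives predicted > 2
  expect_equal(row$specificity, 100)  # both negatives predicted <= 2
})

test_that("variance-decomposed correlation matches a least-squares oracle", {
  summ <- make_summaries(n_pat = 6, recs = 4, noise = 0.1, seed = 8)
  out <- ptp_correlation(summ)
  xs <- summ$mean_delta_pocc; ys <- summ$mean_ptp_mus
  pid <- summ$patient
  xm <- tapply(xs, pid, mean); ym <- tapply(ys, pid, mean)
  fit_b <- lm(as.numeric(ym) ~ as.numeric(xm))
  r2_b <- suppressWarnings(summary(fit_b)$r.squared)
  expect_equal(out$r2_between, r2_b, tolerance = 1e-9)
  xc <- xs - xm[pid]; yc <- ys - ym[pid]
  fit_w <- lm(yc ~ xc)
  r2_w <- suppressWarnings(summary(fit_w)$r.squared)
  expect_equal(out$r2_within, r2_w, tolerance = 1e-9)
})

test_that("proportional PTP gives unit R2; shuffled within-patient values give none", {
  summ <- make_summaries(n_pat = 6, recs = 4, noise = 0, seed = 2)
  summ$mean_ptp_mus <- -0.4 * summ$mean_delta_pocc
  out <- ptp_correlation(summ)
  expect_equal(out$r2_between, 1, tolerance = 1e-9)
  expect_equal(out$r2_within, 1, tolerance = 1e-9)

  set.seed(3)
  summ$mean_ptp_mus <- ave(summ$mean_ptp_mus, summ$patient,
                           FUN = function(x) mean(x) + rnorm(length(x), 0, 2))
  out2 <- ptp_correlation(summ)
  expect_lt(out2$r2_within, 0.3)
})

test_that("cross-validation is deterministic and leak-free", {
  summ <- make_summaries(n_pat = 8, noise = 0.05, seed = 4)
  cv1 <- suppressMessages(cross_validate(summ, reps = 3, seed = 17,
                                         agreement_method = "moments"))
  cv2 <- suppressMessages(cross_validate(summ, reps = 3, seed = 17,
                                         agreement_method = "moments"))
  expect_identical(tidy(cv1), tidy(cv2))
  expect_equal(nrow(tidy(cv1)), 3)
})

test_that("a homogeneous noiseless cohort yields identical factors in every repetition", {
  summ <- make_summaries(n_pat = 8, noise = 0, seed = 6)
  cv <- suppressMessages(cross_validate(summ, reps = 5, seed = 2,
                                        agreement_method = "moments"))
  res <- tidy(cv)
  expect_true(all(abs(res$k1 - -0.75) < 1e-10))
  expect_true(all(abs(res$k2 - 0.66) < 1e-10))
  g <- glance(cv)
  expect_equal(g$k1_median, -0.75, tolerance = 1e-10)
})

test_that("small cohorts are refused by the cross-validation loop", {
  summ <- make_summaries(n_pat = 3)
  expect_error(cross_validate(summ, reps = 2), "at least 4")
})
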