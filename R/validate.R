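# Derivation/validation statistics: conversion-factor estimation with
# patient-level random intercepts, repeated-measures Bland-Altman
# agreement, rank-based ROC discrimination, variance-decomposed
# correlation, and the repeated patient-level cross-validation loop.

# Mixed-model intercept (patient random effect) with a moment fallback for
# degenerate inputs (zero variance, too few patients, non-convergence).
fit_intercept <- function(y, patient) {
  ok <- is.finite(y)
  y <- y[ok]; patient <- patient[ok]
  n_pat <- length(unique(patient))
  moments <- function() {
    pm <- tapply(y, patient, mean)
    est <- mean(pm)
    se <- if (length(pm) > 1) sd(pm) / sqrt(length(pm)) else 0
    list(estimate = unname(est),
         ci = unname(est + c(-1, 1) * 1.96 * se),
         method = "patient-means")
  }
  if (n_pat < 2) abort("at least 2 patients are required")
  if (var(y) < 1e-12 || n_pat < 3) return(moments())
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(y ~ 1 + (1 | patient),
                 data = data.frame(y = y, patient = patient),
                 REML = TRUE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore",
                   optCtrl = list(xtol_abs = 1e-8, ftol_abs = 1e-8)
                 ))
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(moments())
  est <- unname(lme4::fixef(fit)[1])
  se <- sqrt(as.numeric(stats::vcov(fit)[1, 1]))
  list(estimate = est, ci = est + c(-1, 1) * 1.96 * se, method = "lmm")
}

#' Derive conversion factors from a cohort of recording summaries
#'
#' Per-recording ratios `mean Pmus / mean delta-Pocc` (k1) and
#' `mean delta-Pes / mean delta-Pocc` (k2) are modeled with a patient-level
#' random intercept to account for repeated daily recordings within
#' subjects; the fixed-effect intercept is returned as the factor with a
#' 95% Wald CI. Singular or degenerate fits fall back to averaging patient
#' means (with a warning-free method note in the result).
#'
#' @param summaries Recording summaries ([analyze_cohort()]); only valid
#'   recordings with at least one occlusion are used.
#' @return A [conversion_factors()] object with CIs.
#' @export
derive_conversion_factors <- function(summaries) {
  use <- filter(summaries, .data$valid, .data$n_occlusions > 0,
                is.finite(.data$mean_delta_pocc),
                .data$mean_delta_pocc < 0)
  if (nrow(use) == 0) abort("no valid recordings to derive factors from")
  if (length(unique(use$patient)) < 2) {
    abort("at least 2 patients with valid recordings are required")
  }
  r1 <- use$mean_pmus / use$mean_delta_pocc
  r2 <- use$mean_delta_pes / use$mean_delta_pocc
  f1 <- fit_intercept(r1, use$patient)
  f2 <- fit_intercept(r2, use$patient)
  conversion_factors(
    k1 = f1$estimate, k2 = f2$estimate,
    k1_ci = f1$ci, k2_ci = f2$ci,
    n_recordings = nrow(use),
    n_patients = length(unique(use$patient)),
    method = f1$method
  )
}

# Bias / between-patient SD / within-patient SD decomposition of a
# difference vector, by mixed model or patient-mean moments.
decompose_diffs <- function(d, patient, method = c("lmm", "moments")) {
  method <- match.arg(method)
  n_pat <- length(unique(patient))
  moments <- function() {
    pm <- tapply(d, patient, mean)
    wv <- tapply(d, patient, function(x) {
      if (length(x) > 1) var(x) else NA_real_
    })
    wv <- wv[is.finite(wv)]
    list(bias = unname(mean(pm)),
         sd_between = if (length(pm) > 1) unname(sd(pm)) else 0,
         sd_within = if (length(wv) > 0) sqrt(mean(wv)) else 0)
  }
  if (method == "moments" || n_pat < 3 || var(d) < 1e-12) return(moments())
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(d ~ 1 + (1 | patient),
                 data = data.frame(d = d, patient = patient), REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(moments())
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(
    bias = unname(lme4::fixef(fit)[1]),
    sd_between = sqrt(vc$vcov[vc$grp == "patient"][1]),
    sd_within = sqrt(vc$vcov[vc$grp == "Residual"][1])
  )
}

#' Repeated-measures Bland-Altman agreement
#'
#' Differences between predicted and measured values are analyzed on the
#' log scale (the distribution of raw differences is right-skewed for
#' positive pressures) and decomposed into a fixed bias, a between-patient
#' bias SD, and a within-patient residual SD. The within-patient limits of
#' agreement are expressed as a percentage of the estimated value
#' (`la_pct_within = 100 * 1.96 * SD_within,log`, the small-sigma
#' proportional reading of log-scale limits). A parallel decomposition of
#' the raw differences provides the between-patient bias SD in cm H2O, and
#' the total limits of agreement across the range of estimates follow
#' `1.96 * SD_bias,btw + LA%,within x estimate`.
#'
#' @param predicted,measured Paired positive values (cm H2O).
#' @param patient Patient identifiers (one per pair); `NULL` treats all
#'   pairs as exchangeable.
#' @param method `"lmm"` (mixed model with moment fallback) or
#'   `"moments"` (patient-mean decomposition).
#' @return An object of class `pocc_agreement`.
#' @export
bland_altman_repeated <- function(predicted, measured, patient = NULL,
                                  method = c("lmm", "moments")) {
  method <- match.arg(method)
  if (length(predicted) != length(measured)) {
    abort("predicted and measured must be paired")
  }
  if (any(predicted <= 0) || any(measured <= 0)) {
    abort("values must be positive (differences are analyzed on the log scale)")
  }
  if (is.null(patient)) patient <- rep("all", length(predicted))
  d_log <- log(predicted) - log(measured)
  d_raw <- predicted - measured
  cl <- decompose_diffs(d_log, patient, method)
  cr <- decompose_diffs(d_raw, patient, method)
  la_pct <- 100 * 1.96 * cl$sd_within
  sd_btw_raw <- cr$sd_between
  structure(
    list(
      bias_log = cl$bias,
      bias_ratio = exp(cl$bias),
      sd_bias_between_log = cl$sd_between,
      la_pct_within = la_pct,
      bias = cr$bias,
      sd_bias_between = sd_btw_raw,
      total_loa = function(estimate) {
        1.96 * sd_btw_raw + la_pct / 100 * estimate
      },
      n = length(predicted),
      n_patients = length(unique(patient)),
      method = method,
      data = tibble(predicted = predicted, measured = measured,
                    patient = patient, d_log = d_log, d_raw = d_raw)
    ),
    class = "pocc_agreement"
  )
}

#' @export
print.pocc_agreement <- function(x, ...) {
  cat(sprintf(
    "<pocc_agreement> bias ratio %.3f, LA%%within %.1f%%, SD_bias,btw %.2f cm H2O (%d pairs, %d patients)\n",
    x$bias_ratio, x$la_pct_within, x$sd_bias_between, x$n, x$n_patients
  ))
  invisible(x)
}

# Rank-statistic AUROC (midranks handle ties: concordant pairs + half ties).
auc_rank <- function(predicted, labels) {
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(predicted)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC discrimination of predicted against measured exceedance
#'
#' Labels are `measured > threshold`. The AUROC is the empirical rank
#' statistic (probability that a randomly chosen exceeding recording gets a
#' higher prediction, ties counted half), with a seeded bootstrap
#' percentile CI (patient-level when `patient` is given). Sensitivity and
#' specificity are tabulated at every observed prediction cutoff plus the
#' measured-scale threshold itself, using the same strict-inequality
#' positivity call as the screening flags.
#'
#' @param predicted Predicted values.
#' @param measured Measured reference values.
#' @param threshold Exceedance threshold on the measured scale, cm H2O.
#' @param patient Optional patient ids for patient-level bootstrap.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `pocc_roc`.
#' @export
discrimination <- function(predicted, measured, threshold, patient = NULL,
                           n_boot = 2000, seed = NULL) {
  labels <- measured > threshold
  if (all(labels) || !any(labels)) {
    abort("both classes must be present at this threshold")
  }
  auroc <- auc_rank(predicted, labels)
  if (!is.null(seed)) set.seed(seed)
  groups <- if (is.null(patient)) seq_along(predicted) else patient
  ug <- unique(groups)
  boot <- vapply(seq_len(n_boot), function(b) {
    g <- sample(ug, length(ug), replace = TRUE)
    idx <- unlist(lapply(g, function(x) which(groups == x)),
                  use.names = FALSE)
    auc_rank(predicted[idx], labels[idx])
  }, numeric(1))
  ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  cuts <- sort(unique(c(predicted, threshold)))
  tab <- tibble(
    cutoff = cuts,
    sensitivity = vapply(cuts, function(cc) {
      100 * mean(predicted[labels] > cc)
    }, numeric(1)),
    specificity = vapply(cuts, function(cc) {
      100 * mean(predicted[!labels] <= cc)
    }, numeric(1))
  )
  structure(
    list(auroc = auroc, ci = ci, threshold = threshold, cutoffs = tab,
         n_pos = sum(labels), n_neg = sum(!labels),
         predicted = predicted, labels = labels),
    class = "pocc_roc"
  )
}

#' @export
print.pocc_roc <- function(x, ...) {
  cat(sprintf(
    "<pocc_roc> AUROC %.3f (95%% CI %.3f-%.3f) for threshold %g cm H2O (%d pos / %d neg)\n",
    x$auroc, x$ci[1], x$ci[2], x$threshold, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' Between- and within-subject R-squared
#'
#' Decomposes the correlation between two per-recording quantities into a
#' between-subjects component (patient means) and a within-subjects
#' component (patient-centered values).
#'
#' @param data Per-recording table.
#' @param x,y Column names of the two quantities (defaults match
#'   [analyze_cohort()] output: mean occlusion pressure vs mean
#'   pressure-time product).
#' @param patient Column name of the patient identifier.
#' @return One-row tibble `r2_between`, `r2_within`, `n_patients`,
#'   `n_recordings`; a component with insufficient replication is `NA`.
#' @export
ptp_correlation <- function(data, x = "mean_delta_pocc",
                            y = "mean_ptp_mus", patient = "patient") {
  xs <- data[[x]]; ys <- data[[y]]; pid <- data[[patient]]
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]; pid <- pid[ok]
  n_pat <- length(unique(pid))
  xm <- tapply(xs, pid, mean); ym <- tapply(ys, pid, mean)
  r2_between <- if (n_pat >= 2) unname(cor(xm, ym)^2) else NA_real_
  xc <- xs - xm[match(pid, names(xm))]
  yc <- ys - ym[match(pid, names(ym))]
  multi <- table(pid)[pid] > 1
  r2_within <- if (sum(multi) >= 3 && var(xc[multi]) > 0) {
    unname(cor(xc[multi], yc[multi])^2)
  } else NA_real_
  tibble(r2_between = r2_between, r2_within = r2_within,
         n_patients = n_pat, n_recordings = length(xs))
}

#' Repeated patient-level cross-validation of the screening method
#'
#' Each repetition randomly splits the patients in half (odd counts round
#' toward derivation), derives conversion factors on the derivation half,
#' predicts Pmus and delta-PL,dyn on the validation half from `n_occ`
#' randomly selected occlusions per recording, and evaluates agreement
#' (repeated-measures Bland-Altman) and discrimination (AUROC at each
#' screening threshold). Derivation and validation patient sets are
#' asserted disjoint in every repetition.
#'
#' @param summaries Recording summaries ([analyze_cohort()]).
#' @param truth Optional per-recording ground-truth table (from
#'   [simulate_cohort()], columns `patient`, `day`, `true_mean_pmus`,
#'   `true_mean_delta_pl`): when supplied, exceedance labels are taken from
#'   the simulator truth instead of the measured reference values.
#' @param reps Number of repetitions (default 100).
#' @param split Fraction of patients assigned to derivation.
#' @param n_occ Occlusions used per prediction (recordings with fewer use
#'   all of theirs).
#' @param pmus_thresholds,pl_thresholds Screening thresholds, cm H2O.
#' @param seed Integer seed; repetition `r` uses a deterministic child seed.
#' @param agreement_method Method passed to [bland_altman_repeated()].
#' @return An object of class `pocc_crossval`: per-repetition tibble
#'   (`tidy()`) and summary quantiles (`glance()`).
#' @export
cross_validate <- function(summaries, truth = NULL, reps = 100,
                           split = 0.5, n_occ = 3,
                           pmus_thresholds = c(10, 15),
                           pl_thresholds = c(15, 20),
                           seed = 1L,
                           agreement_method = "lmm") {
  check_count(reps, "reps", 1)
  check_number(split, "split", 0, 1, allow_equal_lower = FALSE,
               allow_equal_upper = FALSE)
  use <- filter(summaries, .data$valid)
  if (!is.null(truth)) {
    use <- left_join(use,
                     select(truth, "patient", "day",
                            "true_mean_pmus", "true_mean_delta_pl"),
                     by = c("patient", "day"))
    m_pmus_all <- use$true_mean_pmus
    m_pl_all <- use$true_mean_delta_pl
  } else {
    m_pmus_all <- use$mean_pmus
    m_pl_all <- use$mean_delta_pl_dyn
  }
  patients <- unique(use$patient)
  if (length(patients) < 4) {
    abort("at least 4 patients with valid recordings are required")
  }
  n_deriv <- ceiling(split * length(patients))

  rows <- list()
  for (r in seq_len(reps)) {
    set.seed(child_seed(seed, r))
    deriv_pat <- sample(patients, n_deriv)
    valid_pat <- setdiff(patients, deriv_pat)
    stopifnot(length(intersect(deriv_pat, valid_pat)) == 0)

    factors <- tryCatch(
      derive_conversion_factors(filter(use, .data$patient %in% deriv_pat)),
      error = function(e) NULL
    )
    if (is.null(factors)) {
      rows[[r]] <- tibble(rep = r, k1 = NA_real_, k2 = NA_real_)
      next
    }
    vi <- which(use$patient %in% valid_pat)
    pred <- lapply(vi, function(i) {
      pocc <- use$pocc_values[[i]]
      nn <- min(n_occ, length(pocc))
      sel <- select_occlusions(pocc, n = nn,
                               seed = child_seed(seed, r * 1000L + i))
      tibble(
        pmus_pred = predict_pmus(sel, factors),
        pl_pred = predict_delta_pl(use$mean_delta_paw[i], sel, factors)
      )
    })
    pred <- bind_rows(pred)
    m_pmus <- m_pmus_all[vi]
    m_pl <- m_pl_all[vi]
    pat_v <- use$patient[vi]

    auc_at <- function(p, m, thr) {
      lab <- m > thr
      if (all(lab) || !any(lab)) NA_real_ else auc_rank(p, lab)
    }
    ba <- function(p, m) {
      ok <- p > 0 & m > 0
      if (sum(ok) < 3) return(list(bias_log = NA_real_,
                                   la_pct_within = NA_real_))
      bland_altman_repeated(p[ok], m[ok], pat_v[ok],
                            method = agreement_method)
    }
    ba_pmus <- ba(pred$pmus_pred, m_pmus)
    ba_pl <- ba(pred$pl_pred, m_pl)

    row <- tibble(rep = r, k1 = factors$k1, k2 = factors$k2)
    for (thr in pmus_thresholds) {
      row[[sprintf("auroc_pmus_gt%g", thr)]] <-
        auc_at(pred$pmus_pred, m_pmus, thr)
    }
    for (thr in pl_thresholds) {
      row[[sprintf("auroc_pl_gt%g", thr)]] <-
        auc_at(pred$pl_pred, m_pl, thr)
    }
    row$bias_ratio_pmus <- exp(ba_pmus$bias_log)
    row$bias_ratio_pl <- exp(ba_pl$bias_log)
    row$la_pct_pmus <- ba_pmus$la_pct_within
    row$la_pct_pl <- ba_pl$la_pct_within
    row$n_validation <- length(vi)
    rows[[r]] <- row
  }
  results <- bind_rows(rows)
  n_undef <- sum(!stats::complete.cases(
    results[grep("^auroc", names(results))]
  ))
  if (n_undef > 0) {
    inform(sprintf(
      "%d repetition(s) had at least one undefined metric (one-class validation half); excluded from summaries",
      n_undef
    ))
  }
  structure(
    list(results = results, reps = reps, seed = seed,
         split = split, n_occ = n_occ,
         pmus_thresholds = pmus_thresholds, pl_thresholds = pl_thresholds,
         labels = if (is.null(truth)) "measured" else "truth",
         n_undefined = n_undef),
    class = "pocc_crossval"
  )
}

#' @export
print.pocc_crossval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<pocc_crossval> %d repetitions (%s labels): median k1 %.3f, k2 %.3f\n",
    x$reps, x$labels, g$k1_median, g$k2_median
  ))
  aucs <- grep("^auroc", names(x$results), value = TRUE)
  for (a in aucs) {
    cat(sprintf("  median %s = %.3f\n", a,
                median(x$results[[a]], na.rm = TRUE)))
  }
  invisible(x)
}
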