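# broom-style tidiers for the fitted/reported objects.

#' @rdname pocc_tidiers
#' @param x A fitted poccscreen object.
#' @param ... Unused.
#' @method tidy pocc_factors
#' @export
tidy.pocc_factors <- function(x, ...) {
  tibble(
    term = c("k1", "k2"),
    estimate = c(x$k1, x$k2),
    conf.low = c(x$k1_ci[1] %||% NA_real_, x$k2_ci[1] %||% NA_real_),
    conf.high = c(x$k1_ci[2] %||% NA_real_, x$k2_ci[2] %||% NA_real_)
  )
}

#' @rdname pocc_tidiers
#' @method glance pocc_factors
#' @export
glance.pocc_factors <- function(x, ...) {
  tibble(n_recordings = x$n_recordings, n_patients = x$n_patients,
         method = x$method)
}

#' @rdname pocc_tidiers
#' @method tidy pocc_agreement
#' @export
tidy.pocc_agreement <- function(x, ...) {
  tibble(
    term = c("bias_log", "bias_ratio", "sd_bias_between_log",
             "la_pct_within", "bias", "sd_bias_between"),
    estimate = c(x$bias_log, x$bias_ratio, x$sd_bias_between_log,
                 x$la_pct_within, x$bias, x$sd_bias_between)
  )
}

#' @rdname pocc_tidiers
#' @method glance pocc_agreement
#' @export
glance.pocc_agreement <- function(x, ...) {
  tibble(bias_ratio = x$bias_ratio, la_pct_within = x$la_pct_within,
         sd_bias_between = x$sd_bias_between, n = x$n,
         n_patients = x$n_patients, method = x$method)
}

#' @rdname pocc_tidiers
#' @method tidy pocc_roc
#' @export
tidy.pocc_roc <- function(x, ...) {
  x$cutoffs
}

#' @rdname pocc_tidiers
#' @method glance pocc_roc
#' @export
glance.pocc_roc <- function(x, ...) {
  tibble(auroc = x$auroc, conf.low = x$ci[1], conf.high = x$ci[2],
         threshold = x$threshold, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidiers for poccscreen result objects
#'
#' `tidy()` returns the per-term or per-repetition detail as a tibble;
#' `glance()` returns a one-row summary.
#'
#' @name pocc_tidiers
#' @rdname pocc_tidiers
#' @method tidy pocc_crossval
#' @export
tidy.pocc_crossval <- function(x, ...) {
  x$results
}

#' @rdname pocc_tidiers
#' @method glance pocc_crossval
#' @export
glance.pocc_crossval <- function(x, ...) {
  res <- x$results
  num <- setdiff(names(res)[vapply(res, is.numeric, logical(1))],
                 c("rep", "n_validation"))
  out <- tibble(reps = x$reps, n_undefined = x$n_undefined)
  for (nm in num) {
    out[[paste0(nm, "_median")]] <- median(res[[nm]], na.rm = TRUE)
    qs <- quantile(res[[nm]], c(0.25, 0.75), na.rm = TRUE)
    out[[paste0(nm, "_q25")]] <- unname(qs[1])
    out[[paste0(nm, "_q75")]] <- unname(qs[2])
  }
  out
}
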