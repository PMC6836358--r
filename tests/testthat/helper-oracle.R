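# Independent brute-force recomputation of the per-breath metrics:
# explicit loops for every extremum (argmax scan) and integral
# (sample-by-sample trapezoid) on the same conditioned channels and
# discretization as the package implementation.

loop_max <- function(x, idx) {
  m <- -Inf
  for (i in idx) if (x[i] > m) m <- x[i]
  m
}

loop_min <- function(x, idx) {
  m <- Inf
  for (i in idx) if (x[i] < m) m <- x[i]
  m
}

loop_trapz <- function(y, dt) {
  s <- 0
  if (length(y) < 2) return(0)
  for (i in 2:length(y)) s <- s + (y[i - 1] + y[i]) / 2 * dt
  s
}

oracle_breath_metrics <- function(rec, breaths, ecw, set_peep,
                                  lowpass_hz = 5, remove_cardiac = TRUE) {
  pre <- if (all(c("paw_f", "pes_f", "pl_f") %in% names(rec))) rec else
    preprocess_channels(rec, lowpass_hz, remove_cardiac)
  fs <- rec_rate(rec)
  dt <- 1 / fs
  paw_f <- pre$paw_f; pes_f <- pre$pes_f; pl_f <- pre$pl_f
  pes_lp <- if ("pes_lp" %in% names(pre)) pre$pes_lp else pre$pes_f
  w <- round(0.3 * fs)

  rows <- lapply(seq_len(nrow(breaths)), function(j) {
    s <- breaths$start[j]; ie <- breaths$insp_end[j]; e <- breaths$end[j]
    span <- s:(e - 1)

    # Effort onset: scan the pre-inspiratory window for the last local max.
    onset <- s
    w0 <- max(1, s - w)
    if (s - w0 >= 2) {
      for (i in (w0 + 1):(s - 1)) {
        if (pes_f[i] >= pes_f[i - 1] && pes_f[i] >= pes_f[i + 1]) onset <- i
      }
    }
    pes_base <- pes_f[onset]

    if (breaths$occluded[j]) {
      base_lp <- pes_lp[s]
      if (s - w0 >= 2) {
        found <- 0L
        for (i in (w0 + 1):(s - 1)) {
          if (pes_lp[i] >= pes_lp[i - 1] && pes_lp[i] >= pes_lp[i + 1]) {
            found <- i
          }
        }
        if (found > 0) base_lp <- pes_lp[found]
      }
      return(data.frame(
        breath = breaths$breath[j], occluded = TRUE,
        delta_paw_dyn = 0,
        delta_pes = loop_min(pes_lp, span) - base_lp,
        tidal_volume = 0, pcw_ei = 0, pmus_peak = 0, ptp_mus = 0,
        delta_pl_dyn = 0,
        delta_pocc = loop_min(paw_f, span) - set_peep
      ))
    }

    flow_b <- rec$flow[span]
    drift <- loop_trapz(flow_b, dt) / ((length(span) - 1) * dt)
    fc <- flow_b - drift
    vol <- numeric(length(fc))
    for (i in 2:length(fc)) {
      vol[i] <- vol[i - 1] + (fc[i - 1] + fc[i]) / 2 * dt
    }
    insp_pos <- seq_len(ie - s)
    vt <- vol[ie - s]
    pes_rel <- pes_f[span] - pes_base
    pmus_t <- ecw * vol - pes_rel
    data.frame(
      breath = breaths$breath[j], occluded = FALSE,
      delta_paw_dyn = loop_max(paw_f, s:(ie - 1)) - set_peep,
      delta_pes = loop_min(pes_rel, insp_pos),
      tidal_volume = vt,
      pcw_ei = ecw * vt,
      pmus_peak = loop_max(pmus_t, insp_pos),
      ptp_mus = loop_trapz(pmax(pmus_t[insp_pos], 0), dt),
      delta_pl_dyn = loop_max(pl_f, s:(ie - 1)) - pl_f[onset],
      delta_pocc = NA_real_
    )
  })
  do.call(rbind, rows)
}
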