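# Breath segmentation and occlusion-maneuver detection.
#
# Breath spans are 1-based, half-open: inspiration [start, insp_end),
# expiration [insp_end, end). Consecutive breaths never overlap; partial
# breaths at the recording edges are discarded because every metric needs a
# complete cycle.

#' Segment a recording into breaths from the flow signal
#'
#' A breath starts at an upward crossing of the flow hysteresis threshold
#' sustained for at least `min_insp_duration` (this rejects cardiac-artifact
#' and noise crossings); inspiration ends at the subsequent return of flow
#' to zero; the breath ends where the next breath starts. Occluded breaths
#' carry no flow and are added afterwards by [detect_occlusions()].
#'
#' @param rec A [as_recording()] object.
#' @param flow_threshold Hysteresis threshold on inspiratory flow, L/s.
#' @param min_insp_duration Minimum sustained supra-threshold duration, s.
#' @param edge_guard Breaths starting within this margin of the recording
#'   edges are treated as partial and discarded: the pre-inspiratory
#'   baseline window and the zero-phase filters are undefined there.
#' @return A tibble with columns `breath`, `start`, `insp_end`, `end`,
#'   `occluded` (all `FALSE` at this stage). Empty (with a warning) when no
#'   breath is detected.
#' @export
segment_breaths <- function(rec, flow_threshold = 0.02,
                            min_insp_duration = 0.1, edge_guard = 0.5) {
  fs <- rec_rate(rec)
  flow <- rec$flow
  n <- length(flow)
  m <- max(2L, round(min_insp_duration * fs))

  above <- flow > flow_threshold
  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  cand <- run_start[r$values & r$lengths >= m]
  cand <- cand[cand > edge_guard * fs]

  # Keep only starts separated by a return of flow to <= 0 (one start per
  # inspiration even if flow dips below the threshold transiently).
  starts <- integer(0)
  last_kept <- -Inf
  for (s in cand) {
    if (length(starts) == 0 ||
        any(flow[last_kept:s] <= 0)) {
      starts <- c(starts, s)
      last_kept <- s
    }
  }
  if (length(starts) < 2) {
    warn("no complete breaths detected")
    return(tibble(breath = integer(), start = integer(),
                  insp_end = integer(), end = integer(),
                  occluded = logical()))
  }

  ns <- length(starts) - 1
  s_v <- starts[seq_len(ns)]
  e_v <- starts[-1]
  insp_v <- integer(ns)
  keep <- logical(ns)
  for (j in seq_len(ns)) {
    zero_cross <- which(flow[s_v[j]:e_v[j]] <= 0)
    if (length(zero_cross) == 0) next
    ie <- s_v[j] + zero_cross[1] - 1
    if (ie <= s_v[j] || ie >= e_v[j]) next
    insp_v[j] <- ie
    keep[j] <- TRUE
  }
  out <- tibble(start = as.integer(s_v[keep]),
                insp_end = insp_v[keep],
                end = as.integer(e_v[keep]))
  if (nrow(out) == 0) {
    warn("no complete breaths detected")
    return(tibble(breath = integer(), start = integer(),
                  insp_end = integer(), end = integer(),
                  occluded = logical()))
  }
  mutate(out, breath = row_number(), occluded = FALSE, .before = 1)
}

#' Detect end-expiratory occlusion maneuvers
#'
#' An occlusion inscribes the patient's quasi-static effort as a deflection
#' of airway pressure below set PEEP while the one-way valve keeps
#' inspiratory flow at zero. Episodes where low-passed Paw falls more than
#' `deflection_threshold` below PEEP with |flow| < `flow_eps` throughout
#' are added to the breath table as occluded breaths (the containing flow
#' breath is truncated to end where the occlusion starts). Deflections
#' between 0.3 cm H2O and the detection threshold are counted as
#' sub-threshold and reported via a message.
#'
#' @param rec A [as_recording()] object whose metadata contains the set
#'   PEEP (`rec_meta(rec)$peep`), the deflection reference.
#' @param breaths Output of [segment_breaths()].
#' @param deflection_threshold Minimum Paw deflection below PEEP, cm H2O.
#' @param flow_eps Maximum |flow| during an occlusion, L/s.
#' @return The breath table with occluded breaths inserted and flagged,
#'   ordered by start sample.
#' @export
detect_occlusions <- function(rec, breaths, deflection_threshold = 1,
                              flow_eps = 0.02) {
  meta <- rec_meta(rec)
  if (is.null(meta$peep)) {
    abort("set PEEP is missing from the recording metadata; it is the reference for occlusion deflections")
  }
  peep <- meta$peep
  fs <- rec_rate(rec)
  paw_f <- if ("paw_f" %in% names(rec)) rec$paw_f else lowpass(rec$paw, fs, 5)
  flow <- rec$flow
  n <- length(paw_f)

  find_spans <- function(threshold) {
    deep <- paw_f < peep - threshold
    r <- rle(deep)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1
    cbind(run_start[r$values], run_end[r$values])
  }
  deep_spans <- find_spans(deflection_threshold)
  sub_count <- 0L
  spans <- list()
  if (nrow(deep_spans) > 0) {
    # Expand each deep episode out to the 0.3 cm H2O hysteresis level.
    shallow <- paw_f < peep - 0.3
    for (j in seq_len(nrow(deep_spans))) {
      s <- deep_spans[j, 1]; e <- deep_spans[j, 2]
      while (s > 1 && shallow[s - 1]) s <- s - 1
      while (e < n && shallow[e + 1]) e <- e + 1
      spans[[j]] <- c(s, e)
    }
    spans <- unique(spans)
  }
  # Sub-threshold deflection episodes (logged, not flagged).
  shallow_spans <- find_spans(0.3)
  if (nrow(shallow_spans) > 0) {
    for (j in seq_len(nrow(shallow_spans))) {
      s <- shallow_spans[j, 1]; e <- shallow_spans[j, 2]
      depth <- peep - min(paw_f[s:e])
      no_flow <- max(abs(flow[s:e])) < flow_eps
      if (no_flow && depth < deflection_threshold) sub_count <- sub_count + 1L
    }
  }
  if (sub_count > 0) {
    inform(sprintf("%d sub-threshold occlusion-like deflection(s) (< %g cm H2O) not flagged",
                   sub_count, deflection_threshold))
  }

  occ_s <- integer(0); occ_ie <- integer(0); occ_e <- integer(0)
  min_len <- round(0.2 * fs)
  for (sp in spans) {
    s <- sp[1]; e <- sp[2]
    # Reject episodes touching the recording edges (filter transients,
    # partial maneuvers) and implausibly brief deflections.
    if (s <= 1 || e >= n || e - s < min_len) next
    if (max(abs(flow[s:e])) >= flow_eps) next
    imin <- s - 1 + which.min(paw_f[s:e])
    insp_end <- min(max(imin + 1L, s + 1L), e)
    occ_s <- c(occ_s, as.integer(s))
    occ_ie <- c(occ_ie, as.integer(insp_end))
    occ_e <- c(occ_e, as.integer(e) + 1L)
  }
  occ <- tibble(start = occ_s, insp_end = occ_ie, end = occ_e,
                occluded = rep(TRUE, length(occ_s)))
  if (nrow(occ) == 0) {
    return(mutate(breaths, breath = row_number()))
  }

  flowed <- breaths
  # Truncate flow breaths that span an occlusion episode.
  for (j in seq_len(nrow(occ))) {
    s <- occ$start[j]
    covers <- which(flowed$start < s & flowed$end > s)
    if (length(covers) > 0) flowed$end[covers] <- s
  }
  flowed <- filter(flowed, .data$end > .data$insp_end)
  out <- arrange(bind_rows(flowed, occ), .data$start)
  mutate(out, breath = row_number())
}
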