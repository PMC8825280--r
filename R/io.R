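# Plain-text (tab-delimited) readers and writers for the containers the
# analysis stages exchange. All files are ordinary TSV with a header row.

#' Write / read a voltage trace as two-column delimited text
#'
#' Columns `time_s`, `voltage_uv`; the sampling rate is recovered from the
#' time stamps on read.
#'
#' @param trace A [voltage_trace()].
#' @param path File path.
#' @return `read_voltage_trace()` returns a [voltage_trace()];
#'   `write_voltage_trace()` returns `path` invisibly.
#' @export
write_voltage_trace <- function(trace, path) {
  stopifnot(inherits(trace, "voltage_trace"))
  t <- trace$start_time + (seq_along(trace$samples) - 1L) / trace$sampling_rate
  utils::write.table(data.frame(time_s = t, voltage_uv = trace$samples),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_voltage_trace
#' @export
read_voltage_trace <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("time_s", "voltage_uv") %in% names(df)), nrow(df) >= 2L)
  fs <- 1 / stats::median(diff(df$time_s))
  voltage_trace(df$voltage_uv, sampling_rate = fs, start_time = df$time_s[1L])
}

#' Write / read an intake stream as delimited text
#'
#' Columns `timestamp_s`, `channel`, `cumulative_g`.
#'
#' @param stream An [intake_stream()].
#' @param path File path.
#' @return `read_intake_stream()` returns an [intake_stream()].
#' @export
write_intake_stream <- function(stream, path) {
  stopifnot(inherits(stream, "intake_stream"))
  utils::write.table(
    data.frame(timestamp_s = stream$timestamps, channel = stream$channel,
               cumulative_g = stream$cumulative_g),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_intake_stream
#' @export
read_intake_stream <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("timestamp_s", "channel", "cumulative_g") %in% names(df)))
  intake_stream(df$timestamp_s, df$cumulative_g,
                channel = as.character(df$channel[1L]))
}

#' Write / read a cut-back series as delimited text
#'
#' Columns `length_cm`, `output_power`.
#'
#' @param series A [cutback_series()].
#' @param path File path.
#' @param geometry Geometry recorded on read (the file stores only the
#'   measurements).
#' @return `read_cutback_series()` returns a [cutback_series()].
#' @export
write_cutback_series <- function(series, path) {
  stopifnot(inherits(series, "cutback_series"))
  utils::write.table(
    data.frame(length_cm = series$lengths_cm,
               output_power = series$output_power),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cutback_series
#' @export
read_cutback_series <- function(path, geometry = "straight") {
  df <- utils::read.delim(path)
  stopifnot(all(c("length_cm", "output_power") %in% names(df)))
  cutback_series(df$length_cm, df$output_power, geometry = geometry)
}

#' Write / read a Cq matrix as a Biomark-style delimited export
#'
#' One row per cell with metadata columns (`cell_id`, `mouse_id`, `group`)
#' followed by a paired `<gene>` / `<gene>_quality` column per panel gene;
#' undetected wells are empty.
#'
#' @param m A [cq_matrix()].
#' @param path File path.
#' @return `read_cq_export()` returns a [cq_matrix()].
#' @export
write_cq_export <- function(m, path) {
  stopifnot(inherits(m, "cq_matrix"))
  out <- m$meta[, c("cell_id", "mouse_id", "group")]
  for (g in colnames(m$cq)) {
    out[[g]] <- m$cq[, g]
    out[[paste0(g, "_quality")]] <- m$quality[, g]
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cq_export
#' @export
read_cq_export <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta_cols <- c("cell_id", "mouse_id", "group")
  stopifnot(all(meta_cols %in% names(df)))
  qcols <- grep("_quality$", names(df), value = TRUE)
  genes <- sub("_quality$", "", qcols)
  cq <- as.matrix(df[, genes, drop = FALSE])
  quality <- as.matrix(df[, qcols, drop = FALSE])
  rownames(cq) <- rownames(quality) <- df$cell_id
  colnames(quality) <- genes
  cq_matrix(cq, quality, df[, meta_cols])
}
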