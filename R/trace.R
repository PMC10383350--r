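# Displacement-trace container shared by the simulator and the radar
# signal chain.

#' Skin-displacement trace
#'
#' Uniformly sampled skin-displacement time series at the radar frame
#' period.
#'
#' @param values Displacement values (mm).
#' @param sample_period_s Sampling period (s), the radar frame period.
#' @param origin_bin Range bin the trace was demodulated from (NA for
#'   simulated ground truth).
#' @param radar_id Identifier ("chest", "wrist", ...).
#' @return An object of class `displacement_trace`.
#' @export
displacement_trace <- function(values, sample_period_s,
                               origin_bin = NA_integer_,
                               radar_id = NA_character_) {
  stopifnot(is.numeric(values), all(is.finite(values)),
            sample_period_s > 0)
  structure(list(values = as.numeric(values),
                 sample_period_s = sample_period_s,
                 origin_bin = origin_bin,
                 radar_id = radar_id),
            class = "displacement_trace")
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat(sprintf("<displacement_trace> %d samples @ %.4g ms (%s), range %.4g..%.4g mm\n",
              length(x$values), x$sample_period_s * 1e3,
              ifelse(is.na(x$radar_id), "?", x$radar_id),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.displacement_trace <- function(x) length(x$values)

# Time axis (s) of a trace.
trace_time <- function(trace) {
  (seq_along(trace$values) - 1) * trace$sample_period_s
}

#' Write / read a displacement trace as CSV
#'
#' Two-column CSV (`time_s`, `displacement_mm`).
#'
#' @param trace A [displacement_trace()].
#' @param path Output CSV path.
#' @return `write_trace_csv()` returns `path` invisibly;
#'   `read_trace_csv()` returns a [displacement_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "displacement_trace"))
  df <- data.frame(time_s = trace_time(trace),
                   displacement_mm = trace$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "displacement_mm") %in% names(df)),
            nrow(df) >= 2L)
  displacement_trace(df$displacement_mm, sample_period_s = df$time_s[2] - df$time_s[1])
}
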