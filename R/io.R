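# Delimited-text input/output for voltage traces and dataset manifests.
#
# Trace files are two-column delimited text (comma, tab or whitespace):
# time and voltage, with optional '#' comment lines and an optional header.
# On load the voltage is baseline-shifted so that rest = 0 and resampled to
# a uniform grid by linear interpolation.

.read_table_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], file_line = which(keep))
}

#' Read a voltage trace from delimited text
#'
#' @param path path to a two-column (time, voltage) text file.  Comma-, tab-
#'   or whitespace-delimited; `#` comment lines and a single header line are
#'   tolerated.
#' @param dt_target target sample interval (ms) of the returned trace.
#' @param time_unit unit of the time column, `"ms"` or `"s"`.
#' @param rest explicit resting potential (same unit as the voltage column)
#'   to subtract; use when the recording is in absolute mV.
#' @param rest_window optional `c(t_start, t_end)` (ms, after unit
#'   conversion): the mean voltage over this window is taken as rest and
#'   subtracted.  Ignored when `rest` is given.  If neither is given the
#'   file is assumed to be already baseline-shifted.
#' @return A [voltage_trace()] on the `dt_target` grid with rest = 0.
#' @export
read_trace <- function(path, dt_target = 0.1, time_unit = c("ms", "s"),
                       rest = NULL, rest_window = NULL) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("trace file not found: ", path)
  parsed <- .read_table_lines(path)
  if (!length(parsed$lines)) stop("no data in trace file: ", path)
  sep <- if (grepl(",", parsed$lines[[1L]])) "," else ""
  first <- strsplit(trimws(parsed$lines[[1L]]),
                    if (sep == ",") "\\s*,\\s*" else "\\s+")[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  skip <- as.integer(has_header)
  df <- utils::read.table(text = parsed$lines, sep = sep, skip = skip,
                          header = FALSE, col.names = c("time", "voltage"),
                          colClasses = "numeric")
  t <- df$time; v <- df$voltage
  if (time_unit == "s") t <- t * 1000
  nond <- which(diff(t) <= 0)
  if (length(nond)) {
    row <- nond[1L] + 1L + skip
    stop("time column not strictly increasing at file line ",
         parsed$file_line[row], " of ", path)
  }
  if (!is.null(rest)) {
    v <- v - rest
  } else if (!is.null(rest_window)) {
    inw <- t >= rest_window[1L] & t <= rest_window[2L]
    if (!any(inw)) stop("rest_window contains no samples")
    v <- v - mean(v[inw])
  }
  grid <- seq(t[1L], t[length(t)], by = dt_target)
  voltage_trace(stats::approx(t, v, xout = grid)$y, dt = dt_target,
                t0 = t[1L])
}

#' Write a voltage trace as delimited text
#'
#' @param trace a [voltage_trace()].
#' @param path output path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, sep = ",") {
  trace <- as_voltage_trace(trace)
  t <- trace$t0 + (seq_along(trace$values) - 1L) * trace$dt
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# voltage trace (time in ms, voltage in mV relative to rest)",
               paste("time", "voltage", sep = sep)), con)
  writeLines(paste(format(t, trim = TRUE, digits = 15),
                   format(trace$values, trim = TRUE, digits = 15), sep = sep),
             con)
  invisible(path)
}

#' Write a dataset as trace files plus a manifest
#'
#' The manifest is a CSV with one row per component: columns `id`,
#' `trace_file`, `spike_times` (semicolon-separated ms), `repetitions`,
#' `dw`, `dw_unit` (`"fraction"` or `"percent"`).  Rows sharing an `id`
#' are the trial-type components of one protocol outcome.
#'
#' @param data a [vbp_dataset()].
#' @param dir output directory (created if missing).
#' @param dw_unit unit used for the written outcomes.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(data, dir, dw_unit = c("fraction", "percent")) {
  dw_unit <- match.arg(dw_unit)
  if (!inherits(data, "vbp_dataset")) stop("data must be a vbp_dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (r in data) {
    for (k in seq_along(r$components)) {
      cc <- r$components[[k]]
      fn <- sprintf("%s_c%d.csv", gsub("[^A-Za-z0-9._-]", "_", r$id), k)
      write_trace(cc$trace, file.path(dir, fn))
      dw <- if (dw_unit == "percent") 100 * r$dw_exp else r$dw_exp
      rows[[length(rows) + 1L]] <- data.frame(
        id = r$id, trace_file = fn,
        spike_times = paste(as_spike_train(cc$spikes)$times, collapse = ";"),
        repetitions = if (is.null(cc$reps)) 1 else cc$reps,
        dw = dw, dw_unit = dw_unit)
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset manifest
#'
#' @param path path to a manifest CSV as produced by [write_dataset()];
#'   trace files are resolved relative to the manifest's directory.
#' @param dt_target target sample interval (ms) for the loaded traces.
#' @return A [vbp_dataset()]; outcomes are normalized to fractions.
#' @export
read_manifest <- function(path, dt_target = 0.1) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "trace_file", "spike_times", "repetitions", "dw", "dw_unit")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (any(df$repetitions <= 0)) stop("repetitions must be positive")
  base <- dirname(path)
  records <- lapply(split(df, factor(df$id, levels = unique(df$id))),
                    function(g) {
    comps <- lapply(seq_len(nrow(g)), function(k) {
      fp <- file.path(base, g$trace_file[k])
      if (!file.exists(fp)) stop("trace file not found: ", fp)
      st <- if (nzchar(trimws(g$spike_times[k])))
        as.numeric(strsplit(g$spike_times[k], ";")[[1L]]) else numeric(0)
      list(trace = read_trace(fp, dt_target = dt_target),
           spikes = spike_train(st), reps = g$repetitions[k])
    })
    dw <- g$dw[1L]
    if (g$dw_unit[1L] == "percent") dw <- dw / 100
    else if (g$dw_unit[1L] != "fraction")
      stop("dw_unit must be 'fraction' or 'percent', got ", g$dw_unit[1L])
    protocol_record(g$id[1L], comps, dw)
  })
  vbp_dataset(unname(records))
}
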