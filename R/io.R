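#' Read and write gaze sample streams as CSV
#'
#' The on-disk dialect is a plain CSV with columns
#' `time_ms,x_px,y_px,valid`, one row per 1 ms sample.
#'
#' @param stream Gaze sample data frame.
#' @param path File path.
#' @return `read_gaze_csv()` returns the sample data frame.
#' @export
write_gaze_csv <- function(stream, path) {
  utils::write.csv(stream[, c("time_ms", "x_px", "y_px", "valid")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_csv
#' @export
read_gaze_csv <- function(path) {
  df <- utils::read.csv(path)
  req <- c("time_ms", "x_px", "y_px", "valid")
  if (!all(req %in% names(df)))
    stop("gaze CSV must have columns time_ms, x_px, y_px, valid", call. = FALSE)
  df[, req]
}

#' Read parsed gaze events from a simplified ASC-like text export
#'
#' Supports a minimal text dialect of eye-tracker event exports: lines
#' `EFIX <onset> <offset> <x> <y>`, `ESACC <onset> <offset> <sx> <sy> <ex>
#' <ey> <peak_vel>`, and `EBLINK <onset> <offset>`; other lines are ignored.
#' Offsets are converted to the package's half-open convention by adding 1 ms
#' to the (inclusive) end stamps.
#'
#' @param path File path.
#' @param format Only `"asc"` is currently understood; the flag guards
#'   against accidentally feeding sample CSVs to the event reader.
#' @return Event data frame in the layout of [detect_gaze_events()].
#' @export
read_gaze_events <- function(path, format = c("asc")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  parse_num <- function(l) as.numeric(strsplit(trimws(l), "[ \t]+")[[1]][-1])
  ev <- list()
  for (l in lines) {
    if (startsWith(l, "EFIX")) {
      v <- parse_num(l)
      ev[[length(ev) + 1]] <- data.frame(kind = "fixation", onset = v[1],
                                         offset = v[2] + 1, start_x = v[3],
                                         start_y = v[4], end_x = v[3],
                                         end_y = v[4], cx = v[3], cy = v[4],
                                         peak_vel = NA_real_)
    } else if (startsWith(l, "ESACC")) {
      v <- parse_num(l)
      ev[[length(ev) + 1]] <- data.frame(kind = "saccade", onset = v[1],
                                         offset = v[2] + 1, start_x = v[3],
                                         start_y = v[4], end_x = v[5],
                                         end_y = v[6], cx = NA_real_,
                                         cy = NA_real_,
                                         peak_vel = if (length(v) >= 7) v[7] else NA_real_)
    } else if (startsWith(l, "EBLINK")) {
      v <- parse_num(l)
      ev[[length(ev) + 1]] <- data.frame(kind = "blink", onset = v[1],
                                         offset = v[2] + 1,
                                         start_x = NA_real_, start_y = NA_real_,
                                         end_x = NA_real_, end_y = NA_real_,
                                         cx = NA_real_, cy = NA_real_,
                                         peak_vel = NA_real_)
    }
  }
  if (!length(ev)) stop("no event lines found in ", path, call. = FALSE)
  out <- do.call(rbind, ev)
  out[order(out$onset), , drop = FALSE]
}
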