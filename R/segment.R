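#' Multichannel signal segment
#'
#' The unit of both simulation output and analysis input: a fixed-rate
#' multichannel time series with unique channel labels. Data are stored as a
#' channels x samples matrix.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (positive scalar).
#' @param labels character vector of unique channel names, one per row.
#' @return An object of class `signal_segment` with fields `data`, `fs`,
#'   `labels`.
#' @export
signal_segment <- function(data, fs, labels = rownames(data)) {
  data <- as.matrix(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    stop("need one label per channel (", nrow(data), " channels, ",
         length(labels), " labels)")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  fs <- as.numeric(fs)
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels),
            class = "signal_segment")
}

#' @export
print.signal_segment <- function(x, ...) {
  cat(sprintf("<signal_segment> %d channel(s) x %d samples @ %g Hz (%.3g s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.signal_segment <- function(x) dim(x$data)

#' Extract one channel of a segment
#'
#' @param segment a [signal_segment()].
#' @param channel channel label.
#' @return numeric vector of samples.
#' @export
segment_channel <- function(segment, channel) {
  stopifnot(inherits(segment, "signal_segment"))
  if (!channel %in% segment$labels)
    stop("unknown channel label '", channel, "'; available: ",
         paste(segment$labels, collapse = ", "))
  segment$data[channel, ]
}

#' Subset a segment to a set of channels
#'
#' Used e.g. to drop a reference electrode (such as Cb) before network
#' analysis when the electrode-group map excludes it.
#'
#' @param segment a [signal_segment()].
#' @param labels channel labels to keep, in the requested order.
#' @return A [signal_segment()] with the selected channels.
#' @export
select_channels <- function(segment, labels) {
  stopifnot(inherits(segment, "signal_segment"))
  missing <- setdiff(labels, segment$labels)
  if (length(missing))
    stop("unknown channel label(s): ", paste(missing, collapse = ", "))
  signal_segment(segment$data[labels, , drop = FALSE], segment$fs, labels)
}

#' Write a segment to delimited text with a JSON sidecar
#'
#' The native on-disk format: a tab-delimited file with one header row of
#' channel labels and one column per channel, plus a `<path>.json` sidecar
#' holding the sampling rate and labels. The round trip is lossless to full
#' double precision.
#'
#' @param segment a [signal_segment()].
#' @param path output file path (sidecar written to `paste0(path, ".json")`).
#' @return `path`, invisibly.
#' @export
write_segment <- function(segment, path) {
  stopifnot(inherits(segment, "signal_segment"))
  df <- as.data.frame(t(segment$data))
  names(df) <- segment$labels
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(fs = segment$fs, labels = as.list(segment$labels))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a segment written by [write_segment()]
#'
#' @param path path to the delimited-text file; the `<path>.json` sidecar
#'   must exist (no silent defaults are assumed).
#' @return A [signal_segment()].
#' @export
read_segment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("missing sidecar metadata file: ", sidecar_path,
         " (fs and labels are required; no defaults are assumed)")
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$fs) || is.null(meta$labels))
    stop("sidecar ", sidecar_path, " must contain fields 'fs' and 'labels'")
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(header, as.character(meta$labels)))
    stop("line 1 of ", path, ": header labels do not match sidecar labels")
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  if (ncol(df) != length(header))
    stop("line 1 of ", path, ": expected ", length(header),
         " columns, found ", ncol(df))
  signal_segment(t(as.matrix(df)), meta$fs, as.character(meta$labels))
}
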