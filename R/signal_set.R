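#' Multichannel signal container
#'
#' A `signal_set` holds a channels x samples matrix together with its
#' sampling rate and channel labels. It is the common input of the
#' spectral, synchrony, and network-inference functions.
#'
#' @param data Numeric matrix, channels in rows.
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of channel names; defaults to
#'   `"ch001"`, `"ch002"`, ...
#' @return An object of class `signal_set`.
#' @export
#' @examples
#' ss <- signal_set(matrix(rnorm(2000), 2), fs = 1000)
#' ss
signal_set <- function(data, fs, channels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) abort("signal data must be numeric")
  if (fs <= 0) abort("sampling rate must be positive")
  if (is.null(channels))
    channels <- sprintf("ch%03d", seq_len(nrow(data)))
  if (length(channels) != nrow(data))
    abort("one channel name per row is required")
  rownames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat("<signal_set> ", nrow(x$data), " channel(s) x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 2),
      " s)\n", sep = "")
  invisible(x)
}

#' @export
#' @method as_tibble signal_set
as_tibble.signal_set <- function(x, ...) {
  tibble(channel = rep(x$channels, each = ncol(x$data)),
         time_s = rep(seq_len(ncol(x$data)) - 1, nrow(x$data)) / x$fs,
         value = as.vector(t(x$data)))
}

#' Read and write signal sets as delimited text
#'
#' The on-disk format is tab-separated with one row per channel: the first
#' column holds the channel name, the remaining columns the samples. The
#' sampling rate is kept in a `# fs=<Hz>` header comment.
#'
#' @param x A `signal_set`.
#' @param path File path.
#' @return `write_signal_set()` returns `x` invisibly;
#'   `read_signal_set()` returns a `signal_set`.
#' @export
write_signal_set <- function(x, path) {
  stopifnot(inherits(x, "signal_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", x$fs), con)
  utils::write.table(
    data.frame(channel = x$channels, x$data, check.names = FALSE),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(x)
}

#' @rdname write_signal_set
#' @export
read_signal_set <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^# fs=", hdr)) abort("missing '# fs=' header")
  fs <- as.numeric(sub("^# fs=", "", hdr))
  tab <- utils::read.table(path, sep = "\t", skip = 1,
                           stringsAsFactors = FALSE)
  signal_set(as.matrix(tab[, -1, drop = FALSE]), fs = fs,
             channels = as.character(tab[[1]]))
}
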