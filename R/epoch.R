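#' Multichannel epoch container
#'
#' Holds a preprocessed multichannel recording split into fixed-length
#' epochs. With the default pipeline settings (128 Hz, 20 s) every epoch is
#' a 2560 x n_channels matrix.
#'
#' @param epochs list of samples x channels matrices (one per epoch), or a
#'   single matrix for a one-epoch set
#' @param fs sampling rate (Hz)
#' @param channel_names character vector of montage labels
#' @param epoch_length epoch duration (s); defaults to `nrow / fs`
#' @return an object of class `epoch_set`
#' @export
epoch_set <- function(epochs, fs, channel_names, epoch_length = NULL) {
  if (is.matrix(epochs)) epochs <- list(epochs)
  stopifnot(length(epochs) >= 1, fs > 0)
  nch <- ncol(epochs[[1]])
  ns <- nrow(epochs[[1]])
  for (e in epochs) {
    if (!is.matrix(e) || ncol(e) != nch || nrow(e) != ns)
      stop("all epochs must be matrices of identical dimension")
    if (!all(is.finite(e))) stop("non-finite samples in epoch data")
  }
  if (missing(channel_names) || is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nch))
  if (length(channel_names) != nch)
    stop("channel_names length must equal the channel count")
  if (is.null(epoch_length)) epoch_length <- ns / fs
  if (abs(epoch_length * fs - ns) > 1e-6)
    stop("epoch_length inconsistent with sample count and fs")
  structure(list(epochs = epochs, fs = fs, channel_names = channel_names,
                 epoch_length = epoch_length),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d epoch(s) of %.3g s, %d channels @ %g Hz\n",
              length(x$epochs), x$epoch_length,
              length(x$channel_names), x$fs))
  invisible(x)
}

#' @export
length.epoch_set <- function(x) length(x$epochs)

#' Sample times of one epoch
#' @param x an `epoch_set`
#' @return numeric vector of within-epoch sample times (s), starting at 0
#' @export
epoch_times <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  seq(0, by = 1 / x$fs, length.out = nrow(x$epochs[[1]]))
}
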