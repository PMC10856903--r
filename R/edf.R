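# Minimal EDF (European Data Format) reader and writer: continuous
# recordings, 16-bit samples, identical sampling rate across channels.
# Covers what the pipeline needs (polysomnography-style multichannel EEG);
# annotations/EDF+ discontinuities are out of scope.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(signif(x, 7), format = "g", width = 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a multichannel signal to an EDF file
#'
#' @param data samples x channels matrix (physical units, e.g. uV)
#' @param fs sampling rate (Hz, integer)
#' @param labels channel labels
#' @param path output file
#' @param phys_dim physical dimension string (default "uV")
#' @return `path`, invisibly; samples are quantized to the 16-bit EDF grid
#' @export
write_edf <- function(data, fs, labels, path, phys_dim = "uV") {
  data <- as.matrix(data)
  stopifnot(abs(fs - round(fs)) < 1e-9, ncol(data) == length(labels))
  fs <- round(fs)
  n_rec <- nrow(data) %/% fs
  if (n_rec < 1) stop("recording shorter than one 1-s record")
  data <- data[seq_len(n_rec * fs), , drop = FALSE]
  nc <- ncol(data)
  pmin_ <- apply(data, 2, min); pmax_ <- apply(data, 2, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  # pad the stored physical range so that, after rounding to the 8-char
  # header fields, it still covers every sample (no clipping on write)
  span <- pmax_ - pmin_
  pmin_ <- pmin_ - 2e-3 * span
  pmax_ <- pmax_ + 2e-3 * span
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + nc), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(nc, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  field(labels, 16)
  field(rep("", nc), 80)
  field(rep(phys_dim, nc), 8)
  writeChar(paste0(vapply(pmin_, edf_num, "", width = 8), collapse = ""),
            con, eos = NULL)
  writeChar(paste0(vapply(pmax_, edf_num, "", width = 8), collapse = ""),
            con, eos = NULL)
  field(rep("-32768", nc), 8)
  field(rep("32767", nc), 8)
  field(rep("", nc), 80)
  field(rep(fs, nc), 8)
  field(rep("", nc), 32)
  # re-read the physical ranges exactly as a reader will parse them, so the
  # quantization grid matches on round trip
  pmin_r <- as.numeric(vapply(pmin_, edf_num, "", width = 8))
  pmax_r <- as.numeric(vapply(pmax_, edf_num, "", width = 8))
  scale <- (pmax_r - pmin_r) / 65535
  for (r in seq_len(n_rec)) {
    block <- data[((r - 1) * fs + 1):(r * fs), , drop = FALSE]
    dig <- round(sweep(sweep(block, 2, pmin_r), 2, scale, "/")) - 32768
    dig <- pmin(pmax(dig, -32768), 32767)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file with one sampling rate across signals
#' @return list with `data` (samples x channels, physical units), `fs`,
#'   `labels`, `phys_dim`, `n_records`
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(nc), function(i) rd(w), "")
  labels <- rdv(16); rdv(80)
  phys_dim <- rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (length(unique(spr)) != 1)
    stop("mixed sampling rates are not supported")
  fs <- spr[1] / dur
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  data <- matrix(0, n_rec * spr[1], nc)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = spr[1] * nc, size = 2,
                   endian = "little")
    block <- matrix(raw, spr[1], nc)
    data[((r - 1) * spr[1] + 1):(r * spr[1]), ] <-
      sweep(sweep(block, 2, dmin, "-") * rep(scale, each = spr[1]),
            2, pmin_, "+")
  }
  colnames(data) <- labels
  list(data = data, fs = fs, labels = labels, phys_dim = phys_dim,
       n_records = n_rec)
}

#' Load a recording and select montage channels
#'
#' @param path EDF file
#' @param channels channel labels to keep (default: all); matching is
#'   case-insensitive but otherwise exact
#' @return list with `data` (samples x channels, uV), `fs`, `labels`
#' @export
load_recording <- function(path, channels = NULL) {
  rec <- read_edf(path)
  if (is.null(channels)) return(rec[c("data", "fs", "labels")])
  idx <- match(tolower(channels), tolower(rec$labels))
  if (anyNA(idx))
    stop("channel(s) not found: ",
         paste(channels[is.na(idx)], collapse = ", "),
         "; available: ", paste(rec$labels, collapse = ", "))
  list(data = rec$data[, idx, drop = FALSE], fs = rec$fs,
       labels = rec$labels[idx])
}
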