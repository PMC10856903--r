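#' Pipeline configuration
#'
#' Defaults reproduce the reference preprocessing and detection settings:
#' resampling to 128 Hz, zero-phase 4th-order Butterworth band pass
#' 0.5-30 Hz, non-overlapping 20-s epochs, a 200-iteration decomposition
#' over widths 0.1-10 s up to 45 Hz, and the standard spindle criteria.
#'
#' @param target_fs resampling rate (Hz)
#' @param band band-pass edges (Hz)
#' @param filter_order Butterworth order
#' @param epoch_length epoch duration (s)
#' @param dictionary a [dictionary_spec]
#' @param criteria a [spindle_criteria]
#' @param fit_all fit dipoles to every atom (TRUE) or only to atoms passing
#'   the amplitude/frequency/duration/period criteria (FALSE, default;
#'   identical catalog, cheaper)
#' @param snr_channel scoring channel for the SNR criterion (NULL = per-atom
#'   strongest channel)
#' @param seed seed recorded with the outputs (the pipeline itself is
#'   deterministic)
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(target_fs = 128, band = c(0.5, 30),
                            filter_order = 4, epoch_length = 20,
                            dictionary = dictionary_spec(),
                            criteria = spindle_criteria(),
                            fit_all = FALSE, snr_channel = NULL, seed = 1) {
  structure(list(target_fs = target_fs, band = band,
                 filter_order = filter_order, epoch_length = epoch_length,
                 dictionary = dictionary, criteria = criteria,
                 fit_all = fit_all, snr_channel = snr_channel, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields override the defaults of [pipeline_config]; nested
#' `dictionary` and `criteria` blocks override the corresponding spec
#' fields.
#'
#' @param path `.yaml`/`.yml` or `.json` file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  for (nm in intersect(names(raw), setdiff(names(cfg),
                                           c("dictionary", "criteria"))))
    cfg[[nm]] <- raw[[nm]]
  if (!is.null(raw$dictionary))
    cfg$dictionary <- do.call(dictionary_spec,
                              utils::modifyList(unclass(cfg$dictionary),
                                                as.list(raw$dictionary)))
  if (!is.null(raw$criteria))
    cfg$criteria <- do.call(spindle_criteria,
                            utils::modifyList(
                              unclass(cfg$criteria)[
                                names(unclass(cfg$criteria)) != "snr_min_db"],
                              as.list(raw$criteria)))
  cfg
}

#' Preprocess a raw recording into an epoch set
#'
#' Resamples to the target rate, applies a zero-phase (forward-backward)
#' Butterworth band pass, and splits the result into contiguous
#' non-overlapping epochs (a trailing partial epoch is dropped).
#'
#' @param raw list with `data` (samples x channels), `fs`, `labels` (as from
#'   [load_recording]), or a bare matrix with `fs`/`labels` arguments
#' @param config a [pipeline_config]
#' @param fs,labels used when `raw` is a matrix
#' @return an [epoch_set] (possibly empty, with a warning, for recordings
#'   shorter than one epoch)
#' @export
preprocess <- function(raw, config = pipeline_config(), fs = NULL,
                       labels = NULL) {
  if (is.matrix(raw)) raw <- list(data = raw, fs = fs, labels = labels)
  stopifnot(!is.null(raw$fs))
  if (is.null(raw$labels)) raw$labels <- paste0("ch", seq_len(ncol(raw$data)))
  if (raw$fs < 2 * config$band[2])
    stop("native sampling rate below twice the band top")
  x <- as.matrix(raw$data)
  # resample (Fourier method: exact amplitude and zero phase shift for
  # in-band components; edge effects are confined to the recording ends)
  if (abs(raw$fs - config$target_fs) > 1e-9) {
    m <- round(nrow(x) * config$target_fs / raw$fs)
    x <- apply(x, 2, resample_fft, m = m)
    x <- as.matrix(x)
  }
  fs <- config$target_fs
  # zero-phase band pass
  bf <- signal::butter(config$filter_order,
                       config$band / (fs / 2), type = "pass")
  x <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  x <- as.matrix(x)
  ns <- round(config$epoch_length * fs)
  n_ep <- nrow(x) %/% ns
  if (n_ep < 1) {
    warning("recording shorter than one epoch; returning an empty set")
    return(structure(list(epochs = list(), fs = fs,
                          channel_names = raw$labels,
                          epoch_length = config$epoch_length),
                     class = "epoch_set"))
  }
  epochs <- lapply(seq_len(n_ep), function(i)
    x[((i - 1) * ns + 1):(i * ns), , drop = FALSE])
  epoch_set(epochs, fs, raw$labels, config$epoch_length)
}

# Fourier-domain resampling of one channel to m samples; the shared
# Nyquist bin is dropped (irrelevant after the subsequent band pass)
resample_fft <- function(col, m) {
  n <- length(col)
  X <- stats::fft(col)
  Y <- complex(real = numeric(m), imaginary = numeric(m))
  kmax <- ceiling(min(n, m) / 2) - 1     # highest retained positive bin
  Y[1] <- X[1]
  if (kmax >= 1) {
    Y[2:(kmax + 1)] <- X[2:(kmax + 1)]
    Y[m - seq_len(kmax) + 1] <- X[n - seq_len(kmax) + 1]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}
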