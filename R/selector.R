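#' Sleep-spindle selection criteria
#'
#' Parameter ranges for selecting sleep spindles from dipole atoms,
#' following the AASM-style definition (11-16 Hz trains lasting at least
#' 0.5 s) extended with dipole-model plausibility: goodness of fit of the
#' equivalent dipole and its distance to the cortex. Duration is identified
#' with the Gabor width `s`, and oscillation periods are counted within that
#' width, i.e. the period criterion reads `f * s >= min_periods`.
#'
#' @param amp_range peak-to-peak amplitude range, highest across
#'   derivations (uV)
#' @param f_range frequency range (Hz)
#' @param dur_range duration (Gabor width) range (s)
#' @param min_periods minimum number of oscillation periods within the width
#' @param gof_range dipole goodness-of-fit range (percent)
#' @param dtc_range dipole distance-to-cortex range (mm)
#' @param snr_min_db optional local SNR floor in dB (off by default; the
#'   paper-style "clearly visible" setting is -7 dB)
#' @return an object of class `spindle_criteria`
#' @export
spindle_criteria <- function(amp_range = c(12.5, 150), f_range = c(11, 16),
                             dur_range = c(0.5, 3.5), min_periods = 3,
                             gof_range = c(60, 100), dtc_range = c(0, 20),
                             snr_min_db = NULL) {
  for (r in list(amp_range, f_range, dur_range, gof_range, dtc_range))
    stopifnot(length(r) == 2, r[1] <= r[2])
  structure(list(amp_range = amp_range, f_range = f_range,
                 dur_range = dur_range, min_periods = min_periods,
                 gof_range = gof_range, dtc_range = dtc_range,
                 snr_min_db = snr_min_db),
            class = "spindle_criteria")
}

#' Per-channel amplitude of a Gabor atom
#'
#' Peak-to-peak amplitude of the reconstructed atom waveform in each
#' channel, in signal units: `2 * |w_i| * K(gamma)`, where `K(gamma)` is the
#' peak value of the unit-norm atom's envelope on the sampling grid.
#'
#' @param atom one-row slice of an `atom_book` / catalog (or a list with
#'   `u`, `f`, `s`, `phi` and a `weights` vector)
#' @param fs sampling rate (Hz); defaults to the book attribute
#' @param epoch_length epoch duration (s); defaults to the book attribute
#' @return list with `per_channel` (uV), `max` and `channel_of_max`
#' @export
atom_amplitude <- function(atom, fs = NULL, epoch_length = NULL) {
  if (is.data.frame(atom)) {
    if (is.null(fs)) fs <- attr(atom, "fs")
    if (is.null(epoch_length)) epoch_length <- attr(atom, "epoch_length")
    w <- drop(atom_weights(atom))
    u <- atom$u; f <- atom$f; s <- atom$s; phi <- atom$phi
  } else {
    w <- atom$weights; u <- atom$u; f <- atom$f; s <- atom$s; phi <- atom$phi
  }
  stopifnot(!is.null(fs), !is.null(epoch_length))
  tt <- seq(0, by = 1 / fs, length.out = round(epoch_length * fs))
  g <- make_gabor(gabor_params(u, f, s, phi), tt)
  amp <- 2 * abs(w) * attr(g, "K")
  k <- which.max(amp)
  list(per_channel = amp, max = amp[[k]],
       channel_of_max = if (!is.null(names(w))) names(w)[k] else k)
}

#' Local signal-to-noise ratio of an atom (dB)
#'
#' Ratio of the atom's energy in one channel to the energy of the
#' surrounding background: the preprocessed epoch restricted to
#' `[u - s, u + s]` with the atom's own contribution in that channel
#' subtracted,
#' \eqn{SNR = 10 \log_{10}( w_i^2 / || EEG_{u \pm s} - w_i g ||^2 )}.
#'
#' @param atom one-row catalog slice (see [atom_amplitude])
#' @param epoch samples x channels matrix the atom was fitted on, or an
#'   [epoch_set] with one epoch
#' @param channel channel index or label used for scoring
#' @param fs sampling rate (Hz)
#' @return SNR in dB (`Inf` when the windowed background has zero energy);
#'   attribute `truncated` flags windows clipped at the epoch edge
#' @export
snr_db <- function(atom, epoch, channel, fs = NULL) {
  if (inherits(epoch, "epoch_set")) {
    fs <- epoch$fs
    if (is.character(channel)) channel <- match(channel, epoch$channel_names)
    epoch <- epoch$epochs[[1]]
  }
  stopifnot(!is.null(fs))
  if (is.data.frame(atom)) {
    w <- drop(atom_weights(atom))
    if (is.character(channel)) channel <- match(channel, names(w))
    atom <- list(u = atom$u, f = atom$f, s = atom$s, phi = atom$phi,
                 weights = w)
  }
  if (is.na(channel) || channel < 1 || channel > ncol(epoch))
    stop("channel index out of range")
  n <- nrow(epoch)
  tt <- seq(0, by = 1 / fs, length.out = n)
  g <- make_gabor(gabor_params(atom$u, atom$f, atom$s, atom$phi), tt)
  wi <- atom$weights[[channel]]
  lo <- atom$u - atom$s; hi <- atom$u + atom$s
  truncated <- lo < 0 || hi > tt[n]
  win <- which(tt >= lo & tt <= hi)
  bg <- epoch[win, channel] - wi * g[win]
  den <- sum(bg^2)
  out <- if (den <= 0) Inf else 10 * log10(wi^2 / den)
  attr(out, "truncated") <- truncated
  out
}

#' Select sleep spindles from a dipole-atom catalog
#'
#' Applies the selection criteria as a pure filter: an atom is accepted iff
#' its maximum amplitude, frequency, duration, period count, dipole goodness
#' of fit, distance to cortex (and, when enabled, local SNR) all fall in
#' range. Every rejected atom is labelled with the first failing criterion,
#' in that order.
#'
#' @param dipole_atoms a `dipole_atoms` data frame (from [mp_dip])
#' @param criteria a [spindle_criteria]
#' @param epoch optional samples x channels matrix (or one-epoch
#'   [epoch_set]) for the SNR criterion
#' @param snr_channel scoring channel for SNR (default the channel with the
#'   largest absolute weight per atom)
#' @return list with `accepted` (catalog subset, order preserved, extra
#'   columns `amplitude_max`, `amplitude_channel`, `snr_db`), `rejections`
#'   (data frame `iteration`, `reason`) and `reasons` (per-input-atom label,
#'   `"accepted"` for kept rows)
#' @export
select_spindles <- function(dipole_atoms, criteria = spindle_criteria(),
                            epoch = NULL, snr_channel = NULL) {
  stopifnot(inherits(criteria, "spindle_criteria"))
  n <- nrow(dipole_atoms)
  fs <- attr(dipole_atoms, "fs")
  epoch_length <- attr(dipole_atoms, "epoch_length")
  W <- atom_weights(dipole_atoms)
  reasons <- character(n)
  amp_max <- amp_ch <- rep(NA_real_, n)
  amp_ch <- rep(NA_character_, n)
  snr <- rep(NA_real_, n)
  inr <- function(v, r) !is.na(v) & v >= r[1] & v <= r[2]
  for (i in seq_len(n)) {
    a <- atom_amplitude(dipole_atoms[i, , drop = FALSE], fs, epoch_length)
    amp_max[i] <- a$max; amp_ch[i] <- as.character(a$channel_of_max)
    row <- dipole_atoms[i, ]
    reasons[i] <- if (!inr(amp_max[i], criteria$amp_range)) "amplitude"
      else if (!inr(row$f, criteria$f_range)) "frequency"
      else if (!inr(row$s, criteria$dur_range)) "duration"
      else if (row$f * row$s < criteria$min_periods) "periods"
      else if (!inr(row$gof, criteria$gof_range)) "goodness_of_fit"
      else if (!inr(row$dtc, criteria$dtc_range)) "distance_to_cortex"
      else "accepted"
    if (reasons[i] == "accepted" && !is.null(criteria$snr_min_db)) {
      if (is.null(epoch))
        stop("snr_min_db is set but no epoch signal was supplied")
      ch <- if (is.null(snr_channel)) which.max(abs(W[i, ])) else snr_channel
      snr[i] <- as.numeric(snr_db(dipole_atoms[i, , drop = FALSE],
                                  epoch, ch, fs))
      if (snr[i] < criteria$snr_min_db) reasons[i] <- "snr"
    }
  }
  keep <- reasons == "accepted"
  accepted <- dipole_atoms[keep, , drop = FALSE]
  accepted$amplitude_max <- amp_max[keep]
  accepted$amplitude_channel <- amp_ch[keep]
  accepted$snr_db <- snr[keep]
  for (a in c("fs", "epoch_length", "channel_names"))
    attr(accepted, a) <- attr(dipole_atoms, a)
  list(accepted = accepted,
       rejections = data.frame(
         iteration = dipole_atoms$iteration[!keep],
         reason = reasons[!keep]),
       reasons = reasons)
}

#' Detection interval of an accepted atom
#'
#' Scoring interval `[u - s/2, u + s/2]`: centred on the atom, with length
#' equal to its duration.
#'
#' @param catalog data frame with `u` and `s` columns
#' @return data frame with `start` and `end` (s)
#' @export
atom_intervals <- function(catalog) {
  data.frame(start = catalog$u - catalog$s / 2,
             end = catalog$u + catalog$s / 2)
}
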