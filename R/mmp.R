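#' Multivariate matching-pursuit decomposition of one epoch
#'
#' Greedily decomposes a multichannel epoch into Gabor atoms with a common
#' envelope, frequency and phase and per-channel signed weights. At each
#' iteration the atom maximizing \eqn{\sum_i \langle R^n x_i,
#' g_\gamma\rangle^2} over the discrete dictionary is located by an
#' FFT-based scan, refined by a coordinate search on `(u, f, s)` (the optimal
#' phase is closed-form), and its projection is subtracted from every
#' channel. The recursion stops after `spec$n_iterations` atoms or when the
#' residual energy falls below `1e-12` of the input energy. The
#' decomposition is fully deterministic.
#'
#' @param x samples x channels matrix (one epoch), or an [epoch_set] with a
#'   single epoch
#' @param spec a [dictionary_spec]
#' @param fs sampling rate (Hz); taken from `x` when it is an `epoch_set`
#' @param refine logical; refine the grid optimum by coordinate search
#'   (default TRUE)
#' @param channel_names optional channel labels for the atom book
#' @return an `atom_book` data frame: one row per atom with columns
#'   `iteration`, `u`, `f`, `s`, `phi`, `criterion` and one `w_<label>`
#'   column per channel, plus attributes `residual` (samples x channels),
#'   `fs`, `epoch_length`, `channel_names`
#' @export
mmp_decompose <- function(x, spec = dictionary_spec(), fs = NULL,
                          refine = TRUE, channel_names = NULL) {
  if (inherits(x, "epoch_set")) {
    if (length(x$epochs) != 1)
      stop("pass a single epoch; use run_pipeline() for full sets")
    fs <- x$fs
    channel_names <- x$channel_names
    x <- x$epochs[[1]]
  }
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("input error: non-finite samples")
  if (is.null(fs)) stop("fs is required for matrix input")
  stopifnot(inherits(spec, "dictionary_spec"))
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(x)))
  dict <- build_dictionary(spec, nrow(x) / fs, fs)
  g <- dict$grid
  res <- mmp_engine(x, fs, g$s, as.integer(g$du_samples),
                    as.integer(g$nfft), spec$f_max,
                    min(g$s), max(g$s), spec$n_iterations, 1e-12, refine)
  W <- res$weights
  colnames(W) <- paste0("w_", channel_names)
  book <- data.frame(iteration = seq_along(res$u), u = res$u, f = res$f,
                     s = res$s, phi = res$phi, criterion = res$crit)
  book <- cbind(book, as.data.frame(W))
  attr(book, "residual") <- res$residual
  attr(book, "fs") <- fs
  attr(book, "epoch_length") <- nrow(x) / fs
  attr(book, "channel_names") <- channel_names
  class(book) <- c("atom_book", "data.frame")
  book
}

#' Per-channel weight matrix of an atom book
#' @param book an `atom_book` (or catalog data frame with `w_` columns)
#' @return atoms x channels numeric matrix
#' @export
atom_weights <- function(book) {
  wcols <- grep("^w_", names(book), value = TRUE)
  if (length(wcols) == 0) stop("no w_<channel> columns found")
  m <- as.matrix(book[, wcols, drop = FALSE])
  colnames(m) <- sub("^w_", "", wcols)
  m
}

#' Reconstruct the signal contribution of selected atoms
#'
#' @param book an `atom_book`
#' @param rows which atoms to include (default all)
#' @return samples x channels matrix of the summed atom waveforms
#' @export
reconstruct_atoms <- function(book, rows = seq_len(nrow(book))) {
  fs <- attr(book, "fs")
  tt <- seq(0, by = 1 / fs, length.out = round(attr(book, "epoch_length") * fs))
  W <- atom_weights(book)
  out <- matrix(0, length(tt), ncol(W))
  for (i in rows) {
    gp <- gabor_params(book$u[i], book$f[i], book$s[i], book$phi[i])
    g <- make_gabor(gp, tt)
    out <- out + outer(as.numeric(g), W[i, ])
  }
  colnames(out) <- colnames(W)
  out
}

#' Time-frequency energy density of a decomposition
#'
#' Cross-term free energy-density map of one channel: the weighted sum of
#' the Wigner distributions of the selected atoms. The Wigner distribution
#' of a unit-norm Gabor atom is the 2-D Gaussian
#' \eqn{2 \exp(-2\pi((t-u)/s)^2 - 2\pi(s(f-f_0))^2)}, which integrates to 1
#' over the time-frequency plane, so each atom contributes its squared
#' weight to the map's integral.
#'
#' @param book an `atom_book`
#' @param channel channel index or label
#' @param t_grid,f_grid numeric vectors defining the map axes (s, Hz)
#' @return matrix `length(t_grid)` x `length(f_grid)` of energy density
#' @export
energy_density <- function(book, channel, t_grid, f_grid) {
  W <- atom_weights(book)
  if (is.character(channel)) channel <- match(channel, colnames(W))
  if (is.na(channel) || channel < 1 || channel > ncol(W))
    stop("channel index out of range")
  map <- matrix(0, length(t_grid), length(f_grid))
  for (i in seq_len(nrow(book))) {
    w2 <- W[i, channel]^2
    if (w2 == 0) next
    gt <- exp(-2 * pi * ((t_grid - book$u[i]) / book$s[i])^2)
    gf <- exp(-2 * pi * (book$s[i] * (f_grid - book$f[i]))^2)
    map <- map + (2 * w2) * outer(gt, gf)
  }
  map
}

#' Write / read an atom book
#'
#' CSV holds one record per atom (epoch index, iteration, u, f, s, phi and
#' per-channel weights with channel labels in the header); the JSON dialect
#' also stores `fs` and `epoch_length` and round-trips bit-stably.
#'
#' @param book an `atom_book` or catalog data frame
#' @param path output file; `.json` selects the JSON dialect
#' @return `path`, invisibly
#' @export
write_atom_book <- function(book, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(fs = attr(book, "fs"),
                    epoch_length = attr(book, "epoch_length"),
                    channel_names = attr(book, "channel_names"),
                    atoms = as.data.frame(book))
    jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  } else {
    utils::write.csv(as.data.frame(book), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_atom_book
#' @export
read_atom_book <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    book <- as.data.frame(payload$atoms)
    attr(book, "fs") <- payload$fs
    attr(book, "epoch_length") <- payload$epoch_length
    attr(book, "channel_names") <- payload$channel_names
    class(book) <- c("atom_book", "data.frame")
    book
  } else {
    utils::read.csv(path)
  }
}
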