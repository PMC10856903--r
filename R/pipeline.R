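#' Run the full spindle-detection pipeline
#'
#' Chains preprocessing (for raw input), per-epoch matching-pursuit
#' decomposition, dipole fitting of the atom topographies, and the spindle
#' selection criteria. Deterministic for a fixed configuration; per-epoch
#' failures are logged and skipped.
#'
#' @param input an [epoch_set] (already preprocessed), a raw recording list
#'   (`data`/`fs`/`labels`), or a path to an EDF file
#' @param config a [pipeline_config]
#' @param model a `head_model`; default 3-shell sphere with electrodes at
#'   the input's channel labels (canonical 10-20 positions)
#' @param cortex_points cortex point cloud for the distance-to-cortex
#'   criterion (default [synthetic_cortex_points])
#' @param verbose print per-stage counts (default TRUE)
#' @return list with `catalog` (accepted spindles: epoch, start, end, atom
#'   and dipole parameters, amplitude, SNR when enabled), `atoms` (all
#'   dipole atoms, all epochs), `counts` (per-epoch atoms / fitted /
#'   accepted), `config`
#' @export
run_pipeline <- function(input, config = pipeline_config(), model = NULL,
                         cortex_points = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(input)) input <- load_recording(input)
  if (!inherits(input, "epoch_set")) input <- preprocess(input, config)
  eset <- input
  if (length(eset$epochs) == 0) stop("empty epoch set")
  if (is.null(model)) {
    elec <- tryCatch(
      electrode_positions_1020(labels = eset$channel_names),
      error = function(e)
        electrode_positions_1020(n_channels = length(eset$channel_names)))
    model <- head_model_sphere(electrodes = elec)
  }
  if (is.null(cortex_points)) cortex_points <- synthetic_cortex_points(model)
  crit <- config$criteria
  all_atoms <- list(); all_catalog <- list(); counts <- list()
  for (ep in seq_along(eset$epochs)) {
    res <- tryCatch({
      book <- mmp_decompose(eset$epochs[[ep]], config$dictionary,
                            fs = eset$fs,
                            channel_names = eset$channel_names)
      rows <- seq_len(nrow(book))
      if (!config$fit_all)
        rows <- rows[prefilter_atoms(book, crit, eset$fs,
                                     eset$epoch_length)]
      datoms <- mp_dip(book, model, cortex_points, rows = rows)
      sel <- select_spindles(datoms, crit, epoch = eset$epochs[[ep]],
                             snr_channel = config$snr_channel)
      list(book = book, datoms = datoms, sel = sel)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      say("epoch %d failed: %s", ep, conditionMessage(res))
      next
    }
    res$datoms$epoch <- ep
    acc <- res$sel$accepted
    acc$epoch <- if (nrow(acc)) ep else integer(0)
    all_atoms[[length(all_atoms) + 1]] <- as.data.frame(res$datoms)
    all_catalog[[length(all_catalog) + 1]] <- as.data.frame(acc)
    counts[[length(counts) + 1]] <- data.frame(
      epoch = ep, atoms = nrow(res$datoms),
      fitted = sum(res$datoms$fit_ok %in% TRUE),
      accepted = nrow(acc))
    say("epoch %d: %d atoms, %d dipoles fitted, %d spindles accepted",
        ep, nrow(res$datoms), sum(res$datoms$fit_ok %in% TRUE), nrow(acc))
  }
  atoms <- do.call(rbind, all_atoms)
  catalog <- do.call(rbind, all_catalog)
  if (!is.null(catalog) && nrow(catalog) > 0) {
    iv <- atom_intervals(catalog)
    catalog$start <- iv$start
    catalog$end <- iv$end
  }
  out <- list(catalog = catalog, atoms = atoms,
              counts = do.call(rbind, counts), config = config)
  attr(out$catalog, "fs") <- eset$fs
  attr(out$catalog, "epoch_length") <- eset$epoch_length
  attr(out$catalog, "channel_names") <- eset$channel_names
  out
}

# cheap Table-1 screening (amplitude / frequency / duration / periods);
# dipole-dependent criteria are evaluated after fitting
prefilter_atoms <- function(book, crit, fs, epoch_length) {
  W <- atom_weights(book)
  ok <- logical(nrow(book))
  for (i in seq_len(nrow(book))) {
    g <- tryCatch(make_gabor(gabor_params(book$u[i], book$f[i], book$s[i],
                                          book$phi[i]),
                             seq(0, by = 1 / fs,
                                 length.out = round(epoch_length * fs))),
                  error = function(e) NULL)
    if (is.null(g)) next
    amp <- 2 * max(abs(W[i, ])) * attr(g, "K")
    ok[i] <- amp >= crit$amp_range[1] && amp <= crit$amp_range[2] &&
      book$f[i] >= crit$f_range[1] && book$f[i] <= crit$f_range[2] &&
      book$s[i] >= crit$dur_range[1] && book$s[i] <= crit$dur_range[2] &&
      book$f[i] * book$s[i] >= crit$min_periods
  }
  ok
}

#' Merge temporally overlapping accepted detections
#'
#' Optional scoring-time consolidation: detections within one epoch whose
#' `[start, end]` intervals overlap are merged into a single event spanning
#' their union, keeping the parameters of the strongest (largest amplitude)
#' member.
#'
#' @param catalog accepted-spindle catalog with `epoch`, `start`, `end`
#' @return catalog with merged rows
#' @export
merge_overlapping_detections <- function(catalog) {
  if (is.null(catalog) || nrow(catalog) < 2) return(catalog)
  out <- list()
  for (ep in unique(catalog$epoch)) {
    d <- catalog[catalog$epoch == ep, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    grp <- cumsum(c(1, ifelse(d$start[-1] > cummax(d$end[-nrow(d)]), 1, 0)))
    for (g in unique(grp)) {
      m <- d[grp == g, , drop = FALSE]
      lead <- which.max(if ("amplitude_max" %in% names(m)) m$amplitude_max
                        else abs(m$criterion))
      row <- m[lead, , drop = FALSE]
      row$start <- min(m$start); row$end <- max(m$end)
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}

#' Write / read a spindle catalog CSV
#'
#' @param catalog data frame (accepted spindles or dipole atoms)
#' @param path CSV path
#' @return `path` / the catalog
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) utils::read.csv(path)
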