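#' Match detected intervals against reference annotations
#'
#' One-to-one matching: a detection can match a reference iff their overlap
#' length divided by the shorter of the two interval lengths is at least
#' `min_overlap`; `min_overlap = 0` means "overlap by at least one point".
#' Pairs are assigned greedily by descending overlap (ties broken
#' deterministically by the earlier detection start, then the earlier
#' reference start) and the pairing is then completed to a
#' maximum-cardinality matching by augmenting paths, so the TP count equals
#' the brute-force optimal assignment. Annotations shorter than
#' `min_duration` are rejected before scoring.
#'
#' @param detections,references data frames with `start` and `end` columns
#'   (s); extra columns are preserved in the pairing
#' @param min_overlap minimum overlap fraction of the shorter interval
#'   (default 0)
#' @param min_duration minimum reference/detection duration retained (s);
#'   default 0.5, the textbook minimum spindle length
#' @return `match_result`: counts `tp`, `fp`, `fn`; `pairs` (data frame of
#'   matched detection/reference indices and overlaps); `detection_label`
#'   (`"TP"`/`"FP"` per retained detection); the filtered inputs
#' @export
match_intervals <- function(detections, references, min_overlap = 0,
                            min_duration = 0.5) {
  chk <- function(x, nm) {
    x <- as.data.frame(x)
    if (nrow(x) > 0) {
      stopifnot(all(c("start", "end") %in% names(x)))
      if (any(x$end <= x$start)) stop(nm, ": intervals must have end > start")
      x <- x[x$end - x$start >= min_duration, , drop = FALSE]
      if (is.unsorted(x$start)) {
        warning(nm, " unsorted by start; sorting")
        x <- x[order(x$start), , drop = FALSE]
      }
    }
    x
  }
  det <- chk(detections, "detections")
  ref <- chk(references, "references")
  nd <- nrow(det); nr <- nrow(ref)
  cand <- NULL
  if (nd > 0 && nr > 0) {
    for (i in seq_len(nd)) {
      ov <- pmin(det$end[i], ref$end) - pmax(det$start[i], ref$start)
      lmin <- pmin(det$end[i] - det$start[i], ref$end - ref$start)
      frac <- ov / lmin
      ok <- which(ov > 0 & frac >= min_overlap)
      if (length(ok))
        cand <- rbind(cand, data.frame(det = i, ref = ok, overlap = ov[ok],
                                       frac = frac[ok]))
    }
  }
  pairs <- data.frame(det = integer(0), ref = integer(0),
                      overlap = numeric(0), frac = numeric(0))
  if (!is.null(cand) && nrow(cand) > 0) {
    cand <- cand[order(-cand$overlap, det$start[cand$det],
                       ref$start[cand$ref]), , drop = FALSE]
    match_of_r <- rep(NA_integer_, nr)   # detection paired to reference
    match_of_d <- rep(NA_integer_, nd)
    for (i in seq_len(nrow(cand))) {
      d <- cand$det[i]; r <- cand$ref[i]
      if (is.na(match_of_d[d]) && is.na(match_of_r[r])) {
        match_of_d[d] <- r; match_of_r[r] <- d
      }
    }
    # complete the greedy pairing to a maximum-cardinality matching by
    # augmenting paths (deterministic: detections by start order,
    # candidate references by descending overlap)
    adj <- split(cand$ref, cand$det)
    augment <- function(d0) {
      seen <- logical(nr)
      try_d <- function(d) {
        for (r in adj[[as.character(d)]]) {
          if (seen[r]) next
          seen[r] <<- TRUE
          if (is.na(match_of_r[r]) || try_d(match_of_r[r])) {
            match_of_r[r] <<- d; match_of_d[d] <<- r
            return(TRUE)
          }
        }
        FALSE
      }
      try_d(d0)
    }
    for (d in which(is.na(match_of_d)))
      if (!is.null(adj[[as.character(d)]]))
        augment(d)
    got <- which(!is.na(match_of_d))
    if (length(got)) {
      key_c <- paste(cand$det, cand$ref)
      key_p <- paste(got, match_of_d[got])
      pairs <- cand[match(key_p, key_c), , drop = FALSE]
      pairs <- pairs[order(pairs$det), , drop = FALSE]
    }
  }
  tp <- nrow(pairs)
  lab <- rep("FP", nd); lab[pairs$det] <- "TP"
  structure(list(tp = tp, fp = nd - tp, fn = nr - tp, pairs = pairs,
                 detection_label = lab, detections = det, references = ref),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: TP %d, FP %d, FN %d (F1 = %.3f)\n",
              x$tp, x$fp, x$fn, f1_score(x)))
  invisible(x)
}

#' F1 score of a match result
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`; defined as 0 when the denominator is 0.
#'
#' @param match a `match_result`, or TP count when `fp`/`fn` given
#' @param fp,fn counts (when `match` is numeric)
#' @return F1 in `[0, 1]`
#' @export
f1_score <- function(match, fp = NULL, fn = NULL) {
  if (inherits(match, "match_result")) {
    tp <- match$tp; fp <- match$fp; fn <- match$fn
  } else tp <- match
  den <- 2 * tp + fp + fn
  if (den == 0) 0 else 2 * tp / den
}

#' F1 as a function of a minimum-SNR threshold
#'
#' Recomputes the interval matching after dropping detections whose local
#' SNR falls below each threshold of the grid, emulating the rejection of
#' structures "hidden in noise".
#'
#' @param detections data frame with `start`, `end` and `snr_db`
#' @param references data frame with `start`, `end`
#' @param snr_grid thresholds in dB (default `seq(-30, 10, by = 1)`)
#' @param ... passed to [match_intervals]
#' @return data frame `threshold`, `f1`, `tp`, `fp`, `fn`, with attribute
#'   `best_threshold` (maximizer; earliest on ties)
#' @export
f1_vs_snr <- function(detections, references,
                      snr_grid = seq(-30, 10, by = 1), ...) {
  stopifnot("snr_db" %in% names(detections))
  rows <- lapply(snr_grid, function(th) {
    keep <- detections$snr_db >= th
    m <- match_intervals(detections[keep, , drop = FALSE], references, ...)
    data.frame(threshold = th, f1 = f1_score(m), tp = m$tp, fp = m$fp,
               fn = m$fn)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_threshold") <- out$threshold[which.max(out$f1)]
  out
}

#' Parameter-recovery errors of detections against a simulation manifest
#'
#' Pairs detections with ground-truth events by interval overlap on the
#' global timeline (epoch index times epoch length plus within-epoch time),
#' then reports per-pair absolute errors of frequency, time centre, and
#' reconstructed amplitude on a named derivation, plus the Euclidean error
#' of the fitted dipole location, with aggregates overall and per SNR bin.
#'
#' @param catalog accepted-spindle catalog (needs `epoch`, `u`, `f`, `s`,
#'   `x`, `y`, `z` and amplitude columns `amp_<channel>` or per-channel
#'   weights)
#' @param manifest simulation manifest (from [simulate_dataset])
#' @param epoch_length epoch duration (s)
#' @param amp_channel derivation for the amplitude error (default "Fp1")
#' @param snr_breaks bin edges (dB) for the per-SNR aggregation
#' @param min_overlap passed to [match_intervals]
#' @return list with `errors` (per matched pair), `summary` (mean, sd,
#'   median of each error), `by_snr` (aggregates per SNR bin), `match`
#'   (the `match_result`), `missed` (unmatched manifest rows)
#' @export
param_errors <- function(catalog, manifest, epoch_length = 20,
                         amp_channel = "Fp1",
                         snr_breaks = seq(-40, 5, by = 5),
                         min_overlap = 0) {
  gl <- function(ep, u) (ep - 1) * epoch_length + u
  det <- data.frame(start = gl(catalog$epoch, catalog$u - catalog$s / 2),
                    end = gl(catalog$epoch, catalog$u + catalog$s / 2),
                    row = seq_len(nrow(catalog)))
  ref <- data.frame(start = gl(manifest$epoch, manifest$u - manifest$s / 2),
                    end = gl(manifest$epoch, manifest$u + manifest$s / 2),
                    row = seq_len(nrow(manifest)))
  det <- det[order(det$start), ]
  ref <- ref[order(ref$start), ]
  m <- match_intervals(det, ref, min_overlap = min_overlap)
  if (nrow(m$pairs) == 0)
    return(list(errors = NULL, summary = NULL, by_snr = NULL, match = m,
                missed = manifest))
  di <- m$detections$row[m$pairs$det]
  ri <- m$references$row[m$pairs$ref]
  cat_m <- catalog[di, , drop = FALSE]
  man_m <- manifest[ri, , drop = FALSE]
  # estimated peak-to-peak amplitude on the requested derivation
  wcol <- paste0("w_", amp_channel)
  if (!wcol %in% names(cat_m))
    stop("catalog lacks weights for channel ", amp_channel)
  fs <- attr_or(catalog, "fs", 128)
  tt <- seq(0, by = 1 / fs, length.out = round(epoch_length * fs))
  K <- vapply(seq_len(nrow(cat_m)), function(i)
    attr(make_gabor(gabor_params(cat_m$u[i], cat_m$f[i], cat_m$s[i],
                                 cat_m$phi[i]), tt), "K"),
    numeric(1))
  amp_est <- 2 * abs(cat_m[[wcol]]) * K
  mancol <- paste0("amp_", tolower(amp_channel), "_uV")
  amp_true <- if (mancol %in% names(man_m)) man_m[[mancol]] else NA_real_
  errors <- data.frame(
    detection = di, event = man_m$event, snr_db = man_m$snr_db,
    df = abs(cat_m$f - man_m$f),
    du = abs(cat_m$u - man_m$u),
    damp = abs(amp_est - amp_true),
    dloc = sqrt((cat_m$x - man_m$src_x)^2 + (cat_m$y - man_m$src_y)^2 +
                  (cat_m$z - man_m$src_z)^2))
  agg <- function(d) data.frame(
    n = nrow(d),
    f_mean = mean(d$df), f_sd = stats::sd(d$df), f_median = stats::median(d$df),
    u_mean = mean(d$du), u_sd = stats::sd(d$du), u_median = stats::median(d$du),
    amp_mean = mean(d$damp), amp_sd = stats::sd(d$damp),
    amp_median = stats::median(d$damp),
    loc_mean = mean(d$dloc), loc_sd = stats::sd(d$dloc),
    loc_median = stats::median(d$dloc))
  bins <- cut(errors$snr_db, snr_breaks)
  by_snr <- do.call(rbind, lapply(split(errors, bins), agg))
  by_snr <- cbind(bin = rownames(by_snr), by_snr)
  list(errors = errors, summary = agg(errors), by_snr = by_snr, match = m,
       missed = manifest[-ri, , drop = FALSE])
}

attr_or <- function(x, name, default) {
  v <- attr(x, name)
  if (is.null(v)) default else v
}

#' Compare TP and FP parameter distributions (two-sample KS test)
#'
#' @param tp_values,fp_values numeric samples of one parameter
#' @param min_n minimum sample size per group (default 5); smaller inputs
#'   are flagged and excluded
#' @return list with `statistic`, `p_value`, `excluded` (logical), `n_tp`,
#'   `n_fp`
#' @export
ks_compare <- function(tp_values, fp_values, min_n = 5) {
  tp_values <- tp_values[is.finite(tp_values)]
  fp_values <- fp_values[is.finite(fp_values)]
  if (length(tp_values) < min_n || length(fp_values) < min_n)
    return(list(statistic = NA_real_, p_value = NA_real_, excluded = TRUE,
                n_tp = length(tp_values), n_fp = length(fp_values)))
  kt <- suppressWarnings(stats::ks.test(tp_values, fp_values))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       excluded = FALSE, n_tp = length(tp_values), n_fp = length(fp_values))
}
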