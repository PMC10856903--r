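#' Gabor dictionary specification
#'
#' Density and range parameters of the time-frequency dictionary used by the
#' matching-pursuit decomposition. `energy_error` bounds the worst-case
#' energy loss from dictionary discretization: neighbouring atoms (adjacent
#' in time shift, frequency, or scale) have squared inner products of at
#' least `1 - energy_error`.
#'
#' @param energy_error dictionary density parameter (default 0.05)
#' @param s_range range of Gabor widths in seconds (default `c(0.1, 10)`)
#' @param f_max maximum frequency in Hz (default 45)
#' @param n_iterations number of matching-pursuit iterations (default 200)
#' @return an object of class `dictionary_spec`
#' @export
dictionary_spec <- function(energy_error = 0.05, s_range = c(0.1, 10),
                            f_max = 45, n_iterations = 200) {
  stopifnot(energy_error > 0, energy_error < 1,
            length(s_range) == 2, s_range[1] > 0, s_range[2] > s_range[1],
            n_iterations >= 1)
  if (f_max <= 0) stop("configuration error: f_max must be positive")
  structure(list(energy_error = energy_error, s_range = s_range,
                 f_max = f_max, n_iterations = n_iterations),
            class = "dictionary_spec")
}

#' Build the discrete Gabor dictionary grid
#'
#' Constructs per-scale sampling of the `(u, f, s)` parameter space. Widths
#' are log-spaced in `s_range` with ratio `r` solving
#' `2r/(1+r^2) = 1 - energy_error` (the squared inner product of two Gabors
#' differing only in scale); time shifts are spaced `beta * s` and
#' frequencies `beta / s` with `beta = sqrt(-log(1 - energy_error)/pi)`, the
#' half-width at which the Gabor autocorrelation squared drops to
#' `1 - energy_error`.
#'
#' @param spec a [dictionary_spec]
#' @param epoch_length epoch duration (s)
#' @param fs sampling rate (Hz)
#' @return list of class `gabor_dictionary` with a per-scale `grid` data
#'   frame (`s`, `du_samples`, `n_u`, `nfft`, `n_f`) and the total candidate
#'   count `n_candidates`
#' @export
build_dictionary <- function(spec, epoch_length, fs) {
  stopifnot(inherits(spec, "dictionary_spec"), epoch_length > 0, fs > 0)
  eps <- spec$energy_error
  beta <- sqrt(-log(1 - eps) / pi)
  # scale ratio from 2r/(1+r^2) = 1 - eps
  a <- 1 - eps
  r <- (1 + sqrt(1 - a^2)) / a
  s_min <- max(spec$s_range[1], 2 / fs)
  s_max <- min(spec$s_range[2], epoch_length)
  if (s_max <= s_min) stop("configuration error: empty width range")
  n_s <- max(2, ceiling(log(s_max / s_min) / log(r)) + 1)
  svals <- exp(seq(log(s_min), log(s_max), length.out = n_s))
  n <- round(epoch_length * fs)
  du <- pmax(1L, as.integer(floor(beta * svals * fs)))
  nfft <- vapply(svals, function(s) {
    need <- fs * s / beta
    as.integer(2^ceiling(log2(max(need, 16))))
  }, integer(1))
  n_u <- (n - 1L) %/% du + 1L
  n_f <- pmin(as.integer(floor(spec$f_max * nfft / fs)), nfft %/% 2L) + 1L
  grid <- data.frame(s = svals, du_samples = du, n_u = n_u,
                     nfft = nfft, n_f = n_f)
  structure(list(spec = spec, fs = fs, epoch_length = epoch_length,
                 beta = beta, scale_ratio = r, grid = grid,
                 n_candidates = sum(as.numeric(n_u) * n_f)),
            class = "gabor_dictionary")
}

#' @export
print.gabor_dictionary <- function(x, ...) {
  cat(sprintf(paste0("Gabor dictionary: %d scales (%.3g-%.3g s), ",
                     "%.3g candidates, energy error %.3g\n"),
              nrow(x$grid), min(x$grid$s), max(x$grid$s),
              x$n_candidates, x$spec$energy_error))
  invisible(x)
}

#' Brute-force scan of the matching-pursuit criterion over a parameter grid
#'
#' Evaluates `max_phi sum_i <r_i, g_(u,f,s,phi)>^2` at every combination of
#' the supplied `u`, `f` and `s` values by direct inner products (closed-form
#' phase). Used as an exhaustive oracle against the FFT-based engine; scales
#' as the product of the grid sizes, so keep it for short epochs.
#'
#' @param x samples x channels matrix
#' @param fs sampling rate (Hz)
#' @param u_grid,f_grid,s_grid numeric vectors of candidate parameters
#' @return data frame of the best candidate: `u`, `f`, `s`, `phi`,
#'   `criterion`
#' @export
scan_dictionary <- function(x, fs, u_grid, f_grid, s_grid) {
  x <- as.matrix(x)
  n <- nrow(x)
  tt <- seq(0, by = 1 / fs, length.out = n)
  best <- list(criterion = -1)
  for (s in s_grid) for (u in u_grid) {
    idx <- which(abs(tt - u) <= 3 * s)
    if (length(idx) < 3) next
    td <- tt[idx] - u
    E <- exp(-pi * (td / s)^2)
    R <- x[idx, , drop = FALSE]
    th <- outer(td, 2 * pi * f_grid)        # len(idx) x n_f
    A <- E * cos(th); B <- E * sin(th)
    CC <- crossprod(A, R); DD <- crossprod(B, R)   # n_f x n_ch
    a11 <- rowSums(CC^2); a22 <- rowSums(DD^2); acd <- rowSums(CC * DD)
    b11 <- colSums(A^2); b22 <- colSums(B^2); bab <- colSums(A * B)
    # vectorized largest generalized eigenvalue of ([a], [b]) per frequency
    p <- b11 * b22 - bab^2
    q <- a11 * b22 + a22 * b11 - 2 * (-acd) * (-bab)
    rr <- a11 * a22 - acd^2
    lam <- ifelse(p > 1e-12 * pmax(b11, b22)^2,
                  (q + sqrt(pmax(q^2 - 4 * p * rr, 0))) / (2 * p),
                  ifelse(b11 > 0, a11 / b11, 0))
    k <- which.max(lam)
    if (lam[k] > best$criterion) {
      ph <- rayleigh_max2x2(a11[k], -acd[k], a22[k],
                            b11[k], -bab[k], b22[k])$phi
      best <- list(u = u, f = f_grid[k], s = s, phi = ph %% (2 * pi),
                   criterion = lam[k])
    }
  }
  if (best$criterion < 0) stop("empty scan grid")
  as.data.frame(best)
}
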