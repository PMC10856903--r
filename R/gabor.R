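#' Gabor atom parameters
#'
#' Bundle of the four parameters of a Gabor atom: a sinusoid modulated by a
#' Gaussian envelope, \eqn{g(t) = K \exp(-\pi ((t-u)/s)^2) \cos(2\pi f (t-u)
#' + \phi)}, where \eqn{K} normalizes the waveform to unit energy on the
#' sampling grid.
#'
#' @param u time center (s)
#' @param f frequency center (Hz)
#' @param s width of the Gaussian envelope (s)
#' @param phi phase (rad); stored modulo \eqn{2\pi}
#' @return an object of class `gabor_params`
#' @export
gabor_params <- function(u, f, s, phi = 0) {
  stopifnot(is.finite(u), is.finite(f), is.finite(s), is.finite(phi))
  if (s <= 0) stop("Gabor width s must be positive")
  if (f < 0) stop("Gabor frequency must be non-negative")
  structure(list(u = u, f = f, s = s, phi = phi %% (2 * pi)),
            class = "gabor_params")
}

#' @export
print.gabor_params <- function(x, ...) {
  cat(sprintf("Gabor atom: u = %.4g s, f = %.4g Hz, s = %.4g s, phi = %.4g rad\n",
              x$u, x$f, x$s, x$phi))
  invisible(x)
}

#' Evaluate a unit-norm Gabor atom on a time grid
#'
#' The envelope is truncated at `|t - u| > 3 s` (where it has fallen below
#' `exp(-9 pi) ~ 5e-13` of its peak) and the waveform is renormalized to unit
#' Euclidean norm on the intersection of that support with the grid, so that
#' atoms near epoch boundaries remain unit-norm on the epoch.
#'
#' @param params a [gabor_params] object
#' @param time_grid uniformly sampled time points (s)
#' @return numeric vector of the same length as `time_grid`, with attributes
#'   `K` (the normalization constant, i.e. the peak value of the normalized
#'   envelope) and `support` (index range of nonzero samples)
#' @export
make_gabor <- function(params, time_grid) {
  stopifnot(inherits(params, "gabor_params"), length(time_grid) >= 2)
  dt <- diff(time_grid)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("time_grid must be uniformly sampled")
  if (params$s < 2 * dt[1])
    stop("degenerate atom: width s is below two sample intervals")
  t <- time_grid - params$u
  idx <- which(abs(t) <= 3 * params$s)
  if (length(idx) < 3)
    stop("atom support does not intersect the time grid")
  g <- numeric(length(time_grid))
  env <- exp(-pi * (t[idx] / params$s)^2)
  g[idx] <- env * cos(2 * pi * params$f * t[idx] + params$phi)
  nrm <- sqrt(sum(g[idx]^2))
  if (nrm == 0) stop("degenerate atom: zero norm on the grid")
  g <- g / nrm
  attr(g, "K") <- 1 / nrm
  attr(g, "support") <- range(idx)
  g
}

#' Optimal common phase and per-channel weights for a Gabor envelope
#'
#' For fixed `(u, f, s)` finds the phase \eqn{\phi} maximizing the
#' multichannel matching-pursuit criterion \eqn{\sum_i \langle r_i,
#' g_{(u,f,s,\phi)}\rangle^2} in closed form: the criterion is a Rayleigh
#' quotient of two 2x2 quadratic forms in \eqn{(\cos\phi, \sin\phi)}, solved
#' as a generalized eigenproblem.
#'
#' @param residuals samples x channels matrix
#' @param envelope numeric vector `c(u, f, s)` (or a [gabor_params] whose
#'   phase is ignored)
#' @param time_grid sample times (s)
#' @return list with `phi` (in `[0, 2pi)`), `weights` (per-channel inner
#'   products with the unit-norm atom at `phi`), and `criterion`
#'   (= sum of squared weights)
#' @export
best_phase_and_weights <- function(residuals, envelope, time_grid) {
  residuals <- as.matrix(residuals)
  if (!all(is.finite(residuals))) stop("residuals must be finite")
  if (inherits(envelope, "gabor_params"))
    envelope <- c(envelope$u, envelope$f, envelope$s)
  u <- envelope[1]; f <- envelope[2]; s <- envelope[3]
  t <- time_grid - u
  idx <- which(abs(t) <= 3 * s)
  if (length(idx) < 3) stop("atom support does not intersect the time grid")
  E <- exp(-pi * (t[idx] / s)^2)
  th <- 2 * pi * f * t[idx]
  a <- E * cos(th); b <- E * sin(th)
  R <- residuals[idx, , drop = FALSE]
  cc <- drop(crossprod(a, R)); dd <- drop(crossprod(b, R))
  b11 <- sum(a^2); b22 <- sum(b^2); bab <- sum(a * b)
  a11 <- sum(cc^2); a22 <- sum(dd^2); acd <- sum(cc * dd)
  sol <- rayleigh_max2x2(a11, -acd, a22, b11, -bab, b22)
  g <- a * cos(sol$phi) - b * sin(sol$phi)
  ng <- sqrt(sum(g^2))
  if (ng == 0) return(list(phi = 0, weights = rep(0, ncol(residuals)),
                           criterion = 0))
  w <- drop(crossprod(g / ng, R))
  list(phi = sol$phi %% (2 * pi), weights = w, criterion = sum(w^2))
}

# largest generalized eigenvalue of the symmetric 2x2 pencil (A, B) and the
# angle of its eigenvector (cos phi, sin phi)
rayleigh_max2x2 <- function(a11, a12, a22, b11, b12, b22) {
  sb <- max(b11, b22)
  if (sb <= 0) return(list(lambda = 0, phi = 0))
  p <- b11 * b22 - b12^2
  if (p <= 1e-12 * sb^2)
    return(list(lambda = if (b11 > 0) a11 / b11 else 0, phi = 0))
  q <- a11 * b22 + a22 * b11 - 2 * a12 * b12
  r <- a11 * a22 - a12^2
  lam <- (q + sqrt(max(q^2 - 4 * p * r, 0))) / (2 * p)
  m11 <- a11 - lam * b11; m12 <- a12 - lam * b12; m22 <- a22 - lam * b22
  if (m11^2 + m12^2 >= m12^2 + m22^2) v <- c(-m12, m11) else v <- c(-m22, m12)
  if (all(v == 0)) v <- c(1, 0)
  list(lambda = lam, phi = atan2(v[2], v[1]))
}
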