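#' Spatial gradient of spindle frequencies
#'
#' Treats the dipole locations of detected spindles and their frequencies
#' as a sparsely sampled scalar field and estimates its mean gradient by
#' ordinary least squares on the linear model
#' `f(x, y, z) = j x + k y + l z + c` (frequency in Hz, coordinates in mm).
#' The gradient vector `(j, k, l)` is normalized to unit length; positions
#' are then projected on that direction and the Spearman correlation between
#' the projected coordinate and frequency is computed, along with the
#' per-axis correlations.
#'
#' @param positions n x 3 matrix of dipole locations (mm)
#' @param freqs spindle frequencies (Hz)
#' @return `gradient_fit`: coefficients `j`, `k`, `l` (Hz/mm), intercept
#'   `c` (Hz), `unit_gradient`, `magnitude` (Hz/mm), per-direction Spearman
#'   `rho`/`p` (x, y, z, gradient), `degenerate` flag for a zero gradient
#' @export
fit_gradient <- function(positions, freqs) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) == length(freqs))
  if (nrow(positions) < 4) stop("at least 4 spindles are required")
  df <- data.frame(f = freqs, x = positions[, 1], y = positions[, 2],
                   z = positions[, 3])
  fit <- stats::lm(f ~ x + y + z, data = df)
  if (fit$rank < 4)
    stop("degenerate-geometry error: dipole locations are rank deficient")
  co <- stats::coef(fit)
  grad <- unname(co[c("x", "y", "z")])
  mag <- sqrt(sum(grad^2))
  degenerate <- mag < 1e-12
  unit <- if (degenerate) c(NA_real_, NA_real_, NA_real_) else grad / mag
  cors <- list(
    x = project_and_correlate(positions, freqs, c(1, 0, 0)),
    y = project_and_correlate(positions, freqs, c(0, 1, 0)),
    z = project_and_correlate(positions, freqs, c(0, 0, 1)),
    gradient = if (degenerate) list(rho = NA_real_, p = NA_real_)
               else project_and_correlate(positions, freqs, unit))
  structure(list(j = unname(co["x"]), k = unname(co["y"]),
                 l = unname(co["z"]), c = unname(co["(Intercept)"]),
                 unit_gradient = unit, magnitude = mag,
                 correlations = cors, degenerate = degenerate,
                 n = length(freqs)),
            class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("frequency gradient: (%.4g, %.4g, %.4g) Hz/mm, |grad| = %.4g\n",
              x$j, x$k, x$l, x$magnitude))
  if (!x$degenerate)
    cat(sprintf("  along gradient: Spearman rho = %.3f (p = %.3g, n = %d)\n",
                x$correlations$gradient$rho, x$correlations$gradient$p, x$n))
  invisible(x)
}

#' Project positions on a direction and correlate with frequency
#'
#' The dot product of each dipole location with a unit direction yields a
#' positional coordinate; the Spearman rank correlation between that
#' coordinate and spindle frequency is returned with its two-sided p-value
#' (ties handled by average ranks).
#'
#' @param positions n x 3 matrix (mm)
#' @param freqs frequencies (Hz)
#' @param direction unit 3-vector
#' @return list with `rho` and `p`
#' @export
project_and_correlate <- function(positions, freqs, direction) {
  direction <- as.numeric(direction)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-6)
    stop("direction must have unit norm")
  coord <- drop(as.matrix(positions) %*% direction)
  ct <- suppressWarnings(stats::cor.test(coord, freqs, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Per-subject gradient fits and their average direction
#'
#' @param catalog data frame with `x`, `y`, `z`, `f` and a `subject` column
#' @return list with `per_subject` (data frame of j, k, l, rho, p along the
#'   gradient) and `average_unit_gradient` (vector average of the
#'   per-subject unit gradients, renormalized)
#' @export
gradient_by_subject <- function(catalog) {
  stopifnot(all(c("x", "y", "z", "f", "subject") %in% names(catalog)))
  subs <- split(catalog, catalog$subject)
  rows <- lapply(names(subs), function(sb) {
    d <- subs[[sb]]
    if (nrow(d) < 4) return(NULL)
    g <- tryCatch(fit_gradient(as.matrix(d[, c("x", "y", "z")]), d$f),
                  error = function(e) NULL)
    if (is.null(g) || g$degenerate) return(NULL)
    data.frame(subject = sb, j = g$j, k = g$k, l = g$l,
               ux = g$unit_gradient[1], uy = g$unit_gradient[2],
               uz = g$unit_gradient[3],
               rho = g$correlations$gradient$rho,
               p = g$correlations$gradient$p, n = g$n)
  })
  per <- do.call(rbind, rows)
  avg <- NULL
  if (!is.null(per) && nrow(per) > 0) {
    v <- colMeans(per[, c("ux", "uy", "uz")])
    avg <- v / sqrt(sum(v^2))
  }
  list(per_subject = per, average_unit_gradient = avg)
}
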