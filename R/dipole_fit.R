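#' Fit a single equivalent current dipole to a scalp topography
#'
#' Finds the dipole location minimizing the residual between an
#' average-referenced topography and the forward solution, with the moment
#' solved linearly (least squares on the 3-column gain matrix) at every
#' candidate location. The nonlinear search over location runs Nelder-Mead
#' from a fixed lattice of deterministic start points inside the brain
#' compartment; no randomness is involved.
#'
#' @param topography per-electrode weights (signal units); re-referenced to
#'   the average internally
#' @param model a `head_model`
#' @param n_starts number of deterministic multistart locations (default 10)
#' @return list with `location` (mm), `moment` (nAm), `gof` (percent of
#'   topography energy explained), `direction_angles` (azimuth, inclination
#'   of the unit moment, rad) and `current_density` (moment magnitude, nAm)
#' @export
fit_dipole <- function(topography, model, n_starts = 10) {
  topo <- as.numeric(topography)
  if (length(topo) < 5) stop("at least 5 electrodes are required")
  topo <- topo - mean(topo)
  e0 <- sum(topo^2)
  if (e0 <= 0) stop("undefined-fit error: all-zero topography")
  if (model$kind == "table") return(fit_dipole_table(topo, model))

  elec <- as.matrix(model$electrodes[, c("x", "y", "z")])
  elec <- sweep(elec, 2, model$center)
  rmax <- 0.97 * model$brain_radius
  H <- diag(length(topo)) - 1 / length(topo)   # average-reference projector

  resid_at <- function(loc) {
    r <- sqrt(sum(loc^2))
    if (r >= rmax) {
      # pull back to the admissible ball, penalized
      return(e0 * (1 + (r - rmax)^2))
    }
    G <- H %*% gain_matrix_sphere(model, loc, elec)
    fit <- stats::lm.fit(G, topo)
    sum(fit$residuals^2)
  }
  starts <- dipole_start_lattice(n_starts, model$brain_radius)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- stats::optim(starts[i, ], resid_at, method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-9))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  loc <- best$par
  r <- sqrt(sum(loc^2))
  if (r >= rmax) loc <- loc * (rmax - 1e-6) / r
  G <- H %*% gain_matrix_sphere(model, loc, elec)
  fit <- stats::lm.fit(G, topo)
  m <- fit$coefficients
  m[is.na(m)] <- 0
  res <- sum((topo - drop(G %*% m))^2)
  gof <- 100 * max(0, 1 - res / e0)
  mn <- sqrt(sum(m^2))
  ang <- if (mn > 0) c(azimuth = atan2(m[2], m[1]),
                       inclination = acos(min(max(m[3] / mn, -1), 1)))
         else c(azimuth = NA_real_, inclination = NA_real_)
  list(location = as.numeric(loc + model$center), moment = as.numeric(m),
       gof = gof, direction_angles = ang, current_density = mn)
}

# fixed lattice of start locations: two rings plus two midline points
dipole_start_lattice <- function(n_starts, brain_radius) {
  r1 <- 0.55 * brain_radius
  az <- seq(0, 2 * pi, length.out = 9)[1:8]
  ring <- cbind(r1 * cos(az), r1 * sin(az), 0.35 * brain_radius)
  pts <- rbind(ring,
               c(0, 0, 0.15 * brain_radius),
               c(0, 0, 0.75 * brain_radius),
               c(0, 0.5 * brain_radius, -0.2 * brain_radius),
               c(0, -0.5 * brain_radius, -0.2 * brain_radius))
  pts[seq_len(min(n_starts, nrow(pts))), , drop = FALSE]
}

# discrete search over the lead-field grid for table models
fit_dipole_table <- function(topo, model) {
  H <- diag(length(topo)) - 1 / length(topo)
  e0 <- sum(topo^2)
  best <- list(res = Inf)
  for (i in seq_len(nrow(model$grid))) {
    G <- H %*% model$gain[, , i]
    fit <- stats::lm.fit(G, topo)
    res <- sum(fit$residuals^2)
    if (res < best$res) best <- list(res = res, i = i, m = fit$coefficients)
  }
  m <- best$m; m[is.na(m)] <- 0
  mn <- sqrt(sum(m^2))
  list(location = as.numeric(model$grid[best$i, ]), moment = as.numeric(m),
       gof = 100 * max(0, 1 - best$res / e0),
       direction_angles = c(azimuth = atan2(m[2], m[1]),
                            inclination = acos(min(max(
                              if (mn > 0) m[3] / mn else 0, -1), 1))),
       current_density = mn)
}

#' Distance from a point to the nearest cortical point
#'
#' @param location query position (mm), or an n x 3 matrix of positions
#' @param cortex_points n x 3 matrix of cortical point coordinates (mm)
#' @return minimum Euclidean distance(s), mm
#' @export
distance_to_cortex <- function(location, cortex_points) {
  cortex_points <- as.matrix(cortex_points)
  if (nrow(cortex_points) == 0)
    stop("configuration error: empty cortex point set")
  loc <- matrix(as.numeric(location), ncol = 3)
  apply(loc, 1, function(p)
    sqrt(min(rowSums(sweep(cortex_points, 2, p)^2))))
}

#' Synthetic cortical point cloud
#'
#' Deterministic stand-in for a cortical surface sampling: Fibonacci
#' lattices on concentric shells spanning the depth range occupied by cortex
#' in the spherical brain compartment. It is generated in code (no atlas
#' data) and is intended only to make the distance-to-cortex criterion
#' operational; supply a real surface sampling for anatomical work.
#'
#' @param model a `head_model` (sets the outer shell at 93% of the brain
#'   radius and the centre), or NULL for the default geometry
#' @param radii shell radii in mm (default `seq(35, 75, by = 8)` scaled to
#'   the brain radius when a model is given)
#' @param n_per_shell points per shell (default 400)
#' @return n x 3 matrix of points (mm)
#' @export
synthetic_cortex_points <- function(model = NULL, radii = NULL,
                                    n_per_shell = 400) {
  center <- c(0, 0, 0)
  if (!is.null(model)) center <- model$center
  if (is.null(radii)) {
    # effective brain radius: innermost shell, or the standard ~88% of the
    # scalp sphere for single-shell (homogeneous) models
    eff <- if (is.null(model)) 81
           else if (model$kind == "sphere" && length(model$radii) == 1)
             0.88 * model$radii[1]
           else model$brain_radius
    radii <- seq(35, 75, by = 8) * eff / 81
  }
  golden <- pi * (3 - sqrt(5))
  pts <- lapply(radii, function(r) {
    i <- seq_len(n_per_shell) - 0.5
    z <- 1 - 2 * i / n_per_shell
    rho <- sqrt(pmax(1 - z^2, 0))
    th <- golden * i
    r * cbind(rho * cos(th), rho * sin(th), z)
  })
  sweep(do.call(rbind, pts), 2, -center)
}

#' Fit dipoles to every atom of a decomposition ("MP-dip" second stage)
#'
#' Extends each Gabor atom with the parameters of the equivalent current
#' dipole fitted to its scalp weight vector: location, moment, direction
#' angles, goodness of fit and distance to the nearest cortical point.
#' Per-atom failures (e.g. all-zero weights) are flagged, not fatal.
#'
#' @param book an `atom_book` or catalog data frame with `w_` columns
#' @param model a `head_model`
#' @param cortex_points n x 3 matrix (default [synthetic_cortex_points])
#' @param rows which atoms to fit (default all); unfitted rows carry NA
#'   dipole columns and `fit_ok = NA`
#' @return `dipole_atoms` data frame: the input columns plus `x`, `y`, `z`
#'   (mm), `mx`, `my`, `mz` (nAm), `gof` (percent), `dtc` (mm), `azimuth`,
#'   `inclination` (rad), `current_density` (nAm), `fit_ok`, `fit_error`
#' @export
mp_dip <- function(book, model, cortex_points = NULL,
                   rows = seq_len(nrow(book))) {
  if (is.null(cortex_points)) cortex_points <- synthetic_cortex_points(model)
  W <- atom_weights(book)
  n <- nrow(book)
  out <- as.data.frame(book)
  out$x <- out$y <- out$z <- out$mx <- out$my <- out$mz <- NA_real_
  out$gof <- out$dtc <- out$azimuth <- out$inclination <- NA_real_
  out$current_density <- NA_real_
  out$fit_ok <- NA
  out$fit_error <- NA_character_
  for (i in rows) {
    fit <- tryCatch(fit_dipole(W[i, ], model), error = function(e) e)
    if (inherits(fit, "error")) {
      out$fit_ok[i] <- FALSE
      out$fit_error[i] <- conditionMessage(fit)
      next
    }
    out$x[i] <- fit$location[1]; out$y[i] <- fit$location[2]
    out$z[i] <- fit$location[3]
    out$mx[i] <- fit$moment[1]; out$my[i] <- fit$moment[2]
    out$mz[i] <- fit$moment[3]
    out$gof[i] <- fit$gof
    out$azimuth[i] <- fit$direction_angles[1]
    out$inclination[i] <- fit$direction_angles[2]
    out$current_density[i] <- fit$current_density
    out$dtc[i] <- distance_to_cortex(fit$location, cortex_points)
    out$fit_ok[i] <- TRUE
  }
  for (a in c("fs", "epoch_length", "channel_names"))
    attr(out, a) <- attr(book, a)
  class(out) <- c("dipole_atoms", "data.frame")
  out
}
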