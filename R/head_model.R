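#' Canonical 10-20 electrode positions on a sphere
#'
#' Builds idealized 10-20 electrode coordinates by the classical arc
#' construction on a sphere: the circumferential ring lies 72 degrees from
#' the vertex with 36-degree azimuthal spacing, the midline and central
#' electrodes 36 degrees from the vertex, and F3/F4/P3/P4 midway (great
#' circle) between their midline and ring neighbours. Coordinates are
#' RAS-oriented (x right, y anterior, z superior), in mm, origin at the
#' sphere centre ("MNI-like").
#'
#' @param labels electrode subset to return; default the 19-channel 10-20
#'   set; `n_channels = 20` appends Oz
#' @param n_channels convenience: 19 or 20
#' @param radius scalp radius in mm (default 92)
#' @param center 3-vector added to all positions (mm)
#' @return data frame with `label`, `x`, `y`, `z` (mm)
#' @export
electrode_positions_1020 <- function(labels = NULL, n_channels = 19,
                                     radius = 92, center = c(0, 0, 0)) {
  base <- list(
    # label = c(inclination from vertex, azimuth from anterior, left positive)
    Fp1 = c(72, 18),   Fp2 = c(72, -18),
    F7  = c(72, 54),   F8  = c(72, -54),
    T3  = c(72, 90),   T4  = c(72, -90),
    T5  = c(72, 126),  T6  = c(72, -126),
    O1  = c(72, 162),  O2  = c(72, -162),
    Fpz = c(72, 0),    Oz  = c(72, 180),
    Fz  = c(36, 0),    Pz  = c(36, 180),
    Cz  = c(0, 0),
    C3  = c(36, 90),   C4  = c(36, -90))
  sph <- function(th, az) {
    th <- th * pi / 180; az <- az * pi / 180
    c(-sin(th) * sin(az), sin(th) * cos(az), cos(th))
  }
  pos <- lapply(base, function(p) sph(p[1], p[2]))
  slerp <- function(p, q) {
    m <- p + q
    m / sqrt(sum(m^2))
  }
  pos$F3 <- slerp(pos$Fz, pos$F7); pos$F4 <- slerp(pos$Fz, pos$F8)
  pos$P3 <- slerp(pos$Pz, pos$T5); pos$P4 <- slerp(pos$Pz, pos$T6)
  std19 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
             "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  if (is.null(labels)) {
    labels <- if (n_channels >= 20) c(std19, "Oz") else std19
    labels <- labels[seq_len(min(n_channels, length(labels)))]
    if (n_channels > length(labels))
      stop("at most ", length(c(std19, "Oz")), " canonical labels available")
  }
  missing <- setdiff(labels, names(pos))
  if (length(missing))
    stop("unknown electrode label(s): ", paste(missing, collapse = ", "))
  m <- t(vapply(pos[labels], identity, numeric(3))) * radius
  data.frame(label = labels, x = m[, 1] + center[1], y = m[, 2] + center[2],
             z = m[, 3] + center[3], stringsAsFactors = FALSE)
}

#' Three-shell spherical head model
#'
#' Analytic concentric-spheres volume conductor (brain, skull, scalp) with a
#' linear lead field mapping a current dipole to average-referenced scalp
#' potentials. The radial transfer coefficients are obtained per spherical
#' harmonic degree by solving the Laplace boundary-value problem (potential
#' and radial current continuity at the two interfaces, zero current through
#' the scalp) and are cached in the model object.
#'
#' @param radii shell radii in mm, innermost first (brain, skull, scalp);
#'   default `c(81, 86, 92)`. A single radius gives the classic homogeneous
#'   sphere.
#' @param conductivities shell conductivities in S/m; default
#'   `c(0.3, 0.006, 0.3)`, the customary BEM defaults of the common EEG
#'   forward-modeling toolchains (skull 1/50 of brain)
#' @param electrodes data frame as from [electrode_positions_1020]; default
#'   19-channel 10-20 set on the scalp shell
#' @param center sphere centre in mm (default origin)
#' @param n_terms series truncation order (default 100)
#' @return an object of class `head_model`
#' @export
head_model_sphere <- function(radii = c(81, 86, 92),
                              conductivities = c(0.3, 0.006, 0.3),
                              electrodes = NULL, center = c(0, 0, 0),
                              n_terms = 100) {
  stopifnot(length(radii) == length(conductivities), length(radii) >= 1,
            all(diff(radii) > 0), all(conductivities > 0))
  if (is.null(electrodes))
    electrodes <- electrode_positions_1020(radius = max(radii),
                                           center = center)
  gcoef <- shell_transfer_coefficients(radii / max(radii), conductivities,
                                       n_terms)
  model <- structure(list(kind = "sphere", radii = radii,
                          conductivities = conductivities,
                          center = as.numeric(center),
                          electrodes = electrodes,
                          brain_radius = radii[1],
                          n_terms = n_terms, gcoef = gcoef),
                     class = "head_model")
  model
}

# Radial transfer coefficients g_n for an N-shell sphere, in radii scaled to
# the outermost radius. Layer potentials V_k = A_k r^n + B_k r^-(n+1); the
# innermost layer carries the source term 1 * r^-(n+1). g_n is the scalp
# value of the transfer solution.
shell_transfer_coefficients <- function(rho, sigma, n_terms) {
  N <- length(rho)
  g <- numeric(n_terms)
  for (n in seq_len(n_terms)) {
    if (N == 1) {
      # homogeneous sphere, insulated boundary
      # A1 from sigma * (n A1 - (n+1) r^-(2n+1)) = 0 at r = 1
      A1 <- (n + 1) / n
      g[n] <- A1 + 1
      next
    }
    nun <- 2 * N - 1
    M <- matrix(0, nun, nun)
    rhs <- numeric(nun)
    # unknowns: A_1, A_2, B_2, ..., A_N, B_N
    row <- 0
    for (k in seq_len(N - 1)) {
      r <- rho[k]
      iA1 <- if (k == 1) 1 else 2 * k - 2
      iB1 <- if (k == 1) NA else 2 * k - 1
      iA2 <- 2 * k; iB2 <- 2 * k + 1
      # potential continuity at interface k
      row <- row + 1
      M[row, iA1] <- r^n
      if (!is.na(iB1)) M[row, iB1] <- r^(-n - 1)
      M[row, iA2] <- -r^n; M[row, iB2] <- -r^(-n - 1)
      if (k == 1) rhs[row] <- -r^(-n - 1)       # source B_1 = 1
      # radial current continuity
      row <- row + 1
      M[row, iA1] <- sigma[k] * n * r^(n - 1)
      if (!is.na(iB1)) M[row, iB1] <- -sigma[k] * (n + 1) * r^(-n - 2)
      M[row, iA2] <- -sigma[k + 1] * n * r^(n - 1)
      M[row, iB2] <- sigma[k + 1] * (n + 1) * r^(-n - 2)
      if (k == 1) rhs[row] <- sigma[1] * (n + 1) * r^(-n - 2)
    }
    # insulated outer boundary at r = 1
    row <- row + 1
    M[row, 2 * N - 2] <- n
    M[row, 2 * N - 1] <- -(n + 1)
    sol <- solve(M, rhs)
    g[n] <- sol[2 * N - 2] + sol[2 * N - 1]
  }
  g
}

#' Forward solution: dipole to average-referenced scalp potentials
#'
#' @param model a `head_model`
#' @param location dipole position (mm, model frame)
#' @param moment dipole moment (nAm, 3-vector)
#' @return named vector of potentials in microvolts, average-referenced
#' @export
forward_potentials <- function(model, location, moment) {
  UseMethod("forward_potentials")
}

#' @export
forward_potentials.head_model <- function(model, location, moment) {
  if (model$kind == "table") return(forward_table(model, location, moment))
  loc <- as.numeric(location) - model$center
  q <- as.numeric(moment)
  rq <- sqrt(sum(loc^2))
  if (rq >= model$brain_radius)
    stop("geometry error: dipole outside the innermost shell")
  elec <- as.matrix(model$electrodes[, c("x", "y", "z")])
  elec <- sweep(elec, 2, model$center)
  G <- gain_matrix_sphere(model, loc, elec)
  v <- drop(G %*% q)
  names(v) <- model$electrodes$label
  v - mean(v)
}

# n_elec x 3 gain (uV per nAm) at one source location (centred coordinates,
# mm), before average referencing
gain_matrix_sphere <- function(model, loc, elec) {
  R <- max(model$radii) * 1e-3                       # scalp radius, m
  rq <- sqrt(sum(loc^2))
  ne <- nrow(elec)
  nmax <- model$n_terms
  er <- elec / sqrt(rowSums(elec^2))                  # unit electrode dirs
  if (rq < 1e-9) {
    # central dipole: only the n = 1 term survives; field along q
    # V = g_1 /(4 pi sigma1 R^2) * (q . e_r)
    k <- model$gcoef[1] / (4 * pi * model$conductivities[1] * R^2)
    G <- k * er
  } else {
    rqh <- loc / rq
    ca <- pmin(pmax(drop(er %*% rqh), -1), 1)         # cos(alpha) per elec
    tv <- er - outer(ca, rqh)                         # tangential component
    tn <- sqrt(rowSums(tv^2))
    th <- tv / ifelse(tn > 1e-12, tn, 1)              # unit t-hat per elec
    th[tn <= 1e-12, ] <- 0
    ratio <- rq * 1e-3 / R
    # Legendre P_n(ca) and derivatives P_n'(ca) by recursion
    n <- seq_len(nmax)
    fac <- model$gcoef * ratio^(n - 1) / (4 * pi * model$conductivities[1] * R^2)
    # adaptive truncation: drop the geometric tail once negligible
    keep <- abs(fac) * n^2 > 1e-10 * max(abs(fac))
    nmax <- max(2, which(keep)[sum(keep)])
    Pm1 <- rep(1, ne); P <- ca                        # P_0, P_1
    dP <- rep(1, ne)                                  # P_1'
    sa <- sqrt(pmax(1 - ca^2, 0))
    radial <- fac[1] * 1 * P                          # n * P_n
    tang <- fac[1] * sa * dP                          # P_n^1 = sin * P_n'
    for (nn in 2:nmax) {
      Pn <- ((2 * nn - 1) * ca * P - (nn - 1) * Pm1) / nn
      dPn <- nn * P + ca * dP                         # P_n' via recursion
      Pm1 <- P; P <- Pn; dP <- dPn
      radial <- radial + fac[nn] * nn * Pn
      tang <- tang + fac[nn] * sa * dPn
    }
    G <- radial * matrix(rqh, ne, 3, byrow = TRUE) + tang * th
  }
  # q in nAm = 1e-9 Am, V -> uV factor 1e6
  G * 1e-3
}

#' Lead-field table head model
#'
#' Wraps a precomputed lead field (e.g. BEM-derived) as a drop-in for the
#' analytic model: a source grid with a 3-column gain block per grid point.
#'
#' @param grid data frame or matrix of source-grid coordinates (mm)
#' @param gain numeric array `n_electrodes x 3 x n_points` (uV per nAm),
#'   or matrix `n_electrodes x (3 * n_points)`
#' @param electrodes data frame with `label`, `x`, `y`, `z`
#' @return an object of class `head_model` (kind `"table"`)
#' @export
head_model_table <- function(grid, gain, electrodes) {
  grid <- as.matrix(grid)[, 1:3, drop = FALSE]
  if (length(dim(gain)) == 2)
    gain <- array(gain, c(nrow(gain), 3, ncol(gain) / 3))
  stopifnot(dim(gain)[3] == nrow(grid), dim(gain)[1] == nrow(electrodes))
  structure(list(kind = "table", grid = grid, gain = gain,
                 electrodes = electrodes, center = colMeans(grid),
                 brain_radius = max(sqrt(rowSums(
                   sweep(grid, 2, colMeans(grid))^2)))),
            class = "head_model")
}

forward_table <- function(model, location, moment) {
  d2 <- rowSums(sweep(model$grid, 2, as.numeric(location))^2)
  i <- which.min(d2)
  v <- drop(model$gain[, , i] %*% as.numeric(moment))
  names(v) <- model$electrodes$label
  v - mean(v)
}

#' Import a lead-field table from plain-text files
#'
#' @param gain_path whitespace/comma matrix file, `n_electrodes` rows and
#'   `3 * n_points` columns (x/y/z moment blocks per grid point)
#' @param grid_path CSV of source-grid coordinates with columns x, y, z (mm)
#' @param electrodes data frame with `label`, `x`, `y`, `z`
#' @return a `head_model` of kind `"table"`
#' @export
read_leadfield_table <- function(gain_path, grid_path, electrodes) {
  gain <- as.matrix(utils::read.csv(gain_path, header = FALSE))
  grid <- utils::read.csv(grid_path)
  head_model_table(grid, gain, electrodes)
}

#' @export
print.head_model <- function(x, ...) {
  if (x$kind == "sphere")
    cat(sprintf(paste0("3-shell spherical head model: radii %s mm, ",
                       "conductivities %s S/m, %d electrodes\n"),
                paste(x$radii, collapse = "/"),
                paste(signif(x$conductivities, 3), collapse = "/"),
                nrow(x$electrodes)))
  else
    cat(sprintf("lead-field table head model: %d grid points, %d electrodes\n",
                nrow(x$grid), nrow(x$electrodes)))
  invisible(x)
}
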