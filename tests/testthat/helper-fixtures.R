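# shared fixtures: everything is generated in code, no data files

fs_default <- 128

time_grid <- function(T, fs = fs_default) seq(0, by = 1 / fs,
                                              length.out = round(T * fs))

# a small 20-electrode head model reused across tests
test_head_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- head_model_sphere(
      electrodes = electrode_positions_1020(n_channels = 20))
    m
  }
})

# direct per-sample evaluation of the Gabor formula (independent oracle)
gabor_oracle <- function(u, f, s, phi, tt) {
  g <- exp(-pi * ((tt - u) / s)^2) * cos(2 * pi * f * (tt - u) + phi)
  g[abs(tt - u) > 3 * s] <- 0
  g / sqrt(sum(g^2))
}

# exhaustive phase grid oracle for the multichannel criterion
phase_grid_oracle <- function(residuals, u, f, s, tt, dphi = 1e-3) {
  phis <- seq(0, pi, by = dphi)
  crit <- vapply(phis, function(p) {
    g <- gabor_oracle(u, f, s, p, tt)
    sum(colSums(residuals * g)^2)
  }, numeric(1))
  k <- which.max(crit)
  list(phi = phis[k], criterion = crit[k])
}
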