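test_that("least-squares MVAR fit recovers a known stable MVAR(2)", {
  A <- array(0, c(2, 2, 2))
  A[1, , ] <- rbind(c(0.5, 0.1), c(-0.2, 0.4))
  A[2, , ] <- rbind(c(-0.3, 0.05), c(0.1, -0.2))
  truth <- mvar_model(A, diag(2))
  x <- gen_background(truth, 10000, seed = 4)
  fit <- fit_mvar(x, 2)
  expect_lt(max(abs(fit$A - A)), 0.05 * max(abs(A)))
  expect_equal(fit$Sigma, diag(2), tolerance = 0.1)
  expect_lt(fit$spectral_radius, 1)
})

test_that("white noise fits to near-zero coefficients", {
  set.seed(2)
  x <- matrix(rnorm(8000 * 3), ncol = 3)
  fit <- fit_mvar(x, 3)
  expect_lt(max(abs(fit$A)), 0.08)
  expect_equal(fit$Sigma, cov(x), tolerance = 0.05)
})

test_that("order-14 fit on 19 channels yields the full coefficient tensor", {
  bg <- builtin_mvar(19, 128)
  x <- gen_background(bg, 6000, seed = 9)
  fit <- fit_mvar(x, 14)
  expect_equal(dim(fit$A), c(14L, 19L, 19L))
  expect_lt(fit$spectral_radius, 1)
})

test_that("background generation is seeded and reproducible", {
  bg <- builtin_mvar(4, 128)
  x1 <- gen_background(bg, 1000, seed = 33)
  x2 <- gen_background(bg, 1000, seed = 33)
  expect_identical(x1, x2)
  x3 <- gen_background(bg, 1000, seed = 34)
  expect_false(identical(x1, x3))
  # same spectral shape across seeds (coarse band powers)
  bp <- function(x) {
    sp <- stats::spec.pgram(stats::ts(x[, 1], frequency = 128),
                            spans = 31, plot = FALSE)
    bands <- cut(sp$freq, c(0, 4, 8, 16, 32, 64))
    tapply(sp$spec, bands, mean)
  }
  r <- bp(x1) / bp(x3)
  expect_true(all(r > 0.5 & r < 2))
})

test_that("zero innovation covariance gives zero output", {
  bg <- builtin_mvar(3, 128)
  bg$Sigma <- bg$Sigma * 0
  x <- gen_background(bg, 500, seed = 1)
  expect_equal(max(abs(x)), 0)
})

test_that("unstable models are refused", {
  A <- array(0, c(1, 2, 2)); A[1, , ] <- diag(2) * 1.05
  expect_error(gen_background(mvar_model(A, diag(2)), 100),
               "stability")
  set.seed(6)
  x <- gen_background(mvar_model(array(diag(2) * 0.9, c(1, 2, 2)),
                                 diag(2)), 400, seed = 2)
  expect_error(fit_mvar(x[1:100, ], 14), "few samples")
})

test_that("simulated dataset matches its manifest exactly (linear mixing)", {
  m <- test_head_model()
  cfg <- sim_config(n_epochs = 3, n_spindles = 9, seed = 5)
  sim <- simulate_dataset(cfg, m)
  expect_equal(nrow(sim$manifest), 9)
  expect_equal(length(sim$epochs$epochs), 3)
  tt <- epoch_times(sim$epochs)
  for (ep in 1:3) {
    ev <- sim$manifest[sim$manifest$epoch == ep, ]
    contrib <- Reduce(`+`, lapply(seq_len(nrow(ev)), function(i) {
      topo <- forward_potentials(m, c(ev$src_x[i], ev$src_y[i], ev$src_z[i]),
                                 ev$amp_nAm[i] *
                                   c(ev$ori_x[i], ev$ori_y[i], ev$ori_z[i]))
      outer(exp(-pi * ((tt - ev$u[i]) / ev$s[i])^2) *
              cos(2 * pi * ev$f[i] * (tt - ev$u[i]) + ev$phi[i]),
            as.numeric(topo))
    }))
    expect_lt(max(abs(sim$epochs$epochs[[ep]] - sim$background[[ep]] -
                        contrib)), 1e-10)
  }
  # events stay inside the guard margin and separated
  expect_true(all(sim$manifest$u >= cfg$guard_s - 1e-9))
  expect_true(all(sim$manifest$u <= cfg$epoch_length - cfg$guard_s + 1e-9))
})

test_that("a fixed seed reproduces the manifest byte for byte", {
  m <- test_head_model()
  cfg <- sim_config(n_epochs = 2, n_spindles = 6, seed = 17)
  s1 <- simulate_dataset(cfg, m)
  s2 <- simulate_dataset(cfg, m)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$epochs$epochs, s2$epochs$epochs)
})

test_that("without background the decomposition recovers the spindle", {
  m <- test_head_model()
  cfg <- sim_config(n_epochs = 1, n_spindles = 1, bg_rms_uV = 0, seed = 3)
  sim <- simulate_dataset(cfg, m)
  ev <- sim$manifest[1, ]
  book <- mmp_decompose(sim$epochs$epochs[[1]],
                        dictionary_spec(n_iterations = 1), fs = 128)
  expect_lt(abs(book$f[1] - ev$f), 0.01)
  expect_lt(abs(book$u[1] - ev$u), 0.005)
})

test_that("manifest SNR equals an independent windowed evaluation", {
  m <- test_head_model()
  cfg <- sim_config(n_epochs = 2, n_spindles = 4, seed = 21)
  sim <- simulate_dataset(cfg, m)
  tt <- epoch_times(sim$epochs)
  ev <- sim$manifest[2, ]
  topo <- forward_potentials(m, c(ev$src_x, ev$src_y, ev$src_z),
                             ev$amp_nAm * c(ev$ori_x, ev$ori_y, ev$ori_z))
  ch <- which.max(abs(topo))
  wave <- exp(-pi * ((tt - ev$u) / ev$s)^2) *
    cos(2 * pi * ev$f * (tt - ev$u) + ev$phi)
  win <- which(tt >= ev$u - ev$s & tt <= ev$u + ev$s)
  bg <- sim$epochs$epochs[[ev$epoch]][win, ch] - topo[[ch]] * wave[win]
  oracle <- 10 * log10(topo[[ch]]^2 * sum(wave^2) / sum(bg^2))
  expect_equal(ev$snr_db, oracle, tolerance = 1e-9)
})
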