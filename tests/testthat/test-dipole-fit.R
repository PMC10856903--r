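test_that("noiseless forward fields are recovered exactly", {
  m <- test_head_model()
  cases <- list(list(loc = c(22, -31, 44), q = c(40, 70, -30)),
                list(loc = c(-30, 10, 25), q = c(-80, 20, 50)),
                list(loc = c(0, 50, 45), q = c(10, -60, 90)))
  for (cs in cases) {
    topo <- forward_potentials(m, cs$loc, cs$q)
    fit <- fit_dipole(topo, m)
    expect_lt(sqrt(sum((fit$location - cs$loc)^2)), 1)
    expect_gte(fit$gof, 99.9)
    expect_equal(fit$moment, cs$q, tolerance = 0.01)
    expect_equal(fit$current_density, sqrt(sum(cs$q^2)), tolerance = 0.01)
  }
})

test_that("gof reflects a constructed orthogonal perturbation", {
  m <- test_head_model()
  loc <- c(20, -25, 40); q <- c(50, 30, -40)
  topo <- forward_potentials(m, loc, q)
  # perturbation orthogonal to the 3-column gain space at the true location
  elec <- as.matrix(m$electrodes[, c("x", "y", "z")])
  H <- diag(20) - 1 / 20
  G <- H %*% mpdip:::gain_matrix_sphere(m, loc, elec)
  set.seed(9)
  w <- rnorm(20); w <- w - mean(w)
  w <- w - G %*% qr.solve(G, w)                 # project out the gain space
  for (r in c(0.05, 0.2)) {
    pert <- drop(w) * sqrt(r / (1 - r) * sum(topo^2) / sum(w^2))
    fit <- fit_dipole(topo + pert, m)
    expect_equal(fit$gof, 100 * (1 - r), tolerance = 1)
  }
})

test_that("nonlinear fit is at least as good as a brute-force grid", {
  m <- test_head_model()
  topo <- forward_potentials(m, c(28, 12, 38), c(-30, 60, 45))
  fit <- fit_dipole(topo, m)
  elec <- as.matrix(m$electrodes[, c("x", "y", "z")])
  H <- diag(20) - 1 / 20
  grid <- expand.grid(x = seq(-70, 70, by = 10), y = seq(-70, 70, by = 10),
                      z = seq(-70, 70, by = 10))
  grid <- grid[sqrt(rowSums(grid^2)) < 0.95 * m$brain_radius, ]
  # refine near the truth at 5 mm
  near <- expand.grid(x = seq(13, 43, by = 5), y = seq(-3, 27, by = 5),
                      z = seq(23, 53, by = 5))
  grid <- rbind(grid, near)
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    G <- H %*% mpdip:::gain_matrix_sphere(m, as.numeric(grid[i, ]), elec)
    best <- min(best, sum(stats::lm.fit(G, topo)$residuals^2))
  }
  res_fit <- (1 - fit$gof / 100) * sum(topo^2)
  expect_lte(res_fit, best + 1e-9 * sum(topo^2))
})

test_that("gof is invariant to scaling and location to sign flips", {
  m <- test_head_model()
  topo <- forward_potentials(m, c(25, 20, 35), c(40, -20, 60)) +
    c(rnorm(20, sd = 1))
  f1 <- fit_dipole(topo, m)
  f2 <- fit_dipole(topo * 37.5, m)
  f3 <- fit_dipole(-topo, m)
  expect_equal(f1$gof, f2$gof, tolerance = 1e-6)
  expect_equal(f1$location, f3$location, tolerance = 1e-3)
  expect_equal(f1$moment, -f3$moment, tolerance = 1e-3)
})

test_that("degenerate topographies raise errors", {
  m <- test_head_model()
  expect_error(fit_dipole(rep(0, 20), m), "all-zero")
  expect_error(fit_dipole(c(1, 2, 3), m), "5 electrodes")
})

test_that("distance to cortex equals the brute-force minimum", {
  expect_equal(distance_to_cortex(c(1, 2, 3), rbind(c(1, 2, 3))), 0)
  expect_equal(distance_to_cortex(c(0, 0, 0), rbind(c(10, 0, 0))), 10)
  set.seed(7)
  cloud <- matrix(rnorm(300 * 3, sd = 30), ncol = 3)
  for (i in 1:5) {
    p <- rnorm(3, sd = 30)
    expect_equal(distance_to_cortex(p, cloud),
                 min(sqrt(colSums((t(cloud) - p)^2))), tolerance = 1e-9)
  }
  expect_error(distance_to_cortex(c(0, 0, 0), cloud[0, , drop = FALSE]),
               "empty")
})

test_that("mp_dip fits a batch and routes per-atom failures", {
  m <- test_head_model()
  tt <- time_grid(4)
  topo <- forward_potentials(m, c(20, -30, 40), c(60, 30, -20))
  x <- outer(gabor_oracle(2, 13, 0.8, 0.4, tt), as.numeric(topo))
  book <- mmp_decompose(x, dictionary_spec(n_iterations = 3,
                                           s_range = c(0.2, 2)), fs = 128,
                        channel_names = m$electrodes$label)
  # zero out the weights of atom 2 to force an undefined fit
  wcols <- grep("^w_", names(book))
  book[2, wcols] <- 0
  datoms <- mp_dip(book, m, rows = 1:3)
  expect_equal(nrow(datoms), nrow(book))
  expect_true(datoms$fit_ok[1])
  expect_false(datoms$fit_ok[2])
  expect_match(datoms$fit_error[2], "zero")
  expect_gte(datoms$gof[1], 99.9)
  expect_lt(sqrt(sum((c(datoms$x[1], datoms$y[1], datoms$z[1]) -
                        c(20, -30, 40))^2)), 1.5)
  expect_gte(min(datoms$dtc[datoms$fit_ok %in% TRUE]), 0)
})
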