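test_that("a noiseless injected atom is recovered at iteration 1", {
  tt <- time_grid(20)
  g <- gabor_oracle(8, 13, 1, 0.5, tt)
  x <- outer(g, c(30, -15, 6))
  book <- mmp_decompose(x, dictionary_spec(n_iterations = 3), fs = 128)
  expect_lt(abs(book$f[1] - 13), 0.05)
  expect_lt(abs(book$u[1] - 8), 0.01)
  W <- atom_weights(book)
  expect_equal(unname(W[1, ]), c(30, -15, 6), tolerance = 0.01)
  res <- attr(book, "residual")
  expect_lt(sum(res^2) / sum(x^2), 1e-3)
})

test_that("parameter recovery is amplitude invariant", {
  tt <- time_grid(8)
  for (amp in c(0.01, 1, 1e4)) {
    x <- outer(gabor_oracle(3, 12, 0.8, 2.1, tt), c(1, 0.5)) * amp
    book <- mmp_decompose(x, dictionary_spec(n_iterations = 1,
                                             s_range = c(0.1, 4)), fs = 128)
    expect_lt(abs(book$f[1] - 12), 0.05)
    expect_lt(abs(book$u[1] - 3), 0.01)
  }
})

test_that("two disjoint atoms are recovered in the first two iterations", {
  tt <- time_grid(20)
  x <- outer(gabor_oracle(4, 12, 0.5, 0.3, tt), c(10, 5)) +
       outer(gabor_oracle(16, 9, 0.5, 4.0, tt), c(-6, 8))
  book <- mmp_decompose(x, dictionary_spec(n_iterations = 2), fs = 128)
  u_got <- sort(book$u[1:2])
  expect_equal(u_got, c(4, 16), tolerance = 0.02)
  f_got <- book$f[order(book$u[1:2])][1:2]
  expect_equal(sort(book$f[1:2]), c(9, 12), tolerance = 0.05)
  # the brute-force dictionary scan agrees on the first argmax
  scan <- scan_dictionary(x, 128, u_grid = seq(3, 17, by = 0.05),
                          f_grid = seq(8, 13, by = 0.1),
                          s_grid = c(0.4, 0.5, 0.6))
  expect_equal(scan$u, book$u[1], tolerance = 0.1)
  expect_equal(scan$f, book$f[1], tolerance = 0.2)
})

test_that("energy is conserved and reconstruction is exact", {
  set.seed(11)
  x <- matrix(rnorm(512 * 4), 512, 4)
  book <- mmp_decompose(x, dictionary_spec(n_iterations = 25,
                                           s_range = c(0.1, 2)), fs = 128)
  W <- atom_weights(book)
  res <- attr(book, "residual")
  # orthogonal-update identity
  expect_equal(sum(W^2) + sum(res^2), sum(x^2), tolerance = 1e-6 * sum(x^2))
  expect_true(all(book$criterion >= 0))
  # additive reconstruction: atoms + residual reproduce the input
  recon <- reconstruct_atoms(book) + res
  expect_lt(max(abs(recon - x)), 1e-8 * max(abs(x)))
})

test_that("residual energy is non-increasing across iterations", {
  set.seed(5)
  x <- matrix(rnorm(256 * 3), 256, 3)
  book <- mmp_decompose(x, dictionary_spec(n_iterations = 12,
                                           s_range = c(0.1, 1)), fs = 128)
  # energy removed at iteration n equals the criterion, all >= 0, so the
  # residual trajectory E0 - cumsum(criterion) is non-increasing
  resid_traj <- sum(x^2) - cumsum(book$criterion)
  expect_true(all(diff(resid_traj) <= 1e-12 * sum(x^2)))
  expect_gte(min(resid_traj), -1e-9 * sum(x^2))
})

test_that("engine matches a 10x denser brute-force grid on short epochs", {
  set.seed(21)
  fs <- 64
  tt <- time_grid(2, fs)
  x <- outer(gabor_oracle(0.9, 7.3, 0.45, 1.0, tt), c(2, -1)) +
    0.2 * matrix(rnorm(length(tt) * 2), ncol = 2)
  spec <- dictionary_spec(energy_error = 0.05, s_range = c(0.3, 0.6),
                          f_max = 10, n_iterations = 1)
  book <- mmp_decompose(x, spec, fs = fs)
  beta <- sqrt(-log(0.95) / pi)
  s_grid <- exp(seq(log(0.3), log(0.6), length.out = 12))
  best <- -Inf
  for (s in s_grid) {
    sc <- scan_dictionary(x, fs, u_grid = seq(0, 2, by = beta * s / 10),
                          f_grid = seq(0, 10, by = beta / s / 10),
                          s_grid = s)
    best <- max(best, sc$criterion)
  }
  expect_gte(book$criterion[1], (1 - 0.05) * best)
})

test_that("non-finite input errors out", {
  x <- matrix(0, 256, 2); x[5, 1] <- NA
  expect_error(mmp_decompose(x, dictionary_spec(n_iterations = 1), fs = 128),
               "non-finite")
})

test_that("energy density maps behave like a sum of 2-D Gaussians", {
  tt <- time_grid(8)
  x <- outer(gabor_oracle(4, 10, 0.8, 0.7, tt), c(1))
  book <- mmp_decompose(x, dictionary_spec(n_iterations = 1,
                                           s_range = c(0.2, 3)), fs = 128)
  tg <- seq(0, 8, length.out = 161)
  fg <- seq(0, 30, length.out = 301)
  map <- energy_density(book, 1, tg, fg)
  peak <- which(map == max(map), arr.ind = TRUE)
  expect_equal(tg[peak[1]], book$u[1], tolerance = 0.06)
  expect_equal(fg[peak[2]], book$f[1], tolerance = 0.11)
  # integral over the plane equals the squared weight (within quadrature)
  W <- atom_weights(book)
  integral <- sum(map) * diff(tg)[1] * diff(fg)[1]
  expect_equal(integral, sum(W[1, 1]^2), tolerance = 0.02 * sum(W[1, 1]^2))
  # no cross terms: two-atom map is the sum of single-atom maps
  book2 <- rbind(as.data.frame(book), as.data.frame(book))
  map2 <- energy_density(book2, 1, tg, fg)
  expect_equal(map2, 2 * map, tolerance = 1e-12)
  # quadratic in the weights: doubling weights scales the map by 4
  book4 <- book
  book4$w_ch1 <- book4$w_ch1 * 2
  expect_equal(energy_density(book4, 1, tg, fg), 4 * map, tolerance = 1e-12)
  expect_error(energy_density(book, 5, tg, fg), "out of range")
})
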