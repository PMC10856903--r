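# build a one-atom catalog with prescribed parameters (no decomposition)
fake_catalog <- function(u = 10, f = 13, s = 1, phi = 0, weights,
                         gof = 80, dtc = 5, fs = 128, epoch_length = 20,
                         labels = paste0("ch", seq_along(weights))) {
  df <- data.frame(iteration = 1, u = u, f = f, s = s, phi = phi,
                   criterion = sum(weights^2))
  for (i in seq_along(weights)) df[[paste0("w_", labels[i])]] <- weights[i]
  df$x <- 0; df$y <- 0; df$z <- 40
  df$gof <- gof; df$dtc <- dtc; df$fit_ok <- TRUE
  attr(df, "fs") <- fs; attr(df, "epoch_length") <- epoch_length
  attr(df, "channel_names") <- labels
  df
}

test_that("atom amplitude is peak-to-peak: 2 |w| K(gamma)", {
  tt <- time_grid(20)
  g <- make_gabor(gabor_params(10, 13, 1, 0.3), tt)
  K <- attr(g, "K")
  cat1 <- fake_catalog(weights = c(1))
  a <- atom_amplitude(cat1[1, ], fs = 128, epoch_length = 20)
  expect_equal(a$max, 2 * K, tolerance = 1e-9)
  cat2 <- fake_catalog(weights = c(10, -20))
  a2 <- atom_amplitude(cat2[1, ], fs = 128, epoch_length = 20)
  expect_equal(a2$channel_of_max, "ch2")
  expect_equal(a2$max, 40 * K, tolerance = 1e-9)
})

test_that("closed-form amplitude matches the reconstructed waveform", {
  tt <- time_grid(20)
  for (cs in list(c(13, 0.5), c(14.5, 3), c(11, 1))) {   # f * s >= 3
    f <- cs[1]; s <- cs[2]
    g <- make_gabor(gabor_params(10, f, s, 0.9), tt)
    w <- 17
    numeric_p2p <- max(w * g) - min(w * g)
    expect_equal(2 * abs(w) * attr(g, "K"), numeric_p2p,
                 tolerance = 0.01 * numeric_p2p)
  }
})

test_that("snr follows the windowed-ratio definition", {
  tt <- time_grid(20)
  g <- make_gabor(gabor_params(10, 13, 1, 0), tt)
  w <- 5
  win <- which(tt >= 9 & tt <= 11)
  # background crafted to carry exactly the atom energy within the window
  set.seed(3)
  bg <- rnorm(length(tt))
  bg <- bg * sqrt(w^2 / sum(bg[win]^2))
  epoch <- cbind(w * g + bg)
  cat1 <- fake_catalog(u = 10, f = 13, s = 1, weights = c(w))
  got <- snr_db(cat1[1, ], epoch, 1, fs = 128)
  expect_equal(as.numeric(got), 0, tolerance = 1e-6)
  # atom only: zero background energy -> +Inf sentinel
  got2 <- snr_db(cat1[1, ], cbind(w * g), 1, fs = 128)
  expect_identical(as.numeric(got2), Inf)
  # white background of known variance: independent windowed-sum oracle
  epoch3 <- cbind(w * g + bg * 3)
  oracle <- 10 * log10(w^2 / sum((3 * bg[win])^2))
  expect_equal(as.numeric(snr_db(cat1[1, ], epoch3, 1, fs = 128)), oracle,
               tolerance = 1e-9)
  # window clipped at the epoch edge is flagged
  cat_edge <- fake_catalog(u = 0.5, f = 13, s = 1, weights = c(w))
  expect_true(attr(snr_db(cat_edge[1, ], epoch, 1, fs = 128), "truncated"))
})

test_that("selection follows the criteria ranges with first-fail reasons", {
  tt <- time_grid(20)
  K <- attr(make_gabor(gabor_params(10, 13, 1, 0), tt), "K")
  w40 <- 40 / (2 * K)                       # 40 uV peak-to-peak
  ok <- fake_catalog(f = 13, s = 1, weights = c(w40), gof = 80, dtc = 5)
  sel <- select_spindles(ok, spindle_criteria())
  expect_equal(nrow(sel$accepted), 1)

  freq_bad <- fake_catalog(f = 10.5, s = 1, weights = c(w40))
  expect_equal(select_spindles(freq_bad, spindle_criteria())$reasons,
               "frequency")
  gof_bad <- fake_catalog(f = 13, s = 1, weights = c(w40), gof = 55)
  expect_equal(select_spindles(gof_bad, spindle_criteria())$reasons,
               "goodness_of_fit")
  amp_bad <- fake_catalog(weights = c(5 / (2 * K)))
  expect_equal(select_spindles(amp_bad, spindle_criteria())$reasons,
               "amplitude")
  dur_bad <- fake_catalog(s = 0.4, f = 13,
                          weights = c(40 / (2 * attr(make_gabor(
                            gabor_params(10, 13, 0.4, 0), tt), "K"))))
  expect_equal(select_spindles(dur_bad, spindle_criteria())$reasons,
               "duration")
  # 2 Hz * 2 s = 4 periods but f out of range first; periods: f=12, s=0.2?
  per_bad <- fake_catalog(f = 11.2, s = 0.25,
                          weights = c(40 / (2 * attr(make_gabor(
                            gabor_params(10, 11.2, 0.25, 0), tt), "K"))))
  # duration 0.25 < 0.5 fails before periods
  expect_equal(select_spindles(per_bad, spindle_criteria())$reasons,
               "duration")
  per_bad2 <- fake_catalog(f = 11, s = 0.26,
                           weights = c(40 / (2 * attr(make_gabor(
                             gabor_params(10, 11, 0.26, 0), tt), "K"))))
  crit_low_periods <- spindle_criteria(dur_range = c(0.2, 3.5))
  expect_equal(select_spindles(per_bad2, crit_low_periods)$reasons,
               "periods")
})

test_that("snr threshold keeps -6 dB and drops -8 dB atoms", {
  tt <- time_grid(20)
  g <- make_gabor(gabor_params(10, 13, 1, 0), tt)
  K <- attr(g, "K")
  w40 <- 40 / (2 * K)
  win <- which(tt >= 9 & tt <= 11)
  set.seed(8)
  base <- rnorm(length(tt)); base <- base / sqrt(sum(base[win]^2))
  crit <- spindle_criteria(snr_min_db = -7)
  for (case in list(c(-8, 0), c(-6, 1))) {
    bg <- base * sqrt(w40^2 / 10^(case[1] / 10))
    epoch <- cbind(w40 * g + bg)
    cat1 <- fake_catalog(weights = c(w40))
    sel <- select_spindles(cat1, crit, epoch = epoch)
    expect_equal(nrow(sel$accepted), case[2])
  }
})

test_that("selection is a pure idempotent filter and monotone in ranges", {
  tt <- time_grid(20)
  set.seed(12)
  n <- 40
  Ks <- numeric(n)
  rows <- lapply(1:n, function(i) {
    f <- runif(1, 9, 18); s <- runif(1, 0.3, 4)
    K <- attr(make_gabor(gabor_params(10, f, s, 0), tt), "K")
    fake_catalog(f = f, s = s, weights = c(runif(1, 5, 200) / (2 * K)),
                 gof = runif(1, 40, 100), dtc = runif(1, 0, 30))
  })
  cat_all <- do.call(rbind, rows)
  attr(cat_all, "fs") <- 128; attr(cat_all, "epoch_length") <- 20
  attr(cat_all, "channel_names") <- "ch1"
  sel <- select_spindles(cat_all, spindle_criteria())
  # subset of input, order preserved
  expect_true(all(sel$accepted$iteration %in% cat_all$iteration))
  expect_true(!is.unsorted(match(rownames(sel$accepted), rownames(cat_all))))
  # idempotent
  acc2 <- sel$accepted[, names(cat_all)]
  attr(acc2, "fs") <- 128; attr(acc2, "epoch_length") <- 20
  attr(acc2, "channel_names") <- "ch1"
  sel2 <- select_spindles(acc2, spindle_criteria())
  expect_equal(nrow(sel2$accepted), nrow(sel$accepted))
  # tightening any single range never increases the count
  base_n <- nrow(sel$accepted)
  tighter <- list(spindle_criteria(f_range = c(12, 15)),
                  spindle_criteria(amp_range = c(20, 100)),
                  spindle_criteria(dur_range = c(0.8, 2.5)),
                  spindle_criteria(gof_range = c(80, 100)),
                  spindle_criteria(dtc_range = c(0, 10)),
                  spindle_criteria(min_periods = 10))
  for (cr in tighter)
    expect_lte(nrow(select_spindles(cat_all, cr)$accepted), base_n)
})
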