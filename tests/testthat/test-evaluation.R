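iv <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(start = m[, 1], end = m[, 2])
}

test_that("interval matching covers the canonical cases", {
  refs <- iv(1, 2, 5, 6)
  m0 <- match_intervals(refs, refs)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(2, 0, 0))
  m1 <- match_intervals(iv(1.5, 2.5), refs)
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(1, 0, 1))
  m2 <- match_intervals(iv(numeric(0), numeric(0))[0, ], refs)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 0, 2))
  # annotations shorter than the minimum duration are rejected up front
  m3 <- match_intervals(iv(1, 2), iv(1, 1.3, 0.9, 2.1))
  expect_equal(m3$fn + m3$tp, 1)
})

test_that("unsorted interval lists are auto-sorted with a warning", {
  refs <- iv(1, 2, 5, 6)
  expect_warning(m <- match_intervals(iv(5.1, 6.1, 1.1, 2.1), refs),
                 "unsorted")
  expect_equal(m$tp, 2)
})

test_that("counts balance: tp + fn = refs, tp + fp = detections", {
  set.seed(14)
  for (rep in 1:20) {
    nd <- sample(0:8, 1); nr <- sample(0:8, 1)
    det <- data.frame(start = sort(runif(nd, 0, 30)))
    det$end <- det$start + runif(nd, 0.5, 2)
    ref <- data.frame(start = sort(runif(nr, 0, 30)))
    ref$end <- ref$start + runif(nr, 0.5, 2)
    m <- match_intervals(det, ref, min_overlap = 0.2)
    expect_equal(m$tp + m$fn, nrow(m$references))
    expect_equal(m$tp + m$fp, nrow(m$detections))
    expect_equal(sum(m$detection_label == "TP"), m$tp)
  }
})

test_that("greedy pairing equals brute-force optimal matching (<=10)", {
  # brute force: maximize pair count over all injective assignments
  brute_tp <- function(det, ref, min_overlap) {
    ov <- function(i, j) {
      o <- min(det$end[i], ref$end[j]) - max(det$start[i], ref$start[j])
      lm <- min(det$end[i] - det$start[i], ref$end[j] - ref$start[j])
      o > 0 && o / lm >= min_overlap
    }
    best <- 0
    rec <- function(i, used) {
      if (i > nrow(det)) { best <<- max(best, sum(used)); return() }
      rec(i + 1, used)
      for (j in which(!used)) if (ov(i, j)) {
        used[j] <- TRUE; rec(i + 1, used); used[j] <- FALSE
      }
    }
    if (nrow(det) == 0 || nrow(ref) == 0) return(0)
    rec(1, rep(FALSE, nrow(ref)))
    best
  }
  set.seed(31)
  for (rep in 1:25) {
    nd <- sample(1:6, 1); nr <- sample(1:6, 1)
    det <- data.frame(start = sort(runif(nd, 0, 12)))
    det$end <- det$start + runif(nd, 0.5, 3)
    ref <- data.frame(start = sort(runif(nr, 0, 12)))
    ref$end <- ref$start + runif(nr, 0.5, 3)
    mo <- runif(1, 0, 0.5)
    m <- match_intervals(det, ref, min_overlap = mo, min_duration = 0)
    expect_equal(m$tp, brute_tp(det, ref, mo))
  }
})

test_that("F1 follows 2TP/(2TP+FP+FN) with the zero convention", {
  expect_equal(f1_score(0, fp = 0, fn = 0), 0)
  expect_equal(f1_score(1, fp = 0, fn = 1), 2 / 3)
  refs <- iv(1, 2, 4, 5)
  expect_equal(f1_score(match_intervals(refs, refs)), 1)
})

test_that("F1 respects TP/FP monotonicity", {
  expect_gte(f1_score(3, fp = 2, fn = 1), f1_score(2, fp = 2, fn = 2))
  expect_lte(f1_score(3, fp = 3, fn = 1), f1_score(3, fp = 2, fn = 1))
})

test_that("the F1-vs-SNR sweep reduces to plain F1 and finds the knee", {
  refs <- iv(1, 2, 5, 6, 9, 10)
  det <- iv(1.2, 2.2, 5.1, 6.1, 20, 21, 25, 26)
  det$snr_db <- c(5, 3, -12, -15)      # the two FPs carry low SNR
  curve <- f1_vs_snr(det, refs, snr_grid = c(-20, -10, 0, 10))
  expect_equal(curve$f1[1],
               f1_score(match_intervals(det, refs)))   # -Inf-like threshold
  expect_equal(curve$f1[curve$threshold == 10], 0)     # everything dropped
  expect_equal(attr(curve, "best_threshold"), -10)
  # FPs filtered out: tp = 2, fp = 0, fn = 1 (one unmatched reference)
  expect_equal(max(curve$f1), 0.8)
})

test_that("parameter errors are zero for perfect detections", {
  m <- test_head_model()
  cfg <- sim_config(n_epochs = 2, n_spindles = 6, seed = 2)
  sim <- simulate_dataset(cfg, m)
  man <- sim$manifest
  catalog <- data.frame(epoch = man$epoch, u = man$u, f = man$f, s = man$s,
                        phi = man$phi, x = man$src_x, y = man$src_y,
                        z = man$src_z)
  # exact reconstruction weights on Fp1: w = A_fp1 / K
  tt <- epoch_times(sim$epochs)
  K <- vapply(seq_len(nrow(man)), function(i)
    attr(make_gabor(gabor_params(man$u[i], man$f[i], man$s[i],
                                 man$phi[i]), tt), "K"), numeric(1))
  catalog$w_Fp1 <- man$amp_fp1_uV / 2 / K
  pe <- param_errors(catalog, man, epoch_length = 20)
  expect_equal(pe$match$tp, 6)
  expect_lt(pe$summary$f_mean, 1e-12)
  expect_lt(pe$summary$u_mean, 1e-12)
  expect_lt(pe$summary$loc_mean, 1e-12)
  expect_lt(pe$summary$amp_mean, 1e-6)
})

test_that("location error is Euclidean", {
  man <- data.frame(event = 1, epoch = 1, u = 10, f = 14.5, s = 3, phi = 0,
                    src_x = 0, src_y = 0, src_z = 40, amp_fp1_uV = 0,
                    snr_db = -5)
  catalog <- data.frame(epoch = 1, u = 10, f = 14.5, s = 3, phi = 0,
                        x = 3, y = 4, z = 40, w_Fp1 = 0)
  pe <- param_errors(catalog, man, epoch_length = 20)
  expect_equal(pe$errors$dloc, 5, tolerance = 1e-12)
})

test_that("KS comparison flags tiny samples and detects shifts", {
  same <- ks_compare(1:20, 1:20)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(44)
  shifted <- ks_compare(rnorm(200), rnorm(200, mean = 1))
  expect_lt(shifted$p_value, 0.01)
  tiny <- ks_compare(c(1, 2, 3), rnorm(100))
  expect_true(tiny$excluded)
})
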