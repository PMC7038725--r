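test_that("the 20% rule flags against the last clean reference interval", {
  # 1000 vs 800 = +25% flags; the following 800 is compared to the clean 800
  expect_equal(detect_rr_artifacts(c(800, 800, 1000, 800)),
               c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(detect_rr_artifacts(c(800, 900)), c(FALSE, FALSE))   # 12.5%
  expect_equal(detect_rr_artifacts(c(800, 970)), c(FALSE, TRUE))    # 21.25%
  expect_warning(f <- detect_rr_artifacts(800), "fewer than 2")
  expect_equal(f, FALSE)
})

test_that("spline correction replaces only flagged intervals and stays in range", {
  rr <- c(800, 810, 820, 830, 840)
  expect_equal(correct_rr(rr, rep(FALSE, 5)), rr)   # identity without flags

  # interior flagged beat between linear-trend neighbours
  rr2 <- c(800, 810, 1200, 830, 840)
  fl2 <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  out <- correct_rr(rr2, fl2)
  expect_equal(out[-3], rr2[-3])
  expect_gt(out[3], 810); expect_lt(out[3], 830)
  # spline oracle on the same 5-point fixture
  oracle <- stats::spline(c(1, 2, 4, 5), c(800, 810, 830, 840), xout = 3,
                          method = "natural")$y
  expect_equal(out[3], oracle, tolerance = 1e-9)

  # flagged edge beats: nearest-valid extrapolation clamped to valid range
  rr3 <- c(2000, 800, 810, 820, 1900)
  fl3 <- c(TRUE, FALSE, FALSE, FALSE, TRUE)
  out3 <- correct_rr(rr3, fl3)
  expect_true(all(out3[c(1, 5)] >= 800 & out3[c(1, 5)] <= 820))

  expect_error(correct_rr(c(800, 900, 1000), c(TRUE, TRUE, FALSE)),
               "more than 50%")
})

test_that("re-detection after correction never flags more intervals", {
  withr::with_seed(5, {
    for (i in 1:20) {
      rr <- rnorm(60, 800, 30)
      rr[sample(2:60, 5)] <- rr[sample(2:60, 5)] * runif(5, 1.4, 1.9)
      fl <- detect_rr_artifacts(rr)
      if (mean(fl) > 0.5) next
      rr2 <- correct_rr(rr, fl)
      expect_lte(sum(detect_rr_artifacts(rr2)), sum(fl))
    }
  })
})

test_that("window rejection keeps exactly 10% flagged and drops above it", {
  expect_true(reject_window(rep(c(TRUE, FALSE), c(6, 54))))    # 6/60 = 10.0%
  expect_false(reject_window(rep(c(TRUE, FALSE), c(7, 53))))   # 11.7%
  expect_true(reject_window(rep(FALSE, 60)))
  expect_false(reject_window(logical(0)))
})

test_that("windowing is contiguous, half-open, and drops the trailing partial", {
  rec <- withr::with_seed(1, make_recording(360))
  w <- segment_windows(rec)
  expect_equal(nrow(w), 3)
  expect_equal(w$window_index, 0:2)
  expect_equal(w$t_start, c(0, 120, 240))

  rec2 <- withr::with_seed(1, make_recording(350))
  expect_equal(nrow(segment_windows(rec2)), 2)

  expect_warning(w0 <- segment_windows(withr::with_seed(1, make_recording(100))),
                 "shorter than one window")
  expect_equal(nrow(w0), 0)

  # beat at exactly 120.0 s belongs to window 1, not window 0
  rec3 <- withr::with_seed(1, make_recording(240))
  rec3$channels$ibi <- make_ibi(rep(0.75, 320))  # beat #160 at exactly 120.0
  w3 <- segment_windows(rec3)
  expect_equal(length(w3$rr_ms[[1]]), 159)
  expect_true(120 %in% w3$beat_t[[2]])
})

test_that("windowing conserves beats over the covered span", {
  rec <- withr::with_seed(3, {
    r <- make_recording(500, rr_s = 0.77)
    r
  })
  w <- segment_windows(rec)
  covered <- sum(vapply(w$rr_ms, length, integer(1)))
  ev <- rec$channels$ibi$events
  expect_equal(covered, sum(ev$offset_s >= 0 & ev$offset_s < max(w$t_end)))
})

test_that("EDA artifact screen needs a steep step AND motion, or a bounds breach", {
  still <- matrix(rep(c(0, 0, 64), each = 320), ncol = 3)
  moving <- still + matrix(rnorm(960, 0, 20), ncol = 3)
  flat <- rep(2, 40)                     # two 5 s epochs at 4 Hz
  stepped <- c(rep(2, 30), rep(4.5, 10)) # +2.5 µS step in epoch 2

  expect_equal(detect_eda_artifacts(flat, still), c(FALSE, FALSE))
  expect_equal(detect_eda_artifacts(stepped, still), c(FALSE, FALSE))   # no burst
  expect_equal(detect_eda_artifacts(stepped, moving), c(FALSE, TRUE))   # co-occurring
  expect_equal(detect_eda_artifacts(c(rep(2, 20), rep(0, 20)), still),
               c(FALSE, TRUE))          # 0.0 µS below the plausibility floor
  expect_warning(f <- detect_eda_artifacts(stepped, NULL), "EDA-only")
  expect_equal(f, c(FALSE, TRUE))
})

test_that("injected EDA step with motion burst is flagged by the screen", {
  rec <- withr::with_seed(8, make_recording(300, acc_noise = 0.5))
  out <- inject_artifacts(rec, sim_params(artifact_rate_rr = 0,
                                          artifact_rate_eda = 2), seed = 3)
  mask <- attr(out, "artifact_mask")$eda
  expect_gt(nrow(mask), 0)
  flags <- detect_eda_artifacts(out$channels$eda$values, out$channels$acc$values)
  hit_epochs <- unique(ceiling(mask$sample / 20))
  expect_true(all(flags[hit_epochs]))
})

test_that("tonic/phasic split reconstructs exactly and tracks injected pulses", {
  const <- rep(2.5, 480)
  d <- decompose_eda(const)
  expect_equal(d$tonic, const, tolerance = 1e-5)
  expect_equal(d$phasic, rep(0, 480), tolerance = 1e-5)

  # single SCR pulse on a flat tonic level
  prof <- state_profile(120, "relaxed")
  eda <- simulate_eda(prof, quiet_params(scr_rate_relaxed = 0), seed = 1)
  tt <- (seq_len(480) - 1) / 4
  pulse_t <- 60
  x <- eda$values + 0.6 * pmax(0, exp(-(tt - pulse_t) / 2) - exp(-(tt - pulse_t) / 0.75)) /
    max(exp(-(0:100 / 10) / 2) - exp(-(0:100 / 10) / 0.75))
  d2 <- decompose_eda(x)
  expect_equal(d2$tonic + d2$phasic, x, tolerance = 1e-10)   # exact reconstruction
  truth_peak <- which.max(x - mean(x[1:200]))
  expect_lte(abs(which.max(d2$phasic) - truth_peak), 1)      # within one sample
  expect_lt(mean(abs(diff(d2$tonic))), mean(abs(diff(x))))   # tonic is smoother

  expect_error(decompose_eda(rep(2, 100)), "at least 30 s")
})

test_that("artifact recovery on injected fixtures is exact: full recall, no false positives", {
  # constant 800 ms series with 5 isolated +60% jumps
  rr <- rep(800, 60)
  pos <- c(10, 20, 30, 40, 50)
  rr[pos] <- 800 * 1.6
  flags <- detect_rr_artifacts(rr)
  expect_equal(which(flags), pos)

  # generator-injected jumps (all factors beyond ±30%) on a clean recording
  rec <- withr::with_seed(4, make_recording(480))
  out <- inject_artifacts(rec, sim_params(artifact_rate_rr = 2,
                                          artifact_rate_eda = 0), seed = 17)
  mask <- attr(out, "artifact_mask")$rr_idx
  rr2 <- out$channels$ibi$events$rr_s * 1000
  flags2 <- detect_rr_artifacts(rr2)
  iso <- setdiff(mask, c(mask + 1, mask - 1))   # isolated injections
  expect_true(all(flags2[iso]))                 # recall 1.0 on isolated jumps
  expect_false(any(flags2[-mask]))              # zero false positives on clean beats
})
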