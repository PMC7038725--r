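test_that("degenerate constant RR series yields the textbook feature values", {
  f <- hrv_time_features(rep(800, 150))
  expect_equal(unname(f["mean_rr"]), 800)
  expect_equal(unname(f[c("sdnn", "rmssd", "pnn50", "sdsd", "tinn")]),
               rep(0, 5))
  expect_equal(unname(f["tri_index"]), 1)   # 150 beats / modal bin of 150
})

test_that("alternating 60 ms jumps give pNN50 of 100%", {
  rr <- rep(c(800, 860), 10)
  f <- hrv_time_features(rr)
  expect_equal(unname(f["pnn50"]), 100)
})

test_that("time-domain features match brute-force oracles to 1e-9", {
  withr::with_seed(11, {
    for (i in 1:5) {
      rr <- round(rnorm(20, 820, 45), 3)
      f <- hrv_time_features(rr)
      expect_equal(unname(f["mean_rr"]), sum(rr) / length(rr), tolerance = 1e-9)
      expect_equal(unname(f["sdnn"]), oracle_sd(rr), tolerance = 1e-9)
      expect_equal(unname(f["rmssd"]), oracle_rmssd(rr), tolerance = 1e-9)
      expect_equal(unname(f["pnn50"]), oracle_pnn50(rr), tolerance = 1e-9)
      expect_equal(unname(f["sdsd"]), oracle_sd(diff(rr)), tolerance = 1e-9)
    }
  })
})

test_that("triangular index equals beat count over the modal 1/128 s bin", {
  # 30 beats in one bin, 10 in another: modal count 30, index 40/30
  rr <- c(rep(800, 30), rep(900, 10))
  f <- hrv_time_features(rr)
  expect_equal(unname(f["tri_index"]), 40 / 30, tolerance = 1e-9)
  expect_gt(unname(f["tinn"]), 0)
  expect_warning(hrv_time_features(rep(800, 5)), "fewer than 10")
})

test_that("spectral band powers localise pure sinusoidal modulations", {
  tt <- seq(0, 180, by = 0.8)
  beat_t <- tt[-1]
  # HF modulation at 0.25 Hz
  rr_hf <- 800 + 50 * sin(2 * pi * 0.25 * beat_t)
  f <- hrv_freq_features(rr_hf, beat_t, t_start = 0.8, t_end = 180)
  expect_gt(unname(f["hf_power"]), 10 * unname(f["lf_power"]))
  bin <- 4 / length(seq(0.8, 180 - 0.25, by = 0.25))
  expect_lt(abs(unname(f["hf_peak"]) - 0.25), bin + 1e-9)

  # LF modulation at 0.10 Hz
  rr_lf <- 800 + 50 * sin(2 * pi * 0.10 * beat_t)
  g <- hrv_freq_features(rr_lf, beat_t, t_start = 0.8, t_end = 180)
  expect_gt(unname(g["lf_hf"]), 1)
  expect_lt(abs(unname(g["lf_peak"]) - 0.10), bin + 1e-9)
})

test_that("constant RR has zero band powers and a missing LF/HF ratio", {
  beat_t <- cumsum(rep(0.8, 150))
  f <- hrv_freq_features(rep(800, 150), beat_t, t_start = 0.8, t_end = 120)
  expect_equal(unname(f[c("vlf_power", "lf_power", "hf_power")]), rep(0, 3),
               tolerance = 1e-12)
  expect_true(is.na(f["lf_hf"]))
})

test_that("band powers integrate to the tachogram variance (Parseval)", {
  withr::with_seed(12, {
    beat_t <- cumsum(rep(0.8, 150))
    rr <- 800 + 30 * sin(2 * pi * 0.1 * beat_t) + rnorm(150, 0, 15)
    f <- hrv_freq_features(rr, beat_t, t_start = 0.8, t_end = 120)
    grid <- seq(0.8, 120 - 0.25, by = 0.25)
    x <- stats::splinefun(beat_t, rr, method = "natural")(grid)
    x <- x - mean(x)
    total <- oracle_band_power(x, 4, 0, 2.0001)
    expect_lt(abs(sum(f[c("vlf_power", "lf_power", "hf_power")]) +
                    oracle_band_power(x, 4, 0.4, 2.0001) - total) / total, 1e-9)
    expect_lt(abs(total - mean(x^2)) / mean(x^2), 0.05)
  })
})

test_that("EDA component features match oracles on small fixtures", {
  const <- rep(1.3, 200)
  f <- eda_component_features(const)
  expect_equal(unname(f["mean"]), 1.3)
  expect_equal(unname(f[c("sd", "n_peaks", "n_strong_peaks", "quart_dev")]),
               rep(0, 4))
  expect_equal(unname(f[c("p20", "p80")]), c(1.3, 1.3))

  x <- as.numeric(1:100)  # percentile oracle fixture (25 s at 4 Hz is enough)
  g <- eda_component_features(c(x, x[100:61]))
  xs <- c(x, x[100:61])
  expect_equal(unname(g["p20"]), oracle_percentile(xs, 0.2), tolerance = 1e-9)
  expect_equal(unname(g["p80"]), oracle_percentile(xs, 0.8), tolerance = 1e-9)
  expect_equal(unname(g["quart_dev"]),
               (oracle_percentile(xs, 0.75) - oracle_percentile(xs, 0.25)) / 2,
               tolerance = 1e-9)
})

test_that("SCR counting distinguishes weak and strong peaks by prominence", {
  tt <- (0:479) / 4
  pulse <- function(at, amp) amp * pmax(0, exp(-(tt - at) / 2) - exp(-(tt - at) / 0.75))
  x <- rep(0, 480) + pulse(20, 1) + pulse(60, 1) + pulse(100, 1)
  f <- eda_component_features(x)
  expect_equal(unname(f["n_peaks"]), 3)
  expect_equal(unname(f["n_strong_peaks"]), 3)

  weak <- rep(0, 480) + pulse(30, 0.05) + pulse(90, 0.05)
  g <- eda_component_features(weak)
  expect_equal(unname(g["n_peaks"]), 2)
  expect_equal(unname(g["n_strong_peaks"]), 0)
  expect_lte(unname(g["n_strong_peaks"]), unname(g["n_peaks"]))
})

test_that("window feature vectors have the full 27-name schema in stable order", {
  rec <- withr::with_seed(6, make_recording(240))
  win <- suppressWarnings(preprocess_recording(rec))
  v <- build_feature_vector(win[1, ])
  expect_equal(names(v), feature_schema())
  expect_equal(ncol(v), 27)
  expect_equal(sum(startsWith(names(v), "hrv_")), 13)
  expect_equal(sum(startsWith(names(v), "eda_phasic_")), 7)
  expect_equal(sum(startsWith(names(v), "eda_tonic_")), 7)
  v2 <- build_feature_vector(win[2, ])
  expect_identical(names(v), names(v2))
})

test_that("a fully artifact-flagged EDA window keeps HRV and drops EDA only", {
  rec <- withr::with_seed(6, make_recording(240))
  win <- suppressWarnings(preprocess_recording(rec))
  win$eda_epoch_flags[[1]] <- rep(TRUE, 24)
  v <- build_feature_vector(win[1, ])
  expect_true(all(is.na(v[feature_schema("eda")])))
  expect_false(anyNA(v[paste0("hrv_", c("mean_rr", "sdnn", "rmssd"))]))
})

test_that("session aggregation averages per feature and skips missing blocks", {
  w1 <- tibble::as_tibble(setNames(as.list(rep(1, 27)), feature_schema()))
  w2 <- w1
  w2$hrv_mean_rr <- 3
  agg <- aggregate_session(dplyr::bind_rows(w1, w2))
  expect_equal(agg$n_windows, 2)
  expect_equal(agg$hrv_mean_rr, 2)

  # idempotence on identical windows
  same <- dplyr::bind_rows(w1, w1, w1)
  expect_equal(aggregate_session(same)[, feature_schema()], w1)

  # hrv.mean_rr 700/900 -> 800; EDA missing in one window ignored per feature
  a <- w1; a$hrv_mean_rr <- 700
  b <- w1; b$hrv_mean_rr <- 900; b[feature_schema("eda")] <- NA_real_
  agg2 <- aggregate_session(dplyr::bind_rows(a, b))
  expect_equal(agg2$hrv_mean_rr, 800)
  expect_equal(agg2$eda_tonic_mean, 1)

  expect_message(out <- aggregate_session(w1[0, ]), "dropped")
  expect_null(out)
})

test_that("raising HF amplitude raises HF power and RMSSD in expectation", {
  prof <- state_profile(180, "relaxed")
  vals <- sapply(1:10, function(s) {
    lo <- simulate_ibi(prof, sim_params(hf_amp_relaxed = 10), seed = s)
    hi <- simulate_ibi(prof, sim_params(hf_amp_relaxed = 60), seed = s)
    f <- function(ibi) {
      rr <- ibi$events$rr_s * 1000
      c(hrv_freq_features(rr, ibi$events$offset_s)["hf_power"],
        hrv_time_features(rr)["rmssd"])
    }
    f(hi) - f(lo)
  })
  expect_gt(mean(vals["hf_power", ]), 0)
  expect_gt(mean(vals["rmssd", ]), 0)
  expect_gt(mean(vals["hf_power", ] > 0), 0.8)
})
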