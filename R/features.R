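#' Time-domain HRV features
#'
#' Seven features of the corrected RR series: mean RR, SDNN (sample SD),
#' RMSSD, pNN50 (% of successive differences exceeding 50 ms), the
#' triangular index (total beat count divided by the modal bin count of the
#' RR histogram on a 1/128 s grid), TINN (base width of the best
#' least-squares triangle fit to that histogram, ms) and SDSD (SD of
#' successive differences).
#'
#' @param rr_ms Corrected RR intervals (ms); at least 10.
#' @return Named numeric vector `mean_rr, sdnn, rmssd, pnn50, tri_index,
#'   tinn, sdsd`, or all-NA with a warning when too few intervals remain.
#' @export
hrv_time_features <- function(rr_ms) {
  out <- c(mean_rr = NA_real_, sdnn = NA_real_, rmssd = NA_real_,
           pnn50 = NA_real_, tri_index = NA_real_, tinn = NA_real_,
           sdsd = NA_real_)
  if (length(rr_ms) < 10) {
    warn("fewer than 10 RR intervals; time-domain HRV features dropped")
    return(out)
  }
  d <- diff(rr_ms)
  h <- rr_histogram(rr_ms)
  tri <- triangular_fit(h)
  out["mean_rr"] <- mean(rr_ms)
  out["sdnn"] <- sd(rr_ms)
  out["rmssd"] <- sqrt(mean(d^2))
  out["pnn50"] <- 100 * mean(abs(d) > 50)
  out["tri_index"] <- length(rr_ms) / max(h$counts)
  out["tinn"] <- tri$tinn
  out["sdsd"] <- sd(d)
  out
}

# Histogram of RR intervals on the standard 1/128 s (= 1000/128 ms) grid.
rr_histogram <- function(rr_ms) {
  bw <- 1000 / 128
  lo <- floor(min(rr_ms) / bw) * bw
  hi <- ceiling(max(rr_ms) / bw + 1e-9) * bw
  if (hi <= lo) hi <- lo + bw
  breaks <- seq(lo, hi, by = bw)
  counts <- tabulate(
    pmin(pmax(floor((rr_ms - lo) / bw) + 1, 1), length(breaks) - 1),
    nbins = length(breaks) - 1
  )
  list(mids = (head(breaks, -1) + tail(breaks, -1)) / 2, counts = counts, bw = bw)
}

# Best least-squares triangle over the RR histogram: apex fixed at the modal
# bin, base corners searched on the bin grid; ties -> narrowest triangle.
# TINN = base width (ms). A single-bin histogram degenerates to width 0.
triangular_fit <- function(h) {
  k <- which.max(h$counts)
  if (sum(h$counts > 0) <= 1) return(list(tinn = 0))
  mids <- h$mids
  y <- h$counts
  peak_x <- mids[k]
  peak_y <- y[k]
  best <- NULL
  for (i in seq_len(k)) {
    for (j in k:length(mids)) {
      if (i == j) next
      n_x <- mids[i] - h$bw / 2
      m_x <- mids[j] + h$bw / 2
      tri <- numeric(length(mids))
      left <- mids >= n_x & mids <= peak_x
      right <- mids > peak_x & mids <= m_x
      if (peak_x > n_x) tri[left] <- peak_y * (mids[left] - n_x) / (peak_x - n_x)
      if (m_x > peak_x) tri[right] <- peak_y * (m_x - mids[right]) / (m_x - peak_x)
      err <- sum((y - tri)^2)
      width <- m_x - n_x
      if (is.null(best) || err < best$err - 1e-12 ||
          (abs(err - best$err) <= 1e-12 && width < best$width)) {
        best <- list(err = err, width = width)
      }
    }
  }
  list(tinn = best$width)
}

#' Frequency-domain HRV features
#'
#' The RR tachogram is resampled at 4 Hz on the window grid by cubic
#' spline, mean-removed, and its FFT periodogram integrated (rectangle
#' rule, half-open bands) over VLF (0-0.04 Hz, DC excluded), LF
#' (0.04-0.15 Hz) and HF (0.15-0.4 Hz). Peaks are the frequencies of the
#' maximal spectral ordinate within each band. When HF power is zero the
#' LF/HF ratio is reported missing, never infinite.
#'
#' @param rr_ms Corrected RR intervals (ms).
#' @param beat_t Beat times (s) closing each interval.
#' @param t_start,t_end Window bounds (s); defaults span the beats.
#' @param fs Resampling rate (Hz).
#' @return Named vector `vlf_power, lf_power, hf_power, lf_hf, lf_peak,
#'   hf_peak` (powers in ms²).
#' @export
hrv_freq_features <- function(rr_ms, beat_t, t_start = NULL, t_end = NULL,
                              fs = 4) {
  out <- c(vlf_power = NA_real_, lf_power = NA_real_, hf_power = NA_real_,
           lf_hf = NA_real_, lf_peak = NA_real_, hf_peak = NA_real_)
  if (length(rr_ms) < 10 || length(beat_t) != length(rr_ms)) return(out)
  if (is.null(t_start)) t_start <- min(beat_t)
  if (is.null(t_end)) t_end <- max(beat_t)
  if (t_end - t_start < 60) return(out)
  grid <- seq(t_start, t_end - 1 / fs, by = 1 / fs)
  x <- splinefun(beat_t, rr_ms, method = "natural")(grid)
  x <- x - mean(x)
  n <- length(x)
  spec <- Mod(fft(x))^2
  k <- seq_len(floor(n / 2))             # one-sided, DC excluded
  freq <- k * fs / n
  psd <- 2 * spec[k + 1] / (fs * n)      # density; integral ~ variance
  if (n %% 2 == 0) psd[length(psd)] <- psd[length(psd)] / 2
  df <- fs / n
  band <- function(lo, hi) freq >= lo & freq < hi
  vlf <- band(0, 0.04); lf <- band(0.04, 0.15); hf <- band(0.15, 0.4)
  out["vlf_power"] <- sum(psd[vlf]) * df
  out["lf_power"] <- sum(psd[lf]) * df
  out["hf_power"] <- sum(psd[hf]) * df
  out["lf_hf"] <- if (out["hf_power"] > 0) out["lf_power"] / out["hf_power"] else NA_real_
  out["lf_peak"] <- if (any(lf) && out["lf_power"] > 0) freq[lf][which.max(psd[lf])] else NA_real_
  out["hf_peak"] <- if (any(hf) && out["hf_power"] > 0) freq[hf][which.max(psd[hf])] else NA_real_
  out
}

# Local maxima with topographic prominence (scipy-compatible definition)
# and a minimum separation enforced greedily from the highest peak down.
find_scr_peaks <- function(x, prominence, min_sep) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    lmin <- h
    j <- i - 1
    while (j >= 1 && x[j] <= h) { lmin <- min(lmin, x[j]); j <- j - 1 }
    rmin <- h
    j <- i + 1
    while (j <= n && x[j] <= h) { rmin <- min(rmin, x[j]); j <- j + 1 }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= prominence]
  if (length(keep) <= 1) return(keep)
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord) {
    if (!length(sel) || all(abs(sel - i) >= min_sep)) sel <- c(sel, i)
  }
  sort(sel)
}

#' EDA component features
#'
#' Seven features of one EDA component (phasic or tonic): mean, SD, number
#' of peaks (local maxima with prominence at least `peak_prom` and 1 s
#' minimum separation), number of strong peaks (prominence at least
#' `strong_prom`), 20th and 80th percentiles (linear interpolation), and
#' the quartile deviation `(p75 - p25) / 2`.
#'
#' @param x Component samples (µS), artifact epochs already excluded.
#' @param fs Sample rate (Hz).
#' @param peak_prom,strong_prom Peak prominence thresholds (µS).
#' @return Named vector `mean, sd, n_peaks, n_strong_peaks, p20, p80,
#'   quart_dev`, or all-NA when fewer than 30 s of samples remain.
#' @export
eda_component_features <- function(x, fs = 4, peak_prom = 0.01,
                                   strong_prom = 0.10) {
  out <- c(mean = NA_real_, sd = NA_real_, n_peaks = NA_real_,
           n_strong_peaks = NA_real_, p20 = NA_real_, p80 = NA_real_,
           quart_dev = NA_real_)
  if (length(x) < 30 * fs) return(out)
  q <- quantile(x, c(0.2, 0.25, 0.75, 0.8), names = FALSE, type = 7)
  out["mean"] <- mean(x)
  out["sd"] <- sd(x)
  out["n_peaks"] <- length(find_scr_peaks(x, peak_prom, fs))
  out["n_strong_peaks"] <- length(find_scr_peaks(x, strong_prom, fs))
  out["p20"] <- q[1]
  out["p80"] <- q[4]
  out["quart_dev"] <- (q[3] - q[2]) / 2
  out
}

#' Build the 27-feature vector for one preprocessed window
#'
#' Assembles the 13 HRV features and 7 features per EDA component into the
#' fixed [feature_schema()] order. A modality whose inputs are unusable
#' (too few corrected beats; all EDA epochs artifact-flagged) is reported
#' missing as a block, leaving the other modality intact.
#'
#' @param window One row of [preprocess_recording()] output.
#' @param config [preprocess_config()].
#' @param fs_eda EDA sample rate (Hz).
#' @return One-row tibble with the 27 feature columns.
#' @export
build_feature_vector <- function(window, config = preprocess_config(),
                                 fs_eda = 4) {
  rr <- window$rr_ms_corrected[[1]]
  beat_t <- window$beat_t[[1]]
  hrv <- if (length(rr) >= config$min_rr) {
    c(
      suppressWarnings(hrv_time_features(rr))[c("mean_rr", "sdnn", "rmssd",
                                                "pnn50", "tri_index", "tinn")],
      hrv_freq_features(rr, beat_t, window$t_start, window$t_end)[
        c("lf_power", "hf_power", "lf_hf", "lf_peak", "hf_peak", "vlf_power")],
      suppressWarnings(hrv_time_features(rr))["sdsd"]
    )
  } else {
    setNames(rep(NA_real_, 13), character(13))
  }

  eda <- window$eda_uS[[1]]
  flags <- window$eda_epoch_flags[[1]]
  ep_len <- config$epoch_s * fs_eda
  keep <- rep(TRUE, length(eda))
  if (length(flags)) {
    for (e in which(flags)) {
      keep[((e - 1) * ep_len + 1):min(e * ep_len, length(eda))] <- FALSE
    }
    keep[seq2_safe(length(flags) * ep_len + 1, length(eda))] <- TRUE
  }
  eda_clean <- eda[keep]
  eda_feats <- if (length(eda_clean) >= 30 * fs_eda) {
    dec <- decompose_eda(eda_clean, fs = fs_eda, config = config)
    c(eda_component_features(dec$phasic, fs = fs_eda),
      eda_component_features(dec$tonic, fs = fs_eda))
  } else {
    rep(NA_real_, 14)
  }

  vec <- c(unname(hrv), unname(eda_feats))
  tibble::as_tibble(setNames(as.list(vec), feature_schema()))
}

#' Average window feature vectors into a session record
#'
#' Per-feature arithmetic mean over the valid windows, skipping per-feature
#' missing entries (a window missing one modality still contributes its
#' other modality). Returns `NULL` (with a message) when no valid window
#' remains, matching the study's drop-and-log handling of unusable
#' sessions.
#'
#' @param window_features Tibble of per-window feature vectors
#'   ([build_feature_vector()] rows).
#' @return One-row tibble: `n_windows` plus the 27 mean features, or
#'   `NULL`.
#' @export
aggregate_session <- function(window_features) {
  if (is.null(window_features) || nrow(window_features) == 0) {
    message("session dropped: no valid windows")
    return(NULL)
  }
  means <- vapply(window_features[feature_schema()], function(col) {
    if (all(is.na(col))) NA_real_ else mean(col, na.rm = TRUE)
  }, numeric(1))
  dplyr::bind_cols(
    tibble::tibble(n_windows = nrow(window_features)),
    tibble::as_tibble(as.list(means))
  )
}
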