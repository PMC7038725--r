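#' Preprocessing configuration
#'
#' All thresholds in one place. Defaults are the published values where the
#' study states them (120 s windows, 20 % RR rule, 10 % rejection) and
#' documented package choices elsewhere (EDA screen thresholds, low-pass
#' split of the EDA signal).
#'
#' @param window_s Analysis window length (s).
#' @param rr_threshold Relative successive-difference threshold of the RR
#'   artifact rule (fraction).
#' @param reject_frac Maximum tolerated fraction of flagged RR intervals per
#'   window; windows strictly above it are rejected.
#' @param epoch_s EDA artifact-screen epoch length (s).
#' @param slope_thr Max per-sample EDA step (µS) tolerated without a
#'   co-occurring motion burst.
#' @param acc_thr Accelerometer magnitude SD (g) above which an epoch counts
#'   as a motion burst.
#' @param floor_uS,ceil_uS EDA plausibility bounds (µS).
#' @param eda_cutoff_hz Tonic/phasic split cutoff (Hz).
#' @param eda_filter_order Butterworth order of the split filter.
#' @param min_rr Minimum corrected RR intervals per window for HRV features.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(window_s = 120, rr_threshold = 0.20,
                              reject_frac = 0.10, epoch_s = 5,
                              slope_thr = 0.5, acc_thr = 0.1,
                              floor_uS = 0.01, ceil_uS = 60,
                              eda_cutoff_hz = 0.05, eda_filter_order = 4,
                              min_rr = 10) {
  structure(as.list(environment()), class = "preprocess_config")
}

#' Detect RR-interval artifacts by the 20 % successive-difference rule
#'
#' An interval is flagged when it deviates from the reference interval by
#' more than `threshold` (relative). The reference is the last non-flagged
#' interval, so a single ectopic beat does not drag its normal successor
#' into the flag set; the first interval is never flagged.
#'
#' @param rr_ms Ordered RR intervals (ms).
#' @param threshold Relative threshold (default 0.20).
#' @return Logical flags aligned with `rr_ms`.
#' @export
#' @examples
#' detect_rr_artifacts(c(800, 800, 1000, 800))  # F F T F
detect_rr_artifacts <- function(rr_ms, threshold = 0.20) {
  n <- length(rr_ms)
  if (n < 2) {
    if (n > 0) warn("fewer than 2 RR intervals; no artifact detection possible")
    return(rep(FALSE, n))
  }
  flags <- logical(n)
  ref <- rr_ms[1]
  for (i in 2:n) {
    if (abs(rr_ms[i] - ref) / ref > threshold) {
      flags[i] <- TRUE
    } else {
      ref <- rr_ms[i]
    }
  }
  flags
}

#' Replace flagged RR intervals by cubic-spline interpolation
#'
#' A cubic spline is fitted over (beat index, RR) of the non-flagged
#' intervals and evaluated at the flagged positions (Kubios-style
#' replacement). Values extrapolated beyond the first/last valid beat are
#' clamped to the range of the valid intervals.
#'
#' @param rr_ms RR intervals (ms).
#' @param flags Logical flags from [detect_rr_artifacts()].
#' @return Corrected RR intervals, same length; unflagged values unchanged.
#'   Errors if more than half the intervals are flagged (such a window is
#'   invalid and must be rejected instead).
#' @export
correct_rr <- function(rr_ms, flags) {
  stopifnot(length(flags) == length(rr_ms))
  if (!any(flags)) return(rr_ms)
  if (mean(flags) > 0.5) {
    abort("more than 50% of intervals flagged; window cannot be corrected")
  }
  idx <- seq_along(rr_ms)
  good <- idx[!flags]
  bad <- idx[flags]
  if (length(good) < 2) abort("need at least 2 clean intervals for interpolation")
  f <- splinefun(good, rr_ms[good], method = "natural")
  repl <- f(bad)
  outside <- bad < min(good) | bad > max(good)
  repl[outside] <- clamp(repl[outside], min(rr_ms[good]), max(rr_ms[good]))
  out <- rr_ms
  out[bad] <- repl
  out
}

#' Window validity by artifact fraction
#'
#' A window is kept while at most `max_frac` of its intervals are flagged
#' ("more than 10 %" rejects, so exactly 10 % is kept). Computed on the
#' pre-correction flags.
#'
#' @param flags Logical artifact flags.
#' @param max_frac Rejection boundary (default 0.10).
#' @return `TRUE` (valid) or `FALSE`; empty flags are invalid.
#' @export
reject_window <- function(flags, max_frac = 0.10) {
  if (!length(flags)) return(FALSE)
  mean(flags) <= max_frac
}

#' Screen EDA epochs for motion artifacts
#'
#' Deterministic rule stand-in for a trained artifact classifier: a 5 s
#' epoch is flagged when a steep skin-conductance step (per-sample change
#' above `slope_thr`) co-occurs with a motion burst (accelerometer magnitude
#' SD above `acc_thr`), or when the signal leaves the plausibility bounds.
#' Skin temperature is accepted for interface compatibility but unused by
#' the default rule.
#'
#' @param eda EDA samples (µS) at `fs` Hz.
#' @param acc Accelerometer matrix (3 columns, 1/64 g units) covering the
#'   same span, or `NULL` (falls back to EDA-only rules, with a warning).
#' @param temp Optional temperature samples (unused by the default rule).
#' @param fs,acc_fs Sample rates (Hz).
#' @param config [preprocess_config()].
#' @return Logical vector, one flag per epoch.
#' @export
detect_eda_artifacts <- function(eda, acc = NULL, temp = NULL,
                                 fs = 4, acc_fs = 32,
                                 config = preprocess_config()) {
  ep_len <- config$epoch_s * fs
  n_ep <- floor(length(eda) / ep_len)
  if (n_ep == 0) return(logical(0))
  have_acc <- !is.null(acc) && NROW(acc) > 0
  if (!have_acc) warn("no accelerometer channel; EDA-only artifact rules applied")
  # a sample-to-sample step between samples i and i+1 is charged to the
  # epoch containing sample i+1, so steps across epoch boundaries are seen
  d <- if (length(eda) > 1) abs(diff(eda)) else numeric(0)
  d_epoch <- if (length(d)) (seq_along(d) + 1 - 1) %/% ep_len + 1 else integer(0)
  d_epoch <- pmin(d_epoch, n_ep)
  vapply(seq_len(n_ep), function(e) {
    i0 <- (e - 1) * ep_len + 1
    seg <- eda[i0:(i0 + ep_len - 1)]
    dd <- d[d_epoch == e]
    steep <- length(dd) > 0 && max(dd) > config$slope_thr
    moving <- if (have_acc) {
      a0 <- (e - 1) * config$epoch_s * acc_fs + 1
      a1 <- min(e * config$epoch_s * acc_fs, NROW(acc))
      if (a0 > a1) {
        TRUE  # no motion evidence for this epoch: the slope rule stands alone
      } else {
        mag <- sqrt(rowSums((acc[a0:a1, , drop = FALSE] / 64)^2))
        sd(mag) > config$acc_thr
      }
    } else {
      TRUE  # without motion evidence the slope rule stands alone
    }
    out_of_bounds <- any(seg < config$floor_uS | seg > config$ceil_uS)
    (steep && moving) || out_of_bounds
  }, logical(1))
}

# Zero-phase filtering with full odd-reflection padding; signal::filtfilt
# alone leaves long edge transients at very low cutoffs.
zero_phase_lowpass <- function(x, fs, cutoff, order) {
  n <- length(x)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  p <- n - 1
  pre <- 2 * x[1] - x[(p + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(p + 1):(p + n)]
}

#' Decompose EDA into tonic and phasic components
#'
#' Tonic = zero-phase low-pass of the cleaned signal (order-4 Butterworth,
#' 0.05 Hz cutoff by default); phasic = signal minus tonic, so the
#' reconstruction is exact by construction and the tonic component is
#' smoother than the input.
#'
#' @param eda Clean EDA samples (µS) at `fs` Hz; at least 30 s.
#' @param fs Sample rate (Hz).
#' @param config [preprocess_config()].
#' @return List with `tonic` and `phasic` numeric vectors.
#' @export
decompose_eda <- function(eda, fs = 4, config = preprocess_config()) {
  if (length(eda) < 30 * fs) abort("need at least 30 s of clean EDA for decomposition")
  tonic <- zero_phase_lowpass(eda, fs, config$eda_cutoff_hz, config$eda_filter_order)
  list(tonic = tonic, phasic = eda - tonic)
}

#' Segment a recording into analysis windows
#'
#' Non-overlapping, contiguous, half-open `[t_start, t_end)` windows from
#' the session start; the trailing partial window is dropped. Every RR
#' interval is assigned to exactly one window by the time of its closing
#' beat; a beat at exactly a window boundary belongs to the later window.
#'
#' @param recording An `e4_recording`.
#' @param window_s Window length (s).
#' @return Tibble with one row per window: `session_id`, `window_index`
#'   (0-based), `t_start`, `t_end`, and list-columns `rr_ms`, `beat_t`,
#'   `eda_uS`, `acc` (matrix slice), `temp_C`. Returns an empty tibble with
#'   a warning if the recording is shorter than one window.
#' @export
segment_windows <- function(recording, window_s = 120) {
  span <- recording_span(recording)
  n_win <- floor(span / window_s)
  empty <- tibble::tibble(
    session_id = character(0), window_index = integer(0),
    t_start = numeric(0), t_end = numeric(0),
    rr_ms = list(), beat_t = list(), eda_uS = list(), acc = list(),
    temp_C = list()
  )
  if (n_win == 0) {
    warn(paste0("recording ", recording$session_id, " shorter than one window"))
    return(empty)
  }
  ev <- recording$channels$ibi$events
  eda <- recording$channels$eda
  acc <- recording$channels$acc
  temp <- recording$channels$temp
  purrr::map_dfr(seq_len(n_win) - 1L, function(w) {
    t0 <- w * window_s
    t1 <- t0 + window_s
    in_w <- ev$offset_s >= t0 & ev$offset_s < t1
    e0 <- round(t0 * eda$sample_rate) + 1
    e1 <- round(t1 * eda$sample_rate)
    a0 <- round(t0 * acc$sample_rate) + 1
    a1 <- min(round(t1 * acc$sample_rate), NROW(acc$values))
    m0 <- round(t0 * temp$sample_rate) + 1
    m1 <- min(round(t1 * temp$sample_rate), length(temp$values))
    tibble::tibble(
      session_id = recording$session_id, window_index = w,
      t_start = t0, t_end = t1,
      rr_ms = list(ev$rr_s[in_w] * 1000),
      beat_t = list(ev$offset_s[in_w]),
      eda_uS = list(eda$values[e0:min(e1, length(eda$values))]),
      acc = list(acc$values[seq2_safe(a0, a1), , drop = FALSE]),
      temp_C = list(if (m1 >= m0) temp$values[m0:m1] else numeric(0))
    )
  })
}

seq2_safe <- function(from, to) if (to >= from) from:to else integer(0)

#' Preprocess a recording into validated window records
#'
#' Runs the full preprocessing chain per window: RR artifact detection
#' (20 % rule), window rejection (10 % rule on pre-correction flags),
#' cubic-spline correction of surviving windows, and the per-epoch EDA
#' artifact screen.
#'
#' @param recording An `e4_recording`.
#' @param config [preprocess_config()].
#' @return The window tibble of [segment_windows()] plus `rr_flags`,
#'   `rr_ms_corrected`, `eda_epoch_flags` list-columns and a `valid` flag.
#' @export
preprocess_recording <- function(recording, config = preprocess_config()) {
  win <- segment_windows(recording, config$window_s)
  if (!nrow(win)) return(win)
  win$rr_flags <- purrr::map(win$rr_ms, detect_rr_artifacts,
                             threshold = config$rr_threshold)
  win$valid <- purrr::map_lgl(win$rr_flags, reject_window,
                              max_frac = config$reject_frac)
  win$rr_ms_corrected <- purrr::map2(win$rr_ms, win$rr_flags, function(rr, fl) {
    if (!length(rr) || mean(fl) > 0.5) return(rr)
    correct_rr(rr, fl)
  })
  win$eda_epoch_flags <- purrr::pmap(
    list(win$eda_uS, win$acc, win$temp_C),
    function(eda, acc, temp) {
      detect_eda_artifacts(eda, acc, temp, config = config)
    }
  )
  win
}
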