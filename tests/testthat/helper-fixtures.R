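# Fixture builders and independent brute-force oracles used across tests.
# Oracles are written from definitions, never by calling the package path
# they check.

# ---- oracles ----------------------------------------------------------------

oracle_rmssd <- function(rr) {
  d <- rr[-1] - rr[-length(rr)]
  sqrt(sum(d^2) / length(d))
}

oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracle_pnn50 <- function(rr) {
  d <- abs(diff(rr))
  100 * sum(d > 50) / length(d)
}

# Linear-interpolation percentile (type-7 definition, from first principles)
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# One-sided FFT periodogram band power of a mean-removed series (density
# scaling, rectangle rule), written independently of the package.
oracle_band_power <- function(x, fs, lo, hi) {
  x <- x - mean(x)
  n <- length(x)
  spec <- Mod(fft(x))^2
  k <- seq_len(floor(n / 2))
  freq <- k * fs / n
  psd <- 2 * spec[k + 1] / (fs * n)
  if (n %% 2 == 0) psd[length(psd)] <- psd[length(psd)] / 2
  sum(psd[freq >= lo & freq < hi]) * (fs / n)
}

# ---- fixture builders -------------------------------------------------------

make_channel <- function(values, fs = 4, start = 0) {
  structure(list(start_time = start, sample_rate = fs, values = values),
            class = "channel_series")
}

make_ibi <- function(rr_s, start = 0) {
  structure(
    list(start_time = start,
         events = tibble::tibble(offset_s = cumsum(rr_s), rr_s = rr_s)),
    class = "ibi_series"
  )
}

# A quiet recording with constant RR and EDA signals of given duration.
make_recording <- function(duration_s = 360, rr_s = 0.8, eda_level = 2,
                           session_id = "S1", environment = "lab",
                           acc_noise = 0.5) {
  n_rr <- floor(duration_s / rr_s)
  acc <- cbind(rnorm(duration_s * 32, 0, acc_noise),
               rnorm(duration_s * 32, 0, acc_noise),
               rnorm(duration_s * 32, 64, acc_noise))
  structure(
    list(
      session_id = session_id, participant_id = "P1",
      environment = environment,
      channels = list(
        eda = make_channel(rep(eda_level, duration_s * 4), 4),
        temp = make_channel(rep(33, duration_s * 4), 4),
        acc = structure(list(start_time = 0, sample_rate = 32, values = acc),
                        class = "channel_series"),
        ibi = make_ibi(rep(rr_s, n_rr))
      ),
      phases = NULL
    ),
    class = "e4_recording"
  )
}

# Small noiseless simulation parameters for deterministic fixtures.
quiet_params <- function(...) {
  args <- list(
    rr_noise_sd = 0, lf_amp_relaxed = 0, lf_amp_stressed = 0,
    hf_amp_relaxed = 0, hf_amp_stressed = 0,
    tonic_walk_sd = 0, scr_rate_relaxed = 0, scr_rate_stressed = 0,
    artifact_rate_rr = 0, artifact_rate_eda = 0
  )
  do.call(sim_params, utils::modifyList(args, list(...)))
}

# Separable two-class tabular fixture in the labeled_dataset shape.
make_labeled <- function(n_per_class = 30, shift = 3, sd = 0.3, seed = 1,
                         environment = "lab", n_feats = 27) {
  withr::with_seed(seed, {
    feats <- feature_schema()[seq_len(n_feats)]
    n <- 2 * n_per_class
    lab <- rep(c("relaxed", "stressed"), each = n_per_class)
    m <- sapply(seq_len(n_feats), function(j) {
      rnorm(n, ifelse(lab == "stressed" & j <= 5, shift, 0), sd)
    })
    colnames(m) <- feats
    dplyr::bind_cols(
      tibble::tibble(
        session_id = sprintf("S%03d", seq_len(n)),
        environment = environment,
        label = factor(lab, levels = c("relaxed", "stressed"))
      ),
      tibble::as_tibble(m)
    )
  })
}
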