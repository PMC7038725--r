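#' Simulation parameters
#'
#' Defaults define the study conditions the generator emulates: stress
#' shortens the mean RR interval and suppresses the high-frequency
#' (parasympathetic) oscillation while raising the low-frequency one, and it
#' raises both the tonic skin-conductance level and the skin conductance
#' response (SCR) rate. Self-report labels are noisier in the field than in
#' the lab (symmetric flip model).
#'
#' @param rr_mean_relaxed,rr_mean_stressed Mean RR interval (ms).
#' @param lf_amp_relaxed,lf_amp_stressed LF sinusoid amplitude (ms).
#' @param hf_amp_relaxed,hf_amp_stressed HF sinusoid amplitude (ms).
#' @param lf_freq,hf_freq Oscillation frequencies (Hz); must sit inside the
#'   LF (0.04-0.15) and HF (0.15-0.4) analysis bands.
#' @param rr_noise_sd Gaussian beat-to-beat noise (ms).
#' @param scr_rate_relaxed,scr_rate_stressed SCR events per minute.
#' @param scr_amp_range SCR amplitude range (µS), length 2.
#' @param tonic_level_relaxed,tonic_level_stressed Tonic level (µS).
#' @param tonic_walk_sd Tonic random-walk innovation SD (µS per sqrt(s)).
#' @param artifact_rate_rr Injected RR artifacts per 100 beats.
#' @param artifact_rate_eda Injected EDA artifacts per minute.
#' @param selfreport_flip_p_lab,selfreport_flip_p_daily Probability that a
#'   simulated self-report is drawn from the opposite state's item
#'   distribution; the field value exceeds the lab value.
#' @return A `sim_params` list, validated.
#' @export
sim_params <- function(rr_mean_relaxed = 850, rr_mean_stressed = 700,
                       lf_amp_relaxed = 25, lf_amp_stressed = 35,
                       hf_amp_relaxed = 50, hf_amp_stressed = 15,
                       lf_freq = 0.1, hf_freq = 0.25,
                       rr_noise_sd = 10,
                       scr_rate_relaxed = 2, scr_rate_stressed = 8,
                       scr_amp_range = c(0.1, 0.8),
                       tonic_level_relaxed = 1.5, tonic_level_stressed = 4,
                       tonic_walk_sd = 0.02,
                       artifact_rate_rr = 2, artifact_rate_eda = 0.5,
                       selfreport_flip_p_lab = 0.05,
                       selfreport_flip_p_daily = 0.20) {
  p <- as.list(environment())
  rates <- c(
    p$lf_amp_relaxed, p$lf_amp_stressed, p$hf_amp_relaxed, p$hf_amp_stressed,
    p$rr_noise_sd, p$scr_rate_relaxed, p$scr_rate_stressed, p$scr_amp_range,
    p$tonic_level_relaxed, p$tonic_level_stressed, p$tonic_walk_sd,
    p$artifact_rate_rr, p$artifact_rate_eda
  )
  if (any(rates < 0)) abort("rates and amplitudes must be >= 0")
  if (p$selfreport_flip_p_lab < 0 || p$selfreport_flip_p_lab >= 0.5 ||
      p$selfreport_flip_p_daily < 0 || p$selfreport_flip_p_daily >= 0.5) {
    abort("flip probabilities must lie in [0, 0.5)")
  }
  if (p$rr_mean_relaxed <= 300 || p$rr_mean_relaxed >= 1500 ||
      p$rr_mean_stressed <= 300 || p$rr_mean_stressed >= 1500) {
    abort("rr means must lie in (300, 1500) ms")
  }
  if (p$lf_freq <= 0.04 || p$lf_freq >= 0.15) abort("lf_freq must lie in (0.04, 0.15) Hz")
  if (p$hf_freq <= 0.15 || p$hf_freq >= 0.4) abort("hf_freq must lie in (0.15, 0.4) Hz")
  structure(p, class = "sim_params")
}

#' State profile
#'
#' Ordered segments of latent affective state driving the generator.
#'
#' @param duration_s Segment durations (s), all positive.
#' @param state Matching states over `{relaxed, stressed}`.
#' @return Tibble with columns `duration_s`, `state`, `t_start`, `t_end`.
#' @export
state_profile <- function(duration_s, state) {
  if (!length(duration_s) || any(duration_s <= 0)) {
    abort("profile needs at least one segment with positive duration")
  }
  if (length(state) != length(duration_s) ||
      !all(state %in% c("relaxed", "stressed"))) {
    abort("state must match duration_s over {relaxed, stressed}")
  }
  ends <- cumsum(duration_s)
  tibble::tibble(
    duration_s = as.double(duration_s), state = state,
    t_start = c(0, head(ends, -1)), t_end = ends
  )
}

#' Default lab protocol profile: baseline, stressor, recovery
#'
#' Scaled-down analogue of a baseline / Trier-style stressor / recovery lab
#' session; recovery is generated as relaxed.
#'
#' @param baseline_s,stress_s,recovery_s Phase durations (s).
#' @return A [state_profile()] with a `phase` column.
#' @export
lab_profile <- function(baseline_s = 360, stress_s = 360, recovery_s = 240) {
  p <- state_profile(
    c(baseline_s, stress_s, recovery_s),
    c("relaxed", "stressed", "relaxed")
  )
  p$phase <- c("baseline", "stress", "recovery")
  p
}

state_at <- function(profile, t) {
  idx <- findInterval(t, c(0, profile$t_end), rightmost.closed = FALSE)
  idx <- clamp(idx, 1, nrow(profile))
  profile$state[idx]
}

#' Simulate an interbeat-interval series
#'
#' RR intervals follow a sinusoid-plus-noise model:
#' `rr(t) = rr_mean(state) + lf_amp(state) sin(2 pi lf_freq t) +
#'  hf_amp(state) sin(2 pi hf_freq t) + N(0, rr_noise_sd)`,
#' with beat times accumulating the generated durations. Stressed segments
#' have a shorter mean RR and a smaller HF amplitude, so band powers of the
#' resampled series are analytically known.
#'
#' @param profile A [state_profile()].
#' @param params [sim_params()].
#' @param seed Integer seed (full determinism).
#' @return An IBI series object with `$events` (`offset_s`, `rr_s`).
#' @export
simulate_ibi <- function(profile, params = sim_params(), seed = NULL) {
  short <- profile$duration_s <
    2 * ifelse(profile$state == "stressed",
               params$rr_mean_stressed, params$rr_mean_relaxed) / 1000
  if (any(short)) abort("profile segment shorter than 2 beats")
  total <- sum(profile$duration_s)
  with_seed(seed, {
    t <- 0
    offs <- numeric(0)
    rrs <- numeric(0)
    repeat {
      st <- state_at(profile, t)
      mu <- if (st == "stressed") params$rr_mean_stressed else params$rr_mean_relaxed
      lf <- if (st == "stressed") params$lf_amp_stressed else params$lf_amp_relaxed
      hf <- if (st == "stressed") params$hf_amp_stressed else params$hf_amp_relaxed
      rr_ms <- mu + lf * sin(2 * pi * params$lf_freq * t) +
        hf * sin(2 * pi * params$hf_freq * t) +
        if (params$rr_noise_sd > 0) rnorm(1, 0, params$rr_noise_sd) else 0
      rr_ms <- max(rr_ms, 250)  # physiological floor
      rr_s <- rr_ms / 1000
      if (t + rr_s > total + 1e-9) break
      t <- t + rr_s
      offs <- c(offs, t)
      rrs <- c(rrs, rr_s)
    }
    new_ibi_series(0, offs, rrs)
  })
}

scr_pulse <- function(t, tau_rise = 0.75, tau_decay = 2.0) {
  # bi-exponential SCR kinetics, normalised to unit peak
  raw <- function(u) exp(-u / tau_decay) - exp(-u / tau_rise)
  t_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  out <- ifelse(t < 0, 0, raw(t) / raw(t_peak))
  out
}

#' Simulate a 4 Hz electrodermal activity channel
#'
#' Tonic = state-dependent level plus a slow random walk; phasic = Poisson
#' SCR events (rate per state) with bi-exponential pulses (rise 0.75 s,
#' decay 2.0 s) and amplitudes uniform over `scr_amp_range`. Output is
#' tonic + phasic, floored strictly above zero. The injected SCR ground
#' truth is attached as attribute `"scr_events"`.
#'
#' @inheritParams simulate_ibi
#' @param fs Sample rate (Hz).
#' @return A channel series (µS) of length `fs * sum(duration_s)`.
#' @export
simulate_eda <- function(profile, params = sim_params(), seed = NULL, fs = 4) {
  total <- sum(profile$duration_s)
  n <- round(total * fs)
  tt <- (seq_len(n) - 1) / fs
  st <- state_at(profile, tt)
  with_seed(seed, {
    level <- ifelse(st == "stressed", params$tonic_level_stressed,
                    params$tonic_level_relaxed)
    walk <- if (params$tonic_walk_sd > 0) {
      cumsum(rnorm(n, 0, params$tonic_walk_sd / sqrt(fs)))
    } else {
      numeric(n)
    }
    tonic <- level + walk
    phasic <- numeric(n)
    ev_t <- numeric(0)
    ev_a <- numeric(0)
    for (i in seq_len(nrow(profile))) {
      rate <- if (profile$state[i] == "stressed") params$scr_rate_stressed else params$scr_rate_relaxed
      k <- rpois(1, rate * profile$duration_s[i] / 60)
      if (k > 0) {
        onsets <- sort(runif(k, profile$t_start[i], profile$t_end[i]))
        amps <- runif(k, params$scr_amp_range[1], params$scr_amp_range[2])
        for (j in seq_len(k)) {
          phasic <- phasic + amps[j] * scr_pulse(tt - onsets[j])
        }
        ev_t <- c(ev_t, onsets)
        ev_a <- c(ev_a, amps)
      }
    }
    out <- new_channel_series(0, fs, pmax(tonic + phasic, 0.01))
    attr(out, "scr_events") <- tibble::tibble(onset_s = ev_t, amp_uS = ev_a)
    attr(out, "tonic_truth") <- tonic
    out
  })
}

simulate_acc <- function(total_s, seed = NULL, fs = 32, noise_counts = 1) {
  n <- round(total_s * fs)
  with_seed(seed, {
    m <- cbind(
      rnorm(n, 0, noise_counts), rnorm(n, 0, noise_counts),
      rnorm(n, 64, noise_counts)  # gravity on z, 1/64 g units
    )
    structure(list(start_time = 0, sample_rate = fs, values = m),
              class = "channel_series")
  })
}

simulate_temp <- function(total_s, seed = NULL, fs = 4) {
  n <- round(total_s * fs)
  with_seed(seed, new_channel_series(0, fs, 33 + cumsum(rnorm(n, 0, 0.002))))
}

#' Inject artifacts into a clean recording
#'
#' RR artifacts scale randomly chosen beats by a factor drawn from
#' `{0.5} U [1.5, 2]` (ectopic-like jumps well beyond the 20 % detection
#' rule); beat offsets are rebuilt from the corrupted durations. EDA
#' artifacts are transient step discontinuities (5-15 s) or spikes, each
#' co-occurring with an injected accelerometer burst. The exact injected positions are returned as a
#' ground-truth mask.
#'
#' @param recording A clean `e4_recording`.
#' @param params [sim_params()]; `artifact_rate_rr` is per 100 beats,
#'   `artifact_rate_eda` per minute.
#' @param seed Integer seed.
#' @return The corrupted recording, with attribute `"artifact_mask"`: a list
#'   with `rr_idx` (corrupted beat indices) and `eda` (tibble of sample
#'   index, type).
#' @export
inject_artifacts <- function(recording, params = sim_params(), seed = NULL) {
  with_seed(seed, {
    ch <- recording$channels
    rr <- ch$ibi$events$rr_s
    n_rr <- length(rr)
    rr_idx <- integer(0)
    if (params$artifact_rate_rr > 0 && n_rr > 2) {
      p <- params$artifact_rate_rr / 100
      # never corrupt the first beat (it anchors the detector's reference)
      rr_idx <- which(runif(n_rr) < p & seq_len(n_rr) > 1)
      if (length(rr_idx)) {
        fac <- ifelse(runif(length(rr_idx)) < 0.5, 0.5,
                      runif(length(rr_idx), 1.5, 2.0))
        rr[rr_idx] <- rr[rr_idx] * fac
      }
    }
    ibi <- new_ibi_series(ch$ibi$start_time, cumsum(rr), rr)

    eda <- ch$eda$values
    fs <- ch$eda$sample_rate
    acc <- ch$acc$values
    acc_fs <- ch$acc$sample_rate
    eda_mask <- tibble::tibble(sample = integer(0), type = character(0))
    if (params$artifact_rate_eda > 0 && length(eda)) {
      total_min <- length(eda) / fs / 60
      k <- rpois(1, params$artifact_rate_eda * total_min)
      if (k > 0) {
        pos <- sort(sample(seq_len(max(1, length(eda) - 8)), min(k, length(eda) - 8)))
        type <- sample(c("step", "spike"), length(pos), replace = TRUE)
        for (j in seq_along(pos)) {
          i <- pos[j]
          if (type[j] == "step") {
            i1 <- min(i + round(runif(1, 5, 15) * fs), length(eda))
            eda[i:i1] <- eda[i:i1] + sample(c(-1.5, 1.5), 1)
          } else {
            eda[i:min(i + 1, length(eda))] <- eda[i:min(i + 1, length(eda))] + 2
          }
          # co-occurring motion burst on the accelerometer, spanning the
          # artifact so the epoch-level screen sees the conjunction
          if (nrow(acc) > 0) {
            a0 <- clamp(round((i - 1) / fs * acc_fs) - 2 * acc_fs + 1, 1, nrow(acc))
            a1 <- clamp(a0 + 4 * acc_fs, 1, nrow(acc))
            acc[a0:a1, ] <- acc[a0:a1, ] + rnorm((a1 - a0 + 1) * 3, 0, 20)
          }
        }
        eda_mask <- tibble::tibble(sample = pos, type = type)
        eda <- pmax(eda, 0.005)
      }
    }
    out <- recording
    out$channels$ibi <- ibi
    out$channels$eda <- new_channel_series(ch$eda$start_time, fs, eda)
    out$channels$acc$values <- acc
    attr(out, "artifact_mask") <- list(rr_idx = rr_idx, eda = eda_mask)
    out
  })
}

#' Simulate a PSS-5 self-report for a latent state
#'
#' With probability `1 - flip_p` the items are drawn from the
#' state-consistent distribution (relaxed: happy/cheerful 5-6, negative
#' items 1-3, so the score binarizes below 15; stressed: happy/cheerful 1-2,
#' negative items 4-6, score at least 22), otherwise from the opposite
#' state's distribution. This one-parameter symmetric flip reproduces the
#' lab-versus-field label-quality asymmetry.
#'
#' @param latent_state `"relaxed"` or `"stressed"`.
#' @param flip_p Flip probability in \[0, 0.5).
#' @param seed Integer seed.
#' @return One-row tibble with columns `H, C, A, S, F`.
#' @export
simulate_selfreport <- function(latent_state, flip_p, seed = NULL) {
  latent_state <- match.arg(latent_state, c("relaxed", "stressed"))
  if (flip_p < 0 || flip_p >= 0.5) abort("flip_p must lie in [0, 0.5)")
  with_seed(seed, {
    eff <- latent_state
    if (flip_p > 0 && runif(1) < flip_p) {
      eff <- setdiff(c("relaxed", "stressed"), latent_state)
    }
    if (eff == "relaxed") {
      tibble::tibble(
        H = sample(5:6, 1), C = sample(5:6, 1),
        A = sample(1:3, 1), S = sample(1:3, 1), F = sample(1:3, 1)
      )
    } else {
      tibble::tibble(
        H = sample(1:2, 1), C = sample(1:2, 1),
        A = sample(4:6, 1), S = sample(4:6, 1), F = sample(4:6, 1)
      )
    }
  })
}

#' Study design for the synthetic generator
#'
#' Scaled-down analogue of the cohort protocol: one lab session per
#' participant (baseline / stressor / recovery phases, context-labelled,
#' with per-phase self-reports) and several daily-life sessions per
#' participant (self-reports only, no known context), with the daily class
#' imbalance set by `relaxed_share_daily`.
#'
#' @param n_participants Number of participants (>= 2; default mirrors a
#'   14-participant cohort).
#' @param lab_profile A [lab_profile()].
#' @param n_daily_sessions Daily-life sessions per participant.
#' @param daily_session_s Duration of one daily session (s); a scaled-down
#'   stand-in for a 3-hour ambulatory block.
#' @param relaxed_share_daily Expected share of relaxed daily sessions.
#' @param params [sim_params()].
#' @return A `study_design` list.
#' @export
study_design <- function(n_participants = 14, lab_profile = stresspipe::lab_profile(),
                         n_daily_sessions = 6, daily_session_s = 360,
                         relaxed_share_daily = 0.73, params = sim_params()) {
  if (!is_count(n_participants) || n_participants < 2) {
    abort("n_participants must be an integer >= 2")
  }
  structure(as.list(environment()), class = "study_design")
}

#' Simulate a full multi-session study
#'
#' Generates, per participant, one lab recording whose phases are labelled
#' by known context and by simulated self-reports (lab flip probability),
#' and `n_daily_sessions` field recordings with self-reports only (daily
#' flip probability, exceeding the lab one by default). Artifacts are
#' injected at the design rates. The per-session latent state is returned
#' in a separate `truth` table that no pipeline stage may read.
#'
#' @param design A [study_design()].
#' @param seed Integer seed; the whole dataset is byte-identical under the
#'   same seed.
#' @return A `stress_study` list: `recordings` (named list of
#'   `e4_recording`), `labels` (one row per session: ids, environment,
#'   phase, context, items), `truth` (session id, latent state).
#' @export
simulate_study <- function(design = study_design(), seed = 1) {
  p <- design$params
  labels <- list()
  truth <- list()
  recordings <- list()
  for (i in seq_len(design$n_participants)) {
    pid <- sprintf("P%02d", i)

    # --- lab session: one recording, three phases ---
    lab_id <- paste0(pid, "_lab")
    prof <- design$lab_profile
    ibi <- simulate_ibi(prof, p, seed = derive_seed(seed, i * 101 + 1))
    eda <- simulate_eda(prof, p, seed = derive_seed(seed, i * 101 + 2))
    total <- sum(prof$duration_s)
    rec <- new_recording(
      lab_id, pid, "lab",
      eda, simulate_temp(total, derive_seed(seed, i * 101 + 3)),
      simulate_acc(total, derive_seed(seed, i * 101 + 4)), ibi,
      phases = prof[, c("phase", "state", "t_start", "t_end")]
    )
    rec <- inject_artifacts(rec, p, seed = derive_seed(seed, i * 101 + 5))
    recordings[[lab_id]] <- rec
    for (j in seq_len(nrow(prof))) {
      sid <- paste0(lab_id, "_", prof$phase[j])
      items <- simulate_selfreport(prof$state[j], p$selfreport_flip_p_lab,
                                   seed = derive_seed(seed, i * 101 + 10 + j))
      labels[[sid]] <- tibble::tibble(
        session_id = sid, participant_id = pid, environment = "lab",
        phase = prof$phase[j], context = prof$phase[j], items
      )
      truth[[sid]] <- tibble::tibble(session_id = sid, latent_state = prof$state[j])
    }

    # --- daily sessions: one recording each, self-report only ---
    states <- with_seed(derive_seed(seed, i * 101 + 50), {
      ifelse(runif(design$n_daily_sessions) < design$relaxed_share_daily,
             "relaxed", "stressed")
    })
    for (d in seq_len(design$n_daily_sessions)) {
      sid <- sprintf("%s_daily%02d", pid, d)
      dprof <- state_profile(design$daily_session_s, states[d])
      dibi <- simulate_ibi(dprof, p, seed = derive_seed(seed, i * 1009 + d * 7 + 1))
      deda <- simulate_eda(dprof, p, seed = derive_seed(seed, i * 1009 + d * 7 + 2))
      drec <- new_recording(
        sid, pid, "daily",
        deda, simulate_temp(design$daily_session_s, derive_seed(seed, i * 1009 + d * 7 + 3)),
        simulate_acc(design$daily_session_s, derive_seed(seed, i * 1009 + d * 7 + 4)),
        dibi
      )
      drec <- inject_artifacts(drec, p, seed = derive_seed(seed, i * 1009 + d * 7 + 5))
      recordings[[sid]] <- drec
      items <- simulate_selfreport(states[d], p$selfreport_flip_p_daily,
                                   seed = derive_seed(seed, i * 1009 + d * 7 + 6))
      labels[[sid]] <- tibble::tibble(
        session_id = sid, participant_id = pid, environment = "daily",
        phase = NA_character_, context = NA_character_, items
      )
      truth[[sid]] <- tibble::tibble(session_id = sid, latent_state = states[d])
    }
  }
  structure(
    list(
      recordings = recordings,
      labels = dplyr::bind_rows(labels),
      truth = dplyr::bind_rows(truth)
    ),
    class = "stress_study"
  )
}

#' @export
print.stress_study <- function(x, ...) {
  env <- vapply(x$recordings, function(r) r$environment, character(1))
  cat("<stress_study> ", sum(env == "lab"), " lab + ", sum(env == "daily"),
      " daily recordings, ", nrow(x$labels), " labelled sessions\n", sep = "")
  invisible(x)
}
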