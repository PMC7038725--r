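# End-to-end pipeline: recordings -> per-session 27-feature table.

# Cut a recording to [t0, t1) and re-zero offsets, so a lab phase can be
# processed as its own session.
slice_recording <- function(recording, t0, t1, session_id = recording$session_id) {
  ch <- recording$channels
  cut_sampled <- function(x, ncol_ = 1) {
    i0 <- round(t0 * x$sample_rate) + 1
    i1 <- min(round(t1 * x$sample_rate), NROW(x$values))
    vals <- if (is.matrix(x$values)) {
      x$values[seq2_safe(i0, i1), , drop = FALSE]
    } else {
      x$values[seq2_safe(i0, i1)]
    }
    structure(list(start_time = x$start_time + t0, sample_rate = x$sample_rate,
                   values = vals), class = "channel_series")
  }
  ev <- ch$ibi$events
  keep <- ev$offset_s >= t0 & ev$offset_s < t1
  ibi <- new_ibi_series(ch$ibi$start_time + t0, ev$offset_s[keep] - t0, ev$rr_s[keep])
  new_recording(session_id, recording$participant_id, recording$environment,
                cut_sampled(ch$eda), cut_sampled(ch$temp), cut_sampled(ch$acc), ibi)
}

#' Extract session-level features from one recording
#'
#' Preprocesses the recording, builds window feature vectors for the valid
#' windows and averages them. A lab recording with a phase table is split
#' into one session per phase.
#'
#' @param recording An `e4_recording`.
#' @param config [preprocess_config()].
#' @return Tibble with one row per session: `session_id`,
#'   `participant_id`, `environment`, `phase`, `n_windows` and the 27
#'   features. Sessions with no valid window are dropped (with a message).
#' @export
process_recording <- function(recording, config = preprocess_config()) {
  parts <- if (!is.null(recording$phases)) {
    purrr::pmap(recording$phases, function(phase, state, t_start, t_end, ...) {
      list(rec = slice_recording(recording, t_start, t_end,
                                 paste0(recording$session_id, "_", phase)),
           phase = phase)
    })
  } else {
    list(list(rec = recording, phase = NA_character_))
  }
  purrr::map_dfr(parts, function(part) {
    win <- suppressWarnings(preprocess_recording(part$rec, config))
    win <- win[win$valid, , drop = FALSE]
    if (!nrow(win)) {
      message("session dropped: no valid windows in ", part$rec$session_id)
      return(NULL)
    }
    feats <- purrr::map_dfr(seq_len(nrow(win)), function(i) {
      build_feature_vector(win[i, ], config = config)
    })
    agg <- aggregate_session(feats)
    if (is.null(agg)) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(
        session_id = part$rec$session_id,
        participant_id = part$rec$participant_id,
        environment = part$rec$environment,
        phase = part$phase
      ),
      agg
    )
  })
}

#' Run the full pipeline over a simulated or ingested study
#'
#' Extracts session feature vectors for every recording and joins the label
#' table ([add_stress_labels()] applied to the study's self-report items and
#' lab phases). The study's latent-state `truth` table is never consulted.
#'
#' @param study A `stress_study` (see [simulate_study()]) or a list with
#'   `recordings` and `labels`.
#' @param config [preprocess_config()].
#' @return Session feature table: meta + label columns and the 27 features,
#'   one row per usable session (the [write_feature_table()] schema).
#' @export
process_study <- function(study, config = preprocess_config()) {
  feats <- purrr::map_dfr(study$recordings, process_recording, config = config)
  labels <- add_stress_labels(study$labels)
  out <- dplyr::inner_join(
    feats,
    labels[, c("session_id", "context", "H", "C", "A", "S", "F",
               "pss_score", "stress_selfreport", "stress_context")],
    by = "session_id"
  )
  out[, c(session_meta_cols(), feature_schema())]
}
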