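#' Feature schema
#'
#' Names, in fixed order, of the 27 features the extractor emits: 13 heart
#' rate variability (HRV) features followed by 7 features for each of the
#' phasic and tonic electrodermal activity (EDA) components.
#'
#' @param modality One of `"combined"` (all 27), `"hrv"` (13) or `"eda"` (14).
#' @return Character vector of feature column names.
#' @export
#' @examples
#' length(feature_schema())        # 27
#' length(feature_schema("hrv"))   # 13
feature_schema <- function(modality = c("combined", "hrv", "eda")) {
  modality <- match.arg(modality)
  hrv <- paste0("hrv_", c(
    "mean_rr", "sdnn", "rmssd", "pnn50", "tri_index", "tinn",
    "lf_power", "hf_power", "lf_hf", "lf_peak", "hf_peak",
    "vlf_power", "sdsd"
  ))
  eda <- as.vector(outer(
    c("mean", "sd", "n_peaks", "n_strong_peaks", "p20", "p80", "quart_dev"),
    c("eda_phasic_", "eda_tonic_"),
    function(f, p) paste0(p, f)
  ))
  eda <- c(eda[1:7], eda[8:14])
  switch(modality, combined = c(hrv, eda), hrv = hrv, eda = eda)
}

# Reserved token written for absent labels / per-modality missing features in
# the tabular files; never an empty cell, so missingness survives round trips.
MISSING_TOKEN <- "missing"

# Meta + label columns of the session feature table, in order.
session_meta_cols <- function() {
  c(
    "session_id", "participant_id", "environment", "phase", "n_windows",
    "context", "H", "C", "A", "S", "F", "pss_score",
    "stress_selfreport", "stress_context"
  )
}

new_channel_series <- function(start_time, sample_rate, values) {
  stopifnot(is.numeric(values))
  if (!is.null(sample_rate) && (!is.numeric(sample_rate) || sample_rate <= 0)) {
    abort("sample_rate must be a positive number")
  }
  if (length(values) && !all(is.finite(values))) {
    abort("channel values must be finite")
  }
  structure(
    list(start_time = start_time, sample_rate = sample_rate, values = values),
    class = "channel_series"
  )
}

new_ibi_series <- function(start_time, offset_s, rr_s) {
  if (length(offset_s) != length(rr_s)) abort("offset/duration length mismatch")
  if (length(offset_s) > 1 && any(diff(offset_s) <= 0)) {
    abort("IBI offsets must be strictly increasing")
  }
  if (length(rr_s) && any(rr_s <= 0)) abort("IBI durations must be positive")
  structure(
    list(
      start_time = start_time,
      events = tibble::tibble(offset_s = as.double(offset_s), rr_s = as.double(rr_s))
    ),
    class = "ibi_series"
  )
}

new_recording <- function(session_id, participant_id, environment,
                          eda, temp, acc, ibi, phases = NULL) {
  environment <- match.arg(environment, c("lab", "daily"))
  structure(
    list(
      session_id = session_id, participant_id = participant_id,
      environment = environment,
      channels = list(eda = eda, temp = temp, acc = acc, ibi = ibi),
      phases = phases
    ),
    class = "e4_recording"
  )
}

#' @export
print.e4_recording <- function(x, ...) {
  cat(
    "<e4_recording> ", x$session_id, " [", x$environment, "]\n",
    "  EDA: ", length(x$channels$eda$values), " samples @ ",
    x$channels$eda$sample_rate, " Hz\n",
    "  IBI: ", nrow(x$channels$ibi$events), " beats\n",
    sep = ""
  )
  if (!is.null(x$phases)) {
    cat("  phases:", paste(x$phases$phase, collapse = ", "), "\n")
  }
  invisible(x)
}

# Duration (s) jointly covered by the EDA channel and the IBI event list,
# measured from the recording's common time origin.
recording_span <- function(recording) {
  eda <- recording$channels$eda
  ibi <- recording$channels$ibi
  spans <- c()
  if (length(eda$values)) spans <- c(spans, length(eda$values) / eda$sample_rate)
  if (nrow(ibi$events)) spans <- c(spans, max(ibi$events$offset_s))
  if (!length(spans)) 0 else min(spans)
}

read_sampled_channel <- function(path, n_cols = 1) {
  lines <- readLines(path)
  if (length(lines) < 2) {
    abort(paste0("format error in ", basename(path), ": need timestamp and rate header rows"))
  }
  hdr1 <- suppressWarnings(as.numeric(strsplit(lines[1], ",")[[1]]))
  hdr2 <- suppressWarnings(as.numeric(strsplit(lines[2], ",")[[1]]))
  if (any(is.na(hdr1))) abort(paste0("format error in ", basename(path), " line 1: non-numeric timestamp"))
  if (any(is.na(hdr2)) || any(hdr2 <= 0)) {
    abort(paste0("format error in ", basename(path), " line 2: invalid sample rate"))
  }
  body <- lines[-(1:2)]
  vals <- if (length(body)) {
    m <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
    if (anyNA(m)) abort(paste0("format error in ", basename(path), ": non-numeric sample"))
    m
  } else {
    matrix(numeric(0), ncol = n_cols)
  }
  if (ncol(vals) != n_cols) {
    abort(paste0("format error in ", basename(path), ": expected ", n_cols, " column(s)"))
  }
  list(start_time = hdr1[1], sample_rate = hdr2[1], values = vals)
}

#' Read an Empatica-E4-dialect session directory
#'
#' Expects `EDA.csv`, `TEMP.csv`, `ACC.csv` and `IBI.csv` in the vendor's
#' export dialect: sampled channels carry the session-start UNIX timestamp on
#' row 1 and the sample rate (Hz) on row 2, samples after; `IBI.csv` carries
#' the timestamp plus a literal `IBI` header token on row 1, then
#' `offset,duration` rows in seconds. Accelerometer values are in 1/64 g per
#' axis, EDA in microsiemens, temperature in degrees Celsius.
#'
#' @param path Session directory.
#' @param environment `"lab"` or `"daily"`.
#' @param session_id,participant_id Identifiers; default to the directory name.
#' @return An `e4_recording` object. Missing optional channels (`TEMP`,
#'   `ACC`) yield empty series with a warning; `EDA.csv` and `IBI.csv` are
#'   required.
#' @export
read_e4_session <- function(path, environment = c("lab", "daily"),
                            session_id = basename(path),
                            participant_id = basename(path)) {
  environment <- match.arg(environment)
  if (!dir.exists(path)) abort(paste0("no such session directory: ", path))
  need <- file.path(path, c("EDA.csv", "IBI.csv"))
  if (!all(file.exists(need))) {
    abort(paste0("session directory must contain EDA.csv and IBI.csv: ", path))
  }

  eda_raw <- read_sampled_channel(file.path(path, "EDA.csv"), 1)
  eda <- new_channel_series(eda_raw$start_time, eda_raw$sample_rate, as.vector(eda_raw$values))

  temp <- if (file.exists(file.path(path, "TEMP.csv"))) {
    t_raw <- read_sampled_channel(file.path(path, "TEMP.csv"), 1)
    new_channel_series(t_raw$start_time, t_raw$sample_rate, as.vector(t_raw$values))
  } else {
    warn(paste0("TEMP.csv missing in ", path, "; using empty temperature channel"))
    new_channel_series(eda_raw$start_time, 4, numeric(0))
  }

  acc <- if (file.exists(file.path(path, "ACC.csv"))) {
    a_raw <- read_sampled_channel(file.path(path, "ACC.csv"), 3)
    structure(
      list(start_time = a_raw$start_time, sample_rate = a_raw$sample_rate,
           values = a_raw$values),
      class = "channel_series"
    )
  } else {
    warn(paste0("ACC.csv missing in ", path, "; using empty accelerometer channel"))
    structure(
      list(start_time = eda_raw$start_time, sample_rate = 32,
           values = matrix(numeric(0), ncol = 3)),
      class = "channel_series"
    )
  }

  ibi_lines <- readLines(file.path(path, "IBI.csv"))
  if (!length(ibi_lines)) abort("format error in IBI.csv line 1: empty file")
  hdr <- strsplit(ibi_lines[1], ",")[[1]]
  ts <- suppressWarnings(as.numeric(hdr[1]))
  if (is.na(ts) || length(hdr) < 2 || trimws(hdr[2]) != "IBI") {
    abort("format error in IBI.csv line 1: expected '<timestamp>, IBI' header")
  }
  body <- ibi_lines[-1]
  if (length(body)) {
    m <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
    if (anyNA(m) || ncol(m) != 2) abort("format error in IBI.csv: expected 'offset,duration' rows")
    ibi <- new_ibi_series(ts, m[, 1], m[, 2])
  } else {
    ibi <- new_ibi_series(ts, numeric(0), numeric(0))
  }

  new_recording(session_id, participant_id, environment, eda, temp, acc, ibi)
}

#' Write a recording as an E4-dialect session directory
#'
#' Inverse of [read_e4_session()]; `read_e4_session(write_e4_session(x, d))`
#' reproduces all channel values.
#'
#' @param recording An `e4_recording`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_e4_session <- function(recording, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ch <- recording$channels
  write_sampled <- function(x, file, digits = 6) {
    vals <- x$values
    if (is.matrix(vals)) {
      body <- apply(vals, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE), collapse = ","))
    } else {
      body <- format(vals, trim = TRUE, scientific = FALSE)
    }
    rate_row <- paste(rep(format(x$sample_rate, trim = TRUE), max(1, ncol(as.matrix(vals)))), collapse = ",")
    ts_row <- paste(rep(format(x$start_time, trim = TRUE, scientific = FALSE), max(1, ncol(as.matrix(vals)))), collapse = ",")
    writeLines(c(ts_row, rate_row, body), file.path(path, file))
  }
  write_sampled(ch$eda, "EDA.csv")
  write_sampled(ch$temp, "TEMP.csv")
  write_sampled(ch$acc, "ACC.csv")
  ev <- ch$ibi$events
  writeLines(
    c(
      paste0(format(ch$ibi$start_time, trim = TRUE, scientific = FALSE), ", IBI"),
      sprintf("%.9g,%.9g", ev$offset_s, ev$rr_s)
    ),
    file.path(path, "IBI.csv")
  )
  invisible(path)
}

#' Write / read the session feature table
#'
#' The pipeline's tabular interchange format: one row per session, meta and
#' label columns followed by the 27 feature columns of [feature_schema()].
#' Absent labels and per-modality missing features are written as the
#' reserved token `"missing"`, never as an empty cell, so a round trip is
#' lossless.
#'
#' @param records Tibble of session records (as produced by
#'   [process_study()]).
#' @param path CSV file path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the tibble.
#' @export
write_feature_table <- function(records, path) {
  want <- c(session_meta_cols(), feature_schema())
  miss <- setdiff(want, names(records))
  if (length(miss)) {
    abort(paste0("records do not match the feature schema; missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  extra <- setdiff(names(records), want)
  if (length(extra)) {
    abort(paste0("records carry columns outside the feature schema: ",
                 paste(extra, collapse = ", ")))
  }
  readr::write_csv(records[, want], path, na = MISSING_TOKEN)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  x <- readr::read_csv(path, na = MISSING_TOKEN, show_col_types = FALSE)
  want <- c(session_meta_cols(), feature_schema())
  miss <- setdiff(want, names(x))
  extra <- setdiff(names(x), want)
  if (length(miss) || length(extra)) {
    abort(paste0(
      "feature table schema mismatch",
      if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")) else "",
      if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")) else ""
    ))
  }
  for (col in c("phase", "context", "stress_selfreport", "stress_context",
                "session_id", "participant_id", "environment")) {
    x[[col]] <- as.character(x[[col]])
  }
  x[, want]
}
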