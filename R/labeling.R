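#' Score a five-item ambulatory Perceived Stress Scale (PSS-5) response
#'
#' Each item is an integer from 1 to 6. The positive-affect items (happiness
#' `H`, cheerfulness `C`) count inversely; anger `A`, sadness `S` and
#' frustration `F` count directly:
#' \deqn{score = (7 - H) + (7 - C) + A + S + F}
#'
#' @param H,C,A,S,F Item responses, integers in 1..6 (vectorised).
#' @return Integer score(s). Over all admissible responses the score spans
#'   5 to 30; higher means more perceived stress.
#' @export
#' @examples
#' score_pss5(1, 1, 6, 6, 6)  # 30, the maximum
score_pss5 <- function(H, C, A, S, F) {
  items <- list(H = H, C = C, A = A, S = S, F = F)
  for (nm in names(items)) {
    v <- items[[nm]]
    bad <- !is.na(v) & (v < 1 | v > 6 | v != floor(v))
    if (any(bad)) {
      abort(paste0("PSS-5 item ", nm, " out of range [1, 6]: ",
                   paste(unique(v[bad]), collapse = ", ")))
    }
  }
  as.integer((7 - H) + (7 - C) + A + S + F)
}

#' Binarize a perceived-stress score
#'
#' Scores below 15 are labelled `relaxed`, scores of 15 and above `stressed`.
#' The published banding places 15 in both the low and the high band; this
#' implementation assigns the boundary to `stressed`, and the boundary is
#' configurable.
#'
#' @param score Numeric score(s) in \[0, 30\].
#' @param boundary First score counted as stressed (default 15).
#' @return Character vector of `"relaxed"` / `"stressed"` (NA passes through).
#' @export
binarize_stress <- function(score, boundary = 15) {
  bad <- !is.na(score) & (score < 0 | score > 30)
  if (any(bad)) {
    abort(paste0("PSS score out of range [0, 30]: ",
                 paste(unique(score[bad]), collapse = ", ")))
  }
  ifelse(is.na(score), NA_character_,
         ifelse(score >= boundary, "stressed", "relaxed"))
}

#' Known-context label for a lab protocol phase
#'
#' The two-class known-context task separates the stressor phase from
#' baseline; recovery windows are excluded from that task (they carry
#' self-report labels only).
#'
#' @param phase Character vector over `{baseline, stress, recovery}`.
#' @return `"relaxed"`, `"stressed"` or `"excluded"` per element; NA passes
#'   through.
#' @export
context_label <- function(phase) {
  out <- ifelse(is.na(phase), NA_character_,
    c(baseline = "relaxed", stress = "stressed", recovery = "excluded")[phase])
  bad <- !is.na(phase) & is.na(out)
  if (any(bad)) {
    abort(paste0("unknown lab phase: ", paste(unique(phase[bad]), collapse = ", ")))
  }
  unname(out)
}

#' Attach PSS-5 scores and binary labels to a label table
#'
#' Convenience verb over [score_pss5()], [binarize_stress()] and
#' [context_label()]: adds `pss_score`, `stress_selfreport` and
#' `stress_context` columns. Rows with missing self-report items get missing
#' score/self-report labels (the study behaviour for sessions with missed
#' EMAs: dropped downstream, with a note).
#'
#' @param labels Tibble with item columns `H,C,A,S,F` and (for lab rows) a
#'   `phase` column.
#' @param boundary Passed to [binarize_stress()].
#' @return The tibble with the three derived columns added.
#' @export
add_stress_labels <- function(labels, boundary = 15) {
  have_items <- complete.cases(labels[, c("H", "C", "A", "S", "F")])
  score <- rep(NA_integer_, nrow(labels))
  if (any(have_items)) {
    score[have_items] <- score_pss5(
      labels$H[have_items], labels$C[have_items], labels$A[have_items],
      labels$S[have_items], labels$F[have_items]
    )
  }
  labels$pss_score <- score
  labels$stress_selfreport <- binarize_stress(score, boundary)
  labels$stress_context <- if ("phase" %in% names(labels)) {
    context_label(labels$phase)
  } else {
    NA_character_
  }
  labels
}
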