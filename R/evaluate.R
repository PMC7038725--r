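# Evaluation protocols: k-fold CV, 80/20 split, lab-to-daily transfer,
# and the five-way model matrix.

new_stress_eval <- function(model_type, eval_method, spec, accuracy, fold_sd,
                            confusion, n_train, n_test, selected) {
  structure(
    list(model_type = model_type, eval_method = eval_method, spec = spec,
         accuracy = accuracy, fold_sd = fold_sd, confusion = confusion,
         n_train = n_train, n_test = n_test, selected = selected),
    class = "stress_eval"
  )
}

#' @export
print.stress_eval <- function(x, ...) {
  cat(sprintf(
    "<stress_eval> %s / %s / %s / %s: accuracy %.2f%%%s (n_train %d, n_test %d)\n",
    x$model_type, x$eval_method, x$spec$modality, x$spec$classifier,
    x$accuracy,
    if (!is.na(x$fold_sd)) sprintf(" (fold SD %.2f)", x$fold_sd) else "",
    x$n_train, x$n_test
  ))
  invisible(x)
}

empty_confusion <- function() {
  matrix(0L, 2, 2, dimnames = list(truth = STRESS_LEVELS, pred = STRESS_LEVELS))
}

confusion_add <- function(conf, truth, pred) {
  t2 <- table(factor(truth, STRESS_LEVELS), factor(pred, STRESS_LEVELS))
  conf + unclass(t2)
}

# One train/test execution of the leakage-free protocol: undersample the
# training rows, select features on them, fit min-max scaling on them,
# fit the classifier, score the held-out rows.
run_fold <- function(train, test, spec, seed, paper_order = FALSE,
                     preselected = NULL, prenormalized = FALSE) {
  if (!paper_order) train <- undersample(train, seed = seed)
  sel <- preselected %||% select_features(train, spec$k_features, spec$select_method)
  keep_cols <- c("session_id", "environment", "label", sel)
  train <- train[, keep_cols, drop = FALSE]
  test <- test[, keep_cols, drop = FALSE]
  if (!prenormalized) {
    nz <- normalize_features(train, test)
    train <- nz$train
    test <- nz$test
  }
  model <- fit_stress_classifier(train, spec, seed = seed)
  pred <- predict_stress(model, test)
  list(pred = pred, truth = test$label, selected = sel, n_train = nrow(train))
}

stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

check_min_per_class <- function(ds, folds) {
  n_min <- min(table(ds$label))
  if (n_min < folds) {
    abort(paste0("need at least ", folds, " rows per class after undersampling; ",
                 "minority class has ", n_min))
  }
}

#' Stratified k-fold cross-validation
#'
#' Default protocol is leakage-free: undersampling, feature selection and
#' normalization are re-fit inside each training fold. `paper_order = TRUE`
#' reproduces the original global order (balance, normalize and select once
#' on the full data before folding).
#'
#' @param ds A [labeled_dataset()].
#' @param spec A [model_spec()].
#' @param folds Number of folds (default 10).
#' @param seed Integer seed (fold assignment, undersampling, classifiers).
#' @param paper_order Use the global preprocessing order.
#' @param model_type Label for the result (e.g. `"LLSR"`).
#' @return A `stress_eval`: accuracy = mean fold accuracy (%), `fold_sd` =
#'   SD over folds, confusion summed over folds.
#' @export
evaluate_cv <- function(ds, spec, folds = 10, seed = 1, paper_order = FALSE,
                        model_type = "CV") {
  check_min_per_class(ds, folds)
  preselected <- NULL
  if (paper_order) {
    ds <- undersample(ds, seed = seed)
    ds <- normalize_features(ds)$train
    preselected <- select_features(ds, spec$k_features, spec$select_method)
  }
  fold <- stratified_folds(ds$label, folds, seed)
  accs <- numeric(folds)
  conf <- empty_confusion()
  sel_last <- NULL
  for (f in seq_len(folds)) {
    res <- run_fold(ds[fold != f, , drop = FALSE], ds[fold == f, , drop = FALSE],
                    spec, seed = derive_seed(seed, f),
                    paper_order = paper_order, preselected = preselected,
                    prenormalized = paper_order)
    accs[f] <- mean(res$pred == res$truth)
    conf <- confusion_add(conf, res$truth, res$pred)
    sel_last <- res$selected
  }
  new_stress_eval(model_type, "cv", spec, 100 * mean(accs), 100 * sd(accs),
                  conf, nrow(ds), nrow(ds), sel_last)
}

#' Single stratified train/test split
#'
#' As [evaluate_cv()] with one stratified 80/20 (by default) split and no
#' fold SD.
#'
#' @inheritParams evaluate_cv
#' @param train_frac Training fraction.
#' @return A `stress_eval`.
#' @export
evaluate_split <- function(ds, spec, train_frac = 0.8, seed = 1,
                           paper_order = FALSE, model_type = "split") {
  if (min(table(ds$label)) < 2) abort("need at least 2 rows per class")
  test_idx <- with_seed(seed, {
    unlist(lapply(levels(ds$label), function(lv) {
      idx <- which(ds$label == lv)
      sample(idx, max(1, round((1 - train_frac) * length(idx))))
    }))
  })
  train <- ds[-test_idx, , drop = FALSE]
  test <- ds[test_idx, , drop = FALSE]
  preselected <- NULL
  if (paper_order) {
    full <- undersample(ds, seed = seed)
    preselected <- select_features(full, spec$k_features, spec$select_method)
  }
  res <- run_fold(train, test, spec, seed = derive_seed(seed, 999),
                  preselected = preselected)
  conf <- confusion_add(empty_confusion(), res$truth, res$pred)
  new_stress_eval(model_type, "split", spec, 100 * mean(res$pred == res$truth),
                  NA_real_, conf, res$n_train, nrow(test), res$selected)
}

#' Cross-environment (lab-to-daily) transfer evaluation
#'
#' Trains on the laboratory environment only (undersampling, selection and
#' normalization fit there) and scores every daily session against its
#' self-report label — also when the training labels are known-context
#' (the LDKC configuration), mirroring that no known context exists in the
#' field.
#'
#' @param train_ds Lab [labeled_dataset()] (context or self-report labels).
#' @param test_ds Daily [labeled_dataset()] (self-report labels).
#' @param spec A [model_spec()].
#' @param seed Integer seed.
#' @param model_type Result label (`"LDSR"` or `"LDKC"`).
#' @return A `stress_eval` (single accuracy, no fold SD).
#' @export
evaluate_transfer <- function(train_ds, test_ds, spec, seed = 1,
                              model_type = "LDSR") {
  if (!nrow(test_ds)) abort("transfer evaluation needs a non-empty test set")
  if (length(intersect(unique(train_ds$environment), unique(test_ds$environment)))) {
    abort("training and test environments must be disjoint")
  }
  res <- run_fold(train_ds, test_ds, spec, seed = seed)
  conf <- confusion_add(empty_confusion(), res$truth, res$pred)
  new_stress_eval(model_type, "transfer", spec,
                  100 * mean(res$pred == res$truth), NA_real_, conf,
                  res$n_train, nrow(test_ds), res$selected)
}

#' Run the five-way cross-environment model matrix
#'
#' Evaluates every cell of the study's design space: LLKC and LLSR on lab
#' data and DDSR on daily data (each by 10-fold CV and an 80/20 split),
#' plus the LDKC and LDSR lab-to-daily transfers — crossed with the three
#' modalities and five classifiers. Cells whose preconditions fail (e.g.
#' too few rows per class) are skipped with the reason recorded.
#'
#' @param sessions Session feature table ([process_study()] output).
#' @param classifiers,modalities Subsets of the defaults to run.
#' @param folds CV folds.
#' @param seed Integer run seed; every cell derives its own stream.
#' @param paper_order Passed to the CV/split protocols.
#' @return Tibble (class `stress_matrix`): `model_type`, `eval_method`,
#'   `modality`, `classifier`, `accuracy`, `fold_sd`, `n_train`, `n_test`,
#'   `note`, and the `stress_eval` objects in a list-column `result`.
#' @export
run_model_matrix <- function(sessions,
                             classifiers = c("mlp", "rf", "knn", "svm", "logreg"),
                             modalities = c("combined", "hrv", "eda"),
                             folds = 10, seed = 1, paper_order = FALSE) {
  cells <- tidyr::expand_grid(
    model_type = c("LLKC", "LLSR", "DDSR", "LDKC", "LDSR"),
    modality = modalities,
    classifier = classifiers
  )
  rows <- purrr::pmap(cells, function(model_type, modality, classifier) {
    spec <- model_spec(classifier, modality)
    cfg <- switch(model_type,
      LLKC = list(env = "lab", label = "context", evals = c("cv", "split")),
      LLSR = list(env = "lab", label = "selfreport", evals = c("cv", "split")),
      DDSR = list(env = "daily", label = "selfreport", evals = c("cv", "split")),
      LDKC = list(label = "context", evals = "transfer"),
      LDSR = list(label = "selfreport", evals = "transfer")
    )
    purrr::map_dfr(cfg$evals, function(ev) {
      cell_seed <- derive_seed(seed, sum(utf8ToInt(paste(model_type, modality,
                                                         classifier, ev))))
      res <- tryCatch({
        if (ev == "transfer") {
          train <- labeled_dataset(sessions, cfg$label, modality, environment = "lab")
          test <- labeled_dataset(sessions, "selfreport", modality, environment = "daily")
          evaluate_transfer(train, test, spec, seed = cell_seed,
                            model_type = model_type)
        } else {
          ds <- labeled_dataset(sessions, cfg$label, modality, environment = cfg$env)
          if (ev == "cv") {
            evaluate_cv(ds, spec, folds = folds, seed = cell_seed,
                        paper_order = paper_order, model_type = model_type)
          } else {
            evaluate_split(ds, spec, seed = cell_seed,
                           paper_order = paper_order, model_type = model_type)
          }
        }
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) {
        tibble::tibble(
          model_type = model_type, eval_method = ev, modality = modality,
          classifier = classifier, accuracy = NA_real_, fold_sd = NA_real_,
          n_train = NA_integer_, n_test = NA_integer_,
          note = paste0("skipped: ", res), result = list(NULL)
        )
      } else {
        tibble::tibble(
          model_type = model_type, eval_method = ev, modality = modality,
          classifier = classifier, accuracy = res$accuracy,
          fold_sd = res$fold_sd, n_train = res$n_train, n_test = res$n_test,
          note = NA_character_, result = list(res)
        )
      }
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stress_matrix", class(out))
  out
}

# ---- broom-style methods ---------------------------------------------------

#' Tidy a stress evaluation
#'
#' @param x A `stress_eval`.
#' @param ... Unused.
#' @return Long tibble of confusion-matrix counts with cell metadata.
#' @export
tidy.stress_eval <- function(x, ...) {
  conf <- as.data.frame(as.table(x$confusion))
  names(conf) <- c("truth", "prediction", "n")
  dplyr::bind_cols(
    tibble::tibble(
      model_type = x$model_type, eval_method = x$eval_method,
      modality = x$spec$modality, classifier = x$spec$classifier
    )[rep(1, nrow(conf)), ],
    tibble::as_tibble(conf)
  )
}

#' @rdname tidy.stress_eval
#' @return `glance()`: one-row tibble with accuracy, fold SD and sizes.
#' @export
glance.stress_eval <- function(x, ...) {
  tibble::tibble(
    model_type = x$model_type, eval_method = x$eval_method,
    modality = x$spec$modality, classifier = x$spec$classifier,
    accuracy = x$accuracy, fold_sd = x$fold_sd,
    n_train = x$n_train, n_test = x$n_test,
    selected_features = paste(x$selected, collapse = ";")
  )
}
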