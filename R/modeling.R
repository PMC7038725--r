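#' Classifier specification
#'
#' Hyperparameters default to the study's values: MLP with two hidden
#' layers of five units, random forest with 100 trees, kNN with k = 3, SVM
#' with an RBF kernel (library-default cost/gamma), logistic regression
#' thresholded at 0.5. `k_features` defaults to 10 for the combined
#' modality and 5 for a single modality.
#'
#' @param classifier One of `"mlp", "rf", "knn", "svm", "logreg"`.
#' @param modality `"combined"`, `"hrv"` or `"eda"`.
#' @param k_features Number of features kept by selection; `NULL` for the
#'   modality default.
#' @param select_method `"correlation_rank"` (default) or `"cfs_subset"`.
#' @param hyper Optional overrides (e.g. `list(hidden = c(5, 5))`).
#' @return A `model_spec` list.
#' @export
model_spec <- function(classifier = c("mlp", "rf", "knn", "svm", "logreg"),
                       modality = c("combined", "hrv", "eda"),
                       k_features = NULL,
                       select_method = c("correlation_rank", "cfs_subset"),
                       hyper = list()) {
  classifier <- match.arg(classifier)
  modality <- match.arg(modality)
  select_method <- match.arg(select_method)
  if (is.null(k_features)) k_features <- if (modality == "combined") 10L else 5L
  dim_mod <- length(feature_schema(modality))
  if (!is_count(k_features) || k_features > dim_mod) {
    abort(paste0("k_features must be an integer in [1, ", dim_mod, "]"))
  }
  defaults <- list(hidden = c(5, 5), ntree = 100, k = 3, kernel = "radial",
                   threshold = 0.5, mlp_maxit = 500)
  hyper <- utils::modifyList(defaults, hyper)
  structure(
    list(classifier = classifier, modality = modality,
         k_features = as.integer(k_features), select_method = select_method,
         hyper = hyper),
    class = "model_spec"
  )
}

STRESS_LEVELS <- c("relaxed", "stressed")

#' Materialize a labeled dataset from the session feature table
#'
#' Picks the label family (`selfreport` = binarized PSS-5 score, `context`
#' = known lab context with recovery excluded) and the modality's feature
#' columns; rows with a missing label or any missing feature are dropped.
#'
#' @param sessions Session feature table ([process_study()] output).
#' @param label `"selfreport"` or `"context"`.
#' @param modality `"combined"`, `"hrv"` or `"eda"`.
#' @param environment Optional filter: `"lab"` or `"daily"`.
#' @return Tibble with `session_id`, `environment`, `label` (factor over
#'   relaxed/stressed) and the feature columns.
#' @export
labeled_dataset <- function(sessions, label = c("selfreport", "context"),
                            modality = c("combined", "hrv", "eda"),
                            environment = NULL) {
  label <- match.arg(label)
  modality <- match.arg(modality)
  feats <- feature_schema(modality)
  x <- sessions
  if (!is.null(environment)) x <- x[x$environment == environment, , drop = FALSE]
  y <- if (label == "selfreport") x$stress_selfreport else x$stress_context
  keep <- !is.na(y) & y %in% STRESS_LEVELS &
    stats::complete.cases(x[, feats, drop = FALSE])
  out <- dplyr::bind_cols(
    tibble::tibble(
      session_id = x$session_id[keep],
      environment = x$environment[keep],
      label = factor(y[keep], levels = STRESS_LEVELS)
    ),
    x[keep, feats, drop = FALSE]
  )
  out
}

#' Rank or search features on training data
#'
#' `correlation_rank` (default) ranks features by the absolute
#' point-biserial correlation with the binary label and keeps the top `k`
#' (ties broken by schema order). `cfs_subset` runs a forward best-first
#' search maximizing the correlation-based subset merit
#' `k r_cf / sqrt(k + k (k - 1) r_ff)` and returns at most `k` features.
#' Selection sees training data only.
#'
#' @param train A [labeled_dataset()].
#' @param k Number of features to keep.
#' @param method `"correlation_rank"` or `"cfs_subset"`.
#' @return Character vector of selected feature names.
#' @export
select_features <- function(train, k, method = c("correlation_rank", "cfs_subset")) {
  method <- match.arg(method)
  feats <- setdiff(names(train), c("session_id", "environment", "label"))
  if (k > length(feats)) abort(paste0("k = ", k, " exceeds ", length(feats), " features"))
  if (nlevels(droplevels(train$label)) < 2) abort("training data must contain both classes")
  y <- as.numeric(train$label == "stressed")
  r_cf <- vapply(feats, function(f) {
    v <- train[[f]]
    if (sd(v) == 0) 0 else abs(stats::cor(v, y))
  }, numeric(1))
  if (method == "correlation_rank") {
    ord <- order(-r_cf, seq_along(feats))  # ties -> schema order
    return(feats[ord[seq_len(k)]])
  }
  # CFS merit with forward best-first search
  cmat <- abs(suppressWarnings(stats::cor(train[, feats, drop = FALSE])))
  cmat[is.na(cmat)] <- 0
  merit <- function(sel) {
    kk <- length(sel)
    rcf <- mean(r_cf[sel])
    rff <- if (kk > 1) mean(cmat[sel, sel][upper.tri(matrix(0, kk, kk))]) else 0
    kk * rcf / sqrt(kk + kk * (kk - 1) * rff)
  }
  sel <- character(0)
  best_m <- -Inf
  stale <- 0
  while (length(sel) < k && stale < 5) {
    cand <- setdiff(feats, sel)
    ms <- vapply(cand, function(f) merit(c(sel, f)), numeric(1))
    i <- which.max(ms)
    if (ms[i] > best_m + 1e-12) {
      best_m <- ms[i]
      sel <- c(sel, cand[i])
      stale <- 0
    } else {
      sel <- c(sel, cand[i])  # keep expanding, but count staleness
      stale <- stale + 1
    }
  }
  head(sel, k)
}

#' Balance classes by random undersampling
#'
#' Uniformly samples the majority class without replacement down to the
#' minority count; minority rows are untouched. Deterministic under `seed`.
#'
#' @param ds A [labeled_dataset()].
#' @param seed Integer seed.
#' @return The balanced dataset (exact 50/50), original row order.
#' @export
undersample <- function(ds, seed = NULL) {
  tab <- table(ds$label)
  if (any(tab == 0)) abort("undersampling needs both classes present")
  n_min <- min(tab)
  maj <- names(tab)[which.max(tab)]
  keep <- with_seed(seed, {
    idx_maj <- which(ds$label == maj)
    sort(c(which(ds$label != maj), sample(idx_maj, n_min)))
  })
  ds[keep, , drop = FALSE]
}

#' Min-max normalization fit on training data
#'
#' Scales each feature to \[0, 1\] using the training minimum and maximum
#' and applies the same parameters to the test set (test values may leave
#' \[0, 1\]). Constant training features map to 0.
#'
#' @param train,test Labeled datasets sharing feature columns; `test` may
#'   be `NULL`.
#' @return List `train`, `test`, `params` (tibble feature/min/max).
#' @export
normalize_features <- function(train, test = NULL) {
  feats <- setdiff(names(train), c("session_id", "environment", "label"))
  params <- tibble::tibble(
    feature = feats,
    min = unname(vapply(feats, function(f) min(train[[f]]), numeric(1))),
    max = unname(vapply(feats, function(f) max(train[[f]]), numeric(1)))
  )
  apply_to <- function(x) {
    for (i in seq_along(feats)) {
      f <- feats[i]
      rng <- params$max[i] - params$min[i]
      x[[f]] <- if (rng == 0) rep(0, nrow(x)) else (x[[f]] - params$min[i]) / rng
    }
    x
  }
  list(train = apply_to(train), test = if (!is.null(test)) apply_to(test), params = params)
}

# ---- classifiers -----------------------------------------------------------

# Minimal feed-forward net: two tanh hidden layers, logistic output,
# cross-entropy loss (small ridge penalty) minimized by BFGS with analytic
# backpropagated gradients and a fixed iteration budget.
mlp_fit <- function(x, y01, hidden = c(5, 5), maxit = 500, seed = 1) {
  p <- ncol(x)
  h1 <- hidden[1]; h2 <- hidden[2]
  n_par <- (p + 1) * h1 + (h1 + 1) * h2 + (h2 + 1)
  lambda <- 1e-4
  unpack <- function(w) {
    i <- 0
    W1 <- matrix(w[i + seq_len((p + 1) * h1)], p + 1, h1); i <- i + (p + 1) * h1
    W2 <- matrix(w[i + seq_len((h1 + 1) * h2)], h1 + 1, h2); i <- i + (h1 + 1) * h2
    W3 <- matrix(w[i + seq_len(h2 + 1)], h2 + 1, 1)
    list(W1 = W1, W2 = W2, W3 = W3)
  }
  fwd <- function(w, xm) {
    ww <- unpack(w)
    a1 <- tanh(cbind(1, xm) %*% ww$W1)
    a2 <- tanh(cbind(1, a1) %*% ww$W2)
    stats::plogis(cbind(1, a2) %*% ww$W3)
  }
  loss <- function(w) {
    pr <- clamp(fwd(w, x), 1e-10, 1 - 1e-10)
    -mean(y01 * log(pr) + (1 - y01) * log(1 - pr)) + lambda * sum(w^2)
  }
  grad <- function(w) {
    ww <- unpack(w)
    n <- nrow(x)
    X1 <- cbind(1, x)
    a1 <- tanh(X1 %*% ww$W1)
    A1 <- cbind(1, a1)
    a2 <- tanh(A1 %*% ww$W2)
    A2 <- cbind(1, a2)
    pr <- stats::plogis(A2 %*% ww$W3)
    dz3 <- (pr - y01) / n
    dW3 <- crossprod(A2, dz3) + 2 * lambda * ww$W3
    dz2 <- (dz3 %*% t(ww$W3[-1, , drop = FALSE])) * (1 - a2^2)
    dW2 <- crossprod(A1, dz2) + 2 * lambda * ww$W2
    dz1 <- (dz2 %*% t(ww$W2[-1, , drop = FALSE])) * (1 - a1^2)
    dW1 <- crossprod(X1, dz1) + 2 * lambda * ww$W1
    c(as.vector(dW1), as.vector(dW2), as.vector(dW3))
  }
  w0 <- with_seed(seed, rnorm(n_par, 0, 0.5))
  fit <- optim(w0, loss, grad, method = "BFGS", control = list(maxit = maxit))
  list(w = fit$par, fwd = fwd)
}

#' Fit one of the five stress classifiers
#'
#' The fit sees training rows only; prediction is a separate step
#' ([predict_stress()]), so test labels can never influence the fitted
#' state.
#'
#' @param train Normalized [labeled_dataset()] restricted to the selected
#'   features.
#' @param spec A [model_spec()].
#' @param seed Integer seed (forest bootstrap, MLP initialization).
#' @return A `stress_model` object.
#' @export
fit_stress_classifier <- function(train, spec, seed = 1) {
  feats <- setdiff(names(train), c("session_id", "environment", "label"))
  x <- as.matrix(train[, feats, drop = FALSE])
  y <- droplevels(train$label)
  if (nlevels(y) < 2) abort("training data must contain both classes")
  y <- factor(as.character(y), levels = STRESS_LEVELS)
  fit <- switch(spec$classifier,
    rf = with_seed(seed, randomForest::randomForest(x, y, ntree = spec$hyper$ntree)),
    svm = with_seed(seed, e1071::svm(x, y, kernel = spec$hyper$kernel)),
    knn = list(x = x, y = y, k = spec$hyper$k),
    logreg = suppressWarnings(glm(y == "stressed" ~ ., family = binomial(),
                                  data = data.frame(y = y, x, check.names = FALSE))),
    mlp = mlp_fit(x, as.numeric(y == "stressed"), hidden = spec$hyper$hidden,
                  maxit = spec$hyper$mlp_maxit, seed = seed)
  )
  structure(list(spec = spec, features = feats, fit = fit, seed = seed),
            class = "stress_model")
}

#' Predict stress labels
#'
#' @param model A `stress_model` from [fit_stress_classifier()].
#' @param newdata Data frame containing the model's feature columns
#'   (normalized with the training parameters).
#' @return Factor over `relaxed`/`stressed`.
#' @export
predict_stress <- function(model, newdata) {
  x <- as.matrix(newdata[, model$features, drop = FALSE])
  spec <- model$spec
  out <- switch(spec$classifier,
    rf = as.character(predict(model$fit, x)),
    svm = as.character(predict(model$fit, x)),
    knn = as.character(class::knn(model$fit$x, x, model$fit$y, k = model$fit$k)),
    logreg = {
      pr <- predict(model$fit, newdata = data.frame(x, check.names = FALSE),
                    type = "response")
      ifelse(pr >= spec$hyper$threshold, "stressed", "relaxed")
    },
    mlp = {
      pr <- model$fit$fwd(model$fit$w, x)
      ifelse(pr >= 0.5, "stressed", "relaxed")
    }
  )
  factor(out, levels = STRESS_LEVELS)
}
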