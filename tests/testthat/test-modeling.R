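test_that("correlation ranking matches a brute-force point-biserial oracle", {
  ds <- make_labeled(n_per_class = 20, n_feats = 5, seed = 3)
  feats <- feature_schema()[1:5]
  y <- as.numeric(ds$label == "stressed")
  oracle <- sapply(feats, function(f) abs(cor(ds[[f]], y)))
  ranked <- select_features(ds, 5)
  expect_equal(ranked, feats[order(-oracle)])
  expect_equal(sort(select_features(ds, 5)), sort(feats))  # k = all is identity

  # a feature equal to the label is ranked first
  ds$hrv_tinn <- y
  expect_equal(select_features(ds, 1), "hrv_tinn")
  expect_error(select_features(ds, 7), "exceeds")
})

test_that("CFS subset search prefers relevant, non-redundant features", {
  withr::with_seed(4, {
    n <- 80
    y <- rep(c(0, 1), each = n / 2)
    ds <- tibble::tibble(
      session_id = as.character(1:n), environment = "lab",
      label = factor(ifelse(y == 1, "stressed", "relaxed"),
                     c("relaxed", "stressed")),
      hrv_mean_rr = y + rnorm(n, 0, 0.3),        # informative
      hrv_sdnn = y + rnorm(n, 0, 0.3),           # informative, semi-redundant
      hrv_rmssd = rnorm(n),                      # noise
      hrv_pnn50 = rnorm(n)                       # noise
    )
    sel <- select_features(ds, 2, method = "cfs_subset")
    expect_setequal(sel, c("hrv_mean_rr", "hrv_sdnn"))
  })
})

test_that("undersampling yields exact 50/50 balance, untouched minority, and is seeded", {
  ds <- make_labeled(n_per_class = 73, seed = 7)
  imb <- ds[c(1:73, 74:100), ]                   # 73 relaxed / 27 stressed
  bal <- undersample(imb, seed = 2)
  expect_equal(as.integer(table(bal$label)), c(27L, 27L))
  expect_setequal(bal$session_id[bal$label == "stressed"],
                  imb$session_id[imb$label == "stressed"])
  expect_identical(undersample(imb, seed = 2), undersample(imb, seed = 2))

  # balanced input is an identity up to ordering
  expect_setequal(undersample(ds, seed = 1)$session_id, ds$session_id)
  empty <- imb[imb$label == "relaxed", ]
  expect_error(undersample(empty, seed = 1), "both classes")
})

test_that("min-max normalization is fit on train and applied to test", {
  tr <- make_labeled(3, n_feats = 2, seed = 1)[1:3, ]
  tr$hrv_mean_rr <- c(2, 4, 6)
  tr$hrv_sdnn <- 5
  te <- tr[1, ]
  te$hrv_mean_rr <- 8
  nz <- normalize_features(tr, te)
  expect_equal(nz$train$hrv_mean_rr, c(0, 0.5, 1))
  expect_equal(nz$test$hrv_mean_rr, 1.5)        # out-of-range allowed
  expect_equal(nz$train$hrv_sdnn, rep(0, 3))    # constant column maps to 0
})

test_that("every classifier separates a strongly separated fixture perfectly in CV", {
  ds <- make_labeled(n_per_class = 20, shift = 6, sd = 0.2, seed = 9)
  for (cl in c("mlp", "rf", "knn", "svm", "logreg")) {
    ev <- evaluate_cv(ds, model_spec(cl), folds = 10, seed = 1)
    expect_equal(ev$accuracy, 100, info = cl)
    expect_equal(ev$fold_sd, 0, info = cl)
    # accuracy is consistent with the summed confusion matrix
    expect_equal(ev$accuracy,
                 100 * sum(diag(ev$confusion)) / sum(ev$confusion),
                 tolerance = 1.5, info = cl)
  }
  expect_error(evaluate_cv(ds[1:15, ], model_spec("rf"), folds = 10, seed = 1),
               "at least 10 rows per class")
})

test_that("the 80/20 split is stratified, seeded, and perfect on separable data", {
  ds <- make_labeled(n_per_class = 50, shift = 6, sd = 0.2, seed = 10)
  ev <- evaluate_split(ds, model_spec("rf"), seed = 3)
  expect_equal(ev$n_test, 20)
  expect_equal(ev$accuracy, 100)
  ev2 <- evaluate_split(ds, model_spec("rf"), seed = 3)
  expect_identical(ev$confusion, ev2$confusion)
})

test_that("paper-order preprocessing reproduces the global protocol", {
  ds <- make_labeled(n_per_class = 25, shift = 4, sd = 0.5, seed = 12)
  ev <- evaluate_cv(ds, model_spec("logreg"), folds = 5, seed = 2,
                    paper_order = TRUE)
  expect_gt(ev$accuracy, 90)
})

test_that("transfer evaluation enforces disjoint environments and scores daily self-reports", {
  lab <- make_labeled(n_per_class = 20, shift = 5, sd = 0.5, seed = 5,
                      environment = "lab")
  daily <- make_labeled(n_per_class = 15, shift = 5, sd = 0.8, seed = 6,
                        environment = "daily")
  ev <- evaluate_transfer(lab, daily, model_spec("rf"), seed = 1)
  expect_equal(ev$n_test, 30)
  expect_gt(ev$accuracy, 80)
  expect_error(evaluate_transfer(lab, lab, model_spec("rf")), "disjoint")
  expect_error(evaluate_transfer(lab, daily[0, ], model_spec("rf")),
               "non-empty")
})

test_that("permuting test labels never changes the fitted model or its predictions", {
  ds <- make_labeled(n_per_class = 20, shift = 2, sd = 1, seed = 8)
  train <- ds[1:30, ]
  test <- ds[31:40, ]
  for (cl in c("mlp", "rf", "knn", "svm", "logreg")) {
    nz <- normalize_features(train, test)
    model <- fit_stress_classifier(nz$train, model_spec(cl), seed = 4)
    p1 <- predict_stress(model, nz$test)
    test_perm <- nz$test
    test_perm$label <- sample(test_perm$label)
    model2 <- fit_stress_classifier(nz$train, model_spec(cl), seed = 4)
    p2 <- predict_stress(model2, test_perm)
    expect_identical(p1, p2, info = cl)
  }
})

test_that("label-permuted data scores at chance in CV", {
  ds <- make_labeled(n_per_class = 25, shift = 4, sd = 0.5, seed = 20)
  accs <- sapply(1:10, function(s) {
    perm <- ds
    perm$label <- withr::with_seed(s, sample(perm$label))
    evaluate_cv(perm, model_spec("logreg"), folds = 5, seed = s)$accuracy
  })
  expect_lt(abs(mean(accs) - 50), 3 * sd(accs) / sqrt(length(accs)))
})

test_that("tidy and glance methods expose confusion counts and headline numbers", {
  ds <- make_labeled(n_per_class = 15, shift = 5, sd = 0.4, seed = 30)
  ev <- evaluate_cv(ds, model_spec("rf"), folds = 5, seed = 1, model_type = "LLSR")
  td <- tidy(ev)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$n), ev$n_test)
  gl <- glance(ev)
  expect_equal(gl$accuracy, ev$accuracy)
  expect_equal(gl$model_type, "LLSR")
})
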