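test_that("hyperparameter grids carry exactly the printed axes", {
  rf <- hyperparameter_grid("random_forest")
  expect_equal(nrow(rf$combinations), 3 * 2 * 4 * 10 * 3)  # 720
  expect_setequal(rf$axes$criterion, c("gini", "entropy"))
  expect_setequal(rf$axes$max_features, c("log2", "auto", "sqrt"))

  gb <- hyperparameter_grid("gradient_boosting")
  expect_equal(gb$axes$max_depth, c(3, 5, 7, 10, 15))

  svm <- hyperparameter_grid("svm")
  expect_equal(nrow(svm$combinations), 8)
  mlp <- hyperparameter_grid("mlp")
  expect_setequal(mlp$axes$hidden_layer_sizes, c("50", "100", "50,50"))
  expect_equal(mlp$axes$max_iter, 10000)

  expect_error(hyperparameter_grid("naive_bayes"), class = "ligandscreen_unknown_family")
})

test_that("confusion counts agree with exhaustive pairing on random vectors", {
  cc <- confusion_counts(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                         c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]), c(TP = 5, TN = 5, FP = 0, FN = 0))

  cc2 <- confusion_counts(c(1, 1, 1, 0, 0), rep(1, 5))
  expect_equal(unlist(cc2[c("TP", "FP", "TN", "FN")]), c(TP = 3, FP = 2, TN = 0, FN = 0))

  set.seed(3)
  for (trial in 1:50) {
    n <- sample(1:500, 1)
    yt <- rbinom(n, 1, 0.4); yp <- rbinom(n, 1, 0.6)
    cc <- confusion_counts(yt, yp)
    # recount by walking the pairs
    ref <- c(0, 0, 0, 0)
    for (i in seq_len(n)) {
      ref <- ref + c(yt[i] & yp[i], !yt[i] & yp[i], !yt[i] & !yp[i], yt[i] & !yp[i])
    }
    expect_equal(c(cc$TP, cc$FP, cc$TN, cc$FN), ref)
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, n)
  }

  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), class = "ligandscreen_length_mismatch")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), class = "ligandscreen_non_binary")
})

test_that("the metric suite reproduces hand-evaluated formulas", {
  perfect <- compute_metrics(confusion_counts(rep(c(1, 0), each = 50),
                                              rep(c(1, 0), each = 50)))
  expect_equal(perfect$MCC, 1)
  expect_equal(perfect$BA, 1)
  expect_equal(perfect$F1, 1)

  r <- compute_metrics(structure(list(TP = 3, FP = 1, TN = 4, FN = 2),
                                 class = "confusion_counts"))
  expect_equal(r$SE, 0.6)
  expect_equal(r$SP, 0.8)
  expect_equal(r$ACC, 0.7)
  expect_equal(r$P, 0.75)
  expect_equal(r$BA, 0.7)
  expect_equal(r$MCC, 10 / sqrt(600))
})

test_that("AUC by midranks equals the exhaustive pair-counting oracle", {
  set.seed(11)
  for (trial in 1:60) {
    n <- sample(4:100, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))   # both classes guaranteed
    scores <- round(runif(n), sample(c(1, 2, 8), 1))  # induce ties sometimes
    expect_equal(auc_rank(scores, labels), auc_pair_oracle(scores, labels))
  }
  # label-independent scores concentrate near 1/2
  set.seed(12)
  labels <- rbinom(2000, 1, 0.5)
  scores <- runif(2000)
  expect_equal(auc_rank(scores, labels), 0.5, tolerance = 0.03)
  # third route: an established ROC implementation agrees
  proc_auc <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                             direction = "<", levels = c(0, 1))))
  expect_equal(auc_rank(scores, labels), proc_auc, tolerance = 1e-10)
})

test_that("metric identities hold: BA, MCC sign flip, zero-denominator policy", {
  set.seed(7)
  for (trial in 1:200) {
    cts <- as.list(rmultinom(1, sample(1:200, 1), rep(0.25, 4))[, 1])
    names(cts) <- c("TP", "FP", "TN", "FN")
    r <- compute_metrics(structure(cts, class = "confusion_counts"))
    expect_identical(r$BA, (r$SE + r$SP) / 2)
    # inverted predictions: TP<->FN, TN<->FP flips the MCC sign
    inv <- structure(list(TP = cts$FN, FP = cts$TN, TN = cts$FP, FN = cts$TP),
                     class = "confusion_counts")
    expect_equal(compute_metrics(inv)$MCC, -r$MCC, tolerance = 1e-12)
  }
  allpos <- compute_metrics(structure(list(TP = 5, FP = 5, TN = 0, FN = 0),
                                      class = "confusion_counts"))
  expect_equal(allpos$SP, 0)
  expect_equal(allpos$MCC, 0)   # zero marginal (TN+FN) convention
  allneg <- compute_metrics(structure(list(TP = 0, FP = 0, TN = 3, FN = 2),
                                      class = "confusion_counts"))
  expect_equal(allneg$P, 0)
  expect_true("P" %in% allneg$undefined)
})

test_that("grid search selects by CV AUC and is reproducible", {
  set.seed(2)
  X <- matrix(rbinom(120 * 40, 1, 0.3), 120, 40)
  colnames(X) <- paste0("b", 1:40)
  y <- as.integer(X[, 1] | X[, 2])
  single <- data.frame(max_depth = 7)
  tm <- tune_and_train(X, y, "gradient_boosting", grid = single, folds = 5, seed = 9)
  expect_equal(tm$best_params$max_depth, 7)

  grid2 <- data.frame(max_depth = c(3, 5))
  a <- tune_and_train(X, y, "gradient_boosting", grid = grid2, folds = 5, seed = 9)
  b <- tune_and_train(X, y, "gradient_boosting", grid = grid2, folds = 5, seed = 9)
  expect_identical(a$best_params, b$best_params)
  expect_identical(a$cv_mean, b$cv_mean)

  expect_error(tune_and_train(X, rep(1L, nrow(X)), "gradient_boosting", grid = single),
               class = "ligandscreen_empty_class")
  expect_error(tune_and_train(X[1:8, ], y[1:8], "gradient_boosting", grid = single,
                              folds = 5),
               class = "ligandscreen_too_few_records")
})

test_that("the motif-separable benchmark is learnable and certified by a 1-NN oracle", {
  b <- bench_small()
  fp <- bench_fps("morgan1024")
  y <- as.integer(b$label == "active")
  # 1-nearest-neighbour on Tanimoto similarity, leave-one-out: certifies that
  # the fingerprint space separates the classes before any model is trained
  S <- ligandscreen:::tanimoto_matrix(fp)
  diag(S) <- -1
  nn_score <- y[apply(S, 1, which.max)]
  expect_gte(auc_rank(nn_score, y), 0.9)

  colnames(fp) <- paste0("b", seq_len(ncol(fp)))
  tm <- tune_and_train(fp, y, "gradient_boosting", grid = data.frame(max_depth = 3),
                       folds = 5, seed = 42)
  expect_gte(tm$cv_mean[["AUC"]], 0.9)
})

test_that("every fingerprint/family combination is evaluated with all eight metrics", {
  cfg <- synthetic_config(40, 40, label_noise = 0, seed = 23)
  d <- gen_benchmark_set(cfg)
  d$std_smiles <- d$smiles
  sp <- split_dataset(d, ratio = 0.8, seed = 23)
  grids <- list(
    random_forest = data.frame(n_estimators = 100, criterion = "gini",
                               max_depth = "none", min_samples_leaf = 1,
                               max_features = "sqrt", stringsAsFactors = FALSE),
    svm = data.frame(gamma = "scale", C = 1, stringsAsFactors = FALSE),
    mlp = data.frame(hidden_layer_sizes = "50", activation = "relu", solver = "adam",
                     learning_rate_init = 0.01, max_iter = 150, stringsAsFactors = FALSE),
    gradient_boosting = data.frame(max_depth = 3)
  )
  ev <- evaluate_combinations(d, sp, folds = 3, seed = 23, grids = grids)
  expect_equal(nrow(ev$metrics), 5 * 4 * 2)  # cv_mean and test stage per combination
  metric_cols <- c("SE", "SP", "ACC", "MCC", "P", "F1", "BA", "AUC")
  expect_true(all(is.finite(as.matrix(ev$metrics[, metric_cols]))))
  expect_true(all(ev$metrics$BA == (ev$metrics$SE + ev$metrics$SP) / 2))
  # noise-free planted-motif data is separable for every combination
  expect_true(all(ev$metrics$AUC[ev$metrics$stage == "test"] >= 0.8))
  expect_length(ev$confusion, 5)
  expect_s3_class(ev$confusion[[1]], "confusion_counts")
})
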