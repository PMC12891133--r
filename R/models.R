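# The fingerprint x model evaluation grid: four model families (random
# forest, SVM, MLP, gradient boosting), their printed hyperparameter grids,
# five-fold cross-validated grid search selecting on mean CV AUC, and the
# held-out evaluation across all fingerprint/family combinations.

MODEL_FAMILIES <- c("random_forest", "svm", "mlp", "gradient_boosting")

#' Hyperparameter grid for a model family
#'
#' Returns the full tuning grid for one of the four supported families. The
#' grid is returned both as named axes and as the expanded table of
#' combinations, in deterministic order (first axis varies fastest).
#'
#' @param family One of \code{random_forest}, \code{svm}, \code{mlp},
#'   \code{gradient_boosting}.
#' @return List of class \code{hyperparameter_grid}: \code{family},
#'   \code{axes} (named list of value sets) and \code{combinations}
#'   (data.frame, one row per grid point).
#' @export
hyperparameter_grid <- function(family) {
  axes <- switch(family,
    random_forest = list(
      n_estimators = c(50, 100, 200),
      criterion = c("gini", "entropy"),
      max_depth = c("none", "5", "10", "15"),
      min_samples_leaf = 1:10,
      max_features = c("log2", "auto", "sqrt")
    ),
    svm = list(
      gamma = c("scale", "auto"),
      C = c(0.01, 0.1, 1, 10)
    ),
    mlp = list(
      hidden_layer_sizes = c("50", "100", "50,50"),
      activation = c("tanh", "relu"),
      solver = c("sgd", "adam"),
      learning_rate_init = c(0.001, 0.01),
      max_iter = 10000
    ),
    gradient_boosting = list(
      max_depth = c(3, 5, 7, 10, 15)
    ),
    ls_stop("unknown_family", "unknown model family: %s", family)
  )
  comb <- expand.grid(axes, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  structure(list(family = family, axes = axes, combinations = comb),
            class = "hyperparameter_grid")
}

resolve_gamma <- function(gamma, X) {
  p <- ncol(X)
  if (identical(gamma, "scale")) 1 / (p * stats::var(as.numeric(X)))
  else if (identical(gamma, "auto")) 1 / p
  else as.numeric(gamma)
}

parse_hidden <- function(s) as.integer(strsplit(as.character(s), ",", fixed = TRUE)[[1]])

# Fit one model family at one grid point. X is a numeric feature matrix,
# y a 0/1 integer vector. Returns a ligandscreen_model whose scores are
# probabilities of the positive class.
fit_model <- function(family, params, X, y, seed = 42) {
  y <- as.integer(y)
  fit <- switch(family,
    random_forest = {
      # ranger backend: 'criterion' is recorded but ranger splits on Gini
      # impurity for both values; max_features 'auto' is the sqrt alias.
      p <- ncol(X)
      mtry <- switch(as.character(params$max_features),
                     log2 = max(1, floor(log2(p))),
                     auto = , sqrt = max(1, floor(sqrt(p))))
      md <- if (identical(as.character(params$max_depth), "none")) 0 else as.integer(params$max_depth)
      ranger::ranger(
        x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
        num.trees = as.integer(params$n_estimators),
        mtry = mtry, min.node.size = as.integer(params$min_samples_leaf),
        max.depth = md, probability = TRUE, seed = seed, num.threads = 1
      )
    },
    svm = {
      with_stream(seed, "svm_fit",
        e1071::svm(x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
                   gamma = resolve_gamma(params$gamma, X), cost = as.numeric(params$C),
                   probability = TRUE, scale = FALSE))
    },
    mlp = {
      mlp_fit(X, y, hidden = parse_hidden(params$hidden_layer_sizes),
              activation = as.character(params$activation),
              solver = as.character(params$solver),
              learning_rate_init = as.numeric(params$learning_rate_init),
              max_iter = as.integer(params$max_iter %||% 200),
              seed = seed)
    },
    gradient_boosting = {
      dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = as.integer(params$max_depth),
                      nthread = 1, seed = seed),
        data = dm, nrounds = 100, verbose = 0)
    },
    ls_stop("unknown_family", "unknown model family: %s", family)
  )
  structure(list(family = family, params = as.list(params), fit = fit, seed = seed),
            class = "ligandscreen_model")
}

#' Predict positive-class scores from a fitted model
#' @param object A \code{ligandscreen_model}.
#' @param newdata Feature matrix with the columns used in training.
#' @param ... Unused.
#' @export
predict.ligandscreen_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  switch(object$family,
    random_forest = {
      pr <- stats::predict(object$fit, data = as.data.frame(X), num.threads = 1)$predictions
      as.numeric(pr[, "1"])
    },
    svm = {
      pr <- attr(stats::predict(object$fit, X, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    },
    mlp = mlp_predict(object$fit, X),
    gradient_boosting = as.numeric(stats::predict(object$fit, X))
  )
}

# Stratified fold assignment: each class is spread as evenly as possible
# across folds so every fold sees both classes.
make_folds <- function(y, folds, seed) {
  with_stream(seed, "make_folds", {
    assign <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      assign[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
    assign
  })
}

#' Grid search with cross-validation, then refit on the full training set
#'
#' Evaluates every grid point with k-fold cross-validation (folds stratified
#' by class), selects the point maximizing mean CV AUC (ties: higher mean
#' ACC, then first in deterministic grid order) and refits it on all
#' training data.
#'
#' @param X Feature matrix (training set).
#' @param y Binary 0/1 labels.
#' @param family Model family (see \code{\link{hyperparameter_grid}}).
#' @param grid Optional \code{hyperparameter_grid} or data.frame of
#'   combinations; defaults to the family's full grid.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed controlling folds and every fit.
#' @return List of class \code{tuned_model}: \code{model} (refit on all
#'   data), \code{best_params}, \code{cv_mean} (mean CV metric report of the
#'   winner), \code{cv_folds} (per-fold reports of the winner) and
#'   \code{cv_table} (mean AUC/ACC per grid point).
#' @export
tune_and_train <- function(X, y, family, grid = NULL, folds = 5, seed = 42) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) ls_stop("empty_class", "training data must contain both classes")
  if (min(table(y)) < folds) {
    ls_stop("too_few_records", "need at least %d records per class for %d folds", folds, folds)
  }
  comb <- if (is.null(grid)) hyperparameter_grid(family)$combinations
          else if (inherits(grid, "hyperparameter_grid")) grid$combinations
          else grid
  fold_id <- make_folds(y, folds, seed)
  eval_point <- function(params) {
    reports <- lapply(seq_len(folds), function(f) {
      tr <- fold_id != f; te <- !tr
      m <- fit_model(family, params, X[tr, , drop = FALSE], y[tr], seed = seed)
      sc <- predict(m, X[te, , drop = FALSE])
      compute_metrics(confusion_counts(y[te], as.integer(sc >= 0.5)), sc, y[te])
    })
    reports
  }
  cv_table <- data.frame(point = seq_len(nrow(comb)), AUC = NA_real_, ACC = NA_real_)
  all_reports <- vector("list", nrow(comb))
  for (i in seq_len(nrow(comb))) {
    reports <- eval_point(comb[i, , drop = FALSE])
    cv_table$AUC[i] <- mean(vapply(reports, `[[`, numeric(1), "AUC"))
    cv_table$ACC[i] <- mean(vapply(reports, `[[`, numeric(1), "ACC"))
    all_reports[[i]] <- reports
  }
  best <- order(-cv_table$AUC, -cv_table$ACC, cv_table$point)[1]
  best_params <- comb[best, , drop = FALSE]
  model <- fit_model(family, best_params, X, y, seed = seed)
  cv_folds <- all_reports[[best]]
  cv_mean <- colMeans(do.call(rbind, lapply(cv_folds, metric_report_row)))
  structure(list(model = model, best_params = as.list(best_params),
                 cv_mean = cv_mean, cv_folds = cv_folds, cv_table = cv_table,
                 folds = folds, seed = seed),
            class = "tuned_model")
}

#' Evaluate every fingerprint x model-family combination
#'
#' For each combination: features are computed from standardized SMILES,
#' grid search with k-fold CV runs on the training partition, and the
#' selected model is evaluated exactly once on the held-out test partition.
#' CV and test metrics are reported side by side.
#'
#' @param dataset data.frame with \code{id}, \code{std_smiles}, \code{label}.
#' @param split A \code{dataset_split} fixing the train/test partition.
#' @param fingerprint_types Fingerprint types (default the five modeling
#'   types).
#' @param families Model families (default all four).
#' @param grids Optional named list (by family) of reduced grids.
#' @param folds CV folds.
#' @param seed Integer seed.
#' @return List of class \code{evaluation_grid}: \code{metrics} (one row per
#'   combination and evaluation stage), \code{best_family} (highest mean test
#'   AUC) and \code{confusion} (test-set confusion counts of the best family,
#'   per fingerprint).
#' @export
evaluate_combinations <- function(dataset, split,
                                  fingerprint_types = MODEL_FP_TYPES,
                                  families = MODEL_FAMILIES,
                                  grids = NULL, folds = 5, seed = 42) {
  lab <- as.integer(dataset$label == "active")
  names(lab) <- dataset$id
  tr_idx <- match(split$train, dataset$id)
  te_idx <- match(split$test, dataset$id)
  rows <- list(); conf <- list()
  for (fp_type in fingerprint_types) {
    fp <- fingerprint_matrix(dataset$std_smiles, fp_type)
    rownames(fp) <- dataset$id
    colnames(fp) <- paste0("b", seq_len(ncol(fp)))
    Xtr <- fp[tr_idx, , drop = FALSE]; ytr <- lab[tr_idx]
    Xte <- fp[te_idx, , drop = FALSE]; yte <- lab[te_idx]
    for (family in families) {
      tuned <- tune_and_train(Xtr, ytr, family,
                              grid = grids[[family]], folds = folds, seed = seed)
      sc <- predict(tuned$model, Xte)
      cc <- confusion_counts(yte, as.integer(sc >= 0.5))
      test_rep <- compute_metrics(cc, sc, yte)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(fingerprint = fp_type, family = family, stage = "cv_mean",
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(tuned$cv_mean))[c("SE", "SP", "ACC", "MCC", "P", "F1", "BA", "AUC")]
      )
      rows[[length(rows) + 1]] <- cbind(
        data.frame(fingerprint = fp_type, family = family, stage = "test",
                   stringsAsFactors = FALSE),
        metric_report_row(test_rep)[c("SE", "SP", "ACC", "MCC", "P", "F1", "BA", "AUC")]
      )
      conf[[paste(fp_type, family, sep = ".")]] <- cc
    }
  }
  metrics <- do.call(rbind, rows)
  test_rows <- metrics[metrics$stage == "test", ]
  mean_auc <- tapply(test_rows$AUC, test_rows$family, mean)
  best_family <- names(mean_auc)[which.max(mean_auc)]
  best_conf <- conf[paste(fingerprint_types, best_family, sep = ".")]
  names(best_conf) <- fingerprint_types
  structure(list(metrics = metrics, best_family = best_family,
                 confusion = best_conf, seed = seed),
            class = "evaluation_grid")
}

#' Write the metric matrix as TSV
#' @param evaluation An \code{evaluation_grid}.
#' @param path Output path.
#' @export
write_metric_tsv <- function(evaluation, path) {
  utils::write.table(evaluation$metrics, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
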