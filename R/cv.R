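# Method panel and nested (double) cross-validation.
#
# Each panel entry is a self-contained wrapper: a fit(x, y, params, seed)
# closure, a predict(fit, x) closure, and an optional hyperparameter grid
# tuned by inner CV. Methods without a grid run at their defaults.

needsPkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("method requires package '", pkg, "'", call. = FALSE)
}

classifierFromProb <- function(prob) {
  factor(ifelse(prob > 0.5, "positive", "negative"),
         levels = c("negative", "positive"))
}

# thinned log-scale default grids (overridable via the `grid` element);
# the conventional wide 1-step grids are disproportionate at these
# sample sizes
gridC <- 2^seq(-5, 10, by = 3)
gridGamma <- 2^seq(-20, 10, by = 5)
gridEpsilon <- 2^seq(-10, 0, by = 5)
gridLambda <- 10^seq(-3, 2, by = 1)

methodDefs <- function() {
  list(
    # ---- classification ----
    logistic = list(task = "classification", grid = NULL,
      fit = function(x, y, params, seed) {
        # ridge-regularized logistic at a fixed light penalty (the
        # multinomial MLE is ill-posed when p > n)
        glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                       lambda = 1 / nrow(x))
      },
      predict = function(fit, x)
        classifierFromProb(as.numeric(
          stats::predict(fit, x, type = "response")))),
    lda = list(task = "classification", grid = NULL,
      fit = function(x, y, params, seed) {
        needsPkg("MASS")
        MASS::lda(x, grouping = y)
      },
      predict = function(fit, x)
        factor(as.character(stats::predict(fit, x)$class),
               levels = c("negative", "positive"))),
    naive_bayes = list(task = "classification", grid = NULL,
      fit = function(x, y, params, seed) e1071::naiveBayes(x, y),
      predict = function(fit, x)
        factor(as.character(stats::predict(fit, x)),
               levels = c("negative", "positive"))),
    knn = list(task = "classification", grid = NULL,
      fit = function(x, y, params, seed) {
        needsPkg("class")
        list(x = x, y = y)
      },
      predict = function(fit, x)
        factor(as.character(class::knn(fit$x, x, fit$y, k = 5)),
               levels = c("negative", "positive"))),
    svm_linear = list(task = "classification", grid = list(cost = gridC),
      fit = function(x, y, params, seed)
        e1071::svm(x, y, kernel = "linear", cost = params$cost, scale = FALSE),
      predict = function(fit, x)
        factor(as.character(stats::predict(fit, x)),
               levels = c("negative", "positive"))),
    svm_rbf = list(task = "classification",
      grid = list(cost = gridC, gamma = gridGamma),
      fit = function(x, y, params, seed)
        e1071::svm(x, y, kernel = "radial", cost = params$cost,
                   gamma = params$gamma, scale = FALSE),
      predict = function(fit, x)
        factor(as.character(stats::predict(fit, x)),
               levels = c("negative", "positive"))),
    tree = list(task = "classification", grid = NULL,
      fit = function(x, y, params, seed) {
        needsPkg("rpart")
        df <- data.frame(.y = y, x, check.names = FALSE)
        rpart::rpart(.y ~ ., data = df, method = "class")
      },
      predict = function(fit, x)
        factor(as.character(stats::predict(fit,
                 data.frame(x, check.names = FALSE), type = "class")),
               levels = c("negative", "positive"))),
    rf = list(task = "classification", grid = NULL,
      fit = function(x, y, params, seed)
        ranger::ranger(x = x, y = y, num.trees = 500, seed = seed,
                       num.threads = 1),
      predict = function(fit, x)
        factor(as.character(stats::predict(fit, data = x,
                                           num.threads = 1)$predictions),
               levels = c("negative", "positive"))),
    xgb = list(task = "classification", grid = NULL,
      fit = function(x, y, params, seed) {
        needsPkg("xgboost")
        dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y == "positive"))
        xgboost::xgb.train(params = list(objective = "binary:logistic",
                                         nthread = 1, seed = seed),
                           data = dtrain, nrounds = 100, verbose = 0)
      },
      predict = function(fit, x) classifierFromProb(
        stats::predict(fit, xgboost::xgb.DMatrix(x)))),

    # ---- regression ----
    ols = list(task = "regression", grid = NULL,
      fit = function(x, y, params, seed) {
        fit <- stats::lm.fit(cbind(1, x), y)
        coef <- fit$coefficients
        coef[is.na(coef)] <- 0    # rank deficiency: drop aliased columns
        coef
      },
      predict = function(fit, x) as.numeric(cbind(1, x) %*% fit)),
    pls = list(task = "regression", grid = list(ncomp = 1:10),
      fit = function(x, y, params, seed) {
        needsPkg("mixOmics")
        nc <- min(params$ncomp, ncol(x), nrow(x) - 1L)
        mixOmics::pls(x, y, ncomp = nc, scale = FALSE)
      },
      predict = function(fit, x) {
        p <- stats::predict(fit, x)$predict
        as.numeric(p[, 1, dim(p)[3]])
      }),
    ridge = list(task = "regression", grid = list(lambda = gridLambda),
      fit = function(x, y, params, seed)
        glmnet::glmnet(x, y, alpha = 0, lambda = params$lambda),
      predict = function(fit, x) as.numeric(stats::predict(fit, x))),
    lasso = list(task = "regression", grid = list(lambda = gridLambda),
      fit = function(x, y, params, seed)
        glmnet::glmnet(x, y, alpha = 1, lambda = params$lambda),
      predict = function(fit, x) as.numeric(stats::predict(fit, x))),
    enet = list(task = "regression",
      grid = list(alpha = seq(0.1, 0.9, by = 0.2), lambda = gridLambda),
      fit = function(x, y, params, seed)
        glmnet::glmnet(x, y, alpha = params$alpha, lambda = params$lambda),
      predict = function(fit, x) as.numeric(stats::predict(fit, x))),
    svr_linear = list(task = "regression",
      grid = list(cost = gridC, epsilon = gridEpsilon),
      fit = function(x, y, params, seed)
        e1071::svm(x, y, type = "eps-regression", kernel = "linear",
                   cost = params$cost, epsilon = params$epsilon, scale = FALSE),
      predict = function(fit, x) as.numeric(stats::predict(fit, x))),
    svr_rbf = list(task = "regression",
      grid = list(cost = gridC, epsilon = gridEpsilon, gamma = gridGamma),
      fit = function(x, y, params, seed)
        e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                   cost = params$cost, epsilon = params$epsilon,
                   gamma = params$gamma, scale = FALSE),
      predict = function(fit, x) as.numeric(stats::predict(fit, x))),
    tree_reg = list(task = "regression", grid = NULL,
      fit = function(x, y, params, seed) {
        needsPkg("rpart")
        df <- data.frame(.y = y, x, check.names = FALSE)
        rpart::rpart(.y ~ ., data = df, method = "anova")
      },
      predict = function(fit, x)
        as.numeric(stats::predict(fit, data.frame(x, check.names = FALSE)))),
    rf_reg = list(task = "regression", grid = NULL,
      fit = function(x, y, params, seed)
        ranger::ranger(x = x, y = y, num.trees = 500, seed = seed,
                       num.threads = 1),
      predict = function(fit, x)
        as.numeric(stats::predict(fit, data = x, num.threads = 1)$predictions)),
    xgb_reg = list(task = "regression", grid = NULL,
      fit = function(x, y, params, seed) {
        needsPkg("xgboost")
        dtrain <- xgboost::xgb.DMatrix(x, label = y)
        xgboost::xgb.train(params = list(objective = "reg:squarederror",
                                         nthread = 1, seed = seed),
                           data = dtrain, nrounds = 100, verbose = 0)
      },
      predict = function(fit, x)
        as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x)))),
    gpr = list(task = "regression", grid = NULL,
      fit = function(x, y, params, seed) {
        needsPkg("kernlab")
        kernlab::gausspr(x, y, scaled = FALSE)
      },
      predict = function(fit, x) as.numeric(kernlab::predict(fit, x)))
  )
}

#' Method panel for model selection
#'
#' Returns the named method wrappers considered for a task. The full
#' classification panel holds logistic regression, LDA, naive Bayes,
#' k-NN, linear and RBF SVM, a decision tree, random forest and gradient
#' boosting; the full regression panel holds OLS, PLS, ridge, LASSO,
#' elastic net, linear and RBF SVR, a decision tree, random forest,
#' gradient boosting and Gaussian-process regression. The `"fast"`
#' profile restricts to a cheap representative trio per task.
#'
#' @param task `"classification"` or `"regression"`.
#' @param profile `"full"` or `"fast"`.
#' @param methods optional character vector restricting the panel.
#' @return named list of method definitions.
#' @export
methodPanel <- function(task = c("classification", "regression"),
                        profile = c("full", "fast"), methods = NULL) {
  task <- match.arg(task); profile <- match.arg(profile)
  defs <- methodDefs()
  defs <- defs[vapply(defs, function(d) d$task == task, TRUE)]
  if (is.null(methods)) {
    methods <- if (profile == "fast") {
      if (task == "classification") c("logistic", "rf", "xgb")
      else c("ridge", "rf_reg", "xgb_reg")
    } else names(defs)
  }
  unknown <- setdiff(methods, names(defs))
  if (length(unknown)) stop("unknown method(s): ", paste(unknown, collapse = ", "))
  defs[methods]
}

#' Cross-validation fold assignment
#'
#' Stratified by class for classification (each class is shuffled and
#' dealt round-robin), plain random split for regression; seeded.
#'
#' @param y outcome vector.
#' @param nFolds number of folds.
#' @param seed integer seed.
#' @param stratify stratify on `y`.
#' @return integer fold id per sample.
#' @export
makeFolds <- function(y, nFolds = 5L, seed = 1L, stratify = is.factor(y)) {
  set.seed(seed)
  fold <- integer(length(y))
  if (stratify) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  } else {
    fold[sample(seq_along(y))] <- rep_len(seq_len(nFolds), length(y))
  }
  fold
}

tuneParams <- function(def, x, y, innerFolds, seed) {
  if (is.null(def$grid)) return(list())
  grid <- expand.grid(def$grid, KEEP.OUT.ATTRS = FALSE)
  fold <- makeFolds(y, nFolds = min(innerFolds, nrow(x)), seed = seed,
                    stratify = is.factor(y))
  score <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, , drop = FALSE])
    errs <- vapply(unique(fold), function(f) {
      tr <- fold != f; te <- !tr
      if (is.factor(y) && length(unique(y[tr])) < 2) return(NA_real_)
      fit <- def$fit(x[tr, , drop = FALSE], y[tr], params,
                     seed = deriveSeed(seed, paste0("inner", f)))
      pred <- def$predict(fit, x[te, , drop = FALSE])
      if (is.factor(y)) mean(pred != y[te])
      else sqrt(mean((pred - y[te])^2))
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  as.list(grid[which.min(score), , drop = FALSE])   # ties: first grid row
}

#' Tune (inner CV) and fit one method
#'
#' @param def a method definition from [methodPanel()].
#' @param x feature matrix; `y` outcome.
#' @param y outcome vector (factor for classification).
#' @param innerFolds inner CV folds for hyperparameter selection.
#' @param seed integer seed.
#' @return list with `fit`, `params` and the closures needed to predict.
#' @export
tuneAndFit <- function(def, x, y, innerFolds = 5L, seed = 1L) {
  params <- tuneParams(def, x, y, innerFolds, seed)
  fit <- def$fit(x, y, params, seed = deriveSeed(seed, "refit"))
  list(fit = fit, params = params, predict = def$predict)
}

#' Nested (double) cross-validation over a method panel
#'
#' Outer folds give unbiased test sets; for each outer fold,
#' hyperparameters are selected by inner CV on the outer-training data
#' only, the model is refit on the outer-training data and predicts the
#' outer test fold. Metrics are computed on the pooled out-of-fold
#' predictions. For classification the outer-training data is rebalanced
#' by [clusterUndersample()] before tuning and fitting (test folds are
#' never undersampled). Outer-train and outer-test index sets are
#' asserted disjoint at run time.
#'
#' @param x numeric feature matrix.
#' @param y outcome: factor with levels `negative`/`positive`
#'   (classification) or numeric (regression).
#' @param task `"classification"` or `"regression"`.
#' @param methods named list from [methodPanel()] (or a character vector
#'   of method names).
#' @param outerFolds,innerFolds fold counts (both default 5).
#' @param seed integer seed driving folds, undersampling and any
#'   stochastic learner.
#' @param undersample rebalance outer-training folds (classification
#'   only).
#' @param selectBy metric used to pick the best classification method
#'   (`"f_measure"` default, `"accuracy"`, or `"balanced_accuracy"`);
#'   regression always selects by r2.
#' @return list with per-method pooled predictions, metrics and per-fold
#'   chosen hyperparameters, the fold assignment, and `best` (the method
#'   with the highest pooled F-measure / r2).
#' @export
nestedCV <- function(x, y, task = c("classification", "regression"),
                     methods = NULL, outerFolds = 5L, innerFolds = 5L,
                     seed = 1L, undersample = (task == "classification"),
                     selectBy = c("f_measure", "accuracy", "balanced_accuracy")) {
  task <- match.arg(task)
  selectBy <- match.arg(selectBy)
  if (task == "classification") {
    y <- factor(as.character(y), levels = c("negative", "positive"))
    if (any(table(y) < outerFolds))
      stop("each class needs at least 'outerFolds' samples")
  }
  if (is.character(methods) || is.null(methods))
    methods <- methodPanel(task, profile = "full", methods = methods)
  stopifnot(nrow(x) == length(y))

  fold <- makeFolds(y, nFolds = outerFolds, seed = seed,
                    stratify = task == "classification")
  pred <- lapply(methods, function(m) {
    if (task == "classification")
      factor(rep(NA_character_, length(y)), levels = levels(y))
    else rep(NA_real_, length(y))
  })
  chosen <- lapply(methods, function(m) vector("list", outerFolds))
  failed <- character()

  for (f in seq_len(outerFolds)) {
    testIdx <- which(fold == f)
    trainIdx <- which(fold != f)
    stopifnot(length(intersect(trainIdx, testIdx)) == 0)  # no-leakage guard
    xtr <- x[trainIdx, , drop = FALSE]; ytr <- y[trainIdx]
    if (task == "classification" && undersample) {
      us <- clusterUndersample(xtr, as.character(ytr),
                               seed = deriveSeed(seed, paste0("us", f)))
      xtr <- xtr[keptIndices(us), , drop = FALSE]
      ytr <- ytr[keptIndices(us)]
    }
    for (mn in names(methods)) {
      res <- tryCatch(
        tuneAndFit(methods[[mn]], xtr, ytr, innerFolds = innerFolds,
                   seed = deriveSeed(seed, paste0(mn, f))),
        error = function(e) e)
      if (inherits(res, "error")) {
        failed <- unique(c(failed, mn))
        next
      }
      pred[[mn]][testIdx] <- res$predict(res$fit, x[testIdx, , drop = FALSE])
      chosen[[mn]][[f]] <- res$params
    }
  }
  if (length(failed)) {
    warning("method(s) failed and were dropped: ",
            paste(failed, collapse = ", "))
    pred <- pred[setdiff(names(pred), failed)]
    chosen <- chosen[setdiff(names(chosen), failed)]
  }
  if (!length(pred)) stop("every method in the panel failed")

  metrics <- lapply(pred, function(p) {
    if (task == "classification") {
      cc <- confusionCounts(as.character(y), as.character(p))
      classificationMetrics(cc$TP, cc$TN, cc$FP, cc$FN)
    } else regressionMetrics(y, p)
  })
  scores <- vapply(metrics, function(m)
    if (task == "classification") m[[selectBy]] else m$r2, numeric(1))
  best <- names(metrics)[which.max(scores)]
  structure(list(task = task, fold = fold, predictions = pred,
                 metrics = metrics, chosenParams = chosen, best = best,
                 observed = y),
            class = "nestedCVResult")
}

#' @export
print.nestedCVResult <- function(x, ...) {
  cat(sprintf("Nested CV (%s), %d samples, %d outer folds\n",
              x$task, length(x$observed), max(x$fold)))
  key <- if (x$task == "classification") "f_measure" else "r2"
  for (mn in names(x$metrics))
    cat(sprintf("  %-12s %s = %.3f%s\n", mn, key, x$metrics[[mn]][[key]],
                if (mn == x$best) "  <- best" else ""))
  invisible(x)
}

#' Serialize a nested-CV evaluation report
#'
#' JSON with pooled per-method metrics and the hyperparameters chosen in
#' each outer fold; optionally a CSV of pooled out-of-fold predictions.
#'
#' @param result a [nestedCV()] result.
#' @param jsonPath output JSON path.
#' @param csvPath optional CSV path for pooled out-of-fold predictions.
#' @export
writeEvaluationReport <- function(result, jsonPath, csvPath = NULL) {
  rep <- list(task = result$task,
              pooled = "metrics are computed on pooled out-of-fold predictions",
              best = result$best,
              metrics = lapply(result$metrics, function(m)
                m[setdiff(names(m), "undefined")]),
              chosen_hyperparameters = result$chosenParams)
  jsonlite::write_json(rep, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(csvPath)) {
    df <- data.frame(fold = result$fold, observed = result$observed)
    for (mn in names(result$predictions))
      df[[paste0("pred_", mn)]] <- result$predictions[[mn]]
    utils::write.csv(df, csvPath, row.names = FALSE)
  }
  invisible(jsonPath)
}
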