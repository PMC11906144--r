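separableData <- function(n = 120, seed = 31) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * 5), n, 5,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:5)))
  y <- factor(ifelse(x[, 1] + x[, 2] > 0, "positive", "negative"),
              levels = c("negative", "positive"))
  x[, 1] <- x[, 1] + 2 * (y == "positive")   # widen the margin
  list(x = x, y = y)
}

test_that("fold assignment partitions samples and stratifies classes", {
  d <- separableData()
  fold <- makeFolds(d$y, nFolds = 5, seed = 4)
  expect_equal(length(fold), length(d$y))
  expect_true(all(fold %in% 1:5))
  # each sample in exactly one fold, classes spread over all folds
  counts <- table(fold, d$y)
  expect_true(all(counts > 0))
  expect_lte(diff(range(counts[, "positive"])), 1)
  expect_identical(fold, makeFolds(d$y, nFolds = 5, seed = 4))
})

test_that("nested CV separates an easy two-class problem", {
  d <- separableData()
  cv <- nestedCV(d$x, d$y, "classification",
                 methods = methodPanel("classification",
                                       methods = c("logistic", "svm_linear")),
                 seed = 8, undersample = FALSE)
  expect_gte(cv$metrics[[cv$best]]$accuracy, 0.95)
  # every sample appears in exactly one outer test fold and is predicted
  expect_false(anyNA(cv$predictions[[cv$best]]))
  # hyperparameters were chosen per outer fold for the gridded method
  expect_true(all(lengths(cv$chosenParams$svm_linear) == 1))
})

test_that("nested CV is reproducible under a fixed seed", {
  d <- separableData(n = 60)
  run <- function() nestedCV(d$x, d$y, "classification",
                             methods = methodPanel("classification",
                                                   methods = "logistic"),
                             seed = 12, undersample = FALSE)
  a <- run(); b <- run()
  expect_identical(a$fold, b$fold)
  expect_identical(as.character(a$predictions$logistic),
                   as.character(b$predictions$logistic))
})

test_that("nested CV recovers a linear regression signal", {
  set.seed(33)
  x <- matrix(stats::rnorm(600), 120, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- 2 * x[, 1] - x[, 3] + stats::rnorm(120, sd = 0.3)
  cv <- nestedCV(x, y, "regression",
                 methods = methodPanel("regression", methods = "ridge"),
                 seed = 2)
  expect_gte(cv$metrics$ridge$r2, 0.9)
})

test_that("classification requires enough samples per class", {
  x <- matrix(stats::rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(c(rep("negative", 8), rep("positive", 2)),
              levels = c("negative", "positive"))
  expect_error(nestedCV(x, y, "classification",
                        methods = methodPanel("classification",
                                              methods = "logistic")),
               "outerFolds")
})

test_that("evaluation reports serialize pooled metrics and parameters", {
  d <- separableData(n = 60)
  cv <- suppressWarnings(
    nestedCV(d$x, d$y, "classification",
             methods = methodPanel("classification", methods = "logistic"),
             seed = 5, undersample = FALSE))
  js <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  writeEvaluationReport(cv, js, csv)
  rep <- jsonlite::read_json(js)
  expect_equal(rep$best, "logistic")
  expect_true("accuracy" %in% names(rep$metrics$logistic))
  df <- utils::read.csv(csv)
  expect_equal(nrow(df), 60)
  expect_true("pred_logistic" %in% names(df))
})

test_that("the method panel exposes the documented profiles", {
  full <- methodPanel("classification", "full")
  expect_true(all(c("logistic", "lda", "naive_bayes", "knn", "svm_linear",
                    "svm_rbf", "tree", "rf", "xgb") %in% names(full)))
  fullReg <- methodPanel("regression", "full")
  expect_true(all(c("ols", "pls", "ridge", "lasso", "enet", "svr_linear",
                    "svr_rbf", "tree_reg", "rf_reg", "xgb_reg", "gpr")
                  %in% names(fullReg)))
  expect_equal(names(methodPanel("classification", "fast")),
               c("logistic", "rf", "xgb"))
  expect_error(methodPanel("classification", methods = "nope"), "unknown")
})
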