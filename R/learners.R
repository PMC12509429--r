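# Internal learner registry: a uniform fit/predict wrapper over the
# established implementations (stats::lm, e1071::svm, rpart, ranger,
# xgboost). Every fit is seeded and single-threaded so results are
# reproducible on one CPU.

#' Tuned boosted-tree defaults
#'
#' The gradient-boosting configuration used as the package default base
#' learner (number of rounds 300, depth 5, learning rate 0.05, subsample
#' 0.8, column subsample 0.9, L2 3.0, L1 0.1, minimum child weight 3,
#' gamma 0.01).
#'
#' @return Named list of xgboost parameters plus `nrounds`.
#' @export
xgb_default_params <- function() {
  list(nrounds = 300, max_depth = 5, eta = 0.05, subsample = 0.8,
       colsample_bytree = 0.9, lambda = 3.0, alpha = 0.1,
       min_child_weight = 3, gamma = 0.01)
}

learner_families <- function() c("ols", "svm", "tree", "rf", "xgboost", "lm")

# returns list(fit = function(X, y, seed), predict = function(model, X))
make_learner <- function(family, params = list()) {
  family <- match.arg(family, learner_families())
  if (family == "lm") family <- "ols"
  switch(family,
    ols = list(
      fit = function(X, y, seed = 1) {
        lm.fit(cbind(1, as.matrix(X)), y)
      },
      predict = function(model, X) {
        drop(cbind(1, as.matrix(X)) %*% model$coefficients)
      }),
    svm = list(
      fit = function(X, y, seed = 1) {
        args <- c(list(x = as.matrix(X), y = y, type = "eps-regression"),
                  params)
        with_seed(seed, do.call(e1071::svm, args))
      },
      predict = function(model, X) {
        as.numeric(predict(model, as.matrix(X)))
      }),
    tree = list(
      fit = function(X, y, seed = 1) {
        df <- data.frame(.y = y, as.data.frame(X))
        ctrl <- do.call(rpart::rpart.control,
                        params[names(params) %in%
                                 c("minsplit", "cp", "maxdepth", "minbucket")])
        with_seed(seed, rpart::rpart(.y ~ ., data = df, control = ctrl))
      },
      predict = function(model, X) {
        as.numeric(predict(model, newdata = as.data.frame(X)))
      }),
    rf = list(
      fit = function(X, y, seed = 1) {
        args <- c(list(x = as.data.frame(X), y = y,
                       num.trees = params$num.trees %||% 500,
                       mtry = params$mtry,
                       min.node.size = params$min.node.size %||% 5,
                       seed = seed, num.threads = 1))
        args <- args[!vapply(args, is.null, TRUE)]
        do.call(ranger::ranger, args)
      },
      predict = function(model, X) {
        predict(model, data = as.data.frame(X), num.threads = 1)$predictions
      }),
    xgboost = list(
      fit = function(X, y, seed = 1) {
        pr <- modifyList(xgb_default_params(), params)
        nrounds <- pr$nrounds
        pr$nrounds <- NULL
        dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
        with_seed(seed, xgboost::xgb.train(
          params = c(list(objective = "reg:squarederror", nthread = 1,
                          seed = seed), pr),
          data = dtrain, nrounds = nrounds, verbose = 0))
      },
      predict = function(model, X) {
        as.numeric(predict(model, xgboost::xgb.DMatrix(as.matrix(X))))
      })
  )
}

# fit + predict helper used by the cross-fitting engine
fit_predict <- function(family, params, X_train, y_train, X_test, seed = 1) {
  lrn <- make_learner(family, params)
  model <- lrn$fit(X_train, y_train, seed = seed)
  lrn$predict(model, X_test)
}
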