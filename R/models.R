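#' Train/test split with optional quantile stratification
#'
#' Random 80:20-style partition of `n` rows. With `stratify_on` supplied,
#' rows are binned into deciles of that variable and the test quota is
#' allocated across bins by largest remainder, so the test share of every
#' outcome stratum matches the overall ratio — the "proportional
#' stratification" reading for a continuous outcome.
#'
#' @param n number of rows (or a data frame, whose rows are counted).
#' @param ratio training fraction in (0, 1).
#' @param seed integer seed.
#' @param stratify_on optional numeric vector of length `n` to stratify on.
#' @param bins number of quantile bins for stratification (default 10).
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(n, ratio = 0.8, seed = 1, stratify_on = NULL,
                             bins = 10) {
  if (is.data.frame(n) || is.matrix(n)) n <- nrow(n)
  if (ratio <= 0 || ratio >= 1) stop_gapdml("ratio must be in (0, 1)")
  n_test <- round(n * (1 - ratio))
  if (n_test < 1 || n_test >= n)
    stop_gapdml("n = %d too small for a nonempty %0.2f split", n, ratio)
  with_seed(seed, {
    if (is.null(stratify_on)) {
      test <- sort(sample.int(n, n_test))
    } else {
      stopifnot(length(stratify_on) == n)
      qs <- unique(quantile(stratify_on, probs = seq(0, 1, length.out = bins + 1)))
      strat <- cut(stratify_on, qs, include.lowest = TRUE, labels = FALSE)
      groups <- split(seq_len(n), strat)
      quota <- vapply(groups, length, 0L) * (1 - ratio)
      base <- floor(quota)
      rem <- n_test - sum(base)
      if (rem > 0) {
        extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      } else if (rem < 0) {
        cut_back <- order(quota - base)[seq_len(-rem)]
        base[cut_back] <- pmax(base[cut_back] - 1, 0)
      }
      test <- sort(unlist(mapply(function(g, k) {
        if (k == 0) integer(0) else sample(g, min(k, length(g)))
      }, groups, base, SIMPLIFY = FALSE), use.names = FALSE))
    }
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Regression test-set metrics
#'
#' Mean squared error, its root, mean absolute error and the coefficient of
#' determination `R2 = 1 - SS_res/SS_tot` computed on the evaluated set.
#'
#' @param y_true,y_pred equal-length nonempty numeric vectors.
#' @return Named list `mse`, `rmse`, `mae`, `r2` (`r2` is `NA` with a
#'   warning when `y_true` is constant).
#' @export
evaluate_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  err <- y_true - y_pred
  mse <- mean(err^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot > 0) 1 - sum(err^2) / ss_tot else {
    warning("constant y_true: r2 undefined", call. = FALSE)
    NA_real_
  }
  list(mse = mse, rmse = sqrt(mse), mae = mean(abs(err)), r2 = r2)
}

#' Cross-validated grid search
#'
#' Exhaustive hyperparameter search for one learner family: every grid row
#' is scored by K-fold cross-validated MSE on the training data, and the
#' minimizer wins, ties broken by enumeration order (no seeded shuffling,
#' so the selection is fully reproducible). Fold assignment depends only on
#' the seed.
#'
#' @param family learner family: `"ols"`, `"svm"`, `"tree"`, `"rf"` or
#'   `"xgboost"`.
#' @param grid named list of parameter value vectors (crossed via
#'   [expand.grid()]), or a data frame of parameter rows. An empty grid
#'   means defaults only.
#' @param X,y training design matrix and response.
#' @param folds number of CV folds (>= 2; 5 and 10 are the conventional
#'   choices).
#' @param seed integer seed controlling fold assignment and learner RNG.
#' @return List with `best_params`, `best_cv_mse` and the full `cv_table`.
#' @export
grid_search <- function(family, grid, X, y, folds = 5, seed = 1) {
  family <- match.arg(family, learner_families())
  if (folds < 2) stop_gapdml("grid_search needs folds >= 2")
  grid_df <- if (is.data.frame(grid)) grid else expand.grid(grid, stringsAsFactors = FALSE)
  if (nrow(grid_df) == 0) grid_df <- data.frame(row.names = 1)
  fold_id <- make_folds(nrow(as.matrix(X)), folds, seed)
  X <- as.matrix(X)
  cv_mse <- numeric(nrow(grid_df))
  for (i in seq_len(nrow(grid_df))) {
    params <- as.list(grid_df[i, , drop = FALSE])
    se <- 0
    for (k in seq_len(folds)) {
      hold <- fold_id == k
      pred <- fit_predict(family, params, X[!hold, , drop = FALSE], y[!hold],
                          X[hold, , drop = FALSE],
                          seed = derive_seed(seed, paste0("gs", i, "f", k)))
      se <- se + sum((y[hold] - pred)^2)
    }
    cv_mse[i] <- se / length(y)
  }
  best <- which.min(cv_mse)  # first minimum = enumeration-order tie-break
  cv_table <- cbind(grid_df, cv_mse = cv_mse)
  list(best_params = as.list(grid_df[best, , drop = FALSE]),
       best_cv_mse = cv_mse[best], cv_table = cv_table)
}

default_family_params <- function(family) {
  switch(family,
         ols = list(), svm = list(), tree = list(),
         rf = list(num.trees = 500),
         xgboost = xgb_default_params(),
         list())
}

#' Default hyperparameter grids
#'
#' Bracketing grids around each tuned default; used when grid search is
#' enabled in [compare_algorithms()]. The boosted-tree grid brackets every
#' tuned value (see [xgb_default_params()]); the full cross of that grid is
#' large, so a reduced cross is the default and the full one is opt-in.
#'
#' @param full return the full bracketing boosted-tree grid instead of the
#'   reduced one.
#' @return Named list of per-family grids.
#' @export
default_grids <- function(full = FALSE) {
  xgb <- if (full) list(
    nrounds = c(100, 300, 500), max_depth = c(3, 5, 7),
    eta = c(0.01, 0.05, 0.1), subsample = c(0.8, 1.0),
    colsample_bytree = c(0.9, 1.0), lambda = c(1, 3), alpha = c(0, 0.1),
    min_child_weight = c(1, 3), gamma = c(0, 0.01)
  ) else list(nrounds = c(100, 300), max_depth = c(3, 5), eta = c(0.05, 0.1))
  list(ols = list(),
       svm = list(cost = c(0.5, 1, 2), gamma = c(0.01, 0.05)),
       tree = list(cp = c(0.001, 0.01), maxdepth = c(5, 10)),
       rf = list(num.trees = c(300, 500), min.node.size = c(5, 10)),
       xgboost = xgb)
}

fit_one_report <- function(family, data, outcome, seed, ratio, folds,
                           use_grid, grids) {
  y <- data[[outcome]]
  X <- as.matrix(data[setdiff(names(data), outcome)])
  sp <- split_train_test(nrow(data), ratio, seed, stratify_on = y)
  Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  if (use_grid && length(grids[[family]] %||% list())) {
    gs <- grid_search(family, grids[[family]], Xtr, ytr, folds = folds,
                      seed = derive_seed(seed, paste0("grid_", family)))
    params <- gs$best_params
  } else {
    params <- default_family_params(family)
    gs <- NULL
  }
  pred <- fit_predict(family, params, Xtr, ytr, X[sp$test, , drop = FALSE],
                      seed = derive_seed(seed, paste0("fit_", family)))
  m <- evaluate_metrics(y[sp$test], pred)
  structure(list(algorithm = family, mse = m$mse, rmse = m$rmse, mae = m$mae,
                 r2 = m$r2, best_hyperparameters = params,
                 split_seed = seed, cv_folds = if (use_grid) folds else NA_integer_),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("%-8s MSE %.4f  RMSE %.4f  MAE %.4f  R2 %.4f (seed %s)\n",
              x$algorithm, x$mse, x$rmse, x$mae, x$r2, x$split_seed))
  invisible(x)
}

#' Benchmark the candidate algorithms over multiple splits
#'
#' Runs the five-algorithm comparison (OLS, support-vector regression,
#' decision tree, random forest, gradient-boosted trees) over a set of
#' random-split seeds: stratified 80:20 split per seed, optional
#' cross-validated grid search on the training side, and the full metric
#' suite (MSE, RMSE, MAE, R2) on the held-out side. Reports per-seed
#' results and a leaderboard of per-algorithm means and SDs; the winner is
#' the algorithm with the highest mean R2. A family that fails to fit is
#' recorded as a failure and the leaderboard is still produced. With grid
#' search disabled, the boosted-tree family runs at its tuned defaults
#' ([xgb_default_params()]).
#'
#' @param data data frame of predictors plus the outcome column.
#' @param seeds integer vector of split seeds (>= 1 seed).
#' @param outcome outcome column name (default `"delta_z"`).
#' @param families learner families to compare.
#' @param ratio training fraction.
#' @param use_grid run [grid_search()] per family (default `FALSE`).
#' @param grids per-family grids, see [default_grids()].
#' @param folds CV folds for grid search.
#' @return Object of class `leaderboard`: list with `per_seed` (data
#'   frame), `summary` (data frame of means/SDs), `winner`, `failures`.
#' @export
compare_algorithms <- function(data, seeds = 1:20, outcome = "delta_z",
                               families = c("ols", "svm", "tree", "rf", "xgboost"),
                               ratio = 0.8, use_grid = FALSE,
                               grids = default_grids(), folds = 5) {
  if (length(seeds) < 1) stop_gapdml("need at least one seed")
  if (!outcome %in% names(data)) stop_gapdml("outcome '%s' not in data", outcome)
  families <- match.arg(families, learner_families(), several.ok = TRUE)
  rows <- list(); failures <- list()
  for (s in seeds) for (fam in families) {
    rep <- tryCatch(
      fit_one_report(fam, data, outcome, s, ratio, folds, use_grid, grids),
      error = function(e) e)
    if (inherits(rep, "error")) {
      failures[[paste(fam, s, sep = "_")]] <- conditionMessage(rep)
    } else {
      rows[[paste(fam, s, sep = "_")]] <-
        data.frame(algorithm = fam, seed = s, mse = rep$mse, rmse = rep$rmse,
                   mae = rep$mae, r2 = rep$r2)
    }
  }
  per_seed <- do.call(rbind, rows)
  rownames(per_seed) <- NULL
  agg <- do.call(rbind, lapply(split(per_seed, per_seed$algorithm), function(d) {
    data.frame(algorithm = d$algorithm[1], n_seeds = nrow(d),
               mse = mean(d$mse), rmse = mean(d$rmse), mae = mean(d$mae),
               r2 = mean(d$r2), r2_sd = if (nrow(d) > 1) sd(d$r2) else 0)
  }))
  agg <- agg[order(-agg$r2), ]
  rownames(agg) <- NULL
  structure(list(per_seed = per_seed, summary = agg,
                 winner = agg$algorithm[1], failures = failures,
                 seeds = seeds, use_grid = use_grid),
            class = "leaderboard")
}

#' @export
print.leaderboard <- function(x, ...) {
  cat(sprintf("Algorithm leaderboard over %d seed(s); winner: %s\n",
              length(x$seeds), x$winner))
  print(x$summary, digits = 4)
  if (length(x$failures))
    cat(sprintf("failures: %s\n", paste(names(x$failures), collapse = ", ")))
  invisible(x)
}
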