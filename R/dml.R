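# Cross-fitted partial-linear double machine learning.
#
# Partialling-out form: with outcome Y, treatment T and covariates W
# (all observed predictors except the treatment), the nuisances
# g(W) = E[Y|W] and h(W) = E[T|W] are estimated by cross-fitting, the
# out-of-fold residuals E_y = Y - g(W) and E_t = T - h(W) are formed, and
# the effect is the no-intercept residual-on-residual regression
# theta = sum(E_t * E_y) / sum(E_t^2), either pooled over all folds or
# averaged over per-fold estimates theta = mean(theta_k).

#' Cross-fitted nuisance residuals
#'
#' Partitions the sample into K folds; for each fold, the outcome and
#' treatment nuisance models are trained on the other K-1 folds and predict
#' the held-out fold, so every residual is out-of-fold. Rejects a constant
#' treatment (no identifying variation) and a treatment column accidentally
#' included among the covariates.
#'
#' @param Y outcome vector.
#' @param T_ treatment vector.
#' @param W covariate matrix/data frame (must not contain the treatment).
#' @param learner nuisance learner family (`"xgboost"`, `"rf"`, `"lm"`,
#'   ...); see [make_learner()] families.
#' @param params learner parameters (for the default boosted trees, the
#'   tuned defaults of [xgb_default_params()]).
#' @param K number of folds (>= 2, default 5).
#' @param seed integer seed (fold assignment + learner RNG).
#' @return Object of class `dml_residuals`: list with `e_y`, `e_t`,
#'   `fold`, `g_hat`, `h_hat` and out-of-fold `nuisance_r2` for both
#'   nuisances.
#' @export
crossfit_residuals <- function(Y, T_, W, learner = "xgboost", params = list(),
                               K = 5, seed = 1) {
  if (K < 2) stop_gapdml("crossfit_residuals needs K >= 2")
  W <- as.matrix(W)
  n <- length(Y)
  stopifnot(length(T_) == n, nrow(W) == n)
  if (sd(T_) == 0) stop_gapdml("treatment is constant: no identifying variation")
  dup <- which(apply(W, 2, function(col) isTRUE(all.equal(col, T_))))
  if (length(dup))
    stop_gapdml("treatment variable also present in W (column %s)",
                paste(colnames(W)[dup], collapse = ", "))
  fold <- make_folds(n, K, derive_seed(seed, "folds"))
  g_hat <- h_hat <- numeric(n)
  for (k in seq_len(K)) {
    hold <- fold == k
    g_hat[hold] <- fit_predict(learner, params, W[!hold, , drop = FALSE],
                               Y[!hold], W[hold, , drop = FALSE],
                               seed = derive_seed(seed, paste0("g", k)))
    h_hat[hold] <- fit_predict(learner, params, W[!hold, , drop = FALSE],
                               T_[!hold], W[hold, , drop = FALSE],
                               seed = derive_seed(seed, paste0("h", k)))
  }
  r2 <- function(obs, pred) {
    ss <- sum((obs - mean(obs))^2)
    if (ss == 0) NA_real_ else 1 - sum((obs - pred)^2) / ss
  }
  structure(list(e_y = Y - g_hat, e_t = T_ - h_hat, fold = fold,
                 g_hat = g_hat, h_hat = h_hat, K = K,
                 nuisance_r2 = c(outcome = r2(Y, g_hat),
                                 treatment = r2(T_, h_hat))),
            class = "dml_residuals")
}

#' Residual-on-residual effect estimate
#'
#' The no-intercept least-squares coefficient of the outcome residuals on
#' the treatment residuals, `theta = sum(e_t * e_y) / sum(e_t^2)`.
#'
#' @param e_y,e_t residual vectors.
#' @return Scalar theta.
#' @export
theta_hat <- function(e_y, e_t) {
  stopifnot(length(e_y) == length(e_t))
  s <- sum(e_t^2)
  if (s <= 0) stop_gapdml("treatment residuals have zero variance")
  sum(e_t * e_y) / s
}

#' Pooled and per-fold effect estimates
#'
#' `"pooled"`: one residual regression over all folds. `"per_fold"`:
#' `theta_k` within each fold, averaged (`theta = mean(theta_k)`). A fold
#' whose treatment residuals are degenerate is dropped from the average
#' with a warning. Both quantities are always returned; `mode` selects
#' which one is reported as `theta`.
#'
#' @param res a `dml_residuals`.
#' @param mode `"pooled"` (default) or `"per_fold"`.
#' @return List with `theta`, `theta_pooled`, `theta_per_fold`, `mode`.
#' @export
kfold_theta <- function(res, mode = c("pooled", "per_fold")) {
  mode <- match.arg(mode)
  stopifnot(inherits(res, "dml_residuals"))
  pooled <- theta_hat(res$e_y, res$e_t)
  per_fold <- vapply(seq_len(res$K), function(k) {
    hold <- res$fold == k
    if (sum(res$e_t[hold]^2) <= 0) {
      warning(sprintf("fold %d has degenerate treatment residuals; dropped", k),
              call. = FALSE)
      return(NA_real_)
    }
    theta_hat(res$e_y[hold], res$e_t[hold])
  }, 0)
  list(theta = if (mode == "pooled") pooled else mean(per_fold, na.rm = TRUE),
       theta_pooled = pooled, theta_per_fold = per_fold, mode = mode)
}

#' Bootstrap inference for the effect estimate
#'
#' Resamples residual pairs `(e_y, e_t)` with replacement, recomputes
#' `theta` per replicate, and reports the replicate SD as the standard
#' error with the normal-approximation interval `theta +/- 1.96 * se`.
#' Degenerate replicates (zero treatment-residual variance) are discarded
#' and counted. Resampling the cross-fitted residual pairs, rather than
#' refitting the whole pipeline per replicate, is the tractable default;
#' the full-pipeline bootstrap is available via `dml_ate(..., full_bootstrap
#' = TRUE)`.
#'
#' @param res a `dml_residuals` (or list with `e_y`, `e_t`).
#' @param B bootstrap replications (>= 100).
#' @param seed integer seed.
#' @param theta point estimate the interval is centred on (default: pooled
#'   [theta_hat()] of the residuals).
#' @return List with `se`, `ci95`, `B_effective`, `replicates`.
#' @export
bootstrap_inference <- function(res, B = 5000, seed = 1, theta = NULL) {
  if (B < 100) stop_gapdml("bootstrap needs B >= 100")
  e_y <- res$e_y; e_t <- res$e_t
  n <- length(e_y)
  if (is.null(theta)) theta <- theta_hat(e_y, e_t)
  reps <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
    num <- colSums(matrix(e_t[idx] * e_y[idx], n, B))
    den <- colSums(matrix(e_t[idx]^2, n, B))
    ifelse(den > 0, num / den, NA_real_)
  })
  dropped <- sum(is.na(reps))
  reps <- reps[!is.na(reps)]
  se <- sd(reps)
  structure(list(se = se, ci95 = theta + c(-1, 1) * 1.96 * se,
                 theta = theta, B = B, B_effective = length(reps),
                 dropped = dropped, replicates = reps),
            class = "dml_bootstrap")
}

#' Double-machine-learning average treatment effect
#'
#' The package's central fitting function: estimates the average treatment
#' effect of one (standardized, continuous) treatment variable on the
#' outcome by cross-fitted partialling-out. All predictors other than the
#' treatment and the outcome form the covariate set W; both nuisances are
#' fit by the chosen learner with K-fold cross-fitting; the effect is the
#' residual-on-residual regression coefficient; inference is by residual
#' bootstrap with a normal-approximation 95% interval. For a treatment on
#' a 1-SD scale, theta is the change in the outcome per one standard
#' deviation of the treatment.
#'
#' @param data data frame holding the outcome, the treatment and the
#'   covariates.
#' @param treatment treatment column name.
#' @param outcome outcome column name (default `"delta_z"`).
#' @param covariates covariate column names; default: all columns except
#'   treatment and outcome.
#' @param learner,params nuisance learner, see [crossfit_residuals()].
#' @param K folds (default 5).
#' @param B bootstrap replications (default 5000).
#' @param mode `"pooled"` or `"per_fold"` reporting, see [kfold_theta()].
#' @param seed integer seed.
#' @param full_bootstrap refit the whole cross-fitting pipeline in every
#'   bootstrap replicate (slow; default `FALSE` resamples residual pairs).
#' @return Object of class `dml_ate` with `theta`, `theta_per_fold`, `se`,
#'   `ci95`, the `dml_residuals`, and all settings. Methods: `print`,
#'   `summary`, `coef`, `confint`, `residuals`, `plot`.
#' @examples
#' bench <- generate_dml_benchmark(n = 400, seed = 1)
#' fit <- dml_ate(bench$data, "BAR", learner = "lm", B = 200, seed = 1)
#' coef(fit); confint(fit)
#' @export
dml_ate <- function(data, treatment, outcome = "delta_z", covariates = NULL,
                    learner = "xgboost", params = list(), K = 5, B = 5000,
                    mode = c("pooled", "per_fold"), seed = 1,
                    full_bootstrap = FALSE) {
  mode <- match.arg(mode)
  data <- as.data.frame(data)
  if (!treatment %in% names(data)) stop_gapdml("treatment '%s' not in data", treatment)
  if (!outcome %in% names(data)) stop_gapdml("outcome '%s' not in data", outcome)
  if (is.null(covariates)) covariates <- setdiff(names(data), c(treatment, outcome))
  if (treatment %in% covariates) stop_gapdml("treatment must not appear in covariates")
  Y <- as.numeric(data[[outcome]])
  T_ <- as.numeric(data[[treatment]])
  W <- as.matrix(data[covariates])
  res <- crossfit_residuals(Y, T_, W, learner = learner, params = params,
                            K = K, seed = derive_seed(seed, "crossfit"))
  th <- kfold_theta(res, mode)
  if (full_bootstrap) {
    reps <- vapply(seq_len(B), function(b) {
      idx <- with_seed(derive_seed(seed, paste0("fb", b)),
                       sample.int(length(Y), replace = TRUE))
      r <- crossfit_residuals(Y[idx], T_[idx], W[idx, , drop = FALSE],
                              learner = learner, params = params, K = K,
                              seed = derive_seed(seed, paste0("fbfit", b)))
      kfold_theta(r, mode)$theta
    }, 0)
    se <- sd(reps)
    boot <- list(se = se, ci95 = th$theta + c(-1, 1) * 1.96 * se,
                 B = B, B_effective = B, dropped = 0, replicates = reps)
  } else {
    boot <- bootstrap_inference(res, B = B, seed = derive_seed(seed, "boot"),
                                theta = th$theta)
  }
  structure(list(treatment = treatment, outcome = outcome,
                 theta = th$theta, theta_pooled = th$theta_pooled,
                 theta_per_fold = th$theta_per_fold, mode = mode,
                 se = boot$se, ci95 = boot$ci95, B = boot$B,
                 B_effective = boot$B_effective,
                 residuals = res, K = K, learner = learner,
                 nuisance_r2 = res$nuisance_r2, seed = seed,
                 n = length(Y), full_bootstrap = full_bootstrap),
            class = "dml_ate")
}

#' @export
print.dml_ate <- function(x, ...) {
  stars <- if (abs(x$theta) / x$se > 3.29) "***"
  else if (abs(x$theta) / x$se > 2.58) "**"
  else if (abs(x$theta) / x$se > 1.96) "*" else ""
  cat(sprintf("DML ATE of %s on %s (n = %d, K = %d, %s nuisances, %s mode)\n",
              x$treatment, x$outcome, x$n, x$K, x$learner, x$mode))
  cat(sprintf("  theta = %.4f%s, se = %.4f, 95%% CI [%.4f, %.4f] (B = %d)\n",
              x$theta, stars, x$se, x$ci95[1], x$ci95[2], x$B))
  invisible(x)
}

#' @export
summary.dml_ate <- function(object, ...) {
  print(object)
  cat(sprintf("  per-fold theta_k: %s (mean %.4f)\n",
              paste(sprintf("%.4f", object$theta_per_fold), collapse = ", "),
              mean(object$theta_per_fold, na.rm = TRUE)))
  cat(sprintf("  out-of-fold nuisance R2: outcome %.3f, treatment %.3f\n",
              object$nuisance_r2["outcome"], object$nuisance_r2["treatment"]))
  invisible(object)
}

#' @export
coef.dml_ate <- function(object, ...) setNames(object$theta, object$treatment)

#' @export
confint.dml_ate <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  ci <- object$theta + c(-1, 1) * z * object$se
  out <- matrix(ci, 1, dimnames = list(object$treatment,
                                       sprintf("%g %%", c((1 - level) / 2,
                                                          1 - (1 - level) / 2) * 100)))
  out
}

#' @export
residuals.dml_ate <- function(object, ...) {
  data.frame(e_y = object$residuals$e_y, e_t = object$residuals$e_t,
             fold = object$residuals$fold)
}

#' @export
plot.dml_ate <- function(x, ...) {
  r <- x$residuals
  graphics::plot(r$e_t, r$e_y, pch = 16, cex = 0.4, col = "grey40",
                 xlab = sprintf("treatment residuals (%s)", x$treatment),
                 ylab = sprintf("outcome residuals (%s)", x$outcome), ...)
  graphics::abline(0, x$theta, col = "red3", lwd = 2)
  invisible(x)
}

#' ATE table for several treatments
#'
#' Runs [dml_ate()] for each treatment and assembles the results in a
#' treatment / ATE / SE / CI table.
#'
#' @param data data frame.
#' @param treatments character vector of treatment columns.
#' @param ... passed to [dml_ate()].
#' @return List with `table` (data frame) and `fits` (named list of
#'   `dml_ate` objects), class `dml_ate_table`.
#' @export
dml_ate_table <- function(data, treatments, ...) {
  fits <- lapply(treatments, function(tr) dml_ate(data, tr, ...))
  names(fits) <- treatments
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(variable = f$treatment, ate = f$theta, se = f$se,
               ci_lower = f$ci95[1], ci_upper = f$ci95[2])))
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "dml_ate_table")
}

#' @export
print.dml_ate_table <- function(x, ...) {
  cat("DML average treatment effects:\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Median-split subgroup effects
#'
#' Dichotomizes the sample at the median of a (numeric) split variable —
#' ties assigned to the lower group — and re-runs the full DML pipeline for
#' every treatment within each side, provided both sides meet the minimum
#' subgroup size (default 250, the conventional floor for subgroup causal
#' analyses). Each subgroup block also reports the out-of-fold outcome
#' nuisance R2 as the subgroup's predictive fit.
#'
#' @param data data frame.
#' @param split_var numeric column to split on.
#' @param treatments treatment columns to estimate within each side (the
#'   split variable is excluded from its own covariate sets automatically
#'   by [dml_ate()] semantics: it remains a covariate for other
#'   treatments).
#' @param min_size minimum rows per side (default 250).
#' @param ... passed to [dml_ate()].
#' @return Object of class `dml_subgroups`: list with `split_var`,
#'   `median`, `groups` (per-side list with `n`, `table`, `r2_outcome`),
#'   `rule`.
#' @export
subgroup_ates <- function(data, split_var, treatments, min_size = 250, ...) {
  data <- as.data.frame(data)
  if (!split_var %in% names(data)) stop_gapdml("split variable '%s' not in data", split_var)
  v <- as.numeric(data[[split_var]])
  med <- median(v)
  lower <- v <= med   # ties to the lower group
  sizes <- c(lower = sum(lower), higher = sum(!lower))
  if (any(sizes < min_size))
    stop_gapdml(paste0("subgroup sizes %d/%d below the minimum of %d; ",
                       "subgroup causal estimates refused"),
                sizes[1], sizes[2], min_size)
  run_side <- function(rows) {
    d <- data[rows, , drop = FALSE]
    at <- dml_ate_table(d, treatments, ...)
    r2 <- mean(vapply(at$fits, function(f) f$nuisance_r2[["outcome"]], 0))
    list(n = nrow(d), table = at$table, fits = at$fits, r2_outcome = r2)
  }
  structure(list(split_var = split_var, median = med,
                 rule = "ties assigned to the lower group",
                 groups = list(lower = run_side(lower),
                               higher = run_side(!lower)),
                 min_size = min_size),
            class = "dml_subgroups")
}

#' @export
print.dml_subgroups <- function(x, ...) {
  cat(sprintf("Median-split subgroup effects on %s (median %.4f; %s)\n",
              x$split_var, x$median, x$rule))
  for (side in names(x$groups)) {
    g <- x$groups[[side]]
    cat(sprintf("-- %s %s (n = %d, outcome nuisance R2 = %.3f)\n",
                side, x$split_var, g$n, g$r2_outcome))
    print(g$table, digits = 4)
  }
  invisible(x)
}
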