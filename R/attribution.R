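# Shapley attribution with an exact enumeration oracle.
#
# The value function is interventional: the value of a coalition S for an
# instance x is the mean model prediction over the background sample with
# the S-features fixed to x and the rest left at background values. Exact
# enumeration over all 2^p coalitions is the definition of correctness; the
# permutation-sampling estimator is the scalable path certified against it.

# v(S) for all subsets of features, batched through the predict function
coalition_values <- function(predict_fn, instance, background, chunk_rows = 2e5) {
  background <- as.matrix(background)
  p <- length(instance)
  nb <- nrow(background)
  n_sub <- 2^p
  vals <- numeric(n_sub)
  masks <- 0:(n_sub - 1)
  per_chunk <- max(1L, floor(chunk_rows / nb))
  for (start in seq(1, n_sub, by = per_chunk)) {
    idx <- start:min(start + per_chunk - 1, n_sub)
    big <- background[rep(seq_len(nb), length(idx)), , drop = FALSE]
    for (i in seq_along(idx)) {
      m <- masks[idx[i]]
      on <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) != 0L)
      if (length(on)) {
        rows <- ((i - 1) * nb + 1):(i * nb)
        big[rows, on] <- matrix(instance[on], nb, length(on), byrow = TRUE)
      }
    }
    pred <- predict_fn(big)
    vals[idx] <- colMeans(matrix(pred, nrow = nb))
  }
  vals
}

#' Exact Shapley values by coalition enumeration
#'
#' Computes the exact interventional Shapley decomposition of one
#' prediction: `phi_j` is the combinatorially weighted average of
#' `v(S + j) - v(S)` over all coalitions `S` not containing `j`, with
#' `v(S)` the mean prediction over the background set when the features in
#' `S` are fixed to the instance. Satisfies local accuracy
#' (`baseline + sum(phi) = f(x)`), symmetry and the dummy axiom by
#' construction.
#'
#' @param predict_fn function taking a numeric matrix and returning a
#'   numeric prediction vector.
#' @param instance named numeric vector (one row of features).
#' @param background numeric matrix of background rows (nonempty, same
#'   columns as `instance`).
#' @param max_features enumeration cap (default 15); larger problems are
#'   directed to [sampled_shapley()].
#' @return Named numeric `phi` vector with attributes `baseline` (mean
#'   background prediction) and `prediction` (`f(x)`).
#' @export
exact_shapley <- function(predict_fn, instance, background, max_features = 15) {
  instance <- unlist(instance)
  p <- length(instance)
  background <- as.matrix(background)
  if (nrow(background) < 1) stop_gapdml("background set is empty")
  if (ncol(background) != p)
    stop_gapdml("background has %d columns, instance has %d features",
                ncol(background), p)
  if (p > max_features)
    stop_gapdml("p = %d exceeds the enumeration cap (%d); use sampled_shapley()",
                p, max_features)
  v <- coalition_values(predict_fn, instance, background)
  fact <- factorial(0:p)
  phi <- numeric(p)
  bits <- bitwShiftL(1L, 0:(p - 1))
  sizes <- vapply(0:(2^p - 1), function(m) sum(bitwAnd(m, bits) != 0L), 0L)
  for (j in seq_len(p)) {
    bj <- bits[j]
    without <- which(bitwAnd(0:(2^p - 1), bj) == 0L)  # 1-based subset ids
    s <- sizes[without]
    w <- fact[s + 1] * fact[p - s] / fact[p + 1]
    phi[j] <- sum(w * (v[without + bj] - v[without]))
  }
  names(phi) <- names(instance)
  structure(phi, baseline = v[1],
            prediction = as.numeric(predict_fn(matrix(instance, 1))))
}

#' Permutation-sampling Shapley estimator
#'
#' Monte-Carlo estimate of the same interventional Shapley values as
#' [exact_shapley()]: for each sampled permutation a background row is
#' drawn, features are switched to the instance's values in permutation
#' order, and each feature is credited with the induced prediction change.
#' The estimator is unbiased and converges to the exact values as the
#' number of permutations grows; a per-feature Monte-Carlo standard error
#' is reported.
#'
#' @inheritParams exact_shapley
#' @param permutations number of sampled permutations (>= 1).
#' @param seed integer seed.
#' @return Named numeric `phi` vector with attributes `se` (Monte-Carlo
#'   standard errors), `baseline` and `prediction`.
#' @export
sampled_shapley <- function(predict_fn, instance, background,
                            permutations = 2000, seed = 1) {
  instance <- unlist(instance)
  p <- length(instance)
  background <- as.matrix(background)
  if (permutations < 1) stop_gapdml("permutations must be >= 1")
  if (ncol(background) != p)
    stop_gapdml("background has %d columns, instance has %d features",
                ncol(background), p)
  nb <- nrow(background)
  with_seed(seed, {
    contrib <- matrix(0, permutations, p)
    chunk <- max(1L, floor(2e5 / (p + 1)))
    for (start in seq(1, permutations, by = chunk)) {
      ms <- start:min(start + chunk - 1, permutations)
      rows <- matrix(0, length(ms) * (p + 1), p)
      orders <- vector("list", length(ms))
      for (i in seq_along(ms)) {
        z <- background[sample.int(nb, 1), ]
        ord <- sample.int(p)
        orders[[i]] <- ord
        x_cur <- z
        block <- (i - 1) * (p + 1)
        rows[block + 1, ] <- x_cur
        for (step in seq_len(p)) {
          x_cur[ord[step]] <- instance[ord[step]]
          rows[block + 1 + step, ] <- x_cur
        }
      }
      pred <- predict_fn(rows)
      for (i in seq_along(ms)) {
        block <- (i - 1) * (p + 1)
        d <- diff(pred[block + 1:(p + 1)])
        contrib[ms[i], orders[[i]]] <- d
      }
    }
    phi <- colMeans(contrib)
    se <- apply(contrib, 2, sd) / sqrt(permutations)
    names(phi) <- names(se) <- names(instance)
    structure(phi, se = se,
              baseline = mean(predict_fn(background)),
              prediction = as.numeric(predict_fn(matrix(instance, 1))))
  })
}

#' Shapley attribution matrix for a dataset
#'
#' Applies [exact_shapley()] or [sampled_shapley()] to each row of `X`,
#' against a fixed background sample (up to `background_size` rows drawn
#' once with the seed), returning the respondent-by-feature matrix of
#' attributions plus the shared baseline.
#'
#' @param predict_fn prediction function over feature matrices.
#' @param X numeric matrix or data frame of instances to explain.
#' @param background background matrix; defaults to (a sample of) `X`.
#' @param mode `"exact"` or `"sampled"`.
#' @param background_size background subsample cap (default 200).
#' @param permutations permutations per instance in sampled mode.
#' @param seed integer seed.
#' @return Object of class `attribution_matrix`: list with `phi` (matrix),
#'   `baseline`, `feature_names`, `predictions`, `mode`.
#' @export
shapley_attribution <- function(predict_fn, X, background = NULL,
                                mode = c("exact", "sampled"),
                                background_size = 200, permutations = 500,
                                seed = 1) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (is.null(background)) background <- X
  background <- as.matrix(background)
  if (nrow(background) > background_size) {
    keep <- with_seed(derive_seed(seed, "background"),
                      sample.int(nrow(background), background_size))
    background <- background[keep, , drop = FALSE]
  }
  phi <- matrix(0, nrow(X), ncol(X), dimnames = list(NULL, colnames(X)))
  preds <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    res <- if (mode == "exact")
      exact_shapley(predict_fn, X[i, ], background)
    else
      sampled_shapley(predict_fn, X[i, ], background,
                      permutations = permutations,
                      seed = derive_seed(seed, paste0("row", i)))
    phi[i, ] <- res
    preds[i] <- attr(res, "prediction")
  }
  structure(list(phi = phi, baseline = mean(predict_fn(background)),
                 feature_names = colnames(X), predictions = preds,
                 mode = mode, background_n = nrow(background)),
            class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf("<attribution_matrix> %d instances x %d features (%s mode), baseline %.4f\n",
              nrow(x$phi), ncol(x$phi), x$mode, x$baseline))
  invisible(x)
}

#' Feature importance ranking with dimension aggregates
#'
#' Ranks features by mean absolute Shapley value and aggregates named
#' groups of features into dimension-level sums (e.g. a
#' psychological-cognition dimension BAR + SE against a smart-sport
#' dimension UI + SS). Also reports each feature's mean signed value, whose
#' sign is the direction of its average effect.
#'
#' @param am an `attribution_matrix` (or a plain phi matrix).
#' @param dimension_map named list of feature-name groups to aggregate.
#' @return Object of class `importance_ranking`: list with `table` (data
#'   frame: feature, mean_abs_phi, mean_phi, rank) and `dimension_sums`.
#' @export
importance_ranking <- function(am, dimension_map = list()) {
  phi <- if (inherits(am, "attribution_matrix")) am$phi else as.matrix(am)
  if (length(phi) == 0) stop_gapdml("empty attribution matrix")
  imp <- colMeans(abs(phi))
  signed <- colMeans(phi)
  ord <- order(-imp)
  tab <- data.frame(feature = colnames(phi), mean_abs_phi = imp,
                    mean_phi = signed)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  dims <- lapply(dimension_map, function(feats) {
    unknown <- setdiff(feats, colnames(phi))
    if (length(unknown))
      stop_gapdml("dimension map names unknown feature(s): %s",
                  paste(unknown, collapse = ", "))
    sum(imp[feats])
  })
  structure(list(table = tab, dimension_sums = dims),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat("Feature importance (mean |phi|):\n")
  print(head(x$table, 10), digits = 4)
  if (length(x$dimension_sums)) {
    cat("Dimension aggregates:\n")
    for (nm in names(x$dimension_sums))
      cat(sprintf("  %s = %.4f\n", nm, x$dimension_sums[[nm]]))
  }
  invisible(x)
}

#' Gain-based importance of a boosted-tree model
#'
#' The split-gain importance ranking native to gradient-boosted trees,
#' emitted alongside the Shapley ranking so the two can be compared.
#'
#' @param model an xgboost model handle.
#' @return Data frame with `feature` and `gain`, sorted descending.
#' @export
gain_importance <- function(model) {
  imp <- xgboost::xgb.importance(model = model)
  data.frame(feature = imp$Feature, gain = imp$Gain)
}

#' LOWESS dependence curve
#'
#' Locally weighted scatterplot smoothing of Shapley values against a
#' feature's values — the curve read off a dependence plot. Uses tricube
#' weights with configurable robustness iterations; smoothed values are
#' clamped to the observed range of the response so the summary never
#' overshoots the data.
#'
#' @param x feature values (length >= 10).
#' @param phi Shapley values, same length.
#' @param span smoother span in (0, 1] (default 0.6).
#' @param iterations robustness iterations (default 2).
#' @return Object of class `dependence_curve`: list with `x`, `phi`,
#'   `smooth_x`, `smooth_y`, `span`.
#' @export
dependence_curve <- function(x, phi, span = 0.6, iterations = 2) {
  if (length(x) != length(phi)) stop_gapdml("x and phi lengths differ")
  if (length(x) < 10) stop_gapdml("dependence_curve needs >= 10 points")
  if (span <= 0 || span > 1) stop_gapdml("span must be in (0, 1]")
  if (ceiling(span * length(x)) < 2)
    stop_gapdml("smoother window smaller than 2 points; increase span")
  sm <- lowess(x, phi, f = span, iter = iterations)
  ux <- !duplicated(sm$x)
  structure(list(x = x, phi = phi, smooth_x = sm$x[ux],
                 smooth_y = pmin(pmax(sm$y[ux], min(phi)), max(phi)),
                 span = span, iterations = iterations),
            class = "dependence_curve")
}

#' @export
print.dependence_curve <- function(x, ...) {
  cat(sprintf("<dependence_curve> %d points, span %.2f; smooth range [%.4f, %.4f]\n",
              length(x$x), x$span, min(x$smooth_y), max(x$smooth_y)))
  invisible(x)
}

#' @export
plot.dependence_curve <- function(x, ...) {
  graphics::plot(x$x, x$phi, pch = 16, cex = 0.4, col = "grey50",
                 xlab = "feature value", ylab = "phi", ...)
  graphics::lines(x$smooth_x, x$smooth_y, col = "red3", lwd = 2)
  invisible(x)
}

#' Tidy beeswarm/summary table
#'
#' Long-format (feature, value, phi) table behind a summary plot: plotting
#' data, not a figure.
#'
#' @param am an `attribution_matrix`.
#' @param X the feature matrix the attributions were computed on.
#' @return Data frame with `feature`, `value`, `phi`.
#' @export
beeswarm_data <- function(am, X) {
  stopifnot(inherits(am, "attribution_matrix"))
  X <- as.matrix(X)
  stopifnot(all(dim(X) == dim(am$phi)))
  data.frame(feature = rep(colnames(am$phi), each = nrow(am$phi)),
             value = as.vector(X), phi = as.vector(am$phi))
}
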