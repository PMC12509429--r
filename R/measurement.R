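#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' `alpha = k/(k-1) * (1 - sum(var_i)/var_total)` where `var_i` are the item
#' variances and `var_total` the variance of the item sum.
#'
#' @param items numeric matrix or data frame, respondents in rows and the
#'   items of one construct in columns (>= 2 items, >= 3 respondents).
#' @return Scalar alpha (can be negative for badly behaved scales; at most 1).
#' @export
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  if (ncol(x) < 2) stop_gapdml("cronbach_alpha needs at least 2 items")
  if (nrow(x) < 3) stop_gapdml("cronbach_alpha needs at least 3 respondents")
  k <- ncol(x)
  vt <- var(rowSums(x))
  if (!is.finite(vt) || vt <= 0)
    stop_gapdml("total score variance is zero: alpha undefined")
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / vt)
}

#' Average variance extracted
#'
#' Convergent-validity statistic `AVE = mean(lambda^2)` over a construct's
#' standardized loadings; the share of item variance captured by the latent
#' construct. Values above 0.5 are conventionally taken as adequate.
#'
#' @param loadings numeric vector of standardized loadings in (0, 1], or a
#'   [construct_spec()].
#' @param digits decimals for reporting (half-away-from-zero); `NULL` for
#'   the unrounded value.
#' @return Scalar AVE.
#' @examples
#' ave(c(0.850, 0.913))  # 0.778
#' @export
ave <- function(loadings, digits = 3) {
  lam <- if (inherits(loadings, "construct_spec")) loadings$loadings else loadings
  if (length(lam) < 1) stop_gapdml("ave: empty loading vector")
  if (any(lam <= 0 | lam > 1)) stop_gapdml("ave: loadings must lie in (0, 1]")
  out <- mean(lam^2)
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Composite reliability
#'
#' McDonald-style composite reliability
#' `CR = (sum lambda)^2 / ((sum lambda)^2 + sum(1 - lambda^2))`, the
#' reliability of the unit-weighted composite implied by the standardized
#' loadings. Values above 0.7 are conventionally adequate.
#'
#' @inheritParams ave
#' @return Scalar CR in \[0, 1\].
#' @examples
#' composite_reliability(c(0.850, 0.913))  # 0.875
#' @export
composite_reliability <- function(loadings, digits = 3) {
  lam <- if (inherits(loadings, "construct_spec")) loadings$loadings else loadings
  if (length(lam) < 1) stop_gapdml("composite_reliability: empty loading vector")
  if (any(lam <= 0 | lam > 1))
    stop_gapdml("composite_reliability: loadings must lie in (0, 1]")
  s2 <- sum(lam)^2
  out <- s2 / (s2 + sum(1 - lam^2))
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Overall KMO statistic `sum(r^2) / (sum(r^2) + sum(q^2))` over the
#' off-diagonal entries, where `r` are the observed correlations and `q` the
#' anti-image partial correlations obtained from the inverse correlation
#' matrix (`q_ij = -inv_ij / sqrt(inv_ii * inv_jj)`). Values near 1 mean the
#' correlation structure is dominated by shared variance and is suitable for
#' factoring. For an exact identity matrix (no shared variance at all) the
#' 0/0 form is defined as 0.
#'
#' @param R correlation matrix, dimension >= 3, invertible.
#' @return Scalar KMO in \[0, 1\].
#' @export
kmo <- function(R) {
  R <- as.matrix(R)
  p <- ncol(R)
  if (p < 3 || nrow(R) != p) stop_gapdml("kmo needs a square matrix, dim >= 3")
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv)) {
    stop_gapdml("kmo: correlation matrix is singular (condition number %.3g)",
                kappa(R))
  }
  d <- sqrt(diag(inv))
  Q <- -inv / tcrossprod(d)
  off <- upper.tri(R)
  num <- sum(R[off]^2)
  den <- num + sum(Q[off]^2)
  if (den == 0) return(0)
  num / den
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix differs from the identity:
#' `chisq = -(n - 1 - (2p + 5)/6) * log(det(R))` on `p(p-1)/2` degrees of
#' freedom. A significant result licenses factor-analytic use of the matrix.
#'
#' @param R correlation matrix with positive determinant.
#' @param n number of observations behind `R` (must exceed `ncol(R)`).
#' @return List with `chisq`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(R, n) {
  R <- as.matrix(R)
  p <- ncol(R)
  if (n <= p) stop_gapdml("bartlett_sphericity needs n > number of variables")
  dt <- det(R)
  if (!is.finite(dt) || dt <= 0)
    stop_gapdml("bartlett_sphericity: determinant of R is not positive")
  chisq <- -(n - 1 - (2 * p + 5) / 6) * log(dt)
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df, p_value = pchisq(chisq, df, lower.tail = FALSE))
}

#' Validate a construct's measurement
#'
#' Bundles [cronbach_alpha()] (from item responses) with [ave()] and
#' [composite_reliability()] (from the supplied loadings) into one report
#' row for a construct.
#'
#' @param spec a [construct_spec()].
#' @param items respondent x item matrix of that construct's responses.
#' @param digits reporting decimals for AVE/CR.
#' @return Object of class `construct_validation` (a list).
#' @export
validate_construct <- function(spec, items, digits = 3) {
  stopifnot(inherits(spec, "construct_spec"))
  if (ncol(as.matrix(items)) != length(spec$loadings))
    stop_gapdml("item count does not match %s loadings", spec$name)
  structure(list(name = spec$name,
                 alpha = cronbach_alpha(items),
                 ave = ave(spec, digits = digits),
                 cr = composite_reliability(spec, digits = digits),
                 loadings = spec$loadings),
            class = "construct_validation")
}

#' @export
print.construct_validation <- function(x, ...) {
  cat(sprintf("%s: alpha = %.3f, AVE = %.3f, CR = %.3f (%d items)\n",
              x$name, x$alpha, x$ave, x$cr, length(x$loadings)))
  invisible(x)
}

#' Z-score and one-hot encode a predictor table
#'
#' Applies the modelling encoding step: continuous columns are standardized
#' to mean 0, SD 1; categorical columns are expanded to one-hot indicator
#' groups (all levels kept for reporting; the model-matrix convention of
#' dropping the first level is recorded in `encoding_map` and applied by
#' `drop_first = TRUE`). After encoding, the pairwise Pearson correlations
#' are screened against the `r_max` threshold; exceedances raise a warning
#' (a diagnostic gate, not a hard failure) and are recorded in the result.
#'
#' @param data data frame of predictors.
#' @param schema named character vector mapping every column to
#'   `"continuous"` or `"categorical"`.
#' @param r_max correlation-screen threshold (default 0.60).
#' @param drop_first drop the first level of each one-hot group in the
#'   returned matrix (default `FALSE`: keep all levels).
#' @return Object of class `encoded_table`: list with `matrix`,
#'   `feature_names`, `encoding_map`, `standardization`, `max_abs_r`,
#'   `screen_pass`.
#' @export
encode_features <- function(data, schema, r_max = 0.60, drop_first = FALSE) {
  data <- as.data.frame(data)
  if (is.null(names(schema)) || !all(names(data) %in% names(schema)))
    stop_gapdml("schema must label every column continuous or categorical")
  bad <- setdiff(unique(schema[names(data)]), c("continuous", "categorical"))
  if (length(bad))
    stop_gapdml("unknown schema role(s): %s", paste(bad, collapse = ", "))
  cols <- list(); emap <- list(); std <- list()
  for (nm in names(data)) {
    v <- data[[nm]]
    if (schema[[nm]] == "continuous") {
      v <- as.numeric(v)
      s <- sd(v)
      if (!is.finite(s) || s == 0)
        stop_gapdml("constant column '%s' cannot be z-scored", nm)
      m <- mean(v)
      cols[[nm]] <- (v - m) / s
      emap[[nm]] <- nm
      std[[nm]] <- c(mean = m, sd = s)
    } else {
      f <- factor(v)
      lev <- levels(f)
      keep <- if (drop_first) lev[-1] else lev
      ind <- sapply(keep, function(l) as.numeric(f == l))
      colnames(ind) <- paste(nm, keep, sep = ".")
      for (j in seq_along(keep)) cols[[colnames(ind)[j]]] <- ind[, j]
      emap[[nm]] <- paste(nm, keep, sep = ".")
      attr(emap[[nm]], "dropped") <- if (drop_first) paste(nm, lev[1], sep = ".") else NA_character_
    }
  }
  M <- do.call(cbind, cols)
  rownames(M) <- NULL
  # the screen runs on the model-matrix version (first one-hot level
  # dropped): with all levels kept, complements within a group are
  # perfectly correlated by construction, which is not the collinearity
  # the screen is after
  reduced <- unlist(lapply(names(data), function(nm) {
    produced <- emap[[nm]]
    if (schema[[nm]] == "categorical" && !drop_first && length(produced) > 1)
      produced[-1] else produced
  }))
  cc <- suppressWarnings(cor(M[, reduced, drop = FALSE]))
  diag(cc) <- 0
  cc[is.na(cc)] <- 0
  max_r <- max(abs(cc))
  pass <- max_r < r_max
  if (!pass)
    warning(sprintf("correlation screen: max |r| = %.3f exceeds %.2f", max_r, r_max),
            call. = FALSE)
  structure(list(matrix = M, feature_names = colnames(M), encoding_map = emap,
                 standardization = std, max_abs_r = max_r, screen_pass = pass,
                 r_max = r_max),
            class = "encoded_table")
}

#' @export
print.encoded_table <- function(x, ...) {
  cat(sprintf("<encoded_table> %d x %d; correlation screen max |r| = %.3f (%s %0.2f)\n",
              nrow(x$matrix), ncol(x$matrix), x$max_abs_r,
              if (x$screen_pass) "<" else ">=", x$r_max))
  invisible(x)
}

#' Measurement validation report for a simulated survey
#'
#' Runs [validate_construct()] for every construct with items present in the
#' item table, plus scale-block [kmo()] and [bartlett_sphericity()] on the
#' item correlation matrices of the HBM and UTAUT blocks.
#'
#' @param items respondent x item data frame (columns named like `BEN1`).
#' @param specs list of [construct_spec()]; default [hbm_utaut_constructs()].
#' @return List with per-construct rows (`constructs`, a data frame), and
#'   `kmo_hbm`, `kmo_utaut`, `bartlett_hbm`, `bartlett_utaut`.
#' @export
validation_report <- function(items, specs = hbm_utaut_constructs()) {
  rows <- lapply(specs, function(sp) {
    have <- sp$item_labels[sp$item_labels %in% names(items)]
    if (length(have) < 2) return(NULL)
    v <- validate_construct(sp, items[have])
    data.frame(construct = v$name, n_items = length(v$loadings),
               alpha = v$alpha, ave = v$ave, cr = v$cr)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  block <- function(codes) {
    labs <- unlist(lapply(specs[codes], `[[`, "item_labels"))
    labs <- labs[labs %in% names(items)]
    as.matrix(items[labs])
  }
  hbm <- block(intersect(hbm_codes(), names(specs)))
  uta <- block(intersect(utaut_codes(), names(specs)))
  out <- list(constructs = tab)
  if (ncol(hbm) >= 3) {
    R <- cor(hbm)
    out$kmo_hbm <- kmo(R)
    out$bartlett_hbm <- bartlett_sphericity(R, nrow(hbm))
  }
  if (ncol(uta) >= 3) {
    R <- cor(uta)
    out$kmo_utaut <- kmo(R)
    out$bartlett_utaut <- bartlett_sphericity(R, nrow(uta))
  }
  out
}
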