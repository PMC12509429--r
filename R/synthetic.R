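#' Structural specification of the synthetic outcome
#'
#' Defines the ground-truth data-generating process for the standardized
#' intention-behavior gap in simulated surveys: signed linear effects per
#' construct (units: outcome change per 1 SD of the construct), optional
#' non-linear shape terms, optional pairwise interactions, and the residual
#' noise SD. The default effect pattern follows the direction and magnitude
#' of the study conditions the package emulates: perceived barriers and
#' late-night frequency widen the gap; self-efficacy, perceived benefits,
#' usage intention, social support, social influence and personal innovation
#' narrow it; usage intention additionally carries an inverted-U shape,
#' social support a downward threshold past 0.5 and social influence a mild
#' U shape.
#'
#' @param linear_coeffs named numeric vector: construct/demographic code ->
#'   signed linear effect.
#' @param nonlinear_terms list of terms, each a list with `construct`,
#'   `shape` (`"inverted_u"`, `"threshold"`, `"u_shape"`) and shape
#'   parameters (`center`/`strength` for the quadratic shapes,
#'   `location`/`drop` for the threshold).
#' @param interactions list of `list(a =, b =, coef =)` product terms, or
#'   `"default"` for the moderation pattern the package emulates: the
#'   protective tool effects (usage intention, social support) are stronger
#'   at low self-efficacy and the usage-intention effect is amplified by
#'   high perceived barriers (`SE:UI` +0.10, `SE:SS` +0.08, `BAR:UI`
#'   -0.08). With `NULL` (the default) the moderation set is used only when
#'   both `linear_coeffs` and `nonlinear_terms` are left at their defaults;
#'   a customized spec starts from no interactions.
#' @param noise_sd residual SD of the structural noise (>= 0).
#' @return Object of class `structural_spec`.
#' @export
structural_spec <- function(linear_coeffs = NULL, nonlinear_terms = NULL,
                            interactions = NULL, noise_sd = 0.30) {
  if (is.null(interactions))
    interactions <- if (is.null(linear_coeffs) && is.null(nonlinear_terms))
      "default" else list()
  if (is.null(linear_coeffs))
    linear_coeffs <- c(BAR = 0.186, SE = -0.157, UI = -0.118, SS = -0.076,
                       BEN = -0.116, Midnight = 0.108, PN = -0.095, SI = -0.026)
  if (is.null(nonlinear_terms))
    nonlinear_terms <- list(
      list(construct = "UI", shape = "inverted_u", center = -0.75, strength = 0.15),
      list(construct = "SS", shape = "threshold", location = 0.5, drop = 0.40),
      list(construct = "SI", shape = "u_shape", center = 0.8, strength = 0.08))
  if (identical(interactions, "default"))
    interactions <- list(list(a = "SE", b = "UI", coef = 0.10),
                         list(a = "SE", b = "SS", coef = 0.08),
                         list(a = "BAR", b = "UI", coef = -0.08))
  if (noise_sd < 0) stop_gapdml("noise_sd must be >= 0")
  shapes <- vapply(nonlinear_terms, `[[`, "", "shape")
  bad <- setdiff(shapes, c("inverted_u", "threshold", "u_shape"))
  if (length(bad)) stop_gapdml("unknown shape(s): %s", paste(bad, collapse = ", "))
  structure(list(linear_coeffs = linear_coeffs,
                 nonlinear_terms = nonlinear_terms,
                 interactions = interactions,
                 noise_sd = noise_sd),
            class = "structural_spec")
}

# columns a structural_spec refers to
spec_columns <- function(spec) {
  unique(c(names(spec$linear_coeffs),
           vapply(spec$nonlinear_terms, `[[`, "", "construct"),
           unlist(lapply(spec$interactions, function(tr) c(tr$a, tr$b)))))
}

#' Default latent correlation matrix for the instrument
#'
#' Inter-construct correlations default to 0.3 within a theory block (HBM or
#' UTAUT) and 0.15 across blocks — enough shared variance to look like real
#' attitude data while keeping every pairwise correlation well under the
#' 0.60 multicollinearity screen. Constructs with negative effects on the
#' gap (BAR vs the protective constructs) are given negative within-block
#' correlations of the same magnitude.
#'
#' @param codes construct codes (default: the thirteen instrument codes).
#' @param within,cross correlation magnitudes within and across blocks.
#' @return Correlation matrix.
#' @export
default_latent_corr <- function(codes = names(hbm_utaut_constructs()),
                                within = 0.3, cross = 0.15) {
  p <- length(codes)
  R <- matrix(cross, p, p, dimnames = list(codes, codes))
  blocks <- list(intersect(codes, hbm_codes()), intersect(codes, utaut_codes()))
  for (b in blocks) R[b, b] <- within
  # barriers and perceived risk run against the protective constructs
  negative <- intersect(codes, c("BAR", "PR"))
  for (nm in negative) {
    others <- setdiff(codes, negative)
    R[nm, others] <- -R[nm, others]
    R[others, nm] <- -R[others, nm]
  }
  diag(R) <- 1
  R
}

#' Simulate latent constructs and their Likert items
#'
#' Draws latent construct scores from a multivariate normal with the given
#' correlation matrix, then generates each item as
#' `lambda * factor + sqrt(1 - lambda^2) * unique_noise` and (unless
#' `continuous = TRUE`) discretizes to the construct's Likert levels using
#' equal-probability normal quantile thresholds, which preserves the rank
#' correlation between item and factor without extra parameters.
#'
#' @param specs list of [construct_spec()] objects.
#' @param n number of respondents (>= 2).
#' @param corr latent correlation matrix (positive semi-definite, all
#'   off-diagonal magnitudes < 0.60).
#' @param seed integer seed.
#' @param continuous keep items on the continuous scale (for calibration
#'   checks) instead of discretizing.
#' @return List with `latent` (n x construct matrix) and `items`
#'   (n x item data frame).
#' @export
generate_constructs <- function(specs, n, corr = NULL, seed = 1,
                                continuous = FALSE) {
  if (n < 2) stop_gapdml("generate_constructs needs n >= 2")
  codes <- vapply(specs, `[[`, "", "name")
  names(specs) <- codes
  if (is.null(corr)) corr <- default_latent_corr(codes)
  corr <- as.matrix(corr)
  if (!all(dim(corr) == length(codes)))
    stop_gapdml("corr dimension does not match the number of constructs")
  off <- abs(corr[upper.tri(corr)])
  if (any(off >= 0.60))
    stop_gapdml("latent correlations must satisfy |r| < 0.60 (max given: %.3f)",
                max(off))
  ch <- tryCatch(chol(corr), error = function(e) NULL)
  if (is.null(ch))
    stop_gapdml("corr is not positive semi-definite (chol failed; min eigenvalue %.3g)",
                min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values))
  with_seed(seed, {
    Z <- matrix(rnorm(n * length(codes)), n)
    latent <- Z %*% ch
    colnames(latent) <- codes
    items <- list()
    for (code in codes) {
      sp <- specs[[code]]
      for (j in seq_along(sp$loadings)) {
        lam <- sp$loadings[j]
        y <- lam * latent[, code] + sqrt(1 - lam^2) * rnorm(n)
        if (!continuous) {
          cuts <- qnorm(seq_len(sp$n_levels - 1) / sp$n_levels)
          y <- findInterval(y, cuts) + 1L
        }
        items[[sp$item_labels[j]]] <- y
      }
    }
    list(latent = latent, items = as.data.frame(items))
  })
}

# ---------------------------------------------------------------------------
# demographics

#' Demographic target distributions
#'
#' The sixteen demographic / activity-profile / smart-tool-profile variables
#' carried as predictors, with the ordinal support and the marginal mean and
#' SD each variable is calibrated to. Category probabilities are obtained by
#' moment-matching a maximum-entropy categorical distribution
#' (`p_k` proportional to `exp(a*k + b*k^2)`) to the target mean/SD — the
#' targets are documented configuration defaults describing a realistic
#' adult smart-sports-user sample, not an attempt to reproduce any real
#' sample's full joint distribution. `Sm_number` carries a 0 = non-user
#' level so its printed moments are attainable. BMI is continuous normal.
#'
#' @return Named list of target definitions (`values`, `mean`, `sd`, `role`).
#' @export
demographic_targets <- function() {
  list(
    PA_level          = list(values = 1:4, mean = 2.27, sd = 0.777, role = "ordinal"),
    PA_organize       = list(values = 1:3, mean = 1.36, sd = 0.479, role = "ordinal"),
    PA_purpose        = list(values = 1:7, mean = 4.11, sd = 1.856, role = "ordinal"),
    PA_comsume        = list(values = 1:5, mean = 1.82, sd = 0.980, role = "ordinal"),
    Sm_duration       = list(values = 0:5, mean = 1.45, sd = 1.324, role = "ordinal"),
    Sm_frequency      = list(values = 0:4, mean = 1.57, sd = 1.109, role = "ordinal"),
    Sm_number         = list(values = 0:3, mean = 1.51, sd = 1.152, role = "ordinal"),
    Sm_purpose        = list(values = 1:7, mean = 2.93, sd = 2.017, role = "ordinal"),
    Sex               = list(values = 1:2, mean = 1.51, sd = 0.500, role = "nominal"),
    Age               = list(values = 1:4, mean = 2.13, sd = 1.046, role = "ordinal"),
    Career            = list(values = 1:4, mean = 2.57, sd = 1.104, role = "nominal"),
    Education         = list(values = 1:4, mean = 2.58, sd = 0.874, role = "ordinal"),
    Consumption_level = list(values = 1:5, mean = 2.61, sd = 0.841, role = "ordinal"),
    Health            = list(values = 1:5, mean = 3.48, sd = 0.910, role = "ordinal"),
    Midnight          = list(values = 1:5, mean = 3.44, sd = 1.205, role = "ordinal"),
    BMI               = list(values = NULL, mean = 21.31, sd = 2.948, role = "continuous")
  )
}

# moment-match p_k ~ exp(a*k + b*k^2) on `values` to (mean, sd)
fit_moment_probs <- function(values, mean_target, sd_target) {
  obj <- function(par) {
    w <- exp(par[1] * values + par[2] * values^2)
    p <- w / sum(w)
    m <- sum(p * values)
    s <- sqrt(sum(p * (values - m)^2))
    (m - mean_target)^2 + (s - sd_target)^2
  }
  fit <- optim(c(0, 0), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  w <- exp(fit$par[1] * values + fit$par[2] * values^2)
  w / sum(w)
}

#' Sample a demographic table
#'
#' @param n respondents.
#' @param seed integer seed.
#' @param targets target list as from [demographic_targets()].
#' @return Data frame with one column per target variable.
#' @export
generate_demographics <- function(n, seed = 1, targets = demographic_targets()) {
  with_seed(seed, {
    cols <- lapply(names(targets), function(nm) {
      tg <- targets[[nm]]
      if (tg$role == "continuous") {
        rnorm(n, tg$mean, tg$sd)
      } else {
        p <- fit_moment_probs(tg$values, tg$mean, tg$sd)
        sample(tg$values, n, replace = TRUE, prob = p)
      }
    })
    names(cols) <- names(targets)
    as.data.frame(cols)
  })
}

# ---------------------------------------------------------------------------
# PARS-3 triples

#' Simulate actual and ideal PARS-3 triples
#'
#' Actual grades for intensity, duration and frequency are binomial on the
#' adopted grade coding (see [pars3_ranges()]), with per-respondent success
#' probability `plogis(qlogis(base) - slope * index)`: respondents with a
#' higher gap-propensity `index` achieve systematically less actual
#' activity, which is the baseline heterogeneity the standardized gap
#' outcome is designed to correct for. Ideal grades are the actual grades
#' plus non-negative binomial increments with probability
#' `plogis(qlogis(rate) + slope * index)`, so ideal >= actual holds
#' componentwise (hence ideal score >= actual score) and the
#' intended-vs-achieved inflation grows with the index. A zero `rate`
#' gives ideal == actual exactly. With no index supplied both channels are
#' homogeneous.
#'
#' @param n respondents.
#' @param seed integer seed.
#' @param ideal_inflation list with `rate` (baseline increment probability
#'   in \[0, 1\]), `slope` (log-odds effect of the index, default 2) and
#'   optionally `index` (length-n numeric, standardized internally).
#' @param actual_link list with `base` (named per-grade success
#'   probabilities) and `slope` (log-odds decrease per index SD, default
#'   1); the same `index` is used.
#' @param ranges grade coding, see [pars3_ranges()].
#' @return Data frame with actual and ideal grades and scores.
#' @export
generate_pars3 <- function(n, seed = 1,
                           ideal_inflation = list(rate = 0.35, slope = 2),
                           actual_link = list(base = c(intensity = 0.44,
                                                       duration = 0.475,
                                                       frequency = 0.46),
                                              slope = 1),
                           ranges = pars3_ranges()) {
  rate <- ideal_inflation$rate %||% 0.35
  slope_i <- ideal_inflation$slope %||% 2
  base <- actual_link$base %||% c(intensity = 0.44, duration = 0.475,
                                  frequency = 0.46)
  slope_a <- actual_link$slope %||% 1
  index <- ideal_inflation$index
  if (rate < 0 || rate > 1) stop_gapdml("inflation rate must be in [0, 1]")
  if (any(base <= 0 | base >= 1)) stop_gapdml("actual_link base must be in (0, 1)")
  if (!is.null(index)) {
    if (length(index) != n) stop_gapdml("index must have length n")
    index <- if (sd(index) > 0) (index - mean(index)) / sd(index) else index * 0
  } else index <- rep(0, n)
  p_inc <- if (rate == 0) rep(0, n) else plogis(qlogis(rate) + slope_i * index)
  with_seed(seed, {
    out <- list()
    for (nm in c("intensity", "duration", "frequency")) {
      r <- ranges[[nm]]
      p_act <- plogis(qlogis(base[[nm]]) - slope_a * index)
      g <- r[1] + rbinom(n, size = r[2] - r[1], prob = p_act)
      inc <- rbinom(n, size = r[2] - g, prob = p_inc)
      out[[paste0("actual_", nm)]] <- g
      out[[paste0("ideal_", nm)]] <- g + inc
    }
    out <- as.data.frame(out)
    out$actual_score <- pars3_score(out$actual_intensity, out$actual_duration,
                                    out$actual_frequency, ranges)
    out$ideal_score <- pars3_score(out$ideal_intensity, out$ideal_duration,
                                   out$ideal_frequency, ranges)
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# structural outcome

eval_shape <- function(term, x) {
  switch(term$shape,
         inverted_u = -term$strength * (x - term$center)^2,
         u_shape    =  term$strength * (x - term$center)^2,
         threshold  = -term$drop * as.numeric(x > term$location),
         stop_gapdml("unknown shape '%s'", term$shape))
}

#' Evaluate the structural outcome model
#'
#' Computes the ground-truth outcome `eta + noise` where `eta` sums the
#' linear, shape and interaction terms of a [structural_spec()] over latent
#' construct scores and (z-scored) demographic columns. With `noise_sd = 0`
#' and a single linear term the outcome is exactly that term.
#'
#' @param latent n x construct matrix of latent scores.
#' @param demographics optional demographic data frame (columns referenced
#'   by the spec are z-scored before use).
#' @param spec a [structural_spec()].
#' @param seed integer seed for the noise draw.
#' @return List with `outcome`, `structural` (the noiseless part) and the
#'   column matrix `X` the spec was evaluated on.
#' @export
generate_outcome <- function(latent, demographics = NULL, spec = structural_spec(),
                             seed = 1) {
  latent <- as.matrix(latent)
  cols <- list()
  for (nm in colnames(latent)) cols[[nm]] <- latent[, nm]
  if (!is.null(demographics))
    for (nm in names(demographics)) {
      v <- as.numeric(demographics[[nm]])
      s <- sd(v)
      cols[[nm]] <- if (is.finite(s) && s > 0) (v - mean(v)) / s else v * 0
    }
  need <- spec_columns(spec)
  missing <- setdiff(need, names(cols))
  if (length(missing))
    stop_gapdml("structural spec references unknown column(s): %s",
                paste(missing, collapse = ", "))
  n <- nrow(latent)
  eta <- rep(0, n)
  for (nm in names(spec$linear_coeffs))
    eta <- eta + spec$linear_coeffs[[nm]] * cols[[nm]]
  for (term in spec$nonlinear_terms)
    eta <- eta + eval_shape(term, cols[[term$construct]])
  for (tr in spec$interactions)
    eta <- eta + tr$coef * cols[[tr$a]] * cols[[tr$b]]
  noise <- if (spec$noise_sd > 0)
    with_seed(seed, rnorm(n, 0, spec$noise_sd)) else rep(0, n)
  list(outcome = eta + noise, structural = eta,
       X = do.call(cbind, cols))
}

# ---------------------------------------------------------------------------
# full survey

#' Configuration for the survey simulator
#'
#' @param constructs list of [construct_spec()]s (default: the shipped
#'   instrument).
#' @param latent_corr latent correlation matrix (default
#'   [default_latent_corr()]).
#' @param structural a [structural_spec()].
#' @param ideal_inflation PARS-3 inflation settings, see [generate_pars3()];
#'   the structural index is always passed as the inflation index.
#' @param actual_link PARS-3 actual-grade link settings, see
#'   [generate_pars3()]; the same structural index drives lower actual
#'   activity for high-gap-propensity respondents.
#' @param demographics demographic targets, see [demographic_targets()].
#' @param sd_convention SD convention for [delta_z()].
#' @param outcome `"pars3"` (default: the outcome is the standardized gap
#'   computed from simulated PARS-3 triples whose ideal-inflation follows
#'   the structural index) or `"structural"` (the outcome is the continuous
#'   structural index itself — useful for exact ground-truth checks).
#' @return List of class `survey_config`.
#' @export
survey_config <- function(constructs = hbm_utaut_constructs(),
                          latent_corr = NULL,
                          structural = structural_spec(),
                          ideal_inflation = list(rate = 0.35, slope = 2),
                          actual_link = list(slope = 1),
                          demographics = demographic_targets(),
                          sd_convention = "sample",
                          outcome = c("pars3", "structural")) {
  outcome <- match.arg(outcome)
  structure(list(constructs = constructs, latent_corr = latent_corr,
                 structural = structural, ideal_inflation = ideal_inflation,
                 actual_link = actual_link,
                 demographics = demographics, sd_convention = sd_convention,
                 outcome = outcome),
            class = "survey_config")
}

#' Simulate a full survey dataset
#'
#' Generates a respondent-level table with exactly 29 predictors (13
#' construct composite scores + 16 demographic variables under the default
#' configuration) and one outcome column `delta_z`, together with the latent
#' ground truth needed to test every downstream stage. The outcome is the
#' baseline-corrected standardized gap computed by [delta_z()] from
#' simulated PARS-3 triples whose ideal-side inflation follows the
#' structural index, so known effect directions propagate into the observed
#' outcome; zero ideal-inflation yields an identically zero outcome.
#'
#' @param n respondents (>= 10).
#' @param seed integer master seed; all stage seeds derive from it.
#' @param config a [survey_config()].
#' @return Object of class `synthetic_survey`: list with `survey_table`
#'   (29 predictors + `delta_z`), `items`, `latent`, `demographics`,
#'   `pars3`, `gap`, `true_effects`, `schema` (encoding roles) and `seed`.
#' @export
generate_survey <- function(n, seed = 1, config = survey_config()) {
  if (n < 10) stop_gapdml("generate_survey needs n >= 10")
  stopifnot(inherits(config, "survey_config"))
  codes <- vapply(config$constructs, `[[`, "", "name")
  known <- c(codes, names(config$demographics))
  missing <- setdiff(spec_columns(config$structural), known)
  if (length(missing))
    stop_gapdml("config references unknown column(s): %s",
                paste(missing, collapse = ", "))
  gc <- generate_constructs(config$constructs, n, config$latent_corr,
                            seed = derive_seed(seed, "constructs"))
  demo <- generate_demographics(n, seed = derive_seed(seed, "demographics"),
                                targets = config$demographics)
  outc <- generate_outcome(gc$latent, demo, config$structural,
                           seed = derive_seed(seed, "outcome"))
  infl <- config$ideal_inflation
  infl$index <- outc$outcome
  p3 <- generate_pars3(n, seed = derive_seed(seed, "pars3"),
                       ideal_inflation = infl,
                       actual_link = config$actual_link %||% list(slope = 1))
  gap <- if (sd(p3$actual_score) > 0)
    delta_z(p3$ideal_score, p3$actual_score, config$sd_convention)
  else list(delta_z = rep(0, n), sigma_actual = NA_real_)
  # composite construct scores: mean of the construct's Likert items
  comp <- sapply(codes, function(code) {
    labs <- config$constructs[[code]]$item_labels
    rowMeans(gc$items[labs])
  })
  survey <- data.frame(comp, demo, check.names = FALSE)
  survey$delta_z <- if (config$outcome == "pars3") gap$delta_z else outc$outcome
  roles <- vapply(names(config$demographics), function(nm) {
    if (config$demographics[[nm]]$role == "nominal") "categorical" else "continuous"
  }, "")
  schema <- c(setNames(rep("continuous", length(codes)), codes), roles)
  structure(list(survey_table = survey, items = gc$items, latent = gc$latent,
                 demographics = demo, pars3 = p3, gap = gap,
                 structural_index = outc$outcome,
                 true_effects = config$structural, schema = schema,
                 seed = seed, config = config),
            class = "synthetic_survey")
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat(sprintf("<synthetic_survey> %d respondents, %d predictors + delta_z (seed %d)\n",
              nrow(x$survey_table), ncol(x$survey_table) - 1L, x$seed))
  invisible(x)
}

#' Write a synthetic survey to CSV with a JSON sidecar
#'
#' @param x a `synthetic_survey`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return Invisibly, the two paths.
#' @export
write_survey <- function(x, path) {
  stopifnot(inherits(x, "synthetic_survey"))
  write.csv(x$survey_table, path, row.names = FALSE)
  meta <- list(seed = x$seed,
               n = nrow(x$survey_table),
               schema = as.list(x$schema),
               sd_convention = x$config$sd_convention,
               linear_coeffs = as.list(x$true_effects$linear_coeffs),
               noise_sd = x$true_effects$noise_sd)
  side <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

# ---------------------------------------------------------------------------
# linear-confounding benchmark for the causal estimator

#' Linear-confounding benchmark design
#'
#' A fully linear design with known treatment effects, built for calibrating
#' and testing the cross-fitted causal estimator: `q` baseline confounders
#' `W ~ N(0, I)`; each treatment `T_j = W %*% gamma_j + nu_j` is confounded
#' by `W`; the outcome is `Y = T %*% theta + W %*% delta + eps`. When one
#' treatment is analyzed, the remaining treatments belong to the covariate
#' set, so every `theta_j` is identified by partialling out. Coefficients
#' are drawn once from the seed and returned as ground truth.
#'
#' @param n observations.
#' @param seed integer seed.
#' @param theta named treatment-effect vector; default: the eight focal
#'   effects with the direction pattern of the emulated study.
#' @param q number of baseline confounders.
#' @param confounding scale of `gamma` and `delta` draws.
#' @param treat_noise_sd SD of the treatment residual `nu`.
#' @param noise_sd SD of the outcome noise `eps`.
#' @return List with `data` (treatments, `W1..Wq`, `delta_z`) and `theta`.
#' @export
generate_dml_benchmark <- function(n, seed = 1, theta = NULL, q = 10,
                                   confounding = 0.35, treat_noise_sd = 0.7,
                                   noise_sd = 0.5) {
  if (is.null(theta))
    theta <- c(BAR = 0.186, SE = -0.157, UI = -0.118, SS = -0.076,
               BEN = -0.116, Midnight = 0.108, PN = -0.095, SI = -0.026)
  p <- length(theta)
  with_seed(seed, {
    W <- matrix(rnorm(n * q), n, dimnames = list(NULL, paste0("W", seq_len(q))))
    Gamma <- matrix(rnorm(q * p, 0, confounding), q)
    delta <- rnorm(q, 0, confounding)
    Tm <- W %*% Gamma + matrix(rnorm(n * p, 0, treat_noise_sd), n)
    colnames(Tm) <- names(theta)
    y <- drop(Tm %*% theta + W %*% delta + rnorm(n, 0, noise_sd))
    dat <- data.frame(Tm, W, check.names = FALSE)
    dat$delta_z <- y
    list(data = dat, theta = theta, q = q)
  })
}
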