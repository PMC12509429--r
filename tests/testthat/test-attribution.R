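test_that("exact Shapley matches the linear closed form and the axioms", {
  set.seed(1)
  w <- c(2, -1, 0.5, 0, 3)
  f <- linear_model(w)
  bg <- matrix(rnorm(60 * 5), 60)
  x <- setNames(rnorm(5), paste0("f", 1:5))
  phi <- exact_shapley(f, x, bg)
  expect_equal(unname(c(phi)), unname(linear_shapley_oracle(w, x, bg)),
               tolerance = 1e-10)
  # efficiency (local accuracy)
  expect_equal(attr(phi, "baseline") + sum(phi), f(matrix(x, 1)),
               tolerance = 1e-10)
  # dummy axiom: zero-weight feature gets zero
  expect_equal(unname(phi[4]), 0, tolerance = 1e-12)
  # constant model: all phi zero
  phc <- exact_shapley(constant_model(3.7), x, bg)
  expect_equal(unname(c(phc)), rep(0, 5), tolerance = 1e-12)
})

test_that("symmetry: duplicated features in a symmetric model share credit", {
  set.seed(2)
  f <- function(M) M[, 1] + M[, 2] + 0.5 * M[, 3]
  z <- rnorm(40)
  bg <- cbind(z, z, rnorm(40))  # features 1 and 2 identical everywhere
  x <- c(a = 1.3, b = 1.3, c = -0.4)
  phi <- exact_shapley(f, x, bg)
  expect_equal(unname(phi[1]), unname(phi[2]), tolerance = 1e-10)
})

test_that("exact Shapley satisfies local accuracy on a nonlinear model", {
  set.seed(3)
  f <- function(M) M[, 1] * M[, 2] + exp(M[, 3] / 2) - (M[, 4] > 0)
  bg <- matrix(rnorm(80 * 4), 80)
  for (i in 1:5) {
    x <- rnorm(4)
    phi <- exact_shapley(f, x, bg)
    expect_lt(abs(attr(phi, "baseline") + sum(phi) - f(matrix(x, 1))), 1e-6)
  }
})

test_that("enumeration cap directs large problems to the sampler", {
  f <- linear_model(rep(1, 16))
  expect_error(exact_shapley(f, rnorm(16), matrix(rnorm(32), 2), max_features = 15),
               "sampled_shapley")
})

test_that("sampled Shapley converges to the exact oracle within Monte-Carlo error", {
  set.seed(4)
  p <- 8
  f <- function(M) M[, 1] * M[, 2] + sin(M[, 3]) + M[, 4]^2 - 0.5 * M[, 5]
  bg <- matrix(rnorm(40 * p), 40)
  x <- setNames(rnorm(p), paste0("f", 1:p))
  exact <- exact_shapley(f, x, bg)
  est <- sampled_shapley(f, x, bg, permutations = 20000, seed = 5)
  expect_true(all(abs(est - exact) < 3 * attr(est, "se") + 1e-10))
  # reproducible under a fixed seed
  est2 <- sampled_shapley(f, x, bg, permutations = 500, seed = 6)
  est3 <- sampled_shapley(f, x, bg, permutations = 500, seed = 6)
  expect_identical(c(est2), c(est3))
  # precision improves roughly with permutations
  est_small <- sampled_shapley(f, x, bg, permutations = 500, seed = 7)
  expect_lt(mean(attr(est, "se")), mean(attr(est_small, "se")))
})

test_that("attribution matrix: local accuracy per instance and shared baseline", {
  set.seed(5)
  w <- c(1, -2, 0.5)
  f <- linear_model(w)
  X <- matrix(rnorm(30 * 3), 30, dimnames = list(NULL, c("a", "b", "c")))
  am <- shapley_attribution(f, X, mode = "exact", seed = 1)
  expect_equal(dim(am$phi), c(30, 3))
  recon <- am$baseline + rowSums(am$phi)
  expect_equal(recon, am$predictions, tolerance = 1e-8)
})

test_that("importance ranking orders by mean |phi| and aggregates dimensions", {
  phi <- cbind(BAR = c(2, -2, 2), SE = c(1, 1, -1), UI = c(0.5, 0.5, 0.5),
               SS = c(0.1, -0.1, 0.1))
  r <- importance_ranking(phi, dimension_map = list(psy = c("BAR", "SE"),
                                                    tool = c("UI", "SS")))
  expect_equal(r$table$feature, c("BAR", "SE", "UI", "SS"))
  expect_equal(r$table$rank, 1:4)
  expect_equal(r$dimension_sums$psy, 2 + 1)
  expect_equal(r$dimension_sums$tool, 0.5 + 0.1)
  expect_error(importance_ranking(phi, dimension_map = list(x = "NOPE")),
               "unknown feature")
  # all-zero matrix: zero importances, stable ranks
  r0 <- importance_ranking(matrix(0, 3, 2, dimnames = list(NULL, c("a", "b"))))
  expect_equal(r0$table$mean_abs_phi, c(0, 0))
  expect_equal(r0$table$rank, 1:2)
})

test_that("a dominant feature is ranked first across seeds", {
  w <- c(BAR = 2, SE = 1, UI = 1, SS = 1)
  f <- linear_model(w)
  firsts <- sapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 4), 40, dimnames = list(NULL, names(w)))
    am <- shapley_attribution(f, X, mode = "exact", seed = s)
    importance_ranking(am)$table$feature[1]
  })
  expect_true(mean(firsts == "BAR") >= 0.9)
})

test_that("dependence curve reproduces a line and respects the data range", {
  set.seed(6)
  x <- sort(rnorm(200))
  phi <- 0.3 * x - 0.1
  dc <- dependence_curve(x, phi, span = 0.6)
  # linear signal is a fixed point of local linear smoothing
  expect_lt(max(abs(dc$smooth_y - (0.3 * dc$smooth_x - 0.1))), 1e-6)
  phi2 <- phi + rnorm(200, 0, 0.1)
  dc2 <- dependence_curve(x, phi2)
  expect_gte(min(dc2$smooth_y), min(phi2))
  expect_lte(max(dc2$smooth_y), max(phi2))
  expect_error(dependence_curve(x[1:5], phi[1:5]), ">= 10")
  expect_error(dependence_curve(x, phi, span = 1.5), "span")
})

test_that("dependence curve recovers an interior peak and a threshold drop", {
  set.seed(7)
  x <- rnorm(800)
  # inverted-U: peak strictly inside the range
  phi_u <- -(x + 1)^2 + rnorm(800, 0, 0.3)
  dc <- dependence_curve(x, phi_u, span = 0.4)
  peak <- dc$smooth_x[which.max(dc$smooth_y)]
  expect_gt(peak, min(x)); expect_lt(peak, max(x))
  expect_equal(peak, -1, tolerance = 0.5)
  # threshold at 0.5: largest decrease localizes near the cut
  phi_t <- -0.8 * (x > 0.5) + rnorm(800, 0, 0.1)
  dct <- dependence_curve(x, phi_t, span = 0.25)
  drop_at <- dct$smooth_x[which.min(diff(dct$smooth_y))]
  expect_equal(drop_at, 0.5, tolerance = 0.3)
})

test_that("signed mean attributions on default synthetic data match the configured directions", {
  s <- generate_survey(900, seed = 31)
  d <- s$survey_table
  feats <- c("BAR", "SE", "UI", "SS", "BEN", "Midnight", "PN", "SI")
  X <- scale(as.matrix(d[feats]))
  y <- d$delta_z
  fit <- lm(y ~ X)
  f <- function(M) as.numeric(cbind(1, M) %*% coef(fit))
  am <- shapley_attribution(f, X, mode = "sampled", permutations = 300, seed = 1,
                            background_size = 100)
  # direction of effect: correlation between feature value and its phi
  dir <- sapply(feats, function(nm) cor(X[, nm], am$phi[, nm]))
  want <- c(BAR = 1, SE = -1, UI = -1, SS = -1, BEN = -1, Midnight = 1,
            PN = -1, SI = -1)
  expect_equal(sign(dir[names(want)]), want)
})
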