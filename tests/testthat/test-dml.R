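test_that("theta_hat: exact relation, orthogonality and normal-equations oracle", {
  set.seed(1)
  e_t <- rnorm(50)
  expect_equal(theta_hat(2 * e_t, e_t), 2, tolerance = 1e-12)
  # orthogonal residuals -> zero effect
  e_y <- rnorm(50)
  e_y_orth <- e_y - theta_hat(e_y, e_t) * e_t
  expect_equal(theta_hat(e_y_orth, e_t), 0, tolerance = 1e-12)
  # equals the least-squares solution from an independent solver
  for (i in 1:5) {
    a <- rnorm(50); b <- rnorm(50)
    oracle <- qr.solve(matrix(b, ncol = 1), a)
    expect_equal(theta_hat(a, b), as.numeric(oracle), tolerance = 1e-10)
  }
  expect_error(theta_hat(rnorm(5), rep(0, 5)), "zero variance")
})

test_that("cross-fitted residuals are out-of-fold and centered", {
  b <- generate_dml_benchmark(800, seed = 2)
  Y <- b$data$delta_z; T_ <- b$data$BAR
  W <- as.matrix(b$data[setdiff(names(b$data), c("BAR", "delta_z"))])
  res <- crossfit_residuals(Y, T_, W, learner = "lm", K = 5, seed = 3)
  expect_s3_class(res, "dml_residuals")
  expect_equal(sort(unique(res$fold)), 1:5)
  expect_lt(abs(mean(res$e_y)), 0.05)
  expect_lt(abs(mean(res$e_t)), 0.05)
  # refitting a fold's nuisance on its own training rows reproduces the
  # held-out predictions (out-of-fold contract)
  k <- 1L; hold <- res$fold == k
  g_refit <- gapdml:::fit_predict("lm", list(), W[!hold, ], Y[!hold], W[hold, ])
  expect_equal(res$g_hat[hold], g_refit, tolerance = 1e-10)
  # guards
  expect_error(crossfit_residuals(Y, rep(1, 800), W, "lm"), "constant")
  expect_error(crossfit_residuals(Y, T_, cbind(W, T_), "lm"), "present in W")
  expect_error(crossfit_residuals(Y, T_, W, "lm", K = 1), "K >= 2")
})

test_that("a flexible learner drives outcome residuals to zero in the noiseless limit", {
  set.seed(4)
  W <- matrix(rnorm(500 * 3), 500, dimnames = list(NULL, paste0("W", 1:3)))
  Y <- drop(W %*% c(1, -2, 0.5))          # Y is exactly g(W), no noise
  T_ <- rnorm(500) + W[, 1]
  res <- crossfit_residuals(Y, T_, W, learner = "lm", K = 5, seed = 1)
  expect_lt(max(abs(res$e_y)), 1e-10)
})

test_that("kfold_theta: homogeneity, reduction and the averaging formula", {
  b <- generate_dml_benchmark(600, seed = 6)
  Y <- b$data$delta_z; T_ <- b$data$SE
  W <- as.matrix(b$data[setdiff(names(b$data), c("SE", "delta_z"))])
  res <- crossfit_residuals(Y, T_, W, learner = "lm", K = 4, seed = 7)
  th <- kfold_theta(res, "per_fold")
  expect_length(th$theta_per_fold, 4)
  expect_equal(th$theta, mean(th$theta_per_fold))
  # pooled and per-fold agree closely on homogeneous data
  expect_equal(th$theta_pooled, th$theta, tolerance = 0.05)
  # constructed folds with theta_k = (1, 2, 3) average to 2
  fake <- structure(list(e_y = c(1, 2, 3) * c(1, 1, 1), e_t = rep(1, 3),
                         fold = 1:3, K = 3), class = "dml_residuals")
  expect_equal(kfold_theta(fake, "per_fold")$theta, 2)
})

test_that("bootstrap inference: noiseless collapse and stability in B", {
  set.seed(8)
  e_t <- rnorm(300)
  e_y <- 0.7 * e_t                      # exact relation, no noise
  bt <- bootstrap_inference(list(e_y = e_y, e_t = e_t), B = 300, seed = 1)
  expect_lt(bt$se, 1e-12)
  expect_equal(bt$ci95, c(0.7, 0.7), tolerance = 1e-10)
  # doubling B leaves the SE stable within Monte-Carlo tolerance
  e_y2 <- 0.5 * e_t + rnorm(300, 0, 0.5)
  b1 <- bootstrap_inference(list(e_y = e_y2, e_t = e_t), B = 1000, seed = 2)
  b2 <- bootstrap_inference(list(e_y = e_y2, e_t = e_t), B = 2000, seed = 3)
  expect_equal(b1$se, b2$se, tolerance = 0.15)
  expect_error(bootstrap_inference(list(e_y = e_y, e_t = e_t), B = 50), "B >= 100")
})

test_that("dml_ate recovers a known effect under confounding and reduces naive bias", {
  runs <- lapply(1:10, function(s) {
    b <- generate_dml_benchmark(2000, seed = s)
    fit <- dml_ate(b$data, "BAR", learner = "lm", B = 200, seed = s)
    naive <- coef(lm(delta_z ~ BAR, data = b$data))[2]
    c(dml = coef(fit)[["BAR"]], naive = unname(naive), truth = b$theta[["BAR"]])
  })
  runs <- do.call(rbind, runs)
  expect_lt(mean(abs(runs[, "dml"] - runs[, "truth"])), 0.05)
  # orthogonalization beats the unadjusted slope in >= 90% of runs
  better <- abs(runs[, "dml"] - runs[, "truth"]) <
    abs(runs[, "naive"] - runs[, "truth"])
  expect_gte(mean(better), 0.9)
})

test_that("dml_ate object contract and its S3 methods", {
  b <- generate_dml_benchmark(500, seed = 9)
  fit <- dml_ate(b$data, "UI", learner = "lm", B = 200, seed = 1)
  expect_s3_class(fit, "dml_ate")
  expect_equal(unname(coef(fit)), fit$theta)
  ci <- confint(fit)
  expect_equal(unname(ci[1, ]), fit$theta + c(-1, 1) * qnorm(0.975) * fit$se)
  expect_true(fit$ci95[1] <= fit$theta && fit$theta <= fit$ci95[2])
  r <- residuals(fit)
  expect_named(r, c("e_y", "e_t", "fold"))
  expect_equal(nrow(r), 500)
  # pooled orthogonality at the estimate
  expect_lt(abs(sum(r$e_t * (r$e_y - fit$theta_pooled * r$e_t))), 1e-8)
  expect_output(print(fit), "DML ATE of UI")
  expect_output(summary(fit), "per-fold")
  # determinism
  fit2 <- dml_ate(b$data, "UI", learner = "lm", B = 200, seed = 1)
  expect_equal(coef(fit2), coef(fit))
  expect_equal(fit2$se, fit$se)
  expect_error(dml_ate(b$data, "NOPE"), "not in data")
})

test_that("K = 2 and K = 5 agree within sampling error on a large sample", {
  b <- generate_dml_benchmark(3000, seed = 10)
  f2 <- dml_ate(b$data, "SS", learner = "lm", K = 2, B = 200, seed = 1)
  f5 <- dml_ate(b$data, "SS", learner = "lm", K = 5, B = 200, seed = 1)
  expect_equal(coef(f2), coef(f5), tolerance = 3 * (f2$se + f5$se))
})

test_that("subgroup analysis: median split rule, guard and homogeneous limit", {
  b <- generate_dml_benchmark(1200, seed = 11)
  sg <- subgroup_ates(b$data, "SE", c("UI", "SS"), learner = "lm",
                      B = 200, seed = 2)
  expect_s3_class(sg, "dml_subgroups")
  ns <- c(sg$groups$lower$n, sg$groups$higher$n)
  expect_equal(sum(ns), 1200)
  expect_true(all(ns >= 250))
  # ties go to the lower group
  expect_gte(sg$groups$lower$n, sg$groups$higher$n)
  # homogeneous truth: both subgroup estimates near the pooled effect
  pooled <- dml_ate(b$data, "UI", learner = "lm", B = 200, seed = 2)
  lo <- sg$groups$lower$table$ate[sg$groups$lower$table$variable == "UI"]
  hi <- sg$groups$higher$table$ate[sg$groups$higher$table$variable == "UI"]
  expect_lt(abs(lo - coef(pooled)[["UI"]]), 0.1)
  expect_lt(abs(hi - coef(pooled)[["UI"]]), 0.1)
  # undersized groups refused with the threshold cited
  small <- generate_dml_benchmark(300, seed = 12)
  expect_error(subgroup_ates(small$data, "SE", "UI", learner = "lm"),
               "minimum of 250")
})
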