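test_that("construct generation recovers specified loadings in continuous mode", {
  specs <- list(construct_spec("BEN", c(0.850, 0.913)),
                construct_spec("SE", c(0.829, 0.934, 0.942, 0.837)))
  corr <- diag(2); corr[1, 2] <- corr[2, 1] <- 0.3
  dimnames(corr) <- list(c("BEN", "SE"), c("BEN", "SE"))
  devs <- sapply(1:5, function(s) {
    g <- generate_constructs(specs, n = 5000, corr = corr, seed = s,
                             continuous = TRUE)
    lam_hat <- c(cor(g$items$BEN1, g$latent[, "BEN"]),
                 cor(g$items$BEN2, g$latent[, "BEN"]),
                 cor(g$items$SE1, g$latent[, "SE"]),
                 cor(g$items$SE2, g$latent[, "SE"]),
                 cor(g$items$SE3, g$latent[, "SE"]),
                 cor(g$items$SE4, g$latent[, "SE"]))
    max(abs(lam_hat - c(0.850, 0.913, 0.829, 0.934, 0.942, 0.837)))
  })
  expect_lt(max(devs), 0.03)
})

test_that("degenerate loading of 1 makes the continuous item equal the factor", {
  g <- generate_constructs(list(construct_spec("X", 1)), n = 200,
                           corr = matrix(1, 1, 1, dimnames = list("X", "X")),
                           seed = 1, continuous = TRUE)
  expect_equal(g$items$X1, unname(g$latent[, "X"]), tolerance = 1e-12)
})

test_that("discretized items live on the Likert levels and track the factor", {
  g <- generate_constructs(hbm_utaut_constructs(), n = 2000, seed = 5)
  expect_true(all(as.matrix(g$items) %in% 1:7))
  expect_gt(cor(g$items$UI1, g$latent[, "UI"]), 0.7)
})

test_that("construct generation rejects bad correlation inputs", {
  specs <- list(construct_spec("A", 0.8), construct_spec("B", 0.9))
  bad <- matrix(c(1, 0.7, 0.7, 1), 2)  # violates the 0.60 screen
  expect_error(generate_constructs(specs, 100, bad, 1), "0.60")
  nonpsd <- matrix(c(1, 0.5, 0.5, 0.5, 1, -0.59, 0.5, -0.59, 1), 3)
  specs3 <- list(construct_spec("A", 0.8), construct_spec("B", 0.9),
                 construct_spec("C", 0.7))
  expect_error(generate_constructs(specs3, 100, nonpsd, 1), "positive semi-definite")
  expect_error(construct_spec("A", c(0.5, 1.3)), "0, 1")
})

test_that("pars3 triples: ideal dominates actual, ranges hold, no-gap limit", {
  p <- generate_pars3(1000, seed = 2)
  expect_true(all(p$ideal_score >= p$actual_score))
  expect_true(all(p$actual_score >= 0 & p$actual_score <= 100))
  expect_true(all(p$ideal_score >= 0 & p$ideal_score <= 100))
  expect_gt(mean(p$ideal_score), mean(p$actual_score))
  # zero inflation -> ideal == actual -> all gaps zero downstream
  p0 <- generate_pars3(500, seed = 3, ideal_inflation = list(rate = 0))
  expect_identical(p0$ideal_score, p0$actual_score)
  expect_equal(delta_z(p0$ideal_score, p0$actual_score)$delta_z, rep(0, 500))
})

test_that("structural outcome: identity, sign pattern and threshold oracle", {
  set.seed(10)
  lat <- matrix(rnorm(2000 * 13), 2000,
                dimnames = list(NULL, names(hbm_utaut_constructs())))
  # single linear term, no noise -> outcome is exactly that score
  sp1 <- structural_spec(linear_coeffs = c(BAR = 1), nonlinear_terms = list(),
                         noise_sd = 0)
  o1 <- generate_outcome(lat, spec = sp1)
  expect_equal(o1$outcome, unname(lat[, "BAR"]), tolerance = 1e-12)
  # default spec: marginal correlation signs match the configured pattern
  demo <- generate_demographics(2000, seed = 4)
  o <- generate_outcome(lat, demo, structural_spec(), seed = 6)
  signs <- c(BAR = 1, SE = -1, UI = -1, SS = -1, BEN = -1, PN = -1, SI = -1)
  for (nm in names(signs))
    expect_equal(sign(cor(lat[, nm], o$outcome)), unname(signs[nm]),
                 info = nm)
  expect_gt(cor(demo$Midnight, o$outcome), 0)
  # threshold shape: group-mean difference across the cut equals the drop
  spt <- structural_spec(linear_coeffs = c(SS = 0),
                         nonlinear_terms = list(list(construct = "SS",
                                                     shape = "threshold",
                                                     location = 0.5, drop = 0.4)),
                         noise_sd = 0)
  ot <- generate_outcome(lat, spec = spt)
  expect_equal(mean(ot$outcome[lat[, "SS"] <= 0.5]) -
                 mean(ot$outcome[lat[, "SS"] > 0.5]), 0.4, tolerance = 1e-12)
  # unknown construct rejected
  expect_error(generate_outcome(lat, spec = structural_spec(linear_coeffs = c(XX = 1))),
               "unknown column")
})

test_that("full survey: shape contract, determinism and demographic targets", {
  s <- generate_survey(1334, seed = 21)
  expect_equal(ncol(s$survey_table), 30)  # 29 predictors + outcome
  expect_equal(nrow(s$survey_table), 1334)
  expect_false(anyNA(s$survey_table))
  expect_identical(generate_survey(1334, seed = 21)$survey_table, s$survey_table)
  expect_false(identical(generate_survey(1334, seed = 22)$survey_table,
                         s$survey_table))
  # demographic moment targets at large n (Monte-Carlo tolerance)
  big <- generate_demographics(10000, seed = 1)
  expect_equal(mean(big$Midnight), 3.44, tolerance = 0.1)
  expect_equal(sd(big$Midnight), 1.205, tolerance = 0.1)
  expect_equal(mean(big$Health), 3.48, tolerance = 0.1)
  expect_equal(mean(big$BMI), 21.31, tolerance = 0.15)
  # encoded predictors pass the 0.60 correlation screen
  enc <- encode_features(s$survey_table[setdiff(names(s$survey_table), "delta_z")],
                         s$schema, drop_first = TRUE)
  expect_true(enc$screen_pass)
  # config referencing unknown columns rejected; n guard
  bad <- survey_config(structural = structural_spec(linear_coeffs = c(ZZZ = 1)))
  expect_error(generate_survey(100, seed = 1, config = bad), "unknown column")
  expect_error(generate_survey(5, seed = 1), "n >= 10")
})

test_that("zero ideal-inflation propagates to an identically zero outcome", {
  cfg <- survey_config(ideal_inflation = list(rate = 0, slope = 1.5))
  s <- generate_survey(300, seed = 8, config = cfg)
  expect_equal(s$survey_table$delta_z, rep(0, 300))
})

test_that("linear-confounding benchmark is confounded and carries its truth", {
  b <- generate_dml_benchmark(1500, seed = 5)
  expect_equal(names(b$theta)[1], "BAR")
  expect_equal(ncol(b$data), 8 + b$q + 1)
  # naive slope is biased away from truth by construction
  naive <- coef(lm(delta_z ~ BAR, data = b$data))[2]
  expect_gt(abs(naive - b$theta["BAR"]), 0.03)
  expect_identical(generate_dml_benchmark(1500, seed = 5)$data, b$data)
})

test_that("survey CSV round-trips with its JSON sidecar", {
  s <- generate_survey(50, seed = 2)
  tmp <- file.path(tempdir(), "survey_test.csv")
  paths <- write_survey(s, tmp)
  back <- read.csv(tmp)
  expect_equal(dim(back), dim(s$survey_table))
  expect_equal(back$delta_z, s$survey_table$delta_z, tolerance = 1e-12)
  meta <- jsonlite::read_json(paths[2])
  expect_equal(meta$seed, 2)
  expect_equal(meta$n, 50)
  unlink(paths)
})
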