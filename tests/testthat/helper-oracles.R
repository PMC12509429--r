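# Independent oracles used across tests.

# partial correlation of variables i and j given all others, computed from
# the correlation matrix by the regression route (solve on submatrices) —
# independent of the anti-image/inverse formula inside kmo()
partial_cor_oracle <- function(R, i, j) {
  others <- setdiff(seq_len(ncol(R)), c(i, j))
  if (!length(others)) return(R[i, j])
  S <- R[others, others, drop = FALSE]
  ri <- R[others, i]
  rj <- R[others, j]
  bi <- solve(S, ri)
  bj <- solve(S, rj)
  num <- R[i, j] - sum(ri * bj)
  den <- sqrt((1 - sum(ri * bi)) * (1 - sum(rj * bj)))
  num / den
}

# brute-force KMO from the oracle partials
kmo_oracle <- function(R) {
  p <- ncol(R)
  r2 <- 0; q2 <- 0
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    r2 <- r2 + R[i, j]^2
    q2 <- q2 + partial_cor_oracle(R, i, j)^2
  }
  r2 / (r2 + q2)
}

# closed-form Shapley values of a linear model with an independent
# background: phi_j = w_j * (x_j - mean(background_j))
linear_shapley_oracle <- function(w, x, background) {
  w * (x - colMeans(background))
}

# standard toy models
linear_model <- function(w) function(M) as.numeric(as.matrix(M) %*% w)
constant_model <- function(c0) function(M) rep(c0, nrow(as.matrix(M)))

# a small survey config with an SE x UI interaction (heterogeneity tests)
interaction_config <- function(coef = 0.08) {
  survey_config(structural = structural_spec(
    interactions = list(list(a = "SE", b = "UI", coef = coef))))
}
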