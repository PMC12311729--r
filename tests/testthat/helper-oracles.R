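# Independent oracles used across the suite.

# Closed-form solution of a purely first-order (linear) reaction network:
# y(t) = expm(K t) y0, with K assembled from unimolecular steps.
# `steps` is a list of list(from =, to =, k =) entries over species `ns`.
expm_trajectory <- function(species, steps, y0, times) {
  K <- matrix(0, length(species), length(species),
              dimnames = list(species, species))
  for (st in steps) {
    K[st$from, st$from] <- K[st$from, st$from] - st$k
    K[st$to, st$from] <- K[st$to, st$from] + st$k
  }
  t(sapply(times, function(tt) {
    as.numeric(Matrix::expm(K * tt) %*% y0)
  }))
}

# Build an edx_mechanism from the same first-order step list, with all
# constants fixed, for comparison against the matrix exponential.
linear_mechanism <- function(species, steps, y0) {
  rs <- lapply(seq_along(steps), function(j) {
    st <- steps[[j]]
    reaction_step(st$from, st$to, kf = st$k, kf_name = paste0("k", j),
                  kf_status = "fixed")
  })
  mechanism(data.frame(name = species, conc0 = y0), rs)
}

# Quadratic-SSE fixture: ordinary linear model y = X beta + e. Returns the
# exact SSE function of beta and the analytic pieces of its quadratic form
# SSE(beta) = sse_min + (beta - bhat)' XtX (beta - bhat).
linear_sse_fixture <- function(seed = 42, n = 60) {
  set.seed(seed)
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  beta_true <- c(x1 = 1.5, x2 = 0.7)
  y <- X %*% beta_true + rnorm(n, 0, 0.3)
  bhat <- drop(solve(crossprod(X), crossprod(X, y)))
  sse_min <- sum((y - X %*% bhat)^2)
  list(
    sse = function(beta) sum((y - X %*% beta)^2),
    bhat = stats::setNames(bhat, c("x1", "x2")),
    sse_min = sse_min,
    XtX = crossprod(X))
}

# A small, fast variant of the single-turnover generator used where the
# full 500-point grid is not needed.
quick_traces <- function(seed, replicates = 15, noise_sd = 0.002,
                         n_points = 200) {
  gen_stopped_flow(seed = seed, replicates = replicates, noise_sd = noise_sd,
                   n_points = n_points)
}
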