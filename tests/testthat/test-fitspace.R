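# FitSpace profiling engine on an exactly quadratic SSE surface, where the
# confidence region has a closed form: SSE(b) = SSE_min + d' XtX d, so the
# boundary {ratio = thr} is the ellipse d' XtX d = SSE_min (1/thr - 1).

fixture_refit <- function(fx) {
  function(fixed, start) {
    list(par = fixed, sse = fx$sse(fixed[c("x1", "x2")]), converged = TRUE)
  }
}

test_that("the 0.83-threshold region matches the analytic SSE ellipse", {
  fx <- linear_sse_fixture()
  gs <- fit_space_grid(fixture_refit(fx), fx$bhat, fx$sse_min,
                       pair = c("x1", "x2"), grid_size = 21, span = 3,
                       threshold = 0.83)
  cc <- fx$sse_min * (1 / 0.83 - 1)
  analytic <- outer(gs$axes$x1, gs$axes$x2, Vectorize(function(b1, b2) {
    d <- c(b1, b2) - fx$bhat
    drop(t(d) %*% fx$XtX %*% d) <= cc
  }))
  expect_identical(gs$sse_ratio >= 0.83, analytic)
  # projection intervals match the analytic ellipse extent within one cell
  half <- sqrt(cc * diag(solve(fx$XtX)))
  step1 <- max(diff(gs$axes$x1)); step2 <- max(diff(gs$axes$x2))
  expect_lt(abs(gs$intervals$x1[1] - (fx$bhat[1] - half[1])), step1)
  expect_lt(abs(gs$intervals$x1[2] - (fx$bhat[1] + half[1])), step1)
  expect_lt(abs(gs$intervals$x2[1] - (fx$bhat[2] - half[2])), step2)
  expect_lt(abs(gs$intervals$x2[2] - (fx$bhat[2] + half[2])), step2)
})

test_that("threshold 1 keeps only the best-fit node", {
  fx <- linear_sse_fixture()
  gs <- fit_space_grid(fixture_refit(fx), fx$bhat, fx$sse_min,
                       pair = c("x1", "x2"), grid_size = 21, span = 3,
                       threshold = 1)
  expect_equal(sum(gs$sse_ratio >= 1 - 1e-12), 1)
  i <- which(gs$sse_ratio == max(gs$sse_ratio), arr.ind = TRUE)
  expect_equal(gs$axes$x1[i[1]], unname(fx$bhat["x1"]), tolerance = 1e-9)
  expect_equal(gs$axes$x2[i[2]], unname(fx$bhat["x2"]), tolerance = 1e-9)
})

test_that("independent parameters give an axis-aligned region", {
  # disjoint halves of the data: SSE(b1,b2) = S1(b1) + S2(b2); the region is
  # then symmetric under reflecting either coordinate about the best fit
  set.seed(5)
  x <- runif(40, 0.5, 2)
  y1 <- 2.0 * x[1:20] + rnorm(20, 0, 0.2)
  y2 <- 0.8 * x[21:40] + rnorm(20, 0, 0.2)
  sse <- function(beta) {
    sum((y1 - beta[1] * x[1:20])^2) + sum((y2 - beta[2] * x[21:40])^2)
  }
  b1 <- sum(x[1:20] * y1) / sum(x[1:20]^2)
  b2 <- sum(x[21:40] * y2) / sum(x[21:40]^2)
  best <- c(x1 = b1, x2 = b2)
  refit <- function(fixed, start) {
    list(par = fixed, sse = sse(fixed[c("x1", "x2")]), converged = TRUE)
  }
  # symmetric linear axes about the optimum so reflections are exact nodes
  axes <- list(b1 + seq(-0.3, 0.3, length.out = 21),
               b2 + seq(-0.3, 0.3, length.out = 21))
  gs <- fit_space_grid(refit, best, sse(best), pair = c("x1", "x2"),
                       axes = axes, threshold = 0.83)
  reg <- gs$sse_ratio >= 0.83
  expect_identical(reg, reg[rev(seq_len(nrow(reg))), ])
  expect_identical(reg, reg[, rev(seq_len(ncol(reg)))])
})

test_that("intervals contain the best fit and empty regions are reported", {
  fx <- linear_sse_fixture()
  gs <- fit_space_grid(fixture_refit(fx), fx$bhat, fx$sse_min,
                       pair = c("x1", "x2"), grid_size = 11, span = 2,
                       threshold = 0.83)
  expect_true(gs$intervals$x1[1] <= fx$bhat["x1"] &&
                fx$bhat["x1"] <= gs$intervals$x1[2])
  expect_true(gs$intervals$x2[1] <= fx$bhat["x2"] &&
                fx$bhat["x2"] <= gs$intervals$x2[2])
  # axes that miss the optimum entirely: no node reaches the threshold
  far <- list(fx$bhat[["x1"]] + 10 + 0:4, fx$bhat[["x2"]] + 10 + 0:4)
  expect_warning(
    gs2 <- fit_space_grid(fixture_refit(fx), fx$bhat, fx$sse_min,
                          pair = c("x1", "x2"), axes = far, threshold = 0.83),
    "no grid node")
  expect_true(gs2$region_empty)
  expect_true(all(is.na(unlist(gs2$intervals))))
})

test_that("mechanism FitSpace re-optimizes the remaining free parameter", {
  avg <- average_traces(quick_traces(seed = 21, replicates = 5,
                                     n_points = 120))
  m <- build_scheme1(7.51, 7.35, e0 = 56, s0 = 5.6, o2_0 = 1000)
  obs <- observable_model(a = 38950, b = 33256)
  prob <- fit_problem(m, obs, avg, free = c("k6", "k7", "a"))
  best <- fit_mechanism(prob, start = c(k6 = 1, k7 = 0.5, a = 30000))
  gs <- fit_space(best, pair = c("k6", "k7"), grid_size = 5, span = 1.6)
  # the generating values fall inside the profile intervals
  expect_true(gs$intervals$k6[1] <= best$par["k6"] &&
                best$par["k6"] <= gs$intervals$k6[2])
  expect_true(gs$intervals$k7[1] <= best$par["k7"] &&
                best$par["k7"] <= gs$intervals$k7[2])
  # ratios are proper and peak at the center node
  expect_true(all(gs$sse_ratio > 0 & gs$sse_ratio <= 1 + 1e-9))
  expect_equal(gs$sse_ratio[3, 3], 1, tolerance = 1e-6)
})
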