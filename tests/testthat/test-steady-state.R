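test_that("initial_rate converts an exactly linear trace by unit arithmetic", {
  tr <- kinetic_trace(0:29, 0.001 * (0:29))
  r <- initial_rate(tr, epsilon = 40740)
  expect_equal(as.numeric(r), 60 * 1e6 * 0.001 / 40740, tolerance = 1e-12)
  # flat trace: zero rate, linear by convention
  flat <- kinetic_trace(0:29, rep(0.2, 30))
  expect_equal(as.numeric(initial_rate(flat, 40740)), 0)
  # a trace with no linear region anywhere fails loudly
  set.seed(2)
  jagged <- kinetic_trace(0:29, rep(c(0, 0.4), 15) + rnorm(30, 0, 0.05))
  expect_error(initial_rate(jagged, 40740), "best R\\^2")
})

test_that("initial_rate tracks the true v0 of a simulated progress curve", {
  # independent progress-curve oracle: dP/dt = kcat E0 S/(KM + S), S = S0 - P
  kcat <- 2.1; km <- 922; e0 <- 0.5; s0 <- 400; eps <- 40740
  f <- function(t, y, p) list(kcat * e0 * (s0 - y) / (km + (s0 - y)))
  tt <- seq(0, 20, 0.25)
  P <- deSolve::ode(c(P = 0), tt, f, NULL)[, "P"]
  tr <- kinetic_trace(tt, 1e-6 * eps * P)
  v0 <- 60 * kcat * e0 * s0 / (km + s0)
  expect_equal(as.numeric(initial_rate(tr, eps)), v0, tolerance = 0.03)
})

test_that("both Michaelis-Menten parameterizations recover printed-scale constants", {
  s <- c(50, 100, 200, 400, 800, 1600, 3200, 6000)
  d <- gen_mm_rates(kcat = 2.1, km = 922, e0 = 0.5, s_grid = s)
  f1 <- fit_mm_traditional(d)
  expect_equal(f1$kcat, 2.1, tolerance = 1e-6)
  expect_equal(f1$km, 922, tolerance = 1e-6)
  expect_equal(f1$ksp, 60 * 2.1 / 922, tolerance = 1e-6)
  f2 <- fit_mm_ksp(d)
  expect_equal(f2$ksp, 60 * 2.1 / 922, tolerance = 1e-6)
  expect_equal(f2$km, 922, tolerance = 1e-4)
  # a slow substrate on the x10^2 display scale
  d2 <- gen_mm_rates(kcat = 6.7e-4, km = 131, e0 = 2,
                     s_grid = c(20, 50, 100, 200, 400, 800))
  f3 <- fit_mm_traditional(d2)
  expect_equal(100 * f3$ksp, 3.07e-2, tolerance = 1e-2)
})

test_that("the two parameterizations are equivalent on any dataset", {
  set.seed(9)
  for (rep in 1:5) {
    s <- sort(runif(8, 20, 4000))
    d <- gen_mm_rates(kcat = runif(1, 0.1, 3), km = runif(1, 100, 1500),
                      e0 = 0.5, s_grid = s, noise_rel = 0.05)
    f1 <- fit_mm_traditional(d)
    f2 <- fit_mm_ksp(d)
    # identical fitted curves pointwise and identical reported ksp
    expect_lt(max(abs(f1$fitted - f2$fitted)), 1e-8)
    expect_equal(f1$ksp, f2$ksp, tolerance = 1e-6)
    expect_equal(f1$ksp, 60 * f1$kcat / f1$km, tolerance = 1e-9)
  }
})

test_that("kcat is invariant under a joint rescaling of concentrations and KM", {
  s <- c(50, 100, 200, 400, 800, 1600)
  d1 <- gen_mm_rates(kcat = 1.5, km = 300, e0 = 0.5, s_grid = s)
  d2 <- gen_mm_rates(kcat = 1.5, km = 3000, e0 = 0.5, s_grid = 10 * s)
  f1 <- fit_mm_traditional(d1); f2 <- fit_mm_traditional(d2)
  expect_equal(f1$kcat, f2$kcat, tolerance = 1e-8)
  expect_equal(f2$km / f1$km, 10, tolerance = 1e-6)
})

test_that("noisy Michaelis-Menten data recover KM within 20%", {
  km <- 922
  recovered <- sapply(1:10, function(seed) {
    s <- seq(0.2, 5, length.out = 10) * km
    d <- gen_mm_rates(kcat = 2.1, km = km, e0 = 0.5, s_grid = s,
                      noise_rel = 0.05, seed = 100 + seed)
    fit_mm_traditional(d)$km
  })
  expect_lt(abs(median(recovered) - km) / km, 0.20)
})

test_that("oxygen percent converts linearly against the printed anchors", {
  expect_equal(o2_percent_to_conc(100), 1300)
  expect_equal(o2_percent_to_conc(0), 0)
  expect_equal(o2_percent_to_conc(21), 273)
  expect_error(o2_percent_to_conc(50, temperature = 30), "saturation")
  expect_equal(o2_percent_to_conc(50, temperature = 30, saturation = 1100), 550)
})

test_that("endpoint series return the generating extinction coefficient", {
  gen <- gen_endpoint_series(33256, c(2, 5, 10, 15, 20))
  fit <- extinction_from_endpoint(gen$concentrations, gen$absorbances)
  expect_equal(fit$epsilon, 33256, tolerance = 1e-9)
  # single point is exact (with a warning about the SE)
  expect_warning(
    f1 <- extinction_from_endpoint(10, 1e-6 * 33256 * 10),
    "fewer than 3")
  expect_equal(f1$epsilon, 33256, tolerance = 1e-9)
  # Monte-Carlo: mean recovered epsilon within 1% at sigma = 0.002 AU
  eps_hat <- sapply(1:50, function(seed) {
    g <- gen_endpoint_series(33256, seq(2, 20, 2), noise_sd = 0.002,
                             seed = 500 + seed)
    extinction_from_endpoint(g$concentrations, g$absorbances)$epsilon
  })
  expect_lt(abs(mean(eps_hat) - 33256) / 33256, 0.01)
  # non-monotone series is flagged
  expect_warning(extinction_from_endpoint(c(2, 5, 10), c(0.1, 0.3, 0.2)),
                 "not monotone")
})
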