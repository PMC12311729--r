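test_that("a single irreversible step matches first-order kinetics", {
  m <- mechanism(data.frame(name = c("A", "B"), conc0 = c(1, 0)),
                 list(reaction_step("A", "B", 0.5, kf_name = "k1",
                                    kf_status = "fixed")))
  times <- seq(0, 10, by = 0.1)
  tr <- simulate_mechanism(m, times)
  expect_lt(max(abs(tr$conc[, "B"] - (1 - exp(-0.5 * times)))), 1e-6)
})

test_that("all-zero rate constants freeze the system", {
  m <- mechanism(data.frame(name = c("A", "B"), conc0 = c(2, 3)),
                 list(reaction_step("A", "B", 0, kf_name = "k1",
                                    kf_status = "fixed")))
  tr <- simulate_mechanism(m, seq(0, 5, 1))
  expect_true(all(tr$conc[, "A"] == 2))
  expect_true(all(tr$conc[, "B"] == 3))
})

test_that("simulated linear networks agree with the matrix exponential", {
  set.seed(11)
  times <- c(0, 10^seq(-2, 1.2, length.out = 40))
  for (rep in 1:5) {
    species <- c("A", "B", "C")
    steps <- list(list(from = "A", to = "B", k = runif(1, 0.1, 5)),
                  list(from = "B", to = "A", k = runif(1, 0.1, 5)),
                  list(from = "B", to = "C", k = runif(1, 0.1, 5)),
                  list(from = "C", to = "B", k = runif(1, 0, 1)))
    y0 <- c(runif(1, 0.5, 2), 0, 0)
    m <- linear_mechanism(species, steps, y0)
    tr <- simulate_mechanism(m, times, rtol = 1e-11, atol = 1e-14)
    oracle <- expm_trajectory(species, steps, y0, times)
    expect_lt(max(abs(tr$conc - oracle)), 1e-8)
  }
})

test_that("enzyme and substrate totals are conserved through a full turnover", {
  m <- build_scheme1(7.51, 7.35, e0 = 56, s0 = 5.6, o2_0 = 1000)
  times <- c(0, exp(seq(log(2e-3), log(45), length.out = 300)))
  tr <- simulate_mechanism(m, times)
  enz <- conservation_total(tr, c("E", "ES", "ESO2", "ESQ", "ESQX", "EI", "EP"))
  sub <- conservation_total(tr, c("SA", "SB", "ES", "ESO2", "ESQ", "ESQX",
                                  "EI", "EP", "P", "PX"))
  expect_equal(enz$initial, 56)
  expect_equal(sub$initial, 5.6)
  expect_lt(enz$max_rel_dev, 1e-6)
  expect_lt(sub$max_rel_dev, 1e-6)
  expect_true(all(diff(tr$conc[, "O2"]) <= 1e-12))  # O2 non-increasing
  expect_gt(min(tr$conc), -1e-9)                    # concentrations physical
})

test_that("the productive yield equals the k6/(k6+k7) branch ratio", {
  fast <- list(value = 10, status = "fixed")
  m <- build_scheme1(7.51, 7.35, e0 = 56, s0 = 5.6, o2_0 = 1000,
                     rate_spec = list(k2 = fast, k5 = fast, k8 = fast,
                                      k9 = fast))
  tr <- simulate_mechanism(m, c(0, exp(seq(log(0.01), log(120), length.out = 200))))
  final <- tr$conc[nrow(tr$conc), ]
  yield <- (final[["P"]] + final[["PX"]] + final[["EP"]]) / 5.6
  expect_equal(yield, 0.55 / (0.55 + 0.3), tolerance = 1e-3)
  expect_equal(final[["ESQX"]] / 5.6, 0.3 / 0.85, tolerance = 1e-3)
})

test_that("stronger inactivation never increases the product yield", {
  final_product <- sapply(c(0, 0.1, 0.3, 0.6, 1, 2), function(k7) {
    m <- build_scheme1(7.51, 7.35, e0 = 56, s0 = 5.6, o2_0 = 1000,
                       rate_spec = list(k7 = list(value = k7, status = "fixed")))
    tr <- simulate_mechanism(m, c(0, exp(seq(log(0.01), log(200),
                                             length.out = 150))))
    sum(tr$conc[nrow(tr$conc), c("P", "PX")])
  })
  expect_true(all(diff(final_product) <= 1e-9))
})

test_that("the isolated charge-state step reaches its configured equilibrium", {
  r <- 10^(7.35 - 7.51)
  m <- mechanism(
    data.frame(name = c("SA", "SB"), conc0 = c(1, 0)),
    list(reaction_step("SA", "SB", kf = 100 * r, kr = 100,
                       kf_name = "k1", kr_name = "km1",
                       kf_status = "ratio_linked",
                       kf_ratio = list(partner = "km1", ratio = r))))
  tr <- simulate_mechanism(m, seq(0, 1, 0.01))
  final <- tr$conc[nrow(tr$conc), ]
  expect_equal(final[["SB"]] / final[["SA"]], r, tolerance = 1e-6)
})

test_that("the observable maps concentrations to absorbance by Beer-Lambert", {
  conc <- matrix(0, nrow = 3, ncol = 4,
                 dimnames = list(NULL, c("ESQ", "ESQX", "EP", "P")))
  traj <- structure(list(times = 0:2, conc = conc), class = "edx_trajectory")
  obs <- observable_model(a = 38950, b = 33256, c = 0)
  expect_true(all(observe_absorbance(traj, obs)$absorbance == 0))
  # 1 uM of product at b = 33256, 1 cm: 0.033256 AU
  conc2 <- conc; conc2[, "P"] <- 1
  traj2 <- structure(list(times = 0:2, conc = conc2), class = "edx_trajectory")
  expect_equal(observe_absorbance(traj2, obs)$absorbance,
               rep(0.033256, 3), tolerance = 1e-12)
  # literal mode: equal ESQ and quenched-ESQ cancel exactly, any a
  conc3 <- conc; conc3[, "ESQ"] <- 0.7; conc3[, "ESQX"] <- 0.7
  traj3 <- structure(list(times = 0:2, conc = conc3), class = "edx_trajectory")
  expect_equal(observe_absorbance(traj3, obs)$absorbance, rep(0, 3))
  # physical mode keeps the ESQ contribution
  obs_phys <- observable_model(a = 38950, b = 33256, literal_mode = FALSE)
  expect_equal(observe_absorbance(traj3, obs_phys)$absorbance,
               rep(1e-6 * 38950 * 0.7, 3))
  # missing species is an error
  traj4 <- structure(list(times = 0:2,
                          conc = conc[, c("ESQ", "EP", "P")]),
                     class = "edx_trajectory")
  expect_error(observe_absorbance(traj4, obs), "lacks species")
})

test_that("time grids must be strictly increasing from zero", {
  m <- mechanism(data.frame(name = c("A", "B"), conc0 = c(1, 0)),
                 list(reaction_step("A", "B", 1, kf_name = "k1",
                                    kf_status = "fixed")))
  expect_error(simulate_mechanism(m, c(0, 1, 1, 2)), "strictly increasing")
  expect_error(simulate_mechanism(m, c(1, 2)), "times")
  expect_error(kinetic_trace(c(0, 0, 1), c(0, 0, 0)), "strictly increasing")
  expect_error(kinetic_trace(c(0, 1), c(0, NaN)), "finite")
})
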