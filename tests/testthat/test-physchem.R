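test_that("titration preprocessing subtracts blanks and zeroes 600 nm", {
  td <- gen_titration(8.36, noise_sd = 0, seed = 1)
  corr <- preprocess_titration(td)
  expect_true(all(abs(corr[nrow(corr), ]) < 1e-14))  # 600 nm exactly 0
  # data equal to blank -> all-zero matrix
  td0 <- titration_dataset(td$wavelengths, td$ph, td$blank, td$blank)
  expect_true(all(preprocess_titration(td0) == 0))
  # an additive per-column offset leaves the corrected spectrum unchanged
  td2 <- td
  td2$absorbance[, 3] <- td2$absorbance[, 3] + 0.123
  expect_equal(preprocess_titration(td2), corr, tolerance = 1e-12)
  # a plate without the 600-nm row is refused
  keep <- td$wavelengths < 600
  td3 <- titration_dataset(td$wavelengths[keep], td$ph,
                           td$absorbance[keep, ], td$blank[keep, ])
  expect_error(preprocess_titration(td3), "600-nm")
})

test_that("difference spectra locate the shifting bands", {
  td <- gen_titration(8.36, band_ha = c(280, 25, 0.8), band_a = c(350, 25, 0.9),
                      noise_sd = 0, seed = 1)
  corr <- preprocess_titration(td)
  ds <- difference_spectra(corr, td$wavelengths, td$ph, reference_ph = 3.0)
  expect_lte(abs(ds$lambda_positive - 350), 2)
  expect_lte(abs(ds$lambda_negative - 280), 2)
  # reference column differenced against itself is identically zero
  ds4 <- difference_spectra(corr, td$wavelengths, td$ph, reference_ph = td$ph[1])
  expect_false(format(td$ph[1]) %in% colnames(ds4$delta))
  expect_error(difference_spectra(corr, td$wavelengths, td$ph,
                                  reference_ph = 2.2), "not present")
  # pH-independent spectrum reports no usable wavelength
  flat <- corr; flat[] <- 0
  expect_warning(dsf <- difference_spectra(flat, td$wavelengths, td$ph, 3.0),
                 "pH-independent")
  expect_true(is.na(dsf$lambda_positive))
})

test_that("the two-state fit recovers a noiseless pKa and its midpoint", {
  ph <- seq(3, 12.5, length.out = 25)
  r <- 10^(ph - 6.94)
  A <- 200 * (0.0002 + 0.004 * r) / (1 + r)
  fit <- fit_pka(ph, A, s_t = 200)
  expect_equal(unname(fit$pka), 6.94, tolerance = 1e-4)
  # absorbance at pH = pKa is the mean of the plateaus
  A_mid <- 200 * (fit$eps_ha + fit$eps_a) / 2
  expect_equal(predict(fit$fit, newdata = data.frame(ph = 6.94))[1],
               A_mid, tolerance = 1e-6)
  # flat data are refused
  expect_error(fit_pka(ph, rep(0.4, 25)), "flat")
})

test_that("fit_pka is invariant to swapping acid/base roles with a sign flip", {
  ph <- seq(3, 12.5, length.out = 20)
  r <- 10^(ph - 7.51)
  A <- 200 * (0.0001 + 0.005 * r) / (1 + r)
  f1 <- fit_pka(ph, A)
  f2 <- fit_pka(ph, -A)
  expect_equal(unname(f1$pka), unname(f2$pka), tolerance = 1e-6)
  expect_equal(unname(f1$eps_ha), -unname(f2$eps_ha), tolerance = 1e-8)
  expect_equal(unname(f1$eps_a), -unname(f2$eps_a), tolerance = 1e-8)
})

test_that("the full plate pipeline recovers generating pKa values", {
  for (pka in c(8.36, 6.94)) {
    rec <- sapply(1:10, function(seed) {
      td <- gen_titration(pka, seed = 900 + seed)
      titration_pka(td)$pka
    })
    expect_lt(abs(median(rec) - pka), 0.05)
  }
  # both reference buffers and both response modes work
  td <- gen_titration(7.51, ph_list = c(3, 4, seq(5, 12.5, length.out = 18)),
                      seed = 77)
  for (ref in c(3, 4)) {
    for (mode in c("single", "total")) {
      f <- titration_pka(td, reference_ph = ref, mode = mode)
      expect_lt(abs(f$pka - 7.51), 0.1)
    }
  }
})

test_that("Hammett regression reproduces the sigma-para correlation", {
  ref <- edx_reference("pka_values")
  sig <- hammett_sigma()
  m <- merge(ref, sig, by = "substituent")
  h <- hammett_regression(m$pka, m$sigma_para)
  expect_equal(h$r_squared, 0.9806, tolerance = 2e-3)
  expect_lt(h$rho, 0)  # electron withdrawal acidifies
  # sigma_meta correlates too, but less strongly
  hm <- hammett_regression(m$pka, m$sigma_meta)
  expect_gt(hm$r_squared, 0.9)
  expect_lt(hm$r_squared, h$r_squared)
  # degenerate inputs
  expect_error(hammett_regression(c(1, 2), c(0, 1)), ">= 3")
  expect_error(hammett_regression(c(1, 2, 3), c(0.5, 0.5, 0.5)), "zero variance")
  expect_warning(h0 <- hammett_regression(c(1, 1, 1), c(0, 0.3, 0.7)),
                 "constant pKa")
  expect_equal(h0$r_squared, 0)
  # two points fit exactly (R^2 = 1); bypass the n >= 3 guard deliberately
  expect_equal(suppressWarnings(summary(lm(c(1, 2) ~ c(0, 1)))$r.squared), 1)
})

test_that("voltammetric arithmetic is exact on the bundled peak table", {
  cv <- edx_reference("cv_peaks")
  out <- cv_summary(cv$ep_a_mV, cv$ep_c_mV, ph = cv$ph)
  both <- !is.na(cv$ep_c_mV)
  expect_identical(out$e_half[both], cv$e_half_mV[both])
  expect_identical(out$delta_ep[both], cv$delta_ep_mV[both])
  expect_true(all(is.na(out$e_half[!both])))
  expect_true(all(out$delta_ep[both] >= 0))
  # degenerate equal peaks
  expect_equal(cv_summary(150, 150)$delta_ep, 0)
  expect_equal(cv_summary(150, 150)$e_half, 150)
  expect_error(cv_summary(100, 50, i_pa = -1, i_pc = 2), "currents")
})

test_that("protein epsilon280 counts chromophores per the composition rule", {
  expect_equal(protein_epsilon280("Y"), 1280)
  expect_equal(protein_epsilon280("WWY"), 12660)
  expect_equal(protein_epsilon280("ACDEFGHIKLMNPQRSTV"), 0)
  expect_equal(protein_epsilon280("CCYW", n_cystine = 1), 1280 + 5690 + 125)
  expect_error(protein_epsilon280("CCY", n_cystine = 2), "disulfide")
  expect_error(protein_epsilon280("YXZ"), "unknown residue")
  expect_equal(protein_epsilon280("YXZ", skip_unknown = TRUE), 1280)
})

test_that("relative profiles are percentages of the reference row", {
  df <- data.frame(name = c("L-DOPA", "DHHCA", "other"),
                   e_half = c(231.5, 198.5, NA),
                   pka = c(8.81, 8.87, 7.0))
  out <- relative_profile(df, "L-DOPA")
  expect_equal(out$e_half[1], 100)
  expect_equal(out$pka[1], 100)
  expect_equal(out$e_half[2], 100 * 198.5 / 231.5, tolerance = 1e-12)
  expect_equal(round(out$e_half[2], 1), 85.7)
  expect_true(is.na(out$e_half[3]))
  # offset normalization reports differences in native units
  diffs <- relative_profile(df, "L-DOPA", mode = "difference")
  expect_equal(diffs$e_half[2], 198.5 - 231.5)
  expect_identical(attr(diffs, "normalization"), "difference")
  df$pka[1] <- 0
  expect_error(relative_profile(df, "L-DOPA"), "zero")
  expect_error(relative_profile(df, "missing"), "not found")
})
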