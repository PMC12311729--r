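# Synthetic-data generators. Every generator records its generating
# parameters in a "ground_truth" attribute so recovery can be asserted
# end-to-end without real instrument data. A fixed seed gives bit-identical
# output.

.set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
}

#' Simulate replicate single-turnover stopped-flow traces
#'
#' Emulates a single-turnover experiment: substrate at 5.6 uM with a
#' tenfold excess of enzyme (56 uM) under ~1000 uM O2, observed at 380 nm
#' from 0 to 45 s. The underlying mechanism is [build_scheme1()] at the
#' given pKa/pH; the noiseless observable trace is computed once and each
#' replicate adds homoscedastic Gaussian noise, mimicking instrument
#' shots that are later averaged. Sampling is logarithmically dense
#' (default 500 points from 2 ms to 45 s) so both the early semiquinone
#' transient and the slow product rise are resolved.
#'
#' @param pka,ph substrate pKa and reaction pH.
#' @param e0,s0,o2 enzyme, substrate, O2 concentrations (uM).
#' @param rate_spec overrides passed to [build_scheme1()].
#' @param a,b,c,pathlength,literal_mode observable parameters, see
#'   [observable_model()].
#' @param wavelength,temperature trace metadata.
#' @param noise_sd Gaussian noise on absorbance, AU.
#' @param replicates number of traces.
#' @param n_points,t_min,t_max sampling grid controls (s).
#' @param seed RNG seed.
#' @return list of [kinetic_trace()] objects with attribute
#'   `ground_truth` (generating parameters and the noiseless trace).
#' @export
gen_stopped_flow <- function(pka = 7.51, ph = 7.35, e0 = 56, s0 = 5.6,
                             o2 = 1000, rate_spec = list(),
                             a = 38950, b = 33256, c = 0, pathlength = 1,
                             literal_mode = TRUE,
                             wavelength = 380, temperature = 14,
                             noise_sd = 0.002, replicates = 15,
                             n_points = 500, t_min = 2e-3, t_max = 45,
                             seed = NULL) {
  .set_seed(seed)
  mech <- build_scheme1(pka, ph, e0 = e0, s0 = s0, o2_0 = o2,
                        rate_spec = rate_spec)
  obs <- observable_model(a, b, c, pathlength, literal_mode)
  times <- c(0, exp(seq(log(t_min), log(t_max), length.out = n_points - 1)))
  traj <- simulate_mechanism(mech, times)
  meta <- list(wavelength = wavelength, ph = ph, temperature = temperature,
               enzyme = e0, substrate = s0, o2 = o2)
  clean <- observe_absorbance(traj, obs, metadata = meta)
  traces <- lapply(seq_len(replicates), function(i) {
    tr <- clean
    if (noise_sd > 0) {
      tr$absorbance <- tr$absorbance + stats::rnorm(length(tr$times), 0, noise_sd)
    }
    tr
  })
  attr(traces, "ground_truth") <- list(
    mechanism = mech, observable = obs, rate_constants = rate_constants(mech),
    a = a, b = b, c = c, pka = pka, ph = ph, e0 = e0, s0 = s0, o2 = o2,
    noise_sd = noise_sd, replicates = replicates, seed = seed,
    noiseless = clean, trajectory = traj)
  traces
}

#' Generate a Michaelis-Menten rate dataset
#'
#' `rate = 60 * e0 * kcat * s / (km + s) * (1 + noise)` with relative
#' Gaussian noise, in uM/min.
#'
#' @param kcat s^-1.
#' @param km uM.
#' @param e0 enzyme concentration, uM.
#' @param s_grid substrate concentrations, uM.
#' @param noise_rel relative noise SD (e.g. 0.05 for 5%).
#' @param varied_substrate,temperature passed to [rate_dataset()].
#' @param seed RNG seed.
#' @return an [rate_dataset()] with attribute `ground_truth`.
#' @export
gen_mm_rates <- function(kcat, km, e0, s_grid, noise_rel = 0,
                         varied_substrate = "catechol", temperature = 22,
                         seed = NULL) {
  stopifnot(kcat > 0, km > 0, e0 > 0, all(s_grid > 0))
  .set_seed(seed)
  v <- 60 * e0 * kcat * s_grid / (km + s_grid)
  if (noise_rel > 0) {
    v <- v * (1 + stats::rnorm(length(v), 0, noise_rel))
  }
  v <- pmax(v, 0)
  out <- rate_dataset(s_grid, v, e0, varied_substrate, temperature)
  attr(out, "ground_truth") <- list(kcat = kcat, km = km, e0 = e0,
                                    ksp = 60 * kcat / km,
                                    noise_rel = noise_rel, seed = seed)
  out
}

.gauss_band <- function(wl, band) {
  band[3] * exp(-(wl - band[1])^2 / (2 * band[2]^2))
}

#' Generate a two-state titration plate
#'
#' Emulates the microplate pKa experiment: spectra from 210 to 600 nm in
#' 2-nm steps over a set of buffers. The acid form contributes one
#' Gaussian band and the base form another; they mix with
#' Henderson-Hasselbalch fractions at each pH. A smooth nonzero blank is
#' added, and Gaussian noise is applied independently to the compound and
#' blank readings (as a plate reader would produce).
#'
#' @param pka generating pKa.
#' @param band_ha,band_a `c(center_nm, width_nm, height_AU)` of the acid
#'   and base bands (heights are the full-formation absorbance at 200 uM).
#' @param ph_list buffer pH values.
#' @param wavelengths nm grid.
#' @param s_t compound concentration, uM.
#' @param noise_sd Gaussian noise, AU.
#' @param seed RNG seed.
#' @return an [titration_dataset()] with attribute `ground_truth`.
#' @export
gen_titration <- function(pka, band_ha = c(280, 25, 0.8),
                          band_a = c(350, 25, 0.9),
                          ph_list = seq(3, 12.5, length.out = 20),
                          wavelengths = seq(210, 600, by = 2),
                          s_t = 200, noise_sd = 0.005, seed = NULL) {
  stopifnot(band_ha[1] >= min(wavelengths), band_ha[1] <= max(wavelengths),
            band_a[1] >= min(wavelengths), band_a[1] <= max(wavelengths))
  .set_seed(seed)
  blank_true <- 0.05 * exp(-(wavelengths - 230)^2 / (2 * 60^2)) + 0.02
  spec_ha <- .gauss_band(wavelengths, band_ha)
  spec_a <- .gauss_band(wavelengths, band_a)
  A <- sapply(ph_list, function(p) {
    f <- speciation_ratio(pka, p)$fraction_deprotonated
    blank_true + (1 - f) * spec_ha + f * spec_a
  })
  B <- matrix(blank_true, nrow = length(wavelengths), ncol = length(ph_list))
  if (noise_sd > 0) {
    A <- A + stats::rnorm(length(A), 0, noise_sd)
    B <- B + stats::rnorm(length(B), 0, noise_sd)
  }
  out <- titration_dataset(wavelengths, ph_list, A, B, s_t)
  attr(out, "ground_truth") <- list(pka = pka, band_ha = band_ha,
                                    band_a = band_a, noise_sd = noise_sd,
                                    seed = seed)
  out
}

#' Generate a Beer-Lambert endpoint series
#'
#' `A = 1e-6 * epsilon * conc * pathlength + noise`, emulating the
#' endpoint extinction-coefficient experiment (substrate reacted to
#' completion with excess enzyme).
#'
#' @param epsilon M^-1 cm^-1.
#' @param concentrations uM.
#' @param pathlength cm.
#' @param noise_sd AU.
#' @param seed RNG seed.
#' @return list with `concentrations`, `absorbances`, and attribute
#'   `ground_truth`.
#' @export
gen_endpoint_series <- function(epsilon, concentrations = seq(2, 20, by = 2),
                                pathlength = 1, noise_sd = 0, seed = NULL) {
  stopifnot(epsilon > 0)
  .set_seed(seed)
  A <- 1e-6 * epsilon * concentrations * pathlength
  if (noise_sd > 0) A <- A + stats::rnorm(length(A), 0, noise_sd)
  out <- list(concentrations = concentrations, absorbances = A)
  attr(out, "ground_truth") <- list(epsilon = epsilon,
                                    pathlength = pathlength,
                                    noise_sd = noise_sd, seed = seed)
  out
}
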