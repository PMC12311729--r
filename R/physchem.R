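# Spectrophotometric pKa determination, Hammett correlation, voltammetric
# summary arithmetic, protein epsilon280, and relative substrate profiles.

#' A microplate titration dataset
#'
#' Wavelength x pH absorbance matrices for a compound and for the
#' matching buffer blanks.
#'
#' @param wavelengths nm (rows), typically 210-600 in 2-nm steps.
#' @param ph buffer pH values (columns), distinct.
#' @param absorbance,blank matrices `length(wavelengths)` x `length(ph)`.
#' @param compound_concentration total compound concentration `[St]`, uM.
#' @return an `edx_titration`.
#' @export
titration_dataset <- function(wavelengths, ph, absorbance, blank,
                              compound_concentration = 200) {
  absorbance <- as.matrix(absorbance); blank <- as.matrix(blank)
  stopifnot(nrow(absorbance) == length(wavelengths),
            ncol(absorbance) == length(ph),
            all(dim(absorbance) == dim(blank)),
            compound_concentration > 0)
  if (anyDuplicated(ph)) stop("pH values must be distinct", call. = FALSE)
  dimnames(absorbance) <- dimnames(blank) <-
    list(wavelengths, format(ph, trim = TRUE))
  structure(list(wavelengths = as.numeric(wavelengths), ph = as.numeric(ph),
                 absorbance = absorbance, blank = blank,
                 st = compound_concentration),
            class = "edx_titration")
}

#' Blank-subtract and baseline-normalize titration spectra
#'
#' Subtracts the blank reading per buffer, then shifts each pH column so
#' that its absorbance at 600 nm is exactly zero (600 nm lies outside the
#' absorption bands of these catechols and serves as the baseline).
#'
#' @param data an [titration_dataset()].
#' @return corrected wavelength x pH matrix.
#' @export
preprocess_titration <- function(data) {
  stopifnot(inherits(data, "edx_titration"))
  i600 <- which(data$wavelengths == 600)
  if (length(i600) != 1) stop("no 600-nm row in the titration data", call. = FALSE)
  corr <- data$absorbance - data$blank
  sweep(corr, 2, corr[i600, ], "-")
}

#' Difference spectra against a reference pH
#'
#' Computes `delta(lambda, pH) = A(lambda, pH) - A(lambda, reference_pH)`
#' on the corrected matrix and selects the reporting wavelengths as the
#' maximum positive and maximum negative difference in the highest-pH
#' column. If no difference exceeds `tol` the spectrum is pH-independent
#' and no usable wavelength exists.
#'
#' @param corrected matrix from [preprocess_titration()].
#' @param wavelengths,ph the row/column coordinates of `corrected`.
#' @param reference_ph reference buffer pH (3.0 or 4.0 in practice; any
#'   present value accepted).
#' @param tol absolute difference below which the spectrum is considered
#'   pH-independent (AU).
#' @return list with `delta` (matrix over the non-reference columns),
#'   `lambda_positive`, `lambda_negative` (nm, `NA` when unusable).
#' @export
difference_spectra <- function(corrected, wavelengths, ph, reference_ph = 3.0,
                               tol = 1e-12) {
  iref <- which(abs(ph - reference_ph) < 1e-9)
  if (length(iref) != 1) stop("reference pH ", reference_ph,
                              " not present", call. = FALSE)
  keep <- setdiff(seq_along(ph), iref)
  delta <- corrected[, keep, drop = FALSE] - corrected[, iref]
  colnames(delta) <- format(ph[keep], trim = TRUE)
  top <- delta[, which.max(ph[keep])]
  if (max(abs(top)) <= tol) {
    warning("pH-independent spectrum: no usable wavelength")
    return(list(delta = delta, ph = ph[keep],
                lambda_positive = NA_real_, lambda_negative = NA_real_))
  }
  list(delta = delta, ph = ph[keep],
       lambda_positive = wavelengths[which.max(top)],
       lambda_negative = wavelengths[which.min(top)])
}

#' Fit a two-state spectrophotometric titration
#'
#' Fits the Henderson-Hasselbalch two-state model
#' `A(pH) = [St] * (eps_HA + eps_A * 10^(pH - pKa)) / (1 + 10^(pH - pKa))`
#' by nonlinear least squares, where `eps_HA` and `eps_A` are the
#' effective absorptivities (AU per uM of total compound) of the acid and
#' base forms at the chosen wavelength; for difference data they are the
#' minima and maxima of the absorbance-difference curve.
#'
#' @param ph pH values (>= 6 points spanning the transition).
#' @param absorbance absorbance (or absorbance-difference) at the chosen
#'   wavelength, AU.
#' @param s_t total compound concentration, uM.
#' @return an `edx_pka_fit`: `pka`, `se`, `eps_ha`, `eps_a`, `fit`.
#' @export
fit_pka <- function(ph, absorbance, s_t = 200) {
  stopifnot(length(ph) == length(absorbance), s_t > 0)
  if (length(ph) < 6) stop("need >= 6 pH points", call. = FALSE)
  if (stats::sd(absorbance) < 1e-12) {
    stop("no titration transition in the data (flat absorbance); fit refused",
         call. = FALSE)
  }
  ord <- order(ph)
  phs <- ph[ord]; As <- absorbance[ord]
  lo <- mean(As[seq_len(min(3, length(As)))])
  hi <- mean(As[seq(length(As) - min(3, length(As)) + 1, length(As))])
  mid <- (lo + hi) / 2
  pka0 <- phs[which.min(abs(As - mid))]
  pka0 <- min(max(pka0, min(phs) + 0.1), max(phs) - 0.1)
  fit <- minpack.lm::nlsLM(
    absorbance ~ s_t * (eha + ea * 10^(ph - pka)) / (1 + 10^(ph - pka)),
    start = list(eha = lo / s_t, ea = hi / s_t, pka = pka0),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- summary(fit)$coefficients
  if (cf["pka", 1] < min(ph) || cf["pka", 1] > max(ph)) {
    warning("fitted pKa lies outside the scanned pH range")
  }
  structure(list(pka = cf["pka", 1], se = cf["pka", 2],
                 eps_ha = cf["eha", 1], eps_a = cf["ea", 1],
                 s_t = s_t, fit = fit),
            class = "edx_pka_fit")
}

#' @export
print.edx_pka_fit <- function(x, ...) {
  cat(sprintf("Titration fit: pKa = %.3f +/- %.3f (eps_HA %.4g, eps_A %.4g AU/uM)\n",
              x$pka, x$se, x$eps_ha, x$eps_a))
  invisible(x)
}

#' End-to-end pKa from a titration plate
#'
#' Runs the full pipeline: blank subtraction and 600-nm normalization,
#' difference spectra against the reference buffer, wavelength selection,
#' and the two-state fit. Two response modes are supported:
#' `"single"` fits the difference at the positive wavelength;
#' `"total"` fits `|delta(lambda+)| + |delta(lambda-)|` per pH (the total
#' absorbance difference).
#'
#' @param data an [titration_dataset()].
#' @param reference_ph 3.0 (default) or 4.0.
#' @param mode `"single"` or `"total"`.
#' @return an `edx_pka_fit` with extra fields `lambda_positive`,
#'   `lambda_negative`, `reference_ph`, `mode`.
#' @export
titration_pka <- function(data, reference_ph = 3.0,
                          mode = c("single", "total")) {
  mode <- match.arg(mode)
  corr <- preprocess_titration(data)
  ds <- difference_spectra(corr, data$wavelengths, data$ph, reference_ph)
  if (is.na(ds$lambda_positive)) {
    stop("no usable wavelength: spectrum is pH-independent", call. = FALSE)
  }
  ip <- which(data$wavelengths == ds$lambda_positive)
  im <- which(data$wavelengths == ds$lambda_negative)
  y <- if (mode == "single") ds$delta[ip, ] else
    abs(ds$delta[ip, ]) + abs(ds$delta[im, ])
  out <- fit_pka(ds$ph, as.numeric(y), s_t = data$st)
  out$lambda_positive <- ds$lambda_positive
  out$lambda_negative <- ds$lambda_negative
  out$reference_ph <- reference_ph
  out$mode <- mode
  out
}

#' Built-in Hammett substituent constants
#'
#' Standard Hansch sigma_para and sigma_meta values for the substituents
#' occurring at ring position 6 of the DHHCA series (Hansch, Leo & Taft,
#' Chem. Rev. 1991, 91, 165). User-supplied values can always be passed
#' directly to [hammett_regression()].
#'
#' @return data.frame with `substituent`, `sigma_para`, `sigma_meta`.
#' @export
hammett_sigma <- function() {
  data.frame(substituent = c("H", "Br", "CN", "NO2"),
             sigma_para = c(0.00, 0.23, 0.66, 0.78),
             sigma_meta = c(0.00, 0.39, 0.56, 0.71))
}

#' Hammett linear free-energy regression
#'
#' Ordinary least-squares regression of pKa values on substituent sigma
#' constants; the slope is the reaction constant rho.
#'
#' @param pka_values numeric, one per compound (>= 3).
#' @param sigma_values paired substituent constants.
#' @return list with `rho` (slope), `intercept`, `r_squared`, `fit`.
#' @export
hammett_regression <- function(pka_values, sigma_values) {
  stopifnot(length(pka_values) == length(sigma_values))
  if (length(pka_values) < 3) stop("need >= 3 compounds", call. = FALSE)
  if (stats::sd(sigma_values) == 0) {
    stop("zero variance in sigma constants", call. = FALSE)
  }
  if (stats::sd(pka_values) == 0) {
    warning("constant pKa values: R^2 is 0")
  }
  fit <- stats::lm(pka_values ~ sigma_values)
  list(rho = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       fit = fit)
}

#' Voltammetric summary arithmetic
#'
#' Midpoint potential `E1/2 = (Epa + Epc)/2`, peak separation
#' `deltaEp = Epa - Epc`, and peak-current ratio `Ipa/Ipc` from anodic and
#' cathodic peak values. A missing cathodic peak (irreversible oxidation,
#' `NA`) leaves `E1/2` and `deltaEp` undefined. Vectorized.
#'
#' @param ep_a,ep_c anodic / cathodic peak potentials, mV.
#' @param i_pa,i_pc peak currents, uA (optional).
#' @param ph solution pH (annotation).
#' @return data.frame with `ep_a`, `ep_c`, `e_half`, `delta_ep`,
#'   `peak_ratio`, `ph`.
#' @examples
#' cv_summary(178, 54)   # E1/2 116, deltaEp 124
#' cv_summary(333, -95)  # E1/2 119, deltaEp 428
#' @export
cv_summary <- function(ep_a, ep_c, i_pa = NA_real_, i_pc = NA_real_,
                       ph = NA_real_) {
  stopifnot(all(is.finite(ep_a)))
  if (any(!is.na(i_pa) & i_pa <= 0) || any(!is.na(i_pc) & i_pc <= 0)) {
    stop("peak currents must be > 0 when supplied", call. = FALSE)
  }
  data.frame(ep_a = ep_a, ep_c = ep_c,
             e_half = (ep_a + ep_c) / 2,
             delta_ep = ep_a - ep_c,
             peak_ratio = i_pa / i_pc,
             ph = ph)
}

#' Protein extinction coefficient at 280 nm from sequence
#'
#' `eps280 = #Tyr * 1280 + #Trp * 5690 + #cystine * 125` (M^-1 cm^-1),
#' with the cystine term counting disulfide pairs.
#'
#' @param sequence amino-acid string (standard 20-letter alphabet).
#' @param n_cystine number of disulfide bonds (<= floor(#Cys / 2)).
#' @param skip_unknown if `TRUE`, unknown letters are ignored instead of
#'   raising an error.
#' @return eps280 in M^-1 cm^-1.
#' @examples
#' protein_epsilon280("WWY")  # 12660
#' @export
protein_epsilon280 <- function(sequence, n_cystine = 0, skip_unknown = FALSE) {
  aa <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1]]
  alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V")
  unknown <- setdiff(unique(aa), alphabet)
  if (length(unknown)) {
    if (!skip_unknown) {
      stop("unknown residue letters: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    aa <- aa[aa %in% alphabet]
  }
  if (n_cystine > floor(sum(aa == "C") / 2)) {
    stop("n_cystine exceeds the number of possible disulfide pairs",
         call. = FALSE)
  }
  sum(aa == "Y") * 1280 + sum(aa == "W") * 5690 + n_cystine * 125
}

#' Express substrate properties relative to a reference compound
#'
#' Each numeric field of each row is reported as a percentage of the
#' reference compound's value (`100 * value / reference`); missing values
#' propagate as `NA`. The reference row is 100% in every defined field.
#'
#' Whether "relative to the reference" means a ratio or an offset is a
#' reporting convention; both are provided. The default (and the one used
#' for tabulation) is `"percent"`; `"difference"` reports `value -
#' reference` in the property's own units. The chosen mode is recorded in
#' a `normalization` attribute on the result.
#'
#' @param profiles data.frame with a `name` column and numeric property
#'   columns (e.g. `csev`, `e_half`, `pka`, `ksp_o2`).
#' @param reference_name the reference compound's `name`.
#' @param mode `"percent"` (default) or `"difference"`.
#' @return data.frame of percentages (or offsets) with the same shape.
#' @export
relative_profile <- function(profiles, reference_name,
                             mode = c("percent", "difference")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(profiles), "name" %in% names(profiles))
  iref <- which(profiles$name == reference_name)
  if (length(iref) != 1) stop("reference '", reference_name,
                              "' not found exactly once", call. = FALSE)
  out <- profiles
  for (col in setdiff(names(profiles), "name")) {
    if (!is.numeric(profiles[[col]])) next
    ref <- profiles[[col]][iref]
    if (mode == "percent") {
      if (!is.na(ref) && ref == 0) {
        stop("reference value for '", col, "' is zero", call. = FALSE)
      }
      out[[col]] <- 100 * profiles[[col]] / ref
    } else {
      out[[col]] <- profiles[[col]] - ref
    }
  }
  attr(out, "normalization") <- mode
  out
}
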