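# Initial-rate extraction and Michaelis-Menten analysis.
#
# Rates are expressed in uM/min and normalized by enzyme concentration
# before fitting (y = rate/E0, min^-1), matching the units in which
# steady-state constants for these enzymes are reported: KM in uM, kcat
# in s^-1, and the specificity constant kSP = kcat/KM in uM^-1 min^-1
# (hence the factor 60 between kcat in s^-1 and kSP).

#' A steady-state initial-rate dataset
#'
#' @param substrate_concentrations uM, all > 0.
#' @param rates initial rates, uM/min, >= 0.
#' @param enzyme_concentration E0, uM.
#' @param varied_substrate `"catechol"` or `"O2"`.
#' @param temperature deg C.
#' @return an `edx_rates` object.
#' @export
rate_dataset <- function(substrate_concentrations, rates, enzyme_concentration,
                         varied_substrate = c("catechol", "O2"),
                         temperature = 22) {
  varied_substrate <- match.arg(varied_substrate)
  stopifnot(length(substrate_concentrations) == length(rates),
            all(substrate_concentrations > 0), all(rates >= 0),
            enzyme_concentration > 0)
  if (length(unique(substrate_concentrations)) < 4) {
    stop("need >= 4 distinct substrate concentrations", call. = FALSE)
  }
  structure(list(s = as.numeric(substrate_concentrations),
                 rate = as.numeric(rates),
                 e0 = enzyme_concentration,
                 varied_substrate = varied_substrate,
                 temperature = temperature),
            class = "edx_rates")
}

#' Initial rate from a progress curve
#'
#' Converts absorbance to product concentration via the product extinction
#' coefficient, then finds the earliest window of at least `min_points`
#' points whose linear fit has R^2 >= `r2_min`, expands it point by point
#' until R^2 drops below the threshold, and returns the slope of the last
#' accepted window converted to uM/min. A signal with zero variance
#' (flat trace) is linear by convention and yields rate 0.
#'
#' @param trace a [kinetic_trace()] (>= 10 points).
#' @param epsilon product extinction coefficient, M^-1 cm^-1.
#' @param r2_min linearity criterion (default 0.995).
#' @param min_points minimum window length (default 8).
#' @return rate in uM/min, with attributes `window` (index range used) and
#'   `r_squared`.
#' @export
initial_rate <- function(trace, epsilon, r2_min = 0.995, min_points = 8) {
  stopifnot(inherits(trace, "edx_trace"), epsilon > 0,
            length(trace$times) >= 10)
  conc <- 1e6 * trace$absorbance / (epsilon * trace$meta$pathlength)  # uM
  tt <- trace$times
  n <- length(tt)
  fit_window <- function(i1, i2) {
    x <- tt[i1:i2]; y <- conc[i1:i2]
    sxx <- sum((x - mean(x))^2)
    syy <- sum((y - mean(y))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    r2 <- if (syy < 1e-20) 1 else (slope^2 * sxx) / syy
    list(slope = slope, r2 = r2)
  }
  best_r2 <- -Inf
  for (i1 in seq_len(n - min_points + 1)) {
    f <- fit_window(i1, i1 + min_points - 1)
    best_r2 <- max(best_r2, f$r2)
    if (f$r2 >= r2_min) {
      i2 <- i1 + min_points - 1
      while (i2 < n) {
        f2 <- fit_window(i1, i2 + 1)
        if (f2$r2 < r2_min) break
        i2 <- i2 + 1
        f <- f2
      }
      rate <- 60 * f$slope
      attr(rate, "window") <- c(i1, i2)
      attr(rate, "r_squared") <- f$r2
      return(rate)
    }
  }
  stop("no window of >= ", min_points, " points meets R^2 >= ", r2_min,
       " (best R^2 = ", signif(best_r2, 4), ")", call. = FALSE)
}

# Polish an LM solution to a machine-precision minimum. The hyperbola is
# linear in its amplitude given the KM-like axis, so the amplitude is
# profiled out analytically and the stationarity condition
# d(SSE)/d(KM) = 0 (envelope theorem) is solved by root-finding, which
# localizes the optimum far better than comparison-based minimization.
# Both parameterizations are polished through the same profile, so their
# fitted curves agree to rounding error.
.profile_polish <- function(x, y, km0) {
  profile_kc <- function(km) {
    g <- x / (km + x)
    sum(y * g) / sum(g * g)
  }
  dsse <- function(km) {
    g <- x / (km + x)
    kc <- sum(y * g) / sum(g * g)
    -2 * kc * sum((kc * g - y) * x / (km + x)^2)
  }
  lo <- km0 / 1.5; hi <- km0 * 1.5
  for (i in 1:30) {
    if (sign(dsse(lo)) != sign(dsse(hi))) break
    lo <- lo / 2; hi <- hi * 2
  }
  km <- if (sign(dsse(lo)) != sign(dsse(hi))) {
    stats::uniroot(dsse, c(lo, hi), tol = .Machine$double.eps * km0)$root
  } else km0
  list(km = km, kcat_min = profile_kc(km))
}

.mm_result <- function(kcat_min, km, se_kcat_min, se_km, parameterization,
                       data, fitted) {
  kcat <- kcat_min / 60
  structure(list(kcat = kcat, km = km, ksp = kcat_min / km,
                 se = list(kcat = se_kcat_min / 60, km = se_km),
                 parameterization = parameterization,
                 extrapolated = max(data$s) < km,
                 data = data, fitted = fitted),
            class = "edx_mm")
}

#' @export
print.edx_mm <- function(x, ...) {
  cat(sprintf(
    "Michaelis-Menten fit (%s form)%s\n  kcat = %.4g +/- %.2g s^-1\n  KM   = %.4g +/- %.2g uM\n  kSP  = %.4g uM^-1 min^-1 (%.3g on the x10^2 scale)\n",
    x$parameterization,
    if (x$extrapolated) " [KM above data range: extrapolated]" else "",
    x$kcat, x$se$kcat, x$km, x$se$km, x$ksp, 100 * x$ksp))
  invisible(x)
}

#' Michaelis-Menten fit, traditional parameterization
#'
#' Fits `y = kcat * x / (KM + x)` with `y = rate/E0` (min^-1) by nonlinear
#' least squares; the specificity constant is derived as
#' `kSP = 60 * kcat[s^-1] / KM`. Data whose largest concentration is
#' below the fitted KM are flagged as extrapolated.
#'
#' @param data an [rate_dataset()].
#' @return an `edx_mm` with `kcat` (s^-1), `km` (uM), `ksp`
#'   (uM^-1 min^-1) and standard errors.
#' @export
fit_mm_traditional <- function(data) {
  stopifnot(inherits(data, "edx_rates"))
  y <- data$rate / data$e0
  x <- data$s
  start <- list(kcat = max(y) * 1.2 + 1e-12,
                km = max(stats::median(x), min(x)))
  fit <- minpack.lm::nlsLM(y ~ kcat * x / (km + x), start = start,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 1000, ftol = 1e-15, ptol = 1e-15))
  cf <- summary(fit)$coefficients
  p <- .profile_polish(x, y, cf["km", 1])
  .mm_result(p$kcat_min, p$km, cf["kcat", 2], cf["km", 2],
             "traditional", data, p$kcat_min * x / (p$km + x))
}

#' Michaelis-Menten fit, specificity-constant parameterization
#'
#' Fits the algebraically equivalent hyperbola
#' `y = kSP * x / (1 + (kSP/kcat) * x)` so that the specificity constant
#' is a fitted parameter rather than a derived ratio; `KM` is then
#' derived as `kcat / kSP`. On noiseless hyperbolic data both
#' parameterizations give identical curves.
#'
#' @param data an [rate_dataset()].
#' @return an `edx_mm` (same fields as [fit_mm_traditional()]).
#' @export
fit_mm_ksp <- function(data) {
  stopifnot(inherits(data, "edx_rates"))
  y <- data$rate / data$e0
  x <- data$s
  kcat0 <- max(y) * 1.2 + 1e-12
  start <- list(ksp = kcat0 / max(stats::median(x), min(x)), kcat = kcat0)
  fit <- minpack.lm::nlsLM(y ~ ksp * x / (1 + (ksp / kcat) * x), start = start,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 1000, ftol = 1e-15, ptol = 1e-15))
  cf <- summary(fit)$coefficients
  # the KM-like axis of this parameterization is kcat/kSP
  p <- .profile_polish(x, y, cf["kcat", 1] / cf["ksp", 1])
  kcat_min <- p$kcat_min; km <- p$km
  ksp <- kcat_min / km
  # delta-method SE for the derived KM
  V <- stats::vcov(fit)
  gr <- c(-kcat_min / ksp^2, 1 / ksp)  # d km / d(ksp, kcat)
  se_km <- sqrt(drop(t(gr) %*% V[c("ksp", "kcat"), c("ksp", "kcat")] %*% gr))
  .mm_result(kcat_min, km, cf["kcat", 2], se_km, "ksp_form", data,
             ksp * x / (1 + (ksp / kcat_min) * x))
}

#' Convert an O2 gas percentage to dissolved concentration
#'
#' Linear map anchored at 100% O2 = 1300 uM dissolved at the reference
#' temperature of 22 deg C (so 21% ~ 273 uM). Other temperatures require
#' an explicit user-supplied saturation constant.
#'
#' @param percent O2 percentage in the gas blend, 0-100.
#' @param temperature deg C (only 22 supported without `saturation`).
#' @param saturation dissolved O2 at 100% (uM); default 1300 at 22 deg C.
#' @return dissolved O2, uM.
#' @examples
#' o2_percent_to_conc(100)  # 1300
#' o2_percent_to_conc(21)   # 273
#' @export
o2_percent_to_conc <- function(percent, temperature = 22, saturation = NULL) {
  stopifnot(all(percent >= 0), all(percent <= 100))
  if (is.null(saturation)) {
    if (temperature != 22) {
      stop("no O2 saturation constant known for ", temperature,
           " deg C; supply `saturation`", call. = FALSE)
    }
    saturation <- 1300
  }
  percent / 100 * saturation
}

#' Extinction coefficient from endpoint absorbances
#'
#' For reactions run to completion with excess enzyme, the endpoint
#' absorbance is Beer-Lambert linear in the starting substrate
#' concentration. Fits a through-origin line of A against
#' `1e-6 * conc * pathlength` whose slope is the product extinction
#' coefficient in M^-1 cm^-1.
#'
#' @param concentrations substrate concentrations, uM (>= 3 values).
#' @param endpoint_absorbances endpoint A, AU.
#' @param pathlength cm.
#' @return list with `epsilon`, `se`, and the underlying `fit`.
#' @export
extinction_from_endpoint <- function(concentrations, endpoint_absorbances,
                                     pathlength = 1) {
  stopifnot(length(concentrations) == length(endpoint_absorbances),
            length(concentrations) >= 1, pathlength > 0)
  if (length(concentrations) < 3) {
    warning("fewer than 3 concentrations: slope is exact but its standard ",
            "error is unreliable")
  }
  x <- 1e-6 * concentrations * pathlength
  ord <- order(concentrations)
  if (is.unsorted(endpoint_absorbances[ord])) {
    warning("endpoint absorbances are not monotone in concentration")
  }
  fit <- stats::lm(endpoint_absorbances ~ 0 + x)
  eps <- unname(stats::coef(fit)[1])
  if (eps < 0) stop("negative fitted extinction coefficient", call. = FALSE)
  se <- suppressWarnings(summary(fit)$coefficients[1, 2])
  list(epsilon = eps, se = se, fit = fit)
}
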