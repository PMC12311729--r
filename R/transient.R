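# Fitting averaged stopped-flow traces to a mechanism, and FitSpace-style
# two-dimensional confidence contours (profile SSE with re-optimization of
# the remaining free parameters).

#' Average replicate stopped-flow traces
#'
#' Replicate shots recorded under the same conditions are averaged
#' pointwise before fitting. Metadata (wavelength, pH, temperature) must
#' agree across replicates; traces on different time grids are linearly
#' interpolated onto the grid of the first trace, restricted to the
#' overlap of all grids.
#'
#' @param traces list of [kinetic_trace()] objects (>= 2).
#' @return a single [kinetic_trace()] with `n_averaged` set to the total
#'   replicate count.
#' @export
average_traces <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 2)
  m1 <- traces[[1]]$meta
  for (tr in traces[-1]) {
    for (f in c("wavelength", "ph", "temperature")) {
      a <- m1[[f]]; b <- tr$meta[[f]]
      if (!identical(is.na(a), is.na(b)) || (!is.na(a) && a != b)) {
        stop("replicate metadata mismatch in '", f, "': ", a, " vs ", b,
             call. = FALSE)
      }
    }
  }
  grid <- traces[[1]]$times
  same <- all(vapply(traces, function(tr) {
    length(tr$times) == length(grid) && all(tr$times == grid)
  }, logical(1)))
  if (!same) {
    lo <- max(vapply(traces, function(tr) min(tr$times), numeric(1)))
    hi <- min(vapply(traces, function(tr) max(tr$times), numeric(1)))
    grid <- grid[grid >= lo & grid <= hi]
    if (length(grid) < 2) stop("replicate time grids do not overlap", call. = FALSE)
  }
  A <- vapply(traces, function(tr) {
    if (same) tr$absorbance else stats::approx(tr$times, tr$absorbance, grid)$y
  }, numeric(length(grid)))
  out <- traces[[1]]
  out$times <- grid
  out$absorbance <- rowMeans(A)
  out$meta$n_averaged <- sum(vapply(traces, function(tr) tr$meta$n_averaged,
                                    integer(1)))
  out
}

#' Define a transient fitting problem
#'
#' Couples a mechanism, an observable model, and an averaged data trace,
#' naming the parameters to be optimized. Free parameters may be any
#' non-ratio-linked rate constant plus the observable's `a` (semiquinone
#' extinction coefficient) and `c` (offset). The product extinction
#' coefficient `b` is independently determined experimentally and is
#' always held fixed.
#'
#' @param mechanism an `edx_mechanism`.
#' @param observable an [observable_model()].
#' @param data a [kinetic_trace()].
#' @param free character vector of free parameter names.
#' @param window fit window `c(t_start, t_end)` in s. The default drops
#'   the first 0.8 s, where real traces of slowly oxidized substrates show
#'   additional low-intensity features that are excluded from fitting.
#' @return an `edx_fit_problem`.
#' @export
fit_problem <- function(mechanism, observable, data,
                        free = c("k6", "k7", "a"), window = c(0.8, 45)) {
  stopifnot(inherits(mechanism, "edx_mechanism"),
            inherits(observable, "edx_observable"),
            inherits(data, "edx_trace"), length(window) == 2)
  if ("b" %in% free) {
    stop("'b' is an independently determined extinction coefficient and is ",
         "never free", call. = FALSE)
  }
  kn <- names(rate_constants(mechanism))
  bad <- setdiff(free, c(kn, "a", "c"))
  if (length(bad)) stop("unknown free parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (st in mechanism$steps) {
    for (side in c("kf", "kr")) {
      nm <- st[[paste0(side, "_name")]]
      if (!is.null(nm) && nm %in% free &&
          st[[paste0(side, "_status")]] == "ratio_linked") {
        stop("ratio_linked constant '", nm, "' cannot be free", call. = FALSE)
      }
    }
  }
  if (window[1] < min(data$times) - 1e-12 || window[2] > max(data$times) + 1e-12) {
    stop("fit window must lie within the data time span", call. = FALSE)
  }
  structure(list(mechanism = mechanism, observable = observable, data = data,
                 free = free, window = window),
            class = "edx_fit_problem")
}

# apply a named parameter vector (natural scale) to a problem and return
# the predicted absorbance on the data grid
.predict_problem <- function(problem, par) {
  mech <- problem$mechanism
  obs <- problem$observable
  kn <- names(rate_constants(mech))
  kpar <- par[names(par) %in% kn]
  if (length(kpar)) mech <- set_rate_constants(mech, kpar)
  if ("a" %in% names(par)) obs$a <- unname(par["a"])
  if ("c" %in% names(par)) obs$c <- unname(par["c"])
  times <- problem$data$times
  if (times[1] > 0) times <- c(0, times)
  traj <- simulate_mechanism(mech, times)
  pred <- observe_absorbance(traj, obs)
  pred$absorbance[match(problem$data$times, pred$times)]
}

#' Predicted trace for a parameter vector
#'
#' @param problem an [fit_problem()].
#' @param par named numeric vector (natural scale) of any subset of the
#'   mechanism's rate constants and `a`, `c`.
#' @return a [kinetic_trace()] on the data's time grid.
#' @export
predict_trace <- function(problem, par = numeric()) {
  A <- .predict_problem(problem, par)
  kinetic_trace(problem$data$times, A, pathlength = problem$observable$pathlength)
}

.default_start <- function(problem) {
  k <- rate_constants(problem$mechanism)
  start <- numeric(0)
  for (nm in problem$free) {
    start[nm] <- switch(nm, a = problem$observable$a, c = problem$observable$c,
                        k[[nm]])
  }
  start
}

# c is fitted untransformed (it may legitimately be ~0 or negative);
# everything else (rate constants, a) is log-transformed so positivity is
# structural rather than enforced by hard walls.
.to_theta <- function(par) {
  ifelse(names(par) == "c", par, log(pmax(par, 1e-300)))
}
.from_theta <- function(theta) {
  out <- ifelse(names(theta) == "c", theta, exp(theta))
  stats::setNames(as.numeric(out), names(theta))
}

#' Fit a mechanism to an averaged trace by nonlinear least squares
#'
#' Minimizes the sum of squared residuals between the observed and the
#' simulated absorbance over the fit window, using Levenberg-Marquardt
#' (trust-region) iterations on log-transformed positive parameters.
#' Fixed and ratio-linked constants are never touched. A trial point at
#' which the stiff integration fails is rejected by returning large
#' residuals rather than aborting the fit.
#'
#' @param problem an [fit_problem()].
#' @param start named numeric start values (natural scale); defaults to
#'   the values currently stored in the mechanism/observable.
#' @param lower,upper named bounds (natural scale); defaults span wide
#'   factors around the start.
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @return an `edx_fit`: list with `par` (natural scale), `sse`,
#'   `n_points`, `converged`, `info`, `message`.
#' @export
fit_mechanism <- function(problem, start = NULL, lower = NULL, upper = NULL,
                          control = list(maxiter = 200)) {
  stopifnot(inherits(problem, "edx_fit_problem"))
  if (length(problem$free) == 0) stop("no free parameters", call. = FALSE)
  if (is.null(start)) start <- .default_start(problem)
  start <- start[problem$free]
  if (anyNA(start)) stop("start values missing for some free parameters",
                         call. = FALSE)
  if (is.null(lower)) {
    lower <- ifelse(names(start) == "c", -10, start / 1e4)
  }
  if (is.null(upper)) {
    upper <- ifelse(names(start) == "c", 10, start * 1e4)
  }
  names(lower) <- names(upper) <- names(start)
  if (any(start < lower | start > upper)) {
    stop("start values must lie within bounds", call. = FALSE)
  }
  w <- problem$window
  sel <- problem$data$times >= w[1] & problem$data$times <= w[2]
  obs <- problem$data$absorbance[sel]
  resid_fn <- function(theta) {
    names(theta) <- problem$free
    par <- .from_theta(theta)
    pred <- tryCatch(.predict_problem(problem, par), error = function(e) NULL)
    if (is.null(pred) || anyNA(pred)) return(rep(1e6, sum(sel)))
    pred[sel] - obs
  }
  fit <- minpack.lm::nls.lm(
    par = .to_theta(start), fn = resid_fn,
    lower = as.numeric(.to_theta(lower)), upper = as.numeric(.to_theta(upper)),
    control = do.call(minpack.lm::nls.lm.control, control))
  theta <- stats::setNames(fit$par, problem$free)
  structure(list(par = .from_theta(theta),
                 sse = fit$deviance, n_points = sum(sel),
                 converged = fit$info %in% 1:4,
                 info = fit$info, message = fit$message,
                 problem = problem, start = start,
                 lower = lower, upper = upper),
            class = "edx_fit")
}

#' @export
print.edx_fit <- function(x, ...) {
  cat("Transient least-squares fit (", x$n_points, " points, SSE ",
      signif(x$sse, 5), if (!x$converged) ", NOT converged", ")\n", sep = "")
  print(signif(x$par, 5))
  invisible(x)
}

#' Two-dimensional profile-SSE (FitSpace-style) grid, generic engine
#'
#' Scans a grid over a pair of parameters; at each node the pair is held
#' fixed and all remaining free parameters are re-optimized by the
#' supplied `refit` function. The confidence measure at a node is
#' `sse_ratio = SSE_min / SSE_node`, and the confidence region is
#' `{sse_ratio >= threshold}` (the default threshold 0.83 admits fits
#' whose SSE exceeds the minimum by no more than ~20%). Per-parameter
#' intervals are the projections of the region onto each axis. Nodes are
#' visited in serpentine order so each inner fit can be warm-started from
#' its neighbor.
#'
#' @param refit function `(fixed, start)` where `fixed` is the named
#'   2-vector of pinned parameter values and `start` named start values
#'   for the remaining parameters (may be empty); must return
#'   `list(par =, sse =, converged =)`.
#' @param best_par named numeric vector of all free parameters at the
#'   best fit.
#' @param best_sse SSE at the best fit.
#' @param pair character 2-vector naming the scanned parameters.
#' @param axes optional list of two numeric grid vectors; by default
#'   `grid_size` log-spaced nodes spanning a factor of `span` on either
#'   side of the best-fit value.
#' @param grid_size,span defaults for automatic axes (21 nodes, x/ 5).
#' @param threshold SSE-ratio threshold (default 0.83).
#' @return an `edx_fitspace`: `sse`, `sse_ratio` and `converged` matrices
#'   (axis1 x axis2), `axes`, `intervals` (region projections per
#'   parameter), `threshold`, `region_empty` flag.
#' @export
fit_space_grid <- function(refit, best_par, best_sse, pair, axes = NULL,
                           grid_size = 21, span = 5, threshold = 0.83) {
  stopifnot(length(pair) == 2, all(pair %in% names(best_par)),
            threshold > 0, threshold <= 1)
  if (is.null(axes)) {
    axes <- lapply(pair, function(nm) {
      v <- best_par[[nm]]
      if (v <= 0) stop("automatic log axes need a positive best-fit value for '",
                       nm, "'", call. = FALSE)
      ax <- exp(seq(log(v / span), log(v * span), length.out = grid_size))
      # pin the center node to the exact best-fit value (odd-sized grids)
      if (grid_size %% 2 == 1) ax[(grid_size + 1) / 2] <- v
      ax
    })
  }
  names(axes) <- pair
  n1 <- length(axes[[1]]); n2 <- length(axes[[2]])
  sse <- matrix(NA_real_, n1, n2)
  conv <- matrix(TRUE, n1, n2)
  others <- setdiff(names(best_par), pair)
  warm <- best_par[others]
  for (i in seq_len(n1)) {
    jorder <- if (i %% 2 == 1) seq_len(n2) else rev(seq_len(n2))
    for (j in jorder) {
      fixed <- stats::setNames(c(axes[[1]][i], axes[[2]][j]), pair)
      res <- refit(fixed, warm)
      sse[i, j] <- res$sse
      conv[i, j] <- isTRUE(res$converged)
      if (length(others) && !is.null(res$par)) warm <- res$par[others]
    }
    warm <- best_par[others]  # re-anchor each row
  }
  # A node may legitimately undercut the nominal minimum by solver slack;
  # ratios are computed against the smallest SSE seen anywhere.
  sse_min <- min(best_sse, min(sse, na.rm = TRUE))
  ratio <- sse_min / sse
  in_region <- ratio >= threshold
  region_empty <- !any(in_region)
  if (region_empty) {
    warning("no grid node reaches the SSE-ratio threshold ", threshold)
  }
  intervals <- list()
  intervals[[pair[1]]] <-
    if (region_empty) c(NA_real_, NA_real_) else
      range(axes[[1]][apply(in_region, 1, any)])
  intervals[[pair[2]]] <-
    if (region_empty) c(NA_real_, NA_real_) else
      range(axes[[2]][apply(in_region, 2, any)])
  structure(list(pair = pair, axes = axes, sse = sse, sse_ratio = ratio,
                 converged = conv, threshold = threshold,
                 intervals = intervals, region_empty = region_empty,
                 best_par = best_par, best_sse = best_sse),
            class = "edx_fitspace")
}

#' @export
print.edx_fitspace <- function(x, ...) {
  cat("FitSpace grid ", length(x$axes[[1]]), "x", length(x$axes[[2]]),
      " over (", paste(x$pair, collapse = ", "), "), threshold ",
      x$threshold, "\n", sep = "")
  for (nm in x$pair) {
    cat(sprintf("  %s in [%.4g, %.4g]\n", nm, x$intervals[[nm]][1],
                x$intervals[[nm]][2]))
  }
  invisible(x)
}

#' FitSpace contours for a transient fit
#'
#' Convenience wrapper around [fit_space_grid()] for a mechanism fit: at
#' each node the scanned pair is pinned and the remaining free parameters
#' of the problem are re-optimized with [fit_mechanism()].
#'
#' @param best an `edx_fit` from [fit_mechanism()] (must be converged).
#' @param pair character 2-vector of free parameter names.
#' @inheritParams fit_space_grid
#' @return an `edx_fitspace`.
#' @export
fit_space <- function(best, pair, axes = NULL, grid_size = 21, span = 5,
                      threshold = 0.83) {
  stopifnot(inherits(best, "edx_fit"))
  if (!best$converged) stop("the reference fit is not converged", call. = FALSE)
  problem <- best$problem
  stopifnot(all(pair %in% problem$free))
  others <- setdiff(problem$free, pair)
  w <- problem$window
  sel <- problem$data$times >= w[1] & problem$data$times <= w[2]
  obsA <- problem$data$absorbance[sel]
  # When only observable parameters (a, c) remain free, they enter the
  # predicted absorbance linearly, so the inner re-optimization at a node
  # is one simulation plus closed-form linear least squares.
  linear_refit <- function(fixed, start) {
    mech <- problem$mechanism
    kn <- names(rate_constants(mech))
    kfix <- fixed[names(fixed) %in% kn]
    if (length(kfix)) mech <- set_rate_constants(mech, kfix)
    ob <- problem$observable
    if ("a" %in% names(fixed)) ob$a <- unname(fixed["a"])
    if ("c" %in% names(fixed)) ob$c <- unname(fixed["c"])
    times <- problem$data$times
    if (times[1] > 0) times <- c(0, times)
    traj <- tryCatch(simulate_mechanism(mech, times), error = function(e) NULL)
    if (is.null(traj)) return(list(par = start, sse = Inf, converged = FALSE))
    at <- match(problem$data$times, traj$times)[sel]
    esq_term <- traj$conc[at, ob$esq]
    if (ob$literal_mode) esq_term <- esq_term - traj$conc[at, ob$esqx]
    prod_term <- rowSums(traj$conc[at, ob$product_species, drop = FALSE])
    scale <- 1e-6 * ob$pathlength
    base <- scale * ob$b * prod_term
    X <- cbind(a = if ("a" %in% others) scale * esq_term,
               c = if ("c" %in% others) rep(-1, sum(sel)))
    colnames(X) <- others
    rhs <- obsA - base -
      (if ("a" %in% others) 0 else scale * ob$a * esq_term) -
      (if ("c" %in% others) 0 else -ob$c)
    beta <- tryCatch(drop(solve(crossprod(X), crossprod(X, rhs))),
                     error = function(e) NULL)
    if (is.null(beta)) return(list(par = start, sse = Inf, converged = FALSE))
    beta <- stats::setNames(pmin(pmax(beta, best$lower[others]),
                                 best$upper[others]), others)
    resid <- drop(X %*% beta) - rhs
    list(par = beta, sse = sum(resid^2), converged = TRUE)
  }
  refit <- function(fixed, start) {
    if (length(others) && all(others %in% c("a", "c"))) {
      return(linear_refit(fixed, start))
    }
    if (length(others) == 0) {
      pred <- tryCatch(.predict_problem(problem, fixed), error = function(e) NULL)
      if (is.null(pred)) return(list(par = fixed, sse = Inf, converged = FALSE))
      return(list(par = fixed, sse = sum((pred[sel] - obsA)^2), converged = TRUE))
    }
    inner <- problem
    # pin the pair by fixing their values in mechanism/observable
    kn <- names(rate_constants(problem$mechanism))
    kfix <- fixed[names(fixed) %in% kn]
    if (length(kfix)) inner$mechanism <- set_rate_constants(inner$mechanism, kfix)
    if ("a" %in% names(fixed)) inner$observable$a <- unname(fixed["a"])
    if ("c" %in% names(fixed)) inner$observable$c <- unname(fixed["c"])
    inner$free <- others
    f <- tryCatch(
      fit_mechanism(inner, start = start, lower = best$lower[others],
                    upper = best$upper[others]),
      error = function(e) NULL)
    if (is.null(f)) return(list(par = start, sse = Inf, converged = FALSE))
    list(par = f$par, sse = f$sse, converged = f$converged)
  }
  fit_space_grid(refit, best$par, best$sse, pair, axes = axes,
                 grid_size = grid_size, span = span, threshold = threshold)
}
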