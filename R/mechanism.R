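# Rate-constant status keywords. fixed_fast / fixed_slow resolve to sentinel
# magnitudes used when a step is known to be much faster / slower than the
# observable timescale but its actual rate is unconstrained by the data.
.rate_statuses <- c("free", "fixed", "fixed_fast", "fixed_slow", "ratio_linked")
.FIXED_FAST <- 1e9
.FIXED_SLOW <- 1e-12

#' Define one mass-action reaction step
#'
#' A step has one or two reactants, one or more products, a forward and an
#' optional reverse rate constant. Units follow the package-wide contract:
#' concentrations in uM, time in s, so unimolecular constants are s^-1 and
#' bimolecular constants uM^-1 s^-1. A reverse constant of 0 with status
#' `"fixed"` denotes an irreversible step.
#'
#' Each constant carries a status: `"free"` (adjustable in fitting),
#' `"fixed"` (held at its value), `"fixed_fast"` (resolves to 1e9),
#' `"fixed_slow"` (resolves to 1e-12), or `"ratio_linked"` (its value is
#' `ratio` times the current value of the named partner constant, re-derived
#' on every resolution so the ratio is honored after any parameter update).
#'
#' @param reactants character vector of 1 or 2 species names.
#' @param products character vector of species names.
#' @param kf,kr forward / reverse rate constant values. `kr = 0` means
#'   irreversible.
#' @param kf_name,kr_name unique names for the two constants (e.g. `"k6"`).
#'   `kr_name` may be `NULL` for irreversible steps.
#' @param kf_status,kr_status status keywords (see Details).
#' @param kf_ratio,kr_ratio for `ratio_linked` status, a
#'   `list(partner = <constant name>, ratio = <numeric>)`.
#' @return an object of class `edx_step`.
#' @export
reaction_step <- function(reactants, products, kf, kr = 0,
                          kf_name, kr_name = NULL,
                          kf_status = "free",
                          kr_status = if (kr > 0) "free" else "fixed",
                          kf_ratio = NULL, kr_ratio = NULL) {
  stopifnot(length(reactants) %in% 1:2, length(products) >= 1)
  for (s in list(kf_status, kr_status)) {
    if (!s %in% .rate_statuses) {
      stop("unknown rate-constant status keyword: '", s, "'", call. = FALSE)
    }
  }
  for (side in list(list(kf_status, kf_ratio, "kf"),
                    list(kr_status, kr_ratio, "kr"))) {
    if (side[[1]] == "ratio_linked" && is.null(side[[2]])) {
      stop("status 'ratio_linked' for ", side[[3]],
           " requires a ratio specification", call. = FALSE)
    }
    if (side[[1]] != "ratio_linked" && !is.null(side[[2]])) {
      stop("ratio specified for a non-ratio_linked constant (", side[[3]], ")",
           call. = FALSE)
    }
  }
  if (kf < 0 || kr < 0) stop("rate constants must be >= 0", call. = FALSE)
  structure(
    list(reactants = as.character(reactants),
         products = as.character(products),
         kf = kf, kr = kr,
         kf_name = kf_name, kr_name = kr_name,
         kf_status = kf_status, kr_status = kr_status,
         kf_ratio = kf_ratio, kr_ratio = kr_ratio),
    class = "edx_step")
}

#' Assemble a mass-action mechanism
#'
#' @param species data.frame with columns `name`, `conc0` (initial
#'   concentration, uM) and optionally `enzyme_tag` / `substrate_tag`
#'   (0/1 flags marking which species carry the enzyme or the substrate
#'   skeleton; used for conservation checks) and `active`
#'   (spectroscopically active flag, informational).
#' @param steps list of [reaction_step()] objects.
#' @param label free-text label.
#' @return an object of class `edx_mechanism`.
#' @export
mechanism <- function(species, steps, label = "") {
  stopifnot(is.data.frame(species), all(c("name", "conc0") %in% names(species)))
  species$name <- as.character(species$name)
  mech <- structure(list(species = species, steps = steps, label = label),
                    class = "edx_mechanism")
  validate_mechanism(mech)
  mech
}

#' Validate a mechanism
#'
#' Checks species-name uniqueness, non-negative initial concentrations,
#' that every species referenced by a step exists, uniqueness of
#' rate-constant names, and (when tag columns are present) that each step
#' conserves the enzyme and substrate tags.
#'
#' @param mech an `edx_mechanism`.
#' @return `mech`, invisibly; errors on violation.
#' @export
validate_mechanism <- function(mech) {
  sp <- mech$species
  if (anyDuplicated(sp$name)) stop("species names must be unique", call. = FALSE)
  if (any(sp$conc0 < 0)) stop("negative initial concentration", call. = FALSE)
  knames <- unlist(lapply(mech$steps, function(s) c(s$kf_name, s$kr_name)))
  if (anyDuplicated(knames)) {
    stop("rate-constant names must be unique: ",
         paste(unique(knames[duplicated(knames)]), collapse = ", "),
         call. = FALSE)
  }
  for (st in mech$steps) {
    unknown <- setdiff(c(st$reactants, st$products), sp$name)
    if (length(unknown)) {
      stop("step references unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (tag in c("enzyme_tag", "substrate_tag")) {
      if (tag %in% names(sp)) {
        tv <- stats::setNames(sp[[tag]], sp$name)
        if (sum(tv[st$reactants]) != sum(tv[st$products])) {
          stop("step does not conserve ", tag, ": ",
               paste(st$reactants, collapse = " + "), " -> ",
               paste(st$products, collapse = " + "), call. = FALSE)
        }
      }
    }
  }
  invisible(mech)
}

#' Resolve every rate constant to a numeric value
#'
#' Applies the status semantics: `fixed_fast` -> 1e9, `fixed_slow` -> 1e-12,
#' `ratio_linked` -> ratio x partner value (partner resolved first).
#'
#' @param mech an `edx_mechanism`.
#' @return named numeric vector over all constant names.
#' @export
rate_constants <- function(mech) {
  vals <- c(); stats_ <- c(); ratios <- list()
  for (st in mech$steps) {
    vals[st$kf_name] <- st$kf; stats_[st$kf_name] <- st$kf_status
    ratios[[st$kf_name]] <- st$kf_ratio
    if (!is.null(st$kr_name)) {
      vals[st$kr_name] <- st$kr; stats_[st$kr_name] <- st$kr_status
      ratios[[st$kr_name]] <- st$kr_ratio
    }
  }
  out <- vals
  out[stats_ == "fixed_fast"] <- .FIXED_FAST
  out[stats_ == "fixed_slow"] <- .FIXED_SLOW
  for (nm in names(vals)[stats_ == "ratio_linked"]) {
    r <- ratios[[nm]]
    if (!r$partner %in% names(vals)) {
      stop("ratio_linked partner '", r$partner, "' is not a rate constant",
           call. = FALSE)
    }
    if (stats_[r$partner] == "ratio_linked") {
      stop("ratio_linked partner must itself be a plain constant", call. = FALSE)
    }
    out[nm] <- r$ratio * out[r$partner]
  }
  out
}

#' Update rate-constant values by name
#'
#' Values of `ratio_linked` constants cannot be set directly (they are
#' re-derived from their partner on resolution, so the configured ratio is
#' honored after any update).
#'
#' @param mech an `edx_mechanism`.
#' @param values named numeric vector.
#' @return the updated mechanism.
#' @export
set_rate_constants <- function(mech, values) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (any(values < 0)) stop("rate constants must be >= 0", call. = FALSE)
  found <- stats::setNames(logical(length(values)), names(values))
  for (i in seq_along(mech$steps)) {
    st <- mech$steps[[i]]
    if (st$kf_name %in% names(values)) {
      if (st$kf_status == "ratio_linked") {
        stop("cannot set ratio_linked constant '", st$kf_name, "' directly",
             call. = FALSE)
      }
      st$kf <- unname(values[st$kf_name]); found[st$kf_name] <- TRUE
    }
    if (!is.null(st$kr_name) && st$kr_name %in% names(values)) {
      if (st$kr_status == "ratio_linked") {
        stop("cannot set ratio_linked constant '", st$kr_name, "' directly",
             call. = FALSE)
      }
      st$kr <- unname(values[st$kr_name]); found[st$kr_name] <- TRUE
    }
    mech$steps[[i]] <- st
  }
  if (!all(found)) {
    stop("unknown rate constant(s): ",
         paste(names(found)[!found], collapse = ", "), call. = FALSE)
  }
  mech
}

#' Henderson-Hasselbalch speciation of a monoprotic group
#'
#' @param pka acid dissociation constant (log units).
#' @param ph solution pH.
#' @return list with `ratio` = `[A-]/[HA]` = 10^(pH - pKa) and
#'   `fraction_deprotonated` = ratio / (1 + ratio).
#' @examples
#' speciation_ratio(7.51, 7.35)$fraction_deprotonated  # 0.409
#' @export
speciation_ratio <- function(pka, ph) {
  stopifnot(is.finite(pka), is.finite(ph))
  r <- 10^(ph - pka)
  list(ratio = r, fraction_deprotonated = r / (1 + r))
}

#' Build the canonical single-turnover ring-cleavage mechanism
#'
#' Constructs the ten-step reaction network used to model single-turnover
#' stopped-flow traces of an extradiol dioxygenase acting on a catechol
#' whose two charge states interconvert in solution:
#'
#' 1. `SA <-> SB` - solution acid/base interconversion of the substrate;
#'    `k1` is ratio-linked to `km1` so that the equilibrium
#'    `[SB]/[SA] = 10^(pH - pKa)` (Henderson-Hasselbalch) always holds.
#' 2. `E + SA <-> ES` - binding of the protonated (acid) charge state.
#' 3. `E + SB <-> ES` - binding of the deprotonated state. By default one
#'    of steps 2/3 is driven to `fixed_slow` (only one charge state is
#'    binding-competent); which one is controlled by `binding_state`.
#' 4. `ES + O2 -> ESO2` - oxygen binding, irreversible and `fixed_fast`
#'    by default.
#' 5. `ESO2 -> ESQ` - semiquinone radical formation, irreversible.
#' 6. `ESQ -> EI` (`k6`) - productive decay of the semiquinone into
#'    UV-silent intermediates, irreversible.
#' 7. `ESQ -> ESQX` (`k7`) - nonproductive quenching of the semiquinone
#'    (enzyme inactivation branch), irreversible.
#' 8. `EI -> EP` - a single lumped rate for all UV-silent steps between
#'    the semiquinone and the semialdehyde product.
#' 9. `EP -> E + P` - product release.
#' 10. `P <-> PX` - reversible decay of the released semialdehyde into a
#'    spectroscopically silent form.
#'
#' The substrate pool is initialized pre-equilibrated across `SA`/`SB`
#' at the Henderson-Hasselbalch fractions. `SA` is the more protonated
#' form and `SB` its conjugate base throughout.
#'
#' @param pka catecholic pKa of the substrate.
#' @param ph reaction pH.
#' @param e0,s0,o2_0 initial enzyme, substrate and dissolved O2 (uM).
#' @param rate_spec named list overriding defaults per constant; each
#'   element is a `list(value =, status =)` (either may be omitted).
#'   Constant names: `k1, km1, k2, km2, k3, km3, k4, k5, k6, k7, k8, k9,
#'   k10, km10`.
#' @param binding_state which charge state forms ES: `"SA"` (default;
#'   step 3 is then `fixed_slow`) or `"SB"` (step 2 `fixed_slow`).
#' @return an `edx_mechanism` with enzyme/substrate conservation tags.
#' @examples
#' m <- build_scheme1(pka = 7.51, ph = 7.35, e0 = 56, s0 = 5.6, o2_0 = 1000)
#' rate_constants(m)[["k1"]] / rate_constants(m)[["km1"]]  # 10^(7.35-7.51)
#' @export
build_scheme1 <- function(pka, ph, e0, s0, o2_0,
                          rate_spec = list(),
                          binding_state = c("SA", "SB")) {
  stopifnot(pka > 0, pka < 14, ph > 0, ph < 14, e0 >= 0, s0 >= 0, o2_0 >= 0)
  binding_state <- match.arg(binding_state)
  r <- speciation_ratio(pka, ph)$ratio

  # defaults: value, status. k1 enforces [SB]/[SA] = 10^(pH-pKa) against km1.
  defaults <- list(
    k1   = list(value = 100 * r, status = "ratio_linked",
                ratio = list(partner = "km1", ratio = r)),
    km1  = list(value = 100, status = "fixed"),
    k2   = list(value = 1,   status = "fixed"),
    km2  = list(value = 1,   status = "fixed"),
    k3   = list(value = 1,   status = "fixed"),
    km3  = list(value = 1,   status = "fixed"),
    k4   = list(value = .FIXED_FAST, status = "fixed_fast"),
    k5   = list(value = 1,    status = "fixed"),
    k6   = list(value = 0.55, status = "free"),
    k7   = list(value = 0.3,  status = "free"),
    k8   = list(value = 0.15, status = "fixed"),
    k9   = list(value = 2,    status = "fixed"),
    k10  = list(value = 0.05, status = "fixed"),
    km10 = list(value = 0.05, status = "fixed"))
  # one binding pathway is driven to zero (only one charge state competent)
  if (binding_state == "SA") {
    defaults$k3$status <- defaults$km3$status <- "fixed_slow"
  } else {
    defaults$k2$status <- defaults$km2$status <- "fixed_slow"
  }
  unknown <- setdiff(names(rate_spec), names(defaults))
  if (length(unknown)) {
    stop("rate_spec names not in scheme: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(rate_spec)) {
    ov <- rate_spec[[nm]]
    if (!is.null(ov$value)) defaults[[nm]]$value <- ov$value
    if (!is.null(ov$status)) defaults[[nm]]$status <- ov$status
    if (!is.null(ov$ratio)) defaults[[nm]]$ratio <- ov$ratio
  }
  g <- function(nm) defaults[[nm]]
  species <- data.frame(
    name = c("E", "SA", "SB", "ES", "O2", "ESO2", "ESQ", "ESQX",
             "EI", "EP", "P", "PX"),
    conc0 = c(e0, s0 / (1 + r), s0 * r / (1 + r), 0, o2_0, 0, 0, 0, 0, 0, 0, 0),
    enzyme_tag    = c(1, 0, 0, 1, 0, 1, 1, 1, 1, 1, 0, 0),
    substrate_tag = c(0, 1, 1, 1, 0, 1, 1, 1, 1, 1, 1, 1),
    active        = c(0, 0, 0, 0, 0, 0, 1, 0, 0, 1, 1, 0))
  mk <- function(reac, prod, fn, rn = NULL) {
    f <- g(fn); rv <- if (is.null(rn)) NULL else g(rn)
    reaction_step(reac, prod,
                  kf = f$value, kr = if (is.null(rv)) 0 else rv$value,
                  kf_name = fn, kr_name = rn,
                  kf_status = f$status,
                  kr_status = if (is.null(rv)) "fixed" else rv$status,
                  kf_ratio = f$ratio, kr_ratio = if (is.null(rv)) NULL else rv$ratio)
  }
  steps <- list(
    mk("SA", "SB", "k1", "km1"),
    mk(c("E", "SA"), "ES", "k2", "km2"),
    mk(c("E", "SB"), "ES", "k3", "km3"),
    mk(c("ES", "O2"), "ESO2", "k4"),
    mk("ESO2", "ESQ", "k5"),
    mk("ESQ", "EI", "k6"),
    mk("ESQ", "ESQX", "k7"),
    mk("EI", "EP", "k8"),
    mk("EP", c("E", "P"), "k9"),
    mk("P", "PX", "k10", "km10"))
  m <- mechanism(species, steps, label = "single-turnover ring cleavage")
  attr(m, "conditions") <- list(pka = pka, ph = ph, e0 = e0, s0 = s0,
                                o2_0 = o2_0, binding_state = binding_state)
  m
}

#' @export
print.edx_mechanism <- function(x, ...) {
  cat("Mass-action mechanism", if (nzchar(x$label)) paste0("(", x$label, ")"),
      "\n")
  cat(nrow(x$species), "species,", length(x$steps), "steps\n")
  kk <- rate_constants(x)
  for (st in x$steps) {
    arrow <- if (!is.null(st$kr_name) || st$kr > 0) "<->" else "->"
    cat(sprintf("  %s %s %s   %s=%.4g", paste(st$reactants, collapse = " + "),
                arrow, paste(st$products, collapse = " + "),
                st$kf_name, kk[st$kf_name]))
    if (!is.null(st$kr_name)) cat(sprintf("  %s=%.4g", st$kr_name, kk[st$kr_name]))
    cat(sprintf("  [%s/%s]\n", st$kf_status,
                if (is.null(st$kr_name)) "-" else st$kr_status))
  }
  invisible(x)
}

#' Names of the free (fittable) rate constants of a mechanism
#' @param mech an `edx_mechanism`.
#' @return character vector.
#' @export
free_rate_constants <- function(mech) {
  out <- character()
  for (st in mech$steps) {
    if (st$kf_status == "free") out <- c(out, st$kf_name)
    if (!is.null(st$kr_name) && st$kr_status == "free") out <- c(out, st$kr_name)
  }
  out
}
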