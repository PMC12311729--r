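# CSV dialects, FASTA input, mechanism serialization, bundled reference
# tables, and report assembly. All files are plain text with '.' decimals;
# numeric values are written with 17 significant digits so that write ->
# read round-trips are lossless.

.fmt <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

.meta_fields <- c("wavelength", "ph", "temperature", "enzyme", "substrate",
                  "o2", "pathlength", "n_averaged")

#' Write / read a kinetic trace CSV
#'
#' Dialect: `#`-prefixed metadata header lines (`# key: value`), then a
#' header row `time_s,absorbance` and one row per point.
#'
#' @param trace a [kinetic_trace()].
#' @param path file path.
#' @return `read_trace_csv` returns a [kinetic_trace()];
#'   `write_trace_csv` returns `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "edx_trace"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# edxkin kinetic trace", con)
  for (f in .meta_fields) {
    writeLines(sprintf("# %s: %s", f, .fmt(trace$meta[[f]])), con)
  }
  writeLines("time_s,absorbance", con)
  writeLines(paste(.fmt(trace$times), .fmt(trace$absorbance), sep = ","), con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (f in .meta_fields) {
    m <- grep(paste0("^# ", f, ": "), hdr, value = TRUE)
    if (length(m)) meta[[f]] <- as.numeric(sub(paste0("^# ", f, ": "), "", m[1]))
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2 || body[1] != "time_s,absorbance") {
    stop("malformed trace CSV (expected 'time_s,absorbance' header): ", path,
         call. = FALSE)
  }
  df <- utils::read.csv(text = body)
  bad <- which(!is.finite(df$time_s) | !is.finite(df$absorbance))
  if (length(bad)) {
    stop("malformed rows (line ",
         paste(bad + length(hdr) + 1, collapse = ", "), ") in ", path,
         call. = FALSE)
  }
  if (any(diff(df$time_s) <= 0)) {
    stop("non-monotone time column in ", path, call. = FALSE)
  }
  kinetic_trace(df$time_s, df$absorbance,
                wavelength = meta$wavelength %||% NA_real_,
                ph = meta$ph %||% NA_real_,
                temperature = meta$temperature %||% NA_real_,
                enzyme = meta$enzyme %||% NA_real_,
                substrate = meta$substrate %||% NA_real_,
                o2 = meta$o2 %||% NA_real_,
                pathlength = meta$pathlength %||% 1,
                n_averaged = as.integer(meta$n_averaged %||% 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a titration plate (pair of CSVs)
#'
#' Dialect: first column `wavelength_nm`, remaining columns one per
#' buffer, labelled by pH value. The blank file has the same shape.
#'
#' @param data an [titration_dataset()].
#' @param data_path,blank_path paths for the compound and blank matrices.
#' @param compound_concentration uM (for `read_plate_csv`).
#' @return `read_plate_csv` returns an [titration_dataset()].
#' @export
write_plate_csv <- function(data, data_path, blank_path) {
  stopifnot(inherits(data, "edx_titration"))
  wr <- function(M, path) {
    df <- data.frame(wavelength_nm = data$wavelengths)
    for (j in seq_along(data$ph)) df[[.fmt(data$ph[j])]] <- M[, j]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  wr(data$absorbance, data_path)
  wr(data$blank, blank_path)
  invisible(data_path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(data_path, blank_path,
                           compound_concentration = 200) {
  rd <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    if (!nrow(df)) stop("empty file: ", path, call. = FALSE)
    if (names(df)[1] != "wavelength_nm") {
      stop("first column must be 'wavelength_nm' in ", path, call. = FALSE)
    }
    ph_labels <- names(df)[-1]
    dup <- ph_labels[duplicated(ph_labels)]
    if (length(dup)) {
      stop("duplicated pH column '", dup[1], "' in ", path, call. = FALSE)
    }
    if (anyNA(as.matrix(df))) stop("ragged or non-numeric matrix in ", path,
                                   call. = FALSE)
    df
  }
  d <- rd(data_path); b <- rd(blank_path)
  if (!identical(dim(d), dim(b)) || !identical(names(d), names(b))) {
    stop("blank matrix shape does not match the data matrix", call. = FALSE)
  }
  titration_dataset(d$wavelength_nm, as.numeric(names(d)[-1]),
                    as.matrix(d[, -1]), as.matrix(b[, -1]),
                    compound_concentration)
}

#' Write / read an initial-rate CSV
#'
#' Dialect: metadata header lines, then `substrate_uM,rate_uM_per_min`.
#'
#' @param data an [rate_dataset()].
#' @param path file path.
#' @return `read_rates_csv` returns an [rate_dataset()].
#' @export
write_rates_csv <- function(data, path) {
  stopifnot(inherits(data, "edx_rates"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# edxkin rates",
               sprintf("# enzyme_uM: %s", .fmt(data$e0)),
               sprintf("# varied_substrate: %s", data$varied_substrate),
               sprintf("# temperature: %s", .fmt(data$temperature)),
               "substrate_uM,rate_uM_per_min",
               paste(.fmt(data$s), .fmt(data$rate), sep = ",")), con)
  invisible(path)
}

#' @rdname write_rates_csv
#' @export
read_rates_csv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  gv <- function(key, default = NA) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, ": "), "", m[1]) else default
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!all(c("substrate_uM", "rate_uM_per_min") %in% names(df))) {
    stop("rates CSV needs columns substrate_uM, rate_uM_per_min", call. = FALSE)
  }
  rate_dataset(df$substrate_uM, df$rate_uM_per_min,
               enzyme_concentration = as.numeric(gv("enzyme_uM", "1")),
               varied_substrate = gv("varied_substrate", "catechol"),
               temperature = as.numeric(gv("temperature", "22")))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             seqonly = FALSE)
  stats::setNames(toupper(vapply(seqs, function(s) as.character(s)[1],
                                 character(1))),
                  vapply(seqs, function(s) attr(s, "name"), character(1)))
}

# ---- mechanism serialization -------------------------------------------

.fmt_side <- function(name, status, ratio, value) {
  st <- if (status == "ratio_linked") {
    sprintf("ratio_linked(%s,%s)", ratio$partner, .fmt(ratio$ratio))
  } else status
  sprintf("%s:%s=%s", name, st, .fmt(value))
}

#' Write / read a mechanism as a plain-text reaction list
#'
#' Format: a `[species]` block (`name,conc0[,enzyme_tag,substrate_tag,active]`
#' CSV) followed by a `[steps]` block with one line per step:
#' `A + B -> C ; kf=<name>:<status>=<value> ; kr=<name>:<status>=<value>`,
#' where `<status>` is a status keyword, possibly
#' `ratio_linked(partner,ratio)`. Round-trips are lossless.
#'
#' @param mech an `edx_mechanism`.
#' @param path file path.
#' @return `read_mechanism` returns an `edx_mechanism`.
#' @export
write_mechanism <- function(mech, path) {
  stopifnot(inherits(mech, "edx_mechanism"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# edxkin mechanism: %s", mech$label), con)
  writeLines("[species]", con)
  sp <- mech$species
  extra <- intersect(c("enzyme_tag", "substrate_tag", "active"), names(sp))
  writeLines(paste(c("name", "conc0", extra), collapse = ","), con)
  for (i in seq_len(nrow(sp))) {
    writeLines(paste(c(sp$name[i], .fmt(sp$conc0[i]),
                       vapply(extra, function(e) .fmt(sp[[e]][i]), "")),
                     collapse = ","), con)
  }
  writeLines("[steps]", con)
  for (st in mech$steps) {
    parts <- c(paste(paste(st$reactants, collapse = " + "), "->",
                     paste(st$products, collapse = " + ")),
               paste0("kf=", .fmt_side(st$kf_name, st$kf_status,
                                       st$kf_ratio, st$kf)))
    if (!is.null(st$kr_name)) {
      parts <- c(parts, paste0("kr=", .fmt_side(st$kr_name, st$kr_status,
                                                st$kr_ratio, st$kr)))
    }
    writeLines(paste(parts, collapse = " ; "), con)
  }
  invisible(path)
}

.parse_side <- function(txt) {
  m <- regmatches(txt, regexec(
    "^([A-Za-z0-9_]+):([a-z_]+)(\\(([A-Za-z0-9_]+),([-+0-9.eE]+)\\))?=(.+)$",
    txt))[[1]]
  if (!length(m)) stop("cannot parse rate-constant spec: ", txt, call. = FALSE)
  ratio <- if (nzchar(m[4])) list(partner = m[5], ratio = as.numeric(m[6]))
  list(name = m[2], status = m[3], ratio = ratio, value = as.numeric(m[7]))
}

#' @rdname write_mechanism
#' @export
read_mechanism <- function(path) {
  lines <- readLines(path)
  label <- sub("^# edxkin mechanism: ?", "",
               grep("^# edxkin mechanism", lines, value = TRUE)[1])
  if (is.na(label)) label <- ""
  isp <- which(lines == "[species]"); ist <- which(lines == "[steps]")
  if (length(isp) != 1 || length(ist) != 1 || ist < isp) {
    stop("mechanism file needs [species] then [steps] blocks", call. = FALSE)
  }
  sp <- utils::read.csv(text = lines[(isp + 1):(ist - 1)])
  steps <- list()
  for (ln in lines[(ist + 1):length(lines)]) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- trimws(strsplit(ln, ";", fixed = TRUE)[[1]])
    rx <- strsplit(parts[1], "->", fixed = TRUE)[[1]]
    if (length(rx) != 2) stop("malformed step line: ", ln, call. = FALSE)
    reactants <- trimws(strsplit(rx[1], "+", fixed = TRUE)[[1]])
    products <- trimws(strsplit(rx[2], "+", fixed = TRUE)[[1]])
    kf <- kr <- NULL
    for (p in parts[-1]) {
      if (startsWith(p, "kf=")) kf <- .parse_side(sub("^kf=", "", p))
      if (startsWith(p, "kr=")) kr <- .parse_side(sub("^kr=", "", p))
    }
    if (is.null(kf)) stop("step without kf: ", ln, call. = FALSE)
    steps[[length(steps) + 1]] <- reaction_step(
      reactants, products,
      kf = kf$value, kr = if (is.null(kr)) 0 else kr$value,
      kf_name = kf$name, kr_name = if (is.null(kr)) NULL else kr$name,
      kf_status = kf$status,
      kr_status = if (is.null(kr)) "fixed" else kr$status,
      kf_ratio = kf$ratio, kr_ratio = if (is.null(kr)) NULL else kr$ratio)
  }
  mechanism(sp, steps, label = label)
}

#' Write a generator's ground truth as a JSON sidecar
#'
#' Serializes the scalar ground-truth parameters recorded by the
#' synthetic-data generators (objects such as mechanisms or trajectories
#' are dropped) so a test suite can recover them next to the data files.
#'
#' @param x an object with a `ground_truth` attribute.
#' @param path output JSON path.
#' @export
write_ground_truth <- function(x, path) {
  gt <- attr(x, "ground_truth")
  if (is.null(gt)) stop("object carries no ground_truth attribute", call. = FALSE)
  keep <- Filter(function(v) is.numeric(v) || is.character(v) || is.logical(v),
                 gt)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- bundled reference tables ------------------------------------------

#' Bundled reference measurements for the catechol substrate series
#'
#' Small plain-text tables shipped with the package: measured anodic and
#' cathodic peak potentials at pH 6.0 and 7.4 (`"cv_peaks"`),
#' spectrophotometric pKa values (`"pka_values"`), and steady-state
#' constants for two L-DOPA 2,3-dioxygenase homologues
#' (`"mm_constants"`) for L-DOPA, dopamine, DHHCA and its 6-substituted
#' derivatives. They serve as worked-example inputs and as fixtures for
#' the arithmetic cross-checks in the test suite.
#'
#' @param name one of `"cv_peaks"`, `"pka_values"`, `"mm_constants"`.
#' @return a data.frame.
#' @export
edx_reference <- function(name = c("cv_peaks", "pka_values", "mm_constants")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "edxkin",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}

# ---- report assembly ----------------------------------------------------

#' Assemble result tables
#'
#' `report_mm`, `report_pka` and `report_transient` shape individual fit
#' objects into one-row (or long) data.frames mirroring the conventional
#' presentation: KM/kcat with the specificity constant on the x10^2
#' uM^-1 min^-1 display scale; pKa with its standard error; fitted
#' transient parameters with their FitSpace ranges. `assemble_report`
#' writes each non-empty table as CSV into a directory.
#'
#' @param fit an `edx_mm`, `edx_pka_fit`, or `edx_fit`.
#' @param compound,homologue annotation columns.
#' @param fitspaces optional named list of `edx_fitspace` objects keyed by
#'   parameter name (for `report_transient`).
#' @return a data.frame.
#' @export
report_mm <- function(fit, compound = NA_character_,
                      homologue = NA_character_) {
  stopifnot(inherits(fit, "edx_mm"))
  data.frame(compound = compound, homologue = homologue,
             km_uM = fit$km, km_se = fit$se$km,
             kcat_s = fit$kcat, kcat_se = fit$se$kcat,
             ksp_uM_min = fit$ksp, ksp_x100 = 100 * fit$ksp,
             parameterization = fit$parameterization,
             extrapolated = fit$extrapolated)
}

#' @rdname report_mm
#' @export
report_pka <- function(fit, compound = NA_character_) {
  stopifnot(inherits(fit, "edx_pka_fit"))
  data.frame(compound = compound, pka = fit$pka, pka_se = fit$se,
             lambda_positive = fit$lambda_positive %||% NA_real_,
             lambda_negative = fit$lambda_negative %||% NA_real_)
}

#' @rdname report_mm
#' @export
report_transient <- function(fit, fitspaces = list()) {
  stopifnot(inherits(fit, "edx_fit"))
  rows <- lapply(names(fit$par), function(nm) {
    lo <- hi <- NA_real_
    for (fs in fitspaces) {
      if (nm %in% names(fs$intervals)) {
        lo <- fs$intervals[[nm]][1]; hi <- fs$intervals[[nm]][2]
      }
    }
    data.frame(parameter = nm, value = fit$par[[nm]],
               fitspace_low = lo, fitspace_high = hi,
               plus_minus = if (is.na(lo)) NA_real_ else (hi - lo) / 2)
  })
  out <- do.call(rbind, rows)
  out$sse <- fit$sse
  out$converged <- fit$converged
  out
}

#' @rdname report_mm
#' @param tables named list of data.frames.
#' @param dir output directory (created if needed).
#' @export
assemble_report <- function(tables, dir) {
  stopifnot(is.list(tables))
  tables <- Filter(function(x) is.data.frame(x) && nrow(x) > 0, tables)
  if (!length(tables)) {
    warning("no completed stages: empty report")
    return(invisible(character(0)))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
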