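# Run configuration, deterministic report writers and the analytic oracle
# cases used by the invariant test suites.

.default_config <- list(
  structure = "baseline",
  metal = "Ag",
  n_a = 1.335,
  wavelength = list(start = 750, stop = 1100, step = 0.1),
  theta = 0,
  polarization = "TE",
  output = "."
)

#' Load and validate a run configuration
#'
#' YAML with keys `structure` (builder name `"baseline"`/`"enhanced"` or a
#' stack file path under `stack_file`), `metal`, `n_a` (scalar or list),
#' `wavelength` (`start`, `stop`, `step` in nm), `theta` (degrees, scalar or
#' list), `polarization`, `output`. Missing keys take defaults
#' (theta = 0, TE, 750-1100 nm at 0.1 nm). Schema violations error naming
#' the field.
#'
#' @param path Path to the YAML configuration.
#' @return Validated config list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg <- utils::modifyList(.default_config, cfg)
  validate_config(cfg)
}

#' Validate a configuration list
#'
#' @param cfg Configuration list (see [load_config()]).
#' @return The config, classed `run_config`, or an error naming the field.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, expected)
    stop(sprintf("config field '%s': expected %s", field, expected),
         call. = FALSE)
  if (is.null(cfg$stack_file)) {
    if (!is.character(cfg$structure) ||
        !cfg$structure %in% c("baseline", "enhanced"))
      fail("structure", "'baseline' or 'enhanced' (or provide stack_file)")
    if (!cfg$metal %in% c("Ag", "Au", "Cu")) fail("metal", "Ag, Au or Cu")
  } else if (!is.character(cfg$stack_file)) {
    fail("stack_file", "a file path")
  }
  if (!is.numeric(unlist(cfg$n_a)) || any(unlist(cfg$n_a) < 1))
    fail("n_a", "numeric >= 1")
  w <- cfg$wavelength
  if (!is.list(w) || !all(c("start", "stop", "step") %in% names(w)))
    fail("wavelength", "a map with start, stop, step")
  if (!is.numeric(w$start) || !is.numeric(w$stop) || !is.numeric(w$step) ||
      w$start >= w$stop || w$step <= 0)
    fail("wavelength", "numeric start < stop and step > 0")
  th <- unlist(cfg$theta)
  if (!is.numeric(th) || any(th < 0) || any(th >= 90))
    fail("theta", "numeric in [0, 90)")
  if (!all(unlist(cfg$polarization) %in% c("TE", "TM")))
    fail("polarization", "TE or TM")
  structure(cfg, class = c("run_config", "list"))
}

#' Save a configuration
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 17)
  invisible(path)
}

#' Resolve the stack described by a configuration
#'
#' @param cfg A `run_config`.
#' @param n_a Optional analyte index overriding the config's first value.
#' @return A [stack_spec()].
#' @export
config_stack <- function(cfg, n_a = NULL) {
  if (!is.null(cfg$stack_file)) return(read_stack(cfg$stack_file))
  na <- if (is.null(n_a)) unlist(cfg$n_a)[1] else n_a
  if (cfg$structure == "baseline") build_baseline(na, metal = cfg$metal)
  else build_enhanced(na)
}

#' Wavelength grid of a configuration
#' @param cfg A `run_config`.
#' @return Numeric grid in nm.
#' @export
config_grid <- function(cfg) {
  w <- cfg$wavelength
  seq(w$start, w$stop, by = w$step)
}

# fixed float formatting: 3 decimals for nm quantities and metrics,
# 6 significant digits elsewhere
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.3f", x))
}

#' Write a result table as deterministic delimited text
#'
#' Writes a `#`-commented metadata header followed by tab-separated values
#' with fixed 3-decimal float formatting, so identical inputs give
#' byte-identical files. JSON output uses sorted keys and the same rounding.
#'
#' @param x Data frame (spectra, mode tables, sweeps, sensing reports).
#' @param path Output file.
#' @param format `"csv"` (delimited text) or `"json"`.
#' @param metadata Named character vector written into the header.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("csv", "json"),
                         metadata = character(0)) {
  format <- match.arg(format)
  x <- as.data.frame(x)
  if (format == "json") {
    num <- vapply(x, is.numeric, TRUE)
    x[num] <- lapply(x[num], round, digits = 3)
    x <- x[, order(names(x)), drop = FALSE]
    obj <- list(metadata = as.list(metadata), rows = x)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(path))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(metadata))
    writeLines(sprintf("# %s: %s", nm, metadata[[nm]]), con)
  writeLines(paste(names(x), collapse = "\t"), con)
  if (nrow(x)) {
    cols <- lapply(x, function(col) {
      if (is.numeric(col)) .fmt_num(col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Standard metadata header for a physics run
#'
#' Records the stack fingerprint and the metal-table provenance and
#' interpolation scheme, so any written spectrum states how its metal
#' indices were obtained.
#'
#' @param stack A [stack_spec()].
#' @param theta_deg,pol Evaluation condition.
#' @return Named character vector for [write_report()]'s `metadata`.
#' @export
run_metadata <- function(stack, theta_deg = 0, pol = "TE") {
  tabs <- Filter(Negate(is.null), lapply(stack$layers, function(l) {
    m <- l$material$model
    if (inherits(m, "tabulated_nk"))
      sprintf("%s [%s; %s]", l$material$name, m$provenance, m$scheme)
    else NULL
  }))
  c(generator = "tammsensor",
    stack = sprintf("%d layers, %s|...|%s, analyte n=%s",
                    length(stack$layers), stack$incident_medium$name,
                    stack$exit_medium$name,
                    format(stack$analyte_index)),
    theta_deg = format(theta_deg), polarization = pol,
    material_tables = if (length(tabs)) paste(unique(unlist(tabs)),
                                              collapse = "; ") else "none")
}

# --- analytic oracles ------------------------------------------------------

#' Closed-form Fresnel intensity coefficients of a single interface
#'
#' Independent of the transfer-matrix code path; used as an oracle.
#'
#' @param n1,n2 Real indices of the two media.
#' @param theta_deg Incidence angle in medium 1, degrees.
#' @param pol `"TE"` or `"TM"`.
#' @return List with `R` and `T` (power coefficients).
#' @export
fresnel_rt <- function(n1, n2, theta_deg = 0, pol = c("TE", "TM")) {
  pol <- match.arg(pol)
  th1 <- theta_deg * pi / 180
  s2 <- n1 * sin(th1) / n2
  th2 <- asin(s2)
  if (pol == "TE") {
    r <- (n1 * cos(th1) - n2 * cos(th2)) / (n1 * cos(th1) + n2 * cos(th2))
  } else {
    r <- (n2 * cos(th1) - n1 * cos(th2)) / (n2 * cos(th1) + n1 * cos(th2))
  }
  R <- r^2
  list(R = R, T = 1 - R)
}

#' Closed-form Airy reflectance of a single lossless layer
#'
#' Two-beam-summation (Airy) formula for a slab of index n2 and thickness
#' d_nm between media n1 and n3, normal incidence; independent oracle for
#' the etalon tests.
#'
#' @param n1,n2,n3 Real indices.
#' @param d_nm Slab thickness, nm.
#' @param lambda_nm Wavelength(s), nm.
#' @return Reflectance vector.
#' @export
airy_reflectance <- function(n1, n2, n3, d_nm, lambda_nm) {
  r12 <- (n1 - n2) / (n1 + n2)
  r23 <- (n2 - n3) / (n2 + n3)
  delta <- 2 * pi * n2 * d_nm / lambda_nm
  r <- (r12 + r23 * exp(2i * delta)) / (1 + r12 * r23 * exp(2i * delta))
  Mod(r)^2
}

#' Synthetic Lorentzian reflectance dip
#'
#' R(lambda) = baseline - depth / (1 + (2 (lambda - lambda0)/fwhm)^2), a
#' closed-form generator whose stated lambda0 and FWHM the dip finder must
#' recover.
#'
#' @param lambda_nm Wavelength grid.
#' @param lambda0_nm Dip centre.
#' @param fwhm_nm Full width at half depth.
#' @param depth Dip depth below the baseline.
#' @param baseline Plateau reflectance.
#' @return A `spectral_result`-shaped data frame (no stack attached).
#' @export
lorentzian_dip <- function(lambda_nm, lambda0_nm, fwhm_nm, depth = 0.9,
                           baseline = 1.0) {
  R <- baseline - depth / (1 + (2 * (lambda_nm - lambda0_nm) / fwhm_nm)^2)
  res <- data.frame(wavelength_nm = lambda_nm, R = R, T = 1 - R,
                    A = 0 * lambda_nm)
  class(res) <- c("spectral_result", "data.frame")
  res
}

#' Analytic oracle cases
#'
#' The closed-form cases exercised by the invariant suites: a bare Fresnel
#' interface, a lossless etalon with its Airy curve and free spectral range,
#' a small lossless quarter-wave Bragg mirror (energy-conservation case) and
#' a synthetic Lorentzian dip. Each entry carries its generator, the
#' closed-form answer and the tolerance at which the transfer-matrix path
#' must agree.
#'
#' @return Named list of oracle-case lists.
#' @export
generate_oracles <- function() {
  lib <- material_library()
  glass <- lib$glass; air <- lib$air
  n2 <- 1.8; d <- 300
  center <- 2 * n2 * d  # half-wave resonance of the etalon, nm
  list(
    fresnel = list(
      name = "single interface air/glass",
      stack = stack_spec(air, list(), glass),
      closed_form = function(theta_deg = 0, pol = "TE")
        fresnel_rt(1.0, 1.5, theta_deg, pol),
      tolerance = 1e-10),
    etalon = list(
      name = "lossless single-layer etalon",
      stack = stack_spec(air, list(layer(material("slab", constant_index(n2)),
                                         d)), air),
      closed_form = function(lambda_nm) airy_reflectance(1, n2, 1, d,
                                                         lambda_nm),
      resonance_nm = center,
      fsr_nm = center^2 / (2 * n2 * d),
      tolerance = 1e-8),
    dbr = list(
      name = "lossless 5-period quarter-wave mirror at 800 nm",
      stack = stack_spec(glass, {
        hi <- material("hi", constant_index(2.3))
        lo <- material("lo", constant_index(1.45))
        ls <- list()
        for (i in 1:5) ls <- c(ls, list(layer(hi, 800 / 4 / 2.3),
                                        layer(lo, 800 / 4 / 1.45)))
        ls
      }, glass),
      tolerance = 1e-10),
    lorentzian = list(
      name = "synthetic Lorentzian dip",
      lambda0_nm = 900, fwhm_nm = 2,
      generator = function(grid = seq(880, 920, by = 0.05))
        lorentzian_dip(grid, 900, 2),
      tolerance = 1e-3)
  )
}
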