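#' Cauchy dispersion model
#'
#' Describes a transparent dielectric by the standard Cauchy relation
#' \deqn{n(\lambda) = A + B/\lambda^2 + C/\lambda^4,}
#' with \eqn{\lambda} in micrometres. The third coefficient may be negative.
#' Evaluation is restricted to `valid_range`; outside it the model errors
#' rather than extrapolating.
#'
#' @param A Dimensionless limiting index.
#' @param B Coefficient of \eqn{1/\lambda^2}, in \eqn{\mu m^2}.
#' @param C Coefficient of \eqn{1/\lambda^4}, in \eqn{\mu m^4}.
#' @param valid_range Length-2 numeric, wavelength validity window in
#'   micrometres. Defaults to 0.30--1.25.
#' @return An object of class `cauchy_model`.
#' @examples
#' tio2 <- cauchy_model(2.39513, 0.03471, -0.00835)
#' cauchy_index(tio2, 1)   # 2.42149
#' @export
cauchy_model <- function(A, B, C, valid_range = c(0.30, 1.25)) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C),
            length(valid_range) == 2, valid_range[1] < valid_range[2])
  structure(list(A = A, B = B, C = C, valid_range = as.numeric(valid_range)),
            class = "cauchy_model")
}

#' Evaluate a Cauchy model
#'
#' @param model A [cauchy_model()].
#' @param lambda_um Vacuum wavelength(s) in micrometres.
#' @param name Material name used in range-error messages.
#' @return Real refractive index, same length as `lambda_um`.
#' @export
cauchy_index <- function(model, lambda_um, name = "material") {
  stopifnot(inherits(model, "cauchy_model"))
  rng <- model$valid_range
  if (any(lambda_um < rng[1] - 1e-12 | lambda_um > rng[2] + 1e-12)) {
    stop(sprintf(
      "wavelength %.4g um outside the validity range [%.3g, %.3g] um of %s",
      lambda_um[which(lambda_um < rng[1] | lambda_um > rng[2])[1]],
      rng[1], rng[2], name), call. = FALSE)
  }
  model$A + model$B / lambda_um^2 + model$C / lambda_um^4
}

#' Tabulated complex refractive index
#'
#' Holds (wavelength, n, kappa) rows for an absorbing medium, e.g. a noble
#' metal. Rows must be strictly increasing in wavelength and kappa must be
#' non-negative (passive medium). Interpolation between rows uses
#' monotone-preserving piecewise-cubic splines (Fritsch--Carlson), fitted
#' separately to n and kappa; the scheme is recorded so that downstream
#' output can state it. Evaluation outside the tabulated span is an error.
#'
#' @param lambda_um Strictly increasing wavelengths, micrometres.
#' @param n Real part of the refractive index.
#' @param k Imaginary part (extinction coefficient), must be >= 0.
#' @param provenance Character tag identifying the data source.
#' @return An object of class `tabulated_nk`.
#' @export
tabulated_nk <- function(lambda_um, n, k, provenance = "unspecified") {
  stopifnot(length(lambda_um) >= 2,
            length(n) == length(lambda_um), length(k) == length(lambda_um))
  if (any(diff(lambda_um) <= 0))
    stop("tabulated wavelengths must be strictly increasing", call. = FALSE)
  if (any(k < 0))
    stop("extinction coefficient must be >= 0 (passive medium)", call. = FALSE)
  structure(list(lambda_um = as.numeric(lambda_um),
                 n = as.numeric(n), k = as.numeric(k),
                 provenance = provenance,
                 scheme = "monotone-cubic (Fritsch-Carlson)",
                 fn = stats::splinefun(lambda_um, n, method = "monoH.FC"),
                 fk = stats::splinefun(lambda_um, k, method = "monoH.FC")),
            class = "tabulated_nk")
}

#' Read a 3-column n/k table file
#'
#' Expects whitespace- or tab-delimited columns `lambda_um n k`, with comment
#' lines starting `#`. A `# provenance:` comment line, when present, is used
#' as the provenance tag.
#'
#' @param path File path.
#' @param provenance Optional provenance override.
#' @return A [tabulated_nk()] object.
#' @export
read_nk_table <- function(path, provenance = NULL) {
  lines <- readLines(path)
  if (is.null(provenance)) {
    pv <- grep("^#\\s*provenance:", lines, value = TRUE)
    provenance <- if (length(pv)) trimws(sub("^#\\s*provenance:", "", pv[1])) else path
  }
  d <- utils::read.table(text = lines, comment.char = "#",
                         col.names = c("lambda_um", "n", "k"))
  tabulated_nk(d$lambda_um, d$n, d$k, provenance = provenance)
}

#' Interpolate a tabulated index
#'
#' @param table A [tabulated_nk()].
#' @param lambda_um Wavelength(s) in micrometres, inside the tabulated span.
#' @param name Material name used in range-error messages.
#' @return Complex refractive index n + i*kappa.
#' @export
tabulated_index <- function(table, lambda_um, name = "material") {
  stopifnot(inherits(table, "tabulated_nk"))
  lo <- table$lambda_um[1]; hi <- table$lambda_um[length(table$lambda_um)]
  if (any(lambda_um < lo - 1e-12 | lambda_um > hi + 1e-12)) {
    stop(sprintf(
      "wavelength %.4g um outside the tabulated span [%.4g, %.4g] um of %s",
      lambda_um[which(lambda_um < lo | lambda_um > hi)[1]], lo, hi, name),
      call. = FALSE)
  }
  complex(real = table$fn(lambda_um), imaginary = pmax(table$fk(lambda_um), 0))
}

#' Constant complex index
#'
#' @param n Real part of the refractive index.
#' @param k Extinction coefficient, >= 0. Default 0 (lossless).
#' @return An object of class `constant_index`.
#' @export
constant_index <- function(n, k = 0) {
  stopifnot(is.numeric(n), is.numeric(k), k >= 0)
  structure(list(n = n, k = k), class = "constant_index")
}

#' Material: a named dispersion rule
#'
#' @param name Material name.
#' @param model One of [cauchy_model()], [tabulated_nk()] or
#'   [constant_index()].
#' @return An object of class `material`.
#' @export
material <- function(name, model) {
  stopifnot(is.character(name), length(name) == 1,
            inherits(model, c("cauchy_model", "tabulated_nk", "constant_index")))
  structure(list(name = name, model = model), class = "material")
}

#' Complex refractive index of a material
#'
#' @param mat A [material()].
#' @param lambda_um Wavelength(s) in micrometres.
#' @return Complex index n + i*kappa (imaginary part 0 for lossless models).
#' @export
material_index <- function(mat, lambda_um) {
  stopifnot(inherits(mat, "material"))
  m <- mat$model
  if (inherits(m, "cauchy_model"))
    complex(real = cauchy_index(m, lambda_um, name = mat$name), imaginary = 0)
  else if (inherits(m, "tabulated_nk"))
    tabulated_index(m, lambda_um, name = mat$name)
  else
    complex(real = rep(m$n, length(lambda_um)),
            imaginary = rep(m$k, length(lambda_um)))
}

#' Complex relative permittivity of a material
#'
#' Uses the fields-proportional-to exp(-i omega t) convention, under which a
#' passive medium has kappa >= 0 and Im(epsilon) >= 0, with
#' epsilon = (n + i*kappa)^2.
#'
#' @inheritParams material_index
#' @return Complex permittivity, same length as `lambda_um`.
#' @export
permittivity <- function(mat, lambda_um) {
  material_index(mat, lambda_um)^2
}

#' Built-in noble-metal optical constants
#'
#' Loads the vendored Johnson & Christy (1972) n/k tables for Ag, Au or Cu
#' (0.58--1.94 um) shipped with the package.
#'
#' @param metal One of `"Ag"`, `"Au"`, `"Cu"`.
#' @return A [material()] with a tabulated model.
#' @export
jc_metal <- function(metal = c("Ag", "Au", "Cu")) {
  metal <- match.arg(metal)
  path <- system.file("extdata",
                      sprintf("johnson_christy_%s.tsv", tolower(metal)),
                      package = "tammsensor", mustWork = TRUE)
  material(metal, read_nk_table(path))
}

#' Default material library
#'
#' The dielectrics of the sensor stacks: TiO2 (high index, H) and SiO2
#' (low index, L) by their Cauchy fits valid over 0.30--1.25 um, the three
#' noble metals by tabulated Johnson & Christy data, plus non-dispersive
#' glass (n = 1.5) and air (n = 1).
#'
#' @return Named list of [material()] objects.
#' @export
material_library <- function() {
  list(
    TiO2  = material("TiO2", cauchy_model(2.39513, 0.03471, -0.00835)),
    SiO2  = material("SiO2", cauchy_model(1.46705, 0.00364, -3.049e-6)),
    Ag    = jc_metal("Ag"),
    Au    = jc_metal("Au"),
    Cu    = jc_metal("Cu"),
    glass = material("glass", constant_index(1.5)),
    air   = material("air", constant_index(1.0))
  )
}

#' Load a material library from a structured-text file
#'
#' The file is YAML mapping material name to one of
#' `{cauchy: [A, B, C]}`, `{table: path}` or `{constant: [n, k]}`.
#' Table paths are resolved relative to the library file.
#'
#' @param path Path to the YAML library file.
#' @return Named list of [material()] objects.
#' @export
read_material_library <- function(path) {
  spec <- yaml::read_yaml(path)
  base <- dirname(path)
  out <- lapply(names(spec), function(nm) {
    entry <- spec[[nm]]
    if (!is.null(entry$cauchy)) {
      cf <- as.numeric(entry$cauchy)
      if (length(cf) != 3) stop(sprintf("material %s: cauchy needs [A,B,C]", nm))
      rng <- if (!is.null(entry$valid_range)) as.numeric(entry$valid_range) else c(0.30, 1.25)
      material(nm, cauchy_model(cf[1], cf[2], cf[3], rng))
    } else if (!is.null(entry$table)) {
      p <- entry$table
      if (!file.exists(p)) p <- file.path(base, entry$table)
      material(nm, read_nk_table(p))
    } else if (!is.null(entry$constant)) {
      cv <- as.numeric(entry$constant)
      material(nm, constant_index(cv[1], if (length(cv) > 1) cv[2] else 0))
    } else {
      stop(sprintf("material %s: need one of cauchy/table/constant", nm),
           call. = FALSE)
    }
  })
  names(out) <- names(spec)
  out
}

#' @export
print.material <- function(x, ...) {
  m <- x$model
  desc <- if (inherits(m, "cauchy_model")) {
    sprintf("Cauchy A=%.5f B=%.5g C=%.5g, valid %.2f-%.2f um",
            m$A, m$B, m$C, m$valid_range[1], m$valid_range[2])
  } else if (inherits(m, "tabulated_nk")) {
    sprintf("tabulated n/k, %d rows over %.3f-%.3f um [%s; %s]",
            length(m$lambda_um), m$lambda_um[1],
            m$lambda_um[length(m$lambda_um)], m$provenance, m$scheme)
  } else {
    sprintf("constant n = %g + %gi", m$n, m$k)
  }
  cat(sprintf("<material> %s: %s\n", x$name, desc))
  invisible(x)
}
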