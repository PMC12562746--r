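#' A single finite layer
#'
#' @param material A [material()].
#' @param thickness_nm Physical thickness in nanometres, strictly positive
#'   and finite.
#' @param role Optional semantic tag: `"dielectric"`, `"metal"` or
#'   `"analyte"`. Used by the resonance classifier to locate the analyte
#'   interval and the metal films.
#' @return An object of class `layer`.
#' @export
layer <- function(material, thickness_nm, role = "dielectric") {
  stopifnot(inherits(material, "material"),
            is.numeric(thickness_nm), length(thickness_nm) == 1,
            is.finite(thickness_nm), thickness_nm > 0)
  role <- match.arg(role, c("dielectric", "metal", "analyte"))
  structure(list(material = material, thickness_nm = thickness_nm,
                 role = role), class = "layer")
}

#' Layered-structure specification
#'
#' An ordered stack of finite layers between two semi-infinite media, indexed
#' from the incidence side. The coordinate origin z = 0 sits at the
#' incident-medium/first-layer interface, z increasing toward the exit
#' medium.
#'
#' @param incident_medium Semi-infinite [material()] on the incidence side.
#' @param layers List of [layer()] objects (may be empty).
#' @param exit_medium Semi-infinite [material()] on the exit side.
#' @param analyte_index Real refractive index of the analyte layer, if the
#'   stack has one (metadata; the analyte layer itself carries the value).
#' @return An object of class `stack_spec`.
#' @export
stack_spec <- function(incident_medium, layers, exit_medium,
                       analyte_index = NA_real_) {
  stopifnot(inherits(incident_medium, "material"),
            inherits(exit_medium, "material"),
            is.list(layers), all(vapply(layers, inherits, TRUE, "layer")))
  structure(list(incident_medium = incident_medium,
                 layers = layers,
                 exit_medium = exit_medium,
                 analyte_index = analyte_index),
            class = "stack_spec")
}

#' @export
print.stack_spec <- function(x, ...) {
  cat(sprintf("<stack_spec> %d finite layers, %s | ... | %s\n",
              length(x$layers), x$incident_medium$name, x$exit_medium$name))
  if (length(x$layers)) {
    d <- vapply(x$layers, `[[`, 0, "thickness_nm")
    nm <- vapply(x$layers, function(l) l$material$name, "")
    cat(sprintf("  total thickness %.0f nm: %s\n", sum(d),
                paste(sprintf("%s(%g)", nm, d), collapse = " ")))
  }
  if (!is.na(x$analyte_index))
    cat(sprintf("  analyte index n_a = %.4f\n", x$analyte_index))
  invisible(x)
}

#' Layer thicknesses of a stack
#' @param stack A [stack_spec()].
#' @return Numeric vector of thicknesses in nm.
#' @export
thicknesses <- function(stack) {
  vapply(stack$layers, `[[`, 0, "thickness_nm")
}

#' Interface coordinates of a stack
#' @param stack A [stack_spec()].
#' @return Cumulative z positions (nm) of all interfaces, starting at 0.
#' @export
z_breaks <- function(stack) {
  cumsum(c(0, thicknesses(stack)))
}

#' Index of the analyte layer within a stack
#' @param stack A [stack_spec()].
#' @return Integer position, or NA when the stack has no analyte layer.
#' @export
analyte_layer <- function(stack) {
  roles <- vapply(stack$layers, `[[`, "", "role")
  i <- which(roles == "analyte")
  if (length(i)) i[1] else NA_integer_
}

# shared geometry constants of the two sensor designs
.baseline_geometry <- list(d_H1 = 75, d_L1 = 130, d_Hp = 65, d_M = 30,
                           d_A = 1000, d_H2 = 100, d_L2 = 150, N = 6)
.enhanced_geometry <- list(d_H1 = 47, d_L1 = 60, d_Hp = 47, d_M = 60,
                           d_A = 1000, d_H2 = 120, d_L2 = 200, N = 6)

.build_sensor <- function(geom, n_a, metal, pc1_periods, pc1_trailing_L, ambient) {
  stopifnot(is.numeric(n_a), n_a >= 1)
  lib <- material_library()
  if (!metal %in% c("Ag", "Au", "Cu"))
    stop(sprintf("unknown metal '%s'; expected one of Ag, Au, Cu", metal),
         call. = FALSE)
  H <- lib$TiO2; L <- lib$SiO2; M <- lib[[metal]]
  amb <- if (is.character(ambient)) lib[[ambient]] else ambient
  ana <- material("analyte", constant_index(n_a))

  # PC1, incidence side: substrate -> (L H) periods -> terminal thinned H'
  # adjacent to the first metal film
  pc1 <- list()
  for (i in seq_len(pc1_periods)) {
    pc1 <- c(pc1, list(layer(L, geom$d_L1), layer(H, geom$d_H1)))
  }
  if (pc1_trailing_L) pc1 <- c(pc1, list(layer(L, geom$d_L1)))
  pc1 <- c(pc1, list(layer(H, geom$d_Hp)))

  # PC2, exit side: high-index layer adjacent to the second metal film
  pc2 <- list()
  for (i in seq_len(geom$N)) {
    pc2 <- c(pc2, list(layer(H, geom$d_H2), layer(L, geom$d_L2)))
  }

  layers <- c(pc1,
              list(layer(M, geom$d_M, role = "metal"),
                   layer(ana, geom$d_A, role = "analyte"),
                   layer(M, geom$d_M, role = "metal")),
              pc2)
  stack_spec(amb, layers, amb, analyte_index = n_a)
}

#' Build the baseline sensor stack
#'
#' Glass | PC1 | metal(30 nm) | analyte(1000 nm) | metal(30 nm) | PC2 | glass.
#' PC1 is a 12-layer mirror, (SiO2 130 / TiO2 75) x 5 periods followed by
#' SiO2 130 and a thinned terminal TiO2 layer of 65 nm adjacent to the metal
#' film; its quarter-wave design wavelength is 760 nm. PC2 is
#' (TiO2 100 / SiO2 150) x 6 with the high-index layer adjacent to the metal,
#' designed around 1000 nm. Light is incident from the PC1 side; both
#' semi-infinite media default to glass (n = 1.5).
#'
#' @param n_a Analyte refractive index (real, >= 1).
#' @param metal Metal film material: `"Ag"`, `"Au"` or `"Cu"`.
#' @param ambient Semi-infinite media: a library material name or a
#'   [material()]. Default `"glass"`.
#' @return A [stack_spec()] with 27 finite layers.
#' @export
build_baseline <- function(n_a = 1.335, metal = "Ag", ambient = "glass") {
  .build_sensor(.baseline_geometry, n_a, metal,
                pc1_periods = 5, pc1_trailing_L = TRUE, ambient = ambient)
}

#' Build the enhanced sensor stack
#'
#' Variant tuned for a sharper cavity resonance: PC1 is the 13-layer
#' (SiO2 60 / TiO2 47) x 6 + TiO2 47 mirror, PC2 uses TiO2 120 / SiO2 200,
#' and the Ag films are 60 nm. The analyte cavity stays at 1000 nm.
#'
#' @inheritParams build_baseline
#' @return A [stack_spec()] with 28 finite layers.
#' @export
build_enhanced <- function(n_a = 1.335, ambient = "glass") {
  .build_sensor(.enhanced_geometry, n_a, metal = "Ag",
                pc1_periods = 6, pc1_trailing_L = FALSE, ambient = ambient)
}

#' Piecewise refractive-index profile
#'
#' @param stack A [stack_spec()].
#' @param lambda_um Single wavelength in micrometres.
#' @return Data frame with one row per region (incident medium, each layer,
#'   exit medium): `z_from_nm`, `z_to_nm` (infinite for the media),
#'   `material`, complex `index`. The intervals partition the z axis.
#' @export
index_profile <- function(stack, lambda_um) {
  stopifnot(length(lambda_um) == 1)
  zb <- z_breaks(stack)
  nlay <- length(stack$layers)
  mats <- c(list(stack$incident_medium),
            lapply(stack$layers, `[[`, "material"),
            list(stack$exit_medium))
  idx <- vapply(mats, function(m) material_index(m, lambda_um), complex(1))
  data.frame(
    z_from_nm = c(-Inf, zb[seq_len(nlay)], zb[nlay + 1]),
    z_to_nm   = c(0, zb[-1], Inf),
    material  = vapply(mats, `[[`, "", "name"),
    index     = idx
  )
}

# --- serialization ---------------------------------------------------------

.model_to_list <- function(model) {
  if (inherits(model, "cauchy_model"))
    list(cauchy = c(model$A, model$B, model$C), valid_range = model$valid_range)
  else if (inherits(model, "tabulated_nk"))
    list(table_inline = list(lambda_um = model$lambda_um, n = model$n,
                             k = model$k, provenance = model$provenance))
  else
    list(constant = c(model$n, model$k))
}

.model_from_list <- function(x) {
  if (!is.null(x$cauchy))
    cauchy_model(x$cauchy[1], x$cauchy[2], x$cauchy[3],
                 if (is.null(x$valid_range)) c(0.30, 1.25) else x$valid_range)
  else if (!is.null(x$table_inline))
    tabulated_nk(x$table_inline$lambda_um, x$table_inline$n,
                 x$table_inline$k, x$table_inline$provenance)
  else
    constant_index(x$constant[1], x$constant[2])
}

#' Serialize a stack to a structured-text (YAML) file
#'
#' Thicknesses and material definitions are written at full precision so
#' that [read_stack()] reproduces an identical stack.
#'
#' @param stack A [stack_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  obj <- list(
    incident_medium = c(list(name = stack$incident_medium$name),
                        .model_to_list(stack$incident_medium$model)),
    exit_medium = c(list(name = stack$exit_medium$name),
                    .model_to_list(stack$exit_medium$model)),
    layers = lapply(stack$layers, function(l) {
      c(list(material = l$material$name, thickness_nm = l$thickness_nm,
             role = l$role), .model_to_list(l$material$model))
    }),
    analyte = if (!is.na(stack$analyte_index))
      list(n = stack$analyte_index) else NULL
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' Read a stack from a structured-text (YAML) file
#'
#' @param path File written by [write_stack()].
#' @return A [stack_spec()].
#' @export
read_stack <- function(path) {
  obj <- yaml::read_yaml(path)
  mk_mat <- function(x) material(x$name, .model_from_list(x))
  layers <- lapply(obj$layers, function(l) {
    if (l$thickness_nm <= 0)
      stop("layer thickness must be strictly positive", call. = FALSE)
    layer(material(l$material, .model_from_list(l)), l$thickness_nm,
          role = if (is.null(l$role)) "dielectric" else l$role)
  })
  stack_spec(mk_mat(obj$incident_medium), layers, mk_mat(obj$exit_medium),
             analyte_index = if (is.null(obj$analyte)) NA_real_ else obj$analyte$n)
}
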