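#' Incident plane wave
#'
#' @param lambda_nm Vacuum wavelength in nanometres (> 0).
#' @param theta_deg Incidence angle in the incident medium, degrees,
#'   0 <= theta < 90.
#' @param pol Polarization, `"TE"` (E transverse to the plane of incidence)
#'   or `"TM"`.
#' @return An object of class `plane_wave`.
#' @export
plane_wave <- function(lambda_nm, theta_deg = 0, pol = c("TE", "TM")) {
  pol <- match.arg(pol)
  stopifnot(is.numeric(lambda_nm), all(lambda_nm > 0),
            theta_deg >= 0, theta_deg < 90)
  structure(list(lambda_nm = lambda_nm, theta_deg = theta_deg, pol = pol),
            class = "plane_wave")
}

# normal z-component of the wavevector, nm^-1, for permittivity eps.
# Branch fixed to Im(kz) >= 0 so that evanescent/absorbed waves decay
# along +z under the exp(-i omega t) convention.
.kz <- function(eps, k0, kx) {
  v <- sqrt(eps * k0^2 - kx^2 + 0i)
  ifelse(Im(v) < 0, -v, v)
}

# impedance step ratio at an interface prev -> next
.h_ratio <- function(kz_prev, kz_next, eps_prev, eps_next, pol) {
  if (pol == "TE") kz_next / kz_prev
  else (kz_next / eps_next) / (kz_prev / eps_prev)
}

#' Elementary transfer matrix of one interface-plus-layer step
#'
#' Returns the 2x2 matrix relating wave amplitudes on the incidence side of
#' an interface to the amplitudes in the following layer of thickness
#' `gamma_nm`,
#' \deqn{T = \frac12 \begin{pmatrix} (1+h)e^{-i k_z \gamma} & (1-h)e^{+i k_z \gamma}\\
#'  (1-h)e^{-i k_z \gamma} & (1+h)e^{+i k_z \gamma} \end{pmatrix},}
#' where \eqn{k_z} is the normal wavevector component of the entered layer
#' and \eqn{h} the impedance step ratio, \eqn{h = k_{z,next}/k_{z,prev}} for
#' TE and \eqn{h = (k_{z,next}/\epsilon_{next})/(k_{z,prev}/\epsilon_{prev})}
#' for TM (both reduce to \eqn{\sqrt{\epsilon_{next}/\epsilon_{prev}}} and
#' its reciprocal at normal incidence). `gamma_nm = 0` gives the bare
#' interface matrix; the evanescent branch is fixed by Im(kz) >= 0.
#'
#' @param eps_prev,eps_next Complex permittivities on the two sides.
#' @param gamma_nm Thickness of the entered layer, nm (>= 0; 0 for the final
#'   interface into the exit medium).
#' @param wave A [plane_wave()] (single wavelength).
#' @param n_inc Real refractive index of the incident medium, needed to fix
#'   the transverse wavevector at oblique incidence. Default 1.
#' @return A 2x2 complex matrix of class `transfer_matrix`.
#' @export
layer_matrix <- function(eps_prev, eps_next, gamma_nm, wave, n_inc = 1) {
  stopifnot(inherits(wave, "plane_wave"), length(wave$lambda_nm) == 1,
            gamma_nm >= 0)
  k0 <- 2 * pi / wave$lambda_nm
  kx <- k0 * n_inc * sin(wave$theta_deg * pi / 180)
  kzp <- .kz(eps_prev, k0, kx)
  kzn <- .kz(eps_next, k0, kx)
  h <- .h_ratio(kzp, kzn, eps_prev, eps_next, wave$pol)
  ph <- exp(-1i * kzn * gamma_nm)
  m <- 0.5 * matrix(c((1 + h) * ph, (1 - h) * ph,
                      (1 - h) / ph, (1 + h) / ph), 2, 2)
  if (any(!is.finite(m)))
    stop("non-finite transfer-matrix entries (check permittivities)",
         call. = FALSE)
  structure(m, class = c("transfer_matrix", "matrix"))
}

# permittivities of all regions (incident, layers..., exit) at lambda_nm
# (vectorized over wavelength): list of complex vectors
.stack_eps <- function(stack, lambda_nm) {
  lam_um <- lambda_nm / 1000
  n <- length(lambda_nm)
  mats <- c(list(stack$incident_medium),
            lapply(stack$layers, `[[`, "material"),
            list(stack$exit_medium))
  lapply(mats, function(m) rep_len(permittivity(m, lam_um), n))
}

# core engine: vectorized transfer-matrix product over a wavelength grid.
# Returns list(M11, M12, M21, M22, kz = list per region, eps = list).
.tmm_chain <- function(stack, lambda_nm, theta_deg, pol) {
  eps <- .stack_eps(stack, lambda_nm)
  k0 <- 2 * pi / lambda_nm
  n_inc <- Re(sqrt(eps[[1]]))
  kx <- k0 * n_inc * sin(theta_deg * pi / 180)
  kz <- lapply(eps, .kz, k0 = k0, kx = kx)
  d <- c(thicknesses(stack), 0)
  n <- length(lambda_nm)
  M11 <- M22 <- rep(1 + 0i, n)
  M12 <- M21 <- rep(0 + 0i, n)
  for (j in seq_along(d)) {
    h <- .h_ratio(kz[[j]], kz[[j + 1]], eps[[j]], eps[[j + 1]], pol)
    ph <- exp(-1i * kz[[j + 1]] * d[j])
    t11 <- 0.5 * (1 + h) * ph; t21 <- 0.5 * (1 - h) * ph
    t12 <- 0.5 * (1 - h) / ph; t22 <- 0.5 * (1 + h) / ph
    N11 <- M11 * t11 + M12 * t21; N12 <- M11 * t12 + M12 * t22
    N21 <- M21 * t11 + M22 * t21; N22 <- M21 * t12 + M22 * t22
    M11 <- N11; M12 <- N12; M21 <- N21; M22 <- N22
  }
  list(M11 = M11, M12 = M12, M21 = M21, M22 = M22, kz = kz, eps = eps)
}

#' Transfer matrix of a whole stack
#'
#' Ordered product of [layer_matrix()] steps from the incident medium to the
#' exit medium. Material range errors gain the offending layer's context.
#'
#' @param stack A [stack_spec()].
#' @param wave A [plane_wave()] (single wavelength).
#' @return A 2x2 complex matrix of class `transfer_matrix`.
#' @export
transfer_matrix <- function(stack, wave) {
  stopifnot(inherits(stack, "stack_spec"), inherits(wave, "plane_wave"),
            length(wave$lambda_nm) == 1)
  ch <- withCallingHandlers(
    .tmm_chain(stack, wave$lambda_nm, wave$theta_deg, wave$pol),
    error = function(e) {
      stop(sprintf("transfer_matrix at lambda = %g nm: %s",
                   wave$lambda_nm, conditionMessage(e)), call. = FALSE)
    })
  structure(matrix(c(ch$M11, ch$M21, ch$M12, ch$M22), 2, 2),
            class = c("transfer_matrix", "matrix"))
}

# admittance ratio turning |t|^2 into a power transmittance
.admittance_ratio <- function(ch, pol) {
  first <- ch$kz[[1]]; last <- ch$kz[[length(ch$kz)]]
  if (pol == "TE") {
    Re(last) / Re(first)
  } else {
    Re(last / ch$eps[[length(ch$eps)]]) / Re(first / ch$eps[[1]])
  }
}

.rta_vec <- function(stack, lambda_nm, theta_deg, pol) {
  ch <- .tmm_chain(stack, lambda_nm, theta_deg, pol)
  if (any(abs(ch$M11) == 0))
    stop("singular transfer matrix (|M11| = 0); unphysical stack",
         call. = FALSE)
  R <- Mod(ch$M21 / ch$M11)^2
  T <- Mod(1 / ch$M11)^2 * .admittance_ratio(ch, pol)
  list(R = R, T = T, A = 1 - R - T)
}

#' Reflectance, transmittance and absorptance at one condition
#'
#' R = |M21/M11|^2 and T = |1/M11|^2 scaled by the admittance ratio of the
#' semi-infinite media (a power ratio; the factor is 1 for identical media
#' at normal incidence); A = 1 - R - T by construction.
#'
#' @param stack A [stack_spec()].
#' @param wave A [plane_wave()] (single wavelength).
#' @return Named list with elements `R`, `T`, `A`.
#' @export
rta <- function(stack, wave) {
  stopifnot(inherits(wave, "plane_wave"), length(wave$lambda_nm) == 1)
  .rta_vec(stack, wave$lambda_nm, wave$theta_deg, wave$pol)
}

#' Spectral response over a wavelength grid
#'
#' @param stack A [stack_spec()].
#' @param lambda_nm Strictly increasing wavelength grid, nm.
#' @param theta_deg Incidence angle, degrees.
#' @param pol `"TE"` or `"TM"`.
#' @return A data frame of class `spectral_result` with columns
#'   `wavelength_nm`, `R`, `T`, `A`; the evaluation condition and the stack
#'   are kept as attributes so resonance finding can refine extrema by
#'   re-evaluating the continuous response.
#' @export
stack_spectrum <- function(stack, lambda_nm, theta_deg = 0,
                           pol = c("TE", "TM")) {
  pol <- match.arg(pol)
  stopifnot(length(lambda_nm) >= 1, all(diff(lambda_nm) > 0))
  out <- .rta_vec(stack, lambda_nm, theta_deg, pol)
  res <- data.frame(wavelength_nm = lambda_nm, R = out$R, T = out$T, A = out$A)
  attr(res, "theta_deg") <- theta_deg
  attr(res, "pol") <- pol
  attr(res, "stack") <- stack
  class(res) <- c("spectral_result", "data.frame")
  res
}

#' Internal electric-field profile
#'
#' Resolves forward/backward amplitudes in every region from the
#' transfer-matrix chain with unit incident amplitude, then samples the
#' transverse field on a z grid. For TE the sampled quantity is E_y; for TM
#' it is the transverse electric component reconstructed from the magnetic
#' amplitude. Intensity is reported as |E|^2 relative to the incident
#' amplitude.
#'
#' @param stack A [stack_spec()].
#' @param wave A [plane_wave()] (single wavelength).
#' @param z_resolution Maximum sample spacing, nm.
#' @param pad_nm How far to extend into the semi-infinite media, nm.
#' @return A data frame of class `field_profile` with columns `z_nm`,
#'   `Re_E`, `Im_E`, `abs2_E`, `n_real`, `n_imag` and a `region` index
#'   (0 = incident medium, 1..N layers, N+1 = exit medium).
#' @export
field_profile <- function(stack, wave, z_resolution = 2, pad_nm = 300) {
  stopifnot(inherits(wave, "plane_wave"), length(wave$lambda_nm) == 1)
  lam <- wave$lambda_nm
  pol <- wave$pol
  ch <- .tmm_chain(stack, lam, wave$theta_deg, pol)
  nlay <- length(stack$layers)
  d <- c(thicknesses(stack), 0)
  zb <- z_breaks(stack)
  tamp <- 1 / ch$M11

  # amplitudes per region, referenced at each region's right edge
  # (exit medium: left edge). amps[[j]] for region j (1 = incident medium).
  amps <- vector("list", nlay + 2)
  amps[[nlay + 2]] <- c(tamp, 0 + 0i)
  acc <- c(tamp, 0 + 0i)
  for (j in rev(seq_len(nlay + 1))) {
    h <- .h_ratio(ch$kz[[j]], ch$kz[[j + 1]], ch$eps[[j]], ch$eps[[j + 1]], pol)
    ph <- exp(-1i * ch$kz[[j + 1]] * d[j])
    Tm <- 0.5 * matrix(c((1 + h) * ph, (1 - h) * ph,
                         (1 - h) / ph, (1 + h) / ph), 2, 2)
    acc <- as.vector(Tm %*% acc)
    amps[[j]] <- acc
  }

  # sample field region by region
  zs <- list(); Es <- list(); regs <- list()
  edges_right <- c(0, zb[-1], zb[nlay + 1])   # reference z per region
  for (j in seq_len(nlay + 2)) {
    zr <- if (j == 1) seq(-pad_nm, 0, by = z_resolution)
          else if (j == nlay + 2) seq(zb[nlay + 1], zb[nlay + 1] + pad_nm,
                                      by = z_resolution)
          else seq(zb[j - 1], zb[j], by = min(z_resolution, d[j - 1]))
    zeta <- zr - edges_right[j]
    a <- amps[[j]][1]; b <- amps[[j]][2]
    kz <- ch$kz[[j]]
    if (pol == "TE") {
      E <- a * exp(1i * kz * zeta) + b * exp(-1i * kz * zeta)
    } else {
      # amplitudes propagate H_y; transverse E_x = (kz / (k0 eps)) H_y with
      # opposite sign for the backward wave; normalized to the incident E_x
      k0 <- 2 * pi / lam
      coef <- ch$kz[[j]] / (k0 * ch$eps[[j]])
      coef0 <- ch$kz[[1]] / (k0 * ch$eps[[1]])
      E <- (coef / coef0) * (a * exp(1i * kz * zeta) - b * exp(-1i * kz * zeta))
    }
    zs[[j]] <- zr; Es[[j]] <- E; regs[[j]] <- rep(j - 1L, length(zr))
  }
  z <- unlist(zs); E <- unlist(Es); region <- unlist(regs)
  lam_um <- lam / 1000
  mats <- c(list(stack$incident_medium), lapply(stack$layers, `[[`, "material"),
            list(stack$exit_medium))
  nz <- vapply(mats, function(m) material_index(m, lam_um), complex(1))
  out <- data.frame(z_nm = z, Re_E = Re(E), Im_E = Im(E), abs2_E = Mod(E)^2,
                    n_real = Re(nz)[region + 1L], n_imag = Im(nz)[region + 1L],
                    region = region)
  attr(out, "wave") <- wave
  attr(out, "stack") <- stack
  class(out) <- c("field_profile", "data.frame")
  out
}

#' Fraction of field intensity inside the analyte layer
#'
#' Trapezoidal integral of |E|^2 over the analyte interval divided by the
#' integral over the whole finite stack (z in [0, total thickness]).
#'
#' @param profile A [field_profile()].
#' @return Numeric in [0, 1], or NA when the stack has no analyte layer.
#' @export
analyte_fraction <- function(profile) {
  stack <- attr(profile, "stack")
  ia <- analyte_layer(stack)
  if (is.na(ia)) return(NA_real_)
  zb <- z_breaks(stack)
  trapz <- function(x, y) {
    if (length(x) < 2) return(0)
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  inside <- profile$z_nm >= zb[ia] & profile$z_nm <= zb[ia + 1]
  finite <- profile$z_nm >= 0 & profile$z_nm <= zb[length(zb)]
  num <- trapz(profile$z_nm[inside], profile$abs2_E[inside])
  den <- trapz(profile$z_nm[finite], profile$abs2_E[finite])
  num / den
}

#' Angular/spectral reflectance map
#'
#' @param stack A [stack_spec()].
#' @param lambda_nm Strictly increasing wavelength grid, nm.
#' @param theta_deg Angle grid in [0, 90), degrees.
#' @param pol `"TE"` or `"TM"`.
#' @return An object of class `angular_map`: list with `lambda_nm`,
#'   `theta_deg`, and reflectance matrix `R` (wavelengths x angles).
#' @export
angular_map <- function(stack, lambda_nm, theta_deg, pol = c("TE", "TM")) {
  pol <- match.arg(pol)
  stopifnot(all(theta_deg >= 0), all(theta_deg < 90))
  R <- vapply(theta_deg,
              function(th) .rta_vec(stack, lambda_nm, th, pol)$R,
              numeric(length(lambda_nm)))
  R <- matrix(R, nrow = length(lambda_nm))
  structure(list(lambda_nm = lambda_nm, theta_deg = theta_deg, R = R,
                 pol = pol, stack = stack),
            class = "angular_map")
}

#' @export
print.angular_map <- function(x, ...) {
  cat(sprintf("<angular_map> %s, %d wavelengths x %d angles (%g-%g nm, %g-%g deg)\n",
              x$pol, length(x$lambda_nm), length(x$theta_deg),
              min(x$lambda_nm), max(x$lambda_nm),
              min(x$theta_deg), max(x$theta_deg)))
  invisible(x)
}
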