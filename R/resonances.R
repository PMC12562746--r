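# Resonance detection, characterization (Q, G), classification by field
# localization, and the phase-matching eigenmode machinery.

# continuous reflectance evaluator bound to a spectral_result's condition;
# NULL when the spectrum carries no stack (e.g. synthetic data)
.r_continuous <- function(spec) {
  stack <- attr(spec, "stack")
  if (is.null(stack)) return(NULL)
  th <- attr(spec, "theta_deg"); pol <- attr(spec, "pol")
  function(l) .rta_vec(stack, l, th, pol)$R
}

# crossing of R with level `half` between grid points i and i+1 (linear),
# optionally polished with uniroot on the continuous response
.half_crossing <- function(lam, R, i, half, fcont) {
  x0 <- lam[i]; x1 <- lam[i + 1]
  y0 <- R[i]; y1 <- R[i + 1]
  x <- x0 + (half - y0) * (x1 - x0) / (y1 - y0)
  if (!is.null(fcont)) {
    g <- function(l) fcont(l) - half
    lo <- min(x0, x1); hi <- max(x0, x1)
    if (g(lo) * g(hi) < 0)
      x <- stats::uniroot(g, c(lo, hi), tol = 1e-6)$root
  }
  x
}

#' Locate and characterize reflectance-dip resonances
#'
#' Finds local reflectance minima whose prominence (local baseline minus dip
#' reflectance) exceeds `prominence`. The local baseline is the median
#' reflectance in a window of roughly ten estimated linewidths around the
#' dip, excluding the dip itself; the full width is measured at the midpoint
#' between that baseline and the dip minimum, which stays meaningful when
#' dips sit on a plateau below unity. When the spectrum carries its stack
#' (see [stack_spectrum()]) the dip position is refined by golden-section
#' minimization of the continuous response and the width crossings are
#' polished by root finding, making both resolution-independent; otherwise
#' grid interpolation is used. Dips whose half-level crossing falls outside
#' the grid are returned with `fwhm = NA` and flagged.
#'
#' @param spec A `spectral_result` (or any data frame with `wavelength_nm`
#'   and `R` columns).
#' @param prominence Minimum dip prominence (reflectance units), default 0.05.
#' @param baseline_level Optional known plateau reflectance. By default the
#'   baseline is estimated per dip as the windowed median described above;
#'   closed-form oracle spectra whose asymptotic plateau a finite window
#'   cannot see may pass it explicitly.
#' @return A data frame of class `mode_table`, one row per mode sorted by
#'   wavelength: `lambda0_nm`, `fwhm_nm`, `R0`, `baseline`, `prominence`,
#'   `Q`, `G_per_um`, `label` (initially `"unknown"`), `f_A` (NA until
#'   classified), `m` (NA), `flagged`.
#' @export
find_resonances <- function(spec, prominence = 0.05, baseline_level = NULL) {
  lam <- spec$wavelength_nm; R <- spec$R
  n <- length(lam)
  fcont <- .r_continuous(spec)
  rows <- list()
  if (n >= 3) {
    imin <- which(diff(sign(diff(R))) == 2) + 1
    for (i in imin) {
      # rough width at half depth vs neighborhood maximum, on the grid
      nb <- max(R[max(1, i - 200):min(n, i + 200)])
      half0 <- (nb + R[i]) / 2
      il <- i; while (il > 1 && R[il] < half0) il <- il - 1
      ir <- i; while (ir < n && R[ir] < half0) ir <- ir + 1
      w <- max(lam[ir] - lam[il], lam[min(i + 1, n)] - lam[max(i - 1, 1)])
      # local baseline: median in +/- 10 widths, excluding +/- 2 widths
      win <- abs(lam - lam[i]) <= 10 * w
      excl <- abs(lam - lam[i]) <= 2 * w
      base_pts <- R[win & !excl]
      baseline <- if (!is.null(baseline_level)) baseline_level
                  else if (length(base_pts)) stats::median(base_pts) else nb

      # refine the minimum: golden-section on the continuous response when
      # the stack is available, else a 3-point parabola through the grid
      l0 <- lam[i]; R0 <- R[i]
      if (!is.null(fcont)) {
        lo <- lam[max(1, i - 2)]; hi <- lam[min(n, i + 2)]
        o <- stats::optimize(fcont, c(lo, hi), tol = 1e-6)
        l0 <- o$minimum; R0 <- o$objective
      } else if (i > 1 && i < n) {
        # centered 3-point parabola (x and x^2 are collinear at ~1e3 nm)
        x <- lam[(i - 1):(i + 1)] - lam[i]; y <- R[(i - 1):(i + 1)]
        denom <- (x[1] - x[2]) * (x[2] - x[3]) * (x[1] - x[3])
        a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) +
              x[1] * (y[3] - y[2])) / denom
        b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
              x[1]^2 * (y[2] - y[3])) / denom
        if (a > 0) {
          v <- -b / (2 * a)
          if (v > x[1] && v < x[3]) {
            l0 <- lam[i] + v
            R0 <- y[2] - b^2 / (4 * a)
          }
        }
      }
      prom <- baseline - R0
      if (prom < prominence) next

      # half-depth crossings
      half <- (baseline + R0) / 2
      flagged <- FALSE
      il <- i; while (il > 1 && R[il] < half) il <- il - 1
      ir <- i; while (ir < n && R[ir] < half) ir <- ir + 1
      if (R[il] < half || R[ir] < half) {
        fw <- NA_real_; flagged <- TRUE
      } else {
        xl <- .half_crossing(lam, R, il, half, fcont)
        xr <- .half_crossing(lam, R, ir - 1, half, fcont)
        fw <- xr - xl
      }
      rows[[length(rows) + 1]] <- data.frame(
        lambda0_nm = l0, fwhm_nm = fw, R0 = R0, baseline = baseline,
        prominence = prom,
        Q = if (is.na(fw)) NA_real_ else l0 / fw,
        G_per_um = if (is.na(fw)) NA_real_ else (1 - R0) / (fw / 1000),
        label = "unknown", f_A = NA_real_, m = NA_integer_,
        flagged = flagged)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lambda0_nm = numeric(0), fwhm_nm = numeric(0), R0 = numeric(0),
               baseline = numeric(0), prominence = numeric(0), Q = numeric(0),
               G_per_um = numeric(0), label = character(0), f_A = numeric(0),
               m = integer(0), flagged = logical(0))
  out <- out[order(out$lambda0_nm), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stack") <- attr(spec, "stack")
  attr(out, "theta_deg") <- attr(spec, "theta_deg")
  attr(out, "pol") <- attr(spec, "pol")
  class(out) <- c("mode_table", "data.frame")
  out
}

#' Quality factor of a resonance
#'
#' Q = lambda0 / FWHM (both in the same length unit).
#'
#' @param mode One row of a [find_resonances()] table, or any list with
#'   `lambda0_nm` and `fwhm_nm`.
#' @return Dimensionless Q.
#' @export
q_factor <- function(mode) {
  stopifnot(mode$fwhm_nm > 0)
  mode$lambda0_nm / mode$fwhm_nm
}

#' Guidance factor of a resonance
#'
#' G = (1 - R0) / FWHM with the width in micrometres, so G carries units of
#' inverse micrometres; it balances dip depth against sharpness.
#'
#' @param mode As in [q_factor()]; needs `R0` and `fwhm_nm`.
#' @return G in um^-1.
#' @export
g_factor <- function(mode) {
  stopifnot(mode$fwhm_nm > 0, mode$R0 >= 0, mode$R0 <= 1)
  (1 - mode$R0) / (mode$fwhm_nm / 1000)
}

#' Classify one resonance by its field localization
#'
#' A mode holding more than half its intensity in the analyte layer is the
#' cavity mode; between the hybrid thresholds it is labelled `"hybrid"`
#' (the anticrossing regime); otherwise it is a Tamm mode, attributed to the
#' metal film nearest the intensity maximum (TPP1 on the incidence side,
#' TPP2 on the exit side).
#'
#' @param mode One row of a [find_resonances()] table.
#' @param profile A [field_profile()] computed at the mode wavelength.
#' @param stack The [stack_spec()] the profile belongs to.
#' @param hybrid Length-2 thresholds on the analyte fraction delimiting the
#'   hybrid regime, default `c(0.3, 0.5)`.
#' @return Character label: `"cavity"`, `"hybrid"`, `"TPP1"`, `"TPP2"` or
#'   `"unknown"`.
#' @export
classify_mode <- function(mode, profile, stack, hybrid = c(0.3, 0.5)) {
  fA <- analyte_fraction(profile)
  if (is.na(fA)) return("unknown")
  if (fA > hybrid[2]) return("cavity")
  if (fA >= hybrid[1]) return("hybrid")
  roles <- vapply(stack$layers, `[[`, "", "role")
  im <- which(roles == "metal")
  if (!length(im)) return("unknown")
  zb <- z_breaks(stack)
  centers <- (zb[im] + zb[im + 1]) / 2
  inside <- profile$z_nm >= 0 & profile$z_nm <= zb[length(zb)]
  zmax <- profile$z_nm[inside][which.max(profile$abs2_E[inside])]
  nearest <- which.min(abs(centers - zmax))
  if (nearest == 1) "TPP1" else "TPP2"
}

#' Classify all modes of a table
#'
#' Computes a field profile at each mode wavelength and fills the `label`
#' and `f_A` columns.
#'
#' @param modes A [find_resonances()] table carrying its stack.
#' @param z_resolution Field sampling step, nm.
#' @inheritParams classify_mode
#' @return The table with `label` and `f_A` filled in.
#' @export
classify_resonances <- function(modes, hybrid = c(0.3, 0.5),
                                z_resolution = 5) {
  stack <- attr(modes, "stack")
  if (is.null(stack)) stop("mode table carries no stack", call. = FALSE)
  th <- attr(modes, "theta_deg"); pol <- attr(modes, "pol")
  for (i in seq_len(nrow(modes))) {
    pr <- field_profile(stack, plane_wave(modes$lambda0_nm[i], th, pol),
                        z_resolution = z_resolution)
    modes$f_A[i] <- analyte_fraction(pr)
    modes$label[i] <- classify_mode(modes[i, ], pr, stack, hybrid)
  }
  modes
}

#' Reflection coefficient of a half-stack seen from the analyte
#'
#' Amplitude reflection coefficient for a wave inside the (semi-infinite)
#' analyte medium travelling toward the named side: the adjacent metal film,
#' that side's Bragg mirror and the substrate beyond.
#'
#' @param stack A sensor [stack_spec()] containing an analyte layer.
#' @param side `"PC1"` (incidence side) or `"PC2"` (exit side).
#' @param lambda_nm Wavelength(s), nm.
#' @return Complex reflection coefficient(s).
#' @export
half_stack_reflection <- function(stack, side = c("PC1", "PC2"), lambda_nm) {
  side <- match.arg(side)
  ia <- analyte_layer(stack)
  if (is.na(ia)) stop("stack has no analyte layer", call. = FALSE)
  ana <- stack$layers[[ia]]$material
  sub <- if (side == "PC1") {
    stack_spec(ana, rev(stack$layers[seq_len(ia - 1)]), stack$incident_medium)
  } else {
    nl <- length(stack$layers)
    stack_spec(ana, stack$layers[seq(ia + 1, nl)], stack$exit_medium)
  }
  ch <- .tmm_chain(sub, lambda_nm, 0, "TE")
  ch$M21 / ch$M11
}

#' Solve the round-trip phase-matching condition of the analyte cavity
#'
#' The cavity eigenmode satisfies phi1 + phi2 + phi_A = 2 pi m, where phi1,
#' phi2 are the reflection phases of the two metal-coated mirrors seen from
#' the analyte and phi_A = 4 pi n_a d_A k is the round-trip propagation
#' phase (k = 1/lambda in inverse micrometres). Rearranged for the
#' wavenumber,
#' \deqn{k = \frac{2\pi m - \arg r_1 - \arg r_2}{4 \pi n_a d_A},}
#' which is solved self-consistently by damped fixed-point iteration since
#' r1 and r2 are themselves frequency dependent.
#'
#' @param stack A sensor [stack_spec()].
#' @param m Integer mode order.
#' @param n_a Analyte refractive index; defaults to the stack's.
#' @param d_A_nm Analyte thickness, nm; defaults to the stack's.
#' @param k_init Initial wavenumber guess, um^-1 (default: PBG centre,
#'   1/0.93).
#' @param tol Convergence tolerance on k, um^-1.
#' @param max_iter Iteration cap; non-convergence errors with the residual
#'   trace attached.
#' @param damping Fixed-point damping factor in (0, 1].
#' @return List of class `phase_solve_result`: `k_per_um`, `lambda_nm`, `m`,
#'   `phi1`, `phi2`, `phi_A` (radians), `residual` (phase residual of the
#'   matching condition, radians) and `iterations`.
#' @export
solve_phase_condition <- function(stack, m, n_a = NULL, d_A_nm = NULL,
                                  k_init = 1 / 0.93, tol = 1e-10,
                                  max_iter = 200, damping = 0.5) {
  ia <- analyte_layer(stack)
  if (is.na(ia)) stop("stack has no analyte layer", call. = FALSE)
  if (is.null(n_a)) n_a <- Re(material_index(stack$layers[[ia]]$material, 0.93))
  if (is.null(d_A_nm)) d_A_nm <- stack$layers[[ia]]$thickness_nm
  d_um <- d_A_nm / 1000
  rhs <- function(k) {
    lam_nm <- 1000 / k
    r1 <- half_stack_reflection(stack, "PC1", lam_nm)
    r2 <- half_stack_reflection(stack, "PC2", lam_nm)
    list(k = (2 * pi * m - Arg(r1) - Arg(r2)) / (4 * pi * n_a * d_um),
         phi1 = Arg(r1), phi2 = Arg(r2))
  }
  k <- k_init
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    s <- rhs(k)
    knew <- (1 - damping) * k + damping * s$k
    # keep the iteration local: reflection phases jump by 2 pi across the
    # sharp Tamm features, so large steps can hop between branches
    if (abs(knew - k) > 0.05) knew <- k + sign(knew - k) * 0.05
    trace <- c(trace, abs(knew - k))
    if (abs(knew - k) < tol) {
      phiA <- 4 * pi * n_a * d_um * knew
      res <- abs(s$phi1 + s$phi2 + phiA - 2 * pi * m)
      return(structure(list(k_per_um = knew, lambda_nm = 1000 / knew, m = m,
                            phi1 = s$phi1, phi2 = s$phi2, phi_A = phiA,
                            residual = res, iterations = it),
                       class = "phase_solve_result"))
    }
    k <- knew
  }
  stop(sprintf(
    "phase-condition iteration did not converge after %d steps (last |dk| = %.3g); residual trace: %s",
    max_iter, trace[length(trace)],
    paste(signif(utils::tail(trace, 5), 3), collapse = ", ")), call. = FALSE)
}

#' Algebraic phase-condition map
#'
#' The bare rearrangement of the round-trip condition for the wavenumber,
#' k = (2 pi m - phi1 - phi2) / (4 pi n_a d_A), with k in inverse
#' micrometres. Exposed separately so closed-form cases (e.g. perfect
#' mirrors with phi = pi) can be checked without any stack.
#'
#' @param phi1,phi2 Mirror reflection phases, radians.
#' @param m Mode order.
#' @param n_a Analyte index.
#' @param d_A_nm Analyte thickness, nm.
#' @return Wavenumber in um^-1.
#' @export
phase_condition_wavenumber <- function(phi1, phi2, m, n_a, d_A_nm) {
  (2 * pi * m - phi1 - phi2) / (4 * pi * n_a * d_A_nm / 1000)
}

#' Scan mode orders for cavity solutions inside a wavelength window
#'
#' @param stack A sensor [stack_spec()].
#' @param m_range Integer orders to try, default 1:6.
#' @param window_nm Wavelength window the solution must fall into.
#' @return List of `phase_solve_result` objects (possibly empty).
#' @export
scan_mode_orders <- function(stack, m_range = 1:6, window_nm = c(750, 1100)) {
  out <- list()
  for (m in m_range) {
    sol <- tryCatch(solve_phase_condition(stack, m), error = function(e) NULL)
    if (!is.null(sol) && sol$lambda_nm >= window_nm[1] &&
        sol$lambda_nm <= window_nm[2])
      out[[length(out) + 1]] <- sol
  }
  out
}

#' Tamm-mode phase-matching residual (diagnostic)
#'
#' Evaluates one reading of the interface condition
#' phi_PC + phi_metal = 2 pi m at the terminal-dielectric/metal interface of
#' the named side: both reflection phases are taken for a wave in the
#' terminal dielectric material at that interface, looking into the Bragg
#' mirror and into the metal film (plus everything beyond), respectively.
#' The reported residual is the distance of the phase sum from the nearest
#' multiple of 2 pi; this is a diagnostic, not a solver.
#'
#' @param stack A sensor [stack_spec()].
#' @param side `"PC1"` or `"PC2"`.
#' @param lambda_nm Single wavelength, nm.
#' @return List of class `tpp_condition`: `phi_pc`, `phi_metal` (radians),
#'   `m_nearest`, `residual` (radians).
#' @export
tpp_phase_residual <- function(stack, side = c("PC1", "PC2"), lambda_nm) {
  side <- match.arg(side)
  ia <- analyte_layer(stack)
  if (is.na(ia)) stop("stack has no analyte layer", call. = FALSE)
  nl <- length(stack$layers)
  if (side == "PC1") {
    i_metal <- ia - 1
    term <- stack$layers[[i_metal - 1]]$material  # terminal dielectric of PC1
    mirror <- stack_spec(term, rev(stack$layers[seq_len(i_metal - 1)]),
                         stack$incident_medium)
    beyond <- stack_spec(term, stack$layers[seq(i_metal, nl)],
                         stack$exit_medium)
  } else {
    i_metal <- ia + 1
    term <- stack$layers[[i_metal + 1]]$material
    mirror <- stack_spec(term, stack$layers[seq(i_metal + 1, nl)],
                         stack$exit_medium)
    beyond <- stack_spec(term, rev(stack$layers[seq_len(i_metal)]),
                         stack$incident_medium)
  }
  r_pc <- {ch <- .tmm_chain(mirror, lambda_nm, 0, "TE"); ch$M21 / ch$M11}
  r_me <- {ch <- .tmm_chain(beyond, lambda_nm, 0, "TE"); ch$M21 / ch$M11}
  s <- Arg(r_pc) + Arg(r_me)
  m_near <- round(s / (2 * pi))
  structure(list(phi_pc = Arg(r_pc), phi_metal = Arg(r_me),
                 m_nearest = m_near, residual = abs(s - 2 * pi * m_near)),
            class = "tpp_condition")
}

#' Trace two resonance branches over angle and locate their anticrossing
#'
#' Follows two reflectance-dip branches through an [angular_map()] by
#' nearest-dip continuation (maximum jump `max_jump_nm_per_deg` per degree).
#' The anticrossing angle is where the spectral separation of the traced
#' branches is minimal. If a branch is lost (its dip vanishes, leaves the
#' grid, or merges with the other branch) the trace is truncated there and
#' flagged as partial; a trace whose separation never develops a clear
#' interior minimum (constant-separation parallel branches) is flagged with
#' `theta_star = NA`.
#'
#' @param map An [angular_map()].
#' @param branch_a,branch_b Starting wavelengths (nm) of the two branches at
#'   the first angle of the map.
#' @param prominence Dip prominence threshold passed to the per-angle dip
#'   finder.
#' @param max_jump_nm_per_deg Continuation tolerance.
#' @return List of class `anticrossing`: `theta_star_deg`,
#'   `min_separation_nm`, `partial` (logical), and `trace` (data frame
#'   `theta_deg`, `lambda_a_nm`, `lambda_b_nm`, `separation_nm`).
#' @export
find_anticrossing <- function(map, branch_a, branch_b, prominence = 0.02,
                              max_jump_nm_per_deg = 10) {
  lam <- map$lambda_nm
  th <- map$theta_deg
  pa <- branch_a; pb <- branch_b
  rows <- list(); partial <- FALSE
  prev_th <- th[1]
  for (j in seq_along(th)) {
    R <- map$R[, j]
    i <- which(diff(sign(diff(R))) == 2) + 1
    if (length(i)) {
      nb <- vapply(i, function(ii)
        max(R[max(1, ii - 100):min(length(R), ii + 100)]), 0)
      i <- i[nb - R[i] >= prominence]
    }
    if (!length(i)) { partial <- TRUE; break }
    dips <- lam[i]
    jump <- max_jump_nm_per_deg * max(th[j] - prev_th, 1)
    ia <- which.min(abs(dips - pa)); ib <- which.min(abs(dips - pb))
    if (abs(dips[ia] - pa) > jump || abs(dips[ib] - pb) > jump ||
        ia == ib) { partial <- TRUE; break }
    pa <- dips[ia]; pb <- dips[ib]; prev_th <- th[j]
    rows[[length(rows) + 1]] <- data.frame(
      theta_deg = th[j], lambda_a_nm = pa, lambda_b_nm = pb,
      separation_nm = abs(pb - pa))
  }
  trace <- if (length(rows)) do.call(rbind, rows) else
    data.frame(theta_deg = numeric(0), lambda_a_nm = numeric(0),
               lambda_b_nm = numeric(0), separation_nm = numeric(0))
  if (!nrow(trace)) {
    return(structure(list(theta_star_deg = NA_real_,
                          min_separation_nm = NA_real_,
                          partial = TRUE, trace = trace),
                     class = "anticrossing"))
  }
  k <- which.min(trace$separation_nm)
  # parallel branches: no interior minimum of the separation
  theta_star <- trace$theta_deg[k]
  spread <- diff(range(trace$separation_nm))
  if (spread < 1e-9 || (k == nrow(trace) && !partial && spread <
                        0.05 * stats::median(trace$separation_nm))) {
    theta_star <- NA_real_
    partial <- TRUE
  }
  structure(list(theta_star_deg = theta_star,
                 min_separation_nm = trace$separation_nm[k],
                 partial = partial, trace = trace),
            class = "anticrossing")
}

#' @export
print.anticrossing <- function(x, ...) {
  if (is.na(x$theta_star_deg))
    cat("<anticrossing> no interior minimum found (flagged)\n")
  else
    cat(sprintf("<anticrossing> theta* = %.2f deg, min separation %.2f nm%s\n",
                x$theta_star_deg, x$min_separation_nm,
                if (x$partial) " (partial trace)" else ""))
  invisible(x)
}
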