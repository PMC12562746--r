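# Analyte refractive-index sweeps, reference-corrected sensitivity and
# figure of merit, and the glucose-concentration map for urine sensing.

#' Glucose concentration to urine refractive index
#'
#' Literature-derived map between urinary glucose concentration and the real
#' refractive index of human urine used for the sensing sweeps. The
#' physiological (renal-threshold) band 0-15 mg/dL corresponds to normal
#' urine, n = 1.335.
#'
#' @return Data frame with columns `concentration` and `n_a`.
#' @export
glucose_map <- function() {
  data.frame(
    concentration = c("0-15 mg/dL", "0.625 g/dL", "1.25 g/dL",
                      "2.5 g/dL", "5 g/dL"),
    n_a = c(1.335, 1.336, 1.337, 1.338, 1.341)
  )
}

#' Look up the urine refractive index for a glucose concentration
#'
#' @param concentration A concentration label from [glucose_map()].
#' @return The tabulated refractive index.
#' @export
glucose_to_index <- function(concentration) {
  gm <- glucose_map()
  i <- match(concentration, gm$concentration)
  if (is.na(i))
    stop(sprintf("unknown concentration '%s'; valid labels: %s",
                 concentration, paste(gm$concentration, collapse = ", ")),
         call. = FALSE)
  gm$n_a[i]
}

.sweep_builder <- function(structure, metal) {
  structure <- match.arg(structure, c("baseline", "enhanced"))
  if (structure == "baseline")
    function(n_a) build_baseline(n_a, metal = metal)
  else
    function(n_a) build_enhanced(n_a)
}

#' Sweep the analyte refractive index and track the three modes
#'
#' For each n_a the stack is rebuilt, its reflectance spectrum computed and
#' refined, and the detected dips classified by field localization. Rows
#' where one of the three labels is missing are flagged rather than dropped.
#'
#' @param structure `"baseline"` or `"enhanced"`.
#' @param n_a Vector of analyte refractive indices (>= 1).
#' @param theta_deg Incidence angle, degrees (default 0).
#' @param metal Metal film for the baseline builder.
#' @param lambda_nm Wavelength grid for the scan.
#' @param prominence Dip prominence threshold.
#' @return Data frame of class `ri_sweep` with one row per n_a: `n_a`,
#'   `lambda_TPP1_nm`, `lambda_cavity_nm`, `lambda_TPP2_nm`,
#'   `fwhm_cavity_nm`, `R0_cavity`, `flagged`. The structure id and
#'   reference index (1.335) are kept as attributes.
#' @export
ri_sweep <- function(structure = c("baseline", "enhanced"), n_a,
                     theta_deg = 0, metal = "Ag",
                     lambda_nm = seq(750, 1100, by = 0.25),
                     prominence = 0.05) {
  structure <- match.arg(structure)
  stopifnot(all(n_a >= 1))
  build <- .sweep_builder(structure, metal)
  rows <- lapply(n_a, function(na) {
    st <- build(na)
    sp <- stack_spectrum(st, lambda_nm, theta_deg)
    modes <- classify_resonances(find_resonances(sp, prominence))
    pick <- function(lbl) {
      i <- which(modes$label == lbl)
      if (length(i)) modes$lambda0_nm[i[1]] else NA_real_
    }
    ic <- which(modes$label == "cavity")
    data.frame(
      n_a = na,
      lambda_TPP1_nm = pick("TPP1"),
      lambda_cavity_nm = pick("cavity"),
      lambda_TPP2_nm = pick("TPP2"),
      fwhm_cavity_nm = if (length(ic)) modes$fwhm_nm[ic[1]] else NA_real_,
      R0_cavity = if (length(ic)) modes$R0[ic[1]] else NA_real_,
      flagged = anyNA(c(pick("TPP1"), pick("cavity"), pick("TPP2")))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "structure") <- structure
  attr(out, "metal") <- metal
  attr(out, "reference_index") <- 1.335
  class(out) <- c("ri_sweep", "data.frame")
  out
}

#' Reference-corrected sensitivity
#'
#' \deqn{S = \frac{\Delta\lambda_{cavity} - \Delta\lambda_{TPP}}{n_a - n_{ref}},}
#' where the shifts are taken relative to the reference index (normal urine,
#' n_ref = 1.335) and the stationary Tamm mode acts as the spectral
#' reference, cancelling any common-mode drift.
#'
#' @param sweep An [ri_sweep()] result containing the reference index.
#' @param reference Which Tamm mode to use as reference: `"TPP1"` or
#'   `"TPP2"`; `"none"` sets the reference shift to zero (the conventional
#'   S = dlambda_cavity/dn), for structures whose Tamm dips are too shallow
#'   to detect, such as the enhanced design.
#' @param n_a The analyte index at which to evaluate S (must differ from the
#'   reference index and be present in the sweep).
#' @return Sensitivity in nm per refractive-index unit.
#' @export
sensitivity <- function(sweep, reference = c("TPP1", "TPP2", "none"), n_a) {
  reference <- match.arg(reference)
  n_ref <- attr(sweep, "reference_index")
  if (isTRUE(all.equal(n_a, n_ref)))
    stop("sensitivity is undefined at the reference index n_a = n_ref",
         call. = FALSE)
  row_a <- sweep[match(n_a, sweep$n_a), ]
  row_r <- sweep[match(n_ref, sweep$n_a), ]
  if (anyNA(row_a$n_a) || anyNA(row_r$n_a))
    stop("both n_a and the reference index must be rows of the sweep",
         call. = FALSE)
  d_cav <- row_a$lambda_cavity_nm - row_r$lambda_cavity_nm
  d_tpp <- if (reference == "none") 0 else {
    tpp_col <- paste0("lambda_", reference, "_nm")
    row_a[[tpp_col]] - row_r[[tpp_col]]
  }
  (d_cav - d_tpp) / (n_a - n_ref)
}

#' Figure of merit
#'
#' FoM = S / FWHM in inverse refractive-index units, combining sensitivity
#' with the spectral sharpness of the cavity dip.
#'
#' @param S Sensitivity, nm/RIU.
#' @param fwhm_nm Cavity-dip full width at half depth, nm, at the same n_a.
#' @return FoM in RIU^-1.
#' @export
figure_of_merit <- function(S, fwhm_nm) {
  stopifnot(fwhm_nm > 0)
  S / fwhm_nm
}

#' Per-concentration sensing report
#'
#' Tabulates, for every non-reference row of a sweep, the mode wavelengths,
#' the reference-corrected sensitivity and the figure of merit (using the
#' cavity FWHM at the same n_a).
#'
#' @param sweep An [ri_sweep()] result including the reference index row.
#' @param reference `"TPP1"` or `"TPP2"`.
#' @return Data frame of class `sensitivity_report`.
#' @export
sensing_report <- function(sweep, reference = c("TPP1", "TPP2", "none")) {
  reference <- match.arg(reference)
  n_ref <- attr(sweep, "reference_index")
  rows <- sweep[!vapply(sweep$n_a, function(x) isTRUE(all.equal(x, n_ref)),
                        TRUE), ]
  S <- vapply(rows$n_a, function(na) sensitivity(sweep, reference, na), 0)
  out <- data.frame(
    n_a = rows$n_a,
    lambda_TPP1_nm = rows$lambda_TPP1_nm,
    lambda_cavity_nm = rows$lambda_cavity_nm,
    lambda_TPP2_nm = rows$lambda_TPP2_nm,
    S_nm_per_RIU = S,
    FoM_per_RIU = S / rows$fwhm_cavity_nm
  )
  attr(out, "reference") <- reference
  attr(out, "reference_index") <- n_ref
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' Linearity of a mode's wavelength against the analyte index
#'
#' Least-squares line lambda0 ~ n_a with its coefficient of determination.
#'
#' @param sweep An [ri_sweep()] result (or the output of
#'   [broad_ri_sweep()]).
#' @param mode `"cavity"`, `"TPP1"` or `"TPP2"`.
#' @return List with `slope_nm_per_RIU`, `intercept_nm`, `r_squared`, `n`.
#' @export
linearity_report <- function(sweep, mode = c("cavity", "TPP1", "TPP2")) {
  mode <- match.arg(mode)
  col <- paste0("lambda_", mode, "_nm")
  ok <- !is.na(sweep[[col]])
  if (sum(ok) < 3)
    stop("need at least 3 sweep points with the mode present", call. = FALSE)
  y <- sweep[[col]][ok]
  fit <- stats::lm(y ~ sweep$n_a[ok])
  tss <- sum((y - mean(y))^2)
  rss <- sum(stats::residuals(fit)^2)
  list(slope_nm_per_RIU = unname(stats::coef(fit)[2]),
       intercept_nm = unname(stats::coef(fit)[1]),
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       n = sum(ok))
}

#' Broad refractive-index sweep via the phase condition
#'
#' Follows a single cavity-mode branch of fixed order m across a wide
#' analyte-index range (the Fabry-Perot resonance between the metal films
#' exists well beyond the Bragg-mirror bandgap, so the branch can be traced
#' where dip detection among the Tamm features would be ambiguous). Each
#' point solves the round-trip phase condition self-consistently.
#'
#' @param structure `"baseline"` or `"enhanced"`.
#' @param n_a Increasing vector of analyte indices (>= 1).
#' @param m Mode order of the tracked branch under principal-value mirror
#'   phases (default 2, the branch at ~930 nm for n_a = 1.335; each metal
#'   mirror reflects with a phase near -pi).
#' @param metal Metal film for the baseline builder.
#' @return Data frame of class `ri_sweep` with `n_a` and
#'   `lambda_cavity_nm`.
#' @export
broad_ri_sweep <- function(structure = c("baseline", "enhanced"), n_a,
                           m = 2, metal = "Ag") {
  structure <- match.arg(structure)
  build <- .sweep_builder(structure, metal)
  k_guess <- NULL
  lam <- vapply(n_a, function(na) {
    st <- build(na)
    d_um <- st$layers[[analyte_layer(st)]]$thickness_nm / 1000
    # first-point guess: both mirror phases near -2.7 rad (metal films)
    init <- if (is.null(k_guess))
      phase_condition_wavenumber(-2.7, -2.7, m, na, d_um * 1000)
    else k_guess
    sol <- solve_phase_condition(st, m = m, k_init = init)
    k_guess <<- sol$k_per_um
    sol$lambda_nm
  }, 0)
  out <- data.frame(n_a = n_a, lambda_cavity_nm = lam)
  attr(out, "structure") <- structure
  attr(out, "reference_index") <- 1.335
  class(out) <- c("ri_sweep", "data.frame")
  out
}

# --- table twins -----------------------------------------------------------

#' Metal-comparison table of cavity-mode quality metrics
#'
#' Builds the baseline stack with each requested metal film, refines the
#' cavity dip and reports its wavelength, Q factor and G factor.
#'
#' @param metals Character vector of metals, default Ag/Au/Cu.
#' @param lambda_nm Scan grid.
#' @return Data frame: `metal`, `lambda_cavity_nm`, `Q`, `G_per_um`.
#' @export
metal_comparison_table <- function(metals = c("Ag", "Au", "Cu"),
                                   lambda_nm = seq(750, 1100, by = 0.25)) {
  rows <- lapply(metals, function(m) {
    st <- build_baseline(1.335, metal = m)
    sp <- stack_spectrum(st, lambda_nm)
    modes <- classify_resonances(find_resonances(sp))
    ic <- which(modes$label == "cavity")
    if (!length(ic))
      return(data.frame(metal = m, lambda_cavity_nm = NA_real_,
                        Q = NA_real_, G_per_um = NA_real_))
    md <- modes[ic[1], ]
    data.frame(metal = m, lambda_cavity_nm = md$lambda0_nm,
               Q = q_factor(md), G_per_um = g_factor(md))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Glucose-sensing table for the baseline structure
#'
#' One row per glucose concentration of [glucose_map()]: the three mode
#' wavelengths plus sensitivity and figure of merit relative to normal
#' urine.
#'
#' @param reference Tamm reference mode.
#' @param lambda_nm Scan grid.
#' @return Data frame mirroring the per-concentration sensing summary.
#' @export
baseline_sensing_table <- function(reference = "TPP1",
                                   lambda_nm = seq(750, 1100, by = 0.25)) {
  gm <- glucose_map()
  sw <- ri_sweep("baseline", gm$n_a, lambda_nm = lambda_nm)
  rep <- sensing_report(sw, reference)
  first <- sw[1, ]
  out <- data.frame(
    concentration = gm$concentration,
    n_a = gm$n_a,
    lambda_TPP1_nm = c(first$lambda_TPP1_nm, rep$lambda_TPP1_nm),
    lambda_cavity_nm = c(first$lambda_cavity_nm, rep$lambda_cavity_nm),
    lambda_TPP2_nm = c(first$lambda_TPP2_nm, rep$lambda_TPP2_nm),
    S_nm_per_RIU = c(NA, rep$S_nm_per_RIU),
    FoM_per_RIU = c(NA, rep$FoM_per_RIU)
  )
  out
}

#' Glucose-sensing table for the enhanced structure
#'
#' @inheritParams baseline_sensing_table
#' @return Data frame: `n_a`, `lambda_cavity_nm`, `S_nm_per_RIU`,
#'   `FoM_per_RIU`.
#' @export
enhanced_sensing_table <- function(reference = "none",
                                   lambda_nm = seq(750, 1100, by = 0.25)) {
  gm <- glucose_map()
  sw <- ri_sweep("enhanced", gm$n_a, lambda_nm = lambda_nm)
  rep <- sensing_report(sw, reference)
  data.frame(
    n_a = gm$n_a,
    lambda_cavity_nm = sw$lambda_cavity_nm,
    S_nm_per_RIU = c(NA, rep$S_nm_per_RIU),
    FoM_per_RIU = c(NA, rep$FoM_per_RIU)
  )
}
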