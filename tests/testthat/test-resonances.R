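test_that("a synthetic Lorentzian dip is recovered at stated precision", {
  grid <- seq(880, 920, by = 0.05)
  d <- lorentzian_dip(grid, 900.3217, 2.1)
  m <- find_resonances(d, prominence = 0.1, baseline_level = 1.0)
  expect_equal(nrow(m), 1)
  expect_equal(m$lambda0_nm, 900.3217, tolerance = 1e-3 / 900)
  expect_lt(abs(m$fwhm_nm - 2.1), 1e-3)
  expect_false(m$flagged)

  # flat spectrum: no dips, empty table, not an error
  flat <- lorentzian_dip(grid, 900, 2, depth = 0)
  flat$R <- rep(0.9, nrow(flat))
  expect_equal(nrow(find_resonances(flat)), 0)

  # dip whose half-level crossing falls off the grid edge is flagged
  short <- lorentzian_dip(seq(899.9, 920, by = 0.05), 900.3217, 2.1)
  ms <- find_resonances(short, prominence = 0.1, baseline_level = 1.0)
  expect_true(ms$flagged[1])
  expect_true(is.na(ms$fwhm_nm[1]))
})

test_that("refined dip positions are independent of the scan resolution", {
  st <- baseline_stack()
  coarse <- stack_spectrum(st, seq(925, 940, by = 0.25))
  fine <- stack_spectrum(st, seq(925, 940, by = 0.1))
  lc <- find_resonances(coarse)$lambda0_nm
  lf <- find_resonances(fine)$lambda0_nm
  expect_equal(lc, lf, tolerance = 5e-3 / 900)
})

test_that("Q and G factors satisfy their defining algebra", {
  mk <- function(l0, fw, R0) list(lambda0_nm = l0, fwhm_nm = fw, R0 = R0)
  expect_equal(q_factor(mk(1000, 1000, 0)), 1)
  expect_equal(q_factor(mk(931.129, 1.2953, 0.02)), 718.8, tolerance = 1e-3)
  expect_equal(q_factor(mk(938.009, 4.9554, 0.1)), 189.3, tolerance = 1e-3)
  expect_equal(g_factor(mk(900, 1000, 1)), 0)     # no dip, no guidance
  expect_equal(g_factor(mk(900, 1000, 0)), 1)     # full dip, 1 um width
  expect_equal(g_factor(mk(931.129, 1.2953, 0.0199)), 756.6, tolerance = 1e-3)

  # identity G * lambda0(um) = (1 - R0) * Q on the detected baseline modes
  modes <- baseline_modes()
  for (i in seq_len(nrow(modes))) {
    md <- modes[i, ]
    expect_equal(md$Q, md$lambda0_nm / md$fwhm_nm, tolerance = 1e-9)
    expect_equal(md$G_per_um, (1 - md$R0) / (md$fwhm_nm / 1000),
                 tolerance = 1e-9)
    expect_equal(md$G_per_um * md$lambda0_nm / 1000, (1 - md$R0) * md$Q,
                 tolerance = 1e-9)
  }
})

test_that("the three baseline modes are found and classified by localization", {
  modes <- baseline_modes()
  expect_equal(nrow(modes), 3)
  expect_equal(modes$label, c("TPP1", "cavity", "TPP2"))
  # exactly one mode holds the majority of its field in the analyte
  expect_equal(sum(modes$f_A > 0.5), 1)
  expect_gt(modes$f_A[modes$label == "cavity"], 0.5)
  expect_true(all(modes$f_A[modes$label != "cavity"] < 0.3))
  # the metal ranking of cavity sharpness: Ag above Au above Cu
  tab <- metal_comparison_table(lambda_nm = seq(900, 960, by = 0.25))
  expect_true(tab$Q[tab$metal == "Ag"] > tab$Q[tab$metal == "Au"])
  expect_true(tab$Q[tab$metal == "Au"] > tab$Q[tab$metal == "Cu"])
  expect_true(tab$G_per_um[tab$metal == "Ag"] > tab$G_per_um[tab$metal == "Au"])
  expect_true(tab$G_per_um[tab$metal == "Au"] > tab$G_per_um[tab$metal == "Cu"])
})

test_that("half-stack reflections are passive, highly reflective in the gap, and phase-continuous", {
  st <- baseline_stack()
  lam <- seq(750, 1100, by = 2)
  for (side in c("PC1", "PC2")) {
    r <- half_stack_reflection(st, side, lam)
    expect_true(all(Mod(r) <= 1 + 1e-12))
  }
  # inside the bandgap, away from the Tamm features, the mirrors are strong
  mid <- seq(860, 905, by = 1)
  expect_true(all(Mod(half_stack_reflection(st, "PC1", mid)) > 0.9))

  # unwrapped phase continuity at 0.1-nm sampling through the TPP1 region
  fine <- seq(780, 820, by = 0.1)
  ph <- Arg(half_stack_reflection(st, "PC1", fine))
  jumps <- diff(ph)
  jumps <- (jumps + pi) %% (2 * pi) - pi   # principal-value steps
  expect_true(all(abs(jumps) < pi / 2))
})

test_that("the phase-matching condition solves the cavity eigenmode", {
  # perfect-mirror toy: phi1 = phi2 = pi gives lambda = 2 n d / (m - 1)
  for (m in 2:4) {
    k <- phase_condition_wavenumber(pi, pi, m, 1.335, 1000)
    expect_equal(1000 / k, 2 * 1.335 * 1000 / (m - 1), tolerance = 1e-12)
  }

  # full solver lands within half a linewidth of the reflectance dip
  st <- baseline_stack()
  modes <- baseline_modes()
  cav <- modes[modes$label == "cavity", ]
  sol <- solve_phase_condition(st, m = 2)
  expect_lt(abs(sol$lambda_nm - cav$lambda0_nm), cav$fwhm_nm / 2)
  expect_lt(sol$residual, 1e-6)
  expect_lt(abs(sol$phi1 + sol$phi2 + sol$phi_A - 2 * pi * sol$m), 1e-6)

  est <- build_enhanced(1.335)
  esol <- solve_phase_condition(est, m = 2)
  ecav <- enhanced_modes()
  ecav <- ecav[ecav$label == "cavity", ]
  expect_lt(abs(esol$lambda_nm - ecav$lambda0_nm), ecav$fwhm_nm / 2)

  # eigenwavelength rises monotonically with the analyte index
  lams <- vapply(c(1.335, 1.338, 1.341), function(na)
    solve_phase_condition(build_baseline(na), m = 2)$lambda_nm, 0)
  expect_true(all(diff(lams) > 0))

  # the order scan isolates the in-gap solution
  sols <- scan_mode_orders(st)
  expect_length(sols, 1)
  expect_equal(sols[[1]]$m, 2)

  expect_error(solve_phase_condition(st, m = 2, max_iter = 2),
               "did not converge")
})

test_that("the Tamm phase residual closes at the detected Tamm dips", {
  st <- baseline_stack()
  modes <- baseline_modes()
  r1 <- tpp_phase_residual(st, "PC1",
                           modes$lambda0_nm[modes$label == "TPP1"])
  expect_lt(r1$residual, 0.5)
  r2 <- tpp_phase_residual(st, "PC2",
                           modes$lambda0_nm[modes$label == "TPP2"])
  expect_lt(r2$residual, 0.5)
  # the residual is a distance to the nearest 2 pi multiple
  expect_gte(r1$residual, 0)
  expect_lte(r1$residual, pi)
})

test_that("anticrossings are located on synthetic branch maps", {
  # two narrow lines crossing at theta = 8.5
  lam <- seq(800, 900, by = 0.25)
  th <- seq(0, 15, by = 1)
  la <- 880 - 4.0 * th          # steep branch
  lb <- 846 + 0.0 * th          # flat branch; intersection at theta = 8.5
  R <- vapply(seq_along(th), function(j) {
    1 - 0.6 * exp(-(lam - la[j])^2) - 0.6 * exp(-(lam - lb[j])^2)
  }, numeric(length(lam)))
  mp <- structure(list(lambda_nm = lam, theta_deg = th, R = R, pol = "TE"),
                  class = "angular_map")
  ac <- find_anticrossing(mp, branch_a = 880, branch_b = 846)
  expect_false(is.na(ac$theta_star_deg))
  expect_lt(abs(ac$theta_star_deg - 8.5), 1.01)

  # parallel non-interacting branches: separation constant, flagged
  lb2 <- 846 - 4.0 * th
  R2 <- vapply(seq_along(th), function(j) {
    1 - 0.6 * exp(-(lam - la[j])^2) - 0.6 * exp(-(lam - lb2[j])^2)
  }, numeric(length(lam)))
  mp2 <- structure(list(lambda_nm = lam, theta_deg = th, R = R2, pol = "TE"),
                   class = "angular_map")
  ac2 <- find_anticrossing(mp2, branch_a = 880, branch_b = 846)
  expect_true(is.na(ac2$theta_star_deg))
  expect_true(ac2$partial)
})
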