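test_that("elementary transfer matrices take their closed forms", {
  w <- plane_wave(800, 0, "TE")

  # equal permittivities: pure propagation, diag(exp(-i a g), exp(+i a g))
  eps <- 2.25 + 0i
  g <- 140
  m <- layer_matrix(eps, eps, g, w)
  alpha <- 2 * pi / 800 * sqrt(eps)
  expect_equal(m[1, 1], exp(-1i * alpha * g), tolerance = 1e-12)
  expect_equal(m[2, 2], exp(1i * alpha * g), tolerance = 1e-12)
  expect_equal(m[1, 2], 0 + 0i)
  expect_equal(m[2, 1], 0 + 0i)

  # bare interface, h = sqrt(2.25/1) = 1.5
  m2 <- layer_matrix(1 + 0i, 2.25 + 0i, 0, w)
  expect_equal(unclass(m2), 0.5 * matrix(c(2.5, -0.5, -0.5, 2.5), 2, 2) + 0i,
               tolerance = 1e-12)

  # TE and TM describe the same interface at normal incidence: identical
  # reflectance (the transmitted amplitudes differ by the admittance
  # bookkeeping, which rta() resolves into equal power transmittance)
  for (ep in list(c(1, 2.25), c(2.89, 1.96), c(2.25, -35.99 + 1.2i))) {
    mte <- layer_matrix(ep[1], ep[2], 55, plane_wave(800, 0, "TE"))
    mtm <- layer_matrix(ep[1], ep[2], 55, plane_wave(800, 0, "TM"))
    rte <- mte[2, 1] / mte[1, 1]; rtm <- mtm[2, 1] / mtm[1, 1]
    expect_equal(Mod(rte), Mod(rtm), tolerance = 1e-12)
  }
})

test_that("transfer matrices compose and stay consistent", {
  glass <- material_library()$glass
  w <- plane_wave(900, 0, "TE")

  # no layers, identical media: identity
  m <- transfer_matrix(stack_spec(glass, list(), glass), w)
  expect_equal(unclass(m), diag(2) + 0i, tolerance = 1e-14)

  # group property: a layer equals two half-thickness layers
  slab <- material("s", constant_index(1.8))
  amb <- material("amb", constant_index(1.0))
  whole <- stack_spec(amb, list(layer(slab, 321)), amb)
  split <- stack_spec(amb, list(layer(slab, 160.5), layer(slab, 160.5)), amb)
  expect_equal(unclass(transfer_matrix(whole, w)),
               unclass(transfer_matrix(split, w)), tolerance = 1e-12)

  # lossless stack: |det M| is wavelength-independent (media-impedance
  # factors only)
  toy <- toy_stack()
  dets <- vapply(seq(700, 1000, by = 50), function(l) {
    m <- transfer_matrix(toy, plane_wave(l, 0, "TE"))
    Mod(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
  }, 0)
  expect_lt(diff(range(dets)), 1e-10)
})

test_that("single-interface response matches the Fresnel closed forms", {
  amb <- material("a", constant_index(1.0))
  glass <- material("g", constant_index(1.5))
  st <- stack_spec(amb, list(), glass)

  out <- rta(st, plane_wave(800, 0, "TE"))
  expect_equal(out$R, 0.04, tolerance = 1e-10)
  expect_equal(out$T, 0.96, tolerance = 1e-10)
  expect_equal(out$A, 0, tolerance = 1e-12)

  for (th in c(0, 30, 60)) {
    for (pol in c("TE", "TM")) {
      got <- rta(st, plane_wave(800, th, pol))
      want <- fresnel_rt(1.0, 1.5, th, pol)
      expect_equal(got$R, want$R, tolerance = 1e-10)
      expect_equal(got$T, want$T, tolerance = 1e-10)
    }
  }
})

test_that("energy is conserved exactly and absorbed only by the metals", {
  # lossless quarter-wave mirror: A vanishes to numerical precision
  dbr <- generate_oracles()$dbr$stack
  sp <- stack_spectrum(dbr, seq(600, 1000, by = 2))
  expect_true(all(abs(sp$A) < 1e-10))
  expect_true(all(sp$R >= 0 & sp$R <= 1))
  expect_true(all(sp$T >= 0 & sp$T <= 1))

  # absorbing sensor stack: closure holds by construction, A bounded below
  sp2 <- baseline_spectrum()
  expect_equal(sp2$R + sp2$T + sp2$A, rep(1, nrow(sp2)))
  expect_true(all(sp2$A > -1e-9))
  expect_true(all(sp2$R >= 0 & sp2$R <= 1 & sp2$T >= 0 & sp2$T <= 1))
})

test_that("a single lossless layer reproduces the Airy etalon curve", {
  orc <- generate_oracles()$etalon
  lam <- seq(orc$resonance_nm - orc$fsr_nm / 2,
             orc$resonance_nm + orc$fsr_nm / 2, by = 1)
  sp <- stack_spectrum(orc$stack, lam)
  expect_equal(sp$R, orc$closed_form(lam), tolerance = 1e-8)

  # half-wave resonance of the symmetric etalon transmits fully
  at_res <- rta(orc$stack, plane_wave(orc$resonance_nm, 0, "TE"))
  expect_equal(at_res$T, 1, tolerance = 1e-8)
})

test_that("transmittance is reciprocal even through absorbing stacks", {
  st <- baseline_stack()
  rev_st <- reverse_stack(st)
  for (lam in c(805, 860, 931, 1030)) {
    w <- plane_wave(lam, 0, "TE")
    expect_equal(rta(st, w)$T, rta(rev_st, w)$T, tolerance = 1e-10)
  }
  # also at oblique incidence and TM
  w <- plane_wave(900, 25, "TM")
  expect_equal(rta(st, w)$T, rta(rev_st, w)$T, tolerance = 1e-10)
})

test_that("polarizations are degenerate at normal incidence", {
  st <- baseline_stack()
  lam <- seq(780, 1060, by = 20)
  te <- stack_spectrum(st, lam, 0, "TE")
  tm <- stack_spectrum(st, lam, 0, "TM")
  expect_equal(te$R, tm$R, tolerance = 1e-12)
  expect_equal(te$T, tm$T, tolerance = 1e-12)
})

test_that("spectra are deterministic and consistent with pointwise rta", {
  st <- baseline_stack()
  lam <- seq(900, 960, by = 0.5)
  a <- stack_spectrum(st, lam)
  b <- stack_spectrum(st, lam)
  expect_identical(a$R, b$R)
  expect_identical(a$T, b$T)

  one <- stack_spectrum(st, 931)
  pt <- rta(st, plane_wave(931, 0, "TE"))
  expect_equal(one$R, pt$R)
  expect_equal(one$T, pt$T)
  expect_equal(nrow(one), 1)
})

test_that("field profiles are physical", {
  # uniform medium everywhere: no reflections, |E| = 1
  amb <- material("amb", constant_index(1.4))
  uni <- stack_spec(amb, list(layer(amb, 500)), amb)
  pr <- field_profile(uni, plane_wave(800, 0, "TE"), z_resolution = 10)
  expect_equal(pr$abs2_E, rep(1, nrow(pr)), tolerance = 1e-12)

  # E and dE/dz continuous across dielectric interfaces (TE)
  toy <- toy_stack()
  prt <- field_profile(toy, plane_wave(700, 0, "TE"), z_resolution = 0.25)
  for (zi in c(0, 100, 300)) {
    at <- which(prt$z_nm == zi)
    expect_length(at, 2)  # right edge of one region, left edge of the next
    El <- complex(real = prt$Re_E[at[1]], imaginary = prt$Im_E[at[1]])
    Er <- complex(real = prt$Re_E[at[2]], imaginary = prt$Im_E[at[2]])
    expect_lt(Mod(El - Er), 1e-9)
    # one-sided slopes from either side of the interface
    sl <- (El - complex(real = prt$Re_E[at[1] - 1],
                        imaginary = prt$Im_E[at[1] - 1])) / 0.25
    sr <- (complex(real = prt$Re_E[at[2] + 1],
                   imaginary = prt$Im_E[at[2] + 1]) - Er) / 0.25
    # one-sided finite differences carry O(dz * k^2 |E|) ~ 1e-4 error
    expect_lt(Mod(sl - sr), 5e-4)
  }
})

test_that("mode fields localize where their labels claim", {
  modes <- baseline_modes()
  st <- baseline_stack()
  zb <- z_breaks(st)
  cavity <- modes[modes$label == "cavity", ]
  tpp1 <- modes[modes$label == "TPP1", ]

  prc <- field_profile(st, plane_wave(cavity$lambda0_nm, 0, "TE"),
                       z_resolution = 5)
  zmax <- prc$z_nm[which.max(prc$abs2_E)]
  expect_gt(zmax, zb[13])   # inside the analyte interval
  expect_lt(zmax, zb[15])

  prt <- field_profile(st, plane_wave(tpp1$lambda0_nm, 0, "TE"),
                       z_resolution = 5)
  zmax1 <- prt$z_nm[which.max(prt$abs2_E)]
  metal1_center <- (zb[13] + zb[14]) / 2
  expect_lt(abs(zmax1 - metal1_center), 200)
})

test_that("angular maps blueshift the resonances and embed the normal-incidence spectrum", {
  st <- baseline_stack()
  lam <- seq(750, 1100, by = 0.5)
  mp <- angular_map(st, lam, c(0, 10, 20), "TE")

  sp0 <- stack_spectrum(st, lam, 0, "TE")
  expect_equal(mp$R[, 1], sp0$R, tolerance = 1e-12)

  dips_at <- function(R) {
    i <- which(diff(sign(diff(R))) == 2) + 1
    i <- i[R[i] < 0.9]
    lam[i]
  }
  # follow each mode branch in two hops so the large shifts at 20 degrees
  # cannot jump it onto a neighbouring branch
  modes <- baseline_modes()
  for (x0 in modes$lambda0_nm) {
    x <- x0
    for (j in 2:3) {
      dj <- dips_at(mp$R[, j])
      x <- dj[which.min(abs(dj - x))]
    }
    expect_lt(x, x0)
  }
})
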