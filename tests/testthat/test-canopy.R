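test_that("diffuse fraction evaluates the clearness polynomial", {
  expect_identical(diffuse_fraction(0), 0.7527)
  expect_equal(diffuse_fraction(1), 0.1638, tolerance = 1e-12)
  expect_equal(diffuse_fraction(0.5), 0.5240875, tolerance = 1e-12)
  expect_error(diffuse_fraction(1.2), "\\[0, 1\\]")
  expect_error(diffuse_fraction(-0.1), "\\[0, 1\\]")
})

test_that("PAR split is exact and non-negative", {
  expect_equal(split_par(0, 0.5), list(par_dif = 0, par_dir = 0))
  sp <- split_par(100, 0)
  expect_equal(sp$par_dif, 75.27)
  expect_equal(sp$par_dir, 24.73)
  R <- runif(200)
  par <- runif(200, 0, 500)
  sp <- split_par(par, R)
  expect_identical(sp$par_dif + sp$par_dir, par) # exact closure
  expect_true(all(sp$par_dif >= 0 & sp$par_dir >= 0))
})

test_that("sunlit/shaded LAI split closes exactly and saturates", {
  expect_equal(
    sunlit_shaded_lai(0, 0.8, 0.5),
    list(lai_sun = 0, lai_shade = 0)
  )
  s <- sunlit_shaded_lai(2, 0.8, 0.5)
  expect_equal(s$lai_sun, 1 - exp(-1.6), tolerance = 1e-15)
  expect_equal(sunlit_shaded_lai(500, 0.8, 0.5)$lai_sun, 2 * 0.5, tolerance = 1e-10)
  lai <- runif(300, 0, 10)
  om <- runif(300, 0.4, 1)
  ct <- runif(300, 0.05, 1)
  sp <- sunlit_shaded_lai(lai, om, ct)
  expect_identical(sp$lai_sun + sp$lai_shade, lai)
  expect_true(all(sp$lai_shade >= 0))
  expect_true(all(sp$lai_sun <= pmin(lai, 2 * ct) + 1e-12))
  # monotone in lai and clumping
  l <- seq(0, 8, by = 0.25)
  expect_true(all(diff(sunlit_shaded_lai(l, 0.7, 0.6)$lai_sun) >= 0))
  o <- seq(0.3, 1, by = 0.05)
  expect_true(all(diff(sunlit_shaded_lai(3, o, 0.6)$lai_sun) >= 0))
  expect_error(sunlit_shaded_lai(2, 0.8, 0), "daylight")
})

test_that("multiple scattering follows the printed form with a zero floor", {
  expect_identical(multiple_scatter(0, 3, 0.8, 0.6), 0)
  expect_identical(multiple_scatter(200, 11, 0.8, 0.6), 0) # root of linear term
  expect_identical(multiple_scatter(200, 14, 0.8, 0.6), 0) # floored
  expect_equal(multiple_scatter(200, 3, 0.8, 0.6), 4.917352259402477,
    tolerance = 1e-12
  )
})

test_that("under-canopy diffuse transmission", {
  expect_identical(diffuse_zenith_cosine(0), 0.537)
  expect_equal(under_canopy_diffuse(120, 0, 0.9), 120) # no canopy
  expect_identical(under_canopy_diffuse(0, 4, 0.9), 0)
  expect_equal(under_canopy_diffuse(150, 4, 0.9), 8.88966717958227,
    tolerance = 1e-12
  )
  # transmission never exceeds the incoming diffuse flux
  lai <- runif(100, 0, 9)
  pd <- runif(100, 0, 300)
  expect_true(all(under_canopy_diffuse(pd, lai, 0.8) <= pd))
})

test_that("absorbed PAR matches the worked decomposition", {
  p <- partition_radiation(
    par = 300, clearness_R = 0.6, lai = 2,
    clumping = 0.8, albedo = 0.18, cos_theta = 0.5
  )
  expect_equal(p$par_dif, 109.295424, tolerance = 1e-12)
  expect_equal(p$par_dir, 190.704576, tolerance = 1e-12)
  expect_equal(p$scatter_C, 5.829675883491501, tolerance = 1e-12)
  expect_equal(p$par_dif_u, 27.971678542596402, tolerance = 1e-12)
  expect_equal(p$apar_shade, 45.81998492240299, tolerance = 1e-12)
  expect_equal(p$apar_sun, 155.23178343635537, tolerance = 1e-12)
})

test_that("degenerate canopies and diffuse-only light behave correctly", {
  # no leaves absorb nothing
  p0 <- partition_radiation(250, 0.4, 0, 0.8, 0.2, 0.6)
  expect_identical(c(p0$apar_sun, p0$apar_shade), c(0, 0))
  # without a direct beam, per-leaf absorption is equal for both fractions
  p <- partition_radiation(200, 0, 3, 0.8, 0.2, 0.6)
  # clearness 0 -> diffuse fraction 0.7527, so a direct beam remains; force
  # pure diffuse via the components instead
  ll <- sunlit_shaded_lai(3, 0.8, 0.6)
  pdu <- under_canopy_diffuse(200, 3, 0.8)
  per_leaf <- (200 - pdu) / 3
  apar_sun <- (1 - 0.2) * per_leaf * ll$lai_sun
  apar_shade <- (1 - 0.2) * per_leaf * ll$lai_shade
  expect_equal(apar_sun / ll$lai_sun, apar_shade / ll$lai_shade)
})

test_that("whole-module equivalence with an independent transcription", {
  cases <- random_admissible(400, seed = 31)
  for (i in seq_len(nrow(cases))) {
    cc <- cases[i, ]
    cosz <- solar_cos_zenith(cc$latitude, cc$doy)
    if (cosz <= 0) next
    R <- runif(1)
    p <- partition_radiation(
      par = cc$sw_down, clearness_R = R, lai = cc$lai,
      clumping = cc$clumping, albedo = cc$albedo, cos_theta = cosz
    )
    # straight-line re-evaluation
    fd <- min(1, max(0, 0.7527 + 3.8453 * R - 16.316 * R^2 + 18.962 * R^3 - 7.0802 * R^4))
    pdif <- cc$sw_down * fd
    pdir <- cc$sw_down - pdif
    lsun <- min(cc$lai, 2 * cosz * (1 - exp(-cc$lai * cc$clumping / (2 * cosz))))
    C <- max(0, 0.07 * cc$clumping * pdir * (1.1 - 0.1 * cc$lai) * exp(-cosz))
    pdu <- pdif * exp(-0.5 * cc$clumping * cc$lai / (0.537 + 0.025 * cc$lai))
    ash <- (1 - cc$albedo) * ((pdif - pdu) / cc$lai + C) * (cc$lai - lsun)
    asu <- (1 - cc$albedo) * (pdir * 0.5 / cosz + (pdif - pdu) / cc$lai + C) * lsun
    expect_equal(p$apar_shade, ash, tolerance = 1e-12)
    expect_equal(p$apar_sun, asu, tolerance = 1e-12)
  }
})
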