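toy_spec <- grid_spec(0, 1, 44, 45, res = 0.25)

test_that("GeoTIFF codec round-trips int16, float64 and multi-band rasters", {
  set.seed(71)
  m <- matrix(as.double(sample(-30000:30000, 16)), 4, 4)
  f <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(m, f, toy_spec, type = "int16", nodata = -32768)
  g <- read_geotiff(f)
  expect_true(all(g$values == m))
  expect_equal(g$nodata, -32768)
  expect_equal(unclass(g$spec), unclass(toy_spec))

  x <- matrix(rnorm(16), 4, 4)
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(x, f2, toy_spec, type = "float64")
  expect_identical(read_geotiff(f2)$values, x)

  a <- array(rnorm(48), c(4, 4, 3))
  f3 <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(a, f3, toy_spec, type = "float64")
  expect_identical(read_geotiff(f3)$values, a)
})

test_that("codec output is readable by an independent TIFF implementation", {
  # libtiff (via the tiff package) parses the file structure; it returns
  # 16-bit samples as unsigned, so compare modulo 2^16
  set.seed(73)
  m <- matrix(as.double(sample(-1000:1000, 16)), 4, 4)
  f <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(m, f, toy_spec, type = "int16", nodata = -32768)
  ext <- tiff::readTIFF(f, as.is = TRUE)
  expect_true(all(ifelse(ext > 32767, ext - 65536, ext) == m))
})

test_that("product files follow the archive naming convention", {
  expect_identical(product_filename("GPP", "annual", 1999), "GPP_v21_1999.tif")
  expect_identical(
    product_filename("Shade_GPP", "eight_day", 1999, 249),
    "Shade_GPP_v21_1999_249.tif"
  )
  expect_identical(
    product_filename("Sun_GPP", "monthly", 1999, 1),
    "Sun_GPP_v21_1999_01.tif"
  )
})

test_that("integer encoding round-trips within half a quantum", {
  expect_identical(product_scale_factor("monthly"), 0.1)
  expect_identical(product_scale_factor("eight_day"), 0.01)
  # stated rounding rule: half away from zero
  expect_identical(encode_product(123.45, 0.1), 1235)
  expect_identical(encode_product(-123.45, 0.1), -1235)
  expect_error(encode_product(400, 0.01), "overflow")
  for (scale in c(0.1, 0.01)) {
    v <- runif(1000, 0, 300)
    err <- abs(decode_product(encode_product(v, scale), scale) - v)
    expect_lte(max(err), scale / 2)
  }
})

test_that("written products decode to the original field within one quantum", {
  set.seed(75)
  v <- matrix(runif(16, 0, 500), 4, 4)
  v[2, 3] <- NA # nodata pixel
  dir <- withr::local_tempdir()
  p_m <- write_product(v, toy_spec, "GPP", "monthly", 1999, 6, dir)
  expect_identical(basename(p_m), "GPP_v21_1999_06.tif")
  back <- read_product(p_m)
  expect_lte(max(abs(back$values - v), na.rm = TRUE), 0.05)
  expect_true(is.na(back$values[2, 3]))
  expect_identical(back$scale_factor, 0.1)
  # annual products are stored unscaled as doubles
  p_a <- write_product(v, toy_spec, "GPP", "annual", 1999, NULL, dir)
  back_a <- read_product(p_a)
  expect_identical(back_a$values[1, 1], v[1, 1])
  expect_true(is.na(back_a$values[2, 3]))
})

test_that("a grid run writes a complete, additive product set with manifest", {
  g <- make_grid(
    spec = grid_spec(0, 0.5, 44.5, 45, res = 0.1), years = 1,
    seed = 3
  )
  dir <- withr::local_tempdir()
  write_product_set(g$truth, g$drivers$spec, dir)
  files <- list.files(dir, pattern = "tif$")
  # 3 variables x (46 eight-day + 12 monthly + 1 annual)
  expect_length(files, 3 * (46 + 12 + 1))
  expect_true(file.exists(file.path(dir, "manifest.txt")))
  manifest <- readLines(file.path(dir, "manifest.txt"))
  expect_length(manifest, length(files))
  # annual equals the decoded monthly sum within the encoding quantum
  ann <- read_product(file.path(dir, "GPP_v21_2001.tif"))$values
  msum <- 0
  for (m in 1:12) {
    msum <- msum + read_product(file.path(
      dir,
      sprintf("GPP_v21_2001_%02d.tif", m)
    ))$values
  }
  expect_lte(max(abs(msum - ann), na.rm = TRUE), 12 * 0.05)
  # non-vegetated pixels are nodata everywhere, not zero
  if (any(is.na(g$truth$gpp[, , 1]))) {
    expect_true(all(is.na(ann[is.na(g$truth$gpp[, , 1])])))
  }
})

test_that("grid runs agree with per-pixel site runs", {
  g <- make_grid(
    spec = grid_spec(0, 0.25, 44.75, 45, res = 0.125), years = 1,
    seed = 9
  )
  d <- g$drivers
  ctr <- grid_centers(d$spec)
  for (px in list(c(1, 1), c(2, 2))) {
    i <- px[1]
    j <- px[2]
    code <- d$pft[i, j]
    if (is.na(code)) next
    forcing <- data.frame(
      date = d$dates,
      t_air_K = d$t_air_K[i, j, ], vpd = d$vpd[i, j, ],
      sw_down = d$sw_down[i, j, ], co2_ppm = d$co2_ppm,
      lai = d$lai[i, j, ], latitude = ctr$lat[i],
      doy = as.integer(format(d$dates, "%j"))
    )
    out <- run_series(forcing, pft_parameters(code), diagnostics = FALSE)
    expect_equal(g$truth$gpp[i, j, ], out$gpp, tolerance = 1e-12)
    expect_equal(g$truth$gpp_sun[i, j, ], out$gpp_sun, tolerance = 1e-12)
  }
})

test_that("driver directories round-trip through write and read", {
  g <- make_grid(
    spec = grid_spec(0, 0.25, 44.75, 45, res = 0.125), years = 1,
    seed = 13
  )
  dir <- withr::local_tempdir()
  write_driver_dir(g$drivers, dir)
  back <- read_driver_dir(dir)
  expect_identical(back$pft, g$drivers$pft)
  expect_equal(back$lai, g$drivers$lai, tolerance = 1e-12)
  expect_identical(back$t_air_K, g$drivers$t_air_K)
  expect_equal(back$co2_ppm, g$drivers$co2_ppm, tolerance = 1e-9) # CSV text round trip
  expect_identical(as.Date(back$dates), as.Date(g$drivers$dates))
})
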