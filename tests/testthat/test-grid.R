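toy_spec <- grid_spec(0, 1, 44, 45, res = 0.25) # 4 x 4 cells

test_that("land-cover remapping is a faithful table lookup", {
  tab <- lccs_igbp_table()
  # all-water input -> all nodata under vegetated_only
  water <- matrix(210, 3, 3)
  expect_true(all(is.na(remap_landcover(water, vegetated_only = TRUE))))
  expect_true(all(remap_landcover(water) == 17))
  # a single known cropland code maps uniformly to IGBP cropland
  crop <- matrix(10, 2, 5)
  expect_true(all(remap_landcover(crop) == 12))
  expect_true(all(pft_from_igbp(remap_landcover(crop)) == "CRO"))
  # mixed toy raster vs a hand-applied lookup
  codes <- matrix(c(50, 70, 130, 210, 61, 0, 9999, 180, 30), 3, 3)
  got <- remap_landcover(codes)
  manual <- matrix(as.numeric(tab$igbp_code[match(as.vector(codes), tab$lccs_code)]), 3, 3)
  expect_equal(got, manual)
  expect_true(is.na(got[1, 3])) # unknown code 9999 -> nodata
  # remapping never invents a class absent from the table
  expect_true(all(stats::na.omit(as.vector(got)) %in% tab$igbp_code))
})

test_that("nearest-neighbour resampling matches a brute-force search", {
  src <- grid_spec(0, 1, 44, 45, res = 1 / 11) # awkward 0.0909 deg cells
  set.seed(61)
  v <- matrix(
    as.double(sample(1:9, src$nrow * src$ncol, replace = TRUE)),
    src$nrow, src$ncol
  )
  dst <- grid_spec(0, 1, 44, 45, res = 0.05)
  got <- resample_nearest(v, src, dst)
  sc <- grid_centers(src)
  dc <- grid_centers(dst)
  brute <- matrix(0, dst$nrow, dst$ncol)
  for (i in seq_len(dst$nrow)) {
    for (j in seq_len(dst$ncol)) {
      brute[i, j] <- v[
        which.min(abs(sc$lat - dc$lat[i])),
        which.min(abs(sc$lon - dc$lon[j]))
      ]
    }
  }
  expect_identical(got, brute)
  # categorical values preserved exactly; no new classes invented
  expect_true(all(got %in% v))
  # identity resampling
  expect_identical(resample_nearest(v, src, src), v)
  # 2x2 -> 1x1 takes the nearest source centre
  s22 <- grid_spec(0, 1, 0, 1, res = 0.5)
  s11 <- grid_spec(0, 1, 0, 1, res = 1)
  m <- matrix(1:4, 2, 2)
  expect_length(resample_nearest(m, s22, s11), 1)
  expect_error(
    resample_nearest(v, src, grid_spec(0, 1, 44, 45, res = 0.05, crs = "EPSG:3857")),
    "CRS"
  )
})

test_that("stamped LAI interpolates linearly in time per pixel", {
  stack <- array(0, c(2, 2, 2))
  stack[, , 1] <- 2
  stack[, , 2] <- 4
  daily <- interpolate_lai_daily(stack, c(1, 17), 1:17)
  expect_equal(daily[1, 1, 9], 3) # midpoint
  expect_equal(daily[, , 1], matrix(2, 2, 2))
  expect_equal(daily[, , 17], matrix(4, 2, 2))
  # endpoints held constant outside the stamped range
  out <- interpolate_lai_daily(stack, c(5, 10), 1:15)
  expect_equal(out[1, 1, 1], 2)
  expect_equal(out[1, 1, 15], 4)
  # constant series stays constant; single slice replicates
  cs <- interpolate_lai_daily(array(3, c(2, 2, 3)), c(1, 8, 16), 1:16)
  expect_true(all(cs == 3))
  one <- interpolate_lai_daily(array(5, c(2, 2, 1)), 1, 1:4)
  expect_true(all(one == 5))
  # irregular stamps vs per-pixel 1-D interpolation oracle
  set.seed(63)
  st <- c(1, 4, 20, 33)
  stk <- array(runif(2 * 2 * 4), c(2, 2, 4))
  got <- interpolate_lai_daily(stk, st, 1:33)
  for (i in 1:2) {
    for (j in 1:2) {
      want <- approx(st, stk[i, j, ], xout = 1:33, rule = 2)$y
      expect_equal(got[i, j, ], want)
    }
  }
})

test_that("temporal aggregation is additive and follows the 8-day DOY grid", {
  dates <- seq(as.Date("1999-01-01"), as.Date("1999-12-31"), by = "day")
  set.seed(65)
  daily <- array(runif(2 * 2 * 365, 0, 10), c(2, 2, 365))
  agg <- aggregate_products(daily, dates)
  # annual equals the sums of months and of 8-day periods exactly
  ann <- agg$annual$values[, , 1]
  expect_equal(rowSums(agg$monthly$values, dims = 2), ann, tolerance = 1e-12)
  expect_equal(rowSums(agg$eight_day$values, dims = 2), ann, tolerance = 1e-12)
  expect_equal(ann, rowSums(daily, dims = 2), tolerance = 1e-12)
  # MODIS-style period starts and the short final period
  expect_equal(agg$eight_day$index$period, seq(1, 361, by = 8))
  expect_false(any(agg$eight_day$partial))
  expect_false(any(agg$monthly$partial))
  # constant 1 g C m-2 d-1 over a 31-day month sums to 31
  expect_equal(
    aggregate_products(
      array(1, c(1, 1, 31)),
      seq(as.Date("1999-01-01"), by = "day", length.out = 31)
    )$monthly$values[1, 1, 1], 31
  )
  # all-zero days give all-zero products
  z <- aggregate_products(array(0, c(1, 1, 365)), dates)
  expect_true(all(z$eight_day$values == 0) && all(z$annual$values == 0))
  # an incomplete month is flagged partial
  part <- aggregate_products(daily[, , 1:40, drop = FALSE], dates[1:40])
  expect_true(part$monthly$partial[2])
  expect_false(part$monthly$partial[1])
})

test_that("per-pixel trend matches closed-form OLS and masks non-significance", {
  years <- 2001:2010
  # perfectly linear pixel: slope 20, p ~ 0, retained
  lin <- array(rep(100 + 20 * (years - 2001), each = 1), c(1, 1, 10))
  tr <- pixel_trend(lin, years)
  expect_equal(tr$slope[1, 1], 20, tolerance = 1e-10)
  expect_lt(tr$p_value[1, 1], 1e-12)
  expect_equal(tr$slope_masked[1, 1], 20, tolerance = 1e-10)
  # constant pixel: zero slope, masked
  cst <- array(5, c(1, 1, 10))
  tc <- pixel_trend(cst, years)
  expect_identical(tc$slope[1, 1], 0)
  expect_true(is.na(tc$slope_masked[1, 1]))
  # hand-computed 5-point regression vs lm oracle
  y <- c(3.2, 4.1, 3.9, 5.5, 6.0)
  stack <- array(y, c(1, 1, 5))
  t5 <- pixel_trend(stack, 1:5)
  fit <- summary(lm(y ~ x, data.frame(x = 1:5, y = y)))
  expect_equal(t5$slope[1, 1], unname(fit$coefficients["x", "Estimate"]))
  expect_equal(t5$p_value[1, 1], unname(fit$coefficients["x", "Pr(>|t|)"]))
})
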