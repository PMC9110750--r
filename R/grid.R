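#' Regular lon/lat grid specification
#'
#' Pixel-centre registered regular grid in geographic coordinates, rows
#' ordered north to south, columns west to east.
#'
#' @param xmin,xmax,ymin,ymax Grid edges in degrees.
#' @param res Cell size in degrees (default 0.05; the global default grid is
#'   7200 x 3600 cells).
#' @param crs Coordinate reference identifier (only "EPSG:4326" is handled).
#' @return List of class `grid_spec` with `nrow`, `ncol` and cell-centre
#'   coordinate accessors.
#' @export
grid_spec <- function(xmin = -180, xmax = 180, ymin = -90, ymax = 90,
                      res = 0.05, crs = "EPSG:4326") {
  nc <- (xmax - xmin) / res
  nr <- (ymax - ymin) / res
  if (abs(nc - round(nc)) > 1e-8 || abs(nr - round(nr)) > 1e-8) {
    stop("extent is not an integer number of cells at this resolution", call. = FALSE)
  }
  structure(list(
    xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
    res = res, crs = crs, nrow = as.integer(round(nr)),
    ncol = as.integer(round(nc))
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "grid_spec: %d x %d cells at %g deg, lon [%g, %g], lat [%g, %g], %s\n",
    x$nrow, x$ncol, x$res, x$xmin, x$xmax, x$ymin, x$ymax, x$crs
  ))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param spec A [grid_spec()].
#' @return List with `lon` (west to east) and `lat` (north to south).
#' @export
grid_centers <- function(spec) {
  list(
    lon = spec$xmin + (seq_len(spec$ncol) - 0.5) * spec$res,
    lat = spec$ymax - (seq_len(spec$nrow) - 0.5) * spec$res
  )
}

#' LCCS to IGBP land-cover lookup table
#'
#' Crosswalk from the UN Land Cover Classification System codes (as used by
#' the ESA-CCI land-cover product) to IGBP classes, plus the model
#' vegetation-type code each IGBP class resolves to (`NA` for non-vegetated
#' classes). The shipped table can be overridden.
#'
#' @param file Path to a CSV with columns `lccs_code`, `lccs_label`,
#'   `igbp_code`, `igbp_class`, `model_pft`.
#' @return Data frame lookup table.
#' @export
lccs_igbp_table <- function(file = system.file("extdata", "lccs_to_igbp.csv",
                              package = "tllue"
                            )) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Remap LCCS land-cover codes to IGBP codes
#'
#' Table lookup; codes absent from the table become `NA` (nodata), as do
#' classes mapping to non-vegetated IGBP types when `vegetated_only = TRUE`.
#'
#' @param lccs_codes Matrix (or vector) of LCCS class codes.
#' @param table Lookup table from [lccs_igbp_table()].
#' @param vegetated_only If `TRUE`, non-vegetated IGBP classes (urban, snow,
#'   barren, water) are returned as `NA`.
#' @return Object of the same shape holding IGBP codes.
#' @export
remap_landcover <- function(lccs_codes, table = lccs_igbp_table(),
                            vegetated_only = FALSE) {
  idx <- match(as.vector(lccs_codes), table$lccs_code)
  igbp <- table$igbp_code[idx]
  if (vegetated_only) {
    igbp[is.na(table$model_pft[idx])] <- NA
  }
  out <- lccs_codes
  out[] <- igbp
  out
}

#' Model vegetation type for IGBP codes
#'
#' @param igbp_codes Matrix or vector of IGBP class codes (1--17).
#' @param table Lookup table from [lccs_igbp_table()].
#' @return Character object of the same shape: model parameter codes (DNF
#'   resolves to DBF parameters downstream), `NA` for non-vegetated classes.
#' @export
pft_from_igbp <- function(igbp_codes, table = lccs_igbp_table()) {
  lut <- unique(table[!is.na(table$igbp_code), c("igbp_code", "model_pft")])
  pft <- lut$model_pft[match(as.vector(igbp_codes), lut$igbp_code)]
  pft[pft == ""] <- NA
  if (is.matrix(igbp_codes)) {
    matrix(pft, nrow(igbp_codes), ncol(igbp_codes))
  } else {
    pft
  }
}

#' Nearest-neighbour resampling between regular lon/lat grids
#'
#' For each target cell centre, takes the value of the nearest source cell
#' centre. Categorical values are preserved exactly (no interpolation).
#'
#' @param values Matrix on the source grid (rows north to south).
#' @param src,dst Source and target [grid_spec()]s; their `crs` must match.
#' @return Matrix on the target grid.
#' @export
resample_nearest <- function(values, src, dst) {
  if (!identical(src$crs, dst$crs)) {
    stop("CRS mismatch between source and target grids", call. = FALSE)
  }
  stopifnot(nrow(values) == src$nrow, ncol(values) == src$ncol)
  ctr <- grid_centers(dst)
  col_idx <- pmin(src$ncol, pmax(1, round((ctr$lon - src$xmin) / src$res + 0.5)))
  row_idx <- pmin(src$nrow, pmax(1, round((src$ymax - ctr$lat) / src$res + 0.5)))
  values[row_idx, col_idx, drop = FALSE]
}

#' Interpolate a stamped LAI raster series to daily values
#'
#' Per-pixel linear interpolation in time between the stamped slices (8-day
#' or half-month products); outside the stamped range the endpoint slices
#' are held constant.
#'
#' @param stack 3-D array `[row, col, slice]` of LAI.
#' @param stamp_dates Dates (or numeric day stamps) of the slices, sorted.
#' @param target_dates Dates (or numeric) at which daily values are wanted.
#' @return 3-D array `[row, col, day]`.
#' @export
interpolate_lai_daily <- function(stack, stamp_dates, target_dates) {
  st <- as.numeric(stamp_dates)
  tg <- as.numeric(target_dates)
  k <- dim(stack)[3]
  if (length(st) != k) stop("stamp_dates must match the number of slices", call. = FALSE)
  if (is.unsorted(st, strictly = TRUE)) stop("stamp_dates must be sorted", call. = FALSE)
  out <- array(NA_real_, c(dim(stack)[1], dim(stack)[2], length(tg)))
  if (k == 1) {
    for (j in seq_along(tg)) out[, , j] <- stack[, , 1]
    return(out)
  }
  for (j in seq_along(tg)) {
    t <- min(max(tg[j], st[1]), st[k])
    i <- findInterval(t, st, rightmost.closed = TRUE)
    i <- min(i, k - 1)
    w <- (t - st[i]) / (st[i + 1] - st[i])
    out[, , j] <- (1 - w) * stack[, , i] + w * stack[, , i + 1]
  }
  out
}

.eight_day_starts <- function() seq(1, 361, by = 8)

#' Aggregate daily GPP fields to 8-day, monthly and annual products
#'
#' 8-day sums follow the MODIS day-of-year convention (periods start at DOY
#' 001, 009, ..., 361; the final period of the year is short and restarts on
#' 1 January). Monthly and annual products are calendar sums. Periods with
#' fewer days present than expected are flagged partial. Units are
#' g C m^-2 per period; annual sums equal the sum of the monthly (and 8-day)
#' sums exactly.
#'
#' @param daily 3-D array `[row, col, day]` of daily GPP (g C m^-2 d^-1).
#' @param dates Vector of dates, one per daily slice, sorted.
#' @return List with elements `eight_day`, `monthly`, `annual`, each a list
#'   of `values` (3-D array), `index` (data frame of period labels) and
#'   `partial` (logical per period).
#' @export
aggregate_products <- function(daily, dates) {
  dates <- as.Date(dates)
  stopifnot(dim(daily)[3] == length(dates))
  year <- as.integer(format(dates, "%Y"))
  doy <- as.integer(format(dates, "%j"))
  month <- as.integer(format(dates, "%m"))

  sum_groups <- function(fac, expected_fun) {
    groups <- split(seq_along(dates), fac, drop = TRUE)
    vals <- array(0, c(dim(daily)[1], dim(daily)[2], length(groups)))
    partial <- logical(length(groups))
    for (g in seq_along(groups)) {
      idx <- groups[[g]]
      sl <- daily[, , idx, drop = FALSE]
      vals[, , g] <- rowSums(sl, dims = 2)
      partial[g] <- length(idx) < expected_fun(idx)
    }
    list(values = vals, keys = names(groups), partial = partial)
  }

  period_start <- .eight_day_starts()[findInterval(doy, .eight_day_starts())]
  fac8 <- factor(sprintf("%04d_%03d", year, period_start),
    levels = unique(sprintf("%04d_%03d", year, period_start))
  )
  days_in_year <- function(y) ifelse(y %% 4 == 0 & (y %% 100 != 0 | y %% 400 == 0), 366L, 365L)
  e8 <- sum_groups(fac8, function(idx) {
    ps <- period_start[idx[1]]
    if (ps == 361) days_in_year(year[idx[1]]) - 360 else 8L
  })
  facm <- factor(sprintf("%04d_%02d", year, month),
    levels = unique(sprintf("%04d_%02d", year, month))
  )
  em <- sum_groups(facm, function(idx) {
    fom <- as.Date(format(dates[idx[1]], "%Y-%m-01"))
    as.integer(format(seq(fom, by = "1 month", length.out = 2)[2] - 1, "%d"))
  })
  faca <- factor(year, levels = unique(year))
  ea <- sum_groups(faca, function(idx) days_in_year(year[idx[1]]))

  key_df <- function(keys, has_period) {
    parts <- strsplit(keys, "_")
    df <- data.frame(year = as.integer(vapply(parts, `[`, "", 1)))
    if (has_period) df$period <- as.integer(vapply(parts, `[`, "", 2))
    df
  }
  list(
    eight_day = list(
      values = e8$values, index = key_df(e8$keys, TRUE),
      partial = e8$partial
    ),
    monthly = list(
      values = em$values, index = key_df(em$keys, TRUE),
      partial = em$partial
    ),
    annual = list(
      values = ea$values, index = key_df(ea$keys, FALSE),
      partial = ea$partial
    )
  )
}

#' Per-pixel linear trend with significance mask
#'
#' Ordinary-least-squares slope of annual GPP on year for every pixel, with
#' a two-sided t-test on the slope. The masked slope retains only pixels
#' with p <= 0.05; constant series get zero slope and are masked.
#'
#' @param annual 3-D array `[row, col, year]` of annual values (>= 3 years).
#' @param years Numeric vector of years, one per slice.
#' @return List of matrices: `slope` (g C m^-2 a^-2), `p_value`, and
#'   `slope_masked` (slope with non-significant pixels set to `NA`).
#' @export
pixel_trend <- function(annual, years) {
  ny <- length(years)
  stopifnot(dim(annual)[3] == ny, ny >= 3)
  nr <- dim(annual)[1]
  nc <- dim(annual)[2]
  y <- matrix(annual, nr * nc, ny)
  x <- years - mean(years)
  sxx <- sum(x^2)
  xbar_y <- rowMeans(y)
  slope <- (y %*% x) / sxx
  resid <- y - xbar_y - slope %*% t(x)
  rss <- rowSums(resid^2)
  se <- sqrt(rss / (ny - 2) / sxx)
  # se = 0 with a non-zero slope is an exact linear series (p -> 0);
  # se = 0 with zero slope is a constant series (masked)
  tstat <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
  p <- 2 * stats::pt(-abs(tstat), df = ny - 2)
  p[se == 0 & slope == 0] <- 1
  slope_m <- matrix(slope, nr, nc)
  p_m <- matrix(p, nr, nc)
  masked <- slope_m
  masked[p_m > 0.05] <- NA
  list(slope = slope_m, p_value = p_m, slope_masked = masked)
}
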