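#' Product file naming convention
#'
#' Builds the archive file name for a product: `GPP_v21_<YYYY>.tif` for
#' annual, `<Var>_v21_<YYYY>_<MM>.tif` for monthly, and
#' `<Var>_v21_<YYYY>_<DOY>.tif` for 8-day products (e.g.
#' `Shade_GPP_v21_1999_249.tif`).
#'
#' @param variable One of "GPP", "Shade_GPP", "Sun_GPP".
#' @param cadence One of "eight_day", "monthly", "annual".
#' @param year Calendar year.
#' @param period Month (monthly) or period start DOY (8-day); ignored for
#'   annual.
#' @return File name (no directory).
#' @export
product_filename <- function(variable = c("GPP", "Shade_GPP", "Sun_GPP"),
                             cadence = c("eight_day", "monthly", "annual"),
                             year, period = NULL) {
  variable <- match.arg(variable)
  cadence <- match.arg(cadence)
  switch(cadence,
    annual = sprintf("%s_v21_%d.tif", variable, year),
    monthly = sprintf("%s_v21_%d_%02d.tif", variable, year, period),
    eight_day = sprintf("%s_v21_%d_%03d.tif", variable, year, period)
  )
}

#' Scale factor of a product cadence
#'
#' 0.01 for 8-day, 0.1 for monthly products (stored as 16-bit integers);
#' annual products are stored as doubles without scaling.
#'
#' @param cadence One of "eight_day", "monthly", "annual".
#' @return Numeric scale factor, or `NA` for annual.
#' @export
product_scale_factor <- function(cadence = c("eight_day", "monthly", "annual")) {
  cadence <- match.arg(cadence)
  c(eight_day = 0.01, monthly = 0.1, annual = NA_real_)[[cadence]]
}

.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Encode / decode product values for integer storage
#'
#' Sub-annual products are stored as `value / scale` rounded
#' half-away-from-zero to 16-bit integers; decoding multiplies back. The
#' round trip is within half a quantum everywhere.
#'
#' @param values Numeric values (g C m^-2 per period).
#' @param scale Scale factor (0.01 or 0.1).
#' @return Integer-valued numeric (encode) or numeric (decode).
#' @export
encode_product <- function(values, scale) {
  stored <- .round_half_away(values / scale)
  over <- which(is.finite(stored) & (stored < -32767 | stored > 32767))
  if (length(over)) {
    stop(
      "int16 overflow after scaling at element(s) ",
      paste(utils::head(over, 5), collapse = ", "),
      call. = FALSE
    )
  }
  stored
}

#' @rdname encode_product
#' @export
decode_product <- function(values, scale) values * scale

#' Write one product raster in the archive encoding
#'
#' Applies the cadence's scale factor and storage type (16-bit integer with
#' nodata -32768 for 8-day and monthly, 64-bit float with NaN nodata for
#' annual), names the file by the archive convention, and writes a
#' georeferenced GeoTIFF.
#'
#' @param values Matrix of period GPP, g C m^-2 per period; `NA` marks
#'   non-vegetated nodata.
#' @param spec [grid_spec()] of the raster.
#' @inheritParams product_filename
#' @param dir Output directory.
#' @return Full path of the written file, invisibly.
#' @export
write_product <- function(values, spec, variable, cadence, year,
                          period = NULL, dir = ".") {
  cadence <- match.arg(cadence, c("eight_day", "monthly", "annual"))
  path <- file.path(dir, product_filename(variable, cadence, year, period))
  scale <- product_scale_factor(cadence)
  desc <- sprintf(
    "tllue GPP product; variable=%s; cadence=%s; scale_factor=%s; units=g C m-2 per period; rounding=half-away-from-zero",
    variable, cadence, ifelse(is.na(scale), "1", format(scale))
  )
  if (cadence == "annual") {
    v <- values
    v[is.na(v)] <- NaN
    write_geotiff(v, path, spec, type = "float64", nodata = NULL, description = desc)
  } else {
    stored <- encode_product(values, scale)
    write_geotiff(stored, path, spec,
      type = "int16", nodata = -32768,
      description = desc
    )
  }
  invisible(path)
}

#' Read a product raster back to physical units
#'
#' @param path Path to a file written by [write_product()].
#' @return List with `values` (numeric matrix, g C m^-2 per period, `NA`
#'   for nodata), `spec`, `scale_factor`, `description`.
#' @export
read_product <- function(path) {
  g <- read_geotiff(path)
  scale <- 1
  m <- regmatches(g$description, regexec("scale_factor=([0-9.]+)", g$description))[[1]]
  if (length(m) == 2) scale <- as.numeric(m[2])
  v <- g$values
  if (!is.null(g$nodata)) v[v == g$nodata] <- NA
  v[is.nan(v)] <- NA
  list(
    values = decode_product(v, scale), spec = g$spec,
    scale_factor = scale, description = g$description
  )
}

#' Write a checksum manifest for a product directory
#'
#' @param dir Directory of product files.
#' @param path Manifest path (default `manifest.txt` inside `dir`).
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(dir, path = file.path(dir, "manifest.txt")) {
  files <- sort(list.files(dir, pattern = "\\.tif$", full.names = TRUE))
  sums <- tools::md5sum(files)
  writeLines(sprintf("%s  %s", sums, basename(files)), path)
  invisible(path)
}

#' Run the model over gridded drivers
#'
#' Applies the two-leaf model pixel-wise over driver stacks and returns
#' daily GPP fields for the three variables. Non-vegetated pixels (no model
#' vegetation type) are `NA` (nodata), distinguishing "no vegetation" from
#' "zero flux".
#'
#' @param drivers List with elements `spec` ([grid_spec()]), `pft`
#'   (character matrix of vegetation-type codes, `NA` = non-vegetated),
#'   `lai` (3-D array `[row, col, day]`), `t_air_K`, `vpd`, `sw_down` (each
#'   a 3-D daily array), `co2_ppm` (numeric vector per day, or 3-D array),
#'   and `dates` (one per day).
#' @param params_table Vegetation parameter table.
#' @param par_factor Shortwave-to-PAR conversion factor.
#' @return List with `gpp`, `gpp_sun`, `gpp_shade` 3-D arrays
#'   `[row, col, day]` and `dates`.
#' @export
run_grid <- function(drivers, params_table = pft_parameters(), par_factor = 0.43) {
  spec <- drivers$spec
  nr <- spec$nrow
  nc <- spec$ncol
  dates <- as.Date(drivers$dates)
  nd <- length(dates)
  lat <- matrix(grid_centers(spec)$lat, nr, nc)
  doy <- as.integer(format(dates, "%j"))

  gpp <- array(NA_real_, c(nr, nc, nd))
  gpp_sun <- gpp
  gpp_shade <- gpp
  co2 <- drivers$co2_ppm
  pfts <- unique(as.vector(drivers$pft))
  pfts <- pfts[!is.na(pfts)]
  for (code in pfts) {
    sel <- which(drivers$pft == code) # pixel indices (row-major in matrix sense)
    params <- pft_parameters(code, file = system.file("extdata", "pft_parameters.csv", package = "tllue"))
    npx <- length(sel)
    co2_day <- if (is.array(co2) && length(dim(co2)) == 3) NULL else co2
    forcing <- data.frame(
      t_air_K = as.vector(sapply(seq_len(nd), function(d) drivers$t_air_K[, , d][sel])),
      vpd = as.vector(sapply(seq_len(nd), function(d) drivers$vpd[, , d][sel])),
      sw_down = as.vector(sapply(seq_len(nd), function(d) drivers$sw_down[, , d][sel])),
      lai = as.vector(sapply(seq_len(nd), function(d) drivers$lai[, , d][sel])),
      co2_ppm = if (is.null(co2_day)) {
        as.vector(sapply(seq_len(nd), function(d) co2[, , d][sel]))
      } else {
        rep(co2_day, each = npx)
      },
      latitude = rep(lat[sel], nd),
      doy = rep(doy, each = npx)
    )
    out <- gpp_step(forcing, params, par_factor = par_factor, diagnostics = FALSE)
    for (d in seq_len(nd)) {
      i <- ((d - 1) * npx + 1):(d * npx)
      sl_g <- gpp[, , d]
      sl_s <- gpp_sun[, , d]
      sl_h <- gpp_shade[, , d]
      sl_g[sel] <- out$gpp[i]
      sl_s[sel] <- out$gpp_sun[i]
      sl_h[sel] <- out$gpp_shade[i]
      gpp[, , d] <- sl_g
      gpp_sun[, , d] <- sl_s
      gpp_shade[, , d] <- sl_h
    }
  }
  list(gpp = gpp, gpp_sun = gpp_sun, gpp_shade = gpp_shade, dates = dates)
}

#' Write the full product set for a model grid run
#'
#' Aggregates daily grid output to 8-day, monthly and annual products and
#' writes every file plus a checksum manifest.
#'
#' @param grid_out Output of [run_grid()].
#' @param spec [grid_spec()] of the run.
#' @param dir Output directory (created if needed).
#' @return Data frame listing the written files, invisibly.
#' @export
write_product_set <- function(grid_out, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vars <- c(gpp = "GPP", gpp_shade = "Shade_GPP", gpp_sun = "Sun_GPP")
  files <- character(0)
  for (v in names(vars)) {
    agg <- aggregate_products(grid_out[[v]], grid_out$dates)
    for (i in seq_len(dim(agg$eight_day$values)[3])) {
      files <- c(files, write_product(
        agg$eight_day$values[, , i], spec, vars[[v]], "eight_day",
        agg$eight_day$index$year[i], agg$eight_day$index$period[i], dir
      ))
    }
    for (i in seq_len(dim(agg$monthly$values)[3])) {
      files <- c(files, write_product(
        agg$monthly$values[, , i], spec, vars[[v]], "monthly",
        agg$monthly$index$year[i], agg$monthly$index$period[i], dir
      ))
    }
    for (i in seq_len(dim(agg$annual$values)[3])) {
      files <- c(files, write_product(
        agg$annual$values[, , i], spec, vars[[v]], "annual",
        agg$annual$index$year[i], NULL, dir
      ))
    }
  }
  write_manifest(dir)
  invisible(data.frame(file = files))
}
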