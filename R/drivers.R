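.igbp_canonical <- c(
  ENF = 1, EBF = 2, DNF = 3, DBF = 4, MF = 5, OSH = 7, WSA = 8,
  SAV = 9, GRA = 10, WET = 11, CRO = 12
)

#' Write a driver stack to a directory of GeoTIFF and text files
#'
#' On-disk layout consumed by [read_driver_dir()]: the vegetation map as an
#' int16 GeoTIFF of IGBP codes, LAI slices and daily meteorology as
#' multi-band float GeoTIFFs, plus plain-text date stamps and the monthly
#' CO2 table.
#'
#' @param drivers Driver list as produced by [make_grid()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_driver_dir <- function(drivers, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- drivers$spec
  igbp <- matrix(.igbp_canonical[drivers$pft], spec$nrow, spec$ncol)
  write_geotiff(igbp, file.path(dir, "landcover_igbp.tif"), spec,
    type = "int16", nodata = -32768, description = "tllue driver; IGBP land cover"
  )
  write_geotiff(drivers$lai_slices, file.path(dir, "lai_slices.tif"), spec,
    type = "float64", description = "tllue driver; stamped LAI slices"
  )
  writeLines(format(as.Date(drivers$lai_stamps)), file.path(dir, "lai_stamps.txt"))
  for (v in c("t_air_K", "vpd", "sw_down")) {
    write_geotiff(drivers[[v]], file.path(dir, paste0(v, ".tif")), spec,
      type = "float64", description = paste("tllue driver;", v, "daily")
    )
  }
  writeLines(format(as.Date(drivers$dates)), file.path(dir, "dates.txt"))
  utils::write.csv(drivers$co2_monthly, file.path(dir, "co2_monthly.csv"),
    row.names = FALSE
  )
  invisible(dir)
}

#' Read a driver stack from a directory written by [write_driver_dir()]
#'
#' @param dir Driver directory.
#' @return Driver list as consumed by [run_grid()].
#' @export
read_driver_dir <- function(dir) {
  lc <- read_geotiff(file.path(dir, "landcover_igbp.tif"))
  igbp <- lc$values
  igbp[igbp == lc$nodata] <- NA
  spec <- lc$spec
  pft <- matrix(pft_from_igbp(igbp), spec$nrow, spec$ncol)
  lai_slices <- read_geotiff(file.path(dir, "lai_slices.tif"))$values
  if (length(dim(lai_slices)) == 2) lai_slices <- array(lai_slices, c(dim(lai_slices), 1))
  stamps <- as.Date(readLines(file.path(dir, "lai_stamps.txt")))
  dates <- as.Date(readLines(file.path(dir, "dates.txt")))
  lai <- interpolate_lai_daily(lai_slices, as.numeric(stamps), as.numeric(dates))
  met <- lapply(c("t_air_K", "vpd", "sw_down"), function(v) {
    read_geotiff(file.path(dir, paste0(v, ".tif")))$values
  })
  names(met) <- c("t_air_K", "vpd", "sw_down")
  co2_tab <- utils::read.csv(file.path(dir, "co2_monthly.csv"))
  co2_daily <- co2_tab$co2_ppm[match(format(dates, "%Y-%m"), co2_tab$month)]
  c(
    list(
      spec = spec, pft = pft, lai = lai, dates = dates,
      co2_ppm = co2_daily, lai_slices = lai_slices, lai_stamps = stamps,
      co2_monthly = co2_tab
    ),
    met
  )
}
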