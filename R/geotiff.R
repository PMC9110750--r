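# Minimal single/multi-band GeoTIFF codec (uncompressed, little-endian,
# one strip per band, pixel-centre lon/lat georeferencing). Written in base R
# because the product encoding needs signed 16-bit integer and 64-bit float
# samples, which no installed raster/TIFF package can produce.

.tiff_types <- c(ASCII = 2L, SHORT = 3L, LONG = 4L, DOUBLE = 12L)
.tiff_type_size <- c(`2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)

.entry_bytes <- function(type, values) {
  .tiff_type_size[[as.character(.tiff_types[[type]])]] * length(values)
}

.serialize_value <- function(type, values) {
  switch(type,
    ASCII = as.raw(values),
    SHORT = writeBin(as.integer(values), raw(), size = 2, endian = "little"),
    LONG = writeBin(as.integer(values), raw(), size = 4, endian = "little"),
    DOUBLE = writeBin(as.double(values), raw(), size = 8, endian = "little")
  )
}

#' Write a (Geo)TIFF raster
#'
#' Writes an uncompressed single- or multi-band TIFF with GeoTIFF
#' georeferencing tags (pixel scale, tiepoint, geographic EPSG:4326 keys), a
#' GDAL-style ASCII nodata tag, and an image description. Bands are stored
#' as chained IFDs, one strip each. Sample types: signed 16-bit integer or
#' 64-bit IEEE float.
#'
#' @param values Matrix `[row, col]` (rows north to south) or 3-D array
#'   `[row, col, band]`.
#' @param file Output path.
#' @param spec [grid_spec()] describing the georeferencing.
#' @param type "int16" or "float64".
#' @param nodata Nodata sentinel recorded in the file (and used to encode
#'   `NA` values for int16).
#' @param description Free-text ImageDescription tag.
#' @return `file`, invisibly.
#' @export
write_geotiff <- function(values, file, spec, type = c("float64", "int16"),
                          nodata = NULL, description = "tllue raster") {
  type <- match.arg(type)
  if (length(dim(values)) == 2) values <- array(values, c(dim(values), 1))
  nr <- dim(values)[1]
  nc <- dim(values)[2]
  nb <- dim(values)[3]
  stopifnot(nr == spec$nrow, nc == spec$ncol)
  bpp <- if (type == "int16") 2L else 8L
  strip_bytes <- nr * nc * bpp

  desc_raw <- c(charToRaw(description), as.raw(0))
  nod_raw <- if (!is.null(nodata)) c(charToRaw(format(nodata)), as.raw(0))
  geokeys <- c(1, 1, 0, 3, 1024, 0, 1, 2, 1025, 0, 1, 1, 2048, 0, 1, 4326)
  pixscale <- c(spec$res, spec$res, 0)
  tiepoint <- c(0, 0, 0, spec$xmin, spec$ymax, 0)

  entries <- list(
    list(256L, "LONG", nc),
    list(257L, "LONG", nr),
    list(258L, "SHORT", bpp * 8L),
    list(259L, "SHORT", 1L),
    list(262L, "SHORT", 1L),
    list(270L, "ASCII", desc_raw),
    list(273L, "LONG", 0L), # strip offset, patched per band below
    list(277L, "SHORT", 1L),
    list(278L, "LONG", nr),
    list(279L, "LONG", strip_bytes),
    list(339L, "SHORT", if (type == "int16") 2L else 3L),
    list(33550L, "DOUBLE", pixscale),
    list(33922L, "DOUBLE", tiepoint),
    list(34735L, "SHORT", geokeys)
  )
  if (!is.null(nod_raw)) entries <- c(entries, list(list(42113L, "ASCII", nod_raw)))
  n_entries <- length(entries)
  ifd_fixed <- 2L + n_entries * 12L + 4L
  ext_sizes <- vapply(entries, function(e) {
    nbytes <- .entry_bytes(e[[2]], e[[3]])
    if (nbytes > 4) nbytes + nbytes %% 2 else 0L
  }, numeric(1))
  per_ifd_block <- ifd_fixed + sum(ext_sizes)

  data_start <- 8L
  ifd_area_start <- data_start + nb * strip_bytes
  if (ifd_area_start %% 2 == 1) ifd_area_start <- ifd_area_start + 1L

  con <- base::file(file, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  writeBin(as.integer(ifd_area_start), con, size = 4, endian = "little")
  for (b in seq_len(nb)) {
    v <- as.vector(t(values[, , b]))
    if (type == "int16") {
      v[is.na(v)] <- if (!is.null(nodata)) nodata else 0
      if (any(v < -32768 | v > 32767)) {
        stop("int16 overflow while writing ", basename(file), call. = FALSE)
      }
      writeBin(as.integer(v), con, size = 2, endian = "little")
    } else {
      writeBin(as.double(v), con, size = 8, endian = "little")
    }
  }
  pad <- ifd_area_start - (data_start + nb * strip_bytes)
  if (pad > 0) writeBin(as.raw(rep(0, pad)), con)

  for (b in seq_len(nb)) {
    entries[[7]][[3]] <- data_start + (b - 1L) * strip_bytes # StripOffsets
    ifd_off <- ifd_area_start + (b - 1L) * per_ifd_block
    ext_off <- ifd_off + ifd_fixed
    writeBin(as.integer(n_entries), con, size = 2, endian = "little")
    ext_blobs <- list()
    for (i in seq_along(entries)) {
      e <- entries[[i]]
      writeBin(as.integer(e[[1]]), con, size = 2, endian = "little")
      writeBin(as.integer(.tiff_types[[e[[2]]]]), con, size = 2, endian = "little")
      writeBin(as.integer(length(e[[3]])), con, size = 4, endian = "little")
      blob <- .serialize_value(e[[2]], e[[3]])
      if (length(blob) > 4) {
        writeBin(as.integer(ext_off), con, size = 4, endian = "little")
        if (length(blob) %% 2 == 1) blob <- c(blob, as.raw(0))
        ext_blobs[[length(ext_blobs) + 1]] <- blob
        ext_off <- ext_off + length(blob)
      } else {
        writeBin(c(blob, as.raw(rep(0, 4 - length(blob)))), con)
      }
    }
    next_ifd <- if (b < nb) ifd_area_start + b * per_ifd_block else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    for (blob in ext_blobs) writeBin(blob, con)
  }
  invisible(file)
}

.r_u16 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 2)], "integer", size = 2, signed = FALSE, endian = "little")
}
.r_u32 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = "little")
}

#' Read a (Geo)TIFF raster written by [write_geotiff()]
#'
#' Baseline reader for uncompressed single-strip-per-band TIFFs with int16
#' or float samples.
#'
#' @param file Path to the TIFF.
#' @return List: `values` (matrix or 3-D array), `spec` ([grid_spec()]
#'   reconstructed from the georeferencing tags, or `NULL` if absent),
#'   `nodata` (numeric or `NULL`), `description`.
#' @export
read_geotiff <- function(file) {
  raw <- readBin(file, "raw", n = file.size(file))
  if (rawToChar(raw[1:2]) != "II" || .r_u16(raw, 2) != 42) {
    stop("not a little-endian TIFF file", call. = FALSE)
  }
  ifd_off <- .r_u32(raw, 4)
  bands <- list()
  tags_first <- NULL
  while (ifd_off != 0) {
    n <- .r_u16(raw, ifd_off)
    tags <- list()
    for (i in seq_len(n)) {
      eo <- ifd_off + 2 + (i - 1) * 12
      tag <- .r_u16(raw, eo)
      typ <- .r_u16(raw, eo + 2)
      cnt <- .r_u32(raw, eo + 4)
      size <- .tiff_type_size[[as.character(typ)]] * cnt
      voff <- if (size > 4) .r_u32(raw, eo + 8) else eo + 8
      vals <- switch(as.character(typ),
        `2` = rawToChar(raw[(voff + 1):(voff + cnt - 1)]),
        `3` = vapply(seq_len(cnt), function(j) .r_u16(raw, voff + (j - 1) * 2), numeric(1)),
        `4` = vapply(seq_len(cnt), function(j) .r_u32(raw, voff + (j - 1) * 4), numeric(1)),
        `12` = readBin(raw[(voff + 1):(voff + 8 * cnt)], "double",
          n = cnt, size = 8, endian = "little"
        ),
        stop("unsupported TIFF type ", typ, call. = FALSE)
      )
      tags[[as.character(tag)]] <- vals
    }
    if (is.null(tags_first)) tags_first <- tags
    w <- tags[["256"]]
    h <- tags[["257"]]
    bits <- tags[["258"]]
    fmt <- if (!is.null(tags[["339"]])) tags[["339"]] else 1
    so <- tags[["273"]]
    sbc <- tags[["279"]]
    data <- raw[(so + 1):(so + sbc)]
    v <- if (fmt == 3) {
      readBin(data, "double", n = w * h, size = bits / 8, endian = "little")
    } else {
      readBin(data, "integer", n = w * h, size = bits / 8, signed = TRUE, endian = "little")
    }
    bands[[length(bands) + 1]] <- matrix(v, nrow = h, byrow = TRUE)
    ifd_off <- .r_u32(raw, ifd_off + 2 + n * 12)
  }
  spec <- NULL
  if (!is.null(tags_first[["33550"]]) && !is.null(tags_first[["33922"]])) {
    res <- tags_first[["33550"]][1]
    tp <- tags_first[["33922"]]
    nr <- nrow(bands[[1]])
    nc <- ncol(bands[[1]])
    spec <- grid_spec(
      xmin = tp[4], xmax = tp[4] + nc * res,
      ymin = tp[5] - nr * res, ymax = tp[5], res = res
    )
  }
  nodata <- if (!is.null(tags_first[["42113"]])) as.numeric(tags_first[["42113"]])
  values <- if (length(bands) == 1) {
    bands[[1]]
  } else {
    array(unlist(bands), c(dim(bands[[1]]), length(bands)))
  }
  list(
    values = values, spec = spec, nodata = nodata,
    description = tags_first[["270"]]
  )
}
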