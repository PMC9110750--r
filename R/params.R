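.pft_codes <- c(
  "DBF", "EBF", "ENF", "MF", "CRO", "GRA", "OSH", "SAV", "WET", "WSA", "DNF"
)

#' Vegetation-type model parameters
#'
#' Loads the per-vegetation-type parameter table (maximum light-use
#' efficiencies of shaded and sunlit leaves in g C MJ^-1, VPD ramp bounds in
#' kPa, optimum temperature in degrees C, albedo, clumping index). The
#' shipped default table holds the calibrated means; the standard deviations
#' (`*_sd` columns) are metadata and are not used in computation. Deciduous
#' needleleaf forest (DNF) has no row of its own and resolves to the DBF
#' parameter values.
#'
#' @param pft Optional vegetation-type code (one of DBF, EBF, ENF, MF, CRO,
#'   GRA, OSH, SAV, WET, WSA, DNF). If `NULL`, the full table is returned.
#' @param file Path to a delimited parameter file mirroring the shipped
#'   default (one row per type).
#' @return A data frame: the full table, or a single row for `pft`.
#' @examples
#' pft_parameters("DBF")
#' @export
pft_parameters <- function(pft = NULL,
                           file = system.file("extdata", "pft_parameters.csv",
                             package = "tllue"
                           )) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (is.null(pft)) {
    return(tab)
  }
  if (!pft %in% .pft_codes) {
    stop("unknown vegetation type code: ", pft, call. = FALSE)
  }
  lookup <- if (pft == "DNF") "DBF" else pft
  row <- tab[tab$pft == lookup, , drop = FALSE]
  if (nrow(row) != 1) {
    stop("parameter file has no row for vegetation type ", lookup, call. = FALSE)
  }
  row$pft <- pft
  rownames(row) <- NULL
  row
}
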