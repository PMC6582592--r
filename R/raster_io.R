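# ESRI ASCII grid reader/writer. This is the package's raster exchange
# format: plain text, NODATA-aware, and supported by every GIS. (GeoTIFF
# would need a GDAL-backed reader, which is deliberately not a
# dependency; .tif paths are rejected with a clear message.)

#' Read a raster from an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file.
#' @return A list of class `ascii_grid`: `data` (numeric matrix, row 1 =
#'   northernmost row, `NA` where NODATA), `xll`, `yll`, `cellsize`,
#'   `nodata`.
#' @export
read_raster <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("GeoTIFF input is not supported (no GDAL reader available); ",
         "convert to ESRI ASCII grid (.asc)")
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  req <- c("ncols", "nrows")
  if (!all(req %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing ncols/nrows header in ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else NA
  if (!is.na(nodata)) m[m == nodata] <- NA
  structure(list(data = m,
                 xll = if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0,
                 yll = if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0,
                 cellsize = if (!is.null(hdr$cellsize)) hdr$cellsize else 100,
                 nodata = nodata),
            class = "ascii_grid")
}

#' Write a raster as an ESRI ASCII grid
#'
#' `NA` cells are written as the NODATA value; reading the file back
#' restores them as `NA` (round-trip identity).
#'
#' @param data Numeric matrix (row 1 = northernmost row).
#' @param path Output path.
#' @param xll,yll Lower-left corner coordinates.
#' @param cellsize Cell size in map units (default 100 m).
#' @param nodata NODATA sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_raster <- function(data, path, xll = 0, yll = 0, cellsize = 100,
                         nodata = -9999) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("GeoTIFF output is not supported; write an .asc grid instead")
  m <- as.matrix(data)
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               paste("xllcorner", xll), paste("yllcorner", yll),
               paste("cellsize", cellsize),
               paste("NODATA_value", nodata)), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
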