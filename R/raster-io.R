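# Esri ASCII grid I/O. Single band, row-major from the top row (north) down,
# which matches R matrix row order as used throughout the raster stage.

#' Write a matrix as an Esri ASCII grid
#'
#' @param mat Numeric matrix; row 1 is the top (northernmost) row.
#' @param path Output file path.
#' @param xll,yll Lower-left corner coordinates.
#' @param cellsize Cell size in map units.
#' @param nodata NODATA sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(mat, path, xll = 0, yll = 0, cellsize = 1,
                             nodata = -9999) {
  if (!is.matrix(mat)) stop_input("`mat` must be a matrix")
  header <- c(
    sprintf("ncols %d", ncol(mat)),
    sprintf("nrows %d", nrow(mat)),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(mat, 1, function(row) {
    row[is.na(row)] <- nodata
    paste(format(row, trim = TRUE, digits = 15, scientific = FALSE),
          collapse = " ")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an Esri ASCII grid into a matrix
#'
#' @param path File path.
#' @return A numeric matrix with NODATA cells set to `NA`; attributes
#'   `xllcorner`, `yllcorner`, `cellsize` carry the georeferencing.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (key in c("ncols", "nrows")) {
    if (is.null(hdr[[key]])) stop_input("ASCII grid header missing `%s`", key)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop_input("ASCII grid body has %d values, expected %d",
               length(vals), hdr$ncols * hdr$nrows)
  }
  mat <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) mat[mat == hdr$nodata_value] <- NA
  attr(mat, "xllcorner") <- hdr$xllcorner %||% 0
  attr(mat, "yllcorner") <- hdr$yllcorner %||% 0
  attr(mat, "cellsize") <- hdr$cellsize %||% 1
  mat
}
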