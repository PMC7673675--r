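#' Elevation grid container
#'
#' A planar raster of elevations (m, relative to present mean sea level)
#' on square cells.  Rows run south to north, columns west to east, so
#' `z[1, 1]` is the south-west corner cell.
#'
#' @param z numeric matrix of elevations; `NA` marks nodata cells.
#' @param cell_size cell edge length in metres (> 0).
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param nodata value used for nodata cells when written to disk.
#' @return an object of class `elevation_grid`.
#' @export
elevation_grid <- function(z, cell_size, xll = 0, yll = 0, nodata = -9999) {
  z <- as.matrix(z)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (!is.numeric(z) || nrow(z) < 1L || ncol(z) < 1L)
    stop("z must be a non-empty numeric matrix")
  structure(list(z = z, cell_size = cell_size, xll = xll, yll = yll,
                 nodata = nodata),
            class = "elevation_grid")
}

#' @export
print.elevation_grid <- function(x, ...) {
  cat(sprintf("Elevation grid: %d x %d cells at %.6g m (%.2f x %.2f km)\n",
              nrow(x$z), ncol(x$z), x$cell_size,
              ncol(x$z) * x$cell_size / 1000,
              nrow(x$z) * x$cell_size / 1000))
  zr <- range(x$z, na.rm = TRUE)
  cat(sprintf("  elevation range: %.2f to %.2f m rel. present MSL; %d nodata cells\n",
              zr[1], zr[2], sum(is.na(x$z))))
  invisible(x)
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows
#' of elevations from the northern edge southward.
#'
#' @param path file path.
#' @param grid an [elevation_grid()].
#' @return `read_ascii_grid` returns an `elevation_grid`;
#'   `write_ascii_grid` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header: need ", paste(need, collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = " "),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("grid body has ", length(vals), " values, expected ", nr * nc)
  # file rows run north -> south; flip to our south -> north convention
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)[nr:1, , drop = FALSE]
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  m[m == nodata] <- NA_real_
  elevation_grid(m, hdr$cellsize,
                 xll = if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner,
                 yll = if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner,
                 nodata = nodata)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "elevation_grid"))
  z <- grid$z
  z[is.na(z)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(z)),
               sprintf("nrows %d", nrow(z)),
               sprintf("xllcorner %.6f", grid$xll),
               sprintf("yllcorner %.6f", grid$yll),
               sprintf("cellsize %.6f", grid$cell_size),
               sprintf("NODATA_value %g", grid$nodata)), con)
  for (r in nrow(z):1)
    writeLines(paste(formatC(z[r, ], format = "g", digits = 8),
                     collapse = " "), con)
  invisible(path)
}
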