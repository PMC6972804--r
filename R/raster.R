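#' In-memory single-band raster grid
#'
#' A minimal raster container: a numeric matrix of cell values (row 1 is
#' the northernmost row, cell-centre registration) with an affine
#' georeference (lower-left corner, square cell size), a nodata convention
#' (`NA` in memory) and an optional scenario tag such as `"current"` or
#' `"2070_RCP8.5"`.
#'
#' @param values numeric matrix; `NA` marks nodata cells.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize positive cell edge length.
#' @param scenario optional character tag.
#' @param nodata sentinel written to disk for `NA` cells.
#' @return A `raster_grid` object.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                        scenario = NULL, nodata = -9999) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("raster dimensions must be positive", call. = FALSE)
  }
  if (!is.numeric(cellsize) || cellsize <= 0) {
    stop("cellsize must be positive", call. = FALSE)
  }
  storage.mode(values) <- "double"
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, scenario = scenario,
                 nodata = nodata),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat("raster_grid: ", nrow(x$values), " x ", ncol(x$values),
      " cells (cellsize ", x$cellsize, ")", sep = "")
  if (!is.null(x$scenario)) cat(", scenario '", x$scenario, "'", sep = "")
  cat("\n  nodata cells: ", sum(is.na(x$values)),
      "; value range: ", sep = "")
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(format(rng[1]), "..", format(rng[2]), "\n")
  invisible(x)
}

same_georef <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner` or
#' `xllcenter`, `yllcorner`/`yllcenter`, `cellsize`, `nodata_value`)
#' followed by row-major cell values, northernmost row first.
#'
#' @param path file path.
#' @param scenario optional scenario tag to attach.
#' @return A [raster_grid()].
#' @export
read_esri_ascii <- function(path, scenario = NULL) {
  lines <- readLines(path, n = 6L)
  header <- list()
  n_header <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && is.na(suppressWarnings(as.numeric(parts[1])))) {
      header[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_header <- n_header + 1L
    } else break
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(header))) {
    stop("not an ESRI ASCII grid: missing header field(s) in ", path,
         call. = FALSE)
  }
  nc <- as.integer(header$ncols); nr <- as.integer(header$nrows)
  cs <- header$cellsize
  xll <- header$xllcorner %||% (header$xllcenter - cs / 2)
  yll <- header$yllcorner %||% (header$yllcenter - cs / 2)
  nodata <- header$nodata_value %||% -9999
  vals <- scan(path, what = double(), skip = n_header, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("ESRI ASCII grid ", path, ": expected ", nr * nc,
         " values, found ", length(vals), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[abs(m - nodata) < 1e-9] <- NA_real_
  raster_grid(m, xll = xll, yll = yll, cellsize = cs,
              scenario = scenario, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param grid a [raster_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(grid$xll, digits = 17)),
    paste("yllcorner", format(grid$yll, digits = 17)),
    paste("cellsize", format(grid$cellsize, digits = 17)),
    paste("nodata_value", format(grid$nodata, digits = 17))
  ), con)
  writeLines(apply(m, 1L, function(r) {
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " ")
  }), con)
  invisible(path)
}

#' Read a co-registered stack of climate rasters
#'
#' Loads one raster per climate variable, checks that all grids share
#' shape and georeference, and harmonizes nodata across layers: any cell
#' missing in at least one layer becomes missing in every layer (union
#' mask).
#'
#' @param paths character vector of ESRI ASCII grid paths, one per variable.
#' @param variables character vector of climate variable names, same length.
#' @param scenario optional scenario tag applied to all layers.
#' @return Named list of [raster_grid()]s (a raster stack) with attribute
#'   `mask`, the logical union-nodata matrix (`TRUE` = masked).
#' @export
read_raster_stack <- function(paths, variables, scenario = NULL) {
  stopifnot(length(paths) == length(variables), length(paths) >= 1L)
  layers <- lapply(paths, read_esri_ascii, scenario = scenario)
  names(layers) <- variables
  harmonize_stack(layers)
}

#' Harmonize a raster stack to a shared union nodata mask
#'
#' @param layers named list of co-registered [raster_grid()]s.
#' @return The stack with every layer masked by the union of nodata cells;
#'   attribute `mask` holds the logical mask (`TRUE` = masked).
#' @export
harmonize_stack <- function(layers) {
  ref <- layers[[1L]]
  for (nm in names(layers)[-1L]) {
    if (!same_georef(ref, layers[[nm]])) {
      stop("raster stack alignment error: layer '", nm,
           "' does not match shape/georeference of '", names(layers)[1L],
           "'", call. = FALSE)
    }
  }
  mask <- Reduce(`|`, lapply(layers, function(g) is.na(g$values)))
  layers <- lapply(layers, function(g) {
    g$values[mask] <- NA_real_
    g
  })
  attr(layers, "mask") <- mask
  layers
}

#' Crop a raster grid to a row/column window
#'
#' @param grid a [raster_grid()].
#' @param rows,cols integer index ranges (contiguous).
#' @return The windowed [raster_grid()] with adjusted georeference.
#' @export
crop_raster <- function(grid, rows, cols) {
  stopifnot(inherits(grid, "raster_grid"))
  nr <- nrow(grid$values)
  vals <- grid$values[rows, cols, drop = FALSE]
  # row 1 is north: dropping trailing (southern) rows raises yll
  new_yll <- grid$yll + (nr - max(rows)) * grid$cellsize
  new_xll <- grid$xll + (min(cols) - 1L) * grid$cellsize
  raster_grid(vals, xll = new_xll, yll = new_yll,
              cellsize = grid$cellsize, scenario = grid$scenario,
              nodata = grid$nodata)
}
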