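#' Lightweight in-memory georeferenced raster
#'
#' A `raster_grid` wraps a numeric matrix with a planar cell size (m), an
#' origin (the x/y coordinate of the lower-left cell centre) and a free-text
#' CRS note. Missing cells are `NA`; all statistics in the package exclude
#' them. Rows of the matrix run north to south (row 1 is the top of the map),
#' matching how gridded elevation products are usually delivered.
#'
#' @param values Numeric matrix of cell values (`NA` = nodata).
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Length-2 numeric, x/y of the lower-left cell centre.
#' @param crs_note Free-text note on the coordinate system.
#' @return An object of class `raster_grid`.
#' @examples
#' r <- raster_grid(matrix(1:12, 3, 4), cell_size = 1000)
#' dim(r)
#' @export
raster_grid <- function(values, cell_size, origin = c(0, 0),
                        crs_note = "planar, metres") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cell_size), length(cell_size) == 1, cell_size > 0,
            length(origin) == 2)
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs_note = crs_note),
    class = "raster_grid"
  )
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<raster_grid> %d x %d cells, %.0f m resolution\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  if (length(v)) {
    cat(sprintf("  values: [%.4g, %.4g], %d nodata cells\n",
                min(v), max(v), sum(is.na(x$values))))
  } else {
    cat("  all cells nodata\n")
  }
  invisible(x)
}

#' @export
as.matrix.raster_grid <- function(x, ...) x$values

#' Coordinates of every cell centre as a tibble
#'
#' Long-format bridge to the tidyverse: one row per cell with projected
#' `x`/`y` (m) and the cell `value`.
#'
#' @param x A [raster_grid()].
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @method as_tibble raster_grid
#' @export
as_tibble.raster_grid <- function(x, ...) {
  nr <- nrow(x$values)
  nc <- ncol(x$values)
  origin <- x$origin
  cs <- x$cell_size
  vals <- as.vector(t(x$values))
  g <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc))
  dplyr::mutate(
    g,
    x = origin[1] + (.data$col - 1) * cs,
    y = origin[2] + (nr - .data$row) * cs,
    value = vals[(.data$row - 1) * nc + .data$col]
  )
}

#' @rdname as_tibble.raster_grid
#' @method autoplot raster_grid
#' @export
autoplot.raster_grid <- function(x, ...) {
  ggplot2::ggplot(as_tibble(x), ggplot2::aes(.data$x, .data$y,
                                             fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

# internal: map values through f, keep georeferencing
grid_map <- function(x, f) {
  x$values <- f(x$values)
  x
}

# internal: error unless all grids share shape and cell size
check_coregistered <- function(...) {
  gs <- list(...)
  ref <- dim(gs[[1]]$values)
  for (g in gs[-1]) {
    if (!identical(dim(g$values), ref)) {
      stop("grids are not co-registered: shapes ",
           paste(ref, collapse = "x"), " vs ",
           paste(dim(g$values), collapse = "x"), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read and write single-band rasters as ESRI ASCII grid text
#'
#' Plain-text raster exchange: the standard `.asc` header (ncols, nrows,
#' xllcenter, yllcenter, cellsize, NODATA_value) followed by rows of values,
#' north to south. Round-trips a [raster_grid()] exactly at the printed
#' precision.
#'
#' @param x A [raster_grid()].
#' @param path File path to write to / read from.
#' @param digits Significant digits written (default 10).
#' @return `write_raster()` returns `path` invisibly; `read_raster()` returns
#'   a [raster_grid()].
#' @export
write_raster <- function(x, path, digits = 10) {
  stopifnot(inherits(x, "raster_grid"))
  nodata <- -9999
  v <- x$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcenter %.10g", x$origin[1]),
    sprintf("yllcenter %.10g", x$origin[2]),
    sprintf("cellsize %.10g", x$cell_size),
    sprintf("NODATA_value %d", nodata)
  )
  body <- apply(v, 1, function(r) paste(formatC(r, digits = digits,
                                                format = "g"),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    as.numeric(sub("^\\S+\\s+", "", ln))
  }
  nc <- val("ncols"); nr <- val("nrows")
  nodata <- val("NODATA_value")
  nums <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(nums, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, cell_size = val("cellsize"),
              origin = c(val("xllcenter"), val("yllcenter")))
}
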