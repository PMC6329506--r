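#' Lightweight single-band raster on a square projected grid
#'
#' `graze_raster()` wraps a numeric matrix together with its grid geometry:
#' square cells of `cell_size` metres in a projected coordinate system, with
#' row 1 at the northern edge. The lower-left corner of the grid is at
#' (`xll`, `yll`) metres. This is the container every gridded quantity in the
#' package (NPP, land cover, energy supply, claims, intensity) travels in.
#'
#' @param values numeric matrix; row 1 is the northernmost row.
#' @param cell_size cell edge length in metres (> 0).
#' @param xll,yll projected coordinates (m) of the lower-left grid corner.
#' @param crs_label free-text label of the projected CRS; purely descriptive.
#' @return an object of class `graze_raster`.
#' @export
graze_raster <- function(values, cell_size, xll = 0, yll = 0,
                         crs_label = "local-metric") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    rlang::abort("`cell_size` must be a single positive number of metres.",
                 class = "grazemap_error_geometry")
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll),
         crs_label = crs_label),
    class = "graze_raster"
  )
}

#' @export
dim.graze_raster <- function(x) dim(x$values)

#' @export
print.graze_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<graze_raster> %d x %d cells, %g m resolution (%s)\n",
              nrow(v), ncol(v), x$cell_size, x$crs_label))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] m\n",
              x$xll, x$xll + ncol(v) * x$cell_size,
              x$yll, x$yll + nrow(v) * x$cell_size))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values: [%g, %g], %d NA\n", rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' Area of one raster cell in square metres
#' @param x a `graze_raster`.
#' @export
cell_area <- function(x) {
  stopifnot(inherits(x, "graze_raster"))
  x$cell_size^2
}

#' Do two rasters share the same grid geometry?
#' @param a,b `graze_raster` objects.
#' @return `TRUE`/`FALSE`.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$xll, b$xll)) &&
    isTRUE(all.equal(a$yll, b$yll))
}

check_same_grid <- function(a, b, what = "rasters") {
  if (!same_grid(a, b)) {
    rlang::abort(paste0("Grid geometry mismatch between ", what, "."),
                 class = "grazemap_error_geometry")
  }
  invisible(TRUE)
}

#' Pixel-centre coordinates
#'
#' Returns the projected x (easting) and y (northing) coordinates of every
#' cell centre, in row-major order (row 1 = north).
#'
#' @param x a `graze_raster`.
#' @return list with numeric vectors `x` and `y` of length `nrow * ncol`.
#' @export
cell_centers <- function(x) {
  nr <- nrow(x$values); nc <- ncol(x$values); cs <- x$cell_size
  col <- rep(seq_len(nc), times = nr)
  row <- rep(seq_len(nr), each = nc)
  list(x = x$xll + (col - 0.5) * cs,
       y = x$yll + (nr - row + 0.5) * cs)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.graze_raster <- function(x, ...) {
  cc <- cell_centers(x)
  vals <- as.vector(t(x$values))
  tibble::tibble(x = cc$x, y = cc$y, value = vals)
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.graze_raster <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = "easting (km)", y = "northing (km)")
}

#' Land-cover class codes
#'
#' Integer encoding of the categorical land-cover classes used throughout the
#' package. Grassland and bare soil are grazeable, cropland contributes
#' post-harvest residues, and the remaining classes (forest, water, ice,
#' artificial surfaces and strictly protected preserves) are masked out of the
#' supply map.
#'
#' @return named integer vector mapping class name to raster code.
#' @export
cover_classes <- function() {
  c(grassland = 1L, bare = 2L, cropland = 3L, forest = 4L,
    water = 5L, ice = 6L, artificial = 7L, preserve = 8L)
}

#' Read / write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` interchange for rasters: a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of values from north to south. Lossless to the printed precision
#' (values are written with 15 significant digits).
#'
#' @param path file path.
#' @param x a `graze_raster`.
#' @param nodata value standing in for `NA` on disk.
#' @return `read_raster_asc()` returns a `graze_raster`;
#'   `write_raster_asc()` returns `path` invisibly.
#' @export
read_raster_asc <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- lapply(strsplit(trimws(lines), "\\s+"), function(p) {
    stats::setNames(as.numeric(p[2]), tolower(p[1]))
  })
  hdr <- unlist(hdr)
  vals <- scan(path, skip = 6L, quiet = TRUE)
  nr <- as.integer(hdr[["nrows"]]); nc <- as.integer(hdr[["ncols"]])
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if ("nodata_value" %in% names(hdr)) m[m == hdr[["nodata_value"]]] <- NA_real_
  graze_raster(m, cell_size = hdr[["cellsize"]],
               xll = hdr[["xllcorner"]], yll = hdr[["yllcorner"]])
}

#' @rdname read_raster_asc
#' @export
write_raster_asc <- function(x, path, nodata = -9999) {
  stopifnot(inherits(x, "graze_raster"))
  v <- x$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", x$xll),
    sprintf("yllcorner %.10g", x$yll),
    sprintf("cellsize %.10g", x$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(v, 1L, function(r) paste(sprintf("%.15g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Resample a raster to a different cell size
#'
#' Helpers to bring input rasters onto a common grid before modelling,
#' e.g. 1 km NPP and 250 m land cover onto the default 500 m working grid.
#' Only integer aggregation/disaggregation factors are supported. Continuous
#' fields should use `method = "mean"` (area-weighted mean, which for equal
#' square cells is the block mean); categorical rasters must use
#' `method = "nearest"`.
#'
#' @param x a `graze_raster`.
#' @param target_cell desired cell size in metres; must be an integer
#'   multiple or divisor of `x$cell_size`.
#' @param method `"mean"` or `"nearest"`.
#' @return a `graze_raster` on the new grid (same lower-left corner).
#' @export
resample_raster <- function(x, target_cell, method = c("mean", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "graze_raster"), target_cell > 0)
  ratio <- target_cell / x$cell_size
  if (abs(ratio - round(ratio)) < 1e-9 && round(ratio) >= 1) {
    f <- as.integer(round(ratio))            # aggregate
    v <- x$values
    nr <- nrow(v) %/% f; nc <- ncol(v) %/% f
    if (nr < 1 || nc < 1) {
      rlang::abort("Aggregation factor exceeds raster extent.",
                   class = "grazemap_error_geometry")
    }
    v <- v[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
    out <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) {
      rows <- ((i - 1L) * f + 1L):(i * f)
      block <- v[rows, , drop = FALSE]
      if (method == "mean") {
        cm <- colMeans(block, na.rm = TRUE)
        agg <- vapply(seq_len(nc), function(j) {
          mean(cm[((j - 1L) * f + 1L):(j * f)], na.rm = TRUE)
        }, numeric(1))
      } else {
        # nearest: centre cell of each block (upper-left of the two middles)
        ci <- (f + 1L) %/% 2L
        agg <- v[rows[ci], ((seq_len(nc) - 1L) * f) + ci]
      }
      out[i, ] <- agg
    }
    out[is.nan(out)] <- NA_real_
    # keep the top-left corner fixed; yll moves up by the trimmed remainder
    yll_new <- x$yll + (nrow(x$values) - nr * f) * x$cell_size
    graze_raster(out, cell_size = target_cell, xll = x$xll, yll = yll_new,
                 crs_label = x$crs_label)
  } else {
    inv <- x$cell_size / target_cell
    if (abs(inv - round(inv)) > 1e-9) {
      rlang::abort("`target_cell` must be an integer multiple or divisor of the source cell size.",
                   class = "grazemap_error_geometry")
    }
    f <- as.integer(round(inv))              # disaggregate (both methods copy)
    v <- x$values
    out <- v[rep(seq_len(nrow(v)), each = f), rep(seq_len(ncol(v)), each = f),
             drop = FALSE]
    graze_raster(out, cell_size = target_cell, xll = x$xll, yll = x$yll,
                 crs_label = x$crs_label)
  }
}

#' Arithmetic-mean composite of a stack of NPP rasters
#'
#' The model consumes a single annual NPP composite; multi-year inputs are
#' averaged cell-wise.
#'
#' @param rasters list of `graze_raster` objects on one grid.
#' @return a `graze_raster` of cell-wise means (NA where all layers are NA).
#' @export
composite_mean <- function(rasters) {
  stopifnot(length(rasters) >= 1L)
  for (r in rasters[-1]) check_same_grid(rasters[[1]], r, "composite layers")
  arr <- vapply(rasters, function(r) r$values,
                matrix(0, nrow(rasters[[1]]$values), ncol(rasters[[1]]$values)))
  m <- apply(arr, c(1, 2), function(z) {
    if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
  })
  graze_raster(m, rasters[[1]]$cell_size, rasters[[1]]$xll, rasters[[1]]$yll,
               rasters[[1]]$crs_label)
}
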