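#' Georeferenced raster grids
#'
#' `land_raster()` builds the light-weight raster container used throughout
#' the package: a numeric matrix of cell values plus a georeference.  The
#' georeference follows common projected-GeoTIFF conventions: coordinates in
#' projected map units (metres), `origin` is the map coordinate of the
#' *top-left corner* of the top-left cell, rows run north to south, columns
#' west to east, cells are square, and registration is at pixel centres (the
#' centre of cell `[r, c]` is at `origin + (c - 0.5, -(r - 0.5)) * cell_size`).
#'
#' Two raster types exist.  `"categorical"` rasters hold integer land-cover
#' class codes (e.g. NLCD/Anderson codes: 22 = developed low intensity,
#' 41 = deciduous forest, 82 = cultivated crops) with an integer `nodata`
#' code; `"continuous"` rasters hold real values (class fractions, gradient
#' surfaces) with `NA` marking nodata cells.
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param origin length-2 numeric, map coordinates (x, y) of the top-left
#'   corner of the grid.
#' @param cell_size positive cell edge length in map units.
#' @param type `"categorical"` or `"continuous"`.
#' @param nodata integer nodata code (categorical only; such cells are
#'   converted to `NA` internally and restored on write).
#' @param crs free-text coordinate reference tag carried along unchanged.
#' @param classes optional integer vector declaring the class table of a
#'   categorical raster; defaults to the sorted codes present.
#' @return An object of class `land_raster`: a list with elements `values`,
#'   `origin`, `cell_size`, `type`, `nodata`, `crs`, `classes`.
#' @examples
#' r <- land_raster(matrix(c(41, 41, 82, 21), 2, 2), cell_size = 30)
#' composition(r)
#' @export
land_raster <- function(values, origin = c(0, 0), cell_size = 30,
                        type = c("categorical", "continuous"),
                        nodata = -9999L, crs = "", classes = NULL) {
  type <- match.arg(type)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a positive scalar")
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("`origin` must be two finite map coordinates")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster must have at least one row and one column")
  storage.mode(values) <- "double"
  if (type == "categorical") {
    nd <- as.integer(nodata)
    if (any(!is.na(values) & values != round(values)))
      stop("categorical raster values must be integer class codes")
    values[!is.na(values) & values == nd] <- NA_real_
    if (is.null(classes)) classes <- sort(unique(values[!is.na(values)]))
    classes <- as.integer(classes)
    bad <- values[!is.na(values) & !(values %in% classes)]
    if (length(bad))
      warning("codes not in declared class table: ",
              paste(sort(unique(bad)), collapse = ", "))
  } else {
    nd <- NA_integer_
    if (any(is.infinite(values))) stop("continuous raster values must be finite or NA")
    classes <- NULL
  }
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size), type = type,
                 nodata = nd, crs = as.character(crs), classes = classes),
            class = "land_raster")
}

#' @export
print.land_raster <- function(x, ...) {
  cat(sprintf("<land_raster: %s, %d x %d cells at %g map units>\n",
              x$type, nrow(x$values), ncol(x$values), x$cell_size))
  cat(sprintf("  origin (top-left): %g, %g%s\n", x$origin[1], x$origin[2],
              if (nzchar(x$crs)) paste0("  [", x$crs, "]") else ""))
  if (x$type == "categorical")
    cat("  classes:", paste(x$classes, collapse = " "), "\n")
  else
    cat(sprintf("  range: [%g, %g], NA cells: %d\n",
                suppressWarnings(min(x$values, na.rm = TRUE)),
                suppressWarnings(max(x$values, na.rm = TRUE)),
                sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.land_raster <- function(x) dim(x$values)

## extent as c(xmin, xmax, ymin, ymax); outer edges of the grid
raster_extent <- function(r) {
  c(r$origin[1], r$origin[1] + ncol(r$values) * r$cell_size,
    r$origin[2] - nrow(r$values) * r$cell_size, r$origin[2])
}

#' Number of cells spanned by a window length
#'
#' A window of physical length `window` on a grid of `cell_size` spans
#' `round(window / cell_size)` cells; the quotient is rounded to the nearest
#' integer because common window lengths are not exact cell multiples
#' (50 000 m at 30 m cells gives 1667 columns).
#'
#' @param window window length in map units.
#' @param cell_size cell edge length in map units.
#' @return integer cell count.
#' @export
window_cells <- function(window, cell_size) {
  if (window <= 0 || cell_size <= 0) stop("window and cell_size must be positive")
  as.integer(round(window / cell_size))
}

# ---- ESRI ASCII grid -------------------------------------------------------

read_asc <- function(path, type, crs = "") {
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "[[:space:]]+")
  hdr <- list()
  for (p in kv) {
    if (length(p) != 2L) stop("malformed ESRI ASCII header in ", path)
    hdr[[tolower(p[1])]] <- as.numeric(p[2])
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("ESRI ASCII header incomplete in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  cs <- hdr$cellsize
  # header gives the lower-left corner (or lower-left cell centre)
  if (!is.null(hdr$xllcorner)) {
    xll <- hdr$xllcorner; yll <- hdr$yllcorner
  } else if (!is.null(hdr$xllcenter)) {
    xll <- hdr$xllcenter - cs / 2; yll <- hdr$yllcenter - cs / 2
  } else stop("ESRI ASCII header lacks corner/centre coordinates in ", path)
  vals <- scan(path, skip = 6L, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("ESRI ASCII body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (type == "continuous") m[m == nodata] <- NA_real_
  land_raster(m, origin = c(xll, yll + nr * cs), cell_size = cs, type = type,
              nodata = if (type == "categorical") as.integer(nodata) else -9999L,
              crs = crs)
}

write_asc <- function(r, path) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  nodata <- if (r$type == "categorical") r$nodata else -9999L
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", r$origin[1]),
           sprintf("yllcorner %.10g", r$origin[2] - nr * r$cell_size),
           sprintf("cellsize %.10g", r$cell_size),
           sprintf("NODATA_value %d", as.integer(nodata)))
  m <- r$values
  m[is.na(m)] <- nodata
  body <- if (r$type == "categorical")
    apply(m, 1L, function(row) paste(formatC(row, format = "d"), collapse = " "))
  else
    apply(m, 1L, function(row) paste(formatC(row, format = "g", digits = 17),
                                     collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- GeoTIFF (TIFF + ESRI world file sidecar) ------------------------------

# Categorical codes are stored as 16-bit unsigned integers (bit-exact for
# codes 0..65534; 65535 is reserved for nodata).  Continuous layers are
# stored as float samples and must lie in [0, 1] -- the natural range of
# smoothed class fractions; use the ASCII format for general-range surfaces
# such as gradient scores.

worldfile_path <- function(path) sub("\\.tiff?$", ".tfw", path, ignore.case = TRUE)

write_tfw <- function(r, path) {
  writeLines(sprintf("%.10g", c(r$cell_size, 0, 0, -r$cell_size,
                                r$origin[1] + r$cell_size / 2,
                                r$origin[2] - r$cell_size / 2)),
             worldfile_path(path))
}

read_tfw <- function(path) {
  wf <- worldfile_path(path)
  if (!file.exists(wf)) stop("world file not found: ", wf)
  v <- as.numeric(readLines(wf))
  if (length(v) != 6L || v[2] != 0 || v[3] != 0 || v[1] <= 0 || v[4] >= 0)
    stop("unsupported world file (rotation or non-north-up): ", wf)
  if (abs(v[1] + v[4]) > 1e-9 * v[1]) stop("non-square cells in ", wf)
  list(cell_size = v[1], origin = c(v[5] - v[1] / 2, v[6] + v[1] / 2))
}

TIFF_NODATA16 <- 65535

read_tif <- function(path, type, crs = "") {
  g <- read_tfw(path)
  m <- tiff::readTIFF(path, as.is = (type == "categorical"))
  if (is.array(m) && length(dim(m)) == 3L)
    stop("multi-band TIFF not supported: ", path)
  m <- matrix(as.numeric(m), nrow = nrow(m), ncol = ncol(m))
  if (type == "categorical") {
    m[m == TIFF_NODATA16] <- -9999
    land_raster(m, origin = g$origin, cell_size = g$cell_size,
                type = "categorical", nodata = -9999L, crs = crs)
  } else {
    land_raster(m, origin = g$origin, cell_size = g$cell_size,
                type = "continuous", crs = crs)
  }
}

write_tif <- function(r, path) {
  m <- r$values
  if (r$type == "categorical") {
    m[is.na(m)] <- TIFF_NODATA16
    if (any(m < 0 | m > TIFF_NODATA16))
      stop("categorical GeoTIFF supports codes 0..65534 only; use .asc")
    tiff::writeTIFF(m / TIFF_NODATA16, path, bits.per.sample = 16L)
  } else {
    if (anyNA(m) || any(m < 0 | m > 1))
      stop("continuous GeoTIFF supports complete values in [0, 1] only; use .asc")
    tiff::writeTIFF(m, path, bits.per.sample = 32L)
  }
  write_tfw(r, path)
  invisible(path)
}

guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("asc", "tif")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "tif"
  else if (ext %in% c("asc", "txt", "grd")) "asc"
  else stop("cannot guess raster format from extension: ", path)
}

#' Read or write a raster
#'
#' Supported formats: ESRI ASCII grid (`.asc`, plain text, any values) and
#' single-band GeoTIFF (`.tif`) with an ESRI world-file (`.tfw`) sidecar
#' carrying the georeference.  GeoTIFF categorical codes are stored as
#' 16-bit integers (codes must be in 0..65534); GeoTIFF continuous values
#' must lie in `[0, 1]`.  Both formats round-trip exactly on class codes.
#'
#' @param path file path.
#' @param type `"categorical"` or `"continuous"`.
#' @param format `"asc"` or `"tif"`; guessed from the extension by default.
#' @param crs optional CRS tag to attach (not stored in either format).
#' @return `read_land_raster()` returns a [land_raster]; `write_land_raster()`
#'   invisibly returns `path`.
#' @export
read_land_raster <- function(path, type = c("categorical", "continuous"),
                             format = NULL, crs = "") {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- guess_format(path, format)
  if (fmt == "asc") read_asc(path, type, crs) else read_tif(path, type, crs)
}

#' @rdname read_land_raster
#' @param r a [land_raster].
#' @export
write_land_raster <- function(r, path, format = NULL) {
  stopifnot(inherits(r, "land_raster"))
  fmt <- guess_format(path, format)
  if (fmt == "asc") write_asc(r, path) else write_tif(r, path)
}

# ---- window cropping -------------------------------------------------------

#' Crop a square window around a point
#'
#' Extracts the sub-grid covering `center_xy +/- half_width` in each map
#' direction, snapped to the source grid.  The output spans
#' `round(2 * half_width / cell_size)` cells per side; cells of the window
#' that fall outside the source raster become nodata, so a window centred
#' near an edge keeps its full declared extent.
#'
#' @param r a [land_raster].
#' @param center_xy length-2 map coordinates of the window centre.
#' @param half_width half the window edge length, map units.
#' @return a [land_raster] of the same type.
#' @export
crop_window <- function(r, center_xy, half_width) {
  stopifnot(inherits(r, "land_raster"), half_width > 0)
  cs <- r$cell_size
  n_out <- window_cells(2 * half_width, cs)
  # snap window origin to source grid
  c0 <- as.integer(round((center_xy[1] - half_width - r$origin[1]) / cs))
  r0 <- as.integer(round((r$origin[2] - (center_xy[2] + half_width)) / cs))
  src_rows <- (r0 + 1L):(r0 + n_out)
  src_cols <- (c0 + 1L):(c0 + n_out)
  in_r <- src_rows >= 1L & src_rows <= nrow(r$values)
  in_c <- src_cols >= 1L & src_cols <= ncol(r$values)
  if (!any(in_r) || !any(in_c)) stop("crop window does not intersect raster")
  out <- matrix(NA_real_, n_out, n_out)
  out[which(in_r), which(in_c)] <- r$values[src_rows[in_r], src_cols[in_c]]
  new_origin <- c(r$origin[1] + c0 * cs, r$origin[2] - r0 * cs)
  if (r$type == "categorical")
    land_raster(out, origin = new_origin, cell_size = cs, type = "categorical",
                nodata = r$nodata, crs = r$crs, classes = r$classes)
  else
    land_raster(out, origin = new_origin, cell_size = cs, type = "continuous",
                crs = r$crs)
}

# ---- point extraction ------------------------------------------------------

#' Extract raster values at points
#'
#' Nearest-pixel extraction: each point takes the value of the cell whose
#' centre is nearest (equivalently, the cell containing the point).  No
#' interpolation is performed -- smoothed class fractions are already local
#' averages and interpolating would re-smooth them.  Points outside the
#' raster extent are flagged (`inside = FALSE`, value `NA`) with a warning,
#' never silently dropped; nodata cells yield `NA`.
#'
#' @param r a [land_raster].
#' @param points data frame with columns `id`, `x`, `y` (map units), or a
#'   path to a CSV file with that header.
#' @return data frame with columns `id`, `value`, `inside`.
#' @export
extract_at_points <- function(r, points) {
  stopifnot(inherits(r, "land_raster"))
  if (is.character(points)) points <- utils::read.csv(points)
  if (!all(c("id", "x", "y") %in% names(points)))
    stop("`points` needs columns id, x, y")
  if (anyDuplicated(points$id)) stop("point ids must be unique")
  cs <- r$cell_size
  col <- floor((points$x - r$origin[1]) / cs) + 1L
  row <- floor((r$origin[2] - points$y) / cs) + 1L
  # points exactly on the far edges belong to the last cell
  col[points$x == r$origin[1] + ncol(r$values) * cs] <- ncol(r$values)
  row[points$y == r$origin[2] - nrow(r$values) * cs] <- nrow(r$values)
  inside <- row >= 1L & row <= nrow(r$values) & col >= 1L & col <= ncol(r$values)
  val <- rep(NA_real_, nrow(points))
  val[inside] <- r$values[cbind(row[inside], col[inside])]
  if (any(!inside))
    warning(sum(!inside), " point(s) fall outside the raster extent")
  data.frame(id = points$id, value = val, inside = inside)
}
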