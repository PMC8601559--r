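#' Discrete Gaussian smoothing kernel
#'
#' Builds the truncated, discretised Gaussian kernel used to turn binary
#' class indicators into continuous class-fraction surfaces.  Weights are
#' `w(dx, dy) ~ exp(-(dx^2 + dy^2) / (2 sigma^2))` evaluated at cell-centre
#' offsets on a square support of half-width `floor(truncation / cell_size)`
#' cells, then renormalised to sum to one.  The "500-m kernel" convention of
#' the package is that `sigma` *is* the Gaussian standard deviation; at
#' `sigma = 500` and 30-m cells the default 4-sigma truncation gives a
#' 135 x 135 weight matrix.  The kernel is separable: `matrix` equals the
#' outer product of the normalised 1-D `profile`.
#'
#' @param sigma Gaussian standard deviation, map units.
#' @param cell_size cell edge length, map units.
#' @param truncation support half-width in map units (default `4 * sigma`,
#'   which discards < 1e-3 of the kernel mass, floored at one cell so a
#'   kernel much narrower than a cell degrades to a delta).
#' @return object of class `kernel_spec`: list with `sigma`, `cell_size`,
#'   `truncation`, `half_width` (cells), `profile` (length `2*half_width+1`,
#'   sums to 1) and `matrix` (square, sums to 1).
#' @examples
#' k <- build_kernel(sigma = 500, cell_size = 30)
#' dim(k$matrix)  # 135 x 135
#' @export
build_kernel <- function(sigma, cell_size, truncation = NULL) {
  if (sigma <= 0 || cell_size <= 0) stop("sigma and cell_size must be positive")
  if (is.null(truncation)) truncation <- max(4 * sigma, cell_size)
  else if (truncation < cell_size)
    stop("truncation radius must be at least one cell")
  h <- as.integer(floor(truncation / cell_size))
  d <- (-h:h) * cell_size
  prof <- exp(-d^2 / (2 * sigma^2))
  prof <- prof / sum(prof)
  structure(list(sigma = sigma, cell_size = cell_size, truncation = truncation,
                 half_width = h, profile = prof,
                 matrix = outer(prof, prof)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec: Gaussian sigma = %g, cell = %g, %d x %d weights>\n",
              x$sigma, x$cell_size, 2L * x$half_width + 1L, 2L * x$half_width + 1L))
  invisible(x)
}

## separable 1-D convolution pass over rows (along each column) with
## zero padding outside the grid; w is the normalised profile
conv_cols <- function(m, w) {
  h <- (length(w) - 1L) %/% 2L
  nr <- nrow(m)
  out <- matrix(0, nr, ncol(m))
  for (k in seq_along(w)) {
    d <- k - h - 1L          # source row offset
    lo <- max(1L, 1L - d); hi <- min(nr, nr - d)
    if (lo > hi) next        # kernel arm falls entirely off-grid
    dst <- lo:hi
    out[dst, ] <- out[dst, ] + w[k] * m[dst + d, ]
  }
  out
}

conv_sep <- function(m, w) t(conv_cols(t(conv_cols(m, w)), w))

#' Binary class indicator
#'
#' Extracts the indicator surface of one land-cover class: 1 where the cell
#' carries `class_code`, 0 otherwise, `NA` where the input is nodata.
#'
#' @param r categorical [land_raster].
#' @param class_code integer class code; must be in the raster's class table.
#' @return continuous [land_raster] with values in \{0, 1\}.
#' @export
binary_indicator <- function(r, class_code) {
  stopifnot(inherits(r, "land_raster"))
  if (r$type != "categorical") stop("indicator requires a categorical raster")
  if (!(class_code %in% r$classes))
    stop("class code ", class_code, " not in the raster's class table")
  m <- (r$values == class_code) * 1
  land_raster(m, origin = r$origin, cell_size = r$cell_size,
              type = "continuous", crs = r$crs)
}

#' Gaussian kernel smoothing of a continuous surface
#'
#' Computes the kernel-weighted local average of a surface (usually a binary
#' class indicator), giving a continuous landscape-context layer: 0 where no
#' focal class falls within the smoothing neighbourhood, 1 where the
#' neighbourhood is entirely focal class.
#'
#' Two edge policies are offered.  `"renormalize"` (default) rescales the
#' kernel at each pixel to the weight mass that falls inside the grid (and on
#' non-`NA` cells), so a constant surface maps to itself everywhere and class
#' layers that partition the landscape still sum to one at the borders.
#' `"zero_pad"` treats cells outside the grid as zeros, the convention of
#' FFT-based smoothers.
#'
#' @param x continuous [land_raster] (or a bare matrix, returned as matrix).
#' @param kernel a [build_kernel] spec whose `cell_size` matches the raster.
#' @param edge_policy `"renormalize"` or `"zero_pad"`.
#' @return smoothed surface of the same class as `x`; `NA` cells propagate.
#' @export
smooth_surface <- function(x, kernel, edge_policy = c("renormalize", "zero_pad")) {
  edge_policy <- match.arg(edge_policy)
  stopifnot(inherits(kernel, "kernel_spec"))
  is_rast <- inherits(x, "land_raster")
  m <- if (is_rast) x$values else x
  if (is_rast && abs(x$cell_size - kernel$cell_size) > 1e-9 * kernel$cell_size)
    stop("kernel cell size (", kernel$cell_size,
         ") does not match raster cell size (", x$cell_size, ")")
  mask <- is.finite(m)
  m0 <- ifelse(mask, m, 0)
  num <- conv_sep(m0, kernel$profile)
  out <- if (edge_policy == "renormalize") {
    den <- conv_sep(mask * 1, kernel$profile)
    ifelse(den > 0, num / den, NA_real_)
  } else num
  out[!mask] <- NA_real_
  # guard against float drift outside the input's range
  if (all(m0 >= 0 & m0 <= 1)) out <- pmin(pmax(out, 0), 1)
  if (!is_rast) return(out)
  land_raster(out, origin = x$origin, cell_size = x$cell_size,
              type = "continuous", crs = x$crs)
}

#' Smoothed per-class surface stack
#'
#' Applies [binary_indicator()] and [smooth_surface()] to every class of a
#' categorical land-cover raster with a shared Gaussian kernel, producing the
#' stack of continuous class-fraction surfaces that feeds the gradient PCA.
#' Under the `"renormalize"` edge policy the layers form a partition of
#' unity: at every non-nodata pixel the per-class values sum to 1.
#'
#' @param r categorical [land_raster].
#' @param sigma Gaussian kernel standard deviation, map units (landscape
#'   grain; 500 m is a typical songbird breeding home-range scale).
#' @param class_codes classes to extract; defaults to the raster's class
#'   table.  A warning is given if codes not listed occur in the raster.
#' @param edge_policy see [smooth_surface()].
#' @param truncation kernel support half-width, map units.
#' @return object of class `smoothed_stack`: list with `codes`, `layers`
#'   (named list of matrices), `origin`, `cell_size`, `crs`, `sigma`,
#'   `edge_policy`.
#' @export
smooth_stack <- function(r, sigma, class_codes = NULL,
                         edge_policy = c("renormalize", "zero_pad"),
                         truncation = NULL) {
  edge_policy <- match.arg(edge_policy)
  stopifnot(inherits(r, "land_raster"), r$type == "categorical")
  if (is.null(class_codes)) class_codes <- r$classes
  class_codes <- as.integer(class_codes)
  if (length(class_codes) < 1L) stop("empty class code list")
  present <- sort(unique(r$values[!is.na(r$values)]))
  if (!all(present %in% class_codes))
    warning("raster contains codes not being smoothed: ",
            paste(setdiff(present, class_codes), collapse = ", "))
  kern <- build_kernel(sigma, r$cell_size, truncation)
  layers <- lapply(class_codes, function(code) {
    ind <- (r$values == code) * 1
    smooth_surface(ifelse(is.na(r$values), NA_real_, ind), kern, edge_policy)
  })
  names(layers) <- as.character(class_codes)
  structure(list(codes = class_codes, layers = layers, origin = r$origin,
                 cell_size = r$cell_size, crs = r$crs, sigma = sigma,
                 edge_policy = edge_policy),
            class = "smoothed_stack")
}

#' @export
print.smoothed_stack <- function(x, ...) {
  cat(sprintf("<smoothed_stack: %d classes, %d x %d cells, sigma = %g, edges: %s>\n",
              length(x$codes), nrow(x$layers[[1]]), ncol(x$layers[[1]]),
              x$sigma, x$edge_policy))
  invisible(x)
}

#' Extract one layer of a stack as a raster
#'
#' @param stack a [smooth_stack()] result.
#' @param class_code class whose smoothed layer to return.
#' @return continuous [land_raster].
#' @export
stack_layer <- function(stack, class_code) {
  stopifnot(inherits(stack, "smoothed_stack"))
  i <- match(as.integer(class_code), stack$codes)
  if (is.na(i)) stop("class ", class_code, " not in stack")
  land_raster(stack$layers[[i]], origin = stack$origin,
              cell_size = stack$cell_size, type = "continuous", crs = stack$crs)
}

## pixels x classes matrix of a stack; rows with any NA dropped
stack_matrix <- function(stack, drop_na = TRUE) {
  X <- vapply(stack$layers, as.vector, numeric(length(stack$layers[[1]])))
  colnames(X) <- as.character(stack$codes)
  if (drop_na) X <- X[stats::complete.cases(X), , drop = FALSE]
  X
}

#' Write a smoothed stack to a directory
#'
#' One raster file per class, named by class code.
#'
#' @param stack a `smoothed_stack`.
#' @param dir output directory (created if missing).
#' @param format `"asc"` or `"tif"`.
#' @return invisibly, the written paths.
#' @export
write_stack <- function(stack, dir, format = c("asc", "tif")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(stack$codes, function(code) {
    p <- file.path(dir, sprintf("class_%d.%s", code, format))
    write_land_raster(stack_layer(stack, code), p, format)
    p
  }, character(1))
  invisible(paths)
}
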