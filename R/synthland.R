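#' Recipe for a synthetic city landscape
#'
#' Describes a city-like categorical landscape: an urban core whose developed
#' classes decay with distance from the centre, set in a spatially
#' autocorrelated mosaic of the remaining classes, optionally split into
#' "sectors" (e.g. an agricultural belt on one side, forest on the other) so
#' that agricultural and natural cover occupy distinct parts of the map, as
#' they do around real cities.
#'
#' @param proportions named numeric vector: integer class codes to target
#'   landscape proportions (must be non-negative and sum to 1 within 1e-9).
#' @param center_xy map coordinates of the urban centre.
#' @param urban_decay e-folding scale (map units) of the radial urban score.
#' @param autocorr_scale Gaussian scale (map units) of the latent smoothed
#'   noise fields controlling patch size.
#' @param urban_classes codes whose score includes the radial urban term
#'   (default: NLCD developed classes 21-24).
#' @param sector_weights optional named numeric vector (same codes as
#'   `proportions`, defaults 0) multiplying a smooth east-west sector field;
#'   positive values pull a class towards the east, negative towards the
#'   west.
#' @param urban_weight strength of the radial urban term relative to the
#'   unit-variance latent fields: either a scalar applied to every urban
#'   class, or a named vector (by class code) giving per-class weights --
#'   grading the weights from low-intensity to high-intensity development
#'   produces the concentric rings of real urban cores.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return object of class `landscape_recipe`.
#' @export
landscape_recipe <- function(proportions, center_xy = NULL,
                             urban_decay = 5000, autocorr_scale = 1000,
                             urban_classes = c(21L, 22L, 23L, 24L),
                             sector_weights = NULL, urban_weight = 2,
                             seed = 1L) {
  if (is.null(names(proportions)) || any(!nzchar(names(proportions))))
    stop("`proportions` must be named by integer class code")
  codes <- as.integer(names(proportions))
  if (anyNA(codes)) stop("class names must be integer codes")
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (urban_decay <= 0 || autocorr_scale <= 0) stop("scales must be positive")
  if (is.null(sector_weights)) {
    sector_weights <- stats::setNames(numeric(length(codes)), names(proportions))
  } else {
    sw <- stats::setNames(numeric(length(codes)), names(proportions))
    sw[names(sector_weights)] <- sector_weights
    sector_weights <- sw
  }
  uw <- stats::setNames(numeric(length(codes)), names(proportions))
  if (is.null(names(urban_weight))) {
    uw[as.character(intersect(codes, urban_classes))] <- urban_weight[1]
  } else {
    uw[names(urban_weight)] <- urban_weight
  }
  structure(list(codes = codes, proportions = as.numeric(proportions),
                 center_xy = center_xy, urban_decay = urban_decay,
                 autocorr_scale = autocorr_scale,
                 urban_classes = as.integer(urban_classes),
                 sector_weights = as.numeric(sector_weights),
                 urban_weight = as.numeric(uw), seed = as.integer(seed)),
            class = "landscape_recipe")
}

## run expr with a private, seeded RNG stream, restoring global state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

standardize <- function(m) (m - mean(m)) / stats::sd(as.vector(m))

#' Generate a synthetic city landscape
#'
#' Draws one latent field per class -- white noise convolved with the same
#' Gaussian kernel machinery used for class smoothing, then standardised --
#' adds the radial urban score to the developed classes and the sector field
#' where requested, and assigns each pixel to the class with the largest
#' score plus a per-class offset.  Offsets are adjusted iteratively (at most
#' `max_iter` rounds) until every realised class proportion is within `tol`
#' of its target, so composition matches the recipe while spatial structure
#' comes from the latent fields.
#'
#' @param recipe a [landscape_recipe].
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size cell edge length, map units.
#' @param origin top-left corner map coordinates.
#' @param crs CRS tag.
#' @param tol composition tolerance (absolute proportion, default 0.02).
#' @param max_iter maximum reweighting iterations (default 100).
#' @return categorical [land_raster]; deterministic given `recipe$seed`.
#' @examples
#' rec <- landscape_recipe(c(`41` = 0.5, `82` = 0.3, `22` = 0.2), seed = 7)
#' r <- generate_landscape(rec, 80, 80, cell_size = 100)
#' composition(r)
#' @export
generate_landscape <- function(recipe, n_rows, n_cols, cell_size = 30,
                               origin = c(0, 0), crs = "", tol = 0.02,
                               max_iter = 100L) {
  stopifnot(inherits(recipe, "landscape_recipe"))
  if (n_rows < 1L || n_cols < 1L) stop("zero-area grid")
  p <- length(recipe$codes)
  n <- n_rows * n_cols
  if (p == 1L) {
    return(land_raster(matrix(recipe$codes, n_rows, n_cols), origin = origin,
                       cell_size = cell_size, nodata = -9999L, crs = crs,
                       classes = recipe$codes))
  }
  center <- if (is.null(recipe$center_xy))
    c(origin[1] + n_cols * cell_size / 2, origin[2] - n_rows * cell_size / 2)
  else recipe$center_xy

  kern <- build_kernel(recipe$autocorr_scale, cell_size,
                       truncation = max(cell_size, 3 * recipe$autocorr_scale))
  xs <- origin[1] + (seq_len(n_cols) - 0.5) * cell_size
  ys <- origin[2] - (seq_len(n_rows) - 0.5) * cell_size
  d2 <- outer(ys - center[2], xs - center[1],
              function(dy, dx) dx^2 + dy^2)
  urban <- standardize(exp(-d2 / (2 * recipe$urban_decay^2)))
  sector <- standardize(matrix(rep(xs, each = n_rows), n_rows, n_cols))

  scores <- with_seed(recipe$seed, {
    lapply(seq_len(p), function(i) {
      latent <- standardize(smooth_surface(matrix(stats::rnorm(n), n_rows, n_cols),
                                           kern, "renormalize"))
      latent + recipe$sector_weights[i] * sector +
        recipe$urban_weight[i] * urban
    })
  })

  target <- recipe$proportions
  offset <- ifelse(target > 0, 0, -Inf)
  S <- vapply(scores, as.vector, numeric(n))
  classify <- function(off) max.col(sweep(S, 2L, off, `+`), ties.method = "first")
  best <- list(err = Inf, cls = classify(offset))
  for (it in seq_len(max_iter)) {
    cls <- classify(offset)
    realized <- tabulate(cls, p) / n
    err <- target - realized
    if (max(abs(err)) < best$err) best <- list(err = max(abs(err)), cls = cls)
    if (best$err <= tol / 2) break
    # decaying gain damps the oscillation of the discrete argmax
    offset <- ifelse(is.finite(offset), offset + 3 / it^0.3 * err, offset)
  }
  cls <- best$cls
  realized <- tabulate(cls, p) / n
  if (max(abs(target - realized)) > tol)
    warning("composition matching stopped ", max(abs(target - realized)) - tol,
            " beyond tolerance")
  land_raster(matrix(recipe$codes[cls], n_rows, n_cols), origin = origin,
              cell_size = cell_size, nodata = -9999L, crs = crs,
              classes = recipe$codes)
}

#' Landscape composition
#'
#' Per-class cell counts and proportions over non-nodata cells.  Proportions
#' are exact ratios of integer counts and sum to 1.
#'
#' @param r categorical [land_raster].
#' @return data frame with columns `code`, `count`, `proportion`.
#' @export
composition <- function(r) {
  stopifnot(inherits(r, "land_raster"), r$type == "categorical")
  v <- r$values[!is.na(r$values)]
  if (!length(v)) stop("all-nodata raster has no composition")
  tab <- table(factor(v, levels = sort(unique(v))))
  data.frame(code = as.integer(names(tab)), count = as.integer(tab),
             proportion = as.integer(tab) / length(v), row.names = NULL)
}

#' A typical fifteen-class landscape recipe
#'
#' Default recipe emulating the aggregate composition of mid-sized US
#' urban-exurban regions across the fifteen commonly occurring NLCD/Anderson
#' classes: roughly one-fifth developed, one-quarter forested, one-third
#' agricultural, with water, barren land, scrub, grassland and wetlands
#' making up the rest.  Developed classes (21-24) form the urban core;
#' cultivated classes (81, 82) and grassland lean into an eastern
#' agricultural sector while forests and wetlands lean west.
#'
#' @param seed seed passed to [landscape_recipe()].
#' @param ... further arguments overriding [landscape_recipe()] defaults.
#' @return a [landscape_recipe] with 15 classes.
#' @export
default_city_recipe <- function(seed = 1L, ...) {
  pr <- c(`11` = 2.7, `21` = 6.5, `22` = 6.7, `23` = 4.8, `24` = 1.6,
          `31` = 0.8, `41` = 10.2, `42` = 9.0, `43` = 2.1, `52` = 10.6,
          `71` = 10.9, `81` = 11.3, `82` = 19.4, `90` = 2.8, `95` = 0.8)
  landscape_recipe(pr / sum(pr),
                   sector_weights = c(`81` = 0.85, `82` = 0.85, `71` = 0.4,
                                      `41` = -0.85, `42` = -0.85, `43` = -0.85,
                                      `90` = -0.55, `95` = -0.55),
                   urban_weight = c(`21` = 2.6, `22` = 3.3, `23` = 4.0,
                                    `24` = 4.6),
                   seed = seed, ...)
}
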