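#' Streaming moments of smoothed class surfaces
#'
#' Accumulates pixel counts, per-class sums and cross-product sums over one
#' or more smoothed stacks so that the pooled multi-city correlation matrix
#' can be formed without concatenating pixel matrices.  Accumulation is
#' associative: accumulating stacks one by one equals accumulating the
#' concatenated pixels.
#'
#' @param stacks a `smoothed_stack` or a list of them (all sharing the same
#'   class list, in the same order).  Pixels with `NA` in any layer are
#'   skipped.
#' @return object of class `moment_acc` with fields `codes`, `n`, `sums`
#'   (length p) and `crossprod` (p x p).
#' @export
accumulate_moments <- function(stacks) {
  if (inherits(stacks, "smoothed_stack")) stacks <- list(stacks)
  if (!length(stacks)) stop("empty stack list")
  if (!all(vapply(stacks, inherits, logical(1), "smoothed_stack")))
    stop("all elements must be smoothed stacks")
  codes <- stacks[[1]]$codes
  acc <- NULL
  for (s in stacks) {
    if (!identical(s$codes, codes))
      stop("stacks have mismatched class lists")
    X <- stack_matrix(s)
    part <- structure(list(codes = codes, n = nrow(X), sums = colSums(X),
                           crossprod = crossprod(X)),
                      class = "moment_acc")
    acc <- if (is.null(acc)) part else combine_moments(acc, part)
  }
  acc
}

#' @rdname accumulate_moments
#' @param a,b `moment_acc` objects over the same classes.
#' @export
combine_moments <- function(a, b) {
  stopifnot(inherits(a, "moment_acc"), inherits(b, "moment_acc"))
  if (!identical(a$codes, b$codes)) stop("accumulators have mismatched classes")
  structure(list(codes = a$codes, n = a$n + b$n, sums = a$sums + b$sums,
                 crossprod = a$crossprod + b$crossprod),
            class = "moment_acc")
}

#' Broken-stick proportions
#'
#' Expected share of total variance for each of `p` ordered components when
#' unit variance is split at random: `b_k = (1/p) * sum_{i=k}^{p} 1/i`.
#' Components are worth retaining when they explain more variance than this
#' random expectation; for `p = 15` classes the first proportion is 0.221
#' (the 22.1% threshold).
#'
#' @param p number of components (>= 1).
#' @return numeric vector of length `p` summing to 1.
#' @examples
#' round(100 * broken_stick(15)[1], 1)  # 22.1
#' @export
broken_stick <- function(p) {
  if (p < 1) stop("p must be >= 1")
  p <- as.integer(p)
  rev(cumsum(rev(1 / seq_len(p)))) / p
}

#' Correlation-matrix PCA of smoothed landscape surfaces
#'
#' Eigen-decomposes the Pearson correlation matrix of the per-class smoothed
#' surfaces (pixels are observations, classes are variables), pooling all
#' supplied stacks.  Standardising each class to unit variance (the
#' correlation convention) keeps rare classes from being drowned out by
#' dominant ones; under it the percent variance explained by component `k`
#' is `100 * sdev_k^2 / p`.  Classes with zero variance are dropped with a
#' warning (their correlations are undefined) and recorded in the model.
#'
#' Axis retention follows the broken-stick rule (see [broken_stick()]):
#' with `rule = "cumulative"` (default) the retained count `m` is the
#' smallest `k` whose cumulative variance share exceeds the first
#' broken-stick proportion `b_1`; `rule = "per_component"` instead keeps
#' leading axes while `v_k/100 > b_k`.
#'
#' @param x a `smoothed_stack`, list of stacks, or [accumulate_moments()]
#'   result.
#' @param rule broken-stick retention variant.
#' @return object of class `gradient_model` with eigenvalues, `sdev`,
#'   `var_pct`, unit-norm `loadings` (p x p, classes x components),
#'   `broken_stick`, retained axis count `m`, standardisation `center` and
#'   `scale`, `dropped` codes and an `orientation` record.
#' @seealso [orient_axes()], [gradient_surface()], [predict.gradient_model()]
#' @export
gradient_pca <- function(x, rule = c("cumulative", "per_component")) {
  rule <- match.arg(rule)
  acc <- if (inherits(x, "moment_acc")) x else accumulate_moments(x)
  p_all <- length(acc$codes)
  if (acc$n <= p_all)
    stop("need more pixels (", acc$n, ") than classes (", p_all, ")")
  mu <- acc$sums / acc$n
  cov <- (acc$crossprod - acc$n * tcrossprod(mu)) / (acc$n - 1)
  sds <- sqrt(pmax(diag(cov), 0))
  keep <- sds > 1e-12 * max(sds, 1)
  dropped <- acc$codes[!keep]
  if (length(dropped))
    warning("zero-variance class(es) dropped from PCA: ",
            paste(dropped, collapse = ", "))
  codes <- acc$codes[keep]
  p <- length(codes)
  if (p < 2L) stop("fewer than two classes with variance")
  cor_mat <- cov[keep, keep, drop = FALSE] /
    tcrossprod(sds[keep])
  cor_mat <- (cor_mat + t(cor_mat)) / 2
  eig <- eigen(cor_mat, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  loadings <- eig$vectors
  dimnames(loadings) <- list(as.character(codes), paste0("PC", seq_len(p)))
  var_pct <- 100 * lambda / p
  bs <- broken_stick(p)
  m <- retain_axes(var_pct, p, rule)
  structure(list(codes = codes, eigenvalues = lambda,
                 sdev = sqrt(lambda), var_pct = var_pct,
                 loadings = loadings, broken_stick = bs,
                 m = as.integer(m), retention_rule = rule,
                 center = mu[keep], scale = sds[keep],
                 dropped = dropped, n = acc$n,
                 orientation = list()),
            class = "gradient_model")
}

#' @export
print.gradient_model <- function(x, digits = 3, ...) {
  cat(sprintf("<gradient_model: %d classes, %d pixels, %d axis(es) retained (broken stick %.1f%%)>\n",
              length(x$codes), x$n, x$m, 100 * x$broken_stick[1]))
  k <- min(length(x$codes), max(x$m, 3L))
  tab <- rbind(`Std.Dev.` = x$sdev[1:k],
               `Variance Explained (%)` = x$var_pct[1:k],
               `Cumulative (%)` = cumsum(x$var_pct)[1:k])
  colnames(tab) <- paste0("PC", 1:k)
  print(round(tab, digits))
  if (length(x$dropped))
    cat("dropped (zero variance):", paste(x$dropped, collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.gradient_model <- function(object, ...) {
  print(object, ...)
  cat("\nLoadings (retained axes):\n")
  print(round(object$loadings[, seq_len(object$m), drop = FALSE], 3))
  invisible(object)
}

#' Broken-stick axis retention
#'
#' Given percent-variance-explained values for `p` components, returns the
#' number of axes to retain.  The `"cumulative"` rule keeps the smallest
#' leading set whose cumulative variance share exceeds the first
#' broken-stick proportion `b_1` (so `v = (16.7, 11.1, ...)` with `p = 15`
#' retains 2 axes past the 22.1% threshold); `"per_component"` keeps
#' leading axes while each `v_k/100` exceeds its own `b_k`.  At least one
#' axis is always retained.
#'
#' @param var_pct percent variance explained per component, descending.
#' @param p total number of components (defaults to `length(var_pct)`).
#' @param rule retention variant.
#' @return integer retained axis count `m >= 1`.
#' @export
retain_axes <- function(var_pct, p = length(var_pct),
                        rule = c("cumulative", "per_component")) {
  rule <- match.arg(rule)
  bs <- broken_stick(p)
  if (rule == "cumulative") {
    hit <- which(cumsum(var_pct) / 100 > bs[1])
    if (!length(hit)) length(var_pct) else hit[1]
  } else {
    above <- var_pct / 100 > bs[seq_along(var_pct)]
    if (!above[1]) 1L else max(which(cumsum(!above) == 0))
  }
}

#' Percent variance explained from a component standard deviation
#'
#' Under correlation-matrix PCA on `p` variables the total variance is `p`,
#' so a component with standard deviation `sdev` explains
#' `100 * sdev^2 / p` percent of the variance.
#'
#' @param sdev component standard deviation(s) (square roots of eigenvalues).
#' @param p number of variables.
#' @return percent variance explained.
#' @examples
#' variance_explained(1.581, 15)  # 16.66 -> prints as 16.7
#' @export
variance_explained <- function(sdev, p) 100 * sdev^2 / p

#' Default gradient axis anchors
#'
#' Sign conventions for the two retained landscape axes: the first axis is
#' the hard-to-soft gradient, anchored so the developed classes (21-24) load
#' *negative* (hard/built at low values, soft/vegetated at high); the second
#' is the brown-to-green gradient, anchored so forest classes (41-43) load
#' *positive* (green high, agricultural brown low).
#'
#' @return list of per-axis anchors: `list(axis, classes, sign)`.
#' @export
default_anchors <- function() {
  list(list(axis = 1L, classes = c(21L, 22L, 23L, 24L), sign = -1),
       list(axis = 2L, classes = c(41L, 42L, 43L), sign = +1))
}

#' Orient gradient axes by anchor classes
#'
#' Eigenvectors are sign-indeterminate; this fixes interpretable directions
#' by flipping any anchored axis whose summed loading over the anchor
#' classes has the wrong sign.  Eigenvalues are untouched and the operation
#' is idempotent.  Anchors for axes beyond the retained count, or whose
#' anchor classes are all absent, raise an error.
#'
#' @param model a [gradient_pca()] fit.
#' @param anchors list of anchors as in [default_anchors()].
#' @return the model with oriented loadings and an updated `orientation`
#'   record (one entry per anchored axis, with the applied sign).
#' @export
orient_axes <- function(model, anchors = default_anchors()) {
  stopifnot(inherits(model, "gradient_model"))
  codes <- as.integer(rownames(model$loadings))
  for (a in anchors) {
    if (a$axis > ncol(model$loadings)) stop("anchor axis ", a$axis, " not present")
    rows <- which(codes %in% a$classes)
    if (!length(rows))
      stop("anchor classes absent from model for axis ", a$axis)
    s <- sum(model$loadings[rows, a$axis])
    flip <- sign(s) != 0 && sign(s) != sign(a$sign)
    if (flip) model$loadings[, a$axis] <- -model$loadings[, a$axis]
    model$orientation[[paste0("axis", a$axis)]] <-
      list(classes = a$classes, sign = a$sign, flipped = flip ||
             isTRUE(model$orientation[[paste0("axis", a$axis)]]$flipped))
  }
  model
}

#' Gradient surface from a smoothed stack
#'
#' Projects a smoothed stack onto one retained axis, pixel by pixel.  The
#' default `"weighted_average"` mode is the plain weighted sum of the raw
#' smoothed class fractions by the axis loadings,
#' `s(x) = sum_c z_c(x) w_c`; `"score"` mode standardises each class by the
#' model's centring and scaling first, giving a true principal-component
#' score surface.
#'
#' @param stack a `smoothed_stack` whose classes match the model's.
#' @param model a [gradient_pca()] fit (usually after [orient_axes()]).
#' @param axis retained axis index (<= `model$m` unless `allow_unretained`).
#' @param mode `"weighted_average"` or `"score"`.
#' @param allow_unretained set `TRUE` to project on non-retained axes.
#' @return continuous [land_raster].
#' @export
gradient_surface <- function(stack, model, axis = 1L,
                             mode = c("weighted_average", "score"),
                             allow_unretained = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "smoothed_stack"), inherits(model, "gradient_model"))
  if (axis < 1L || axis > ncol(model$loadings)) stop("no such axis: ", axis)
  if (!allow_unretained && axis > model$m)
    stop("axis ", axis, " is beyond the ", model$m, " retained axis(es)")
  codes <- as.integer(rownames(model$loadings))
  if (!all(codes %in% stack$codes))
    stop("stack lacks model classes: ",
         paste(setdiff(codes, stack$codes), collapse = ", "))
  w <- model$loadings[, axis]
  out <- 0
  for (i in seq_along(codes)) {
    z <- stack$layers[[match(codes[i], stack$codes)]]
    if (mode == "score") z <- (z - model$center[i]) / model$scale[i]
    out <- out + w[i] * z
  }
  land_raster(out, origin = stack$origin, cell_size = stack$cell_size,
              type = "continuous", crs = stack$crs)
}

#' @describeIn gradient_surface `predict` method projecting a stack on an
#'   axis; equivalent to `gradient_surface(stack, object, ...)`.
#' @param object a `gradient_model`.
#' @param ... passed on to `gradient_surface()`.
#' @export
predict.gradient_model <- function(object, stack, axis = 1L,
                                   mode = c("weighted_average", "score"), ...) {
  gradient_surface(stack, object, axis = axis, mode = match.arg(mode), ...)
}

#' Serialise / restore a gradient model as JSON
#'
#' @param model a `gradient_model`.
#' @param path JSON file path.
#' @return `write_gradient_model()` invisibly returns `path`;
#'   `read_gradient_model()` returns the restored `gradient_model`.
#' @export
write_gradient_model <- function(model, path) {
  stopifnot(inherits(model, "gradient_model"))
  obj <- model
  obj$loadings <- apply(model$loadings, 2L, identity, simplify = FALSE)
  obj$codes <- as.integer(model$codes)
  jsonlite::write_json(unclass(obj), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_gradient_model
#' @export
read_gradient_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- do.call(cbind, obj$loadings)
  dimnames(L) <- list(as.character(obj$codes), paste0("PC", seq_len(ncol(L))))
  obj$loadings <- L
  obj$codes <- as.integer(obj$codes)
  obj$m <- as.integer(obj$m)
  if (is.null(obj$orientation)) obj$orientation <- list()
  if (is.null(obj$dropped)) obj$dropped <- integer(0)
  structure(obj, class = "gradient_model")
}
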