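test_that("moment accumulation is associative and matches dense statistics", {
  set.seed(23)
  A <- fake_stack(list(matrix(runif(50), 10), matrix(runif(50), 10),
                       matrix(runif(50), 10)), codes = c(21, 41, 82))
  B <- fake_stack(list(matrix(runif(40), 8), matrix(runif(40), 8),
                       matrix(runif(40), 8)), codes = c(21, 41, 82))
  acc <- accumulate_moments(list(A, B))
  acc2 <- combine_moments(accumulate_moments(A), accumulate_moments(B))
  expect_equal(acc, acc2)
  X <- rbind(do.call(cbind, lapply(A$layers, as.vector)),
             do.call(cbind, lapply(B$layers, as.vector)))
  expect_equal(acc$n, nrow(X))
  expect_equal(acc$sums, colSums(X), ignore_attr = TRUE)
  expect_equal(acc$crossprod, crossprod(X), ignore_attr = TRUE)
  m <- gradient_pca(acc)
  expect_equal(m$center, colMeans(X), ignore_attr = TRUE)
  expect_equal(m$eigenvalues, eigen(cor(X), symmetric = TRUE)$values,
               tolerance = 1e-10)
  expect_error(accumulate_moments(list()), "empty")
  expect_error(accumulate_moments(list(A, fake_stack(list(matrix(0, 2, 2)), 5))),
               "mismatch")
})

test_that("two perfectly anticorrelated classes give eigenvalues 2 and 0", {
  set.seed(4)
  z <- matrix(runif(100), 10)
  st <- fake_stack(list(z, 1 - z), codes = c(22, 41))
  m <- gradient_pca(st)
  expect_equal(m$eigenvalues, c(2, 0), tolerance = 1e-10)
  expect_equal(m$var_pct[1], 100, tolerance = 1e-8)
  expect_equal(m$m, 1L)
})

test_that("correlation-matrix convention: variance explained is 100 sdev^2 / p", {
  expect_equal(round(variance_explained(1.581, 15), 1), 16.7)
  expect_equal(round(variance_explained(1.182, 15), 1), 9.3)
  # and internally: var_pct always equals 100 * sdev^2 / p
  set.seed(8)
  st <- fake_stack(lapply(1:4, function(i) matrix(runif(64), 8)))
  m <- gradient_pca(st)
  expect_equal(m$var_pct, variance_explained(m$sdev, 4), tolerance = 1e-12)
})

test_that("independent white-noise classes have near-unit eigenvalues", {
  set.seed(101)
  st <- fake_stack(lapply(1:15, function(i) matrix(rnorm(10000), 100)))
  m <- gradient_pca(st)
  expect_true(all(abs(m$eigenvalues - 1) < 0.1))
})

test_that("broken stick proportions follow the closed form", {
  expect_equal(broken_stick(1), 1)
  # independent direct-summation oracle
  oracle <- function(p) vapply(1:p, function(k) sum(1 / (k:p)) / p, numeric(1))
  for (p in c(3, 7, 15)) expect_equal(broken_stick(p), oracle(p), tolerance = 1e-12)
  expect_equal(round(broken_stick(3), 4), c(0.6111, 0.2778, 0.1111))
  expect_equal(round(100 * broken_stick(15)[1], 1), 22.1)
  expect_equal(sum(broken_stick(12)), 1, tolerance = 1e-12)
  expect_error(broken_stick(0))
})

test_that("cumulative broken-stick retention reproduces the two-axis decision", {
  v <- c(16.7, 11.1, 9.3, rep(62.9 / 12, 12))
  expect_equal(retain_axes(v, 15), 2L)
  expect_equal(retain_axes(c(100, rep(0, 4)), 5), 1L)
  # uniform variance: direct-scan oracle
  for (p in c(4, 9, 15)) {
    v_u <- rep(100 / p, p)
    b1 <- broken_stick(p)[1]
    oracle <- which(cumsum(v_u) / 100 > b1)[1]
    expect_equal(retain_axes(v_u, p), oracle)
  }
})

test_that("axis orientation flips by anchor sign and is idempotent", {
  set.seed(12)
  st <- fake_stack(lapply(1:4, function(i) matrix(runif(100), 10)),
                   codes = c(21, 22, 41, 82))
  m <- gradient_pca(st)
  m$m <- 2L  # exercise both anchors regardless of retention
  anchors <- list(list(axis = 1L, classes = c(21L, 22L), sign = -1),
                  list(axis = 2L, classes = 41L, sign = +1))
  o1 <- orient_axes(m, anchors)
  expect_lte(sum(o1$loadings[c("21", "22"), 1]), 0)
  expect_gte(o1$loadings["41", 2], 0)
  expect_equal(abs(o1$loadings), abs(m$loadings))
  expect_equal(o1$eigenvalues, m$eigenvalues)
  o2 <- orient_axes(o1, anchors)
  expect_equal(o2$loadings, o1$loadings)
  expect_error(orient_axes(m, list(list(axis = 1L, classes = 99L, sign = 1))),
               "absent")
})

test_that("the weighted-average surface is the loading-weighted sum of layers", {
  # one pixel entirely of a class with loading -0.545 maps to -0.545
  layers <- list(matrix(c(1, 0), 1), matrix(c(0, 1), 1))
  st <- fake_stack(layers, codes = c(22, 41))
  m <- gradient_pca(fake_stack(list(matrix(runif(100), 10),
                                    matrix(runif(100), 10)), codes = c(22, 41)))
  m$loadings[, 1] <- c(-0.545, 0.3)
  s <- gradient_surface(st, m, axis = 1)
  expect_equal(s$values[1, 1], -0.545)
  expect_equal(s$values[1, 2], 0.3)
  # all-zero stack maps to zero
  z <- fake_stack(list(matrix(0, 3, 3), matrix(0, 3, 3)), codes = c(22, 41))
  expect_true(all(gradient_surface(z, m, 1)$values == 0))
})

test_that("surfaces match a dense matrix-vector oracle and negate under flips", {
  set.seed(77)
  st <- fake_stack(lapply(1:5, function(i) matrix(runif(64), 8)))
  m <- gradient_pca(st)
  m$m <- 2L
  for (mode in c("weighted_average", "score")) {
    s <- gradient_surface(st, m, 2, mode)
    X <- do.call(cbind, lapply(st$layers, as.vector))
    if (mode == "score") X <- scale(X, center = m$center, scale = m$scale)
    expect_equal(as.vector(s$values), drop(X %*% m$loadings[, 2]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  flipped <- m
  flipped$loadings[, 2] <- -flipped$loadings[, 2]
  expect_equal(gradient_surface(st, flipped, 2)$values,
               -gradient_surface(st, m, 2)$values)
  expect_error(gradient_surface(st, m, 5, allow_unretained = FALSE), "retained")
})

test_that("eigen-structure invariants hold on a synthetic city", {
  r <- generate_landscape(default_city_recipe(seed = 6), 60, 60, cell_size = 100)
  m <- gradient_pca(smooth_stack(r, sigma = 500))
  p <- length(m$codes)
  expect_equal(sum(m$eigenvalues), p, tolerance = 1e-8)
  expect_equal(crossprod(m$loadings), diag(p), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(m$broken_stick), 1, tolerance = 1e-12)
  expect_equal(sum(m$var_pct), 100, tolerance = 1e-8)
})

test_that("zero-variance classes are dropped with a warning", {
  set.seed(3)
  st <- fake_stack(list(matrix(runif(100), 10), matrix(0.5, 10, 10),
                        matrix(runif(100), 10)), codes = c(11, 22, 41))
  expect_warning(m <- gradient_pca(st), "zero-variance")
  expect_equal(m$dropped, 22L)
  expect_equal(length(m$codes), 2L)
})

test_that("pooled axes recover the hard/soft and brown/green structure", {
  stacks <- lapply(1:2, function(k) {
    r <- generate_landscape(default_city_recipe(seed = 40 + k), 100, 100,
                            cell_size = 100)
    smooth_stack(r, sigma = 500)
  })
  m <- orient_axes(gradient_pca(stacks))
  expect_gte(m$m, 2L)
  hs <- unlist(lapply(stacks, function(s) gradient_surface(s, m, 1)$values))
  bg <- unlist(lapply(stacks, function(s)
    gradient_surface(s, m, 2, allow_unretained = TRUE)$values))
  dev_frac <- unlist(lapply(stacks, function(s)
    s$layers[["21"]] + s$layers[["22"]] + s$layers[["23"]] + s$layers[["24"]]))
  forest <- unlist(lapply(stacks, function(s)
    s$layers[["41"]] + s$layers[["42"]] + s$layers[["43"]]))
  crop <- unlist(lapply(stacks, function(s) s$layers[["81"]] + s$layers[["82"]]))
  expect_lt(cor(hs, dev_frac), -0.8)    # hard end = developed
  expect_gt(cor(bg, forest), 0)         # green end = forest
  expect_lt(cor(bg, crop), 0)           # brown end = agriculture
})

test_that("gradient models round-trip through JSON", {
  set.seed(14)
  st <- fake_stack(lapply(1:3, function(i) matrix(runif(64), 8)),
                   codes = c(21, 41, 82))
  m <- orient_axes(gradient_pca(st),
                   list(list(axis = 1L, classes = 21L, sign = -1)))
  path <- tempfile(fileext = ".json")
  write_gradient_model(m, path)
  back <- read_gradient_model(path)
  expect_equal(back$loadings, m$loadings, tolerance = 1e-12)
  expect_equal(back$eigenvalues, m$eigenvalues, tolerance = 1e-12)
  expect_identical(back$m, m$m)
})
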