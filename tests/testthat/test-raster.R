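test_that("ASCII grid and GeoTIFF round-trip codes and georeference exactly", {
  r <- pattern_raster(nr = 3, nc = 3, codes = c(41L, 82L, 22L))
  for (fmt in c("asc", "tif")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_land_raster(r, path)
    back <- read_land_raster(path, "categorical")
    expect_identical(back$values, r$values)
    expect_equal(back$origin, r$origin)
    expect_equal(back$cell_size, r$cell_size)
    expect_identical(back$classes, r$classes)
  }
})

test_that("continuous ASCII grids round-trip values and NA cells", {
  m <- matrix(runif(20), 4, 5)
  m[2, 3] <- NA
  r <- land_raster(m, origin = c(-50, 70), cell_size = 10, type = "continuous")
  path <- tempfile(fileext = ".asc")
  write_land_raster(r, path)
  back <- read_land_raster(path, "continuous")
  expect_equal(back$values, r$values, tolerance = 1e-12)
  expect_true(is.na(back$values[2, 3]))
})

test_that("nodata cells are flagged, not treated as a class", {
  txt <- c("ncols 3", "nrows 2", "xllcorner 0", "yllcorner 0",
           "cellsize 30", "NODATA_value -9999",
           "41 -9999 82", "22 41 -9999")
  path <- tempfile(fileext = ".asc")
  writeLines(txt, path)
  r <- read_land_raster(path, "categorical")
  expect_equal(sum(is.na(r$values)), 2L)
  expect_identical(r$classes, c(22L, 41L, 82L))
  expect_equal(composition(r)$proportion, c(1, 2, 1) / 4)
})

test_that("window length to cell count uses round-to-nearest", {
  expect_identical(window_cells(50000, 30), 1667L)
  expect_identical(window_cells(30000, 30), 1000L)
  expect_identical(window_cells(300, 100), 3L)
  expect_error(window_cells(-1, 30))
})

test_that("cropping the full extent reproduces the raster", {
  r <- pattern_raster(nr = 10, nc = 10, cell = 30, origin = c(0, 300))
  cr <- crop_window(r, center_xy = c(150, 150), half_width = 150)
  expect_identical(cr$values, r$values)
  expect_equal(cr$origin, r$origin)
})

test_that("a 30 km window cut from a 50 km landscape is a centred 1000-cell subgrid", {
  n <- window_cells(50000, 30)                 # 1667
  vals <- matrix(rep_len(c(41L, 82L), n * n), n, n)
  r <- land_raster(vals, origin = c(0, n * 30), cell_size = 30)
  center <- c(n * 30 / 2, n * 30 / 2)
  cr <- crop_window(r, center, half_width = 15000)
  expect_equal(dim(cr$values), c(1000L, 1000L))
  expect_equal(cr$cell_size, 30)
  expect_false(anyNA(cr$values))
  # centre cell of the crop matches the centre of the source
  mid_src <- extract_at_points(r, data.frame(id = 1, x = center[1], y = center[2]))
  mid_crp <- extract_at_points(cr, data.frame(id = 1, x = center[1], y = center[2]))
  expect_equal(mid_src$value, mid_crp$value)
})

test_that("cropping beyond the edge pads with nodata and keeps declared extent", {
  r <- pattern_raster(nr = 20, nc = 20, cell = 30, origin = c(0, 600))
  cr <- crop_window(r, center_xy = c(0, 600), half_width = 300)  # top-left corner
  expect_equal(dim(cr$values), c(20L, 20L))
  expect_true(all(is.na(cr$values[, 1:10])))   # west half outside
  expect_true(all(is.na(cr$values[1:10, ])))   # north half outside
  expect_false(anyNA(cr$values[11:20, 11:20]))
  expect_error(crop_window(r, c(1e6, 1e6), 300), "intersect")
})

test_that("crop of a crop equals a single composed crop", {
  r <- pattern_raster(nr = 40, nc = 40, cell = 10, origin = c(0, 400))
  once <- crop_window(r, c(200, 200), 100)
  twice <- crop_window(crop_window(r, c(200, 200), 150), c(200, 200), 100)
  expect_identical(twice$values, once$values)
  expect_equal(twice$origin, once$origin)
})

test_that("point extraction is nearest-pixel and matches direct indexing", {
  nr <- 12; nc <- 9; cell <- 30
  m <- matrix(rep(seq_len(nr), nc), nr, nc)  # value = row index
  r <- land_raster(m, origin = c(0, nr * cell), cell_size = cell,
                   type = "continuous")
  # exactly at a pixel centre, and 1 cm off it
  expect_equal(extract_at_points(r, data.frame(id = 1, x = 45, y = 345))$value,
               1)
  expect_equal(extract_at_points(r, data.frame(id = 1, x = 45.01, y = 344.99))$value,
               1)
  set.seed(9)
  pts <- data.frame(id = 1:100, x = runif(100, 0, nc * cell),
                    y = runif(100, 0, nr * cell))
  got <- extract_at_points(r, pts)
  want <- vapply(seq_len(100), function(i) {
    row <- floor((nr * cell - pts$y[i]) / cell) + 1
    col <- floor(pts$x[i] / cell) + 1
    m[row, col]
  }, numeric(1))
  expect_equal(got$value, want)
})

test_that("points outside the extent are flagged, never dropped", {
  r <- pattern_raster(nr = 4, nc = 4, cell = 30, origin = c(0, 120))
  pts <- data.frame(id = c("in", "out"), x = c(50, 500), y = c(50, 50))
  expect_warning(got <- extract_at_points(r, pts), "outside")
  expect_equal(nrow(got), 2L)
  expect_false(got$inside[2])
  expect_true(is.na(got$value[2]))
})

test_that("malformed inputs error cleanly", {
  expect_error(read_land_raster(tempfile(), "categorical"), "not found")
  bad <- tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "oops"), bad)
  expect_error(read_land_raster(bad, "categorical"))
  expect_error(land_raster(matrix(1.5, 2, 2)), "integer")
})
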