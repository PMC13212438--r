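test_that("gradient recipe gives the closed-form west-east ramp", {
  spec <- landscapeSpec(10, 10, variables = list(
    g = list(recipe = "gradient", axis = "x")), seed = 1)
  stk <- generateStack(spec)
  g <- getLayer(stk, "g")
  for (j in 1:10) expect_equal(unname(g[, j]), rep((j - 1) / 9, 10))
})

test_that("generation is deterministic in (spec, seed) and seed-sensitive", {
  spec <- landscapeSpec(12, 12, variables = list(
    a = list(recipe = "smoothed-noise", width = 5),
    b = list(recipe = "gaussian-bumps", n_bumps = 3)), seed = 7)
  s1 <- generateStack(spec)
  s2 <- generateStack(spec)
  expect_identical(s1@layers, s2@layers)
  spec2 <- spec; spec2$seed <- 8L
  expect_false(identical(generateStack(spec2)@layers, s1@layers))
})

test_that("smoothed noise is spatially autocorrelated (lag-1 > 0.5)", {
  spec <- landscapeSpec(50, 50, variables = list(
    n = list(recipe = "smoothed-noise", width = 5)), seed = 7)
  m <- getLayer(generateStack(spec), "n")
  lag1 <- cor(as.vector(m[, -1]), as.vector(m[, -ncol(m)]))
  expect_gt(lag1, 0.5)
})

test_that("unknown recipe is a configuration error", {
  spec <- landscapeSpec(10, 10, variables = list(
    x = list(recipe = "perlin")), seed = 1)
  expect_error(generateStack(spec), "unknown field recipe")
})

test_that("generated layers share grid and pass the alignment check on re-read", {
  spec <- landscapeSpec(10, 12, variables = list(
    a = list(recipe = "gradient", axis = "x"),
    b = list(recipe = "smoothed-noise", width = 3)),
    nodata_fraction = 0.1, seed = 2)
  stk <- generateStack(spec)
  d <- tempfile(); dir.create(d)
  paths <- writeStack(stk, d)
  back <- readStack(paths, layerNames(stk))
  expect_equal(back@layers, stk@layers)
  expect_equal(sum(nodataMask(stk)), round(0.1 * 120))
})

test_that("zero-coefficient sampling is uniform over cells", {
  spec <- landscapeSpec(8, 8, variables = list(
    v = list(recipe = "gradient", axis = "x")), seed = 1)
  stk <- generateStack(spec)
  occ <- samplePresences(stk, c(v = 0), 10000, seed = 42)
  counts <- table(factor(paste(occ$row, occ$col),
                         levels = paste(validCells(stk)[, 1], validCells(stk)[, 2])))
  p <- chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("positive coefficient shifts presences toward high values", {
  spec <- landscapeSpec(20, 20, variables = list(
    v = list(recipe = "gradient", axis = "x")), seed = 1)
  stk <- generateStack(spec)
  occ <- samplePresences(stk, c(v = 5), 500, seed = 9)
  vals <- extractCells(stk, as.matrix(occ[, c("row", "col")]))
  expect_gt(mean(vals[, "v"]), mean(getLayer(stk, "v"), na.rm = TRUE))
})

test_that("zero presences give an empty set without error", {
  spec <- landscapeSpec(8, 8, variables = list(
    v = list(recipe = "gradient", axis = "x")), seed = 1)
  occ <- samplePresences(generateStack(spec), c(v = 1), 0)
  expect_equal(nrow(occ), 0)
})

test_that("presence sampling errors on an all-nodata stack", {
  spec <- landscapeSpec(8, 8, variables = list(
    v = list(recipe = "gradient", axis = "x")), seed = 1)
  stk <- generateStack(spec)
  m <- getLayer(stk, "v"); m[] <- NA_real_
  empty <- envStack(list(v = m), gridTransform(stk))
  expect_error(samplePresences(empty, c(v = 1), 10), "valid cells")
})

test_that("density fields honour the zero fraction and log-normal positives", {
  spec <- landscapeSpec(100, 100, variables = list(
    v = list(recipe = "gradient", axis = "x")), seed = 1)
  d <- generateDensity(spec, zero_fraction = 0.3, seed = 1)
  zf <- mean(d == 0)
  expect_gte(zf, 0.25); expect_lte(zf, 0.35)
  expect_true(all(d >= 0))
  lp <- log(d[d > 0])
  expect_gt(shapiro.test(sample(lp, 500))$p.value, 1e-4)
  d0 <- generateDensity(spec, zero_fraction = 0, seed = 2)
  expect_true(all(d0 > 0))
  expect_identical(generateDensity(spec, 0.3, seed = 5),
                   generateDensity(spec, 0.3, seed = 5))
})
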