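test_that("full shrinkage collapses to the uniform distribution", {
  fx <- modelFixture()
  sp <- featureSpec(apply(fx$land, 2, range), "L", 5)
  Fp <- buildDesign(fx$pres, sp); Fl <- buildDesign(fx$land, sp)
  m0 <- fitMaxent(Fp, Fl, rep(1e6, ncol(Fl)), sp)
  expect_equal(unname(modelCoefficients(m0)), rep(0, ncol(Fl)))
  raw <- predictRaw(m0, Fl, is_design = TRUE)
  expect_equal(raw, rep(1 / nrow(Fl), nrow(Fl)))
  expect_equal(predictCloglog(m0, Fl, is_design = TRUE),
               rep(1 - exp(-1), nrow(Fl)))
})

test_that("unpenalised fit satisfies the maximum-entropy moment condition", {
  fx <- modelFixture()
  sp <- featureSpec(apply(fx$land, 2, range)[, "temp", drop = FALSE], "L", 5)
  Fp <- buildDesign(fx$pres[, "temp", drop = FALSE], sp)
  Fl <- buildDesign(fx$land[, "temp", drop = FALSE], sp)
  m <- fitMaxent(Fp, Fl, 0, sp, tol = 1e-9, max_iter = 2000)
  q <- predictRaw(m, Fl, is_design = TRUE)
  expect_lt(abs(sum(q * Fl[, 1]) - mean(Fp[, 1])), 1e-4)
  expect_equal(sum(q), 1, tolerance = 1e-10)
})

test_that("raw probabilities normalise and respond monotonically to coefficients", {
  fx <- modelFixture()
  mod <- fitFromValues(fx$pres, fx$land, "LQ", 0.6, K = 6,
                       max_iter = 300, tol = 1e-5)
  raw <- predictRaw(mod, fx$land)
  expect_equal(sum(raw), 1, tolerance = 1e-10)
  expect_true(all(raw >= 0))
  expect_true(all(abs(mod@H) <= log(nrow(fx$land)) + 1e-9))

  # 3-cell toy: doubling a positive coefficient raises the top cell's rank
  sp <- featureSpec(matrix(c(0, 1), 2, 1, dimnames = list(NULL, "v")), "L", 5)
  toy <- matrix(c(0.1, 0.5, 0.9), 3, 1, dimnames = list(NULL, "v"))
  D <- buildDesign(toy, sp)
  m1 <- fitMaxent(D[2:3, , drop = FALSE], D, 0.001, sp, max_iter = 100)
  if (modelCoefficients(m1)[1] > 0) {
    m2 <- m1
    m2@lambda <- m1@lambda * 2
    r1 <- predictRaw(m1, D, is_design = TRUE)
    r2 <- predictRaw(m2, D, is_design = TRUE)
    expect_gt(r2[3] / sum(r2), r1[3] / sum(r1))
  }
})

test_that("cloglog is a rank-preserving map into (0,1)", {
  fx <- modelFixture(seed = 5)
  mod <- fitFromValues(fx$pres, fx$land, "LQH", 1, K = 6,
                       max_iter = 200, tol = 1e-4)
  raw <- predictRaw(mod, fx$bg)
  p <- predictCloglog(mod, fx$bg)
  expect_true(all(p > 0 & p < 1))
  expect_equal(order(raw), order(p))
  expect_equal(p, 1 - exp(-exp(mod@H) * raw))
})

test_that("objective ascends and coefficients sparsify as RM grows", {
  fx <- modelFixture(seed = 7)
  nz <- sapply(c(0.5, 1, 2, 3), function(rm) {
    m <- fitFromValues(fx$pres, fx$land, "LQH", rm, K = 6,
                       max_iter = 200, tol = 1e-5)
    sum(modelCoefficients(m) != 0)
  })
  expect_true(all(diff(nz) <= 0))
})

test_that("gain credits conserve the total objective improvement", {
  fx <- modelFixture(seed = 2)
  mod <- fitFromValues(fx$pres, fx$land, "LQ", 1, K = 6,
                       max_iter = 300, tol = 1e-6)
  # total objective improvement from lambda = 0: J(lambda) - J(0)
  sp <- structure(mod@spec, class = "featureSpec")
  Fp <- buildDesign(fx$pres, sp); Fl <- buildDesign(fx$land, sp)
  J <- mean(Fp %*% mod@lambda) - mod@logZ -
    sum(mod@beta * abs(mod@lambda))
  J0 <- -log(nrow(Fl))
  expect_equal(sum(mod@gain), J - J0, tolerance = 1e-8)
})

test_that("true coefficients are recovered on synthetic Gibbs data", {
  spec <- landscapeSpec(50, 50, variables = list(
    v1 = list(recipe = "smoothed-noise", width = 5),
    v2 = list(recipe = "smoothed-noise", width = 7),
    v3 = list(recipe = "smoothed-noise", width = 9),
    v4 = list(recipe = "gradient", axis = "x")), seed = 11)
  stk <- generateStack(spec)
  lam_true <- c(v1 = 2, v2 = -1.5, v3 = 0.8, v4 = 1.2)
  occ <- samplePresences(stk, lam_true, 2000, seed = 21)
  land <- extractCells(stk, validCells(stk))
  pv <- extractCells(stk, as.matrix(occ[, c("row", "col")]))
  mod <- fitFromValues(pv, land, "L", 0.1, max_iter = 500, tol = 1e-6)
  expect_gt(cor(modelCoefficients(mod), lam_true), 0.9)
})

test_that("response curves reflect the fitted shape", {
  # positive linear term -> monotone increasing curve
  fx <- modelFixture(seed = 4, coefficients = c(temp = 4))
  mod <- fitFromValues(fx$pres, fx$land, "L", 0.5, max_iter = 300)
  rc <- responseCurve(mod, "temp", n_points = 50)
  expect_true(all(diff(rc$suitability) >= -1e-12))
  expect_error(responseCurve(mod, "nope"), "unknown variable")

  # quadratic with known vertex near 0.5 of the scaled range
  sp <- featureSpec(matrix(c(0, 1), 2, 1, dimnames = list(NULL, "v")), "LQ", 5)
  grid_v <- matrix(seq(0, 1, length.out = 200), ncol = 1,
                   dimnames = list(NULL, "v"))
  D <- buildDesign(grid_v, sp)
  m <- new("MaxentModel", spec = unclass(sp),
           lambda = c("line:v" = 4, "quad:v" = -4),
           beta = c("line:v" = 0, "quad:v" = 0),
           logZ = as.numeric(log(sum(exp(D %*% c(4, -4))))),
           H = 1, rm = 1, fc = "LQ",
           gain = c(v = 1), varMeans = c(v = 0.5), nCells = 200L,
           converged = TRUE, sweeps = 1L)
  rc2 <- responseCurve(m, "v", n_points = 101)
  expect_lt(abs(rc2$value[which.max(rc2$suitability)] - 0.5), 0.011)
  # endpoints equal the clamped-boundary predictions
  lo <- matrix(-5, 1, 1, dimnames = list(NULL, "v"))
  expect_equal(rc2$suitability[1], predictCloglog(m, lo))
})

test_that("jackknife flags the informative variable and redundancy", {
  spec <- landscapeSpec(30, 30, variables = list(
    driver = list(recipe = "gradient", axis = "x"),
    noise1 = list(recipe = "smoothed-noise", width = 5),
    noise2 = list(recipe = "smoothed-noise", width = 7)), seed = 13)
  stk <- generateStack(spec)
  occ <- samplePresences(stk, c(driver = 4), 150, seed = 1)
  bg <- sampleBackground(stk, 300, seed = 2)
  pv <- extractCells(stk, as.matrix(occ[, c("row", "col")]))
  bv <- extractCells(stk, as.matrix(bg[, c("row", "col")]))
  jk <- jackknifeTest(pv, rbind(pv, bv), bv, fc = "LQ", rm = 1, K = 5)
  only <- jk[jk$mode == "only", ]
  expect_equal(only$variable[which.max(only$auc)], "driver")
  full_auc <- jk$auc[jk$mode == "full"]
  expect_gte(full_auc, max(only$auc) - 0.02)

  # duplicated variable: removing one copy barely matters
  pv2 <- cbind(pv[, c("driver", "noise1")], dup = pv[, "driver"])
  bv2 <- cbind(bv[, c("driver", "noise1")], dup = bv[, "driver"])
  jk2 <- jackknifeTest(pv2, rbind(pv2, bv2), bv2, fc = "L", rm = 1, K = 5)
  wo <- jk2[jk2$mode == "without" & jk2$variable == "dup", ]
  expect_lt(abs(jk2$auc[jk2$mode == "full"] - wo$auc), 0.01)
})

test_that("permutation importance isolates the variables the model uses", {
  fx <- modelFixture(seed = 6, coefficients = c(temp = 4, prec = 0.5))
  mod <- fitFromValues(fx$pres, fx$land, "L", 0.5, max_iter = 300)
  imp <- permutationImportance(mod, fx$pres, fx$bg, seed = 3)
  expect_equal(sum(imp), 100, tolerance = 0.1)
  expect_gt(imp[["temp"]], imp[["prec"]])

  # single-variable model -> importance 100
  m1 <- fitFromValues(fx$pres[, "temp", drop = FALSE],
                      fx$land[, "temp", drop = FALSE], "L", 0.5)
  imp1 <- permutationImportance(m1, fx$pres[, "temp", drop = FALSE],
                                fx$bg[, "temp", drop = FALSE], seed = 1)
  expect_equal(unname(imp1), 100)

  # a variable with all-zero coefficients scores 0
  zeroed <- mod
  zl <- modelCoefficients(mod)
  zl[grep("prec", names(zl))] <- 0
  zeroed@lambda <- zl
  impz <- permutationImportance(zeroed, fx$pres, fx$bg, seed = 3)
  expect_equal(impz[["prec"]], 0)
})

test_that("percent contribution normalises the gain ledger", {
  fx <- modelFixture(seed = 8)
  mod <- fitFromValues(fx$pres, fx$land, "LQ", 1, K = 6, max_iter = 300)
  pc <- percentContribution(mod)
  expect_equal(sum(pc), 100, tolerance = 0.1)
  expect_named(pc, colnames(fx$land))
})
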