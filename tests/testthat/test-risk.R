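test_that("suitability constraint zeroes extrapolated and unsuitable cells", {
  P <- matrix(c(0.8, 0.2, 0.5, 0.9), 2)
  mask_all <- matrix(TRUE, 2, 2)
  expect_equal(constrainSuitability(P, mask_all, 0.3129),
               matrix(0, 2, 2))
  mask_none <- matrix(FALSE, 2, 2)
  cp <- constrainSuitability(P, mask_none, 0.3129)
  expect_equal(cp[1, 1], 0.8)       # suitable, inside range: unchanged
  expect_equal(cp[2, 1], 0)         # P = 0.2 < tau: no risk contribution
})

test_that("risk values multiply pixel-wise with absorbing zeros", {
  cp <- matrix(c(0.5, 0, 0.8, NA), 2)
  d <- matrix(c(10, 7, 0, 3), 2)
  rv <- riskValues(cp, d)
  expect_equal(rv[1, 1], 5)
  expect_equal(rv[2, 1], 0)         # zero suitability
  expect_equal(rv[1, 2], 0)         # zero density
  expect_true(is.na(rv[2, 2]))
  expect_error(riskValues(cp, -d), "negative")
})

test_that("masking order commutes with multiplication", {
  set.seed(5)
  P <- matrix(runif(100), 10)
  d <- matrix(rexp(100), 10)
  mask <- matrix(runif(100) > 0.7, 10)
  tau <- 0.4
  a <- riskValues(constrainSuitability(P, mask, tau), d)
  b <- P * d
  b[mask | P < tau] <- 0
  expect_equal(a, b)
})

test_that("Jenks partition matches hand case and the exhaustive oracle", {
  jb <- jenksBreaks(c(1, 2, 3, 10, 11, 20), 3)
  expect_equal(jb$breaks, c(10, 20))    # classes {1,2,3} {10,11} {20}
  expect_equal(jb$sdcm, 2 + 0.5)
  # k = n distinct values -> singletons, SDCM 0
  expect_equal(jenksBreaks(c(4, 8, 15), 3)$sdcm, 0)
  # fewer distinct values than classes
  expect_warning(deg <- jenksBreaks(c(7, 7, 7), 3), "distinct")
  expect_equal(deg$k_effective, 1)
  # oracle equivalence on random values
  for (seed in 1:4) {
    set.seed(seed)
    v <- round(runif(sample(8:14, 1), 0, 100), 1)
    for (k in 2:4) {
      got <- jenksBreaks(v, k)
      want <- bruteJenks(v, k)
      expect_equal(got$sdcm, want$sdcm, tolerance = 1e-9)
      expect_equal(got$breaks, want$breaks)
    }
  }
})

test_that("SDCM never increases with more classes", {
  set.seed(9)
  v <- runif(60, 0, 50)
  sdcm <- vapply(2:6, function(k) jenksBreaks(v, k)$sdcm, numeric(1))
  expect_true(all(diff(sdcm) <= 1e-9))
})

test_that("risk classes partition the grid and respect the breaks", {
  tr <- c(0, 5, 0.5, 0.5)
  risk <- matrix(c(0, 1, 100, NA, 50, 2), 2, 3)
  cl <- classifyRisk(risk, breaks = c(10, 60), tr)
  expect_equal(cl$classes[1, 1], 0L)
  expect_equal(cl$classes[2, 1], 1L)
  expect_equal(cl$classes[1, 2], 3L)
  expect_equal(cl$classes[1, 3], 2L)     # 50 in [10, 60)
  expect_true(is.na(cl$classes[2, 2]))
  expect_equal(sum(cl$areas_km2), validArea(risk, tr))
  expect_equal(cl$total_risk_km2, sum(cl$areas_km2[-1]))

  # 3x1 toy from k = 2 Jenks on {1, 100}
  toy <- matrix(c(0, 1, 100), 1)
  jb <- jenksBreaks(c(1, 100), 2)
  cl2 <- classifyRisk(toy, jb$breaks, tr)
  expect_equal(as.vector(cl2$classes), c(0L, 1L, 2L))
})

test_that("increasing density never lowers a cell's class at fixed breaks", {
  tr <- c(0, 5, 0.5, 0.5)
  set.seed(7)
  cp <- matrix(runif(64, 0.4, 1), 8)
  d1 <- matrix(rexp(64), 8)
  d2 <- d1 * runif(64, 1, 3)
  br <- jenksBreaks(as.numeric(cp * d1), 3)$breaks
  c1 <- classifyRisk(riskValues(cp, d1), br, tr)$classes
  c2 <- classifyRisk(riskValues(cp, d2), br, tr)$classes
  expect_true(all(c2 >= c1))
})

test_that("species with disjoint density masks have disjoint risk areas", {
  tr <- c(0, 5, 0.5, 0.5)
  P <- matrix(0.9, 4, 4)
  mask <- matrix(FALSE, 4, 4)
  dA <- matrix(0, 4, 4); dA[, 1:2] <- 1:8
  dB <- matrix(0, 4, 4); dB[, 3:4] <- 2 * (1:8)
  rA <- riskMap(P, mask, 0.3, dA, tr)
  rB <- riskMap(P, mask, 0.3, dB, tr)
  expect_true(all(!(rA$classes > 0 & rB$classes > 0)))
  expect_gt(rA$total_risk_km2, 0)
})

test_that("deterministic subsampling keeps large-input breaks stable", {
  set.seed(11)
  v <- rlnorm(60000)
  b1 <- jenksBreaks(v, 3, max_values = 5000)
  b2 <- jenksBreaks(v, 3, max_values = 5000)
  expect_identical(b1, b2)
  expect_length(b1$breaks, 2)
  expect_true(all(diff(b1$breaks) > 0))
})
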