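test_that("four-tier classification respects the half-open boundaries", {
  br <- presetBreaks()
  P <- matrix(c(0, 0.2, 0.312941, 0.523362, 0.6, 0.684789, 0.70, NA), 2, 4)
  cls <- classifySuitability(P, br)
  expect_equal(as.vector(cls)[1:7], c(0L, 0L, 1L, 2L, 2L, 3L, 3L))
  expect_true(is.na(cls[2, 4]))
  # monotone: raising P never lowers the class
  set.seed(1)
  P1 <- matrix(runif(100), 10)
  P2 <- pmin(P1 + runif(100, 0, 0.3), 1)
  expect_true(all(classifySuitability(P2, br) >= classifySuitability(P1, br)))
  expect_error(classifySuitability(P1, c(0.5, 0.4, 0.9)))
})

test_that("area tables conserve total area and report rounded change", {
  tr <- c(100, 50, 0.5, 0.5)
  set.seed(2)
  cur <- matrix(sample(0:3, 400, replace = TRUE), 20)
  fut <- matrix(sample(0:3, 400, replace = TRUE), 20)
  at <- areaTable(list(current = cur, future = fut), tr)
  expect_true(all(is.na(unlist(at[1, grep("change", names(at))]))))
  # conservation: classes 0..3 sum to the valid area, each period
  for (cr in list(cur, fut)) {
    tot <- sum(vapply(0:3, function(k) classArea(cr, tr, k), numeric(1)))
    expect_equal(tot, validArea(cr, tr))
  }
  # identical periods -> 0.00% everywhere
  at0 <- areaTable(list(current = cur, same = cur), tr)
  expect_equal(unname(unlist(at0[2, grep("change", names(at0))])), rep(0, 4))
})

test_that("percent change reproduces the worked bookkeeping", {
  expect_equal(percentChange(333.49, 236.17), 41.21)
  expect_equal(percentChange(100, 100), 0)
  expect_true(is.na(percentChange(5, 0)))
})

test_that("change maps code the four transitions and satisfy the algebra", {
  cur <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  fut <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  cm <- changeMap(cur, fut)
  expect_equal(as.vector(cm), c(1L, 3L, 2L, 0L))
  # identical rasters: only codes 0 and 1
  expect_true(all(changeMap(cur, cur) %in% c(0L, 1L)))
  # total loss: all suitable cells code 3
  allc <- matrix(TRUE, 3, 3); none <- matrix(FALSE, 3, 3)
  expect_true(all(changeMap(allc, none) == 3L))

  # 4x4 checkerboard vs shifted: counts match manual enumeration
  chk <- matrix(rep(c(TRUE, FALSE), 8), 4)
  shf <- matrix(rep(c(FALSE, TRUE), 8), 4)
  cm2 <- changeMap(chk, shf)
  expect_equal(as.vector(table(cm2)), c(8, 8))  # 8 expansions, 8 contractions
  expect_equal(sort(unique(as.vector(cm2))), c(2L, 3L))

  # algebra: stable + expansion = future suitable area
  tr <- c(0, 10, 0.5, 0.5)
  set.seed(3)
  c1 <- matrix(runif(64) > 0.5, 8); c2 <- matrix(runif(64) > 0.5, 8)
  cm3 <- changeMap(c1, c2)
  a <- function(k) classArea(cm3, tr, k)
  expect_equal(a(1) + a(2), validArea(ifelse(c2, 1, NA), tr))
  expect_equal(a(1) + a(3), validArea(ifelse(c1, 1, NA), tr))
})

test_that("centroids are area-weighted means of suitable cell centers", {
  tr <- c(0, 1, 1, 1)
  single <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  ct <- habitatCentroid(single, tr)
  expect_equal(ct$lon, 0.5); expect_equal(ct$lat, 0.5)
  # symmetric block centers on the block
  block <- matrix(TRUE, 2, 2)
  ctb <- habitatCentroid(block, tr)
  expect_equal(ctb$lon, 1)
  expect_lt(abs(ctb$lat - 0), 1e-2)   # area weighting is symmetric about 0
  expect_error(habitatCentroid(matrix(FALSE, 2, 2), tr), "no suitable")

  # two 1-degree cells centred at 0 and 60 degrees latitude
  tr2 <- c(0, 60.5, 1, 1)
  two <- matrix(FALSE, 61, 1)
  two[c(1, 61), 1] <- TRUE            # centers at 60 and 0
  ct2 <- habitatCentroid(two, tr2)
  a60 <- pixelAreaKm2(tr2, 1); a0 <- pixelAreaKm2(tr2, 61)
  expect_equal(ct2$lat, (a60 * 60 + a0 * 0) / (a60 + a0))
  expect_lt(ct2$lat, 30)
})

test_that("centroid of a union lies between the part centroids", {
  tr <- c(0, 20, 0.5, 0.5)
  a <- matrix(FALSE, 10, 10); a[2:3, 2:3] <- TRUE
  b <- matrix(FALSE, 10, 10); b[8:9, 7:9] <- TRUE
  ca <- habitatCentroid(a, tr); cb <- habitatCentroid(b, tr)
  cu <- habitatCentroid(a | b, tr)
  lam <- (cu$lon - ca$lon) / (cb$lon - ca$lon)
  expect_gte(lam, 0); expect_lte(lam, 1)
  expect_equal(cu$lat, ca$lat + lam * (cb$lat - ca$lat), tolerance = 1e-9)
})

test_that("migration steps report haversine distance and compass bearing", {
  cents <- data.frame(period = c("a", "b", "c", "d", "e"),
                      lon = c(10, 10, 10, 11, 9),
                      lat = c(0, 1, 1, 1, 1))
  mig <- centroidMigration(cents)
  expect_equal(mig$distance_km[1], 111.19, tolerance = 0.1 / 111.19)
  expect_equal(mig$bearing_deg[1], 0)
  expect_equal(mig$distance_km[2], 0)           # identical consecutive centroids
  # east vs west symmetric steps
  expect_equal(mig$distance_km[3], mig$distance_km[4] / 2, tolerance = 1e-6)
  expect_equal(mig$bearing_deg[3], 90, tolerance = 0.02)
  expect_equal(mig$bearing_deg[4], 270, tolerance = 0.02)
})

test_that("break generators produce valid ascending tiers", {
  set.seed(4)
  P <- matrix(runif(400), 20)
  for (m in c("equal", "quantile")) {
    br <- makeBreaks(P, 0.3, m)
    expect_length(br, 3)
    expect_true(all(diff(br) > 0))
    expect_equal(br[1], 0.3)
  }
  pb <- presetBreaks()
  expect_equal(pb, c(0.312941, 0.523362, 0.684789))
})
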