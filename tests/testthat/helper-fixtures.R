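# Shared in-code fixtures: small synthetic landscapes and score sets.

# a 3-variable 30x30 landscape with two smooth fields and one gradient
smallLandscape <- function(seed = 3L, nodata_fraction = 0) {
  landscapeSpec(30, 30, variables = list(
    temp = list(recipe = "smoothed-noise", width = 7),
    prec = list(recipe = "smoothed-noise", width = 5),
    elev = list(recipe = "gradient", axis = "y")),
    cell_size = 0.1, nodata_fraction = nodata_fraction, seed = seed)
}

# presence/background value matrices plus fitted-model inputs
modelFixture <- function(seed = 3L, n_pres = 100L, B = 400L,
                         coefficients = c(temp = 3, elev = -2)) {
  stk <- generateStack(smallLandscape(seed))
  occ <- samplePresences(stk, coefficients, n_pres, seed = seed + 10L)
  bg <- sampleBackground(stk, B, seed = seed + 20L)
  pv <- extractCells(stk, as.matrix(occ[, c("row", "col")]))
  bv <- extractCells(stk, as.matrix(bg[, c("row", "col")]))
  list(stack = stk, occ = occ, pres = pv, bg = bv, land = rbind(pv, bv))
}

# degrees of latitude equal to d km along a meridian (spherical earth)
kmToLatDeg <- function(km) km / (pi / 180 * 6371.0088)

# brute-force maximum subset satisfying the pairwise distance floor
bruteMaxThin <- function(occ, thin_km) {
  n <- nrow(occ)
  best <- integer()
  for (m in 0:(2^n - 1)) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) > 0L)
    if (length(idx) <= length(best)) next
    ok <- TRUE
    if (length(idx) >= 2) {
      pr <- combn(idx, 2)
      d <- haversineKm(occ$lon[pr[1, ]], occ$lat[pr[1, ]],
                       occ$lon[pr[2, ]], occ$lat[pr[2, ]])
      ok <- all(d >= thin_km)
    }
    if (ok) best <- idx
  }
  best
}

# O(n^2) all-pairs AUC oracle with half-credit ties
bruteAuc <- function(p, b) {
  s <- 0
  for (x in p) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(p) * length(b))
}

# brute-force non-dominated sort oracle
bruteRanks <- function(Fm) {
  n <- nrow(Fm)
  dom <- function(a, b) all(Fm[a, ] <= Fm[b, ]) && any(Fm[a, ] < Fm[b, ])
  rank <- rep(NA_integer_, n)
  r <- 1L
  left <- seq_len(n)
  while (length(left)) {
    nd <- left[vapply(left, function(i)
      !any(vapply(left, function(j) j != i && dom(j, i), logical(1))),
      logical(1))]
    rank[nd] <- r
    left <- setdiff(left, nd)
    r <- r + 1L
  }
  rank
}

# exhaustive contiguous-partition Jenks oracle (small n)
bruteJenks <- function(v, k) {
  v <- sort(v)
  n <- length(v)
  ssd <- function(x) sum((x - mean(x))^2)
  best <- Inf; best_breaks <- NULL
  splits <- combn(n - 1, k - 1)
  for (j in seq_len(ncol(splits))) {
    cut <- c(0, splits[, j], n)
    # skip partitions that split runs of equal values
    starts <- splits[, j] + 1
    if (any(v[starts] == v[starts - 1])) next
    s <- sum(vapply(seq_len(k), function(c)
      ssd(v[(cut[c] + 1):cut[c + 1]]), numeric(1)))
    if (s < best - 1e-12) { best <- s; best_breaks <- v[starts] }
  }
  list(breaks = best_breaks, sdcm = best)
}
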