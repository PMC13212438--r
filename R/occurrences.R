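## Occurrence handling: spatial thinning to a minimum great-circle
## separation, uniform background sampling over valid cells, and the
## replicated 75/25 train/test subsampling protocol.

#' Haversine distance in km
#'
#' Great-circle distance on a sphere of radius 6371.0088 km.
#'
#' @param lon1,lat1,lon2,lat2 degrees (vectorised).
#' @return distance(s) in km.
#' @export
haversineKm <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

pairwiseKm <- function(lon, lat) {
  n <- length(lon)
  d <- matrix(0, n, n)
  if (n >= 2L) {
    idx <- combn(n, 2L)
    dv <- haversineKm(lon[idx[1L, ]], lat[idx[1L, ]], lon[idx[2L, ]], lat[idx[2L, ]])
    d[t(idx)] <- dv
    d[t(idx)[, 2:1, drop = FALSE]] <- dv
  }
  d
}

#' Spatially thin occurrence records
#'
#' Randomised greedy maximum-retention thinning: while any pair of retained
#' points is closer than \code{thin_km}, delete a point with the most
#' conflicts (random tie-break); the best of \code{n_restarts} passes
#' (largest surviving set) is returned. The output always satisfies the
#' pairwise distance floor and is a subset of the input in input order.
#'
#' @param occ data.frame with \code{lon}, \code{lat} (extra columns kept).
#' @param thin_km minimum pairwise great-circle distance, km.
#' @param seed integer RNG seed.
#' @param n_restarts number of randomised passes (default 10).
#' @return the thinned data.frame.
#' @export
thinOccurrences <- function(occ, thin_km = 1, seed = 1L, n_restarts = 10L) {
  stopifnot(thin_km > 0)
  n <- nrow(occ)
  if (n <= 1L) return(occ)
  conflict <- pairwiseKm(occ$lon, occ$lat) < thin_km
  diag(conflict) <- FALSE
  best <- NULL
  withr_seed(seed, {
    for (r in seq_len(n_restarts)) {
      keep <- rep(TRUE, n)
      repeat {
        cnt <- rep(0L, n)
        cnt[keep] <- rowSums(conflict[keep, keep, drop = FALSE])
        if (!any(cnt > 0L)) break
        cand <- which(keep & cnt == max(cnt))
        drop <- if (length(cand) == 1L) cand else sample(cand, 1L)
        keep[drop] <- FALSE
      }
      if (is.null(best) || sum(keep) > sum(best)) best <- keep
    }
  })
  occ[best, , drop = FALSE]
}

#' Sample background cells uniformly
#'
#' Uniform sample without replacement over eligible valid cells. If
#' \code{B} exceeds the eligible count, all eligible cells are returned
#' with a warning.
#'
#' @param stack an EnvStack.
#' @param B background size (default 10000).
#' @param seed integer.
#' @param exclude_presence_cells optional integer matrix (row, col) of
#'   presence cells to exclude; default NULL (background may include them).
#' @return data.frame: row, col, lon, lat.
#' @export
sampleBackground <- function(stack, B = 10000L, seed = 1L,
                             exclude_presence_cells = NULL) {
  stopifnot(B >= 1L)
  cells <- validCells(stack)
  if (!is.null(exclude_presence_cells)) {
    key <- paste(cells[, 1L], cells[, 2L])
    bad <- paste(exclude_presence_cells[, 1L], exclude_presence_cells[, 2L])
    cells <- cells[!key %in% bad, , drop = FALSE]
  }
  if (nrow(cells) == 0L) stop("no eligible background cells")
  if (B > nrow(cells)) {
    warning("requested ", B, " background cells; only ", nrow(cells),
            " eligible cells exist - returning all of them")
    pick <- seq_len(nrow(cells))
  } else {
    pick <- withr_seed(seed, sample.int(nrow(cells), B))
  }
  ctr <- cellCenter(gridTransform(stack), cells[pick, 1L], cells[pick, 2L])
  data.frame(row = cells[pick, 1L], col = cells[pick, 2L],
             lon = ctr$lon, lat = ctr$lat)
}

#' Replicated train/test split plans
#'
#' R independent random partitions; each plan holds
#' \code{round(train_fraction * n)} training indices, the rest test.
#' Replicate r is reproducible from (seed, r) alone.
#'
#' @param n number of records (>= 4).
#' @param R number of replicates (default 10).
#' @param train_fraction default 0.75.
#' @param seed master seed.
#' @return list of plans: \code{replicate}, \code{train}, \code{test}.
#' @export
makeSplits <- function(n, R = 10L, train_fraction = 0.75, seed = 1L) {
  stopifnot(n >= 4L, train_fraction > 0, train_fraction < 1)
  n_train <- round(train_fraction * n)
  lapply(seq_len(R), function(r) {
    tr <- withr_seed(seed * 1000L + r, sort(sample.int(n, n_train)))
    list(replicate = r, train = tr, test = setdiff(seq_len(n), tr))
  })
}
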