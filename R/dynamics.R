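## Habitat classification, per-class area bookkeeping, range-change
## overlays and centroid migration between periods.

#' Four-tier suitability classification
#'
#' Half-open intervals, boundary belonging upward:
#' 0 = unsuitable (P < tau_mtss), 1 = marginal [tau_mtss, tau_mid),
#' 2 = moderate [tau_mid, tau_high), 3 = high [tau_high, 1].
#'
#' @param P suitability matrix in [0, 1] (NA = nodata).
#' @param breaks numeric(3): ascending \code{tau_mtss < tau_mid < tau_high}.
#' @return integer-coded matrix.
#' @export
classifySuitability <- function(P, breaks) {
  stopifnot(length(breaks) == 3L, all(diff(breaks) > 0),
            breaks[1L] > 0, breaks[3L] < 1)
  cls <- matrix(0L, nrow(P), ncol(P))
  cls[P >= breaks[1L]] <- 1L
  cls[P >= breaks[2L]] <- 2L
  cls[P >= breaks[3L]] <- 3L
  cls[is.na(P)] <- NA_integer_
  cls
}

#' The published four-tier break preset
#'
#' Suitability cut points 0.312941 / 0.523362 / 0.684789 for the
#' marginal / moderate / high tiers.
#' @return numeric(3).
#' @export
presetBreaks <- function() c(0.312941, 0.523362, 0.684789)

#' Generate class breaks above the MTSS threshold
#'
#' @param P suitability matrix.
#' @param tau_mtss binary suitable/unsuitable threshold.
#' @param method \code{"equal"} (equal-interval between tau_mtss and the
#'   maximum suitable value) or \code{"quantile"} (terciles of suitable
#'   cells).
#' @return numeric(3) ascending breaks starting at tau_mtss.
#' @export
makeBreaks <- function(P, tau_mtss, method = c("equal", "quantile")) {
  method <- match.arg(method)
  suit <- P[!is.na(P) & P >= tau_mtss]
  if (!length(suit)) stop("no suitable cells above the threshold")
  top <- max(suit)
  if (method == "equal") {
    step <- (top - tau_mtss) / 3
    c(tau_mtss, tau_mtss + step, tau_mtss + 2 * step)
  } else {
    q <- quantile(suit, c(1 / 3, 2 / 3), names = FALSE)
    c(tau_mtss, q[1L], q[2L])
  }
}

#' Per-class area table with change versus a baseline
#'
#' Areas are reported in units of 1e4 km² at two decimals, with percent
#' change of each class (and the total of classes 1-3) against the
#' baseline period, rounded to two decimals.
#'
#' @param class_rasters named list of integer class matrices; the first
#'   is the baseline ("current") period.
#' @param transform grid transform.
#' @return data.frame: period, class areas, total, and change columns
#'   (NA for the baseline row and whenever a baseline area is zero).
#' @export
areaTable <- function(class_rasters, transform) {
  per <- lapply(class_rasters, function(cr)
    vapply(1:3, function(k) classArea(cr, transform, k), numeric(1L)) / 1e4)
  base <- per[[1L]]
  base_tot <- sum(base)
  rows <- lapply(seq_along(per), function(i) {
    a <- per[[i]]; tot <- sum(a)
    chg <- function(now, ref) if (i == 1L || ref == 0) NA_real_
                              else round(100 * (now - ref) / ref, 2)
    data.frame(period = names(class_rasters)[i],
               high = round(a[3L], 2), high_change = chg(a[3L], base[3L]),
               moderate = round(a[2L], 2), moderate_change = chg(a[2L], base[2L]),
               marginal = round(a[1L], 2), marginal_change = chg(a[1L], base[1L]),
               total = round(tot, 2), total_change = chg(tot, base_tot))
  })
  do.call(rbind, rows)
}

#' Percent change between two printed area totals
#'
#' The Table-2-style bookkeeping: \code{100 (future - current) / current},
#' rounded to two decimals; NA when the baseline is zero.
#'
#' @param future,current areas in the same unit.
#' @return rounded percent change.
#' @export
percentChange <- function(future, current) {
  if (current == 0) return(NA_real_)
  round(100 * (future - current) / current, 2)
}

#' Range-change overlay between two periods
#'
#' @param current_suitable,future_suitable logical matrices (class > 0).
#' @return integer matrix: 0 never suitable, 1 stable, 2 expansion,
#'   3 contraction; NA propagated.
#' @export
changeMap <- function(current_suitable, future_suitable) {
  stopifnot(identical(dim(current_suitable), dim(future_suitable)))
  out <- matrix(0L, nrow(current_suitable), ncol(current_suitable))
  out[current_suitable & future_suitable] <- 1L
  out[!current_suitable & future_suitable] <- 2L
  out[current_suitable & !future_suitable] <- 3L
  out[is.na(current_suitable) | is.na(future_suitable)] <- NA_integer_
  out
}

#' Area-weighted centroid of suitable habitat
#'
#' lon = sum(a_i lon_i) / sum(a_i) over suitable cell centers, with a_i
#' the latitude-dependent pixel area (lat likewise).
#'
#' @param suitable logical matrix.
#' @param transform grid transform.
#' @return list with \code{lon}, \code{lat}.
#' @export
habitatCentroid <- function(suitable, transform) {
  idx <- which(!is.na(suitable) & suitable, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no suitable cells")
  ctr <- cellCenter(transform, idx[, 1L], idx[, 2L])
  a <- pixelAreaKm2(transform, idx[, 1L])
  list(lon = sum(a * ctr$lon) / sum(a), lat = sum(a * ctr$lat) / sum(a))
}

#' Centroid migration between consecutive periods
#'
#' Haversine distance (R = 6371.0088 km) and initial bearing (degrees
#' clockwise from north, in [0, 360)) between consecutive centroids.
#'
#' @param centroids data.frame with \code{period}, \code{lon}, \code{lat}
#'   ordered by period.
#' @return data.frame: from, to, distance_km, bearing_deg.
#' @export
centroidMigration <- function(centroids) {
  stopifnot(nrow(centroids) >= 2L)
  n <- nrow(centroids)
  i <- seq_len(n - 1L)
  d <- haversineKm(centroids$lon[i], centroids$lat[i],
                   centroids$lon[i + 1L], centroids$lat[i + 1L])
  b <- geosphere::bearing(cbind(centroids$lon[i], centroids$lat[i]),
                          cbind(centroids$lon[i + 1L], centroids$lat[i + 1L]))
  b <- ifelse(is.na(b), 0, (b + 360) %% 360)   # identical points: define 0
  data.frame(from = centroids$period[i], to = centroids$period[i + 1L],
             distance_km = d, bearing_deg = b)
}
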