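## Livestock exposure risk: MESS- and MTSS-constrained suitability
## multiplied by density, risk-free delineation (zero suitability or
## zero density), and per-species Jenks natural-breaks 3-class maps.

#' Constrain suitability for risk mapping
#'
#' Suitability is set to zero on extrapolated cells (MESS <= 0) and on
#' unsuitable cells (P < tau_mtss); unchanged elsewhere. This is the
#' operational meaning of "zero suitability" for the risk-free rule.
#'
#' @param P suitability matrix.
#' @param mess_mask logical matrix, TRUE where MESS <= 0 (NA kept).
#' @param tau_mtss suitable/unsuitable threshold.
#' @return constrained suitability matrix.
#' @export
constrainSuitability <- function(P, mess_mask, tau_mtss) {
  stopifnot(identical(dim(P), dim(mess_mask)))
  out <- P
  out[!is.na(mess_mask) & mess_mask] <- 0
  out[!is.na(out) & out < tau_mtss] <- 0
  out[is.na(P) | is.na(mess_mask)] <- NA_real_
  out
}

#' Pixel-wise risk values
#'
#' @param constrained constrained suitability matrix.
#' @param density nonnegative density matrix on the same grid.
#' @return elementwise product; NA where either input is NA.
#' @export
riskValues <- function(constrained, density) {
  stopifnot(identical(dim(constrained), dim(density)))
  if (any(density < 0, na.rm = TRUE)) stop("negative density values")
  constrained * density
}

#' Jenks natural breaks (Fisher exact partition)
#'
#' Dynamic programme over contiguous partitions of the sorted values
#' minimising the sum of within-class squared deviations (SDCM); ties
#' resolve to the lowest break values. Values are deterministically
#' subsampled (every j-th sorted value) above \code{max_values}.
#'
#' @param values numeric vector (positive risk values).
#' @param k number of classes (default 3).
#' @param max_values deterministic subsampling cap (default 20000).
#' @return list: \code{breaks} (k - 1 ascending cut values, each the
#'   minimum of the class above it), \code{sdcm}, \code{k_effective}.
#' @export
jenksBreaks <- function(values, k = 3L, max_values = 20000L) {
  v <- sort(values)
  nd <- length(unique(v))
  if (nd < k) {
    warning("fewer distinct values (", nd, ") than classes (", k,
            "); each distinct value forms its own class")
    u <- sort(unique(v))
    return(list(breaks = u[-1L], sdcm = 0, k_effective = nd))
  }
  if (length(v) > max_values) {
    idx <- unique(round(seq(1, length(v), length.out = max_values)))
    v <- v[idx]
  }
  res <- jenks_dp(v, as.integer(k))   # starts of classes 2..k (1-based)
  starts <- res$starts
  list(breaks = v[starts], sdcm = res$sdcm, k_effective = k)
}

#' Classify risk values with Jenks breaks
#'
#' Class 0 wherever the risk value is exactly zero (risk-free); positive
#' values fall into classes 1..k by half-open intervals on the breaks,
#' boundaries belonging upward.
#'
#' @param risk matrix of risk values.
#' @param breaks ascending break values from \code{\link{jenksBreaks}}.
#' @param transform grid transform (for the area summary).
#' @return list: \code{classes} (integer matrix), \code{areas_km2}
#'   (named, classes 0..k), \code{total_risk_km2}.
#' @export
classifyRisk <- function(risk, breaks, transform) {
  cls <- matrix(0L, nrow(risk), ncol(risk))
  pos <- !is.na(risk) & risk > 0
  cls[pos] <- 1L
  for (b in seq_along(breaks))
    cls[pos & risk >= breaks[b]] <- b + 1L
  cls[is.na(risk)] <- NA_integer_
  ids <- 0:(length(breaks) + 1L)
  areas <- vapply(ids, function(k) classArea(cls, transform, k), numeric(1L))
  names(areas) <- paste0("class", ids)
  list(classes = cls, areas_km2 = areas,
       total_risk_km2 = sum(areas[-1L]))
}

#' Full per-species risk map
#'
#' Constrains suitability, multiplies by density, fits Jenks breaks on
#' the positive risk values of this species, and classifies.
#'
#' @param P suitability matrix.
#' @param mess_mask extrapolation mask.
#' @param tau_mtss suitability threshold.
#' @param density species density matrix.
#' @param transform grid transform.
#' @param k number of risk classes (default 3).
#' @return list: \code{risk}, \code{classes}, \code{breaks},
#'   \code{areas_km2}, \code{total_risk_km2}.
#' @export
riskMap <- function(P, mess_mask, tau_mtss, density, transform, k = 3L) {
  cp <- constrainSuitability(P, mess_mask, tau_mtss)
  rv <- riskValues(cp, density)
  pos <- rv[!is.na(rv) & rv > 0]
  if (!length(pos)) {
    cl <- classifyRisk(rv, numeric(), transform)
    return(c(list(risk = rv, breaks = numeric()), cl[-1L],
             list(classes = cl$classes)))
  }
  jb <- jenksBreaks(pos, k = k)
  cl <- classifyRisk(rv, jb$breaks, transform)
  list(risk = rv, classes = cl$classes, breaks = jb$breaks,
       areas_km2 = cl$areas_km2, total_risk_km2 = cl$total_risk_km2)
}
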