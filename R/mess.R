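## Multivariate Environmental Similarity Surface: per-variable similarity
## from the empirical position of a target value within the reference
## sample, minimised over variables. S <= 0 flags novel (extrapolated)
## environments.

messSimilarity <- function(ref, p) {
  mn <- min(ref); mx <- max(ref)
  n <- length(ref)
  if (mx == mn) {
    out <- ifelse(p == mn, 0, -Inf)
    return(out)
  }
  f <- 100 * vapply(p, function(x) sum(ref < x), numeric(1L)) / n
  ifelse(f == 0, 100 * (p - mn) / (mx - mn),
  ifelse(f <= 50, 2 * f,
  ifelse(f < 100, 2 * (100 - f),
         100 * (mx - p) / (mx - mn))))
}

#' MESS surface against a reference sample
#'
#' For each variable with reference minimum/maximum and f = percentage of
#' reference values strictly below the target value p:
#' \itemize{
#'   \item f = 0: \code{100 (p - min) / (max - min)} (negative below min)
#'   \item 0 < f <= 50: \code{2 f}
#'   \item 50 < f < 100: \code{2 (100 - f)}
#'   \item f = 100: \code{100 (max - p) / (max - min)}
#' }
#' The cell value S is the minimum over variables; the most dissimilar
#' variable is the argmin (ties to the first variable in stack order).
#'
#' @param reference matrix of reference values (rows = samples, columns =
#'   variables), typically training presence + background cells.
#' @param target an \linkS4class{EnvStack} containing every reference
#'   variable.
#' @return list with \code{S} (matrix), \code{mdv} (matrix of variable
#'   indices), \code{variables}.
#' @export
messSurface <- function(reference, target) {
  vars <- colnames(reference)
  miss <- setdiff(vars, layerNames(target))
  if (length(miss)) stop("target lacks variable(s): ", paste(miss, collapse = ", "))
  if (nrow(reference) < 1L) stop("empty reference sample")
  const <- vars[apply(reference, 2L, function(x) max(x) == min(x))]
  if (length(const))
    warning("constant reference variable(s): ", paste(const, collapse = ", "),
            "; similarity is 0 at the constant and -Inf elsewhere")
  d <- gridDim(target)
  S <- matrix(Inf, d[1L], d[2L])
  mdv <- matrix(NA_integer_, d[1L], d[2L])
  msk <- nodataMask(target)
  for (k in seq_along(vars)) {
    sv <- messSimilarity(reference[, vars[k]], as.numeric(getLayer(target, vars[k])))
    sv <- matrix(sv, d[1L], d[2L])
    better <- !msk & (sv < S)
    mdv[better] <- k
    S[better] <- sv[better]
  }
  S[msk] <- NA_real_
  mdv[msk] <- NA_integer_
  list(S = S, mdv = mdv, variables = vars)
}

#' Extrapolation mask from a MESS result
#'
#' @param mess result of \code{\link{messSurface}}.
#' @return logical matrix, TRUE where S <= 0 (extrapolation); NA cells
#'   stay NA.
#' @export
extrapolationMask <- function(mess) {
  mess$S <= 0
}
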