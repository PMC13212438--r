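## Feature-class machinery: min-max scaled linear, quadratic, product and
## (forward/reverse) hinge transforms, plus the default per-feature L1
## penalty table scaled by the regularisation multiplier.

FC_LEVELS <- c("L", "LQ", "H", "LQH", "LQHP")

## Default-regularisation lookup (reference MaxEnt conventions), linearly
## interpolated in the number of training presences m; the base reaches
## 0.05 for linear/quadratic/product at m >= 100 and is 0.5 for hinge
## features at every m.
BASE_REG <- list(
  linear    = list(m = c(0, 10, 30, 100),     beta = c(1.0, 1.0, 0.2, 0.05)),
  quadratic = list(m = c(0, 10, 30, 100),     beta = c(1.0, 1.0, 0.2, 0.05)),
  product   = list(m = c(0, 10, 17, 30, 100), beta = c(2.6, 1.6, 0.9, 0.55, 0.05)),
  forward_hinge = list(m = c(0, 100), beta = c(0.5, 0.5)),
  reverse_hinge = list(m = c(0, 100), beta = c(0.5, 0.5))
)

baseRegularisation <- function(type, m) {
  tbl <- BASE_REG[[type]]
  if (is.null(tbl)) stop("unknown feature type: ", type)
  if (m >= max(tbl$m)) return(tbl$beta[length(tbl$beta)])
  stats::approx(tbl$m, tbl$beta, xout = m, rule = 2)$y
}

fcHas <- function(fc, what) {
  switch(what,
    L = fc %in% c("L", "LQ", "LQH", "LQHP"),
    Q = fc %in% c("LQ", "LQH", "LQHP"),
    H = fc %in% c("H", "LQH", "LQHP"),
    P = fc %in% "LQHP")
}

#' Build a feature specification from landscape bounds
#'
#' Scaling bounds are taken over the full valid landscape (the background
#' universe), so features are defined wherever predictions are made.
#' Hinge knots are K evenly spaced points strictly inside (0, 1) on the
#' scaled range: t_k = k / (K + 1).
#'
#' @param bounds 2-row matrix (\code{min}, \code{max}) with one column per
#'   variable, or a matrix of landscape values from which bounds are taken.
#' @param fc feature-class combination: one of L, LQ, H, LQH, LQHP.
#' @param K hinge knots per variable per direction (default 50).
#' @return a \code{featureSpec} list: \code{fc}, \code{bounds},
#'   \code{K}, and a \code{features} data.frame (type, var1, var2, knot,
#'   name).
#' @export
featureSpec <- function(bounds, fc = "LQ", K = 50L) {
  fc <- match.arg(fc, FC_LEVELS)
  if (!is.matrix(bounds) || nrow(bounds) != 2L)
    bounds <- apply(bounds, 2L, range)
  rownames(bounds) <- c("min", "max")
  vars <- colnames(bounds)
  bad <- vars[bounds["max", ] - bounds["min", ] <= 0 |
              !is.finite(bounds["min", ]) | !is.finite(bounds["max", ])]
  if (length(bad)) stop("constant or non-finite variable(s): ",
                        paste(bad, collapse = ", "))
  feats <- data.frame(type = character(), var1 = character(),
                      var2 = character(), knot = numeric())
  if (fcHas(fc, "L"))
    feats <- rbind(feats, data.frame(type = "linear", var1 = vars,
                                     var2 = NA, knot = NA))
  if (fcHas(fc, "Q"))
    feats <- rbind(feats, data.frame(type = "quadratic", var1 = vars,
                                     var2 = NA, knot = NA))
  if (fcHas(fc, "P") && length(vars) >= 2L) {
    pr <- combn(vars, 2L)
    feats <- rbind(feats, data.frame(type = "product", var1 = pr[1L, ],
                                     var2 = pr[2L, ], knot = NA))
  }
  if (fcHas(fc, "H")) {
    knots <- seq_len(K) / (K + 1)
    for (v in vars) {
      feats <- rbind(feats,
        data.frame(type = "forward_hinge", var1 = v, var2 = NA, knot = knots),
        data.frame(type = "reverse_hinge", var1 = v, var2 = NA, knot = knots))
    }
  }
  feats$name <- ifelse(feats$type == "product",
                       paste0("prod:", feats$var1, "*", feats$var2),
                       ifelse(is.na(feats$knot),
                              paste0(substr(feats$type, 1, 4), ":", feats$var1),
                              paste0(substr(feats$type, 1, 4), ":", feats$var1,
                                     "@", signif(feats$knot, 6))))
  structure(list(fc = fc, bounds = bounds, K = as.integer(K), features = feats),
            class = "featureSpec")
}

scaleVars <- function(values, spec, clamp = FALSE) {
  vars <- colnames(spec$bounds)
  miss <- setdiff(vars, colnames(values))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  s <- sapply(vars, function(v) {
    lo <- spec$bounds["min", v]; hi <- spec$bounds["max", v]
    x <- values[, v]
    if (clamp) x <- pmin(pmax(x, lo), hi)
    (x - lo) / (hi - lo)
  })
  if (!is.matrix(s)) s <- matrix(s, nrow = nrow(values), dimnames = list(NULL, vars))
  s
}

#' Evaluate the design matrix of a feature spec
#'
#' With \code{clamp = TRUE}, raw values are clipped to the training
#' bounds before scaling (projection to new conditions); inside the
#' training range the transform is identical either way, so projecting
#' the training cells reproduces the training design matrix.
#'
#' @param values numeric matrix of raw variable values (columns named).
#' @param spec a \code{\link{featureSpec}}.
#' @param clamp clip values to training bounds first (default FALSE).
#' @return design matrix, one column per feature, all values in [0, 1].
#' @export
buildDesign <- function(values, spec, clamp = FALSE) {
  s <- scaleVars(values, spec, clamp = clamp)
  f <- spec$features
  out <- matrix(0, nrow(s), nrow(f), dimnames = list(NULL, f$name))
  for (j in seq_len(nrow(f))) {
    out[, j] <- switch(f$type[j],
      linear    = s[, f$var1[j]],
      quadratic = s[, f$var1[j]]^2,
      product   = s[, f$var1[j]] * s[, f$var2[j]],
      forward_hinge = pmax(0, (s[, f$var1[j]] - f$knot[j]) / (1 - f$knot[j])),
      reverse_hinge = pmax(0, (f$knot[j] - s[, f$var1[j]]) / f$knot[j]))
  }
  out
}

#' Per-feature L1 penalties
#'
#' \eqn{\beta_j = RM \cdot base(class, m) \cdot s_j / \sqrt{m}} where
#' \eqn{s_j} is the standard deviation of feature j over the m training
#' presences. Features constant over presences get \eqn{\beta_j = 0}.
#'
#' @param spec a \code{\link{featureSpec}}.
#' @param presence_design design matrix at training presences.
#' @param rm regularisation multiplier (>= 0).
#' @param m number of training presences (default nrow of the design).
#' @return named numeric vector of penalties, \code{beta >= 0}.
#' @export
featurePenalties <- function(spec, presence_design, rm, m = nrow(presence_design)) {
  stopifnot(m >= 2L, rm >= 0)
  s_j <- apply(presence_design, 2L, sd)
  base <- vapply(spec$features$type, baseRegularisation, numeric(1L), m = m)
  setNames(rm * base * s_j / sqrt(m), colnames(presence_design))
}

#' Map features to parent variables
#'
#' Product features credit both parents 50/50; all other features credit
#' their single parent fully.
#'
#' @param spec a featureSpec.
#' @return list of named weight vectors, one per feature.
#' @keywords internal
featureParents <- function(spec) {
  f <- spec$features
  lapply(seq_len(nrow(f)), function(j) {
    if (f$type[j] == "product")
      setNames(c(0.5, 0.5), c(f$var1[j], f$var2[j]))
    else setNames(1, f$var1[j])
  })
}
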