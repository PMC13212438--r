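## Variable pre-selection: Spearman correlation with a t-approximation
## p-value, variance inflation factors, and an importance-guided pruning
## rule that leaves no retained pair with |r| >= 0.8 (P < 0.05) and no
## retained VIF > 5.

#' Spearman correlation matrix with p-values
#'
#' Average ranks for ties; two-sided p from the t approximation
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with n - 2 degrees of freedom.
#'
#' @param values numeric matrix, one column per variable (rows = samples
#'   at presence + background cells).
#' @return list with \code{r} and \code{p} matrices. Constant variables
#'   yield NA correlations and are reported in \code{constant}.
#' @export
spearmanMatrix <- function(values) {
  stopifnot(nrow(values) >= 4L)
  const <- apply(values, 2L, function(x) length(unique(x)) == 1L)
  r <- suppressWarnings(cor(values, method = "spearman"))
  n <- nrow(values)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(p) <- 0
  list(r = r, p = p, constant = colnames(values)[const])
}

#' Variance inflation factors
#'
#' \eqn{VIF_i = 1/(1-R^2_i)} from an OLS regression (with intercept) of
#' each variable on all the others. Perfect collinearity gives +Inf.
#'
#' @param values numeric matrix, one column per variable.
#' @return named numeric vector of VIFs.
#' @export
vifScores <- function(values) {
  p <- ncol(values)
  stopifnot(nrow(values) >= p + 2L)
  if (p == 1L) return(setNames(1, colnames(values)))
  vapply(seq_len(p), function(i) {
    y <- values[, i]
    X <- values[, -i, drop = FALSE]
    fit <- lm(y ~ X)
    r2 <- suppressWarnings(summary(fit)$r.squared)  # singular fits are expected
    if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1L)) |> setNames(colnames(values))
}

#' Screen candidate variables
#'
#' Two deterministic passes: (1) for every pair with |r| >= \code{r_cut}
#' and p < \code{p_cut} (highest |r| handled first), drop the member with
#' lower permutation importance (ties: lower percent contribution, then
#' the lexicographically later name); (2) iteratively drop the
#' highest-VIF variable while any VIF exceeds \code{vif_cut}, recomputing
#' VIFs each round. Constant variables are dropped up front.
#'
#' @param values numeric matrix (samples x variables).
#' @param importance data.frame with rownames = variables and columns
#'   \code{percent_contribution}, \code{permutation_importance}.
#' @param r_cut,p_cut,vif_cut thresholds (defaults 0.8, 0.05, 5).
#' @return list: \code{kept}, \code{dropped} (with reasons),
#'   \code{spearman}, \code{vif} (final VIFs of kept variables).
#' @export
selectVariables <- function(values, importance,
                            r_cut = 0.8, p_cut = 0.05, vif_cut = 5) {
  vars <- colnames(values)
  stopifnot(all(vars %in% rownames(importance)))
  dropped <- character(); reason <- character()
  sp <- spearmanMatrix(values)
  kept <- setdiff(vars, sp$constant)
  if (length(sp$constant)) {
    dropped <- c(dropped, sp$constant)
    reason <- c(reason, rep("constant", length(sp$constant)))
  }
  repeat {
    rr <- abs(sp$r[kept, kept, drop = FALSE])
    pp <- sp$p[kept, kept, drop = FALSE]
    rr[lower.tri(rr, diag = TRUE)] <- NA
    bad <- which(rr >= r_cut & pp < p_cut, arr.ind = TRUE)
    if (nrow(bad) == 0L) break
    top <- bad[order(-rr[bad], bad[, 1L], bad[, 2L])[1L], ]
    a <- kept[top[1L]]; b <- kept[top[2L]]
    imp <- importance[c(a, b), ]
    loser <- if (imp$permutation_importance[1L] != imp$permutation_importance[2L]) {
      c(a, b)[which.min(imp$permutation_importance)]
    } else if (imp$percent_contribution[1L] != imp$percent_contribution[2L]) {
      c(a, b)[which.min(imp$percent_contribution)]
    } else {
      max(a, b)
    }
    kept <- setdiff(kept, loser)
    dropped <- c(dropped, loser)
    reason <- c(reason, sprintf("correlated (|r|>=%.2f) with lower importance", r_cut))
  }
  while (length(kept) > 1L) {
    v <- vifScores(values[, kept, drop = FALSE])
    if (max(v) <= vif_cut) break
    loser <- names(v)[which.max(v)]
    kept <- setdiff(kept, loser)
    dropped <- c(dropped, loser)
    reason <- c(reason, sprintf("VIF %.2f > %.1f", max(v), vif_cut))
  }
  final_vif <- if (length(kept) > 1L) vifScores(values[, kept, drop = FALSE])
               else setNames(rep(1, length(kept)), kept)
  list(kept = vars[vars %in% kept],
       dropped = data.frame(variable = dropped, reason = reason),
       spearman = sp, vif = final_vif)
}
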