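## L1-regularised maximum-entropy (Gibbs) model over landscape cells:
##   q(x) proportional to exp(lambda . f(x)),
## fitted by cyclic coordinate ascent with soft-thresholding on the
## penalised log-likelihood
##   J(lambda) = mean_presence(lambda . f) - ln Z - sum_j beta_j |lambda_j|.
## Each accepted coordinate update's objective gain is credited to the
## feature's parent variable(s), which is what "percent contribution"
## normalises.

#' Fitted maximum-entropy niche model
#'
#' @slot spec the frozen \code{featureSpec} (scaling bounds, feature list).
#' @slot lambda named coefficient vector (sparse: zeros allowed).
#' @slot beta named L1 penalty vector.
#' @slot logZ log partition value over the training landscape.
#' @slot H entropy of the fitted raw distribution.
#' @slot rm,fc provenance: regularisation multiplier and feature classes.
#' @slot gain named per-variable objective-gain credits.
#' @slot varMeans landscape means of the raw variables (response curves).
#' @slot nCells number of training landscape cells.
#' @slot converged logical; \code{sweeps} iterations used.
#' @export
setClass("MaxentModel",
  representation(spec = "list", lambda = "numeric", beta = "numeric",
                 logZ = "numeric", H = "numeric", rm = "numeric",
                 fc = "character", gain = "numeric", varMeans = "numeric",
                 nCells = "integer", converged = "logical", sweeps = "integer"))

setValidity("MaxentModel", function(object) {
  if (length(object@lambda) != nrow(object@spec$features))
    return("lambda length must match the feature list")
  if (any(object@beta < 0)) return("penalties must be nonnegative")
  TRUE
})

setMethod("show", "MaxentModel", function(object) {
  cat(sprintf("MaxentModel: fc=%s rm=%.2f; %d features (%d nonzero)\n",
              object@fc, object@rm, length(object@lambda),
              sum(object@lambda != 0)))
  cat(sprintf("  entropy H=%.4f over %d landscape cells; %s after %d sweeps\n",
              object@H, object@nCells,
              if (object@converged) "converged" else "iteration cap reached",
              object@sweeps))
})

#' @describeIn fitMaxent coefficient accessor.
#' @export
modelCoefficients <- function(model) model@lambda

#' @describeIn fitMaxent entropy accessor.
#' @export
modelEntropy <- function(model) model@H

logSumExp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' Fit the L1-regularised maximum-entropy model
#'
#' Cyclic coordinate ascent: each coordinate takes a 1-D Newton step on
#' the smooth part followed by soft-thresholding at its penalty, with
#' step halving so the penalised objective never decreases. Convergence
#' when the largest single-coordinate improvement in a sweep falls below
#' \code{tol}. After a few full sweeps the cycle restricts to the active
#' (nonzero) set, with periodic full sweeps.
#'
#' @param presence_design design matrix at training presences.
#' @param landscape_design design matrix at landscape cells (presence
#'   cells included).
#' @param beta per-feature penalties (see \code{\link{featurePenalties}}).
#' @param spec the \code{featureSpec} used to build the designs.
#' @param max_iter maximum full sweeps (default 1000).
#' @param tol per-sweep improvement tolerance (default 1e-5).
#' @param rm,fc provenance labels stored on the model.
#' @param var_means optional named landscape means of raw variables.
#' @return a \linkS4class{MaxentModel}.
#' @export
fitMaxent <- function(presence_design, landscape_design, beta, spec,
                      max_iter = 1000L, tol = 1e-5, rm = NA_real_,
                      fc = NA_character_, var_means = numeric()) {
  m <- nrow(presence_design); n <- nrow(landscape_design)
  J <- ncol(landscape_design)
  if (J == 0L) stop("empty feature set")
  if (m < 2L) stop("need at least 2 presences")
  stopifnot(length(beta) == J)
  pbar <- colMeans(presence_design)
  lambda <- numeric(J)
  eta <- numeric(n)
  logZ <- log(n)
  obj <- -logZ    # J(0) = 0 - log n - 0 ... mean term is 0 at lambda = 0
  gain <- numeric(0)
  parents <- featureParents(spec)
  sweep_order <- seq_len(J)
  sweeps_done <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    ## restrict to active set most sweeps once warm (glmnet-style)
    idx <- if (it > 3L && it %% 5L != 0L && any(lambda != 0)) which(lambda != 0)
           else sweep_order
    best_impr <- 0
    for (j in idx) {
      fj <- landscape_design[, j]
      w <- exp(eta - logZ)              # q, since logZ tracks eta
      Ef <- sum(w * fj)
      if (lambda[j] == 0 && abs(pbar[j] - Ef) <= beta[j]) next  # KKT holds
      Ef2 <- sum(w * fj * fj)
      V <- max(Ef2 - Ef * Ef, 1e-12)
      z <- lambda[j] + (pbar[j] - Ef) / V
      lam_new <- sign(z) * max(abs(z) - beta[j] / V, 0)
      d <- lam_new - lambda[j]
      if (d == 0) next
      ## exact objective change with step halving
      impr <- -Inf
      for (h in 0:20) {
        dh <- d / 2^h
        dlogZ <- log(sum(w * exp(dh * fj)))
        impr <- pbar[j] * dh - dlogZ -
          beta[j] * (abs(lambda[j] + dh) - abs(lambda[j]))
        if (impr >= 0) { d <- dh; break }
      }
      if (impr <= 0) next
      lambda[j] <- lambda[j] + d
      eta <- eta + d * fj
      logZ <- logZ + log(sum(w * exp(d * fj)))
      obj <- obj + impr
      best_impr <- max(best_impr, impr)
      for (v in names(parents[[j]]))
        gain[v] <- (if (v %in% names(gain)) gain[[v]] else 0) +
                   parents[[j]][[v]] * impr
    }
    sweeps_done <- it
    if (!is.finite(obj)) stop("non-finite objective during fitting")
    ## declare convergence only off a full sweep; active-set sweeps that
    ## stall simply wait for the next periodic full pass
    if (best_impr < tol && identical(idx, sweep_order)) { converged <- TRUE; break }
  }
  q <- exp(eta - logZ)
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  gv <- setNames(numeric(ncol(spec$bounds)), colnames(spec$bounds))
  gv[names(gain)] <- gain
  names(lambda) <- colnames(landscape_design)
  new("MaxentModel", spec = unclass(spec), lambda = lambda,
      beta = setNames(as.numeric(beta), colnames(landscape_design)),
      logZ = logZ, H = H, rm = as.numeric(rm), fc = as.character(fc),
      gain = gv, varMeans = var_means, nCells = as.integer(n),
      converged = converged, sweeps = sweeps_done)
}

#' Raw (relative occurrence rate) prediction
#'
#' \code{exp(lambda . f) / Z} with the training-time partition value, so
#' raw values over the training landscape sum to one.
#'
#' @param model a MaxentModel.
#' @param values matrix of raw variable values (columns named), or a
#'   pre-built design matrix when \code{is_design = TRUE}.
#' @param is_design skip feature building.
#' @return numeric vector of nonnegative raw probabilities.
#' @export
predictRaw <- function(model, values, is_design = FALSE) {
  Fm <- if (is_design) values
        else buildDesign(values, structure(model@spec, class = "featureSpec"),
                         clamp = TRUE)
  as.numeric(exp(Fm %*% model@lambda - model@logZ))
}

#' Cloglog suitability
#'
#' \eqn{P = 1 - \exp(-e^{H} q_{raw})}: a strictly increasing transform of
#' the raw output into (0, 1); a uniform model yields \eqn{1 - e^{-1}}
#' everywhere.
#'
#' @inheritParams predictRaw
#' @return suitability values in (0, 1).
#' @export
predictCloglog <- function(model, values, is_design = FALSE) {
  1 - exp(-exp(model@H) * predictRaw(model, values, is_design = is_design))
}

#' Response curve of one variable
#'
#' The variable sweeps its training range; every other variable is held
#' at its landscape mean.
#'
#' @param model a MaxentModel (with stored landscape variable means).
#' @param variable variable name.
#' @param n_points sweep resolution (default 100).
#' @return data.frame with \code{value} and \code{suitability}.
#' @export
responseCurve <- function(model, variable, n_points = 100L) {
  b <- model@spec$bounds
  if (!variable %in% colnames(b)) stop("unknown variable: ", variable)
  if (!length(model@varMeans)) stop("model carries no landscape means")
  sweep_vals <- seq(b["min", variable], b["max", variable],
                    length.out = n_points)
  vals <- matrix(rep(model@varMeans[colnames(b)], each = n_points),
                 nrow = n_points, dimnames = list(NULL, colnames(b)))
  vals[, variable] <- sweep_vals
  data.frame(value = sweep_vals,
             suitability = predictCloglog(model, vals))
}

#' Fit a model straight from raw variable values
#'
#' Convenience wrapper: builds the feature spec from the landscape value
#' range, the presence and landscape design matrices and the default
#' penalties, then fits. Shared by jackknife, tuning and the pipeline.
#'
#' @param pres_vals raw variable values at training presences.
#' @param land_vals values at landscape (presence + background) cells.
#' @param fc,rm feature classes and regularisation multiplier.
#' @param K hinge knots; \code{max_iter}, \code{tol} as in
#'   \code{\link{fitMaxent}}.
#' @param max_iter,tol trainer settings.
#' @return a \linkS4class{MaxentModel}.
#' @export
fitFromValues <- function(pres_vals, land_vals, fc, rm, K = 50L,
                          max_iter = 1000L, tol = 1e-5) {
  spec <- featureSpec(apply(land_vals, 2L, range), fc = fc, K = K)
  Fp <- buildDesign(pres_vals, spec)
  Fl <- buildDesign(land_vals, spec)
  beta <- featurePenalties(spec, Fp, rm)
  fitMaxent(Fp, Fl, beta, spec, max_iter = max_iter, tol = tol,
            rm = rm, fc = fc, var_means = colMeans(land_vals))
}

#' Jackknife variable analysis
#'
#' For each variable, fits a model with only that variable and one with
#' all others, reporting training AUC and TSS (at the MTSS threshold)
#' against the background cells, alongside the full-model scores.
#'
#' @param pres_vals,land_vals raw variable values at presences and
#'   landscape (presence + background) cells.
#' @param bg_vals values at background cells (scored as pseudo-absences).
#' @param fc,rm,K,max_iter,tol model settings.
#' @return data.frame: variable, mode (only/without/full), auc, tss.
#' @export
jackknifeTest <- function(pres_vals, land_vals, bg_vals, fc = "LQ", rm = 1,
                          K = 10L, max_iter = 200L, tol = 1e-4) {
  vars <- colnames(land_vals)
  stopifnot(length(vars) >= 2L)
  scoreModel <- function(mod) {
    sp <- predictCloglog(mod, pres_vals)
    sb <- predictCloglog(mod, bg_vals)
    tau <- mtssThreshold(sp, sb)
    c(auc = aucPB(sp, sb), tss = tssStat(sp, sb, tau))
  }
  rows <- list()
  full <- fitFromValues(pres_vals, land_vals, fc, rm, K, max_iter, tol)
  rows[[1L]] <- data.frame(variable = "FULL", mode = "full",
                           t(scoreModel(full)))
  for (v in vars) {
    only <- fitFromValues(pres_vals[, v, drop = FALSE],
                          land_vals[, v, drop = FALSE], fc, rm, K,
                          max_iter, tol)
    rows[[length(rows) + 1L]] <- data.frame(variable = v, mode = "only",
                                            t(scoreModel(only)))
    rest <- setdiff(vars, v)
    wo <- fitFromValues(pres_vals[, rest, drop = FALSE],
                        land_vals[, rest, drop = FALSE], fc, rm, K,
                        max_iter, tol)
    rows[[length(rows) + 1L]] <- data.frame(variable = v, mode = "without",
                                            t(scoreModel(wo)))
  }
  do.call(rbind, rows)
}

#' Permutation importance
#'
#' Permutes each variable jointly across presence + background rows,
#' recomputes training AUC, and normalises the (nonnegative) AUC drops
#' to sum to 100.
#'
#' @param model fitted MaxentModel.
#' @param pres_vals,bg_vals raw variable values.
#' @param seed RNG seed.
#' @param n_perm permutations averaged per variable (default 1).
#' @return named numeric importances summing to 100 (all-zero drops
#'   return all zeros).
#' @export
permutationImportance <- function(model, pres_vals, bg_vals, seed = 1L,
                                  n_perm = 1L) {
  vars <- colnames(model@spec$bounds)
  all_vals <- rbind(pres_vals[, vars, drop = FALSE],
                    bg_vals[, vars, drop = FALSE])
  np <- nrow(pres_vals)
  base_scores <- predictCloglog(model, all_vals)
  auc0 <- aucPB(base_scores[seq_len(np)], base_scores[-seq_len(np)])
  drops <- withr_seed(seed, vapply(vars, function(v) {
    mean(vapply(seq_len(n_perm), function(k) {
      perm <- all_vals
      perm[, v] <- perm[sample.int(nrow(perm)), v]
      s <- predictCloglog(model, perm)
      max(0, auc0 - aucPB(s[seq_len(np)], s[-seq_len(np)]))
    }, numeric(1L)))
  }, numeric(1L)))
  if (sum(drops) == 0) return(setNames(rep(0, length(vars)), vars))
  100 * drops / sum(drops)
}

#' Percent contribution
#'
#' Per-variable objective-gain credits accumulated during coordinate
#' ascent, normalised to 100. Path-dependent by construction; a heuristic
#' companion to \code{\link{permutationImportance}}.
#'
#' @param model fitted MaxentModel.
#' @return named numeric summing to 100 (or all zeros).
#' @export
percentContribution <- function(model) {
  g <- pmax(model@gain, 0)
  if (sum(g) == 0) return(g)
  100 * g / sum(g)
}
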