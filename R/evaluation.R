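## Presence-background evaluation metrics. Background points stand in for
## absences throughout: sensitivity uses scores >= tau (ties count as
## predicted present), specificity uses scores < tau.

#' Presence-background AUC
#'
#' Mann-Whitney probability that a random presence outscores a random
#' background point, ties counted one half; computed from the rank
#' statistic.
#'
#' @param presence,background numeric score vectors (non-empty).
#' @return AUC in [0, 1].
#' @export
aucPB <- function(presence, background) {
  if (!length(presence) || !length(background)) stop("empty score set")
  m <- length(presence); nb <- length(background)
  r <- rank(c(presence, background))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * nb)
}

#' Maximum training sensitivity plus specificity threshold
#'
#' Candidate thresholds are all distinct observed scores; the smallest
#' maximiser of sensitivity(tau) + specificity(tau) is returned.
#'
#' @inheritParams aucPB
#' @return the MTSS threshold.
#' @export
mtssThreshold <- function(presence, background) {
  if (!length(presence) || !length(background)) stop("empty score set")
  cand <- sort(unique(c(presence, background)))
  sums <- vapply(cand, function(tau)
    mean(presence >= tau) + mean(background < tau), numeric(1L))
  cand[which.max(sums)]   # which.max takes the first (smallest) maximiser
}

#' True Skill Statistic at a threshold
#'
#' sensitivity + specificity - 1 with background as pseudo-absence.
#'
#' @inheritParams aucPB
#' @param tau threshold.
#' @return TSS in [-1, 1].
#' @export
tssStat <- function(presence, background, tau) {
  if (!length(presence) || !length(background)) stop("empty score set")
  mean(presence >= tau) + mean(background < tau) - 1
}

#' 10\% omission threshold and rates
#'
#' The threshold is the (floor(0.1 m) + 1)-th smallest training presence
#' score; the omission rate is the fraction of scores strictly below it.
#' With m distinct training scores the training rate is floor(0.1 m)/m
#' (0.10 exactly at m = 100).
#'
#' @param train_scores training presence scores (warns below 10).
#' @param test_scores test presence scores.
#' @return list: \code{tau10}, \code{or10_train}, \code{or10_test}.
#' @export
or10 <- function(train_scores, test_scores) {
  m <- length(train_scores)
  if (m < 10L) {
    warning("fewer than 10 training presences; tau10 set to the minimum score")
    tau10 <- min(train_scores)
  } else {
    tau10 <- sort(train_scores)[floor(0.1 * m) + 1L]
  }
  list(tau10 = tau10,
       or10_train = mean(train_scores < tau10),
       or10_test = mean(test_scores < tau10))
}

#' Sample-size corrected AIC for a maximum-entropy model
#'
#' Raw predictions are normalised over the full landscape grid to sum to
#' one; the log-likelihood is evaluated at the presence cells; k counts
#' nonzero coefficients; \eqn{AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)} with
#' n the number of presences. Returns +Inf when n - k - 1 <= 0 or any
#' presence has zero probability.
#'
#' @param model a MaxentModel.
#' @param presence_vals raw variable values at all presence cells.
#' @param landscape_vals raw variable values over the full valid grid.
#' @return the AICc value.
#' @export
aiccScore <- function(model, presence_vals, landscape_vals) {
  raw_land <- predictRaw(model, landscape_vals)
  raw_pres <- predictRaw(model, presence_vals)
  p <- raw_pres / sum(raw_land)
  k <- sum(model@lambda != 0)
  n <- nrow(presence_vals)
  if (n - k - 1 <= 0) return(Inf)
  if (any(p <= 0)) return(Inf)
  lnL <- sum(log(p))
  2 * k - 2 * lnL + (2 * k * (k + 1)) / (n - k - 1)
}

#' Evaluate one fitted replicate
#'
#' Computes the seven reporting metrics for a train/test split: training
#' and test AUC, TSS at the training MTSS threshold, the OR10 pair, and
#' AICc over all presences.
#'
#' @param model fitted MaxentModel.
#' @param train_vals,test_vals raw values at train and test presences.
#' @param bg_vals raw values at background cells.
#' @param all_pres_vals raw values at all (thinned) presences, for AICc.
#' @param landscape_vals raw values over the full valid grid, for AICc.
#' @return one-row data.frame of metrics plus \code{mtss} and \code{k}.
#' @export
evaluateModel <- function(model, train_vals, test_vals, bg_vals,
                          all_pres_vals = rbind(train_vals, test_vals),
                          landscape_vals = bg_vals) {
  s_tr <- predictCloglog(model, train_vals)
  s_te <- predictCloglog(model, test_vals)
  s_bg <- predictCloglog(model, bg_vals)
  tau <- mtssThreshold(s_tr, s_bg)
  o <- suppressWarnings(or10(s_tr, s_te))
  data.frame(auc_train = aucPB(s_tr, s_bg), auc_test = aucPB(s_te, s_bg),
             tss_train = tssStat(s_tr, s_bg, tau),
             tss_test = tssStat(s_te, s_bg, tau),
             or10_train = o$or10_train, or10_test = o$or10_test,
             aicc = aiccScore(model, all_pres_vals, landscape_vals),
             mtss = tau, k = sum(model@lambda != 0))
}
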