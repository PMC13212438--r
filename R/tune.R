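## Glue between the data and the NSGA-III search: a memoisable evaluator
## that, for one (RM, FC) genotype, fits a model per train/test replicate
## and averages the four objectives (1 - test AUC, 1 - test TSS, test
## OR10, AICc) over replicates.

#' Build a genotype evaluator from data
#'
#' @param pres_vals raw variable values at thinned presences (matrix).
#' @param bg_vals values at background cells.
#' @param landscape_vals values over the full valid grid (AICc
#'   normalisation); defaults to \code{bg_vals}.
#' @param splits list of train/test plans from \code{\link{makeSplits}}.
#' @param K hinge knots.
#' @param max_iter,tol trainer settings.
#' @return function(genotype) -> named numeric(4), minimisation sense.
#' @export
makeEvaluator <- function(pres_vals, bg_vals, landscape_vals = bg_vals,
                          splits, K = 50L, max_iter = 1000L, tol = 1e-5) {
  function(genotype) {
    per <- lapply(splits, function(sp) {
      tr <- pres_vals[sp$train, , drop = FALSE]
      te <- pres_vals[sp$test, , drop = FALSE]
      land <- rbind(tr, bg_vals)
      mod <- fitFromValues(tr, land, genotype$fc, genotype$rm, K = K,
                           max_iter = max_iter, tol = tol)
      evaluateModel(mod, tr, te, bg_vals, all_pres_vals = pres_vals,
                    landscape_vals = landscape_vals)
    })
    mm <- do.call(rbind, per)
    c(one_minus_auc = mean(1 - mm$auc_test),
      one_minus_tss = mean(1 - mm$tss_test),
      or10_test = mean(mm$or10_test),
      aicc = mean(mm$aicc))
  }
}

#' Tune (RM, FC) with NSGA-III or exhaustive enumeration
#'
#' @inheritParams makeEvaluator
#' @param generations,pop_size,seed NSGA-III settings.
#' @param exhaustive evaluate every genotype instead of evolving.
#' @param rm_indices,fc_indices optional restriction of the genotype grid
#'   (exhaustive mode only).
#' @return a \linkS4class{ParetoArchive} with the compromise selected.
#' @export
tuneMaxent <- function(pres_vals, bg_vals, landscape_vals = bg_vals, splits,
                       K = 50L, max_iter = 1000L, tol = 1e-5,
                       generations = 40L, pop_size = 92L, seed = 1L,
                       exhaustive = FALSE, rm_indices = 0:25,
                       fc_indices = 0:4) {
  ev <- makeEvaluator(pres_vals, bg_vals, landscape_vals, splits,
                      K = K, max_iter = max_iter, tol = tol)
  if (exhaustive) exhaustiveArchive(ev, rm_indices, fc_indices)
  else nsga3Evolve(ev, generations = generations, pop_size = pop_size,
                   seed = seed)
}

#' Serialise an archive to JSON
#' @param archive a ParetoArchive.
#' @param path output file.
#' @export
writeArchive <- function(archive, path) {
  sel <- if (archive@selected > 0L)
    archive@table[archive@selected, c("rm", "fc")] else NULL
  jsonlite::write_json(
    list(genotypes = archive@table,
         front = paretoFront(archive)[, c("rm", "fc")],
         selected = sel,
         selection_rule = paste("front member with minimum Euclidean distance",
                                "to the normalised ideal point (package",
                                "convention; ties to lower RM, then fewer",
                                "feature classes)")),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
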