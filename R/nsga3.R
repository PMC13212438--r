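## NSGA-III over the (RM x FC) genotype grid: 26 regularisation
## multipliers (0.5..3.0 by 0.1) x 5 feature-class sets = 130 genotypes.
## The evaluator is memoised, and the returned archive covers every
## genotype ever evaluated, so the reported front is checkable against
## exhaustive enumeration.

RM_VALUES <- seq(0.5, 3.0, by = 0.1)
OBJ_NAMES <- c("one_minus_auc", "one_minus_tss", "or10_test", "aicc")

#' Decode a genotype
#' @param rm_index integer 0..25; RM = 0.5 + 0.1 * rm_index.
#' @param fc_index integer 0..4; order L, LQ, H, LQH, LQHP.
#' @return list with rm, fc and the indices.
#' @export
decodeGenotype <- function(rm_index, fc_index) {
  stopifnot(rm_index >= 0L, rm_index <= 25L, fc_index >= 0L, fc_index <= 4L)
  list(rm_index = as.integer(rm_index), fc_index = as.integer(fc_index),
       rm = RM_VALUES[rm_index + 1L], fc = FC_LEVELS[fc_index + 1L])
}

#' Fast non-dominated sorting
#'
#' Minimisation sense: a dominates b iff a <= b componentwise with at
#' least one strict inequality.
#'
#' @param objectives numeric matrix, one row per solution.
#' @return integer vector of front ranks (1 = non-dominated).
#' @export
nondominatedSort <- function(objectives) {
  n <- nrow(objectives)
  if (n == 0L) return(integer())
  dominates <- function(a, b) all(a <= b) && any(a < b)
  S <- vector("list", n); nd <- integer(n); rank <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(objectives[i, ], objectives[j, ])) S[[i]] <- c(S[[i]], j)
      else if (dominates(objectives[j, ], objectives[i, ])) nd[i] <- nd[i] + 1L
    }
    if (nd[i] == 0L) rank[i] <- 1L
  }
  r <- 1L
  current <- which(rank == 1L)
  while (length(current)) {
    nxt <- integer()
    for (i in current) for (j in S[[i]]) {
      nd[j] <- nd[j] - 1L
      if (nd[j] == 0L) { rank[j] <- r + 1L; nxt <- c(nxt, j) }
    }
    r <- r + 1L
    current <- nxt
  }
  rank
}

#' Das-Dennis reference points
#'
#' All compositions of \code{p} into \code{M} nonnegative parts, divided
#' by \code{p}; each point sums to one.
#'
#' @param M number of objectives (>= 2).
#' @param p number of divisions (>= 1).
#' @return matrix with \code{choose(p + M - 1, M - 1)} rows.
#' @export
referencePoints <- function(M, p) {
  stopifnot(M >= 2L, p >= 1L)
  compose <- function(left, slots) {
    if (slots == 1L) return(matrix(left, ncol = 1L))
    do.call(rbind, lapply(0:left, function(k)
      cbind(k, compose(left - k, slots - 1L))))
  }
  unname(compose(p, M) / p)
}

## Replace +Inf entries per column by a value worse than any finite one,
## so normalisation stays finite. Domination itself sees the raw values.
capInfinite <- function(Fm) {
  for (j in seq_len(ncol(Fm))) {
    inf <- !is.finite(Fm[, j])
    if (any(inf)) {
      fin <- Fm[!inf, j]
      Fm[inf, j] <- if (length(fin)) max(fin) * 10 + 1 else 1
    }
  }
  Fm
}

## NSGA-III environmental selection: pick pop_size members of Fm (rows).
nsga3Select <- function(Fm_raw, pop_size, refs) {
  n <- nrow(Fm_raw)
  if (n <= pop_size) return(seq_len(n))
  ranks <- nondominatedSort(Fm_raw)
  Fm <- capInfinite(Fm_raw)
  ord_fronts <- sort(unique(ranks))
  chosen <- integer(); last <- integer()
  for (r in ord_fronts) {
    fr <- which(ranks == r)
    if (length(chosen) + length(fr) <= pop_size) chosen <- c(chosen, fr)
    else { last <- fr; break }
  }
  if (!length(last)) return(chosen)
  St <- c(chosen, last)
  ## adaptive normalisation over St
  Fs <- Fm[St, , drop = FALSE]
  M <- ncol(Fs)
  ideal <- apply(Fs, 2L, min)
  Ft <- sweep(Fs, 2L, ideal)
  eps <- 1e-6
  extremes <- vapply(seq_len(M), function(j) {
    w <- rep(eps, M); w[j] <- 1
    asf <- apply(sweep(Ft, 2L, w, "/"), 1L, max)
    which.min(asf)
  }, integer(1L))
  a <- rep(NA_real_, M)
  E <- Ft[extremes, , drop = FALSE]
  ok <- FALSE
  if (length(unique(extremes)) == M) {
    b <- tryCatch(solve(E, rep(1, M)), error = function(e) NULL)
    if (!is.null(b) && all(is.finite(b)) && all(b > 1e-12)) {
      a <- 1 / b; ok <- all(a > eps)
    }
  }
  if (!ok) a <- apply(Ft, 2L, max)       # nadir fallback
  a[a < eps] <- eps
  Fn <- sweep(Ft, 2L, a, "/")
  ## perpendicular distance association to reference lines
  ref_norm2 <- rowSums(refs^2)
  assoc <- integer(nrow(Fn)); dist <- numeric(nrow(Fn))
  for (i in seq_len(nrow(Fn))) {
    proj <- (refs %*% Fn[i, ]) / ref_norm2
    d2 <- rowSums((matrix(Fn[i, ], nrow(refs), M, byrow = TRUE) -
                   refs * as.numeric(proj))^2)
    assoc[i] <- which.min(d2)
    dist[i] <- sqrt(min(d2))
  }
  in_chosen <- seq_along(St) <= length(chosen)
  niche <- tabulate(assoc[in_chosen], nbins = nrow(refs))
  pool <- which(!in_chosen)              # indices into St (members of last)
  need <- pop_size - length(chosen)
  active <- rep(TRUE, nrow(refs))
  picked <- integer()
  while (need > 0L) {
    cand_refs <- which(active & niche == min(niche[active]))
    jref <- if (length(cand_refs) == 1L) cand_refs else sample(cand_refs, 1L)
    members <- pool[assoc[pool] == jref]
    if (!length(members)) { active[jref] <- FALSE; next }
    pick <- if (niche[jref] == 0L) members[which.min(dist[members])]
            else if (length(members) == 1L) members else sample(members, 1L)
    picked <- c(picked, pick)
    pool <- setdiff(pool, pick)
    niche[jref] <- niche[jref] + 1L
    need <- need - 1L
  }
  c(St[in_chosen], St[picked])
}

#' Archive of evaluated genotypes
#'
#' @slot table data.frame: rm_index, fc_index, rm, fc, the four averaged
#'   objectives (minimisation sense), and the front rank over the whole
#'   archive.
#' @slot selected integer row index of the compromise genotype (0 before
#'   selection).
#' @export
setClass("ParetoArchive",
  representation(table = "data.frame", selected = "integer"),
  prototype(selected = 0L))

setValidity("ParetoArchive", function(object) {
  need <- c("rm_index", "fc_index", "rm", "fc", OBJ_NAMES, "rank")
  if (!all(need %in% names(object@table))) return("archive table incomplete")
  if (anyDuplicated(object@table[, c("rm_index", "fc_index")]))
    return("duplicate genotypes in archive")
  TRUE
})

setMethod("show", "ParetoArchive", function(object) {
  tb <- object@table
  cat(sprintf("ParetoArchive: %d genotype(s) evaluated, front size %d\n",
              nrow(tb), sum(tb$rank == 1L)))
  if (object@selected > 0L) {
    s <- tb[object@selected, ]
    cat(sprintf("  selected compromise: fc=%s rm=%.1f\n", s$fc, s$rm))
  }
})

#' @describeIn nsga3Evolve archive table accessor.
#' @param archive a ParetoArchive.
#' @export
archiveTable <- function(archive) archive@table

#' @describeIn nsga3Evolve rows of the archive's rank-1 front.
#' @export
paretoFront <- function(archive) archive@table[archive@table$rank == 1L, ]

makeArchive <- function(tbl) {
  obj <- as.matrix(tbl[, OBJ_NAMES])
  tbl$rank <- nondominatedSort(obj)
  new("ParetoArchive", table = tbl, selected = 0L)
}

#' Evolve the genotype population with NSGA-III
#'
#' Uniform crossover (rate 0.9) and per-gene random-reset mutation
#' (rate 0.5) on the 2-gene integer chromosome; environmental selection
#' by non-dominated sorting, adaptive normalisation and reference-point
#' niching. The evaluator is called once per distinct genotype; the
#' archive covers all cached evaluations.
#'
#' @param evaluator function(genotype) -> numeric(4) objective vector in
#'   minimisation sense (1-AUC, 1-TSS, OR10, AICc). Failures score +Inf.
#' @param generations number of generations (default 40).
#' @param pop_size population size (default 92: the smallest multiple of
#'   4 at least the 84 reference points for M = 4, p = 6).
#' @param seed RNG seed.
#' @param p_divisions Das-Dennis divisions (default 6).
#' @return a \linkS4class{ParetoArchive} with the compromise selected.
#' @export
nsga3Evolve <- function(evaluator, generations = 40L, pop_size = 92L,
                        seed = 1L, p_divisions = 6L) {
  refs <- referencePoints(4L, p_divisions)
  cache <- new.env(parent = emptyenv())
  getObj <- function(pop) {
    for (g in pop) evalCachedEnv(cache, evaluator, g[1L], g[2L])
    t(vapply(pop, function(g)
      get(paste0(g[1L], ":", g[2L]), cache)[3:6], numeric(4L)))
  }
  withr_seed(seed, {
    all130 <- expand.grid(rm = 0:25, fc = 0:4)
    init <- all130[sample.int(130L, min(pop_size, 130L)), ]
    pop <- lapply(seq_len(nrow(init)), function(i)
      c(init$rm[i], init$fc[i]))
    while (length(pop) < pop_size)
      pop <- c(pop, list(c(sample(0:25, 1L), sample(0:4, 1L))))
    Fp <- getObj(pop)
    for (gen in seq_len(generations)) {
      ord <- sample(length(pop))
      kids <- list()
      for (i in seq(1L, length(ord) - 1L, by = 2L)) {
        p1 <- pop[[ord[i]]]; p2 <- pop[[ord[i + 1L]]]
        c1 <- p1; c2 <- p2
        if (runif(1) < 0.9) {
          swap <- runif(2) < 0.5
          c1[swap] <- p2[swap]; c2[swap] <- p1[swap]
        }
        mut <- function(g) {
          if (runif(1) < 0.5) g[1L] <- sample(0:25, 1L)
          if (runif(1) < 0.5) g[2L] <- sample(0:4, 1L)
          g
        }
        kids <- c(kids, list(mut(c1), mut(c2)))
      }
      Fk <- getObj(kids)
      comb <- c(pop, kids)
      Fc <- rbind(Fp, Fk)
      keep <- nsga3Select(Fc, pop_size, refs)
      pop <- comb[keep]
      Fp <- Fc[keep, , drop = FALSE]
    }
  })
  keys <- ls(cache)
  tbl <- do.call(rbind, lapply(keys, function(k) get(k, cache)))
  tbl <- as.data.frame(tbl)
  names(tbl) <- c("rm_index", "fc_index", OBJ_NAMES)
  tbl$rm <- RM_VALUES[tbl$rm_index + 1L]
  tbl$fc <- FC_LEVELS[tbl$fc_index + 1L]
  tbl <- tbl[order(tbl$fc_index, tbl$rm_index),
             c("rm_index", "fc_index", "rm", "fc", OBJ_NAMES)]
  rownames(tbl) <- NULL
  arch <- makeArchive(tbl)
  selectCompromise(arch)
}

evalCachedEnv <- function(env, evaluator, rm_index, fc_index) {
  key <- paste0(rm_index, ":", fc_index)
  if (!exists(key, env)) {
    g <- decodeGenotype(rm_index, fc_index)
    obj <- tryCatch(as.numeric(evaluator(g)), error = function(e) {
      warning("evaluator failed for fc=", g$fc, " rm=", g$rm, ": ",
              conditionMessage(e))
      rep(Inf, 4L)
    })
    if (length(obj) != 4L) obj <- rep(Inf, 4L)
    obj[is.na(obj)] <- Inf
    assign(key, c(rm_index, fc_index, obj), env)
  }
  env
}

#' Exhaustively evaluate the genotype grid
#'
#' @inheritParams nsga3Evolve
#' @param rm_indices,fc_indices the grid to enumerate (defaults: all 130).
#' @return a \linkS4class{ParetoArchive} over the enumerated grid.
#' @export
exhaustiveArchive <- function(evaluator, rm_indices = 0:25, fc_indices = 0:4) {
  rows <- list()
  for (fc_i in fc_indices) for (rm_i in rm_indices) {
    g <- decodeGenotype(rm_i, fc_i)
    obj <- tryCatch(as.numeric(evaluator(g)), error = function(e) rep(Inf, 4L))
    if (length(obj) != 4L) obj <- rep(Inf, 4L)
    obj[is.na(obj)] <- Inf
    rows[[length(rows) + 1L]] <-
      data.frame(rm_index = rm_i, fc_index = fc_i, rm = g$rm, fc = g$fc,
                 t(setNames(obj, OBJ_NAMES)))
  }
  selectCompromise(makeArchive(do.call(rbind, rows)))
}

#' Select the compromise genotype from the front
#'
#' Objectives are min-max normalised over the rank-1 front; the front
#' member closest (Euclidean) to the normalised ideal point (the origin)
#' is selected. Ties break to lower RM, then fewer feature classes.
#' Invariant to any positive affine rescaling of an objective.
#'
#' @param archive a ParetoArchive.
#' @return the archive with \code{@selected} set.
#' @export
selectCompromise <- function(archive) {
  tb <- archive@table
  fr <- which(tb$rank == 1L)
  stopifnot(length(fr) > 0L)
  Fm <- capInfinite(as.matrix(tb[fr, OBJ_NAMES]))
  rng <- apply(Fm, 2L, range)
  Fn <- sapply(seq_len(ncol(Fm)), function(j) {
    span <- rng[2L, j] - rng[1L, j]
    if (span <= 0) rep(0, nrow(Fm)) else (Fm[, j] - rng[1L, j]) / span
  })
  if (!is.matrix(Fn)) Fn <- matrix(Fn, nrow = length(fr))
  d <- sqrt(rowSums(Fn^2))
  nclasses <- nchar(tb$fc[fr])
  best <- order(d, tb$rm[fr], nclasses)[1L]
  archive@selected <- fr[best]
  archive
}

#' @describeIn selectCompromise the selected genotype as a list.
#' @export
selectedGenotype <- function(archive) {
  stopifnot(archive@selected > 0L)
  s <- archive@table[archive@selected, ]
  decodeGenotype(s$rm_index, s$fc_index)
}
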