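## Synthetic landscapes: seeded environmental fields, presences drawn from a
## known log-linear suitability surface, and log-normal livestock densities.
## These emulate the shape of real model inputs (smooth spatially
## autocorrelated covariates, clumped occurrences, zero-inflated densities)
## without any external rasters.

#' Specify a synthetic landscape
#'
#' @param n_rows,n_cols grid size (>= 8 each).
#' @param origin_lon,origin_lat north-west corner, degrees.
#' @param cell_size cell size in degrees (square cells).
#' @param variables named list; each element a list with \code{recipe}
#'   (one of \code{"gradient"}, \code{"gaussian-bumps"},
#'   \code{"smoothed-noise"}) and recipe parameters:
#'   \describe{
#'     \item{gradient}{\code{axis} = "x" (west-east, default) or "y"
#'       (north-south); values run 0 to 1.}
#'     \item{gaussian-bumps}{\code{n_bumps} (default 5), \code{width}
#'       in cells (default n_cols/6).}
#'     \item{smoothed-noise}{\code{width}: moving-average window in cells
#'       (odd, default 5).}
#'   }
#' @param nodata_fraction fraction of cells masked out (default 0).
#' @param seed integer; fixed seed gives identical output.
#' @return a \code{landscapeSpec} list.
#' @export
landscapeSpec <- function(n_rows, n_cols, variables,
                          origin_lon = 100, origin_lat = 45,
                          cell_size = 0.1, nodata_fraction = 0, seed = 1L) {
  stopifnot(n_rows >= 8L, n_cols >= 8L, cell_size > 0,
            nodata_fraction >= 0, nodata_fraction < 1,
            length(variables) >= 1L, !is.null(names(variables)))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 origin_lon = origin_lon, origin_lat = origin_lat,
                 cell_size = cell_size, variables = variables,
                 nodata_fraction = nodata_fraction, seed = as.integer(seed)),
            class = "landscapeSpec")
}

## 2-D moving-average smoother with edge renormalisation (no FFT): each cell
## becomes the mean of the w x w window clipped to the grid.
boxSmooth <- function(m, width) {
  if (width <= 1L) return(m)
  k <- (width - 1L) %/% 2L
  csum1 <- function(x) {        # running sum over rows with window clipping
    n <- nrow(x)
    cs <- apply(x, 2L, cumsum)
    top <- pmax(seq_len(n) - k - 1L, 0L)
    bot <- pmin(seq_len(n) + k, n)
    res <- cs[bot, , drop = FALSE]
    res[top > 0L, ] <- res[top > 0L, , drop = FALSE] - cs[top[top > 0L], , drop = FALSE]
    cnt <- bot - top
    sweep(res, 1L, cnt, "/")
  }
  t(csum1(t(csum1(m))))
}

makeField <- function(recipe, params, n_rows, n_cols) {
  switch(recipe,
    "gradient" = {
      axis <- params$axis %||% "x"
      if (identical(axis, "x"))
        matrix(rep((seq_len(n_cols) - 1) / (n_cols - 1), each = n_rows), n_rows)
      else
        matrix(rep((seq_len(n_rows) - 1) / (n_rows - 1), n_cols), n_rows)
    },
    "gaussian-bumps" = {
      nb <- params$n_bumps %||% 5L
      w <- params$width %||% max(2, n_cols / 6)
      rr <- matrix(seq_len(n_rows), n_rows, n_cols)
      cc <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
      f <- matrix(0, n_rows, n_cols)
      for (b in seq_len(nb)) {
        cy <- runif(1, 1, n_rows); cx <- runif(1, 1, n_cols)
        amp <- runif(1, 0.5, 1.5)
        f <- f + amp * exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * w^2))
      }
      f
    },
    "smoothed-noise" = {
      w <- params$width %||% 5L
      boxSmooth(matrix(rnorm(n_rows * n_cols), n_rows, n_cols), w)
    },
    stop("unknown field recipe: ", recipe)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic environmental stack
#'
#' Deterministic given the spec (which carries its own seed).
#'
#' @param spec a \code{\link{landscapeSpec}}.
#' @return An \linkS4class{EnvStack}; one layer per variable, shared grid,
#'   with \code{nodata_fraction} of cells masked in all layers.
#' @export
generateStack <- function(spec) {
  stopifnot(inherits(spec, "landscapeSpec"))
  withr_seed(spec$seed, {
    layers <- lapply(spec$variables, function(v)
      makeField(v$recipe, v, spec$n_rows, spec$n_cols))
    names(layers) <- names(spec$variables)
    if (spec$nodata_fraction > 0) {
      n <- spec$n_rows * spec$n_cols
      drop <- sample.int(n, round(spec$nodata_fraction * n))
      layers <- lapply(layers, function(m) { m[drop] <- NA_real_; m })
    }
    envStack(layers,
             c(spec$origin_lon, spec$origin_lat, spec$cell_size, spec$cell_size))
  })
}

## Evaluate a block with a local RNG state so generators are pure in (spec, seed).
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Sample presences from a known log-linear truth
#'
#' Cells are drawn with replacement with probability proportional to
#' \code{exp(score)}, where the score is \code{coefficients} applied to the
#' landscape-scaled (min-max) variables, plus optional quadratic terms.
#'
#' @param stack an EnvStack.
#' @param coefficients named numeric; weights on scaled linear features.
#' @param n_presences number of records (>= 0).
#' @param quad_coefficients optional named numeric on squared scaled values.
#' @param seed integer.
#' @param jitter if TRUE, add uniform sub-cell jitter (< cell/2) to the
#'   returned coordinates; default FALSE so cell bookkeeping stays exact.
#' @param species species label for the output.
#' @return data.frame: species, lon, lat, row, col.
#' @export
samplePresences <- function(stack, coefficients, n_presences,
                            quad_coefficients = NULL, seed = 1L,
                            jitter = FALSE, species = "synthetic") {
  stopifnot(all(names(coefficients) %in% layerNames(stack)))
  cells <- validCells(stack)
  if (nrow(cells) == 0L) stop("stack has no valid cells")
  if (n_presences == 0L)
    return(data.frame(species = character(), lon = numeric(), lat = numeric(),
                      row = integer(), col = integer()))
  vals <- extractCells(stack, cells)
  score <- rep(0, nrow(cells))
  for (nm in names(coefficients)) {
    v <- vals[, nm]
    s <- (v - min(v)) / (max(v) - min(v))
    score <- score + coefficients[[nm]] * s
    if (!is.null(quad_coefficients) && nm %in% names(quad_coefficients))
      score <- score + quad_coefficients[[nm]] * s^2
  }
  withr_seed(seed, {
    pick <- sample.int(nrow(cells), n_presences, replace = TRUE,
                       prob = exp(score - max(score)))
    ctr <- cellCenter(gridTransform(stack), cells[pick, 1L], cells[pick, 2L])
    if (jitter) {
      cs <- gridTransform(stack)[3:4]
      ctr$lon <- ctr$lon + runif(n_presences, -cs[1] / 2 + 1e-9, cs[1] / 2 - 1e-9)
      ctr$lat <- ctr$lat + runif(n_presences, -cs[2] / 2 + 1e-9, cs[2] / 2 - 1e-9)
    }
    data.frame(species = species, lon = ctr$lon, lat = ctr$lat,
               row = cells[pick, 1L], col = cells[pick, 2L])
  })
}

#' Generate a synthetic livestock-density raster
#'
#' Positive densities are log-normal (smoothed for spatial coherence);
#' a fixed fraction of valid cells is exactly zero, mimicking zero-inflated
#' head-count grids.
#'
#' @param spec a \code{\link{landscapeSpec}} (grid definition reused).
#' @param zero_fraction fraction of valid cells set to exactly 0.
#' @param seed integer.
#' @param meanlog,sdlog log-normal parameters of positive cells.
#' @return numeric matrix on the spec's grid (NA where the spec masks).
#' @export
generateDensity <- function(spec, zero_fraction = 0.3, seed = 1L,
                            meanlog = 2, sdlog = 1) {
  stopifnot(zero_fraction >= 0, zero_fraction < 1)
  withr_seed(seed, {
    n <- spec$n_rows * spec$n_cols
    d <- matrix(exp(meanlog + sdlog * rnorm(n)), spec$n_rows, spec$n_cols)
    if (zero_fraction > 0) {
      z <- sample.int(n, round(zero_fraction * n))
      d[z] <- 0
    }
    d
  })
}

#' Perturb a stack into a simple "scenario"
#'
#' Additive and/or multiplicative shifts per layer; stands in for future
#' climate scenarios when exercising projection, MESS and change mapping.
#'
#' @param stack an EnvStack.
#' @param add named numeric of additive offsets (missing layers: 0).
#' @param mul named numeric of multipliers (missing layers: 1).
#' @return a new EnvStack on the same grid.
#' @export
perturbStack <- function(stack, add = NULL, mul = NULL) {
  pick <- function(v, nm, default) {
    if (!is.null(v) && nm %in% names(v)) v[[nm]] else default
  }
  layers <- lapply(layerNames(stack), function(nm) {
    m <- getLayer(stack, nm)
    m * pick(mul, nm, 1) + pick(add, nm, 0)
  })
  envStack(setNames(layers, layerNames(stack)), gridTransform(stack))
}

#' Write occurrences as CSV (species, lon, lat)
#' @param occ data.frame with species, lon, lat.
#' @param path output file.
#' @export
writeOccurrences <- function(occ, path) {
  write.csv(occ[, c("species", "lon", "lat")], path, row.names = FALSE)
  invisible(path)
}

#' Read occurrences from CSV (species, lon, lat)
#' @param path CSV path.
#' @return data.frame with species, lon, lat.
#' @export
readOccurrences <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df))) stop("occurrence CSV must have species,lon,lat")
  df[, need]
}
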