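#' @import methods
#' @importFrom stats cor pt sd lm rnorm runif quantile setNames aggregate complete.cases var
#' @importFrom utils combn read.csv write.csv head
#' @useDynLib enmopt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Mean Earth radius (km), spherical model used for all areas and distances.
EARTH_RADIUS_KM <- 6371.0088
NODATA_VALUE <- -9999

#' Grid-aligned environmental raster stack
#'
#' An \code{EnvStack} holds one or more named 2-D layers on a shared
#' north-up geographic (WGS84) grid, together with a single nodata mask
#' that is the union of per-layer invalidity. Row 1 is the northernmost
#' row; all coordinates refer to cell centers.
#'
#' @slot layers named list of numeric matrices, all the same dimension.
#' @slot transform numeric(4): \code{origin_lon}, \code{origin_lat}
#'   (north-west corner of the grid), \code{cell_size_x},
#'   \code{cell_size_y} in decimal degrees.
#' @slot mask logical matrix, \code{TRUE} where any layer is nodata.
#' @slot crs character, fixed to \code{"WGS84"}.
#' @export
setClass("EnvStack",
  representation(layers = "list", transform = "numeric",
                 mask = "matrix", crs = "character"),
  prototype(crs = "WGS84"))

setValidity("EnvStack", function(object) {
  msgs <- character()
  if (length(object@layers) < 1L) msgs <- c(msgs, "at least one layer required")
  if (is.null(names(object@layers)) || anyDuplicated(names(object@layers)))
    msgs <- c(msgs, "layers must have unique names")
  dims <- lapply(object@layers, dim)
  if (length(unique(dims)) > 1L) msgs <- c(msgs, "all layers must share one shape")
  if (length(object@transform) != 4L || any(!is.finite(object@transform)))
    msgs <- c(msgs, "transform must be 4 finite numbers")
  if (length(object@transform) == 4L && any(object@transform[3:4] <= 0))
    msgs <- c(msgs, "cell sizes must be positive")
  if (!identical(dim(object@mask), dim(object@layers[[1L]])))
    msgs <- c(msgs, "mask shape must match layers")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EnvStack from matrices
#'
#' @param layers named list of numeric matrices (same shape). Non-finite
#'   cells and cells equal to \code{nodata} are treated as invalid.
#' @param transform numeric(4): north-west corner longitude and latitude,
#'   then cell sizes (degrees) in x and y.
#' @param nodata sentinel value marking invalid cells (default -9999).
#' @return An \linkS4class{EnvStack}. The nodata mask is the union of
#'   invalid cells over all layers; masked cells are set to \code{NA}
#'   in every layer.
#' @export
envStack <- function(layers, transform, nodata = NODATA_VALUE) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  layers <- lapply(layers, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m[!is.finite(m) | m == nodata] <- NA_real_
    m
  })
  mask <- Reduce(`|`, lapply(layers, is.na))
  layers <- lapply(layers, function(m) { m[mask] <- NA_real_; m })
  new("EnvStack", layers = layers, transform = as.numeric(transform),
      mask = mask, crs = "WGS84")
}

#' @describeIn envStack layer names in storage order.
#' @param x an EnvStack.
#' @export
layerNames <- function(x) names(x@layers)

#' @describeIn envStack number of layers.
#' @export
nLayers <- function(x) length(x@layers)

#' @describeIn envStack grid dimension \code{c(nrows, ncols)}.
#' @export
gridDim <- function(x) dim(x@layers[[1L]])

#' @describeIn envStack the 4-number transform.
#' @export
gridTransform <- function(x) x@transform

#' @describeIn envStack logical matrix, TRUE where the cell is invalid.
#' @export
nodataMask <- function(x) x@mask

#' @describeIn envStack extract one layer as a matrix.
#' @param name layer name.
#' @export
getLayer <- function(x, name) {
  if (!name %in% names(x@layers)) stop("unknown layer: ", name)
  x@layers[[name]]
}

setMethod("show", "EnvStack", function(object) {
  d <- gridDim(object)
  cat("EnvStack:", nLayers(object), "layer(s),", d[1], "x", d[2], "cells\n")
  cat("  layers:", paste(layerNames(object), collapse = ", "), "\n")
  tr <- object@transform
  cat(sprintf("  origin (NW): %.4f, %.4f; cell %.5f x %.5f deg (%s)\n",
              tr[1], tr[2], tr[3], tr[4], object@crs))
  cat(sprintf("  valid cells: %d / %d\n", sum(!object@mask), length(object@mask)))
})

#' Cell-center coordinates
#'
#' @param transform the 4-number grid transform.
#' @param row,col 1-based indices (row 1 = northernmost); vectorised.
#' @return data.frame with \code{lon}, \code{lat} of cell centers.
#' @export
cellCenter <- function(transform, row, col) {
  data.frame(lon = transform[1] + (col - 0.5) * transform[3],
             lat = transform[2] - (row - 0.5) * transform[4])
}

#' Indices of valid cells
#'
#' @param stack an EnvStack.
#' @return integer matrix with columns \code{row}, \code{col}, in
#'   row-major (north-to-south, west-to-east) order.
#' @export
validCells <- function(stack) {
  ok <- which(t(!stack@mask))            # row-major ordering
  nc <- gridDim(stack)[2L]
  cbind(row = (ok - 1L) %/% nc + 1L, col = (ok - 1L) %% nc + 1L)
}

#' Extract per-cell values of every layer
#'
#' @param stack an EnvStack.
#' @param cells integer matrix (row, col).
#' @return numeric matrix, one column per layer, named.
#' @export
extractCells <- function(stack, cells) {
  idx <- cbind(cells[, 1L], cells[, 2L])
  out <- vapply(stack@layers, function(m) m[idx], numeric(nrow(idx)))
  if (nrow(idx) == 1L) out <- matrix(out, nrow = 1L,
                                     dimnames = list(NULL, layerNames(stack)))
  out
}

## ---- ASCII grid I/O -------------------------------------------------------
## Single-band rasters travel as ESRI ASCII grids: a 6-line header
## (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
## rows north to south. Values are written at full double precision so
## write -> read round-trips exactly.

#' Read one ESRI ASCII grid
#'
#' @param path file path.
#' @return list with \code{values} (matrix, NA = nodata) and
#'   \code{transform} (NW-corner convention, see \code{\link{envStack}}).
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  for (i in 1:6) {
    ln <- strsplit(trimws(readLines(con, 1L)), "\\s+")[[1L]]
    hdr[[tolower(ln[1L])]] <- as.numeric(ln[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header: ", path)
  vals <- scan(con, what = double(), quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("value count mismatch in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nd <- hdr$nodata_value
  if (!is.null(nd)) m[m == nd] <- NA_real_
  transform <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize,
                 hdr$cellsize, hdr$cellsize)
  list(values = m, transform = transform)
}

#' Write one ESRI ASCII grid
#'
#' @param values numeric matrix (NA written as the nodata value).
#' @param transform 4-number transform; x and y cell sizes must be equal.
#' @param path output file.
#' @param nodata nodata sentinel.
#' @export
writeAsciiGrid <- function(values, transform, path, nodata = NODATA_VALUE) {
  if (abs(transform[3] - transform[4]) > 1e-12)
    stop("ASCII grids require square cells")
  nr <- nrow(values); nc <- ncol(values)
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.12g", transform[1]),
           sprintf("yllcorner %.12g", transform[2] - nr * transform[4]),
           sprintf("cellsize %.12g", transform[3]),
           sprintf("NODATA_value %g", nodata))
  v <- values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read aligned single-band rasters into an EnvStack
#'
#' Refuses (rather than resamples) when grids disagree in shape or
#' transform: inputs are expected to be pre-aligned.
#'
#' @param paths character vector of ASCII-grid files.
#' @param names layer names, same length as \code{paths}.
#' @return An \linkS4class{EnvStack} with the union nodata mask.
#' @export
readStack <- function(paths, names = NULL) {
  if (is.null(names)) names <- sub("\\.[^.]*$", "", basename(paths))
  stopifnot(length(paths) == length(names))
  grids <- lapply(paths, readAsciiGrid)
  ref <- grids[[1L]]
  for (g in grids[-1L]) {
    if (!identical(dim(g$values), dim(ref$values)) ||
        max(abs(g$transform - ref$transform)) > 1e-9)
      stop("alignment error: input rasters do not share one grid")
  }
  envStack(setNames(lapply(grids, `[[`, "values"), names), ref$transform)
}

#' Write every layer of a stack as ASCII grids
#'
#' @param stack an EnvStack.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
writeStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(layerNames(stack), function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    writeAsciiGrid(getLayer(stack, nm), stack@transform, p)
    p
  }, character(1L))
  invisible(paths)
}

## ---- areas ----------------------------------------------------------------

#' Latitude-dependent pixel area
#'
#' Spherical-zone formula
#' \eqn{A = R^2 \Delta\lambda (\sin\phi_{top} - \sin\phi_{bottom})}
#' with R = 6371.0088 km; every column in a row has the same area.
#'
#' @param transform grid transform.
#' @param row row index (1-based, vectorised).
#' @return area per cell in km².
#' @export
pixelAreaKm2 <- function(transform, row) {
  lat_top <- transform[2] - (row - 1) * transform[4]
  lat_bot <- transform[2] - row * transform[4]
  if (any(abs(c(lat_top, lat_bot)) > 90 + 1e-9)) stop("cell edges beyond +/-90 latitude")
  dlon <- transform[3] * pi / 180
  EARTH_RADIUS_KM^2 * dlon * (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
}

#' Total area of one class in a coded raster
#'
#' @param class_raster integer-coded matrix (NA = nodata).
#' @param transform grid transform.
#' @param class_id the class to sum.
#' @return total km² of cells equal to \code{class_id}.
#' @export
classArea <- function(class_raster, transform, class_id) {
  counts <- rowSums(!is.na(class_raster) & class_raster == class_id)
  sum(counts * pixelAreaKm2(transform, seq_len(nrow(class_raster))))
}

#' Area of all valid cells
#' @param raster matrix with NA nodata.
#' @param transform grid transform.
#' @return km² of non-NA cells.
#' @export
validArea <- function(raster, transform) {
  counts <- rowSums(!is.na(raster))
  sum(counts * pixelAreaKm2(transform, seq_len(nrow(raster))))
}
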