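#' Create a grid geometry
#'
#' @param nrow,ncol grid dimensions (cells).
#' @param xmin,ymin lower-left corner of the extent (m).
#' @param cellsize cell edge length (m).
#' @return a [GridSpec-class].
#' @examples
#' g <- gridSpecify(100, 100, 0, 0, 500)
#' @export
gridSpecify <- function(nrow, ncol, xmin = 0, ymin = 0, cellsize = 1000) {
  new("GridSpec", nrow = as.integer(nrow), ncol = as.integer(ncol),
      xmin = as.numeric(xmin), ymin = as.numeric(ymin),
      cellsize = as.numeric(cellsize))
}

#' Construct a single-layer raster
#'
#' @param values numeric matrix (row 1 = north) or a single value recycled.
#' @param grid a [GridSpec-class].
#' @return a [RasterGrid-class].
#' @export
rasterGrid <- function(values, grid) {
  if (!is.matrix(values))
    values <- matrix(as.numeric(values), grid@nrow, grid@ncol)
  new("RasterGrid", values = values, grid = grid)
}

#' Construct a covariate stack
#'
#' @param layers named list of matrices (or \code{RasterGrid}s sharing a grid).
#' @param grid a [GridSpec-class]; inferred from the first \code{RasterGrid}
#'   if omitted.
#' @param standardization optional standardization record.
#' @return a [CovariateStack-class].
#' @export
covariateStack <- function(layers, grid = NULL,
                           standardization = emptyStandardization()) {
  if (length(layers) && methods::is(layers[[1]], "RasterGrid")) {
    if (is.null(grid)) grid <- layers[[1]]@grid
    layers <- lapply(layers, function(l) l@values)
  }
  new("CovariateStack", layers = layers, grid = grid,
      standardization = standardization)
}

emptyStandardization <- function() {
  data.frame(layer = character(), mean = numeric(), sd = numeric(),
             stringsAsFactors = FALSE)
}

## Cell-centre coordinate helpers.  Row 1 is the northern edge.
gridXCenters <- function(g) g@xmin + (seq_len(g@ncol) - 0.5) * g@cellsize
gridYCenters <- function(g) {
  ymax <- g@ymin + g@nrow * g@cellsize
  ymax - (seq_len(g@nrow) - 0.5) * g@cellsize
}

#' Cell-centre coordinates of every cell
#'
#' @param g a [GridSpec-class].
#' @return two-column matrix (x, y) in matrix (row-major by column) order
#'   matching \code{as.vector} of a value matrix.
#' @export
cellCenters <- function(g) {
  xs <- gridXCenters(g); ys <- gridYCenters(g)
  cbind(x = rep(xs, each = g@nrow), y = rep(ys, times = g@ncol))
}

## Map point coordinates to (row, col); points outside the extent get NA.
pointToCell <- function(g, xy) {
  xy <- as.matrix(xy)
  col <- floor((xy[, 1] - g@xmin) / g@cellsize) + 1
  ymax <- g@ymin + g@nrow * g@cellsize
  row <- floor((ymax - xy[, 2]) / g@cellsize) + 1
  ## points exactly on the max edge belong to the last cell
  col[xy[, 1] == g@xmin + g@ncol * g@cellsize] <- g@ncol
  row[xy[, 2] == g@ymin] <- g@nrow
  bad <- col < 1 | col > g@ncol | row < 1 | row > g@nrow
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' @describeIn gridSpec grid of a raster layer
setMethod("gridSpec", "RasterGrid", function(x) x@grid)
#' @describeIn gridSpec shared grid of a stack
setMethod("gridSpec", "CovariateStack", function(x) x@grid)

#' Grid geometry accessor
#' @param x a raster or stack.
#' @name gridSpec
NULL

#' Layer names of a covariate stack
#' @param x a [CovariateStack-class].
#' @name layerNames
NULL
#' @describeIn layerNames names of the layers
setMethod("layerNames", "CovariateStack", function(x) names(x@layers))

#' Extract one layer as a matrix
#' @param x a [CovariateStack-class].
#' @param name layer name.
#' @name getLayer
NULL
#' @describeIn getLayer layer as a value matrix
setMethod("getLayer", "CovariateStack", function(x, name) {
  if (!name %in% names(x@layers)) stop("unknown layer: ", name)
  x@layers[[name]]
})

#' Extract covariate values at point locations
#'
#' Nearest-cell (containing-cell) extraction on the projected grid.
#'
#' @param x a [CovariateStack-class] or [RasterGrid-class].
#' @param xy two-column matrix/data.frame of point coordinates (m).
#' @param layers layer names (stack only; default all).
#' @return data.frame of extracted values, one column per layer; rows for
#'   points outside the extent are NA.
#' @name extractValues
NULL

#' @describeIn extractValues extraction from a stack
setMethod("extractValues", "CovariateStack", function(x, xy, layers = NULL) {
  if (is.null(layers)) layers <- names(x@layers)
  rc <- pointToCell(x@grid, xy)
  idx <- (rc[, "col"] - 1L) * x@grid@nrow + rc[, "row"]
  out <- lapply(layers, function(nm) {
    m <- getLayer(x, nm)
    as.vector(m)[idx]
  })
  names(out) <- layers
  as.data.frame(out, optional = TRUE)
})

#' @describeIn extractValues extraction from a single raster
setMethod("extractValues", "RasterGrid", function(x, xy, layers = NULL) {
  rc <- pointToCell(x@grid, xy)
  idx <- (rc[, "col"] - 1L) * x@grid@nrow + rc[, "row"]
  as.vector(x@values)[idx]
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %g m, origin (%g, %g)\n",
              object@nrow, object@ncol, object@cellsize,
              object@xmin, object@ymin))
})

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("RasterGrid %d x %d (%g m cells): range [%g, %g]\n",
              nrow(v), ncol(v), object@grid@cellsize,
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

setMethod("show", "CovariateStack", function(object) {
  cat(sprintf("CovariateStack: %d layer(s) on a %d x %d grid (%g m cells)\n",
              length(object@layers), object@grid@nrow, object@grid@ncol,
              object@grid@cellsize))
  std <- object@standardization$layer
  for (nm in names(object@layers)) {
    v <- object@layers[[nm]]
    cat(sprintf("  %-22s [%.4g, %.4g]%s\n", nm,
                min(v, na.rm = TRUE), max(v, na.rm = TRUE),
                if (nm %in% std) " (standardized)" else ""))
  }
})
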