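#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text georeferenced raster interchange (readable by QGIS, ArcGIS
#' and GDAL).  NA cells are written as the NODATA value.
#'
#' @param x a [RasterGrid-class].
#' @param file output path (conventionally \code{.asc}).
#' @param nodata NODATA sentinel (default -9999).
#' @export
writeAsciiGrid <- function(x, file, nodata = -9999) {
  g <- x@grid
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g@ncol),
    sprintf("nrows %d", g@nrow),
    sprintf("xllcorner %.10g", g@xmin),
    sprintf("yllcorner %.10g", g@ymin),
    sprintf("cellsize %.10g", g@cellsize),
    sprintf("NODATA_value %g", nodata)), con)
  v <- x@values
  v[is.na(v)] <- nodata
  ## rows are written north to south, matching row 1 = north
  writeLines(apply(v, 1L, function(r) paste(format(r, digits = 9, trim = TRUE),
                                            collapse = " ")), con)
  invisible(file)
}

#' Read an ESRI ASCII grid
#'
#' @param file path to a \code{.asc} file.
#' @return a [RasterGrid-class]; NODATA cells become NA.
#' @export
readAsciiGrid <- function(file) {
  lines <- readLines(file)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  g <- gridSpecify(hdr$nrows, hdr$ncols, hdr$xllcorner, hdr$yllcorner,
                   hdr$cellsize)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = g@nrow, ncol = g@ncol, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  rasterGrid(m, g)
}

#' Write point or line features as GeoJSON
#'
#' Coordinates are projected metres; the CRS is whatever the run
#' configuration records (GeoJSON itself is CRS-agnostic since RFC 7946).
#'
#' @param features for \code{type = "points"} a two-column coordinate
#'   matrix; for \code{"lines"} a list of two-column coordinate matrices;
#'   for \code{"polygons"} a list of closed rings.
#' @param file output path.
#' @param type one of \code{"points"}, \code{"lines"}, \code{"polygons"}.
#' @param properties optional data.frame of per-feature properties.
#' @export
writeGeoJSON <- function(features, file, type = c("points", "lines", "polygons"),
                         properties = NULL) {
  type <- match.arg(type)
  geom <- switch(type,
    points = lapply(seq_len(nrow(features)), function(i)
      list(type = "Point", coordinates = as.numeric(features[i, 1:2]))),
    lines = lapply(features, function(m)
      list(type = "LineString",
           coordinates = lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, 1:2])))),
    polygons = lapply(features, function(m)
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, 1:2]))))))
  feats <- lapply(seq_along(geom), function(i) {
    props <- if (is.null(properties)) setNames(list(), character(0)) else
      as.list(properties[i, , drop = FALSE])
    list(type = "Feature", geometry = geom[[i]], properties = props)
  })
  obj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), file)
  invisible(file)
}

#' Read GeoJSON point or line features
#'
#' @param file GeoJSON path.
#' @return for points a coordinate matrix; for lines/polygons a list of
#'   coordinate matrices.
#' @export
readGeoJSON <- function(file) {
  obj <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  geoms <- lapply(obj$features, `[[`, "geometry")
  types <- vapply(geoms, `[[`, "", "type")
  toMat <- function(coords)
    do.call(rbind, lapply(coords, function(p) as.numeric(unlist(p))))
  if (all(types == "Point")) {
    m <- do.call(rbind, lapply(geoms, function(gm) as.numeric(unlist(gm$coordinates))))
    colnames(m) <- c("x", "y")
    m
  } else if (all(types == "LineString")) {
    lapply(geoms, function(gm) toMat(gm$coordinates))
  } else if (all(types == "Polygon")) {
    lapply(geoms, function(gm) toMat(gm$coordinates[[1]]))
  } else stop("mixed or unsupported geometry types")
}

#' Read/write a flat key-value configuration file
#'
#' One \code{key = value} pair per line; \code{#} starts a comment.
#' Values that parse as numbers become numeric.
#'
#' @param file path.
#' @return named list of values.
#' @export
readKeyValue <- function(file) {
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname readKeyValue
#' @param x named list to write.
#' @export
writeKeyValue <- function(x, file) {
  lines <- vapply(names(x), function(k) {
    v <- x[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 15, trim = TRUE), collapse = ","))
  }, "")
  writeLines(lines, file)
  invisible(file)
}
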