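# Minimal GeoJSON plumbing for the point/polygon features this package
# exchanges (subsector centroids, cluster maps, region boundaries). Features
# live in an abstract projected plane in meters, so no CRS member is written.

#' Write a set of points as a GeoJSON FeatureCollection
#'
#' @param df data frame with coordinate columns and any property columns.
#' @param path output file path.
#' @param x,y names of the coordinate columns.
#' @param properties character vector of column names to carry as feature
#'   properties (defaults to every non-coordinate column).
#' @return `path`, invisibly.
#' @export
write_points_geojson <- function(df, path, x = "x_m", y = "y_m",
                                 properties = setdiff(names(df), c(x, y))) {
  stopifnot(is.data.frame(df), all(c(x, y) %in% names(df)))
  feats <- lapply(seq_len(nrow(df)), function(i) {
    props <- lapply(df[i, properties, drop = FALSE], function(v) {
      if (is.factor(v)) as.character(v) else v
    })
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(df[[x]][i], df[[y]][i])),
      properties = props
    )
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read the first Polygon from a GeoJSON file
#'
#' Accepts a bare Polygon geometry, a Feature, or a FeatureCollection; only
#' the outer ring of the first polygon is used.
#'
#' @param path GeoJSON file path.
#' @return two-column numeric matrix of ring vertices (x, y).
#' @export
read_polygon_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  geom <- switch(gj$type %||% "",
    Polygon = gj,
    Feature = gj$geometry,
    FeatureCollection = gj$features[[1]]$geometry,
    stop("not a GeoJSON Polygon, Feature, or FeatureCollection")
  )
  if (!identical(geom$type, "Polygon")) {
    stop("first geometry is not a Polygon")
  }
  ring <- geom$coordinates[[1]]
  m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  colnames(m) <- c("x", "y")
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
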