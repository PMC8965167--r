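#' Write a geography as GeoJSON FeatureCollections
#'
#' Writes `units.geojson` (Point centroids with `unit_id` and `dwellings`
#' properties), `streets.geojson` (LineString per edge), and `pois.geojson`
#' (Points) under `dir`. Coordinates are planar metres; consumers of these
#' files should treat them as a projected CRS.
#'
#' @param geo An [generate_geography()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_geography <- function(geo, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(units = file.path(dir, "units.geojson"),
             streets = file.path(dir, "streets.geojson"),
             pois = file.path(dir, "pois.geojson"))
  .write_fc(paths[["units"]], lapply(seq_len(nrow(geo$units)), function(i) {
    u <- geo$units[i, ]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(u$x, u$y)),
         properties = list(unit_id = u$unit_id, dwellings = u$dwellings))
  }))
  nodes <- geo$streets$nodes; edges <- geo$streets$edges
  .write_fc(paths[["streets"]], lapply(seq_len(nrow(edges)), function(i) {
    a <- match(edges$from[i], nodes$node_id)
    b <- match(edges$to[i], nodes$node_id)
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(c(nodes$x[a], nodes$y[a]),
                                            c(nodes$x[b], nodes$y[b]))),
         properties = list(from = edges$from[i], to = edges$to[i]))
  }))
  .write_fc(paths[["pois"]], lapply(seq_len(nrow(geo$pois)), function(i) {
    p <- geo$pois[i, ]
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(p$x, p$y)),
         properties = list(poi_id = p$poi_id))
  }))
  invisible(paths)
}

.write_fc <- function(path, features) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
}

#' Read a geography from GeoJSON files
#'
#' Inverse of [write_geography()]; accepts any conforming files (unit
#' centroids as Points with `unit_id`/`dwellings`, streets as LineStrings,
#' POIs as Points).
#'
#' @param dir Directory holding `units.geojson`, `streets.geojson`,
#'   `pois.geojson`.
#' @return A list with `units`, `streets` (`nodes`/`edges`), `pois`, as in
#'   [generate_geography()].
#' @export
read_geography <- function(dir) {
  uf <- jsonlite::read_json(file.path(dir, "units.geojson"))
  units <- do.call(rbind, lapply(uf$features, function(f) {
    data.frame(unit_id = f$properties$unit_id,
               x = f$geometry$coordinates[[1]],
               y = f$geometry$coordinates[[2]],
               dwellings = f$properties$dwellings)
  }))
  sf <- jsonlite::read_json(file.path(dir, "streets.geojson"))
  seg <- lapply(sf$features, function(f) {
    cc <- f$geometry$coordinates
    c(cc[[1]][[1]], cc[[1]][[2]], cc[[2]][[1]], cc[[2]][[2]])
  })
  seg <- do.call(rbind, seg)
  if (is.null(seg)) {
    streets <- list(nodes = data.frame(node_id = integer(0), x = numeric(0),
                                       y = numeric(0)),
                    edges = data.frame(from = integer(0), to = integer(0)))
  } else {
    pts <- rbind(seg[, 1:2, drop = FALSE], seg[, 3:4, drop = FALSE])
    key <- paste(pts[, 1], pts[, 2])
    uk <- !duplicated(key)
    nodes <- data.frame(node_id = seq_len(sum(uk)),
                        x = pts[uk, 1], y = pts[uk, 2])
    idx <- match(key, key[uk])
    m <- nrow(seg)
    streets <- list(nodes = nodes,
                    edges = data.frame(from = idx[seq_len(m)],
                                       to = idx[m + seq_len(m)]))
  }
  pf <- jsonlite::read_json(file.path(dir, "pois.geojson"))
  pois <- do.call(rbind, lapply(pf$features, function(f) {
    data.frame(poi_id = f$properties$poi_id,
               x = f$geometry$coordinates[[1]],
               y = f$geometry$coordinates[[2]])
  }))
  if (is.null(pois))
    pois <- data.frame(poi_id = character(0), x = numeric(0), y = numeric(0))
  if (is.null(units))
    units <- data.frame(unit_id = character(0), x = numeric(0),
                        y = numeric(0), dwellings = integer(0))
  list(units = units, streets = streets, pois = pois)
}

#' Write cohort or record tables as CSV with a column dictionary
#'
#' Dates are written ISO-8601; a JSON sidecar (`<name>.columns.json`)
#' records column names and types.
#'
#' @param x Data frame.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  dict <- lapply(x, function(col) class(col)[1])
  jsonlite::write_json(dict, paste0(sub("\\.csv$", "", path),
                                    ".columns.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
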