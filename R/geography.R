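#' Configuration for the synthetic geography generator
#'
#' Describes a square study region populated with areal units (centroids and
#' dwelling counts), a stylized street network, and points of interest (POIs).
#' All three layers follow a density gradient that decays with distance from
#' an urban core, emulating the open-data inputs (street network, destinations,
#' residential density) from which active-living-environment measures are
#' derived.
#'
#' @param extent_m Side length of the square study region, metres.
#' @param n_units Number of areal units to generate.
#' @param urban_core Numeric length-2, (x, y) of the density-gradient centre.
#'   Defaults to the centre of the extent.
#' @param street_style One of `"grid"`, `"radial"`, `"sparse-rural"`.
#' @param street_spacing_m Characteristic spacing of the street network,
#'   metres (grid cell size, ring spacing, or rural node spacing).
#' @param poi_intensity_core,poi_intensity_edge Expected POIs per square
#'   kilometre at the core and at the maximal distance from it.
#' @param dwelling_core,dwelling_edge Expected dwellings per areal unit at the
#'   core and edge.
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce identical layers.
#' @return An object of class `geography_config`.
#' @export
geography_config <- function(extent_m = 2000, n_units = 100,
                             urban_core = NULL,
                             street_style = c("grid", "radial", "sparse-rural"),
                             street_spacing_m = 100,
                             poi_intensity_core = 60, poi_intensity_edge = 5,
                             dwelling_core = 400, dwelling_edge = 50,
                             seed = 1L) {
  street_style <- match.arg(street_style)
  if (!is.numeric(extent_m) || length(extent_m) != 1 || extent_m <= 0)
    stop("invalid config: `extent_m` must be a single positive number")
  if (n_units < 0) stop("invalid config: `n_units` must be >= 0")
  if (poi_intensity_core < 0 || poi_intensity_edge < 0)
    stop("invalid config: POI intensities must be >= 0")
  if (dwelling_core < 0 || dwelling_edge < 0)
    stop("invalid config: dwelling gradient must be >= 0")
  if (street_spacing_m <= 0)
    stop("invalid config: `street_spacing_m` must be > 0")
  if (is.null(urban_core)) urban_core <- c(extent_m / 2, extent_m / 2)
  structure(list(extent_m = extent_m, n_units = as.integer(n_units),
                 urban_core = as.numeric(urban_core),
                 street_style = street_style,
                 street_spacing_m = street_spacing_m,
                 poi_intensity_core = poi_intensity_core,
                 poi_intensity_edge = poi_intensity_edge,
                 dwelling_core = dwelling_core,
                 dwelling_edge = dwelling_edge,
                 seed = as.integer(seed)),
            class = "geography_config")
}

# Deterministic per-layer sub-seed from the root seed. Keeps partial re-runs
# reproducible and layers independent. Result stays below 2^31.
.sub_seed <- function(seed, layer) {
  (as.double(seed) * 7919 + layer * 104729) %% 2147483629
}

# Exponential-decay weight in [0, 1] with distance from the core;
# w = 1 at the core, exp(-3) at the maximal distance.
.core_weight <- function(x, y, core, extent) {
  corners <- rbind(c(0, 0), c(extent, 0), c(0, extent), c(extent, extent))
  dmax <- max(sqrt((corners[, 1] - core[1])^2 + (corners[, 2] - core[2])^2))
  d <- sqrt((x - core[1])^2 + (y - core[2])^2)
  exp(-3 * d / dmax)
}

#' Generate a synthetic geography
#'
#' Produces the three layers the ALE metrics consume: areal units with
#' centroids and dwelling counts, a stylized street network (nodes + edges),
#' and a POI point layer. Unit placement, dwelling counts, and POI intensity
#' all decay with distance from `urban_core`; the street network is uniform
#' for the `"grid"` style and core-concentrated for `"radial"` and
#' `"sparse-rural"`.
#'
#' @param config A [geography_config()].
#' @return A list of class `ale_geography` with elements `units`
#'   (data frame: `unit_id`, `x`, `y`, `dwellings`), `streets` (list with
#'   `nodes` data frame `node_id`, `x`, `y` and `edges` data frame
#'   `from`, `to`), and `pois` (data frame `poi_id`, `x`, `y`).
#' @export
generate_geography <- function(config) {
  if (!inherits(config, "geography_config"))
    stop("invalid config: expected a `geography_config`")
  ext <- config$extent_m
  core <- config$urban_core

  units <- .gen_units(config)
  streets <- .gen_streets(config)
  pois <- .gen_pois(config)

  structure(list(units = units, streets = streets, pois = pois,
                 config = config),
            class = "ale_geography")
}

.gen_units <- function(config) {
  ext <- config$extent_m; core <- config$urban_core
  n <- config$n_units
  set.seed(.sub_seed(config$seed, 1))
  if (n == 0) {
    return(data.frame(unit_id = character(0), x = numeric(0), y = numeric(0),
                      dwellings = integer(0)))
  }
  # Rejection sampling: acceptance probability floors at 0.2 so rural edges
  # stay populated while density still declines outward.
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2 * (n - length(xs)), 32)
    cx <- stats::runif(m, 0, ext); cy <- stats::runif(m, 0, ext)
    keep <- stats::runif(m) < (0.2 + 0.8 * .core_weight(cx, cy, core, ext))
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  xs <- xs[seq_len(n)]; ys <- ys[seq_len(n)]
  lam <- config$dwelling_edge +
    (config$dwelling_core - config$dwelling_edge) *
      .core_weight(xs, ys, core, ext)
  data.frame(unit_id = sprintf("U%04d", seq_len(n)), x = xs, y = ys,
              dwellings = stats::rpois(n, lam))
}

.gen_streets <- function(config) {
  ext <- config$extent_m; s <- config$street_spacing_m
  set.seed(.sub_seed(config$seed, 2))
  switch(config$street_style,
    "grid" = .streets_grid(ext, s),
    "radial" = .streets_radial(ext, s, config$urban_core),
    "sparse-rural" = .streets_rural(ext, s, config$urban_core))
}

.streets_grid <- function(ext, s) {
  ax <- seq(0, ext, by = s)
  g <- expand.grid(x = ax, y = ax)
  n <- length(ax)
  nodes <- data.frame(node_id = seq_len(nrow(g)), x = g$x, y = g$y)
  idx <- function(i, j) (j - 1L) * n + i    # i along x, j along y
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  right <- ij[ij$i < n, ]
  up <- ij[ij$j < n, ]
  edges <- rbind(
    data.frame(from = idx(right$i, right$j), to = idx(right$i + 1L, right$j)),
    data.frame(from = idx(up$i, up$j), to = idx(up$i, up$j + 1L)))
  list(nodes = nodes, edges = edges)
}

.streets_radial <- function(ext, s, core) {
  rmax <- min(core[1], core[2], ext - core[1], ext - core[2])
  radii <- seq(s, max(rmax, s), by = s)
  n_spokes <- 12L
  ang <- 2 * pi * (seq_len(n_spokes) - 1L) / n_spokes
  # centre node + ring x spoke lattice
  nodes <- data.frame(node_id = 1L, x = core[1], y = core[2])
  id <- function(r_i, s_i) 1L + (r_i - 1L) * n_spokes + s_i
  for (r_i in seq_along(radii)) {
    nodes <- rbind(nodes, data.frame(
      node_id = id(r_i, seq_len(n_spokes)),
      x = core[1] + radii[r_i] * cos(ang),
      y = core[2] + radii[r_i] * sin(ang)))
  }
  edges <- NULL
  for (s_i in seq_len(n_spokes)) {
    chain <- c(1L, id(seq_along(radii), s_i))
    edges <- rbind(edges, data.frame(from = chain[-length(chain)],
                                     to = chain[-1]))
  }
  for (r_i in seq_along(radii)) {
    ring <- id(r_i, seq_len(n_spokes))
    edges <- rbind(edges, data.frame(from = ring, to = c(ring[-1], ring[1])))
  }
  keep <- nodes$x >= 0 & nodes$x <= ext & nodes$y >= 0 & nodes$y <= ext
  kept_ids <- nodes$node_id[keep]
  edges <- edges[edges$from %in% kept_ids & edges$to %in% kept_ids, ]
  list(nodes = nodes[keep, ], edges = edges)
}

.streets_rural <- function(ext, s, core) {
  # A sparse meandering network: core-weighted random nodes joined by a
  # nearest-neighbour chain; degrees stay low so few >=3-way intersections.
  n <- max(2L, as.integer(round((ext / s)^2 / 8)))
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2 * (n - length(xs)), 16)
    cx <- stats::runif(m, 0, ext); cy <- stats::runif(m, 0, ext)
    keep <- stats::runif(m) < (0.15 + 0.85 * .core_weight(cx, cy, core, ext))
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  xs <- xs[seq_len(n)]; ys <- ys[seq_len(n)]
  nodes <- data.frame(node_id = seq_len(n), x = xs, y = ys)
  # greedy nearest-unvisited chain
  visited <- 1L; remaining <- setdiff(seq_len(n), visited)
  edges <- NULL; cur <- 1L
  while (length(remaining)) {
    d <- (xs[remaining] - xs[cur])^2 + (ys[remaining] - ys[cur])^2
    nxt <- remaining[which.min(d)]
    edges <- rbind(edges, data.frame(from = cur, to = nxt))
    cur <- nxt
    remaining <- setdiff(remaining, nxt)
  }
  list(nodes = nodes, edges = edges)
}

.gen_pois <- function(config) {
  ext <- config$extent_m; core <- config$urban_core
  set.seed(.sub_seed(config$seed, 3))
  area_km2 <- (ext / 1000)^2
  lam_core <- config$poi_intensity_core
  lam_edge <- config$poi_intensity_edge
  if (lam_core <= 0 && lam_edge <= 0) {
    return(data.frame(poi_id = character(0), x = numeric(0), y = numeric(0)))
  }
  # Inhomogeneous Poisson process by thinning a homogeneous process at the
  # dominating intensity.
  lam_max <- max(lam_core, lam_edge)
  m <- stats::rpois(1, lam_max * area_km2)
  if (m == 0) {
    return(data.frame(poi_id = character(0), x = numeric(0), y = numeric(0)))
  }
  px <- stats::runif(m, 0, ext); py <- stats::runif(m, 0, ext)
  lam <- lam_edge + (lam_core - lam_edge) * .core_weight(px, py, core, ext)
  keep <- stats::runif(m) < lam / lam_max
  px <- px[keep]; py <- py[keep]
  data.frame(poi_id = sprintf("P%05d", seq_along(px)), x = px, y = py)
}

#' @export
print.ale_geography <- function(x, ...) {
  cat("Synthetic geography (", x$config$street_style, " street style)\n",
      sep = "")
  cat("  extent:", x$config$extent_m, "m;",
      nrow(x$units), "areal units;",
      nrow(x$streets$nodes), "street nodes /", nrow(x$streets$edges),
      "edges;", nrow(x$pois), "POIs\n")
  invisible(x)
}
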