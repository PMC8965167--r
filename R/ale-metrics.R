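#' Identify street intersections (>= 3-way nodes)
#'
#' Merges street-network nodes closer than `snap_tolerance_m` (coincident
#' vertices are common in open street data), collapses duplicate edges
#' between the same node pair, drops self-loops, and computes node degree as
#' the number of distinct incident street approaches. A node is an
#' intersection when its degree is at least 3.
#'
#' @param streets List with `nodes` (data frame `node_id`, `x`, `y`) and
#'   `edges` (data frame `from`, `to` referencing `node_id`).
#' @param snap_tolerance_m Nodes closer than this (metres) are merged.
#' @return Data frame with one row per (merged) node: `node_id`, `x`, `y`,
#'   `degree`, `is_intersection`.
#' @export
count_intersections <- function(streets, snap_tolerance_m = 1) {
  nodes <- streets$nodes; edges <- streets$edges
  if (nrow(edges) > 0 &&
      (!all(edges$from %in% nodes$node_id) ||
       !all(edges$to %in% nodes$node_id)))
    stop("malformed network: edge references a missing node")
  n <- nrow(nodes)
  if (n == 0) {
    return(data.frame(node_id = integer(0), x = numeric(0), y = numeric(0),
                      degree = integer(0), is_intersection = logical(0)))
  }
  rep_of <- .snap_nodes(nodes$x, nodes$y, snap_tolerance_m)
  # map original node ids -> merged representative index
  idx <- rep_of[match(edges$from, nodes$node_id)]
  jdx <- rep_of[match(edges$to, nodes$node_id)]
  keep <- which(!duplicated(rep_of))  # representatives, in node order
  out <- data.frame(node_id = nodes$node_id[keep],
                    x = nodes$x[keep], y = nodes$y[keep])
  # distinct undirected edges among merged nodes, self-loops removed
  if (length(idx)) {
    a <- pmin(idx, jdx); b <- pmax(idx, jdx)
    ok <- a != b
    key <- paste(a[ok], b[ok])
    dup <- duplicated(key)
    a <- a[ok][!dup]; b <- b[ok][!dup]
    deg <- tabulate(c(a, b), nbins = n)
  } else {
    deg <- integer(n)
  }
  out$degree <- deg[rep_of[keep]]
  out$is_intersection <- out$degree >= 3L
  out
}

# Union nodes within `tol` of each other; returns for each node the index of
# its component representative (smallest index). Grid-bucket candidate search
# keeps this near-linear.
.snap_nodes <- function(x, y, tol) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (tol > 0 && n > 1) {
    cx <- floor(x / tol); cy <- floor(y / tol)
    key <- paste(cx, cy)
    buckets <- split(seq_len(n), key)
    lookup <- new.env(hash = TRUE)
    for (b in names(buckets)) assign(b, buckets[[b]], envir = lookup)
    for (i in seq_len(n)) {
      for (dx in -1:1) for (dy in -1:1) {
        kk <- paste(cx[i] + dx, cy[i] + dy)
        cand <- if (exists(kk, envir = lookup, inherits = FALSE))
          get(kk, envir = lookup) else integer(0)
        cand <- cand[cand > i]
        if (length(cand)) {
          close <- cand[sqrt((x[cand] - x[i])^2 + (y[cand] - y[i])^2) < tol]
          for (j in close) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
          }
        }
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Compute built-environment components within Euclidean buffers
#'
#' For each areal unit, counts >= 3-way street intersections and points of
#' interest whose Euclidean distance to the unit centroid is at most
#' `radius_m` (boundary inclusive), and attributes dwellings to the buffer.
#' Densities are counts divided by the buffer area in square kilometres.
#'
#' Dwellings are attributed from the unit layer: a unit's dwelling count
#' belongs to a buffer when that unit's centroid falls inside it. When a
#' dwelling point layer (`dwellings`, data frame `x`, `y` and optional
#' `count`) is supplied it is used instead, with the same in-buffer rule.
#'
#' @param units Data frame with `unit_id`, `x`, `y` and (for the centroid
#'   convention) `dwellings`.
#' @param node_table Output of [count_intersections()].
#' @param pois Data frame of POI points (`x`, `y`).
#' @param dwellings Optional dwelling point layer.
#' @param radius_m Buffer radius in metres (default 1000).
#' @return Data frame of class `ale_components`: `unit_id`,
#'   `intersection_count`, `intersection_density`, `poi_count`,
#'   `dwelling_density`, `buffer_radius_m`.
#' @export
compute_components <- function(units, node_table, pois, dwellings = NULL,
                               radius_m = 1000) {
  if (radius_m <= 0) stop("invalid input: `radius_m` must be > 0")
  if (!all(c("x", "y") %in% names(units)) || anyNA(units$x) || anyNA(units$y))
    stop("malformed unit: every unit needs centroid coordinates")
  area_km2 <- pi * (radius_m / 1000)^2
  inter <- node_table[node_table$is_intersection, , drop = FALSE]
  if (is.null(dwellings)) {
    dw_x <- units$x; dw_y <- units$y
    dw_n <- units$dwellings
    if (is.null(dw_n)) stop("malformed unit: `dwellings` column required")
  } else {
    dw_x <- dwellings$x; dw_y <- dwellings$y
    dw_n <- if (is.null(dwellings$count)) rep(1, nrow(dwellings))
            else dwellings$count
  }
  n <- nrow(units)
  ic <- integer(n); pc <- integer(n); dwell <- numeric(n)
  for (i in seq_len(n)) {
    ic[i] <- sum(.in_buffer(inter$x, inter$y, units$x[i], units$y[i], radius_m))
    pc[i] <- sum(.in_buffer(pois$x, pois$y, units$x[i], units$y[i], radius_m))
    inb <- .in_buffer(dw_x, dw_y, units$x[i], units$y[i], radius_m)
    dwell[i] <- sum(dw_n[inb])
  }
  out <- data.frame(unit_id = units$unit_id,
                    intersection_count = ic,
                    intersection_density = ic / area_km2,
                    poi_count = pc,
                    dwelling_density = dwell / area_km2,
                    buffer_radius_m = radius_m)
  class(out) <- c("ale_components", "data.frame")
  out
}

# Boundary-inclusive Euclidean membership; the single predicate shared by all
# three component computations.
.in_buffer <- function(px, py, cx, cy, r) {
  if (!length(px)) return(logical(0))
  (px - cx)^2 + (py - cy)^2 <= r^2
}

#' Order raw clusters into labelled ALE classes
#'
#' Maps raw k-medians cluster ids to ordered class labels 1..k (least to most
#' favourable for active living). The ordering score of a cluster is the sum
#' of its three standardized component medians; ties are broken by ascending
#' intersection-density median, then POI median, then dwelling median.
#'
#' @param km A [kmedians()] fit on the (possibly standardized) component
#'   matrix, columns in the order intersection density, POI count, dwelling
#'   density.
#' @param standardization List with `center` and `scale` (length-3) recording
#'   the transform applied before clustering; identity if clustering ran on
#'   raw scores.
#' @return List of class `ale_classification_raw`: `label` (per-observation
#'   ordered class), `ordering_score` (per class), `medians` (relabelled,
#'   clustering scale), `k`.
#' @export
order_and_label <- function(km, standardization = NULL) {
  k <- km$k
  if (length(unique(km$cluster)) < k)
    stop("invalid clustering: empty cluster")
  med <- km$medians
  if (is.null(standardization))
    standardization <- list(center = rep(0, ncol(med)),
                            scale = rep(1, ncol(med)))
  # medians are on the clustering scale; express them in standardized units
  z <- sweep(sweep(med, 2, standardization$center), 2,
             standardization$scale, "/")
  score <- rowSums(z)
  ord <- order(score, z[, 1], z[, 2], z[, 3])
  new_label <- integer(k)
  new_label[ord] <- seq_len(k)
  list(label = new_label[km$cluster],
       ordering_score = score[ord],
       medians = med[ord, , drop = FALSE],
       k = k)
}

#' Classify areal units into a 5-class ALE typology
#'
#' Full protocol: compute >= 3-way intersection density, POI count, and
#' dwelling density within `radius_m` Euclidean buffers of unit centroids;
#' z-score the three components (unless `standardize = FALSE`, which clusters
#' literal raw scores); cluster with k-medians; and relabel clusters 1..k in
#' ascending order of summed standardized medians, so class 1 is the least
#' and class k the most favourable for active living.
#'
#' @inheritParams compute_components
#' @param streets Street network (`nodes`/`edges`) as in
#'   [count_intersections()].
#' @param radius_m Buffer radius, metres.
#' @param k Number of classes.
#' @param standardize Z-score components before clustering (default TRUE);
#'   `FALSE` clusters raw scores.
#' @param snap_tolerance_m Node snap tolerance, metres.
#' @param seed,n_init,max_iter,tol Clustering hyperparameters, see
#'   [kmedians()].
#' @return Object of class `ale_classification`: `assignment` (data frame
#'   `unit_id`, `ale_class`), `components` (the [compute_components()]
#'   output), `medians` (clustering scale), `ordering_score`,
#'   `standardization`, and the hyperparameters used, for exact replay.
#' @export
classify_units <- function(units, streets, pois, dwellings = NULL,
                           radius_m = 1000, k = 5, standardize = TRUE,
                           snap_tolerance_m = 1, seed = 1L, n_init = 10L,
                           max_iter = 100L, tol = 1e-6) {
  nodes <- count_intersections(streets, snap_tolerance_m)
  comp <- compute_components(units, nodes, pois, dwellings, radius_m)
  x <- as.matrix(comp[, c("intersection_density", "poi_count",
                          "dwelling_density")])
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1   # constant component: leave centred
  std <- list(center = ctr, scale = scl)
  xs <- if (standardize) sweep(sweep(x, 2, ctr), 2, scl, "/") else x
  km <- kmedians(xs, k = k, seed = seed, n_init = n_init,
                 max_iter = max_iter, tol = tol)
  lab <- order_and_label(km, if (standardize)
    list(center = rep(0, 3), scale = rep(1, 3)) else std)
  structure(list(
    assignment = data.frame(unit_id = comp$unit_id, ale_class = lab$label),
    components = comp,
    medians = lab$medians,
    ordering_score = lab$ordering_score,
    standardization = std,
    standardized = standardize,
    params = list(radius_m = radius_m, k = k,
                  snap_tolerance_m = snap_tolerance_m, seed = seed,
                  n_init = n_init, max_iter = max_iter, tol = tol),
    objective = km$objective),
    class = "ale_classification")
}

#' @export
print.ale_classification <- function(x, ...) {
  cat("ALE classification: k =", x$params$k, "classes over",
      nrow(x$assignment), "units\n")
  print(table(class = x$assignment$ale_class))
  cat("ordering scores (class 1 .. k):",
      format(x$ordering_score, digits = 3), "\n")
  invisible(x)
}

#' Boxplots of the three ALE components by class
#'
#' @param x An `ale_classification`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.ale_classification <- function(x, ...) {
  comp <- x$components
  cls <- x$assignment$ale_class
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  graphics::boxplot(comp$poi_count ~ cls, xlab = "ALE class",
                    ylab = "points of interest", ...)
  graphics::boxplot(comp$dwelling_density ~ cls, xlab = "ALE class",
                    ylab = "dwellings per km2", ...)
  graphics::boxplot(comp$intersection_density ~ cls, xlab = "ALE class",
                    ylab = "intersections per km2", ...)
  invisible(x)
}
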