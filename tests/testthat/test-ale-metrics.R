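make_streets <- function(nodes, edges) list(nodes = nodes, edges = edges)

test_that("intersection detection follows the >=3-way definition", {
  # single straight segment: both endpoints degree 1
  s <- make_streets(data.frame(node_id = 1:2, x = c(0, 100), y = c(0, 0)),
                    data.frame(from = 1, to = 2))
  nt <- count_intersections(s)
  expect_equal(sum(nt$is_intersection), 0)

  # "+" network: centre degree 4, one intersection
  s <- make_streets(data.frame(node_id = 1:5,
                               x = c(0, -100, 100, 0, 0),
                               y = c(0, 0, 0, -100, 100)),
                    data.frame(from = c(1, 1, 1, 1), to = 2:5))
  nt <- count_intersections(s)
  expect_equal(sum(nt$is_intersection), 1)
  expect_equal(nt$degree[nt$is_intersection], 4)

  # 5x5 regular grid: 9 interior (deg 4) + 12 edge (deg 3) = 21
  g <- generate_geography(geography_config(extent_m = 400, n_units = 0,
                                           street_style = "grid",
                                           street_spacing_m = 100, seed = 1))
  nt <- count_intersections(g$streets)
  expect_equal(sum(nt$degree == 4), 9)
  expect_equal(sum(nt$degree == 3), 12)
  expect_equal(sum(nt$is_intersection), 21)
})

test_that("node snapping merges coincident vertices and duplicate edges", {
  # two segments meeting at (0,0) twice, second endpoint 0.5 m off; plus a
  # duplicated edge -- after snapping and dedup the centre has degree 3
  nodes <- data.frame(node_id = 1:5,
                      x = c(0, 0.0004, 100, -100, 0),
                      y = c(0, 0.0003, 0, 0, 100))
  edges <- data.frame(from = c(1, 2, 1, 1), to = c(3, 4, 5, 3))
  nt <- count_intersections(make_streets(nodes, edges), snap_tolerance_m = 1)
  expect_equal(nrow(nt), 4)  # 5 nodes, two merged
  expect_equal(max(nt$degree), 3)
  expect_equal(sum(nt$is_intersection), 1)

  expect_error(count_intersections(
    make_streets(nodes, data.frame(from = 1, to = 99))),
    "malformed network")
})

test_that("buffer membership is Euclidean and boundary-inclusive", {
  units <- data.frame(unit_id = "u1", x = 0, y = 0, dwellings = 10)
  pois <- data.frame(x = c(999, 1000, 1001), y = 0)
  nt <- count_intersections(make_streets(
    data.frame(node_id = 1, x = 0, y = 0), data.frame(from = integer(0),
                                                      to = integer(0))))
  comp <- compute_components(units, nt, pois, radius_m = 1000)
  expect_equal(comp$poi_count, 2)  # 999 and exactly 1000 in; 1001 out
  expect_equal(comp$intersection_count, 0)
  expect_equal(comp$dwelling_density, 10 / (pi * 1^2))

  expect_error(compute_components(data.frame(unit_id = "u", x = NA, y = 1,
                                             dwellings = 1),
                                  nt, pois), "malformed unit")
})

test_that("buffer counts agree with whole-network enumeration", {
  # centroid at the centre of the 5x5 grid; 1000 m covers every node
  g <- generate_geography(geography_config(extent_m = 400, n_units = 0,
                                           street_style = "grid",
                                           street_spacing_m = 100, seed = 1))
  nt <- count_intersections(g$streets)
  units <- data.frame(unit_id = "centre", x = 200, y = 200, dwellings = 0)
  comp <- compute_components(units, nt, data.frame(x = numeric(0),
                                                   y = numeric(0)))
  expect_equal(comp$intersection_count, sum(nt$is_intersection))
  expect_equal(comp$intersection_density, 21 / (pi * 1^2))
})

test_that("cluster ordering and labelling are deterministic and invariant", {
  km <- list(cluster = c(1L, 1L, 2L, 2L),
             medians = rbind(c(0.8, 0, 0), c(-1.2, 0, 0)),
             k = 2L)
  lab <- order_and_label(km)
  expect_equal(lab$label, c(2L, 2L, 1L, 1L))
  expect_true(all(diff(lab$ordering_score) > 0))

  # permuting raw cluster ids leaves final labels unchanged
  km2 <- list(cluster = c(2L, 2L, 1L, 1L),
              medians = km$medians[2:1, ], k = 2L)
  expect_equal(order_and_label(km2)$label, lab$label)

  km_empty <- list(cluster = c(1L, 1L, 1L, 1L), medians = km$medians, k = 2L)
  expect_error(order_and_label(km_empty), "empty cluster")
})

test_that("classification is translation-invariant and replayable", {
  g <- generate_geography(geography_config(extent_m = 3000, n_units = 60,
                                           seed = 5))
  cl1 <- classify_units(g$units, g$streets, g$pois, k = 3, n_init = 5,
                        seed = 11)
  # shift all coordinates by a constant
  g2 <- g
  g2$units$x <- g2$units$x + 5000; g2$units$y <- g2$units$y - 1234
  g2$streets$nodes$x <- g2$streets$nodes$x + 5000
  g2$streets$nodes$y <- g2$streets$nodes$y - 1234
  g2$pois$x <- g2$pois$x + 5000; g2$pois$y <- g2$pois$y - 1234
  cl2 <- classify_units(g2$units, g2$streets, g2$pois, k = 3, n_init = 5,
                        seed = 11)
  expect_equal(cl1$assignment, cl2$assignment)

  # re-running with the stored seed reproduces the assignment
  cl3 <- classify_units(g$units, g$streets, g$pois, k = 3,
                        n_init = cl1$params$n_init, seed = cl1$params$seed)
  expect_identical(cl1$assignment, cl3$assignment)
})

test_that("an all-zero component still permits clustering on the rest", {
  g <- generate_geography(geography_config(extent_m = 3000, n_units = 40,
                                           poi_intensity_core = 0,
                                           poi_intensity_edge = 0, seed = 8))
  cl <- classify_units(g$units, g$streets, g$pois, k = 3, n_init = 5)
  expect_equal(nrow(cl$assignment), 40)
  expect_true(all(cl$components$poi_count == 0))
  expect_equal(sort(unique(cl$assignment$ale_class)), 1:3)
})

test_that("components rise with ALE class on a core-gradient geography", {
  g <- generate_geography(geography_config(extent_m = 5000, n_units = 150,
                                           poi_intensity_core = 80,
                                           poi_intensity_edge = 2,
                                           dwelling_core = 500,
                                           dwelling_edge = 30, seed = 21))
  cl <- classify_units(g$units, g$streets, g$pois, k = 5, n_init = 10,
                       seed = 2)
  m <- merge(cl$assignment, cl$components, by = "unit_id")
  poi_means <- tapply(m$poi_count, m$ale_class, mean)
  dw_means <- tapply(m$dwelling_density, m$ale_class, mean)
  expect_true(all(diff(poi_means) > 0))
  expect_true(all(diff(dw_means) > 0))
})
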