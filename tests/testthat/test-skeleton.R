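test_that("two points give a single edge with their distance", {
  g <- build_neighbor_graph(tibble::tibble(x = c(0, 3), y = 0, z = c(0, 4)),
                            k = 1)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$w, 5)
})

test_that("collinear points connect after symmetrization and bridging", {
  g <- build_neighbor_graph(tibble::tibble(x = c(0, 1, 2), y = 0, z = 0),
                            k = 1)
  expect_setequal(paste(g$edges$i, g$edges$j),
                  c("1 2", "2 3"))
  expect_equal(sort(g$edges$w), c(1, 1))
})

test_that("disconnected clusters are bridged by the closest pair", {
  a <- cylinder_cloud(60, radius = 0.01, length = 0.05, seed = 1)
  b <- cylinder_cloud(60, radius = 0.01, length = 0.05,
                      base = c(1, 0, 0), seed = 2)
  cloud <- rbind(a, b)
  g <- build_neighbor_graph(cloud, k = 4)
  expect_gte(g$n_bridges, 1)
  # the bridge weight equals the brute-force minimal inter-cluster distance
  m <- as.matrix(cloud[, 1:3])
  cross <- as.matrix(dist(m))[1:60, 61:120]
  expect_true(any(abs(g$edges$w - min(cross)) < 1e-12))
})

test_that("Dijkstra distances and parents satisfy the tree relations", {
  g <- make_graph(4, rbind(c(1, 2, 1), c(2, 3, 1), c(1, 3, 3), c(3, 4, 1)))
  spt <- shortest_path_tree(g, 1)
  expect_equal(spt$dist, c(0, 1, 2, 3))
  expect_equal(spt$parent, c(NA, 1L, 2L, 3L))
  # path graph sanity
  g2 <- make_graph(3, rbind(c(1, 2, 1), c(2, 3, 1)))
  spt2 <- shortest_path_tree(g2, 1)
  expect_equal(spt2$dist, c(0, 1, 2))
  expect_equal(spt2$parent, c(NA, 1L, 2L))
})

test_that("Dijkstra matches exhaustive path enumeration on random graphs", {
  withr::with_seed(42, {
    for (rep in 1:60) {
      g <- random_small_graph(8)
      spt <- shortest_path_tree(g, 1)
      expect_equal(spt$dist, brute_force_dist(g, 1), tolerance = 1e-12)
      # per-vertex tree relation dist[v] = dist[parent] + w(parent, v)
      for (v in seq_len(g$n)[-1]) {
        p <- spt$parent[v]
        w <- g$edges$w[(g$edges$i == p & g$edges$j == v) |
                         (g$edges$i == v & g$edges$j == p)]
        expect_equal(spt$dist[v], spt$dist[p] + min(w), tolerance = 1e-9)
      }
    }
  })
})

test_that("a straight cylinder cloud condenses to a single centered chain", {
  cloud <- cylinder_cloud(2000, radius = 0.02, length = 0.5, seed = 3)
  g <- build_neighbor_graph(cloud, k = 10)
  src <- select_root_vertex(cloud)
  spt <- shortest_path_tree(g, src)
  skel <- extract_skeleton(cloud, spt, bin_length = 0.06)
  nd <- skel$nodes
  # single chain: each node has at most one child
  expect_true(all(table(nd$parent_id) == 1))
  # partition: every point in exactly one node
  expect_equal(sort(unname(unlist(split(seq_len(nrow(cloud)),
                                        skel$membership)))),
               seq_len(nrow(cloud)))
  expect_equal(length(skel$membership), nrow(cloud))
  # centroids lie near the true axis (x = y = 0)
  expect_lt(max(abs(nd$x)), 0.01)
  expect_lt(max(abs(nd$y)), 0.01)
  # geodesic monotonicity: children sit in bins at least as deep
  kid <- !is.na(nd$parent_id)
  expect_true(all(nd$bin[kid] >= nd$bin[nd$parent_id[kid]]))
})

test_that("a Y-shaped cloud yields one trunk that splits into two chains", {
  trunk <- cylinder_cloud(1500, radius = 0.02, length = 0.4, seed = 4)
  arm1 <- cylinder_cloud(1000, radius = 0.012, length = 0.3,
                         axis = c(0.6, 0, 0.8), base = c(0, 0, 0.4), seed = 5)
  arm2 <- cylinder_cloud(1000, radius = 0.012, length = 0.3,
                         axis = c(-0.6, 0, 0.8), base = c(0, 0, 0.4), seed = 6)
  cloud <- rbind(trunk, arm1, arm2)
  g <- build_neighbor_graph(cloud, k = 10)
  spt <- shortest_path_tree(g, select_root_vertex(cloud))
  skel <- extract_skeleton(cloud, spt, bin_length = 0.06)
  nd <- skel$nodes
  leaves <- setdiff(nd$node_id, nd$parent_id)
  # two main arms (a short wrap stub near the source may add a third leaf)
  expect_gte(length(leaves), 2)
  lx <- nd$x[nd$node_id %in% leaves]
  expect_true(any(lx > 0.1) && any(lx < -0.1))
})

test_that("the collar vertex is found near the true collar", {
  spec <- root_synth_spec(taproot_length = 0.5, taproot_basal_radius = 0.015,
                          n_first_order = 2, n_second_order_per_first = 0,
                          point_density = 15000, noise_sigma = 0, seed = 9)
  gen <- generate_root_system(spec)
  v <- select_root_vertex(gen$cloud)
  p <- unlist(gen$cloud[v, c("x", "y", "z")], use.names = FALSE)
  expect_lt(sqrt(sum(p^2)), 0.02) # collar is at the origin
  # tie rule: duplicated minimum z returns the lowest index
  flat <- tibble::tibble(x = c(0, 1, 2), y = 0, z = c(0, 0, 1))
  expect_equal(select_root_vertex(flat), 1L)
})

test_that("skeleton input validation", {
  cloud <- cylinder_cloud(200, seed = 8)
  g <- build_neighbor_graph(cloud, k = 6)
  spt <- shortest_path_tree(g, 1)
  expect_error(extract_skeleton(cloud, spt, bin_length = 0), "bin_length")
  expect_error(shortest_path_tree(g, 0), "source")
  expect_error(build_neighbor_graph(cloud[1, ]), "at least 2")
})
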