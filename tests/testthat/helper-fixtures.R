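# Shared in-code fixtures: clouds are generated, never stored.

# points on the lateral surface of a cylinder (optionally noisy)
cylinder_cloud <- function(n = 200, radius = 0.05, length = 0.4,
                           axis = c(0, 0, 1), base = c(0, 0, 0),
                           sigma = 0, seed = 1, regular_t = FALSE) {
  withr::with_seed(seed, {
    axis <- axis / sqrt(sum(axis^2))
    e1 <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * axis) * axis
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
    t <- if (regular_t) seq(0, length, length.out = n) else
      runif(n, 0, length)
    th <- runif(n, 0, 2 * pi)
    r <- radius + rnorm(n, 0, sigma)
    tibble::tibble(
      x = base[1] + t * axis[1] + r * (cos(th) * e1[1] + sin(th) * e2[1]),
      y = base[2] + t * axis[2] + r * (cos(th) * e1[2] + sin(th) * e2[2]),
      z = base[3] + t * axis[3] + r * (cos(th) * e1[3] + sin(th) * e2[3])
    )
  })
}

# hand-built weighted graph in the neighbor_graph container
make_graph <- function(n, edges) {
  structure(list(n = n,
                 edges = tibble::tibble(i = edges[, 1], j = edges[, 2],
                                        w = edges[, 3]),
                 n_bridges = 0L),
            class = "neighbor_graph")
}

# exhaustive shortest-path oracle: enumerate all simple paths (tiny graphs)
brute_force_dist <- function(graph, source) {
  adj <- vector("list", graph$n)
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[r]; j <- graph$edges$j[r]; w <- graph$edges$w[r]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  best <- rep(Inf, graph$n)
  walk <- function(v, visited, acc) {
    if (acc < best[v]) best[v] <<- acc
    nb <- adj[[v]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      u <- nb[r, 1]
      if (!visited[u]) {
        visited[u] <- TRUE
        walk(u, visited, acc + nb[r, 2])
        visited[u] <- FALSE
      }
    }
  }
  vis <- rep(FALSE, graph$n)
  vis[source] <- TRUE
  walk(source, vis, 0)
  best
}

# random connected weighted graph with <= n_max vertices
random_small_graph <- function(n_max = 8) {
  n <- sample(2:n_max, 1)
  # spanning tree for connectivity, then extra random edges
  edges <- cbind(2:n, vapply(2:n, function(v) sample(v - 1, 1), integer(1)))
  extra <- matrix(sample(n, 2 * sample(0:4, 1), replace = TRUE), ncol = 2)
  extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
  edges <- rbind(edges, extra)
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[!duplicated(edges), , drop = FALSE]
  make_graph(n, cbind(edges, runif(nrow(edges), 0.1, 2)))
}

# one-branch cylinder model built by hand (for closed-form trait checks)
single_cylinder_model <- function(radius = 0.05, length = 1.0) {
  cyl <- tibble::tibble(
    cyl_id = 1L, from_node = 1L, to_node = 2L,
    start_x = 0, start_y = 0, start_z = 0,
    end_x = 0, end_y = 0, end_z = length,
    radius = radius, rmse_fit = 0, flagged = FALSE,
    branch_id = 1L, order = 0L, length = length
  )
  br <- tibble::tibble(
    branch_id = 1L, order = 0L, parent_branch = NA_integer_,
    attach_node = 1L, attach_x = 0, attach_y = 0, attach_z = 0,
    basal_radius = radius, length = length, n_cylinders = 1L
  )
  skel <- structure(list(
    nodes = tibble::tibble(node_id = 1:2, x = 0, y = 0, z = c(0, length),
                           bin = 0:1, parent_id = c(NA, 1L),
                           n_points = c(1L, 1L)),
    membership = c(1L, 2L), root_node = 1L, bin_length = length
  ), class = "root_skeleton")
  structure(list(cylinders = cyl, branches = br,
                 segments = NULL, skeleton = skel),
            class = "root_model")
}
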