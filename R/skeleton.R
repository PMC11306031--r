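#' Build a symmetric k-nearest-neighbour graph over a cloud
#'
#' Edge weights are Euclidean distances in meters. The k-NN graph stands in
#' for a full 3D Delaunay triangulation: for surface-sampled clouds the two
#' give essentially the same geodesics at a fraction of the cost. If the
#' graph comes out disconnected (occlusion gaps), components are bridged by
#' repeatedly adding the single shortest edge between the currently smallest
#' component and the rest of the cloud until one component remains.
#'
#' @param data a cloud tibble with >= 2 points.
#' @param k neighbours per point (default 10).
#' @return an object of class `neighbor_graph`: a list with `n`, an `edges`
#'   tibble (`i`, `j`, `w`, `i < j`), and `n_bridges`.
#' @export
build_neighbor_graph <- function(data, k = 10) {
  data <- as_cloud(data)
  n <- nrow(data)
  if (n < 2) abort("build_neighbor_graph: need at least 2 points.")
  m <- cloud_matrix(data)
  nn <- .knn_cpp(m, as.integer(k))
  kk <- ncol(nn$idx)
  ii <- rep(seq_len(n), kk)
  jj <- as.vector(nn$idx)
  ww <- as.vector(nn$dist)
  # symmetrize and deduplicate (store i < j)
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  dup <- duplicated(cbind(a, b))
  edges <- tibble(i = a[!dup], j = b[!dup], w = ww[!dup])

  g <- igraph::graph_from_edgelist(cbind(edges$i, edges$j), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)
  n_bridges <- 0L
  while (comp$no > 1) {
    sizes <- comp$csize
    small <- which.min(sizes)
    in_small <- which(comp$membership == small)
    rest <- which(comp$membership != small)
    cp <- .closest_pair_cpp(m[in_small, , drop = FALSE], m[rest, , drop = FALSE])
    vi <- in_small[cp[1]]; vj <- rest[cp[2]]
    edges <- dplyr::bind_rows(edges, tibble(i = min(vi, vj), j = max(vi, vj), w = cp[3]))
    g <- igraph::add_edges(g, c(vi, vj))
    comp <- igraph::components(g)
    n_bridges <- n_bridges + 1L
  }
  structure(list(n = n, edges = edges, n_bridges = n_bridges),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("<neighbor_graph> ", x$n, " vertices, ", nrow(x$edges), " edges",
      if (x$n_bridges > 0) paste0(" (", x$n_bridges, " bridge edges)"), "\n",
      sep = "")
  invisible(x)
}

#' Pick the root-collar vertex of an inverted cloud
#'
#' After inversion the collar is the lowest, densest part of the cloud. The
#' rule: take the 1 cm z-slab with the most points among the slabs covering
#' the bottom of the cloud, then return the lowest-z point inside it (ties
#' broken by lowest point index).
#'
#' @param data an inverted cloud tibble (collar at low z).
#' @param slab_thickness slab height in meters (default 0.01).
#' @return the row index of the collar vertex.
#' @export
select_root_vertex <- function(data, slab_thickness = 0.01) {
  data <- as_cloud(data)
  z0 <- min(data$z)
  slab <- floor((data$z - z0) / slab_thickness)
  # densest of the lowest few slabs: the collar cross-section is the
  # thickest structure at the very bottom
  counts <- tabulate(slab[slab <= 2] + 1L, nbins = 3L)
  best_slab <- which.max(counts) - 1L
  in_slab <- which(slab == best_slab)
  in_slab[order(data$z[in_slab], in_slab)][1]
}

#' Add a synthetic source point at the collar center
#'
#' A geodesic source on the root *surface* distorts the first decimeters of
#' the shortest-path field: shells wrap around the taproot circumference and
#' the far side of the collar appears as a separate chain. Placing a single
#' synthetic anchor point on the collar axis, just below the lowest return,
#' makes the geodesic shells azimuthally symmetric rings from the start.
#' The anchor's x/y is the centroid of the bottom slab.
#'
#' @param data an inverted cloud tibble (collar at low z).
#' @param slab_thickness slab height used to localize the collar (m).
#' @return a list with `cloud` (input plus one appended anchor row) and
#'   `index` (the anchor's row index, to be used as the Dijkstra source).
#' @export
anchor_collar <- function(data, slab_thickness = 0.01) {
  data <- as_cloud(data)
  z0 <- min(data$z)
  # the collar is the thickest cross-section near the bottom: take the
  # densest slab in the lowest decimeter, not blindly the lowest returns
  # (a drooping lateral tip can undercut the collar)
  k <- floor((data$z - z0) / slab_thickness)
  counts <- tabulate(k[k <= 9] + 1L, nbins = 10L)
  best <- which.max(counts) - 1L
  slab <- k == best
  anchor <- tibble(x = mean(data$x[slab]), y = mean(data$y[slab]),
                   z = z0 + best * slab_thickness - 0.5 * slab_thickness)
  list(cloud = dplyr::bind_rows(data[, c("x", "y", "z")], anchor),
       index = nrow(data) + 1L,
       slab = which(slab))
}

# Connect a source vertex to an explicit set of target vertices, so the
# geodesic field starts from the whole collar ring rather than one side of
# it. The anchor stands for the collar cross-section, so its edge weights
# are offset to start at ~0: the ring then shares the first geodesic bin
# instead of trickling in one azimuth at a time.
add_source_edges <- function(graph, data, src, targets) {
  targets <- setdiff(targets, src)
  if (length(targets) == 0) return(graph)
  w <- sqrt((data$x[targets] - data$x[src])^2 +
            (data$y[targets] - data$y[src])^2 +
            (data$z[targets] - data$z[src])^2)
  w <- w - min(w) + 1e-6
  new <- tibble(i = pmin(targets, src), j = pmax(targets, src), w = w)
  all <- dplyr::bind_rows(graph$edges, new)
  dup <- duplicated(all[, c("i", "j")])
  graph$edges <- all[!dup, , drop = FALSE]
  graph
}

#' Dijkstra shortest-path tree from the collar vertex
#'
#' Computes per-vertex geodesic distance and predecessor along the
#' shortest-path tree rooted at `source`. Distances come from Dijkstra's
#' algorithm; the parent of each vertex is the neighbour `u` that attains
#' `dist[v] = dist[u] + w(u, v)` (smallest distance, then smallest index,
#' when several do).
#'
#' @param graph a `neighbor_graph`.
#' @param source source vertex index.
#' @return an object of class `shortest_path_tree`: list with `source`,
#'   `dist`, `parent` (NA at the source) and the originating `graph`.
#' @export
shortest_path_tree <- function(graph, source) {
  stopifnot(inherits(graph, "neighbor_graph"))
  source <- as.integer(source)
  if (source < 1 || source > graph$n) abort("shortest_path_tree: invalid source vertex.")
  g <- igraph::graph_from_edgelist(cbind(graph$edges$i, graph$edges$j),
                                   directed = FALSE)
  if (igraph::vcount(g) < graph$n) {
    g <- igraph::add_vertices(g, graph$n - igraph::vcount(g))
  }
  d <- as.vector(igraph::distances(g, v = source, weights = graph$edges$w,
                                   algorithm = "dijkstra"))
  if (any(!is.finite(d))) {
    abort("shortest_path_tree: graph is disconnected; bridge components first.")
  }
  # recover predecessors: u is a parent candidate of v if dist[u]+w == dist[v]
  ei <- c(graph$edges$i, graph$edges$j)
  ej <- c(graph$edges$j, graph$edges$i)
  ew <- rep(graph$edges$w, 2)
  ok <- d[ei] + ew <= d[ej] + 1e-9 * (1 + d[ej])
  cand_child <- ej[ok]
  cand_par <- ei[ok]
  ord <- order(cand_child, d[cand_par], cand_par)
  cand_child <- cand_child[ord]; cand_par <- cand_par[ord]
  parent <- rep(NA_integer_, graph$n)
  first <- !duplicated(cand_child)
  parent[cand_child[first]] <- cand_par[first]
  parent[source] <- NA_integer_
  structure(list(source = source, dist = d, parent = parent, graph = graph),
            class = "shortest_path_tree")
}

#' @export
print.shortest_path_tree <- function(x, ...) {
  cat("<shortest_path_tree> source ", x$source, ", ", length(x$dist),
      " vertices, max geodesic ", signif(max(x$dist), 4), " m\n", sep = "")
  invisible(x)
}

#' Condense a shortest-path tree into a curve skeleton
#'
#' Points are binned by geodesic distance from the collar
#' (`floor(dist / bin_length)`). Within each bin, points are split into
#' connected clusters of the neighbour graph restricted to the bin — distinct
#' roots passing through the same geodesic shell stay separate — and clusters
#' whose spatial extent exceeds `4 * bin_length` are further split by seeded
#' K-means. Each cluster becomes a skeleton node at its centroid; the node's
#' parent is the lower-bin node reached by walking the member points'
#' shortest-path predecessors (majority vote; ties to the spatially nearest
#' candidate).
#'
#' @param data the cloud the tree was built on.
#' @param spt a `shortest_path_tree`.
#' @param bin_length geodesic bin length in meters (> 0); the "height
#'   segmentation" knob.
#' @return an object of class `root_skeleton`: list with a `nodes` tibble
#'   (`node_id`, `x`, `y`, `z`, `bin`, `parent_id`, `n_points`),
#'   `membership` (node id per input point), `root_node`, `bin_length`.
#' @export
extract_skeleton <- function(data, spt, bin_length) {
  data <- as_cloud(data)
  stopifnot(inherits(spt, "shortest_path_tree"))
  if (!is.numeric(bin_length) || bin_length <= 0) {
    abort("extract_skeleton: `bin_length` must be > 0.")
  }
  n <- nrow(data)
  if (length(spt$dist) != n) {
    abort("extract_skeleton: shortest-path tree does not cover this cloud.")
  }
  m <- cloud_matrix(data)
  bin <- as.integer(floor(spt$dist / bin_length))

  # adjacency restricted to equal-bin endpoints
  eb_i <- spt$graph$edges$i
  eb_j <- spt$graph$edges$j
  same <- bin[eb_i] == bin[eb_j]

  membership <- integer(n)
  node_bin <- integer(0)
  node_members <- list()
  next_id <- 0L
  for (b in sort(unique(bin))) {
    vb <- which(bin == b)
    sel <- same & bin[eb_i] == b
    # local connected components on the bin's subgraph
    lid <- match(vb, vb)
    gi <- match(eb_i[sel], vb)
    gj <- match(eb_j[sel], vb)
    sub <- igraph::graph_from_edgelist(cbind(gi, gj), directed = FALSE)
    if (igraph::vcount(sub) < length(vb)) {
      sub <- igraph::add_vertices(sub, length(vb) - igraph::vcount(sub))
    }
    cl <- igraph::components(sub)$membership
    for (c0 in seq_len(max(cl))) {
      pts <- vb[cl == c0]
      pieces <- split_cluster(m[pts, , drop = FALSE], 4 * bin_length)
      for (p in pieces) {
        next_id <- next_id + 1L
        idx <- pts[p]
        membership[idx] <- next_id
        node_bin[next_id] <- b
        node_members[[next_id]] <- idx
      }
    }
  }

  n_nodes <- next_id
  cen <- t(vapply(node_members, function(ix) colMeans(m[ix, , drop = FALSE]),
                  numeric(3)))
  root_node <- membership[spt$source]

  # parent: walk each member's SPT predecessor chain down to a lower-bin node
  parent_id <- rep(NA_integer_, n_nodes)
  for (nd in seq_len(n_nodes)) {
    if (nd == root_node) next
    b <- node_bin[nd]
    votes <- integer(0)
    for (p0 in node_members[[nd]]) {
      p <- spt$parent[p0]
      steps <- 0L
      while (!is.na(p)) {
        nb <- membership[p]
        if (nb != nd && (node_bin[nb] < b || nb == root_node)) break
        p <- spt$parent[p]
        steps <- steps + 1L
        if (steps > n) abort("extract_skeleton: predecessor walk did not terminate.")
      }
      if (!is.na(p)) votes <- c(votes, membership[p])
    }
    if (length(votes) == 0) {
      # fell through to the source without leaving the node: attach to root
      parent_id[nd] <- root_node
      next
    }
    tb <- table(votes)
    top <- as.integer(names(tb)[tb == max(tb)])
    if (length(top) > 1) {
      dd <- colSums((t(cen[top, , drop = FALSE]) - cen[nd, ])^2)
      top <- top[order(dd, top)]
    }
    parent_id[nd] <- top[1]
  }

  nodes <- tibble(
    node_id = seq_len(n_nodes),
    x = cen[, 1], y = cen[, 2], z = cen[, 3],
    bin = node_bin,
    parent_id = parent_id,
    n_points = lengths(node_members)
  )
  structure(list(nodes = nodes, membership = membership,
                 root_node = root_node, bin_length = bin_length),
            class = "root_skeleton")
}

# Split a cluster with K-means until every piece's bounding-box diagonal
# (an upper bound on pairwise extent) is at most `max_extent`. Seeded for
# determinism. Returns a list of local index vectors.
split_cluster <- function(pts, max_extent) {
  extent <- function(p) {
    if (nrow(p) < 2) return(0)
    sqrt(sum((apply(p, 2, max) - apply(p, 2, min))^2))
  }
  if (extent(pts) <= max_extent) return(list(seq_len(nrow(pts))))
  for (k in 2:max(2L, nrow(pts))) {
    km <- withr::with_seed(0L, kmeans(pts, centers = min(k, nrow(pts)),
                                      nstart = 3, iter.max = 50))
    pieces <- split(seq_len(nrow(pts)), km$cluster)
    if (all(vapply(pieces, function(ix) extent(pts[ix, , drop = FALSE]),
                   numeric(1)) <= max_extent)) {
      return(unname(pieces))
    }
    if (k >= nrow(pts)) return(unname(pieces))
  }
  list(seq_len(nrow(pts)))
}

#' @export
print.root_skeleton <- function(x, ...) {
  cat("<root_skeleton> ", nrow(x$nodes), " nodes, bin_length ",
      x$bin_length, " m, root node ", x$root_node, "\n", sep = "")
  invisible(x)
}

#' @rdname extract_skeleton
#' @param x a `root_skeleton`.
#' @param ... unused.
#' @export
tidy.root_skeleton <- function(x, ...) x$nodes

#' Plot a skeleton as a projected line tree
#'
#' @param object a `root_skeleton`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.root_skeleton <- function(object, ...) {
  nd <- object$nodes
  seg <- dplyr::inner_join(
    dplyr::filter(nd, !is.na(.data$parent_id)),
    dplyr::select(nd, pid = "node_id", px = "x", py = "y", pz = "z"),
    by = c(parent_id = "pid")
  )
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$px, y = .data$pz,
                                       xend = .data$x, yend = .data$z),
                          linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "z (m)", title = "Root skeleton (x-z view)") +
    ggplot2::theme_minimal()
}
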