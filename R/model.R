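#' Build a cylinder model from a skeleton
#'
#' Fits one cylinder per skeleton edge by nonlinear least squares
#' ([fit_cylinder()]) on the member points of the edge's two endpoint nodes.
#' Cylinder endpoints are the two node centroids, so consecutive cylinders
#' chain exactly and total model length equals the skeleton polyline length.
#' Edges whose fit fails (too few points, no convergence) get their radius
#' interpolated along the branch from neighbouring successful fits and are
#' flagged. Chains between bifurcations become provisional branch segments;
#' call [assign_orders()] to merge continuations and grade branching orders.
#'
#' @param data the cloud the skeleton was extracted from.
#' @param skeleton a `root_skeleton`.
#' @param max_fit_points cap on points per cylinder fit (deterministic
#'   thinning of the member set; default 400).
#' @param trim_ratio drop member points farther than `trim_ratio` times the
#'   median axis distance before fitting, which keeps junction contamination
#'   from neighbouring roots out of the fit (default 2.5).
#' @return an object of class `root_model`; see [assign_orders()].
#' @export
model_from_skeleton <- function(data, skeleton, max_fit_points = 400,
                                trim_ratio = 2.5) {
  data <- as_cloud(data)
  stopifnot(inherits(skeleton, "root_skeleton"))
  nd <- skeleton$nodes
  if (nrow(nd) < 2) {
    abort("model_from_skeleton: skeleton has a single node; nothing to fit.")
  }
  m <- cloud_matrix(data)
  members <- split(seq_len(nrow(data)), skeleton$membership)
  cen <- as.matrix(nd[, c("x", "y", "z")])

  edges <- nd[!is.na(nd$parent_id), c("parent_id", "node_id")]
  names(edges) <- c("from", "to")

  fit_one <- function(from, to) {
    pts_idx <- c(members[[as.character(from)]], members[[as.character(to)]])
    p0 <- cen[from, ]
    dir <- cen[to, ] - p0
    if (vnorm(dir) < 1e-12) dir <- c(0, 0, 1)
    pts <- m[pts_idx, , drop = FALSE]
    # trim contamination far from the edge axis
    u <- dir / vnorm(dir)
    q <- sweep(pts, 2, p0)
    t <- q %*% u
    d <- sqrt(pmax(rowSums(q^2) - t^2, 0))
    keep <- d <= trim_ratio * max(stats::median(d), 1e-6)
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) > max_fit_points) {
      pts <- pts[round(seq(1, nrow(pts), length.out = max_fit_points)), ,
                 drop = FALSE]
    }
    fit <- tryCatch(
      fit_cylinder(pts, init_axis = list(point = p0, direction = dir)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      c(radius = NA_real_, rmse = NA_real_)
    } else {
      c(radius = fit$radius, rmse = fit$rmse_fit)
    }
  }
  fits <- t(mapply(fit_one, edges$from, edges$to))

  cylinders <- tibble(
    cyl_id = seq_len(nrow(edges)),
    from_node = edges$from,
    to_node = edges$to,
    start_x = cen[edges$from, 1], start_y = cen[edges$from, 2],
    start_z = cen[edges$from, 3],
    end_x = cen[edges$to, 1], end_y = cen[edges$to, 2],
    end_z = cen[edges$to, 3],
    radius = fits[, "radius"],
    rmse_fit = fits[, "rmse"],
    flagged = !is.finite(fits[, "radius"]),
    branch_id = NA_integer_,
    order = NA_integer_
  )
  # tip completion: node centroids sit half a bin short of the true extent,
  # so extend leaf cylinders to the farthest member point and the collar
  # cylinder back to the lowest collar point
  is_leaf <- !(cylinders$to_node %in% cylinders$from_node)
  for (i in which(is_leaf)) {
    u <- c(cylinders$end_x[i] - cylinders$start_x[i],
           cylinders$end_y[i] - cylinders$start_y[i],
           cylinders$end_z[i] - cylinders$start_z[i])
    if (vnorm(u) < 1e-9) next
    u <- u / vnorm(u)
    mem <- m[members[[as.character(cylinders$to_node[i])]], , drop = FALSE]
    t_max <- max(sweep(mem, 2, c(cylinders$end_x[i], cylinders$end_y[i],
                                 cylinders$end_z[i])) %*% u)
    if (t_max > 0) {
      cylinders$end_x[i] <- cylinders$end_x[i] + t_max * u[1]
      cylinders$end_y[i] <- cylinders$end_y[i] + t_max * u[2]
      cylinders$end_z[i] <- cylinders$end_z[i] + t_max * u[3]
    }
  }
  at_root <- cylinders$from_node == skeleton$root_node
  for (i in which(at_root)) {
    u <- c(cylinders$end_x[i] - cylinders$start_x[i],
           cylinders$end_y[i] - cylinders$start_y[i],
           cylinders$end_z[i] - cylinders$start_z[i])
    if (vnorm(u) < 1e-9) next
    u <- u / vnorm(u)
    mem <- m[members[[as.character(skeleton$root_node)]], , drop = FALSE]
    t_min <- min(sweep(mem, 2, c(cylinders$start_x[i], cylinders$start_y[i],
                                 cylinders$start_z[i])) %*% u)
    if (t_min < 0) {
      cylinders$start_x[i] <- cylinders$start_x[i] + t_min * u[1]
      cylinders$start_y[i] <- cylinders$start_y[i] + t_min * u[2]
      cylinders$start_z[i] <- cylinders$start_z[i] + t_min * u[3]
    }
  }
  cylinders$length <- sqrt((cylinders$end_x - cylinders$start_x)^2 +
                           (cylinders$end_y - cylinders$start_y)^2 +
                           (cylinders$end_z - cylinders$start_z)^2)

  segments <- decompose_segments(skeleton)
  structure(list(cylinders = cylinders, segments = segments,
                 branches = NULL, skeleton = skeleton),
            class = "root_model")
}

# Chains of skeleton edges between bifurcations. Returns list with a tibble
# (segment_id, parent_segment, attach_node, first_node) and `seg_of_edge`
# mapping each child node (edge = parent->node) to its segment.
decompose_segments <- function(skeleton) {
  nd <- skeleton$nodes
  kids <- split(nd$node_id[!is.na(nd$parent_id)],
                nd$parent_id[!is.na(nd$parent_id)])
  n_children <- function(v) length(kids[[as.character(v)]])
  seg_of_edge <- rep(NA_integer_, nrow(nd)) # indexed by child node id
  seg_parent <- integer(0)
  seg_attach <- integer(0)
  seg_first <- integer(0)
  next_seg <- 0L
  # queue of (start_child_node, parent_segment, attach_node)
  root <- skeleton$root_node
  queue <- lapply(kids[[as.character(root)]], function(c0)
    list(child = c0, parent_seg = NA_integer_, attach = root))
  while (length(queue) > 0) {
    job <- queue[[1]]; queue <- queue[-1]
    next_seg <- next_seg + 1L
    seg_parent[next_seg] <- job$parent_seg
    seg_attach[next_seg] <- job$attach
    seg_first[next_seg] <- job$child
    cur <- job$child
    repeat {
      seg_of_edge[cur] <- next_seg
      ch <- kids[[as.character(cur)]]
      if (length(ch) == 1) {
        cur <- ch
      } else {
        if (length(ch) > 1) {
          queue <- c(queue, lapply(ch, function(c0)
            list(child = c0, parent_seg = next_seg, attach = cur)))
        }
        break
      }
    }
  }
  list(
    table = tibble(segment_id = seq_len(next_seg),
                   parent_segment = seg_parent,
                   attach_node = seg_attach,
                   first_node = seg_first),
    seg_of_edge = seg_of_edge
  )
}

#' Assign branching orders bottom-up
#'
#' Grades the model from the collar upward: at every bifurcation the child
#' chain whose first cylinder has the largest fitted radius continues the
#' parent's branch and order (ties go to the chain with the smaller axis
#' direction change); every other child starts a new branch with order
#' parent + 1. The maximal order-0 path is the taproot. Failed cylinder fits
#' are back-filled by linear interpolation of radius along their branch, and
#' a tapering prior caps every cylinder at 1.2 times its predecessor's
#' radius (capped cylinders are flagged).
#'
#' @param model a `root_model` from [model_from_skeleton()].
#' @param continuation `"largest_radius"` (default) or `"longest_path"`:
#'   whether the thickest child chain or the one with the longest downstream
#'   path continues the parent branch.
#' @return the model with `branches` populated and per-cylinder `branch_id`
#'   and `order` filled in.
#' @export
assign_orders <- function(model,
                          continuation = c("largest_radius", "longest_path")) {
  continuation <- match.arg(continuation)
  stopifnot(inherits(model, "root_model"))
  segs <- model$segments$table
  seg_of_edge <- model$segments$seg_of_edge
  cyl <- model$cylinders
  n_seg <- nrow(segs)
  if (n_seg == 0) abort("assign_orders: model has no branch segments.")

  # cylinders of each segment in chain order
  cyl_seg <- seg_of_edge[cyl$to_node]
  ord_in_seg <- order(cyl_seg, cyl$cyl_id)
  cyls_of_seg <- split(cyl$cyl_id[ord_in_seg], cyl_seg[ord_in_seg])

  seg_children <- split(segs$segment_id[!is.na(segs$parent_segment)],
                        segs$parent_segment[!is.na(segs$parent_segment)])
  first_radius <- vapply(seq_len(n_seg), function(s) {
    cyl$radius[cyls_of_seg[[as.character(s)]][1]]
  }, numeric(1))
  # entry radius robust to junction contamination: median of the chain's
  # first three cylinders (the first one shares the bifurcation node's
  # mixed points)
  entry_radius <- vapply(seq_len(n_seg), function(s) {
    ids <- cyls_of_seg[[as.character(s)]]
    stats::median(cyl$radius[head(ids, 3)], na.rm = TRUE)
  }, numeric(1))
  own_length <- vapply(seq_len(n_seg), function(s) {
    sum(cyl$length[cyls_of_seg[[as.character(s)]]])
  }, numeric(1))
  # downstream path length per segment (children carry higher ids)
  subtree_length <- own_length
  for (s in rev(seq_len(n_seg))) {
    ch <- seg_children[[as.character(s)]]
    if (!is.null(ch)) subtree_length[s] <- own_length[s] + max(subtree_length[ch])
  }
  seg_score <- if (continuation == "largest_radius") entry_radius else
    subtree_length
  radius_tie_tol <- if (continuation == "largest_radius") 0.25 else 1e-9
  seg_dir <- function(s, which = c("last", "first")) {
    ids <- cyls_of_seg[[as.character(s)]]
    id <- if (match.arg(which) == "last") ids[length(ids)] else ids[1]
    v <- c(cyl$end_x[id] - cyl$start_x[id],
           cyl$end_y[id] - cyl$start_y[id],
           cyl$end_z[id] - cyl$start_z[id])
    v / max(vnorm(v), 1e-12)
  }
  pick_continuation <- function(cands, ref_dir) {
    r <- seg_score[cands]
    r[is.na(r)] <- -Inf
    best <- max(r)
    # radius estimates within the tie band are not reliably distinguishable
    # (junction contamination); inside it, taper plausibility applies — a
    # root of entry radius r runs for many multiples of r before vanishing,
    # so a thick chain that dead-ends immediately is a severed ring arc,
    # not the continuation — then the longest downstream path, then the
    # straighter chain
    tied <- cands[r >= best * (1 - radius_tie_tol)]
    if (length(tied) > 1) {
      plaus <- is.finite(entry_radius[tied]) &
        subtree_length[tied] >= 8 * entry_radius[tied]
      if (any(plaus)) tied <- tied[plaus]
    }
    if (length(tied) > 1) {
      sub <- subtree_length[tied]
      tied <- tied[sub >= max(sub) - 1e-9]
    }
    if (length(tied) > 1) {
      ang <- vapply(tied, function(s) {
        -sum(seg_dir(s, "first") * ref_dir) # smaller angle = larger dot
      }, numeric(1))
      tied <- tied[order(ang, tied)]
    }
    tied[1]
  }

  branch_of_seg <- rep(NA_integer_, n_seg)
  br_order <- integer(0); br_parent <- integer(0); br_attach <- integer(0)
  br_first_seg <- integer(0)
  next_branch <- 0L
  visited <- 0L

  # roots of the segment forest (normally one; several if the collar node
  # itself bifurcates — the thickest is the taproot, the rest order 1)
  root_segs <- segs$segment_id[is.na(segs$parent_segment)]
  queue <- list()
  if (length(root_segs) == 1) {
    queue[[1]] <- list(seg = root_segs, order = 0L, parent_branch = NA_integer_,
                       attach = segs$attach_node[root_segs])
  } else {
    tap <- pick_continuation(root_segs, c(0, 0, 1))
    queue[[1]] <- list(seg = tap, order = 0L, parent_branch = NA_integer_,
                       attach = segs$attach_node[tap])
    for (s in setdiff(root_segs, tap)) {
      queue[[length(queue) + 1L]] <- list(seg = s, order = 1L,
                                          parent_branch = 1L,
                                          attach = segs$attach_node[s])
    }
  }

  while (length(queue) > 0) {
    job <- queue[[1]]; queue <- queue[-1]
    next_branch <- next_branch + 1L
    br_order[next_branch] <- job$order
    br_parent[next_branch] <- job$parent_branch
    br_attach[next_branch] <- job$attach
    br_first_seg[next_branch] <- job$seg
    cur <- job$seg
    repeat {
      if (!is.na(branch_of_seg[cur])) abort("assign_orders: cyclic branch topology.")
      branch_of_seg[cur] <- next_branch
      visited <- visited + 1L
      if (visited > n_seg) abort("assign_orders: cyclic branch topology.")
      ch <- seg_children[[as.character(cur)]]
      if (is.null(ch) || length(ch) == 0) break
      cont <- pick_continuation(ch, seg_dir(cur, "last"))
      for (s in setdiff(ch, cont)) {
        queue[[length(queue) + 1L]] <- list(seg = s, order = job$order + 1L,
                                            parent_branch = next_branch,
                                            attach = segs$attach_node[s])
      }
      cur <- cont
    }
  }

  cyl$branch_id <- branch_of_seg[cyl_seg]
  cyl$order <- br_order[cyl$branch_id]
  # order cylinders within branch by construction order (chain order)
  cyl <- cyl[order(cyl$branch_id, cyl$cyl_id), , drop = FALSE]
  cyl$cyl_id <- seq_len(nrow(cyl))

  cyl <- backfill_radii(cyl)
  cyl <- taper_clamp(cyl)

  nd <- model$skeleton$nodes
  first_cyl <- cyl[!duplicated(cyl$branch_id), ]
  br <- tibble(
    branch_id = seq_len(next_branch),
    order = br_order,
    parent_branch = br_parent,
    attach_node = br_attach,
    attach_x = nd$x[br_attach], attach_y = nd$y[br_attach],
    attach_z = nd$z[br_attach],
    basal_radius = first_cyl$radius[match(seq_len(next_branch),
                                          first_cyl$branch_id)]
  )
  lens <- tapply(cyl$length, cyl$branch_id, sum)
  br$length <- as.numeric(lens[as.character(br$branch_id)])
  br$n_cylinders <- as.integer(table(factor(cyl$branch_id,
                                            levels = br$branch_id)))

  model$cylinders <- cyl
  model$branches <- br
  refine_attachments(model)
}

# Junction refinement: a side branch's first decimeters are welded to the
# parent surface, so its chain only separates some way above the true
# junction. Back-cast the branch's own axis onto nearby parent (and, where
# the bases of neighbouring roots are entangled, grandparent) axes, move
# the branch base to the closest-approach point, and reparent the branch
# when its axis clearly emanates from the grandparent instead. Recovers the
# hidden base length and a truer attachment position.
refine_attachments <- function(model) {
  cyl <- model$cylinders
  br <- model$branches

  # closest approach of the backward ray (p1, -v) with segment (q0, q1);
  # returns c(miss, t_child, s_par, J) or NULL
  backcast <- function(p1, v, q0, q1, max_back, allow_before = TRUE) {
    w <- q1 - q0
    lw <- vnorm(w)
    if (lw < 1e-9) return(NULL)
    w <- w / lw
    d0 <- p1 - q0
    a <- sum(v * w)
    denom <- 1 - a^2
    if (denom < 1e-6) return(NULL)
    t_child <- (a * sum(d0 * w) - sum(d0 * v)) / denom
    s_par <- (sum(d0 * w) - a * sum(d0 * v)) / denom
    if (t_child > 1e-6 || -t_child > max_back) return(NULL)
    # a hit behind a branch's own base is not on that branch at all
    if (s_par < (if (allow_before) -lw else 0) || s_par > 2 * lw) return(NULL)
    j <- q0 + s_par * w
    miss <- vnorm(p1 + t_child * v - j)
    c(miss, t_child, s_par, j)
  }
  cyl_ends <- function(k) {
    list(q0 = c(cyl$start_x[k], cyl$start_y[k], cyl$start_z[k]),
         q1 = c(cyl$end_x[k], cyl$end_y[k], cyl$end_z[k]))
  }

  for (i in seq_len(nrow(br))) {
    if (is.na(br$parent_branch[i])) next
    ix <- which(cyl$branch_id == br$branch_id[i])
    first <- ix[1]
    # the first cylinder is a chord from the parent axis; the branch's own
    # axis direction starts at that cylinder's end (the first own node)
    p1 <- c(cyl$end_x[first], cyl$end_y[first], cyl$end_z[first])
    k <- ix[min(3, length(ix))]
    v <- if (length(ix) >= 2) {
      c(cyl$end_x[k], cyl$end_y[k], cyl$end_z[k]) - p1
    } else {
      p1 - c(cyl$start_x[first], cyl$start_y[first], cyl$start_z[first])
    }
    if (vnorm(v) < 1e-9) next
    v <- v / vnorm(v)

    pj <- which(cyl$to_node == br$attach_node[i] &
                cyl$branch_id == br$parent_branch[i])
    if (length(pj) != 1) next
    max_back <- 8 * max(cyl$radius[pj], 0.02, na.rm = TRUE)
    # scan the parent chain near the base: the true junction can sit
    # several segments below the node where the chains first separate
    px <- which(cyl$branch_id == br$parent_branch[i])
    pmid_d <- sqrt((0.5 * (cyl$start_x[px] + cyl$end_x[px]) - p1[1])^2 +
                   (0.5 * (cyl$start_y[px] + cyl$end_y[px]) - p1[2])^2 +
                   (0.5 * (cyl$start_z[px] + cyl$end_z[px]) - p1[3])^2)
    hit_p <- NULL; p_cyl <- NA_integer_
    for (k2 in px[pmid_d <= max_back + 0.1]) {
      ce2 <- cyl_ends(k2)
      h <- backcast(p1, v, ce2$q0, ce2$q1, max_back,
                    allow_before = k2 != px[1])
      if (!is.null(h) && (is.null(hit_p) || h[1] < hit_p[1])) {
        hit_p <- h
        p_cyl <- k2
      }
    }

    # entangled bases: test whether the axis really emanates from the
    # grandparent chain instead of the recorded parent
    gp <- br$parent_branch[match(br$parent_branch[i], br$branch_id)]
    hit_g <- NULL; gp_cyl <- NA_integer_
    if (!is.na(gp)) {
      gx <- which(cyl$branch_id == gp)
      mid_d <- sqrt((0.5 * (cyl$start_x[gx] + cyl$end_x[gx]) - p1[1])^2 +
                    (0.5 * (cyl$start_y[gx] + cyl$end_y[gx]) - p1[2])^2 +
                    (0.5 * (cyl$start_z[gx] + cyl$end_z[gx]) - p1[3])^2)
      for (k2 in gx[mid_d <= max_back + 0.1]) {
        ce2 <- cyl_ends(k2)
        h <- backcast(p1, v, ce2$q0, ce2$q1, max_back)
        if (!is.null(h) && (is.null(hit_g) || h[1] < hit_g[1])) {
          hit_g <- h
          gp_cyl <- k2
        }
      }
    }

    use <- hit_p
    reparent <- FALSE
    if (!is.null(hit_g) &&
        (is.null(hit_p) || hit_g[1] < 0.8 * hit_p[1])) {
      use <- hit_g
      reparent <- TRUE
    }
    if (is.null(use)) next
    j <- use[4:6]
    cyl$start_x[first] <- j[1]
    cyl$start_y[first] <- j[2]
    cyl$start_z[first] <- j[3]
    cyl$length[first] <- vnorm(p1 - j)
    # the chord cylinder was fitted on junction-mixed points; its radius
    # follows the branch's own taper, so cap it by the next clean cylinder
    if (length(ix) >= 2 && is.finite(cyl$radius[ix[2]])) {
      cyl$radius[first] <- min(cyl$radius[first], cyl$radius[ix[2]])
    }
    br$attach_x[i] <- j[1]; br$attach_y[i] <- j[2]; br$attach_z[i] <- j[3]
    if (reparent) {
      br$parent_branch[i] <- gp
      br$attach_node[i] <- cyl$to_node[gp_cyl]
    }
  }

  # reparenting can change depths: recompute orders from the collar down
  ord <- rep(NA_integer_, nrow(br))
  ord[is.na(br$parent_branch)] <- 0L
  while (anyNA(ord)) {
    prog <- FALSE
    for (i in which(is.na(ord))) {
      p <- match(br$parent_branch[i], br$branch_id)
      if (!is.na(ord[p])) {
        ord[i] <- ord[p] + 1L
        prog <- TRUE
      }
    }
    if (!prog) abort("refine_attachments: branch parent links form a cycle.")
  }
  br$order <- ord
  cyl$order <- br$order[match(cyl$branch_id, br$branch_id)]

  lens <- tapply(cyl$length, cyl$branch_id, sum)
  br$length <- as.numeric(lens[as.character(br$branch_id)])
  model$cylinders <- cyl
  model$branches <- br
  model
}

# Interpolate missing radii along each branch; a branch with no successful
# fit falls back to the model-wide median radius.
backfill_radii <- function(cyl) {
  global_med <- stats::median(cyl$radius, na.rm = TRUE)
  for (b in unique(cyl$branch_id)) {
    ix <- which(cyl$branch_id == b)
    r <- cyl$radius[ix]
    if (!anyNA(r)) next
    good <- which(is.finite(r))
    if (length(good) == 0) {
      cyl$radius[ix] <- global_med
    } else if (length(good) == 1) {
      r[is.na(r)] <- r[good]
      cyl$radius[ix] <- r
    } else {
      cyl$radius[ix] <- stats::approx(good, r[good], xout = seq_along(r),
                                      rule = 2)$y
    }
  }
  cyl
}

# Tapering prior: cylinder radius <= 1.2 x predecessor radius, walking from
# the collar outwards (predecessor = previous cylinder in the branch, or the
# parent-branch cylinder ending at the attach node for a branch's first).
taper_clamp <- function(cyl, ratio = 1.2) {
  pred <- rep(NA_integer_, nrow(cyl))
  for (i in seq_len(nrow(cyl))) {
    b <- cyl$branch_id[i]
    prev <- which(cyl$branch_id == b & cyl$cyl_id < cyl$cyl_id[i])
    if (length(prev) > 0) {
      pred[i] <- max(prev)
    } else {
      j <- which(cyl$to_node == cyl$from_node[i] & cyl$branch_id != b)
      if (length(j) == 1) pred[i] <- j
    }
  }
  # process in an order where predecessors come first (cyl_id order works:
  # parents were emitted before children in the traversal)
  for (i in order(cyl$cyl_id)) {
    if (!is.na(pred[i])) {
      cap <- ratio * cyl$radius[pred[i]]
      if (is.finite(cap) && cyl$radius[i] > cap) {
        cyl$radius[i] <- cap
        cyl$flagged[i] <- TRUE
      }
    }
  }
  cyl
}

#' @export
print.root_model <- function(x, ...) {
  cat("<root_model> ", nrow(x$cylinders), " cylinders", sep = "")
  if (!is.null(x$branches)) {
    tab <- table(x$branches$order)
    cat(", ", nrow(x$branches), " branches (orders: ",
        paste(names(tab), tab, sep = ":", collapse = ", "), ")", sep = "")
  } else {
    cat(" (orders not yet assigned)")
  }
  cat("\n")
  invisible(x)
}

#' Tidy a root model into its cylinder table
#'
#' @param x a `root_model`.
#' @param ... unused.
#' @return a tibble with one row per cylinder.
#' @export
tidy.root_model <- function(x, ...) {
  dplyr::select(x$cylinders, "cyl_id", "branch_id", "order",
                "start_x", "start_y", "start_z",
                "end_x", "end_y", "end_z",
                "radius", "length", "rmse_fit", "flagged")
}

#' One-row summary of a root model
#'
#' @param x a `root_model` with orders assigned.
#' @param ... unused.
#' @export
glance.root_model <- function(x, ...) {
  cyl <- x$cylinders
  tibble(
    n_cylinders = nrow(cyl),
    n_branches = if (is.null(x$branches)) NA_integer_ else nrow(x$branches),
    max_order = if (is.null(x$branches)) NA_integer_ else max(x$branches$order),
    total_length_m = sum(cyl$length),
    total_volume_m3 = sum(pi * cyl$radius^2 * cyl$length),
    total_surface_m2 = sum(2 * pi * cyl$radius * cyl$length),
    n_flagged = sum(cyl$flagged)
  )
}

# order palette: taproot and 1st..4th order laterals
order_palette <- c("0" = "#8B5A2B", "1" = "#2E8B57", "2" = "#00CED1",
                   "3" = "#DC143C", "4" = "#1E5AA8")

#' Plot a root model projected to the x-z plane, colored by branching order
#'
#' @param object a `root_model` with orders assigned.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.root_model <- function(object, ...) {
  cyl <- object$cylinders
  if (all(is.na(cyl$order))) abort("autoplot.root_model: assign orders first.")
  cyl$order_f <- factor(pmin(cyl$order, 4))
  ggplot2::ggplot(cyl) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_x, y = .data$start_z,
                   xend = .data$end_x, yend = .data$end_z,
                   color = .data$order_f, linewidth = .data$radius)) +
    ggplot2::scale_color_manual(values = order_palette, name = "order") +
    ggplot2::scale_linewidth(range = c(0.3, 3), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "z (m)", title = "Root model (x-z view)") +
    ggplot2::theme_minimal()
}

#' Export a model's cylinders to CSV
#'
#' @param model a `root_model` with orders assigned.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_model_csv <- function(model, path) {
  utils::write.csv(tidy(model), path, row.names = FALSE)
  invisible(path)
}

#' Export a model as an OBJ mesh of cylinders colored by order
#'
#' Writes capped prisms (n-gon tubes) per cylinder, grouped by branching
#' order with brown/green/cyan/red/blue material names for orders 0-4.
#'
#' @param model a `root_model` with orders assigned.
#' @param path output OBJ path.
#' @param sides number of facets around each cylinder.
#' @return `path`, invisibly.
#' @export
write_model_obj <- function(model, path, sides = 12) {
  cyl <- model$cylinders
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# rootqsm cylinder model", con)
  voff <- 0L
  mats <- c("brown", "green", "cyan", "red", "blue")
  for (i in seq_len(nrow(cyl))) {
    s <- c(cyl$start_x[i], cyl$start_y[i], cyl$start_z[i])
    e <- c(cyl$end_x[i], cyl$end_y[i], cyl$end_z[i])
    u <- e - s
    if (vnorm(u) < 1e-9) next
    u <- u / vnorm(u)
    b1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    b1 <- b1 - sum(b1 * u) * u; b1 <- b1 / vnorm(b1)
    b2 <- c(u[2] * b1[3] - u[3] * b1[2], u[3] * b1[1] - u[1] * b1[3],
            u[1] * b1[2] - u[2] * b1[1])
    th <- 2 * pi * (seq_len(sides) - 1) / sides
    ring <- cyl$radius[i] * (outer(cos(th), b1) + outer(sin(th), b2))
    verts <- rbind(sweep(ring, 2, s, `+`), sweep(ring, 2, e, `+`))
    writeLines(paste0("usemtl ", mats[min(cyl$order[i], 4) + 1]), con)
    writeLines(sprintf("v %.6f %.6f %.6f", verts[, 1], verts[, 2], verts[, 3]), con)
    j <- seq_len(sides); jn <- c(seq(2, sides), 1)
    writeLines(sprintf("f %d %d %d %d", voff + j, voff + jn,
                       voff + sides + jn, voff + sides + j), con)
    voff <- voff + 2L * sides
  }
  invisible(path)
}
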