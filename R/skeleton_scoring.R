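# point-to-segment distances: points (n x 3) vs segment a-b
dist_point_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-12) {
    return(sqrt(rowSums(sweep(pts, 2, a)^2)))
  }
  tpar <- pmin(1, pmax(0, (sweep(pts, 2, a) %*% ab) / len2))
  proj <- cbind(a[1] + tpar * ab[1], a[2] + tpar * ab[2], a[3] + tpar * ab[3])
  sqrt(rowSums((pts - proj)^2))
}

#' Remove SSE regions from a skeleton
#'
#' Clears every foreground voxel within `radius` of any stick axis so that
#' only loop regions remain before tracing.
#'
#' @param grid a [skeleton_grid()]
#' @param sticks stick table
#' @param radius removal radius in Angstrom
#' @return the pruned `skeleton_grid`
#' @export
remove_sse_regions <- function(grid, sticks, radius = 2.5) {
  vox <- skeleton_voxels(grid)
  if (nrow(vox) == 0 || nrow(sticks) == 0) return(grid)
  pts <- as.matrix(vox[, c("x", "y", "z")])
  drop <- rep(FALSE, nrow(pts))
  for (k in seq_len(nrow(sticks))) {
    a <- c(sticks$x0[k], sticks$y0[k], sticks$z0[k])
    b <- c(sticks$x1[k], sticks$y1[k], sticks$z1[k])
    drop <- drop | (dist_point_segment(pts, a, b) <= radius)
  }
  occ <- grid$occ
  occ[cbind(vox$ix[drop], vox$iy[drop], vox$iz[drop])] <- 0L
  skeleton_grid(occ, grid$spacing, grid$origin)
}

#' Reduce a skeleton grid to centroid clusters
#'
#' Greedy clustering of foreground voxels: a cluster starts at a random
#' unassigned voxel; while some unassigned voxel lies within
#' `cluster_radius` of the running centroid, the nearest one is added and
#' the centroid recomputed. The partition depends on the seed, which is why
#' it is a required, reproducibility-logged argument.
#'
#' @param grid a [skeleton_grid()]
#' @param cluster_radius growth radius in Angstrom
#' @param rng_seed integer seed for the random cluster seeds
#' @return a tibble of clusters: `cluster`, centroid `x, y, z`, `size`, and
#'   a `members` list column of voxel coordinate matrices
#' @export
reduce_skeleton <- function(grid, cluster_radius = 2.0, rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is required for reproducibility", call. = FALSE)
  vox <- skeleton_voxels(grid)
  if (nrow(vox) == 0) {
    return(tibble(cluster = integer(), x = double(), y = double(), z = double(),
                  size = integer(), members = list()))
  }
  set.seed(rng_seed)
  pts <- as.matrix(vox[, c("x", "y", "z")])
  n <- nrow(pts)
  unassigned <- rep(TRUE, n)
  clusters <- list()
  while (any(unassigned)) {
    open <- which(unassigned)
    seed_idx <- if (length(open) == 1) open else sample(open, 1)
    members <- seed_idx
    unassigned[seed_idx] <- FALSE
    centroid <- pts[seed_idx, ]
    repeat {
      open <- which(unassigned)
      if (length(open) == 0) break
      d <- sqrt(colSums((t(pts[open, , drop = FALSE]) - centroid)^2))
      ok <- d <= cluster_radius
      if (!any(ok)) break
      add <- open[ok][which.min(d[ok])]
      members <- c(members, add)
      unassigned[add] <- FALSE
      centroid <- colMeans(pts[members, , drop = FALSE])
    }
    clusters[[length(clusters) + 1L]] <- list(centroid = centroid, members = members)
  }
  tibble(
    cluster = seq_along(clusters),
    x = vapply(clusters, function(cl) cl$centroid[1], double(1)),
    y = vapply(clusters, function(cl) cl$centroid[2], double(1)),
    z = vapply(clusters, function(cl) cl$centroid[3], double(1)),
    size = vapply(clusters, function(cl) length(cl$members), integer(1)),
    members = lapply(clusters, function(cl) pts[cl$members, , drop = FALSE])
  )
}

new_skel_graph <- function(nodes, edges, anchors = NULL) {
  structure(list(nodes = nodes, edges = edges, anchors = anchors),
            class = "skel_graph")
}

#' @export
print.skel_graph <- function(x, ...) {
  cat("<skel_graph>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges",
      if (!is.null(x$anchors)) paste0(", ", nrow(x$anchors), " anchors"), "\n")
  invisible(x)
}

#' Build the skeleton graph from centroid clusters
#'
#' Two cluster centroids are linked iff some voxel of one cluster lies
#' within `link_cutoff` of some voxel of the other; the edge weight is the
#' Euclidean distance between the centroids.
#'
#' @param clusters cluster table from [reduce_skeleton()]
#' @param link_cutoff inter-cluster voxel distance (strictly less than)
#' @return a `skel_graph`: node tibble (`node, x, y, z, members`) and edge
#'   tibble (`from, to, weight`)
#' @export
build_skelg <- function(clusters, link_cutoff = 3.0) {
  nodes <- tibble(node = clusters$cluster, x = clusters$x, y = clusters$y,
                  z = clusters$z, members = clusters$members)
  n <- nrow(nodes)
  from <- integer(0); to <- integer(0); w <- double(0)
  if (n > 1) {
    for (a in seq_len(n - 1)) {
      ma <- nodes$members[[a]]
      for (b in (a + 1):n) {
        mb <- nodes$members[[b]]
        # min inter-cluster voxel distance
        dmin <- min(vapply(seq_len(nrow(ma)), function(r) {
          min(sqrt(colSums((t(mb) - ma[r, ])^2)))
        }, double(1)))
        if (dmin < link_cutoff) {
          from <- c(from, a); to <- c(to, b)
          w <- c(w, sqrt(sum((c(nodes$x[a], nodes$y[a], nodes$z[a]) -
                              c(nodes$x[b], nodes$y[b], nodes$z[b]))^2)))
        }
      }
    }
  }
  new_skel_graph(nodes, tibble(from = from, to = to, weight = w))
}

#' Merge dense cliques of the skeleton graph
#'
#' Maximal cliques of size `min_clique` or more (Bron-Kerbosch, via igraph)
#' mark crowded regions; each is replaced by one node at the geometric
#' center of all member-cluster voxels. Cliques are processed in decreasing
#' size and nodes already absorbed are excluded from later cliques. An edge
#' between two merged nodes exists iff some original edge connected their
#' member sets; weights are recomputed as centroid distances.
#'
#' @param g a `skel_graph`
#' @param min_clique smallest clique size to merge
#' @return the reduced `skel_graph`
#' @export
merge_cliques <- function(g, min_clique = 3L) {
  if (nrow(g$edges) == 0) return(g)
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = g$nodes$node))
  cl <- igraph::max_cliques(ig, min = min_clique)
  if (length(cl) == 0) return(g)
  cl <- lapply(cl, function(x) as.integer(names(x)))
  sizes <- lengths(cl)
  ord <- order(-sizes, vapply(cl, min, integer(1)))
  absorbed <- integer(0)
  groups <- list()
  for (k in ord) {
    members <- cl[[k]]
    if (any(members %in% absorbed)) next
    groups[[length(groups) + 1L]] <- members
    absorbed <- c(absorbed, members)
  }
  if (length(groups) == 0) return(g)

  # group id per original node: merged groups first, singletons after
  gid <- setNames(rep(NA_integer_, nrow(g$nodes)), g$nodes$node)
  for (k in seq_along(groups)) gid[as.character(groups[[k]])] <- k
  singles <- g$nodes$node[is.na(gid)]
  gid[as.character(singles)] <- length(groups) + seq_along(singles)
  n_new <- length(groups) + length(singles)

  members_of <- vector("list", n_new)
  for (r in seq_len(nrow(g$nodes))) {
    gg <- gid[[as.character(g$nodes$node[r])]]
    members_of[[gg]] <- rbind(members_of[[gg]], g$nodes$members[[r]])
  }
  cent <- t(vapply(members_of, colMeans, double(3)))
  nodes <- tibble(node = seq_len(n_new), x = cent[, 1], y = cent[, 2],
                  z = cent[, 3], members = members_of)

  ef <- gid[as.character(g$edges$from)]
  et <- gid[as.character(g$edges$to)]
  keep <- ef != et
  pairs <- unique(cbind(pmin(ef[keep], et[keep]), pmax(ef[keep], et[keep])))
  w <- sqrt(rowSums((cent[pairs[, 1], , drop = FALSE] -
                     cent[pairs[, 2], , drop = FALSE])^2))
  new_skel_graph(nodes, tibble(from = as.integer(pairs[, 1]),
                               to = as.integer(pairs[, 2]), weight = w))
}

skelg_degree <- function(g) {
  tabulate(c(g$edges$from, g$edges$to), nbins = nrow(g$nodes))
}

#' Bridge gaps between skeleton trace ends
#'
#' Gaps in the skeleton break loop traces. Any two end nodes (degree one)
#' at most `gap_cutoff` apart are joined by a new edge weighted with their
#' Euclidean distance.
#'
#' @param g a `skel_graph`
#' @param gap_cutoff maximum bridged distance in Angstrom
#' @return the `skel_graph` with bridge edges added
#' @export
bridge_gaps <- function(g, gap_cutoff = 10.0) {
  deg <- skelg_degree(g)
  # a gap end has one neighbor; a fully orphaned fragment (degree 0) is an
  # end in both directions and is eligible too
  ends <- which(deg <= 1L)
  if (length(ends) < 2) return(g)
  have <- paste(pmin(g$edges$from, g$edges$to), pmax(g$edges$from, g$edges$to))
  add_f <- integer(0); add_t <- integer(0); add_w <- double(0)
  for (a in seq_along(ends)[-length(ends)]) {
    for (b in (a + 1):length(ends)) {
      na <- ends[a]; nb <- ends[b]
      d <- sqrt((g$nodes$x[na] - g$nodes$x[nb])^2 +
                (g$nodes$y[na] - g$nodes$y[nb])^2 +
                (g$nodes$z[na] - g$nodes$z[nb])^2)
      if (d <= gap_cutoff && !(paste(min(na, nb), max(na, nb)) %in% have)) {
        add_f <- c(add_f, na); add_t <- c(add_t, nb); add_w <- c(add_w, d)
      }
    }
  }
  if (length(add_f) == 0) return(g)
  new_skel_graph(g$nodes,
                 dplyr::bind_rows(g$edges,
                                  tibble(from = add_f, to = add_t, weight = add_w)),
                 g$anchors)
}

#' Mark stick-endpoint anchors on the skeleton graph
#'
#' For each stick endpoint (`p0` and `p1`) the nearest graph node is marked
#' as that endpoint's anchor; traces are searched between anchors.
#'
#' @param g a `skel_graph`
#' @param sticks stick table
#' @return the `skel_graph` with an `anchors` tibble (`j`, `end`, `node`)
#' @export
mark_endpoints <- function(g, sticks) {
  if (nrow(g$nodes) == 0) stop("cannot mark endpoints on an empty skeleton graph",
                               call. = FALSE)
  rows <- list()
  for (k in seq_len(nrow(sticks))) {
    for (end in 0:1) {
      p <- stick_endpoint(sticks, sticks$j[k], end)
      d <- sqrt((g$nodes$x - p[1])^2 + (g$nodes$y - p[2])^2 + (g$nodes$z - p[3])^2)
      rows[[length(rows) + 1L]] <- tibble(j = sticks$j[k], end = end,
                                          node = g$nodes$node[which.min(d)])
    }
  }
  g$anchors <- dplyr::bind_rows(rows)
  g
}

anchor_node <- function(g, j, end) {
  row <- g$anchors[g$anchors$j == j & g$anchors$end == end, ]
  if (nrow(row) != 1) stop("anchor for stick ", j, " end ", end, " not marked",
                           call. = FALSE)
  row$node
}

# bounded DFS over simple paths; returns min |cost - s_len| or Inf
trace_fit <- function(g, from, to, s_len, slack = 20, max_nodes = 60L) {
  adj <- vector("list", nrow(g$nodes))
  for (r in seq_len(nrow(g$edges))) {
    f <- g$edges$from[r]; tt <- g$edges$to[r]; w <- g$edges$weight[r]
    adj[[f]] <- rbind(adj[[f]], c(tt, w))
    adj[[tt]] <- rbind(adj[[tt]], c(f, w))
  }
  max_cost <- s_len + slack
  best <- Inf
  visited <- rep(FALSE, nrow(g$nodes))
  dfs <- function(node, cost, depth) {
    if (node == to) {
      best <<- min(best, abs(cost - s_len))
      return()
    }
    if (depth >= max_nodes) return()
    a <- adj[[node]]
    if (is.null(a)) return()
    for (r in seq_len(nrow(a))) {
      v2 <- a[r, 1]; w <- a[r, 2]
      if (!visited[v2] && cost + w <= max_cost) {
        visited[v2] <<- TRUE
        dfs(v2, cost + w, depth + 1L)
        visited[v2] <<- FALSE
      }
    }
  }
  visited[from] <- TRUE
  dfs(from, 0, 1L)
  best
}

#' Skeleton-trace fit of a candidate connection
#'
#' Enumerates simple paths between the exit anchor of `(j, t)` and the entry
#' anchor of `(j2, t2)` by depth-first search bounded in path cost
#' (`s_len + slack`) and node count, and returns the best absolute mismatch
#' `min |path cost - sLength|`. `Inf` when no path is found within the
#' limits -- the skeleton then gives no evidence for the connection.
#'
#' @param g a `skel_graph` with anchors marked
#' @param j,t,j2,t2 stick indices and directions
#' @param s_len expected loop span `sLength(i, i2)` in Angstrom
#' @param slack extra path cost allowed beyond `s_len`
#' @param max_nodes maximum nodes per path
#' @return the trace mismatch in Angstrom, or `Inf`
#' @export
w_trace <- function(g, j, t, j2, t2, s_len, slack = 20, max_nodes = 60L) {
  if (is.null(g$anchors)) stop("anchors not marked; call mark_endpoints() first",
                               call. = FALSE)
  from <- anchor_node(g, j, if (t == 0) 1 else 0)   # exit endpoint anchor
  to <- anchor_node(g, j2, if (t2 == 0) 0 else 1)   # entry endpoint anchor
  # paths are undirected: canonicalize the query so both orientations of the
  # same anchor pair give the bit-identical cost (ties must fall to the
  # solver's lexicographic rule, not to summation order)
  trace_fit(g, min(from, to), max(from, to), s_len, slack, max_nodes)
}

#' Combined skeleton edge weight
#'
#' `min(W_Eucl + e, W_trace)`: a missing trace costs the loop-span slack
#' plus the penalty `e`; a found trace costs its mismatch with the expected
#' loop span.
#'
#' @param w_eucl loop-span slack of the edge (Angstrom)
#' @param w_trace trace mismatch ([w_trace()]), possibly `Inf`
#' @param e_penalty missing-trace penalty in Angstrom
#' @return the skeleton score `W_sk`
#' @export
skeleton_edge_weight <- function(w_eucl, w_trace, e_penalty = 15) {
  pmin(w_eucl + e_penalty, w_trace)
}

#' Full skeleton graph pipeline from a grid
#'
#' Convenience wrapper: remove SSE regions, reduce to clusters, build the
#' centroid graph, merge cliques, bridge gaps, mark anchors.
#'
#' @param grid a [skeleton_grid()]
#' @param sticks stick table
#' @param rng_seed seed for the cluster reduction
#' @param sse_radius SSE removal radius (Angstrom)
#' @param cluster_radius cluster growth radius (Angstrom)
#' @param link_cutoff cluster linking cutoff (Angstrom)
#' @param gap_cutoff gap bridging cutoff (Angstrom)
#' @param min_clique smallest merged clique
#' @return an anchored `skel_graph`
#' @export
skeleton_graph <- function(grid, sticks, rng_seed,
                           sse_radius = 2.5, cluster_radius = 2.0,
                           link_cutoff = 3.0, gap_cutoff = 10.0,
                           min_clique = 3L) {
  pruned <- remove_sse_regions(grid, sticks, sse_radius)
  clusters <- reduce_skeleton(pruned, cluster_radius, rng_seed)
  g <- build_skelg(clusters, link_cutoff)
  g <- merge_cliques(g, min_clique)
  g <- bridge_gaps(g, gap_cutoff)
  mark_endpoints(g, sticks)
}

#' Attach skeleton scores to a topology graph
#'
#' Computes `W_sk = min(W_Eucl + e, W_trace)` for every edge and stores it
#' in the edge table (column `wsk`).
#'
#' @param graph a `topology_graph`
#' @param skelg an anchored `skel_graph`
#' @param e_penalty missing-trace penalty (Angstrom)
#' @param slack,max_nodes DFS limits passed to [w_trace()]
#' @return the graph with a `wsk` edge column
#' @export
compute_skeleton_scores <- function(graph, skelg, e_penalty = 15,
                                    slack = 20, max_nodes = 60L) {
  e <- graph$edges
  if (nrow(e) > 0) {
    # trace fit depends on (j,t,j2,t2,s_len); cache identical queries
    key <- paste(e$j, e$t, e$j2, e$t2, signif(e$s_len, 10))
    uk <- !duplicated(key)
    tr <- setNames(
      mapply(function(j, t, j2, t2, sl)
        w_trace(skelg, j, t, j2, t2, sl, slack, max_nodes),
        e$j[uk], e$t[uk], e$j2[uk], e$t2[uk], e$s_len[uk]),
      key[uk])
    e$wsk <- skeleton_edge_weight(e$w_eucl, as.numeric(tr[key]), e_penalty)
  } else {
    e$wsk <- double(0)
  }
  graph$edges <- e
  graph
}

#' Export a skeleton graph for visualization
#'
#' `write_skelg_edges()` writes the edge list as TSV; `write_skelg_pdb()`
#' writes nodes as pseudo-atoms (HETATM records) so the trace can be opened
#' in a molecular viewer.
#'
#' @param g a `skel_graph`
#' @param file output path
#' @export
write_skelg_edges <- function(g, file) {
  utils::write.table(g$edges, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_skelg_edges
#' @export
write_skelg_pdb <- function(g, file) {
  lines <- sprintf(
    "HETATM%5d  C   SKL A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    g$nodes$node, g$nodes$node, g$nodes$x, g$nodes$y, g$nodes$z)
  writeLines(c(lines, "END"), file)
  invisible(file)
}
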