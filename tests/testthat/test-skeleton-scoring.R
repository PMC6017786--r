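# a skel_graph built by hand: nodes on a line/shape with explicit edges
manual_skelg <- function(coords, edges_mat) {
  nodes <- tibble::tibble(node = seq_len(nrow(coords)),
                          x = coords[, 1], y = coords[, 2], z = coords[, 3],
                          members = lapply(seq_len(nrow(coords)),
                                           function(k) coords[k, , drop = FALSE]))
  w <- as.numeric(apply(edges_mat, 1, function(e)
    sqrt(sum((coords[e[1], ] - coords[e[2], ])^2))))
  topomatch:::new_skel_graph(
    nodes, tibble::tibble(from = edges_mat[, 1], to = edges_mat[, 2], weight = w))
}

test_that("remove_sse_regions clears only voxels near stick axes", {
  empty <- skeleton_grid(array(0L, c(3, 3, 3)))
  st <- toy_sticks("H", p0 = rbind(c(0, 0, 0)), p1 = rbind(c(0, 0, 5)))
  expect_equal(sum(remove_sse_regions(empty, st, 2.5)$occ), 0)

  occ <- array(0L, c(11, 11, 11))
  occ[1, 1, 3] <- 1L   # on the axis (x=0, y=0, z=2)
  occ[9, 1, 3] <- 1L   # 8 A away in x
  g <- skeleton_grid(occ, spacing = 1, origin = c(0, 0, 0))
  out <- remove_sse_regions(g, st, 2.5)
  expect_equal(sum(out$occ), 1)
  expect_equal(skeleton_voxels(out)$x, 8)
})

test_that("reduce_skeleton partitions foreground voxels into local clusters", {
  occ <- array(0L, c(3, 3, 3)); occ[2, 2, 2] <- 1L
  cl <- reduce_skeleton(skeleton_grid(occ), rng_seed = 1)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$x, cl$y, cl$z), c(1, 1, 1))
  expect_error(reduce_skeleton(skeleton_grid(occ)), "rng_seed")

  occ2 <- array(0L, c(12, 1, 1)); occ2[c(1, 11), 1, 1] <- 1L
  cl2 <- reduce_skeleton(skeleton_grid(occ2), rng_seed = 1)  # 10 A apart
  expect_equal(nrow(cl2), 2)

  # 30-voxel line at 1 A spacing: always a partition; cluster count in a band
  occ3 <- array(0L, c(30, 1, 1)); occ3[, 1, 1] <- 1L
  counts <- integer(0)
  for (s in 1:20) {
    cl3 <- reduce_skeleton(skeleton_grid(occ3), rng_seed = s)
    expect_equal(sum(cl3$size), 30)
    expect_equal(sum(vapply(cl3$members, nrow, integer(1))), 30)
    counts <- c(counts, nrow(cl3))
  }
  expect_true(all(counts >= 5 & counts <= 15))
})

test_that("build_skelg links clusters by inter-voxel distance", {
  # two clusters whose nearest voxels are 1 A apart -> edge; then 10 A -> none
  cl <- tibble::tibble(
    cluster = 1:2, x = c(0.5, 3.5), y = 0, z = 0, size = c(2L, 2L),
    members = list(rbind(c(0, 0, 0), c(1, 0, 0)), rbind(c(2, 0, 0), c(3, 0, 0))))
  g <- build_skelg(cl)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, 3)
  cl$members <- list(rbind(c(0, 0, 0)), rbind(c(10, 0, 0)))
  expect_equal(nrow(build_skelg(cl)$edges), 0)
})

test_that("chain of clusters gives a connected path of about the chain length", {
  occ <- array(0L, c(25, 1, 1)); occ[, 1, 1] <- 1L  # 24 A line
  cl <- reduce_skeleton(skeleton_grid(occ), rng_seed = 3)
  g <- build_skelg(cl)
  ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = FALSE,
                                      vertices = data.frame(name = g$nodes$node))
  expect_equal(igraph::components(ig)$no, 1)
  ends <- c(which.min(g$nodes$x), which.max(g$nodes$x))
  d <- igraph::distances(ig, weights = g$edges$weight)
  span <- g$nodes$x[ends[2]] - g$nodes$x[ends[1]]
  expect_equal(d[ends[1], ends[2]], span, tolerance = 0.35)
})

test_that("merge_cliques collapses cliques of three or more", {
  tri <- manual_skelg(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1.5, 0)),
                      rbind(c(1, 2), c(1, 3), c(2, 3)))
  out <- merge_cliques(tri)
  expect_equal(nrow(out$nodes), 1)
  expect_equal(nrow(out$edges), 0)
  expect_equal(c(out$nodes$x, out$nodes$y), c(1, 0.5))

  path <- manual_skelg(cbind(seq(0, 8, by = 2), 0, 0),
                       cbind(1:4, 2:5))
  expect_equal(merge_cliques(path)$nodes[, 1:4], path$nodes[, 1:4])

  # two triangles sharing node 3: larger-first policy with ties on the
  # smallest member; {1,2,3} merges, {3,4,5} is skipped (3 absorbed)
  two <- manual_skelg(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1.5, 0),
                            c(0, 3, 0), c(2, 3, 0)),
                      rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(3, 5), c(4, 5)))
  out2 <- merge_cliques(two)
  expect_equal(nrow(out2$nodes), 3)
  # the merged node keeps its connections to the surviving triangle
  ig <- igraph::graph_from_data_frame(out2$edges[, 1:2], directed = FALSE,
                                      vertices = data.frame(name = out2$nodes$node))
  expect_equal(igraph::components(ig)$no, 1)
})

test_that("bridge_gaps joins nearby trace ends only", {
  two_seg <- manual_skelg(rbind(c(0, 0, 0), c(2, 0, 0), c(7, 0, 0), c(9, 0, 0)),
                          rbind(c(1, 2), c(3, 4)))
  out <- bridge_gaps(two_seg)  # all four nodes are trace ends here
  expect_true(any((out$edges$from == 2 & out$edges$to == 3) |
                  (out$edges$from == 3 & out$edges$to == 2)))
  expect_equal(nrow(out$edges), 6)  # every cross pair is within 10 A
  far <- manual_skelg(rbind(c(0, 0, 0), c(2, 0, 0), c(14, 0, 0), c(16, 0, 0)),
                      rbind(c(1, 2), c(3, 4)))
  expect_equal(nrow(bridge_gaps(far)$edges), 2)  # 12 A: not bridged

  # bridging never shortens a pair already connected by a cheaper route
  loopish <- manual_skelg(rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0)),
                          rbind(c(1, 2), c(2, 3)))
  out2 <- bridge_gaps(loopish)  # ends 1 and 3 are 6 A apart -> bridged
  ig <- igraph::graph_from_data_frame(out2$edges[, 1:2], directed = FALSE,
                                      vertices = data.frame(name = out2$nodes$node))
  d <- igraph::distances(ig, weights = out2$edges$weight)
  expect_equal(d[1, 3], 6)  # the two-hop route, not changed by the bridge
})

test_that("mark_endpoints anchors each stick endpoint to its nearest node", {
  single <- manual_skelg(rbind(c(1, 1, 1)), matrix(integer(0), 0, 2))
  st <- toy_sticks("H", p0 = rbind(c(0, 0, 0)), p1 = rbind(c(9, 9, 9)))
  m <- mark_endpoints(single, st)
  expect_equal(m$anchors$node, c(1, 1))

  g <- manual_skelg(rbind(c(0, 0, 0), c(5, 0, 0)), rbind(c(1, 2)))
  m2 <- mark_endpoints(g, toy_sticks("H", p0 = rbind(c(0, 0, 0)),
                                     p1 = rbind(c(5.2, 0, 0))))
  expect_equal(m2$anchors$node[m2$anchors$end == 0], 1)
  expect_equal(m2$anchors$node[m2$anchors$end == 1], 2)
  empty <- topomatch:::new_skel_graph(
    tibble::tibble(node = integer(), x = double(), y = double(), z = double(),
                   members = list()),
    tibble::tibble(from = integer(), to = integer(), weight = double()))
  expect_error(mark_endpoints(empty, st), "empty")
})

test_that("w_trace returns the best absolute trace mismatch", {
  # two routes between the anchors: costs 10 (direct-ish) and 20 (detour)
  coords <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0),
                  c(2.5, 5, 0), c(7.5, 5, 0))
  edges <- rbind(c(1, 2), c(2, 3), c(1, 4), c(4, 5), c(5, 3))
  g <- manual_skelg(coords, edges)
  g$edges$weight[3:5] <- c(20 / 3, 20 / 3, 20 / 3)  # detour totals 20
  st <- toy_sticks(c("H", "H"),
                   p0 = rbind(c(-3, 0, 0), c(13, 0, 0)),
                   p1 = rbind(c(-0.2, 0, 0), c(10.2, 0, 0)))
  g <- mark_endpoints(g, st)
  # exit anchor of (1, t=0) is node 1; entry anchor of (2, t2=0) is node 3
  expect_equal(w_trace(g, 1, 0, 2, 0, s_len = 10), 0)
  expect_equal(w_trace(g, 1, 0, 2, 0, s_len = 18), 2)  # the longer path fits
  expect_equal(w_trace(g, 1, 0, 2, 0, s_len = 15), 5)

  # disconnected anchors
  g2 <- manual_skelg(rbind(c(0, 0, 0), c(30, 0, 0)), matrix(integer(0), 0, 2))
  g2 <- mark_endpoints(g2, toy_sticks(c("H", "H"),
                                      p0 = rbind(c(-5, 0, 0), c(35, 0, 0)),
                                      p1 = rbind(c(-1, 0, 0), c(31, 0, 0))))
  expect_equal(w_trace(g2, 1, 0, 2, 0, s_len = 15), Inf)
})

test_that("skeleton_edge_weight takes the better of trace and penalized slack", {
  expect_equal(skeleton_edge_weight(5.2, Inf, 10), 15.2)
  expect_equal(skeleton_edge_weight(3, 0, 10), 0)
  expect_equal(skeleton_edge_weight(5.2, 3, 10), 3)
})

test_that("cluster partition and trace positivity hold on rasterized bundles", {
  b <- make_bundle(3, 0, seed = 21)
  grid <- remove_sse_regions(rasterize_skeleton(b), b$sticks, 2.5)
  n_fg <- sum(grid$occ)
  for (s in c(1, 9)) {
    cl <- reduce_skeleton(grid, rng_seed = s)
    expect_equal(sum(cl$size), n_fg)
  }
  sg <- skeleton_graph(rasterize_skeleton(b), b$sticks, rng_seed = 4)
  g <- compute_skeleton_scores(build_graph(b$segments, b$sticks, b$chain), sg)
  expect_true(all(g$edges$wsk >= 0))
  # every consecutive true pair has a finite trace
  tr <- b$truth
  for (k in seq_len(nrow(tr) - 1)) {
    sl <- s_length(b$segments, tr$i[k], tr$i[k + 1], b$chain)
    expect_true(is.finite(w_trace(sg, tr$j[k], tr$t[k], tr$j[k + 1], tr$t[k + 1], sl)))
  }
  # and the truth is the top-ranked topology under the skeleton scheme
  kb <- k_best(apply_scheme(g, "sk"), 10)
  expect_equal(rank_of_truth(kb, b$truth), 1L)
})
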