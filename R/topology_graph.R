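#' Estimated maximum loop span between two sequence segments
#'
#' The loop connecting two SSE segments can stretch to at most
#' `(loop_aa + 1) * 3.8` Angstrom, where `loop_aa` is the number of residues
#' strictly between the two segments on the chain and 3.8 A is the distance
#' between consecutive CA atoms. When segments are skipped (left unassigned)
#' their residues count toward the loop. If a chain table is supplied the
#' count uses sequential chain positions, not author numbering gaps.
#'
#' @param segments segment table ([extract_segments()])
#' @param i,i_next order indices of the two segments; `i_next` must follow `i`
#' @param chain optional chain table ([read_chain()]) for position-based
#'   residue counting
#' @return the loop span in Angstrom
#' @export
s_length <- function(segments, i, i_next, chain = NULL) {
  if (i_next <= i) stop("i_next must be greater than i", call. = FALSE)
  a <- segments[segments$i == i, ]
  b <- segments[segments$i == i_next, ]
  if (nrow(a) != 1 || nrow(b) != 1) stop("segment index not found", call. = FALSE)
  (loop_aa_between(a$last_res, b$first_res, chain) + 1) * 3.8
}

loop_aa_between <- function(last_res_a, first_res_b, chain = NULL) {
  if (is.null(chain)) {
    as.integer(first_res_b - last_res_a - 1L)
  } else {
    pa <- match(last_res_a, chain$res_id)
    pb <- match(first_res_b, chain$res_id)
    if (is.na(pa) || is.na(pb)) {
      stop("segment boundary residue missing from chain", call. = FALSE)
    }
    as.integer(pb - pa - 1L)
  }
}

stick_endpoint <- function(sticks, j, which_end) {
  row <- sticks[sticks$j == j, ]
  if (nrow(row) != 1) stop("stick index ", j, " not found", call. = FALSE)
  if (which_end == 0) c(row$x0, row$y0, row$z0) else c(row$x1, row$y1, row$z1)
}

# direction semantics: t = 0 means the segment runs p0 -> p1 along the stick.
# The exit endpoint of (j, t) is p1 for t = 0, p0 for t = 1; the entry
# endpoint of (j2, t2) is p0 for t2 = 0, p1 for t2 = 1.
stick_exit <- function(sticks, j, t) stick_endpoint(sticks, j, if (t == 0) 1 else 0)
stick_entry <- function(sticks, j, t) stick_endpoint(sticks, j, if (t == 0) 0 else 1)

#' Spatial distance between consecutive stick endpoints
#'
#' Euclidean distance from the exit endpoint of stick `j` traversed in
#' direction `t` to the entry endpoint of stick `j2` traversed in direction
#' `t2`. With `direction_aware = FALSE` the minimum over the four endpoint
#' pairings is returned instead.
#'
#' @param sticks stick table
#' @param j,t,j2,t2 stick indices and directions (0 or 1)
#' @param direction_aware use the direction-resolved endpoints (default)
#' @return distance in Angstrom
#' @export
v_length <- function(sticks, j, t, j2, t2, direction_aware = TRUE) {
  if (j == j2) stop("v_length requires two distinct sticks", call. = FALSE)
  if (direction_aware) {
    sqrt(sum((stick_exit(sticks, j, t) - stick_entry(sticks, j2, t2))^2))
  } else {
    ends1 <- rbind(stick_endpoint(sticks, j, 0), stick_endpoint(sticks, j, 1))
    ends2 <- rbind(stick_endpoint(sticks, j2, 0), stick_endpoint(sticks, j2, 1))
    min(apply(ends1, 1, function(p) apply(ends2, 1, function(q) sqrt(sum((p - q)^2)))))
  }
}

#' Loop-span slack of a candidate connection
#'
#' The base edge weight of the topology graph: `sLength - vLength`, the slack
#' between what the loop could span and what the assignment requires it to
#' span. Non-negative on every feasible edge (infeasible pairs get no edge).
#'
#' @inheritParams v_length
#' @inheritParams s_length
#' @export
w_eucl <- function(segments, sticks, i, i2, j, t, j2, t2, chain = NULL) {
  s_length(segments, i, i2, chain) - v_length(sticks, j, t, j2, t2)
}

#' Number of possible topologies
#'
#' Counts assignments of `N_H` helix sticks among `M_H` helix segments and
#' `N_b` strand sticks among `M_b` strand segments, with two directions per
#' stick: `C(M_H, N_H) N_H! 2^N_H * C(M_b, N_b) N_b! 2^N_b`.
#'
#' @param M_H,N_H helix segment and stick counts
#' @param M_b,N_b strand segment and stick counts
#' @return the topology count (numeric; exact for desk-scale sizes)
#' @export
count_topologies <- function(M_H, N_H, M_b = 0, N_b = 0) {
  if (M_H < N_H || M_b < N_b) {
    stop("segment count must be at least the stick count per type", call. = FALSE)
  }
  choose(M_H, N_H) * factorial(N_H) * 2^N_H *
    choose(M_b, N_b) * factorial(N_b) * 2^N_b
}

#' Build the layered topology graph
#'
#' Creates the assignment nodes `(i, j, t)` for every type-compatible
#' segment/stick pair and both directions, plus START and END, and emits the
#' feasible edges. An edge `(i,j,t) -> (i2,j2,t2)` exists iff `i2 > i`, at
#' most `max_skip` segments are skipped between the two rows, `j2 != j`, and
#' the loop-span constraint `vLength <= sLength` holds; its weight is
#' initialized to the slack `W_Eucl = sLength - vLength`. START reaches a
#' node only if enough rows remain to place all `N` sticks (and symmetrically
#' for END) -- a pruning that never removes a valid path.
#'
#' @param segments segment table
#' @param sticks stick table
#' @param chain optional chain table for loop-residue counting
#' @param max_skip maximum number of consecutive skipped segments between two
#'   assigned rows; defaults to `Delta - 1` with `Delta = M - N + 1`
#' @return a `topology_graph` object: node and edge tibbles plus metadata
#' @export
build_graph <- function(segments, sticks, chain = NULL, max_skip = NULL) {
  M_H <- sum(segments$type == "H"); M_b <- sum(segments$type == "E")
  N_H <- sum(sticks$type == "H");   N_b <- sum(sticks$type == "E")
  if (M_H < N_H || M_b < N_b) {
    stop("more sticks than segments of a type (need M_x >= N_x)", call. = FALSE)
  }
  M <- M_H + M_b; N <- N_H + N_b
  delta <- M - N + 1L
  if (is.null(max_skip)) max_skip <- delta - 1L

  nodes <- tidyr::expand_grid(i = segments$i, j = sticks$j, t = c(0L, 1L))
  seg_type <- setNames(segments$type, segments$i)
  stk_type <- setNames(sticks$type, sticks$j)
  nodes <- nodes[seg_type[as.character(nodes$i)] == stk_type[as.character(nodes$j)], ]
  nodes$node <- seq_len(nrow(nodes))
  nodes <- nodes[, c("node", "i", "j", "t")]

  # precompute loop spans between all row pairs and direction-aware endpoints
  slen <- matrix(NA_real_, M, M)
  for (a in seq_len(M)) {
    for (b in seq_len(M)) if (b > a) slen[a, b] <- s_length(segments, a, b, chain)
  }
  exits <- array(NA_real_, c(N, 2, 3)); entries <- array(NA_real_, c(N, 2, 3))
  for (j in sticks$j) for (t in 0:1) {
    exits[j, t + 1, ] <- stick_exit(sticks, j, t)
    entries[j, t + 1, ] <- stick_entry(sticks, j, t)
  }

  n_nodes <- nrow(nodes)
  from_l <- list(); k <- 0L
  for (a in seq_len(n_nodes)) {
    na <- nodes[a, ]
    cand <- nodes[nodes$i > na$i & nodes$i - na$i - 1L <= max_skip & nodes$j != na$j, ]
    if (nrow(cand) == 0) next
    ex <- exits[na$j, na$t + 1, ]
    vlen <- sqrt((entries[cbind(cand$j, cand$t + 1, 1)] - ex[1])^2 +
                 (entries[cbind(cand$j, cand$t + 1, 2)] - ex[2])^2 +
                 (entries[cbind(cand$j, cand$t + 1, 3)] - ex[3])^2)
    sl <- slen[cbind(na$i, cand$i)]
    ok <- vlen <= sl
    if (!any(ok)) next
    k <- k + 1L
    from_l[[k]] <- tibble(
      from = na$node, to = cand$node[ok],
      i = na$i, j = na$j, t = na$t,
      i2 = cand$i[ok], j2 = cand$j[ok], t2 = cand$t[ok],
      s_len = sl[ok], v_len = vlen[ok], w_eucl = sl[ok] - vlen[ok]
    )
  }
  edges <- if (k > 0) dplyr::bind_rows(from_l) else
    tibble(from = integer(), to = integer(), i = integer(), j = integer(),
           t = integer(), i2 = integer(), j2 = integer(), t2 = integer(),
           s_len = double(), v_len = double(), w_eucl = double())
  edges$weight <- edges$w_eucl

  # START/END usability pruning: enough rows must remain to place all N
  # columns. Leading/trailing skips are otherwise unconstrained; max_skip
  # bounds only the gap between two consecutive assigned rows.
  start_nodes <- nodes$node[nodes$i <= delta]
  end_nodes <- nodes$node[nodes$i >= N]

  structure(
    list(segments = segments, sticks = sticks, chain = chain,
         nodes = nodes, edges = edges,
         start_nodes = start_nodes, end_nodes = end_nodes,
         M_H = M_H, M_b = M_b, N_H = N_H, N_b = N_b,
         M = M, N = N, delta = delta, max_skip = max_skip,
         scheme = "eucl"),
    class = "topology_graph"
  )
}

#' @export
print.topology_graph <- function(x, ...) {
  cat("<topology_graph> M =", x$M, "segments (", x$M_H, "H /", x$M_b, "E ), N =",
      x$N, "sticks;", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges; scheme:", x$scheme, "\n")
  invisible(x)
}

#' Export graph edges as a TSV edge list (debugging aid)
#'
#' @param graph a `topology_graph`
#' @param file output path
#' @export
write_graph_edges <- function(graph, file) {
  utils::write.table(graph$edges, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
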