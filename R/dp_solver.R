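# Solver internals ------------------------------------------------------
#
# The search space is the expanded state DAG over (node, used-column mask):
# every START -> END path in it is automatically a valid topology (rows
# increase along graph edges, the mask forbids column reuse, END is only
# reachable once all N columns are used). A backward dynamic program over
# states gives the exact cost-to-go h(state); best-first enumeration with
# priority g + h then emits complete paths in exactly nondecreasing total
# cost. Ties are broken lexicographically on the (i, j, t) assignment
# sequence, which makes ranks deterministic. The mask bounds the stick count
# at about 24 columns (state count O(Delta^2 N^2 2^N)); benchmark-scale
# problems (N <= 22) fit, desk-scale tests use N <= 7.

solver_prep <- function(graph) {
  nodes <- graph$nodes
  v <- nrow(nodes)
  colbit <- bitwShiftL(1L, nodes$j - 1L)
  adj <- vector("list", v)
  if (nrow(graph$edges) > 0) {
    sp <- split(seq_len(nrow(graph$edges)), graph$edges$from)
    for (nm in names(sp)) {
      rows <- sp[[nm]]
      adj[[as.integer(nm)]] <- list(to = graph$edges$to[rows],
                                    w = graph$edges$weight[rows])
    }
  }
  is_end <- rep(FALSE, v); is_end[graph$end_nodes] <- TRUE
  full_count <- graph$N
  list(nodes = nodes, v = v, colbit = colbit, adj = adj,
       is_end = is_end, full_count = full_count,
       start_nodes = graph$start_nodes)
}

popcount32 <- function(x) {
  n <- 0L
  while (x > 0L) { n <- n + bitwAnd(x, 1L); x <- bitwShiftR(x, 1L) }
  n
}

# exact cost-to-go from state (node, mask) to END; memoized recursion
solver_h <- function(prep, memo) {
  h <- function(node, mask) {
    key <- paste0(node, ".", mask)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- Inf
    if (prep$is_end[node] && popcount32(mask) == prep$full_count) best <- 0
    a <- prep$adj[[node]]
    if (!is.null(a)) {
      for (k in seq_along(a$to)) {
        v2 <- a$to[k]
        b <- prep$colbit[v2]
        if (bitwAnd(mask, b) == 0L) {
          sub <- h(v2, bitwOr(mask, b))
          if (is.finite(sub)) best <- min(best, a$w[k] + sub)
        }
      }
    }
    memo[[key]] <- best
    best
  }
  h
}

# lexicographic comparison of node-index paths; node indices are assigned in
# (i, j, t) order when the graph is built, so index order is triple order
path_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (k in seq_len(n)) {
    if (a[k] != b[k]) return(a[k] < b[k])
  }
  length(a) < length(b)
}

topology_assignment_string <- function(path_tbl) {
  paste0("SQ", path_tbl$i, "->D", path_tbl$j,
         ifelse(path_tbl$t == 0, "+", "-"), collapse = " ")
}

new_topology_ranking <- function(paths, scores, graph) {
  nodes <- graph$nodes
  tbls <- lapply(paths, function(p) nodes[match(p, nodes$node), c("i", "j", "t")])
  out <- tibble(
    rank = seq_along(paths),
    total_score = as.numeric(scores),
    assignment = vapply(tbls, topology_assignment_string, character(1)),
    path = tbls
  )
  class(out) <- c("topology_ranking", class(out))
  attr(out, "N") <- graph$N
  attr(out, "scheme") <- graph$scheme
  out
}

empty_topology_ranking <- function(graph) {
  new_topology_ranking(list(), numeric(0), graph)
}

#' Best-K valid topologies
#'
#' Enumerates up to `K` valid topologies (every stick used exactly once,
#' segment rows strictly increasing) in nondecreasing total edge weight.
#' Equal-cost topologies are ordered lexicographically by their `(i, j, t)`
#' assignment triples, so ranks are deterministic. The list may be shorter
#' than `K` when fewer valid topologies exist.
#'
#' @param graph a `topology_graph` (optionally re-weighted by
#'   [apply_scheme()])
#' @param K maximum number of topologies to return
#' @return a `topology_ranking`: a tibble with columns `rank`,
#'   `total_score`, `assignment` (e.g. `"SQ1->D3+ SQ2->D1-"`) and `path`
#'   (list column of `(i, j, t)` tibbles)
#' @export
k_best <- function(graph, K = 100L) {
  stopifnot(K >= 1)
  prep <- solver_prep(graph)
  if (prep$v == 0) return(empty_topology_ranking(graph))
  memo <- new.env(parent = emptyenv())
  h <- solver_h(prep, memo)

  # queue of partial paths; complete entries are flagged done
  q_cost <- numeric(0); q_g <- numeric(0); q_path <- list()
  q_mask <- integer(0); q_done <- logical(0)
  push <- function(cost, g, path, mask, done) {
    q_cost[[length(q_cost) + 1L]] <<- cost
    q_g[[length(q_g) + 1L]] <<- g
    q_path[[length(q_path) + 1L]] <<- path
    q_mask[[length(q_mask) + 1L]] <<- mask
    q_done[[length(q_done) + 1L]] <<- done
  }
  for (s in sort(prep$start_nodes)) {
    hs <- h(s, prep$colbit[s])
    if (is.finite(hs)) push(hs, 0, s, prep$colbit[s], FALSE)
  }

  out_paths <- list(); out_scores <- numeric(0)
  while (length(q_cost) > 0 && length(out_paths) < K) {
    # costs within the numerical tie tolerance are equal-cost: break by the
    # lexicographic rule, not by floating-point summation noise
    best <- which(q_cost <= min(q_cost) + 1e-9)
    if (length(best) > 1) {
      pick <- best[1]
      for (b in best[-1]) if (path_less(q_path[[b]], q_path[[pick]])) pick <- b
    } else pick <- best
    cost <- q_cost[pick]; g <- q_g[pick]
    path <- q_path[[pick]]; mask <- q_mask[pick]; done <- q_done[pick]
    q_cost <- q_cost[-pick]; q_g <- q_g[-pick]
    q_path[pick] <- NULL; q_mask <- q_mask[-pick]; q_done <- q_done[-pick]
    if (done) {
      out_paths[[length(out_paths) + 1L]] <- path
      out_scores[[length(out_scores) + 1L]] <- cost
      next
    }
    node <- path[length(path)]
    if (prep$is_end[node] && popcount32(mask) == prep$full_count) {
      push(g, g, path, mask, TRUE)          # take the zero-weight END edge
    }
    a <- prep$adj[[node]]
    if (!is.null(a)) {
      for (k in seq_along(a$to)) {
        v2 <- a$to[k]
        b <- prep$colbit[v2]
        if (bitwAnd(mask, b) == 0L) {
          m2 <- bitwOr(mask, b)
          h2 <- h(v2, m2)
          if (is.finite(h2)) push(g + a$w[k] + h2, g + a$w[k], c(path, v2), m2, FALSE)
        }
      }
    }
  }
  new_topology_ranking(out_paths, out_scores, graph)
}

#' Shortest valid topology
#'
#' The minimum-total-weight valid path through the topology graph, found by
#' the subset dynamic program. Returns a zero-row ranking (with a message)
#' when no valid topology exists.
#'
#' @inheritParams k_best
#' @return a one-row (or zero-row) `topology_ranking`
#' @export
shortest_valid_path <- function(graph) {
  out <- k_best(graph, K = 1L)
  if (nrow(out) == 0) message("no topology: no valid path through the graph")
  out
}

#' Exhaustively enumerate all valid topologies (test oracle)
#'
#' Depth-first enumeration of every valid path with its exact score, sorted
#' by (score, lexicographic assignment). Independent of the dynamic program
#' and intended as a brute-force oracle at desk scale.
#'
#' @inheritParams k_best
#' @param cap refuse to enumerate if [count_topologies()] exceeds this
#' @return a `topology_ranking` with every valid topology
#' @export
enumerate_all <- function(graph, cap = 1e6) {
  n_possible <- count_topologies(graph$M_H, graph$N_H, graph$M_b, graph$N_b)
  if (n_possible > cap) {
    stop("topology count ", n_possible, " exceeds enumeration cap ", cap,
         call. = FALSE)
  }
  prep <- solver_prep(graph)
  acc_paths <- list(); acc_scores <- numeric(0)
  recurse <- function(path, mask, g) {
    node <- path[length(path)]
    if (prep$is_end[node] && popcount32(mask) == prep$full_count) {
      acc_paths[[length(acc_paths) + 1L]] <<- path
      acc_scores[[length(acc_scores) + 1L]] <<- g
    }
    a <- prep$adj[[node]]
    if (!is.null(a)) {
      for (k in seq_along(a$to)) {
        v2 <- a$to[k]
        b <- prep$colbit[v2]
        if (bitwAnd(mask, b) == 0L) recurse(c(path, v2), bitwOr(mask, b), g + a$w[k])
      }
    }
  }
  for (s in prep$start_nodes) recurse(s, prep$colbit[s], 0)
  if (length(acc_paths) == 0) return(empty_topology_ranking(graph))
  ord <- order(acc_scores)
  # lex order within groups of scores equal up to the tie tolerance
  groups <- cumsum(c(TRUE, diff(acc_scores[ord]) > 1e-9))
  ties <- split(ord, groups)
  ord <- unlist(lapply(ties, function(idx) {
    if (length(idx) == 1) return(idx)
    idx[order_paths_lex(acc_paths[idx])]
  }), use.names = FALSE)
  new_topology_ranking(acc_paths[ord], acc_scores[ord], graph)
}

order_paths_lex <- function(paths) {
  keys <- vapply(paths, function(p) paste(sprintf("%06d", p), collapse = ","),
                 character(1))
  order(keys)
}

#' @export
print.topology_ranking <- function(x, ...) {
  cat("<topology_ranking> ", nrow(x), " topologies, scheme '",
      attr(x, "scheme"), "'\n", sep = "")
  if (nrow(x) == 0) {
    cat("(no topology)\n")
  } else {
    NextMethod()
  }
  invisible(x)
}

#' Write a ranking as a TSV table
#'
#' @param ranking a `topology_ranking`
#' @param file output path
#' @export
write_ranking <- function(ranking, file) {
  utils::write.table(
    data.frame(rank = ranking$rank, score = ranking$total_score,
               assignment = ranking$assignment),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
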