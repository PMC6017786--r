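# shared builders for hand-sized fixtures

# a chain laid out as straight vertical "helices" with CA on the axis and
# N/C slightly offset, so packing vectors are exactly the axis directions
toy_chain <- function(ca) {
  tibble::tibble(
    res_id = seq_len(nrow(ca)),
    aa = "A",
    n_x = ca[, 1] - 0.4, n_y = ca[, 2], n_z = ca[, 3] - 0.8,
    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
    c_x = ca[, 1] + 0.4, c_y = ca[, 2], c_z = ca[, 3] + 0.8
  )
}

toy_segments <- function(types, first, last) {
  tibble::tibble(i = seq_along(types), type = types,
                 first_res = as.integer(first), last_res = as.integer(last),
                 length_aa = as.integer(last - first + 1L))
}

toy_sticks <- function(types, p0, p1) {
  tibble::tibble(j = seq_along(types), type = types,
                 x0 = p0[, 1], y0 = p0[, 2], z0 = p0[, 3],
                 x1 = p1[, 1], y1 = p1[, 2], z1 = p1[, 3])
}

# segments/sticks where every pairing is feasible: sticks tightly packed at
# the origin, loops long enough for any vLength; used to compare graph
# enumeration against combinatorial counts
feasible_fixture <- function(M_H, N_H, M_b, N_b) {
  M <- M_H + M_b; N <- N_H + N_b
  types_seg <- c(rep("H", M_H), rep("E", M_b))
  first <- seq(1, by = 60, length.out = M)
  segments <- toy_segments(types_seg, first, first + 5L)
  types_stk <- c(rep("H", N_H), rep("E", N_b))
  ang <- seq_len(max(N, 1)) * 2.3
  p0 <- cbind(cos(ang), sin(ang), 0)[seq_len(N), , drop = FALSE]
  p1 <- p0 + cbind(0, 0, rep(1.5, N))
  sticks <- toy_sticks(types_stk, p0, p1)
  list(segments = segments, sticks = sticks)
}

# random small geometry fixture for oracle-equivalence tests
random_fixture <- function(seed) {
  set.seed(seed)
  N <- sample(2:5, 1)
  extra <- sample(0:1, 1)
  M <- N + extra
  n_h <- sample(0:M, 1)
  types_seg <- sample(c(rep("H", n_h), rep("E", M - n_h)))
  # stick types drawn as a subset of segment types
  drop_idx <- if (extra > 0) sample(seq_len(M), extra) else integer(0)
  types_stk <- types_seg[setdiff(seq_len(M), drop_idx)]
  types_stk <- c(types_stk[types_stk == "H"], types_stk[types_stk == "E"])
  first <- cumsum(c(1, sample(6:12, M - 1, replace = TRUE) +
                      sample(8:12, M - 1, replace = TRUE)))
  segments <- toy_segments(types_seg, first, first + sample(5:9, M, replace = TRUE))
  N2 <- length(types_stk)
  p0 <- matrix(stats::runif(N2 * 3, 0, 25), N2, 3)
  p1 <- p0 + matrix(stats::rnorm(N2 * 3, 0, 5), N2, 3)
  sticks <- toy_sticks(types_stk, p0, p1)
  list(segments = segments, sticks = sticks)
}

# independent brute-force topology counter: recursive assignment of sticks
# to increasing rows with type compatibility, two directions per stick
brute_count_topologies <- function(segments_types, sticks_types) {
  M <- length(segments_types); N <- length(sticks_types)
  if (N == 0) return(1)
  count <- 0L
  recurse <- function(row, used) {
    n_used <- sum(used)
    if (n_used == N) { count <<- count + 1L; return(invisible()) }
    if (row > M) return(invisible())
    # skip this row
    if (M - row >= N - n_used) recurse(row + 1L, used)
    # or assign any unused type-compatible stick
    for (s in which(!used)) {
      if (sticks_types[s] == segments_types[row]) {
        used[s] <- TRUE
        recurse(row + 1L, used)
        used[s] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, N))
  count * 2^N
}
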