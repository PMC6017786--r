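#' Packing-geometry score parameters
#'
#' The packing of two consecutive SSEs about their connecting loop is
#' described by the dihedral angle `phi` and the packing-angle sum
#' `eta = theta1 + theta2`; across a large survey of loop structures the two
#' are approximately independent bivariate normal. The defaults are the
#' fitted values: mean `(-4.501, 203.207)` degrees and diagonal covariance
#' `(5581.972, 2103.773)` degrees squared, with peak scale `A = 1` so the
#' score is a dimensionless value in `(0, 1]`.
#'
#' @param A peak scale of the score
#' @param lambda length-2 mean vector `(phi, eta)` in degrees
#' @param sigma 2x2 covariance matrix in degrees squared
#' @return a `geometry_params` object
#' @export
geometry_params <- function(A = 1,
                            lambda = c(phi = -4.501, eta = 203.207),
                            sigma = diag(c(5581.972, 2103.773))) {
  sigma <- as.matrix(sigma)
  if (!isTRUE(all.equal(sigma, t(sigma))) || any(eigen(sigma, only.values = TRUE)$values <= 0)) {
    stop("sigma must be symmetric positive definite", call. = FALSE)
  }
  structure(list(A = A, lambda = unname(as.numeric(lambda)), sigma = unname(sigma)),
            class = "geometry_params")
}

#' @export
print.geometry_params <- function(x, ...) {
  cat("<geometry_params> A =", x$A, "; lambda =", paste(round(x$lambda, 3), collapse = ", "),
      "; sigma diag =", paste(round(diag(x$sigma), 3), collapse = ", "), "\n")
  invisible(x)
}

#' Read/write geometry parameters as JSON
#'
#' @param params a `geometry_params`
#' @param file path
#' @export
write_geometry_params <- function(params, file) {
  jsonlite::write_json(list(A = params$A, lambda = params$lambda,
                            sigma = params$sigma),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_geometry_params
#' @export
read_geometry_params <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  geometry_params(A = x$A, lambda = x$lambda, sigma = matrix(unlist(x$sigma), 2, 2))
}

vnorm <- function(v) sqrt(sum(v^2))

angle_deg <- function(a, b) {
  ca <- sum(a * b) / (vnorm(a) * vnorm(b))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}

#' Packing vectors of two consecutive SSEs
#'
#' `V1` runs along the first SSE (start to end), `V3` along the second, and
#' `V2` along the connecting loop, from the end point of the first SSE to
#' the start point of the second. Helix end points are the centers of mass
#' of the backbone (N, CA, C) triangles of the first and last residue;
#' strand end points are the CA atoms of the first and last residue. A pair
#' missing any required coordinate is excluded: the return value is a
#' `geometry_skip` object rather than vectors.
#'
#' @param chain chain table ([read_chain()])
#' @param seg1,seg2 single-row segment tibbles (consecutive in sequence)
#' @return a list with elements `V1`, `V2`, `V3`, or a `geometry_skip`
#' @export
packing_vectors <- function(chain, seg1, seg2) {
  ends <- function(seg) {
    rows <- chain[chain$res_id >= seg$first_res & chain$res_id <= seg$last_res, ]
    if (nrow(rows) < 2) return(NULL)
    if (seg$type == "H") {
      tri <- function(r) c(mean(c(r$n_x, r$ca_x, r$c_x)),
                           mean(c(r$n_y, r$ca_y, r$c_y)),
                           mean(c(r$n_z, r$ca_z, r$c_z)))
      p_start <- tri(rows[1, ]); p_end <- tri(rows[nrow(rows), ])
    } else {
      p_start <- c(rows$ca_x[1], rows$ca_y[1], rows$ca_z[1])
      p_end <- c(rows$ca_x[nrow(rows)], rows$ca_y[nrow(rows)], rows$ca_z[nrow(rows)])
    }
    if (anyNA(p_start) || anyNA(p_end)) return(NULL)
    list(start = p_start, end = p_end)
  }
  e1 <- ends(seg1); e2 <- ends(seg2)
  if (is.null(e1) || is.null(e2)) {
    return(structure(list(reason = "missing backbone coordinates"),
                     class = "geometry_skip"))
  }
  list(V1 = e1$end - e1$start, V2 = e2$start - e1$end, V3 = e2$end - e2$start)
}

#' Signed dihedral angle of two SSE axes about the loop vector
#'
#' The angle from the projection of `V1` to the projection of `V3` in the
#' plane perpendicular to `V2`, signed right-handed about `V2` and reported
#' in `(-180, 180]` (`-180` is canonicalized to `+180`). Degenerate
#' geometry (either axis parallel to the loop vector) returns `NA`.
#'
#' @param V1,V2,V3 packing vectors
#' @return the dihedral in degrees, or `NA_real_`
#' @export
dihedral_phi <- function(V1, V2, V3) {
  u <- V2 / vnorm(V2)
  p1 <- V1 - sum(V1 * u) * u
  p3 <- V3 - sum(V3 * u) * u
  if (vnorm(p1) < 1e-9 * vnorm(V1) || vnorm(p3) < 1e-9 * vnorm(V3)) {
    return(NA_real_)
  }
  ang <- atan2(sum(pracma_cross(p1, p3) * u), sum(p1 * p3)) * 180 / pi
  if (isTRUE(all.equal(ang, -180)) || ang <= -180) ang <- 180
  ang
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Packing-angle sum eta
#'
#' `theta1` is the angle between the first SSE axis and the loop vector,
#' `theta2` between the loop vector and the second axis; both lie in
#' `[0, 180]`, so `eta = theta1 + theta2` lies in `[0, 360]`.
#'
#' @inheritParams dihedral_phi
#' @return eta in degrees
#' @export
packing_eta <- function(V1, V2, V3) {
  angle_deg(V1, V2) + angle_deg(V2, V3)
}

#' Bivariate-normal packing score
#'
#' `f(phi, eta) = A exp(-1/2 (x - lambda)' sigma^-1 (x - lambda))`:
#' maximal (`A`) at the survey mean, decaying with Mahalanobis distance.
#' Vectorized over `phi`/`eta`.
#'
#' @param phi dihedral angle(s), degrees
#' @param eta packing-angle sum(s), degrees
#' @param params a [geometry_params()]
#' @return score value(s) in `(0, A]`
#' @export
geometry_score <- function(phi, eta, params = geometry_params()) {
  si <- tryCatch(solve(params$sigma),
                 error = function(e) stop("singular covariance matrix", call. = FALSE))
  dx <- cbind(phi - params$lambda[1], eta - params$lambda[2])
  md2 <- rowSums((dx %*% si) * dx)
  as.numeric(params$A * exp(-md2 / 2))
}

#' Fit packing-score parameters from angle samples
#'
#' Sample mean and variances with the off-diagonal covariance zeroed (the
#' two angles are treated as independent); the peak scale is set so the
#' maximum score is `A`.
#'
#' @param samples a matrix or data frame with columns `phi` and `eta`
#' @param A peak scale of the fitted score
#' @return a [geometry_params()]
#' @export
fit_params <- function(samples, A = 1) {
  x <- as.matrix(as.data.frame(samples)[, c("phi", "eta")])
  if (nrow(x) < 2) stop("need at least 2 samples", call. = FALSE)
  v <- apply(x, 2, stats::var)
  if (any(v < 1e-12)) stop("degenerate (zero-variance) samples", call. = FALSE)
  geometry_params(A = A, lambda = colMeans(x), sigma = diag(unname(v)))
}

#' Geometry score as an edge weight
#'
#' In `combined` mode the raw score `f` is returned, to be subtracted from
#' the skeleton weight (`Wsk - f`). In `standalone` mode the weight is
#' `A - f`, so that minimization favors high-probability packings when the
#' geometry score is the only edge weight.
#'
#' @inheritParams geometry_score
#' @param mode `"combined"` or `"standalone"`
#' @return weight value(s)
#' @export
geometry_edge_weight <- function(phi, eta, params = geometry_params(),
                                 mode = c("combined", "standalone")) {
  mode <- match.arg(mode)
  f <- geometry_score(phi, eta, params)
  if (mode == "combined") f else params$A - f
}

#' Packing angles of a candidate stick connection
#'
#' Edges are scored before any backbone exists, so `phi` and `eta` are
#' computed from stick endpoint vectors: `V1` is stick `j` traversed in
#' direction `t`, `V3` stick `j2` in `t2`, and `V2` joins the
#' direction-aware exit and entry endpoints. A zero-length loop vector is
#' degenerate and yields `NA` angles.
#'
#' @param sticks stick table
#' @param j,t,j2,t2 stick indices and directions
#' @return a list with `phi` and `eta` (degrees)
#' @export
stick_packing_angles <- function(sticks, j, t, j2, t2) {
  p0 <- stick_endpoint(sticks, j, 0); p1 <- stick_endpoint(sticks, j, 1)
  q0 <- stick_endpoint(sticks, j2, 0); q1 <- stick_endpoint(sticks, j2, 1)
  V1 <- if (t == 0) p1 - p0 else p0 - p1
  V3 <- if (t2 == 0) q1 - q0 else q0 - q1
  exit <- if (t == 0) p1 else p0
  entry <- if (t2 == 0) q0 else q1
  V2 <- entry - exit
  if (vnorm(V2) < 1e-9) return(list(phi = NA_real_, eta = NA_real_))
  list(phi = dihedral_phi(V1, V2, V3), eta = packing_eta(V1, V2, V3))
}

#' Attach geometry scores to a topology graph
#'
#' Computes `f(phi, eta)` from stick endpoint vectors for every edge and
#' stores it in the edge table (column `f`). Degenerate edges (coincident
#' exit/entry points or an axis parallel to the loop vector) get `f = 0`:
#' the geometry gives them no support.
#'
#' @param graph a `topology_graph`
#' @param params a [geometry_params()]
#' @return the graph with an `f` edge column
#' @export
compute_geometry_scores <- function(graph, params = geometry_params()) {
  e <- graph$edges
  if (nrow(e) == 0) { e$f <- double(0); graph$edges <- e; return(graph) }
  key <- paste(e$j, e$t, e$j2, e$t2)
  uk <- !duplicated(key)
  fvals <- vapply(which(uk), function(r) {
    ang <- stick_packing_angles(graph$sticks, e$j[r], e$t[r], e$j2[r], e$t2[r])
    if (is.na(ang$phi) || is.na(ang$eta)) 0 else geometry_score(ang$phi, ang$eta, params)
  }, double(1))
  e$f <- as.numeric(setNames(fvals, key[uk])[key])
  graph$edges <- e
  graph
}

#' Packing-angle table of a chain
#'
#' Extracts `(phi, eta)` for every consecutive segment pair of a chain,
#' skipping pairs with missing coordinates or degenerate geometry. This is
#' the batch extraction used to build an angle survey from structures.
#'
#' @param chain chain table
#' @param segments segment table
#' @return a tibble with columns `i1`, `i2`, `phi`, `eta`
#' @export
chain_packing_angles <- function(chain, segments) {
  out <- list()
  if (nrow(segments) >= 2) {
    for (k in seq_len(nrow(segments) - 1)) {
      pv <- packing_vectors(chain, segments[k, ], segments[k + 1, ])
      if (inherits(pv, "geometry_skip")) next
      phi <- dihedral_phi(pv$V1, pv$V2, pv$V3)
      if (is.na(phi)) next
      out[[length(out) + 1L]] <- tibble(
        i1 = segments$i[k], i2 = segments$i[k + 1],
        phi = phi, eta = packing_eta(pv$V1, pv$V2, pv$V3))
    }
  }
  if (length(out) == 0) {
    return(tibble(i1 = integer(), i2 = integer(), phi = double(), eta = double()))
  }
  dplyr::bind_rows(out)
}
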