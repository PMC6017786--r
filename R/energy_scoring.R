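# rough side-chain centroid distances from CA, Angstrom, per residue type;
# glycine has no side chain (center at CA)
sidechain_distances <- c(
  A = 1.5, R = 4.1, N = 2.5, D = 2.5, C = 2.1, Q = 3.1, E = 3.1, G = 0.0,
  H = 3.1, I = 2.3, L = 2.6, K = 3.5, M = 2.9, F = 3.4, P = 1.9, S = 1.9,
  T = 1.9, V = 2.0, W = 3.9, Y = 3.8
)

#' Multi-well contact energy parameters
#'
#' The exact pair-specific cutoffs, side-chain radii and well shapes of the
#' original knowledge-based potential are an external parameterization; here
#' they are pluggable configuration with physically plausible defaults: one
#' attractive Gaussian well at typical side-chain contact distance, a
#' Lennard-Jones-style short-range repulsion, a uniform contact cutoff, and
#' a neutral no-contact constant.
#'
#' @param cutoff contact cutoff between side-chain centers, Angstrom
#'   (uniform, or a named square matrix by residue type)
#' @param wells data frame of Gaussian wells: center `r` (A), depth `d`,
#'   width `sigma` (A)
#' @param rep_scale repulsion scale: the repulsive term is `(rep_scale/r)^12`
#' @param e_const edge weight used when two SSE models share no contact
#' @param axial_clamp maximum relative axial rescaling when fitting a model
#'   to its stick
#' @return an `energy_params` object
#' @export
energy_params <- function(cutoff = 6.5,
                          wells = data.frame(r = 5.5, d = 1.0, sigma = 1.0),
                          rep_scale = 3.5, e_const = 0, axial_clamp = 0.2) {
  if (any(wells$sigma <= 0)) stop("well widths must be positive", call. = FALSE)
  if (any(cutoff <= 0)) stop("contact cutoffs must be positive", call. = FALSE)
  structure(list(cutoff = cutoff, wells = wells, rep_scale = rep_scale,
                 e_const = e_const, axial_clamp = axial_clamp),
            class = "energy_params")
}

contact_cutoff <- function(type_a, type_b, params) {
  known <- names(sidechain_distances)
  if (!all(c(type_a, type_b) %in% known)) {
    stop("unknown residue type: ",
         paste(setdiff(c(type_a, type_b), known), collapse = ", "), call. = FALSE)
  }
  if (is.matrix(params$cutoff)) params$cutoff[type_a, type_b] else params$cutoff
}

rotation_to <- function(u) {
  # orthonormal frame with third axis u (unit)
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- pracma_cross(ref, u); e1 <- e1 / vnorm(e1)
  e2 <- pracma_cross(u, e1)
  cbind(e1, e2, u)
}

#' Build an ideal-geometry SSE model on a stick
#'
#' Generates a CA trace from ideal secondary-structure geometry -- a helix
#' of radius 2.3 A, rise 1.5 A per residue and 100 degrees of twist, or a
#' pleated strand of rise 3.3 A per residue -- and rigidly places it so the
#' trace axis runs along the stick, from `p0` to `p1` when `t = 0` and
#' reversed when `t = 1`. If the stick length requires rescaling the axis by
#' more than the clamp (default 20 percent), the scaling is clamped with a
#' warning. A side-chain center is placed along the local outward normal at
#' a per-residue-type distance.
#'
#' @param stick one-row stick tibble
#' @param segment one-row segment tibble (same SSE type)
#' @param t direction, 0 or 1
#' @param aa residue types (1-letter), recycled to the segment length
#' @param params an [energy_params()]
#' @return an `sse_model` tibble: `k`, `aa`, CA coordinates `ca_x..ca_z`,
#'   side-chain center `sc_x..sc_z`
#' @export
build_sse_model <- function(stick, segment, t, aa = "A", params = energy_params()) {
  if (stick$type != segment$type) stop("stick/segment types differ", call. = FALSE)
  n <- segment$length_aa
  aa <- rep_len(aa, n)
  a <- c(stick$x0, stick$y0, stick$z0)
  b <- c(stick$x1, stick$y1, stick$z1)
  if (t == 1) { tmp <- a; a <- b; b <- tmp }
  if (n == 1) {
    mid <- (a + b) / 2
    out <- tibble(k = 1L, aa = aa,
                  ca_x = mid[1], ca_y = mid[2], ca_z = mid[3],
                  sc_x = mid[1], sc_y = mid[2], sc_z = mid[3])
    return(structure(out, class = c("sse_model", class(out)), t = t))
  }
  if (segment$type == "H") {
    rise <- 1.5; radius <- 2.3; twist <- 100 * pi / 180
    kk <- seq_len(n) - 1
    local_ca <- cbind(radius * cos(kk * twist), radius * sin(kk * twist), kk * rise)
    # side chain points radially outward from the helix axis
    radial <- cbind(cos(kk * twist), sin(kk * twist), 0)
  } else {
    rise <- 3.3
    # pleat offset chosen so consecutive CA-CA distance is 3.8 A
    pleat <- sqrt(3.8^2 - rise^2) / 2
    kk <- seq_len(n) - 1
    side <- ifelse(kk %% 2 == 0, 1, -1)
    local_ca <- cbind(side * pleat, rep(0, n), kk * rise)
    radial <- cbind(side, rep(0, n), rep(0, n))
  }
  axis_len <- (n - 1) * rise
  target_len <- vnorm(b - a)
  scale <- target_len / axis_len
  lo <- 1 - params$axial_clamp; hi <- 1 + params$axial_clamp
  if (scale < lo || scale > hi) {
    warning("stick/segment length mismatch: axial scale ", round(scale, 2),
            " clamped to [", lo, ", ", hi, "]", call. = FALSE)
    scale <- min(hi, max(lo, scale))
  }
  local_ca[, 3] <- local_ca[, 3] * scale
  u <- (b - a) / target_len
  R <- rotation_to(u)
  ca <- sweep(local_ca %*% t(R), 2, a, `+`)
  sc_dist <- sidechain_distances[aa]
  if (anyNA(sc_dist)) {
    stop("unknown residue type: ", paste(unique(aa[is.na(sc_dist)]), collapse = ", "),
         call. = FALSE)
  }
  sc <- ca + (radial %*% t(R)) * sc_dist
  out <- tibble(k = seq_len(n), aa = aa,
                ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
                sc_x = sc[, 1], sc_y = sc[, 2], sc_z = sc[, 3])
  structure(out, class = c("sse_model", class(out)), t = t)
}

#' Side-chain contact test
#'
#' Two residues are in contact when their side-chain centers are within the
#' type-dependent cutoff (inclusive).
#'
#' @param res_a,res_b single rows of `sse_model` tables
#' @param params an [energy_params()]
#' @return logical
#' @export
in_contact <- function(res_a, res_b, params = energy_params()) {
  d <- sqrt((res_a$sc_x - res_b$sc_x)^2 + (res_a$sc_y - res_b$sc_y)^2 +
            (res_a$sc_z - res_b$sc_z)^2)
  d <= contact_cutoff(res_a$aa, res_b$aa, params)
}

#' Multi-well pairwise energy
#'
#' A Lennard-Jones-style repulsion modified by Gaussian wells:
#' `(rep_scale/r)^12 - sum_k d_k exp(-(r - r_k)^2 / (2 sigma_k^2))`.
#' Continuous in `r`, attractive near well centers, vanishing at long range.
#' Pair parameters are symmetric, so the energy is symmetric in the two
#' residue types.
#'
#' @param r side-chain center distance(s), Angstrom
#' @param type_a,type_b residue types (1-letter)
#' @param params an [energy_params()]
#' @return energy value(s)
#' @export
multiwell_energy <- function(r, type_a = "A", type_b = "A", params = energy_params()) {
  stopifnot(all(r > 0))
  contact_cutoff(type_a, type_b, params)  # validates the types
  rep_term <- (params$rep_scale / r)^12
  well_term <- rep(0, length(r))
  for (k in seq_len(nrow(params$wells))) {
    well_term <- well_term + params$wells$d[k] *
      exp(-(r - params$wells$r[k])^2 / (2 * params$wells$sigma[k]^2))
  }
  rep_term - well_term
}

model_sc <- function(m) as.matrix(m[, c("sc_x", "sc_y", "sc_z")])

#' Pairwise SSE contact energy W_e
#'
#' Sums the multi-well energy over all inter-model residue pairs in contact
#' plus the intra-model contact pairs within each model (sequence
#' separation of at least 2, so bonded neighbors are excluded). Only the
#' two SSE models enter; the rest of the protein is ignored.
#'
#' @param m1,m2 `sse_model` tables
#' @param params an [energy_params()]
#' @return a list: `we` (the summed energy), `n_inter` and `n_intra`
#'   (contact counts), `has_contacts` (any inter-model contact)
#' @export
pair_energy <- function(m1, m2, params = energy_params()) {
  s1 <- model_sc(m1); s2 <- model_sc(m2)
  we <- 0; n_inter <- 0L; n_intra <- 0L
  for (a in seq_len(nrow(s1))) {
    d <- sqrt(colSums((t(s2) - s1[a, ])^2))
    for (b in seq_len(nrow(s2))) {
      if (d[b] <= contact_cutoff(m1$aa[a], m2$aa[b], params)) {
        we <- we + multiwell_energy(d[b], m1$aa[a], m2$aa[b], params)
        n_inter <- n_inter + 1L
      }
    }
  }
  intra <- function(m, s) {
    acc <- 0; cnt <- 0L
    if (nrow(s) > 2) {
      for (a in seq_len(nrow(s) - 2)) {
        for (b in (a + 2):nrow(s)) {
          d <- sqrt(sum((s[a, ] - s[b, ])^2))
          if (d <= contact_cutoff(m$aa[a], m$aa[b], params)) {
            acc <- acc + multiwell_energy(d, m$aa[a], m$aa[b], params)
            cnt <- cnt + 1L
          }
        }
      }
    }
    list(acc = acc, cnt = cnt)
  }
  i1 <- intra(m1, s1); i2 <- intra(m2, s2)
  list(we = we + i1$acc + i2$acc,
       n_inter = n_inter, n_intra = i1$cnt + i2$cnt,
       has_contacts = n_inter > 0L)
}

#' Energy edge weight
#'
#' `W_e` when the two secondary structures are in contact, the constant `e`
#' otherwise.
#'
#' @param we summed contact energy
#' @param has_contacts whether any inter-model contact exists
#' @param e_const no-contact constant
#' @return the edge weight
#' @export
energy_edge_weight <- function(we, has_contacts, e_const = 0) {
  ifelse(has_contacts, we, e_const)
}

#' Attach energy scores to a topology graph
#'
#' Builds the ideal-geometry SSE model for every assignment node (the model
#' depends on segment, stick and direction) and computes the pairwise
#' contact energy for every edge, stored in edge columns `we` and
#' `has_contacts`.
#'
#' @param graph a `topology_graph`
#' @param params an [energy_params()]
#' @param aa_of optional function(segment row) returning the residue types
#'   of a segment; defaults to all-alanine models
#' @return the graph with `we` and `has_contacts` edge columns
#' @export
compute_energy_scores <- function(graph, params = energy_params(), aa_of = NULL) {
  e <- graph$edges
  if (nrow(e) == 0) {
    e$we <- double(0); e$has_contacts <- logical(0)
    graph$edges <- e
    return(graph)
  }
  seg_aa <- function(i) {
    seg <- graph$segments[graph$segments$i == i, ]
    if (is.null(aa_of)) "A" else aa_of(seg)
  }
  models <- new.env(parent = emptyenv())
  model_for <- function(i, j, t) {
    key <- paste(i, j, t)
    got <- models[[key]]
    if (!is.null(got)) return(got)
    m <- suppressWarnings(build_sse_model(
      graph$sticks[graph$sticks$j == j, ],
      graph$segments[graph$segments$i == i, ],
      t, aa = seg_aa(i), params = params))
    models[[key]] <- m
    m
  }
  we <- double(nrow(e)); hc <- logical(nrow(e))
  for (r in seq_len(nrow(e))) {
    pe <- pair_energy(model_for(e$i[r], e$j[r], e$t[r]),
                      model_for(e$i2[r], e$j2[r], e$t2[r]), params)
    we[r] <- energy_edge_weight(pe$we, pe$has_contacts, params$e_const)
    hc[r] <- pe$has_contacts
  }
  e$we <- we; e$has_contacts <- hc
  graph$edges <- e
  graph
}
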