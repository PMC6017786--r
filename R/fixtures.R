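# Synthetic desk-scale fixtures: toy SSE bundles with known topology,
# rasterized loop skeletons and packing-angle samples. The generator mirrors
# the benchmark protocol at toy scale: ideal SSE geometry, sticks derived
# from CA end triangles, a skeleton that traces exactly the loops.

#' Generate a toy SSE bundle with known topology
#'
#' Places `n_helices + n_strands` ideal SSE axes in a serpentine arrangement
#' (consecutive elements antiparallel, axes about `spacing` apart), builds
#' the CA trace (ideal helices of rise 1.5 A and radius 2.3 A; pleated
#' strands of rise 3.3 A), connects consecutive elements with straight
#' loops whose residue counts are drawn from `loop_len_range`, and derives
#' segments and sticks exactly as the structure pipeline does. Loop spans
#' are checked against the placed end-to-end gaps so the true topology is
#' feasible by construction (an error is raised otherwise). Sequence order
#' of SSE types is a seeded random shuffle unless `shuffle_types = FALSE`
#' (all-helix bundles are unaffected).
#'
#' @param n_helices,n_strands number of helices / strands (total >= 1)
#' @param loop_len_range integer range of loop lengths in residues
#' @param seed integer seed; the bundle is a pure function of its arguments
#' @param spacing distance between consecutive SSE axes, Angstrom
#' @param helix_len_range,strand_len_range residue count ranges
#' @param shuffle_types randomize the sequence order of SSE types
#' @return a `fixture_bundle`: chain, annotation, segments, sticks, loops
#'   (polylines + residue counts), the true topology (`i`, `j`, `t`) and the
#'   generator parameters
#' @export
make_bundle <- function(n_helices, n_strands = 0, loop_len_range = c(3, 5),
                        seed = 1, spacing = 13,
                        helix_len_range = c(11, 15), strand_len_range = c(6, 9),
                        shuffle_types = TRUE) {
  n <- n_helices + n_strands
  if (n < 1) stop("need at least one SSE", call. = FALSE)
  set.seed(seed)
  types <- c(rep("H", n_helices), rep("E", n_strands))
  if (shuffle_types && n > 1) types <- sample(types)

  lens <- ifelse(types == "H",
                 sample(seq(helix_len_range[1], helix_len_range[2]), n, replace = TRUE),
                 sample(seq(strand_len_range[1], strand_len_range[2]), n, replace = TRUE))
  loop_aa <- sample(seq(loop_len_range[1], loop_len_range[2]),
                    max(n - 1, 1), replace = TRUE)

  rise <- ifelse(types == "H", 1.5, 3.3)
  axis_len <- (lens - 1) * rise

  # serpentine placement: element k runs vertically at x ~ k*spacing,
  # alternating up/down so consecutive ends face each other
  starts <- ends <- matrix(NA_real_, n, 3)
  dirv <- matrix(NA_real_, n, 3)
  zcur <- 0; updown <- 1
  for (k in seq_len(n)) {
    x <- (k - 1) * spacing + stats::runif(1, -0.5, 0.5)
    y <- stats::runif(1, -1.5, 1.5)
    z0 <- zcur + stats::runif(1, -1, 1)
    starts[k, ] <- c(x, y, z0)
    dirv[k, ] <- c(0, 0, updown)
    ends[k, ] <- starts[k, ] + dirv[k, ] * axis_len[k]
    zcur <- ends[k, 3]
    updown <- -updown
  }

  # feasibility of the truth: every consecutive gap must fit its loop span.
  # Loops are routed over a detour apex so the polyline's contour length is
  # close to the loop's stretched span, as a real loop's skeleton trace is.
  loop_polys <- list()
  if (n > 1) {
    for (k in seq_len(n - 1)) {
      chord <- starts[k + 1, ] - ends[k, ]
      gap <- vnorm(chord)
      s_len_k <- (loop_aa[k] + 1) * 3.8
      if (s_len_k <= gap) {
        stop("infeasible bundle: loop of ", loop_aa[k],
             " residues cannot span the ", round(gap, 1), " A gap", call. = FALSE)
      }
      # the skeleton traces the loop backbone: contour of at least the
      # stretched span (loop_aa + 1) * 3.8 A, usually a little more since
      # skeleton traces wander. The extra length over the straight gap is
      # taken up by a sideways meander whose self-distance stays above the
      # cluster-linking cutoff (a planar horseshoe would fuse with itself)
      arc <- max(s_len_k * stats::runif(1, 1.0, 1.2), gap)
      if (arc > gap * 1.001) {
        # circular corkscrew along the chord: exact contour length
        # sqrt(gap^2 + (2 pi w rho)^2), constant gentle curvature (no
        # hairpins for the clustering to collapse), coil pitch gap/w well
        # above the 3 A cluster-linking cutoff
        u <- chord / gap
        e1 <- pracma_cross(u, c(0, 0, 1))
        if (vnorm(e1) < 1e-6) e1 <- c(0, 1, 0) else e1 <- e1 / vnorm(e1)
        e1 <- e1 * (if (k %% 2 == 0) 1 else -1)
        e2 <- pracma_cross(u, e1)
        w <- 2
        rho <- sqrt(arc^2 - gap^2) / (2 * pi * w)
        tt <- seq(0, 1, length.out = max(16L, ceiling(arc / 0.5)))
        loop_polys[[k]] <- t(vapply(tt, function(f) {
          ends[k, ] + f * chord +
            rho * ((cos(2 * pi * w * f) - 1) * e1 + sin(2 * pi * w * f) * e2)
        }, double(3)))
      } else {
        loop_polys[[k]] <- rbind(ends[k, ], starts[k + 1, ])
      }
    }
  }

  # CA trace: ideal SSE geometry along each axis, loops on straight lines
  chain_rows <- list()
  res_id <- 0L
  first_res <- last_res <- integer(n)
  helix_ca <- function(k) {
    kk <- seq_len(lens[k]) - 1
    twist <- 100 * pi / 180
    u <- dirv[k, ]
    R <- rotation_to(u)
    local <- cbind(2.3 * cos(kk * twist), 2.3 * sin(kk * twist), kk * 1.5)
    sweep(local %*% t(R), 2, starts[k, ], `+`)
  }
  strand_ca <- function(k) {
    kk <- seq_len(lens[k]) - 1
    u <- dirv[k, ]
    R <- rotation_to(u)
    pleat <- sqrt(3.8^2 - 3.3^2) / 2
    side <- ifelse(kk %% 2 == 0, 1, -1)
    local <- cbind(side * pleat, rep(0, lens[k]), kk * 3.3)
    sweep(local %*% t(R), 2, starts[k, ], `+`)
  }
  add_res <- function(p) {
    res_id <<- res_id + 1L
    chain_rows[[length(chain_rows) + 1L]] <<- tibble(
      res_id = res_id, aa = "A",
      n_x = p[1] - 0.5, n_y = p[2], n_z = p[3] - 0.9,
      ca_x = p[1], ca_y = p[2], ca_z = p[3],
      c_x = p[1] + 0.5, c_y = p[2], c_z = p[3] + 0.9)
  }
  for (k in seq_len(n)) {
    ca <- if (types[k] == "H") helix_ca(k) else strand_ca(k)
    first_res[k] <- res_id + 1L
    for (r in seq_len(nrow(ca))) add_res(ca[r, ])
    last_res[k] <- res_id
    if (k < n && loop_aa[k] > 0) {
      poly <- loop_polys[[k]]
      seg_len <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                               poly[-nrow(poly), , drop = FALSE])^2))
      cum <- c(0, cumsum(seg_len))
      total <- cum[length(cum)]
      for (f in seq_len(loop_aa[k]) / (loop_aa[k] + 1)) {
        dtarget <- f * total
        s <- max(which(cum <= dtarget + 1e-12)); s <- min(s, length(seg_len))
        frac <- (dtarget - cum[s]) / seg_len[s]
        add_res(poly[s, ] + frac * (poly[s + 1, ] - poly[s, ]))
      }
    }
  }
  chain <- dplyr::bind_rows(chain_rows)

  annotation <- tibble(type = types, first_res = first_res, last_res = last_res)
  segments <- extract_segments(annotation, min_helix_aa = 1L, min_strand_aa = 1L)
  sticks <- extract_sticks(chain, segments)
  # true topology: segment i sits on the stick derived from it, run forward
  truth <- tibble(i = sticks$seg_i, j = sticks$j, t = 0L)
  truth <- truth[order(truth$i), ]

  loops <- if (n > 1) {
    lapply(seq_len(n - 1), function(k) {
      list(poly = loop_polys[[k]], loop_aa = loop_aa[k])
    })
  } else list()

  # terminal tails: the chain termini leave short skeleton traces beyond the
  # first and last SSE, which is what anchors the free stick ends
  tail1_dir <- (-dirv[1, ] + c(-1.2, 0, 0)); tail1_dir <- tail1_dir / vnorm(tail1_dir)
  tailn_dir <- (dirv[n, ] + c(1.2, 0, 0)); tailn_dir <- tailn_dir / vnorm(tailn_dir)
  tails <- list(
    rbind(starts[1, ], starts[1, ] + 8 * tail1_dir),
    rbind(ends[n, ], ends[n, ] + 8 * tailn_dir)
  )

  structure(
    list(chain = chain, annotation = annotation, segments = segments,
         sticks = sticks, truth = truth, loops = loops, tails = tails,
         axis_starts = starts, axis_ends = ends,
         params = list(n_helices = n_helices, n_strands = n_strands,
                       loop_len_range = loop_len_range, seed = seed,
                       spacing = spacing, types = types, lens = lens,
                       loop_aa = loop_aa)),
    class = "fixture_bundle"
  )
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("<fixture_bundle>", nrow(x$segments), "segments (",
      sum(x$segments$type == "H"), "H /", sum(x$segments$type == "E"),
      "E ),", nrow(x$chain), "residues, seed", x$params$seed, "\n")
  invisible(x)
}

#' Rasterize a bundle's loops into a skeleton grid
#'
#' Voxelizes the loop polylines (and optionally the SSE axes) at the given
#' spacing, emulating the externally produced skeleton of a volume.
#'
#' @param bundle a [make_bundle()] fixture
#' @param spacing voxel spacing in Angstrom
#' @param include_sse also rasterize the SSE axes
#' @param margin grid padding in Angstrom
#' @return a [skeleton_grid()]
#' @export
rasterize_skeleton <- function(bundle, spacing = 1.0, include_sse = FALSE,
                               margin = 3) {
  polys <- c(lapply(bundle$loops, function(l) l$poly), bundle$tails)
  if (include_sse) {
    polys <- c(polys, lapply(seq_len(nrow(bundle$axis_starts)), function(k) {
      rbind(bundle$axis_starts[k, ], bundle$axis_ends[k, ])
    }))
  }
  if (length(polys) == 0) {
    return(skeleton_grid(array(0L, c(2, 2, 2)), spacing, c(0, 0, 0)))
  }
  all_pts <- do.call(rbind, polys)
  lo <- apply(all_pts, 2, min) - margin
  hi <- apply(all_pts, 2, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  occ <- array(0L, dims)
  for (p in polys) {
    for (s in seq_len(nrow(p) - 1)) {
      a <- p[s, ]; b <- p[s + 1, ]
      len <- vnorm(b - a)
      nstep <- max(2L, ceiling(len / (spacing / 2)) + 1L)
      fr <- seq(0, 1, length.out = nstep)
      pts <- cbind(a[1] + fr * (b[1] - a[1]),
                   a[2] + fr * (b[2] - a[2]),
                   a[3] + fr * (b[3] - a[3]))
      idx <- unique(round(sweep(pts, 2, lo) / spacing)) + 1
      occ[idx] <- 1L
    }
  }
  skeleton_grid(occ, spacing, lo)
}

#' Corrupt a skeleton with gaps and spurs
#'
#' Emulates the discontinuities and misleading points of real skeletons:
#' removes `gap_count` runs of voxels (each clearing a sphere of diameter
#' `gap_len` around a random foreground voxel) and appends `spur_count`
#' short random straight branches. Deterministic under `seed`; with zero
#' gaps and spurs the grid is returned unchanged.
#'
#' @param grid a [skeleton_grid()]
#' @param gap_count number of gaps to cut
#' @param gap_len gap length in Angstrom
#' @param spur_count number of spurs to add
#' @param seed integer seed
#' @param spur_len spur length in Angstrom
#' @return the corrupted `skeleton_grid`
#' @export
corrupt_skeleton <- function(grid, gap_count = 0, gap_len = 8, spur_count = 0,
                             seed = 1, spur_len = 4) {
  if (gap_count == 0 && spur_count == 0) return(grid)
  set.seed(seed)
  occ <- grid$occ
  for (g in seq_len(gap_count)) {
    vox <- skeleton_voxels(skeleton_grid(occ, grid$spacing, grid$origin))
    if (nrow(vox) == 0) break
    c_idx <- sample(nrow(vox), 1)
    center <- c(vox$x[c_idx], vox$y[c_idx], vox$z[c_idx])
    d <- sqrt((vox$x - center[1])^2 + (vox$y - center[2])^2 + (vox$z - center[3])^2)
    cut <- d <= gap_len / 2
    occ[cbind(vox$ix[cut], vox$iy[cut], vox$iz[cut])] <- 0L
  }
  dims <- dim(occ)
  for (s in seq_len(spur_count)) {
    vox <- skeleton_voxels(skeleton_grid(occ, grid$spacing, grid$origin))
    if (nrow(vox) == 0) break
    c_idx <- sample(nrow(vox), 1)
    base <- c(vox$x[c_idx], vox$y[c_idx], vox$z[c_idx])
    u <- stats::rnorm(3); u <- u / vnorm(u)
    fr <- seq(0, spur_len, by = min(grid$spacing) / 2)
    pts <- t(vapply(fr, function(f) base + f * u, double(3)))
    idx <- round(sweep(pts, 2, grid$origin) / grid$spacing) + 1
    ok <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
          idx[, 2] >= 1 & idx[, 2] <= dims[2] &
          idx[, 3] >= 1 & idx[, 3] <= dims[3]
    occ[idx[ok, , drop = FALSE]] <- 1L
  }
  skeleton_grid(occ, grid$spacing, grid$origin)
}

#' Sample packing angles from the bivariate normal
#'
#' i.i.d. draws of `(phi, eta)` from the normal with the parameters' mean
#' and covariance; used for parameter-recovery checks of [fit_params()].
#'
#' @param params a [geometry_params()]
#' @param n number of draws
#' @param seed integer seed
#' @return a tibble with columns `phi` and `eta`
#' @export
sample_angles <- function(params, n, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  x <- MASS::mvrnorm(n, mu = params$lambda, Sigma = params$sigma)
  x <- matrix(x, ncol = 2)
  tibble(phi = x[, 1], eta = x[, 2])
}

#' Write a bundle to disk in pipeline formats
#'
#' Writes the chain as PDB, the segments and sticks as TSV tables, the
#' rasterized skeleton as MRC and the truth as TSV, so that tests exercise
#' the same I/O layer the real pipeline uses.
#'
#' @param bundle a [make_bundle()] fixture
#' @param dir output directory (created if needed)
#' @param spacing skeleton voxel spacing
#' @return the directory, invisibly
#' @export
write_bundle <- function(bundle, dir, spacing = 1.0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ch <- bundle$chain
  nres <- nrow(ch)
  xyz <- matrix(NA_real_, nres * 3, 3)
  elety <- character(nres * 3); resno <- integer(nres * 3)
  for (r in seq_len(nres)) {
    base <- (r - 1) * 3
    xyz[base + 1, ] <- c(ch$n_x[r], ch$n_y[r], ch$n_z[r])
    xyz[base + 2, ] <- c(ch$ca_x[r], ch$ca_y[r], ch$ca_z[r])
    xyz[base + 3, ] <- c(ch$c_x[r], ch$c_y[r], ch$c_z[r])
    elety[base + 1:3] <- c("N", "CA", "C")
    resno[base + 1:3] <- ch$res_id[r]
  }
  natom <- nres * 3
  bio3d::write.pdb(file = file.path(dir, "bundle.pdb"),
                   xyz = as.numeric(t(xyz)), resno = resno,
                   resid = rep("ALA", natom), eleno = seq_len(natom),
                   elety = elety, chain = rep("A", natom),
                   o = rep(1, natom), b = rep(0, natom))
  write_segments(bundle$segments, file.path(dir, "segments.tsv"))
  write_sticks(bundle$sticks, file.path(dir, "sticks.tsv"))
  write_skeleton(rasterize_skeleton(bundle, spacing), file.path(dir, "skeleton.mrc"))
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
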