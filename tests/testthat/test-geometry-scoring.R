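test_that("packing vectors follow the SSE and loop construction", {
  # two parallel vertical helices offset in x
  ca <- rbind(cbind(0, 0, 0:6), cbind(8, 0, 6:0))
  chain <- toy_chain(ca)
  seg <- toy_segments(c("H", "H"), first = c(1, 8), last = c(7, 14))
  pv <- packing_vectors(chain, seg[1, ], seg[2, ])
  v1n <- pv$V1 / sqrt(sum(pv$V1^2)); v3n <- pv$V3 / sqrt(sum(pv$V3^2))
  expect_equal(abs(sum(v1n * v3n)), 1, tolerance = 1e-9)  # V1 parallel to V3
  expect_equal(sum(pv$V1 * pv$V3) < 0, TRUE)              # antiparallel here

  # a 2-residue strand: V3 = CA_last - CA_first
  seg2 <- toy_segments(c("H", "E"), first = c(1, 8), last = c(7, 9))
  pv2 <- packing_vectors(chain, seg2[1, ], seg2[2, ])
  expect_equal(pv2$V3, c(ca[9, ] - ca[8, ]), tolerance = 1e-12)

  # missing coordinates exclude the pair
  chain_na <- chain
  chain_na$n_x[1] <- NA
  expect_s3_class(packing_vectors(chain_na, seg[1, ], seg[2, ]), "geometry_skip")
})

test_that("dihedral angle obeys the sign convention and canonicalization", {
  expect_equal(dihedral_phi(c(1, 0, 0), c(0, 0, 1), c(1, 0, 0)), 0)
  expect_equal(dihedral_phi(c(1, 0, 0), c(0, 0, 1), c(-1, 0, 0)), 180)
  expect_equal(dihedral_phi(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0)), 90)
  expect_equal(dihedral_phi(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0)), -90)
  expect_true(is.na(dihedral_phi(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0))))
})

test_that("packing-angle sum spans [0, 360]", {
  expect_equal(packing_eta(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(packing_eta(c(0, 0, 1), c(0, 0, -1), c(0, 0, 1)), 360)
  expect_equal(packing_eta(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0)), 180)
})

test_that("geometry score peaks at the fitted mean", {
  p <- geometry_params()
  expect_identical(geometry_score(-4.501, 203.207, p), p$A)
  expect_equal(geometry_score(-4.501 + sqrt(5581.972), 203.207, p),
               p$A * exp(-1 / 2), tolerance = 1e-12)
  for (d in c(3, 40, 111)) {
    expect_equal(geometry_score(-4.501 + d, 203.207, p),
                 geometry_score(-4.501 - d, 203.207, p))
  }
  f <- geometry_score(seq(-180, 180, by = 20), rep(200, 19), p)
  expect_true(all(f > 0 & f <= p$A))
  expect_error(geometry_params(sigma = matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("score decreases with Mahalanobis distance and ignores the frame", {
  p <- geometry_params()
  md <- seq(0, 3, by = 0.5)
  f <- geometry_score(p$lambda[1] + md * sqrt(p$sigma[1, 1]), p$lambda[2], p)
  expect_true(all(diff(f) < 0))

  # random rigid rotations leave (phi, eta) and hence the score unchanged
  set.seed(42)
  for (k in 1:10) {
    V1 <- stats::rnorm(3); V2 <- stats::rnorm(3); V3 <- stats::rnorm(3)
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    expect_equal(dihedral_phi(q %*% V1, q %*% V2, q %*% V3),
                 dihedral_phi(V1, V2, V3), tolerance = 1e-9)
    expect_equal(packing_eta(q %*% V1, q %*% V2, q %*% V3),
                 packing_eta(V1, V2, V3), tolerance = 1e-9)
  }
})

test_that("fit_params recovers mean and variances from samples", {
  expect_error(fit_params(data.frame(phi = c(1, 1, 1), eta = c(2, 2, 2))),
               "degenerate")
  two <- fit_params(data.frame(phi = c(0, -9), eta = c(200, 206)))
  expect_equal(two$lambda, c(-4.5, 203))

  p <- geometry_params()
  s <- sample_angles(p, 20000, seed = 7)
  hat <- fit_params(s)
  expect_lt(max(abs(hat$lambda - p$lambda)), 1.5)
  expect_lt(max(abs(diag(hat$sigma) / diag(p$sigma) - 1)), 0.08)
  expect_equal(hat$sigma[1, 2], 0)
})

test_that("edge weights use the standalone transform when geometry is alone", {
  p <- geometry_params()
  expect_equal(geometry_edge_weight(p$lambda[1], p$lambda[2], p, "standalone"), 0)
  expect_equal(geometry_edge_weight(p$lambda[1], p$lambda[2], p, "combined"), p$A)
  expect_equal(geometry_edge_weight(170, 10, p, "standalone"), p$A,
               tolerance = 1e-3)
})

test_that("stick packing angles are direction-aware and fill graph edges", {
  st <- toy_sticks(c("H", "H"),
                   p0 = rbind(c(0, 0, 0), c(8, 0, 6)),
                   p1 = rbind(c(0, 0, 6), c(10, 0, 0)))
  a1 <- stick_packing_angles(st, 1, 0, 2, 0)
  a2 <- stick_packing_angles(st, 1, 1, 2, 1)
  expect_false(isTRUE(all.equal(a1$eta, a2$eta)))

  fx <- feasible_fixture(2, 2, 0, 0)
  g <- compute_geometry_scores(build_graph(fx$segments, fx$sticks))
  expect_true("f" %in% names(g$edges))
  expect_true(all(g$edges$f >= 0 & g$edges$f <= 1))
})

test_that("chain angle extraction matches the planted axis geometry", {
  # plant two known axes: V1 along +z, V3 along +x, loop along +y.
  # phi is the signed angle from V1-perp to V3-perp about V2 = -90 here;
  # theta1 = theta2 = 90 so eta = 180.
  ca1 <- cbind(0, 0, seq(0, 6))            # segment 1: up z
  ca_loop <- cbind(0, c(2, 4), 6)
  ca2 <- cbind(seq(0, 6), 6, 6)            # segment 2: along x
  chain <- toy_chain(rbind(ca1, ca_loop, ca2))
  # strands use bare CA endpoints, making the planted vectors exact
  seg <- toy_segments(c("E", "E"), first = c(1, 10), last = c(7, 16))
  tab <- chain_packing_angles(chain, seg)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$eta, 180, tolerance = 1e-9)
  expect_equal(abs(tab$phi), 90, tolerance = 1e-9)
})
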