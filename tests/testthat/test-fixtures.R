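fake_bundle <- function(polys, loop_aa = 2L) {
  structure(list(loops = lapply(polys, function(p) list(poly = p, loop_aa = loop_aa)),
                 tails = list()),
            class = "fixture_bundle")
}

test_that("a minimal bundle is self-consistent and feasible", {
  b <- make_bundle(2, 0, seed = 1)
  expect_equal(nrow(b$segments), 2)
  expect_equal(nrow(b$sticks), 2)
  g <- build_graph(b$segments, b$sticks, b$chain)
  # the truth's edge exists in the graph
  tr <- b$truth
  hit <- g$edges[g$edges$i == tr$i[1] & g$edges$i2 == tr$i[2] &
                 g$edges$j == tr$j[1] & g$edges$j2 == tr$j[2] &
                 g$edges$t == tr$t[1] & g$edges$t2 == tr$t[2], ]
  expect_equal(nrow(hit), 1)
})

test_that("every consecutive true pair satisfies the loop-span constraint", {
  for (s in 1:15) {
    set.seed(s)
    b <- make_bundle(sample(2:4, 1), sample(0:2, 1), seed = s)
    tr <- b$truth
    for (k in seq_len(nrow(tr) - 1)) {
      sl <- s_length(b$segments, tr$i[k], tr$i[k + 1], b$chain)
      vl <- v_length(b$sticks, tr$j[k], tr$t[k], tr$j[k + 1], tr$t[k + 1])
      expect_lte(vl, sl)
    }
  }
})

test_that("rasterization respects discretization bounds", {
  straight <- fake_bundle(list(rbind(c(0, 0, 0), c(10, 0, 0))))
  grid <- rasterize_skeleton(straight, spacing = 1)
  expect_true(sum(grid$occ) %in% 10:12)

  empty <- fake_bundle(list())
  expect_equal(sum(rasterize_skeleton(empty)$occ), 0)

  # measured trace length between the line's ends is close to its length
  sg <- build_skelg(reduce_skeleton(grid, rng_seed = 2))
  sticks <- toy_sticks(c("H", "H"),
                       p0 = rbind(c(-4, 0, 0), c(14, 0, 0)),
                       p1 = rbind(c(-0.5, 0, 0), c(10.5, 0, 0)))
  sg <- mark_endpoints(sg, sticks)
  tr <- w_trace(sg, 1, 0, 2, 0, s_len = 10)
  expect_lt(tr, 2.5)
})

test_that("corruption is seeded, bounded and reversible at zero", {
  b <- make_bundle(3, 0, seed = 8)
  grid <- rasterize_skeleton(b)
  expect_identical(corrupt_skeleton(grid, 0, 8, 0, seed = 1)$occ, grid$occ)
  c1 <- corrupt_skeleton(grid, gap_count = 1, gap_len = 8, seed = 5)
  c2 <- corrupt_skeleton(grid, gap_count = 1, gap_len = 8, seed = 5)
  expect_identical(c1$occ, c2$occ)
  expect_lt(sum(c1$occ), sum(grid$occ))
  withspurs <- corrupt_skeleton(grid, 0, 8, spur_count = 2, seed = 5)
  expect_gt(sum(withspurs$occ), sum(grid$occ))
})

test_that("an 8 A gap is bridged but a 15 A gap breaks the trace", {
  line <- fake_bundle(list(rbind(c(0, 0, 0), c(30, 0, 0))))
  grid <- rasterize_skeleton(line, spacing = 1)
  sticks <- toy_sticks(c("H", "H"),
                       p0 = rbind(c(-5, 0, 0), c(35, 0, 0)),
                       p1 = rbind(c(-0.5, 0, 0), c(30.5, 0, 0)))
  cut8 <- grid; cut8$occ[14:21, , ] <- 0L   # 8 A run removed mid-line
  sg8 <- mark_endpoints(bridge_gaps(merge_cliques(
    build_skelg(reduce_skeleton(cut8, rng_seed = 3)))), sticks)
  expect_true(is.finite(w_trace(sg8, 1, 0, 2, 0, s_len = 30)))

  cut15 <- grid; cut15$occ[9:23, , ] <- 0L  # 15 A run removed
  sg15 <- mark_endpoints(bridge_gaps(merge_cliques(
    build_skelg(reduce_skeleton(cut15, rng_seed = 3)))), sticks)
  expect_equal(w_trace(sg15, 1, 0, 2, 0, s_len = 30), Inf)
})

test_that("angle samples are seeded draws from the stated normal", {
  p <- geometry_params()
  s1 <- sample_angles(p, 500, seed = 9)
  s2 <- sample_angles(p, 500, seed = 9)
  expect_identical(s1, s2)
  s3 <- sample_angles(p, 500, seed = 10)
  expect_false(identical(s1, s3))
  big <- sample_angles(p, 20000, seed = 1)
  expect_equal(mean(big$phi), p$lambda[1], tolerance = 1)
  expect_equal(stats::var(big$eta), p$sigma[2, 2], tolerance = 0.05)

  tiny <- sample_angles(geometry_params(sigma = diag(c(1e-10, 1e-10))), 1, seed = 2)
  expect_equal(c(tiny$phi, tiny$eta), p$lambda, tolerance = 1e-3)
})

test_that("write_bundle emits the pipeline's file formats", {
  b <- make_bundle(2, 1, seed = 14)
  dir <- tempfile()
  write_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir,
    c("bundle.pdb", "segments.tsv", "sticks.tsv", "skeleton.mrc", "truth.tsv")))))
  expect_equal(read_segments(file.path(dir, "segments.tsv")), b$segments)
  expect_equal(read_sticks(file.path(dir, "sticks.tsv")), b$sticks[, 1:8],
               tolerance = 1e-6)
  expect_equal(sum(read_skeleton(file.path(dir, "skeleton.mrc"))$occ),
               sum(rasterize_skeleton(b)$occ))
})
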