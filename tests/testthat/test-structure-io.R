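test_that("read_chain parses a minimal PDB and reports missing chains", {
  pdb <- tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.500  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   0.000   1.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       2.500   0.000   1.500  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       3.000   0.000   2.000  1.00  0.00           C",
    "ATOM      6  C   GLY A   2       3.500   0.000   2.500  1.00  0.00           C",
    "ATOM      7  CA  SER A   3       5.000   0.000   3.000  1.00  0.00           C",
    "END")
  writeLines(lines, pdb)
  ch <- read_chain(pdb, "A")
  expect_equal(nrow(ch), 3)
  expect_equal(ch$aa, c("A", "G", "S"))
  expect_equal(ch$ca_x, c(1, 3, 5))
  expect_true(is.na(ch$n_x[3]))  # SER has CA only
  expect_error(read_chain(pdb, "B"), "available chains: A")
})

test_that("bundle round trip through PDB keeps the residue count", {
  b <- make_bundle(2, 1, seed = 11)
  dir <- tempfile()
  write_bundle(b, dir)
  ch <- read_chain(file.path(dir, "bundle.pdb"), "A")
  expect_equal(nrow(ch), nrow(b$chain))
  expect_equal(ch$ca_x, b$chain$ca_x, tolerance = 1e-3)
})

test_that("extract_segments applies the detectability filters and renumbers", {
  ann <- tibble::tibble(type = c("H", "H", "E", "E"),
                        first_res = c(1L, 20L, 40L, 50L),
                        last_res = c(5L, 25L, 42L, 51L))
  seg <- extract_segments(ann)
  # 5-residue helix dropped, 6-residue helix and 3-residue strand kept,
  # 2-residue strand dropped
  expect_equal(seg$type, c("H", "E"))
  expect_equal(seg$first_res, c(20L, 40L))
  expect_equal(seg$i, c(1L, 2L))
  expect_equal(seg$length_aa, c(6L, 3L))

  expect_equal(nrow(extract_segments(ann[0, ])), 0)
  expect_error(extract_segments(tibble::tibble(
    type = c("H", "H"), first_res = c(1L, 4L), last_res = c(6L, 12L))),
    "overlapping")
  # idempotence
  expect_equal(extract_segments(seg), seg)
})

test_that("extract_sticks builds end-triangle centroids, helices first", {
  ca <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 5), c(3, 0, 5), c(0, 3, 5))
  chain <- toy_chain(ca)
  seg <- toy_segments("E", 1, 6)
  st <- extract_sticks(chain, seg)
  expect_equal(unlist(st[1, c("x0", "y0", "z0")], use.names = FALSE), c(1, 1, 0))
  expect_equal(unlist(st[1, c("x1", "y1", "z1")], use.names = FALSE), c(1, 1, 5))

  # degenerate: first and last triangle are the same three CA atoms
  chain3 <- toy_chain(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)))
  expect_error(extract_sticks(chain3, toy_segments("E", 1, 3)), "degenerate")

  # helices ordered before strands with stable renumbering
  b <- make_bundle(2, 2, seed = 3)
  expect_equal(b$sticks$type, c("H", "H", "E", "E"))
  expect_equal(nrow(b$sticks), nrow(b$segments))
})

test_that("synthetic helix sticks sit on the generator's axes", {
  b <- make_bundle(3, 0, seed = 5)
  for (k in seq_len(nrow(b$sticks))) {
    i <- b$sticks$seg_i[k]
    a <- b$axis_starts[i, ]; bb <- b$axis_ends[i, ]
    u <- (bb - a) / sqrt(sum((bb - a)^2))
    for (end in 0:1) {
      p <- unlist(b$sticks[k, if (end == 0) c("x0", "y0", "z0") else c("x1", "y1", "z1")],
                  use.names = FALSE)
      # distance from the stick endpoint to the axis line
      v <- p - a
      d_axis <- sqrt(sum((v - sum(v * u) * u)^2))
      expect_lt(d_axis, 1.0)
    }
  }
})

test_that("stick tables round trip, validate and reorder", {
  b <- make_bundle(2, 1, seed = 9)
  f <- tempfile(fileext = ".tsv")
  write_sticks(b$sticks[, 1:8], f)
  back <- read_sticks(f)
  expect_equal(back, b$sticks[, 1:8], tolerance = 1e-6)

  writeLines(c("1\tH\t0\t0\t0\t1\t1\t1", "2\tX\t0\t0\t0\t1\t1\t1"), f)
  expect_error(read_sticks(f), "line 2.*type must be H or E")
  writeLines(c("1\tH\t0\t0\t0\t1\t1"), f)
  expect_error(read_sticks(f), "line 1")

  # strand listed before helix: reordered with a warning
  writeLines(c("1\tE\t0\t0\t0\t1\t1\t1", "2\tH\t5\t0\t0\t6\t1\t1"), f)
  expect_warning(st <- read_sticks(f), "reordered")
  expect_equal(st$type, c("H", "E"))
  expect_equal(st$j, c(1L, 2L))
  expect_equal(st$x0, c(5, 0))
})

test_that("segment tables round trip", {
  b <- make_bundle(2, 1, seed = 9)
  f <- tempfile(fileext = ".tsv")
  write_segments(b$segments, f)
  expect_equal(read_segments(f), b$segments)
  writeLines("1\tH\tx\t9", f)
  expect_error(read_segments(f), "line 1")
})
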