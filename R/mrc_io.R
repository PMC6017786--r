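#' Skeleton grid objects
#'
#' A `skeleton_grid` is a binarized voxel model of a cryo-EM skeleton: a 3D
#' occupancy array plus the voxel spacing and origin (in Angstrom) that map
#' array indices to physical coordinates. Voxel centers sit at
#' `origin + (index - 1) * spacing` per axis (1-based indices).
#'
#' @param occ a 3D array; nonzero entries are foreground voxels
#' @param spacing voxel spacing in Angstrom, length 1 or 3
#' @param origin physical coordinate of voxel (1,1,1), length 3
#' @return an object of class `skeleton_grid`
#' @export
skeleton_grid <- function(occ, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(dim(occ)) == 3)
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("voxel spacing must be positive", call. = FALSE)
  structure(
    list(occ = array(as.integer(occ != 0), dim = dim(occ)),
         spacing = spacing,
         origin = rep_len(as.numeric(origin), 3)),
    class = "skeleton_grid"
  )
}

#' @export
print.skeleton_grid <- function(x, ...) {
  cat("<skeleton_grid> ", paste(dim(x$occ), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 3), collapse = "/"),
      " A, ", sum(x$occ), " foreground\n", sep = "")
  invisible(x)
}

#' Foreground voxels of a skeleton grid
#'
#' @param grid a `skeleton_grid`
#' @return a tibble with integer indices `ix, iy, iz` and physical voxel
#'   center coordinates `x, y, z` in Angstrom
#' @export
skeleton_voxels <- function(grid) {
  idx <- which(grid$occ != 0, arr.ind = TRUE)
  tibble(
    ix = as.integer(idx[, 1]), iy = as.integer(idx[, 2]), iz = as.integer(idx[, 3]),
    x = unname(grid$origin[1] + (idx[, 1] - 1) * grid$spacing[1]),
    y = unname(grid$origin[2] + (idx[, 2] - 1) * grid$spacing[2]),
    z = unname(grid$origin[3] + (idx[, 3] - 1) * grid$spacing[3])
  )
}

#' Read a binarized skeleton from an MRC map
#'
#' Minimal MRC2014 reader (modes 0, 1 and 2). Voxels with stored density
#' strictly greater than `threshold` become foreground; spacing and origin
#' come from the map header (cell dimensions over sampling, plus the origin
#' record and any start offsets).
#'
#' @param map_file path to an MRC file
#' @param threshold density threshold; occupancy is `density > threshold`
#' @return a [skeleton_grid()]
#' @export
read_skeleton <- function(map_file, threshold = 0) {
  con <- file(map_file, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  nstart <- ints[5:7]; m <- ints[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")      # cell angles
  readBin(con, "integer", n = 3, size = 4, endian = "little")      # mapc/mapr/maps
  readBin(con, "numeric", n = 3, size = 4, endian = "little")      # dmin/dmax/dmean
  isp <- readBin(con, "integer", n = 2, size = 4, endian = "little") # ispg, nsymbt
  nsymbt <- isp[2]
  seek(con, 4 * 49)                                                # -> word 50
  orig <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  n <- nx * ny * nz
  dens <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    stop("unsupported MRC mode ", mode, call. = FALSE)
  )
  if (length(dens) != n) stop("truncated MRC data section", call. = FALSE)
  m[m == 0] <- c(nx, ny, nz)[m == 0]
  spacing <- cella / m
  if (any(spacing <= 0)) stop("non-positive voxel spacing in MRC header", call. = FALSE)
  origin <- orig + nstart * spacing
  occ <- array(dens > threshold, dim = c(nx, ny, nz))
  skeleton_grid(occ, spacing = spacing, origin = origin)
}

#' Write a skeleton grid as an MRC map
#'
#' Writes mode-2 (float32) MRC2014 with occupancy values 0/1, so that
#' `read_skeleton(write_skeleton(g, f))` round-trips the grid.
#'
#' @param grid a [skeleton_grid()]
#' @param map_file output path
#' @return `map_file`, invisibly
#' @export
write_skeleton <- function(grid, map_file) {
  d <- dim(grid$occ)
  con <- file(map_file, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d); wi(2)                      # nx ny nz, mode
  wi(c(0, 0, 0))                    # nxstart
  wi(d)                             # mx my mz
  wf(d * grid$spacing)              # cella
  wf(c(90, 90, 90))                 # cellb
  wi(c(1, 2, 3))                    # mapc mapr maps
  dens <- as.numeric(grid$occ != 0)
  wf(c(min(dens), max(dens), mean(dens)))
  wi(c(1, 0))                       # ispg, nsymbt
  wi(rep(0L, 25))                   # extra
  wf(grid$origin)                   # origin (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst, little-endian
  wf(stats::sd(dens))               # rms
  wi(0L)                            # nlabl
  writeBin(raw(800), con)           # labels
  wf(dens)
  invisible(map_file)
}
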