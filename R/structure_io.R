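#' Read one chain of a PDB file as a backbone table
#'
#' Extracts the ordered residues of a chain with their backbone (N, CA, C)
#' coordinates. Residues lacking a CA atom are dropped with a warning; N/C
#' may be `NA` (they are only needed for helix packing vectors).
#'
#' @param structure_file path to a PDB file
#' @param chain_id single chain identifier, e.g. `"A"`
#' @return a tibble with columns `res_id`, `aa` (1-letter code) and
#'   coordinate columns `n_x..n_z`, `ca_x..ca_z`, `c_x..c_z` in Angstrom,
#'   ordered by increasing `res_id`.
#' @export
read_chain <- function(structure_file, chain_id) {
  pdb <- bio3d::read.pdb(structure_file, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  chains <- sort(unique(atoms$chain))
  if (!chain_id %in% chains) {
    stop("chain '", chain_id, "' not found; available chains: ",
         paste(chains, collapse = ", "), call. = FALSE)
  }
  atoms <- atoms[atoms$chain == chain_id, , drop = FALSE]
  res_ids <- unique(atoms$resno)

  one <- function(rid) {
    ra <- atoms[atoms$resno == rid, , drop = FALSE]
    pick <- function(elety) {
      hit <- ra[ra$elety == elety, c("x", "y", "z"), drop = FALSE]
      if (nrow(hit) == 0) rep(NA_real_, 3) else as.numeric(hit[1, ])
    }
    ca <- pick("CA")
    if (anyNA(ca)) {
      warning("residue ", rid, " has no CA atom; skipped", call. = FALSE)
      return(NULL)
    }
    n <- pick("N"); cc <- pick("C")
    tibble(
      res_id = as.integer(rid),
      aa = bio3d::aa321(ra$resid[1]),
      n_x = n[1], n_y = n[2], n_z = n[3],
      ca_x = ca[1], ca_y = ca[2], ca_z = ca[3],
      c_x = cc[1], c_y = cc[2], c_z = cc[3]
    )
  }
  out <- dplyr::bind_rows(lapply(res_ids, one))
  if (nrow(out) == 0) stop("chain '", chain_id, "' has no usable residues", call. = FALSE)
  dplyr::arrange(out, .data$res_id)
}

#' Secondary-structure annotation from PDB HELIX/SHEET records
#'
#' @param structure_file path to a PDB file
#' @param chain_id chain to annotate
#' @return a tibble with columns `type` (`"H"`/`"E"`), `first_res`, `last_res`
#' @export
pdb_annotation <- function(structure_file, chain_id) {
  pdb <- bio3d::read.pdb(structure_file, verbose = FALSE)
  rows <- list()
  grab <- function(rec, type) {
    if (is.null(rec) || length(rec$start) == 0) return(NULL)
    keep <- rec$chain == chain_id
    if (!any(keep)) return(NULL)
    tibble(type = type,
           first_res = as.integer(rec$start[keep]),
           last_res = as.integer(rec$end[keep]))
  }
  out <- dplyr::bind_rows(grab(pdb$helix, "H"), grab(pdb$sheet, "E"))
  if (nrow(out) == 0) return(tibble(type = character(), first_res = integer(), last_res = integer()))
  dplyr::arrange(out, .data$first_res)
}

normalize_sse_type <- function(type) {
  up <- toupper(as.character(type))
  out <- ifelse(up %in% c("H", "HELIX"), "H",
                ifelse(up %in% c("E", "S", "STRAND", "SHEET"), "E", NA_character_))
  if (anyNA(out)) {
    stop("unknown SSE type token(s): ",
         paste(unique(type[is.na(out)]), collapse = ", "),
         " (expected H/helix or E/strand)", call. = FALSE)
  }
  out
}

#' Filter and renumber sequence SSE segments
#'
#' Short elements are removed to mimic what is detectable in a sub-nanometer
#' volume: helices of fewer than `min_helix_aa` residues and strands of fewer
#' than `min_strand_aa` residues are dropped (defaults keep helices longer
#' than five residues and strands longer than two). Survivors are renumbered
#' `1..M` in sequence order.
#'
#' @param annotation a data frame with columns `type`, `first_res`, `last_res`
#' @param min_helix_aa minimum helix length kept, in residues
#' @param min_strand_aa minimum strand length kept, in residues
#' @return a tibble of segments: `i`, `type`, `first_res`, `last_res`,
#'   `length_aa`
#' @export
extract_segments <- function(annotation, min_helix_aa = 6L, min_strand_aa = 3L) {
  ann <- as_tibble(annotation)
  need <- c("type", "first_res", "last_res")
  if (!all(need %in% names(ann))) {
    stop("annotation needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(ann) == 0) {
    return(tibble(i = integer(), type = character(),
                  first_res = integer(), last_res = integer(),
                  length_aa = integer()))
  }
  ann$type <- normalize_sse_type(ann$type)
  if (any(ann$first_res > ann$last_res)) stop("segment with first_res > last_res", call. = FALSE)
  ann <- dplyr::arrange(ann, .data$first_res)
  if (nrow(ann) > 1 && any(ann$first_res[-1] <= ann$last_res[-nrow(ann)])) {
    stop("overlapping annotation spans", call. = FALSE)
  }
  ann$length_aa <- as.integer(ann$last_res - ann$first_res + 1L)
  keep <- (ann$type == "H" & ann$length_aa >= min_helix_aa) |
          (ann$type == "E" & ann$length_aa >= min_strand_aa)
  out <- ann[keep, , drop = FALSE]
  out$i <- seq_len(nrow(out))
  out[, c("i", "type", "first_res", "last_res", "length_aa")]
}

seg_ca <- function(chain, seg) {
  rows <- chain[chain$res_id >= seg$first_res & chain$res_id <= seg$last_res, , drop = FALSE]
  as.matrix(rows[, c("ca_x", "ca_y", "ca_z")])
}

#' Derive sticks from a chain and its segments
#'
#' Each stick endpoint is the center of mass of an "end triangle": the CA
#' atoms of the segment's first three residues give `p0` and of its last
#' three give `p1`. Helix sticks are listed before strand sticks and sticks
#' are renumbered `1..N`; the source segment is kept in `seg_i`.
#'
#' @param chain a chain table from [read_chain()]
#' @param segments a segment table from [extract_segments()]
#' @return a tibble of sticks: `j`, `type`, `x0..z0`, `x1..z1`, `seg_i`
#' @export
extract_sticks <- function(chain, segments) {
  if (nrow(segments) == 0) {
    return(tibble(j = integer(), type = character(),
                  x0 = double(), y0 = double(), z0 = double(),
                  x1 = double(), y1 = double(), z1 = double(),
                  seg_i = integer()))
  }
  one <- function(k) {
    seg <- segments[k, ]
    ca <- seg_ca(chain, seg)
    if (nrow(ca) < 3 || anyNA(ca)) {
      stop("segment ", seg$i, " has fewer than 3 residues with CA coordinates",
           call. = FALSE)
    }
    p0 <- unname(colMeans(ca[1:3, , drop = FALSE]))
    p1 <- unname(colMeans(ca[(nrow(ca) - 2):nrow(ca), , drop = FALSE]))
    if (sqrt(sum((p0 - p1)^2)) < 1e-6) {
      stop("segment ", seg$i, " yields a degenerate stick (p0 == p1); ",
           "end triangles coincide", call. = FALSE)
    }
    tibble(type = seg$type,
           x0 = p0[1], y0 = p0[2], z0 = p0[3],
           x1 = p1[1], y1 = p1[2], z1 = p1[3],
           seg_i = seg$i)
  }
  out <- dplyr::bind_rows(lapply(seq_len(nrow(segments)), one))
  out <- out[order(out$type != "H", out$seg_i), , drop = FALSE]  # helices first
  out$j <- seq_len(nrow(out))
  out[, c("j", "type", "x0", "y0", "z0", "x1", "y1", "z1", "seg_i")]
}

stick_header <- "# topomatch sticks v1: j type x0 y0 z0 x1 y1 z1"
segment_header <- "# topomatch segments v1: i type first_res last_res"

#' Read / write a stick table
#'
#' Plain tab-separated text with a documented header comment line and columns
#' `j type x0 y0 z0 x1 y1 z1` (coordinates in Angstrom, type `H` or `E`).
#' Writing then reading a valid table is the identity. On read, a table with
#' a helix listed after a strand is stably reordered (helices first) and
#' renumbered, with a warning.
#'
#' @param table_file path to the TSV file
#' @param sticks a stick table as from [extract_sticks()]
#' @return `read_sticks()` returns a stick tibble; `write_sticks()` returns
#'   `table_file` invisibly.
#' @export
read_sticks <- function(table_file) {
  lines <- readLines(table_file)
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  rows <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    ln <- body_idx[k]
    parts <- strsplit(trimws(lines[ln]), "\t|\\s+")[[1]]
    if (length(parts) != 8) {
      stop("malformed stick row at line ", ln, ": expected 8 fields, got ",
           length(parts), call. = FALSE)
    }
    if (!parts[2] %in% c("H", "E")) {
      stop("malformed stick row at line ", ln, ": type must be H or E, got '",
           parts[2], "'", call. = FALSE)
    }
    coords <- suppressWarnings(as.numeric(parts[c(1, 3:8)]))
    if (anyNA(coords)) {
      stop("malformed stick row at line ", ln, ": non-numeric field", call. = FALSE)
    }
    rows[[k]] <- tibble(j = as.integer(coords[1]), type = parts[2],
                        x0 = coords[2], y0 = coords[3], z0 = coords[4],
                        x1 = coords[5], y1 = coords[6], z1 = coords[7])
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(j = integer(), type = character(),
                  x0 = double(), y0 = double(), z0 = double(),
                  x1 = double(), y1 = double(), z1 = double()))
  }
  if (is.unsorted(out$type != "H")) {  # some H after an E
    warning("sticks reordered: helices must precede strands; renumbering",
            call. = FALSE)
    out <- out[order(out$type != "H", seq_len(nrow(out))), , drop = FALSE]
    out$j <- seq_len(nrow(out))
  }
  out
}

#' @rdname read_sticks
#' @export
write_sticks <- function(sticks, table_file) {
  lines <- c(stick_header,
             sprintf("%d\t%s\t%.6f\t%.6f\t%.6f\t%.6f\t%.6f\t%.6f",
                     sticks$j, sticks$type,
                     sticks$x0, sticks$y0, sticks$z0,
                     sticks$x1, sticks$y1, sticks$z1))
  writeLines(lines, table_file)
  invisible(table_file)
}

#' Read / write a segment table
#'
#' Tab-separated columns `i type first_res last_res`; header comment line.
#'
#' @inheritParams read_sticks
#' @param segments a segment table as from [extract_segments()]
#' @export
read_segments <- function(table_file) {
  lines <- readLines(table_file)
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  rows <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    ln <- body_idx[k]
    parts <- strsplit(trimws(lines[ln]), "\t|\\s+")[[1]]
    if (length(parts) != 4) {
      stop("malformed segment row at line ", ln, call. = FALSE)
    }
    nums <- suppressWarnings(as.integer(parts[c(1, 3, 4)]))
    if (anyNA(nums) || !parts[2] %in% c("H", "E")) {
      stop("malformed segment row at line ", ln, call. = FALSE)
    }
    rows[[k]] <- tibble(i = nums[1], type = parts[2],
                        first_res = nums[2], last_res = nums[3])
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(i = integer(), type = character(),
                  first_res = integer(), last_res = integer(),
                  length_aa = integer()))
  }
  out$length_aa <- out$last_res - out$first_res + 1L
  out
}

#' @rdname read_segments
#' @export
write_segments <- function(segments, table_file) {
  lines <- c(segment_header,
             sprintf("%d\t%s\t%d\t%d",
                     segments$i, segments$type,
                     segments$first_res, segments$last_res))
  writeLines(lines, table_file)
  invisible(table_file)
}
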