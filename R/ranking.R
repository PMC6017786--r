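#' The six edge-scoring schemes
#'
#' `sk` uses the skeleton score alone; `g` the standalone geometry weight
#' `A - f`; the remaining schemes combine skeleton, geometry and energy:
#' `sk+g` is `Wsk - f`, `sk+g+e` is `Wsk - f + We`, `sk+e` is `Wsk + We`,
#' and `g+e` is `(A - f) + We`.
#'
#' @return character vector of scheme names
#' @export
scheme_names <- function() c("sk", "sk+g", "sk+g+e", "sk+e", "g", "g+e")

scheme_components <- list(
  "sk"     = c("wsk"),
  "sk+g"   = c("wsk", "f"),
  "sk+g+e" = c("wsk", "f", "we"),
  "sk+e"   = c("wsk", "we"),
  "g"      = c("f"),
  "g+e"    = c("f", "we")
)

#' Re-weight the topology graph under a scoring scheme
#'
#' Sets every edge weight to the scheme's formula from the per-edge
#' component scores (`wsk` from [compute_skeleton_scores()], `f` from
#' [compute_geometry_scores()], `we` from [compute_energy_scores()]).
#' Geometry-only schemes use the standalone transform `A - f` so that
#' smaller weights remain better.
#'
#' @param graph a `topology_graph` carrying the needed score columns
#' @param scheme one of [scheme_names()]
#' @param A geometry peak scale used by the standalone transform
#' @return the graph with `weight` updated and the scheme recorded
#' @export
apply_scheme <- function(graph, scheme, A = 1) {
  if (!scheme %in% scheme_names()) {
    stop("unknown scheme '", scheme, "'; valid schemes: ",
         paste(scheme_names(), collapse = ", "), call. = FALSE)
  }
  e <- graph$edges
  need <- scheme_components[[scheme]]
  missing_cols <- setdiff(need, names(e))
  if (length(missing_cols) > 0) {
    stop("scheme '", scheme, "' needs edge score column(s) ",
         paste(missing_cols, collapse = ", "),
         "; compute them first", call. = FALSE)
  }
  e$weight <- switch(scheme,
    "sk"     = e$wsk,
    "sk+g"   = e$wsk - e$f,
    "sk+g+e" = e$wsk - e$f + e$we,
    "sk+e"   = e$wsk + e$we,
    "g"      = A - e$f,
    "g+e"    = (A - e$f) + e$we
  )
  graph$edges <- e
  graph$scheme <- scheme
  graph
}

#' Rank of the true topology in a ranking
#'
#' 1-based position of the exact assignment (same sticks, same directions,
#' same rows) in the ranked list, or `NA` when it is absent from the top
#' `cap` -- the benchmark's failure rule (reported as N/A beyond the top
#' 100).
#'
#' @param ranking a `topology_ranking`
#' @param truth a tibble with columns `i`, `j`, `t`
#' @param cap report failure beyond this rank
#' @return integer rank or `NA_integer_`
#' @export
rank_of_truth <- function(ranking, truth, cap = 100L) {
  truth_str <- topology_assignment_string(truth[order(truth$i), ])
  hit <- which(ranking$assignment == truth_str)
  if (length(hit) == 0 || hit[1] > cap) NA_integer_ else as.integer(ranking$rank[hit[1]])
}

#' Fraction of proteins ranked within the top k
#'
#' For a rank table (one row per protein, one column per scheme, `NA` for a
#' failure), the fraction of rows whose rank under `scheme` is at most
#' `top_k`. Failures count against the fraction.
#'
#' @param table a rank table such as [benchmark_ranks()]
#' @param scheme column name, one of [scheme_names()]
#' @param top_k rank threshold
#' @return a fraction in `[0, 1]`
#' @export
summary_fraction <- function(table, scheme, top_k) {
  if (!scheme %in% names(table)) {
    stop("scheme column '", scheme, "' not in table", call. = FALSE)
  }
  r <- table[[scheme]]
  sum(!is.na(r) & r <= top_k) / length(r)
}

#' Published benchmark rank table
#'
#' The ranks of the true topology for the 25 benchmark volumes (15
#' simulated at 10 A resolution, 10 experimental) under the six scoring
#' schemes, as reported for the DP-TOSS benchmark; `NA` means the true
#' topology was not within the top 100. Shipped so the benchmark's summary
#' fractions are reproducible without any volume data.
#'
#' @return a tibble with columns `no`, `id`, `beta` (sheet-containing),
#'   `experimental`, `sses_s`, `sses_v` and one rank column per scheme
#' @export
benchmark_ranks <- function() {
  path <- system.file("extdata", "dptoss_benchmark_ranks.tsv",
                      package = "topomatch", mustWork = TRUE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           na.strings = "NA", check.names = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  out <- as_tibble(raw)
  out$beta <- as.logical(out$beta)
  out$experimental <- as.logical(out$experimental)
  out
}

#' Summary fractions for every scheme at once
#'
#' @param table a rank table
#' @param top_k rank threshold
#' @param schemes scheme columns to summarize
#' @return a tibble with `scheme`, `top_k`, `fraction`
#' @export
summarize_schemes <- function(table, top_k, schemes = scheme_names()) {
  tidyr::expand_grid(scheme = schemes, top_k = top_k) |>
    dplyr::rowwise() |>
    dplyr::mutate(fraction = summary_fraction(table, .data$scheme, .data$top_k)) |>
    dplyr::ungroup()
}
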