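#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with its standard default:
#' cluster radius 2 A, cluster link cutoff 3 A, gap bridging cutoff 10 A,
#' SSE removal radius 2.5 A, missing-trace penalty 15 A, top-100 failure
#' cap, and the fitted geometry parameters. All randomness flows from the
#' single `seed`.
#'
#' @param chain_file,segment_file,stick_file,skeleton_file input paths
#'   (`NULL` entries are allowed when a stage does not need them)
#' @param chain_id chain identifier for `chain_file`
#' @param scheme scoring scheme, one of [scheme_names()]
#' @param K number of topologies to report
#' @param seed root RNG seed
#' @param cap failure cap for the rank of the truth
#' @param max_skip `NULL` for the default `Delta - 1`
#' @param sse_radius,cluster_radius,link_cutoff,gap_cutoff,min_clique
#'   skeleton graph tunables (Angstrom; see [skeleton_graph()])
#' @param e_penalty missing-trace penalty (Angstrom)
#' @param trace_slack,trace_max_nodes DFS limits for [w_trace()]
#' @param geometry a [geometry_params()]
#' @param energy an [energy_params()]
#' @return a `run_config` object
#' @export
run_config <- function(chain_file = NULL, chain_id = "A",
                       segment_file = NULL, stick_file = NULL,
                       skeleton_file = NULL,
                       scheme = "sk", K = 100L, seed = 1L, cap = 100L,
                       max_skip = NULL,
                       sse_radius = 2.5, cluster_radius = 2.0,
                       link_cutoff = 3.0, gap_cutoff = 10.0, min_clique = 3L,
                       e_penalty = 15, trace_slack = 20, trace_max_nodes = 60L,
                       geometry = geometry_params(), energy = energy_params()) {
  if (!scheme %in% scheme_names()) {
    stop("unknown scheme '", scheme, "'; valid schemes: ",
         paste(scheme_names(), collapse = ", "), call. = FALSE)
  }
  structure(
    list(chain_file = chain_file, chain_id = chain_id,
         segment_file = segment_file, stick_file = stick_file,
         skeleton_file = skeleton_file,
         scheme = scheme, K = as.integer(K), seed = as.integer(seed),
         cap = as.integer(cap), max_skip = max_skip,
         sse_radius = sse_radius, cluster_radius = cluster_radius,
         link_cutoff = link_cutoff, gap_cutoff = gap_cutoff,
         min_clique = as.integer(min_clique),
         e_penalty = e_penalty, trace_slack = trace_slack,
         trace_max_nodes = as.integer(trace_max_nodes),
         geometry = geometry, energy = energy),
    class = "run_config")
}

#' Read/write a run configuration (JSON)
#'
#' The write -> read round trip is the identity.
#'
#' @param config a [run_config()]
#' @param file path
#' @export
write_config <- function(config, file) {
  x <- unclass(config)
  x$geometry <- list(A = config$geometry$A, lambda = config$geometry$lambda,
                     sigma = config$geometry$sigma)
  x$energy <- unclass(config$energy)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  geo <- geometry_params(A = x$geometry$A, lambda = x$geometry$lambda,
                         sigma = matrix(unlist(x$geometry$sigma), 2, 2))
  en <- energy_params(cutoff = x$energy$cutoff,
                      wells = as.data.frame(x$energy$wells),
                      rep_scale = x$energy$rep_scale,
                      e_const = x$energy$e_const,
                      axial_clamp = x$energy$axial_clamp)
  run_config(chain_file = x$chain_file, chain_id = x$chain_id,
             segment_file = x$segment_file, stick_file = x$stick_file,
             skeleton_file = x$skeleton_file,
             scheme = x$scheme, K = x$K, seed = x$seed, cap = x$cap,
             max_skip = x$max_skip,
             sse_radius = x$sse_radius, cluster_radius = x$cluster_radius,
             link_cutoff = x$link_cutoff, gap_cutoff = x$gap_cutoff,
             min_clique = x$min_clique, e_penalty = x$e_penalty,
             trace_slack = x$trace_slack, trace_max_nodes = x$trace_max_nodes,
             geometry = geo, energy = en)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full topology pipeline
#'
#' Loads the inputs, builds the topology graph, computes the component
#' scores the scheme needs, re-weights, solves for the best-K topologies
#' and (optionally) writes a ranked TSV plus a run log recording every
#' tunable. Deterministic for a fixed configuration. Stage errors are
#' re-raised with the stage name.
#'
#' @param config a [run_config()]
#' @param truth optional true topology tibble (`i`, `j`, `t`) to rank
#' @param out_dir optional output directory for `ranking.tsv` and `run.log`
#' @return a list: `ranking` (a `topology_ranking`), `graph`, and
#'   `truth_rank` when a truth was supplied
#' @export
run_pipeline <- function(config, truth = NULL, out_dir = NULL) {
  segments <- with_stage("inputs", {
    if (is.null(config$segment_file)) stop("segment_file is required")
    read_segments(config$segment_file)
  })
  sticks <- with_stage("inputs", {
    if (is.null(config$stick_file)) stop("stick_file is required")
    read_sticks(config$stick_file)
  })
  chain <- if (!is.null(config$chain_file)) {
    with_stage("inputs", read_chain(config$chain_file, config$chain_id))
  } else NULL

  graph <- with_stage("graph", build_graph(segments, sticks, chain,
                                           max_skip = config$max_skip))

  need <- scheme_components[[config$scheme]]
  if ("wsk" %in% need) {
    graph <- with_stage("skeleton", {
      if (is.null(config$skeleton_file)) {
        stop("scheme '", config$scheme, "' needs a skeleton_file")
      }
      grid <- read_skeleton(config$skeleton_file)
      skelg <- skeleton_graph(grid, sticks, rng_seed = config$seed,
                              sse_radius = config$sse_radius,
                              cluster_radius = config$cluster_radius,
                              link_cutoff = config$link_cutoff,
                              gap_cutoff = config$gap_cutoff,
                              min_clique = config$min_clique)
      compute_skeleton_scores(graph, skelg, e_penalty = config$e_penalty,
                              slack = config$trace_slack,
                              max_nodes = config$trace_max_nodes)
    })
  }
  if ("f" %in% need) {
    graph <- with_stage("geometry", compute_geometry_scores(graph, config$geometry))
  }
  if ("we" %in% need) {
    graph <- with_stage("energy", compute_energy_scores(graph, config$energy))
  }
  graph <- with_stage("scheme", apply_scheme(graph, config$scheme,
                                             A = config$geometry$A))
  ranking <- with_stage("solve", k_best(graph, K = config$K))

  truth_rank <- if (!is.null(truth)) {
    rank_of_truth(ranking, truth, cap = config$cap)
  } else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ranking(ranking, file.path(out_dir, "ranking.tsv"))
    log_lines <- c(
      paste0("topomatch run, scheme=", config$scheme, ", seed=", config$seed),
      paste0(names(unclass(config))[!vapply(unclass(config), is.list, logical(1))],
             "=",
             vapply(unclass(config)[!vapply(unclass(config), is.list, logical(1))],
                    function(v) paste(format(v), collapse = ","), character(1))),
      paste0("geometry.lambda=", paste(config$geometry$lambda, collapse = ",")),
      paste0("geometry.sigma=", paste(config$geometry$sigma, collapse = ",")),
      paste0("n_topologies=", nrow(ranking)),
      if (!is.null(truth_rank)) paste0("truth_rank=",
                                       ifelse(is.na(truth_rank), "N/A", truth_rank)))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }

  out <- list(ranking = ranking, graph = graph)
  if (!is.null(truth)) out$truth_rank <- truth_rank
  out
}
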