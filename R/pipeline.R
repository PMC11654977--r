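#' Consensus network inference on a count matrix
#'
#' The full three-step procedure: (1) shared subsamples feed every engine,
#' which reports edge selection frequencies over its regularization grid;
#' (2) per-engine grid points are harmonized to a common reproducible-edge
#' density under a mean-stability constraint; (3) the per-edge frequencies
#' are summarized across engines and thresholded into consensus graphs.
#'
#' @param counts samples x taxa count matrix (filtered upstream or via
#'   \code{prevalence}).
#' @param engines list of \code{\link{engine}}s (default
#'   \code{\link{default_engines}}).
#' @param B number of resamples (default 40).
#' @param K grid length per engine (default 30).
#' @param stab mean-stability target for harmonization (default 0.9).
#' @param cutoff frequency/score cutoff c (default 0.9).
#' @param summaries summary tags to compute.
#' @param p_min vote count for the minp summary.
#' @param prevalence optional prevalence threshold applied first.
#' @param pseudocount pseudocount for the log-based normalizations.
#' @param grid_ratio smallest/largest penalty ratio of the penalty grids.
#' @param mrc also compute the majority-rule consensus baseline.
#' @param seed master seed (drives the shared subsamples).
#' @return object of class \code{"consensus_result"}: \code{runs} (one
#'   \code{\link{method_run}} per engine, harmonized), \code{graphs} (named
#'   list of \code{\link{consensus_graph}}s), optional \code{mrc} graph,
#'   \code{subs}, \code{engines} and the call parameters.
#' @export
infer_consensus <- function(counts, engines = default_engines(), B = 40, K = 30,
                            stab = 0.9, cutoff = 0.9,
                            summaries = c("mean", "norm2", "ivw", "minp"),
                            p_min = 3, prevalence = NULL, pseudocount = 1,
                            grid_ratio = 0.01, mrc = FALSE, seed = 1) {
  summaries <- match.arg(summaries, several.ok = TRUE)
  if ("minp" %in% summaries && p_min > length(engines))
    stop(sprintf("p_min (%d) exceeds the number of engines (%d)",
                 p_min, length(engines)))
  if (!is.null(prevalence)) counts <- filter_prevalence(counts, prevalence)
  validate_counts(counts)

  norms <- unique(vapply(engines, function(e) e$normalization, character(1)))
  gdata <- setNames(lapply(norms, function(m) gaussianize(counts, m, pseudocount)),
                    norms)
  subs <- make_subsamples(nrow(counts), B = B, seed = seed)

  runs <- vector("list", length(engines))
  data_by_tag <- list()
  for (m in seq_along(engines)) {
    eng <- engines[[m]]
    x <- gdata[[eng$normalization]]
    grid <- engine_grid(eng, x, K = K, ratio = grid_ratio)
    freqs <- selection_frequencies(eng, x, grid, subs)
    runs[[m]] <- method_run(freqs, c = cutoff)
    data_by_tag[[eng$tag]] <- x
  }
  runs <- harmonize_densities(runs, stab = stab)

  graphs <- setNames(lapply(summaries, function(s) {
    sc <- summarize_frequencies(runs, s, c = cutoff, p_min = p_min)
    consensus_graph(sc, c = cutoff)
  }), summaries)

  mrc_graph <- if (mrc) mrc_consensus(runs, engines, data_by_tag, stab = stab) else NULL

  structure(list(runs = runs, graphs = graphs, mrc = mrc_graph, subs = subs,
                 engines = engines,
                 target_density = attr(runs, "target_density"),
                 params = list(B = B, K = K, stab = stab, cutoff = cutoff,
                               p_min = p_min, pseudocount = pseudocount,
                               grid_ratio = grid_ratio, seed = seed,
                               n = nrow(counts), p = ncol(counts)),
                 taxon_ids = colnames(counts)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> n = %d, p = %d, %d engines, B = %d\n",
              x$params$n, x$params$p, length(x$engines), x$params$B))
  cat(sprintf("  harmonized target density: %s\n", x$target_density))
  for (nm in names(x$graphs))
    cat(sprintf("  %-6s consensus: %d edges\n", nm, length(x$graphs[[nm]]$edges)))
  if (!is.null(x$mrc))
    cat(sprintf("  mrc    consensus: %d edges\n", length(x$mrc$edges)))
  invisible(x)
}

#' Write a consensus graph to files
#'
#' @param graph a \code{"consensus_graph"}.
#' @param prefix file-path prefix; writes \code{<prefix>_edges.tsv} (edge
#'   list with summary score and per-method frequency provenance),
#'   \code{<prefix>_adjacency.tsv} and \code{<prefix>.graphml}.
#' @return invisibly, the vector of written paths.
#' @export
write_consensus_graph <- function(graph, prefix) {
  taxa <- graph$taxon_ids %||% sprintf("taxon_%03d", seq_len(graph$p))
  ei <- edge_index(graph$p)[graph$edges, , drop = FALSE]
  el <- data.frame(taxon_i = taxa[ei[, 1]], taxon_j = taxa[ei[, 2]],
                   score = graph$scores)
  if (!is.null(graph$provenance) && length(graph$edges))
    el <- cbind(el, as.data.frame(graph$provenance))
  p_edges <- paste0(prefix, "_edges.tsv")
  write.table(el, p_edges, sep = "\t", quote = FALSE, row.names = FALSE)

  A <- edges_to_adjacency(graph$edges, graph$p, taxa)
  p_adj <- paste0(prefix, "_adjacency.tsv")
  write.table(data.frame(taxon = taxa, A, check.names = FALSE), p_adj,
              sep = "\t", quote = FALSE, row.names = FALSE)

  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  p_gml <- paste0(prefix, ".graphml")
  igraph::write_graph(g, p_gml, format = "graphml")
  invisible(c(p_edges, p_adj, p_gml))
}

#' Write a frequency table with its sidecar metadata
#'
#' @param freqs a \code{\link{selection_frequencies}} table.
#' @param subs the \code{\link{make_subsamples}} object used.
#' @param prefix path prefix; writes \code{<prefix>_frequencies.tsv} and
#'   \code{<prefix>_frequencies.json}.
#' @return invisibly, the written paths.
#' @export
write_frequency_table <- function(freqs, subs, prefix) {
  taxa <- freqs$taxon_ids %||% sprintf("taxon_%03d", seq_len(freqs$p))
  ei <- edge_index(freqs$p)
  df <- data.frame(taxon_i = taxa[ei[, 1]], taxon_j = taxa[ei[, 2]], freqs$f)
  colnames(df)[-(1:2)] <- sprintf("grid_%02d", seq_along(freqs$grid))
  p_tsv <- paste0(prefix, "_frequencies.tsv")
  write.table(df, p_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  p_json <- paste0(prefix, "_frequencies.json")
  jsonlite::write_json(list(method = freqs$method_tag, grid = freqs$grid,
                            grid_scale = attr(freqs$grid, "scale"),
                            B = freqs$B, n = subs$n, n_sub = subs$n_sub,
                            seed = subs$seed),
                       p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(p_tsv, p_json))
}

#' Run the whole pipeline from a configuration
#'
#' File-in/file-out driver behind the command-line wrapper: reads or
#' simulates counts, runs \code{\link{infer_consensus}}, writes every
#' intermediate table, the consensus graphs, metrics when a truth adjacency
#' is available, and a JSON manifest recording parameters, seeds and any
#' failure point.
#'
#' @param config named list (or path to a JSON file) with keys:
#'   \code{counts} (TSV path) or \code{simulate} (list of
#'   \code{\link{simulate_dataset}} arguments); \code{orientation};
#'   \code{truth} (optional truth-adjacency TSV); \code{outdir}; and any of
#'   \code{engines} (character tags like \code{"glasso-clr"}), \code{B},
#'   \code{K}, \code{stab}, \code{cutoff}, \code{summaries}, \code{p_min},
#'   \code{prevalence}, \code{pseudocount}, \code{mrc}, \code{seed}.
#' @return the \code{"consensus_result"}, invisibly; side effect: files
#'   under \code{outdir}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- list(orientation = "samples_in_rows", outdir = "consenet_out",
                   B = 40, K = 30, stab = 0.9, cutoff = 0.9,
                   summaries = c("mean", "norm2", "ivw", "minp"), p_min = 3,
                   prevalence = NULL, pseudocount = 1, mrc = FALSE, seed = 1,
                   engines = NULL, truth = NULL)
  unknown <- setdiff(names(config), c(names(defaults), "counts", "simulate"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  bad <- setdiff(cfg$summaries, c("mean", "norm2", "ivw", "minp"))
  if (length(bad)) stop("unknown summary name(s): ", paste(bad, collapse = ", "))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(package_version = as.character(utils::packageVersion("consenet")),
                   r_version = R.version.string, config = cfg, status = "started")
  write_manifest <- function()
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  on.exit(write_manifest(), add = TRUE)

  truth <- NULL
  if (!is.null(cfg$simulate)) {
    manifest$stage <- "simulate"
    ds <- do.call(simulate_dataset, c(cfg$simulate, list(seed = cfg$seed)))
    counts <- ds$counts
    truth <- ds$truth$A
    write_counts(counts, file.path(cfg$outdir, "counts.tsv"))
    write.table(data.frame(taxon = colnames(counts), truth),
                file.path(cfg$outdir, "truth_adjacency.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (!is.null(cfg$counts)) {
    manifest$stage <- "read"
    counts <- read_counts(cfg$counts, cfg$orientation)
  } else stop("config needs either 'counts' or 'simulate'")
  if (!is.null(cfg$truth)) {
    tr <- read.table(cfg$truth, header = TRUE, sep = "\t", row.names = 1,
                     check.names = FALSE)
    truth <- as.matrix(tr)
    dimnames(truth) <- list(rownames(tr), rownames(tr))
  }

  engines <- if (is.null(cfg$engines)) default_engines() else {
    lapply(cfg$engines, function(tag) {
      parts <- strsplit(tag, "-", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("engine tag must look like 'family-normalization': ", tag)
      engine(parts[1], parts[2])
    })
  }

  manifest$stage <- "infer"
  res <- infer_consensus(counts, engines = engines, B = cfg$B, K = cfg$K,
                         stab = cfg$stab, cutoff = cfg$cutoff,
                         summaries = cfg$summaries, p_min = cfg$p_min,
                         prevalence = cfg$prevalence,
                         pseudocount = cfg$pseudocount, mrc = cfg$mrc,
                         seed = cfg$seed)

  manifest$stage <- "write"
  for (run in res$runs)
    write_frequency_table(run$freqs, res$subs,
                          file.path(cfg$outdir, run$method_tag))
  prof <- do.call(rbind, lapply(res$runs, function(r)
    data.frame(method = r$method_tag, k = seq_along(r$profile$S),
               lambda = r$profile$grid, S = r$profile$S,
               density = r$profile$density, chosen = seq_along(r$profile$S) == r$chosen_k)))
  write.table(prof, file.path(cfg$outdir, "stability_profiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(res$graphs))
    write_consensus_graph(res$graphs[[nm]], file.path(cfg$outdir, paste0("consensus_", nm)))
  if (!is.null(res$mrc))
    write_consensus_graph(res$mrc, file.path(cfg$outdir, "consensus_mrc"))

  if (!is.null(truth)) {
    manifest$stage <- "evaluate"
    if (!identical(dim(truth), c(ncol(counts), ncol(counts))))
      truth_sub <- truth[colnames(counts), colnames(counts)]
    else truth_sub <- truth
    rows <- list()
    for (r in res$runs) {
      m <- ppv_tpr(edge_set(r$freqs, as.integer(stars_select(r$profile, cfg$stab)),
                            cfg$cutoff), truth_sub)
      rows[[length(rows) + 1]] <- data.frame(method = r$method_tag, kind = "engine",
                                             TP = m$TP, FP = m$FP, FN = m$FN,
                                             PPV = m$PPV, TPR = m$TPR)
    }
    gs <- res$graphs
    if (!is.null(res$mrc)) gs <- c(gs, list(mrc = res$mrc))
    for (nm in names(gs)) {
      m <- ppv_tpr(gs[[nm]]$edges, truth_sub)
      rows[[length(rows) + 1]] <- data.frame(method = nm, kind = "consensus",
                                             TP = m$TP, FP = m$FP, FN = m$FN,
                                             PPV = m$PPV, TPR = m$TPR)
    }
    write.table(do.call(rbind, rows), file.path(cfg$outdir, "metrics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest$status <- "finished"
  manifest$stage <- NULL
  manifest$target_density <- res$target_density
  manifest$consensus_sizes <- lapply(res$graphs, function(g) length(g$edges))
  invisible(res)
}
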