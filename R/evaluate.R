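#' Precision and recall of an inferred edge set
#'
#' Compares inferred edges to a truth adjacency on the canonical edge
#' universe. PPV = TP/(TP+FP) is the fraction of inferred edges that are
#' real; TPR = TP/(TP+FN) the fraction of real edges recovered. An empty
#' prediction has undefined precision, reported as \code{NA} (never silently
#' 0 or 1).
#'
#' @param inferred integer vector of canonical edge ids (e.g. an
#'   \code{\link{edge_set}} or \code{consensus_graph$edges}).
#' @param truth symmetric binary adjacency on the same taxa.
#' @param p number of taxa; defaults to \code{nrow(truth)}.
#' @return list with integer \code{TP}, \code{FP}, \code{FN} and numeric
#'   \code{PPV}, \code{TPR} (possibly \code{NA} when undefined).
#' @export
ppv_tpr <- function(inferred, truth, p = nrow(truth)) {
  validate_adjacency(truth)
  if (!is.null(attr(inferred, "p")) && attr(inferred, "p") != p)
    stop("inferred edge set and truth refer to different taxon universes")
  true_ids <- adjacency_to_edges(truth)
  inferred <- as.integer(inferred)
  TP <- length(intersect(inferred, true_ids))
  FP <- length(inferred) - TP
  FN <- length(true_ids) - TP
  list(TP = TP, FP = FP, FN = FN,
       PPV = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
       TPR = if (TP + FN > 0) TP / (TP + FN) else NA_real_)
}

#' Precision-recall path along a grid
#'
#' Metrics of the reproducible-edge set E(c) at every grid point of a
#' frequency table, together with its density, for precision-recall and
#' precision-density curves.
#'
#' @param freqs a \code{\link{selection_frequencies}} table.
#' @param truth truth adjacency.
#' @param c frequency cutoff.
#' @return data.frame with columns \code{k}, \code{lambda}, \code{density},
#'   \code{TP}, \code{FP}, \code{FN}, \code{PPV}, \code{TPR}.
#' @export
pr_path <- function(freqs, truth, c = 0.9) {
  K <- ncol(freqs$f)
  rows <- lapply(seq_len(K), function(k) {
    ids <- edge_set(freqs, k, c)
    m <- ppv_tpr(ids, truth)
    data.frame(k = k, lambda = freqs$grid[k], density = length(ids),
               TP = m$TP, FP = m$FP, FN = m$FN, PPV = m$PPV, TPR = m$TPR)
  })
  do.call(rbind, rows)
}

#' Edge overlap counts across methods (upset-style)
#'
#' Partitions the union of several edge sets by the exact subset of methods
#' detecting each edge; counts sum to the union size. A truth adjacency can
#' be included as a pseudo-method.
#'
#' @param edge_sets named list (>= 2) of integer edge-id vectors.
#' @param truth optional truth adjacency added as set \code{"truth"}.
#' @return data.frame with columns \code{subset} (method names joined by
#'   \code{"&"}) and \code{count}, sorted by decreasing count.
#' @export
overlap_counts <- function(edge_sets, truth = NULL) {
  if (!is.null(truth)) edge_sets <- c(edge_sets, list(truth = adjacency_to_edges(truth)))
  stopifnot(length(edge_sets) >= 2, !is.null(names(edge_sets)),
            all(nzchar(names(edge_sets))))
  ids <- sort(unique(unlist(edge_sets)))
  if (!length(ids)) return(data.frame(subset = character(0), count = integer(0)))
  member <- vapply(edge_sets, function(s) ids %in% s, logical(length(ids)))
  member <- matrix(member, nrow = length(ids))
  key <- apply(member, 1, function(row) paste(names(edge_sets)[row], collapse = "&"))
  tab <- sort(table(key), decreasing = TRUE)
  data.frame(subset = names(tab), count = as.integer(tab), row.names = NULL)
}
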