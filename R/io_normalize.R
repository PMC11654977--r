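#' Read a count abundance table from TSV
#'
#' Reads a tab-delimited count table with one header row and one identifier
#' column, and returns it in the package's canonical orientation: samples in
#' rows, taxa in columns. No orientation guessing is performed; files stored
#' taxa-in-rows must say so via \code{orientation}.
#'
#' @param path path to a TSV file (UTF-8, header row, first column = ids).
#' @param orientation \code{"samples_in_rows"} (default) or
#'   \code{"taxa_in_rows"}; the latter transposes the table on read.
#' @return a numeric count matrix, samples x taxa, with sample ids as row
#'   names and taxon ids as column names.
#' @export
read_counts <- function(path, orientation = c("samples_in_rows", "taxa_in_rows")) {
  orientation <- match.arg(orientation)
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE, comment.char = "", quote = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric values in column '%s' of %s",
                 colnames(df)[bad], path))
  }
  if (orientation == "taxa_in_rows") m <- t(m)
  validate_counts(m)
  m
}

#' Write a count table to TSV
#'
#' @param counts samples x taxa count matrix.
#' @param path output file.
#' @param id_header name of the identifier column in the output header.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(counts, path, id_header = "sample_id") {
  df <- data.frame(id = rownames(counts), counts, check.names = FALSE)
  colnames(df)[1] <- id_header
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_counts <- function(m) {
  if (any(!is.finite(m))) stop("count table contains non-finite values")
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at row '%s', column '%s'",
                 rownames(m)[idx[1]] %||% idx[1],
                 colnames(m)[idx[2]] %||% idx[2]))
  }
  if (nrow(m) < 2 || ncol(m) < 2) stop("count table needs >= 2 samples and >= 2 taxa")
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(m))) stop("duplicate taxon ids")
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter taxa by prevalence
#'
#' Keeps taxa observed (count > 0) in a fraction of samples strictly greater
#' than \code{threshold}. Interactions between prevalent taxa are easier to
#' reconstruct, so inference is typically restricted to taxa seen in more
#' than half the samples.
#'
#' @param counts samples x taxa count matrix.
#' @param threshold prevalence fraction in [0, 1]; a taxon is kept when
#'   \code{mean(count > 0) > threshold} (strict inequality).
#' @return the filtered count matrix (same samples, subset of taxa, original
#'   taxon order preserved).
#' @export
filter_prevalence <- function(counts, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  prev <- colMeans(counts > 0)
  keep <- prev > threshold
  if (sum(keep) < 2) stop("too few taxa after filtering")
  counts[, keep, drop = FALSE]
}

#' Centered log-ratio transform
#'
#' Per-sample CLR on pseudocounted counts: each row of the result is
#' \code{log(x + pseudocount)} centered to mean zero, making abundances
#' comparable across samples of different depths while removing the
#' compositional total.
#'
#' @param counts samples x taxa count matrix.
#' @param pseudocount positive value added before taking logs (default 1).
#' @return numeric matrix of the same shape; every row sums to zero. The
#'   transform is recorded in \code{attr(, "transform")}.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  lx <- log(counts + pseudocount)
  out <- lx - rowMeans(lx)
  attr(out, "transform") <- "CLR"
  out
}

#' GMPR size factors
#'
#' Geometric mean of pairwise ratios: robust library-size factors for
#' zero-inflated counts. For sample i the factor is the geometric mean, over
#' all other samples j, of the median count ratio i/j computed on taxa
#' positive in both samples. Factors are rescaled to geometric mean 1.
#'
#' @param counts samples x taxa count matrix.
#' @return positive numeric vector of length n (named by sample), with
#'   attribute \code{method = "GMPR"}.
#' @export
gmpr_size_factors <- function(counts) {
  n <- nrow(counts)
  logr <- matrix(NA_real_, n, n)
  pos <- counts > 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- pos[i, ] & pos[j, ]
      if (any(shared))
        logr[i, j] <- median(log(counts[i, shared]) - log(counts[j, shared]))
    }
  }
  lf <- rowMeans(logr, na.rm = TRUE)
  bad <- !is.finite(lf)
  if (any(bad))
    stop(sprintf("sample '%s' shares no positive taxon with any other sample",
                 rownames(counts)[which(bad)[1]] %||% which(bad)[1]))
  f <- exp(lf - mean(lf))                       # geometric mean 1
  names(f) <- rownames(counts)
  attr(f, "method") <- "GMPR"
  f
}

#' RLE (median-of-ratios) size factors
#'
#' Relative log expression factors: each sample's median ratio to the
#' per-taxon geometric mean, computed over the reference set of taxa
#' positive in all samples. Factors are rescaled to geometric mean 1.
#'
#' @inheritParams gmpr_size_factors
#' @return positive numeric vector of length n with attribute
#'   \code{method = "RLE"}.
#' @export
rle_size_factors <- function(counts) {
  ref <- colSums(counts > 0) == nrow(counts)
  if (!any(ref))
    stop("no taxon is positive in every sample (empty RLE reference set); consider GMPR")
  lx <- log(counts[, ref, drop = FALSE])
  lgm <- colMeans(lx)                           # per-taxon log geometric mean
  lf <- apply(sweep(lx, 2, lgm), 1, median)
  f <- exp(lf - mean(lf))
  names(f) <- rownames(counts)
  attr(f, "method") <- "RLE"
  f
}

#' Rank-based gaussianization (nonparanormal marginal transform)
#'
#' Replaces each column by standard-normal quantiles of its mid-ranks,
#' \eqn{\Phi^{-1}((rank - 0.5)/n)}, with average ranks for ties (all zeros of
#' a count column form a single tie group). The result depends only on the
#' within-column ordering, so it is invariant to strictly monotone marginal
#' distortions.
#'
#' @param x numeric matrix (counts or any per-column monotone transform of
#'   them), samples in rows; needs n >= 3.
#' @return matrix of the same shape; constant columns map to all zeros with
#'   a warning. \code{attr(, "transform")} records the step.
#' @export
rank_gaussianize <- function(x) {
  n <- nrow(x)
  stopifnot(n >= 3)
  out <- apply(x, 2, function(col) {
    if (max(col) == min(col)) return(rep(0, n))
    qnorm((rank(col, ties.method = "average") - 0.5) / n)
  })
  const <- apply(x, 2, function(col) max(col) == min(col))
  if (any(const))
    warning(sprintf("%d constant column(s) mapped to zeros", sum(const)))
  dimnames(out) <- dimnames(x)
  attr(out, "transform") <- "NPN"
  out
}

#' Normalize and gaussianize a count matrix
#'
#' Dispatcher producing the matrix each inference engine consumes.
#'
#' @param counts samples x taxa count matrix.
#' @param method one of \code{"clr"} (centered log-ratio), \code{"clr_npn"}
#'   (CLR followed by rank gaussianization), \code{"gmpr"}
#'   (log of GMPR-size-factor-scaled pseudocounted counts) or \code{"rle"}
#'   (same with RLE factors).
#' @param pseudocount pseudocount for the log transforms.
#' @return numeric matrix, samples x taxa, with a \code{"transform"} attribute
#'   (\code{"CLR"}, \code{"CLR+NPN"}, \code{"GMPR-log"} or \code{"RLE-log"}).
#' @export
gaussianize <- function(counts, method = c("clr", "clr_npn", "gmpr", "rle"),
                        pseudocount = 1) {
  method <- match.arg(method)
  out <- switch(method,
    clr = clr_transform(counts, pseudocount),
    clr_npn = {
      z <- rank_gaussianize(clr_transform(counts, pseudocount))
      attr(z, "transform") <- "CLR+NPN"
      z
    },
    gmpr = {
      f <- gmpr_size_factors(counts)
      z <- log(sweep(counts + pseudocount, 1, f, "/"))
      attr(z, "transform") <- "GMPR-log"
      z
    },
    rle = {
      f <- rle_size_factors(counts)
      z <- log(sweep(counts + pseudocount, 1, f, "/"))
      attr(z, "transform") <- "RLE-log"
      z
    })
  out
}
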