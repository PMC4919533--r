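# Beta-series connectivity: spatial subsampling, FDR-thresholded voxel and
# region graphs.

#' Spatially subsample a beta-image set
#'
#' Averages non-overlapping \code{factor^3} voxel blocks (in-mask voxels
#' only); blocks without any in-mask voxel are dropped from the output mask.
#' The recorded voxel size is scaled by \code{factor} (e.g. factor 4 turns
#' 2 mm data into 8 mm data).
#'
#' @param betas a \code{\link{beta_image_set}}.
#' @param factor integer block edge length (>= 1).
#' @return a \code{\link{beta_image_set}} on the coarser grid.
#' @export
subsample_betas <- function(betas, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  d <- dim(betas$data)
  if (any(factor > d[1:3]))
    stop("subsampling factor exceeds a grid dimension")
  if (factor == 1L) return(betas)
  nd <- as.integer(ceiling(d[1:3] / factor))
  t_len <- d[4L]

  # block id of every fine voxel
  bx <- (seq_len(d[1L]) - 1L) %/% factor
  by <- (seq_len(d[2L]) - 1L) %/% factor
  bz <- (seq_len(d[3L]) - 1L) %/% factor
  block <- outer(outer(bx, by * nd[1L], "+"), bz * nd[1L] * nd[2L], "+") + 1L
  bvec <- as.vector(block)
  mvec <- as.vector(betas$mask)

  nblocks <- prod(nd)
  counts <- tabulate(bvec[mvec], nbins = nblocks)
  mat <- matrix(betas$data, prod(d[1:3]), t_len)
  sums <- rowsum(mat[mvec, , drop = FALSE], group = bvec[mvec])
  gids <- as.integer(rownames(sums))
  out <- matrix(NA_real_, nblocks, t_len)
  out[gids, ] <- sums / counts[gids]
  newmask <- array(counts > 0L, dim = nd)
  outdata <- array(out, dim = c(nd, t_len))
  outdata[is.na(outdata)] <- 0
  beta_image_set(outdata, betas$labels, newmask,
                 voxel_size_mm = betas$voxel_size_mm * factor)
}

# correlation matrix -> thresholded nonnegative adjacency:
# negatives zeroed, positive edges kept iff BH-adjusted two-sided p < alpha
.threshold_cor <- function(r, n_obs, fdr_alpha) {
  zerovar <- is.na(diag(r))
  diag(r) <- 0
  if (any(is.na(r))) {
    warning(sum(zerovar), " zero-variance node(s): edges set to 0")
    r[is.na(r)] <- 0
  }
  w <- r
  w[w < 0] <- 0
  ut <- which(upper.tri(w) & w > 0)
  if (length(ut)) {
    rv <- w[ut]
    df <- n_obs - 2L
    tv <- rv * sqrt(df / pmax(1 - rv^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tv), df)
    padj <- stats::p.adjust(p, method = "BH")
    kill <- ut[padj >= fdr_alpha]
    w[kill] <- 0
    w[cbind(col(w)[kill], row(w)[kill])] <- 0
    # symmetrize explicitly (w was symmetric; keep lower in step with upper)
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
  }
  w
}

#' Build a voxel-wise beta-series connectivity graph
#'
#' Correlates every pair of in-mask voxels' beta series across the instances
#' of one phase (Pearson), sets negative correlations to zero and keeps the
#' remaining edges whose Benjamini-Hochberg-adjusted two-sided p-value falls
#' below \code{fdr_alpha}; surviving edge weights are the correlation values.
#'
#' @param betas a \code{\link{beta_image_set}} (typically subsampled).
#' @param phase \code{"retrieval"} or \code{"iti"}.
#' @param fdr_alpha FDR level for edge retention.
#' @return list of class \code{connectivity_graph}: \code{adjacency}
#'   (symmetric nonnegative, zero diagonal), \code{nodes} (k x 3 voxel
#'   coordinates), \code{node_index} (linear indices into the grid),
#'   \code{dim}, \code{phase}, \code{n_instances}.
#' @export
build_connectivity <- function(betas, phase = c("retrieval", "iti"),
                               fdr_alpha = 0.05) {
  phase <- match.arg(phase)
  cols <- which(betas$labels$phase == phase)
  if (length(cols) < 4L)
    stop("need at least 4 instances in phase '", phase, "'")
  d <- dim(betas$data)
  idx <- which(betas$mask)
  mat <- matrix(betas$data, prod(d[1:3]), d[4L])[idx, cols, drop = FALSE]
  r <- suppressWarnings(stats::cor(t(mat)))
  w <- .threshold_cor(r, length(cols), fdr_alpha)
  structure(list(adjacency = w, nodes = arrayInd(idx, d[1:3]),
                 node_index = idx, dim = d[1:3], phase = phase,
                 n_instances = length(cols)),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  ne <- sum(x$adjacency[upper.tri(x$adjacency)] > 0)
  cat("<connectivity_graph> ", nrow(x$adjacency), " nodes (", x$phase,
      " phase, ", x$n_instances, " instances), ", ne, " edges\n", sep = "")
  invisible(x)
}

#' Region-by-region connectivity graph
#'
#' Averages the beta series over each atlas region, correlates the region
#' means across the phase's instances, zeroes negatives and FDR-thresholds
#' the positive edges, yielding the region-level weighted adjacency that the
#' module partition is computed from.
#'
#' @param betas a \code{\link{beta_image_set}}.
#' @param atlas 3-D integer label array on the beta grid (0 = outside).
#' @param phase \code{"retrieval"} or \code{"iti"}.
#' @param fdr_alpha FDR level for edge retention.
#' @return list of class \code{region_graph}: \code{adjacency} (symmetric
#'   nonnegative) with region ids as dimnames, \code{region_ids},
#'   \code{phase}.
#' @export
region_graph <- function(betas, atlas, phase = c("retrieval", "iti"),
                         fdr_alpha = 0.05) {
  phase <- match.arg(phase)
  d <- dim(betas$data)
  if (!identical(dim(atlas), d[1:3]))
    stop("atlas does not cover the beta grid")
  cols <- which(betas$labels$phase == phase)
  if (length(cols) < 4L)
    stop("need at least 4 instances in phase '", phase, "'")
  lab <- as.vector(atlas)
  use <- lab != 0L & as.vector(betas$mask)
  ids <- sort(unique(lab[use]))
  empty <- setdiff(sort(unique(as.vector(atlas)[as.vector(atlas) != 0L])), ids)
  if (length(empty))
    message("region_graph: excluding empty region(s) ",
            paste(empty, collapse = ", "))
  mat <- matrix(betas$data, prod(d[1:3]), d[4L])[use, cols, drop = FALSE]
  means <- rowsum(mat, group = lab[use]) / as.vector(table(lab[use]))
  r <- suppressWarnings(stats::cor(t(means)))
  w <- .threshold_cor(r, length(cols), fdr_alpha)
  dimnames(w) <- list(ids, ids)
  structure(list(adjacency = w, region_ids = ids, phase = phase),
            class = "region_graph")
}
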