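# Searchlight RSA: spherical neighbourhoods, Spearman pattern similarity and
# the contrast GLM producing the voxel-wise conjunctiveness map.

#' Enumerate searchlight spheres
#'
#' For every in-mask voxel, collects the in-mask voxels within a Euclidean
#' radius (in voxel units). Centres whose sphere holds fewer than
#' \code{min_voxels} grey-matter voxels are dropped. Defaults follow the
#' common 4-voxel-radius / 30-voxel-minimum convention.
#'
#' @param mask 3-D logical grey-matter mask.
#' @param radius_voxels sphere radius in voxels (>= 1).
#' @param min_voxels minimum in-mask sphere size to keep a centre.
#' @param centres optional integer matrix (k x 3) of candidate centre
#'   coordinates, or a 3-D logical array restricting centres; default all
#'   in-mask voxels.
#' @return list of class \code{searchlight_set}: \code{centres} (k x 3
#'   integer matrix), \code{voxels} (list of linear-index vectors into the
#'   grid), \code{dim}, \code{radius}, \code{min_voxels}.
#' @export
searchlight_spheres <- function(mask, radius_voxels = 4, min_voxels = 30,
                                centres = NULL) {
  if (radius_voxels < 1) stop("radius_voxels must be >= 1")
  d <- dim(mask)
  if (sum(mask) == 0L) stop("mask is empty")
  r <- floor(radius_voxels)
  off <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  off <- off[rowSums(off^2) <= radius_voxels^2, , drop = FALSE]

  if (is.null(centres)) {
    cmask <- mask
  } else if (is.matrix(centres) && ncol(centres) == 3L) {
    cmask <- array(FALSE, dim = d)
    cmask[centres] <- TRUE
    cmask <- cmask & mask
  } else if (is.array(centres) && length(dim(centres)) == 3L) {
    cmask <- centres & mask
  } else {
    cmask <- array(FALSE, dim = d)
    cmask[as.integer(centres)] <- TRUE
    cmask <- cmask & mask
  }
  cidx <- which(cmask)
  if (!length(cidx))
    return(structure(list(centres = matrix(integer(), 0L, 3L),
                          voxels = list(), dim = d, radius = radius_voxels,
                          min_voxels = min_voxels),
                     class = "searchlight_set"))
  cc <- arrayInd(cidx, d)

  nc <- length(cidx)
  no <- nrow(off)
  # neighbour linear indices per (centre, offset); NA when out of grid/mask
  nb <- matrix(NA_integer_, nc, no)
  mvec <- as.vector(mask)
  for (o in seq_len(no)) {
    x <- cc[, 1L] + off[o, 1L]
    y <- cc[, 2L] + off[o, 2L]
    z <- cc[, 3L] + off[o, 3L]
    ok <- x >= 1L & x <= d[1L] & y >= 1L & y <= d[2L] & z >= 1L & z <= d[3L]
    lin <- rep(NA_integer_, nc)
    lin[ok] <- (z[ok] - 1L) * d[1L] * d[2L] + (y[ok] - 1L) * d[1L] + x[ok]
    lin[!is.na(lin) & !mvec[ifelse(is.na(lin), 1L, lin)]] <- NA_integer_
    nb[, o] <- lin
  }
  sizes <- rowSums(!is.na(nb))
  keep <- which(sizes >= min_voxels)
  voxels <- lapply(keep, function(i) nb[i, !is.na(nb[i, ])])
  structure(list(centres = cc[keep, , drop = FALSE], voxels = voxels,
                 dim = d, radius = radius_voxels, min_voxels = min_voxels),
            class = "searchlight_set")
}

#' @export
print.searchlight_set <- function(x, ...) {
  sizes <- lengths(x$voxels)
  cat("<searchlight_set> ", length(x$voxels), " spheres, radius ",
      x$radius, " voxels, sizes ",
      if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "-", "\n",
      sep = "")
  invisible(x)
}

# Spearman similarity of the columns of a voxels x instances matrix.
# Zero-variance columns yield NA rows/columns (undefined marker).
.spearman_sim <- function(pat) {
  n <- ncol(pat)
  if (nrow(pat) < 3L) stop("need at least 3 voxels per pattern")
  rk <- apply(pat, 2L, rank)
  # a column is all-tied iff every average rank equals (p+1)/2
  bad <- colSums(abs(rk - (nrow(pat) + 1) / 2)) == 0
  s <- matrix(NA_real_, n, n)
  if (any(!bad)) {
    s[!bad, !bad] <- stats::cor(rk[, !bad, drop = FALSE])
  }
  diag(s) <- ifelse(bad, NA_real_, 1)
  s
}

#' Pairwise Spearman similarity between instance patterns
#'
#' @param patterns numeric matrix, instances x voxels (>= 3 voxels).
#' @param labels optional label data.frame carried along.
#' @return list of class \code{similarity_matrix}: \code{values} (symmetric,
#'   unit diagonal; rows/columns of zero-variance patterns are \code{NA} and
#'   excluded downstream) and \code{labels}.
#' @export
pattern_similarity <- function(patterns, labels = NULL) {
  if (ncol(patterns) < 3L) stop("need at least 3 voxels per pattern")
  vals <- .spearman_sim(t(patterns))
  structure(list(values = vals, labels = labels),
            class = "similarity_matrix")
}

#' Fit the contrast GLM to a similarity matrix
#'
#' Ordinary least squares of the included upper-triangle similarity values on
#' an intercept plus the contrast weight; returns the slope (the
#' conjunctiveness estimate) and its t statistic. Cells whose similarity is
#' undefined (zero-variance pattern) are dropped.
#'
#' @param sim \code{\link{pattern_similarity}} result, or a plain symmetric
#'   matrix of similarities.
#' @param contrast \code{\link{build_contrast_matrix}} result.
#' @return list with \code{beta} (slope) and \code{t}.
#' @export
fit_contrast <- function(sim, contrast) {
  values <- if (inherits(sim, "similarity_matrix")) sim$values else sim
  if (!all(dim(values) == dim(contrast$weights)))
    stop("similarity and contrast dimensions differ")
  ut <- upper.tri(values)
  sel <- contrast$include & ut
  y <- values[sel]
  w <- contrast$weights[sel]
  ok <- !is.na(y)
  y <- y[ok]; w <- w[ok]
  if (length(unique(w)) < 2L)
    stop("degenerate design matrix: fewer than 2 distinct contrast weights")
  wc <- w - mean(w)
  sxx <- sum(wc^2)
  beta <- sum(wc * (y - mean(y))) / sxx
  resid <- y - mean(y) - beta * wc
  df <- length(y) - 2L
  sigma2 <- sum(resid^2) / df
  tval <- if (sigma2 > 0) beta / sqrt(sigma2 / sxx) else
    ifelse(beta == 0, 0, sign(beta) * Inf)
  list(beta = beta, t = tval)
}

#' Subject-level searchlight conjunctiveness map
#'
#' For each searchlight sphere, extracts the retrieval-phase patterns,
#' computes their Spearman similarity and fits the associative contrast; the
#' resulting slope is assigned to the sphere's centre voxel. Voxels without a
#' surviving sphere are masked out.
#'
#' @param betas a \code{\link{beta_image_set}}.
#' @param contrast \code{\link{build_contrast_matrix}} built from the same
#'   retrieval labels (order included).
#' @param spheres \code{\link{searchlight_spheres}} result on the same grid.
#' @return a subject-level \code{\link{stat_map}} of conjunctiveness slopes.
#' @export
conjunctiveness_map <- function(betas, contrast, spheres) {
  ret_rows <- which(betas$labels$phase == "retrieval")
  lab <- betas$labels[ret_rows, ]
  key <- function(l) paste(l$association_id, l$order_index, l$instance_index,
                           l$run_id, sep = "/")
  if (!identical(key(lab), key(contrast$labels)))
    stop("contrast was not built from this beta set's retrieval labels")
  d <- dim(betas$data)
  if (!identical(d[1:3], spheres$dim))
    stop("searchlight grid does not match the beta grid")
  mat <- matrix(betas$data, prod(d[1:3]), d[4L])[, ret_rows, drop = FALSE]

  ut <- upper.tri(contrast$weights)
  sel <- which(contrast$include & ut)
  n_inst <- nrow(contrast$weights)
  cell_i <- ((sel - 1L) %% n_inst) + 1L   # row index within the matrix
  cell_j <- ((sel - 1L) %/% n_inst) + 1L  # column index
  w_all <- contrast$weights[sel]

  slopes <- .searchlight_slopes_cpp(mat, spheres$voxels, cell_i, cell_j,
                                    w_all)
  vals <- array(NA_real_, dim = d[1:3])
  outmask <- array(FALSE, dim = d[1:3])
  ok <- !is.na(slopes)
  cidx <- spheres$centres[ok, , drop = FALSE]
  lin <- (cidx[, 3L] - 1L) * d[1L] * d[2L] + (cidx[, 2L] - 1L) * d[1L] +
    cidx[, 1L]
  vals[lin] <- slopes[ok]
  outmask[lin] <- TRUE
  stat_map(vals, outmask, metric = "conjunctiveness", level = "subject",
           voxel_size_mm = betas$voxel_size_mm)
}
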