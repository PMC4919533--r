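# Synthetic atlas: compact contiguous parcels tiling the grid, each assigned
# to one subnetwork module. Stands in for an anatomical parcellation when the
# pipeline runs on simulated data.

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic atlas of compact regions
#'
#' Partitions the full grid into \code{n_regions} compact, contiguous,
#' non-overlapping regions by k-means on voxel coordinates (a centroidal
#' Voronoi tessellation, whose cells are convex and hence connected on the
#' grid). Regions are relabelled 1..n_regions by centroid position so that
#' ids are stable, then assigned round-robin to \code{n_modules} subnetwork
#' modules.
#'
#' @param grid_shape integer triple, e.g. \code{c(16, 16, 16)}.
#' @param n_regions number of regions (>= 4).
#' @param n_modules number of subnetwork modules the regions are assigned to.
#' @param seed RNG seed; the same seed reproduces the same atlas.
#' @return list with \code{atlas} (3-D integer array, values 1..n_regions),
#'   \code{region_names} (character), \code{region_to_module} (integer vector
#'   indexed by region id).
#' @export
generate_atlas <- function(grid_shape, n_regions, n_modules = 2L, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be three positive integers")
  n_regions <- as.integer(n_regions)
  if (n_regions < 4L) stop("n_regions must be >= 4")
  if (prod(grid_shape) < n_regions)
    stop("n_regions (", n_regions, ") exceeds the number of grid voxels (",
         prod(grid_shape), ")")
  coords <- as.matrix(expand.grid(x = seq_len(grid_shape[1L]),
                                  y = seq_len(grid_shape[2L]),
                                  z = seq_len(grid_shape[3L])))
  km <- .with_seed(seed, stats::kmeans(coords, centers = n_regions,
                                       nstart = 5L, iter.max = 100L))
  # stable region ids: order clusters by centroid (x, then y, then z)
  ord <- order(km$centers[, 1L], km$centers[, 2L], km$centers[, 3L])
  relabel <- integer(n_regions)
  relabel[ord] <- seq_len(n_regions)
  atlas <- array(relabel[km$cluster], dim = grid_shape)
  region_names <- sprintf("region_%02d", seq_len(n_regions))
  region_to_module <- rep(seq_len(as.integer(n_modules)),
                          length.out = n_regions)
  list(atlas = atlas, region_names = region_names,
       region_to_module = region_to_module)
}

#' Subsample an atlas to a coarser grid
#'
#' Assigns each non-overlapping \code{factor^3} block the modal region label
#' of its voxels (ties broken by the smallest label). Used to carry region
#' membership onto the subsampled connectivity grid.
#'
#' @param atlas 3-D integer label array.
#' @param factor integer subsampling factor.
#' @return 3-D integer array of dimension \code{ceiling(dim(atlas)/factor)}.
#' @export
subsample_atlas <- function(atlas, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  d <- dim(atlas)
  nd <- as.integer(ceiling(d / factor))
  out <- array(0L, dim = nd)
  for (i in seq_len(nd[1L])) for (j in seq_len(nd[2L])) for (k in seq_len(nd[3L])) {
    xs <- ((i - 1L) * factor + 1L):min(i * factor, d[1L])
    ys <- ((j - 1L) * factor + 1L):min(j * factor, d[2L])
    zs <- ((k - 1L) * factor + 1L):min(k * factor, d[3L])
    block <- atlas[xs, ys, zs]
    block <- block[block != 0L]
    if (length(block)) {
      tab <- table(block)
      out[i, j, k] <- as.integer(names(tab)[which.max(tab)])
    }
  }
  out
}
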