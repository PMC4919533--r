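# Graph-theoretical hubness: Louvain module partition, participation
# coefficient, eigenvector centrality, and the retrieval-vs-ITI contrast.

#' Louvain module partition of a region graph
#'
#' Runs seeded Louvain modularity maximisation (via igraph) on the weighted
#' region-by-region adjacency. An edgeless graph degenerates to one module
#' per region (with a message). Voxel nodes inherit the module of their atlas
#' region via \code{\link{node_modules}}.
#'
#' @param rgraph a \code{\link{region_graph}} (or any symmetric nonnegative
#'   matrix with region-id dimnames).
#' @param seed RNG seed; the partition is deterministic given the seed.
#' @return list of class \code{module_partition}: \code{region_module}
#'   (named integer vector, region id -> module id) and \code{n_modules}.
#' @export
louvain_partition <- function(rgraph, seed = 1L) {
  adj <- if (inherits(rgraph, "region_graph")) rgraph$adjacency else rgraph
  if (nrow(adj) == 0L) stop("empty region graph")
  ids <- if (!is.null(rownames(adj))) as.integer(rownames(adj))
         else seq_len(nrow(adj))
  if (all(adj[upper.tri(adj)] == 0)) {
    message("louvain_partition: graph has no edges; ",
            "every region becomes its own module")
    membership <- seq_len(nrow(adj))
  } else {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    cl <- .with_seed(seed, igraph::cluster_louvain(g))
    membership <- as.integer(igraph::membership(cl))
  }
  region_module <- stats::setNames(membership, ids)
  structure(list(region_module = region_module,
                 n_modules = length(unique(membership))),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("<module_partition> ", length(x$region_module), " regions in ",
      x$n_modules, " modules\n", sep = "")
  invisible(x)
}

#' Module assignment of connectivity-graph nodes
#'
#' @param graph a \code{\link{build_connectivity}} result.
#' @param atlas 3-D integer label array on the graph's grid.
#' @param partition a \code{\link{module_partition}}.
#' @return integer vector, one module id per graph node.
#' @export
node_modules <- function(graph, atlas, partition) {
  if (!identical(dim(atlas), graph$dim))
    stop("atlas grid does not match the connectivity graph")
  regs <- as.vector(atlas)[graph$node_index]
  mods <- partition$region_module[as.character(regs)]
  if (any(is.na(mods)))
    stop("some graph nodes fall in regions absent from the partition")
  as.integer(mods)
}

#' Participation coefficient of every graph node
#'
#' PC_i = 1 - sum_s (e_is / k_i)^2, where e_is is the connection weight of
#' node i into module s and k_i its total connection weight. Nodes with
#' k_i = 0 get PC 0 by convention. PC is 0 for a provincial node (edges only
#' within its own module) and approaches 1 - 1/NM for a node spread evenly
#' over NM modules. With \code{weighted = FALSE} edges count as 0/1
#' (edge-count PC, matching the formula read literally).
#'
#' @param graph a \code{\link{connectivity_graph}} or a plain symmetric
#'   nonnegative adjacency matrix.
#' @param modules integer vector of module ids, one per node (e.g. from
#'   \code{\link{node_modules}}).
#' @param weighted use summed edge weights (default) or edge counts.
#' @return numeric vector of participation coefficients in [0, 1].
#' @export
participation_coefficient <- function(graph, modules, weighted = TRUE) {
  w <- if (inherits(graph, "connectivity_graph")) graph$adjacency else graph
  if (!weighted) w <- (w > 0) + 0
  n <- nrow(w)
  if (length(modules) != n)
    stop("every node must be assigned a module")
  mod <- as.integer(factor(modules))
  ind <- matrix(0, n, max(mod))
  ind[cbind(seq_len(n), mod)] <- 1
  e_is <- w %*% ind
  k <- rowSums(w)
  pc <- 1 - rowSums((e_is / ifelse(k > 0, k, 1))^2)
  pc[k == 0] <- 0
  unname(pmin(pmax(pc, 0), 1))
}

#' Eigenvector centrality of a connectivity graph
#'
#' The leading eigenvector of the nonnegative symmetric adjacency matrix,
#' oriented nonnegative and scaled to unit Euclidean norm. An all-zero graph
#' yields an all-zero vector (with a message).
#'
#' @param graph a \code{\link{connectivity_graph}} or adjacency matrix.
#' @return numeric vector of centralities, one per node.
#' @export
eigenvector_centrality <- function(graph) {
  w <- if (inherits(graph, "connectivity_graph")) graph$adjacency else graph
  if (all(w == 0)) {
    message("eigenvector_centrality: graph has no edges; returning zeros")
    return(rep(0, nrow(w)))
  }
  es <- eigen(w, symmetric = TRUE)
  v <- es$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  v[abs(v) < 1e-12] <- 0
  v / sqrt(sum(v^2))
}

#' Voxel-wise hubness map from a connectivity graph
#'
#' Assembles per-node hubness scores (participation coefficient or
#' eigenvector centrality) into a \code{\link{stat_map}} on the graph's
#' (subsampled) grid.
#'
#' @param graph a \code{\link{connectivity_graph}}.
#' @param scores numeric vector, one score per node.
#' @param metric metric name recorded in the map.
#' @param voxel_size_mm voxel size of the graph's grid.
#' @return a subject-level \code{\link{stat_map}}.
#' @export
hubness_map <- function(graph, scores, metric = "participation_coefficient",
                        voxel_size_mm = 8) {
  vals <- array(NA_real_, dim = graph$dim)
  mask <- array(FALSE, dim = graph$dim)
  vals[graph$node_index] <- scores
  mask[graph$node_index] <- TRUE
  stat_map(vals, mask, metric = metric, level = "subject",
           voxel_size_mm = voxel_size_mm)
}

#' Retrieval-minus-ITI hubness contrast
#'
#' @param retrieval,iti subject-level \code{\link{stat_map}}s of the same
#'   metric on the same grid.
#' @return a subject-level \code{\link{stat_map}} of voxel-wise differences,
#'   defined where both inputs are.
#' @export
hubness_contrast <- function(retrieval, iti) {
  if (!identical(dim(retrieval$values), dim(iti$values)))
    stop("hubness maps are on different grids")
  if (!identical(retrieval$metric, iti$metric))
    stop("hubness maps use different metrics")
  mask <- retrieval$mask & iti$mask
  vals <- retrieval$values - iti$values
  vals[!mask] <- NA_real_
  stat_map(vals, mask, metric = paste0(retrieval$metric, "_contrast"),
           level = "subject", voxel_size_mm = retrieval$voxel_size_mm)
}

#' Upsample a subsampled stat map by block replication
#'
#' Inverse of the spatial subsampling step: each coarse voxel's value is
#' replicated over its \code{factor^3} fine-grid block, cropped to
#' \code{target_dim}.
#'
#' @param map a \code{\link{stat_map}} on the coarse grid.
#' @param factor integer upsampling factor.
#' @param target_dim integer triple, the fine grid dimensions.
#' @return a \code{\link{stat_map}} on the fine grid.
#' @export
upsample_map <- function(map, factor, target_dim) {
  factor <- as.integer(factor)
  target_dim <- as.integer(target_dim)
  ix <- pmin((seq_len(target_dim[1L]) - 1L) %/% factor + 1L,
             dim(map$values)[1L])
  iy <- pmin((seq_len(target_dim[2L]) - 1L) %/% factor + 1L,
             dim(map$values)[2L])
  iz <- pmin((seq_len(target_dim[3L]) - 1L) %/% factor + 1L,
             dim(map$values)[3L])
  vals <- map$values[ix, iy, iz]
  mask <- map$mask[ix, iy, iz]
  vals[!mask] <- NA_real_
  stat_map(vals, mask, metric = map$metric, level = map$level,
           voxel_size_mm = map$voxel_size_mm / factor)
}
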