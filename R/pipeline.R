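# End-to-end orchestration: RSA -> network -> group inference -> overlap.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Defaults follow the
#' standard settings: searchlight radius 4 voxels with a 30-voxel minimum,
#' FDR 0.05 edge thresholding, 10000 sign-flip and resampling permutations,
#' and two resampled regions per permutation. For small synthetic grids the
#' searchlight radius and subsampling factor are usually reduced.
#'
#' @param radius searchlight radius in voxels.
#' @param min_voxels minimum in-mask sphere size.
#' @param subsample_factor spatial subsampling factor for connectivity.
#' @param fdr_alpha FDR level for edge retention.
#' @param metric hubness metric, \code{"pc"} or \code{"evc"}.
#' @param share_partition define the subnetwork partition once from the
#'   baseline (ITI) region graph and use it for both phases; the default
#'   computes one partition per phase from that phase's own graph.
#' @param n_perm_group sign-flip permutations.
#' @param side group test sidedness.
#' @param alpha binarization threshold for the group p maps.
#' @param target_region_ids atlas regions forming the overlap ROI.
#' @param n_perm_overlap resampling permutations.
#' @param n_draw regions drawn per resampling permutation.
#' @param exclude_targets if TRUE, overlap null draws avoid the target
#'   regions (see \code{\link{spatial_resampling_test}}).
#' @param seed global seed; stage seeds are derived from it.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(radius = 4, min_voxels = 30,
                            subsample_factor = 4L, fdr_alpha = 0.05,
                            metric = c("pc", "evc"),
                            share_partition = FALSE,
                            n_perm_group = 10000L,
                            side = "greater", alpha = 0.05,
                            target_region_ids = 1L,
                            n_perm_overlap = 10000L, n_draw = 2L,
                            exclude_targets = FALSE, seed = 1L) {
  metric <- match.arg(metric)
  cfg <- list(radius = radius, min_voxels = min_voxels,
              subsample_factor = as.integer(subsample_factor),
              fdr_alpha = fdr_alpha, metric = metric,
              share_partition = isTRUE(share_partition),
              n_perm_group = as.integer(n_perm_group), side = side,
              alpha = alpha,
              target_region_ids = as.integer(target_region_ids),
              n_perm_overlap = as.integer(n_perm_overlap),
              n_draw = as.integer(n_draw),
              exclude_targets = isTRUE(exclude_targets),
              seed = as.integer(seed))
  stopifnot(cfg$radius >= 1, cfg$min_voxels >= 1, cfg$subsample_factor >= 1,
            cfg$fdr_alpha > 0, cfg$fdr_alpha <= 1, cfg$alpha > 0,
            cfg$alpha <= 1, cfg$n_perm_group >= 1, cfg$n_perm_overlap >= 1,
            cfg$n_draw >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Subject-level hubness-contrast map
#'
#' Runs the full network stage for one subject: spatial subsampling, voxel
#' and region connectivity graphs per phase, Louvain module partition,
#' participation coefficient (or eigenvector centrality) per phase, and the
#' retrieval-minus-ITI contrast, upsampled back to the analysis grid.
#'
#' @param betas a \code{\link{beta_image_set}} on the analysis grid.
#' @param atlas 3-D integer label array on the analysis grid.
#' @param config a \code{\link{pipeline_config}}.
#' @return list: \code{contrast} (subject-level \code{\link{stat_map}} on the
#'   analysis grid), \code{retrieval}, \code{iti} (maps on the subsampled
#'   grid), \code{partitions}.
#' @export
subject_hubness <- function(betas, atlas, config = pipeline_config()) {
  f <- config$subsample_factor
  sub <- subsample_betas(betas, f)
  sub_atlas <- if (f > 1L) subsample_atlas(atlas, f) else atlas
  phases <- c("retrieval", "iti")
  maps <- list()
  partitions <- list()
  # with share_partition, subnetworks are defined once from the baseline
  # (ITI) graph — the usual practice of deriving canonical modules from
  # task-free data — and participation is measured per phase against them
  part_shared <- if (config$metric == "pc" && config$share_partition) {
    louvain_partition(region_graph(sub, sub_atlas, phase = "iti",
                                   fdr_alpha = config$fdr_alpha),
                      seed = config$seed)
  }
  for (ph in phases) {
    g <- build_connectivity(sub, phase = ph, fdr_alpha = config$fdr_alpha)
    if (config$metric == "pc") {
      part <- if (config$share_partition) part_shared else
        louvain_partition(region_graph(sub, sub_atlas, phase = ph,
                                       fdr_alpha = config$fdr_alpha),
                          seed = config$seed)
      partitions[[ph]] <- part
      scores <- participation_coefficient(g, node_modules(g, sub_atlas, part))
      metric_name <- "participation_coefficient"
    } else {
      scores <- eigenvector_centrality(g)
      metric_name <- "eigenvector_centrality"
    }
    maps[[ph]] <- hubness_map(g, scores, metric = metric_name,
                              voxel_size_mm = sub$voxel_size_mm)
  }
  contrast_sub <- hubness_contrast(maps$retrieval, maps$iti)
  contrast <- if (f > 1L)
    upsample_map(contrast_sub, f, dim(betas$data)[1:3]) else contrast_sub
  list(contrast = contrast, retrieval = maps$retrieval, iti = maps$iti,
       partitions = partitions)
}

#' Run the full convergence-zone analysis
#'
#' Orchestrates the pipeline on an in-memory dataset: per-subject searchlight
#' conjunctiveness maps, per-subject hubness contrasts, sign-flip group tests
#' for both metrics, binarized group masks, the region-resampling overlap
#' test and the across-voxel metric correlation. Fully deterministic given
#' the dataset and configuration.
#'
#' @param subjects list of \code{\link{beta_image_set}}s on one grid.
#' @param atlas 3-D integer label array on that grid.
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir optional directory; when given, maps, masks, the overlap
#'   JSON and a manifest recording all seeds and parameters are written.
#' @return list of class \code{convergence_result}: \code{conj_maps},
#'   \code{hub_maps} (per subject), \code{group_conj}, \code{group_hub}
#'   (\code{group_result}s), \code{conj_mask}, \code{hub_mask},
#'   \code{overlap} (\code{\link{spatial_resampling_test}} result),
#'   \code{metric_cor}, \code{config}.
#' @export
run_all <- function(subjects, atlas, config = pipeline_config(),
                    out_dir = NULL) {
  stopifnot(length(subjects) >= 3L)
  grid <- dim(subjects[[1L]]$data)[1:3]
  if (!identical(dim(atlas), grid)) stop("[atlas] grid mismatch")

  message("run_all: searchlight RSA (radius ", config$radius,
          ", min ", config$min_voxels, " voxels)")
  mask <- subjects[[1L]]$mask
  spheres <- searchlight_spheres(mask, config$radius, config$min_voxels)
  ret_labels <- subjects[[1L]]$labels[
    subjects[[1L]]$labels$phase == "retrieval", ]
  contrast <- build_contrast_matrix(ret_labels)
  conj_maps <- lapply(seq_along(subjects), function(s) {
    tryCatch(conjunctiveness_map(subjects[[s]], contrast, spheres),
             error = function(e) stop("[rsa] subject ", s, ": ",
                                      conditionMessage(e)))
  })

  message("run_all: beta-series connectivity (subsample ",
          config$subsample_factor, ", metric ", config$metric, ")")
  hub <- lapply(seq_along(subjects), function(s) {
    tryCatch(subject_hubness(subjects[[s]], atlas, config),
             error = function(e) stop("[network] subject ", s, ": ",
                                      conditionMessage(e)))
  })
  hub_maps <- lapply(hub, `[[`, "contrast")

  message("run_all: sign-flip group tests (", config$n_perm_group,
          " permutations, side ", config$side, ")")
  group_conj <- signflip_permutation_test(conj_maps, config$n_perm_group,
                                          side = config$side,
                                          seed = config$seed)
  group_hub <- signflip_permutation_test(hub_maps, config$n_perm_group,
                                         side = config$side,
                                         seed = config$seed + 1L)
  conj_mask <- binarize_map(group_conj, config$alpha)
  hub_mask <- binarize_map(group_hub, config$alpha)

  message("run_all: overlap test on region(s) ",
          paste(config$target_region_ids, collapse = ","))
  overlap <- tryCatch(
    spatial_resampling_test(conj_mask, hub_mask, atlas,
                            config$target_region_ids,
                            n_perm = config$n_perm_overlap,
                            n_draw = config$n_draw,
                            seed = config$seed + 2L,
                            exclude_targets = config$exclude_targets),
    error = function(e) stop("[overlap] ", conditionMessage(e)))

  roi <- array(as.vector(atlas) %in% config$target_region_ids, dim = grid)
  metric_cor <- tryCatch(
    metric_correlation(conj_maps, hub_maps, roi),
    error = function(e) {
      message("[overlap] metric correlation unavailable: ",
              conditionMessage(e))
      NULL
    })

  res <- structure(list(conj_maps = conj_maps, hub_maps = hub_maps,
                        group_conj = group_conj, group_hub = group_hub,
                        conj_mask = conj_mask, hub_mask = hub_mask,
                        overlap = overlap, metric_cor = metric_cor,
                        config = config),
                   class = "convergence_result")
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' @export
print.convergence_result <- function(x, ...) {
  cat("<convergence_result> ", length(x$conj_maps), " subjects\n", sep = "")
  cat("  conjunctiveness voxels p<alpha: ", sum(x$conj_mask), "\n", sep = "")
  cat("  hubness voxels p<alpha:         ", sum(x$hub_mask), "\n", sep = "")
  print(x$overlap)
  if (!is.null(x$metric_cor)) print(x$metric_cor)
  invisible(x)
}

#' Write pipeline results and a manifest to a directory
#'
#' @param res a \code{convergence_result}.
#' @param out_dir output directory (created if absent).
#' @return \code{out_dir}, invisibly.
#' @export
write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(res$conj_maps)) {
    write_stat_map(res$conj_maps[[s]],
                   file.path(out_dir, sprintf("sub-%02d_conj.nii.gz", s)))
    write_stat_map(res$hub_maps[[s]],
                   file.path(out_dir, sprintf("sub-%02d_hub.nii.gz", s)))
  }
  write_stat_map(res$group_conj$t, file.path(out_dir, "group_conj_t.nii.gz"))
  write_stat_map(res$group_conj$p, file.path(out_dir, "group_conj_p.nii.gz"))
  write_stat_map(res$group_hub$t, file.path(out_dir, "group_hub_t.nii.gz"))
  write_stat_map(res$group_hub$p, file.path(out_dir, "group_hub_p.nii.gz"))
  write_nifti(res$conj_mask + 0L, file.path(out_dir, "conj_mask.nii.gz"),
              datatype = "uint8")
  write_nifti(res$hub_mask + 0L, file.path(out_dir, "hub_mask.nii.gz"),
              datatype = "uint8")
  ov <- res$overlap
  jsonlite::write_json(
    list(dice = ov$dice, relative_overlap = ov$relative_overlap,
         p_dice = ov$p_dice, p_relative = ov$p_relative,
         n_permutations = ov$n_permutations,
         n_regions_drawn = ov$n_regions_drawn,
         target_region_ids = ov$target_region_ids,
         null_dice = ov$null_dice, null_relative = ov$null_relative),
    file.path(out_dir, "overlap.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(config = unclass(res$config),
                   n_subjects = length(res$conj_maps),
                   conj_voxels = sum(res$conj_mask),
                   hub_voxels = sum(res$hub_mask),
                   degenerate_voxels_conj = res$group_conj$degenerate_voxels,
                   degenerate_voxels_hub = res$group_hub$degenerate_voxels,
                   metric_cor = if (!is.null(res$metric_cor))
                     list(rho = res$metric_cor$rho,
                          statistic = res$metric_cor$statistic,
                          p = res$metric_cor$p) else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
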