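# Multi-subject synthetic beta-image generator with planted effects.
#
# The generative model mirrors the statistical structure the downstream
# analysis assumes:
#   * conjunctive term  — one standard-normal voxel pattern per association,
#     restricted to the planted region, identical for both cue-associate
#     orders (order-invariant), scaled by conjunctive_effect;
#   * perceptual term   — one pattern per stimulus category over the "visual"
#     regions; a retrieval beta receives 1.0 x the cue-category pattern plus
#     0.5 x the associate-category pattern, scaled by perceptual_effect
#     (order-DEpendent, the confound the perception penalty must reject);
#   * connectivity term — every voxel loads on its module's i.i.d. N(0,1)
#     latent instance series (weight module_coupling); planted-region voxels
#     additionally load on every OTHER module's series with weight
#     hub_effect, retrieval phase only;
#   * i.i.d. Gaussian noise with sd noise_sd, both phases.
# ITI betas contain only the own-module loading plus noise.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the scaled-down study world used throughout the test
#' suite: 12 subjects on a 16x16x16 grid with 8 regions in 2 modules, the
#' full 12-association / 2-order / 2-instance / 2-run design (96 retrieval +
#' 96 ITI betas), planted conjunctive and hub effects at 1.5x the noise sd,
#' and a perceptual confound at 1.0x.
#'
#' @param grid_shape integer triple.
#' @param n_regions,n_modules atlas layout (see \code{\link{generate_atlas}}).
#' @param n_subjects number of simulated subjects.
#' @param n_associations,instances_per_condition,runs design parameters
#'   passed to \code{\link{make_design}}.
#' @param conjunctive_effect,perceptual_effect,hub_effect nonnegative effect
#'   magnitudes in beta units; all zero (with \code{module_coupling = 0})
#'   defines the fully degenerate model, while zero effects with
#'   \code{module_coupling = 1} defines the global null of the pipeline.
#' @param module_coupling nonnegative weight of the own-module latent series.
#' @param noise_sd positive Gaussian noise sd.
#' @param planted_region_id atlas region carrying the planted conjunctive
#'   and hub effects (the simulated convergence zone).
#' @param voxel_size_mm voxel edge length recorded in the outputs.
#' @param seed RNG seed; the whole dataset is deterministic given the config.
#' @return a list of class \code{synth_config}.
#' @export
synth_config <- function(grid_shape = c(16L, 16L, 16L), n_regions = 8L,
                         n_modules = 2L, n_subjects = 12L,
                         n_associations = 12L, instances_per_condition = 2L,
                         runs = 2L, conjunctive_effect = 1.5,
                         perceptual_effect = 1.0, hub_effect = 1.5,
                         module_coupling = 1.0, noise_sd = 1.0,
                         planted_region_id = 1L, voxel_size_mm = 2,
                         seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              n_regions = as.integer(n_regions),
              n_modules = as.integer(n_modules),
              n_subjects = as.integer(n_subjects),
              n_associations = as.integer(n_associations),
              instances_per_condition = as.integer(instances_per_condition),
              runs = as.integer(runs),
              conjunctive_effect = conjunctive_effect,
              perceptual_effect = perceptual_effect,
              hub_effect = hub_effect,
              module_coupling = module_coupling,
              noise_sd = noise_sd,
              planted_region_id = as.integer(planted_region_id),
              voxel_size_mm = voxel_size_mm,
              seed = as.integer(seed))
  if (any(c(cfg$conjunctive_effect, cfg$perceptual_effect, cfg$hub_effect,
            cfg$module_coupling) < 0))
    stop("effect magnitudes must be nonnegative")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$planted_region_id < 1L || cfg$planted_region_id > cfg$n_regions)
    stop("planted_region_id must be a valid region code (1..n_regions)")
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1")
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a multi-subject synthetic dataset with planted effects
#'
#' Draws per-subject beta-image sets under the generative model described in
#' \code{\link{synth_config}}, together with the ground truth needed to score
#' recovery: the atlas, the planted convergence-zone mask, the "visual"
#' confound mask (all non-planted regions of the last module) and each
#' subject's latent association and category patterns.
#'
#' @param config a \code{\link{synth_config}}.
#' @return list with \code{subjects} (list of \code{\link{beta_image_set}})
#'   and \code{truth} (list: \code{atlas}, \code{region_names},
#'   \code{region_to_module}, \code{planted_mask}, \code{visual_mask},
#'   \code{visual_region_ids}, \code{latents} per subject, \code{config}).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  at <- generate_atlas(config$grid_shape, config$n_regions,
                       config$n_modules, seed = config$seed)
  labels <- make_design(config$n_associations, config$instances_per_condition,
                        config$runs)
  grid <- config$grid_shape
  nvox <- prod(grid)
  mask <- array(TRUE, dim = grid)
  planted_mask <- at$atlas == config$planted_region_id
  visual_module <- config$n_modules
  visual_region_ids <- setdiff(which(at$region_to_module == visual_module),
                               config$planted_region_id)
  visual_mask <- array(at$atlas %in% visual_region_ids, dim = grid)

  module_of_voxel <- at$region_to_module[as.vector(at$atlas)]
  planted_idx <- which(as.vector(planted_mask))
  visual_idx <- which(as.vector(visual_mask))
  planted_module <- at$region_to_module[config$planted_region_id]

  ret <- labels[labels$phase == "retrieval", ]
  iti <- labels[labels$phase == "iti", ]
  n_ret <- nrow(ret); n_iti <- nrow(iti)
  K <- config$n_modules
  cats <- .cz_categories

  subjects <- vector("list", config$n_subjects)
  latents <- vector("list", config$n_subjects)
  .with_seed(config$seed, {
    for (s in seq_len(config$n_subjects)) {
      assoc_pat <- matrix(stats::rnorm(config$n_associations *
                                         length(planted_idx)),
                          nrow = config$n_associations)
      cat_pat <- matrix(stats::rnorm(3L * length(visual_idx)), nrow = 3L,
                        dimnames = list(cats, NULL))
      z_ret <- matrix(stats::rnorm(K * n_ret), nrow = K)
      z_iti <- matrix(stats::rnorm(K * n_iti), nrow = K)

      dat <- matrix(stats::rnorm(nvox * (n_ret + n_iti),
                                 sd = config$noise_sd), nrow = nvox)
      # own-module loading, both phases
      if (config$module_coupling > 0) {
        dat[, seq_len(n_ret)] <- dat[, seq_len(n_ret)] +
          config$module_coupling * z_ret[module_of_voxel, , drop = FALSE]
        dat[, n_ret + seq_len(n_iti)] <- dat[, n_ret + seq_len(n_iti)] +
          config$module_coupling * z_iti[module_of_voxel, , drop = FALSE]
      }
      # conjunctive term: order-invariant association pattern, planted region
      if (config$conjunctive_effect > 0 && length(planted_idx))
        dat[planted_idx, seq_len(n_ret)] <-
          dat[planted_idx, seq_len(n_ret)] + config$conjunctive_effect *
            t(assoc_pat[ret$association_id, , drop = FALSE])
      # perceptual term: cue pattern x1.0 + associate pattern x0.5, visual rois
      if (config$perceptual_effect > 0 && length(visual_idx))
        dat[visual_idx, seq_len(n_ret)] <-
          dat[visual_idx, seq_len(n_ret)] + config$perceptual_effect *
            (t(cat_pat[ret$cue_category, , drop = FALSE]) +
               0.5 * t(cat_pat[ret$associate_category, , drop = FALSE]))
      # hub term: planted voxels load on every other module, retrieval only
      if (config$hub_effect > 0 && length(planted_idx) && K > 1L) {
        other <- colSums(z_ret[-planted_module, , drop = FALSE])
        dat[planted_idx, seq_len(n_ret)] <-
          dat[planted_idx, seq_len(n_ret)] +
            config$hub_effect * rep(other, each = length(planted_idx))
      }
      subjects[[s]] <- beta_image_set(array(dat, dim = c(grid, n_ret + n_iti)),
                                      rbind(ret, iti), mask,
                                      config$voxel_size_mm)
      latents[[s]] <- list(association_patterns = assoc_pat,
                           category_patterns = cat_pat)
    }
  })
  truth <- list(atlas = at$atlas, region_names = at$region_names,
                region_to_module = at$region_to_module,
                planted_mask = planted_mask, visual_mask = visual_mask,
                visual_region_ids = visual_region_ids,
                planted_region_id = config$planted_region_id,
                latents = latents, config = config)
  list(subjects = subjects, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Writes one 4-D NIfTI beta stack plus a tab-separated label table per
#' subject, the atlas NIfTI, the grey-matter mask NIfTI, a region-name TSV
#' and a ground-truth JSON (region/module assignment, planted region,
#' generator configuration).
#'
#' @param dataset output of \code{\link{generate_dataset}}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(dataset$subjects)) {
    bs <- dataset$subjects[[s]]
    write_nifti(bs$data, file.path(dir, sprintf("sub-%02d_betas.nii.gz", s)),
                voxel_size_mm = bs$voxel_size_mm)
    write_labels(bs$labels, file.path(dir, sprintf("sub-%02d_labels.tsv", s)))
  }
  tr <- dataset$truth
  write_nifti(tr$atlas, file.path(dir, "atlas.nii.gz"),
              voxel_size_mm = tr$config$voxel_size_mm, datatype = "int16")
  write_nifti(array(1L, dim = dim(tr$atlas)) * (tr$atlas > 0),
              file.path(dir, "mask.nii.gz"),
              voxel_size_mm = tr$config$voxel_size_mm, datatype = "uint8")
  utils::write.table(
    data.frame(region_id = seq_along(tr$region_names),
               region_name = tr$region_names,
               module = tr$region_to_module),
    file.path(dir, "regions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- list(planted_region_id = tr$planted_region_id,
             visual_region_ids = tr$visual_region_ids,
             region_to_module = tr$region_to_module,
             config = unclass(tr$config))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
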