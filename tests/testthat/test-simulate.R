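test_that("degenerate generative model produces all-zero betas", {
  cfg <- synth_config(grid_shape = c(6, 6, 6), n_regions = 4, n_subjects = 1,
                      n_associations = 3, instances_per_condition = 1,
                      runs = 1, conjunctive_effect = 0, perceptual_effect = 0,
                      hub_effect = 0, module_coupling = 0, noise_sd = 1e-12,
                      seed = 1)
  ds <- generate_dataset(cfg)
  expect_lt(max(abs(ds$subjects[[1]]$data)), 1e-8)
})

test_that("generation is bit-identical given the same config", {
  d1 <- tiny_dataset(seed = 3, n_subjects = 2, grid = 8)
  d2 <- tiny_dataset(seed = 3, n_subjects = 2, grid = 8)
  expect_identical(d1$subjects[[1]]$data, d2$subjects[[1]]$data)
  expect_identical(d1$subjects[[2]]$data, d2$subjects[[2]]$data)
  expect_identical(d1$truth$atlas, d2$truth$atlas)
  d3 <- tiny_dataset(seed = 4, n_subjects = 2, grid = 8)
  expect_false(identical(d1$subjects[[1]]$data, d3$subjects[[1]]$data))
})

test_that("strong conjunctive effect creates order-invariant association codes", {
  # oracle: sample correlations computed directly from the generated draws
  ds <- tiny_dataset(seed = 5, n_subjects = 1, grid = 8, conjunctive = 3,
                     perceptual = 0, hub = 0, coupling = 0, noise = 1)
  bs <- ds$subjects[[1]]
  ret <- which(bs$labels$phase == "retrieval")
  lab <- bs$labels[ret, ]
  mat <- matrix(bs$data, prod(dim(bs$data)[1:3]), dim(bs$data)[4])[
    which(ds$truth$planted_mask), ret]
  cc <- cor(mat)
  same_assoc <- outer(lab$association_id, lab$association_id, "==")
  diff_order <- outer(lab$order_index, lab$order_index, "!=")
  ut <- upper.tri(cc)
  within_cross_order <- mean(cc[same_assoc & diff_order & ut])
  between <- mean(cc[!same_assoc & ut])
  expect_gt(within_cross_order, between + 0.3)
})

test_that("labels, masks and ground truth are mutually consistent", {
  ds <- tiny_dataset(seed = 2, n_subjects = 1, grid = 8)
  bs <- ds$subjects[[1]]
  expect_equal(nrow(bs$labels), dim(bs$data)[4])
  expect_equal(sum(bs$labels$phase == "retrieval"),
               sum(bs$labels$phase == "iti"))
  tr <- ds$truth
  expect_identical(tr$planted_mask, tr$atlas == tr$planted_region_id)
  expect_false(any(tr$visual_mask & tr$planted_mask))
  expect_true(all(tr$atlas[tr$visual_mask] %in% tr$visual_region_ids))
  # visual regions belong to one module, excluding the planted region
  expect_true(all(tr$region_to_module[tr$visual_region_ids] ==
                    tr$region_to_module[tr$visual_region_ids][1]))
})

test_that("planted-effect monotonicity holds over repeated seeds", {
  # expected conjunctiveness statistic (within- minus between-association
  # planted-mask correlation) never decreases in conjunctive_effect
  stat_for <- function(effect, seed) {
    ds <- generate_dataset(synth_config(
      grid_shape = c(6, 6, 6), n_regions = 4, n_subjects = 1,
      n_associations = 3, instances_per_condition = 2, runs = 1,
      conjunctive_effect = effect, perceptual_effect = 0, hub_effect = 0,
      module_coupling = 0, noise_sd = 1, seed = seed))
    bs <- ds$subjects[[1]]
    ret <- which(bs$labels$phase == "retrieval")
    lab <- bs$labels[ret, ]
    m <- matrix(bs$data, 216, dim(bs$data)[4])[which(ds$truth$planted_mask),
                                               ret]
    cc <- cor(m)
    sa <- outer(lab$association_id, lab$association_id, "==")
    ut <- upper.tri(cc)
    mean(cc[sa & ut]) - mean(cc[!sa & ut])
  }
  seeds <- 1:20
  low <- mean(vapply(seeds, function(s) stat_for(0.5, s), numeric(1)))
  high <- mean(vapply(seeds, function(s) stat_for(1.5, s), numeric(1)))
  zero <- mean(vapply(seeds, function(s) stat_for(0, s), numeric(1)))
  expect_gt(high, low)
  expect_gt(low, zero)
  expect_lt(abs(zero), 0.1)   # null centred
})

test_that("a dataset round-trips through the on-disk format", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset(seed = 6, n_subjects = 2, grid = 6)
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "sub-01_betas.nii.gz")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  bs <- read_beta_set(file.path(dir, "sub-01_betas.nii.gz"),
                      file.path(dir, "sub-01_labels.tsv"),
                      file.path(dir, "mask.nii.gz"))
  expect_equal(bs$data, ds$subjects[[1]]$data, tolerance = 0)
  expect_equal(bs$labels$association_id,
               ds$subjects[[1]]$labels$association_id)
  at <- read_nifti(file.path(dir, "atlas.nii.gz"))$data
  expect_equal(array(as.integer(at), dim = dim(at)), ds$truth$atlas)
})
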