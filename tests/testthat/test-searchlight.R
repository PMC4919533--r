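test_that("sphere geometry follows the Euclidean radius and mask minimum", {
  # radius 1 inside a fully-true mask: centre + 6 face neighbours
  mask <- array(TRUE, dim = c(5, 5, 5))
  sp <- searchlight_spheres(mask, radius_voxels = 1, min_voxels = 1)
  centre <- which(sp$centres[, 1] == 3 & sp$centres[, 2] == 3 &
                    sp$centres[, 3] == 3)
  expect_length(sp$voxels[[centre]], 7L)
  # an isolated voxel cannot reach a 30-voxel minimum
  lone <- array(FALSE, dim = c(9, 9, 9)); lone[5, 5, 5] <- TRUE
  expect_length(searchlight_spheres(lone, 4, 30)$voxels, 0L)
  # default settings: 4-voxel radius, 30 grey-matter voxels minimum
  expect_equal(formals(searchlight_spheres)$radius_voxels, 4)
  expect_equal(formals(searchlight_spheres)$min_voxels, 30)
  # centres failing the minimum are omitted, the rest keep every in-mask voxel
  m2 <- array(TRUE, dim = c(4, 4, 4))
  sp2 <- searchlight_spheres(m2, 2, 20)
  expect_true(all(lengths(sp2$voxels) >= 20))
})

test_that("pattern similarity is Spearman's rank correlation", {
  a <- c(0.1, 0.5, 2, 7)
  sim <- pattern_similarity(rbind(a, a * 3 + 1, rev(a)))
  expect_equal(sim$values[1, 2], 1)       # monotone transform -> rho 1
  expect_equal(sim$values[1, 3], -1)      # rank reversal -> rho -1
  expect_equal(diag(sim$values), rep(1, 3))
  # frozen value from the explicit rank/product-moment formula:
  # ranks (1,2,3,4) vs (1,2,4,3) -> rho = 4/5
  s <- pattern_similarity(rbind(c(1, 2, 3, 5), c(1, 2, 4, 3)))
  expect_equal(s$values[1, 2], 0.8)
  # zero-variance pattern is marked undefined
  s2 <- pattern_similarity(rbind(c(1, 1, 1, 1), c(1, 2, 4, 3)))
  expect_true(is.na(s2$values[1, 2]) && is.na(s2$values[1, 1]))
  expect_equal(s2$values[2, 2], 1)
})

test_that("contrast GLM recovers slopes", {
  lab <- toy_labels()
  ctr <- build_contrast_matrix(lab)
  # similarities equal to weights plus a constant -> slope 1, zero residuals
  sim <- ctr$weights + 0.3
  fit <- fit_contrast(sim, ctr)
  expect_equal(fit$beta, 1, tolerance = 1e-12)
  # constant similarities -> slope 0
  expect_equal(fit_contrast(matrix(0.4, 4, 4), ctr)$beta, 0)
  # random similarities match the closed-form normal-equations solution
  set.seed(1)
  sim <- matrix(0, 4, 4)
  sim[upper.tri(sim)] <- runif(6)
  sim <- sim + t(sim); diag(sim) <- 1
  sel <- ctr$include & upper.tri(sim)
  X <- cbind(1, ctr$weights[sel])
  beta_hat <- solve(t(X) %*% X, t(X) %*% sim[sel])
  fit <- fit_contrast(sim, ctr)
  expect_equal(fit$beta, beta_hat[2], tolerance = 1e-12)
  expect_equal(fit$t,
               summary(lm(sim[sel] ~ ctr$weights[sel]))$coefficients[2, 3],
               tolerance = 1e-8)
})

test_that("the searchlight map agrees with the reference R path", {
  ds <- tiny_dataset(seed = 11, n_subjects = 1, grid = 8)
  bs <- ds$subjects[[1]]
  sp <- searchlight_spheres(bs$mask, 2, 10)
  ctr <- build_contrast_matrix(bs$labels[bs$labels$phase == "retrieval", ])
  map <- conjunctiveness_map(bs, ctr, sp)
  ret <- which(bs$labels$phase == "retrieval")
  mat <- matrix(bs$data, 512, dim(bs$data)[4])[, ret]
  set.seed(2)
  for (i in sample(length(sp$voxels), 4)) {
    fit <- fit_contrast(pattern_similarity(t(mat[sp$voxels[[i]], ])), ctr)
    cx <- sp$centres[i, ]
    expect_equal(map$values[cx[1], cx[2], cx[3]], fit$beta,
                 tolerance = 1e-10)
  }
})

test_that("null data yield a centred conjunctiveness map", {
  ds <- tiny_dataset(seed = 12, n_subjects = 1, grid = 12, conjunctive = 0,
                     perceptual = 0, hub = 0, coupling = 0)
  bs <- ds$subjects[[1]]
  # non-overlapping spheres so the slopes are independent and the standard
  # error of their mean is honest
  centres <- as.matrix(expand.grid(c(3L, 8L), c(3L, 8L), c(3L, 8L)))
  sp <- searchlight_spheres(bs$mask, 2, 10, centres = centres)
  ctr <- build_contrast_matrix(bs$labels[bs$labels$phase == "retrieval", ])
  map <- conjunctiveness_map(bs, ctr, sp)
  v <- map$values[map$mask]
  expect_length(v, 8L)
  expect_lt(abs(mean(v)), 3 * sd(v) / sqrt(length(v)))
})

test_that("planted conjunctive signal is localized and label-dependent", {
  ds <- tiny_dataset(seed = 13, n_subjects = 1, grid = 8, conjunctive = 2,
                     perceptual = 0, hub = 0, coupling = 0)
  bs <- ds$subjects[[1]]
  sp <- searchlight_spheres(bs$mask, 2, 10)
  ctr <- build_contrast_matrix(bs$labels[bs$labels$phase == "retrieval", ])
  map <- conjunctiveness_map(bs, ctr, sp)
  pm <- ds$truth$planted_mask
  expect_gt(mean(map$values[pm & map$mask]),
            mean(map$values[!pm & map$mask]))

  # permuting the instance dimension without relabelling destroys the effect
  set.seed(3)
  ret <- which(bs$labels$phase == "retrieval")
  perm <- sample(ret)
  shuf <- bs
  shuf$data[, , , ret] <- bs$data[, , , perm]
  map0 <- conjunctiveness_map(shuf, ctr, sp)
  v0 <- map0$values[map0$mask]
  expect_lt(mean(map0$values[pm & map0$mask]), mean(v0) + 3 * sd(v0))

  # permuting data and labels together leaves the map unchanged
  cons <- bs
  cons$data[, , , ret] <- bs$data[, , , perm]
  cons$labels[ret, ] <- bs$labels[perm, ]
  ctr2 <- build_contrast_matrix(cons$labels[cons$labels$phase == "retrieval", ])
  map2 <- conjunctiveness_map(cons, ctr2, sp)
  expect_equal(map2$values, map$values, tolerance = 1e-10)
})
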