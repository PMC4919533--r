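test_that("Dice and relative overlap match their formulas", {
  H <- c(TRUE, TRUE, FALSE, FALSE)
  C <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(dice_coefficient(H, H), 1)
  expect_equal(dice_coefficient(H, !H), 0)
  expect_equal(dice_coefficient(H, C), 0.5)        # 2*1 / (2+2)
  expect_equal(dice_coefficient(logical(4), logical(4)), 0)  # both empty
  expect_error(dice_coefficient(H, C[1:3]), "equal lengths")

  expect_equal(relative_overlap(rep(TRUE, 7), rep(TRUE, 7)), 1)
  expect_equal(relative_overlap(H, !H), 0)
  expect_equal(relative_overlap(c(rep(TRUE, 5), rep(FALSE, 95)),
                                rep(TRUE, 100)), 0.05)
  expect_error(relative_overlap(logical(0), logical(0)), "positive")

  # symmetry and monotonicity in the intersection
  set.seed(1)
  A <- runif(50) > 0.5; B <- runif(50) > 0.5
  expect_equal(dice_coefficient(A, B), dice_coefficient(B, A))
  expect_equal(relative_overlap(A, B), relative_overlap(B, A))
  B2 <- B; B2[which(A & !B)[1]] <- TRUE   # one more intersecting voxel
  expect_gt(dice_coefficient(A, B2), dice_coefficient(A, B))
})

test_that("resampling null on a 4-region toy equals exhaustive enumeration", {
  atlas <- array(rep(1:4, each = 4), dim = c(4, 4, 1))
  set.seed(2)
  conj <- array(runif(16) > 0.4, dim = c(4, 4, 1))
  hub <- array(runif(16) > 0.4, dim = c(4, 4, 1))
  res <- spatial_resampling_test(conj, hub, atlas, target_region_ids = 1L,
                                 n_perm = 400, n_draw = 2, seed = 3)
  # oracle: all C(4,2) = 6 unordered pairs
  pairs <- combn(4, 2)
  enum <- apply(pairs, 2, function(pr) {
    roi <- as.vector(atlas) %in% pr
    c(dice = dice_coefficient(hub[roi], conj[roi]),
      rel = sum(hub[roi] & conj[roi]) / sum(roi))
  })
  expect_true(all(round(res$null_dice, 12) %in% round(enum["dice", ], 12)))
  expect_true(all(round(res$null_relative, 12) %in% round(enum["rel", ], 12)))
  expect_setequal(round(unique(res$null_dice), 12),
                  round(unique(enum["dice", ]), 12))
  # p is consistent with the enumerated exceedance proportion
  frac <- mean(enum["dice", ] >= res$dice)
  expect_lt(abs(res$p_dice - frac), 3 * sqrt(frac * (1 - frac) / 400) + 0.01)
  expect_length(res$null_dice, 400)
})

test_that("degenerate overlap cases behave as documented", {
  atlas <- array(rep(1:4, each = 4), dim = c(4, 4, 1))
  none <- array(FALSE, dim = c(4, 4, 1))
  res <- spatial_resampling_test(none, none, atlas, 1L, n_perm = 50, seed = 1)
  expect_equal(res$dice, 0)
  expect_equal(res$relative_overlap, 0)
  expect_equal(res$p_dice, 1)            # every null ties at 0
  expect_error(spatial_resampling_test(none, none, atlas, 9L, 10),
               "absent")
  tiny <- array(c(1L, 2L), dim = c(2, 1, 1))
  expect_error(
    spatial_resampling_test(none[1:2, 1, 1, drop = FALSE],
                            none[1:2, 1, 1, drop = FALSE], tiny, 1L, 10),
    "more than n_draw")
})

test_that("target exclusion removes target redraws from the null", {
  atlas <- array(rep(1:4, each = 4), dim = c(4, 4, 1))
  full1 <- array(as.vector(atlas) == 1, dim = c(4, 4, 1))
  res <- spatial_resampling_test(full1, full1, atlas, 1L, n_perm = 300,
                                 seed = 4, exclude_targets = TRUE)
  expect_equal(res$dice, 1)
  expect_true(all(res$null_dice == 0))   # masks empty outside the target
  expect_equal(res$p_dice, 1 / 301)
  # without exclusion, {1, x} redraws tie with the observed dice
  res2 <- spatial_resampling_test(full1, full1, atlas, 1L, n_perm = 300,
                                  seed = 4, exclude_targets = FALSE)
  expect_gt(res2$p_dice, 0.05)
})

test_that("metric correlation and its group signed-rank test are correct", {
  dimv <- c(3, 3, 3)
  mask <- array(TRUE, dimv)
  roi <- array(TRUE, dimv)
  set.seed(5)
  base <- lapply(1:8, function(s) array(rnorm(27), dimv))
  conj <- lapply(base, function(v) stat_map(v, mask))
  hub_same <- lapply(base, function(v) stat_map(v * 2 + 1, mask))
  res <- metric_correlation(conj, hub_same, roi)
  expect_equal(res$rho, rep(1, 8))
  # all rho tie at 1, so the exact distribution is unavailable; the V
  # statistic is still maximal and p small for n = 8
  expect_equal(res$statistic, sum(1:8))
  expect_lt(res$p, 0.05)
  hub_neg <- lapply(base, function(v) stat_map(-v, mask))
  expect_equal(metric_correlation(conj, hub_neg, roi)$rho, rep(-1, 8))

  # n = 10 random maps: statistic and p match a 2^10 enumeration oracle
  set.seed(6)
  conj10 <- lapply(1:10, function(s) stat_map(array(rnorm(27), dimv), mask))
  hub10 <- lapply(1:10, function(s) stat_map(array(rnorm(27), dimv), mask))
  res10 <- metric_correlation(conj10, hub10, roi)
  rho <- res10$rho
  v_obs <- sum(rank(abs(rho))[rho > 0])
  expect_equal(res10$statistic, v_obs)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), 10)))
  rk <- rank(abs(rho))
  v_null <- apply(signs, 1, function(s) sum(rk[s > 0]))
  pl <- mean(v_null <= v_obs); pg <- mean(v_null >= v_obs)
  expect_equal(res10$p, min(2 * min(pl, pg), 1), tolerance = 1e-12)

  # constant map within the ROI is excluded with a warning
  conj_const <- conj10
  conj_const[[1]] <- stat_map(array(1, dimv), mask)
  expect_warning(resc <- metric_correlation(conj_const, hub10, roi),
                 "constant")
  expect_true(is.na(resc$rho[1]))
  expect_equal(resc$n_used, 9L)
  expect_error(metric_correlation(conj10, hub10,
                                  array(FALSE, dimv)), "at least 5")
})
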