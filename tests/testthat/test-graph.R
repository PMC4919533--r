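clique_pair <- function() {
  # two disconnected 5-cliques
  w <- matrix(0, 10, 10)
  w[1:5, 1:5] <- 1; w[6:10, 6:10] <- 1
  diag(w) <- 0
  rownames(w) <- colnames(w) <- 1:10
  w
}

test_that("Louvain recovers unambiguous block structure", {
  part <- louvain_partition(clique_pair(), seed = 1)
  expect_equal(part$n_modules, 2L)
  expect_length(unique(part$region_module[1:5]), 1L)
  expect_length(unique(part$region_module[6:10]), 1L)
  expect_false(part$region_module[1] == part$region_module[6])
  # determinism
  expect_identical(part$region_module,
                   louvain_partition(clique_pair(), seed = 1)$region_module)
})

test_that("degenerate region graphs are handled", {
  w1 <- matrix(0, 1, 1); rownames(w1) <- colnames(w1) <- 1
  expect_equal(louvain_partition(w1, 1)$n_modules, 1L)
  w0 <- matrix(0, 4, 4); rownames(w0) <- colnames(w0) <- 1:4
  expect_message(p0 <- louvain_partition(w0, 1), "no edges")
  expect_equal(p0$n_modules, 4L)
})

test_that("Louvain matches exhaustive 2-partition modularity maximisation", {
  # planted 2-block weighted model: within 1.0, between 0.05
  set.seed(4)
  n <- 8
  truth <- rep(1:2, each = 4)
  w <- matrix(0.05, n, n)
  w[truth == 1, truth == 1] <- 1
  w[truth == 2, truth == 2] <- 1
  diag(w) <- 0
  rownames(w) <- colnames(w) <- 1:n
  part <- louvain_partition(w, seed = 2)

  # oracle: best modularity over all 2^(n-1) bipartitions (plus the trivial
  # one-module partition)
  modularity_of <- function(memb) {
    m2 <- sum(w)                      # 2m for weighted graphs
    k <- rowSums(w)
    q <- 0
    for (i in 1:n) for (j in 1:n)
      if (memb[i] == memb[j]) q <- q + w[i, j] - k[i] * k[j] / m2
    q / m2
  }
  best <- -Inf; best_memb <- NULL
  for (code in 0:(2^(n - 1) - 1)) {
    memb <- c(1L, as.integer(intToBits(code))[1:(n - 1)] + 1L)
    q <- modularity_of(memb)
    if (q > best) { best <- q; best_memb <- memb }
  }
  # the planted split is the modularity optimum, and Louvain finds it
  expect_equal(best_memb, truth, ignore_attr = TRUE)
  agree <- outer(part$region_module, part$region_module, "==")
  expect_identical(agree, outer(truth, truth, "=="), ignore_attr = TRUE)
})

test_that("participation coefficient follows its defining formula", {
  # provincial node: all edges within its own module -> PC 0
  w <- clique_pair()
  modules <- rep(1:2, each = 5)
  pc <- participation_coefficient(w, modules)
  expect_equal(pc, rep(0, 10))
  # even split across 2 modules -> 1 - 2 (1/2)^2 = 0.5
  w2 <- matrix(0, 3, 3)
  w2[1, 2] <- w2[2, 1] <- 1
  w2[1, 3] <- w2[3, 1] <- 1
  pc2 <- participation_coefficient(w2, c(1, 1, 2))
  expect_equal(pc2[1], 0.5)
  # isolated node -> PC 0 by convention
  w3 <- rbind(cbind(w2, 0), 0)
  expect_equal(participation_coefficient(w3, c(1, 1, 2, 2))[4], 0)
  # even spread over NM modules approaches 1 - 1/NM
  nm <- 4
  star <- matrix(0, nm + 1, nm + 1)
  star[1, 2:(nm + 1)] <- star[2:(nm + 1), 1] <- 2.5
  pcs <- participation_coefficient(star, c(1, seq_len(nm) + 1))
  expect_equal(pcs[1], 1 - 1 / nm)
})

test_that("weighted PC equals edge-count PC on binary graphs", {
  set.seed(5)
  w <- matrix(rbinom(400, 1, 0.3), 20, 20)
  w <- w * t(w); diag(w) <- 0
  modules <- sample(1:3, 20, TRUE)
  expect_equal(participation_coefficient(w, modules, weighted = TRUE),
               participation_coefficient(w, modules, weighted = FALSE))
  expect_equal(participation_coefficient(w, modules),
               oracle_pc(w, modules), tolerance = 1e-12)
})

test_that("eigenvector centrality matches a power-iteration oracle", {
  # ring of identical weights: all centralities equal by symmetry
  n <- 6
  ring <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    ring[i, j] <- ring[j, i] <- 1
  }
  ev <- eigenvector_centrality(ring)
  expect_equal(ev, rep(1 / sqrt(n), n))
  # star graph: centre strictly maximal
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  evs <- eigenvector_centrality(star)
  expect_true(all(evs[1] > evs[2:5]))
  # random weighted graph vs power iteration
  set.seed(6)
  w <- matrix(runif(144), 12, 12)
  w <- (w + t(w)) / 2; diag(w) <- 0
  expect_equal(eigenvector_centrality(w), oracle_power_iteration(w),
               tolerance = 1e-8)
  expect_equal(sum(eigenvector_centrality(w)^2), 1)
  # edgeless graph
  expect_message(z <- eigenvector_centrality(matrix(0, 3, 3)), "no edges")
  expect_equal(z, rep(0, 3))
})

test_that("hubness contrast subtracts phases voxel-wise", {
  dimv <- c(3, 3, 3)
  mask <- array(TRUE, dimv)
  a <- stat_map(array(runif(27), dimv), mask, "participation_coefficient")
  b <- stat_map(array(runif(27), dimv), mask, "participation_coefficient")
  d1 <- hubness_contrast(a, b)
  d2 <- hubness_contrast(b, a)
  expect_equal(d1$values, -d2$values)                       # antisymmetry
  expect_true(all(hubness_contrast(a, a)$values[mask] == 0))
  small <- stat_map(array(0, c(2, 2, 2)), array(TRUE, c(2, 2, 2)),
                    "participation_coefficient")
  expect_error(hubness_contrast(a, small), "different grids")
})

test_that("upsampling replicates coarse blocks onto the fine grid", {
  coarse <- stat_map(array(1:8 + 0, c(2, 2, 2)), array(TRUE, c(2, 2, 2)),
                     voxel_size_mm = 4)
  fine <- upsample_map(coarse, 2, c(4, 4, 3))
  expect_equal(dim(fine$values), c(4, 4, 3))
  for (i in 1:4) for (j in 1:4) for (k in 1:3)
    expect_equal(fine$values[i, j, k],
                 coarse$values[(i + 1) %/% 2, (j + 1) %/% 2, (k + 1) %/% 2])
})
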