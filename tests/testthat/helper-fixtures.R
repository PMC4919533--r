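# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures are stored.

# small planted-effect dataset used by several unit tests
tiny_dataset <- function(seed = 1L, n_subjects = 2L, grid = 10L,
                         conjunctive = 1.5, perceptual = 1, hub = 1.5,
                         coupling = 1, noise = 1) {
  generate_dataset(synth_config(
    grid_shape = rep(grid, 3L), n_regions = 4L, n_modules = 2L,
    n_subjects = n_subjects, conjunctive_effect = conjunctive,
    perceptual_effect = perceptual, hub_effect = hub,
    module_coupling = coupling, noise_sd = noise, seed = seed))
}

# hand-built toy retrieval design: two face-house associations, both orders,
# one instance each
toy_labels <- function() {
  data.frame(
    index = 1:4,
    association_id = c(1L, 1L, 2L, 2L),
    cue_category = c("face", "house", "face", "house"),
    associate_category = c("house", "face", "house", "face"),
    order_index = c(0L, 1L, 0L, 1L),
    phase = "retrieval",
    instance_index = 1L,
    run_id = 1L,
    stringsAsFactors = FALSE
  )
}

# independent double-loop participation coefficient
oracle_pc <- function(w, modules) {
  n <- nrow(w)
  pc <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ])
    if (k == 0) next
    acc <- 0
    for (m in unique(modules)) {
      e_im <- sum(w[i, modules == m])
      acc <- acc + (e_im / k)^2
    }
    pc[i] <- 1 - acc
  }
  pc
}

# independent Benjamini-Hochberg step-up rule: returns logical keep vector
oracle_bh <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= (seq_len(m) / m) * alpha)
  keep <- logical(m)
  if (length(below)) keep[o[seq_len(max(below))]] <- TRUE
  keep
}

# independent power-iteration leading eigenvector (nonnegative orientation)
oracle_power_iteration <- function(w, tol = 1e-12, max_iter = 10000) {
  v <- rep(1, nrow(w)) / sqrt(nrow(w))
  lambda <- 0
  for (i in seq_len(max_iter)) {
    nv <- w %*% v
    nl <- sqrt(sum(nv^2))
    nv <- nv / nl
    if (max(abs(nv - v)) < tol) { v <- nv; break }
    v <- nv
  }
  v <- drop(v)
  if (sum(v) < 0) v <- -v
  v
}

# exhaustive sign-flip one-sample test: p at every column of X (n x v),
# one-sided greater, identity flip included in the count
oracle_signflip_exhaustive <- function(X) {
  n <- nrow(X)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  tstat <- function(x) {
    m <- mean(x)
    s <- stats::sd(x)
    if (s == 0) {
      if (m == 0) return(NA_real_)
      return(sign(m) * Inf)
    }
    m / (s / sqrt(n))
  }
  apply(X, 2L, function(col) {
    t_obs <- tstat(col)
    if (is.na(t_obs)) return(1)
    tn <- apply(signs, 1L, function(s) tstat(s * col))
    sum(tn >= t_obs, na.rm = TRUE) / nrow(signs)
  })
}

# rule enumerator for the associative contrast: cell types over all pairs
oracle_contrast_cells <- function(labels) {
  n <- nrow(labels)
  pos <- matrix(FALSE, n, n)
  neg <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    same_assoc <- labels$association_id[i] == labels$association_id[j]
    if (same_assoc && labels$order_index[i] != labels$order_index[j])
      pos[i, j] <- TRUE
    if (!same_assoc &&
        labels$cue_category[i] == labels$cue_category[j] &&
        labels$associate_category[i] == labels$associate_category[j])
      neg[i, j] <- TRUE
  }
  list(pos = pos, neg = neg)
}
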