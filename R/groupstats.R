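# Nonparametric group inference: voxel-wise one-sample t with a sign-flip
# permutation null, map binarization, and the post-hoc similarity breakdown.

# subject maps -> n_subjects x n_voxels matrix restricted to the common mask
.stack_maps <- function(maps) {
  mask <- Reduce(`&`, lapply(maps, function(m) m$mask))
  X <- do.call(rbind, lapply(maps, function(m) m$values[mask]))
  list(X = X, mask = mask, dim = dim(maps[[1L]]$values),
       voxel_size_mm = maps[[1L]]$voxel_size_mm)
}

# one-sample t statistics for sign-flipped data, vectorized over voxels.
# signs: n_perm x n; X: n x v. Uses sum(x^2) invariance under sign flips.
.flip_t <- function(signs, X) {
  n <- ncol(signs)
  ss <- colSums(X^2)
  M <- (signs %*% X) / n
  V <- (rep(1, nrow(signs)) %o% ss - n * M^2) / (n - 1)
  V[V < 0] <- 0
  # V = 0 with nonzero mean gives +/-Inf (a legitimate extreme); 0/0 is
  # genuinely undefined and becomes NA
  Tm <- M / sqrt(V / n)
  Tm[is.nan(Tm)] <- NA_real_
  Tm
}

#' Sign-flip permutation test on subject maps
#'
#' Voxel-wise one-sample t statistic across subjects; the null distribution
#' is built by flipping each subject's sign at random (or exhaustively, when
#' \code{2^n_subjects <= n_perm}). The permutation p-value includes the
#' observed statistic: in Monte-Carlo mode
#' \code{p = (1 + #(null >= observed)) / (n_perm + 1)}; in exhaustive mode
#' \code{p = #(null >= observed) / 2^n} (the identity flip counts itself).
#' Voxels with zero variance across subjects have an undefined t; they are
#' flagged and assigned p = 1.
#'
#' @param maps list of subject-level \code{\link{stat_map}}s on one grid.
#' @param n_perm number of permutations (default 10000).
#' @param side \code{"greater"}, \code{"less"} or \code{"two.sided"}.
#' @param seed RNG seed for Monte-Carlo flips.
#' @return list of class \code{group_result}: \code{t} and \code{p}
#'   (\code{\link{stat_map}}s), \code{n_permutations} (actual null size),
#'   \code{exhaustive}, \code{degenerate_voxels} (count), \code{seed}.
#' @export
signflip_permutation_test <- function(maps, n_perm = 10000,
                                      side = c("greater", "less",
                                               "two.sided"),
                                      seed = 1L) {
  side <- match.arg(side)
  if (length(maps) < 3L) stop("need at least 3 subject maps")
  dims <- lapply(maps, function(m) dim(m$values))
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("subject maps are on different grids")
  st <- .stack_maps(maps)
  n <- nrow(st$X); v <- ncol(st$X)

  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    colnames(signs) <- NULL
  } else {
    signs <- .with_seed(seed,
      matrix(sample(c(1, -1), n_perm * n, replace = TRUE), n_perm, n))
  }

  score <- switch(side,
                  greater = identity,
                  less = function(t) -t,
                  two.sided = abs)
  t_obs <- drop(.flip_t(matrix(1, 1L, n), st$X))
  degenerate <- is.na(t_obs)
  s_obs <- score(t_obs)

  count <- numeric(v)
  chunk <- max(1L, floor(5e6 / max(v, 1L)))
  done <- 0L
  # comparison tolerance: the identity flip must count as >= the observed
  # statistic even under BLAS summation-order jitter
  thresh <- s_obs - 1e-9 * pmax(1, abs(s_obs))
  thresh[is.infinite(s_obs)] <- s_obs[is.infinite(s_obs)]
  while (done < nrow(signs)) {
    rows <- (done + 1L):min(done + chunk, nrow(signs))
    Tn <- score(.flip_t(signs[rows, , drop = FALSE], st$X))
    cmp <- Tn >= rep(thresh, each = length(rows))
    count <- count + colSums(cmp, na.rm = TRUE)
    done <- done + length(rows)
  }
  p <- if (exhaustive) count / nrow(signs) else (1 + count) / (n_perm + 1)
  p[degenerate] <- 1
  t_out <- t_obs
  t_out[degenerate] <- 0   # stored 0, flagged via degenerate_voxels; p = 1

  tvals <- array(NA_real_, dim = st$dim); tvals[st$mask] <- t_out
  pvals <- array(NA_real_, dim = st$dim); pvals[st$mask] <- p
  tmap <- stat_map(tvals, st$mask, metric = "group_t", level = "group",
                   p = pvals, voxel_size_mm = st$voxel_size_mm,
                   allow_infinite = TRUE)
  pmap <- stat_map(pvals, st$mask, metric = "group_p", level = "group",
                   voxel_size_mm = st$voxel_size_mm)
  structure(list(t = tmap, p = pmap, n_permutations = nrow(signs),
                 exhaustive = exhaustive, side = side,
                 degenerate_voxels = sum(degenerate), seed = seed),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat("<group_result> sign-flip test (", x$side, "), ",
      x$n_permutations, if (x$exhaustive) " exhaustive" else " Monte-Carlo",
      " flips, ", sum(x$p$values[x$p$mask] < 0.05), " of ",
      sum(x$p$mask), " voxels with p < 0.05\n", sep = "")
  invisible(x)
}

#' Binarize a group p map
#'
#' @param pmap a \code{\link{stat_map}} of p-values (or a \code{group_result},
#'   whose \code{$p} is used).
#' @param alpha threshold; voxels with \code{p < alpha} are TRUE.
#' @return 3-D logical array (FALSE outside the map's mask).
#' @export
binarize_map <- function(pmap, alpha = 0.05) {
  if (inherits(pmap, "group_result")) pmap <- pmap$p
  out <- pmap$values < alpha
  out[!pmap$mask] <- FALSE
  out[is.na(out)] <- FALSE
  out
}

#' Post-hoc similarity breakdown in a region of interest
#'
#' Computes the mean Spearman pattern similarity over the ROI voxels for the
#' four comparison types — same/different association crossed with
#' same/different cue-associate order — with no perception-penalty
#' exclusions, then demeans the four values within the subject.
#'
#' @param betas a \code{\link{beta_image_set}}.
#' @param roi 3-D logical ROI mask (>= 3 voxels).
#' @return named numeric vector of length 4
#'   (\code{same_assoc_same_order}, \code{same_assoc_diff_order},
#'   \code{diff_assoc_same_order}, \code{diff_assoc_diff_order}); the values
#'   sum to 0.
#' @export
posthoc_breakdown <- function(betas, roi) {
  if (sum(roi) < 3L) stop("ROI must contain at least 3 voxels")
  ret <- which(betas$labels$phase == "retrieval")
  lab <- betas$labels[ret, ]
  d <- dim(betas$data)
  mat <- matrix(betas$data, prod(d[1:3]), d[4L])[which(roi), ret,
                                                 drop = FALSE]
  s <- .spearman_sim(mat)
  ut <- upper.tri(s)
  same_assoc <- outer(lab$association_id, lab$association_id, "==")
  same_order <- outer(lab$order_index, lab$order_index, "==")
  groups <- list(
    same_assoc_same_order = same_assoc & same_order,
    same_assoc_diff_order = same_assoc & !same_order,
    diff_assoc_same_order = !same_assoc & same_order,
    diff_assoc_diff_order = !same_assoc & !same_order
  )
  vals <- vapply(groups, function(g) mean(s[g & ut], na.rm = TRUE),
                 numeric(1))
  vals - mean(vals)
}
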