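# Spatial coincidence of the two convergence metrics: Dice and relative
# overlap within a target ROI, a region-label resampling null, and the
# voxel-wise metric correlation.

#' Dice coefficient of two binary masks
#'
#' \code{2 |H & C| / (|H| + |C|)}; defined as 0 when both masks are empty.
#'
#' @param H,C logical vectors (or arrays) of equal length.
#' @return a real in [0, 1].
#' @export
dice_coefficient <- function(H, C) {
  H <- as.logical(H); C <- as.logical(C)
  if (length(H) != length(C)) stop("H and C must have equal lengths")
  denom <- sum(H) + sum(C)
  if (denom == 0) return(0)
  2 * sum(H & C) / denom
}

#' Relative overlap of two binary masks
#'
#' \code{|H & C| / n}: the proportion of the ROI's n voxels carrying both
#' effects.
#'
#' @param H,C logical vectors of equal length.
#' @param n total ROI voxel count (defaults to \code{length(H)}).
#' @return a real in [0, 1].
#' @export
relative_overlap <- function(H, C, n = length(H)) {
  H <- as.logical(H); C <- as.logical(C)
  if (length(H) != length(C)) stop("H and C must have equal lengths")
  if (n == 0) stop("n must be positive")
  sum(H & C) / n
}

#' Region-resampling test of conjunctiveness/hubness overlap
#'
#' Computes the observed Dice and relative-overlap statistics between the
#' binarized conjunctiveness and hubness masks over the union of the target
#' atlas regions, then compares them with a null distribution obtained by
#' recomputing both statistics on the union of \code{n_draw} regions drawn
#' uniformly without replacement in each permutation. The p-value uses the
#' add-one estimator \code{(1 + #(null >= observed)) / (n_perm + 1)}; ties
#' count against the hypothesis. By default target regions may be redrawn in
#' the null.
#'
#' @param conj_mask,hub_mask 3-D logical masks (group-level binarized maps).
#' @param atlas 3-D integer label array on the same grid.
#' @param target_region_ids integer vector of region codes forming the ROI.
#' @param n_perm number of permutations.
#' @param n_draw regions drawn per permutation.
#' @param seed RNG seed.
#' @param exclude_targets if TRUE, null draws avoid the target regions.
#' @return list of class \code{overlap_result}: \code{dice},
#'   \code{relative_overlap}, \code{null_dice}, \code{null_relative},
#'   \code{p_dice}, \code{p_relative}, \code{n_permutations},
#'   \code{n_regions_drawn}, \code{seed}.
#' @export
spatial_resampling_test <- function(conj_mask, hub_mask, atlas,
                                    target_region_ids, n_perm = 10000,
                                    n_draw = 2L, seed = 1L,
                                    exclude_targets = FALSE) {
  if (!identical(dim(conj_mask), dim(atlas)) ||
      !identical(dim(hub_mask), dim(atlas)))
    stop("masks and atlas are on different grids")
  ids <- sort(unique(as.vector(atlas)))
  ids <- ids[ids != 0L]
  if (!all(target_region_ids %in% ids))
    stop("target region(s) absent from the atlas: ",
         paste(setdiff(target_region_ids, ids), collapse = ", "))
  pool <- if (exclude_targets) setdiff(ids, target_region_ids) else ids
  if (length(pool) <= n_draw)
    stop("atlas must contain more than n_draw (", n_draw, ") regions")

  avec <- as.vector(atlas)
  Hv <- as.vector(hub_mask); Cv <- as.vector(conj_mask)
  stat_pair <- function(region_set) {
    roi <- avec %in% region_set
    h <- Hv[roi]; c_ <- Cv[roi]
    c(dice = dice_coefficient(h, c_),
      rel = relative_overlap(h, c_, n = sum(roi)))
  }
  obs <- stat_pair(target_region_ids)
  null_mat <- .with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) stat_pair(sample(pool, n_draw, replace = FALSE)),
           numeric(2))
  })
  p_dice <- (1 + sum(null_mat["dice", ] >= obs["dice"])) / (n_perm + 1)
  p_rel <- (1 + sum(null_mat["rel", ] >= obs["rel"])) / (n_perm + 1)
  structure(list(dice = unname(obs["dice"]),
                 relative_overlap = unname(obs["rel"]),
                 null_dice = unname(null_mat["dice", ]),
                 null_relative = unname(null_mat["rel", ]),
                 p_dice = p_dice, p_relative = p_rel,
                 n_permutations = n_perm, n_regions_drawn = n_draw,
                 target_region_ids = target_region_ids, seed = seed),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result> target region(s) ",
      paste(x$target_region_ids, collapse = ","),
      ": Dice = ", signif(x$dice, 3), " (p = ", signif(x$p_dice, 3),
      "), relative overlap = ", signif(x$relative_overlap, 3),
      " (p = ", signif(x$p_relative, 3), "), ",
      x$n_permutations, " permutations of ", x$n_regions_drawn,
      " regions\n", sep = "")
  invisible(x)
}

#' Across-voxel correlation between conjunctiveness and hubness maps
#'
#' For each subject, Spearman's rho across ROI voxels between the two maps;
#' at the group level, a two-tailed Wilcoxon signed-rank test of the rho
#' values against zero. Subjects whose map is constant within the ROI have
#' an undefined rho and are excluded with a warning.
#'
#' @param conj_maps,hub_maps lists of subject-level \code{\link{stat_map}}s
#'   (parallel, same grid).
#' @param roi 3-D logical ROI mask (>= 5 voxels).
#' @return list of class \code{metric_correlation}: \code{rho} (per-subject,
#'   NA where undefined), \code{statistic} (signed-rank V), \code{p}
#'   (two-tailed), \code{n_used}.
#' @export
metric_correlation <- function(conj_maps, hub_maps, roi) {
  if (length(conj_maps) != length(hub_maps))
    stop("need one hubness map per conjunctiveness map")
  if (sum(roi) < 5L) stop("ROI must contain at least 5 voxels")
  rho <- rep(NA_real_, length(conj_maps))
  for (s in seq_along(conj_maps)) {
    use <- roi & conj_maps[[s]]$mask & hub_maps[[s]]$mask
    a <- conj_maps[[s]]$values[use]
    b <- hub_maps[[s]]$values[use]
    if (length(a) < 5L) next
    if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
      warning("subject ", s, ": constant map within ROI; rho undefined")
      next
    }
    rho[s] <- stats::cor(a, b, method = "spearman")
  }
  used <- rho[!is.na(rho)]
  if (length(used) < 2L)
    stop("fewer than 2 subjects with a defined correlation")
  # the exact null is unavailable under ties or zeros; fall back silently
  exact_ok <- length(used) < 50 && !any(used == 0) &&
    !any(duplicated(abs(used)))
  wt <- stats::wilcox.test(used, mu = 0, alternative = "two.sided",
                           exact = exact_ok, correct = !exact_ok)
  structure(list(rho = rho, statistic = unname(wt$statistic),
                 p = wt$p.value, n_used = length(used)),
            class = "metric_correlation")
}

#' @export
print.metric_correlation <- function(x, ...) {
  cat("<metric_correlation> median rho = ",
      signif(stats::median(x$rho, na.rm = TRUE), 3), " over ", x$n_used,
      " subjects; Wilcoxon V = ", x$statistic, ", two-tailed p = ",
      signif(x$p, 3), "\n", sep = "")
  invisible(x)
}
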