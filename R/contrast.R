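# Balanced associative-similarity contrast with perception-penalty
# exclusions.
#
# Cell inclusion rule over unordered pairs of retrieval condition instances:
#   * POSITIVE  — same association AND different cue-associate order
#                 (perceptually dissimilar comparisons of one memory);
#   * NEGATIVE  — different associations AND identical cue category AND
#                 identical associate category (perceptually matched
#                 comparisons of different memories);
#   * everything else, and the diagonal, is excluded.
# Positive cells get weight +1/n_pos, negative cells -1/n_neg, so the mean
# over included cells is exactly 0 and the contrast codes a pure
# associative-similarity difference.

#' Build the associative-similarity contrast matrix
#'
#' @param labels retrieval-phase condition labels (data.frame as produced by
#'   \code{\link{make_design}}, subset to \code{phase == "retrieval"}).
#' @return list of class \code{contrast_matrix} with \code{weights} (n x n
#'   symmetric matrix, 0 on excluded cells), \code{include} (logical n x n,
#'   FALSE on the diagonal), and \code{labels}.
#' @export
build_contrast_matrix <- function(labels) {
  if (any(labels$phase != "retrieval"))
    stop("contrast labels must be retrieval-phase only")
  validate_labels(labels)
  n <- nrow(labels)
  if (length(unique(labels$association_id)) < 2L)
    stop("contrast undefined: need at least 2 associations")
  if (length(unique(labels$order_index)) < 2L)
    stop("contrast undefined: need both cue-associate orders")

  same_assoc <- outer(labels$association_id, labels$association_id, "==")
  diff_order <- outer(labels$order_index, labels$order_index, "!=")
  same_cue <- outer(labels$cue_category, labels$cue_category, "==")
  same_asc <- outer(labels$associate_category, labels$associate_category, "==")

  pos <- same_assoc & diff_order
  neg <- !same_assoc & same_cue & same_asc
  diag(pos) <- FALSE
  diag(neg) <- FALSE
  include <- pos | neg

  # counts over unordered pairs (upper triangle)
  ut <- upper.tri(include)
  n_pos <- sum(pos & ut)
  n_neg <- sum(neg & ut)
  if (n_pos == 0L || n_neg == 0L)
    stop("contrast undefined: no included positive or negative cells")

  weights <- matrix(0, n, n)
  weights[pos] <- 1 / n_pos
  weights[neg] <- -1 / n_neg
  structure(list(weights = weights, include = include, labels = labels),
            class = "contrast_matrix")
}

#' @export
print.contrast_matrix <- function(x, ...) {
  ut <- upper.tri(x$include)
  cat("<contrast_matrix> ", nrow(x$weights), "x", ncol(x$weights),
      " conditions, ", sum(x$include & ut & x$weights > 0),
      " positive / ", sum(x$include & ut & x$weights < 0),
      " negative included pairs, included-cell mean ",
      format(mean(x$weights[x$include]), digits = 3), "\n", sep = "")
  invisible(x)
}
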