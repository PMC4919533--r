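# Condition labels and the beta-image-set container.

.cz_categories <- c("face", "house", "body")
.cz_phases <- c("retrieval", "iti")

#' Build the paired-associate retrieval design
#'
#' Enumerates one condition label per (association, cue-associate order,
#' instance, run) cell, for the retrieval phase and its complementary
#' inter-trial-interval (ITI) phase. Associations are paired stimuli drawn
#' from the face/house/body categories; the three unordered category pairs
#' (face-house, face-body, house-body) are assigned in equal thirds, so the
#' full 12-association design has four pairs of each type. With the default
#' 12 associations, 2 instances per condition and 2 runs this yields the
#' canonical 96 retrieval + 96 ITI conditions.
#'
#' @param n_associations number of paired associations; must be divisible by
#'   3 so the three category-pair types occur equally often.
#' @param instances_per_condition repeated beta estimates per condition cell
#'   within a run.
#' @param runs number of scanning runs.
#' @return a data.frame of condition labels with columns \code{index},
#'   \code{association_id}, \code{cue_category}, \code{associate_category},
#'   \code{order_index} (0 or 1), \code{phase}, \code{instance_index},
#'   \code{run_id}. Retrieval rows come first, then ITI rows.
#' @export
make_design <- function(n_associations = 12L, instances_per_condition = 2L,
                        runs = 2L) {
  n_associations <- as.integer(n_associations)
  instances_per_condition <- as.integer(instances_per_condition)
  runs <- as.integer(runs)
  if (any(c(n_associations, instances_per_condition, runs) < 1L))
    stop("all design arguments must be >= 1")
  if (n_associations %% 3L != 0L)
    stop("n_associations must be divisible by 3: the face-house, face-body ",
         "and house-body pair types must occur in equal counts")

  pair_types <- list(c("face", "house"), c("face", "body"), c("house", "body"))
  # association a gets pair type ((a-1) %% 3) + 1 -> equal thirds
  type_of <- ((seq_len(n_associations) - 1L) %% 3L) + 1L

  grid <- expand.grid(
    instance_index = seq_len(instances_per_condition),
    run_id = seq_len(runs),
    order_index = 0:1,
    association_id = seq_len(n_associations),
    KEEP.OUT.ATTRS = FALSE
  )
  pt <- pair_types
  cue <- character(nrow(grid)); assoc <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pair <- pt[[type_of[grid$association_id[i]]]]
    if (grid$order_index[i] == 0L) {
      cue[i] <- pair[1L]; assoc[i] <- pair[2L]
    } else {
      cue[i] <- pair[2L]; assoc[i] <- pair[1L]
    }
  }
  one_phase <- data.frame(
    association_id = grid$association_id,
    cue_category = cue,
    associate_category = assoc,
    order_index = grid$order_index,
    instance_index = grid$instance_index,
    run_id = grid$run_id,
    stringsAsFactors = FALSE
  )
  labels <- rbind(
    cbind(one_phase, phase = "retrieval", stringsAsFactors = FALSE),
    cbind(one_phase, phase = "iti", stringsAsFactors = FALSE)
  )
  labels <- data.frame(index = seq_len(nrow(labels)), labels,
                       stringsAsFactors = FALSE)
  labels <- labels[, c("index", "association_id", "cue_category",
                       "associate_category", "order_index", "phase",
                       "instance_index", "run_id")]
  rownames(labels) <- NULL
  validate_labels(labels)
  labels
}

#' Validate a condition-label table
#'
#' Enforces the label invariants: known categories and phases, cue and
#' associate categories differ, order 1 swaps the categories of order 0 for
#' the same association, and each association keeps one unordered category
#' pair throughout.
#'
#' @param labels data.frame as returned by \code{\link{make_design}}.
#' @return \code{labels}, invisibly, or an error.
#' @export
validate_labels <- function(labels) {
  req <- c("index", "association_id", "cue_category", "associate_category",
           "order_index", "phase", "instance_index", "run_id")
  miss <- setdiff(req, names(labels))
  if (length(miss)) stop("label table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!all(labels$cue_category %in% .cz_categories))
    stop("unknown cue_category value(s): ",
         paste(unique(setdiff(labels$cue_category, .cz_categories)),
               collapse = ", "))
  if (!all(labels$associate_category %in% .cz_categories))
    stop("unknown associate_category value(s)")
  if (!all(labels$phase %in% .cz_phases))
    stop("phase must be one of: ", paste(.cz_phases, collapse = ", "))
  if (!all(labels$order_index %in% 0:1)) stop("order_index must be 0 or 1")
  if (any(labels$cue_category == labels$associate_category))
    stop("cue_category and associate_category must differ within a label")
  for (a in unique(labels$association_id)) {
    sub <- labels[labels$association_id == a, ]
    pairs <- unique(t(apply(cbind(sub$cue_category, sub$associate_category),
                            1L, sort)))
    if (nrow(pairs) != 1L)
      stop("association ", a, " uses more than one unordered category pair")
    o0 <- sub[sub$order_index == 0L, ]
    o1 <- sub[sub$order_index == 1L, ]
    if (nrow(o0) && nrow(o1)) {
      if (!all(o0$cue_category[1L] == o1$associate_category) ||
          !all(o0$associate_category[1L] == o1$cue_category))
        stop("association ", a,
             ": order 1 must swap the cue/associate categories of order 0")
    }
  }
  invisible(labels)
}

#' Construct a beta-image set
#'
#' Bundles a 4-D stack of beta volumes (one 3-D volume per condition
#' instance) with its condition labels, grey-matter mask and voxel size.
#'
#' @param data 4-D numeric array (x, y, z, condition instance).
#' @param labels condition-label data.frame, one row per 4th-dim index.
#' @param mask 3-D logical grey-matter mask matching \code{dim(data)[1:3]}.
#' @param voxel_size_mm positive voxel edge length in mm.
#' @return an object of class \code{beta_image_set}.
#' @export
beta_image_set <- function(data, labels, mask, voxel_size_mm = 2) {
  if (length(dim(data)) != 4L) stop("`data` must be a 4-D array")
  validate_labels(labels)
  if (nrow(labels) != dim(data)[4L])
    stop("label count (", nrow(labels), ") does not match 4th-dimension ",
         "extent (", dim(data)[4L], ")")
  if (!identical(dim(mask), dim(data)[1:3]))
    stop("mask dimensions do not match the beta grid")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")
  n_ret <- sum(labels$phase == "retrieval")
  n_iti <- sum(labels$phase == "iti")
  if (n_iti > 0L && n_ret != n_iti)
    stop("retrieval and ITI phases must have equal instance counts (",
         n_ret, " vs ", n_iti, ")")
  structure(list(data = data, labels = labels, mask = mask,
                 voxel_size_mm = voxel_size_mm),
            class = "beta_image_set")
}

#' @export
print.beta_image_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<beta_image_set> grid ", paste(d[1:3], collapse = "x"),
      ", ", d[4L], " volumes (",
      sum(x$labels$phase == "retrieval"), " retrieval / ",
      sum(x$labels$phase == "iti"), " ITI), ",
      sum(x$mask), " in-mask voxels, ",
      x$voxel_size_mm, " mm voxels\n", sep = "")
  invisible(x)
}

#' Construct a voxel-wise statistic map
#'
#' A \code{stat_map} holds one scalar per voxel (conjunctiveness slope,
#' participation coefficient, t statistic, ...) plus the mask of voxels on
#' which it is defined; values outside the mask are \code{NA}.
#'
#' @param values 3-D numeric array.
#' @param mask 3-D logical array; where the map is defined.
#' @param metric short metric name, e.g. \code{"conjunctiveness"}.
#' @param level \code{"subject"} or \code{"group"}.
#' @param p optional 3-D array of p-values in (0, 1], defined on \code{mask}.
#' @param voxel_size_mm voxel edge length.
#' @param allow_infinite permit infinite values inside the mask (used for
#'   degenerate t statistics with zero variance but nonzero mean).
#' @return an object of class \code{stat_map}.
#' @export
stat_map <- function(values, mask, metric = "statistic",
                     level = c("subject", "group"), p = NULL,
                     voxel_size_mm = 2, allow_infinite = FALSE) {
  level <- match.arg(level)
  if (!identical(dim(values), dim(mask)))
    stop("values and mask dimensions differ")
  mask <- array(as.logical(mask), dim = dim(mask))
  bad <- if (allow_infinite) is.na(values[mask]) else
    !is.finite(values[mask])
  if (any(bad))
    stop("stat_map values must be finite inside the mask")
  values[!mask] <- NA_real_
  if (!is.null(p)) {
    if (!identical(dim(p), dim(mask))) stop("p map dimensions differ")
    pin <- p[mask]
    if (any(!is.na(pin) & (pin <= 0 | pin > 1)))
      stop("p-values must lie in (0, 1]")
    p[!mask] <- NA_real_
  }
  structure(list(values = values, mask = mask, metric = metric,
                 level = level, p = p, voxel_size_mm = voxel_size_mm),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat("<stat_map> ", x$metric, " (", x$level, " level), grid ",
      paste(dim(x$values), collapse = "x"), ", ", sum(x$mask),
      " voxels, range [", signif(min(v), 4), ", ", signif(max(v), 4), "]",
      if (!is.null(x$p)) " with p-values", "\n", sep = "")
  invisible(x)
}
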