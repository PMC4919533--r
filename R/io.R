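# On-disk formats: NIfTI beta stacks with tab-separated label sidecars.

#' Write a condition-label table
#'
#' Tab-separated, fixed header, one row per 4th-dimension volume. The format
#' is diff-able and round-trips through \code{\link{read_labels}}.
#'
#' @param labels label data.frame.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_labels <- function(labels, path) {
  cols <- c("index", "association_id", "cue_category", "associate_category",
            "order_index", "phase", "instance_index", "run_id")
  utils::write.table(labels[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a condition-label table
#'
#' @param path TSV path written by \code{\link{write_labels}}.
#' @return validated label data.frame.
#' @export
read_labels <- function(path) {
  labels <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_labels(labels)
  labels
}

#' Read a beta-image set from NIfTI + label table
#'
#' @param nifti_path 4-D NIfTI beta stack.
#' @param labels_path sidecar TSV of condition labels.
#' @param mask optional 3-D logical mask or path to a mask NIfTI; default all
#'   voxels.
#' @return a validated \code{\link{beta_image_set}}.
#' @export
read_beta_set <- function(nifti_path, labels_path, mask = NULL) {
  nii <- read_nifti(nifti_path)
  if (length(dim(nii$data)) != 4L)
    stop("expected a 4-D beta stack in ", nifti_path)
  labels <- read_labels(labels_path)
  if (nrow(labels) != dim(nii$data)[4L])
    stop("label table has ", nrow(labels), " rows but the volume has ",
         dim(nii$data)[4L], " frames")
  if (is.null(mask)) {
    mask <- array(TRUE, dim = dim(nii$data)[1:3])
  } else if (is.character(mask)) {
    mask <- read_nifti(mask)$data > 0
  }
  beta_image_set(nii$data, labels, mask,
                 voxel_size_mm = nii$voxel_size_mm[1L])
}

#' Write a stat map as NIfTI
#'
#' Values outside the map's mask are written as 0; the mask itself can be
#' recovered from a companion call with \code{what = "mask"}.
#'
#' @param map a \code{\link{stat_map}}.
#' @param path output NIfTI path.
#' @param what \code{"values"}, \code{"p"} or \code{"mask"}.
#' @return \code{path}, invisibly.
#' @export
write_stat_map <- function(map, path, what = c("values", "p", "mask")) {
  what <- match.arg(what)
  out <- switch(what,
                values = {
                  v <- map$values; v[!map$mask] <- 0; v
                },
                p = {
                  if (is.null(map$p)) stop("stat map carries no p-values")
                  v <- map$p; v[!map$mask] <- 0; v
                },
                mask = map$mask + 0)
  write_nifti(out, path, voxel_size_mm = map$voxel_size_mm,
              datatype = if (what == "mask") "uint8" else "double")
  invisible(path)
}
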