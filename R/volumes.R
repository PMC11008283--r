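#' Create a labelled segmentation volume
#'
#' A \code{LabelVolume} is a 3D integer array on an isotropic voxel grid
#' together with a dictionary mapping compartment names to integer codes.
#' It plays the role of an anatomical segmentation: every voxel carries
#' exactly one label, and the dictionary must name at least a background,
#' CSF, white matter, a cerebellar reference region, and two or more
#' cortical ROIs.
#'
#' @param labels 3D integer array of label codes.
#' @param voxel_size_mm positive scalar, isotropic voxel edge length in mm.
#' @param label_map named integer vector or list, name -> code. Must contain
#'   entries named \code{background}, \code{csf}, \code{white_matter} and
#'   \code{cerebellum_reference}.
#' @param check logical; validate invariants (default TRUE).
#' @return object of class \code{LabelVolume}.
#' @export
label_volume <- function(labels, voxel_size_mm, label_map, check = TRUE) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  label_map <- unlist(label_map)
  storage.mode(label_map) <- "integer"
  if (is.null(names(label_map)) || any(names(label_map) == ""))
    stop("label_map must be fully named")
  obj <- structure(list(
    labels = labels,
    voxel_size_mm = as.numeric(voxel_size_mm),
    label_map = label_map
  ), class = "LabelVolume")
  if (check) validate_label_volume(obj)
  obj
}

validate_label_volume <- function(lv) {
  stopifnot(inherits(lv, "LabelVolume"))
  if (!is.finite(lv$voxel_size_mm) || lv$voxel_size_mm <= 0)
    stop("voxel_size_mm must be a positive scalar")
  required <- c("background", "csf", "white_matter", "cerebellum_reference")
  missing <- setdiff(required, names(lv$label_map))
  if (length(missing))
    stop("label_map is missing required compartments: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(lv$label_map))
    stop("label_map codes must be unique")
  codes <- sort(unique(as.vector(lv$labels)))
  unknown <- setdiff(codes, lv$label_map)
  if (length(unknown))
    stop("label array contains codes absent from label_map: ",
         paste(unknown, collapse = ", "))
  if (!any(lv$labels == lv$label_map[["cerebellum_reference"]]))
    stop("cerebellum_reference region is empty")
  invisible(lv)
}

#' Create an activity (tracer) volume
#'
#' An \code{ActivityVolume} holds a nonnegative 3D image (arbitrary activity
#' units) on the same isotropic grid as a paired \code{LabelVolume}.
#'
#' @param values 3D numeric array, finite and nonnegative.
#' @param voxel_size_mm positive scalar, mm.
#' @return object of class \code{ActivityVolume}.
#' @export
activity_volume <- function(values, voxel_size_mm) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("activity values must be finite")
  if (any(values < 0)) stop("activity values must be nonnegative")
  if (!is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("voxel_size_mm must be a positive scalar")
  structure(list(values = values, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "ActivityVolume")
}

#' Isotropic Gaussian point-spread-function model
#'
#' The scanner plus reconstruction blur is modelled as a single isotropic
#' Gaussian parameterized by its full width at half maximum. The single-site
#' natural-history setting corresponds to about 5 mm, the multisite
#' harmonized setting to a target resolution of 8 mm. \code{fwhm_mm = 0}
#' denotes a delta PSF (no blurring).
#'
#' @param fwhm_mm nonnegative scalar, full width at half maximum in mm.
#' @return object of class \code{PSFModel}.
#' @export
psf_model <- function(fwhm_mm) {
  if (!is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("fwhm_mm must be a nonnegative scalar")
  structure(list(fwhm_mm = as.numeric(fwhm_mm),
                 sigma_mm = as.numeric(fwhm_mm) / (2 * sqrt(2 * log(2)))),
            class = "PSFModel")
}

#' @export
print.LabelVolume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("LabelVolume %dx%dx%d @ %.3g mm, %d labels\n",
              d[1], d[2], d[3], x$voxel_size_mm, length(x$label_map)))
  invisible(x)
}

#' @export
print.ActivityVolume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("ActivityVolume %dx%dx%d @ %.3g mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size_mm,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Per-label voxel counts
#'
#' @param lv LabelVolume.
#' @return named integer vector of voxel counts, one entry per label_map name
#'   (zero for labels absent from the array).
#' @export
label_counts <- function(lv) {
  stopifnot(inherits(lv, "LabelVolume"))
  tab <- tabulate(match(as.vector(lv$labels), lv$label_map),
                  nbins = length(lv$label_map))
  names(tab) <- names(lv$label_map)
  tab
}

#' Binary mask of one or more labels
#'
#' @param lv LabelVolume.
#' @param names character vector of label names.
#' @return logical 3D array.
#' @export
label_mask <- function(lv, names) {
  stopifnot(inherits(lv, "LabelVolume"))
  unknown <- setdiff(names, names(lv$label_map))
  if (length(unknown))
    stop("unknown label name(s): ", paste(unknown, collapse = ", "))
  array(as.vector(lv$labels) %in% lv$label_map[names], dim = dim(lv$labels))
}

#' Merge labels into a coarser segmentation
#'
#' Reassigns every voxel of the source labels to a single target label,
#' mimicking a segmentation that cannot distinguish sub-compartments (for
#' example ventricular vs. sulcal CSF). The merged names are dropped from
#' the dictionary.
#'
#' @param lv LabelVolume.
#' @param from character vector of label names to absorb.
#' @param into single label name that absorbs them (must exist).
#' @return new LabelVolume.
#' @export
merge_labels <- function(lv, from, into) {
  stopifnot(inherits(lv, "LabelVolume"), length(into) == 1L)
  unknown <- setdiff(c(from, into), names(lv$label_map))
  if (length(unknown))
    stop("unknown label name(s): ", paste(unknown, collapse = ", "))
  from <- setdiff(from, into)
  labs <- lv$labels
  labs[as.vector(labs) %in% lv$label_map[from]] <- lv$label_map[[into]]
  label_volume(labs, lv$voxel_size_mm,
               lv$label_map[setdiff(names(lv$label_map), from)])
}

check_same_grid <- function(a, b) {
  da <- dim(if (!is.null(a$values)) a$values else a$labels)
  db <- dim(if (!is.null(b$values)) b$values else b$labels)
  if (!identical(da, db))
    stop("volume grids do not match: ", paste(da, collapse = "x"),
         " vs ", paste(db, collapse = "x"))
  va <- a$voxel_size_mm; vb <- b$voxel_size_mm
  if (abs(va - vb) > 1e-9)
    stop("voxel sizes do not match: ", va, " vs ", vb)
  invisible(TRUE)
}
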