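# Partial-volume-correction methods.
#
# All methods operate on an ActivityVolume and (except van Cittert) a
# segmentation on the same grid. Each returns a PvcResult: the corrected
# image (where defined), per-label regional values, and method diagnostics.
# The geometric transfer matrix route returns regional values only.

pvc_result <- function(method, regional_values, corrected_image = NULL,
                       diagnostics = list(), valid_mask = NULL) {
  if (!all(is.finite(unlist(regional_values))))
    stop("non-finite regional value produced by method ", method)
  structure(list(method = method,
                 regional_values = regional_values,
                 corrected_image = corrected_image,
                 valid_mask = valid_mask,
                 diagnostics = diagnostics),
            class = "PvcResult")
}

#' @export
print.PvcResult <- function(x, ...) {
  cat("PvcResult [", x$method, "]\n", sep = "")
  print(round(unlist(x$regional_values), 4))
  invisible(x)
}

# per-label means over valid voxels
regional_means <- function(values, labels_vec, label_map, valid = NULL) {
  keep <- if (is.null(valid)) rep(TRUE, length(values)) else valid
  sums <- rowsum(values[keep], labels_vec[keep])
  cnts <- rowsum(rep(1, sum(keep)), labels_vec[keep])
  m <- stats::setNames(rep(NA_real_, length(label_map)), names(label_map))
  got <- match(as.integer(rownames(sums)), label_map)
  m[got] <- sums[, 1] / cnts[, 1]
  m
}

#' Plain (uncorrected) regional means
#'
#' The \code{method = "none"} baseline: per-label means of the observed
#' image with no correction applied.
#'
#' @param pet ActivityVolume.
#' @param labels LabelVolume on the same grid.
#' @return PvcResult with \code{regional_values} = per-label means.
#' @export
pvc_none <- function(pet, labels) {
  check_same_grid(pet, labels)
  m <- regional_means(as.vector(pet$values), as.vector(labels$labels),
                      labels$label_map)
  pvc_result("none", as.list(m[!is.na(m)]), corrected_image = pet)
}

#' Meltzer 2-compartment partial volume correction
#'
#' Divides the PET image by the PSF-smoothed brain (GM+WM) mask, correcting
#' primarily for CSF dilution caused by differing levels of atrophy. Voxels
#' where the smoothed mask falls below \code{mask_threshold} are excluded
#' from the corrected image and from regional means.
#'
#' @param pet ActivityVolume.
#' @param brain_mask logical 3D array: union of gray and white matter.
#' @param psf PSFModel.
#' @param mask_threshold smoothed-mask validity cutoff (default 0.5).
#' @param labels optional LabelVolume for regional means of the corrected
#'   image.
#' @return PvcResult; diagnostics carry the excluded-voxel count.
#' @export
pvc_meltzer <- function(pet, brain_mask, psf, mask_threshold = 0.5,
                        labels = NULL) {
  stopifnot(inherits(pet, "ActivityVolume"))
  if (!any(brain_mask)) stop("brain mask is empty")
  if (!identical(dim(brain_mask), dim(pet$values)))
    stop("mask grid does not match image grid")
  smask <- psf_blur(brain_mask * 1, pet$voxel_size_mm, psf)
  valid <- smask >= mask_threshold
  corr <- array(0, dim = dim(pet$values))
  corr[valid] <- pet$values[valid] / smask[valid]
  out_img <- activity_volume(corr, pet$voxel_size_mm)
  reg <- list()
  if (!is.null(labels)) {
    check_same_grid(pet, labels)
    m <- regional_means(as.vector(corr), as.vector(labels$labels),
                        labels$label_map, valid = as.vector(valid))
    reg <- as.list(m[!is.na(m)])
  }
  pvc_result("meltzer2c", reg, out_img,
             diagnostics = list(excluded_voxels = sum(!valid),
                                mask_threshold = mask_threshold),
             valid_mask = valid)
}

#' Mueller-Gartner 3-compartment partial volume correction
#'
#' Estimates the white-matter activity as the mean of the uncorrected image
#' over an eroded white-matter mask, subtracts the PSF-spread white-matter
#' contribution, and divides by the PSF-smoothed gray-matter mask (CSF is
#' assumed to contribute zero signal). Corrected values are defined where
#' the smoothed GM mask reaches \code{gm_threshold}; negative corrected
#' voxels are floored at zero and counted.
#'
#' @param pet ActivityVolume.
#' @param gm_mask,wm_mask disjoint logical 3D arrays.
#' @param psf PSFModel.
#' @param wm_erosion_shells erosion depth for the WM estimate (default 2).
#' @param gm_threshold smoothed-GM validity cutoff (default 0.3).
#' @param labels optional LabelVolume for regional means over valid GM.
#' @return PvcResult; diagnostics carry \code{wm_estimate}, the excluded and
#'   floored voxel counts.
#' @export
pvc_muller_gartner <- function(pet, gm_mask, wm_mask, psf,
                               wm_erosion_shells = 2, gm_threshold = 0.3,
                               labels = NULL) {
  stopifnot(inherits(pet, "ActivityVolume"))
  if (!any(gm_mask)) stop("gray-matter mask is empty")
  if (any(gm_mask & wm_mask)) stop("gm_mask and wm_mask must be disjoint")
  wm_eroded <- erode_mask(wm_mask, wm_erosion_shells)
  wm_estimate <- mean(pet$values[wm_eroded])
  sgm <- psf_blur(gm_mask * 1, pet$voxel_size_mm, psf)
  swm <- psf_blur(wm_mask * 1, pet$voxel_size_mm, psf)
  valid <- sgm >= gm_threshold & gm_mask
  corr <- array(0, dim = dim(pet$values))
  num <- pet$values[valid] - wm_estimate * swm[valid]
  corr[valid] <- num / sgm[valid]
  floored <- sum(corr[valid] < 0)
  corr[corr < 0] <- 0
  out_img <- activity_volume(corr, pet$voxel_size_mm)
  reg <- list()
  if (!is.null(labels)) {
    check_same_grid(pet, labels)
    m <- regional_means(as.vector(corr), as.vector(labels$labels),
                        labels$label_map, valid = as.vector(valid))
    reg <- as.list(m[!is.na(m)])
  }
  pvc_result("mg3c", reg, out_img, valid_mask = valid,
             diagnostics = list(wm_estimate = wm_estimate,
                                excluded_gm_voxels = sum(gm_mask & !valid),
                                floored_voxels = floored,
                                gm_threshold = gm_threshold,
                                wm_erosion_shells = wm_erosion_shells))
}

#' Van Cittert iterative deconvolution
#'
#' Classical fixed-point sharpening
#' \code{f_{k+1} = f_k + alpha * (pet - psf x f_k)} starting from
#' \code{f_0 = pet}, with a nonnegativity clamp after each update; no
#' anatomical segmentation is required. Iteration stops after
#' \code{n_iterations} or when the relative change of the residual norm
#' falls below \code{tol}.
#'
#' @param pet ActivityVolume.
#' @param psf PSFModel.
#' @param alpha relaxation parameter in (0, 2]; 1.5 is the reference choice.
#' @param n_iterations maximum iterations (default 30).
#' @param tol relative residual-change stopping tolerance (default 1e-4).
#' @param labels optional LabelVolume for regional means.
#' @return PvcResult; diagnostics carry the residual norm per iteration.
#' @export
pvc_van_cittert <- function(pet, psf, alpha = 1.5, n_iterations = 30,
                            tol = 1e-4, labels = NULL) {
  stopifnot(inherits(pet, "ActivityVolume"))
  if (alpha <= 0 || alpha > 2) stop("alpha must be in (0, 2]")
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  g <- pet$values
  f <- g
  resid <- numeric(0)
  for (k in seq_len(n_iterations)) {
    r <- g - psf_blur(f, pet$voxel_size_mm, psf)
    if (!all(is.finite(r)))
      stop("non-finite intermediate at van Cittert iteration ", k)
    resid[k] <- sqrt(sum(r^2))
    f <- f + alpha * r
    f[f < 0] <- 0
    if (resid[k] == 0) break
    if (k > 1 && abs(resid[k] - resid[k - 1]) < tol * resid[k - 1]) break
  }
  out_img <- activity_volume(f, pet$voxel_size_mm)
  reg <- list()
  if (!is.null(labels)) {
    check_same_grid(pet, labels)
    m <- regional_means(as.vector(f), as.vector(labels$labels),
                        labels$label_map)
    reg <- as.list(m[!is.na(m)])
  }
  pvc_result(sprintf("vc(alpha=%g)", alpha), reg, out_img,
             diagnostics = list(alpha = alpha, iterations = length(resid),
                                residual_norms = resid))
}

#' Build the geometric transfer matrix
#'
#' For every pair of non-background regions i, j the entry W[i, j] is the
#' mean over region i of the PSF-blurred indicator of region j: the
#' fraction of region j's signal observed inside region i. All segmented
#' compartments (cortical ROIs, white matter, CSF, and skull/meninges when
#' present) enter the model, so extra-cortical spill is modelled rather
#' than assumed zero.
#'
#' @param labels LabelVolume.
#' @param psf PSFModel.
#' @param condition_cap error when the condition number of W exceeds this
#'   (default 1e6); ill-conditioning signals that regions should be merged.
#' @return object of class \code{GtmModel}: \code{region_names}, matrix
#'   \code{W}, \code{condition_number}, per-region voxel counts.
#' @export
build_gtm <- function(labels, psf, condition_cap = 1e6) {
  stopifnot(inherits(labels, "LabelVolume"))
  lm <- labels$label_map
  regions <- names(lm)[names(lm) != "background"]
  labvec <- as.vector(labels$labels)
  counts <- label_counts(labels)[regions]
  if (any(counts == 0))
    stop("empty region(s) in GTM: ",
         paste(regions[counts == 0], collapse = ", "))
  n <- length(regions)
  W <- matrix(0, n, n, dimnames = list(regions, regions))
  idx_list <- lapply(regions, function(r) which(labvec == lm[[r]]))
  for (j in seq_len(n)) {
    ind <- array(0, dim = dim(labels$labels))
    ind[idx_list[[j]]] <- 1
    sm <- as.vector(psf_blur(ind, labels$voxel_size_mm, psf))
    for (i in seq_len(n)) W[i, j] <- mean(sm[idx_list[[i]]])
  }
  cond <- kappa(W, exact = TRUE)
  if (cond > condition_cap)
    stop(sprintf(paste0("GTM is ill conditioned (condition number %.3g > ",
                        "cap %.3g); merge or drop small regions"),
                 cond, condition_cap))
  structure(list(region_names = regions, W = W, condition_number = cond,
                 region_counts = counts, fwhm_mm = psf$fwhm_mm),
            class = "GtmModel")
}

#' Geometric transfer matrix correction
#'
#' Solves \code{W a = m} (least squares) where m are the observed regional
#' means, recovering partial-volume-free regional activities. No corrected
#' image is produced; pair with \code{\link{pvc_rbv}} for a voxel map.
#'
#' @param pet ActivityVolume.
#' @param gtm GtmModel built on the matching LabelVolume.
#' @param labels the LabelVolume the model was built on.
#' @return PvcResult with regional estimates and the observed means and
#'   condition number in diagnostics.
#' @export
pvc_gtm <- function(pet, gtm, labels) {
  stopifnot(inherits(gtm, "GtmModel"))
  check_same_grid(pet, labels)
  obs <- regional_means(as.vector(pet$values), as.vector(labels$labels),
                        labels$label_map)[gtm$region_names]
  if (anyNA(obs))
    stop("observed mean unavailable for region(s): ",
         paste(gtm$region_names[is.na(obs)], collapse = ", "))
  est <- qr.solve(gtm$W, obs)
  names(est) <- gtm$region_names
  pvc_result("gtm", as.list(est),
             diagnostics = list(observed_means = obs,
                                condition_number = gtm$condition_number))
}

#' Region-based voxelwise correction (after GTM)
#'
#' Paints the GTM regional estimates into a synthetic piecewise-constant
#' image s and rescales the PET image voxelwise by s / (s x PSF), yielding
#' a corrected voxel map whose regional means follow the GTM estimates
#' while preserving within-region detail.
#'
#' @param pet ActivityVolume.
#' @param labels LabelVolume.
#' @param psf PSFModel.
#' @param gtm_values named regional values from \code{\link{pvc_gtm}}.
#' @param denom_threshold voxels where the blurred synthetic image falls
#'   below this fraction of its maximum are left uncorrected (default 0.01).
#' @param max_invalid_fraction error if more than this fraction of brain
#'   voxels is below threshold (default 0.5).
#' @return PvcResult with corrected image and regional means.
#' @export
pvc_rbv <- function(pet, labels, psf, gtm_values, denom_threshold = 0.01,
                    max_invalid_fraction = 0.5) {
  check_same_grid(pet, labels)
  lm <- labels$label_map
  gtm_values <- unlist(gtm_values)
  s_per_label <- stats::setNames(numeric(length(lm)), names(lm))
  s_per_label[names(gtm_values)] <- gtm_values
  idx <- match(as.vector(labels$labels), lm)
  s <- array(unname(s_per_label[names(lm)])[idx], dim = dim(labels$labels))
  sb <- psf_blur(s, pet$voxel_size_mm, psf)
  thr <- denom_threshold * max(abs(sb))
  valid <- abs(sb) > thr
  brain <- as.vector(labels$labels) != lm[["background"]]
  frac_bad <- sum(brain & !as.vector(valid)) / max(1, sum(brain))
  if (frac_bad > max_invalid_fraction)
    stop(sprintf("RBV denominator near zero on %.1f%% of brain voxels",
                 100 * frac_bad))
  corr <- pet$values
  corr[valid] <- pet$values[valid] * s[valid] / sb[valid]
  corr[corr < 0] <- 0
  out_img <- activity_volume(corr, pet$voxel_size_mm)
  m <- regional_means(as.vector(corr), as.vector(labels$labels), lm)
  pvc_result("rbv", as.list(m[!is.na(m)]), out_img,
             diagnostics = list(invalid_voxels = sum(!valid),
                                denom_threshold = denom_threshold))
}

#' Run one named PVC method with default settings
#'
#' Convenience dispatcher used by the pipeline and CLI: derives the masks a
#' method needs from the segmentation (gray matter = the phantom's cortical
#' labels plus cerebellar reference, white matter = \code{white_matter}) and
#' runs the chosen correction.
#'
#' @param method one of "none", "meltzer", "mg", "vc", "gtm", "rbv".
#' @param pet ActivityVolume.
#' @param labels LabelVolume.
#' @param psf PSFModel.
#' @param gm_names gray-matter label names; default: labels with codes >= 10
#'   plus the cerebellar reference.
#' @param alpha van Cittert relaxation (default 1.5).
#' @param ... passed to the underlying method.
#' @return PvcResult.
#' @export
run_pvc <- function(method, pet, labels, psf, gm_names = NULL, alpha = 1.5,
                    ...) {
  if (is.null(gm_names))
    gm_names <- c(names(labels$label_map)[labels$label_map >= 10L],
                  "cerebellum_reference")
  gm_names <- intersect(gm_names, names(labels$label_map))
  switch(method,
    none = pvc_none(pet, labels),
    meltzer = pvc_meltzer(pet, label_mask(labels, c(gm_names, "white_matter")),
                          psf, labels = labels, ...),
    mg = pvc_muller_gartner(pet, label_mask(labels, gm_names),
                            label_mask(labels, "white_matter"), psf,
                            labels = labels, ...),
    vc = pvc_van_cittert(pet, psf, alpha = alpha, labels = labels, ...),
    gtm = pvc_gtm(pet, build_gtm(labels, psf), labels),
    rbv = {
      est <- pvc_gtm(pet, build_gtm(labels, psf), labels)
      pvc_rbv(pet, labels, psf, est$regional_values, ...)
    },
    stop("unknown PVC method: ", method))
}
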