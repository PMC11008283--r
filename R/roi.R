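# Regional SUVR quantification: composite ROI schemes, reference-region
# normalization, tau-level stratification, and annualized percent change.

#' Default composite ROI scheme
#'
#' Maps the analysis composites onto the phantom's atomic labels. The
#' temporal meta-ROI (TMP) is the union of the mesial temporal (MT) and
#' lateral temporal components; mTMP is TMP minus MT. WCG is the whole
#' cortical gray. The reference composite is the inferior cerebellar gray,
#' and white matter / CSF composites are carried for diagnostics (e.g. the
#' RBV overcorrection check).
#'
#' @param include_ventricle include the ventricle label in the CSF
#'   diagnostic composite (default TRUE, matching the default phantom).
#' @return object of class \code{RoiScheme}: list with \code{composite_map}.
#' @export
default_roi_scheme <- function(include_ventricle = TRUE) {
  roi_scheme(list(
    MT = "mesial_temporal",
    mTMP = "lateral_temporal",
    TMP = c("mesial_temporal", "lateral_temporal"),
    rest_of_temporal = "rest_temporal",
    parietal = "parietal",
    occipital = "occipital",
    frontal = "frontal",
    WCG = c("frontal", "parietal", "occipital", "rest_temporal",
            "lateral_temporal", "mesial_temporal"),
    reference = "cerebellum_reference",
    white_matter = "white_matter",
    csf = if (include_ventricle) c("csf", "ventricle") else "csf"
  ))
}

#' Construct and validate an ROI scheme
#'
#' @param composite_map named list: composite name -> character vector of
#'   atomic label names. Must contain \code{reference}; if \code{MT},
#'   \code{mTMP} and \code{TMP} are all present, TMP must equal the disjoint
#'   union of MT and mTMP.
#' @return RoiScheme.
#' @export
roi_scheme <- function(composite_map) {
  stopifnot(is.list(composite_map), !is.null(names(composite_map)))
  if (!"reference" %in% names(composite_map))
    stop("scheme must define a 'reference' composite")
  cm <- lapply(composite_map, as.character)
  if (all(c("MT", "mTMP", "TMP") %in% names(cm))) {
    if (!all(cm$MT %in% cm$TMP))
      stop("TMP must contain MT")
    if (!setequal(cm$mTMP, setdiff(cm$TMP, cm$MT)))
      stop("mTMP must equal TMP minus MT")
  }
  targets <- setdiff(names(cm), c("reference", "white_matter", "csf"))
  overlap <- intersect(cm$reference, unlist(cm[targets]))
  if (length(overlap))
    stop("reference labels overlap target composites: ",
         paste(overlap, collapse = ", "))
  structure(list(composite_map = cm), class = "RoiScheme")
}

#' Composite ROI means of an image
#'
#' Unweighted voxel means over the member voxels of each composite.
#'
#' @param img ActivityVolume.
#' @param labels LabelVolume on the same grid.
#' @param scheme RoiScheme.
#' @param valid_mask optional logical array restricting the mean to valid
#'   voxels (e.g. the validity mask of a PVC result).
#' @return named numeric vector, one mean per composite.
#' @export
roi_means <- function(img, labels, scheme, valid_mask = NULL) {
  stopifnot(inherits(scheme, "RoiScheme"))
  check_same_grid(img, labels)
  vals <- as.vector(img$values)
  labvec <- as.vector(labels$labels)
  valid <- if (is.null(valid_mask)) rep(TRUE, length(vals))
    else as.vector(valid_mask)
  vapply(names(scheme$composite_map), function(comp) {
    members <- scheme$composite_map[[comp]]
    unknown <- setdiff(members, names(labels$label_map))
    if (length(unknown))
      stop("composite ", comp, " references unknown label(s): ",
           paste(unknown, collapse = ", "))
    sel <- labvec %in% labels$label_map[members] & valid
    if (!any(sel)) stop("composite ", comp, " has no (valid) voxels")
    mean(vals[sel])
  }, numeric(1))
}

#' Composite means from per-label regional values
#'
#' Voxel-count-weighted aggregation of per-label values (e.g. GTM regional
#' estimates, which come without a corrected image) into composites.
#'
#' @param regional_values named per-label values.
#' @param label_counts named per-label voxel counts.
#' @param scheme RoiScheme.
#' @return named numeric vector of composite means.
#' @export
composite_from_regional <- function(regional_values, label_counts, scheme) {
  stopifnot(inherits(scheme, "RoiScheme"))
  rv <- unlist(regional_values)
  vapply(names(scheme$composite_map), function(comp) {
    members <- scheme$composite_map[[comp]]
    missing <- setdiff(members, names(rv))
    if (length(missing))
      stop("composite ", comp, " missing regional value(s): ",
           paste(missing, collapse = ", "))
    w <- label_counts[members]
    if (any(is.na(w)) || sum(w) == 0)
      stop("composite ", comp, " has no voxels")
    sum(rv[members] * w) / sum(w)
  }, numeric(1))
}

#' SUVR from composite means
#'
#' Divides every target composite mean by the reference composite mean; the
#' reference itself is dropped from the output. SUVR is invariant to global
#' rescaling of the image.
#'
#' @param means named composite means including \code{reference}.
#' @param scheme RoiScheme (used only to identify the reference name).
#' @return named numeric vector of SUVRs.
#' @export
compute_suvr <- function(means, scheme = NULL) {
  if (!"reference" %in% names(means))
    stop("means must include a 'reference' entry")
  ref <- means[["reference"]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference mean must be > 0, got ", ref)
  out <- means[setdiff(names(means), "reference")] / ref
  out
}

#' Stratify AD subjects into tau-level groups
#'
#' Cut points are the first and third quartiles of the AD subjects' baseline
#' temporal meta-ROI SUVR (linear-interpolation quantiles by default,
#' \code{type = 7}). Subjects at or below Q1 form the low-tau group,
#' subjects above Q3 the high-tau group, the rest the mid-tau group;
#' cognitively unimpaired subjects are never stratified. Fixed cut points
#' (e.g. the published 1.30 / 1.75 pair) can be supplied to override the
#' quartiles.
#'
#' @param baseline_tmp_suvr named numeric vector, subject -> baseline TMP
#'   SUVR.
#' @param ad_subjects character vector of AD subject ids to stratify.
#' @param cutpoints optional numeric length-2 vector (Q1, Q3) override.
#' @param quantile_type quantile convention passed to
#'   \code{stats::quantile} (default 7, linear interpolation).
#' @return list with \code{tau_level} (named factor: low/mid/high for AD
#'   subjects) and \code{cutpoints}.
#' @export
stratify_tau_levels <- function(baseline_tmp_suvr, ad_subjects,
                                cutpoints = NULL, quantile_type = 7) {
  missing <- setdiff(ad_subjects, names(baseline_tmp_suvr))
  if (length(missing))
    stop("no baseline TMP SUVR for subject(s): ",
         paste(missing, collapse = ", "))
  x <- baseline_tmp_suvr[ad_subjects]
  if (is.null(cutpoints)) {
    if (length(x) < 4) stop("need at least 4 AD subjects for quartiles")
    if (length(unique(x)) == 1)
      stop("degenerate quartiles: all baseline TMP SUVR values identical")
    cutpoints <- unname(stats::quantile(x, c(0.25, 0.75),
                                        type = quantile_type))
  }
  if (length(cutpoints) != 2 || cutpoints[1] > cutpoints[2])
    stop("cutpoints must be (Q1, Q3) with Q1 <= Q3")
  lev <- ifelse(x <= cutpoints[1], "low",
                ifelse(x > cutpoints[2], "high", "mid"))
  list(tau_level = stats::setNames(factor(lev, c("low", "mid", "high")),
                                   ad_subjects),
       cutpoints = cutpoints)
}

#' Annualized percent SUVR change between two visits
#'
#' \code{100 * (followup / baseline - 1) / time_years}.
#'
#' @param baseline_suvr positive baseline SUVR.
#' @param followup_suvr follow-up SUVR.
#' @param time_years elapsed time in years (> 0).
#' @return percent change per year.
#' @export
annualized_pct_change <- function(baseline_suvr, followup_suvr, time_years) {
  if (any(baseline_suvr <= 0)) stop("baseline SUVR must be > 0")
  if (any(time_years <= 0)) stop("time_years must be > 0")
  100 * (followup_suvr / baseline_suvr - 1) / time_years
}

#' Classify amyloid status from a centiloid value
#'
#' Positive iff the centiloid value is strictly above the threshold
#' (default 26).
#'
#' @param centiloid numeric centiloid value(s); NA -> "unknown".
#' @param threshold positivity cutoff (default 26).
#' @return character vector "positive"/"negative"/"unknown".
#' @export
classify_amyloid <- function(centiloid, threshold = 26) {
  out <- ifelse(is.na(centiloid), "unknown",
                ifelse(centiloid > threshold, "positive", "negative"))
  out
}

#' Weeks-to-years conversion constant
#'
#' One Julian year = 365.25 days = 52.1775 weeks; fixed so that visit-week
#' schedules convert reproducibly.
#' @export
WEEKS_PER_YEAR <- 365.25 / 7

#' Quantify a phantom time series into a long-format SUVR table
#'
#' Applies one or more PVC methods at each time point of a longitudinal
#' phantom series and converts composite means to SUVR.
#'
#' @param series output of \code{\link{simulate_longitudinal_phantom}}.
#' @param scheme RoiScheme.
#' @param psf PSFModel used by the corrections.
#' @param methods character vector of method names for \code{\link{run_pvc}}.
#' @param subject_id id string recorded in the table.
#' @return data.frame with columns subject_id, time_years, method, roi, suvr.
#' @export
quantify_series <- function(series, scheme, psf,
                            methods = c("none", "meltzer", "mg", "vc",
                                        "gtm", "rbv"),
                            subject_id = "phantom01") {
  rows <- list()
  for (entry in series) {
    labels <- entry$label_volume
    counts <- label_counts(labels)
    for (method in methods) {
      res <- run_pvc(method, entry$activity, labels, psf)
      if (is.null(res$corrected_image)) {
        means <- composite_from_regional(res$regional_values, counts, scheme)
      } else {
        # composites with no valid voxels under this method (e.g. white
        # matter for the GM-only 3-compartment correction) are dropped
        means <- unlist(lapply(names(scheme$composite_map), function(comp) {
          sub <- roi_scheme(scheme$composite_map[unique(c(comp, "reference"))])
          tryCatch(roi_means(res$corrected_image, labels, sub,
                             valid_mask = res$valid_mask)[comp],
                   error = function(e) NULL)
        }))
      }
      suvr <- compute_suvr(means, scheme)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject_id, time_years = entry$time, method = method,
        roi = names(suvr), suvr = unname(suvr), row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
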