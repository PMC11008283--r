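# Digital brain phantom: nested-sphere head geometry with named cortical
# sectors, known per-label activities, PSF blurring, multiplicative noise and
# longitudinal atrophy. Every partial-volume-correction method in the package
# can therefore be checked against exact ground truth.

#' Default phantom geometry
#'
#' Nested head geometry in mm, relative to the grid centre: a skull shell,
#' a meningeal shell, a CSF envelope, a cerebral gray-matter shell divided
#' into six named cortical sectors, a white-matter core with a ventricular
#' CSF cavity, and a separate cerebellar gray reference blob. True
#' activities are on an SUVR-like scale (cerebellar gray = 1): cortical
#' values sit in the 1.15-1.55 range typical of prodromal-AD tau tracer
#' uptake, white matter and meninges carry off-target signal, CSF is low
#' but nonzero.
#'
#' @param cortical_names names of the cortical sectors.
#' @param cortical_widths_deg azimuthal widths (degrees, must sum to 360).
#' @param cortical_activity named true activities for the sectors.
#' @param include_skull,include_meninges,include_ventricle logical switches.
#' @return geometry configuration list.
#' @export
default_phantom_geometry <- function(
    cortical_names = c("frontal", "parietal", "occipital", "rest_temporal",
                       "lateral_temporal", "mesial_temporal"),
    cortical_widths_deg = c(90, 70, 60, 60, 50, 30),
    cortical_activity = c(frontal = 1.15, parietal = 1.30, occipital = 1.35,
                          rest_temporal = 1.30, lateral_temporal = 1.55,
                          mesial_temporal = 1.45),
    include_skull = TRUE, include_meninges = TRUE, include_ventricle = TRUE) {
  stopifnot(length(cortical_names) >= 2,
            length(cortical_widths_deg) == length(cortical_names),
            abs(sum(cortical_widths_deg) - 360) < 1e-6,
            all(cortical_names %in% names(cortical_activity)))
  list(
    skull_outer_mm = 40, skull_inner_mm = 37,
    meninges_inner_mm = 35,
    cerebrum_center_mm = c(0, 0, 10), cerebrum_radius_mm = 24,
    wm_radius_mm = 18, ventricle_radius_mm = 5.5,
    cerebellum_center_mm = c(0, 0, -27), cerebellum_radius_mm = 7,
    cortical_names = cortical_names,
    cortical_widths_deg = cortical_widths_deg,
    include_skull = include_skull, include_meninges = include_meninges,
    include_ventricle = include_ventricle,
    true_activity = c(
      background = 0, csf = 0.10,
      ventricle = if (include_ventricle) 0.10 else NULL,
      white_matter = 1.10, cerebellum_reference = 1.00,
      skull = if (include_skull) 0.10 else NULL,
      meninges = if (include_meninges) 0.30 else NULL,
      cortical_activity[cortical_names])
  )
}

#' Build a ground-truth digital brain phantom
#'
#' Partitions the grid into the compartments of
#' \code{\link{default_phantom_geometry}} and records the per-label true
#' activities. The construction is fully deterministic; the \code{seed}
#' argument is accepted for interface symmetry with the stochastic
#' simulators but does not currently influence the geometry.
#'
#' @param grid integer triple, voxels per axis.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param geometry_config list from \code{\link{default_phantom_geometry}}.
#' @param seed unused (deterministic geometry).
#' @param margin_fwhm_mm PSF FWHM the phantom must support: a background
#'   margin of at least 3 times this value must surround the head so that
#'   blurring conserves in-volume activity. Default 8 mm.
#' @return object of class \code{PhantomTruth}: list with
#'   \code{label_volume}, \code{true_activity}, \code{atrophy_fraction},
#'   \code{cortical_labels}.
#' @export
make_brain_phantom <- function(grid = c(64, 64, 64), voxel_size_mm = 2,
                               geometry_config = default_phantom_geometry(),
                               seed = 1L, margin_fwhm_mm = 8) {
  g <- geometry_config
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3, all(grid > 0))
  half_extent <- grid * voxel_size_mm / 2
  outer_r <- if (g$include_skull) g$skull_outer_mm else g$meninges_inner_mm
  if (any(half_extent - outer_r < 3 * margin_fwhm_mm))
    stop(sprintf(paste0("phantom does not fit: head radius %.1f mm plus a ",
                        "3x%.0f mm background margin needs a half-extent of ",
                        "%.1f mm but the grid provides %.1f mm"),
                 outer_r, margin_fwhm_mm, outer_r + 3 * margin_fwhm_mm,
                 min(half_extent)))

  # voxel-centre coordinates in mm relative to the grid centre
  ax <- lapply(1:3, function(k)
    (seq_len(grid[k]) - 0.5) * voxel_size_mm - half_extent[k])
  X <- array(rep(ax[[1]], times = grid[2] * grid[3]), dim = grid)
  Y <- array(rep(rep(ax[[2]], each = grid[1]), times = grid[3]), dim = grid)
  Z <- array(rep(ax[[3]], each = grid[1] * grid[2]), dim = grid)

  in_ball <- function(center, radius)
    (X - center[1])^2 + (Y - center[2])^2 + (Z - center[3])^2 <= radius^2

  codes <- c(background = 0L, csf = 1L, white_matter = 2L,
             cerebellum_reference = 3L)
  nxt <- 4L
  if (g$include_ventricle) { codes["ventricle"] <- nxt; nxt <- nxt + 1L }
  if (g$include_skull) { codes["skull"] <- nxt; nxt <- nxt + 1L }
  if (g$include_meninges) { codes["meninges"] <- nxt; nxt <- nxt + 1L }
  cort_codes <- seq.int(10L, by = 1L, length.out = length(g$cortical_names))
  names(cort_codes) <- g$cortical_names
  codes <- c(codes, cort_codes)

  labs <- array(0L, dim = grid)
  head0 <- sqrt(X^2 + Y^2 + Z^2)
  if (g$include_skull)
    labs[head0 <= g$skull_outer_mm] <- codes[["skull"]]
  if (g$include_meninges)
    labs[head0 <= g$skull_inner_mm] <- codes[["meninges"]]
  labs[head0 <= g$meninges_inner_mm] <- codes[["csf"]]
  labs[in_ball(g$cerebellum_center_mm, g$cerebellum_radius_mm)] <-
    codes[["cerebellum_reference"]]

  cerebrum <- in_ball(g$cerebrum_center_mm, g$cerebrum_radius_mm)
  # azimuthal cortical sectors around the cerebrum axis
  phi <- (atan2(Y - g$cerebrum_center_mm[2], X - g$cerebrum_center_mm[1]) /
            pi * 180) %% 360
  edges <- cumsum(c(0, g$cortical_widths_deg))
  sector <- findInterval(phi, edges, rightmost.closed = TRUE)
  sector[sector > length(g$cortical_names)] <- length(g$cortical_names)
  labs[cerebrum] <- cort_codes[sector[cerebrum]]
  labs[in_ball(g$cerebrum_center_mm, g$wm_radius_mm)] <- codes[["white_matter"]]
  if (g$include_ventricle)
    labs[in_ball(g$cerebrum_center_mm, g$ventricle_radius_mm)] <-
      codes[["ventricle"]]

  lv <- label_volume(labs, voxel_size_mm, codes)
  counts <- label_counts(lv)
  empty <- names(counts)[counts == 0 & names(counts) != "background"]
  if (length(empty))
    stop("phantom geometry produced empty label(s): ",
         paste(empty, collapse = ", "))
  truth <- g$true_activity[names(codes)]
  names(truth) <- names(codes)
  if (anyNA(truth)) stop("geometry true_activity is missing label(s): ",
                         paste(names(codes)[is.na(truth)], collapse = ", "))
  phantom_truth(lv, truth, cortical_labels = g$cortical_names)
}

#' Construct a PhantomTruth object
#'
#' @param label_volume LabelVolume.
#' @param true_activity named vector of per-label ground-truth activities
#'   (must cover every label; background must be 0).
#' @param atrophy_fraction cumulative gray-matter atrophy fraction in [0,1).
#' @param cortical_labels names of the gray-matter labels subject to atrophy.
#' @return object of class \code{PhantomTruth}.
#' @export
phantom_truth <- function(label_volume, true_activity, atrophy_fraction = 0,
                          cortical_labels = character()) {
  true_activity <- unlist(true_activity)
  missing <- setdiff(names(label_volume$label_map), names(true_activity))
  if (length(missing))
    stop("true_activity is missing label(s): ", paste(missing, collapse = ", "))
  if (!isTRUE(all.equal(unname(true_activity[["background"]]), 0)))
    stop("background truth activity must be 0")
  if (atrophy_fraction < 0 || atrophy_fraction >= 1)
    stop("atrophy_fraction must be in [0, 1)")
  structure(list(label_volume = label_volume,
                 true_activity = true_activity[names(label_volume$label_map)],
                 atrophy_fraction = atrophy_fraction,
                 cortical_labels = cortical_labels),
            class = "PhantomTruth")
}

#' Paint the piecewise-constant activity image of a phantom
#'
#' @param truth PhantomTruth.
#' @return ActivityVolume whose value at every voxel equals the true
#'   activity of the voxel's label.
#' @export
paint_activity <- function(truth) {
  stopifnot(inherits(truth, "PhantomTruth"))
  lv <- truth$label_volume
  idx <- match(as.vector(lv$labels), lv$label_map)
  if (anyNA(idx)) {
    bad <- unique(as.vector(lv$labels)[is.na(idx)])
    stop("no truth activity for label code(s): ", paste(bad, collapse = ", "))
  }
  vals <- unname(truth$true_activity[names(lv$label_map)])[idx]
  activity_volume(array(vals, dim = dim(lv$labels)), lv$voxel_size_mm)
}

#' Add multiplicative Gaussian noise to an image
#'
#' Each voxel is multiplied by \code{1 + N(0, noise_sd_fraction)}; results
#' are clipped at zero. Deterministic for a given seed.
#'
#' @param img ActivityVolume.
#' @param noise_sd_fraction nonnegative scalar, e.g. 0.03 for ~3\% noise.
#' @param seed integer RNG seed.
#' @return noised ActivityVolume.
#' @export
add_noise <- function(img, noise_sd_fraction, seed) {
  stopifnot(inherits(img, "ActivityVolume"))
  if (!is.finite(noise_sd_fraction) || noise_sd_fraction < 0)
    stop("noise_sd_fraction must be >= 0")
  if (noise_sd_fraction == 0) return(img)
  v <- img$values
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  v <- v * (1 + array(stats::rnorm(length(v), 0, noise_sd_fraction),
                      dim = dim(v)))
  v[v < 0] <- 0
  activity_volume(v, img$voxel_size_mm)
}

# save/restore the global RNG state so library calls do not perturb user code
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a longitudinal phantom series with atrophy and tau accumulation
#'
#' At each requested time the cortical gray-matter labels are eroded from
#' their boundaries until the cumulative atrophy fraction
#' \code{annual_atrophy_fraction * t} of baseline gray-matter voxels has been
#' reassigned to CSF (removal order: erosion depth, ties broken by array
#' index, so the series is deterministic and monotone). True activities
#' evolve as \code{a0 * exp(rate * t)} per label, after which the image is
#' blurred with the PSF and multiplicative noise is applied. This
#' construction reproduces, by design, the confound in which a region with
#' constant true tau level shows a declining blurred signal purely because
#' it atrophies.
#'
#' @param truth0 baseline PhantomTruth (with nonempty
#'   \code{cortical_labels} if atrophy is requested).
#' @param times_years sorted nonnegative times, first must be 0.
#' @param annual_log_change_per_label named vector of per-label annual log
#'   activity change rates (unnamed labels default to 0).
#' @param annual_atrophy_fraction gray-matter fraction lost per year.
#' @param psf PSFModel.
#' @param noise_sd_fraction multiplicative noise SD.
#' @param seed integer; per-time sub-seeds are derived deterministically.
#' @return list with one entry per time:
#'   \code{list(time, label_volume, activity, truth)} where \code{activity}
#'   is the blurred+noised image.
#' @export
simulate_longitudinal_phantom <- function(truth0, times_years,
                                          annual_log_change_per_label = NULL,
                                          annual_atrophy_fraction = 0,
                                          psf = psf_model(8),
                                          noise_sd_fraction = 0,
                                          seed = 1L) {
  stopifnot(inherits(truth0, "PhantomTruth"))
  if (is.unsorted(times_years) || times_years[1] != 0)
    stop("times_years must be sorted ascending and start at 0")
  if (annual_atrophy_fraction < 0) stop("atrophy fraction must be >= 0")
  lv0 <- truth0$label_volume
  rates <- stats::setNames(numeric(length(lv0$label_map)),
                           names(lv0$label_map))
  if (!is.null(annual_log_change_per_label)) {
    unknown <- setdiff(names(annual_log_change_per_label), names(rates))
    if (length(unknown))
      stop("rate given for unknown label(s): ", paste(unknown, collapse = ", "))
    rates[names(annual_log_change_per_label)] <-
      unlist(annual_log_change_per_label)
  }

  gm_names <- truth0$cortical_labels
  if (annual_atrophy_fraction > 0 && length(gm_names) == 0)
    stop("atrophy requested but truth0 has no cortical_labels")
  if (length(gm_names)) {
    gm_mask <- label_mask(lv0, gm_names)
    n_gm0 <- sum(gm_mask)
    # atrophy advances from the CSF-facing surface (sulcal widening), not
    # from the white-matter interface
    csf_names <- intersect(c("csf", "ventricle", "meninges", "background"),
                           names(lv0$label_map))
    front <- label_mask(lv0, csf_names)
    depth <- front_distance(gm_mask, front)
    # deterministic removal order: closest to the CSF front, then array order
    ord <- order(depth[gm_mask], which(gm_mask))
    gm_idx_sorted <- which(gm_mask)[ord]
  }

  old <- local_seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(times_years))
  restore_seed(old)

  out <- vector("list", length(times_years))
  for (k in seq_along(times_years)) {
    t <- times_years[k]
    cum_atrophy <- min(annual_atrophy_fraction * t, 0.99)
    labs <- lv0$labels
    if (cum_atrophy > 0) {
      n_remove <- round(cum_atrophy * n_gm0)
      if (n_remove > 0) {
        rm_idx <- gm_idx_sorted[seq_len(min(n_remove, n_gm0))]
        labs[rm_idx] <- lv0$label_map[["csf"]]
      }
    }
    lv_t <- label_volume(labs, lv0$voxel_size_mm, lv0$label_map, check = FALSE)
    if (cum_atrophy > 0) {
      cnt <- label_counts(lv_t)[gm_names]
      if (any(cnt == 0))
        stop("atrophy removed an entire ROI: ",
             paste(gm_names[cnt == 0], collapse = ", "))
    }
    act_t <- truth0$true_activity * exp(rates * t)
    truth_t <- phantom_truth(lv_t, act_t, atrophy_fraction = cum_atrophy,
                             cortical_labels = gm_names)
    img <- paint_activity(truth_t)
    img <- apply_psf(img, psf)
    img <- add_noise(img, noise_sd_fraction, sub_seeds[k])
    out[[k]] <- list(time = t, label_volume = lv_t, activity = img,
                     truth = truth_t)
  }
  out
}
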