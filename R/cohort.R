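# Longitudinal cohort simulator.
#
# Generates long-format per-subject, per-visit, per-ROI SUVR tables with the
# statistical structure the mixed model assumes:
#   lnSUVR_ij = mu_{g,roi} + beta'x_i + u_i + (b_{g,roi} + v_i) t_ij + eps_ij
# with independent subject random intercepts u_i ~ N(0, sigma_u^2(g)) and
# slopes v_i ~ N(0, sigma_v^2(g)), iid residuals eps ~ N(0, sigma^2), visit
# schedules with jitter and per-visit retention, and covariates (age, sex,
# APOE4 status, centiloid). Defaults reproduce the two published cohorts:
# a single-site natural-history study (NHS: CU/prodromal/mild/moderate,
# visits at 0/26/52/78 weeks) and a multisite trial population (Tauriel:
# prodromal/mild, visits at 0/49/73 weeks).

ROI_NAMES <- c("MT", "mTMP", "rest_of_temporal", "parietal", "occipital",
               "frontal", "TMP", "WCG")

# Baseline group-mean SUVR per ROI and annualized %change per year per ROI,
# as published for the two cohorts; the generator converts both to the ln
# scale (mu = ln(mean SUVR), b = ln(1 + pct/100)).
NHS_BASELINE_SUVR <- list(
  CU       = c(MT = 1.30, mTMP = 1.28, rest_of_temporal = 1.16,
               parietal = 1.16, occipital = 1.24, frontal = 1.09,
               TMP = 1.28, WCG = 1.16),
  prodromal = c(MT = 1.36, mTMP = 1.37, rest_of_temporal = 1.18,
               parietal = 1.19, occipital = 1.26, frontal = 1.08,
               TMP = 1.37, WCG = 1.18),
  mild     = c(MT = 1.47, mTMP = 1.67, rest_of_temporal = 1.32,
               parietal = 1.35, occipital = 1.39, frontal = 1.17,
               TMP = 1.63, WCG = 1.32),
  moderate = c(MT = 1.63, mTMP = 1.98, rest_of_temporal = 1.54,
               parietal = 1.62, occipital = 1.60, frontal = 1.33,
               TMP = 1.91, WCG = 1.52))

NHS_SLOPE_PCT <- list(
  CU       = c(MT = -1.70, mTMP = -1.07, rest_of_temporal = -2.37,
               parietal = -1.75, occipital = -1.19, frontal = -2.35,
               TMP = -1.22, WCG = -1.77),
  prodromal = c(MT = 2.37, mTMP = 3.10, rest_of_temporal = 1.96,
               parietal = 2.09, occipital = 2.64, frontal = 1.50,
               TMP = 2.96, WCG = 2.09),
  mild     = c(MT = 0.04, mTMP = 2.35, rest_of_temporal = 0.88,
               parietal = 2.24, occipital = 1.95, frontal = 1.00,
               TMP = 2.00, WCG = 1.48),
  moderate = c(MT = -0.52, mTMP = 3.33, rest_of_temporal = 1.83,
               parietal = 3.72, occipital = 4.24, frontal = 2.76,
               TMP = 2.63, WCG = 2.96))

TAURIEL_BASELINE_SUVR <- list(
  prodromal = c(MT = 1.45, mTMP = 1.50, rest_of_temporal = 1.23,
               parietal = 1.27, occipital = 1.31, frontal = 1.13,
               TMP = 1.49, WCG = 1.24),
  mild     = c(MT = 1.49, mTMP = 1.62, rest_of_temporal = 1.30,
               parietal = 1.36, occipital = 1.38, frontal = 1.16,
               TMP = 1.59, WCG = 1.30))

TAURIEL_SLOPE_PCT <- list(
  prodromal = c(MT = 0.66, mTMP = 3.46, rest_of_temporal = 2.46,
               parietal = 2.93, occipital = 2.20, frontal = 2.47,
               TMP = 2.98, WCG = 2.51),
  mild     = c(MT = 0.81, mTMP = 4.04, rest_of_temporal = 3.38,
               parietal = 3.31, occipital = 2.77, frontal = 3.46,
               TMP = 3.47, WCG = 3.15))

group_config <- function(n, baseline_suvr, slope_pct, sigma_u, sigma_v,
                         age_mean, age_sd, female_frac, apoe4_frac,
                         apoe4_unknown_frac = 0, ctl_mean, ctl_sd) {
  list(n = n,
       baseline_lnsuvr = log(baseline_suvr[ROI_NAMES]),
       slope_lnsuvr = log(1 + slope_pct[ROI_NAMES] / 100),
       sigma_u = sigma_u, sigma_v = sigma_v,
       age_mean = age_mean, age_sd = age_sd,
       female_frac = female_frac, apoe4_frac = apoe4_frac,
       apoe4_unknown_frac = apoe4_unknown_frac,
       ctl_mean = ctl_mean, ctl_sd = ctl_sd)
}

#' Default configuration of the single-site natural-history cohort
#'
#' 63 subjects: 10 cognitively unimpaired, 24 prodromal, 15 mild and 14
#' moderate AD. Baseline group-mean SUVRs and annualized slopes per ROI are
#' the published group estimates; visit schedule 0/26/52/78 weeks with the
#' published jitter SDs and retention matched to realized follow-up counts
#' (63/63, 56/63, 51/63). Residual SD 0.03 on the ln scale (the ~3\%
#' within-subject variability of the uncorrected data). Random-intercept
#' SDs come from the baseline TMP coefficient of variation per group;
#' random-slope SDs from the whole-cortical-gray effect sizes (SD =
#' mean/ES on the percent scale).
#'
#' @param seed integer seed stored in the config.
#' @return CohortConfig list.
#' @export
nhs_default_config <- function(seed = 1L) {
  groups <- list(
    CU = group_config(10, NHS_BASELINE_SUVR$CU, NHS_SLOPE_PCT$CU,
                      sigma_u = 0.11 / 1.28, sigma_v = 0.0099,
                      age_mean = 67.2, age_sd = 6.2, female_frac = 0.70,
                      apoe4_frac = 0.40, apoe4_unknown_frac = 0,
                      ctl_mean = 37.4, ctl_sd = 43.9),
    prodromal = group_config(24, NHS_BASELINE_SUVR$prodromal,
                      NHS_SLOPE_PCT$prodromal,
                      sigma_u = 0.17 / 1.37, sigma_v = 0.0087,
                      age_mean = 69.5, age_sd = 7.1, female_frac = 0.67,
                      apoe4_frac = 16 / 24, apoe4_unknown_frac = 5 / 24,
                      ctl_mean = 77.7, ctl_sd = 33.2),
    mild = group_config(15, NHS_BASELINE_SUVR$mild, NHS_SLOPE_PCT$mild,
                      sigma_u = 0.25 / 1.63, sigma_v = 0.0138,
                      age_mean = 73.1, age_sd = 4.4, female_frac = 0.47,
                      apoe4_frac = 9 / 15, apoe4_unknown_frac = 1 / 15,
                      ctl_mean = 77.1, ctl_sd = 29.2),
    moderate = group_config(14, NHS_BASELINE_SUVR$moderate,
                      NHS_SLOPE_PCT$moderate,
                      sigma_u = 0.38 / 1.91, sigma_v = 0.0121,
                      age_mean = 70.4, age_sd = 7.1, female_frac = 0.29,
                      apoe4_frac = 13 / 14, apoe4_unknown_frac = 1 / 14,
                      ctl_mean = 87.4, ctl_sd = 34.4))
  cohort_config(study = "NHS", groups = groups, sigma = 0.03,
                visit_weeks = c(0, 26, 52, 78),
                visit_jitter_sd_weeks = c(0, 2.5, 3.23, 3.6),
                retention = c(1, 63 / 63, 56 / 63, 51 / 63),
                seed = seed)
}

#' Default configuration of the multisite trial cohort
#'
#' 334 subjects (122 prodromal, 212 mild AD), visits at 0/49/73 weeks with
#' the published jitter SDs and retention matched to realized counts
#' (314/334 and 288/334). Residual SD 0.04 on the ln scale: multisite
#' imaging carries more within-subject variability than the single-site
#' study.
#'
#' @param seed integer seed stored in the config.
#' @return CohortConfig list.
#' @export
tauriel_default_config <- function(seed = 1L) {
  groups <- list(
    prodromal = group_config(122, TAURIEL_BASELINE_SUVR$prodromal,
                      TAURIEL_SLOPE_PCT$prodromal,
                      sigma_u = 0.26 / 1.49, sigma_v = 0.0244,
                      age_mean = 70.2, age_sd = 7.1, female_frac = 0.53,
                      apoe4_frac = 90 / 122, apoe4_unknown_frac = 0,
                      ctl_mean = 90.7, ctl_sd = 33.3),
    mild = group_config(212, TAURIEL_BASELINE_SUVR$mild,
                      TAURIEL_SLOPE_PCT$mild,
                      sigma_u = 0.31 / 1.59, sigma_v = 0.0239,
                      age_mean = 69.1, age_sd = 6.9, female_frac = 0.55,
                      apoe4_frac = 163 / 212, apoe4_unknown_frac = 0,
                      ctl_mean = 89.5, ctl_sd = 30.6))
  cohort_config(study = "Tauriel", groups = groups, sigma = 0.04,
                visit_weeks = c(0, 49, 73),
                visit_jitter_sd_weeks = c(0, 3.35, 3.8),
                retention = c(1, 314 / 334, 288 / 334),
                seed = seed)
}

#' Construct and validate a cohort configuration
#'
#' @param study study label ("NHS" or "Tauriel" or custom).
#' @param groups named list of per-group configurations (n, per-ROI
#'   baseline_lnsuvr and slope_lnsuvr, sigma_u, sigma_v, covariate
#'   generators).
#' @param sigma residual SD on the ln scale.
#' @param covariate_effects named coefficients on lnSUVR for
#'   \code{apoe4} (carrier indicator), \code{age} (per year, centred at 70),
#'   \code{sexF} (female indicator) and \code{ctl} (per centiloid, centred
#'   at 80). Default all zero: the published model treats them as nuisance
#'   adjustments and prints no coefficients.
#' @param visit_weeks scheduled visit weeks, first must be 0.
#' @param visit_jitter_sd_weeks per-visit jitter SD in weeks (baseline 0).
#' @param retention per-visit retention probability (baseline 1).
#' @param monotone_dropout if TRUE a subject missing one visit misses all
#'   later ones; default FALSE (independent retention).
#' @param rise_fall_fraction fraction of subjects given a piecewise
#'   rise-then-fall trajectory (slope flips sign after the midpoint of the
#'   observation window); default 0, used only in robustness experiments.
#' @param seed integer seed.
#' @return CohortConfig list.
#' @export
cohort_config <- function(study, groups, sigma,
                          covariate_effects = c(apoe4 = 0, age = 0,
                                                sexF = 0, ctl = 0),
                          visit_weeks, visit_jitter_sd_weeks, retention,
                          monotone_dropout = FALSE,
                          rise_fall_fraction = 0,
                          seed = 1L) {
  stopifnot(length(visit_weeks) == length(visit_jitter_sd_weeks),
            length(visit_weeks) == length(retention),
            visit_weeks[1] == 0)
  if (sigma < 0) stop("sigma must be >= 0")
  if (any(retention <= 0 | retention > 1))
    stop("retention must be in (0, 1]")
  for (g in names(groups)) {
    gc <- groups[[g]]
    if (gc$sigma_u < 0 || gc$sigma_v < 0)
      stop("negative random-effect SD in group ", g)
    if (!all(ROI_NAMES %in% names(gc$baseline_lnsuvr)) ||
        !all(ROI_NAMES %in% names(gc$slope_lnsuvr)))
      stop("group ", g, " must define baseline and slope for all ROIs")
  }
  structure(list(study = study, groups = groups, sigma = sigma,
                 covariate_effects = covariate_effects,
                 visit_weeks = visit_weeks,
                 visit_jitter_sd_weeks = visit_jitter_sd_weeks,
                 retention = retention,
                 monotone_dropout = monotone_dropout,
                 rise_fall_fraction = rise_fall_fraction,
                 seed = as.integer(seed)),
            class = "CohortConfig")
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws subjects, covariates, random effects, jittered visit times and
#' per-visit retention from the configuration, then builds the long-format
#' SUVR table. The exact per-subject random intercepts and slopes are
#' recorded in \code{truth} so that parameter-recovery tests can compare
#' fitted values against the generating ones. Tau-level strata are assigned
#' from the generated baseline TMP SUVR quartiles of the AD subjects.
#'
#' @param config CohortConfig.
#' @return object of class \code{GeneratedCohort}: \code{subjects}
#'   (data.frame of covariates), \code{scans} (long data.frame subject_id,
#'   study, group, tau_level, visit_week, time_years, method, roi, suvr),
#'   \code{truth} (per-subject u, v and the group parameters used).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))

  subj_rows <- list()
  scan_rows <- list()
  truth_rows <- list()
  sid <- 0L
  n_visits <- length(config$visit_weeks)
  beta <- config$covariate_effects

  for (g in names(config$groups)) {
    gc <- config$groups[[g]]
    if (gc$n == 0) { warning("group ", g, " has n = 0; skipped"); next }
    for (i in seq_len(gc$n)) {
      sid <- sid + 1L
      id <- sprintf("S%03d", sid)
      age <- stats::rnorm(1, gc$age_mean, gc$age_sd)
      sex <- if (stats::runif(1) < gc$female_frac) "F" else "M"
      apoe_u <- stats::runif(1)
      apoe4 <- if (apoe_u < gc$apoe4_unknown_frac) "unknown"
        else if (apoe_u < gc$apoe4_unknown_frac +
                   (1 - gc$apoe4_unknown_frac) * gc$apoe4_frac) "carrier"
        else "noncarrier"
      ctl <- stats::rnorm(1, gc$ctl_mean, gc$ctl_sd)
      u_i <- stats::rnorm(1, 0, gc$sigma_u)
      v_i <- stats::rnorm(1, 0, gc$sigma_v)
      rise_fall <- stats::runif(1) < config$rise_fall_fraction

      cov_shift <- beta[["apoe4"]] * (apoe4 == "carrier") +
        beta[["age"]] * (age - 70) + beta[["sexF"]] * (sex == "F") +
        beta[["ctl"]] * (ctl - 80)

      jit <- stats::rnorm(n_visits, 0, config$visit_jitter_sd_weeks)
      weeks <- config$visit_weeks + jit
      weeks[1] <- 0
      weeks <- pmax(weeks, 0)
      times <- weeks / WEEKS_PER_YEAR
      keep <- stats::runif(n_visits) < config$retention
      keep[1] <- TRUE
      if (config$monotone_dropout && any(!keep))
        keep[seq_len(n_visits) >= which(!keep)[1]] <- FALSE
      keep[1] <- TRUE

      t_mid <- max(times) / 2
      for (k in which(keep)) {
        t <- times[k]
        # optional rise-then-fall confound: slope sign flips after midpoint
        t_eff <- if (rise_fall && t > t_mid) 2 * t_mid - t else t
        eps <- stats::rnorm(length(ROI_NAMES), 0, config$sigma)
        lnsuvr <- gc$baseline_lnsuvr[ROI_NAMES] + cov_shift + u_i +
          (gc$slope_lnsuvr[ROI_NAMES] + v_i) * t_eff + eps
        scan_rows[[length(scan_rows) + 1L]] <- data.frame(
          subject_id = id, study = config$study, group = g,
          visit_week = config$visit_weeks[k], time_years = t,
          method = "none", roi = ROI_NAMES, suvr = exp(unname(lnsuvr)),
          row.names = NULL)
      }
      subj_rows[[sid]] <- data.frame(
        subject_id = id, study = config$study, group = g,
        age_years = age, sex = sex, apoe4 = apoe4, centiloid = ctl,
        row.names = NULL)
      truth_rows[[sid]] <- data.frame(
        subject_id = id, group = g, u = u_i, v = v_i,
        rise_fall = rise_fall, row.names = NULL)
    }
  }
  subjects <- do.call(rbind, subj_rows)
  scans <- do.call(rbind, scan_rows)
  truth <- do.call(rbind, truth_rows)

  # tau-level stratification from generated baseline TMP SUVR (AD only)
  base_tmp <- scans[scans$time_years == 0 & scans$roi == "TMP", ]
  tmp_by_subj <- stats::setNames(base_tmp$suvr, base_tmp$subject_id)
  ad_ids <- subjects$subject_id[subjects$group != "CU"]
  subjects$tau_level <- NA_character_
  if (length(ad_ids) >= 4) {
    strat <- stratify_tau_levels(tmp_by_subj, ad_ids)
    subjects$tau_level[match(ad_ids, subjects$subject_id)] <-
      as.character(strat$tau_level)
    attr(subjects, "tau_cutpoints") <- strat$cutpoints
  }
  subjects$tau_level[subjects$group == "CU"] <- "CU"
  scans$tau_level <- subjects$tau_level[match(scans$subject_id,
                                              subjects$subject_id)]
  scans <- scans[, c("subject_id", "study", "group", "tau_level",
                     "visit_week", "time_years", "method", "roi", "suvr")]

  structure(list(subjects = subjects, scans = scans,
                 truth = list(per_subject = truth,
                              groups = config$groups,
                              sigma = config$sigma),
                 config = config),
            class = "GeneratedCohort")
}

#' @export
print.GeneratedCohort <- function(x, ...) {
  cat(sprintf("GeneratedCohort [%s]: %d subjects, %d scan rows\n",
              x$config$study, nrow(x$subjects), nrow(x$scans)))
  print(table(x$subjects$group))
  invisible(x)
}
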