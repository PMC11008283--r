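# Linear mixed-effects estimation of longitudinal lnSUVR trajectories and
# every derived statistic: residual %CV (within-subject variability),
# group-separation t-scores, slope-derived annualized percent change,
# per-subject slopes via BLUPs, longitudinal effect sizes, bootstrap CIs,
# and rank correlations of baseline SUVR vs change.

#' Fit the longitudinal linear mixed-effects model for one ROI
#'
#' Fits \code{lnSUVR ~ covariates + time * group + (1|subject) +
#' (0 + time|subject)} by REML (default) using lme4: a linear ln-scale
#' trajectory per subject, group-specific mean slopes, and independent
#' per-subject random intercept and random slope. Covariates enter the
#' intercept only, mirroring the published model; subjects with unknown
#' APOE4 status are retained through an explicit "unknown" factor level.
#'
#' @param scans long-format scan table (columns subject_id, time_years,
#'   method, roi, suvr).
#' @param subjects subject covariate table (subject_id, group, tau_level,
#'   age_years, sex, apoe4, centiloid).
#' @param roi ROI name to model.
#' @param grouping subject column giving the slope groups: "group"
#'   (diagnostic), "tau_level", or "diagnostic_x_tau" (their interaction,
#'   as cell means; the multisite model's three-way expansion).
#' @param reference_group factor level used as slope reference; default
#'   "CU" when present, otherwise the first level.
#' @param covariates intercept covariates; any of "apoe4", "age", "sex",
#'   "ctl". Default includes ctl (single-site model); drop it when not all
#'   subjects have amyloid PET.
#' @param method PVC method tag to filter scans on (default "none").
#' @param REML logical, REML (default) vs ML.
#' @return object of class \code{LmemFit}: \code{beta} (estimate, se, t per
#'   coefficient), \code{sigma}, \code{sigma_u}, \code{sigma_v},
#'   \code{blups}, \code{group_slopes}, \code{loglik}, \code{converged},
#'   \code{n_obs}, \code{n_subjects}, plus the underlying lme4 fit.
#' @export
fit_lmem <- function(scans, subjects, roi,
                     grouping = c("group", "tau_level", "diagnostic_x_tau"),
                     reference_group = NULL,
                     covariates = c("apoe4", "age", "sex", "ctl"),
                     method = "none", REML = TRUE) {
  grouping <- match.arg(grouping)
  d <- scans[scans$roi == roi & scans$method == method, , drop = FALSE]
  if (nrow(d) == 0) stop("no scans for roi ", roi, " / method ", method)
  if (any(d$suvr <= 0)) stop("SUVR must be > 0 for the log transform")
  si <- match(d$subject_id, subjects$subject_id)
  if (anyNA(si)) stop("scan subjects missing from subject table")

  grp <- switch(grouping,
    group = subjects$group[si],
    tau_level = subjects$tau_level[si],
    diagnostic_x_tau = paste(subjects$group[si], subjects$tau_level[si],
                             sep = ":"))
  if (anyNA(grp)) stop("missing grouping value for some subjects")
  grp <- factor(grp)
  if (is.null(reference_group))
    reference_group <- if ("CU" %in% levels(grp)) "CU" else levels(grp)[1]
  if (!reference_group %in% levels(grp))
    stop("reference group ", reference_group, " not present")
  grp <- stats::relevel(grp, ref = reference_group)

  # every slope cell needs at least two distinct times
  for (g in levels(grp)) {
    if (length(unique(d$time_years[grp == g])) < 2)
      stop("design cell '", g, "' has fewer than two distinct times; ",
           "the interaction is not estimable")
  }

  df <- data.frame(
    lnsuvr = log(d$suvr),
    time = d$time_years,
    grp = grp,
    subject_id = factor(d$subject_id),
    age = subjects$age_years[si] - 70,
    sex = factor(subjects$sex[si]),
    apoe4 = factor(subjects$apoe4[si],
                   levels = c("noncarrier", "carrier", "unknown")),
    ctl = subjects$centiloid[si] - 80)
  df$apoe4 <- droplevels(df$apoe4)

  terms <- character(0)
  if ("apoe4" %in% covariates && nlevels(df$apoe4) > 1) terms <- c(terms, "apoe4")
  if ("age" %in% covariates) terms <- c(terms, "age")
  if ("sex" %in% covariates && nlevels(df$sex) > 1) terms <- c(terms, "sex")
  if ("ctl" %in% covariates) {
    if (anyNA(df$ctl))
      stop("centiloid missing for some subjects; drop 'ctl' from covariates")
    terms <- c(terms, "ctl")
  }
  rhs <- paste(c(terms, "time * grp",
                 "(1 | subject_id)", "(0 + time | subject_id)"),
               collapse = " + ")
  form <- stats::as.formula(paste("lnsuvr ~", rhs))

  fit <- lme4::lmer(form, data = df, REML = REML,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore", calc.derivs = FALSE))
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) || length(msgs) == 0
  if (!converged)
    warning("lmer convergence messages: ", paste(msgs, collapse = "; "))

  co <- as.data.frame(summary(fit)$coefficients)
  beta <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                     se = co[, "Std. Error"],
                     t = co[, "Estimate"] / co[, "Std. Error"],
                     row.names = NULL)

  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u <- vc$sdcor[vc$grp == "subject_id" & vc$var1 == "(Intercept)"]
  sigma_v <- vc$sdcor[grepl("^subject_id", vc$grp) & vc$var1 == "time" &
                        is.na(vc$var2)]
  sig <- stats::sigma(fit)

  re <- lme4::ranef(fit)
  u <- v <- stats::setNames(numeric(nlevels(df$subject_id)),
                            levels(df$subject_id))
  for (el in seq_along(re)) {
    r <- re[[el]]
    if ("(Intercept)" %in% colnames(r)) u[rownames(r)] <- r[, "(Intercept)"]
    if ("time" %in% colnames(r)) v[rownames(r)] <- r[, "time"]
  }
  blups <- data.frame(subject_id = names(u), u = unname(u), v = unname(v),
                      row.names = NULL)

  # fixed group slopes: reference slope plus interaction offsets
  bvec <- stats::setNames(beta$estimate, beta$term)
  slopes <- stats::setNames(rep(bvec[["time"]], nlevels(grp)), levels(grp))
  for (g in setdiff(levels(grp), reference_group)) {
    term <- paste0("time:grp", g)
    if (!term %in% names(bvec)) stop("missing interaction term ", term)
    slopes[g] <- slopes[g] + bvec[[term]]
  }

  subj_grp <- stats::setNames(as.character(grp), as.character(df$subject_id))
  structure(list(beta = beta, sigma = sig, sigma_u = sigma_u,
                 sigma_v = sigma_v, blups = blups, group_slopes = slopes,
                 subject_groups = subj_grp[!duplicated(names(subj_grp))],
                 reference_group = reference_group,
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = converged, n_obs = nrow(df),
                 n_subjects = nlevels(df$subject_id),
                 roi = roi, pvc_method = method, grouping = grouping,
                 fit = fit, data = df),
            class = "LmemFit")
}

#' @export
print.LmemFit <- function(x, ...) {
  cat(sprintf("LmemFit roi=%s method=%s: %d obs / %d subjects\n",
              x$roi, x$pvc_method, x$n_obs, x$n_subjects))
  cat(sprintf("  sigma=%.4f sigma_u=%.4f sigma_v=%.4f (%%CV=%.2f)\n",
              x$sigma, x$sigma_u, x$sigma_v, residual_pct_cv(x$sigma)))
  cat("  group slopes (%/yr):\n")
  print(round(annualized_pct_from_slope(x$group_slopes), 3))
  invisible(x)
}

#' Residual percent coefficient of variation
#'
#' Within-subject variability implied by the ln-scale residual SD:
#' \code{100 * sqrt(exp(sigma^2) - 1)}, approximately \code{100 * sigma}
#' for small sigma.
#'
#' @param sigma nonnegative residual SD on the ln scale.
#' @return percent CV.
#' @export
residual_pct_cv <- function(sigma) {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  100 * sqrt(exp(sigma^2) - 1)
}

#' Annualized percent change from an ln-scale slope
#'
#' \code{100 * (exp(b) - 1)}.
#'
#' @param slope_ln_per_year ln-scale slope(s) per year.
#' @return percent change per year.
#' @export
annualized_pct_from_slope <- function(slope_ln_per_year) {
  100 * (exp(slope_ln_per_year) - 1)
}

#' Group-separation t-scores from the time-by-group interaction
#'
#' For every non-reference group the interaction coefficient estimates the
#' slope difference against the reference; its t-score (estimate / SE,
#' normal approximation with the 1.96 significance threshold) measures
#' longitudinal separability and can be read as a longitudinal Cohen's d.
#'
#' @param fit LmemFit.
#' @return data.frame: contrast, estimate (ln slope difference), se,
#'   t_score, significant (\code{t_score > 1.96}).
#' @export
interaction_tscores <- function(fit) {
  stopifnot(inherits(fit, "LmemFit"))
  if (!fit$converged) warning("fit did not converge cleanly")
  rows <- fit$beta[grepl("^time:grp", fit$beta$term), , drop = FALSE]
  if (nrow(rows) == 0) stop("no interaction coefficients in fit")
  data.frame(contrast = paste0(sub("^time:grp", "", rows$term), " vs ",
                               fit$reference_group),
             group = sub("^time:grp", "", rows$term),
             estimate = rows$estimate, se = rows$se, t_score = rows$t,
             significant = rows$t > 1.96, row.names = NULL)
}

#' Per-subject annualized percent change from the fitted model
#'
#' Each subject's ln slope is the fixed slope of their group plus their
#' random-slope BLUP; covariates shift intercepts only, so they do not
#' enter. The slope is transformed to percent per year.
#'
#' @param fit LmemFit.
#' @param subject_ids subjects to report (default: all in the fit).
#' @return named numeric vector, subject -> percent per year.
#' @export
subject_annualized_changes <- function(fit, subject_ids = NULL) {
  stopifnot(inherits(fit, "LmemFit"))
  if (is.null(subject_ids)) subject_ids <- fit$blups$subject_id
  missing <- setdiff(subject_ids, fit$blups$subject_id)
  if (length(missing))
    stop("subject(s) absent from fit: ", paste(missing, collapse = ", "))
  idx <- match(subject_ids, fit$blups$subject_id)
  g <- fit$subject_groups[subject_ids]
  slopes <- fit$group_slopes[g] + fit$blups$v[idx]
  stats::setNames(annualized_pct_from_slope(slopes), subject_ids)
}

#' Longitudinal effect size
#'
#' Mean annualized percent change divided by its standard deviation.
#'
#' @param changes numeric vector (length >= 2) of percent changes.
#' @return scalar effect size.
#' @export
longitudinal_effect_size <- function(changes) {
  if (length(changes) < 2) stop("need at least 2 values")
  s <- stats::sd(changes)
  if (s == 0) stop("zero standard deviation: effect size undefined")
  mean(changes) / s
}

#' Bootstrap confidence interval
#'
#' Two resampling flavours. \code{method = "parametric"} draws fixed-effect
#' vectors from \code{N(beta_hat, Vbeta_hat)} (posterior simulation of the
#' fitted model) and recomputes the statistic per draw;
#' \code{statistic_fn} receives the named coefficient vector.
#' \code{method = "subject"} resamples elements (subjects) of \code{data}
#' with replacement; \code{statistic_fn} receives the resampled vector.
#' Percentile 95\% intervals; deterministic per seed.
#'
#' @param statistic_fn function of one argument returning a scalar.
#' @param fit LmemFit (required for parametric draws).
#' @param data numeric vector of per-subject values (for subject draws).
#' @param n_draws number of draws (default 1000).
#' @param seed RNG seed.
#' @param method "parametric" or "subject".
#' @return named numeric vector: mean, lo95, hi95.
#' @export
bootstrap_ci <- function(statistic_fn, fit = NULL, data = NULL,
                         n_draws = 1000, seed = 1L,
                         method = c("parametric", "subject")) {
  method <- match.arg(method)
  if (n_draws < 1) stop("n_draws must be >= 1")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  stats_out <- numeric(n_draws)
  if (method == "parametric") {
    stopifnot(inherits(fit, "LmemFit"))
    beta_hat <- stats::setNames(fit$beta$estimate, fit$beta$term)
    V <- as.matrix(stats::vcov(fit$fit))
    # draw via Cholesky of the coefficient covariance
    R <- chol(V + diag(1e-14, nrow(V)))
    for (b in seq_len(n_draws)) {
      draw <- beta_hat + as.vector(t(R) %*% stats::rnorm(length(beta_hat)))
      names(draw) <- names(beta_hat)
      val <- tryCatch(statistic_fn(draw), error = function(e)
        stop("statistic_fn failed at draw ", b, ": ", conditionMessage(e)))
      stats_out[b] <- val
    }
  } else {
    if (is.null(data)) stop("data required for subject bootstrap")
    n <- if (is.data.frame(data)) nrow(data) else length(data)
    for (b in seq_len(n_draws)) {
      idx <- sample.int(n, n, replace = TRUE)
      resampled <- if (is.data.frame(data)) data[idx, , drop = FALSE]
        else data[idx]
      val <- tryCatch(statistic_fn(resampled), error = function(e)
        stop("statistic_fn failed at draw ", b, ": ", conditionMessage(e)))
      stats_out[b] <- val
    }
  }
  # draws where the statistic is undefined (e.g. degenerate resamples) are
  # dropped from the percentile interval
  qs <- stats::quantile(stats_out, c(0.025, 0.975), names = FALSE,
                        na.rm = TRUE)
  c(mean = mean(stats_out, na.rm = TRUE), lo95 = qs[1], hi95 = qs[2])
}

#' Spearman correlation between baseline SUVR and annualized change
#'
#' Tie-corrected rank correlation with a subject-resampling bootstrap CI.
#'
#' @param baseline named numeric vector, subject -> baseline SUVR.
#' @param change named numeric vector, subject -> percent change per year.
#' @param n_draws bootstrap draws (default 1000).
#' @param seed RNG seed.
#' @return list: rho, lo95, hi95, n.
#' @export
spearman_baseline_vs_change <- function(baseline, change, n_draws = 1000,
                                        seed = 1L) {
  ids <- intersect(names(baseline), names(change))
  if (length(ids) < 3) stop("need at least 3 paired subjects")
  x <- baseline[ids]; y <- change[ids]
  rho <- stats::cor(x, y, method = "spearman")
  pairs <- data.frame(x = x, y = y)
  ci <- bootstrap_ci(function(d) {
    if (length(unique(d$x)) < 2 || length(unique(d$y)) < 2) return(NA_real_)
    stats::cor(d$x, d$y, method = "spearman")
  }, data = pairs, n_draws = n_draws, seed = seed, method = "subject")
  list(rho = rho, lo95 = unname(ci["lo95"]), hi95 = unname(ci["hi95"]),
       n = length(ids))
}

#' Evaluate PVC methods on the within-subject variability vs separability plane
#'
#' Fits one mixed model per (method, ROI), extracts the residual percent CV
#' (within-subject variability) and the group-separation t-score for every
#' contrast, and flags dominance: method A dominates B for a given (ROI,
#' contrast) when it has both a smaller residual \%CV and a larger t-score.
#'
#' @param scan_tables a scan table carrying a \code{method} column with one
#'   or more PVC method tags (or a list of such tables, rbind-ed).
#' @param subjects subject covariate table.
#' @param rois ROI names to evaluate.
#' @param grouping,reference_group,covariates passed to
#'   \code{\link{fit_lmem}}.
#' @return object of class \code{MethodEvaluation}: \code{rows}
#'   (method, roi, contrast, residual_pct_cv, t_score, significant),
#'   \code{dominance} (pairwise counts), \code{failures}.
#' @export
evaluate_methods <- function(scan_tables, subjects, rois = c("TMP", "WCG"),
                             grouping = "group", reference_group = NULL,
                             covariates = c("apoe4", "age", "sex", "ctl")) {
  scans <- if (is.data.frame(scan_tables)) scan_tables
    else do.call(rbind, scan_tables)
  methods <- unique(scans$method)
  rows <- list(); failures <- list()
  for (m in methods) {
    for (r in rois) {
      res <- tryCatch({
        f <- fit_lmem(scans, subjects, r, grouping = grouping,
                      reference_group = reference_group,
                      covariates = covariates, method = m)
        ts <- interaction_tscores(f)
        data.frame(method = m, roi = r, contrast = ts$contrast,
                   residual_pct_cv = residual_pct_cv(f$sigma),
                   t_score = ts$t_score, significant = ts$significant,
                   row.names = NULL)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[paste(m, r, sep = "/")]] <- conditionMessage(res)
      } else rows[[length(rows) + 1L]] <- res
    }
  }
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(method = character(), roi = character(),
               contrast = character(), residual_pct_cv = numeric(),
               t_score = numeric(), significant = logical())

  dom <- list()
  if (nrow(rows)) {
    cells <- unique(rows[, c("roi", "contrast")])
    for (i in seq_len(nrow(cells))) {
      cell <- rows[rows$roi == cells$roi[i] &
                     rows$contrast == cells$contrast[i], ]
      for (a in cell$method) for (b in setdiff(cell$method, a)) {
        ra <- cell[cell$method == a, ]; rb <- cell[cell$method == b, ]
        dom[[length(dom) + 1L]] <- data.frame(
          roi = cells$roi[i], contrast = cells$contrast[i],
          method = a, over = b,
          dominates = ra$residual_pct_cv < rb$residual_pct_cv &
            ra$t_score > rb$t_score, row.names = NULL)
      }
    }
  }
  dominance <- if (length(dom)) do.call(rbind, dom) else NULL
  structure(list(rows = rows, dominance = dominance, failures = failures),
            class = "MethodEvaluation")
}

#' @export
print.MethodEvaluation <- function(x, ...) {
  cat("MethodEvaluation:", nrow(x$rows), "rows,",
      length(x$failures), "failures\n")
  print(utils::head(x$rows, 12))
  invisible(x)
}
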