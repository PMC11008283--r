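# Small helper: cohort with overridden variance components
cfg_with <- function(sigma = 0.03, sigma_u = NULL, sigma_v = NULL,
                     seed = 1, groups = NULL, n = NULL, jitter = TRUE,
                     retention = TRUE) {
  cfg <- nhs_default_config(seed = seed)
  if (!is.null(groups)) cfg$groups <- cfg$groups[groups]
  for (g in names(cfg$groups)) {
    if (!is.null(sigma_u)) cfg$groups[[g]]$sigma_u <- sigma_u
    if (!is.null(sigma_v)) cfg$groups[[g]]$sigma_v <- sigma_v
    if (!is.null(n)) cfg$groups[[g]]$n <- n
  }
  cfg$sigma <- sigma
  if (!jitter) cfg$visit_jitter_sd_weeks[] <- 0
  if (!retention) cfg$retention[] <- 1
  cfg
}

test_that("noise-free cohorts are recovered exactly", {
  cfg <- cfg_with(sigma = 1e-8, sigma_u = 1e-8, sigma_v = 1e-8, seed = 9,
                  jitter = FALSE, retention = FALSE)
  ch <- generate_cohort(cfg)
  f <- suppressWarnings(fit_lmem(ch$scans, ch$subjects, "WCG"))
  for (g in names(cfg$groups)) {
    expect_equal(unname(f$group_slopes[g]),
                 unname(cfg$groups[[g]]$slope_lnsuvr[["WCG"]]),
                 tolerance = 1e-6, label = g)
  }
  expect_lt(f$sigma, 1e-4)
})

test_that("fixed effects match a closed-form GLS oracle on a balanced
           design", {
  # two groups, two visits, no covariates in the model
  set.seed(21)
  n <- 15
  subj <- data.frame(
    subject_id = sprintf("S%02d", 1:(2 * n)),
    group = rep(c("CU", "prodromal"), each = n),
    tau_level = "CU", age_years = 70, sex = "F", apoe4 = "noncarrier",
    centiloid = 80)
  times <- c(0, 1)
  mk <- function(id, g) {
    u <- rnorm(1, 0, 0.1); v <- rnorm(1, 0, 0.01)
    b <- if (g == "CU") -0.01 else 0.02
    data.frame(subject_id = id, study = "NHS", group = g, tau_level = "CU",
               visit_week = times * 52.1775, time_years = times,
               method = "none", roi = "WCG",
               suvr = exp(0.2 + u + (b + v) * times +
                            rnorm(2, 0, 0.03)))
  }
  scans <- do.call(rbind, Map(mk, subj$subject_id, subj$group))
  f <- fit_lmem(scans, subj, "WCG", covariates = character(0))

  # GLS at the fitted variance components, assembled independently
  su2 <- f$sigma_u^2; sv2 <- f$sigma_v^2; s2 <- f$sigma^2
  Vi <- matrix(su2, 2, 2) + outer(times, times) * sv2 + diag(s2, 2)
  Wi <- solve(Vi)
  XtWX <- matrix(0, 4, 4); XtWy <- numeric(4)
  for (id in subj$subject_id) {
    d <- scans[scans$subject_id == id, ]
    d <- d[order(d$time_years), ]
    g <- subj$group[subj$subject_id == id]
    # columns: intercept, grp=prodromal, time, time:grp
    Xi <- cbind(1, as.numeric(g == "prodromal"), times,
                times * (g == "prodromal"))
    XtWX <- XtWX + t(Xi) %*% Wi %*% Xi
    XtWy <- XtWy + t(Xi) %*% Wi %*% log(d$suvr)
  }
  beta_gls <- solve(XtWX, XtWy)
  got <- stats::setNames(f$beta$estimate, f$beta$term)
  expect_equal(unname(got[c("(Intercept)", "grpprodromal", "time",
                            "time:grpprodromal")]),
               as.vector(beta_gls), tolerance = 1e-6)
})

test_that("residual %CV closed form and small-sigma approximation", {
  expect_identical(residual_pct_cv(0), 0)
  expect_equal(residual_pct_cv(0.03), 3.000675, tolerance = 1e-6)
  for (s in c(0.01, 0.03, 0.05))
    expect_lt(abs(residual_pct_cv(s) - 100 * s), 0.05)
  expect_error(residual_pct_cv(-0.01), ">= 0")
})

test_that("annualized percent change from slope", {
  expect_identical(annualized_pct_from_slope(0), 0)
  expect_equal(annualized_pct_from_slope(log(1.05)), 5)
  expect_equal(annualized_pct_from_slope(0.0296), 3.00425, tolerance = 1e-5)
})

test_that("interaction t-scores: sign, null calibration and power", {
  # sign: larger group slope than reference gives positive t (near noise-free)
  cfg <- cfg_with(sigma = 1e-6, sigma_u = 1e-6, sigma_v = 1e-6, seed = 2,
                  groups = c("CU", "prodromal"))
  ch <- generate_cohort(cfg)
  f <- suppressWarnings(fit_lmem(ch$scans, ch$subjects, "WCG"))
  ts <- interaction_tscores(f)
  expect_gt(ts$t_score[ts$group == "prodromal"], 0)
  expect_identical(ts$significant, ts$t_score > 1.96)

  # null: identical configured slopes -> |t| < 1.96 in >= 90% of replicates
  null_t <- sapply(1:25, function(s) {
    cfg <- cfg_with(seed = 200 + s, groups = c("CU", "prodromal"), n = 40,
                    sigma_u = 0.1, sigma_v = 0.01)
    cfg$groups$prodromal$slope_lnsuvr <- cfg$groups$CU$slope_lnsuvr
    cfg$groups$prodromal$baseline_lnsuvr <- cfg$groups$CU$baseline_lnsuvr
    ch <- generate_cohort(cfg)
    f <- fit_lmem(ch$scans, ch$subjects, "WCG")
    interaction_tscores(f)$t_score
  })
  expect_gte(mean(abs(null_t) < 1.96), 0.9)

  # power: slope difference 0.02/yr, sigma 0.03, 50/group, 4 visits
  pow_t <- sapply(1:20, function(s) {
    cfg <- cfg_with(seed = 400 + s, groups = c("CU", "prodromal"), n = 50,
                    sigma = 0.03, sigma_u = 0.1, sigma_v = 0.01,
                    retention = FALSE)
    cfg$groups$prodromal$slope_lnsuvr[] <-
      cfg$groups$CU$slope_lnsuvr + 0.02
    ch <- generate_cohort(cfg)
    f <- fit_lmem(ch$scans, ch$subjects, "WCG")
    interaction_tscores(f)$t_score
  })
  expect_gt(mean(pow_t > 1.96), 0.5)
})

test_that("per-subject changes come from group slope + BLUP", {
  # near noise-free residuals, real slope heterogeneity: BLUPs recover v_i
  cfg <- cfg_with(sigma = 1e-6, sigma_u = 0.05, sigma_v = 0.01, seed = 13,
                  groups = c("CU", "prodromal"), jitter = FALSE,
                  retention = FALSE)
  ch <- generate_cohort(cfg)
  f <- suppressWarnings(fit_lmem(ch$scans, ch$subjects, "WCG"))
  got <- subject_annualized_changes(f)
  tr <- ch$truth$per_subject
  expected <- sapply(seq_len(nrow(tr)), function(i)
    annualized_pct_from_slope(
      cfg$groups[[tr$group[i]]]$slope_lnsuvr[["WCG"]] + tr$v[i]))
  expect_equal(unname(got[tr$subject_id]), expected, tolerance = 1e-4)
  # BLUPs average ~0 within each group, so group mean ~ fixed value
  for (g in c("CU", "prodromal")) {
    ids <- ch$subjects$subject_id[ch$subjects$group == g]
    expect_equal(mean(f$blups$v[match(ids, f$blups$subject_id)]), 0,
                 tolerance = 5e-3)
  }
  expect_error(subject_annualized_changes(f, "nope"), "absent")
})

test_that("zero random-slope variance collapses subjects onto the group
           value", {
  cfg <- cfg_with(sigma = 0.02, sigma_u = 0.05, sigma_v = 0, seed = 14,
                  groups = c("CU", "prodromal"))
  ch <- generate_cohort(cfg)
  f <- fit_lmem(ch$scans, ch$subjects, "WCG")
  if (f$sigma_v < 1e-8) {  # boundary fit reached, BLUPs all zero
    got <- subject_annualized_changes(f)
    for (g in c("CU", "prodromal")) {
      ids <- ch$subjects$subject_id[ch$subjects$group == g]
      expect_lt(diff(range(got[ids])), 1e-10)
    }
  } else succeed("variance not estimated at boundary for this seed")
})

test_that("longitudinal effect size definition and invariances", {
  expect_equal(longitudinal_effect_size(c(1, 2, 3)), 2)
  x <- rnorm(20, 2, 1)
  expect_equal(longitudinal_effect_size(3 * x), longitudinal_effect_size(x))
  expect_error(longitudinal_effect_size(c(1, 1)), "zero standard deviation")
  expect_error(longitudinal_effect_size(1), "at least 2")
})

test_that("bootstrap is seeded, degenerate-safe and calibrated", {
  cfg <- cfg_with(seed = 3, groups = c("CU", "prodromal"))
  ch <- generate_cohort(cfg)
  f <- fit_lmem(ch$scans, ch$subjects, "WCG")
  stat <- function(b) annualized_pct_from_slope(b[["time"]])
  ci1 <- bootstrap_ci(stat, fit = f, n_draws = 200, seed = 42)
  ci2 <- bootstrap_ci(stat, fit = f, n_draws = 200, seed = 42)
  expect_identical(ci1, ci2)

  # degenerate data: zero-width interval
  ci0 <- bootstrap_ci(mean, data = rep(2, 10), n_draws = 100, seed = 1,
                      method = "subject")
  expect_identical(unname(ci0["hi95"] - ci0["lo95"]), 0)

  # coverage of the subject bootstrap for a normal mean
  hits <- sapply(1:500, function(r) {
    set.seed(9000 + r)
    x <- rnorm(60, 5, 1)
    ci <- bootstrap_ci(mean, data = x, n_draws = 300, seed = r,
                       method = "subject")
    ci["lo95"] <= 5 && 5 <= ci["hi95"]
  })
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.98)
})

test_that("spearman correlation handles perfect, tied and bootstrap cases", {
  b <- stats::setNames(1:6, paste0("s", 1:6))
  expect_equal(spearman_baseline_vs_change(b, b^2, n_draws = 50)$rho, 1)
  expect_equal(spearman_baseline_vs_change(b, -b, n_draws = 50)$rho, -1)
  x <- stats::setNames(c(1, 2, 3, 4), letters[1:4])
  y <- stats::setNames(c(2, 1, 4, 3), letters[1:4])
  expect_equal(spearman_baseline_vs_change(x, y, n_draws = 50)$rho, 0.6)
  expect_error(spearman_baseline_vs_change(x[1:2], y[1:2]), "at least 3")
})

test_that("evaluate_methods: identical tables give identical rows, inflated
           noise raises %CV", {
  ch <- generate_cohort(nhs_default_config(seed = 6))
  a <- ch$scans
  b <- ch$scans; b$method <- "vc"
  ev <- evaluate_methods(rbind(a, b), ch$subjects, rois = "WCG")
  ra <- ev$rows[ev$rows$method == "none", -1]
  rb <- ev$rows[ev$rows$method == "vc", -1]
  rownames(ra) <- rownames(rb) <- NULL
  expect_equal(ra, rb)

  # method with extra multiplicative noise: strictly larger residual %CV
  set.seed(11)
  noisy <- ch$scans
  noisy$method <- "rbv"
  noisy$suvr <- noisy$suvr * exp(rnorm(nrow(noisy), 0, 0.03))
  ev2 <- evaluate_methods(rbind(a, noisy), ch$subjects, rois = "WCG")
  cv <- tapply(ev2$rows$residual_pct_cv, ev2$rows$method, unique)
  expect_gt(cv[["rbv"]], cv[["none"]])
  dom <- ev2$dominance
  expect_true(all(!dom$dominates[dom$method == "rbv"] |
                    ev2$rows$t_score[ev2$rows$method == "rbv"] >
                      ev2$rows$t_score[ev2$rows$method == "none"]))
})

test_that("empty design cells and missing covariates are caught", {
  ch <- generate_cohort(nhs_default_config(seed = 8))
  scans1 <- ch$scans[ch$scans$subject_id %in%
    c(ch$subjects$subject_id[ch$subjects$group != "CU"],
      ch$subjects$subject_id[ch$subjects$group == "CU"][1]), ]
  # keep only the baseline visit for the lone CU subject: slope cell broken
  cu1 <- ch$subjects$subject_id[ch$subjects$group == "CU"][1]
  scans1 <- scans1[!(scans1$subject_id == cu1 & scans1$time_years > 0), ]
  expect_error(fit_lmem(scans1, ch$subjects, "WCG"), "fewer than two")

  subj2 <- ch$subjects
  subj2$centiloid[3] <- NA
  expect_error(fit_lmem(ch$scans, subj2, "WCG"), "centiloid missing")
  expect_silent({
    f <- fit_lmem(ch$scans, subj2, "WCG",
                  covariates = c("apoe4", "age", "sex"))
  })
})

test_that("dropping one group leaves the other groups' slopes unchanged on
           a balanced design", {
  cfg <- cfg_with(sigma = 1e-6, sigma_u = 1e-6, sigma_v = 1e-6, seed = 16,
                  jitter = FALSE, retention = FALSE)
  ch <- generate_cohort(cfg)
  f_all <- suppressWarnings(fit_lmem(ch$scans, ch$subjects, "WCG"))
  keep <- ch$subjects$group != "mild"
  f_sub <- suppressWarnings(fit_lmem(
    ch$scans[ch$scans$subject_id %in% ch$subjects$subject_id[keep], ],
    ch$subjects[keep, ], "WCG"))
  for (g in c("CU", "prodromal", "moderate"))
    expect_equal(unname(f_all$group_slopes[g]),
                 unname(f_sub$group_slopes[g]), tolerance = 1e-6)
})
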