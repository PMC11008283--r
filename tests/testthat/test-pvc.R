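delta <- psf_model(0)

test_that("Meltzer: delta identity, uniform whole-volume mask, and
           spherical recovery", {
  truth <- shell_phantom()
  lv <- truth$label_volume
  img <- paint_activity(truth)
  brain <- label_mask(lv, c("gm", "white_matter", "cerebellum_reference"))

  r <- pvc_meltzer(img, brain, delta, labels = lv)
  expect_equal(r$corrected_image$values[brain], img$values[brain])

  u <- activity_volume(array(1.5, dim = dim(img$values)), 2)
  whole <- array(TRUE, dim = dim(img$values))
  r2 <- pvc_meltzer(u, whole, psf_model(8))
  # with zero padding the eigenfunction identity holds away from the
  # volume boundary (kernel radius 7 voxels at 8 mm FWHM / 2 mm voxels)
  core <- 9:56
  expect_equal(r2$corrected_image$values[core, core, core],
               array(1.5, dim = rep(length(core), 3)), tolerance = 1e-9)

  # uniform sphere A=1.5 in zero background: central region recovered
  labs <- array(0L, dim = c(64, 64, 64))
  ax <- (1:64 - 0.5) * 2 - 64
  r2d <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  labs[r2d <= 30^2] <- 2L
  labs[r2d <= 5^2] <- 3L
  lvs <- label_volume(labs, 2, c(background = 0L, csf = 1L,
                                 white_matter = 2L,
                                 cerebellum_reference = 3L))
  sphere <- activity_volume(array(1.5 * (labs > 0), dim = dim(labs)), 2)
  blurred <- apply_psf(sphere, psf_model(8))
  central <- r2d <= 15^2
  expect_lt(mean(blurred$values[central &
                   label_mask(lvs, "white_matter")]) , 1.5)
  rc <- pvc_meltzer(blurred, labs > 0, psf_model(8))
  got <- mean(rc$corrected_image$values[central])
  expect_lt(abs(got - 1.5) / 1.5, 0.01)
  # whole-sphere uncorrected mean is biased low
  expect_lt(mean(blurred$values[labs > 0]), 1.5 * 0.95)

  expect_error(pvc_meltzer(img, array(FALSE, dim = dim(img$values)), delta),
               "empty")
})

test_that("Mueller-Gartner: delta identity, shell recovery within 2%,
           and null GM signal", {
  truth <- shell_phantom()
  lv <- truth$label_volume
  img <- paint_activity(truth)
  gm <- label_mask(lv, "gm")
  wm <- label_mask(lv, c("white_matter", "cerebellum_reference"))

  r0 <- pvc_muller_gartner(img, gm, wm, delta, labels = lv)
  expect_equal(r0$corrected_image$values[gm], img$values[gm],
               tolerance = 1e-9)
  expect_equal(r0$diagnostics$wm_estimate, 1)

  blurred <- apply_psf(img, psf_model(8))
  r <- pvc_muller_gartner(blurred, gm, wm, psf_model(8), labels = lv)
  expect_lt(abs(r$regional_values$gm - 2) / 2, 0.02)
  # uncorrected is biased low by at least 10%
  expect_lt(mean(blurred$values[gm]), 2 * 0.9)

  # GM activity 0, WM 1: corrected GM mean ~ 0
  truth0 <- shell_phantom(gm = 0, wm = 1)
  b0 <- apply_psf(paint_activity(truth0), psf_model(8))
  rn <- pvc_muller_gartner(b0, gm, wm, psf_model(8), labels = lv)
  expect_lt(abs(rn$regional_values$gm), 0.05)

  expect_error(pvc_muller_gartner(img, gm, gm, delta), "disjoint")
  expect_error(pvc_muller_gartner(img, gm, array(FALSE, dim = dim(gm)),
                                  delta, wm_erosion_shells = 1), "empty")
})

test_that("van Cittert: delta identity, uniform fixed point, monotone
           residuals and agreement with the FFT oracle", {
  img <- paint_activity(shell_phantom())
  r0 <- pvc_van_cittert(img, delta, alpha = 1.3, n_iterations = 5)
  expect_identical(r0$corrected_image$values, img$values)
  expect_equal(r0$diagnostics$residual_norms[1], 0)

  u <- activity_volume(array(2, dim = c(40, 40, 40)), 2)
  ru <- pvc_van_cittert(u, psf_model(6), alpha = 1, n_iterations = 2, tol = 0)
  core <- 15:26  # boundary influence travels one kernel radius per iteration
  expect_equal(ru$corrected_image$values[core, core, core],
               u$values[core, core, core], tolerance = 1e-9)

  # two-box phantom blurred at 6 mm
  a <- array(0, dim = c(40, 40, 40))
  a[8:18, 10:30, 10:30] <- 1
  a[24:34, 10:30, 10:30] <- 2
  pet <- activity_volume(psf_blur(a, 2, psf_model(6)), 2)
  r <- pvc_van_cittert(pet, psf_model(6), alpha = 1.5, n_iterations = 30,
                       tol = 0)
  rn <- r$diagnostics$residual_norms
  expect_true(all(diff(rn) <= 1e-9 * rn[1]))
  # ROI means closer to truth than the blurred means
  box1 <- array(FALSE, dim = dim(a)); box1[8:18, 10:30, 10:30] <- TRUE
  expect_lt(abs(mean(r$corrected_image$values[box1]) - 1),
            abs(mean(pet$values[box1]) - 1))

  # independent oracle: the same iteration coded directly on the FFT route
  f <- pet$values
  for (k in 1:5) f <- pmax(f + 1.5 * (pet$values -
    psf_blur(f, 2, psf_model(6), method = "fft")), 0)
  r5 <- pvc_van_cittert(pet, psf_model(6), alpha = 1.5, n_iterations = 5,
                        tol = 0)
  expect_lt(max(abs(r5$corrected_image$values - f)), 1e-8)

  expect_error(pvc_van_cittert(img, delta, alpha = 3), "alpha")
})

test_that("GTM: identity under delta PSF, partition-of-unity rows, and
           the brute-force integration oracle", {
  lv <- three_region_volume()
  g0 <- build_gtm(lv, delta)
  expect_equal(g0$W, diag(3), ignore_attr = TRUE)

  psf <- psf_model(6)
  g <- build_gtm(lv, psf)
  # brute-force oracle on the independent FFT route
  for (j in seq_along(g$region_names)) {
    ind <- array(0, dim = dim(lv$labels))
    ind[lv$labels == lv$label_map[[g$region_names[j]]]] <- 1
    sm <- psf_blur(ind, lv$voxel_size_mm, psf, method = "fft")
    for (i in seq_along(g$region_names)) {
      sel <- lv$labels == lv$label_map[[g$region_names[i]]]
      expect_lt(abs(g$W[i, j] - sum(sm[sel]) / sum(sel)), 1e-9)
    }
  }

  # partition-of-unity under the zero-padding dialect: row sums match the
  # blurred all-regions indicator, never exceed 1, and approach 1 for
  # regions buried inside the tiling; column sums never exceed 1
  ones <- array(0, dim = dim(lv$labels))
  ones[lv$labels != 0L] <- 1
  sm1 <- psf_blur(ones, lv$voxel_size_mm, psf)
  for (i in seq_along(g$region_names)) {
    sel <- lv$labels == lv$label_map[[g$region_names[i]]]
    expect_lt(abs(sum(g$W[i, ]) - mean(sm1[sel])), 1e-9)
  }
  expect_true(all(rowSums(g$W) <= 1 + 1e-9))
  # mass conservation per source region: the count-weighted column sum
  # (mass of region j observed across all regions) never exceeds region
  # j's own mass; the deficit is mass leaving the volume
  cnt <- g$region_counts
  for (j in seq_along(g$region_names))
    expect_lte(sum(cnt * g$W[, j]), cnt[j] * (1 + 1e-6))
  # innermost region sits ~4 sigma inside the tiling: row sum ~ 1
  expect_lt(abs(sum(g$W[3, ]) - 1), 1e-3)

  expect_error(build_gtm(lv, psf, condition_cap = 1), "ill conditioned")
})

test_that("GTM solve: delta identity, exact phantom recovery, zeros in
           zeros out", {
  truth <- default_phantom()
  lv <- truth$label_volume
  img <- paint_activity(truth)
  psf <- psf_model(8)

  gd <- build_gtm(lv, delta)
  rd <- pvc_gtm(img, gd, lv)
  obs <- rd$diagnostics$observed_means
  expect_equal(unlist(rd$regional_values), obs, tolerance = 1e-9)

  g <- build_gtm(lv, psf)
  blurred <- default_blurred8()
  r <- pvc_gtm(blurred, g, lv)
  tr <- truth$true_activity[g$region_names]
  expect_lt(max(abs(unlist(r$regional_values) - tr) / pmax(tr, 1e-9)), 1e-6)

  zero <- activity_volume(array(0, dim = dim(img$values)), 2)
  rz <- pvc_gtm(zero, g, lv)
  expect_lt(max(abs(unlist(rz$regional_values))), 1e-12)
})

test_that("RBV: delta identity, uniform single region, phantom means match
           GTM values", {
  truth <- default_phantom()
  lv <- truth$label_volume
  img <- paint_activity(truth)
  psf <- psf_model(8)

  g <- build_gtm(lv, delta)
  vals <- pvc_gtm(img, g, lv)$regional_values
  r0 <- pvc_rbv(img, lv, delta, vals)
  expect_equal(r0$corrected_image$values, img$values, tolerance = 1e-9)

  blurred <- default_blurred8()
  gv <- pvc_gtm(blurred, build_gtm(lv, psf), lv)$regional_values
  r <- pvc_rbv(blurred, lv, psf, gv)
  for (nm in truth$cortical_labels)
    expect_lt(abs(r$regional_values[[nm]] - gv[[nm]]) / gv[[nm]], 0.01)
})

test_that("all methods are invariant to global intensity scaling", {
  truth <- shell_phantom()
  lv <- truth$label_volume
  psf <- psf_model(8)
  pet <- apply_psf(paint_activity(truth), psf)
  pet3 <- activity_volume(3 * pet$values, 2)
  for (m in c("none", "meltzer", "mg", "vc", "gtm", "rbv")) {
    a <- unlist(run_pvc(m, pet, lv, psf)$regional_values)
    b <- unlist(run_pvc(m, pet3, lv, psf)$regional_values)
    expect_equal(b, 3 * a, tolerance = 1e-8, label = m)
  }
})
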