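# Fixtures are built in code at test time; heavier ones are memoized for the
# duration of the suite.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

default_phantom <- function() memo("default_phantom", make_brain_phantom())

default_blurred8 <- function() {
  memo("default_blurred8", {
    truth <- default_phantom()
    apply_psf(paint_activity(truth), psf_model(8))
  })
}

# Concentric shell phantom: GM shell (2.0) over WM core (1.0) in zero CSF,
# with a small reference blob buried in the WM centre. Used for the
# Meltzer / Mueller-Gartner recovery checks.
shell_phantom <- function(gm = 2, wm = 1, csf = 0, grid = 64, vox = 2) {
  ax <- (seq_len(grid) - 0.5) * vox - grid * vox / 2
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  labs <- array(0L, dim = rep(grid, 3))
  labs[r2 <= 34^2] <- 1L
  labs[r2 <= 30^2] <- 10L
  labs[r2 <= 22^2] <- 2L
  labs[r2 <= 5^2] <- 3L
  lv <- label_volume(labs, vox, c(background = 0L, csf = 1L,
                                  white_matter = 2L,
                                  cerebellum_reference = 3L, gm = 10L))
  phantom_truth(lv, c(background = 0, csf = csf, white_matter = wm,
                      cerebellum_reference = wm, gm = gm),
                cortical_labels = "gm")
}

# Tiny 3-region partition of a small cube (plus background margin) for GTM
# unit tests.
three_region_volume <- function(n = 30, vox = 2) {
  labs <- array(0L, dim = rep(n, 3))
  core <- 9:(n - 8)
  labs[core, core, core] <- 1L
  mid <- 12:(n - 11)
  labs[mid, mid, mid] <- 2L
  inner <- 14:(n - 13)
  labs[inner, inner, inner] <- 3L
  label_volume(labs, vox, c(background = 0L, csf = 1L, white_matter = 2L,
                            cerebellum_reference = 3L))
}

# NHS-preset config with all group sizes multiplied by k (used by the
# recovery acceptance test at the spec's n~500 operating point).
scaled_nhs_config <- function(seed, k = 8L) {
  cfg <- nhs_default_config(seed = seed)
  for (g in names(cfg$groups)) cfg$groups[[g]]$n <- cfg$groups[[g]]$n * k
  cfg
}

# pooled (variance-weighted) random-effect SD implied by per-group SDs
pooled_sd <- function(ns, sds) sqrt(sum(ns * sds^2) / sum(ns))

nhs_truth_slopes <- function(roi = "WCG") {
  cfg <- nhs_default_config()
  vapply(cfg$groups, function(g) g$slope_lnsuvr[[roi]], numeric(1))
}

# effect size robust to the zero-variance boundary (all BLUPs zero)
es_or_inf <- function(x) if (stats::sd(x) == 0) Inf else
  longitudinal_effect_size(x)

# Wald SE of a group slope from an LmemFit (linear combination of the
# reference slope and the interaction coefficient)
group_slope_se <- function(fit, group) {
  V <- as.matrix(stats::vcov(fit$fit))
  terms <- fit$beta$term
  it <- which(terms == "time")
  if (group == fit$reference_group) return(sqrt(V[it, it]))
  ig <- which(terms == paste0("time:grp", group))
  sqrt(V[it, it] + V[ig, ig] + 2 * V[it, ig])
}
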