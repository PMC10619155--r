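test_that("default prediction grids span the observed rate ranges", {
  g_tau <- neuropool:::default_grid("tau_suvr")
  expect_equal(range(g_tau), c(-0.42, 0.71))
  expect_equal(length(g_tau), 101)
  g_ct <- neuropool:::default_grid("cortical_thickness")
  expect_equal(range(g_ct), c(-0.26, 0.23))
})

test_that("all-zero draws give flat 1/3 curves with zero-width bands", {
  tc <- toy_cohort(n_roi = 4, n_net = 2, n = c(4, 2, 2), seed = 91)
  st <- structure_from_obs(1, tc$obs)
  fit0 <- fake_fit(st, matrix(0, 16, 4), tc$obs)
  cv <- posterior_curves(fit0, "global")
  expect_equal(cv$mean, rep(1 / 3, nrow(cv)), tolerance = 1e-12)
  expect_equal(cv$lo89, cv$hi89)
  expect_equal(cv$lo60, cv$hi60)
})

test_that("curves are simplex-normalized with nested credible bands", {
  sf4 <- small_fit4()
  cv <- posterior_curves(sf4$fit, "roi", id = 3)
  # means sum to 1 at every grid point
  sums <- tapply(cv$mean, cv$x_raw, sum)
  expect_lt(max(abs(sums - 1)), 1e-10)
  expect_true(all(cv$mean >= 0 & cv$mean <= 1))
  # 89% band contains the 60% band, bands contain the pointwise bounds
  expect_true(all(cv$lo89 <= cv$lo60 + 1e-12))
  expect_true(all(cv$hi89 >= cv$hi60 - 1e-12))
  expect_true(all(cv$lo60 <= cv$hi60))
  # grid is expressed in raw units and normalized internally
  expect_equal(cv$x_norm, cv$x_raw / sf4$fit$scale)
})

test_that("model 4 network curves equal ROI curves with deviations
           zeroed", {
  sf4 <- small_fit4()
  u <- 2L
  v <- sf4$fit$structure$roi_network[u]
  net_cv <- posterior_curves(sf4$fit, "network", id = v)
  nodev <- sf4$fit
  zr_cols <- grep("^zr", dimnames(nodev$draws)[[3]])
  nodev$draws[, , zr_cols] <- 0
  roi_cv <- posterior_curves(nodev, "roi", id = u)
  expect_equal(roi_cv$mean, net_cv$mean, tolerance = 1e-12)
  expect_equal(roi_cv$lo89, net_cv$lo89, tolerance = 1e-12)
})

test_that("structure limitations raise informative errors", {
  sf <- small_fit1()
  expect_error(posterior_curves(sf$fit, "roi", id = 1),
               "cannot produce roi-level")
  sf4 <- small_fit4()
  expect_error(posterior_curves(sf4$fit, "global"), "network target")
  expect_error(coefficient_draws(sf4$fit, "roi", id = 99),
               "out of range")
  # model 3 supports networks but not ROIs
  st3 <- structure_from_obs(3, sf4$obs)
  fit3 <- fake_fit(st3, matrix(0, 8, parameter_dim(st3)), sf4$obs)
  expect_error(posterior_curves(fit3, "roi", id = 1),
               "models 2 and 4")
  expect_silent(posterior_curves(fit3, "network", id = 1))
})

test_that("curve reports group by network and order by Braak stage", {
  atlas <- build_atlas("tau_suvr")
  st2 <- model_structure(2, n_roi = 76)
  mk_curve <- function(u) {
    fit <- fake_fit(st2, matrix(0, 8, parameter_dim(st2)),
                    structure(data.frame(x = 0), scale = 1,
                              modality = "tau_suvr"))
    fit$modality <- "tau_suvr"
    posterior_curves(fit, "roi", id = u,
                     grid_raw = c(-0.42, 0, 0.71))
  }
  ent <- atlas_lookup(atlas, "Entorhinal", "right")$roi_index
  it <- atlas_lookup(atlas, "Inferior Temporal", "right")$roi_index
  lorb <- atlas_lookup(atlas, "Lateral Orbitofrontal", "right")$roi_index
  rep_lim <- curve_report(list(mk_curve(it), mk_curve(lorb),
                               mk_curve(ent)), atlas)
  lim <- rep_lim$groups[["Limbic"]]
  ids <- vapply(lim, function(cv) cv$target_id[1], integer(1))
  # stage 1 (entorhinal) before stage 4 (inferior temporal) before 5
  expect_equal(ids, c(ent, it, lorb))
  expect_equal(rep_lim$reference$h, 1 / 3)
  expect_equal(rep_lim$reference$v, 0)
  # singleton group; networks without curves come back empty
  rep_one <- curve_report(list(mk_curve(ent)), atlas)
  expect_length(rep_one$groups[["Limbic"]], 1)
  expect_length(rep_one$groups[["Visual"]], 0)
  # the cortical-thickness atlas has no Subcortical cluster at all
  expect_false("Subcortical" %in%
                 attr(build_atlas("cortical_thickness"), "networks"))
})

test_that("mixed-modality curve sets are rejected", {
  atlas <- build_atlas("tau_suvr")
  st2 <- model_structure(2, n_roi = 76)
  mk <- function(modality) {
    fit <- fake_fit(st2, matrix(0, 8, parameter_dim(st2)),
                    structure(data.frame(x = 0), scale = 1,
                              modality = modality))
    fit$modality <- modality
    posterior_curves(fit, "roi", id = 2, grid_raw = c(0, 0.1))
  }
  expect_error(curve_report(list(mk("tau_suvr"),
                                 mk("cortical_thickness")), atlas),
               "mix")
})
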