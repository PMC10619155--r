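test_that("annualized and relative rates follow the definitions", {
  cases <- list(
    # baseline, followup, days, annualized, relative (SUVR sign)
    c(2.0, 2.2, 365.25, 0.2, 0.1),
    c(1.5, 1.5, 400.00, 0.0, 0.0),
    c(2.0, 2.2, 730.50, 0.1, 0.05),
    c(4.0, 4.0, 365.25, 0.0, 0.0),
    c(1.0, 0.9, 365.25, -0.1, -0.1))
  for (cs in cases) {
    expect_equal(annualized_rate(cs[1], cs[2], cs[3]), cs[4])
    expect_equal(relative_rate_suvr(cs[1], cs[2], cs[3]), cs[5])
  }
  # thinning is positive, growth negative under the thickness convention
  expect_equal(relative_rate_thickness(2.5, 2.45, 365.25), 0.02)
  expect_equal(relative_rate_thickness(2.5, 2.55, 365.25), -0.02)
  expect_equal(relative_rate_thickness(2.5, 2.5, 365.25), 0)
  expect_error(annualized_rate(2, 2.2, 0), "positive")
  expect_error(annualized_rate(2, 2.2, -10), "positive")
  expect_error(relative_rate_suvr(0, 2.2, 365.25), "baseline")
  expect_error(relative_rate_suvr(-1, 2.2, 365.25), "baseline")
})

test_that("SUVR and thickness rates are sign-mirrored", {
  set.seed(1)
  b <- runif(50, 0.5, 4)
  f <- b * runif(50, 0.7, 1.3)
  d <- runif(50, 200, 900)
  expect_equal(relative_rate_suvr(b, f, d),
               -relative_rate_thickness(b, f, d))
})

test_that("normalization scales by the max absolute value", {
  n1 <- normalize_rates(c(0.71, -0.42, 0))
  expect_equal(n1$x, c(1, -0.42 / 0.71, 0))
  expect_equal(n1$scale, 0.71)
  n2 <- normalize_rates(c(-0.26, 0.23))
  expect_equal(n2$x, c(-1, 0.23 / 0.26))
  expect_equal(n2$scale, 0.26)
  expect_equal(normalize_rates(0.5), list(x = 1, scale = 0.5))
  expect_error(normalize_rates(c(0, 0)), "all-zero")
  expect_error(normalize_rates(numeric(0)))
  # round trip recovers inputs
  set.seed(2)
  for (rep in 1:20) {
    r <- rnorm(sample(2:40, 1), sd = runif(1, 1e-3, 10))
    nm <- normalize_rates(r)
    expect_true(all(abs(nm$x) <= 1))
    expect_lt(max(abs(nm$x * nm$scale - r)), 1e-12)
  }
})

test_that("assemble_observations joins, normalizes and filters", {
  atlas <- make_synthetic_atlas(3, 3)
  m <- expand.grid(subject_id = c("a", "b"), roi_index = 1:3,
                   stringsAsFactors = FALSE)
  m$diagnosis <- ifelse(m$subject_id == "a", "CN", "AD")
  m$baseline <- 2
  m$followup <- 2 + 0.1 * m$roi_index
  m$interval_days <- 365.25
  obs <- assemble_observations(m, atlas)
  expect_s3_class(obs, "np_obs")
  expect_equal(nrow(obs), 6)
  expect_equal(max(abs(obs$x)), 1)
  expect_equal(attr(obs, "scale"), max(abs(obs$x_raw)))
  expect_equal(obs$network_id,
               attr(atlas, "roi_network")[obs$roi_index])
  # incomplete pair dropped with a warning
  m2 <- m
  m2$followup[3] <- NA
  expect_warning(obs2 <- assemble_observations(m2, atlas),
                 "dropping 1")
  expect_equal(nrow(obs2), 5)
  # hard errors
  m3 <- m; m3$diagnosis[1] <- "HC"
  expect_error(assemble_observations(m3, atlas), "diagnosis")
  m4 <- m; m4$roi_index[1] <- 99
  expect_error(assemble_observations(m4, atlas), "roi_index")
})

test_that("measure CSV round trip resolves ROI labels via the atlas", {
  atlas <- build_atlas("tau_suvr")
  m <- data.frame(subject_id = "s1", diagnosis = "CN",
                  roi_label = c("Entorhinal", "Hippocampus"),
                  hemisphere = c("right", "left"),
                  modality = "tau_suvr",
                  baseline = c(1.2, 1.1), followup = c(1.25, 1.12),
                  interval_days = 400)
  tmp <- tempfile(fileext = ".csv")
  write_measures(m, tmp)
  back <- read_measures(tmp, atlas)
  expect_equal(back$roi_index,
               c(atlas_lookup(atlas, "Entorhinal", "right")$roi_index,
                 atlas_lookup(atlas, "Hippocampus", "left")$roi_index))
})
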