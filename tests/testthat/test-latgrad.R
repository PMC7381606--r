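test_that("species mean latitude respects the truncation rule", {
  cells <- tibble::tibble(
    species = "sp1", lat = c(5, -5, -15), lon = c(20, 21, 22)
  )
  out <- species_latitudes(cells, truncate_north_of = 0)
  expect_equal(out$mean_latitude, -10)
  expect_equal(out$n_cells, 2L)

  single <- species_latitudes(
    tibble::tibble(species = "sp2", lat = -10, lon = 25), 0)
  expect_equal(single$mean_latitude, -10)

  # all cells truncated away: the species has no latitude
  gone <- species_latitudes(
    tibble::tibble(species = "sp3", lat = c(5, 10), lon = c(20, 21)), 0)
  expect_equal(nrow(gone), 0)
})

test_that("truncated means equal a brute-force recomputation", {
  withr::with_seed(21, {
    cells <- tibble::tibble(
      species = sample(sprintf("sp%02d", 1:20), 1000, replace = TRUE),
      lat = runif(1000, -35, 20),
      lon = runif(1000, 10, 40)
    )
  })
  out <- species_latitudes(cells, truncate_north_of = 15)
  for (i in seq_len(nrow(out))) {
    keep <- cells$lat[cells$species == out$species[i] & cells$lat <= 15]
    expect_equal(out$mean_latitude[i], mean(keep))
    expect_true(out$mean_latitude[i] >= min(keep) &&
                  out$mean_latitude[i] <= max(keep))
  }
})

test_that("pair latitude uses the two-species mean with single-species fallback", {
  pairs <- tibble::tibble(
    species_a = c("p1a", "p2a", "p3a"),
    species_b = c("p1b", "p2b", "p3b"),
    biome = "savanna", age_ma = c(5, 10, 15)
  )
  lats <- tibble::tibble(
    species = c("p1a", "p1b", "p2a"),
    mean_latitude = c(-8, -12, -20),
    n_cells = 1
  )
  out <- attach_pair_latitudes(pairs, lats)
  expect_equal(out$mean_latitude, c(-10, -20, NA))
  expect_equal(out$latitude_source,
               c("both_species", "single_species", "missing"))

  # pairs without latitude reduce the regression n by exactly their count
  sc <- synthetic_scenario(seed = 2)
  sim <- simulate_gradient_pairs(50, sc)
  p <- sim$pairs
  p$mean_latitude[1:7] <- NA
  f <- fit_age_gradient(p, tau = 0.9, n_resamples = 0)
  expect_equal(f$n, 43)
  expect_equal(f$n_dropped, 7)
})

test_that("precomputed means bypass truncation with a warning", {
  pairs <- tibble::tibble(species_a = "a", species_b = "b",
                          biome = "savanna", age_ma = 5)
  sp <- tibble::tibble(species = c("a", "b"), mean_latitude = c(-4, -6))
  expect_warning(out <- attach_pair_latitudes(pairs, sp), "truncation")
  expect_equal(out$mean_latitude, -5)
})

test_that("biome-age prediction evaluates the line and flags extrapolation", {
  f <- structure(
    list(coefficients = c(intercept = 1, slope = 2), tau = 0.9,
         loss = 0, n = 10, x = 0:5, y = 1 + 2 * (0:5),
         convention = "signed", mcmb = NULL),
    class = "quantile_fit"
  )
  pred <- predict_biome_age(f, 3)
  expect_equal(pred$age_ma, 7)
  expect_false(pred$extrapolated)
  expect_warning(out <- predict_biome_age(f, 10), "extrapolation")
  expect_true(out$extrapolated)
})

test_that("prediction at a constructed ceiling is covered by the bootstrap interval", {
  # by construction the tau-quantile of age at latitude L is tau*(b0 + b1*L)
  sc <- synthetic_scenario(seed = 5, beta0 = 16, beta1 = 0.4)
  sim <- simulate_gradient_pairs(1500, sc)
  f <- fit_age_gradient(sim$pairs, tau = 0.9, n_resamples = 299, seed = 9)
  pred <- predict_biome_age(f, -15)
  target <- 0.9 * (16 + 0.4 * (-15))
  expect_true(pred$lower <= target && target <= pred$upper)
})

test_that("HPD envelope fits are ordered and shift-equivariant", {
  sc <- synthetic_scenario(seed = 6)
  sim <- simulate_gradient_pairs(300, sc)
  p <- sim$pairs
  # degenerate HPDs equal to the point age: three identical fits
  p0 <- p
  p0$hpd_lower <- p0$age_ma
  p0$hpd_upper <- p0$age_ma
  env0 <- fit_hpd_envelope(p0, tau = 0.9)
  expect_equal(coef(env0$age_mean), coef(env0$age_hpd_upper))
  expect_equal(coef(env0$age_mean), coef(env0$age_hpd_lower))

  # additive HPDs age +/- 1: intercepts differ by 2 at shared slope
  p1 <- p
  p1$hpd_lower <- p1$age_ma - 1
  p1$hpd_upper <- p1$age_ma + 1
  env1 <- fit_hpd_envelope(p1, tau = 0.9)
  expect_equal(coef(env1$age_hpd_upper)[["slope"]],
               coef(env1$age_hpd_lower)[["slope"]], tolerance = 1e-9)
  expect_equal(coef(env1$age_hpd_upper)[["intercept"]] -
                 coef(env1$age_hpd_lower)[["intercept"]], 2, tolerance = 1e-9)

  # pointwise-ordered HPDs give ordered predictions at observed latitudes
  env <- fit_hpd_envelope(p, tau = 0.9)
  lat <- p$mean_latitude
  up <- coef(env$age_hpd_upper)[1] + coef(env$age_hpd_upper)[2] * lat
  mid <- coef(env$age_mean)[1] + coef(env$age_mean)[2] * lat
  lo <- coef(env$age_hpd_lower)[1] + coef(env$age_hpd_lower)[2] * lat
  expect_true(all(up >= mid - 1e-9))
  expect_true(all(mid >= lo - 1e-9))

  expect_error(fit_hpd_envelope(dplyr::select(p, -hpd_lower, -hpd_upper)),
               "no HPD")
})

test_that("slope reporting records the latitude convention", {
  sc <- synthetic_scenario(seed = 10)
  sim <- simulate_gradient_pairs(200, sc)
  f <- fit_age_gradient(sim$pairs, tau = 0.9, n_resamples = 0)
  signed <- report_slope(f, "signed")
  south <- report_slope(f, "degrees_south")
  expect_equal(signed$slope, -south$slope)
  expect_equal(signed$convention, "signed")
})

test_that("cos-latitude weighting and the oldest-subset mode behave", {
  cells <- tibble::tibble(species = "s", lat = c(-60, 0), lon = c(20, 20))
  unw <- species_latitudes(cells, 0)
  ww <- species_latitudes(cells, 0, weight = "cos")
  expect_equal(unw$mean_latitude, -30)
  # cos weighting pulls the mean toward the equatorial cell
  expect_equal(ww$mean_latitude, -60 * 0.5 / (0.5 + 1))

  sc <- synthetic_scenario(seed = 44, beta0 = 16, beta1 = 0.4)
  sim <- simulate_gradient_pairs(1000, sc)
  f <- fit_age_gradient(sim$pairs, tau = 0.9, method = "oldest_subset")
  expect_equal(f$n, sum(sim$pairs$age_ma >=
                          quantile(sim$pairs$age_ma, 0.9, names = FALSE)))
  expect_true(is.finite(f$ols$t))
  # under the ceiling model the oldest decile also trends with latitude
  expect_gt(coef(f)[["slope"]], 0)
})
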