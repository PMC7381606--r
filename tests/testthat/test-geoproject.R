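test_that("single- and two-pair toy grids are exact", {
  pairs <- tibble::tibble(
    species_a = c("a1", "b1"), species_b = c("a2", "b2"),
    biome = "savanna", age_ma = c(4, 8)
  )
  cells <- tibble::tibble(
    species = c("a1", "a2", "b1"),
    lat = c(-10.05, -10.05, -10.05),
    lon = c(20.05, 20.05, 20.05)
  )
  g <- project_ages(pairs, cells, resolution = 0.1)
  expect_equal(nrow(g), 1)
  # both pairs overlap the shared cell: mean (4+8)/2, each pair once
  expect_equal(g$mean_age, 6)
  expect_equal(g$n_pairs, 2L)
  expect_equal(g$richness, 3L)
  # cell centers at (k + 0.5) * resolution offsets
  expect_equal((g$cell_lat / 0.1) %% 1, 0.5)
  expect_equal((g$cell_lon / 0.1) %% 1, 0.5)
})

test_that("grid values equal per-cell brute-force recomputation", {
  sc <- synthetic_scenario(seed = 14, cells_per_species = 8)
  sim <- simulate_gradient_pairs(40, sc)
  res <- 0.5
  g <- project_ages(sim$pairs, sim$cells, resolution = res)
  oracle <- brute_force_grid(sim$pairs, sim$cells, res)
  key <- paste(round(g$cell_lon / res - 0.5), round(g$cell_lat / res - 0.5))
  m <- match(key, oracle$key)
  expect_false(anyNA(m))
  expect_equal(g$mean_age, oracle$mean_age[m])
  expect_equal(as.numeric(g$n_pairs), oracle$n_pairs[m])
  expect_true(all(g$richness >= 1))
})

test_that("the pair-cell bookkeeping identity holds exactly", {
  sc <- synthetic_scenario(seed = 15, cells_per_species = 10)
  sim <- simulate_gradient_pairs(60, sc)
  res <- 0.25
  g <- project_ages(sim$pairs, sim$cells, resolution = res)
  lhs <- sum(g$mean_age * g$n_pairs)
  # rhs: each pair's age times the number of cells its footprint covers
  cellkey <- function(lat, lon) paste(floor(lon / res), floor(lat / res))
  sp_cells <- split(cellkey(sim$cells$lat, sim$cells$lon), sim$cells$species)
  rhs <- sum(vapply(seq_len(nrow(sim$pairs)), function(i) {
    n_cells <- length(unique(c(sp_cells[[sim$pairs$species_a[i]]],
                               sp_cells[[sim$pairs$species_b[i]]])))
    sim$pairs$age_ma[i] * n_cells
  }, numeric(1)))
  expect_equal(lhs, rhs)
})

test_that("halving the resolution keeps the same contributing pairs", {
  sc <- synthetic_scenario(seed = 16, cells_per_species = 5)
  sim <- simulate_gradient_pairs(30, sc)
  g1 <- project_ages(sim$pairs, sim$cells, resolution = 0.5)
  g2 <- project_ages(sim$pairs, sim$cells, resolution = 0.25)
  expect_equal(sum(g1$mean_age * g1$n_pairs) / sum(g1$n_pairs) * sum(g1$n_pairs),
               sum(g1$mean_age * g1$n_pairs))
  expect_equal(nrow(attr(g1, "skipped_pairs")), 0)
  expect_equal(nrow(attr(g2, "skipped_pairs")), 0)
  # total pair-age mass per pair is resolution-independent once divided by
  # each pair's footprint size, so compare the sets of contributing pairs
  expect_equal(sum(g1$n_pairs > 0), nrow(g1))
  expect_gt(nrow(g2), 0)
})

test_that("predicted layer is the linear form at cell centers", {
  sc <- synthetic_scenario(seed = 18)
  sim <- simulate_gradient_pairs(50, sc)
  f <- fit_age_gradient(sim$pairs, tau = 0.9, n_resamples = 0)
  g <- project_ages(sim$pairs, sim$cells, resolution = 0.5)
  g <- predict_age_map(g, f)
  expect_equal(g$predicted_age,
               unname(f$coefficients["intercept"] +
                        f$coefficients["slope"] * g$cell_lat))

  # slope-zero fit gives a uniform layer
  f0 <- f
  f0$coefficients <- c(intercept = 12, slope = 0)
  g0 <- predict_age_map(g, f0)
  expect_true(all(g0$predicted_age == 12))

  # two cells 10 degrees apart under slope 0.28 differ by 2.8
  idx <- c(which.min(g$cell_lat), which.max(g$cell_lat))
  f28 <- f
  f28$coefficients <- c(intercept = 14, slope = 0.28)
  g28 <- predict_age_map(g, f28)
  dlat <- g$cell_lat[idx[2]] - g$cell_lat[idx[1]]
  expect_equal(g28$predicted_age[idx[2]] - g28$predicted_age[idx[1]],
               0.28 * dlat)

  # convention mismatch is a hard error
  fbad <- f
  fbad$convention <- "degrees_south"
  expect_error(predict_age_map(g, fbad), "convention mismatch")
})

test_that("ESRI ASCII serialization writes a consistent header and cells", {
  pairs <- tibble::tibble(species_a = "a1", species_b = "a2",
                          biome = "savanna", age_ma = 4)
  cells <- tibble::tibble(species = c("a1", "a2"),
                          lat = c(-10.05, -10.15), lon = c(20.05, 20.05))
  g <- project_ages(pairs, cells, resolution = 0.1)
  path <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(g, "mean_age", path)
  lines <- readLines(path)
  expect_match(lines[1], "^ncols 1$")
  expect_match(lines[2], "^nrows 2$")
  expect_match(lines[5], "^cellsize 0.1$")
  vals <- as.numeric(unlist(strsplit(trimws(lines[7:8]), " +")))
  expect_equal(vals, c(4, 4))

  expect_error(project_ages(pairs, cells, resolution = -1), "positive")
  expect_warning(
    g0 <- project_ages(pairs, cells[0, ], resolution = 0.1), "empty grid")
  expect_equal(nrow(g0), 0)
})
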