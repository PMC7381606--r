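#' Define a synthetic scenario with known ground truth
#'
#' Bundles every knob of the generator: a dated birth-death tree,
#' phylogenetically conserved binary biome labels at a target prevalence,
#' and pair latitudes/ages drawn from a uniform-ceiling model in which the
#' age of a pair at latitude `x` is Uniform(0, beta0 + beta1 * x), so the
#' conditional \eqn{\tau}-quantile of age is exactly
#' \eqn{\tau (\beta_0 + \beta_1 x)} — linear in latitude with slope
#' \eqn{\tau \beta_1}, a closed-form recovery target for the gradient fit.
#' Latitudes are in the signed convention (south negative).
#'
#' @param seed Master seed; per-stage seeds derive from it via
#'   [split_seed()].
#' @param n_tips Number of tips of the simulated tree.
#' @param birth,death Speciation/extinction rates per lineage per Ma.
#' @param prevalence Fraction of tips labelled with the focal biome.
#' @param noise_scale White-noise scale (relative to the Brownian tip
#'   standard deviation) added before thresholding the labels; 0 gives pure
#'   threshold-Brownian labels (maximal conservatism, D near 0), large
#'   values approach random labels (D near 1).
#' @param beta0 Ceiling age at the reference latitude 0 (equator), Ma.
#' @param beta1 Ceiling slope, Ma per degree of signed latitude.
#' @param lat_span Latitude span (signed degrees), default 30 S to the
#'   equator.
#' @param hpd_halfwidth Relative HPD half-width: bounds are
#'   `age * (1 -/+ hpd_halfwidth)`.
#' @param truncate_north_of Truncation latitude used downstream.
#' @param cells_per_species Presence cells scattered per species.
#' @param cell_scatter Latitudinal s.d. of the scatter, degrees.
#' @return List of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1, n_tips = 200, birth = 0.25,
                               death = 0, prevalence = 0.3,
                               noise_scale = 0, beta0 = 16, beta1 = 0.4,
                               lat_span = c(-30, 0), hpd_halfwidth = 0.25,
                               truncate_north_of = 0,
                               cells_per_species = 20, cell_scatter = 1.5) {
  stopifnot(n_tips >= 4, birth > 0, death >= 0,
            prevalence > 0, prevalence < 1,
            length(lat_span) == 2, diff(range(lat_span)) > 0,
            hpd_halfwidth >= 0, hpd_halfwidth < 1)
  ceiling_ends <- beta0 + beta1 * lat_span
  if (any(ceiling_ends <= 0)) {
    stop("invalid scenario: ceiling age beta0 + beta1 * x must stay ",
         "positive over the latitude span", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_tips = as.integer(n_tips),
         birth = birth, death = death, prevalence = prevalence,
         noise_scale = noise_scale, beta0 = beta0, beta1 = beta1,
         lat_span = sort(lat_span), hpd_halfwidth = hpd_halfwidth,
         truncate_north_of = truncate_north_of,
         cells_per_species = as.integer(cells_per_species),
         cell_scatter = cell_scatter),
    class = "synthetic_scenario"
  )
}

#' Simulate a dated ultrametric birth-death tree
#'
#' Simulates a tree conditioned on the scenario's tip count under the
#' scenario's birth and death rates (via [ape::rphylo]), with branch
#' lengths in Ma, and wraps it as a `dated_tree`. Under high extinction the
#' simulation is retried up to `retries` times before failing.
#'
#' @param scenario A [synthetic_scenario()].
#' @param retries Retry cap for failed simulations.
#' @return A `dated_tree`.
#' @export
simulate_tree <- function(scenario, retries = 10) {
  seeds <- split_seed(scenario$seed, 4)
  phy <- NULL
  withr::with_seed(seeds[1], {
    for (i in seq_len(retries)) {
      phy <- tryCatch(
        ape::rphylo(scenario$n_tips, birth = scenario$birth,
                    death = scenario$death),
        error = function(e) NULL
      )
      if (!is.null(phy)) break
    }
  })
  if (is.null(phy)) {
    stop("birth-death simulation failed after ", retries, " retries ",
         "(death rate too high?)", call. = FALSE)
  }
  phy$tip.label <- sprintf("sp%04d", seq_len(scenario$n_tips))
  as_dated_tree(phy)
}

#' Simulate phylogenetically conserved binary biome labels
#'
#' Evolves a continuous character by Brownian motion along the tree, adds
#' white noise scaled to `noise_scale` times the Brownian tip s.d., and
#' thresholds at the prevalence quantile so exactly
#' `round(prevalence * n_tips)` tips carry the focal biome. `noise_scale = 0`
#' yields pure threshold-Brownian labels (D-statistic near 0);
#' large `noise_scale` approaches shuffled labels (D near 1).
#'
#' @param tree Tree from [simulate_tree()].
#' @param scenario The scenario.
#' @param biome Label for trait-1 tips; others get `other_biome`.
#' @param other_biome Label for trait-0 tips.
#' @return Species table tibble: `species`, `biome`, `mean_latitude` (NA).
#' @export
simulate_biome_labels <- function(tree, scenario, biome = "savanna",
                                  other_biome = "forest") {
  seeds <- split_seed(scenario$seed, 4)
  n <- ape::Ntip(tree)
  k <- max(1L, min(n - 1L, round(scenario$prevalence * n)))
  z <- withr::with_seed(seeds[2], {
    bm <- as.vector(simulate_bm_tips(tree, 1))
    bm + scenario$noise_scale * stats::sd(bm) * stats::rnorm(n)
  })
  lab <- rep(other_biome, n)
  lab[order(z, decreasing = TRUE)[seq_len(k)]] <- biome
  tibble(species = tree$tip.label, biome = lab, mean_latitude = NA_real_)
}

#' Assign latitudes, ceiling-model ages, HPDs and ranges to sister pairs
#'
#' Gives each pair a latitude uniform on the scenario span and resamples
#' its age from the uniform-ceiling model Uniform(0, beta0 + beta1 * x), so
#' the \eqn{\tau}-quantile of age given latitude is exactly
#' \eqn{\tau(\beta_0 + \beta_1 x)} — the construction oracle for the
#' gradient fit. HPD bounds are set to `age * (1 -/+ hpd_halfwidth)`, and
#' each species receives presence cells scattered around the pair latitude
#' (clipped to the span so northern truncation does not bias the mean).
#'
#' @param pairs A pair table (e.g. from [find_biome_sister_pairs()], or
#'   [simulate_gradient_pairs()] for a table built from scratch).
#' @param scenario The scenario.
#' @return List with `pairs` (ages/HPDs/latitudes overwritten,
#'   `latitude_source = "both_species"`), `cells` (presence cells), and
#'   `truth` (the generating parameters, for self-describing tests).
#' @export
simulate_pair_latitudes <- function(pairs, scenario) {
  seeds <- split_seed(scenario$seed, 4)
  pairs <- as_tibble(pairs)
  n <- nrow(pairs)
  span <- scenario$lat_span
  withr::with_seed(seeds[3], {
    x <- stats::runif(n, span[1], span[2])
    ceiling_age <- scenario$beta0 + scenario$beta1 * x
    age <- stats::runif(n) * ceiling_age
    pairs$mean_latitude <- x
    pairs$latitude_source <- "both_species"
    pairs$age_ma <- age
    pairs$hpd_lower <- age * (1 - scenario$hpd_halfwidth)
    pairs$hpd_upper <- age * (1 + scenario$hpd_halfwidth)
    sp <- c(pairs$species_a, pairs$species_b)  # pair latitude applies to both
    m <- scenario$cells_per_species
    lat <- pmin(pmax(rep(rep(x, 2), each = m) +
                       stats::rnorm(2 * n * m, 0, scenario$cell_scatter),
                     span[1]), span[2])
    cells <- tibble(
      species = rep(sp, each = m),
      lat = lat,
      lon = stats::runif(2 * n * m, 10, 40)
    )
  })
  truth <- scenario[c("beta0", "beta1", "lat_span", "hpd_halfwidth", "seed")]
  list(pairs = pairs, cells = cells, truth = truth)
}

#' Build a synthetic sister-pair table directly from the ceiling model
#'
#' Convenience generator for regression-recovery experiments that do not
#' need a tree: synthesizes `n_pairs` pairs with invented species names and
#' runs [simulate_pair_latitudes()] on them.
#'
#' @param n_pairs Number of pairs.
#' @param scenario The scenario.
#' @param biome Biome label carried by the pairs.
#' @return As [simulate_pair_latitudes()].
#' @export
simulate_gradient_pairs <- function(n_pairs, scenario, biome = "savanna") {
  pairs <- tibble(
    species_a = sprintf("pair%04da", seq_len(n_pairs)),
    species_b = sprintf("pair%04db", seq_len(n_pairs)),
    biome = biome,
    node = NA_integer_,
    age_ma = NA_real_,
    hpd_lower = NA_real_,
    hpd_upper = NA_real_
  )
  simulate_pair_latitudes(pairs, scenario)
}

#' Simulate a complete dataset (tree, labels, pair table, ranges)
#'
#' Runs the full generator: tree, biome labels, sister-pair extraction for
#' the focal biome, then latitudes/ages/ranges from the ceiling model.
#' Optionally writes `tree.nwk`, `species.csv`, `cells.csv` and
#' `truth.json` to a directory.
#'
#' @param scenario A [synthetic_scenario()].
#' @param dir Optional output directory.
#' @param biome Focal biome label.
#' @return List `tree`, `species`, `pairs`, `cells`, `truth` (and `dir` if
#'   written).
#' @export
simulate_dataset <- function(scenario, dir = NULL, biome = "savanna") {
  tree <- simulate_tree(scenario)
  species <- simulate_biome_labels(tree, scenario, biome = biome)
  pairs <- find_biome_sister_pairs(tree, species, biome)
  sim <- simulate_pair_latitudes(pairs, scenario)
  out <- list(tree = tree, species = species, pairs = sim$pairs,
              cells = sim$cells, truth = sim$truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_dated_tree(tree, file.path(dir, "tree.nwk"))
    readr::write_csv(species, file.path(dir, "species.csv"), progress = FALSE)
    readr::write_csv(sim$cells, file.path(dir, "cells.csv"), progress = FALSE)
    jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    out$dir <- dir
  }
  out
}
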