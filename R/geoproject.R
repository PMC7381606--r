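#' Project sister-pair ages onto a regular latitude-longitude grid
#'
#' Overlays species ranges on an axis-aligned grid (default 0.1 degree) and
#' computes, per cell, the mean divergence age of the sister pairs whose
#' ranges overlap it. A pair's footprint is the union of its two species'
#' presence cells, counted once per cell even where the species co-occur
#' (so no pair is double-weighted); richness counts distinct species (not
#' pairs) overlapping the cell. Cells are half-open intervals
#' `[k*r, (k+1)*r)` anchored at (0, 0), with centers at `(k + 0.5)*r`.
#'
#' @param pairs Pair table with `species_a`, `species_b`, `age_ma`.
#' @param cells Presence cells: `species`, `lat`, `lon` (signed degrees).
#' @param resolution Grid resolution in degrees (> 0), default 0.1.
#' @param min_richness Cells with fewer distinct species are flagged
#'   `low_diversity` (the hatch mask); default 1.
#' @return Tibble of class `age_grid`: `cell_lat`, `cell_lon` (cell
#'   centers), `mean_age` (Ma), `n_pairs`, `richness`, `low_diversity`.
#'   Attributes: `resolution`, `convention` (`"signed"`), and
#'   `skipped_pairs` (pairs with no range data).
#' @export
project_ages <- function(pairs, cells, resolution = 0.1, min_richness = 1) {
  if (!is.numeric(resolution) || resolution <= 0) {
    stop("resolution must be a positive number of degrees", call. = FALSE)
  }
  pairs <- as_tibble(pairs)
  cells <- as_tibble(cells)
  if (nrow(cells) == 0) {
    warning("no presence cells: empty grid", call. = FALSE)
    return(empty_age_grid(resolution))
  }
  sp_cells <- cells |>
    mutate(
      species = normalize_species_names(.data$species),
      ix = floor(.data$lon / resolution),
      iy = floor(.data$lat / resolution)
    ) |>
    distinct(.data$species, .data$ix, .data$iy)

  pr <- pairs |>
    mutate(pair_id = dplyr::row_number(),
           species_a = normalize_species_names(.data$species_a),
           species_b = normalize_species_names(.data$species_b))
  long <- bind_rows(
    select(pr, "pair_id", "age_ma", species = "species_a"),
    select(pr, "pair_id", "age_ma", species = "species_b")
  )
  foot <- long |>
    inner_join(sp_cells, by = "species",
               relationship = "many-to-many") |>
    distinct(.data$pair_id, .data$age_ma, .data$ix, .data$iy)

  skipped <- pr |>
    filter(!(.data$pair_id %in% foot$pair_id)) |>
    select("species_a", "species_b", "age_ma")
  if (nrow(foot) == 0) {
    warning("no pair has range data: empty grid", call. = FALSE)
    out <- empty_age_grid(resolution)
    attr(out, "skipped_pairs") <- skipped
    return(out)
  }

  by_cell <- foot |>
    group_by(.data$ix, .data$iy) |>
    summarise(mean_age = mean(.data$age_ma), n_pairs = n(), .groups = "drop")

  pair_species <- unique(long$species)
  richness <- sp_cells |>
    filter(.data$species %in% pair_species) |>
    group_by(.data$ix, .data$iy) |>
    summarise(richness = n(), .groups = "drop")

  out <- by_cell |>
    left_join(richness, by = c("ix", "iy")) |>
    mutate(
      cell_lat = (.data$iy + 0.5) * resolution,
      cell_lon = (.data$ix + 0.5) * resolution,
      low_diversity = .data$richness < min_richness
    ) |>
    select("cell_lat", "cell_lon", "mean_age", "n_pairs", "richness",
           "low_diversity") |>
    arrange(.data$cell_lat, .data$cell_lon)
  structure(out, class = c("age_grid", class(out)),
            resolution = resolution, convention = "signed",
            skipped_pairs = skipped)
}

empty_age_grid <- function(resolution) {
  structure(
    tibble(cell_lat = numeric(0), cell_lon = numeric(0),
           mean_age = numeric(0), n_pairs = integer(0),
           richness = integer(0), low_diversity = logical(0)),
    class = c("age_grid", class(tibble())),
    resolution = resolution, convention = "signed",
    skipped_pairs = tibble(species_a = character(0),
                           species_b = character(0), age_ma = numeric(0))
  )
}

#' Add regression-predicted ages to an age grid
#'
#' Evaluates a fitted quantile line at each supported cell's center
#' latitude, giving the map of biome establishment age implied by the
#' latitudinal gradient. Cells without contributing species are not in the
#' grid, so the predicted layer automatically carries the same support
#' mask. The fit's latitude convention must match the grid's.
#'
#' @param grid An `age_grid` from [project_ages()].
#' @param fit A `quantile_fit` (see [fit_age_gradient()]).
#' @return The grid with a `predicted_age` column.
#' @export
predict_age_map <- function(grid, fit) {
  stopifnot(inherits(grid, "age_grid"), inherits(fit, "quantile_fit"))
  if (!identical(attr(grid, "convention"), fit$convention)) {
    stop("latitude convention mismatch: grid is '",
         attr(grid, "convention"), "', fit is '", fit$convention, "'",
         call. = FALSE)
  }
  grid$predicted_age <- unname(fit$coefficients["intercept"] +
                                 fit$coefficients["slope"] * grid$cell_lat)
  grid
}

#' Write one layer of an age grid as an ESRI ASCII raster
#'
#' Serializes a grid column (`mean_age`, `richness`, `predicted_age`, ...)
#' to the plain-text ESRI ASCII grid format, so results can be inspected in
#' any GIS without binary dependencies. Cells absent from the grid get the
#' nodata value.
#'
#' @param grid An `age_grid`.
#' @param layer Column name to rasterize.
#' @param path Output `.asc` path.
#' @param nodata Nodata sentinel value.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, layer, path, nodata = -9999) {
  stopifnot(inherits(grid, "age_grid"), layer %in% names(grid))
  res <- attr(grid, "resolution")
  if (nrow(grid) == 0) stop("empty grid", call. = FALSE)
  ix <- round(grid$cell_lon / res - 0.5)
  iy <- round(grid$cell_lat / res - 0.5)
  x0 <- min(ix); y0 <- min(iy)
  ncols <- max(ix) - x0 + 1L
  nrows <- max(iy) - y0 + 1L
  m <- matrix(nodata, nrows, ncols)
  # row 1 = northernmost row in the ESRI convention
  m[cbind(nrows - (iy - y0), ix - x0 + 1L)] <- grid[[layer]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncols),
    sprintf("nrows %d", nrows),
    sprintf("xllcorner %.10g", x0 * res),
    sprintf("yllcorner %.10g", y0 * res),
    sprintf("cellsize %.10g", res),
    sprintf("NODATA_value %g", nodata)
  ), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an age grid as a long-format CSV
#'
#' @param grid An `age_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_age_grid_csv <- function(grid, path) {
  readr::write_csv(as_tibble(grid), path, progress = FALSE)
  invisible(path)
}
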