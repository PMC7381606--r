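#' Read a species table (name, biome, optional latitudinal summary)
#'
#' The table must have a header with at least `species` and `biome` columns;
#' an optional `mean_latitude` column (signed decimal degrees, south
#' negative) lets species without range maps enter the latitude analysis.
#' Names are normalized exactly as tree tip labels are
#' ([normalize_species_names()]); biome labels are lower-cased and trimmed
#' and must come from the closed vocabulary
#' `savanna, forest, fynbos, other, unknown` (empty/`NA` becomes `unknown`,
#' which excludes the species from biome-conditioned analyses).
#'
#' @param path CSV (or TSV, by extension) file path.
#' @return Tibble with columns `species`, `biome`, and `mean_latitude`
#'   (`NA` when absent).
#' @export
read_species_table <- function(path) {
  reader <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  validate_species_table(raw, context = path)
}

#' Validate and normalize an in-memory species table
#'
#' @param df Data frame with `species` and `biome` columns.
#' @param context Label used in error messages.
#' @return Normalized tibble (see [read_species_table()]).
#' @export
validate_species_table <- function(df, context = "species table") {
  df <- as_tibble(df)
  need <- c("species", "biome")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(context, " lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- df |>
    mutate(
      species = normalize_species_names(.data$species),
      biome = normalize_biome(.data$biome)
    )
  bad <- which(!out$biome %in% biome_levels())
  if (length(bad) > 0) {
    stop(context, ": biome value(s) outside the vocabulary in row(s) ",
         paste(utils::head(bad, 10), collapse = ", "), ": ",
         paste(unique(out$biome[bad]), collapse = ", "), call. = FALSE)
  }
  if (!"mean_latitude" %in% names(out)) out$mean_latitude <- NA_real_
  out$mean_latitude <- as.numeric(out$mean_latitude)
  select(out, "species", "biome", "mean_latitude",
         dplyr::any_of(setdiff(names(out), c("species", "biome", "mean_latitude"))))
}

#' Read per-species presence cells
#'
#' Presence/absence range maps reduced to cell-center coordinates: one row
#' per species x occupied cell, columns `species`, `lat`, `lon` in decimal
#' degrees (south/west negative).
#'
#' @param path CSV file path.
#' @return Tibble with columns `species`, `lat`, `lon`.
#' @export
read_presence_cells <- function(path) {
  cells <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("species", "lat", "lon") %in% names(cells)))
  cells <- cells |>
    mutate(species = normalize_species_names(.data$species))
  if (any(abs(cells$lat) > 90, na.rm = TRUE) ||
      any(abs(cells$lon) > 180, na.rm = TRUE)) {
    stop("presence cells outside [-90, 90] x [-180, 180] in ", path,
         call. = FALSE)
  }
  as_tibble(cells)
}
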