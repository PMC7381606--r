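#' @importFrom rlang %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join distinct n bind_rows rename across
#' @importFrom tibble tibble as_tibble
NULL

# closed biome vocabulary; "unknown" marks species excluded from
# biome-conditioned analyses
biome_levels <- function() c("savanna", "forest", "fynbos", "other", "unknown")

#' Normalize species names
#'
#' Strips surrounding whitespace and collapses internal whitespace runs to a
#' single underscore, so table names match Newick tip labels. Matching is
#' case-sensitive thereafter.
#'
#' @param x Character vector of species names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_species_names(c(" Vachellia  karroo ", "Senegalia_nigrescens"))
normalize_species_names <- function(x) {
  gsub("\\s+", "_", trimws(x))
}

normalize_biome <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out[is.na(out) | out == ""] <- "unknown"
  out
}

check_biome <- function(biome) {
  biome <- normalize_biome(biome)
  bad <- setdiff(unique(biome), biome_levels())
  if (length(bad) > 0) {
    stop("biome label(s) outside the vocabulary {",
         paste(biome_levels(), collapse = ", "), "}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  biome
}

#' Derive reproducible per-stage seeds from one master seed
#'
#' The master seed is expanded into `n` independent 31-bit integer seeds by
#' drawing from a generator seeded with the master seed; each pipeline stage
#' then seeds its own RNG, so stages are independently reproducible.
#'
#' @param seed Master integer seed.
#' @param n Number of stage seeds to derive.
#' @return Integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  withr::with_seed(as.integer(seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

# one structured log line per pipeline stage
stage_log <- function(stage, ..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
  }
  invisible(NULL)
}
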